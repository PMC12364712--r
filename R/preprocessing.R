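# Preprocessing chain for paired H&E / marker ROIs: per-marker normalization
# (clip -> arcsinh -> background threshold -> standardize -> min-max, with all
# statistics from the training split), Otsu thresholding, mutual-information
# template matching between modalities, Macenko stain normalization, and H&E
# colour deconvolution.

#' Otsu threshold
#'
#' Exhaustive maximization of the between-class variance
#' `w0 w1 (mu0 - mu1)^2` over candidate thresholds (all unique values when few,
#' else `n_bins` histogram bins). Classes are `x <= t` vs `x > t`; ties take
#' the smallest threshold.
#'
#' @param x numeric vector, matrix or array of intensities.
#' @param n_bins maximum number of candidate thresholds.
#' @return the threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  u <- sort(unique(v))
  if (length(u) < 2L) stop("constant image: Otsu threshold undefined")
  if (length(u) > n_bins) {
    br <- seq(u[1], u[length(u)], length.out = n_bins + 1L)
    idx <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), n_bins)
    cand <- (br[-1] + br[-length(br)]) / 2
    cnt <- tabulate(idx, n_bins)
    vals <- cand
  } else {
    cand <- u[-length(u)]
    cnt <- tabulate(match(v, u), length(u))
    vals <- u
  }
  n <- sum(cnt)
  csum <- cumsum(cnt)
  cmu <- cumsum(cnt * vals)
  mu_tot <- cmu[length(cmu)] / n
  best <- -Inf; thr <- vals[1]
  for (i in seq_len(length(vals) - 1L)) {
    w0 <- csum[i] / n
    if (w0 <= 0 || w0 >= 1) next
    mu0 <- cmu[i] / csum[i]
    mu1 <- (cmu[length(cmu)] - cmu[i]) / (n - csum[i])
    bc <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (bc > best + 1e-15) { best <- bc; thr <- if (length(u) > n_bins) cand[i] else vals[i] }
  }
  thr
}

#' Fit per-marker normalization statistics on the training split
#'
#' Pipeline order per marker: clip at the pooled 99.9th percentile, arcsinh
#' transform (cofactor 1), Otsu background threshold (computed per sample on
#' channels Gaussian-smoothed with kernel size 3 and sigma 3, pooled over that
#' sample's ROIs), zero sub-threshold background, centre and standardize, then
#' min-max to `[0, 1]` — every statistic from the training data only.
#'
#' @param train_stacks list of marker stacks (H x W x C arrays with channel
#'   dimnames).
#' @param sample_ids optional per-stack sample identifiers; thresholds are
#'   computed per (sample, marker). Default: one pooled pseudo-sample.
#' @param cofactor arcsinh cofactor.
#' @param clip_q clip quantile.
#' @param otsu_on compute the background threshold on "arcsinh" (pipeline
#'   order) or "raw" counts.
#' @param smooth_ksize,smooth_sigma Gaussian pre-smoothing for the threshold.
#' @return a `marker_norm_stats` object.
#' @export
fit_normalization <- function(train_stacks, sample_ids = NULL, cofactor = 1,
                              clip_q = 0.999, otsu_on = c("arcsinh", "raw"),
                              smooth_ksize = 3L, smooth_sigma = 3) {
  otsu_on <- match.arg(otsu_on)
  if (!length(train_stacks)) stop("need at least one training stack")
  train_stacks <- lapply(train_stacks, function(s) {
    if (length(dim(s)) == 2L) s <- array(s, c(dim(s), 1L)); s
  })
  markers <- dimnames(train_stacks[[1]])[[3]] %||%
    paste0("marker", seq_len(dim(train_stacks[[1]])[3]))
  if (is.null(sample_ids)) sample_ids <- rep("sample1", length(train_stacks))
  kern <- gaussian_kernel_1d(smooth_sigma, ksize = smooth_ksize)
  nm <- length(markers)
  clip <- numeric(nm); names(clip) <- markers
  thr <- matrix(NA_real_, length(unique(sample_ids)), nm,
                dimnames = list(unique(sample_ids), markers))
  mean_ <- sd_ <- min_ <- max_ <- numeric(nm)
  names(mean_) <- names(sd_) <- names(min_) <- names(max_) <- markers
  for (m in seq_len(nm)) {
    pooled <- unlist(lapply(train_stacks, function(s) as.numeric(s[, , m])))
    clip[m] <- stats::quantile(pooled, clip_q, names = FALSE, type = 7)
    # per-sample Otsu on smoothed channels
    for (sid in rownames(thr)) {
      vals <- unlist(lapply(which(sample_ids == sid), function(i) {
        ch <- pmin(train_stacks[[i]][, , m], clip[m])
        if (otsu_on == "arcsinh") ch <- asinh(ch / cofactor)
        sm <- cpp_blur_sep(array(ch, c(dim(ch), 1L, 1L)), kern)
        as.numeric(sm)
      }))
      thr[sid, m] <- if (length(unique(vals)) < 2L) -Inf else otsu_threshold(vals)
    }
    # pooled post-threshold values to fix centring and min-max
    post <- unlist(lapply(seq_along(train_stacks), function(i) {
      ch <- asinh(pmin(train_stacks[[i]][, , m], clip[m]) / cofactor)
      ch[ch < thr[sample_ids[i], m]] <- 0
      as.numeric(ch)
    }))
    mean_[m] <- mean(post); sd_[m] <- stats::sd(post)
    if (!is.finite(sd_[m]) || sd_[m] == 0) {
      warning("constant channel '", markers[m], "': standardization skipped")
      sd_[m] <- 1
    }
    z <- (post - mean_[m]) / sd_[m]
    min_[m] <- min(z); max_[m] <- max(z)
  }
  structure(list(markers = markers, clip = clip, cofactor = cofactor,
                 thresholds = thr, mean = mean_, sd = sd_,
                 min = min_, max = max_, otsu_on = otsu_on,
                 smooth_ksize = smooth_ksize, smooth_sigma = smooth_sigma),
            class = "marker_norm_stats")
}

#' Apply fitted normalization statistics to a marker stack
#'
#' @param stats a `marker_norm_stats` from [fit_normalization()].
#' @param stack H x W x C marker stack (channels matching the fitted panel).
#' @param sample_id which sample's background threshold to use (default: the
#'   first fitted sample).
#' @return normalized stack; training data maps into `[0, 1]` exactly.
#' @export
apply_normalization <- function(stats, stack, sample_id = NULL) {
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  sid <- sample_id %||% rownames(stats$thresholds)[1]
  out <- stack
  for (m in seq_along(stats$markers)) {
    ch <- asinh(pmin(stack[, , m], stats$clip[m]) / stats$cofactor)
    ch[ch < stats$thresholds[sid, m]] <- 0
    z <- (ch - stats$mean[m]) / stats$sd[m]
    rng <- stats$max[m] - stats$min[m]
    out[, , m] <- if (rng <= .Machine$double.eps) z * 0 else (z - stats$min[m]) / rng
  }
  out
}

# exact 90-degree rotations (k quarter-turns counter-clockwise)
rot90_mat <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

mutual_information <- function(a, b, n_bins = 32L) {
  ra <- range(a); rb <- range(b)
  ia <- if (ra[2] > ra[1])
    pmin(floor((a - ra[1]) / (ra[2] - ra[1]) * n_bins) + 1L, n_bins) else rep(1L, length(a))
  ib <- if (rb[2] > rb[1])
    pmin(floor((b - rb[1]) / (rb[2] - rb[1]) * n_bins) + 1L, n_bins) else rep(1L, length(b))
  jt <- tabulate((ib - 1L) * n_bins + ia, n_bins * n_bins) / length(a)
  pj <- matrix(jt, n_bins, n_bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
}

#' Rigid template matching by mutual information
#'
#' Exhaustive search over integer translations and a discrete rotation set for
#' the transform of the moving image that maximizes the mutual information
#' (computed from a B x B joint histogram over the overlap) with the fixed
#' image. Used to pair tumour-marker channels with the H&E haematoxylin
#' channel across serial sections.
#'
#' @param fixed,moving single-channel images (matrices).
#' @param max_shift maximum |translation| in px (default 25% of the image).
#' @param rotations coarse rotation set in degrees.
#' @param fine_deg,fine_step add a fine sweep of `seq(-fine_deg, fine_deg,
#'   fine_step)` degrees around each coarse rotation; 0 disables.
#' @param n_bins joint histogram bins per axis.
#' @param step translation step in px.
#' @return list: `shift` (dx, dy applied to the moving image), `rotation`
#'   (degrees), `mi`, and `transform` (3x3 affine mapping moving to fixed
#'   pixel coordinates).
#' @export
template_match_mi <- function(fixed, moving,
                              max_shift = NULL,
                              rotations = c(0, 90, -90, 180),
                              fine_deg = 5, fine_step = 1,
                              n_bins = 32L, step = 1L) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (is.null(max_shift)) max_shift <- round(0.25 * min(dim(fixed)))
  angles <- unique(as.numeric(outer(rotations,
                                    if (fine_deg > 0) seq(-fine_deg, fine_deg, by = fine_step) else 0,
                                    "+")))
  shifts <- seq(-max_shift, max_shift, by = step)
  best <- list(mi = -Inf)
  H <- nrow(fixed); W <- ncol(fixed)
  for (th in angles) {
    mov_r <- if (th %% 90 == 0) rot90_mat(moving, as.integer(th / 90)) else
      warp_affine(moving,
                  affine_matrix(rot = th, centre = c((ncol(moving) + 1) / 2,
                                                     (nrow(moving) + 1) / 2)),
                  fill = NA)
    mh <- nrow(mov_r); mw <- ncol(mov_r)
    for (dx in shifts) for (dy in shifts) {
      # overlap of fixed[(y), (x)] with mov_r shifted by (dx, dy)
      fy <- max(1, 1 + dy):min(H, mh + dy)
      fx <- max(1, 1 + dx):min(W, mw + dx)
      if (length(fy) < 4 || length(fx) < 4) next
      a <- fixed[fy, fx]
      b <- mov_r[fy - dy, fx - dx]
      ok <- !is.na(b)
      if (sum(ok) < 16) next
      mi <- mutual_information(a[ok], b[ok], n_bins)
      if (mi > best$mi) best <- list(mi = mi, shift = c(dx = dx, dy = dy),
                                     rotation = th)
    }
  }
  if (!is.finite(best$mi)) stop("no candidate transform had a usable overlap")
  ctr <- c((ncol(moving) + 1) / 2, (nrow(moving) + 1) / 2)
  Tm <- affine_matrix(shift = best$shift, rot = 0) %*%
    affine_matrix(rot = best$rotation, centre = ctr)
  best$transform <- Tm
  best
}

# ---- stain handling ------------------------------------------------------

# standard reference stain basis (columns: haematoxylin, eosin; rows R, G, B)
MACENKO_REF <- matrix(c(0.5626, 0.7201, 0.4062,
                        0.2159, 0.8012, 0.5581), nrow = 3,
                      dimnames = list(c("R", "G", "B"), c("H", "E")))
MACENKO_MAXC_REF <- c(1.9705, 1.0308)

.od <- function(rgb) -log((rgb * 255 + 1) / 256)
.od_inv <- function(od) (256 * exp(-od) - 1) / 255

#' Macenko stain normalization
#'
#' Estimates the 2-vector stain basis of an RGB tile from the SVD plane of its
#' optical-density pixels (robust percentile angles), maps stain
#' concentrations onto a reference basis, and reconstructs the tile.
#'
#' @param rgb H x W x 3 array in `[0, 1]`.
#' @param reference 3 x 2 reference stain matrix (columns H, E).
#' @param max_c_ref reference 99th-percentile concentrations.
#' @param alpha robust angle percentile; `beta` minimum OD for tissue pixels.
#' @return normalized H x W x 3 array; near-white tiles (no tissue OD) are
#'   returned unchanged with a warning.
#' @export
macenko_normalize <- function(rgb, reference = MACENKO_REF,
                              max_c_ref = MACENKO_MAXC_REF,
                              alpha = 1, beta = 0.15) {
  d <- dim(rgb)
  od <- matrix(.od(rgb), ncol = 3L)
  tissue <- rowSums(od > beta) == 3L
  if (sum(tissue) < 10L) {
    warning("near-white tile: no tissue optical density, returned unchanged")
    return(rgb)
  }
  odh <- od[tissue, , drop = FALSE]
  ev <- eigen(stats::cov(odh), symmetric = TRUE)$vectors[, 1:2]
  # orient the plane basis so projections cluster away from the atan2 branch
  # cut (OD vectors live in the positive octant)
  if (mean(odh %*% ev[, 1]) < 0) ev[, 1] <- -ev[, 1]
  proj <- odh %*% ev
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alpha / 100, 1 - alpha / 100), names = FALSE)
  v1 <- ev %*% c(cos(q[1]), sin(q[1]))
  v2 <- ev %*% c(cos(q[2]), sin(q[2]))
  if (v1[1] < 0) v1 <- -v1
  if (v2[1] < 0) v2 <- -v2
  HE <- if (v1[1] > v2[1]) cbind(v1, v2) else cbind(v2, v1)
  conc <- t(qr.solve(HE, t(od)))          # n x 2 concentrations
  max_c <- apply(conc, 2, stats::quantile, 0.99, names = FALSE)
  conc <- sweep(conc, 2, max_c_ref / pmax(max_c, 1e-8), "*")
  out <- .od_inv(conc %*% t(reference))
  array(pmin(pmax(out, 0), 1), dim = d)
}

# Ruifrok-Johnston H&E stain vectors (rows: stain; columns R, G, B), unit norm
HE_STAIN_MATRIX <- local({
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  r <- c(h[2] * e[3] - h[3] * e[2], h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  m <- rbind(H = h / sqrt(sum(h^2)), E = e / sqrt(sum(e^2)),
             R = r / sqrt(sum(r^2)))
  m
})

#' Haematoxylin channel by colour deconvolution
#'
#' Unmixes the optical density of an RGB image with the standard H&E stain
#' matrix and returns the haematoxylin concentration image.
#'
#' @param rgb H x W x 3 array in `[0, 1]`.
#' @return matrix of haematoxylin concentrations; the eosin and residual
#'   channels are attached as attributes `eosin` and `residual`.
#' @export
h_channel_deconvolution <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 RGB array")
  od <- matrix(.od(rgb), ncol = 3L)
  conc <- od %*% solve(HE_STAIN_MATRIX)   # n x 3: H, E, residual
  out <- matrix(conc[, 1], d[1], d[2])
  attr(out, "eosin") <- matrix(conc[, 2], d[1], d[2])
  attr(out, "residual") <- matrix(conc[, 3], d[1], d[2])
  out
}

#' Serialize / read normalization stats and affine transforms as JSON
#'
#' @param x a `marker_norm_stats` or 3x3 matrix; `path` file path.
#' @return `read_transform_json` returns a 3x3 matrix; writers return the path.
#' @export
write_norm_stats <- function(x, path) {
  jsonlite::write_json(unclass(x), path, digits = NA, matrix = "rowmajor",
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
write_transform_json <- function(x, path) {
  stopifnot(is.matrix(x), all(dim(x) == c(3L, 3L)))
  jsonlite::write_json(list(matrix = x, convention = "row-major, 0-based origin top-left, pixel units"),
                       path, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  matrix(unlist(j$matrix), 3L, 3L, byrow = FALSE)
}
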