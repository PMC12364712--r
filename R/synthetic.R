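# Synthetic tissue simulator: paired pseudo-H&E / marker-stack images with
# known cell-level ground truth, region masks, and synthetic survival bags.
# The simulator mirrors the data regime of paired serial-section ROIs: markers
# on a 1 um/px grid, H&E on a grid finer by `he_scale_factor`, with optional
# affine jitter of the H&E copy emulating slice-to-slice displacement.

#' Default marker panel and cell types
#'
#' The 11-marker panel (tumour markers MelanA, S100, gp100, SOX10; immune
#' markers CD3, CD8a, CD20, CD16, CD31; antigen-presentation markers HLA-ABC,
#' HLA-DR) and the simulated cell types.
#'
#' @format character vectors.
#' @export
PLEX_MARKERS <- c("MelanA", "S100", "gp100", "SOX10", "CD3", "CD8a", "CD20",
                  "CD16", "CD31", "HLA-ABC", "HLA-DR")

#' @rdname PLEX_MARKERS
#' @export
PLEX_CELL_TYPES <- c("tumour", "CD8T", "CD4T", "B", "endothelial", "other")

#' Default cell-type x marker expression matrix
#'
#' Rows are cell types, columns markers, entries in `[0, 1]`. Tumour types are
#' high on tumour markers (MelanA, S100, gp100, SOX10) and zero on immune
#' markers; lymphocyte types express their lineage markers (CD3/CD8a for CD8 T,
#' CD20 for B); antigen-presentation markers are broadly shared.
#'
#' @return numeric matrix `length(PLEX_CELL_TYPES)` x `length(PLEX_MARKERS)`.
#' @export
default_expression_matrix <- function() {
  E <- matrix(0, length(PLEX_CELL_TYPES), length(PLEX_MARKERS),
              dimnames = list(PLEX_CELL_TYPES, PLEX_MARKERS))
  E["tumour", c("MelanA", "S100", "gp100", "SOX10")] <- c(0.9, 0.8, 0.85, 0.9)
  E["tumour", c("HLA-ABC", "HLA-DR")] <- c(0.6, 0.3)
  E["CD8T", c("CD3", "CD8a", "CD16", "HLA-ABC", "HLA-DR")] <- c(0.9, 0.85, 0.2, 0.5, 0.3)
  E["CD4T", c("CD3", "CD16", "HLA-ABC", "HLA-DR")] <- c(0.9, 0.2, 0.5, 0.4)
  E["B", c("CD20", "CD16", "HLA-ABC", "HLA-DR")] <- c(0.9, 0.1, 0.5, 0.7)
  E["endothelial", c("CD31", "CD16", "HLA-ABC", "HLA-DR")] <- c(0.9, 0.2, 0.4, 0.3)
  E["other", c("S100", "CD16", "HLA-ABC", "HLA-DR")] <- c(0.1, 0.3, 0.3, 0.2)
  E
}

#' Tissue simulator configuration
#'
#' @param canvas marker-grid canvas side in px (1 um/px).
#' @param he_scale_factor integer; the H&E grid is this factor finer.
#' @param n_cells number of cells.
#' @param proportions named cell-type proportions (must sum to 1).
#' @param markers marker panel names.
#' @param expression expression matrix `E[type, marker]` in `[0, 1]`.
#' @param nucleus_radius_um nucleus radius in um.
#' @param noise_sd additive truncated-Gaussian noise sd on marker channels.
#' @param max_shift_px,max_rot_deg bounds of the affine jitter applied to the
#'   H&E copy (H&E pixels / degrees).
#' @param cell_sd,marker_sd log-normal sd of the shared per-cell intensity
#'   factor and the per-cell-per-marker factor (the co-expression copula).
#' @param centre_margin_px erosion margin (marker px) defining the tumour
#'   centre inside the tumour support; maps to the 500 um margin at full scale,
#'   scaled down for desk-size canvases.
#' @param seed RNG seed; fully determines the output.
#' @return a `tissue_sim_config` object.
#' @export
tissue_sim_config <- function(canvas = 96L, he_scale_factor = 4L,
                              n_cells = 150L,
                              proportions = c(tumour = 0.4, CD8T = 0.15,
                                              CD4T = 0.1, B = 0.1,
                                              endothelial = 0.1, other = 0.15),
                              markers = PLEX_MARKERS,
                              expression = default_expression_matrix()[, markers, drop = FALSE],
                              nucleus_radius_um = 3, noise_sd = 0.05,
                              max_shift_px = 0, max_rot_deg = 0,
                              cell_sd = 0.25, marker_sd = 0.25,
                              centre_margin_px = 8L, seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (any(expression < 0 | expression > 1)) stop("expression entries must be in [0, 1]")
  if (!all(colnames(expression) == markers)) stop("expression columns must match markers")
  r <- nucleus_radius_um
  if (n_cells * pi * r^2 > 0.6 * canvas^2)
    stop("canvas too small for n_cells at the given nucleus radius")
  structure(list(canvas = as.integer(canvas),
                 he_scale_factor = as.integer(he_scale_factor),
                 n_cells = as.integer(n_cells), proportions = proportions,
                 markers = markers, expression = expression,
                 nucleus_radius_um = nucleus_radius_um, noise_sd = noise_sd,
                 max_shift_px = max_shift_px, max_rot_deg = max_rot_deg,
                 cell_sd = cell_sd, marker_sd = marker_sd,
                 centre_margin_px = as.integer(centre_margin_px),
                 seed = as.integer(seed)),
            class = "tissue_sim_config")
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dh = -r:r, dw = -r:r)
  g[g$dh^2 + g$dw^2 <= radius^2, , drop = FALSE]
}

# add value to a disk centred at (h, w) in matrix m (clipped at borders)
add_disk <- function(m, h, w, offsets, value) {
  hh <- round(h) + offsets$dh; ww <- round(w) + offsets$dw
  ok <- hh >= 1 & hh <= nrow(m) & ww >= 1 & ww <= ncol(m)
  idx <- cbind(hh[ok], ww[ok])
  m[idx] <- m[idx] + value
  m
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  x <- array(m, dim = c(dim(m), 1L, 1L))
  matrix(cpp_blur_sep(x, gaussian_kernel_1d(sigma)), nrow(m), ncol(m))
}

# binary erosion by a disk structuring element
erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- disk_offsets(radius)
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (i in seq_len(nrow(off))) {
    dh <- off$dh[i]; dw <- off$dw[i]
    shifted <- matrix(FALSE, H, W)
    hs <- max(1, 1 - dh):min(H, H - dh)
    ws <- max(1, 1 - dw):min(W, W - dw)
    shifted[hs, ws] <- mask[hs + dh, ws + dw]
    out <- out & shifted
  }
  out
}

#' Simulate a paired pseudo-H&E / marker ROI
#'
#' Renders each marker channel as the sum of per-cell disks with amplitude
#' `E[type, marker] * s_cell * u_cell_marker` (log-normal factors inducing a
#' known co-expression structure), Gaussian-blurred, with additive truncated
#' Gaussian noise, min-max scaled to `[0, 1]`. The pseudo-H&E renders nuclei as
#' dark basophilic disks on an eosin-like background at `he_scale_factor` times
#' the marker resolution, then applies the configured affine jitter; the exact
#' inverse transform is stored.
#'
#' @param config a [tissue_sim_config()].
#' @return a `paired_roi` list: `he` (H&E array), `markers` (marker-grid array
#'   with channel names), `cells` (data frame: id, x, y, type + one column per
#'   marker), `masks` (logical matrices: tumour_centre, intratumoral, stromal),
#'   `inverse_transform` (3x3 affine, H&E px), and `scene` with pre-blur
#'   channels and render internals.
#' @export
simulate_paired_roi <- function(config = tissue_sim_config()) {
  set.seed(config$seed)
  cs <- config$canvas; f <- config$he_scale_factor
  r <- config$nucleus_radius_um            # marker px (1 um/px)
  nm <- length(config$markers)
  types <- sample(names(config$proportions), config$n_cells, replace = TRUE,
                  prob = config$proportions)
  x <- stats::runif(config$n_cells, r + 1, cs - r)    # marker-grid coords
  y <- stats::runif(config$n_cells, r + 1, cs - r)
  s_cell <- stats::rlnorm(config$n_cells, 0, config$cell_sd)
  expr <- matrix(0, config$n_cells, nm, dimnames = list(NULL, config$markers))
  for (m in seq_len(nm)) {
    u <- stats::rlnorm(config$n_cells, 0, config$marker_sd)
    expr[, m] <- config$expression[types, m] * s_cell * u
  }
  off <- disk_offsets(r)
  raw <- array(0, dim = c(cs, cs, nm), dimnames = list(NULL, NULL, config$markers))
  for (m in seq_len(nm)) {
    ch <- matrix(0, cs, cs)
    for (i in seq_len(config$n_cells))
      if (expr[i, m] > 0) ch <- add_disk(ch, y[i], x[i], off, expr[i, m])
    raw[, , m] <- ch
  }
  stack <- raw
  for (m in seq_len(nm)) {
    ch <- blur_mat(raw[, , m], 1)
    if (config$noise_sd > 0) {
      noise <- stats::rnorm(length(ch), 0, config$noise_sd)
      noise <- pmin(pmax(noise, -2 * config$noise_sd), 2 * config$noise_sd)
      ch <- pmax(ch + noise, 0)
    }
    stack[, , m] <- minmax01(ch)
  }
  # pseudo-H&E: nuclei mask at fine resolution
  hs <- cs * f
  nuc <- matrix(FALSE, hs, hs)
  # nucleus radius slightly inside the marker disk so that the downsampled
  # nucleus mask is contained in the rendered marker foreground
  off_he <- disk_offsets(max(f, (r - 0.75) * f))
  for (i in seq_len(config$n_cells))
    nuc <- add_disk(nuc, (round(y[i]) - 0.5) * f + 0.5,
                    (round(x[i]) - 0.5) * f + 0.5, off_he, TRUE) > 0
  eosin <- c(0.92, 0.78, 0.84); haem <- c(0.30, 0.22, 0.52)
  he <- array(0, dim = c(hs, hs, 3))
  tex <- matrix(stats::rnorm(hs * hs, 0, 0.02), hs, hs)
  for (c3 in 1:3) he[, , c3] <- ifelse(nuc, haem[c3], eosin[c3]) + tex
  he <- pmin(pmax(he, 0), 1)
  # affine jitter of the H&E copy
  shift <- stats::runif(2, -config$max_shift_px, config$max_shift_px)
  rot <- stats::runif(1, -config$max_rot_deg, config$max_rot_deg)
  if (config$max_shift_px == 0) shift <- c(0, 0)
  if (config$max_rot_deg == 0) rot <- 0
  fwd <- affine_matrix(shift, rot, centre = (hs + 1) / 2)
  he_j <- if (all(shift == 0) && rot == 0) he else
    warp_affine(he, fwd, fill = eosin)
  inv <- solve(fwd)
  cells <- data.frame(id = seq_len(config$n_cells), x = x, y = y,
                      type = types, check.names = FALSE)
  cells <- cbind(cells, as.data.frame(expr, check.names = FALSE))
  masks <- region_masks(x, y, types, cs, config$centre_margin_px)
  structure(list(he = he_j, markers = stack, cells = cells, masks = masks,
                 inverse_transform = inv, config = config,
                 scene = list(raw = raw, nuclei = nuc, he_unjittered = he,
                              forward_transform = fwd)),
            class = "paired_roi")
}

# 3x3 row-major affine (0-based-agnostic: acts on 1-based (x, y, 1) pixel coords
# about `centre`): rotation by `rot` degrees then translation by `shift` px
affine_matrix <- function(shift = c(0, 0), rot = 0, centre = 0) {
  th <- rot * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  Tc <- diag(3); Tc[1:2, 3] <- -centre
  Tb <- diag(3); Tb[1:2, 3] <- centre + shift
  Tb %*% R %*% Tc
}

# nearest-neighbour affine warp of (H, W, C) image; `A` maps source -> target
warp_affine <- function(img, A, fill = 0) {
  d <- dim(img); H <- d[1]; W <- d[2]; C <- if (length(d) >= 3) d[3] else 1L
  Ainv <- solve(A)
  g <- expand.grid(xo = seq_len(W), yo = seq_len(H))
  src <- Ainv %*% rbind(g$xo, g$yo, 1)
  xs <- round(src[1, ]); ys <- round(src[2, ])
  ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
  out <- array(0, dim = c(H, W, C))
  fill <- rep(fill, length.out = C)
  for (c3 in seq_len(C)) {
    plane <- matrix(fill[c3], H, W)
    src_idx <- cbind(ys[ok], xs[ok])
    tgt_idx <- cbind(g$yo[ok], g$xo[ok])
    m <- if (length(d) >= 3) img[, , c3] else img
    plane[tgt_idx] <- m[src_idx]
    out[, , c3] <- plane
  }
  if (length(d) < 3) out[, , 1] else out
}

# tumour-centre / intratumoral / stromal masks from the cell layout
region_masks <- function(x, y, types, canvas, margin) {
  dens <- matrix(0, canvas, canvas)
  off <- disk_offsets(3)
  tum <- which(types == "tumour")
  for (i in tum) dens <- add_disk(dens, y[i], x[i], off, 1)
  dens <- blur_mat(dens, 3)
  support <- dens > 0.05 * max(dens)
  centre <- erode_mask(support, margin)
  thr <- stats::quantile(dens[centre], 0.4, names = FALSE)
  intratumoral <- centre & dens >= thr
  stromal <- centre & dens < thr
  list(tumour_centre = centre, intratumoral = intratumoral, stromal = stromal)
}

#' Simulate a survival cohort of MIL bags
#'
#' Each patient carries a latent risk `effect_size * s`, `s ~ N(0, 1)`, embedded
#' in the first `n_informative` feature dimensions of every instance of both
#' modalities; event times are exponential with rate `exp(risk)`, censoring is
#' independent, and discrete time bins are the quartiles of observed times.
#'
#' @param n_patients,bag_size,feature_dim cohort and bag geometry.
#' @param effect_size signal strength (>= 0); 0 gives uninformative features.
#' @param censor_rate probability of censoring, in `[0, 1)`.
#' @param n_informative number of signal-carrying feature dimensions.
#' @param seed RNG seed.
#' @return list of `survival_bag` objects with fields `H`, `P` (instance
#'   feature matrices), `time`, `bin`, `censor` (0 = death observed,
#'   1 = censored), `label` ("high"/"low" latent-risk class) and `risk`.
#' @export
simulate_survival_cohort <- function(n_patients = 60L, bag_size = 16L,
                                     feature_dim = 16L, effect_size = 1,
                                     censor_rate = 0.2, n_informative = 4L,
                                     seed = 1L) {
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  set.seed(seed)
  s <- stats::rnorm(n_patients)
  risk <- effect_size * s
  times <- stats::rexp(n_patients, rate = exp(risk))
  censored <- stats::rbinom(n_patients, 1L, censor_rate)
  obs <- ifelse(censored == 1L, stats::runif(n_patients) * times, times)
  bins <- discretize_times(obs)
  med <- stats::median(risk)
  bags <- lapply(seq_len(n_patients), function(i) {
    mk <- function() {
      m <- matrix(stats::rnorm(bag_size * feature_dim), bag_size, feature_dim)
      m[, seq_len(n_informative)] <- m[, seq_len(n_informative)] + s[i]
      m
    }
    structure(list(H = mk(), P = mk(), time = obs[i],
                   bin = bins$bin[i], censor = censored[i],
                   label = if (risk[i] > med) "high" else "low",
                   risk = risk[i]),
              class = "survival_bag")
  })
  attr(bags, "cuts") <- bins$cuts
  bags
}

#' Write a paired ROI to disk as plain raster/CSV files
#'
#' Writes the H&E as PNG, each marker channel as PNG, the masks as
#' single-channel PNGs, the cell table as CSV, and the inverse transform as
#' JSON (3x3, row-major).
#'
#' @param roi a `paired_roi`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_paired_roi <- function(roi, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- file.path(dir, "he.png")
  png::writePNG(roi$he, p); files <- c(files, p)
  for (m in dimnames(roi$markers)[[3]]) {
    p <- file.path(dir, paste0("marker_", gsub("[^A-Za-z0-9]", "_", m), ".png"))
    png::writePNG(roi$markers[, , m], p); files <- c(files, p)
  }
  for (nm in names(roi$masks)) {
    p <- file.path(dir, paste0("mask_", nm, ".png"))
    png::writePNG(roi$masks[[nm]] * 1, p); files <- c(files, p)
  }
  p <- file.path(dir, "cells.csv")
  utils::write.csv(roi$cells, p, row.names = FALSE); files <- c(files, p)
  p <- file.path(dir, "inverse_transform.json")
  jsonlite::write_json(list(matrix = roi$inverse_transform), p, digits = NA,
                       matrix = "rowmajor")
  files <- c(files, p)
  invisible(files)
}
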