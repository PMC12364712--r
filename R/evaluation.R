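# Full-reference image metrics (PSNR, MS-SSIM, sliding-window RMSE), the HYPE
# human-evaluation score, and Spearman co-localization statistics.

#' Peak signal-to-noise ratio
#'
#' `10 log10(L^2 / MSE)`; identical images give `Inf` (documented sentinel).
#'
#' @param y,y_hat arrays of identical shape.
#' @param L dynamic range of the pixel values (1 for normalized images).
#' @return PSNR in dB.
#' @export
psnr <- function(y, y_hat, L = 1) {
  if (!identical(dim(y), dim(y_hat))) stop("shape mismatch")
  if (L <= 0) stop("L must be positive")
  mse <- mean((y - y_hat)^2)
  if (mse == 0) return(Inf)
  10 * log10(L^2 / mse)
}

# mean local SSIM between two matrices using a Gaussian window; when the
# window does not fit, global (single-window) moments are used
ssim_mean <- function(a, b, C1, C2, window_size = 11L, window_sigma = 1.5) {
  if (window_size >= min(dim(a))) {
    mu_a <- mean(a); mu_b <- mean(b)
    va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
    cab <- mean((a - mu_a) * (b - mu_b))
    return(((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
             ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))
  }
  kern <- gaussian_kernel_1d(window_sigma, ksize = window_size)
  bl <- function(m) matrix(cpp_blur_sep(array(m, c(dim(m), 1L, 1L)), kern),
                           nrow(m), ncol(m))
  mu_a <- bl(a); mu_b <- bl(b)
  va <- bl(a * a) - mu_a^2; vb <- bl(b * b) - mu_b^2
  cab <- bl(a * b) - mu_a * mu_b
  smap <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  r <- (window_size - 1L) %/% 2L        # drop zero-padding boundary
  mean(smap[(r + 1):(nrow(smap) - r), (r + 1):(ncol(smap) - r)])
}

avgpool_mat <- function(m, f = 2L) {
  H <- (nrow(m) %/% f) * f; W <- (ncol(m) %/% f) * f
  matrix(cpp_avgpool(array(m[seq_len(H), seq_len(W)], c(H, W, 1L, 1L)), f),
         H %/% f, W %/% f)
}

#' Multiscale structural similarity (MS-SSIM)
#'
#' Per-scale SSIM from local Gaussian-window moments, combined as a weighted
#' product `prod_j SSIM_j^alpha_j` over `M` dyadic scales (2x average-pooling
#' between scales).
#'
#' @param y,y_hat matrices or single-channel arrays; multi-channel stacks are
#'   averaged over channels.
#' @param M number of scales; `alpha` per-scale exponents (defaults to the
#'   standard published five-scale weights when `M = 5`, else uniform).
#' @param L dynamic range; `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`.
#' @param window_size,window_sigma local statistics window.
#' @return MS-SSIM in `[0, 1]` for nonnegative weights.
#' @export
ms_ssim <- function(y, y_hat, M = 5L,
                    alpha = if (M == 5L) c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
                    else rep(1 / M, M),
                    L = 1, window_size = 11L, window_sigma = 1.5) {
  if (length(alpha) != M) stop("alpha must have length M")
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  per_channel <- function(a, b) {
    if (min(dim(a)) < 2^(M - 1) * 2) stop("image too small for M scales")
    s <- numeric(M)
    for (j in seq_len(M)) {
      s[j] <- ssim_mean(a, b, C1, C2, window_size, window_sigma)
      if (j < M) { a <- avgpool_mat(a); b <- avgpool_mat(b) }
    }
    # M = 1 reduces exactly to classic SSIM (which may be negative); the
    # multiscale product clamps negative per-scale values at 0 so fractional
    # exponents stay defined and the score lies in [0, 1]
    if (M == 1L) s[1]^alpha[1] else prod(pmax(s, 0)^alpha)
  }
  if (is.matrix(y)) return(per_channel(y, as.matrix(y_hat)))
  d <- dim(y)
  if (length(d) == 2L) return(per_channel(as.matrix(y), as.matrix(y_hat)))
  mean(vapply(seq_len(d[3]), function(c3)
    per_channel(y[, , c3], y_hat[, , c3]), numeric(1)))
}

#' Sliding-window RMSE
#'
#' Square root of the mean over windows of the per-window MSE between the two
#' images; with a single full-image window this equals the global RMSE.
#'
#' @param y,y_hat matrices (multi-channel arrays are averaged over channels).
#' @param window window side(s) `c(w, h)` (scalar recycled).
#' @param stride window stride (> 0).
#' @return RMSE-SW value (>= 0).
#' @export
rmse_sw <- function(y, y_hat, window = 8L, stride = 8L) {
  if (stride <= 0) stop("stride must be positive")
  if (!identical(dim(y), dim(y_hat))) stop("shape mismatch")
  d <- dim(y)
  if (length(d) == 3L)
    return(mean(vapply(seq_len(d[3]), function(c3)
      rmse_sw(y[, , c3], y_hat[, , c3], window, stride), numeric(1))))
  window <- rep(as.integer(window), length.out = 2L)
  w <- window[1]; h <- window[2]
  if (w > nrow(y) || h > ncol(y)) stop("window does not fit in the image")
  ys <- seq(1L, nrow(y) - w + 1L, by = stride)
  xs <- seq(1L, ncol(y) - h + 1L, by = stride)
  sq <- (y - y_hat)^2
  tot <- 0
  for (i in ys) for (j in xs)
    tot <- tot + mean(sq[i:(i + w - 1L), j:(j + h - 1L)])
  sqrt(tot / (length(ys) * length(xs)))
}

#' HYPE scores from recorded rater verdicts
#'
#' Error rates at which raters mistake generated images for real ones and vice
#' versa: `HYPE = (FP + FN) / total * 100`, `HYPE_fake = FP / (TN + FP) * 100`
#' (generated judged real), `HYPE_real = FN / (TP + FN) * 100` (real judged
#' generated).
#'
#' @param truth,verdict character vectors with values "real" / "generated".
#' @return named vector `hype`, `hype_fake`, `hype_real` (percent).
#' @export
hype_scores <- function(truth, verdict) {
  stopifnot(length(truth) == length(verdict),
            all(truth %in% c("real", "generated")),
            all(verdict %in% c("real", "generated")))
  if (!all(c("real", "generated") %in% truth))
    stop("need at least one trial of each truth class")
  tp <- sum(truth == "real" & verdict == "real")
  tn <- sum(truth == "generated" & verdict == "generated")
  fp <- sum(truth == "generated" & verdict == "real")
  fn <- sum(truth == "real" & verdict == "generated")
  c(hype = (fp + fn) / (tp + tn + fp + fn) * 100,
    hype_fake = fp / (tn + fp) * 100,
    hype_real = fn / (tp + fn) * 100)
}

#' Spearman co-localization of marker pairs, with MSE between cohorts
#'
#' For every marker pair, the Spearman correlation (average ranks on ties) of
#' cell-level expressions is computed per ROI and averaged across ROIs, for
#' both the ground-truth and the generated cell tables. Pairs whose
#' ground-truth average correlation is strongly positive (> threshold) or
#' strongly negative (< -threshold) are retained, and the mean squared error
#' between ground-truth and generated averages is reported over retained
#' pairs.
#'
#' @param gt_tables,gen_tables lists (one element per ROI) of numeric matrices
#'   or data frames with one column per marker (cell-level mean expressions;
#'   pixel-level matrices may be passed for a pixel-level analysis).
#' @param threshold retention threshold on |average ground-truth SCC|.
#' @return list: `pairs` data frame (marker_a, marker_b, scc_gt, scc_gen,
#'   retained), `mse` over retained pairs, and `skipped` log of constant
#'   marker/ROI combinations.
#' @export
colocalization_scc <- function(gt_tables, gen_tables, threshold = 0.15) {
  gt_tables <- lapply(gt_tables, as.matrix)
  gen_tables <- lapply(gen_tables, as.matrix)
  markers <- colnames(gt_tables[[1]])
  if (!identical(markers, colnames(gen_tables[[1]])))
    stop("marker panels do not match")
  nm <- length(markers)
  skipped <- character(0)
  avg_scc <- function(tables, a, b) {
    vals <- vapply(seq_along(tables), function(i) {
      xa <- tables[[i]][, a]; xb <- tables[[i]][, b]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
        skipped <<- c(skipped, paste0("ROI ", i, ": ", markers[a], ":", markers[b]))
        return(NA_real_)
      }
      stats::cor(xa, xb, method = "spearman")
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  rows <- list()
  for (a in seq_len(nm - 1L)) for (b in (a + 1L):nm) {
    g <- avg_scc(gt_tables, a, b)
    p <- avg_scc(gen_tables, a, b)
    rows[[length(rows) + 1L]] <-
      data.frame(marker_a = markers[a], marker_b = markers[b],
                 scc_gt = g, scc_gen = p,
                 retained = is.finite(g) && abs(g) > threshold)
  }
  pairs <- do.call(rbind, rows)
  kept <- pairs[pairs$retained & is.finite(pairs$scc_gen), , drop = FALSE]
  mse <- if (nrow(kept)) mean((kept$scc_gt - kept$scc_gen)^2) else NA_real_
  list(pairs = pairs, mse = mse, skipped = skipped)
}

#' Per-ROI, per-marker metric report
#'
#' Computes PSNR, MS-SSIM and sliding-window RMSE per ROI and marker channel,
#' with mean and sd aggregation across ROIs.
#'
#' @param gt_stacks,gen_stacks lists (one per ROI) of H x W x C marker arrays
#'   with matching channel dimnames.
#' @param L dynamic range; `M`, `window_size` MS-SSIM settings; `sw_window`,
#'   `sw_stride` RMSE-SW settings.
#' @return a `metric_report` list: `per_roi` (long data frame), `per_marker`
#'   (mean and sd across ROIs), `overall`, and the `config` used.
#' @export
metric_report <- function(gt_stacks, gen_stacks, L = 1, M = 3L,
                          window_size = 7L, sw_window = 8L, sw_stride = 8L) {
  stopifnot(length(gt_stacks) == length(gen_stacks))
  rows <- list()
  for (r in seq_along(gt_stacks)) {
    g <- gt_stacks[[r]]; p <- gen_stacks[[r]]
    if (length(dim(g)) == 2L) { g <- array(g, c(dim(g), 1L)); p <- array(p, c(dim(p), 1L)) }
    markers <- dimnames(g)[[3]] %||% paste0("marker", seq_len(dim(g)[3]))
    for (m in seq_along(markers)) {
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, marker = markers[m],
        psnr = psnr(g[, , m], p[, , m], L = L),
        ms_ssim = ms_ssim(g[, , m], p[, , m], M = M, L = L,
                          window_size = window_size),
        rmse_sw = rmse_sw(g[, , m], p[, , m], window = sw_window,
                          stride = sw_stride))
    }
  }
  per_roi <- do.call(rbind, rows)
  agg <- function(f) stats::aggregate(per_roi[, c("psnr", "ms_ssim", "rmse_sw")],
                                      list(marker = per_roi$marker), f)
  per_marker <- merge(agg(mean), agg(stats::sd),
                      by = "marker", suffixes = c("_mean", "_sd"))
  fin <- per_roi$psnr[is.finite(per_roi$psnr)]
  overall <- c(psnr_mean = mean(fin), ms_ssim_mean = mean(per_roi$ms_ssim),
               rmse_sw_mean = mean(per_roi$rmse_sw))
  structure(list(per_roi = per_roi, per_marker = per_marker, overall = overall,
                 config = list(L = L, M = M, window_size = window_size,
                               sw_window = sw_window, sw_stride = sw_stride)),
            class = "metric_report")
}

#' Write a metric report as CSV + JSON summary
#'
#' @param report a [metric_report()]; `dir` output directory.
#' @return invisibly, the files written.
#' @export
write_metric_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "metrics_per_roi.csv")
  utils::write.csv(report$per_roi, f1, row.names = FALSE)
  f2 <- file.path(dir, "metrics_summary.json")
  jsonlite::write_json(list(per_marker = report$per_marker,
                            overall = as.list(report$overall),
                            config = report$config),
                       f2, digits = NA, auto_unbox = TRUE)
  invisible(c(f1, f2))
}
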