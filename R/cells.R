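# Cell-level analyses: pseudo-cell extraction around nucleus coordinates,
# random-forest cell typing, joint t-SNE of ground-truth and generated
# expression, CD8 density based immune phenotyping, and a hot/cold classifier.

#' Extract pseudo-cells from a marker stack
#'
#' Averages each marker over a circular disk (default 10 um diameter) around
#' every nucleus coordinate; disks are clipped at image borders.
#'
#' @param stack H x W x C marker array (channel dimnames used as column names).
#' @param coords data frame or matrix with columns `x`, `y` (pixel coordinates,
#'   1-based) and optionally `id`.
#' @param diameter_um disk diameter in um.
#' @param res_um_per_px grid resolution (um per pixel).
#' @return `pseudo_cell_table` data frame: id, x, y + one column per marker.
#'   Out-of-bounds coordinates are skipped (attribute `skipped`).
#' @export
extract_pseudo_cells <- function(stack, coords, diameter_um = 10,
                                 res_um_per_px = 1) {
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  coords <- as.data.frame(coords)
  H <- dim(stack)[1]; W <- dim(stack)[2]; C <- dim(stack)[3]
  markers <- dimnames(stack)[[3]] %||% paste0("marker", seq_len(C))
  radius <- (diameter_um / 2) / res_um_per_px
  off <- disk_offsets(radius)
  inb <- round(coords$x) >= 1 & round(coords$x) <= W &
    round(coords$y) >= 1 & round(coords$y) <= H
  skipped <- which(!inb)
  if (length(skipped))
    message(length(skipped), " coordinate(s) outside the image were skipped")
  coords <- coords[inb, , drop = FALSE]
  n <- nrow(coords)
  expr <- matrix(NA_real_, n, C, dimnames = list(NULL, markers))
  for (i in seq_len(n)) {
    hh <- round(coords$y[i]) + off$dh
    ww <- round(coords$x[i]) + off$dw
    ok <- hh >= 1 & hh <= H & ww >= 1 & ww <= W
    idx <- cbind(hh[ok], ww[ok])
    for (m in seq_len(C)) expr[i, m] <- mean(stack[, , m][idx])
  }
  out <- data.frame(id = coords$id %||% seq_len(n), x = coords$x, y = coords$y,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(expr, check.names = FALSE))
  attr(out, "skipped") <- skipped
  class(out) <- c("pseudo_cell_table", class(out))
  out
}

#' Random-forest cell typer
#'
#' Trains a random forest (100 trees, maximum depth 30) on per-cell mean
#' marker expressions to predict cell types; out-of-bag error is reported.
#'
#' @param table data frame with marker columns and a `type` column (>= 2
#'   classes required).
#' @param markers which feature columns to use (default: the 11-marker panel
#'   intersected with the table's columns).
#' @param num_trees,max_depth forest hyperparameters.
#' @param seed RNG seed.
#' @return a `cell_typer` object (`$forest` ranger model, `$oob_error`).
#' @export
train_cell_typer <- function(table, markers = intersect(PLEX_MARKERS, colnames(table)),
                             num_trees = 100L, max_depth = 30L, seed = 1L) {
  if (!length(markers)) stop("no marker feature columns found")
  y <- factor(table$type)
  if (nlevels(droplevels(y)) < 2L) stop("need >= 2 cell-type classes")
  X <- as.data.frame(table[, markers, drop = FALSE], check.names = FALSE)
  colnames(X) <- make.names(colnames(X))
  fit <- ranger::ranger(x = X, y = droplevels(y), num.trees = num_trees,
                        max.depth = max_depth, probability = FALSE,
                        seed = seed)
  structure(list(forest = fit, markers = markers,
                 feature_names = colnames(X),
                 classes = levels(droplevels(y)),
                 oob_error = fit$prediction.error),
            class = "cell_typer")
}

#' @rdname train_cell_typer
#' @param typer a fitted `cell_typer`.
#' @export
apply_cell_typer <- function(typer, table) {
  missing <- setdiff(typer$markers, colnames(table))
  if (length(missing))
    stop("feature column(s) absent at apply time: ", paste(missing, collapse = ", "))
  X <- as.data.frame(table[, typer$markers, drop = FALSE], check.names = FALSE)
  colnames(X) <- typer$feature_names
  table$type_pred <- as.character(stats::predict(typer$forest, data = X)$predictions)
  table
}

#' Macro-averaged F1 score
#'
#' @param truth,pred factors or character vectors of class labels.
#' @return mean over classes of the per-class F1 (classes absent from both are
#'   ignored; empty precision/recall counts as 0).
#' @export
macro_f1 <- function(truth, pred) {
  classes <- union(unique(truth), unique(pred))
  f1 <- vapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    if (tp == 0) return(0)
    pr <- tp / (tp + fp); rc <- tp / (tp + fn)
    2 * pr * rc / (pr + rc)
  }, numeric(1))
  mean(f1)
}

#' Joint t-SNE of ground-truth and generated cell tables
#'
#' Subsamples `n_per_roi` cells per ROI from each source, embeds the
#' concatenated marker-expression matrix jointly in two dimensions, and
#' returns per-marker colour values scaled and clipped at the 99th percentile.
#'
#' @param gt_tables,gen_tables lists (per ROI) of tables with marker columns.
#' @param markers marker columns to embed.
#' @param n_per_roi cells subsampled per ROI and source (all cells if fewer).
#' @param perplexity,iters t-SNE settings.
#' @param seed RNG seed (recorded in the output).
#' @return list: `embedding` (rows = cells, columns V1/V2), `source`, `roi`,
#'   `colors` (matrix of per-marker display values in `[0, 1]`), `seed`.
#' @export
joint_tsne <- function(gt_tables, gen_tables, markers = NULL, n_per_roi = 1000L,
                       perplexity = 50, iters = 1000L, seed = 1L) {
  set.seed(seed)
  markers <- markers %||% colnames(as.matrix(gt_tables[[1]]))
  take <- function(tables, src) {
    do.call(rbind, lapply(seq_along(tables), function(i) {
      m <- as.matrix(tables[[i]])[, markers, drop = FALSE]
      if (nrow(m) > n_per_roi) m <- m[sample.int(nrow(m), n_per_roi), , drop = FALSE]
      else message("ROI ", i, " (", src, "): only ", nrow(m), " cells, taking all")
      cbind(m, roi = i)
    }))
  }
  gt <- take(gt_tables, "gt"); gen <- take(gen_tables, "generated")
  X <- rbind(gt[, markers, drop = FALSE], gen[, markers, drop = FALSE])
  if (3 * perplexity >= nrow(X) - 1) stop("perplexity too large for the number of cells")
  emb <- Rtsne::Rtsne(X, dims = 2L, perplexity = perplexity, max_iter = iters,
                      check_duplicates = FALSE, pca = TRUE)$Y
  colors <- apply(X, 2, function(v) {
    cap <- stats::quantile(v, 0.99, names = FALSE)
    pmin(v, cap) / max(cap, .Machine$double.eps)
  })
  list(embedding = emb,
       source = rep(c("gt", "generated"), c(nrow(gt), nrow(gen))),
       roi = c(gt[, "roi"], gen[, "roi"]),
       colors = colors, seed = seed)
}

#' CD8 T cell densities in tumour-centre compartments
#'
#' Intratumoral (iCD8) and stromal (sCD8) CD8+ T cell densities: counts of
#' typed CD8 T cells whose centre pixel falls in each compartment mask,
#' divided by the compartment area in um^2 (mask pixel count times the pixel
#' area). Cells in excluded regions are removed first.
#'
#' @param table typed cell table (column `type_pred` or `type`; CD8 T cells
#'   labelled "CD8T").
#' @param masks list with logical matrices `intratumoral` and `stromal` (and
#'   optionally `excluded`), in the cell coordinate frame.
#' @param res_um_per_px grid resolution.
#' @param cd8_label label identifying CD8 T cells.
#' @return a `phenotype_densities` list: `icd8`, `scd8` (per um^2), counts and
#'   areas.
#' @export
phenotype_densities <- function(table, masks, res_um_per_px = 1,
                                cd8_label = "CD8T") {
  type <- table$type_pred %||% table$type
  if (is.null(type)) stop("table has no type column")
  px_area <- res_um_per_px^2
  areas <- vapply(masks[c("intratumoral", "stromal")], function(m) sum(m) * px_area,
                  numeric(1))
  if (any(areas == 0)) {
    warning("zero-area compartment: density undefined")
  }
  # half-open centre-pixel convention: a cell belongs to the compartment
  # containing its rounded centre pixel
  hh <- round(table$y); ww <- round(table$x)
  inb <- hh >= 1 & hh <= nrow(masks$intratumoral) &
    ww >= 1 & ww <= ncol(masks$intratumoral)
  keep <- inb & type == cd8_label
  if (!is.null(masks$excluded))
    keep <- keep & !masks$excluded[cbind(pmax(hh, 1), pmax(ww, 1))]
  idx <- cbind(hh[keep], ww[keep])
  n_i <- sum(masks$intratumoral[idx])
  n_s <- sum(masks$stromal[idx])
  structure(list(icd8 = if (areas[1] > 0) unname(n_i / areas[1]) else NA_real_,
                 scd8 = if (areas[2] > 0) unname(n_s / areas[2]) else NA_real_,
                 n_intratumoral = n_i, n_stromal = n_s,
                 area_intratumoral = unname(areas[1]),
                 area_stromal = unname(areas[2])),
            class = "phenotype_densities")
}

#' Immune hot/cold classifier on (iCD8, sCD8) densities
#'
#' Random forest with stratified 5-fold cross-validation; reports per-fold F1
#' (positive class = "hot") and macro AUROC, as mean and sd.
#'
#' @param densities data frame / matrix with columns `icd8`, `scd8`.
#' @param labels factor or character of "hot"/"cold" (>= 2 classes).
#' @param n_folds folds; `seed` RNG seed.
#' @return list: `f1_mean`, `f1_sd`, `auroc_mean`, `auroc_sd`, per-fold table,
#'   and a final forest fit on all data.
#' @export
hot_cold_classifier <- function(densities, labels, n_folds = 5L, seed = 1L) {
  X <- as.data.frame(densities)[, c("icd8", "scd8")]
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2L) stop("need both classes")
  set.seed(seed)
  folds <- integer(length(y))
  for (k in levels(y)) {
    idx <- which(y == k)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  res <- lapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    if (nlevels(droplevels(y[tr])) < 2L)
      stop("a training fold contains a single class; use more data or fewer folds")
    fit <- ranger::ranger(x = X[tr, ], y = droplevels(y[tr]), num.trees = 100L,
                          probability = TRUE, seed = seed + f)
    pr <- stats::predict(fit, data = X[!tr, ])$predictions
    pos <- if ("hot" %in% colnames(pr)) "hot" else colnames(pr)[1]
    pred <- factor(colnames(pr)[max.col(pr)], levels = levels(y))
    f1 <- {
      tp <- sum(y[!tr] == pos & pred == pos)
      fp <- sum(y[!tr] != pos & pred == pos)
      fn <- sum(y[!tr] == pos & pred != pos)
      if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }
    au <- if (nlevels(droplevels(y[!tr])) < 2L) NA_real_ else
      suppressMessages(as.numeric(pROC::auc(y[!tr] == pos, pr[, pos],
                                            quiet = TRUE)))
    c(f1 = f1, auroc = au)
  })
  tab <- do.call(rbind, res)
  final <- ranger::ranger(x = X, y = droplevels(y), num.trees = 100L,
                          probability = TRUE, seed = seed)
  list(f1_mean = mean(tab[, "f1"]), f1_sd = stats::sd(tab[, "f1"]),
       auroc_mean = mean(tab[, "auroc"], na.rm = TRUE),
       auroc_sd = stats::sd(tab[, "auroc"], na.rm = TRUE),
       folds = as.data.frame(tab), forest = final)
}
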