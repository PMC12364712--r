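# Whole-slide inference: tissue segmentation on a thumbnail, tile planning
# over the tissue mask, batched tile translation, and exact stitching into a
# multi-resolution marker pyramid with QC overlays.

#' Segment tissue on a slide thumbnail
#'
#' Otsu threshold on the inverted-luminance transform (stained tissue is darker
#' than background), followed by simple morphological cleanup (majority filter)
#' and connected-region bounding boxes scaled to level-0 coordinates.
#'
#' @param thumb H x W x 3 RGB array in `[0, 1]` (or a grayscale matrix).
#' @param level0_scale factor from thumbnail to level-0 pixels.
#' @param cleanup_radius majority-filter radius in thumbnail px (0 disables).
#' @return list: `mask` (logical matrix), `regions` (data frame of level-0
#'   bounding boxes), `threshold`.
#' @export
segment_tissue <- function(thumb, level0_scale = 1, cleanup_radius = 1L) {
  gray <- if (length(dim(thumb)) == 3L)
    (thumb[, , 1] + thumb[, , 2] + thumb[, , 3]) / 3 else as.matrix(thumb)
  stain <- 1 - gray
  if (max(stain) - min(stain) < 1e-3) stop("no tissue found")
  thr <- otsu_threshold(stain)
  mask <- stain > thr
  if (!any(mask)) stop("no tissue found")
  if (cleanup_radius > 0) {
    k <- 2L * cleanup_radius + 1L
    box <- rep(1 / k, k)
    dens <- matrix(cpp_blur_sep(array(mask * 1, c(dim(mask), 1L, 1L)), box),
                   nrow(mask), ncol(mask))
    mask <- dens > 0.5
    if (!any(mask)) stop("no tissue found")
  }
  lab <- label_components(mask)
  regions <- do.call(rbind, lapply(seq_len(max(lab)), function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    data.frame(region = l,
               x0 = (min(w[, 2]) - 1L) * level0_scale,
               y0 = (min(w[, 1]) - 1L) * level0_scale,
               x1 = max(w[, 2]) * level0_scale,
               y1 = max(w[, 1]) * level0_scale,
               area_px = nrow(w) * level0_scale^2)
  }))
  list(mask = mask, regions = regions, threshold = thr)
}

# 4-connected component labelling (two-pass union-find)
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (w in seq_len(W)) for (h in seq_len(H)) {
    if (!mask[h, w]) next
    up <- if (h > 1L) lab[h - 1L, w] else 0L
    lf <- if (w > 1L) lab[h, w - 1L] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[h, w] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      lab[h, w] <- min(ru, rl)
      parent[max(ru, rl)] <- min(ru, rl)
    } else lab[h, w] <- max(up, lf)
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Plan tiles over a tissue mask
#'
#' Lays a regular grid of `tile_size` tiles (0-based origins, half-open
#' `[x, x + size)` intervals in level-0 pixel units) and keeps tiles whose
#' tissue fraction reaches `min_tissue_frac`.
#'
#' @param mask logical tissue mask (level-0 resolution, or coarser with
#'   `mask_scale` > 1 mapping mask px to level-0 px).
#' @param tile_size tile side in level-0 px.
#' @param min_tissue_frac minimum tissue fraction to keep a tile.
#' @param mask_scale level-0 px per mask px.
#' @param overlap tile overlap in level-0 px (default 0).
#' @return a `slide_tiling` data frame: `x`, `y` (0-based origins),
#'   `tissue_frac`; attributes `tile_size`, `overlap`, `slide_dim`.
#' @export
plan_tiles <- function(mask, tile_size = 1024L, min_tissue_frac = 0.05,
                       mask_scale = 1L, overlap = 0L) {
  H0 <- nrow(mask) * mask_scale; W0 <- ncol(mask) * mask_scale
  step <- tile_size - overlap
  xs <- seq(0L, W0 - tile_size, by = step)
  ys <- seq(0L, H0 - tile_size, by = step)
  # integral image for fast tissue fractions
  cm <- apply(apply(mask * 1, 2, cumsum), 1, cumsum)  # transposed integral
  ii <- function(h, w) if (h < 1 || w < 1) 0 else cm[w, h]
  rows <- list()
  for (y0 in ys) for (x0 in xs) {
    h1 <- y0 %/% mask_scale; h2 <- (y0 + tile_size) %/% mask_scale
    w1 <- x0 %/% mask_scale; w2 <- (x0 + tile_size) %/% mask_scale
    cnt <- ii(h2, w2) - ii(h1, w2) - ii(h2, w1) + ii(h1, w1)
    frac <- cnt / ((h2 - h1) * (w2 - w1))
    if (frac >= min_tissue_frac)
      rows[[length(rows) + 1L]] <- data.frame(x = x0, y = y0, tissue_frac = frac)
  }
  tiling <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = integer(0), y = integer(0), tissue_frac = numeric(0))
  attr(tiling, "tile_size") <- as.integer(tile_size)
  attr(tiling, "overlap") <- as.integer(overlap)
  attr(tiling, "slide_dim") <- c(H0, W0)
  class(tiling) <- c("slide_tiling", class(tiling))
  tiling
}

#' Persist and reload tile coordinates
#'
#' @param tiling a `slide_tiling`; `path` CSV file path.
#' @return `read_tiling` returns the `slide_tiling`.
#' @export
write_tiling <- function(tiling, path) {
  meta <- sprintf("# tile_size=%d overlap=%d slide_h=%d slide_w=%d",
                  attr(tiling, "tile_size"), attr(tiling, "overlap"),
                  attr(tiling, "slide_dim")[1], attr(tiling, "slide_dim")[2])
  writeLines(c(meta, "x,y,tissue_frac"), path)
  utils::write.table(as.data.frame(tiling), path, sep = ",", append = TRUE,
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tiling
#' @export
read_tiling <- function(path) {
  meta <- readLines(path, n = 1L)
  nums <- as.integer(regmatches(meta, gregexpr("[0-9]+", meta))[[1]])
  tiling <- utils::read.csv(path, skip = 1L)
  attr(tiling, "tile_size") <- nums[1]
  attr(tiling, "overlap") <- nums[2]
  attr(tiling, "slide_dim") <- nums[3:4]
  class(tiling) <- c("slide_tiling", class(tiling))
  tiling
}

#' Tile-based whole-slide inference with stitching
#'
#' Runs a translation model over the planned tiles (in batches), stitches the
#' per-tile marker outputs into a slide-level stack at 1/`scale_factor`
#' resolution (zero outside tissue tiles; overlapping tiles feather-blended),
#' and builds a dyadic pyramid plus a QC overlay of the tiling.
#'
#' @param slide H x W x 3 RGB array (level 0).
#' @param tiling a `slide_tiling` over the slide.
#' @param model either a fitted `plexgen` model or a function
#'   `f(tile_array) -> marker_array` (spatial size reduced by `scale_factor`).
#' @param scale_factor spatial reduction from slide to marker grid.
#' @param out_channels number of marker channels produced by the model.
#' @param stain_norm apply [macenko_normalize()] to each tile first.
#' @param batch_size tiles per model call (function models receive one tile).
#' @param pyramid_levels number of additional 2x-downsampled levels.
#' @param norm_range optional per-channel min-max (from the training set) used
#'   for the visualization scaling of the QC pyramid.
#' @return list: `stack` (stitched marker array), `pyramid` (list of arrays),
#'   `qc` (RGB overlay with tile boundaries), `tiling`, `holes` (failed tiles).
#' @export
run_inference <- function(slide, tiling, model, scale_factor = 4L,
                          out_channels = NULL, stain_norm = FALSE,
                          batch_size = 4L, pyramid_levels = 2L,
                          norm_range = NULL) {
  ts <- attr(tiling, "tile_size")
  ov <- attr(tiling, "overlap")
  sd0 <- dim(slide)[1:2]
  oh <- sd0[1] %/% scale_factor; ow <- sd0[2] %/% scale_factor
  ots <- ts %/% scale_factor
  if (nrow(tiling) == 0L) {
    warning("empty tile plan: returning an all-zero output")
    out_channels <- out_channels %||% 1L
    stack <- array(0, dim = c(oh, ow, out_channels))
    return(list(stack = stack, pyramid = list(stack), qc = slide,
                tiling = tiling, holes = integer(0)))
  }
  predict_tile <- function(tile) {
    if (inherits(model, "plexgen")) predict(model, tile)
    else model(tile)
  }
  acc <- NULL; wacc <- NULL
  holes <- integer(0)
  feather <- if (ov > 0) {
    ramp <- pmin(seq_len(ots) / max(ov %/% scale_factor, 1L), 1)
    w2 <- pmin(ramp, rev(ramp))
    outer(w2, w2)
  } else matrix(1, ots, ots)
  for (i in seq_len(nrow(tiling))) {
    x0 <- tiling$x[i]; y0 <- tiling$y[i]
    tile <- slide[(y0 + 1):(y0 + ts), (x0 + 1):(x0 + ts), , drop = FALSE]
    if (stain_norm) tile <- macenko_normalize(tile)
    out <- tryCatch(predict_tile(tile), error = function(e) NULL)
    if (is.null(out)) { holes <- c(holes, i); next }
    if (length(dim(out)) == 2L) out <- array(out, c(dim(out), 1L))
    if (is.null(acc)) {
      out_channels <- dim(out)[3]
      acc <- array(0, dim = c(oh, ow, out_channels))
      wacc <- matrix(0, oh, ow)
    }
    ry <- (y0 %/% scale_factor + 1):(y0 %/% scale_factor + ots)
    rx <- (x0 %/% scale_factor + 1):(x0 %/% scale_factor + ots)
    for (m in seq_len(out_channels))
      acc[ry, rx, m] <- acc[ry, rx, m] + out[, , m] * feather
    wacc[ry, rx] <- wacc[ry, rx] + feather
  }
  if (is.null(acc)) stop("all tiles failed")
  wpos <- wacc > 0
  for (m in seq_len(dim(acc)[3])) {
    plane <- acc[, , m]
    plane[wpos] <- plane[wpos] / wacc[wpos]
    acc[, , m] <- plane
  }
  pyramid <- list(acc)
  cur <- acc
  for (l in seq_len(pyramid_levels)) {
    d <- dim(cur)
    if (min(d[1:2]) < 2L) break
    cur <- array(cpp_avgpool(array(cur, c(d, 1L)), 2L),
                 dim = c(d[1] %/% 2L, d[2] %/% 2L, d[3]))
    pyramid[[l + 1L]] <- cur
  }
  if (!is.null(norm_range))
    pyramid <- lapply(pyramid, function(p) {
      for (m in seq_len(dim(p)[3])) {
        r <- norm_range[[m]] %||% norm_range
        p[, , m] <- pmin(pmax((p[, , m] - r[1]) / max(r[2] - r[1], 1e-12), 0), 1)
      }
      p
    })
  qc <- slide
  for (i in seq_len(nrow(tiling))) {
    x0 <- tiling$x[i]; y0 <- tiling$y[i]
    col <- if (i %in% holes) c(1, 0, 0) else c(0, 0.8, 0)
    for (c3 in 1:3) {
      qc[c(y0 + 1, y0 + ts), (x0 + 1):(x0 + ts), c3] <- col[c3]
      qc[(y0 + 1):(y0 + ts), c(x0 + 1, x0 + ts), c3] <- col[c3]
    }
  }
  list(stack = acc, pyramid = pyramid, qc = qc, tiling = tiling, holes = holes)
}

#' Write a stitched marker pyramid as multi-channel TIFF files
#'
#' One multi-channel 32-bit float TIFF per pyramid level; channel names are
#' recorded in the TIFF description tag.
#'
#' @param pyramid list of H x W x C arrays (from [run_inference()]).
#' @param path_prefix output path prefix; level L is written to
#'   `<prefix>_L<L>.tiff`.
#' @param channels optional channel names.
#' @return invisibly, the files written.
#' @export
write_marker_pyramid <- function(pyramid, path_prefix, channels = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF output")
  files <- character(0)
  for (l in seq_along(pyramid)) {
    p <- file.path(paste0(path_prefix, "_L", l - 1L, ".tiff"))
    desc <- paste0("channels=", paste(channels %||% seq_len(dim(pyramid[[l]])[3]),
                                      collapse = ","))
    tiff::writeTIFF(pyramid[[l]], p, bits.per.sample = 32L,
                    description = desc)
    files <- c(files, p)
  }
  invisible(files)
}
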