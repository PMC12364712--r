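# Translator (fully convolutional U-Net with multiscale sigmoid heads) and
# conditional spectral-norm discriminator.
#
# The translator maps an H&E tile (H x W x 3) to a C-channel marker stack on a
# grid coarser by `he_scale_factor` (default 4, mirroring 0.25 vs 1 um/px).
# Encoder: 6 stride-2 conv blocks (each conv k3 -> batch-norm -> ReLU).
# Decoder: 5 blocks; the first preserves resolution at the bottleneck, the
# remaining 4 use nearest-neighbour upsampling followed by a stride-1 conv,
# with U-Net skip connections at matching resolutions. The net reduction from
# the H&E grid is therefore 2^6 / 2^4 = 4. Dedicated 3x3 conv + sigmoid heads
# emit outputs at the full, 1/2 and 1/4 marker-grid scales.

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Translator configuration
#'
#' @param in_ch number of input channels (3 for RGB H&E).
#' @param out_ch number of predicted marker channels.
#' @param base_width channel width of the first encoder block; deeper blocks
#'   use multiples of it.
#' @param he_scale_factor integer ratio of H&E to marker grid resolution.
#' @param scales output scales relative to the full marker grid.
#' @return a `translator_config` list.
#' @export
translator_config <- function(in_ch = 3L, out_ch = 11L, base_width = 32L,
                              he_scale_factor = 4L, scales = c(1, 0.5, 0.25)) {
  stopifnot(he_scale_factor >= 1, base_width >= 1, out_ch >= 1)
  structure(list(in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
                 base_width = as.integer(base_width),
                 he_scale_factor = as.integer(he_scale_factor),
                 n_down = 6L, n_up = 5L, scales = scales),
            class = "translator_config")
}

#' Build the translator network
#'
#' @param config a [translator_config()].
#' @return an environment holding the network (weights initialized with Xavier
#'   draws from the current RNG state).
#' @export
build_translator <- function(config = translator_config()) {
  w <- config$base_width
  we <- w * c(1L, 2L, 4L, 4L, 4L, 4L)          # encoder widths
  wd <- w * c(4L, 4L, 4L, 2L, 1L)              # decoder widths
  G <- new.env(parent = emptyenv())
  G$cfg <- config
  G$enc <- lapply(seq_len(6L), function(i) {
    cin <- if (i == 1L) config$in_ch else we[i - 1L]
    list(conv = new_conv(cin, we[i], k = 3L, stride = 2L), bn = new_bn(we[i]))
  })
  # decoder block inputs: block 1 takes the bottleneck; blocks 2..5 take the
  # upsampled previous output concatenated with the encoder skip at that res
  skip_w <- c(0L, we[5L], we[4L], we[3L], we[2L])
  G$dec <- lapply(seq_len(5L), function(j) {
    cin <- if (j == 1L) we[6L] else wd[j - 1L] + skip_w[j]
    list(conv = new_conv(cin, wd[j], k = 3L, stride = 1L), bn = new_bn(wd[j]),
         upsample = j > 1L)
  })
  # heads: full scale on dec5, 1/2 on dec4, 1/4 on dec3
  G$heads <- list(full = new_conv(wd[5L], config$out_ch, k = 3L, stride = 1L),
                  half = new_conv(wd[4L], config$out_ch, k = 3L, stride = 1L),
                  quarter = new_conv(wd[3L], config$out_ch, k = 3L, stride = 1L))
  G$layers <- c(unlist(lapply(G$enc, function(b) list(b$conv, b$bn)), recursive = FALSE),
                unlist(lapply(G$dec, function(b) list(b$conv, b$bn)), recursive = FALSE),
                G$heads)
  G
}

#' Run the translator forward
#'
#' @param G translator from [build_translator()].
#' @param x H&E input array (H, W, 3) or batch (H, W, 3, N); spatial size must
#'   be divisible by 2^6.
#' @param training training mode (batch statistics, spectral-norm power
#'   iteration updates).
#' @param keep_cache also return the activation cache used by the backward
#'   pass.
#' @return named list of per-scale outputs (`full`, `half`, `quarter`), each in
#'   `[0, 1]`; with `keep_cache`, a list `outputs` + `cache`.
#' @export
translator_forward <- function(G, x, training = FALSE, keep_cache = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  if (d[1] %% 64L != 0L || d[2] %% 64L != 0L)
    stop("input spatial size must be divisible by 2^6")
  if (d[3] != G$cfg$in_ch) stop("wrong number of input channels")
  caches <- list(enc = vector("list", 6L), dec = vector("list", 5L),
                 heads = list())
  feats <- vector("list", 6L)
  h <- x
  for (i in seq_len(6L)) {
    b <- G$enc[[i]]
    cf <- conv_forward(b$conv, h, training)
    bf <- bn_forward(b$bn, cf$y, training)
    rf <- relu_forward(bf$y)
    h <- rf$y
    feats[[i]] <- h
    caches$enc[[i]] <- list(conv = cf$cache, bn = bf$cache, relu = rf$cache)
  }
  dec_out <- vector("list", 5L)
  skips <- list(NULL, feats[[5L]], feats[[4L]], feats[[3L]], feats[[2L]])
  for (j in seq_len(5L)) {
    b <- G$dec[[j]]
    if (b$upsample) {
      hu <- cpp_upsample_nn(h, 2L)
      hin <- concat_ch(hu, skips[[j]])
      nsplit <- dim(hu)[3]
    } else {
      hin <- h; nsplit <- NA_integer_
    }
    cf <- conv_forward(b$conv, hin, training)
    bf <- bn_forward(b$bn, cf$y, training)
    rf <- relu_forward(bf$y)
    h <- rf$y
    dec_out[[j]] <- h
    caches$dec[[j]] <- list(conv = cf$cache, bn = bf$cache, relu = rf$cache,
                            nsplit = nsplit)
  }
  head_src <- list(full = dec_out[[5L]], half = dec_out[[4L]],
                   quarter = dec_out[[3L]])
  outputs <- list()
  for (nm in names(G$heads)) {
    cf <- conv_forward(G$heads[[nm]], head_src[[nm]], training)
    outputs[[nm]] <- sigmoid(cf$y)
    caches$heads[[nm]] <- list(conv = cf$cache, y = outputs[[nm]])
  }
  wanted <- c("full", "half", "quarter")[match(G$cfg$scales, c(1, 0.5, 0.25))]
  outputs <- outputs[wanted]
  if (keep_cache) list(outputs = outputs, cache = caches) else outputs
}

# backward through the translator; douts is a named list (full/half/quarter)
# of gradients w.r.t. the post-sigmoid outputs (NULL entries allowed)
translator_backward <- function(G, cache, douts) {
  grads <- vector("list", length(G$layers))
  li <- function(part, j, which) {
    # flat index into G$layers: enc pairs, dec pairs, then heads
    base <- switch(part, enc = (j - 1L) * 2L, dec = 12L + (j - 1L) * 2L,
                   head = 22L + j)
    base + switch(which, conv = 1L, bn = 2L, head = 0L)
  }
  ddec <- vector("list", 5L)       # grads w.r.t. dec_out[[j]]
  hj <- c(full = 5L, half = 4L, quarter = 3L)
  for (nm in names(douts)) {
    if (is.null(douts[[nm]])) next
    hc <- cache$heads[[nm]]
    dz <- douts[[nm]] * hc$y * (1 - hc$y)
    k <- which(names(G$heads) == nm)
    cb <- conv_backward(G$heads[[nm]], hc$conv, dz)
    grads[[li("head", k, "head")]] <- cb$grads
    j <- hj[[nm]]
    ddec[[j]] <- add_tensor(ddec[[j]], cb$dx)
  }
  dskips <- vector("list", 6L)     # grads flowing into encoder features
  dh <- NULL
  skip_idx <- c(NA, 5L, 4L, 3L, 2L)
  for (j in 5:1) {
    g <- add_tensor(ddec[[j]], dh)
    if (is.null(g)) { dh <- NULL; next }
    b <- G$dec[[j]]; cc <- cache$dec[[j]]
    g <- relu_backward(cc$relu, g)
    bb <- bn_backward(b$bn, cc$bn, g)
    grads[[li("dec", j, "bn")]] <- bb$grads
    cb <- conv_backward(b$conv, cc$conv, bb$dx)
    grads[[li("dec", j, "conv")]] <- cb$grads
    if (b$upsample) {
      ns <- cc$nsplit
      dup <- cb$dx[, , seq_len(ns), , drop = FALSE]
      dskip <- cb$dx[, , -seq_len(ns), , drop = FALSE]
      si <- skip_idx[j]
      dskips[[si]] <- add_tensor(dskips[[si]], dskip)
      dh <- cpp_upsample_nn_bwd(dup, 2L)
    } else {
      dh <- cb$dx
    }
  }
  denc_next <- dh                  # gradient into enc block 6 output
  for (i in 6:1) {
    g <- add_tensor(denc_next, dskips[[i]])
    b <- G$enc[[i]]; cc <- cache$enc[[i]]
    g <- relu_backward(cc$relu, g)
    bb <- bn_backward(b$bn, cc$bn, g)
    grads[[li("enc", i, "bn")]] <- bb$grads
    cb <- conv_backward(b$conv, cc$conv, bb$dx, need_dx = i > 1L)
    grads[[li("enc", i, "conv")]] <- cb$grads
    denc_next <- cb$dx
  }
  grads
}

add_tensor <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  a + b
}

#' Discriminator configuration
#'
#' Six conv -> spectral-norm -> ReLU blocks followed by a spectral-normalized
#' 1x1 conv and global mean, scoring a marker stack conditioned on the H&E
#' image (average-pooled to the marker grid and channel-concatenated).
#'
#' @param marker_ch number of marker channels scored.
#' @param cond_ch number of conditioning channels (3 for RGB H&E).
#' @param base_width first block width.
#' @param strides per-block strides (adapt to the input size so the spatial
#'   extent never collapses below 1).
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(marker_ch = 11L, cond_ch = 3L,
                                 base_width = 32L,
                                 strides = c(2L, 2L, 2L, 2L, 2L, 2L)) {
  stopifnot(length(strides) == 6L, all(strides %in% c(1L, 2L)))
  structure(list(marker_ch = as.integer(marker_ch),
                 cond_ch = as.integer(cond_ch),
                 base_width = as.integer(base_width),
                 strides = as.integer(strides)),
            class = "discriminator_config")
}

#' Build the conditional discriminator
#'
#' @param config a [discriminator_config()].
#' @return an environment holding the network.
#' @export
build_discriminator <- function(config = discriminator_config()) {
  w <- config$base_width
  widths <- w * c(1L, 2L, 4L, 4L, 4L, 4L)
  D <- new.env(parent = emptyenv())
  D$cfg <- config
  in_ch <- config$marker_ch + config$cond_ch
  D$blocks <- lapply(seq_len(6L), function(i) {
    cin <- if (i == 1L) in_ch else widths[i - 1L]
    new_conv(cin, widths[i], k = 3L, stride = config$strides[i], sn = TRUE)
  })
  D$head <- new_conv(widths[6L], 1L, k = 1L, stride = 1L, pad = 0L, sn = TRUE)
  D$layers <- c(D$blocks, list(D$head))
  D
}

# conditioning: pool the H&E image to the marker grid and concatenate
disc_input <- function(D, y, x_he) {
  y <- as_batch(y); x_he <- as_batch(x_he)
  f <- dim(x_he)[1] %/% dim(y)[1]
  if (dim(x_he)[1] != f * dim(y)[1] || dim(x_he)[2] != f * dim(y)[2])
    stop("H&E and marker grids are spatially incompatible")
  xc <- if (f > 1L) cpp_avgpool(x_he, f) else x_he
  concat_ch(y, xc)
}

#' Score a marker stack with the conditional discriminator
#'
#' @param D discriminator from [build_discriminator()].
#' @param y marker stack (H, W, C) or batch; `x_he` conditioning H&E image on
#'   the grid finer by the resolution factor.
#' @param training training mode (spectral-norm power iteration updates).
#' @return list `scores` (one per batch sample) and `cache`.
#' @export
disc_forward <- function(D, y, x_he, training = FALSE) {
  inp <- disc_input(D, y, x_he)
  caches <- vector("list", 6L)
  h <- inp
  for (i in seq_len(6L)) {
    cf <- conv_forward(D$blocks[[i]], h, training)
    rf <- relu_forward(cf$y)
    h <- rf$y
    caches[[i]] <- list(conv = cf$cache, relu = rf$cache)
  }
  hf <- conv_forward(D$head, h, training)
  d <- dim(hf$y)
  scores <- apply(hf$y, 4, mean)
  list(scores = scores,
       cache = list(blocks = caches, head = hf$cache, out_dim = d,
                    marker_ch = dim(y)[3]))
}

# backward from per-sample score gradients; returns flat grads (7 layers) and
# the gradient w.r.t. the marker input y
disc_backward <- function(D, cache, dscores, need_dy = TRUE,
                          need_grads = TRUE) {
  d <- cache$out_dim
  P <- d[1] * d[2]
  dz <- array(0, dim = d)
  for (n in seq_len(d[4])) dz[, , 1L, n] <- dscores[n] / P
  grads <- vector("list", 7L)
  if (need_grads) {
    cb <- conv_backward(D$head, cache$head, dz)
    grads[[7L]] <- cb$grads
    dh <- cb$dx
  } else {
    dh <- cpp_conv2d_bwd_data(dz, cache$head$wb, D$head$stride, D$head$pad,
                              cache$head$hw[1], cache$head$hw[2])
  }
  for (i in 6:1) {
    cc <- cache$blocks[[i]]
    dh <- relu_backward(cc$relu, dh)
    if (need_grads) {
      cb <- conv_backward(D$blocks[[i]], cc$conv, dh,
                          need_dx = need_dy || i > 1L)
      grads[[i]] <- cb$grads
      dh <- cb$dx
    } else {
      dh <- cpp_conv2d_bwd_data(dh, cc$conv$wb, D$blocks[[i]]$stride,
                                D$blocks[[i]]$pad, cc$conv$hw[1], cc$conv$hw[2])
    }
  }
  dy <- if (need_dy) dh[, , seq_len(cache$marker_ch), , drop = FALSE] else NULL
  list(grads = grads, dy = dy)
}

# R1 penalty and its exact parameter gradient for the piecewise-linear
# discriminator: value = mean_n ||grad_y D(y_n | x_n)||^2. The parameter
# gradient is obtained by an adjoint sweep over the backward (input-gradient)
# graph with the ReLU masks frozen — exact almost everywhere.
disc_r1 <- function(D, y, x_he, need_grads = TRUE) {
  fw <- disc_forward(D, y, x_he, training = FALSE)
  cache <- fw$cache
  N <- cache$out_dim[4]
  P <- cache$out_dim[1] * cache$out_dim[2]
  # backward-data pass, keeping the masked deltas entering each conv
  dz_head <- array(1 / P, dim = cache$out_dim)
  deltas <- vector("list", 7L)     # delta entering conv l (its output-side grad)
  deltas[[7L]] <- dz_head
  dh <- cpp_conv2d_bwd_data(dz_head, cache$head$wb, D$head$stride, D$head$pad,
                            cache$head$hw[1], cache$head$hw[2])
  for (i in 6:1) {
    cc <- cache$blocks[[i]]
    dh <- relu_backward(cc$relu, dh)
    deltas[[i]] <- dh
    dh <- cpp_conv2d_bwd_data(dh, cc$conv$wb, D$blocks[[i]]$stride,
                              D$blocks[[i]]$pad, cc$conv$hw[1], cc$conv$hw[2])
  }
  mc <- cache$marker_ch
  g_y <- dh[, , seq_len(mc), , drop = FALSE]
  r1 <- sum(g_y^2) / N
  if (!need_grads) return(list(value = r1, grads = NULL))
  # adjoint sweep: u starts at dR1/d(input gradient), zero on conditioning chans
  u <- dh * 0
  u[, , seq_len(mc), ] <- (2 / N) * g_y
  grads <- vector("list", 7L)
  layers <- c(D$blocks, list(D$head))
  ccs <- c(lapply(cache$blocks, `[[`, "conv"), list(cache$head))
  for (i in seq_len(7L)) {
    L <- layers[[i]]; cc <- ccs[[i]]
    gw <- cpp_conv2d_bwd_weights(u, deltas[[i]], L$k, L$stride, L$pad)
    dwb <- gw$dw
    s <- cc$sn
    inner <- sum(dwb * cc$wb)
    dw <- dwb / s$sigma - (inner / s$sigma) * array(s$v %o% s$u, dim = dim(L$w))
    grads[[i]] <- list(w = dw)
    if (i < 7L) {
      u <- cpp_conv2d_fwd(u, cc$wb, numeric(L$cout), L$stride, L$pad)
      u <- relu_backward(cache$blocks[[i]]$relu, u)   # mask application
    }
  }
  list(value = r1, grads = grads)
}

# ---- fixed contrastive feature encoder -----------------------------------

# A small conv encoder with fixed random weights plus per-layer 1x1 projection
# heads; used to embed pseudo-RGB marker channels for the patch-wise
# contrastive loss. Weights are drawn once at construction and never trained.
build_patch_encoder <- function(in_ch = 3L, widths = c(16L, 32L, 64L),
                                proj_dim = 32L, seed = 7L) {
  old <- .Random.seed_safe()
  set.seed(seed)
  E <- new.env(parent = emptyenv())
  E$blocks <- lapply(seq_along(widths), function(i) {
    cin <- if (i == 1L) in_ch else widths[i - 1L]
    new_conv(cin, widths[i], k = 3L, stride = 2L)
  })
  E$proj <- lapply(widths, function(wd)
    new_conv(wd, proj_dim, k = 1L, stride = 1L, pad = 0L))
  E$n_layers <- length(widths)
  E$proj_dim <- proj_dim
  .Random.seed_restore(old)
  E
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

encoder_forward <- function(E, x) {
  x <- as_batch(x)
  feats <- vector("list", E$n_layers)
  caches <- vector("list", E$n_layers)
  h <- x
  for (i in seq_len(E$n_layers)) {
    cf <- conv_forward(E$blocks[[i]], h)
    rf <- relu_forward(cf$y)
    h <- rf$y
    pf <- conv_forward(E$proj[[i]], h)
    feats[[i]] <- pf$y
    caches[[i]] <- list(conv = cf$cache, relu = rf$cache, proj = pf$cache)
  }
  list(feats = feats, cache = caches)
}

# backward to the encoder input given per-layer gradients on projected features
encoder_backward <- function(E, cache, dfeats) {
  dh <- NULL
  for (i in E$n_layers:1) {
    cc <- cache[[i]]
    g <- dh
    if (!is.null(dfeats[[i]])) {
      L <- E$proj[[i]]
      dproj <- cpp_conv2d_bwd_data(dfeats[[i]], cc$proj$wb, L$stride, L$pad,
                                   cc$proj$hw[1], cc$proj$hw[2])
      g <- add_tensor(g, dproj)
    }
    if (is.null(g)) next
    g <- relu_backward(cc$relu, g)
    L <- E$blocks[[i]]
    dh <- cpp_conv2d_bwd_data(g, cc$conv$wb, L$stride, L$pad,
                              cc$conv$hw[1], cc$conv$hw[2])
  }
  dh
}
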