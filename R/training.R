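# Adversarial training of the H&E -> marker translator: paired patch sampling,
# augmentation, the alternating D/G loop with Adam, logging and checkpoints.
# `plexgen_fit()` is the model-fitting entry point and returns a classed model
# with predict / print / summary / plot methods.

#' Training configuration
#'
#' The `"paper"` profile carries the full-scale settings (100 epochs, Adam
#' beta1 0.5 / beta2 0.999, lr 0.004 (G) and 0.0008 (D), batch 16, 1024 px H&E
#' / 256 px marker patches); the `"desk"` profile is the CI-scale preset
#' (128 -> 32 px patches, batch 4, narrow widths, ~400 steps) that trains in
#' minutes on one CPU.
#'
#' @param preset "desk" or "paper".
#' @param steps total training steps (overrides the preset).
#' @param batch_size patches per step.
#' @param he_patch,marker_patch patch sides in px (ratio must equal the H&E
#'   scale factor).
#' @param lr_g,lr_d,beta1,beta2 Adam settings for translator / discriminator.
#' @param base_width,disc_width network widths.
#' @param weights a [loss_weights()].
#' @param augment_flags list: `flip`, `rot90`, `color`.
#' @param log_every,checkpoint_every cadences in steps.
#' @param seed RNG seed.
#' @return a `plexgen_train_config`.
#' @export
train_config <- function(preset = c("desk", "paper"), steps = NULL,
                         batch_size = NULL, he_patch = NULL, marker_patch = NULL,
                         lr_g = 0.004, lr_d = 0.0008, beta1 = 0.5, beta2 = 0.999,
                         base_width = NULL, disc_width = NULL,
                         weights = loss_weights(),
                         augment_flags = list(flip = TRUE, rot90 = TRUE, color = TRUE),
                         log_every = 10L, checkpoint_every = Inf, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "desk")
    list(steps = 400L, batch_size = 4L, he_patch = 128L, marker_patch = 32L,
         base_width = 8L, disc_width = 16L)
  else
    list(steps = 10000L, batch_size = 16L, he_patch = 1024L, marker_patch = 256L,
         base_width = 32L, disc_width = 32L)
  cfg <- list(preset = preset,
              steps = as.integer(steps %||% def$steps),
              batch_size = as.integer(batch_size %||% def$batch_size),
              he_patch = as.integer(he_patch %||% def$he_patch),
              marker_patch = as.integer(marker_patch %||% def$marker_patch),
              lr_g = lr_g, lr_d = lr_d, beta1 = beta1, beta2 = beta2,
              base_width = as.integer(base_width %||% def$base_width),
              disc_width = as.integer(disc_width %||% def$disc_width),
              weights = weights, augment_flags = augment_flags,
              log_every = as.integer(log_every),
              checkpoint_every = checkpoint_every, seed = as.integer(seed))
  if (cfg$he_patch %% cfg$marker_patch != 0L)
    stop("he_patch must be an integer multiple of marker_patch")
  if (lr_g <= 0 || lr_d <= 0) stop("learning rates must be positive")
  structure(cfg, class = "plexgen_train_config")
}

#' Sample a spatially corresponding H&E / marker patch pair
#'
#' A random marker-grid origin is drawn; the H&E crop starts at the origin
#' scaled by the resolution factor, so the crops correspond under the factor.
#'
#' @param roi a `paired_roi` (or list with `he` and `markers` arrays).
#' @param he_patch,marker_patch crop sides.
#' @return list `he`, `markers`, `origin` (0-based marker-grid origin).
#' @export
sample_training_pair <- function(roi, he_patch = 128L, marker_patch = 32L) {
  f <- he_patch %/% marker_patch
  md <- dim(roi$markers)
  if (md[1] < marker_patch || md[2] < marker_patch ||
      dim(roi$he)[1] < he_patch)
    stop("ROI smaller than the requested crop")
  oy <- sample.int(md[1] - marker_patch + 1L, 1L) - 1L
  ox <- sample.int(md[2] - marker_patch + 1L, 1L) - 1L
  list(he = roi$he[(oy * f + 1):(oy * f + he_patch),
                   (ox * f + 1):(ox * f + he_patch), , drop = FALSE],
       markers = roi$markers[(oy + 1):(oy + marker_patch),
                             (ox + 1):(ox + marker_patch), , drop = FALSE],
       origin = c(x = ox, y = oy))
}

flip_arr <- function(a, horizontal) {
  if (horizontal) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  else a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
}

rot90_arr <- function(a, k) {
  d <- dim(a)
  out <- NULL
  for (c3 in seq_len(d[3])) {
    r <- rot90_mat(a[, , c3], k)
    if (is.null(out)) out <- array(0, dim = c(dim(r), d[3]))
    out[, , c3] <- r
  }
  out
}

#' Augment a patch pair
#'
#' Geometric transforms (flips, quarter rotations) are applied consistently to
#' both images; colour jitter perturbs the H&E only. All transforms are
#' label-preserving; disabled flags give the identity mapping.
#'
#' @param pair list `he`, `markers`.
#' @param flags list with logicals `flip`, `rot90`, `color`.
#' @return augmented pair.
#' @export
augment <- function(pair, flags = list(flip = TRUE, rot90 = TRUE, color = TRUE)) {
  he <- pair$he; mk <- pair$markers
  if (isTRUE(flags$flip)) {
    if (stats::runif(1) < 0.5) { hz <- stats::runif(1) < 0.5
      he <- flip_arr(he, hz); mk <- flip_arr(mk, hz) }
  }
  if (isTRUE(flags$rot90)) {
    k <- sample(0:3, 1L)
    if (k > 0L) { he <- rot90_arr(he, k); mk <- rot90_arr(mk, k) }
  }
  if (isTRUE(flags$color)) {
    gain <- stats::runif(3, 0.9, 1.1)
    shift <- stats::runif(1, -0.03, 0.03)
    for (c3 in 1:3) he[, , c3] <- he[, , c3] * gain[c3] + shift
    he <- pmin(pmax(he, 0), 1)
  }
  pair$he <- he; pair$markers <- mk
  pair
}

# assemble a batch of pairs into 4-d tensors
.make_batch <- function(rois, cfg) {
  n <- cfg$batch_size
  he <- NULL; mk <- NULL
  for (b in seq_len(n)) {
    roi <- rois[[sample.int(length(rois), 1L)]]
    pr <- sample_training_pair(roi, cfg$he_patch, cfg$marker_patch)
    pr <- augment(pr, cfg$augment_flags)
    if (is.null(he)) {
      he <- array(0, dim = c(dim(pr$he), n))
      mk <- array(0, dim = c(dim(pr$markers), n))
    }
    he[, , , b] <- pr$he
    mk[, , , b] <- pr$markers
  }
  list(he = he, markers = mk)
}

.disc_strides <- function(marker_patch) {
  n2 <- max(1L, min(6L, as.integer(log2(marker_patch)) - 2L))
  c(rep(2L, n2), rep(1L, 6L - n2))
}

#' Fit the H&E -> marker translator
#'
#' Alternating adversarial training: each step updates the discriminator on
#' the least-squares adversarial loss plus the R1 penalty, then the translator
#' on the multiscale adversarial loss plus the Gaussian pyramid loss and the
#' patch-wise contrastive loss (weights from `config$weights`). Lower-scale
#' translator outputs are upsampled to the full marker grid before being
#' scored by the single shared discriminator.
#'
#' @param rois list of paired ROIs ([simulate_paired_roi()] objects or lists
#'   with `he` and `markers` arrays).
#' @param config a [train_config()].
#' @param resume a previously fitted `plexgen` model to continue training.
#' @return a `plexgen` model: translator, discriminator, per-step loss log,
#'   configuration, and a frozen snapshot of the untrained translator.
#' @export
plexgen_fit <- function(rois, config = train_config(), resume = NULL) {
  cfg <- config
  mk_ch <- dim(rois[[1]]$markers)[3]
  f <- cfg$he_patch %/% cfg$marker_patch
  if (is.null(resume)) {
    set.seed(cfg$seed)
    G <- build_translator(translator_config(out_ch = mk_ch,
                                            base_width = cfg$base_width,
                                            he_scale_factor = f))
    D <- build_discriminator(discriminator_config(
      marker_ch = mk_ch, base_width = cfg$disc_width,
      strides = .disc_strides(cfg$marker_patch)))
    enc <- if (cfg$weights$lambda_contrast > 0) build_patch_encoder() else NULL
    G0 <- lapply(G$layers, clone_layer)
    t_g <- 0L; t_d <- 0L; step0 <- 0L
    log <- NULL
    checkpoints <- list()
  } else {
    G <- resume$G; D <- resume$D; enc <- resume$encoder
    G0 <- resume$untrained_layers
    t_g <- resume$opt_t["g"]; t_d <- resume$opt_t["d"]
    step0 <- resume$steps_done
    log <- resume$log
    checkpoints <- resume$checkpoints
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  }
  lw <- cfg$weights
  scale_f <- c(full = 1L, half = 2L, quarter = 4L)
  for (step in (step0 + 1L):(step0 + cfg$steps)) {
    batch <- .make_batch(rois, cfg)
    gw <- translator_forward(G, batch$he, training = TRUE, keep_cache = TRUE)
    fakes_up <- lapply(names(gw$outputs), function(nm) {
      fsc <- scale_f[[nm]]
      if (fsc > 1L) cpp_upsample_nn(gw$outputs[[nm]], fsc) else gw$outputs[[nm]]
    })
    names(fakes_up) <- names(gw$outputs)

    ## -- discriminator update ------------------------------------------
    fr <- disc_forward(D, batch$markers, batch$he, training = TRUE)
    ff <- lapply(fakes_up, function(yf) disc_forward(D, yf, batch$he))
    adv_d <- adv_loss_d(fr$scores, lapply(ff, `[[`, "scores"))
    d_grads <- disc_backward(D, fr$cache, attr(adv_d, "dreal"),
                             need_dy = FALSE)$grads
    dfake <- attr(adv_d, "dfake")
    for (i in seq_along(ff)) {
      g2 <- disc_backward(D, ff[[i]]$cache, dfake[[i]], need_dy = FALSE)$grads
      d_grads <- Map(add_grads, d_grads, g2)
    }
    r1_val <- 0
    if (lw$lambda_r1 > 0) {
      r1 <- disc_r1(D, batch$markers, batch$he)
      r1_val <- r1$value
      d_grads <- Map(function(a, b) {
        if (!is.null(b)) a$w <- a$w + lw$lambda_r1 * b$w
        a
      }, d_grads, r1$grads)
    }
    t_d <- t_d + 1L
    adam_update(D$layers, d_grads, t_d, cfg$lr_d, cfg$beta1, cfg$beta2)

    ## -- translator update ---------------------------------------------
    ff2 <- lapply(fakes_up, function(yf) disc_forward(D, yf, batch$he))
    adv_g <- adv_loss_g(lapply(ff2, `[[`, "scores"))
    dsc <- attr(adv_g, "dscores")
    douts <- list()
    for (nm in names(fakes_up)) {
      dy <- disc_backward(D, ff2[[nm]]$cache, dsc[[nm]],
                          need_grads = FALSE, need_dy = TRUE)$dy
      fsc <- scale_f[[nm]]
      douts[[nm]] <- if (fsc > 1L) cpp_upsample_nn_bwd(dy, fsc) else dy
    }
    gp_val <- 0
    if (lw$lambda_gp > 0) {
      pl <- pyramid_loss(batch$markers, gw$outputs$full,
                         weights = lw$octave_weights, n_gs = lw$n_gs,
                         sigma = lw$sigma, with_grad = TRUE)
      gp_val <- as.numeric(pl)
      douts$full <- douts$full + lw$lambda_gp * attr(pl, "grad")
    }
    ct_val <- 0
    if (lw$lambda_contrast > 0) {
      cl <- patch_contrastive_loss(gw$outputs$full, batch$markers, enc, lw,
                                   step = step, total_steps = step0 + cfg$steps,
                                   with_grad = TRUE)
      ct_val <- as.numeric(cl)
      douts$full <- douts$full + lw$lambda_contrast * attr(cl, "grad")
    }
    g_grads <- translator_backward(G, gw$cache, douts)
    t_g <- t_g + 1L
    adam_update(G$layers, g_grads, t_g, cfg$lr_g, cfg$beta1, cfg$beta2)

    terms <- c(adv_g = as.numeric(adv_g), gp = gp_val, contrast = ct_val,
               adv_d = as.numeric(adv_d), r1 = r1_val)
    if (any(!is.finite(terms)))
      stop("non-finite loss at step ", step, ": ",
           paste(names(terms)[!is.finite(terms)], collapse = ", "))
    if (step %% cfg$log_every == 0L || step == step0 + cfg$steps) {
      tot <- total_losses(terms["adv_g"], terms["gp"], terms["contrast"],
                          terms["adv_d"], terms["r1"], lw)
      log <- rbind(log, data.frame(step = step, t(terms),
                                   L_G = tot$L_G, L_D = tot$L_D))
    }
    if (is.finite(cfg$checkpoint_every) && step %% cfg$checkpoint_every == 0L)
      checkpoints[[as.character(step)]] <- lapply(G$layers, clone_layer)
  }
  structure(list(G = G, D = D, encoder = enc, config = cfg, log = log,
                 untrained_layers = G0, opt_t = c(g = t_g, d = t_d),
                 steps_done = step0 + cfg$steps, marker_ch = mk_ch,
                 he_scale_factor = f, checkpoints = checkpoints,
                 rng_state = get(".Random.seed", envir = globalenv())),
            class = "plexgen")
}

#' Predict marker stacks from H&E input
#'
#' @param object a fitted `plexgen` model.
#' @param he H&E array (H x W x 3), spatial size divisible by 64.
#' @param scale which output head ("full", "half" or "quarter").
#' @param untrained use the frozen initialization snapshot instead of the
#'   trained weights (baseline comparisons).
#' @param ... unused.
#' @return marker array (H/f x W/f x C) in `[0, 1]`.
#' @export
predict.plexgen <- function(object, he, scale = "full", untrained = FALSE, ...) {
  G <- object$G
  if (untrained) {
    G <- build_translator(G$cfg)
    for (i in seq_along(G$layers))
      for (nm in ls(object$untrained_layers[[i]], all.names = TRUE))
        G$layers[[i]][[nm]] <- object$untrained_layers[[i]][[nm]]
  }
  out <- translator_forward(G, as_batch(he), training = FALSE)[[scale]]
  d <- dim(out)
  array(out, dim = d[1:3])
}

#' @export
print.plexgen <- function(x, ...) {
  cat("H&E -> marker translator (", x$marker_ch, " channels, x",
      x$he_scale_factor, " resolution factor)\n", sep = "")
  cat("  preset:", x$config$preset, "| steps:", x$steps_done,
      "| batch:", x$config$batch_size, "\n")
  if (!is.null(x$log)) {
    last <- utils::tail(x$log, 1)
    cat("  final losses: L_G =", signif(last$L_G, 4),
        " L_D =", signif(last$L_D, 4), "\n")
  }
  invisible(x)
}

#' @export
summary.plexgen <- function(object, ...) {
  print(object)
  cat("\nloss log (head/tail):\n")
  print(utils::head(object$log, 3), row.names = FALSE)
  print(utils::tail(object$log, 3), row.names = FALSE)
  invisible(object)
}

#' @export
plot.plexgen <- function(x, ...) {
  if (is.null(x$log)) stop("no training log")
  graphics::matplot(x$log$step, cbind(x$log$L_G, x$log$L_D), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "step", ylab = "loss", ...)
  graphics::legend("topright", c("L_G", "L_D"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted model
#'
#' @param model a `plexgen`; `path` file path (RDS).
#' @return `load_plexgen` returns the model.
#' @export
save_plexgen <- function(model, path) {
  snap <- function(layers) lapply(layers, function(L)
    as.list(L)[ls(L, all.names = TRUE)])
  obj <- list(G_cfg = model$G$cfg, D_cfg = model$D$cfg,
              G_state = snap(model$G$layers), D_state = snap(model$D$layers),
              config = model$config, log = model$log,
              untrained = lapply(model$untrained_layers, function(L)
                as.list(L)[ls(L, all.names = TRUE)]),
              opt_t = model$opt_t, steps_done = model$steps_done,
              marker_ch = model$marker_ch,
              he_scale_factor = model$he_scale_factor,
              rng_state = model$rng_state, seed = model$config$seed)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_plexgen
#' @export
load_plexgen <- function(path) {
  obj <- readRDS(path)
  G <- build_translator(obj$G_cfg)
  D <- build_discriminator(obj$D_cfg)
  restore <- function(layers, states)
    for (i in seq_along(layers))
      for (nm in names(states[[i]])) layers[[i]][[nm]] <- states[[i]][[nm]]
  restore(G$layers, obj$G_state)
  restore(D$layers, obj$D_state)
  G0 <- lapply(seq_along(G$layers), function(i) {
    E <- new.env(parent = emptyenv())
    for (nm in names(obj$untrained[[i]])) E[[nm]] <- obj$untrained[[i]][[nm]]
    E
  })
  enc <- if (obj$config$weights$lambda_contrast > 0) build_patch_encoder() else NULL
  structure(list(G = G, D = D, encoder = enc, config = obj$config,
                 log = obj$log, untrained_layers = G0, opt_t = obj$opt_t,
                 steps_done = obj$steps_done, marker_ch = obj$marker_ch,
                 he_scale_factor = obj$he_scale_factor, checkpoints = list(),
                 rng_state = obj$rng_state),
            class = "plexgen")
}
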