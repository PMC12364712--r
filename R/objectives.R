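# Training objectives: multiscale least-squares adversarial losses, Gaussian
# pyramid reconstruction loss, adaptive patch-wise contrastive (InfoNCE) loss,
# and the R1 gradient penalty. Each loss exposes both its value and, where the
# trainer needs it, an analytic gradient.

#' Loss weights and hyperparameters
#'
#' Defaults: pyramid weight 5, contrastive weight 1, R1 weight 1; 3 pyramid
#' octaves with 3 Gaussian smoothings (sigma 1) per octave and unit per-octave
#' weights; 64 contrastive patches per feature layer at temperature 0.07 with
#' a linear adaptive-weight ramp.
#'
#' @param lambda_gp weight of the Gaussian pyramid loss in the translator loss.
#' @param lambda_contrast weight of the patch-wise contrastive loss.
#' @param lambda_r1 weight of the R1 gradient penalty in the discriminator loss.
#' @param n_octaves,n_gs,sigma,octave_weights Gaussian pyramid settings.
#' @param tau,n_patch contrastive temperature and patches per feature layer.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda_gp = 5.0, lambda_contrast = 1.0,
                         lambda_r1 = 1.0, n_octaves = 3L, n_gs = 3L,
                         sigma = 1, octave_weights = rep(1, n_octaves),
                         tau = 0.07, n_patch = 64L) {
  stopifnot(lambda_gp >= 0, lambda_contrast >= 0, lambda_r1 >= 0,
            all(octave_weights >= 0), tau > 0)
  structure(list(lambda_gp = lambda_gp, lambda_contrast = lambda_contrast,
                 lambda_r1 = lambda_r1, n_octaves = as.integer(n_octaves),
                 n_gs = as.integer(n_gs), sigma = sigma,
                 octave_weights = octave_weights, tau = tau,
                 n_patch = as.integer(n_patch)),
            class = "loss_weights")
}

#' Multiscale least-squares adversarial losses
#'
#' Binary coding: real = 1, generated = 0. The translator loss averages
#' `(D(G^(s)(x)|x) - 1)^2` over scales; the discriminator loss averages
#' `(D(y|x) - 1)^2 + D(G^(s)(x)|x)^2` over scales.
#'
#' @param scores_fake list (one element per scale) of per-sample discriminator
#'   scores for generated images.
#' @param scores_real per-sample scores for real images (`adv_loss_d` only).
#' @return scalar loss; `attr(, "dscores")` carries per-scale score gradients.
#' @export
adv_loss_g <- function(scores_fake) {
  S <- length(scores_fake)
  if (S == 0L) stop("empty scale set")
  terms <- vapply(scores_fake, function(s) mean((s - 1)^2), numeric(1))
  val <- mean(terms)
  dsc <- lapply(scores_fake, function(s) 2 * (s - 1) / (S * length(s)))
  structure(val, dscores = dsc)
}

#' @rdname adv_loss_g
#' @export
adv_loss_d <- function(scores_real, scores_fake) {
  S <- length(scores_fake)
  if (S == 0L) stop("empty scale set")
  real_term <- mean((scores_real - 1)^2)
  fake_terms <- vapply(scores_fake, function(s) mean(s^2), numeric(1))
  val <- mean(real_term + fake_terms)
  structure(val,
            dreal = 2 * (scores_real - 1) / length(scores_real),  # summed S times / S
            dfake = lapply(scores_fake, function(s) 2 * s / (S * length(s))))
}

gaussian_kernel_1d <- function(sigma, ksize = 2L * ceiling(2 * sigma) + 1L) {
  r <- (ksize - 1L) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian pyramid
#'
#' Builds octaves by iterated Gaussian smoothing and 2x decimation: the primary
#' layer of octave r+1 is the downsample of octave r after `n_gs` smoothings.
#'
#' @param image array (H, W[, C[, N]]).
#' @param n_octaves number of octaves requested.
#' @param n_gs smoothings per octave before the downsampling transition.
#' @param sigma Gaussian sigma (zero-padded separable kernel).
#' @param strict error (TRUE) or warn and truncate (FALSE) when the image is
#'   too small for the requested octaves.
#' @return list of per-octave primary layers (same array rank as the input).
#' @export
gaussian_pyramid <- function(image, n_octaves = 3L, n_gs = 3L, sigma = 1,
                             strict = FALSE) {
  nd <- length(dim(image) %||% dim(as.matrix(image)))
  x <- as_batch(if (is.null(dim(image))) as.matrix(image) else image)
  if (min(dim(x)[1:2]) < 2^(n_octaves - 1)) {
    msg <- "image too small for requested octaves"
    if (strict) stop(msg)
    n_octaves <- floor(log2(min(dim(x)[1:2]))) + 1L
    warning(paste0(msg, "; truncating to ", n_octaves))
  }
  kern <- gaussian_kernel_1d(sigma)
  primaries <- vector("list", n_octaves)
  cur <- x
  for (r in seq_len(n_octaves)) {
    primaries[[r]] <- .drop_rank(cur, nd)
    if (r < n_octaves) {
      sm <- cur
      for (i in seq_len(n_gs)) sm <- cpp_blur_sep(sm, kern)
      cur <- cpp_decimate(sm, 2L)
    }
  }
  primaries
}

.drop_rank <- function(x, nd) {
  d <- dim(x)
  if (nd <= 3L) dim(x) <- d[seq_len(max(nd, 2L))]
  x
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian pyramid loss
#'
#' Weighted sum over octaves of the mean absolute difference between the
#' per-octave primary layers of the target and generated images.
#'
#' @param y,y_hat arrays of identical shape.
#' @param weights per-octave weights.
#' @param n_gs,sigma pyramid construction settings.
#' @param with_grad also return the gradient w.r.t. `y_hat`.
#' @return scalar loss (with attribute `grad` when requested).
#' @export
pyramid_loss <- function(y, y_hat, weights = rep(1, 3L), n_gs = 3L, sigma = 1,
                         with_grad = FALSE) {
  if (!identical(dim(y), dim(y_hat))) stop("shape mismatch")
  n_oct <- length(weights)
  py <- gaussian_pyramid(as_batch(y), n_oct, n_gs, sigma)
  ph <- gaussian_pyramid(as_batch(y_hat), n_oct, n_gs, sigma)
  val <- 0
  grads_oct <- vector("list", n_oct)
  for (r in seq_len(n_oct)) {
    diff <- as_batch(ph[[r]]) - as_batch(py[[r]])
    val <- val + weights[r] * mean(abs(diff))
    if (with_grad)
      grads_oct[[r]] <- weights[r] * sign(diff) / length(diff)
  }
  if (!with_grad) return(val)
  # adjoint: propagate each octave gradient back to the full-resolution input
  kern <- gaussian_kernel_1d(sigma)
  hw <- vector("list", n_oct)
  hw[[1]] <- dim(as_batch(y))[1:2]
  for (r in seq_len(n_oct - 1L)) hw[[r + 1L]] <- ceiling(hw[[r]] / 2)
  g <- NULL
  for (r in n_oct:1) {
    gr <- grads_oct[[r]]
    if (r < n_oct && !is.null(g)) gr <- gr + g
    if (r > 1L) {
      g <- cpp_decimate_bwd(gr, 2L, hw[[r - 1L]][1], hw[[r - 1L]][2])
      for (i in seq_len(n_gs)) g <- cpp_blur_sep(g, kern)
    } else g <- gr
  }
  structure(val, grad = array(g, dim = dim(y_hat)))
}

#' InfoNCE objective
#'
#' `-log(exp(z.z+ / tau) / (exp(z.z+ / tau) + sum_n exp(z.z-_n / tau)))`.
#'
#' @param z anchor vector; `z_pos` positive; `z_neg` matrix (negatives in rows).
#' @param tau temperature.
#' @export
info_nce <- function(z, z_pos, z_neg, tau = 0.07) {
  lp <- sum(z * z_pos) / tau
  ln <- drop(z_neg %*% z) / tau
  m <- max(lp, ln)
  -(lp - m) + log(exp(lp - m) + sum(exp(ln - m)))
}

#' Adaptive patch-wise contrastive loss
#'
#' For every output channel, the channel is replicated to a pseudo-RGB image
#' and embedded with a fixed multi-layer conv encoder plus projection heads.
#' At `n_patch` shared pixel locations per feature layer, anchors (from the
#' generated image) are contrasted against their positives (same location in
#' the target) with the other locations' positives as negatives; each term is
#' weighted by the adaptive patch weight
#' `w_t = (1 - g(t/T)) + g(t/T) h(sim(anchor, positive))`.
#'
#' @param y_hat,y generated and target marker stacks (H, W, C[, N]).
#' @param encoder a patch encoder from `build_patch_encoder()`.
#' @param weights a [loss_weights()] (uses `tau`, `n_patch`).
#' @param step,total_steps current and total training step (schedule input).
#' @param schedule ramp `g(u)`; default linear.
#' @param h_fun weighting `h(u)`; default `clamp((u+1)/2, 0, 1)`.
#' @param with_grad also return the gradient w.r.t. `y_hat`.
#' @return scalar loss (attribute `grad` when requested).
#' @export
patch_contrastive_loss <- function(y_hat, y, encoder,
                                   weights = loss_weights(),
                                   step = 0L, total_steps = 1L,
                                   schedule = function(u) u,
                                   h_fun = function(u) pmin(pmax((u + 1) / 2, 0), 1),
                                   with_grad = FALSE) {
  if (weights$n_patch < 2L) stop("need at least 2 patches (no negatives otherwise)")
  y_hat <- as_batch(y_hat); y <- as_batch(y)
  if (!identical(dim(y_hat), dim(y))) stop("shape mismatch")
  C <- dim(y_hat)[3]; N <- dim(y_hat)[4]
  tau <- weights$tau; npc <- weights$n_patch
  gt <- schedule(step / total_steps)
  total <- 0
  dy_hat <- if (with_grad) y_hat * 0 else NULL
  for (ch in seq_len(C)) {
    rgb_hat <- y_hat[, , rep(ch, 3L), , drop = FALSE]
    rgb_gt <- y[, , rep(ch, 3L), , drop = FALSE]
    fa <- encoder_forward(encoder, rgb_hat)
    fp <- encoder_forward(encoder, rgb_gt)
    nl <- encoder$n_layers
    dfeats <- vector("list", nl)
    ch_loss <- 0
    for (l in seq_len(nl)) {
      Fh <- fa$feats[[l]]; Fg <- fp$feats[[l]]
      d <- dim(Fh)
      npick <- min(npc, d[1] * d[2])
      for (n in seq_len(N)) {
        idx <- sample.int(d[1] * d[2], npick)        # shared locations
        A <- matrix(0, npick, d[3]); P <- matrix(0, npick, d[3])
        hi <- (idx - 1L) %% d[1] + 1L; wi <- (idx - 1L) %/% d[1] + 1L
        for (q in seq_len(npick)) {
          A[q, ] <- Fh[hi[q], wi[q], , n]
          P[q, ] <- Fg[hi[q], wi[q], , n]
        }
        An <- A / pmax(sqrt(rowSums(A^2)), 1e-12)
        Pn <- P / pmax(sqrt(rowSums(P^2)), 1e-12)
        logits <- (An %*% t(Pn)) / tau               # npick x npick
        mx <- apply(logits, 1, max)
        lse <- mx + log(rowSums(exp(logits - mx)))
        li <- lse - diag(logits)                     # per-anchor InfoNCE
        simv <- rowSums(An * Pn)
        w <- (1 - gt) * 1 + gt * h_fun(simv)         # stop-gradient weight
        ch_loss <- ch_loss + sum(w * li) / (nl * npick * N)
        if (with_grad) {
          # d li / d logits = softmax - I (per row)
          sm <- exp(logits - lse)
          sm[cbind(seq_len(npick), seq_len(npick))] <-
            sm[cbind(seq_len(npick), seq_len(npick))] - 1
          dlog <- sm * (w / (nl * npick * N))
          dAn <- (dlog %*% Pn) / tau
          # through row L2 normalization of A
          nrm <- pmax(sqrt(rowSums(A^2)), 1e-12)
          dA <- (dAn - An * rowSums(dAn * An)) / nrm
          gmap <- if (is.null(dfeats[[l]])) Fh * 0 else dfeats[[l]]
          for (q in seq_len(npick))
            gmap[hi[q], wi[q], , n] <- gmap[hi[q], wi[q], , n] + dA[q, ]
          dfeats[[l]] <- gmap
        }
      }
    }
    total <- total + ch_loss
    if (with_grad) {
      din <- encoder_backward(encoder, fa$cache, dfeats)
      # pseudo-RGB replication: channel gradient is the sum over the 3 copies
      dy_hat[, , ch, ] <- dy_hat[, , ch, ] +
        din[, , 1, ] + din[, , 2, ] + din[, , 3, ]
    }
  }
  if (with_grad) structure(total, grad = dy_hat) else total
}

#' R1 gradient penalty
#'
#' Mean over the batch of the squared L2 norm of the gradient of the
#' discriminator score with respect to the real marker input.
#'
#' @param D discriminator from [build_discriminator()].
#' @param y real marker stack; `x_he` conditioning H&E image.
#' @export
r1_penalty <- function(D, y, x_he) {
  disc_r1(D, as_batch(y), as_batch(x_he), need_grads = FALSE)$value
}

#' Combine loss terms
#'
#' `L_G = L_G^adv + lambda_gp * L^gp + lambda_contrast * L^contrast` and
#' `L_D = L_D^adv + lambda_r1 * R1`.
#'
#' @param adv_g,gp,contrast,adv_d,r1 individual loss terms.
#' @param weights a [loss_weights()].
#' @return list with `L_G`, `L_D` and a per-term `breakdown`.
#' @export
total_losses <- function(adv_g, gp = 0, contrast = 0, adv_d = 0, r1 = 0,
                         weights = loss_weights()) {
  terms <- c(adv_g = as.numeric(adv_g), gp = as.numeric(gp),
             contrast = as.numeric(contrast), adv_d = as.numeric(adv_d),
             r1 = as.numeric(r1))
  if (any(!is.finite(terms)))
    stop("non-finite loss term(s): ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "))
  L_G <- terms["adv_g"] + weights$lambda_gp * terms["gp"] +
    weights$lambda_contrast * terms["contrast"]
  L_D <- terms["adv_d"] + weights$lambda_r1 * terms["r1"]
  list(L_G = unname(L_G), L_D = unname(L_D), breakdown = terms)
}
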