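# Minimal neural-network core: conv / batch-norm / activation layers with
# explicit forward and backward passes, spectral normalization, and Adam.
# Layers are environments (mutable state: weights, running stats, optimizer
# moments); batched tensors are arrays dim (H, W, C, N).

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 2-, 3- or 4-d array")
  x
}

#' @keywords internal
xavier_init <- function(k, cin, cout) {
  a <- sqrt(6 / (k * k * cin + k * k * cout))
  array(stats::runif(k * k * cin * cout, -a, a), dim = c(k, k, cin, cout))
}

new_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                     sn = FALSE, bias = TRUE) {
  L <- new.env(parent = emptyenv())
  L$type <- "conv"
  L$k <- as.integer(k); L$stride <- as.integer(stride); L$pad <- as.integer(pad)
  L$cin <- as.integer(cin); L$cout <- as.integer(cout)
  L$w <- xavier_init(k, cin, cout)
  L$b <- if (bias) numeric(cout) else NULL
  L$sn <- sn
  if (sn) L$u <- { u <- stats::rnorm(cout); u / sqrt(sum(u^2)) }
  L$params <- if (bias) c("w", "b") else "w"
  L
}

# weight matrix view (K x cout) used by spectral normalization
.w_mat <- function(w) {
  d <- dim(w)
  matrix(w, nrow = d[1] * d[2] * d[3], ncol = d[4])
}

# one power-iteration step; returns list(w_bar, sigma, u, v)
sn_normalize <- function(L, update = TRUE) {
  Wm <- .w_mat(L$w)                       # K x cout
  u <- L$u
  v <- drop(Wm %*% u); v <- v / max(sqrt(sum(v^2)), 1e-12)
  u2 <- drop(crossprod(Wm, v)); u2 <- u2 / max(sqrt(sum(u2^2)), 1e-12)
  sigma <- drop(crossprod(v, Wm %*% u2))
  if (update) L$u <- u2
  wb <- L$w / max(sigma, 1e-12)
  list(wb = wb, sigma = max(sigma, 1e-12), u = u2, v = v)
}

conv_forward <- function(L, x, training = FALSE) {
  if (L$sn) {
    s <- sn_normalize(L, update = training)
    wb <- s$wb
  } else {
    s <- NULL; wb <- L$w
  }
  b <- if (is.null(L$b)) numeric(L$cout) else L$b
  y <- cpp_conv2d_fwd(x, wb, b, L$stride, L$pad)
  list(y = y, cache = list(x = x, wb = wb, sn = s, hw = dim(x)[1:2]))
}

conv_backward <- function(L, cache, dy, need_dx = TRUE) {
  gw <- cpp_conv2d_bwd_weights(cache$x, dy, L$k, L$stride, L$pad)
  dwb <- gw$dw
  if (L$sn) {
    s <- cache$sn
    # w_bar = w / sigma, sigma = v' W u with u, v treated as constants
    inner <- sum(dwb * cache$wb)
    duv <- (s$v %o% s$u)                  # K x cout
    dw <- dwb / s$sigma - (inner / s$sigma) * array(duv, dim = dim(L$w))
  } else dw <- dwb
  grads <- list(w = dw)
  if (!is.null(L$b)) grads$b <- gw$db
  dx <- if (need_dx)
    cpp_conv2d_bwd_data(dy, cache$wb, L$stride, L$pad, cache$hw[1], cache$hw[2])
  else NULL
  list(dx = dx, grads = grads)
}

new_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  L <- new.env(parent = emptyenv())
  L$type <- "bn"; L$c <- as.integer(c)
  L$gamma <- rep(1, c); L$beta <- numeric(c)
  L$rm <- numeric(c); L$rv <- rep(1, c)
  L$momentum <- momentum; L$eps <- eps
  L$params <- c("gamma", "beta")
  L
}

bn_forward <- function(L, x, training = FALSE) {
  d <- dim(x); C <- d[3]
  xr <- x; dim(xr) <- c(d[1] * d[2], C, d[4])
  if (training) {
    mu <- numeric(C); va <- numeric(C)
    for (c in seq_len(C)) {
      s <- xr[, c, ]
      mu[c] <- mean(s); va[c] <- mean((s - mu[c])^2)
    }
    L$rm <- (1 - L$momentum) * L$rm + L$momentum * mu
    L$rv <- (1 - L$momentum) * L$rv + L$momentum * va
  } else {
    mu <- L$rm; va <- L$rv
  }
  ivstd <- 1 / sqrt(va + L$eps)
  xhat <- x
  for (c in seq_len(C)) xhat[, , c, ] <- (x[, , c, ] - mu[c]) * ivstd[c]
  y <- xhat
  for (c in seq_len(C)) y[, , c, ] <- L$gamma[c] * xhat[, , c, ] + L$beta[c]
  list(y = y, cache = list(xhat = xhat, ivstd = ivstd, training = training))
}

bn_backward <- function(L, cache, dy) {
  d <- dim(dy); C <- d[3]; m <- d[1] * d[2] * d[4]
  dgamma <- numeric(C); dbeta <- numeric(C)
  dx <- dy
  for (c in seq_len(C)) {
    xh <- cache$xhat[, , c, , drop = FALSE]
    g <- dy[, , c, , drop = FALSE]
    dgamma[c] <- sum(g * xh); dbeta[c] <- sum(g)
    dxhat <- g * L$gamma[c]
    if (cache$training) {
      dx[, , c, ] <- cache$ivstd[c] *
        (dxhat - mean(dxhat) - xh * mean(dxhat * xh))
    } else {
      dx[, , c, ] <- dxhat * cache$ivstd[c]
    }
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_forward <- function(x) {
  m <- x > 0
  list(y = x * m, cache = m)
}
relu_backward <- function(cache, dy) dy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- Adam ----------------------------------------------------------------

adam_update <- function(layers, grads, step, lr, beta1 = 0.5, beta2 = 0.999,
                        eps = 1e-8) {
  bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
  for (i in seq_along(layers)) {
    L <- layers[[i]]; g <- grads[[i]]
    if (is.null(L) || is.null(g)) next
    for (nm in L$params) {
      gv <- g[[nm]]
      if (is.null(gv)) next
      mn <- paste0(".m_", nm); vn <- paste0(".v_", nm)
      if (is.null(L[[mn]])) { L[[mn]] <- gv * 0; L[[vn]] <- gv * 0 }
      L[[mn]] <- beta1 * L[[mn]] + (1 - beta1) * gv
      L[[vn]] <- beta2 * L[[vn]] + (1 - beta2) * gv^2
      L[[nm]] <- L[[nm]] - lr * (L[[mn]] / bc1) / (sqrt(L[[vn]] / bc2) + eps)
    }
  }
  invisible(NULL)
}

# deep copy of a network's layer environments (snapshot for "untrained" baselines)
clone_layer <- function(L) {
  E <- new.env(parent = emptyenv())
  for (nm in ls(L, all.names = TRUE)) E[[nm]] <- L[[nm]]
  E
}

# accumulate: a + b elementwise over matching named grad lists
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

# hash of all trainable parameters (used to assert update isolation)
params_digest <- function(layers) {
  s <- 0
  for (L in layers) for (nm in L$params) s <- s + sum(L[[nm]] * seq_along(L[[nm]]))
  s
}
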