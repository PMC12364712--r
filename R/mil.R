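# Attention-based multiple-instance learning for bag-level prediction from
# slide patches, with an optional co-attention fusion of two modalities
# (H&E-derived and marker-derived patch features), a discrete-time survival
# head, and survival evaluation (IPCW time-dependent C-index, Kaplan-Meier,
# log-rank).

#' Gated attention pooling
#'
#' `a_i = softmax_i( w' (tanh(V h_i) * sigmoid(U h_i)) )`, `g = sum_i a_i h_i`.
#'
#' @param h instance feature matrix (N x d).
#' @param w,V,U gated-attention parameters (length L, L x d, L x d).
#' @return list `g` (bag vector, length d) and `weights` (length N, sums to 1).
#' @export
gated_attention_pool <- function(h, w, V, U) {
  h <- as.matrix(h)
  t_ <- tanh(h %*% t(V))                 # N x L
  s_ <- sigmoid(h %*% t(U))
  e <- drop((t_ * s_) %*% w)
  e <- e - max(e)
  a <- exp(e) / sum(exp(e))
  list(g = drop(crossprod(h, a)), weights = a)
}

# pooling with cache + backward (features fixed; returns parameter grads)
.pool_forward <- function(h, pa) {
  t_ <- tanh(h %*% t(pa$V)); s_ <- sigmoid(h %*% t(pa$U))
  e <- drop((t_ * s_) %*% pa$w)
  em <- e - max(e)
  a <- exp(em) / sum(exp(em))
  list(g = drop(crossprod(h, a)), a = a, t = t_, s = s_, h = h)
}

.pool_backward <- function(cache, pa, dg, need_dh = FALSE) {
  h <- cache$h; a <- cache$a
  da <- drop(h %*% dg)
  de <- a * (da - sum(a * da))
  ts <- cache$t * cache$s
  dw <- drop(crossprod(ts, de))
  dt <- outer(de, pa$w) * cache$s
  ds <- outer(de, pa$w) * cache$t
  dpre_t <- (1 - cache$t^2) * dt
  dpre_s <- cache$s * (1 - cache$s) * ds
  dV <- crossprod(dpre_t, h)
  dU <- crossprod(dpre_s, h)
  dh <- if (need_dh) {
    outer(a, dg) + dpre_t %*% pa$V + dpre_s %*% pa$U
  } else NULL
  list(w = dw, V = dV, U = dU, dh = dh)
}

#' Co-attention between two modality bags
#'
#' `H_hat = softmax(Q K' / sqrt(d)) W_v H` with `Q = P W_q'`, `K = H W_k'`;
#' rows of the attention matrix sum to 1.
#'
#' @param H,P instance matrices (N x d), matched instance correspondence.
#' @param W_q,W_k,W_v d x d weights.
#' @return list `H_hat` (N x d) and `A` (N x N attention matrix).
#' @export
coattention <- function(H, P, W_q, W_k, W_v) {
  H <- as.matrix(H); P <- as.matrix(P)
  if (!identical(dim(H), dim(P))) stop("modality dimension mismatch")
  d <- ncol(H)
  S <- (P %*% t(W_q)) %*% t(H %*% t(W_k)) / sqrt(d)
  Sm <- S - apply(S, 1, max)
  A <- exp(Sm) / rowSums(exp(Sm))
  list(H_hat = A %*% (H %*% t(W_v)), A = A)
}

.coatt_forward <- function(H, P, pa) {
  d <- ncol(H)
  Q <- P %*% t(pa$W_q); K <- H %*% t(pa$W_k); V <- H %*% t(pa$W_v)
  S <- Q %*% t(K) / sqrt(d)
  Sm <- S - apply(S, 1, max)
  A <- exp(Sm) / rowSums(exp(Sm))
  list(out = A %*% V, A = A, Q = Q, K = K, V = V, H = H, P = P, d = d)
}

.coatt_backward <- function(cache, dout) {
  A <- cache$A
  dA <- dout %*% t(cache$V)
  dV <- t(A) %*% dout
  dS <- A * (dA - rowSums(dA * A))
  dQ <- dS %*% cache$K / sqrt(cache$d)
  dK <- t(dS) %*% cache$Q / sqrt(cache$d)
  list(W_q = t(dQ) %*% cache$P, W_k = t(dK) %*% cache$H,
       W_v = t(dV) %*% cache$H)
}

#' Discretize survival times into quartile bins
#'
#' Cut points are the quartiles of the supplied (training) times; intervals are
#' half-open `[t_{j-1}, t_j)` and times beyond the last training cut fall in
#' the last bin.
#'
#' @param times observed times (event or last follow-up).
#' @param cuts optional pre-computed cut points (from the training split).
#' @param n_bins number of bins when computing cuts.
#' @return list `bin` (integer labels 1..n_bins) and `cuts`.
#' @export
discretize_times <- function(times, cuts = NULL, n_bins = 4L) {
  if (is.null(cuts)) {
    if (length(unique(times)) < n_bins) stop("need >= n_bins distinct times")
    cuts <- stats::quantile(times, probs = seq_len(n_bins - 1L) / n_bins,
                            names = FALSE, type = 7)
  }
  bin <- findInterval(times, cuts, left.open = FALSE) + 1L  # [t_{j-1}, t_j)
  bin <- pmin(bin, length(cuts) + 1L)
  list(bin = as.integer(bin), cuts = cuts)
}

hazards_from_logits <- function(logits) sigmoid(logits)

#' Discrete-time survival quantities from interval logits
#'
#' Hazard `f_hazard(j) = sigmoid(logit_j)`, survival
#' `f_surv(j) = prod_{k<=j} (1 - f_hazard(k))`. The patient-level risk is the
#' negative sum of the survival function over intervals, `-sum_j f_surv(j)`:
#' high hazards depress the survival curve and raise the risk, so higher risk
#' is concordant with shorter survival. (The negated logit sum is also
#' returned as `risk_logit_sum` for reference; with a hazard parametrization
#' it orders patients in the opposite direction.)
#'
#' @param logits numeric vector of J interval logits.
#' @return list `hazard`, `surv` (length J, non-increasing), `risk`,
#'   `risk_logit_sum`.
#' @export
survival_head <- function(logits) {
  hz <- hazards_from_logits(logits)
  sv <- cumprod(1 - hz)
  list(hazard = hz, surv = sv, risk = -sum(sv), risk_logit_sum = -sum(logits))
}

#' Discrete-time survival negative log-likelihood
#'
#' Censorship coding: `c = 0` if death observed, `c = 1` if censored. Per
#' patient the loss is `-c log f_surv(y) - (1-c) log f_surv(y-1)
#' - (1-c) log f_hazard(y)`, summed over the cohort.
#'
#' @param logits J-vector or M x J matrix of interval logits.
#' @param y integer bin labels in 1..J.
#' @param cens censorship indicators (0 = event observed).
#' @return scalar loss; `attr(, "grad")` holds the logit gradients.
#' @export
survival_nll <- function(logits, y, cens) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  J <- ncol(logits)
  if (any(y < 1L | y > J)) stop("bin label out of range")
  stopifnot(all(cens %in% c(0, 1)))
  total <- 0
  grad <- logits * 0
  for (m in seq_len(nrow(logits))) {
    hz <- sigmoid(logits[m, ])
    logs <- cumsum(log1p(-hz))          # log f_surv(1..J)
    sy <- function(j) if (j <= 0) 0 else logs[j]
    if (cens[m] == 1) {
      total <- total - sy(y[m])
      grad[m, seq_len(y[m])] <- hz[seq_len(y[m])]
    } else {
      total <- total - sy(y[m] - 1L) - log(hz[y[m]])
      if (y[m] > 1L) grad[m, seq_len(y[m] - 1L)] <- hz[seq_len(y[m] - 1L)]
      grad[m, y[m]] <- hz[y[m]] - 1
    }
  }
  structure(total, grad = grad)
}

#' Multiclass cross-entropy from logits
#'
#' `-sum_m sum_k y_k log(softmax(logits)_k)` with one-hot targets.
#'
#' @param logits M x K matrix (or K-vector).
#' @param labels integer class labels in 1..K.
#' @return scalar loss; `attr(, "grad")` holds the logit gradients.
#' @export
ce_loss <- function(logits, labels) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  lm <- logits - apply(logits, 1, max)
  p <- exp(lm) / rowSums(exp(lm))
  idx <- cbind(seq_len(nrow(logits)), labels)
  total <- -sum(log(p[idx]))
  g <- p; g[idx] <- g[idx] - 1
  structure(total, grad = g)
}

# ---- MIL model -----------------------------------------------------------

.mil_init <- function(d, L, out_dim, mode) {
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(1 / nc)), nr, nc)
  pa <- list(pool_H = list(w = stats::rnorm(L, 0, 0.1), V = rn(L, d), U = rn(L, d)))
  if (mode == "multimodal") {
    pa$pool_P <- list(w = stats::rnorm(L, 0, 0.1), V = rn(L, d), U = rn(L, d))
    pa$co_PH <- list(W_q = rn(d, d), W_k = rn(d, d), W_v = rn(d, d))
    pa$co_HP <- list(W_q = rn(d, d), W_k = rn(d, d), W_v = rn(d, d))
    pa$fuse <- list(W = rn(d, 2L * d), b = numeric(d))
  }
  pa$head <- list(W = rn(out_dim, d), b = numeric(out_dim))
  pa
}

.mil_forward <- function(pa, bag, mode) {
  H <- bag$H
  if (mode == "multimodal") {
    if (is.null(bag$P)) stop("multimodal mode requires both modalities")
    ca_H <- .coatt_forward(H, bag$P, pa$co_PH)      # P guides H
    ca_P <- .coatt_forward(bag$P, H, pa$co_HP)      # H guides P
    po_H <- .pool_forward(ca_H$out, pa$pool_H)
    po_P <- .pool_forward(ca_P$out, pa$pool_P)
    gc <- c(po_H$g, po_P$g)
    gf <- drop(pa$fuse$W %*% gc) + pa$fuse$b
    logits <- drop(pa$head$W %*% gf) + pa$head$b
    list(logits = logits,
         cache = list(ca_H = ca_H, ca_P = ca_P, po_H = po_H, po_P = po_P,
                      gc = gc, gf = gf))
  } else {
    po <- .pool_forward(H, pa$pool_H)
    logits <- drop(pa$head$W %*% po$g) + pa$head$b
    list(logits = logits, cache = list(po_H = po))
  }
}

.mil_backward <- function(pa, cache, dlogits, mode) {
  gr <- list()
  if (mode == "multimodal") {
    gr$head <- list(W = outer(dlogits, cache$gf), b = dlogits)
    dgf <- drop(crossprod(pa$head$W, dlogits))
    gr$fuse <- list(W = outer(dgf, cache$gc), b = dgf)
    dgc <- drop(crossprod(pa$fuse$W, dgf))
    d <- length(cache$po_H$g)
    pbH <- .pool_backward(cache$po_H, pa$pool_H, dgc[seq_len(d)], need_dh = TRUE)
    pbP <- .pool_backward(cache$po_P, pa$pool_P, dgc[d + seq_len(d)], need_dh = TRUE)
    gr$pool_H <- pbH[c("w", "V", "U")]
    gr$pool_P <- pbP[c("w", "V", "U")]
    gr$co_PH <- .coatt_backward(cache$ca_H, pbH$dh)
    gr$co_HP <- .coatt_backward(cache$ca_P, pbP$dh)
  } else {
    gr$head <- list(W = outer(dlogits, cache$po_H$g), b = dlogits)
    dg <- drop(crossprod(pa$head$W, dlogits))
    gr$pool_H <- .pool_backward(cache$po_H, pa$pool_H, dg)[c("w", "V", "U")]
  }
  gr
}

#' Fit an attention-based MIL model
#'
#' Bag-level prediction with gated attention pooling; `mode = "multimodal"`
#' first aligns the two modalities with co-attention in both directions, pools
#' each, concatenates the bag vectors and projects back to dimension d before
#' the output head. `task = "survival"` uses a discrete-time hazard head
#' trained with the survival NLL; `task = "subtype"` a softmax classifier.
#'
#' @param bags list of bags (`H`, optionally `P`, plus `bin`/`censor` or
#'   `label`), e.g. from [simulate_survival_cohort()].
#' @param task "survival" or "subtype".
#' @param mode "unimodal" or "multimodal".
#' @param hidden attention hidden dimension L.
#' @param epochs maximum epochs (mini-batch size 1).
#' @param lr Adam learning rate.
#' @param val_frac fraction of bags held out for early stopping.
#' @param patience early-stopping patience (epochs without val improvement).
#' @param seed RNG seed for initialization and shuffling.
#' @return a `plexmil` model with `predict`, `print` and `summary` methods.
#' @export
mil_fit <- function(bags, task = c("survival", "subtype"),
                    mode = c("unimodal", "multimodal"), hidden = 32L,
                    epochs = 100L, lr = 1e-4, val_frac = 0.2, patience = 10L,
                    seed = 1L) {
  task <- match.arg(task); mode <- match.arg(mode)
  set.seed(seed)
  d <- ncol(bags[[1L]]$H)
  if (task == "survival") {
    J <- max(vapply(bags, `[[`, integer(1), "bin"))
    out_dim <- J
    classes <- NULL
  } else {
    classes <- sort(unique(vapply(bags, `[[`, character(1), "label")))
    if (length(classes) < 2L) stop("need >= 2 classes")
    out_dim <- length(classes)
  }
  pa <- .mil_init(d, as.integer(hidden), out_dim, mode)
  n <- length(bags)
  nval <- max(1L, round(val_frac * n))
  val_idx <- sample.int(n, nval)
  tr_idx <- setdiff(seq_len(n), val_idx)
  opt <- new.env(parent = emptyenv()); opt$t <- 0L
  best <- list(val = Inf, pa = pa, epoch = 0L)
  wait <- 0L
  bag_loss <- function(pa, bag) {
    fw <- .mil_forward(pa, bag, mode)
    if (task == "survival")
      lo <- survival_nll(fw$logits, bag$bin, bag$censor)
    else
      lo <- ce_loss(fw$logits, match(bag$label, classes))
    list(value = as.numeric(lo), grad = drop(attr(lo, "grad")), cache = fw$cache)
  }
  history <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  for (ep in seq_len(epochs)) {
    tr_loss <- 0
    for (i in sample(tr_idx)) {
      bl <- bag_loss(pa, bags[[i]])
      tr_loss <- tr_loss + bl$value
      gr <- .mil_backward(pa, bl$cache, bl$grad, mode)
      opt$t <- opt$t + 1L
      pa <- .mil_adam(pa, gr, opt, lr)
    }
    val_loss <- sum(vapply(val_idx, function(i) bag_loss(pa, bags[[i]])$value,
                           numeric(1)))
    history <- rbind(history, data.frame(epoch = ep, train = tr_loss / length(tr_idx),
                                         val = val_loss / nval))
    if (val_loss < best$val - 1e-8) {
      best <- list(val = val_loss, pa = pa, epoch = ep); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(params = best$pa, task = task, mode = mode, classes = classes,
                 out_dim = out_dim, d = d, history = history,
                 best_epoch = best$epoch, val_idx = val_idx, seed = seed),
            class = "plexmil")
}

# Adam over the nested MIL parameter list
.mil_adam <- function(pa, gr, opt, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  t <- opt$t
  for (blk in names(gr)) for (nm in names(gr[[blk]])) {
    key <- paste0(blk, ".", nm)
    g <- gr[[blk]][[nm]]
    if (is.null(opt[[key]])) opt[[key]] <- list(m = g * 0, v = g * 0)
    st <- opt[[key]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    opt[[key]] <- st
    pa[[blk]][[nm]] <- pa[[blk]][[nm]] -
      lr * (st$m / (1 - b1^t)) / (sqrt(st$v / (1 - b2^t)) + eps)
  }
  pa
}

#' @export
predict.plexmil <- function(object, bags, type = c("risk", "logits", "class",
                                                   "surv"), ...) {
  type <- match.arg(type)
  if (inherits(bags, "survival_bag")) bags <- list(bags)
  out <- lapply(bags, function(b) .mil_forward(object$params, b, object$mode)$logits)
  logits <- do.call(rbind, out)
  switch(type,
         logits = logits,
         risk = apply(logits, 1, function(l) survival_head(l)$risk),
         surv = t(apply(logits, 1, function(l) survival_head(l)$surv)),
         class = object$classes[max.col(logits)])
}

#' @export
print.plexmil <- function(x, ...) {
  cat("Attention-MIL model (", x$mode, ", task = ", x$task, ")\n", sep = "")
  cat("  feature dim:", x$d, " output dim:", x$out_dim, "\n")
  cat("  best epoch:", x$best_epoch, " (val loss ",
      signif(min(x$history$val), 4), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.plexmil <- function(object, ...) {
  print(object)
  cat("training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Survival evaluation: time-dependent C-index, KM curves, log-rank test
#'
#' Concordance uses the IPCW (Uno-type) time-dependent estimator; risk groups
#' are split at the median predicted risk.
#'
#' @param risks predicted risk scores (higher = worse).
#' @param times observed times; `cens` censorship (0 = death observed).
#' @return list: `cindex`, `km` (survfit object for the two risk groups),
#'   `logrank_p`, `logrank_chisq`, `groups`.
#' @export
evaluate_survival <- function(risks, times, cens) {
  event <- 1 - cens
  if (sum(event) == 0) stop("no events observed; concordance undefined")
  sv <- survival::Surv(times, event)
  cc <- survival::concordance(sv ~ risks, reverse = TRUE, timewt = "n/G2")
  grp <- factor(ifelse(risks > stats::median(risks), "high", "low"),
                levels = c("low", "high"))
  km <- survival::survfit(sv ~ grp)
  lr <- survival::survdiff(sv ~ grp)
  p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  list(cindex = unname(cc$concordance), km = km, logrank_p = p,
       logrank_chisq = unname(lr$chisq), groups = grp)
}
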