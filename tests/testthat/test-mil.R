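# Attention pooling, co-attention, time discretization, survival/CE losses and
# survival evaluation.

test_that("gated attention pooling obeys its closed forms and normalization", {
  set.seed(1)
  d <- 6; L <- 4
  w <- rnorm(L); V <- matrix(rnorm(L * d), L, d); U <- matrix(rnorm(L * d), L, d)
  # N = 1: a = [1], g = h1
  h1 <- matrix(rnorm(d), 1, d)
  p1 <- gated_attention_pool(h1, w, V, U)
  expect_equal(p1$weights, 1)
  expect_equal(p1$g, drop(h1))
  # identical instances -> uniform weights
  hrep <- h1[rep(1, 5), , drop = FALSE]
  p5 <- gated_attention_pool(hrep, w, V, U)
  expect_equal(p5$weights, rep(1 / 5, 5))
  # random case vs explicit term-by-term evaluation
  h <- matrix(rnorm(3 * d), 3, d)
  p <- gated_attention_pool(h, w, V, U)
  e <- numeric(3)
  for (i in 1:3) {
    t_ <- tanh(V %*% h[i, ]); s_ <- 1 / (1 + exp(-U %*% h[i, ]))
    e[i] <- sum(w * t_ * s_)
  }
  a <- exp(e) / sum(exp(e))
  expect_equal(p$weights, a, tolerance = 1e-12)
  expect_equal(p$g, drop(t(h) %*% a), tolerance = 1e-12)
  expect_equal(sum(p$weights), 1)
  # permutation invariance of the bag vector
  pm <- gated_attention_pool(h[c(3, 1, 2), ], w, V, U)
  expect_equal(sort(pm$weights), sort(p$weights))
  expect_equal(pm$g, p$g, tolerance = 1e-12)
})

test_that("co-attention matches a step-by-step matrix oracle and row-normalizes", {
  set.seed(2)
  d <- 4; N <- 3
  H <- matrix(rpois(N * d, 3) + 0, N, d); P <- matrix(rpois(N * d, 2) + 0, N, d)
  Wq <- matrix(rnorm(d * d), d, d); Wk <- matrix(rnorm(d * d), d, d)
  Wv <- matrix(rnorm(d * d), d, d)
  got <- coattention(H, P, Wq, Wk, Wv)
  # explicit arithmetic
  S <- (P %*% t(Wq)) %*% t(H %*% t(Wk)) / sqrt(d)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(got$A, A, tolerance = 1e-12)
  expect_equal(got$H_hat, A %*% H %*% t(Wv), tolerance = 1e-12)
  expect_equal(rowSums(got$A), rep(1, N))
  expect_true(all(got$A >= 0))
  # N = 1: A = [[1]], H_hat = Wv H
  g1 <- coattention(H[1, , drop = FALSE], P[1, , drop = FALSE], Wq, Wk, Wv)
  expect_equal(g1$A, matrix(1, 1, 1))
  expect_equal(g1$H_hat, H[1, , drop = FALSE] %*% t(Wv), tolerance = 1e-12)
  expect_error(coattention(H, P[, 1:2], Wq, Wk, Wv), "mismatch")
})

test_that("time discretization uses train-split quartiles with half-open bins", {
  b <- discretize_times(1:100)
  expect_equal(unname(table(b$bin)), c(25L, 25L, 25L, 25L), ignore_attr = TRUE)
  # a time exactly at a cut point goes to the right bin
  cuts <- c(10, 20, 30)
  expect_equal(discretize_times(c(9.9, 10, 20, 30), cuts = cuts)$bin,
               c(1L, 2L, 3L, 4L))
  # test times beyond the training maximum clamp into the last bin
  expect_equal(discretize_times(1e6, cuts = cuts)$bin, 4L)
  expect_error(discretize_times(rep(5, 10)), "distinct")
})

test_that("survival NLL reproduces closed forms and a brute-force oracle", {
  # J = 1, death observed in bin 1, logit 0: -log(1) - log(0.5)
  l <- survival_nll(matrix(0, 1, 1), 1L, 0)
  expect_equal(as.numeric(l), -log(1) - log(0.5), tolerance = 1e-12)
  expect_equal(round(as.numeric(l), 4), 0.6931)
  # censored with hazards -> 0 gives loss -> 0
  lc <- survival_nll(matrix(-30, 1, 3), 3L, 1)
  expect_lt(as.numeric(lc), 1e-10)
  # random cohort vs term-by-term evaluation
  set.seed(3)
  M <- 12; J <- 4
  logits <- matrix(rnorm(M * J), M, J)
  y <- sample.int(J, M, replace = TRUE)
  cens <- rbinom(M, 1, 0.3)
  got <- survival_nll(logits, y, cens)
  oracle <- 0
  for (m in seq_len(M)) {
    hz <- 1 / (1 + exp(-logits[m, ]))
    surv <- cumprod(1 - hz)
    s_ <- function(j) if (j <= 0) 1 else surv[j]
    oracle <- oracle + if (cens[m] == 1) -log(s_(y[m])) else
      -log(s_(y[m] - 1)) - log(hz[y[m]])
  }
  expect_equal(as.numeric(got), oracle, tolerance = 1e-10)
  # gradient attribute vs finite differences
  gfd <- num_grad(function(v) as.numeric(survival_nll(matrix(v, M, J), y, cens)),
                  as.numeric(logits))
  expect_equal(as.numeric(attr(got, "grad")), gfd, tolerance = 1e-6)
  expect_error(survival_nll(logits, rep(9L, M), cens), "out of range")
})

test_that("survival function is monotone and finite for arbitrary logits", {
  set.seed(4)
  for (i in 1:20) {
    sh <- survival_head(rnorm(5, sd = 3))
    expect_true(all(sh$hazard > 0 & sh$hazard < 1))
    expect_true(all(diff(sh$surv) <= 0))
    expect_true(sh$surv[1] > 0 && sh$surv[1] <= 1)
    expect_true(is.finite(sh$risk))
  }
})

test_that("cross-entropy closed forms hold", {
  # perfect prediction -> 0
  expect_lt(as.numeric(ce_loss(matrix(c(50, 0, 0), 1), 1L)), 1e-12)
  # uniform prediction over 3 classes -> log 3
  expect_equal(as.numeric(ce_loss(matrix(0, 1, 3), 2L)), log(3), tolerance = 1e-12)
  expect_equal(round(as.numeric(ce_loss(matrix(0, 1, 3), 1L)), 4), 1.0986)
  # 2-patient toy vs manual computation
  lg <- rbind(c(1, -1), c(0.5, 0.2))
  p1 <- exp(lg[1, ]) / sum(exp(lg[1, ])); p2 <- exp(lg[2, ]) / sum(exp(lg[2, ]))
  expect_equal(as.numeric(ce_loss(lg, c(1L, 2L))),
               -log(p1[1]) - log(p2[2]), tolerance = 1e-12)
})

test_that("MIL predictions are permutation-invariant and mode contracts hold", {
  bags <- simulate_survival_cohort(n_patients = 20, effect_size = 1, seed = 5)
  m <- mil_fit(bags, task = "survival", epochs = 3, seed = 1)
  b <- bags[[1]]
  bp <- b; perm <- sample(nrow(b$H)); bp$H <- b$H[perm, ]; bp$P <- b$P[perm, ]
  expect_equal(predict(m, list(b), type = "logits"),
               predict(m, list(bp), type = "logits"), tolerance = 1e-10)
  expect_equal(ncol(predict(m, bags[1:2], type = "logits")), 4)  # J bins
  # multimodal requested with one modality errors
  mm <- mil_fit(bags, task = "survival", mode = "multimodal", epochs = 2, seed = 1)
  b1 <- b; b1$P <- NULL
  expect_error(predict(mm, list(b1)), "both modalities")
  # subtype task: output dimension K and class labels
  mc <- mil_fit(bags, task = "subtype", epochs = 3, seed = 1)
  expect_equal(ncol(predict(mc, bags[1:3], type = "logits")), 2)
  expect_true(all(predict(mc, bags[1:3], type = "class") %in% c("high", "low")))
})

test_that("survival evaluation: perfect concordance, hand-computed log-rank", {
  # risks anti-monotone in event times -> C = 1
  times <- c(1, 2, 3, 4, 5, 6)
  risks <- -times                      # earliest death carries the highest risk
  ev <- evaluate_survival(risks, times, rep(0, 6))
  expect_equal(ev$cindex, 1)
  # identical survival in both groups: log-rank statistic vs the
  # observed-vs-expected table computed by hand on a 6-patient toy
  t6 <- c(1, 1, 2, 2, 3, 3)
  g6 <- c(0, 1, 0, 1, 0, 1)    # risks split groups deterministically
  ev2 <- evaluate_survival(g6, t6, rep(0, 6))
  # hand computation: at t=1 risk sets 3/3, events 1/1; t=2 sets 2/2 events
  # 1/1; t=3 sets 1/1 events 1/1 -> O-E = 0 in both groups -> chisq = 0
  expect_equal(ev2$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(ev2$logrank_p, 1, tolerance = 1e-12)
  expect_error(evaluate_survival(risks, times, rep(1, 6)), "no events")
})

test_that("random risks on a large cohort give chance-level concordance", {
  b <- simulate_survival_cohort(n_patients = 300, effect_size = 0, seed = 6)
  set.seed(7)
  cc <- evaluate_survival(rnorm(300), sapply(b, `[[`, "time"),
                          sapply(b, `[[`, "censor"))$cindex
  expect_gt(cc, 0.45); expect_lt(cc, 0.55)
})
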