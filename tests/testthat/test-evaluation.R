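# Image-quality metrics, HYPE arithmetic and co-localization statistics.

test_that("psnr reproduces its closed forms", {
  y <- matrix(runif(64), 8, 8)
  expect_identical(psnr(y, y), Inf)
  # uniform difference c with L = 1 -> 20 log10(1/c)
  expect_equal(psnr(y, y + 0.1), 20 * log10(1 / 0.1), tolerance = 1e-12)
  expect_equal(psnr(y, y + 0.25, L = 1), 20 * log10(4), tolerance = 1e-12)
  # MSE = L^2 -> 0 dB
  expect_equal(psnr(matrix(0, 4, 4), matrix(2, 4, 4), L = 2), 0)
  expect_error(psnr(y, matrix(0, 4, 4)), "mismatch")
  # strictly decreasing with noise sd (matched seeds)
  set.seed(1)
  base <- matrix(runif(400), 20, 20)
  noise <- matrix(rnorm(400), 20, 20)
  ps <- sapply(c(0.01, 0.05, 0.1), function(s) psnr(base, base + s * noise))
  expect_true(all(diff(ps) < 0))
})

test_that("ms_ssim identities: perfect match, degenerate prediction, SSIM equivalence", {
  set.seed(2)
  y <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ms_ssim(y, y, M = 3), 1, tolerance = 1e-12)
  # constant prediction against a structured target scores near zero
  yv <- plexgen:::blur_mat(matrix(rbinom(64 * 64, 1, 0.5), 64, 64), 1)
  expect_lt(ms_ssim(yv, matrix(mean(yv), 64, 64), M = 1, window_size = 11), 0.1)
  # symmetric
  z <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ms_ssim(y, z, M = 2), ms_ssim(z, y, M = 2), tolerance = 1e-12)
  # single scale + single global window equals a hand-moment evaluation
  a <- matrix(runif(144), 12, 12); b <- matrix(runif(144), 12, 12)
  got <- ms_ssim(a, b, M = 1, alpha = 1, window_size = 99)
  C1 <- 0.01^2; C2 <- 0.03^2
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
  cab <- mean((a - mu_a) * (b - mu_b))
  oracle <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(ms_ssim(matrix(runif(16), 4, 4), matrix(runif(16), 4, 4), M = 5),
               "too small")
})

test_that("rmse_sw degenerates to global RMSE and honours closed forms", {
  set.seed(3)
  y <- matrix(runif(256), 16, 16); z <- matrix(runif(256), 16, 16)
  expect_equal(rmse_sw(y, y), 0)
  # whole-image window (N = 1) equals the global RMSE
  expect_equal(rmse_sw(y, z, window = 16, stride = 1),
               sqrt(mean((y - z)^2)), tolerance = 1e-12)
  # uniform difference c gives c for any window/stride
  expect_equal(rmse_sw(y, y + 0.2, window = 4, stride = 2), 0.2, tolerance = 1e-12)
  expect_equal(rmse_sw(y, y + 0.2, window = 5, stride = 3), 0.2, tolerance = 1e-12)
  # exact tiling: windows covering each pixel once equals global RMSE
  expect_equal(rmse_sw(y, z, window = 8, stride = 8),
               sqrt(mean((y - z)^2)), tolerance = 1e-12)
  expect_error(rmse_sw(y, z, stride = 0), "stride")
})

test_that("hype scores reproduce the defining arithmetic", {
  all_right <- hype_scores(rep(c("real", "generated"), each = 10),
                           rep(c("real", "generated"), each = 10))
  expect_equal(unname(all_right), c(0, 0, 0))
  all_wrong <- hype_scores(rep(c("real", "generated"), each = 10),
                           rep(c("generated", "real"), each = 10))
  expect_equal(unname(all_wrong), c(100, 100, 100))
  # TP = 30, TN = 20, FP = 30, FN = 20
  truth <- c(rep("real", 50), rep("generated", 50))
  verdict <- c(rep("real", 30), rep("generated", 20),
               rep("real", 30), rep("generated", 20))
  got <- hype_scores(truth, verdict)
  expect_equal(unname(got), c(50.0, 60.0, 40.0))
  expect_error(hype_scores(rep("real", 4), rep("real", 4)), "each truth class")
})

test_that("co-localization SCC is exact on identical tables and rank-invariant", {
  set.seed(4)
  tabs <- lapply(1:4, function(i) {
    m <- matrix(rexp(200 * 3), 200, 3)
    m[, 2] <- m[, 1] * 2 + rexp(200) * 0.1      # correlated pair
    colnames(m) <- c("A", "B", "C")
    m
  })
  res <- colocalization_scc(tabs, tabs)
  expect_equal(res$mse, 0)
  expect_true(any(res$pairs$retained))
  # strictly increasing transform leaves SCC untouched
  tabs2 <- lapply(tabs, function(m) { m[, 1] <- log1p(m[, 1]); m })
  res2 <- colocalization_scc(tabs, tabs2)
  expect_equal(res2$mse, 0, tolerance = 1e-12)
  # two markers linked by a strictly increasing transform have SCC exactly 1
  one <- list(cbind(A = 1:50 + 0, B = (1:50)^3 + 0, C = rnorm(50)))
  r1 <- colocalization_scc(one, one)
  expect_equal(r1$pairs$scc_gt[r1$pairs$marker_a == "A" &
                                 r1$pairs$marker_b == "B"], 1)
  # threshold filter matches a brute-force filter
  brute_keep <- abs(sapply(seq_len(nrow(res$pairs)), function(i) res$pairs$scc_gt[i])) > 0.15
  expect_equal(res$pairs$retained, brute_keep)
  # constant markers are skipped and logged
  cst <- list(cbind(A = rep(1, 30), B = rnorm(30), C = rnorm(30)),
              cbind(A = rnorm(30), B = rnorm(30), C = rnorm(30)))
  rc <- colocalization_scc(cst, cst)
  expect_gt(length(rc$skipped), 0)
})

test_that("planted co-expression is recovered within 0.05 of the population Spearman", {
  # cohort from the simulator: 20 ROIs x ~2000 cells; the population Spearman
  # of the generative law is computed by large-sample Monte Carlo from the
  # same copula (types + log-normal factors), independently of the renderer
  E <- matrix(0, 6, 2, dimnames = list(PLEX_CELL_TYPES, c("A", "B")))
  E["tumour", ] <- c(0.9, 0.8); E["other", "B"] <- 0.1
  props <- c(tumour = 0.5, CD8T = 0, CD4T = 0, B = 0, endothelial = 0, other = 0.5)
  tabs <- lapply(1:20, function(s) {
    cfg <- tissue_sim_config(canvas = 340, n_cells = 2000, seed = s,
                             markers = c("A", "B"), expression = E,
                             proportions = props)
    as.matrix(simulate_paired_roi(cfg)$cells[, c("A", "B")])
  })
  res <- colocalization_scc(tabs, tabs)
  got <- res$pairs$scc_gt[1]
  # population value by direct simulation of the expression law
  set.seed(999)
  n <- 2e5
  type_tum <- runif(n) < 0.5
  s_cell <- rlnorm(n, 0, 0.25)
  a <- ifelse(type_tum, 0.9, 0) * s_cell * rlnorm(n, 0, 0.25)
  b <- ifelse(type_tum, 0.8, 0.1) * s_cell * rlnorm(n, 0, 0.25)
  pop <- cor(a, b, method = "spearman")
  expect_lt(abs(got - pop), 0.05)
})

test_that("metric report aggregates per-ROI, per-marker metrics", {
  set.seed(5)
  gts <- lapply(1:3, function(i)
    array(runif(32 * 32 * 2), c(32, 32, 2), dimnames = list(NULL, NULL, c("A", "B"))))
  gens <- lapply(gts, function(g) pmin(pmax(g + rnorm(length(g), 0, 0.05), 0), 1))
  rep <- metric_report(gts, gens, M = 2)
  expect_equal(nrow(rep$per_roi), 6)
  expect_equal(sort(unique(rep$per_roi$marker)), c("A", "B"))
  # identical inputs: psnr Inf, ms_ssim 1, rmse 0
  ri <- metric_report(gts, gts, M = 2)
  expect_true(all(is.infinite(ri$per_roi$psnr)))
  expect_equal(ri$overall[["ms_ssim_mean"]], 1, tolerance = 1e-10)
  expect_equal(ri$overall[["rmse_sw_mean"]], 0)
  # round-trips to CSV/JSON
  d <- withr::local_tempdir()
  fs <- write_metric_report(rep, d)
  expect_true(all(file.exists(fs)))
  back <- read.csv(fs[1])
  expect_equal(back$rmse_sw, rep$per_roi$rmse_sw, tolerance = 1e-12)
})
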