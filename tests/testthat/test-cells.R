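# Pseudo-cell extraction, cell typing, t-SNE workflow, density arithmetic and
# the hot/cold classifier.

test_that("pseudo-cell means match construction and a pixel-enumeration oracle", {
  st <- array(0.42, c(40, 40, 2), dimnames = list(NULL, NULL, c("m1", "m2")))
  tab <- extract_pseudo_cells(st, data.frame(x = c(10, 30), y = c(12, 25)))
  expect_equal(tab$m1, c(0.42, 0.42))
  # disk pixel count at 1 um/px, diameter 10: brute-force enumeration
  cnt <- 0
  for (dh in -5:5) for (dw in -5:5) if (dh^2 + dw^2 <= 25) cnt <- cnt + 1
  off <- plexgen:::disk_offsets(5)
  expect_equal(nrow(off), cnt)
  # value-1 plateau covering the disk, 0 beyond -> mean exactly 1
  st2 <- array(0, c(40, 40, 1), dimnames = list(NULL, NULL, "m"))
  for (dh in -5:5) for (dw in -5:5)
    if (dh^2 + dw^2 <= 25) st2[20 + dh, 20 + dw, 1] <- 1
  t2 <- extract_pseudo_cells(st2, data.frame(x = 20, y = 20))
  expect_equal(t2$m, 1)
  # randomized oracle: the mean equals the enumeration mean
  set.seed(1)
  st3 <- array(runif(40 * 40), c(40, 40, 1), dimnames = list(NULL, NULL, "m"))
  t3 <- extract_pseudo_cells(st3, data.frame(x = 17, y = 23))
  vals <- c()
  for (dh in -5:5) for (dw in -5:5)
    if (dh^2 + dw^2 <= 25) vals <- c(vals, st3[23 + dh, 17 + dw, 1])
  expect_equal(t3$m, mean(vals), tolerance = 1e-12)
  # out-of-bounds coordinate skipped with a message
  expect_message(t4 <- extract_pseudo_cells(st3, data.frame(x = c(5, 99), y = c(5, 5))),
                 "skipped")
  expect_equal(nrow(t4), 1)
})

test_that("pseudo-cell extraction is translation-equivariant", {
  set.seed(2)
  st <- array(runif(30 * 30), c(30, 30, 1), dimnames = list(NULL, NULL, "m"))
  shifted <- array(0, c(40, 40, 1), dimnames = list(NULL, NULL, "m"))
  shifted[6:35, 9:38, 1] <- st[, , 1]
  a <- extract_pseudo_cells(st, data.frame(x = 15, y = 16))
  b <- extract_pseudo_cells(shifted, data.frame(x = 15 + 8, y = 16 + 5))
  expect_equal(a$m, b$m, tolerance = 1e-12)
})

test_that("separable synthetic profiles are typed with macro-F1 >= 0.95", {
  set.seed(3)
  roi <- simulate_paired_roi(tissue_sim_config(canvas = 160, n_cells = 450, seed = 3))
  cells <- roi$cells
  n <- nrow(cells)
  tr <- sample.int(n, round(0.7 * n)); te <- setdiff(seq_len(n), tr)
  ty <- train_cell_typer(cells[tr, ], seed = 1)
  expect_true(is.finite(ty$oob_error))
  pred <- apply_cell_typer(ty, cells[te, ])
  f1 <- macro_f1(cells$type[te], pred$type_pred)
  expect_gte(f1, 0.95)
  # degenerate single-class input refuses
  expect_error(train_cell_typer(cells[cells$type == "tumour", ]), "2 cell-type")
  # unseen feature columns at apply time error out
  expect_error(apply_cell_typer(ty, cells[te, c("x", "y")]), "absent")
})

test_that("cell typing improves monotonically with planted class separation", {
  f1_at <- function(sep) {
    # blend every type's profile toward the panel-average profile: sep = 0
    # makes all types identical, sep = 1 is the full default separation
    E0 <- default_expression_matrix()
    Em <- matrix(colMeans(E0), nrow(E0), ncol(E0), byrow = TRUE,
                 dimnames = dimnames(E0))
    E <- pmin(pmax((1 - sep) * Em + sep * E0, 0), 1)
    roi <- simulate_paired_roi(tissue_sim_config(canvas = 160, n_cells = 400,
                                                 seed = 5, expression = E,
                                                 cell_sd = 0.6, marker_sd = 0.6))
    cells <- roi$cells
    tr <- sample.int(nrow(cells), 280); te <- setdiff(seq_len(nrow(cells)), tr)
    ty <- train_cell_typer(cells[tr, ], seed = 1)
    macro_f1(cells$type[te], apply_cell_typer(ty, cells[te, ])$type_pred)
  }
  set.seed(5)
  f1s <- c(f1_at(0.05), f1_at(0.3), f1_at(1))
  expect_true(all(diff(f1s) > -0.02))      # monotone up to small noise
  expect_gt(f1s[3], f1s[1])
})

test_that("joint t-SNE embeds subsampled cells with cluster structure and capped colors", {
  set.seed(6)
  mk <- c("A", "B", "C", "D")
  mk_tab <- function(center) {
    m <- matrix(rnorm(120 * 4, sd = 0.2), 120, 4)
    m <- sweep(m, 2, center, "+")
    colnames(m) <- mk
    m
  }
  gt <- list(rbind(mk_tab(c(0, 0, 0, 0)), mk_tab(c(4, 4, 4, 4))))
  gen <- list(rbind(mk_tab(c(0, 0, 0, 0)), mk_tab(c(4, 4, 4, 4))))
  res <- joint_tsne(gt, gen, n_per_roi = 100, perplexity = 15, iters = 300,
                    seed = 1)
  expect_equal(nrow(res$embedding), 200)   # 2 sources x 1 ROI x n_per_roi
  expect_equal(ncol(res$colors), 4)
  expect_lte(max(res$colors), 1)
  # two well-separated clusters: silhouette on true cluster labels > 0.5
  lab <- res$colors[, "A"] > 0.5
  d2 <- as.matrix(dist(res$embedding))
  sil <- sapply(seq_len(nrow(d2)), function(i) {
    a <- mean(d2[i, lab == lab[i] & seq_along(lab) != i])
    b <- mean(d2[i, lab != lab[i]])
    (b - a) / max(a, b)
  })
  expect_gt(mean(sil), 0.5)
  expect_error(joint_tsne(gt, gen, n_per_roi = 100, perplexity = 1000), "perplexity")
})

test_that("density arithmetic and boundary conventions are exact", {
  # no CD8 cells -> zero densities
  strom <- matrix(FALSE, 50, 50); strom[1:5, ] <- TRUE
  intr <- matrix(TRUE, 50, 50); intr[1:5, ] <- FALSE
  masks <- list(intratumoral = intr, stromal = strom)
  t0 <- data.frame(x = 10, y = 10, type = "tumour")
  d0 <- phenotype_densities(t0, masks)
  expect_equal(d0$icd8, 0); expect_equal(d0$scd8, 0)
  # 50 CD8 cells uniform in a 1000 x 1000 um intratumoral mask -> 5e-5 per um^2
  masks2 <- list(intratumoral = rbind(matrix(FALSE, 100, 1000), matrix(TRUE, 1000, 1000)),
                 stromal = rbind(matrix(TRUE, 100, 1000), matrix(FALSE, 1000, 1000)))
  set.seed(7)
  tab <- data.frame(x = runif(50, 1, 1000), y = runif(50, 101, 1100), type = "CD8T")
  d <- phenotype_densities(tab, masks2)
  expect_equal(d$icd8, 5e-5)
  # boundary cells counted by the centre-pixel rule, checked against a
  # point-in-region oracle on a split mask
  left <- matrix(FALSE, 20, 20); left[, 1:10] <- TRUE
  right <- !left
  msk <- list(intratumoral = left, stromal = right)
  tb <- data.frame(x = c(10, 10.4, 10.6, 11), y = rep(5, 4), type = "CD8T")
  dd <- phenotype_densities(tb, msk)
  oracle_in <- sum(round(tb$x) <= 10)
  expect_equal(dd$n_intratumoral, oracle_in)
  expect_equal(dd$n_stromal, 4 - oracle_in)
  # doubling coordinates and mask at fixed counts quarters the density
  big <- list(intratumoral = rbind(matrix(FALSE, 200, 2000), matrix(TRUE, 2000, 2000)),
              stromal = rbind(matrix(TRUE, 200, 2000), matrix(FALSE, 2000, 2000)))
  tab2 <- tab; tab2$x <- tab2$x * 2; tab2$y <- tab2$y * 2
  d2 <- phenotype_densities(tab2, big)
  expect_equal(d2$icd8, d$icd8 / 4)
  # zero-area compartment flagged
  expect_warning(phenotype_densities(t0, list(intratumoral = matrix(FALSE, 5, 5),
                                              stromal = matrix(TRUE, 5, 5))),
                 "zero-area")
})

test_that("hot/cold classifier separates planted densities and collapses on permuted labels", {
  set.seed(8)
  n <- 40
  hot <- data.frame(icd8 = rlnorm(n, -9, 0.3), scd8 = rlnorm(n, -8.8, 0.3))
  cold <- data.frame(icd8 = rlnorm(n, -12, 0.3), scd8 = rlnorm(n, -11.5, 0.3))
  X <- rbind(hot, cold)
  y <- rep(c("hot", "cold"), each = n)
  res <- hot_cold_classifier(X, y, seed = 1)
  expect_equal(res$f1_mean, 1)
  expect_equal(res$auroc_mean, 1)
  # permuted labels -> chance-level AUROC over repeats
  aucs <- sapply(1:5, function(r) {
    set.seed(100 + r)
    hot_cold_classifier(X, sample(y), seed = r)$auroc_mean
  })
  expect_gt(mean(aucs), 0.35); expect_lt(mean(aucs), 0.65)
  expect_error(hot_cold_classifier(X, rep("hot", 2 * n)), "both classes")
})
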