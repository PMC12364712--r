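# Shared fixtures: a small three-marker simulator configuration and numeric
# gradient helper used across test files.

tiny_markers <- c("MelanA", "CD3", "CD20")

tiny_sim_config <- function(seed = 1L,
                            expression = default_expression_matrix()[, tiny_markers],
                            ...) {
  tissue_sim_config(canvas = 96L, n_cells = 120L, seed = seed,
                    markers = tiny_markers, expression = expression, ...)
}

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rand4 <- function(H, W, C, N, fn = stats::runif) array(fn(H * W * C * N), c(H, W, C, N))
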