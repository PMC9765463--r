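# Small in-code fixtures shared across test files.

# ((A:1,B:1):1,C:2); -- the 3-tip tree used for hand-computed distances
three_tip_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# tiny deterministic count table
tiny_table <- function() {
  asv_table(matrix(c(5, 3, 2,
                     0, 0, 0),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
}

# simulate one plant's seeds under the neutral Dirichlet-multinomial model
simulate_plant_counts <- function(M, S = 20, R = 0.05,
                                  N_range = c(500, 2000), seed = 1) {
  withr::with_seed(seed, {
    mat <- t(vapply(seq_len(M), function(i) {
      N <- sample(N_range[1]:N_range[2], 1)
      theta <- R * (N - 1)
      g <- stats::rgamma(S, theta / S)
      stats::rmultinom(1, N, g / sum(g))[, 1]
    }, numeric(S)))
    dimnames(mat) <- list(sprintf("seed%03d", seq_len(M)),
                          sprintf("ASV%04d", seq_len(S)))
    asv_table(mat)
  })
}

# brute-force betaMNTD: literal double loop over taxa, no matrix tricks
bmntd_brute <- function(x, y, dmat, weighted = TRUE) {
  tx <- names(x)[x > 0]
  ty <- names(y)[y > 0]
  f <- x[tx] / sum(x[tx])
  g <- y[ty] / sum(y[ty])
  if (!weighted) {
    f <- rep(1 / length(tx), length(tx))
    g <- rep(1 / length(ty), length(ty))
  }
  s1 <- 0
  for (i in seq_along(tx)) {
    best <- Inf
    for (j in seq_along(ty)) best <- min(best, dmat[tx[i], ty[j]])
    s1 <- s1 + f[i] * best
  }
  s2 <- 0
  for (j in seq_along(ty)) {
    best <- Inf
    for (i in seq_along(tx)) best <- min(best, dmat[tx[i], ty[j]])
    s2 <- s2 + g[j] * best
  }
  unname(0.5 * (s1 + s2))
}
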