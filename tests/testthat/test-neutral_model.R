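test_that("beta-binomial pmf matches closed form, is symmetric, normalizes", {
  # N = 2, alpha = beta = 1/2: direct Beta-function enumeration gives
  # (3/8, 1/4, 3/8)
  expect_equal(bb_pmf(0:2, 2, 0.5, 0.5), c(3 / 8, 1 / 4, 3 / 8))
  for (N in c(3, 10, 50)) {
    for (ab in list(c(0.2, 0.7), c(1, 1), c(5, 2))) {
      p <- bb_pmf(0:N, N, ab[1], ab[2])
      expect_equal(sum(p), 1)
    }
    p <- bb_pmf(0:N, N, 0.4, 0.4)
    expect_equal(p, rev(p))
  }
  # binomial limit at huge concentration
  N <- 20
  p <- 0.3
  kappa <- 1e6
  expect_lt(max(abs(bb_pmf(0:N, N, kappa * p, kappa * (1 - p)) -
                      dbinom(0:N, N, p))), 1e-3)
  expect_error(bb_pmf(3, 2, 1, 1), "0..N")
})

test_that("concentration parameterization follows from the ratio", {
  lc <- local_concentration(1, 2, 2)
  expect_equal(lc$alpha, 0.5)
  expect_equal(lc$beta, 0.5)
  for (S in c(2, 3, 7)) {
    lc <- local_concentration(0.3, 11, S)
    expect_equal(lc$alpha + lc$beta, 0.3 * 10)
  }
})

test_that("exact Moran stationary distribution is exchangeable and matches the beta-binomial marginal", {
  # S = 1: monomorphic state absorbs all mass
  res1 <- moran_stationary_exact(4, 1, 0.3, 0.6)
  expect_equal(res1$pi, 1)

  res <- moran_stationary_exact(6, 3, 0.3, 0.6)
  expect_equal(sum(res$pi), 1)
  # exchangeability: marginal identical for every species label
  marg2 <- vapply(0:6, function(k) sum(res$pi[res$states[, 2] == k]),
                  numeric(1))
  expect_equal(res$marginal, marg2, tolerance = 1e-12)
  # the closed-form concentration theta = R (N - 1)
  R <- 0.3 / ((1 - 0.3) * 0.6)
  lc <- local_concentration(R, 6, 3)
  expect_lt(max(abs(res$marginal - bb_pmf(0:6, 6, lc$alpha, lc$beta))), 1e-10)
})

test_that("proportion moments are exact in the mean and match simulation", {
  for (S in c(2, 4, 10)) {
    expect_equal(proportion_moments(S, 0.7, 15)$m1, 1 / S)
  }
  # E p^2 at S=2, R=1, N=2 from enumerating the (3/8, 1/4, 3/8) pmf
  expect_equal(proportion_moments(2, 1, 2)$m2, 0.4375)

  # Monte-Carlo Dirichlet-multinomial oracle
  withr::with_seed(42, {
    S <- 5; R <- 0.2; N <- 100
    theta <- R * (N - 1)
    x <- vapply(seq_len(1e5), function(i) {
      g <- rgamma(S, theta / S)
      rmultinom(1, N, g / sum(g))[1, 1]
    }, numeric(1))
    p <- x / N
    pm <- proportion_moments(S, R, N)
    for (k in 1:3) {
      mc <- mean(p^k)
      se <- sd(p^k) / sqrt(length(p))
      expect_lt(abs(mc - pm[[k]]), 3 * se)
    }
  })

  # variance decreases in R at fixed S, N
  v <- vapply(c(0.01, 0.1, 1, 10), function(R) {
    pm <- proportion_moments(8, R, 200)
    pm$m2 - pm$m1^2
  }, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("mixed mean moments reduce correctly in degenerate limits", {
  # degenerate N range: same as single-N composition
  th <- mixed_mean_moments(10, 0.5, 80, 80, M = 1)
  pm <- proportion_moments(10, 0.5, 80)
  expect_equal(th$m1, pm$m1)
  expect_equal(th$m2, pm$m2)
  expect_equal(th$m3, pm$m3)
  # M = 1 equals the unconditional single-seed moments
  th1 <- mixed_mean_moments(10, 0.5, 50, 90, M = 1)
  expect_equal(th1$m2, th1$single$m2)
  # M -> infinity: concentration of the mean
  thB <- mixed_mean_moments(10, 0.5, 50, 90, M = 1e9)
  expect_equal(thB$m2, thB$m1^2, tolerance = 1e-6)
  expect_equal(thB$m3, thB$m1^3, tolerance = 1e-6)
})

test_that("empirical moments match hand arithmetic and the theory on simulated data", {
  # one ASV at proportion 1 in every seed
  tab <- asv_table(matrix(c(10, 20), 2, 1, dimnames = list(c("s1", "s2"), "a")))
  m <- empirical_mean_moments(tab, "a")
  expect_equal(c(m$m1, m$m2, m$m3), c(1, 1, 1))

  # two ASVs with across-seed means 0.75 and 0.25
  tab2 <- asv_table(matrix(c(3, 1,
                             3, 1), 2, 2, byrow = TRUE,
                           dimnames = list(c("s1", "s2"), c("a", "b"))))
  m2 <- empirical_mean_moments(tab2, c("a", "b"))
  expect_equal(m2$m2, (0.75^2 + 0.25^2) / 2)

  # large neutral simulation: empirical moments near theory
  tab3 <- simulate_plant_counts(M = 400, S = 20, R = 0.05, seed = 99)
  fl <- filter_by_total_abundance(tab3, 0.001)
  emp <- empirical_mean_moments(tab3, fl$retained_ids)
  nr <- estimate_n_range(tab3)
  th <- mixed_mean_moments(20, 0.05, nr[1], nr[2], M = emp$n_seeds)
  for (k in c("m1", "m2", "m3")) {
    expect_lt(abs(emp[[k]] - th[[k]]) / th[[k]], 0.15)
  }
})

test_that("local-size range uses 0.1/0.9 type-7 quantiles with a floor of 2", {
  expect_equal(unname(estimate_n_range(rep(500, 6))), c(500, 500))
  expect_equal(unname(estimate_n_range(1:10)), c(2, 9))
  expect_warning(r <- estimate_n_range(c(1, 1, 1)), "clamped")
  expect_equal(unname(r), c(2, 2))
  expect_error(estimate_n_range(c(100)), ">= 2")
})

test_that("the GMM recovers parameters from exact moments and flags monodominance", {
  th <- mixed_mean_moments(37.5, 0.8, 50, 120, M = 40)
  fit <- fit_neutral_gmm_moments(th, c(50, 120), M = 40)
  expect_lt(fit$J, 1e-10)
  expect_equal(fit$S_hat, 37.5, tolerance = 1e-3)
  expect_equal(fit$R_hat, 0.8, tolerance = 1e-3)

  # monodominant data: every seed is 100% one of A ASVs. The pooled
  # per-(ASV, seed) moments are exactly matched by S = A in the R -> 0
  # monodominance limit, so the ratio is driven to the lower boundary.
  withr::with_seed(3, {
    A <- 6; M <- 60
    mat <- matrix(0, M, A, dimnames = list(sprintf("s%02d", 1:M),
                                           sprintf("ASV%02d", 1:A)))
    owner <- sample(A, M, replace = TRUE)
    for (i in seq_len(M)) mat[i, owner[i]] <- 300
    tab <- asv_table(mat)
    fit2 <- fit_neutral_gmm(tab, colnames(mat), n_range = c(250, 350),
                            moment_mode = "pooled")
    fit3 <- fit_neutral_gmm(tab, colnames(mat), n_range = c(250, 350))
  })
  expect_equal(fit2$S_hat, A, tolerance = 0.1)
  expect_lt(fit2$R_hat, 1e-5)
  expect_true(fit2$at_bound)
  # the across-seed-mean mode also lands near S = A with a small ratio
  expect_equal(fit3$S_hat, A, tolerance = 0.25 * A)
  expect_lt(fit3$R_hat * (300 - 1), 2)  # theta in the monodominant regime
})

test_that("the dispersal index follows its convention and decreases with N", {
  tab <- simulate_plant_counts(M = 50, seed = 12)
  fl <- filter_by_total_abundance(tab, 0.001)
  fit <- fit_neutral_gmm(tab, fl$retained_ids)
  nseq <- fit$n_range[1]:fit$n_range[2]
  expect_equal(fit$I_hat, fit$R_hat * mean(1 / (nseq - 1)))
  fit2 <- fit_neutral_gmm(tab, fl$retained_ids,
                          i_convention = "dispersalnumber")
  expect_equal(fit2$I_hat, fit2$R_hat * mean(nseq - 1))
  # I decreasing in N at fixed R (per-capita convention)
  i_small <- 0.3 * mean(1 / ((10:20) - 1))
  i_large <- 0.3 * mean(1 / ((100:200) - 1))
  expect_lt(i_large, i_small)
})

test_that("per-group fitting returns one row per plant-by-stage group", {
  cfg <- scenario_config("neutral", n_plants = 2, seeds_per_plant = 25,
                         stage_days = c(26, 37), rng_seed = 8)
  st <- simulate_study(cfg)
  fits <- fit_neutral_by_group(st$table, st$metadata)
  expect_equal(nrow(fits), 4)
  expect_true(all(fits$fitted))
  expect_true(all(fits$S_hat > 2))
  # recovered pool sizes should sit near the generator's S = 20
  expect_lt(max(abs(fits$S_hat - 20) / 20), 0.25)
})
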