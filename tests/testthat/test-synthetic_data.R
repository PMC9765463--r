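test_that("simulated trees are rooted, bifurcating, exponential-length, seeded", {
  tr <- simulate_tree(2, rng_seed = 1)
  expect_equal(length(tr$tip.label), 2)
  expect_true(ape::is.rooted(tr))

  tr1 <- simulate_tree(50, rng_seed = 9)
  tr2 <- simulate_tree(50, rng_seed = 9)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))

  tr3 <- simulate_tree(100, rng_seed = 2)
  expect_equal(tr3$Nnode, 99)           # 2n - 2 edges, n - 1 internal nodes
  expect_equal(nrow(tr3$edge), 198)
  expect_true(all(tr3$edge.length > 0))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("simulation is deterministic and internally consistent", {
  cfg <- scenario_config("neutral", n_plants = 2, seeds_per_plant = 10,
                         stage_days = c(26), rng_seed = 33)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(asv_counts(s1$table), asv_counts(s2$table))
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))

  # truth covers every sample; every table ASV is a tree tip
  expect_setequal(s1$truth$seeds$sample_id, sample_ids(s1$table))
  expect_true(all(asv_ids(s1$table) %in% s1$tree$tip.label))
  # row totals equal the true local sizes
  expect_equal(unname(sample_totals(s1$table)),
               s1$truth$seeds$N_c[match(sample_ids(s1$table),
                                        s1$truth$seeds$sample_id)])
})

test_that("drift scenario produces the monodominance regime", {
  cfg <- scenario_config("drift", n_plants = 2, seeds_per_plant = 100,
                         stage_days = c(26), theta_drift = 0.1, rng_seed = 6)
  st <- simulate_study(cfg)
  dom <- dominance_profile(st$table)
  expect_gte(mean(dom$rank1_ra), 0.70)
})

test_that("very large concentration flattens compositions toward 1/S", {
  cfg <- scenario_config("neutral", n_plants = 1, seeds_per_plant = 20,
                         stage_days = c(26), S = 10, R = 1000,
                         N_range = c(1000, 1000), rng_seed = 7)
  st <- simulate_study(cfg)
  ct <- asv_counts(st$table)
  p <- ct[, colSums(ct) > 0] / rowSums(ct)
  expect_lt(max(abs(p - 1 / 10)), 0.1)
})

test_that("neutral single-ASV counts follow the beta-binomial marginal", {
  # fixed N so the marginal is a single beta-binomial; chi-square GOF
  S <- 5; R <- 0.2; N <- 60
  cfg <- scenario_config("neutral", n_plants = 1, seeds_per_plant = 10000,
                         stage_days = c(26), S = S, R = R,
                         N_range = c(N, N), n_tips = 10, rng_seed = 13)
  st <- simulate_study(cfg)
  ct <- asv_counts(st$table)
  pool <- st$truth$pools[["P01"]]
  x <- ct[, pool[1]]
  lc <- local_concentration(R, N, S)
  pr <- bb_pmf(0:N, N, lc$alpha, lc$beta)
  # bin the upper tail so expected counts stay above 5
  brk <- c(-0.5, seq(0.5, 20.5, 1), N + 0.5)
  obs <- table(cut(x, brk))
  expp <- vapply(seq_len(length(brk) - 1), function(i) {
    sum(pr[(0:N) > brk[i] & (0:N) < brk[i + 1]])
  }, numeric(1))
  keep <- expp * length(x) >= 5
  chi <- sum((as.numeric(obs[keep]) - length(x) * expp[keep])^2 /
               (length(x) * expp[keep]))
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("the observation model detects at rate q and resamples to depth", {
  cfg <- scenario_config("neutral", n_plants = 1, seeds_per_plant = 1000,
                         stage_days = c(26), rng_seed = 3)
  st <- simulate_study(cfg)

  # q = 0: nothing detected
  st0 <- apply_observation_model(st, q = 0, depth = 100, rng_seed = 1)
  expect_equal(sum(asv_counts(st0$table)), 0)
  det0 <- detection_summary(st0$table, st0$metadata, "stage_day")
  expect_equal(det0$fraction, 0)

  # q = 1 on a single-ASV composition returns all reads on that ASV
  one <- st
  ct <- asv_counts(one$table) * 0
  ct[, 1] <- 777
  one$table <- asv_table(ct)
  st1 <- apply_observation_model(one, q = 1, depth = 777, rng_seed = 2)
  expect_true(all(asv_counts(st1$table)[, 1] == 777))

  # q = 0.6: observed detection fraction within 3 binomial SE
  st6 <- apply_observation_model(st, q = 0.6, depth = 500, rng_seed = 4)
  f <- mean(sample_totals(st6$table) > 0)
  se <- sqrt(0.6 * 0.4 / 1000)
  expect_lt(abs(f - 0.6), 3 * se)
  # detected samples carry exactly `depth` reads
  tot <- sample_totals(st6$table)
  expect_true(all(tot[tot > 0] == 500))
})

test_that("selection scenario clusters plants phylogenetically relative to neutral", {
  hs <- vapply(c("neutral", "selection"), function(sc) {
    cfg <- scenario_config(sc, n_plants = 4, seeds_per_plant = 12,
                           stage_days = c(26), rng_seed = 5)
    st <- apply_observation_model(simulate_study(cfg))
    agg <- aggregate_by_plant(st$table, st$metadata, "plant_id")
    b <- bnti(agg, st$tree, n_null = 199, rng_seed = 3)
    median(b$bnti)
  }, numeric(1))
  expect_lt(hs["selection"], hs["neutral"])
})

test_that("studies round-trip through disk and seedling pairing validates", {
  cfg <- scenario_config("neutral", n_plants = 2, seeds_per_plant = 6,
                         stage_days = c(26, 65), make_seedlings = TRUE,
                         extra_habitats = "atmosphere", rng_seed = 19)
  st <- apply_observation_model(simulate_study(cfg))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  tab <- read_asv_table(paths["table"])
  md <- read_metadata(paths["metadata"])
  tr <- read_newick(paths["tree"])
  expect_identical(asv_counts(tab), asv_counts(st$table))
  expect_silent(validate_metadata(md, tab))
  expect_setequal(tr$tip.label, st$tree$tip.label)
  expect_true(any(md$habitat == "seedling"))
  expect_true(any(md$habitat == "atmosphere"))
})
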