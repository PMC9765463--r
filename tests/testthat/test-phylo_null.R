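test_that("cophenetic distances match hand path sums", {
  tr <- three_tip_tree()
  d <- cophenetic_matrix(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_error(cophenetic_matrix(tr, c("A", "Z")), "Z")

  # star tree with equal lengths L: all off-diagonal 2L
  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  ds <- cophenetic_matrix(star)
  expect_equal(unname(ds[upper.tri(ds)]), rep(6, 6))
})

test_that("Faith PD sums the minimal root-inclusive subtree", {
  tr <- three_tip_tree()
  expect_equal(faith_pd(tr, c("A", "C")), 4)
  expect_equal(faith_pd(tr, c("A", "B", "C")), 5)
  expect_equal(faith_pd(tr, "A"), 2)
  expect_error(faith_pd(tr, character(0)), "no tips")

  # independent cross-check on a bigger random tree
  skip_if_not_installed("picante")
  tr2 <- simulate_tree(40, rng_seed = 21)
  sets <- withr::with_seed(5, replicate(10, sample(tr2$tip.label, sample(2:15, 1)),
                                        simplify = FALSE))
  comm <- t(vapply(sets, function(s) as.numeric(tr2$tip.label %in% s),
                   numeric(40)))
  colnames(comm) <- tr2$tip.label
  ref <- picante::pd(comm, tr2, include.root = TRUE)$PD
  ours <- vapply(sets, function(s) faith_pd(tr2, s), numeric(1))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("betaMNTD matches hand values, brute force, and picante", {
  tr <- three_tip_tree()
  d <- cophenetic_matrix(tr)
  x <- c(A = 1, B = 0, C = 0)
  y <- c(A = 0, B = 0, C = 1)
  expect_equal(bmntd(x, y, d), 4)          # 0.5 * (4 + 4)
  expect_equal(bmntd(x, x, d), 0)          # identical communities
  expect_equal(bmntd(x, y, d, weighted = FALSE), 4)
  expect_error(bmntd(c(A = 0), y, d), "empty")

  # exhaustive brute-force equivalence on random instances up to 10 taxa
  tr2 <- simulate_tree(30, rng_seed = 2)
  d2 <- cophenetic_matrix(tr2)
  withr::with_seed(17, {
    for (rep in 1:30) {
      nx <- sample(1:10, 1); ny <- sample(1:10, 1)
      x <- numeric(30); names(x) <- tr2$tip.label
      y <- x
      x[sample(30, nx)] <- rpois(nx, 8) + 1
      y[sample(30, ny)] <- rpois(ny, 8) + 1
      expect_equal(bmntd(x, y, d2), bmntd_brute(x, y, d2), tolerance = 1e-12)
      expect_equal(bmntd(x, y, d2, weighted = FALSE),
                   bmntd_brute(x, y, d2, weighted = FALSE), tolerance = 1e-12)
    }
  })

  skip_if_not_installed("picante")
  comm <- withr::with_seed(9, {
    m <- matrix(rpois(4 * 30, 2), 4, 30,
                dimnames = list(paste0("c", 1:4), tr2$tip.label))
    m[rowSums(m) == 0, 1] <- 1
    m
  })
  ref <- as.matrix(picante::comdistnt(comm, d2, abundance.weighted = TRUE))
  rel <- comm / rowSums(comm)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(bmntd(rel[i, ], rel[j, ], d2), ref[i, j], tolerance = 1e-10)
  }
})

test_that("betaNTI is seeded, flags degenerate nulls, and is relabeling-invariant", {
  tr <- simulate_tree(40, rng_seed = 4)
  mat <- withr::with_seed(11, {
    m <- matrix(0, 3, 40, dimnames = list(paste0("c", 1:3), tr$tip.label))
    for (i in 1:3) m[i, sample(40, 8)] <- rpois(8, 10) + 1
    m
  })
  tab <- asv_table(mat)
  b1 <- bnti(tab, tr, n_null = 99, rng_seed = 5)
  b2 <- bnti(tab, tr, n_null = 99, rng_seed = 5)
  expect_identical(b1, b2)

  # n_null = 1 cannot estimate a spread
  b3 <- bnti(tab, tr, n_null = 1, rng_seed = 5)
  expect_true(all(b3$flag))
  expect_true(all(is.na(b3$bnti)))

  # joint relabeling of table and tree leaves scores unchanged
  relab <- setNames(sprintf("TAX%02d", seq_len(40)), tr$tip.label)
  tr2 <- tr
  tr2$tip.label <- unname(relab[tr$tip.label])
  mat2 <- mat
  colnames(mat2) <- unname(relab[colnames(mat)])
  b4 <- bnti(asv_table(mat2), tr2, n_null = 99, rng_seed = 5)
  expect_equal(b4$bnti, b1$bnti, tolerance = 1e-12)
})

test_that("communities confined to a compact clade score as clustered", {
  tr <- simulate_tree(100, rng_seed = 42)
  cl <- seedasm:::.pick_clade(tr, 10)
  scores <- withr::with_seed(11, {
    vapply(1:15, function(k) {
      t1 <- sample(cl, 6)
      t2 <- sample(cl, 6)
      u <- union(t1, t2)
      m <- matrix(0, 2, length(u), dimnames = list(c("a", "b"), u))
      m["a", t1] <- rpois(6, 20) + 1
      m["b", t2] <- rpois(6, 20) + 1
      bnti(asv_table(m), tr, n_null = 199, rng_seed = k)$bnti
    }, numeric(1))
  })
  expect_gt(mean(scores < -2), 0.5)
})

test_that("Raup-Crick hits its extremes and stays within [-1, 1]", {
  m <- matrix(c(10, 5, 3, 2,
                10, 5, 3, 2), 2, byrow = TRUE,
              dimnames = list(c("x", "y"), paste0("ASV", 1:4)))
  rc_id <- raup_crick_bray(asv_table(m), n_null = 199, rng_seed = 1)$rc
  expect_lt(abs(rc_id - (-1)), 0.05)

  # disjoint communities over a large shared pool
  big <- withr::with_seed(2, {
    mm <- matrix(rpois(6 * 40, 3), 6, 40,
                 dimnames = list(paste0("c", 1:6), sprintf("ASV%02d", 1:40)))
    mm[1, ] <- 0; mm[1, 1:15] <- 50
    mm[2, ] <- 0; mm[2, 26:40] <- 50
    mm
  })
  rc <- raup_crick_bray(asv_table(big), n_null = 199, rng_seed = 3)
  expect_true(all(rc$rc >= -1 & rc$rc <= 1))
  expect_gt(rc$rc[rc$comm_i == "c1" & rc$comm_j == "c2"], 0.9)
})

test_that("the QPE rule labels pairs and fractions normalize", {
  expect_equal(qpe_classify(-3), "homogeneous selection")
  expect_equal(qpe_classify(3), "variable selection")
  expect_equal(qpe_classify(0.5, 0.99), "dispersal limitation")
  expect_equal(qpe_classify(0.5, -0.99), "homogenizing dispersal")
  expect_equal(qpe_classify(0, 0), "drift")
  expect_error(qpe_classify(0.5), "required")

  s <- qpe_summarize(rep("homogeneous selection", 4))
  expect_equal(s$fraction[s$process == "homogeneous selection"], 1)
  s2 <- qpe_summarize(c("drift", "drift", "dispersal limitation",
                        "dispersal limitation"))
  expect_equal(sum(s2$fraction), 1, tolerance = 1e-12)
  expect_equal(s2$fraction[s2$process == "drift"], 0.5)
  expect_error(qpe_summarize(character(0)), "no labeled pairs")
})
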