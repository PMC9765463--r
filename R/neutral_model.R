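#' Beta-binomial probability mass function
#'
#' P(X = n) = choose(N, n) B(n + alpha, N - n + beta) / B(alpha, beta),
#' computed in log space. This is the stationary marginal of a single taxon's
#' abundance in a local community of fixed size `N` governed by immigration
#' and internal random replacement (see [moran_stationary_exact()]).
#'
#' @param n integer count(s) in `0..N`.
#' @param N local community size.
#' @param alpha,beta positive shape parameters.
#' @param log return log probabilities.
#' @return numeric vector of probabilities.
#' @export
bb_pmf <- function(n, N, alpha, beta, log = FALSE) {
  if (any(n < 0 | n > N | n != round(n))) {
    stop("`n` must be integers in 0..N", call. = FALSE)
  }
  if (alpha <= 0 || beta <= 0) stop("shapes must be positive", call. = FALSE)
  lp <- lchoose(N, n) + lbeta(n + alpha, N - n + beta) - lbeta(alpha, beta)
  if (log) lp else exp(lp)
}

#' Concentration parameters implied by the replacement ratio
#'
#' Under the immigration/replacement model with composite ratio
#' R = mu / ((1 - mu) C), the stationary composition of a community of size N
#' drawn from an S-species pool is Dirichlet-multinomial with symmetric
#' concentration theta = R (N - 1). The single-taxon marginal is then
#' beta-binomial with `alpha = theta / S`, `beta = theta (S - 1) / S`.
#' The identity theta = R (N - 1) follows from detailed balance of the Moran
#' chain and is verified exactly against [moran_stationary_exact()] in the
#' test suite.
#'
#' @param R replacement ratio, > 0.
#' @param N local community size, >= 2 (vectorized).
#' @param S species pool size, >= 2 (real-valued allowed).
#' @return list with `alpha`, `beta`, `theta` (vectorized over `N`).
#' @export
local_concentration <- function(R, N, S) {
  if (R <= 0) stop("`R` must be positive", call. = FALSE)
  if (any(N < 2)) stop("`N` must be >= 2", call. = FALSE)
  if (S < 2) stop("`S` must be >= 2", call. = FALSE)
  theta <- R * (N - 1)
  list(alpha = theta / S, beta = theta * (S - 1) / S, theta = theta)
}

#' Exact stationary distribution of the immigration/replacement Moran chain
#'
#' Brute-force oracle for small state spaces. The community holds exactly `N`
#' individuals from `S` species. Per event a uniformly chosen resident dies;
#' it is replaced by a uniformly chosen pool species with probability `mu`, by
#' a copy of a uniformly chosen surviving resident with probability
#' `(1 - mu) C`, and by an individual of its own species otherwise (the
#' community is unchanged). The full transition matrix over compositions of
#' `N` into `S` parts is built and the stationary distribution solved by
#' linear algebra. Used to validate the closed-form beta-binomial marginal.
#'
#' @param N community size (small; state space grows combinatorially).
#' @param S pool size (small).
#' @param mu immigration probability in (0, 1).
#' @param C internal replacement probability in (0, 1).
#' @param max_states refuse state spaces larger than this.
#' @return list with `states` (matrix, one composition per row), `pi`
#'   (stationary probabilities), and `marginal` (length `N + 1` vector,
#'   stationary pmf of species 1's abundance).
#' @export
moran_stationary_exact <- function(N, S, mu, C, max_states = 5000L) {
  stopifnot(N >= 1, S >= 1, mu > 0, mu < 1, C > 0, C < 1)
  states <- .compositions(N, S)
  ns <- nrow(states)
  if (ns > max_states) {
    stop(sprintf("state space too large (%d > %d)", ns, max_states),
         call. = FALSE)
  }
  key <- apply(states, 1, paste, collapse = ",")
  idx <- stats::setNames(seq_len(ns), key)
  repl <- (1 - mu) * C
  P <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    nvec <- states[s, ]
    for (i in seq_len(S)) {
      if (nvec[i] == 0) next
      p_die <- nvec[i] / N
      for (j in seq_len(S)) {
        # immigration of species j
        p <- p_die * mu / S
        # copy of a surviving resident of species j
        if (N > 1) {
          surv <- nvec[j] - (i == j)
          p <- p + p_die * repl * surv / (N - 1)
        }
        if (i == j) {
          # includes the "unchanged" branch
          p <- p + p_die * (1 - mu) * (1 - C) +
            if (N == 1) p_die * repl else 0
          P[s, s] <- P[s, s] + p
        } else if (p > 0) {
          tgt <- nvec
          tgt[i] <- tgt[i] - 1
          tgt[j] <- tgt[j] + 1
          P[s, idx[[paste(tgt, collapse = ",")]]] <-
            P[s, idx[[paste(tgt, collapse = ",")]]] + p
        }
      }
    }
  }
  A <- t(P) - diag(ns)
  A[ns, ] <- 1
  b <- c(rep(0, ns - 1), 1)
  pi <- solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  marg <- vapply(0:N, function(k) sum(pi[states[, 1] == k]), numeric(1))
  list(states = states, pi = pi, marginal = marg)
}

.compositions <- function(N, S) {
  if (S == 1) return(matrix(N, 1, 1))
  do.call(rbind, lapply(0:N, function(k) {
    cbind(k, .compositions(N - k, S - 1), deparse.level = 0)
  }))
}

#' Closed-form raw moments of a taxon's proportion
#'
#' For X ~ beta-binomial(N, alpha, beta) with alpha = theta/S,
#' theta = R (N - 1), and p = X / N, the first three raw moments follow from
#' the falling factorial moments
#' E[(X)_k] = (N)_k (alpha)^(k) / (theta)^(k) (rising factorials in the
#' shapes):
#' E p = 1/S; E p^2 = (E[(X)_2] + E X) / N^2;
#' E p^3 = (E[(X)_3] + 3 E[(X)_2] + E X) / N^3.
#'
#' @param S pool size >= 2 (real-valued allowed).
#' @param R replacement ratio > 0.
#' @param N local size(s) >= 2 (vectorized).
#' @return list of numeric vectors `m1`, `m2`, `m3` (one element per `N`).
#' @export
proportion_moments <- function(S, R, N) {
  lc <- local_concentration(R, N, S)
  a <- lc$alpha
  th <- lc$theta
  ex1 <- N * a / th                                    # = N / S
  ex2f <- N * (N - 1) * a * (a + 1) / (th * (th + 1))  # E[(X)_2]
  ex3f <- N * (N - 1) * (N - 2) * a * (a + 1) * (a + 2) /
    (th * (th + 1) * (th + 2))                         # E[(X)_3]
  list(
    m1 = rep_len(1 / S, length(N)),
    m2 = (ex2f + ex1) / N^2,
    m3 = (ex3f + 3 * ex2f + ex1) / N^3
  )
}

#' Theoretical moments of the across-seed mean proportion
#'
#' The local size N varies from seed to seed; it is modeled as discrete
#' uniform on `[N_min, N_max]`. Mixing the per-N proportion moments over that
#' range gives unconditional single-seed moments M_k; the statistic actually
#' observed is the mean proportion over `M` i.i.d. seeds, whose raw moments
#' are `T1 = M1`, `T2 = M1^2 + v/M`, `T3 = M1^3 + 3 M1 v / M + g / M^2`, with
#' `v` and `g` the single-seed central second and third moments.
#'
#' @param S,R model parameters.
#' @param N_min,N_max integer bounds of the uniform local-size distribution.
#' @param M number of seeds averaged.
#' @param mode `"mean"`: moments of the across-seed mean (default);
#'   `"pooled"`: unconditional single-seed moments M_k.
#' @return list `m1`, `m2`, `m3` plus `single` (the M_k).
#' @export
mixed_mean_moments <- function(S, R, N_min, N_max, M, mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(N_min >= 2, N_max >= N_min, M >= 1)
  pm <- proportion_moments(S, R, N_min:N_max)
  M1 <- mean(pm$m1)
  M2 <- mean(pm$m2)
  M3 <- mean(pm$m3)
  single <- list(m1 = M1, m2 = M2, m3 = M3)
  if (mode == "pooled") {
    return(c(single, list(single = single)))
  }
  v <- M2 - M1^2
  g <- M3 - 3 * M1 * M2 + 2 * M1^3
  list(
    m1 = M1,
    m2 = M1^2 + v / M,
    m3 = M1^3 + 3 * M1 * v / M + g / M^2,
    single = single
  )
}

#' Empirical moments of seed-borne ASV proportions at the plant level
#'
#' For one plant at one date: per-seed proportions are computed relative to
#' each seed's *unfiltered* read total, so proportions of retained ASVs need
#' not sum to one; the across-seed mean proportion of each retained ASV is
#' formed (zeros counted for absences), and the first three raw moments are
#' taken across ASVs. Seeds with no retained counts are excluded from the
#' seed count `M` (the model describes colonized seeds; non-detection is
#' summarized separately).
#'
#' @param table an `asv_table` restricted to one plant x date group
#'   (unfiltered columns).
#' @param retained_ids ASVs retained by [filter_by_total_abundance()].
#' @param mode `"mean"` (moments across ASVs of the across-seed mean) or
#'   `"pooled"` (moments across all ASV-by-seed proportions).
#' @return list `m1`, `m2`, `m3`, `n_asvs`, `n_seeds`.
#' @export
empirical_mean_moments <- function(table, retained_ids, mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "asv_table"))
  if (length(retained_ids) < 1) stop("no retained ASVs", call. = FALSE)
  ct <- asv_counts(table)
  tot <- rowSums(ct)
  sub <- ct[, retained_ids, drop = FALSE]
  keep <- tot > 0 & rowSums(sub) > 0
  if (sum(keep) < 2) {
    stop("need >= 2 seeds with retained counts", call. = FALSE)
  }
  p <- sub[keep, , drop = FALSE] / tot[keep]
  if (mode == "mean") {
    pbar <- colMeans(p)
    m <- vapply(1:3, function(k) mean(pbar^k), numeric(1))
  } else {
    m <- vapply(1:3, function(k) mean(p^k), numeric(1))
  }
  list(m1 = m[1], m2 = m[2], m3 = m[3],
       n_asvs = ncol(p), n_seeds = nrow(p))
}

#' Estimate the local-size range from per-seed totals
#'
#' The local population size N is taken to range over the 0.1 and 0.9
#' empirical quantiles (type-7 interpolation, rounded to nearest integers,
#' floored at 2) of the per-seed total across the non-empty seeds of one
#' plant at one date. Totals are read counts by default; per-seed richness is
#' available as an alternative reading of "total ASV number".
#'
#' @param table an `asv_table` (one plant x date group) or a numeric vector
#'   of per-seed totals.
#' @param use `"reads"` (per-seed read totals, default) or `"richness"`
#'   (number of ASVs with positive counts).
#' @return integer vector `c(N_min, N_max)`.
#' @export
estimate_n_range <- function(table, use = c("reads", "richness")) {
  use <- match.arg(use)
  if (inherits(table, "asv_table")) {
    ct <- asv_counts(table)
    x <- if (use == "reads") rowSums(ct) else rowSums(ct > 0)
  } else {
    x <- as.numeric(table)
  }
  x <- x[x > 0]
  if (length(x) < 2) stop("need >= 2 non-empty seeds", call. = FALSE)
  q <- stats::quantile(x, c(0.1, 0.9), type = 7, names = FALSE)
  r <- round(q)
  if (any(r < 2)) {
    warning("local-size quantile below 2; clamped", call. = FALSE)
    r <- pmax(r, 2)
  }
  c(N_min = as.integer(r[1]), N_max = as.integer(r[2]))
}

#' Fit the neutral model by generalized moment estimation
#'
#' Minimizes the relative-error criterion
#' J(S, R) = sum_k w_k (m_k - T_k(S, R))^2 with weights w_k = m_k^-2 over the
#' first three moments of the mean proportion, on log S in `[log 2, log 1e6]`
#' and log R in `[-14, 7]`. A coarse 25 x 25 log-grid scan is refined by
#' Nelder-Mead from the best grid points. Returns the fitted pool size S, the
#' replacement ratio R, the expected dispersal index I, and the attained
#' error criterion J*.
#'
#' The dispersal index per seed is I_c = R / (N_c - 1) (per-capita
#' immigration over per-capita replacement); `I_hat` is its expectation over
#' the uniform N range. The alternative convention I_c = R (N_c - 1) is
#' available via `i_convention = "dispersalnumber"`.
#'
#' @param table an `asv_table` restricted to one plant x date group.
#' @param retained_ids ASVs retained by the abundance filter.
#' @param n_range integer `c(N_min, N_max)`; computed by
#'   [estimate_n_range()] when `NULL`.
#' @param moment_mode `"mean"` or `"pooled"`, see
#'   [empirical_mean_moments()].
#' @param i_convention `"percapita"` (default) or `"dispersalnumber"`.
#' @param grid_n grid points per axis for the coarse scan.
#' @param n_starts how many best grid points seed the local refinement.
#' @return an object of class `neutral_fit`: list with `S_hat`, `R_hat`,
#'   `I_hat`, `J`, `moments_emp`, `moments_fit`, `n_range`, `n_seeds`,
#'   `n_asvs`, `converged`, `moment_mode`, `i_convention`.
#' @export
fit_neutral_gmm <- function(table, retained_ids, n_range = NULL,
                            moment_mode = c("mean", "pooled"),
                            i_convention = c("percapita", "dispersalnumber"),
                            grid_n = 25L, n_starts = 3L) {
  moment_mode <- match.arg(moment_mode)
  i_convention <- match.arg(i_convention)
  if (is.null(n_range)) n_range <- estimate_n_range(table)
  emp <- empirical_mean_moments(table, retained_ids, mode = moment_mode)
  fit_neutral_gmm_moments(emp, n_range, M = emp$n_seeds,
                          moment_mode = moment_mode,
                          i_convention = i_convention,
                          grid_n = grid_n, n_starts = n_starts)
}

#' @rdname fit_neutral_gmm
#' @param moments a moment set (list with `m1`, `m2`, `m3`), e.g. from
#'   [empirical_mean_moments()] or [mixed_mean_moments()].
#' @param M number of seeds behind the mean (ignored for pooled mode).
#' @export
fit_neutral_gmm_moments <- function(moments, n_range, M,
                                    moment_mode = c("mean", "pooled"),
                                    i_convention = c("percapita", "dispersalnumber"),
                                    grid_n = 25L, n_starts = 3L) {
  moment_mode <- match.arg(moment_mode)
  i_convention <- match.arg(i_convention)
  mhat <- c(moments$m1, moments$m2, moments$m3)
  if (any(!is.finite(mhat)) || any(mhat <= 0)) {
    stop("empirical moments must be positive and finite", call. = FALSE)
  }
  w <- mhat^-2
  lo <- c(log(2), -14)
  hi <- c(log(1e6), 7)
  nseq <- n_range[1]:n_range[2]
  obj <- function(par) {
    pen <- sum(pmax(par - hi, 0)^2) + sum(pmax(lo - par, 0)^2)
    par <- pmin(pmax(par, lo), hi)
    th <- mixed_mean_moments(exp(par[1]), exp(par[2]),
                             n_range[1], n_range[2], M, mode = moment_mode)
    sum(w * (mhat - c(th$m1, th$m2, th$m3))^2) + 1e6 * pen
  }
  gs <- seq(lo[1], hi[1], length.out = grid_n)
  gr <- seq(lo[2], hi[2], length.out = grid_n)
  grid <- as.matrix(expand.grid(logS = gs, logR = gr))
  jgrid <- apply(grid, 1, obj)
  starts <- grid[order(jgrid)[seq_len(n_starts)], , drop = FALSE]
  best <- NULL
  conv <- FALSE
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    if (is.null(best) || o$value < best$value) {
      best <- o
      conv <- o$convergence == 0
    }
  }
  par <- pmin(pmax(best$par, lo), hi)
  S_hat <- exp(par[1])
  R_hat <- exp(par[2])
  I_hat <- switch(i_convention,
                  percapita = R_hat * mean(1 / (nseq - 1)),
                  dispersalnumber = R_hat * mean(nseq - 1))
  fitm <- mixed_mean_moments(S_hat, R_hat, n_range[1], n_range[2], M,
                             mode = moment_mode)
  structure(list(
    S_hat = unname(S_hat), R_hat = unname(R_hat), I_hat = unname(I_hat),
    J = best$value,
    moments_emp = mhat,
    moments_fit = c(fitm$m1, fitm$m2, fitm$m3),
    n_range = n_range, n_seeds = M,
    n_asvs = moments$n_asvs %||% NA_integer_,
    converged = conv,
    at_bound = any(abs(par - lo) < 1e-8) || any(abs(par - hi) < 1e-8),
    moment_mode = moment_mode, i_convention = i_convention
  ), class = "neutral_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf(
    "<neutral_fit> S = %.3g, R = %.4g, I = %.4g, J* = %.3g (%s%s)\n  N in [%d, %d], %s seeds, %s ASVs\n",
    x$S_hat, x$R_hat, x$I_hat, x$J,
    if (x$converged) "converged" else "NOT converged",
    if (x$at_bound) ", at bound" else "",
    x$n_range[1], x$n_range[2], x$n_seeds, x$n_asvs))
  invisible(x)
}

#' Fit the neutral model for every plant-by-stage group
#'
#' Applies the > `filter_fraction` abundance filter within each group (all
#' seed samples of one plant at one date), estimates the local-size range,
#' and fits the generalized moment criterion. Groups with fewer than
#' `min_seeds` colonized seeds or fewer than `min_asvs` retained ASVs are
#' skipped (reported in the result).
#'
#' @param table an `asv_table` of seed samples.
#' @param metadata metadata covering the table's samples.
#' @param group_by metadata columns defining groups.
#' @param filter_fraction abundance-filter threshold (default 0.001).
#' @param min_seeds,min_asvs minimum group size to attempt a fit.
#' @param ... passed to [fit_neutral_gmm()].
#' @return a `data.frame`, one row per group, with the fitted quantities and
#'   a `fitted` flag.
#' @export
fit_neutral_by_group <- function(table, metadata,
                                 group_by = c("plant_id", "stage_day"),
                                 filter_fraction = 0.001,
                                 min_seeds = 5L, min_asvs = 2L, ...) {
  .check_coverage(metadata, table)
  md <- metadata[match(sample_ids(table), metadata$sample_id), , drop = FALSE]
  key <- interaction(md[group_by], drop = TRUE, sep = "|")
  out <- lapply(levels(key), function(g) {
    ids <- sample_ids(table)[key == g]
    sub <- subset_table(table, samples = ids)
    info <- md[match(ids[1], md$sample_id), group_by, drop = FALSE]
    base <- data.frame(info, n_samples = length(ids), row.names = NULL,
                       check.names = FALSE)
    fl <- try(filter_by_total_abundance(sub, filter_fraction), silent = TRUE)
    if (inherits(fl, "try-error") || length(fl$retained_ids) < min_asvs ||
        sum(rowSums(asv_counts(sub)) > 0) < min_seeds) {
      return(cbind(base, fitted = FALSE, S_hat = NA_real_, R_hat = NA_real_,
                   I_hat = NA_real_, J = NA_real_, N_min = NA_integer_,
                   N_max = NA_integer_, n_seeds = NA_integer_,
                   n_asvs = NA_integer_))
    }
    fit <- fit_neutral_gmm(sub, fl$retained_ids, ...)
    cbind(base, fitted = TRUE, S_hat = fit$S_hat, R_hat = fit$R_hat,
          I_hat = fit$I_hat, J = fit$J, N_min = unname(fit$n_range[1]),
          N_max = unname(fit$n_range[2]), n_seeds = fit$n_seeds,
          n_asvs = fit$n_asvs)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
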