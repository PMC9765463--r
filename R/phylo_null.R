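#' Cophenetic (patristic) distance matrix for a set of tips
#'
#' Sum of branch lengths along the path between every pair of the requested
#' tips, via [ape::cophenetic.phylo()].
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param tips tip labels to include (default: all).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
cophenetic_matrix <- function(tree, tips = tree$tip.label) {
  validate_phylogeny(tree)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) {
    stop("tip(s) not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full <- ape::cophenetic.phylo(tree)
  full[tips, tips, drop = FALSE]
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal rooted subtree connecting the present
#' tips to the root (root-inclusive, so a single tip scores its root-to-tip
#' path length).
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param present_tips non-empty set of tip labels.
#' @return branch-length sum (numeric scalar).
#' @export
faith_pd <- function(tree, present_tips) {
  validate_phylogeny(tree)
  present_tips <- unique(present_tips)
  if (length(present_tips) == 0) stop("no tips given", call. = FALSE)
  idx <- match(present_tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("tip(s) not in tree: ",
         paste(present_tips[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  n_node <- max(tree$edge)
  child2edge <- match(seq_len(n_node), tree$edge[, 2])
  keep <- logical(nrow(tree$edge))
  for (node in idx) {
    while (!is.na(e <- child2edge[node])) {
      if (keep[e]) break
      keep[e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[keep])
}

#' Beta mean-nearest-taxon distance between two communities
#'
#' The abundance-weighted mean, over the taxa of each community, of the
#' phylogenetic distance to the closest relative in the other community:
#' 0.5 * (sum_i f_i min_j d_ij + sum_j g_j min_i d_ij). Taxa shared by both
#' communities contribute zero to their own minimum. With
#' `weighted = FALSE`, taxa are weighted equally (incidence-based).
#'
#' @param abund_i,abund_j named non-negative abundance vectors (relative or
#'   raw; each is normalized over its positive entries).
#' @param dist cophenetic distance matrix indexing all taxa present.
#' @param weighted abundance-weighted (default) or incidence-based.
#' @return numeric scalar.
#' @export
bmntd <- function(abund_i, abund_j, dist, weighted = TRUE) {
  ti <- names(abund_i)[abund_i > 0]
  tj <- names(abund_j)[abund_j > 0]
  if (length(ti) == 0 || length(tj) == 0) {
    stop("empty community", call. = FALSE)
  }
  missing <- setdiff(c(ti, tj), rownames(dist))
  if (length(missing)) {
    stop("taxa absent from distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  f <- abund_i[ti] / sum(abund_i[ti])
  g <- abund_j[tj] / sum(abund_j[tj])
  if (!weighted) {
    f <- rep(1 / length(ti), length(ti))
    g <- rep(1 / length(tj), length(tj))
  }
  sub <- dist[ti, tj, drop = FALSE]
  mins_i <- apply(sub, 1, min)
  mins_j <- apply(sub, 2, min)
  unname(0.5 * (sum(f * mins_i) + sum(g * mins_j)))
}

.pairwise_bmntd <- function(relmat, dist, weighted = TRUE) {
  n <- nrow(relmat)
  pairs <- utils::combn(n, 2)
  vapply(seq_len(ncol(pairs)), function(k) {
    bmntd(relmat[pairs[1, k], ], relmat[pairs[2, k], ], dist,
          weighted = weighted)
  }, numeric(1))
}

#' Beta nearest-taxon index via a tip-shuffling null
#'
#' For every pair of communities (rows of `table`), the observed betaMNTD is
#' standardized against a null distribution obtained by permuting the
#' phylogenetic positions of the ASVs: each null replicate reassigns the
#' observed ASVs to tip positions drawn from the reference tree (one shuffle
#' per replicate, applied to all pairs), recomputes betaMNTD, and
#' betaNTI = (observed - null mean) / null sd. Values below -2 or above +2
#' are conventionally read as selection-driven turnover. If the null sd is
#' zero the score is undefined and returned as `NA` with `flag = TRUE`.
#'
#' By default the shuffle spans all tips of the supplied tree
#' (`null_tips = "tree"`): communities jointly confined to a small clade of
#' a large reference phylogeny are then detected as phylogenetically
#' clustered, which is the signature the index exists to measure. With
#' `null_tips = "union"` positions are permuted only among the ASVs observed
#' in the table; that variant cannot detect clustering shared by all
#' communities and is provided for sensitivity analysis only.
#'
#' @param table an `asv_table` of communities (typically seed counts
#'   aggregated per plant).
#' @param tree phylogeny containing every observed ASV.
#' @param n_null number of null replicates (study convention 999).
#' @param rng_seed integer seed.
#' @param weighted abundance-weighted betaMNTD (default).
#' @param null_tips `"tree"` (default) or `"union"`; tip set over which the
#'   null shuffles phylogenetic positions.
#' @return `data.frame` with one row per community pair: `comm_i`, `comm_j`,
#'   `obs`, `null_mean`, `null_sd`, `bnti`, `n_null`, `flag`.
#' @export
bnti <- function(table, tree, n_null = 999L, rng_seed = 1L, weighted = TRUE,
                 null_tips = c("tree", "union")) {
  null_tips <- match.arg(null_tips)
  stopifnot(inherits(table, "asv_table"), n_null >= 1)
  ct <- asv_counts(table)
  ct <- ct[rowSums(ct) > 0, , drop = FALSE]
  if (nrow(ct) < 2) stop("need >= 2 non-empty communities", call. = FALSE)
  union_taxa <- colnames(ct)[colSums(ct) > 0]
  ct <- ct[, union_taxa, drop = FALSE]
  pool <- if (null_tips == "tree") tree$tip.label else union_taxa
  dist_pool <- cophenetic_matrix(tree, pool)
  dist <- dist_pool[union_taxa, union_taxa, drop = FALSE]
  rel <- ct / rowSums(ct)
  obs <- .pairwise_bmntd(rel, dist, weighted)
  n_pair <- length(obs)
  nulls <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_null), function(b) {
      perm <- sample(pool, length(union_taxa))
      pd <- dist_pool[perm, perm, drop = FALSE]
      dimnames(pd) <- list(union_taxa, union_taxa)
      .pairwise_bmntd(rel, pd, weighted)
    }, numeric(n_pair))
  })
  nulls <- matrix(nulls, nrow = n_pair)
  mu <- rowMeans(nulls)
  sdv <- apply(nulls, 1, stats::sd)
  score <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  pairs <- utils::combn(nrow(rel), 2)
  data.frame(
    comm_i = rownames(rel)[pairs[1, ]],
    comm_j = rownames(rel)[pairs[2, ]],
    obs = obs, null_mean = mu, null_sd = sdv, bnti = score,
    n_null = n_null, flag = !is.finite(score) | sdv == 0,
    stringsAsFactors = FALSE
  )
}

#' Abundance-based Raup-Crick null deviation of Bray-Curtis dissimilarity
#'
#' For each community pair, null communities preserving each community's
#' observed richness and total abundance are assembled from the table-wide
#' species pool: taxa are drawn without replacement with probability
#' proportional to their occurrence frequency across communities, each
#' receives one individual, and the remaining individuals are distributed
#' with probability proportional to the taxa's pooled relative abundances.
#' The Raup-Crick score rescales the rank of the observed Bray-Curtis value
#' within the null distribution to [-1, 1]:
#' RC = 2 (fraction null < observed + 0.5 fraction ties) - 1.
#'
#' @inheritParams bnti
#' @return `data.frame` with one row per pair: `comm_i`, `comm_j`, `obs`
#'   (Bray-Curtis), `null_mean`, `null_sd`, `rc`, `n_null`.
#' @export
raup_crick_bray <- function(table, n_null = 999L, rng_seed = 1L) {
  stopifnot(inherits(table, "asv_table"), n_null >= 1)
  ct <- asv_counts(table)
  ct <- ct[rowSums(ct) > 0, , drop = FALSE]
  if (nrow(ct) < 2) stop("need >= 2 non-empty communities", call. = FALSE)
  ct <- ct[, colSums(ct) > 0, drop = FALSE]
  n_taxa <- ncol(ct)
  occ <- colMeans(ct > 0)
  ab <- colSums(ct) / sum(ct)
  rich <- rowSums(ct > 0)
  tot <- rowSums(ct)
  draw_null <- function(i) {
    k <- rich[i]
    taxa <- sample.int(n_taxa, k, prob = occ)
    x <- numeric(n_taxa)
    x[taxa] <- 1
    extra <- tot[i] - k
    if (extra > 0) {
      x[taxa] <- x[taxa] +
        stats::rmultinom(1, extra, prob = ab[taxa])[, 1]
    }
    x
  }
  pairs <- utils::combn(nrow(ct), 2)
  res <- withr::with_seed(rng_seed, {
    lapply(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      obs <- as.numeric(vegan::vegdist(rbind(ct[i, ], ct[j, ]),
                                       method = "bray"))
      nulls <- vapply(seq_len(n_null), function(b) {
        as.numeric(vegan::vegdist(rbind(draw_null(i), draw_null(j)),
                                  method = "bray"))
      }, numeric(1))
      rc <- 2 * ((sum(nulls < obs) + 0.5 * sum(nulls == obs)) / n_null) - 1
      c(obs = obs, null_mean = mean(nulls), null_sd = stats::sd(nulls),
        rc = rc)
    })
  })
  res <- do.call(rbind, res)
  data.frame(
    comm_i = rownames(ct)[pairs[1, ]],
    comm_j = rownames(ct)[pairs[2, ]],
    res, n_null = n_null, row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify the assembly process of a community pair
#'
#' The quantitative-process-estimates decision rule: betaNTI < -2 indicates
#' homogeneous selection, betaNTI > 2 variable selection; otherwise the
#' Raup-Crick score decides between dispersal limitation (RC > 0.95),
#' homogenizing dispersal (RC < -0.95) and ecological drift.
#'
#' @param bnti_value numeric vector of betaNTI scores.
#' @param rc_value numeric vector of Raup-Crick scores; may be `NA` where
#'   `|betaNTI| > 2` (not consulted there).
#' @param bnti_threshold,rc_threshold decision thresholds (defaults 2, 0.95).
#' @return character vector of process labels.
#' @export
qpe_classify <- function(bnti_value, rc_value = NA_real_,
                         bnti_threshold = 2, rc_threshold = 0.95) {
  n <- length(bnti_value)
  rc_value <- rep_len(rc_value, n)
  out <- character(n)
  for (k in seq_len(n)) {
    b <- bnti_value[k]
    if (is.na(b)) stop("betaNTI value missing", call. = FALSE)
    if (b < -bnti_threshold) {
      out[k] <- "homogeneous selection"
    } else if (b > bnti_threshold) {
      out[k] <- "variable selection"
    } else {
      r <- rc_value[k]
      if (is.na(r)) {
        stop("Raup-Crick score required when |betaNTI| <= ",
             bnti_threshold, call. = FALSE)
      }
      out[k] <- if (r > rc_threshold) {
        "dispersal limitation"
      } else if (r < -rc_threshold) {
        "homogenizing dispersal"
      } else {
        "drift"
      }
    }
  }
  out
}

#' @rdname qpe_classify
#' @export
qpe_processes <- c("homogeneous selection", "variable selection",
                   "dispersal limitation", "homogenizing dispersal", "drift")

#' Summarize process labels into per-group fractions
#'
#' @param labels character vector of process labels (from [qpe_classify()]).
#' @param groups grouping factor/vector of the same length (default: one
#'   group).
#' @return `data.frame` with one row per group x process, columns `group`,
#'   `process`, `fraction`; fractions sum to one within each group.
#' @export
qpe_summarize <- function(labels, groups = rep("all", length(labels))) {
  if (length(labels) == 0) stop("no labeled pairs", call. = FALSE)
  stopifnot(length(groups) == length(labels))
  bad <- setdiff(unique(labels), qpe_processes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tab <- table(factor(groups), factor(labels, levels = qpe_processes))
  frac <- prop.table(tab, margin = 1)
  df <- as.data.frame(frac, stringsAsFactors = FALSE)
  colnames(df) <- c("group", "process", "fraction")
  df
}

#' Run betaNTI + Raup-Crick and classify every pair
#'
#' Convenience wrapper: aggregates seed samples per plant within each group
#' (plant-species x stage by default), runs [bnti()] and [raup_crick_bray()]
#' on the aggregated communities, classifies each plant pair with
#' [qpe_classify()], and summarizes fractions per group.
#'
#' @param table an `asv_table` of seed samples.
#' @param metadata metadata covering the table.
#' @param tree phylogeny containing the observed ASVs.
#' @param group_by metadata columns defining the panels (pairs are formed
#'   within each group).
#' @param aggregate_by metadata column naming the community unit (default
#'   plant).
#' @param n_null null replicates for both null models.
#' @param rng_seed integer seed.
#' @param weighted abundance-weighted betaMNTD.
#' @return list with `pairs` (per-pair data.frame incl. `process`) and
#'   `summary` (per-group fractions).
#' @export
qpe <- function(table, metadata, tree,
                group_by = c("plant_species", "stage_day"),
                aggregate_by = "plant_id",
                n_null = 999L, rng_seed = 1L, weighted = TRUE) {
  .check_coverage(metadata, table)
  md <- metadata[match(sample_ids(table), metadata$sample_id), , drop = FALSE]
  key <- interaction(md[group_by], drop = TRUE, sep = "|")
  out <- lapply(seq_along(levels(key)), function(gi) {
    g <- levels(key)[gi]
    ids <- sample_ids(table)[key == g]
    sub <- subset_table(table, samples = ids)
    agg <- aggregate_by_plant(sub, md[key == g, , drop = FALSE],
                              group_by = aggregate_by)
    agg <- subset_table(agg, samples = sample_ids(agg)[sample_totals(agg) > 0])
    if (nrow(asv_counts(agg)) < 2) return(NULL)
    b <- bnti(agg, tree, n_null = n_null,
              rng_seed = .derive_seed(rng_seed, 2L * gi), weighted = weighted)
    r <- raup_crick_bray(agg, n_null = n_null,
                         rng_seed = .derive_seed(rng_seed, 2L * gi + 1L))
    stopifnot(identical(b$comm_i, r$comm_i), identical(b$comm_j, r$comm_j))
    ok <- !b$flag
    proc <- rep(NA_character_, nrow(b))
    proc[ok] <- qpe_classify(b$bnti[ok], r$rc[ok])
    data.frame(group = g, comm_i = b$comm_i, comm_j = b$comm_j,
               bmntd_obs = b$obs, bnti = b$bnti, bc_obs = r$obs, rc = r$rc,
               process = proc, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, out)
  if (is.null(pairs) || nrow(pairs) == 0) stop("no analyzable group", call. = FALSE)
  lab <- pairs[!is.na(pairs$process), , drop = FALSE]
  list(pairs = pairs, summary = qpe_summarize(lab$process, lab$group))
}
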