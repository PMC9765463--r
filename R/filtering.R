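#' Rarefy a count table to even depth
#'
#' Subsamples each sample without replacement (hypergeometric rarefaction) to
#' exactly `depth` reads. Samples whose total is below `depth` are dropped and
#' reported in the `"dropped_samples"` attribute of the result. The draw is
#' seeded for reproducibility and does not disturb the caller's RNG state.
#'
#' @param table an `asv_table`.
#' @param depth target depth (reads per sample), >= 1. The study convention is
#'   4,000 reads per sample for diversity summaries.
#' @param rng_seed integer seed.
#' @return an `asv_table` of the retained samples, every row summing to
#'   `depth`, with attribute `dropped_samples` (character vector).
#' @export
rarefy_counts <- function(table, depth, rng_seed = 1L) {
  stopifnot(inherits(table, "asv_table"))
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1 ||
      depth != round(depth)) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  ct <- asv_counts(table)
  tot <- rowSums(ct)
  keep <- tot >= depth
  dropped <- rownames(ct)[!keep]
  if (!any(keep)) stop("no sample reaches the rarefaction depth", call. = FALSE)
  kept <- ct[keep, , drop = FALSE]
  out <- withr::with_seed(rng_seed, {
    t(apply(kept, 1, .rarefy_row, depth = depth))
  })
  dimnames(out) <- dimnames(kept)
  res <- asv_table(out)
  attr(res, "dropped_samples") <- dropped
  res
}

.rarefy_row <- function(x, depth) {
  total <- sum(x)
  if (total == depth) return(x)
  pool <- rep.int(seq_along(x), x)
  take <- sample(pool, depth, replace = FALSE)
  tabulate(take, nbins = length(x))
}

#' Filter ASVs by share of the group's total abundance
#'
#' Keeps ASVs whose summed count across all samples of the table strictly
#' exceeds `fraction` of the grand total (the study convention is the most
#' abundant taxa, > 0.1% of total ASV abundance, applied within one plant's
#' seeds at one date). The original, unfiltered per-sample totals are returned
#' alongside so that downstream proportions can still be computed relative to
#' each seed's full read total.
#'
#' @param table an `asv_table` (one analysis group).
#' @param fraction threshold in `[0, 1)`; strict inequality.
#' @return a list with `table` (filtered `asv_table`), `retained_ids`
#'   (character), and `sample_totals` (named numeric, unfiltered totals).
#' @export
filter_by_total_abundance <- function(table, fraction = 0.001) {
  stopifnot(inherits(table, "asv_table"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction >= 1) {
    stop("`fraction` must lie in [0, 1)", call. = FALSE)
  }
  ct <- asv_counts(table)
  grand <- sum(ct)
  if (grand == 0) stop("table has no counts", call. = FALSE)
  asv_tot <- colSums(ct)
  retained <- names(asv_tot)[asv_tot > fraction * grand]
  list(
    table = asv_table(ct[, retained, drop = FALSE]),
    retained_ids = retained,
    sample_totals = rowSums(ct)
  )
}
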