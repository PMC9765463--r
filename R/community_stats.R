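#' Rank-abundance and dominance profile per sample
#'
#' Sorts each sample's ASVs by descending count (ties broken by ASV
#' identifier, lexicographically, and flagged) and reports the rank-1 ASV,
#' its relative abundance and the sample richness. Empty samples are skipped
#' and listed in the `"skipped"` attribute.
#'
#' @param table an `asv_table`.
#' @return `data.frame` with columns `sample_id`, `rank1_asv`, `rank1_ra`,
#'   `richness`, `tie`.
#' @export
dominance_profile <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  ct <- asv_counts(table)
  tot <- rowSums(ct)
  skipped <- rownames(ct)[tot == 0]
  keep <- which(tot > 0)
  rows <- lapply(keep, function(i) {
    x <- ct[i, ]
    ord <- order(-x, colnames(ct))
    top <- ord[1]
    data.frame(
      sample_id = rownames(ct)[i],
      rank1_asv = colnames(ct)[top],
      rank1_ra = x[top] / tot[i],
      richness = sum(x > 0),
      tie = sum(x == x[top]) > 1,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Ranked relative abundances of one sample
#'
#' @param table an `asv_table`.
#' @param sample a sample identifier.
#' @return named numeric vector of relative abundances of detected ASVs,
#'   non-increasing.
#' @export
rank_abundance <- function(table, sample) {
  ct <- asv_counts(table)
  if (!sample %in% rownames(ct)) stop("unknown sample: ", sample, call. = FALSE)
  x <- ct[sample, ]
  x <- x[x > 0]
  if (length(x) == 0) stop("sample is empty: ", sample, call. = FALSE)
  sort(x / sum(x), decreasing = TRUE)
}

#' Aggregate samples by metadata keys
#'
#' Sums counts across all samples sharing the same values of the grouping
#' columns (e.g. all seeds of one plant), producing one pseudo-sample per
#' group. This is the "aggregated at the individual plant level" step used
#' before the pairwise null models.
#'
#' @param table an `asv_table`.
#' @param metadata metadata covering the table.
#' @param group_by metadata columns to aggregate over.
#' @return an `asv_table` of group pseudo-samples.
#' @export
aggregate_by_plant <- function(table, metadata, group_by = "plant_id") {
  missing <- setdiff(group_by, colnames(metadata))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ct <- asv_counts(table)
  md <- metadata[match(rownames(ct), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata does not cover the table", call. = FALSE)
  key <- interaction(md[group_by], drop = TRUE, sep = "|")
  agg <- rowsum(ct, group = key)
  asv_table(agg)
}

#' Detection summary per group
#'
#' A sample is "detected" when its total count is positive (the CFU-detection
#' reading of an all-zero row). Reports per-group detected/undetected counts
#' and the detected fraction.
#'
#' @inheritParams aggregate_by_plant
#' @return `data.frame` with `group`, `n`, `detected`, `undetected`,
#'   `fraction`.
#' @export
detection_summary <- function(table, metadata, group_by = "stage_day") {
  missing <- setdiff(group_by, colnames(metadata))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ct <- asv_counts(table)
  md <- metadata[match(rownames(ct), metadata$sample_id), , drop = FALSE]
  key <- interaction(md[group_by], drop = TRUE, sep = "|")
  det <- rowSums(ct) > 0
  out <- lapply(levels(key), function(g) {
    sel <- key == g
    data.frame(group = g, n = sum(sel), detected = sum(det[sel]),
               undetected = sum(sel) - sum(det[sel]),
               fraction = mean(det[sel]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Seed-to-seedling transmission report
#'
#' Pairs are taken from the metadata's `paired_id` column (a seed sample
#' pointing to its seedling sample). For each pair the detected ASV sets are
#' partitioned into seed-only / shared / seedling-only, and dominance
#' transmission records whether the seed's rank-1 ASV is also the seedling's
#' rank-1 ASV (defined only when both members are non-empty). The cohort
#' summary counts dominance transmissions over the pairs with both members
#' detected, and pools the per-pair partitions.
#'
#' @param table an `asv_table` holding both seed and seedling samples.
#' @param metadata metadata with `habitat` and `paired_id`.
#' @param min_count detection threshold (counts >= `min_count` count as
#'   present; default 1).
#' @return list with `pairs` (per-pair `data.frame`) and `summary` (list with
#'   `n_pairs`, `n_dominance_transmitted`, pooled partition counts).
#' @export
transmission_report <- function(table, metadata, min_count = 1L) {
  validate_metadata(metadata, table)
  if (!"paired_id" %in% colnames(metadata)) {
    stop("metadata lacks `paired_id`", call. = FALSE)
  }
  md <- metadata
  seeds <- md[md$habitat == "seed" & !is.na(md$paired_id) &
                md$paired_id != "", , drop = FALSE]
  if (nrow(seeds) == 0) stop("no seed-seedling pairs in metadata", call. = FALSE)
  partner <- md[match(seeds$paired_id, md$sample_id), , drop = FALSE]
  orphans <- seeds$sample_id[is.na(partner$sample_id) |
                               partner$habitat != "seedling"]
  if (length(orphans)) {
    stop("broken pairing for seed(s): ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  ct <- asv_counts(table)
  dom <- dominance_profile(table)
  rows <- lapply(seq_len(nrow(seeds)), function(k) {
    sid <- seeds$sample_id[k]
    gid <- seeds$paired_id[k]
    a <- colnames(ct)[ct[sid, ] >= min_count]
    b <- colnames(ct)[ct[gid, ] >= min_count]
    both <- length(a) > 0 && length(b) > 0
    dt <- if (both) {
      dom$rank1_asv[dom$sample_id == sid] == dom$rank1_asv[dom$sample_id == gid]
    } else {
      NA
    }
    data.frame(seed = sid, seedling = gid,
               seed_only = length(setdiff(a, b)),
               shared = length(intersect(a, b)),
               seedling_only = length(setdiff(b, a)),
               dominance_transmitted = dt,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  complete <- pairs[!is.na(pairs$dominance_transmitted), , drop = FALSE]
  list(
    pairs = pairs,
    summary = list(
      n_pairs = nrow(complete),
      n_dominance_transmitted = sum(complete$dominance_transmitted),
      seed_only = sum(pairs$seed_only),
      shared = sum(pairs$shared),
      seedling_only = sum(pairs$seedling_only)
    )
  )
}

#' Attribute seed-borne ASVs to source habitats
#'
#' Labels every ASV detected in the seed table with the set of source
#' habitats (e.g. flower, stem, atmosphere) in which it is also detected;
#' ASVs found in no sampled source habitat are labeled `"unknown"`. Multiple
#' habitats give a multi-label (joined with `+`).
#'
#' @param seed_table an `asv_table` of seed samples.
#' @param habitat_tables named list of `asv_table`s, one per source habitat.
#' @param min_count detection threshold.
#' @return list with `per_asv` (`data.frame`: `asv_id`, `sources`) and
#'   `summary` (`data.frame` of label fractions over seed ASVs, summing to
#'   one).
#' @export
source_attribution <- function(seed_table, habitat_tables, min_count = 1L) {
  stopifnot(inherits(seed_table, "asv_table"))
  ct <- asv_counts(seed_table)
  seed_asvs <- colnames(ct)[colSums(ct >= min_count) > 0]
  if (length(seed_asvs) == 0) stop("no ASVs detected in seeds", call. = FALSE)
  detected_in <- function(tab) {
    m <- asv_counts(tab)
    colnames(m)[colSums(m >= min_count) > 0]
  }
  habitat_sets <- lapply(habitat_tables, detected_in)
  labels <- vapply(seed_asvs, function(a) {
    hit <- names(habitat_sets)[vapply(habitat_sets, function(s) a %in% s,
                                      logical(1))]
    if (length(hit) == 0) "unknown" else paste(sort(hit), collapse = "+")
  }, character(1))
  per_asv <- data.frame(asv_id = seed_asvs, sources = unname(labels),
                        stringsAsFactors = FALSE)
  tab <- table(labels)
  summary <- data.frame(sources = names(tab),
                        n = as.integer(tab),
                        fraction = as.numeric(tab) / length(seed_asvs),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(per_asv = per_asv, summary = summary)
}
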