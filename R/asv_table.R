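#' Construct an ASV count table
#'
#' An `asv_table` is the basic container of the package: a non-negative
#' integer matrix of read (or CFU-derived) counts with samples in rows and
#' amplicon sequence variants (ASVs) in columns. Sample and ASV identifiers
#' must be unique. All-zero rows are allowed (seeds in which no bacteria were
#' detected) and are flagged rather than dropped, because non-detection is
#' itself a quantity of interest.
#'
#' @param counts numeric matrix (samples x ASVs) of non-negative integers.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(counts)`.
#' @param asv_ids character vector of unique ASV identifiers; defaults to
#'   `colnames(counts)`.
#' @return an object of class `asv_table`.
#' @export
asv_table <- function(counts, sample_ids = rownames(counts),
                      asv_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(asv_ids)) {
    stop("`counts` must carry sample and ASV identifiers", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  asv_ids <- as.character(asv_ids)
  if (length(sample_ids) != nrow(counts) || length(asv_ids) != ncol(counts)) {
    stop("identifier lengths do not match the count matrix", call. = FALSE)
  }
  .check_unique(sample_ids, "sample")
  .check_unique(asv_ids, "ASV")
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric and complete", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(sample_ids, asv_ids)
  structure(list(counts = counts), class = "asv_table")
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.asv_table <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("<asv_table> %d samples x %d ASVs; total reads %s; %d empty sample(s)\n",
              nrow(ct), ncol(ct), format(sum(ct), big.mark = ","),
              sum(rowSums(ct) == 0)))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Accessors for `asv_table`
#'
#' @param x an `asv_table`.
#' @return `asv_counts()` the count matrix, `sample_ids()`/`asv_ids()` the
#'   identifiers, `sample_totals()` per-sample read totals, `empty_samples()`
#'   identifiers of all-zero samples.
#' @export
asv_counts <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  x$counts
}

#' @rdname asv_counts
#' @export
sample_ids <- function(x) rownames(asv_counts(x))

#' @rdname asv_counts
#' @export
asv_ids <- function(x) colnames(asv_counts(x))

#' @rdname asv_counts
#' @export
sample_totals <- function(x) rowSums(asv_counts(x))

#' @rdname asv_counts
#' @export
empty_samples <- function(x) {
  tot <- sample_totals(x)
  names(tot)[tot == 0]
}

#' Subset an ASV table
#'
#' @param x an `asv_table`.
#' @param samples,asvs identifiers (or logical/integer indices) to keep;
#'   `NULL` keeps everything.
#' @return an `asv_table`.
#' @export
subset_table <- function(x, samples = NULL, asvs = NULL) {
  ct <- asv_counts(x)
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, rownames(ct))
      if (length(missing)) {
        stop("unknown sample(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
    }
    ct <- ct[samples, , drop = FALSE]
  }
  if (!is.null(asvs)) {
    if (is.character(asvs)) {
      missing <- setdiff(asvs, colnames(ct))
      if (length(missing)) {
        stop("unknown ASV(s): ", paste(missing, collapse = ", "), call. = FALSE)
      }
    }
    ct <- ct[, asvs, drop = FALSE]
  }
  asv_table(ct)
}

#' Read an ASV count table from a tab-separated file
#'
#' The file must have a header row and a first column of identifiers. With
#' `orientation = "samples_rows"` rows are samples; with `"asvs_rows"` the
#' matrix is transposed on read so the returned table is always samples x
#' ASVs.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples_rows"` (default) or `"asvs_rows"`.
#' @return an `asv_table`.
#' @export
read_asv_table <- function(path, orientation = c("samples_rows", "asvs_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs an id column plus counts", call. = FALSE)
  ids <- as.character(df[[1]])
  .check_unique(ids, if (orientation == "samples_rows") "sample" else "ASV")
  .check_unique(colnames(df)[-1],
                if (orientation == "samples_rows") "ASV" else "sample")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    stop("non-numeric counts in ", path, call. = FALSE)
  }
  rownames(mat) <- ids
  if (orientation == "asvs_rows") mat <- t(mat)
  asv_table(mat)
}

#' Write an ASV count table as TSV
#'
#' @param x an `asv_table`.
#' @param path output path.
#' @param id_column name of the identifier column (first column).
#' @export
write_asv_table <- function(x, path, id_column = "sample_id") {
  ct <- asv_counts(x)
  df <- data.frame(rownames(ct), ct, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' Required columns: `sample_id`, `plant_id`, `plant_species`, `stage_label`,
#' `stage_day`, `habitat`, `marker`. Optional: `paired_id`, linking a seed to
#' its seedling sample.
#'
#' @param path path to a TSV file.
#' @return a `data.frame`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata a metadata `data.frame`.
#' @param table optionally, an `asv_table` the metadata must annotate (every
#'   table sample must appear exactly once).
#' @export
validate_metadata <- function(metadata, table = NULL) {
  required <- c("sample_id", "plant_id", "plant_species", "stage_label",
                "stage_day", "habitat", "marker")
  missing <- setdiff(required, colnames(metadata))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  .check_unique(as.character(metadata$sample_id), "sample")
  ok_hab <- c("seed", "seedling", "flower", "stem", "atmosphere")
  bad <- setdiff(unique(metadata$habitat), ok_hab)
  if (length(bad)) {
    stop("unknown habitat(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("paired_id" %in% colnames(metadata)) {
    p <- metadata$paired_id
    has <- !is.na(p) & p != ""
    unknown <- setdiff(p[has], metadata$sample_id)
    if (length(unknown)) {
      stop("paired_id refers to unknown sample(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(table)) {
    absent <- setdiff(sample_ids(table), metadata$sample_id)
    if (length(absent)) {
      stop("table sample(s) missing from metadata: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  metadata
}

# coverage-only check for metadata subsets (pairing may point outside the
# subset, so full validate_metadata() would reject legitimate slices)
.check_coverage <- function(metadata, table) {
  absent <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(absent)) {
    stop("table sample(s) missing from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  invisible(metadata)
}

#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
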