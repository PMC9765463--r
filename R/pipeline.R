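# Deterministic per-stage seed derivation: toggling one stage must not shift
# another stage's random stream. Kept below 2^31 - 1.
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 1000003) %%
               2147483647)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages — simulate (or load inputs), abundance filter and
#' rarefaction, neutral-model fit, betaNTI/Raup-Crick/QPE, dominance,
#' detection, transmission and source attribution — writing one TSV/JSON
#' output per stage plus a run manifest. Identical configuration and seed
#' produce byte-identical outputs.
#'
#' @param config either a `list` or a path to a JSON file. Recognized
#'   entries: `scenario` (a [scenario_config()] or its argument list) *or*
#'   `table`/`metadata`/`tree` input paths; `stages` (character subset of
#'   `c("simulate", "fit_neutral", "qpe", "dominance", "detection",
#'   "transmission", "sources")`, default all applicable); `filter_fraction`
#'   (0.001), `rarefaction_depth` (4000), `n_null` (999), `moment_mode`,
#'   `i_convention`, `apply_observation` (`TRUE`).
#' @param outdir output directory.
#' @param rng_seed global integer seed; per-stage seeds are derived from it
#'   deterministically.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir, rng_seed = 1L) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) config[[name]]
  filter_fraction <- p("filter_fraction") %||% 0.001
  depth <- p("rarefaction_depth") %||% 4000L
  n_null <- p("n_null") %||% 999L
  moment_mode <- p("moment_mode") %||% "mean"
  i_convention <- p("i_convention") %||% "percapita"

  stage_fail <- function(stage, e) {
    rec <- list(stage = stage, error = conditionMessage(e))
    jsonlite::write_json(rec, file.path(outdir, "error.json"),
                         auto_unbox = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  have_scenario <- !is.null(config$scenario)
  stages <- p("stages") %||%
    c(if (have_scenario) "simulate", "fit_neutral", "qpe", "alpha",
      "dominance", "detection", "transmission", "sources")
  written <- character(0)

  if (have_scenario) {
    sc <- config$scenario
    if (!inherits(sc, "scenario_config")) {
      sc$rng_seed <- .derive_seed(rng_seed, 10L)
      sc <- do.call(scenario_config, sc)
    }
    study <- tryCatch(simulate_study(sc), error = function(e)
      stage_fail("simulate", e))
    if (isTRUE(p("apply_observation") %||% TRUE)) {
      study <- apply_observation_model(
        study, rng_seed = .derive_seed(rng_seed, 11L))
    }
    if ("simulate" %in% stages) {
      written <- c(written, write_study(study, file.path(outdir, "study")))
    }
    table <- study$table
    metadata <- study$metadata
    tree <- study$tree
  } else {
    table <- read_asv_table(config$table)
    metadata <- read_metadata(config$metadata)
    tree <- read_newick(config$tree)
  }
  validate_metadata(metadata, table)
  seed_ids <- metadata$sample_id[metadata$habitat == "seed"]
  seed_tab <- subset_table(table, samples = intersect(sample_ids(table),
                                                      seed_ids))
  seed_md <- metadata[metadata$habitat == "seed", , drop = FALSE]

  emit_tsv <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
  }

  if ("fit_neutral" %in% stages) {
    fits <- tryCatch(
      fit_neutral_by_group(seed_tab, seed_md,
                           filter_fraction = filter_fraction,
                           moment_mode = moment_mode,
                           i_convention = i_convention),
      error = function(e) stage_fail("fit_neutral", e))
    emit_tsv(fits, "neutral_fits.tsv")
  }
  if ("qpe" %in% stages) {
    qp <- tryCatch(
      qpe(seed_tab, seed_md, tree, n_null = n_null,
          rng_seed = .derive_seed(rng_seed, 20L)),
      error = function(e) stage_fail("qpe", e))
    emit_tsv(qp$pairs, "qpe_pairs.tsv")
    emit_tsv(qp$summary, "qpe_summary.tsv")
  }
  if ("alpha" %in% stages) {
    al <- tryCatch({
      rar <- rarefy_counts(seed_tab, depth,
                           rng_seed = .derive_seed(rng_seed, 30L))
      rct <- asv_counts(rar)
      rich <- data.frame(sample_id = rownames(rct),
                         richness = rowSums(rct > 0),
                         stringsAsFactors = FALSE)
      agg <- aggregate_by_plant(rar, seed_md, group_by = "plant_id")
      act <- asv_counts(agg)
      pd <- vapply(rownames(act), function(g) {
        present <- colnames(act)[act[g, ] > 0]
        if (length(present) == 0) return(NA_real_)
        faith_pd(tree, present)
      }, numeric(1))
      list(richness = rich,
           faith = data.frame(plant_id = rownames(act), faith_pd = pd,
                              stringsAsFactors = FALSE, row.names = NULL))
    }, error = function(e) stage_fail("alpha", e))
    emit_tsv(al$richness, "alpha_richness.tsv")
    emit_tsv(al$faith, "alpha_faith_pd.tsv")
  }
  if ("dominance" %in% stages) {
    dom <- tryCatch(dominance_profile(seed_tab),
                    error = function(e) stage_fail("dominance", e))
    emit_tsv(dom, "dominance.tsv")
  }
  if ("detection" %in% stages) {
    det <- tryCatch(
      detection_summary(seed_tab, seed_md,
                        group_by = c("plant_id", "stage_day")),
      error = function(e) stage_fail("detection", e))
    emit_tsv(det, "detection.tsv")
  }
  if ("transmission" %in% stages &&
      "paired_id" %in% colnames(metadata) &&
      any(!is.na(metadata$paired_id) & metadata$paired_id != "")) {
    tr <- tryCatch(transmission_report(table, metadata),
                   error = function(e) stage_fail("transmission", e))
    emit_tsv(tr$pairs, "transmission_pairs.tsv")
    jsonlite::write_json(tr$summary,
                         file.path(outdir, "transmission_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, file.path(outdir, "transmission_summary.json"))
  }
  src_habs <- intersect(unique(metadata$habitat),
                        c("flower", "stem", "atmosphere"))
  if ("sources" %in% stages && length(src_habs)) {
    habs <- lapply(src_habs, function(h) {
      ids <- metadata$sample_id[metadata$habitat == h]
      subset_table(table, samples = intersect(sample_ids(table), ids))
    })
    names(habs) <- src_habs
    sa <- tryCatch(source_attribution(seed_tab, habs),
                   error = function(e) stage_fail("sources", e))
    emit_tsv(sa$summary, "sources_summary.tsv")
  }

  manifest <- list(
    package = "seedasm",
    version = as.character(utils::packageVersion("seedasm")),
    rng_seed = rng_seed,
    parameters = list(filter_fraction = filter_fraction,
                      rarefaction_depth = depth, n_null = n_null,
                      moment_mode = moment_mode,
                      i_convention = i_convention),
    scenario = if (have_scenario) unclass(sc) else NULL,
    inputs = if (!have_scenario) {
      config[c("table", "metadata", "tree")]
    } else NULL,
    stages = stages,
    outputs = as.list(tools::md5sum(sort(unname(written))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
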