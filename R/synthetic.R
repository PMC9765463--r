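#' Configure a synthetic single-seed study
#'
#' The generator emulates the sampling design of a single-seed microbiota
#' survey: a handful of mother plants, tens of seeds per plant sampled at a
#' few developmental dates, low per-seed richness with one dominant taxon,
#' partial detection, and strong plant-to-plant compositional variation.
#' Three scenarios are available:
#'
#' * `"neutral"` — each seed's composition is a symmetric
#'   Dirichlet-multinomial draw from the plant's pool with concentration
#'   `theta_c = R (N_c - 1)`, i.e. the stationary state of the
#'   immigration/replacement Moran model (see [moran_stationary_exact()]).
#' * `"drift"` — the same draw with a fixed small concentration
#'   (`theta_drift <= 0.5`), producing monodominance by a random pool member.
#' * `"selection"` — pool mass is concentrated (`selection_clade_frac`,
#'   default 90%) on one phylogenetic clade shared across the study, so
#'   communities are phylogenetically clustered.
#'
#' @param scenario `"neutral"`, `"selection"` or `"drift"`.
#' @param n_plants number of plants (study default 5).
#' @param seeds_per_plant seeds per plant per stage (default 32).
#' @param stage_days integer sampling days (default `c(26, 37, 65)`).
#' @param S species-pool size per plant, >= 2 (default 20).
#' @param R replacement ratio > 0 (default 0.05).
#' @param N_range integer `c(min, max)` of the true per-seed local population
#'   size (default `c(500, 2000)`).
#' @param q detection probability per seed in `[0, 1]` (default 0.6).
#' @param depth sequencing depth per detected seed (default 4000).
#' @param theta_drift fixed concentration under `scenario = "drift"`
#'   (default 0.3).
#' @param selection_clade_frac pool mass placed on the selected clade
#'   (default 0.9).
#' @param pool_overlap fraction of each plant pool drawn from a shared core
#'   set (default 0.2, echoing strong inter-plant variability).
#' @param n_tips tips in the simulated reference tree (default 100).
#' @param make_seedlings also generate one paired seedling per final-stage
#'   seed (default `FALSE`).
#' @param extra_habitats character subset of
#'   `c("flower", "stem", "atmosphere")` for optional source-habitat tables
#'   drawn from the same pools (default none).
#' @param rng_seed integer seed.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("neutral", "selection", "drift"),
                            n_plants = 5L, seeds_per_plant = 32L,
                            stage_days = c(26L, 37L, 65L),
                            S = 20, R = 0.05, N_range = c(500L, 2000L),
                            q = 0.6, depth = 4000L,
                            theta_drift = 0.3, selection_clade_frac = 0.9,
                            pool_overlap = 0.2, n_tips = 100L,
                            make_seedlings = FALSE,
                            extra_habitats = character(0),
                            rng_seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(S >= 2, R > 0, n_plants >= 1, seeds_per_plant >= 1,
            length(N_range) == 2, N_range[1] >= 2, N_range[2] >= N_range[1],
            q >= 0, q <= 1, depth >= 1, theta_drift > 0,
            selection_clade_frac > 0, selection_clade_frac <= 1,
            pool_overlap >= 0, pool_overlap <= 1, n_tips >= S)
  bad <- setdiff(extra_habitats, c("flower", "stem", "atmosphere"))
  if (length(bad)) stop("unknown habitat(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(
    scenario = scenario, n_plants = as.integer(n_plants),
    seeds_per_plant = as.integer(seeds_per_plant),
    stage_days = as.integer(stage_days), S = S, R = R,
    N_range = as.integer(N_range), q = q, depth = as.integer(depth),
    theta_drift = theta_drift, selection_clade_frac = selection_clade_frac,
    pool_overlap = pool_overlap, n_tips = as.integer(n_tips),
    make_seedlings = isTRUE(make_seedlings),
    extra_habitats = extra_habitats,
    rng_seed = as.integer(rng_seed)
  ), class = "scenario_config")
}

# sample one value from an integer range; safe for degenerate ranges (base
# sample() would treat a length-1 vector as 1:n)
.sample_range <- function(lo, hi) {
  seq.int(lo, hi)[sample.int(hi - lo + 1L, 1L)]
}

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) {
    # numerically degenerate gammas at tiny shapes: put mass on one category
    x[sample.int(length(alpha), 1, prob = alpha / sum(alpha))] <- 1
  }
  x / sum(x)
}

.rdirmult <- function(n_total, alpha) {
  p <- .rdirichlet(alpha)
  stats::rmultinom(1, n_total, prob = p)[, 1]
}

#' Simulate a complete synthetic study
#'
#' Generates the reference tree, per-plant species pools, per-seed
#' compositions under the configured scenario, metadata and ground truth.
#' The returned table holds the *true* compositions (one count per resident
#' individual, row totals equal to the true local sizes `N_c`); apply
#' [apply_observation_model()] for detection losses and sequencing-depth
#' resampling. Identical configuration and seed reproduce the study exactly.
#'
#' @param config a [scenario_config()].
#' @return an object of class `synthetic_study`: list with `table`
#'   (`asv_table`), `metadata` (`data.frame`), `tree` ([ape::phylo]),
#'   `truth` (per-plant parameters, per-seed `N_c`/`theta_c`, pools, clade),
#'   and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  tree <- simulate_tree(cf$n_tips, rng_seed = .derive_seed(cf$rng_seed, 1L))
  withr::with_seed(.derive_seed(cf$rng_seed, 2L), {
    tips <- tree$tip.label
    S <- cf$S
    clade_tips <- NULL
    if (cf$scenario == "selection") {
      # the clade is shared across the study but each plant hosts its own
      # subset of it, so plants are phylogenetically clustered without
      # sharing most taxa (shared taxa carry no nearest-taxon signal)
      clade_tips <- .pick_clade(
        tree, min_size = min(ceiling(0.75 * S), floor(cf$n_tips / 2)))
    }
    n_core <- round(cf$pool_overlap * S)
    core <- sample(tips, n_core)
    pools <- list()
    base_w <- list()
    for (p in seq_len(cf$n_plants)) {
      if (cf$scenario == "selection") {
        k <- ceiling(S / 2)
        inside <- sample(clade_tips, min(k, length(clade_tips)))
        outside <- sample(setdiff(tips, clade_tips), S - length(inside))
        pool <- c(inside, outside)
        w <- numeric(S)
        w[seq_along(inside)] <- cf$selection_clade_frac / length(inside)
        if (length(outside)) {
          w[seq_along(outside) + length(inside)] <-
            (1 - cf$selection_clade_frac) / length(outside)
        }
        w <- w / sum(w)
      } else {
        extra <- sample(setdiff(tips, core), S - n_core)
        pool <- c(core, extra)
        w <- rep(1 / S, S)
      }
      pools[[p]] <- pool
      base_w[[p]] <- w
    }
    rows <- list()
    meta <- list()
    truth_seeds <- list()
    for (p in seq_len(cf$n_plants)) {
      plant <- sprintf("P%02d", p)
      for (d in cf$stage_days) {
        for (s in seq_len(cf$seeds_per_plant)) {
          sid <- sprintf("%s_D%02d_S%03d", plant, d, s)
          N_c <- .sample_range(cf$N_range[1], cf$N_range[2])
          theta_c <- switch(cf$scenario,
                            drift = cf$theta_drift,
                            cf$R * (N_c - 1))
          x <- .rdirmult(N_c, theta_c * base_w[[p]])
          rows[[sid]] <- stats::setNames(x, pools[[p]])
          meta[[sid]] <- data.frame(
            sample_id = sid, plant_id = plant, plant_species = "synthetic",
            stage_label = paste0("D", d), stage_day = d, habitat = "seed",
            marker = "synthetic", paired_id = NA_character_,
            stringsAsFactors = FALSE)
          truth_seeds[[sid]] <- data.frame(
            sample_id = sid, plant_id = plant, stage_day = d,
            N_c = N_c, theta_c = theta_c, stringsAsFactors = FALSE)
        }
      }
    }
    if (cf$make_seedlings) {
      last <- max(cf$stage_days)
      seed_ids <- names(meta)[vapply(meta, function(m) m$stage_day == last,
                                     logical(1))]
      for (sid in seed_ids) {
        gid <- sub("_S", "_G", sid)
        p <- match(meta[[sid]]$plant_id, sprintf("P%02d", seq_len(cf$n_plants)))
        seedv <- rows[[sid]]
        mix <- 0.8 * seedv / sum(seedv) + 0.2 * base_w[[p]]
        N_g <- .sample_range(cf$N_range[1], cf$N_range[2])
        rows[[gid]] <- stats::setNames(
          .rdirmult(N_g, pmax(5 * mix, 1e-8)), pools[[p]])
        meta[[gid]] <- data.frame(
          sample_id = gid, plant_id = meta[[sid]]$plant_id,
          plant_species = "synthetic", stage_label = "seedling",
          stage_day = last, habitat = "seedling", marker = "synthetic",
          paired_id = NA_character_, stringsAsFactors = FALSE)
        meta[[sid]]$paired_id <- gid
        truth_seeds[[gid]] <- data.frame(
          sample_id = gid, plant_id = meta[[sid]]$plant_id, stage_day = last,
          N_c = N_g, theta_c = NA_real_, stringsAsFactors = FALSE)
      }
    }
    for (hab in cf$extra_habitats) {
      for (p in seq_len(cf$n_plants)) {
        hid <- sprintf("P%02d_%s", p, hab)
        N_h <- cf$N_range[2]
        rows[[hid]] <- stats::setNames(
          .rdirmult(N_h, pmax(2 * base_w[[p]], 1e-8)), pools[[p]])
        meta[[hid]] <- data.frame(
          sample_id = hid, plant_id = sprintf("P%02d", p),
          plant_species = "synthetic", stage_label = hab,
          stage_day = min(cf$stage_days), habitat = hab,
          marker = "synthetic", paired_id = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    all_asvs <- sort(unique(unlist(lapply(rows, names))))
    mat <- matrix(0, length(rows), length(all_asvs),
                  dimnames = list(names(rows), all_asvs))
    for (sid in names(rows)) {
      mat[sid, names(rows[[sid]])] <- rows[[sid]]
    }
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    truth <- list(
      scenario = cf$scenario,
      plants = data.frame(plant_id = sprintf("P%02d", seq_len(cf$n_plants)),
                          S = cf$S, R = cf$R, stringsAsFactors = FALSE),
      pools = stats::setNames(pools, sprintf("P%02d", seq_len(cf$n_plants))),
      clade_tips = clade_tips,
      seeds = do.call(rbind, c(truth_seeds, list(make.row.names = FALSE)))
    )
    structure(list(table = asv_table(mat), metadata = metadata, tree = tree,
                   truth = truth, config = cf),
              class = "synthetic_study")
  })
}

# Pick the selected clade: among clades of adequate size (and at most about
# half the tree), the phylogenetically most compact one — selection for a
# coherent clade means small internal nearest-taxon distances, not just a
# shared ancestor.
.pick_clade <- function(tree, min_size) {
  n_tip <- length(tree$tip.label)
  nodes <- (n_tip + 1):max(tree$edge)
  tipsets <- lapply(nodes, function(nd) .clade_tips(tree, nd))
  sizes <- lengths(tipsets)
  ok <- which(sizes >= min_size & sizes <= ceiling(n_tip / 2))
  if (length(ok) == 0) ok <- which(sizes >= min_size)
  d <- ape::cophenetic.phylo(tree)
  meand <- vapply(ok, function(i) {
    sub <- d[tipsets[[i]], tipsets[[i]]]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  tree$tip.label[tipsets[[ok[which.min(meand)]]]]
}

.clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]
    stack <- stack[-1]
    if (nd <= n_tip) {
      out <- c(out, nd)
    } else {
      stack <- c(stack, tree$edge[tree$edge[, 1] == nd, 2])
    }
  }
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> scenario '%s': %d samples, %d ASVs, %d-tip tree\n",
              x$truth$scenario, nrow(asv_counts(x$table)),
              ncol(asv_counts(x$table)), length(x$tree$tip.label)))
  invisible(x)
}

#' Apply the detection/sequencing observation model
#'
#' Each sample is independently "detected" with probability `q` (undetected
#' samples are zeroed, emulating seeds without recovered CFU); detected
#' samples are resampled multinomially to `depth` reads from their true
#' composition. Truth and metadata are carried over unchanged.
#'
#' @param study a `synthetic_study`.
#' @param q detection probability (default from the study's config).
#' @param depth sequencing depth (default from config).
#' @param rng_seed integer seed (default derived from the config seed).
#' @return the `synthetic_study` with an observed `table`; the true table is
#'   kept as `$true_table`.
#' @export
apply_observation_model <- function(study, q = NULL, depth = NULL,
                                    rng_seed = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  q <- q %||% study$config$q
  depth <- depth %||% study$config$depth
  rng_seed <- rng_seed %||% .derive_seed(study$config$rng_seed, 3L)
  stopifnot(q >= 0, q <= 1, depth >= 1)
  ct <- asv_counts(study$table)
  obs <- withr::with_seed(rng_seed, {
    out <- matrix(0, nrow(ct), ncol(ct), dimnames = dimnames(ct))
    detected <- stats::runif(nrow(ct)) < q
    for (i in which(detected)) {
      tot <- sum(ct[i, ])
      if (tot > 0) {
        out[i, ] <- stats::rmultinom(1, depth, prob = ct[i, ] / tot)[, 1]
      }
    }
    out
  })
  study$true_table <- study$table
  study$table <- asv_table(obs)
  study$observation <- list(q = q, depth = depth, rng_seed = rng_seed)
  study
}

#' Write a synthetic study to disk
#'
#' Emits the count table and metadata as TSV, the tree as Newick, and the
#' ground truth as JSON.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    table = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json")
  )
  write_asv_table(study$table, paths["table"])
  write_metadata(study$metadata, paths["metadata"])
  write_newick(study$tree, paths["tree"])
  truth <- study$truth
  truth$pools <- lapply(truth$pools, as.character)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
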