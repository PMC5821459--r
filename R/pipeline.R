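pipeline_defaults <- function() {
  list(
    seed = NULL,
    out_dir = NULL,
    stages = c("rnase", "split", "mutants", "exchange", "integrate",
               "nuclei"),
    design = list(),
    rnase = list(alpha = 0.001, center = "median", law = "normal",
                 require_direction = FALSE),
    split = list(metric = "diameter", mode = "exact", n_samples = 1e5),
    mutants = list(n_replicates = 3, min_n = 2, bin_width = 2),
    exchange = list(k = 3, linkage = "average"),
    integrate = list(k = 5, linkage = "average", standardize = TRUE,
                     delta = 1e-3),
    nuclei = list(n_fields = 20, field_size = c(400, 400), density = 1e-4,
                  positive_fraction = 0.18, pair_mode = "daughter_pairs",
                  displacement = 10, jitter_sd = 1, n_resamples = 1000,
                  seed = NULL)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key(s)%s: %s",
          if (nzchar(path)) paste0(" in '", path, "'") else "",
          paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         k != "design") {
      merge_config(defaults[[k]], user[[k]], k)
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a named list or a path to a JSON or YAML file, applies defaults,
#' rejects unknown keys, range-checks parameters, and derives explicit
#' per-stage seeds from the top-level seed where none is given (recorded in
#' the echoed config, so a run is fully described by its validated config).
#'
#' @param config named list, or path to a `.json`/`.yaml`/`.yml` file.
#' @return validated config list of class `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stopf("config must be a named list or a file path")
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.null(cfg$seed)) stopf("config requires a top-level `seed`")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stopf("`seed` must be a single integer")
  }
  bad_stages <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad_stages)) {
    stopf("unknown stage(s): %s", paste(bad_stages, collapse = ", "))
  }
  a <- cfg$rnase$alpha
  if (!is.numeric(a) || a <= 0 || a >= 1) {
    stopf("rnase$alpha must lie strictly within (0, 1)")
  }
  if (cfg$exchange$k < 1) stopf("exchange$k must be >= 1")
  if (cfg$integrate$k < 1) stopf("integrate$k must be >= 1")
  if (cfg$nuclei$n_resamples < 1) stopf("nuclei$n_resamples must be >= 1")
  # every stochastic stage gets an explicit recorded seed
  if (is.null(cfg$nuclei$seed)) cfg$nuclei$seed <- cfg$seed + 101L
  if (is.null(cfg$design$seed)) cfg$design$seed <- cfg$seed
  structure(cfg, class = "pipeline_config")
}

write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates one synthetic study from the validated configuration and runs
#' every selected stage in dependency order, writing plain-text artifacts
#' (CSV, JSON, Newick) into `out_dir` plus a manifest of md5 content hashes
#' and a run log of all parameters in effect. Runs are pure functions of
#' the config: identical configs give byte-identical manifests.
#'
#' @param config a list, file path, or [validate_pipeline_config()] result;
#'   must contain `seed` and `out_dir` (the latter may be passed here).
#' @param out_dir output directory (created if needed); overrides the
#'   config entry.
#' @return list with `manifest` (data.frame file, md5), `config`, and the
#'   per-stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) {
    config
  } else {
    validate_pipeline_config(config)
  }
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stopf("an output directory is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- do.call(synthetic_design, cfg$design)
  results <- list()
  files <- character(0)
  out <- function(name) file.path(cfg$out_dir, name)

  if ("rnase" %in% cfg$stages) {
    sim <- simulate_swap_experiment(design, "rnase")
    coords <- merge_swap_pair(filter_groups(sim$mix1),
                              filter_groups(sim$mix2), sim$condition)
    ra <- rnase_radial_test(coords, alpha = cfg$rnase$alpha,
                            center = cfg$rnase$center, law = cfg$rnase$law,
                            require_direction = cfg$rnase$require_direction)
    files <- c(files, write_stage_csv(ra$table, out("rnase_radial.csv")))
    jsonlite::write_json(
      list(center = as.list(ra$center), mu = ra$mu, sigma = ra$sigma,
           alpha = ra$alpha, tau = ra$tau, law = ra$law,
           n_flagged = sum(ra$table$flag)),
      out("rnase_summary.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, out("rnase_summary.json"))
    results$rnase <- ra
  }

  if ("split" %in% cfg$stages) {
    sim <- simulate_swap_experiment(design, "split")
    coords <- merge_swap_pair(filter_groups(sim$mix1),
                              filter_groups(sim$mix2), sim$condition)
    part <- normalize_to_anchor(coords, design$anchor)
    cpr <- cluster_proximity_pvalue(part, design$modules$triple,
                                    metric = cfg$split$metric,
                                    mode = cfg$split$mode,
                                    n_samples = cfg$split$n_samples,
                                    seed = cfg$seed + 211L)
    files <- c(files, write_stage_csv(part$normalized,
                                      out("split_normalized.csv")))
    jsonlite::write_json(unclass(cpr), out("split_cluster_p.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, out("split_cluster_p.json"))
    results$split <- list(partition = part, cluster_p = cpr)
  }

  if ("mutants" %in% cfg$stages) {
    sims <- lapply(c(EN = "EN", RT = "RT"), function(mu) {
      simulate_mutant_experiment(design, mu,
                                 n_replicates = cfg$mutants$n_replicates)
    })
    exps <- lapply(sims, function(s) {
      mutant_experiment(lapply(s$tables, filter_groups), s$mutant,
                        design$bait)
    })
    tabs <- lapply(exps, test_vs_wt, min_n = cfg$mutants$min_n)
    for (mu in names(tabs)) {
      tabs[[mu]]$stars <- significance_stars(tabs[[mu]]$q)
      files <- c(files, write_stage_csv(
        tabs[[mu]], out(sprintf("mutant_%s_vs_wt.csv", tolower(mu)))))
    }
    cross <- test_en_vs_rt(exps$EN, exps$RT, min_n = cfg$mutants$min_n)
    files <- c(files, write_stage_csv(cross, out("mutant_en_vs_rt.csv")))
    dh <- double_histogram(
      stats::setNames(tabs$EN$mean_recovery, tabs$EN$protein),
      stats::setNames(tabs$RT$mean_recovery, tabs$RT$protein),
      bin_width = cfg$mutants$bin_width)
    jsonlite::write_json(dh[c("breaks", "en_counts", "rt_counts",
                              "n_crisscross")],
                         out("mutant_double_histogram.json"), digits = NA)
    files <- c(files, out("mutant_double_histogram.json"))
    results$mutants <- list(tables = tabs, en_vs_rt = cross, histogram = dh)
  }

  if ("exchange" %in% cfg$stages) {
    sim <- simulate_timecourse(design)
    cl <- cluster_exchange(require_complete(sim$matrix),
                           k = cfg$exchange$k,
                           linkage = cfg$exchange$linkage)
    traj <- as.data.frame(unclass(sim$matrix))
    traj <- cbind(protein = rownames(traj), traj, cluster = cl$clusters)
    files <- c(files, write_stage_csv(traj, out("exchange_trajectories.csv")))
    writeLines(as_newick(cl$tree), out("exchange_dendrogram.nwk"))
    files <- c(files, out("exchange_dendrogram.nwk"))
    results$exchange <- cl
  }

  if ("integrate" %in% cfg$stages) {
    sim <- simulate_profile_set(seed = cfg$seed + 307L)
    ic <- integrate_and_cluster(sim$profiles, k = cfg$integrate$k,
                                linkage = cfg$integrate$linkage,
                                standardize = cfg$integrate$standardize,
                                delta = cfg$integrate$delta)
    files <- c(files, write_stage_csv(
      data.frame(protein = names(ic$groups), group = unname(ic$groups)),
      out("integration_groups.csv")))
    writeLines(as_newick(ic$tree), out("integration_dendrogram.nwk"))
    files <- c(files, out("integration_dendrogram.nwk"))
    utils::write.csv(ic$distance, out("integration_distance.csv"))
    files <- c(files, out("integration_distance.csv"))
    results$integrate <- ic
  }

  if ("nuclei" %in% cfg$stages) {
    nu <- cfg$nuclei
    sim <- simulate_nuclei_fields(n_fields = nu$n_fields,
                                  field_size = nu$field_size,
                                  density = nu$density,
                                  positive_fraction = nu$positive_fraction,
                                  pair_mode = nu$pair_mode,
                                  displacement = nu$displacement,
                                  jitter_sd = nu$jitter_sd,
                                  seed = cfg$seed + 401L)
    st <- nuclei_proximity_test(sim$fields, n_resamples = nu$n_resamples,
                                seed = nu$seed)
    files <- c(files, write_stage_csv(sim$fields, out("nuclei_fields.csv")))
    jsonlite::write_json(
      list(observed_distances = st$observed_distances,
           per_pair_p = st$per_pair_p,
           welch_p = st$welch$p_value, welch_t = st$welch$statistic,
           n_resamples = st$n_resamples, seed = st$seed,
           pairing = st$pairing),
      out("nuclei_test.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, out("nuclei_test.json"))
    results$nuclei <- st
  }

  # run log: every parameter in effect, so the run is reproducible; the
  # output path is location metadata, not a parameter, and is omitted so
  # identical configs hash identically wherever they are written
  log_cfg <- unclass(cfg)
  log_cfg$out_dir <- NULL
  jsonlite::write_json(log_cfg, out("run_log.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, out("run_log.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  write_stage_csv(manifest, out("manifest.csv"))
  invisible(list(manifest = manifest, config = cfg, results = results))
}
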