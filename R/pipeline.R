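#' Pipeline configuration
#'
#' Builds and validates the single configuration object driving
#' [run_all()]. Accepts a named list or a path to a JSON file with the same
#' structure. Unknown keys are rejected so typos cannot silently fall back
#' to defaults.
#'
#' Keys: `simulate` (list of [synthetic_config()] overrides) *or* `inputs`
#' (list with `table`, `metadata`, `taxonomy` paths and optional `format`);
#' `min_negatives` (10), `min_samples` (5), `core_threshold` (0.7),
#' `test_min_samples` (5), `metric` ("bray_curtis"), `n_perm` (999),
#' `seed` (1), `exclude_lesional` (TRUE), `severity_models` (FALSE),
#' `out_dir`.
#'
#' @param config named list or JSON file path.
#' @return validated `pipeline_config` list with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(simulate = NULL, inputs = NULL,
                   min_negatives = 10, min_samples = 5,
                   core_threshold = 0.7, test_min_samples = 5,
                   metric = "bray_curtis", n_perm = 999, seed = 1,
                   exclude_lesional = TRUE, severity_models = FALSE,
                   out_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    cfg$simulate <- list()
  }
  if (cfg$core_threshold <= 0 || cfg$core_threshold > 1) {
    stop("core_threshold must be in (0, 1]", call. = FALSE)
  }
  assert_count(cfg$min_negatives, "min_negatives")
  assert_count(cfg$min_samples, "min_samples")
  if (!identical(cfg$n_perm, "exact")) assert_count(cfg$n_perm, "n_perm")
  if (!cfg$metric %in% c("bray_curtis", "jaccard_binary", "euclidean")) {
    stop("unknown metric: ", cfg$metric, call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

permanova_df <- function(x) {
  df <- as.data.frame(x)
  df$F[is.na(df$F)] <- NA
  df
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain inputs (simulate or load), align, preprocess
#' (contaminant/prevalence/taxonomy filters + fourth-root normalization),
#' alpha and within-participant beta diversity, genus aggregation,
#' PERMANOVA variance partition, persistence profiling with depth and
#' status tests, core/ubiquitous community identification and
#' between-status comparison. Per-stage TSV outputs and a machine-readable
#' `summary.json` are written to `out_dir` when given; the summary is a
#' pure function of config + inputs, so a rerun with the same seed is
#' byte-identical.
#'
#' @param config a [pipeline_config()] (or list/path coercible to one).
#' @return invisibly, a list with all stage results plus `summary`.
#' @export
run_all <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- c(sprintf("dermadiv %s", as.character(utils::packageVersion("dermadiv"))),
                 sprintf("seed: %s", cfg$seed),
                 sprintf("params: min_negatives=%d min_samples=%d core_threshold=%g metric=%s n_perm=%s",
                         cfg$min_negatives, cfg$min_samples, cfg$core_threshold,
                         cfg$metric, format(cfg$n_perm)))
  stage <- function(name, expr) {
    log_lines <<- c(log_lines, sprintf("stage: %s", name))
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  study <- stage("inputs", {
    if (!is.null(cfg$simulate)) {
      sim_cfg <- do.call(synthetic_config,
                         utils::modifyList(list(seed = cfg$seed), cfg$simulate))
      generate_study(sim_cfg)
    } else {
      fmt <- cfg$inputs$format %||% "tsv"
      list(table = read_asv_table(cfg$inputs$table, fmt),
           meta = read_metadata(cfg$inputs$metadata),
           taxonomy = read_taxonomy(cfg$inputs$taxonomy),
           truth = NULL)
    }
  })
  aligned <- stage("align", align_samples(study$table, study$meta))
  pre <- stage("preprocess", run_preprocessing(
    aligned$table, aligned$meta, study$taxonomy,
    min_negatives = cfg$min_negatives, min_samples = cfg$min_samples))
  meta <- aligned$meta[!aligned$meta$is_negative_control, , drop = FALSE]
  meta <- meta[meta$sample_id %in% sample_ids(pre$counts), , drop = FALSE]

  alpha <- stage("diversity", alpha_diversity(pre$counts))
  beta <- stage("diversity", within_participant_beta(pre$counts, pre$table, meta))
  genus <- stage("diversity", aggregate_by_genus(pre$table, study$taxonomy))

  partition <- stage("permanova", run_variance_partition(
    pre$table, meta, n_perm = cfg$n_perm,
    seed = stage_seed(cfg$seed, "permanova"), metric = cfg$metric,
    severity_models = cfg$severity_models))

  profile_depth <- stage("persistence", persistence_profile(
    pre$counts, meta, pool = "time",
    exclude_lesional = cfg$exclude_lesional))
  depth_test <- stage("persistence", depth_persistence_test(
    profile_depth, pre$counts, min_samples = cfg$test_min_samples))
  status_tests <- stage("persistence", {
    lapply(stats::setNames(nm = c("surface", "within")), function(dp) {
      status_persistence_test(profile_depth, meta, depth = dp,
                              min_patients = cfg$test_min_samples)
    })
  })

  core <- stage("core", identify_core(pre$counts, pre$table, meta,
                                      threshold = cfg$core_threshold,
                                      exclude_lesional = cfg$exclude_lesional))
  ubiquitous <- stage("core", identify_ubiquitous(
    pre$counts, meta, threshold = cfg$core_threshold,
    include_lesional = !cfg$exclude_lesional))
  core_cmp <- stage("core", compare_core_by_status(
    core, pre$counts, meta, n_perm = cfg$n_perm,
    seed = stage_seed(cfg$seed, "core")))

  pooled <- partition$pooled
  summary <- list(
    seed = cfg$seed,
    n_samples = nrow(pre$counts$values),
    n_asvs = ncol(pre$counts$values),
    filter = as.data.frame(pre$report),
    mean_fraction_reads_removed = pre$report$mean_fraction_removed,
    mean_richness_by_depth = vapply(
      split(alpha$richness, meta$depth[match(alpha$sample_id, meta$sample_id)]),
      mean, 0),
    permanova_pooled = permanova_df(pooled),
    core = list(threshold = core$threshold,
                union_core_size = length(core$union_core),
                n_ubiquitous = length(ubiquitous),
                mean_core_richness = mean(core$richness),
                mean_core_share = mean(core$share)),
    depth_test = list(n_tested = nrow(depth_test),
                      n_q_below_0.05 = sum(depth_test$q < 0.05, na.rm = TRUE)),
    status_test = lapply(status_tests, function(st) {
      list(n_tested = nrow(st), n_p_below_0.05 = sum(st$p < 0.05, na.rm = TRUE))
    })
  )

  if (!is.null(out_dir)) {
    write_tsv(alpha, file.path(out_dir, "alpha.tsv"))
    write_tsv(beta, file.path(out_dir, "beta.tsv"))
    write_tsv(genus, file.path(out_dir, "genus.tsv"))
    for (nm in names(partition)) {
      write_tsv(permanova_df(partition[[nm]]),
                file.path(out_dir, paste0("permanova_", nm, ".tsv")))
    }
    write_tsv(depth_test, file.path(out_dir, "depth_persistence_test.tsv"))
    for (dp in names(status_tests)) {
      write_tsv(status_tests[[dp]],
                file.path(out_dir, paste0("status_persistence_", dp, ".tsv")))
    }
    write_tsv(as.data.frame(pre$report), file.path(out_dir, "filter_report.tsv"))
    jsonlite::write_json(
      list(stages = as.data.frame(pre$report),
           mean_fraction_removed = pre$report$mean_fraction_removed),
      file.path(out_dir, "filter_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    core_df <- data.frame(participant_id = names(core$cores),
                          core_richness = unname(core$richness),
                          core_share = unname(core$share),
                          stringsAsFactors = FALSE)
    write_tsv(core_df, file.path(out_dir, "core_by_participant.tsv"))
    writeLines(ubiquitous, file.path(out_dir, "ubiquitous_asvs.txt"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         na = "null")
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  invisible(list(study = study, preprocessing = pre, alpha = alpha,
                 beta = beta, genus = genus, partition = partition,
                 depth_test = depth_test, status_tests = status_tests,
                 core = core, ubiquitous = ubiquitous,
                 core_comparison = core_cmp, summary = summary))
}
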