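#' Run the biomarker-discovery pipeline end to end
#'
#' Executes: (optional) synthetic cohort generation, preprocessing of
#' raw-scale input, the seeded split search, ensemble training on the best
#' division, frequency + participation feature selection, the multivariate
#' Cox fit, and the biomarker filter. Every stage writes its artifact as
#' plain TSV/JSON into `out_dir`, and a manifest records the configuration
#' hash, all seeds and thresholds, and per-artifact checksums so a rerun
#' with the same configuration is bit-reproducible.
#'
#' @param cohort An [expression_cohort()], or `NULL` to generate one.
#' @param sim_config A [simulation_config()] used when `cohort` is `NULL`.
#' @param out_dir Output directory for artifacts.
#' @param M Ensemble size.
#' @param n_repeats Seed-search repeats.
#' @param config A [penalty_config()].
#' @param freq_threshold Frequency threshold for per-subtype selection;
#'   default `M / 2` (at least half of the ensemble).
#' @param min_subtypes Participation threshold (default 3 of 5).
#' @param coef_thresh,p_thresh Cox biomarker filter thresholds.
#' @param train_frac Training fraction for splits.
#' @param seed Master seed for ensemble training.
#' @return Invisibly, a list with the key stage results (`search`, `split`,
#'   `ensemble`, `panel`, `cox_report`, `biomarkers`, `manifest_path`).
#' @export
run_pipeline <- function(cohort = NULL, sim_config = NULL, out_dir,
                         M = 100, n_repeats = 50,
                         config = penalty_config(),
                         freq_threshold = NULL, min_subtypes = 3,
                         coef_thresh = 0.2, p_thresh = 0.05,
                         train_frac = 0.8, seed = 1) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  freq_threshold <- freq_threshold %||% (M / 2)
  if (min_subtypes < 1 || min_subtypes > 5 || coef_thresh < 0 ||
      p_thresh <= 0 || p_thresh > 1 || freq_threshold < 0 ||
      freq_threshold > M)
    stop_mirmark("pipeline thresholds out of range", class = "config_error")

  truth <- NULL
  if (is.null(cohort)) {
    if (is.null(sim_config))
      stop_mirmark("supply either a cohort or a simulation config",
                   class = "config_error")
    logf("stage simulate: generating synthetic cohort")
    gen <- generate_cohort(sim_config)
    cohort <- gen$cohort
    truth <- gen$truth
    write_cohort(cohort, out_dir)
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
  }
  if (cohort$scale == "raw") {
    logf("stage preprocess: non-expression filter + log2")
    cohort <- preprocess(cohort)
    logf("  removed ", length(attr(cohort, "removed_features")), " features")
  }

  logf("stage seed-search: ", n_repeats, " repeats, M = ", M)
  search <- seed_search(cohort, n_repeats = n_repeats, M = M,
                        config = config, train_frac = train_frac)
  write_tsv(search$per_seed, file.path(out_dir, "seed_search.tsv"))
  logf("  best seed ", search$best_seed)

  split <- stratified_split(cohort$labels, train_frac,
                            seed = search$best_seed)
  logf("stage ensemble: retraining on best division")
  ensemble <- train_ensemble(cohort, split, M = M, config = config,
                             seed = derive_seed(search$best_seed, 0))

  logf("stage select: frequency >= ", freq_threshold,
       ", participation >= ", min_subtypes)
  freq <- count_frequencies(ensemble)
  sets <- select_per_subtype(freq, threshold = freq_threshold)
  panel <- select_features(sets, min_subtypes = min_subtypes)
  write_panel(panel, freq, file.path(out_dir, "feature_panel.tsv"))
  logf("  panel size ", length(panel$selected))

  cox_report <- NULL
  biomarkers <- NULL
  if (length(panel$selected) == 0) {
    logf("stage cox: SKIPPED (empty feature panel)")
  } else {
    logf("stage cox: multivariate fit on ", length(panel$selected),
         " features")
    cox_report <- fit_cox(cohort, panel)
    biomarkers <- filter_biomarkers(cox_report, coef_thresh, p_thresh)
    write_tsv(biomarkers, file.path(out_dir, "biomarkers.tsv"))
    logf("  ", sum(biomarkers$is_biomarker), " biomarkers flagged")
  }

  settings <- list(M = M, n_repeats = n_repeats, seed = seed,
                   train_frac = train_frac,
                   freq_threshold = freq_threshold,
                   min_subtypes = min_subtypes,
                   coef_thresh = coef_thresh, p_thresh = p_thresh,
                   alpha_grid = config$alpha_grid,
                   lambda_path_length = config$lambda_path_length,
                   cv_folds = config$cv_folds,
                   best_seed = search$best_seed)
  artifacts <- list.files(out_dir, pattern = "\\.(tsv|json)$")
  manifest <- list(settings = settings, config_hash = digest_settings(settings),
                   artifacts = as.list(tools::md5sum(
                     file.path(out_dir, artifacts))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  logf("pipeline complete: ", manifest_path)
  invisible(list(cohort = cohort, truth = truth, search = search,
                 split = split, ensemble = ensemble, freq = freq,
                 panel = panel, cox_report = cox_report,
                 biomarkers = biomarkers, manifest_path = manifest_path))
}

digest_settings <- function(settings) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(settings), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}
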