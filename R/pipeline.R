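#' Default pipeline configuration
#'
#' One section per stage: `design` (variant, n_participants, seed),
#' `observer` ([observer_params()]), `pupil` ([pupil_gen_params()]),
#' `preproc` ([preproc_params()]) and `analysis` (search window, folds, bin
#' and window widths). Any key not known to its section is an error, so
#' typos cannot silently fall back to defaults. The default preprocessing
#' coefficients invert the default generator's au scaling.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    design = list(variant = "exp1", n_participants = 16L, seed = 1L),
    observer = list(),
    pupil = list(),
    preproc = list(mm_coeff_a = 0.001, mm_coeff_b = 0),
    analysis = list(search_start_ms = 750, search_end_ms = 3000,
                    n_folds = 4L, bin_ms = 10, window_ms = 100)
  )
}

#' Read a pipeline configuration file
#'
#' @param path YAML file with the sections of [default_config()]; missing
#'   keys take their defaults, unknown keys are errors.
#' @return Validated nested list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' @param config nested list as in [default_config()].
#' @return The completed configuration (defaults filled in).
#' @export
validate_config <- function(config) {
  def <- default_config()
  stop_unknown_keys(config, names(def), "config section")
  cfg <- utils::modifyList(def, config)
  stop_unknown_keys(cfg$design, c("variant", "n_participants", "seed"), "design")
  stop_unknown_keys(cfg$observer, names(formals(observer_params)), "observer")
  stop_unknown_keys(cfg$pupil, names(formals(pupil_gen_params)), "pupil")
  stop_unknown_keys(cfg$preproc, names(formals(preproc_params)), "preproc")
  stop_unknown_keys(cfg$analysis, c("search_start_ms", "search_end_ms",
                                    "n_folds", "bin_ms", "window_ms"),
                    "analysis")
  if (!cfg$design$variant %in% VARIANTS)
    stop("unknown variant '", cfg$design$variant, "'; valid variants are: ",
         paste(VARIANTS, collapse = ", "))
  cfg
}

#' Run the full simulate-preprocess-analyze pipeline
#'
#' Executes, in order: synthetic-data generation, preprocessing, the
#' cross-validated pupil analysis (plus the eccentricity-by-breadth-type
#' interaction model when both breadth types are present, and
#' per-participant effect sizes), and the behavioral analyses (validity
#' model, RT model, staircase-efficacy Bayes factor). Every random draw
#' descends from the single config seed via named substreams, so identical
#' configs give identical reports. A stage that fails is recorded with its
#' error message and the stages depending on it are skipped; the behavioral
#' stage only needs the preprocessed trials and still runs if the pupil
#' analysis is refused.
#'
#' @param config validated configuration list (see [default_config()]).
#' @param out_dir optional directory; if given, the processed tables and a
#'   `results.json` are written there.
#' @return A `pipeline_report` list with per-stage results, counts and
#'   errors.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- validate_config(config)
  observer <- do.call(observer_params, cfg$observer)
  pupil <- do.call(pupil_gen_params, cfg$pupil)
  preproc <- do.call(preproc_params, cfg$preproc)
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  seed <- cfg$design$seed
  dat <- run_stage("simulate", generate_dataset(
    cfg$design$n_participants, cfg$design$variant, observer, pupil, seed))
  proc <- NULL; pupil_res <- NULL; behavior_res <- NULL
  if (!is.null(dat))
    proc <- run_stage("preprocess",
                      preprocess_pipeline(dat$samples, dat$trials, preproc))
  if (!is.null(proc)) {
    an <- cfg$analysis
    pupil_res <- run_stage("analyze_pupil", {
      cv <- crossval_select_window(
        proc$samples, proc$trials,
        search = c(an$search_start_ms, an$search_end_ms),
        n_folds = an$n_folds, bin_ms = an$bin_ms, window_ms = an$window_ms,
        seed = seed)
      res <- list(crossval = cv,
                  effect_sizes = per_participant_effect(
                    proc$samples, proc$trials, cv$selected_window))
      if (length(unique(proc$trials$breadth_type[
        proc$trials$phase == "experimental"])) > 1)
        res$interaction <- fit_interaction_lme(proc$samples, proc$trials,
                                               cv$selected_window)
      res
    })
    behavior_res <- run_stage("analyze_behavior", list(
      validity = accuracy_validity_model(proc$trials),
      rt = rt_model(proc$trials),
      staircase_bf = bf01_staircase_efficacy(proc$trials)))
  }
  report <- structure(list(
    package_version = as.character(utils::packageVersion("pupilbreadth")),
    config = cfg,
    counts = list(
      n_participants = cfg$design$n_participants,
      n_trials = if (!is.null(dat)) nrow(dat$trials) else NA_integer_,
      preprocessing = if (!is.null(proc)) proc$report else NULL),
    pupil = pupil_res, behavior = behavior_res, errors = errors),
    class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(proc)) {
      write_samples(proc$samples, file.path(out_dir, "samples_proc.csv"))
      write_trials(proc$trials, file.path(out_dir, "trials_proc.csv"))
    }
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

lme_row_json <- function(row) {
  if (is.null(row)) return(NULL)
  lapply(split(row, seq_len(nrow(row))), function(r)
    list(term = r$term, b = r$b, se = r$se, stat = r$stat, p = r$p,
         converged = r$converged, random_structure = r$random_structure))
}

report_to_json <- function(report) {
  pr <- report$pupil; br <- report$behavior
  list(
    package_version = report$package_version,
    counts = report$counts,
    selected_window_ms = if (!is.null(pr)) pr$crossval$selected_window,
    fold_peaks_ms = if (!is.null(pr)) pr$crossval$fold_peaks_ms,
    per_fold_heldout_t = if (!is.null(pr)) pr$crossval$per_fold_heldout_stats,
    fulldata_fit = if (!is.null(pr)) lme_row_json(pr$crossval$fulldata_fit),
    interaction = if (!is.null(pr)) lme_row_json(pr$interaction),
    effect_sizes = if (!is.null(pr)) pr$effect_sizes,
    validity = if (!is.null(br)) lme_row_json(br$validity),
    rt = if (!is.null(br)) lme_row_json(br$rt),
    staircase_bf01 = if (!is.null(br)) br$staircase_bf$bf01,
    staircase_bf_method = if (!is.null(br)) br$staircase_bf$method,
    errors = report$errors)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (", x$config$design$variant, ", n = ",
      x$counts$n_participants, ")\n", sep = "")
  if (!is.null(x$counts$preprocessing))
    cat(sprintf("  trials excluded: %d (%.2f%%)\n",
                x$counts$preprocessing$n_excluded,
                100 * x$counts$preprocessing$fraction_excluded))
  if (!is.null(x$pupil)) {
    print(x$pupil$crossval)
  }
  if (!is.null(x$behavior)) {
    v <- x$behavior$validity
    cat(sprintf("  validity effect: b = %.3f, z = %.2f, p = %.4g\n",
                v$b, v$stat, v$p))
    r <- x$behavior$rt
    cat(sprintf("  RT on eccentricity: b = %.3f, t = %.2f, p = %.4g\n",
                r$b, r$stat, r$p))
    cat(sprintf("  staircase-efficacy BF01 = %.2f (%s)\n",
                x$behavior$staircase_bf$bf01, x$behavior$staircase_bf$method))
  }
  for (nm in names(x$errors))
    cat("  stage '", nm, "' failed: ", x$errors[[nm]], "\n", sep = "")
  invisible(x)
}
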