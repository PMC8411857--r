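## End-to-end orchestration: curate -> fit / select k -> calibrate ->
## decompose -> score -> report, with a resolved-config record and a content
## manifest so a rerun with the same config is hash-identical.

#' Build a pipeline configuration
#'
#' @param cohort_csv,controls_csv input CSV paths; when `NULL` the synthetic
#'   generators are used with `seed`.
#' @param out_dir output directory (created if needed).
#' @param k fixed number of archetypes; when `NULL`, selected from
#'   `k_range` by the cross-validated elbow rule.
#' @param k_range candidate k values scanned when `k` is `NULL`.
#' @param folds cross-validation folds (default 10).
#' @param seed integer seed for every stochastic step.
#' @param n_restarts restarts per fit.
#' @param threshold meaningful-weight threshold in percent; when `NULL`,
#'   calibrated from the controls with `margin`.
#' @param margin calibration safety margin in percentage points (default 2).
#' @param sign_rule `"median_split"` or `"explicit"` (with `positive`).
#' @param positive explicit positive archetype names (optional).
#' @param n_eyes,n_control_eyes synthetic cohort sizes when simulating.
#' @param mirror_os mirror left-eye fields at load (default `TRUE`).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_csv = NULL, controls_csv = NULL,
                            out_dir = tempfile("vfarch_run_"),
                            k = NULL, k_range = 2:8, folds = 10L, seed = 1L,
                            n_restarts = 5L, threshold = NULL, margin = 2,
                            sign_rule = "median_split", positive = NULL,
                            n_eyes = 40L, n_control_eyes = 30L,
                            mirror_os = TRUE) {
  structure(list(
    cohort_csv = cohort_csv, controls_csv = controls_csv, out_dir = out_dir,
    k = k, k_range = k_range, folds = folds, seed = seed,
    n_restarts = n_restarts, threshold = threshold, margin = margin,
    sign_rule = sign_rule, positive = positive,
    n_eyes = n_eyes, n_control_eyes = n_control_eyes,
    mirror_os = mirror_os
  ), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort loading (or synthetic generation), curation
#' (reliability filtering and the six-month outcome window), archetype-model
#' fitting on all reliable fields (with cross-validated elbow selection of k
#' when not fixed), control calibration of the meaningful-weight threshold,
#' decomposition of the curated baseline fields, scoring, and report export.
#' The run is deterministic for a fixed config; a manifest listing every
#' artifact with its MD5 content hash is written last.
#'
#' @param config a [pipeline_config()].
#' @return the output directory, invisibly; artifacts: `model.json`,
#'   `rss_curve.csv` (when k is selected), `calibration.csv`,
#'   `decompositions.csv`, `frequencies.csv`, `meaningful_counts.csv`,
#'   `correlations.csv`, `at_sum.csv`, `config.json`, `manifest.csv`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- character(0)
  emit <- function(df, f) {
    write.csv(df, out(f), row.names = FALSE)
    artifacts <<- c(artifacts, f)
  }

  cohort <- stage("load-cohort", {
    if (is.null(config$cohort_csv)) {
      generate_cohort(n_eyes = config$n_eyes, seed = config$seed)$cohort
    } else {
      read_cohort(config$cohort_csv, mirror_os = config$mirror_os)
    }
  })
  controls <- stage("load-controls", {
    if (is.null(config$controls_csv)) {
      generate_controls(n_eyes = config$n_control_eyes,
                        seed = config$seed + 1L)
    } else {
      read_cohort(config$controls_csv, mirror_os = config$mirror_os)
    }
  })

  curated <- stage("curate", curate_cohort(cohort))

  # the model is fit on all reliable (unaveraged) fields, as in the original
  # analysis; the curated per-visit averages feed the downstream scoring
  fit_X <- stage("curate", cohort_matrix(filter_reliable(cohort))$td)

  curve <- NULL
  k <- config$k
  if (is.null(k)) {
    curve <- stage("select-k", {
      if (max(config$k_range) >= nrow(fit_X)) {
        stop(sprintf("kmax (%d) must be below the number of fields (%d)",
                     max(config$k_range), nrow(fit_X)))
      }
      rss_curve(fit_X, k_values = config$k_range, folds = config$folds,
                seed = config$seed, n_restarts = config$n_restarts)
    })
    k <- select_k_elbow(curve)
    emit(as.data.frame(curve), "rss_curve.csv")
  }

  model <- stage("fit", {
    fit_archetypes(fit_X, k, seed = config$seed,
                   n_restarts = config$n_restarts)
  })
  stage("fit", serialize_model(model, out("model.json")))
  artifacts <- c(artifacts, "model.json")

  cal <- stage("calibrate", {
    calibrate_controls(controls, model, margin = config$margin)
  })
  threshold <- if (is.null(config$threshold)) cal$threshold else config$threshold
  cal_out <- cal$stats
  cal_out$threshold <- threshold
  emit(cal_out, "calibration.csv")

  base <- stage("decompose", {
    baseline_fields <- lapply(curated, function(s) {
      Filter(function(f) f$visit == "baseline", s$fields)
    })
    baseline_fields <- unlist(baseline_fields, recursive = FALSE)
    if (!length(baseline_fields)) stop("no baseline fields after curation")
    decompose(model, new_cohort(lapply(baseline_fields,
                                       function(f) eye_series(list(f)))))
  })
  emit(cbind(base$meta[, c("eye_id", "visit", "md", "psd")],
             as.data.frame(base$weights)), "decompositions.csv")

  reports <- stage("score", {
    signs <- assign_signs(model, rule = config$sign_rule,
                          positive = config$positive)
    covars <- base$meta[, c("md", "psd")]
    grp <- base$meta$arm
    grp <- if (length(unique(grp[!is.na(grp) & grp != "NA"])) == 2L) grp else NULL
    rep_tabs <- cohort_report(base, threshold = threshold, signs = signs,
                              covariates = covars, group = grp)
    score <- data.frame(eye_id = base$meta$eye_id, visit = base$meta$visit,
                        at_sum = at_sum(base, signs))
    list(tabs = rep_tabs, score = score, signs = signs)
  })
  emit(reports$tabs$frequencies, "frequencies.csv")
  emit(reports$tabs$meaningful_counts, "meaningful_counts.csv")
  if (!is.null(reports$tabs$correlations)) {
    emit(reports$tabs$correlations, "correlations.csv")
  }
  if (!is.null(reports$tabs$group_tests)) {
    emit(reports$tabs$group_tests, "group_tests.csv")
  }
  emit(reports$score, "at_sum.csv")

  resolved <- config
  resolved$k <- k
  resolved$threshold <- threshold
  resolved$out_dir <- NULL  # run-specific path; would break hash identity
  jsonlite::write_json(resolved[!vapply(resolved, is.null, TRUE)],
                       out("config.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  artifacts <- c(artifacts, "config.json")

  manifest <- data.frame(
    file = artifacts,
    md5 = unname(tools::md5sum(vapply(artifacts, out, ""))),
    row.names = NULL
  )
  write.csv(manifest, out("manifest.csv"), row.names = FALSE)
  invisible(config$out_dir)
}
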