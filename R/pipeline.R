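#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> exclude -> fit -> diagnose -> rescore -> predict
#' -> report: generates (or accepts) a registry, applies the cohort
#' exclusions, runs the four-sample Rasch diagnostic design before and after
#' rescoring, and runs the cross-validated prediction-equivalence
#' experiments (logistic always; random forest optionally), comparing
#' original and rescored feature sets by Brier score, log loss, a Wilcoxon
#' signed-rank test on per-case squared-error differences, and the
#' individual-level risk-difference analysis.
#'
#' The root `seed` is expanded into per-stage seeds by a fixed counter
#' scheme (`seed + 1000 * stage`, stages numbered 1 = simulate, 2 = sample
#' design, 3 = folds, 4 = forest), so stages can be reproduced in isolation.
#'
#' @param config A [registry_config()].
#' @param seed Root integer seed.
#' @param records Optional registry tibble; when supplied, simulation is
#'   skipped.
#' @param out_dir Optional output directory; when given, the fit reports,
#'   rescore map, score summaries, risk-difference table, exclusion log and
#'   run manifest are written there as CSV/JSON.
#' @param folds Cross-validation folds.
#' @param n_class_intervals Class intervals for the chi-square.
#' @param map A [collapse_map()]; defaults to [published_rescore_map()].
#' @param prediction_sample Fraction of the modelling dataset used in the
#'   prediction experiments (1 = all cases).
#' @param forest Run the random-forest arm of experiment 2.
#' @param tree_grid Tree grid for the forest search.
#' @return A `gcs_pipeline` list: `manifest`, `fit_reports`, `scores`,
#'   `wilcoxon`, `risk_differences`, `map`.
#' @export
run_pipeline <- function(config = registry_config(), seed = 1L,
                         records = NULL, out_dir = NULL, folds = 5L,
                         n_class_intervals = 6L,
                         map = published_rescore_map(),
                         prediction_sample = 1,
                         forest = FALSE,
                         tree_grid = c(100, 250, 500, 1000, 2000)) {
  t0 <- Sys.time()
  stage_seed <- function(i) as.integer(seed + 1000L * i)

  if (is.null(records)) {
    records <- generate_registry(config, seed = stage_seed(1L))
  }
  complete <- apply_exclusions(records)
  log <- exclusion_log(complete)

  rm0 <- as_response_matrix(complete)
  design_pre <- run_sample_design(rm0, seed = stage_seed(2L),
                                  n_class_intervals = n_class_intervals)
  rm1 <- apply_collapse(rm0, map)
  design_post <- run_sample_design(rm1, seed = stage_seed(2L),
                                   n_class_intervals = n_class_intervals)
  fit_reports <- dplyr::bind_rows(
    dplyr::mutate(design_pre, scoring = "original", .before = 1),
    dplyr::mutate(design_post, scoring = "rescored", .before = 1)
  )

  modelling <- drop_missing_outcome(complete)
  if (prediction_sample < 1) {
    withr::with_seed(stage_seed(3L), {
      keep <- sample(nrow(modelling), round(prediction_sample * nrow(modelling)))
    })
    modelling <- modelling[sort(keep), , drop = FALSE]
  }
  y <- as.integer(modelling$outcome30d == "dead")
  fold_id <- make_cv_folds(nrow(modelling), folds, seed = stage_seed(3L))
  ids <- modelling$id

  experiments <- list(
    exp1_original = list(map = NULL, ancillary = FALSE),
    exp1_rescored = list(map = map, ancillary = FALSE),
    exp2_original = list(map = NULL, ancillary = TRUE),
    exp2_rescored = list(map = map, ancillary = TRUE)
  )
  preds <- purrr::imap(experiments, function(e, nm) {
    fit_predict_logistic(mortality_features(modelling, e$map, e$ancillary),
                         y, fold_id, ids = ids)
  })
  if (forest) {
    preds$exp2_forest_original <- fit_predict_forest(
      mortality_features(modelling, NULL, TRUE), y, fold_id,
      tree_grid = tree_grid, seed = stage_seed(4L))
    preds$exp2_forest_rescored <- fit_predict_forest(
      mortality_features(modelling, map, TRUE), y, fold_id,
      tree_grid = tree_grid, seed = stage_seed(4L))
  }
  scores <- purrr::imap_dfr(preds, function(p, nm) {
    dplyr::bind_cols(tibble::tibble(experiment = nm), score_summary(p))
  })

  pairings <- list(
    exp1 = c("exp1_original", "exp1_rescored"),
    exp2 = c("exp2_original", "exp2_rescored")
  )
  if (forest) pairings$exp2_forest <- c("exp2_forest_original",
                                        "exp2_forest_rescored")
  wilcox <- purrr::imap_dfr(pairings, function(pair, nm) {
    d <- (preds[[pair[2]]]$p_hat - preds[[pair[2]]]$y)^2 -
      (preds[[pair[1]]]$p_hat - preds[[pair[1]]]$y)^2
    wt <- wilcoxon_signed_rank(d)
    tibble::tibble(comparison = nm, statistic = wt$statistic,
                   p_value = wt$p_value, n_nonzero = wt$n_nonzero,
                   method = wt$method)
  })

  covars <- dplyr::select(modelling, "id", "iss", "age", "region")
  risk <- risk_difference_analysis(preds$exp2_original, preds$exp2_rescored,
                                   covariates = covars)

  manifest <- list(
    seed = seed,
    stage_seeds = stats::setNames(vapply(1:4, stage_seed, integer(1)),
                                  c("simulate", "design", "folds", "forest")),
    config = config[c("n_total", "n_paediatric", "n_incomplete", "n_complete",
                      "extreme3_count", "extreme15_count", "target_mortality",
                      "missing_outcome_rate", "scale")],
    counts = list(
      exclusions = as.list(log),
      modelling_n = nrow(modelling),
      prediction_sample = prediction_sample
    ),
    folds = folds,
    n_class_intervals = n_class_intervals,
    forest = forest,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = character(0)
  )

  result <- structure(list(
    manifest = manifest,
    fit_reports = fit_reports,
    scores = scores,
    wilcoxon = wilcox,
    risk_differences = risk,
    predictions = preds,
    map = map
  ), class = "gcs_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      fit_reports = file.path(out_dir, "fit_reports.csv"),
      rescore_map = file.path(out_dir, "rescore_map.json"),
      scores = file.path(out_dir, "scores.json"),
      wilcoxon = file.path(out_dir, "wilcoxon.csv"),
      risk_counts = file.path(out_dir, "risk_difference_counts.csv"),
      risk_strata = file.path(out_dir, "risk_difference_strata.csv"),
      exclusion_log = file.path(out_dir, "exclusion_log.json"),
      manifest = file.path(out_dir, "manifest.json")
    )
    readr::write_csv(fit_reports, paths["fit_reports"], progress = FALSE)
    collapse_map_json(map, paths["rescore_map"])
    jsonlite::write_json(scores, paths["scores"], dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(wilcox, paths["wilcoxon"], progress = FALSE)
    readr::write_csv(risk$counts, paths["risk_counts"], progress = FALSE)
    if (!is.null(risk$strata)) {
      readr::write_csv(risk$strata, paths["risk_strata"], progress = FALSE)
    } else {
      paths <- paths[names(paths) != "risk_strata"]
    }
    jsonlite::write_json(as.list(log), paths["exclusion_log"],
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs <- unname(paths)
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA)
    result$manifest <- manifest
  }
  result
}

#' @export
print.gcs_pipeline <- function(x, ...) {
  cat("<gcs_pipeline>\n")
  cat(sprintf("  complete sample: %d (of %d input records)\n",
              x$manifest$counts$exclusions$n_retained,
              x$manifest$counts$exclusions$n_input))
  cat(sprintf("  modelling cases: %d\n", x$manifest$counts$modelling_n))
  cat("  score summaries:\n")
  print(x$scores)
  invisible(x)
}
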