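# End-to-end study replica: simulate (or load) -> preprocess -> split ->
# outlier screen -> train -> LOOCV + external validation -> report.

#' Stratified calibration / validation split
#'
#' Splits a per-sample set into disjoint calibration and validation subsets,
#' stratified by class. Two modes: exact per-class counts (the default
#' mirrors the 68/15 FM and 41/13 non-FM calibration/validation design, i.e.
#' 109 calibration and 28 validation samples), or a stratified fraction
#' (e.g. 0.8). Healthy-control (NC) rows are excluded from both subsets and
#' returned separately. The split is deterministic under `seed`.
#'
#' @param set a `spectra_set` with one row per sample.
#' @param calibration named per-class calibration counts (default
#'   `c(FM = 68, NONFM = 41)`); ignored when `fraction` is given.
#' @param validation named per-class validation counts (default
#'   `c(FM = 15, NONFM = 13)`).
#' @param fraction if non-NULL, stratified calibration fraction in (0, 1)
#'   instead of exact counts; the rest goes to validation.
#' @param seed split seed.
#' @return List with `calibration`, `validation` (disjoint `spectra_set`s)
#'   and `nc` (NC rows, possibly empty matrix-wise).
#' @export
split_dataset <- function(set, calibration = c(FM = 68, NONFM = 41),
                          validation = c(FM = 15, NONFM = 13),
                          fraction = NULL, seed = 1L) {
  stopifnot(inherits(set, "spectra_set"))
  if (anyDuplicated(set$sample_id))
    stop("split_dataset expects one row per sample (average replicates first)")
  classes <- c("FM", "NONFM")
  if (!all(classes %in% set$label))
    stop("both FM and NONFM must be present")
  nc_rows <- which(set$label == "NC")
  cal_idx <- integer(0); val_idx <- integer(0)
  set.seed(as.integer(seed))
  for (cl in classes) {
    rows <- which(set$label == cl)
    if (!is.null(fraction)) {
      if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
      n_cal <- round(fraction * length(rows))
      n_val <- length(rows) - n_cal
    } else {
      n_cal <- calibration[[cl]]
      n_val <- validation[[cl]]
      if (n_cal + n_val > length(rows))
        stop("requested ", n_cal + n_val, " ", cl, " samples but only ",
             length(rows), " available")
    }
    perm <- sample(rows)
    cal_idx <- c(cal_idx, perm[seq_len(n_cal)])
    val_idx <- c(val_idx, perm[n_cal + seq_len(n_val)])
  }
  stopifnot(length(intersect(cal_idx, val_idx)) == 0L)
  list(calibration = set[sort(cal_idx)], validation = set[sort(val_idx)],
       nc = if (length(nc_rows)) set[nc_rows] else NULL)
}

#' Study run configuration
#'
#' Bundles every knob of the end-to-end replica: the synthetic-cohort
#' configuration (or an input `spectra_set`), the preprocessing
#' configuration, the model sizes (7 latent variables, 1 OSC component by
#' default), the split design and seeds, and whether the (more expensive)
#' leave-one-out cross-validation and outlier screening steps run.
#'
#' @param synthetic a [synthetic_config()] used to simulate the cohort
#'   (ignored when `run_study()` is given data directly).
#' @param preprocess a [preprocess_config()].
#' @param n_lv,n_osc model sizes (defaults 7 and 1).
#' @param calibration,validation,fraction,split_seed see [split_dataset()].
#' @param run_loocv run leave-one-out cross-validation on the calibration
#'   set (default TRUE).
#' @param screen_outliers run the leverage/studentized-residual screen and
#'   remove up to 3% of calibration samples before the final fit (default
#'   TRUE).
#' @param top_k size of the regression-vector band report (default 10).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       preprocess = preprocess_config(),
                       n_lv = 7L, n_osc = 1L,
                       calibration = c(FM = 68, NONFM = 41),
                       validation = c(FM = 15, NONFM = 13),
                       fraction = NULL, split_seed = 1L,
                       run_loocv = TRUE, screen_outliers = TRUE,
                       top_k = 10L) {
  structure(list(synthetic = synthetic, preprocess = preprocess,
                 n_lv = as.integer(n_lv), n_osc = as.integer(n_osc),
                 calibration = calibration, validation = validation,
                 fraction = fraction, split_seed = as.integer(split_seed),
                 run_loocv = run_loocv, screen_outliers = screen_outliers,
                 top_k = as.integer(top_k)),
            class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass_deep(cfg), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full study replica
#'
#' Executes the whole chain on a synthetic cohort (or supplied replicate
#' spectra): preprocessing (rubberband baseline per replicate, replicate
#' averaging, normalization, region selection, Savitzky-Golay second
#' derivative), the FM-minus-NC difference spectrum on the normalized
#' full-range spectra, the stratified calibration/validation split, an
#' optional leverage/studentized-residual outlier screen of the calibration
#' set, the OSC-PLS-DA fit, leave-one-out cross-validation, external
#' validation with ROC/AUC, and the ranked regression-vector band report.
#'
#' @param cfg a [run_config()].
#' @param data optional replicate-level `spectra_set`; when NULL the cohort
#'   is simulated from `cfg$synthetic`.
#' @return An object of class `"study_report"`: list with the fitted
#'   `model`, `loocv` and `external` validation reports, `roc`,
#'   `regression_report`, `difference_spectrum` (FM - NC, NULL without NC
#'   samples), `outliers` (flags and removals), the score-plot data, and a
#'   `provenance` record (config, config hash, seeds, package version).
#' @export
run_study <- function(cfg = run_config(), data = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  raw <- if (is.null(data)) stage("simulate", generate_cohort(cfg$synthetic))
         else data
  pre <- stage("preprocess", preprocess_set(raw, cfg$preprocess))
  diff_sp <- NULL
  if (any(raw$label == "NC") && any(raw$label == "FM")) {
    # Fig-7-style difference on baseline-corrected, averaged, normalized
    # full-range spectra (before derivative/region selection)
    full <- stage("preprocess", {
      s <- if (cfg$preprocess$do_baseline) rubberband_correct(raw) else raw
      s <- average_replicates(s)
      if (cfg$preprocess$normalization != "none")
        s <- normalize_set(s, cfg$preprocess$normalization)
      s
    })
    diff_sp <- difference_spectrum(class_mean_spectrum(full, "FM"),
                                   class_mean_spectrum(full, "NC"))
  }
  sp <- stage("split", split_dataset(pre, cfg$calibration, cfg$validation,
                                     cfg$fraction, cfg$split_seed))
  cal <- sp$calibration
  flags <- NULL; removed <- character(0)
  if (cfg$screen_outliers) {
    pre_fit <- stage("train", osc_plsda(cal, n_lv = cfg$n_lv, n_osc = cfg$n_osc))
    flags <- stage("outliers", detect_outliers(pre_fit))
    cal <- stage("outliers", remove_flagged(cal, flags))
    removed <- attr(cal, "removed")
  }
  model <- stage("train", osc_plsda(cal, n_lv = cfg$n_lv, n_osc = cfg$n_osc))
  cv <- if (cfg$run_loocv)
    stage("loocv", loocv(cal, n_lv = cfg$n_lv, n_osc = cfg$n_osc)) else NULL
  ext <- stage("validate", external_validate(model, sp$validation))
  rep_bands <- stage("report", regression_vector_report(model, cfg$top_k))
  provenance <- list(config = cfg, config_hash = config_hash(cfg),
                     generator_seed = cfg$synthetic$seed,
                     split_seed = cfg$split_seed,
                     preprocess_steps = attr(pre, "provenance")$steps,
                     removed_samples = removed,
                     package_version = as.character(utils::packageVersion("sersdx")))
  structure(list(model = model, loocv = cv, external = ext, roc = ext$roc,
                 regression_report = rep_bands, difference_spectrum = diff_sp,
                 outliers = flags,
                 scores = data.frame(sample_id = model$sample_id,
                                     label = model$labels,
                                     model$scores[, seq_len(min(3L, cfg$n_lv)),
                                                  drop = FALSE]),
                 calibration_n = n_spectra(cal),
                 validation_n = n_spectra(sp$validation),
                 provenance = provenance),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== OSC-PLS-DA study replica ==\n")
  cat(sprintf("calibration n = %d, validation n = %d (removed: %s)\n",
              x$calibration_n, x$validation_n,
              if (length(x$provenance$removed_samples))
                paste(x$provenance$removed_samples, collapse = ", ") else "none"))
  fom <- function(f, cv, ev)
    cat(sprintf("  %-13s %-12s %s\n", f, cv, ev))
  cat("\nFigures of merit       Calibration  Prediction\n")
  se_cv <- if (!is.null(x$loocv)) sprintf("%.4g", x$loocv$se) else "-"
  r2_cv <- if (!is.null(x$loocv)) sprintf("%.4g", x$loocv$r2) else "-"
  ac_cv <- if (!is.null(x$loocv)) sprintf("%.1f", x$loocv$accuracy) else "-"
  sp_cv <- if (!is.null(x$loocv)) sprintf("%.1f", x$loocv$specificity) else "-"
  sn_cv <- if (!is.null(x$loocv)) sprintf("%.1f", x$loocv$sensitivity) else "-"
  fom("SECV/SEP", se_cv, sprintf("%.4g", x$external$se))
  fom("R2", r2_cv, sprintf("%.4g", x$external$r2))
  fom("Accuracy%", ac_cv, sprintf("%.1f", x$external$accuracy))
  fom("Specificity%", sp_cv, sprintf("%.1f", x$external$specificity))
  fom("Sensitivity%", sn_cv, sprintf("%.1f", x$external$sensitivity))
  cat(sprintf("\nExternal ROC AUC: %.3f\n", x$external$auc))
  cat("\nTop regression-vector bands:\n")
  print(utils::head(x$regression_report, 5L), row.names = FALSE, digits = 3)
  cat(sprintf("\nconfig hash: %s\n", x$provenance$config_hash))
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Writes the headline metrics, regression-vector report, ROC points,
#' score-plot data and the full provenance record (including the exact
#' configuration and its hash) as one JSON document.
#'
#' @param report a `"study_report"`.
#' @param path output file path.
#' @export
write_study_json <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  metr <- function(r) if (is.null(r)) NULL else
    list(n = r$n, r2 = r$r2, r2_ss = r$r2_ss, se = r$se,
         confusion = as.list(r$confusion), accuracy = r$accuracy,
         sensitivity = r$sensitivity, specificity = r$specificity,
         auc = r$auc)
  obj <- list(
    calibration_n = report$calibration_n,
    validation_n = report$validation_n,
    loocv = metr(report$loocv), external = metr(report$external),
    roc_points = report$roc$points,
    regression_report = report$regression_report,
    scores = report$scores,
    explained_x = report$model$explained_x,
    explained_y = report$model$explained_y,
    provenance = unclass_deep(report$provenance))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
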