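# Model assessment: leave-one-out cross-validation (R2cv, SECV), external
# validation (R2pre, SEP, confusion rates), empirical ROC/AUC, and
# leverage/studentized-residual outlier screening.

new_validation_report <- function(kind, y, yhat, class_codes, threshold,
                                  positive = "FM") {
  n <- length(y)
  se <- sqrt(sum((y - yhat)^2) / n)
  r2 <- if (stats::sd(yhat) > 0 && stats::sd(y) > 0)
    stats::cor(y, yhat)^2 else NA_real_
  r2_ss <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  lo <- names(class_codes)[which.min(class_codes)]
  hi <- names(class_codes)[which.max(class_codes)]
  pred <- ifelse(yhat < threshold, lo, hi)
  truth <- ifelse(y < threshold, lo, hi)
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  # ROC orientation: higher score = more positive-like. The positive class
  # carries the lower code, so the continuous prediction is negated.
  fm_score <- if (class_codes[positive] == min(class_codes)) -yhat else yhat
  roc <- roc_auc(fm_score, truth == positive)
  structure(
    list(kind = kind, n = n, r2 = r2, r2_ss = r2_ss, se = se,
         confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
         accuracy = 100 * (tp + tn) / n,
         sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
         auc = roc$auc, roc = roc, positive = positive,
         y = y, y_pred = yhat, class_pred = pred),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  lab <- switch(x$kind, cv = "Leave-one-out cross-validation",
                external = "External validation",
                resub = "Training resubstitution", x$kind)
  se_lab <- switch(x$kind, cv = "SECV", external = "SEP", "RMSE")
  cat(sprintf("%s (n = %d; positive class: %s)\n", lab, x$n, x$positive))
  cat(sprintf("  %-12s %.4g\n", se_lab, x$se))
  cat(sprintf("  %-12s %.4g  (1 - SSres/SStot: %.4g)\n", "R2", x$r2, x$r2_ss))
  cat(sprintf("  %-12s %.1f\n", "Accuracy%", x$accuracy))
  cat(sprintf("  %-12s %.1f\n", "Specificity%", x$specificity))
  cat(sprintf("  %-12s %.1f\n", "Sensitivity%", x$sensitivity))
  cat(sprintf("  %-12s %.3f\n", "AUC", x$auc))
  cat("  confusion:", paste(names(x$confusion), x$confusion, collapse = " "),
      "\n")
  invisible(x)
}

#' Leave-one-out cross-validation of the OSC-PLS-DA chain
#'
#' For each sample in turn, the entire modelling chain — column
#' mean-centering, OSC fitting, and the NIPALS PLS fit — is refit on the
#' remaining samples and the held-out sample is predicted. No statistic of
#' the held-out sample enters its own fold. Reports SECV (root mean squared
#' residual of the coded class over the folds), R2cv (squared Pearson
#' correlation of held-out predictions with the coding), the
#' cross-validated confusion counts and rates, and the ROC/AUC over the
#' held-out continuous predictions.
#'
#' @param x preprocessed spectra (`spectra_set` or matrix).
#' @param y class labels (defaulting to `x$label` for a `spectra_set`).
#' @param n_lv,n_osc,class_codes as in [osc_plsda()].
#' @return A `"validation_report"` (kind `"cv"`).
#' @export
loocv <- function(x, y = NULL, n_lv = 7L, n_osc = 1L,
                  class_codes = c(FM = 1, NONFM = 2)) {
  if (inherits(x, "spectra_set")) {
    if (is.null(y)) y <- x$label
    x <- x$X
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("leave-one-out needs at least 3 samples")
  y_coded <- code_classes(y, class_codes)
  if (length(unique(y_coded)) < 2L) stop("both classes must be present")
  yhat <- loo_predictions(x, y_coded, n_lv, n_osc, class_codes)
  new_validation_report("cv", y_coded, yhat, class_codes,
                        mean(class_codes))
}

# held-out prediction for every sample: the full chain (centering, OSC, PLS)
# refit on the other n-1 samples
loo_predictions <- function(x, y_coded, n_lv, n_osc, class_codes) {
  n <- nrow(x)
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    yi <- y_coded[-i]
    if (length(unique(yi)) < 2L)
      stop("fold ", i, " loses one class entirely")
    fit <- osc_plsda(x[-i, , drop = FALSE], yi, n_lv = n_lv, n_osc = n_osc,
                     class_codes = class_codes)
    yhat[i] <- predict(fit, x[i, , drop = FALSE], type = "response")
  }
  yhat
}

#' Choose the number of latent variables by minimum SECV
#'
#' Computes the leave-one-out SECV profile for every model size from 1 to
#' `n_lv_max` latent variables (each fold refits centering, OSC and PLS once
#' at `n_lv_max`; the nested sub-models share the decomposition) and returns
#' the profile together with the minimizing size. Model selection is not
#' part of the default workflow — the study design fixes 7 latent variables
#' — but is available for exploration.
#'
#' @param x preprocessed spectra (`spectra_set` or matrix).
#' @param y class labels (defaulting to `x$label`).
#' @param n_lv_max largest model size to profile (default 10).
#' @param n_osc,class_codes as in [osc_plsda()].
#' @return List with `secv` (numeric vector indexed by model size) and
#'   `best` (the size minimizing SECV).
#' @export
select_n_lv <- function(x, y = NULL, n_lv_max = 10L, n_osc = 1L,
                        class_codes = c(FM = 1, NONFM = 2)) {
  if (inherits(x, "spectra_set")) {
    if (is.null(y)) y <- x$label
    x <- x$X
  }
  x <- as.matrix(x)
  n <- nrow(x)
  y_coded <- code_classes(y, class_codes)
  res2 <- matrix(0, n, n_lv_max)
  for (i in seq_len(n)) {
    yi <- y_coded[-i]
    if (length(unique(yi)) < 2L) stop("fold ", i, " loses one class entirely")
    mc <- mean_center(x[-i, , drop = FALSE])
    osc <- osc_fit(mc$Xc, yi, n_osc)
    ym <- mean(yi)
    pls <- nipals_pls1(osc$X, yi - ym, n_lv_max)
    xn <- osc_apply(osc$model,
                    sweep(x[i, , drop = FALSE], 2L, mc$column_means))
    for (k in seq_len(n_lv_max)) {
      Wk <- pls$W[, seq_len(k), drop = FALSE]
      Pk <- pls$P[, seq_len(k), drop = FALSE]
      bk <- drop(Wk %*% solve(crossprod(Pk, Wk), pls$q[seq_len(k)]))
      res2[i, k] <- (y_coded[i] - (drop(xn %*% bk) + ym))^2
    }
  }
  secv <- sqrt(colMeans(res2))
  list(secv = secv, best = which.min(secv))
}

#' External validation on an unseen test set
#'
#' Predicts a disjoint test set with a fitted model and reports SEP, R2pre,
#' confusion counts with FM as the positive class, accuracy, sensitivity,
#' specificity and ROC/AUC. Overlap between training and test sample IDs is
#' an error.
#'
#' @param model a fitted `"osc_plsda"` (its embedded OSC model is applied to
#'   the test spectra).
#' @param test a `spectra_set` or matrix of preprocessed test spectra.
#' @param y test labels (defaulting to `test$label`).
#' @return A `"validation_report"` (kind `"external"`).
#' @export
external_validate <- function(model, test, y = NULL) {
  stopifnot(inherits(model, "osc_plsda"))
  ids <- NULL
  if (inherits(test, "spectra_set")) {
    if (is.null(y)) y <- test$label
    ids <- test$sample_id
  }
  if (!is.null(ids) && !is.null(model$sample_id)) {
    shared <- intersect(ids, model$sample_id)
    if (length(shared))
      stop("test set overlaps training IDs: ", paste(shared, collapse = ", "))
  }
  y_coded <- code_classes(y, model$class_codes)
  yhat <- predict(model, test, type = "response")
  new_validation_report("external", y_coded, yhat, model$class_codes,
                        model$threshold)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps all decision thresholds over the scores (higher score = more
#' positive-like) and integrates the curve by trapezoids, which equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, with ties counted one half. If the resulting AUC is below 0.5
#' the score orientation is flipped and the flip recorded.
#'
#' @param scores numeric continuous predictions.
#' @param labels logical (TRUE = positive) or two-level factor/character
#'   where `positive` names the positive level.
#' @param positive positive level when `labels` is not logical.
#' @return An object of class `"roc_curve"`: list with `points` (data.frame
#'   of threshold, fpr, tpr), `auc`, and `flipped`.
#' @export
roc_auc <- function(scores, labels, positive = "FM") {
  if (!is.logical(labels)) labels <- as.character(labels) == positive
  if (!any(labels) || all(labels))
    stop("both classes must be present for a ROC curve")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  build <- function(sc) {
    th <- sort(unique(sc), decreasing = TRUE)
    pos <- sum(labels); neg <- sum(!labels)
    tpr <- vapply(th, function(t) sum(sc >= t & labels) / pos, 0)
    fpr <- vapply(th, function(t) sum(sc >= t & !labels) / neg, 0)
    pts <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
    auc <- sum(diff(pts$fpr) * (pts$tpr[-1L] + pts$tpr[-nrow(pts)]) / 2)
    list(points = pts, auc = auc)
  }
  r <- build(scores)
  flipped <- FALSE
  if (r$auc < 0.5) { r <- build(-scores); flipped <- TRUE }
  structure(list(points = r$points, auc = r$auc, flipped = flipped),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f over %d thresholds%s\n", x$auc,
              nrow(x$points) - 1L, if (x$flipped) " (orientation flipped)" else ""))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' Leverage / studentized-residual outlier screening
#'
#' Computes, for every training sample, the leverage in the latent-variable
#' score space, h_i = 1/n + t_i' (T'T)^-1 t_i, and a studentized residual
#' r_i / (s * sqrt(1 - h_i)). With `residuals = "deletion"` (the default)
#' r_i is the externally studentized form: the residual of sample i when
#' predicted by the chain refit without it, scaled by the cross-validation
#' error s. This catches gross artifact samples that a flexible calibration
#' model bends to fit — such samples show up as leverage points with
#' near-zero calibration residuals, so the in-model (`"calibration"`)
#' residual would miss them. A sample is flagged as influential when both
#' diagnostics exceed their thresholds: h_i > leverage_factor * (n_lv + 1)
#' / n and |studentized residual| > resid_cut. Flagging is diagnostic only;
#' removal is the separate, capped action [remove_flagged()].
#'
#' @param model a fitted `"osc_plsda"` (its stored training data are reused
#'   for the deletion refits).
#' @param residuals `"deletion"` (externally studentized, default) or
#'   `"calibration"` (in-model residuals).
#' @param leverage_factor multiplier on the mean-leverage rule (default 3).
#' @param resid_cut studentized-residual cutoff (default 3).
#' @return An object of class `"outlier_flags"`: data.frame-like list with
#'   per-sample `leverage`, `studentized_residual`, `flagged`, plus the
#'   thresholds used.
#' @export
detect_outliers <- function(model, residuals = c("deletion", "calibration"),
                            leverage_factor = 3, resid_cut = 3) {
  stopifnot(inherits(model, "osc_plsda"))
  residuals <- match.arg(residuals)
  Tm <- model$scores
  n <- nrow(Tm)
  G <- crossprod(Tm)
  if (!is.finite(rcond(G)) || rcond(G) < 1e-14)
    stop("T'T is singular; cannot compute leverages")
  h <- 1 / n + rowSums((Tm %*% solve(G)) * Tm)
  res <- if (residuals == "deletion") {
    model$y - loo_predictions(model$x, model$y, model$n_lv, model$n_osc,
                              model$class_codes)
  } else {
    model$y - model$fitted
  }
  s <- sqrt(mean(res^2))
  sr <- if (s > 0) res / (s * sqrt(pmax(1 - h, 1e-12))) else res * 0
  h_cut <- leverage_factor * (model$n_lv + 1) / n
  flagged <- h > h_cut & abs(sr) > resid_cut
  structure(list(sample_id = model$sample_id, leverage = h,
                 studentized_residual = sr, flagged = flagged,
                 residuals = residuals, leverage_cut = h_cut,
                 resid_cut = resid_cut),
            class = "outlier_flags")
}

#' @export
print.outlier_flags <- function(x, ...) {
  cat(sprintf("<outlier_flags> %d/%d flagged (leverage > %.3f and |stud. resid| > %g)\n",
              sum(x$flagged), length(x$flagged), x$leverage_cut, x$resid_cut))
  invisible(x)
}

#' Remove flagged outliers (capped)
#'
#' Drops flagged samples from a set, largest |studentized residual| first,
#' never more than `max_frac` of the samples. Returns the curated set with a
#' `"removed"` attribute naming what was dropped.
#'
#' @param set the training `spectra_set` the model was fitted on.
#' @param flags an `"outlier_flags"` object for the same samples.
#' @param max_frac removal cap as a fraction of n (default 0.03).
#' @return The curated `spectra_set`.
#' @export
remove_flagged <- function(set, flags, max_frac = 0.03) {
  stopifnot(inherits(set, "spectra_set"), inherits(flags, "outlier_flags"))
  n <- n_spectra(set)
  if (length(flags$flagged) != n) stop("flags do not match the set")
  cap <- floor(max_frac * n)
  idx <- which(flags$flagged)
  if (!length(idx) || cap == 0L) {
    attr(set, "removed") <- character(0)
    return(set)
  }
  idx <- idx[order(abs(flags$studentized_residual[idx]), decreasing = TRUE)]
  idx <- idx[seq_len(min(cap, length(idx)))]
  out <- set[-idx]
  attr(out, "removed") <- set$sample_id[idx]
  out
}

#' Serialize a validation report to JSON
#' @param report a `"validation_report"`.
#' @param path output file path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  obj <- list(kind = report$kind, n = report$n, r2 = report$r2,
              r2_ss = report$r2_ss, se = report$se,
              confusion = as.list(report$confusion),
              accuracy = report$accuracy, sensitivity = report$sensitivity,
              specificity = report$specificity, auc = report$auc,
              positive = report$positive,
              roc_points = report$roc$points)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
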