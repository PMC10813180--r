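# OSC-corrected PLS-DA: one (or more) orthogonal signal correction
# components removed from the centered spectral matrix, then NIPALS PLS1
# against the coded class variable.

#' Fit orthogonal signal correction components
#'
#' Each OSC component is a high-variance direction of the centered spectral
#' matrix X that carries no class information: the weight vector w maximises
#' the variance of the score t = X w subject to t being exactly orthogonal to
#' the (centered) class coding y. This is solved in closed form as the
#' leading right singular vector of X projected onto the subspace orthogonal
#' to X'y, so the stored score satisfies corr(t, y) = 0 to machine precision
#' and applying the component to the training matrix reproduces the training
#' deflation exactly. The component is removed by deflation X <- X - t p'
#' with loading p = X't / (t't).
#'
#' @param X centered numeric matrix (samples x wavenumbers).
#' @param y numeric two-class coding (e.g. 1/2), length `nrow(X)`.
#' @param n_components number of OSC components (>= 0; 0 is a no-op).
#' @return List with `model` (class `"osc_model"`: per-component `w`, `p`,
#'   `t`) and `X` (the corrected matrix).
#' @export
osc_fit <- function(X, y, n_components = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (n_components < 0) stop("n_components must be >= 0")
  if (max(abs(colMeans(X))) > 1e-6 * max(1, max(abs(X))))
    stop("X must be column-centered before osc_fit")
  yc <- y - mean(y)
  comps <- vector("list", n_components)
  scale0 <- sqrt(sum(X^2))
  for (k in seq_len(n_components)) {
    v <- drop(crossprod(X, yc))
    nv <- sqrt(sum(v^2))
    # project columns of X off v: Xp = X (I - v v'/v'v)
    Xp <- if (nv > 0) X - tcrossprod(X %*% v, v) / nv^2 else X
    sv <- svd(Xp, nu = 0L, nv = 1L)
    if (sv$d[1L] < 1e-10 * max(scale0, 1))
      stop("requested OSC components exceed the rank of X")
    w <- drop(sv$v[, 1L])
    if (nv > 0) w <- w - v * sum(v * w) / nv^2   # re-project for exactness
    w <- w / sqrt(sum(w^2))
    sgn <- sign(w[which.max(abs(w))]); if (sgn < 0) w <- -w
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    X <- X - tcrossprod(t, p)
    comps[[k]] <- list(w = w, p = p, t = t)
  }
  list(model = structure(list(components = comps,
                              n_components = as.integer(n_components)),
                         class = "osc_model"),
       X = X)
}

#' Apply fitted OSC components to new data
#'
#' Deflates `X_new` with the training weight and loading vectors only; the
#' class labels of the new samples are never used.
#'
#' @param m an `"osc_model"` from [osc_fit()].
#' @param X_new centered matrix with the training column dimension.
#' @return The corrected matrix.
#' @export
osc_apply <- function(m, X_new) {
  stopifnot(inherits(m, "osc_model"))
  X_new <- as.matrix(X_new)
  for (cmp in m$components) {
    if (ncol(X_new) != length(cmp$w))
      stop("column dimension does not match the OSC model")
    t <- drop(X_new %*% cmp$w)
    X_new <- X_new - tcrossprod(t, cmp$p)
  }
  X_new
}

# NIPALS PLS1 core on centered X, centered y. Returns W, P, q, T, b and
# explained variance fractions. With a univariate response the NIPALS inner
# loop converges in a single pass; the iteration is retained with a
# convergence guard for robustness.
nipals_pls1 <- function(X, yc, n_lv, tol = 1e-12, maxit = 500L) {
  n <- nrow(X); p <- ncol(X)
  ssx0 <- sum(X^2); ssy0 <- sum(yc^2)
  if (ssy0 == 0) stop("degenerate response: only one class present")
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv); evx <- numeric(n_lv); evy <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(X, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(ssx0 * ssy0) / max(n, 1)) || nw == 0)
      stop("n_lv = ", n_lv, " exceeds the effective rank of X")
    w <- w / nw
    for (it in seq_len(maxit)) {
      t <- drop(X %*% w)
      tt <- sum(t^2)
      if (tt < 1e-24 * ssx0) stop("n_lv = ", n_lv, " exceeds the effective rank of X")
      w_new <- drop(crossprod(X, yc))          # PLS1: weight fixed by y
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new
    }
    t <- drop(X %*% w)
    tt <- sum(t^2)
    if (tt < 1e-20 * max(ssx0, 1)) stop("n_lv = ", n_lv, " exceeds the effective rank of X")
    pv <- drop(crossprod(X, t)) / tt
    qa <- sum(t * yc) / tt
    X <- X - tcrossprod(t, pv)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    evx[a] <- tt * sum(pv^2) / ssx0
    evy[a] <- qa^2 * tt / ssy0
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  list(W = W, P = P, q = q, T = Tm, b = b, explained_x = evx, explained_y = evy)
}

#' OSC-corrected PLS discriminant analysis
#'
#' The two-class discriminant workflow for preprocessed spectra: the class
#' labels are coded numerically (class 1 = FM, class 2 = non-FM by default),
#' the spectral matrix is column mean-centered, `n_osc` orthogonal signal
#' correction components are removed (see [osc_fit()]), and a PLS1 regression
#' of the coded class on the corrected matrix is fitted by NIPALS with
#' `n_lv` latent variables. Predictions threshold the continuous PLS
#' prediction at the midpoint of the class codes (1.5 under 1/2 coding;
#' values below the midpoint are class 1, values at or above it class 2).
#'
#' @param x preprocessed spectra: a `spectra_set` (rows = samples) or a
#'   numeric matrix.
#' @param y class labels (character/factor with levels FM/NONFM, or a numeric
#'   coding); taken from `x$label` when `x` is a `spectra_set` and `y` is
#'   missing.
#' @param n_lv number of PLS latent variables (default 7).
#' @param n_osc number of OSC components removed first (default 1).
#' @param class_codes named numeric vector mapping the two class labels to
#'   their codes; default `c(FM = 1, NONFM = 2)`.
#' @return An object of class `"osc_plsda"` with components including
#'   `scores` (training LV scores), `coefficients` (the regression vector,
#'   one per wavenumber), `explained_x`/`explained_y` (per-LV variance
#'   fractions), `osc` (the OSC model), `x_means`, `y_mean`, `fitted`,
#'   and the training metadata.
#' @seealso [predict.osc_plsda()], [loocv()], [external_validate()],
#'   [regression_vector_report()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 30), 40, 30)
#' X[1:20, 5] <- X[1:20, 5] + 2          # class-separating variable
#' y <- rep(c("FM", "NONFM"), each = 20)
#' fit <- osc_plsda(X, y, n_lv = 2, n_osc = 1)
#' table(truth = y, predicted = predict(fit, X, type = "class"))
#' @export
osc_plsda <- function(x, y = NULL, n_lv = 7L, n_osc = 1L,
                      class_codes = c(FM = 1, NONFM = 2)) {
  cl <- match.call()
  grid <- NULL; ids <- NULL
  if (inherits(x, "spectra_set")) {
    if (is.null(y)) y <- x$label
    grid <- x$grid; ids <- x$sample_id
    x <- x$X
  }
  x <- as.matrix(x)
  if (is.null(y)) stop("class labels y are required")
  if (length(class_codes) != 2L || is.null(names(class_codes)))
    stop("class_codes must be a named length-2 numeric vector")
  y_coded <- code_classes(y, class_codes)
  if (length(unique(y_coded)) < 2L)
    stop("degenerate response: only one class present")
  if (n_lv < 1L) stop("n_lv must be >= 1")
  if (n_lv + n_osc > min(nrow(x) - 1L, ncol(x)))
    stop("n_lv + n_osc exceeds what ", nrow(x), " samples x ", ncol(x),
         " variables can support")
  ctr <- mean_center(x)
  osc <- osc_fit(ctr$Xc, y_coded, n_osc)
  y_mean <- mean(y_coded)
  pls <- nipals_pls1(osc$X, y_coded - y_mean, n_lv)
  fitted <- drop(osc$X %*% pls$b) + y_mean
  wn <- if (!is.null(grid)) grid else seq_len(ncol(x))
  names(pls$b) <- format(wn, trim = TRUE)
  structure(
    list(call = cl, n_lv = as.integer(n_lv), n_osc = as.integer(n_osc),
         class_codes = class_codes, threshold = mean(class_codes),
         osc = osc$model, weights = pls$W, loadings = pls$P,
         y_loadings = pls$q, scores = pls$T, coefficients = pls$b,
         explained_x = pls$explained_x, explained_y = pls$explained_y,
         x_means = ctr$column_means, y_mean = y_mean, grid = grid,
         wavenumber = wn, sample_id = ids, y = y_coded, labels = y,
         x = x, fitted = fitted),
    class = "osc_plsda")
}

code_classes <- function(y, class_codes) {
  if (is.numeric(y)) {
    if (!all(y %in% class_codes))
      stop("numeric y contains values outside the class codes")
    return(as.numeric(y))
  }
  y <- as.character(y)
  bad <- setdiff(unique(y), names(class_codes))
  if (length(bad))
    stop("labels not in class_codes: ", paste(bad, collapse = ", "))
  unname(class_codes[y])
}

decode_classes <- function(yhat, class_codes, threshold) {
  lo <- names(class_codes)[which.min(class_codes)]
  hi <- names(class_codes)[which.max(class_codes)]
  # ties at the threshold go to the higher-coded class
  ifelse(yhat < threshold, lo, hi)
}

#' Predict class membership for new spectra
#'
#' Centers the new spectra with the training column means, removes the
#' training OSC components ([osc_apply()]), applies the regression vector,
#' and thresholds at the class-code midpoint.
#'
#' @param object an `"osc_plsda"` fit.
#' @param newdata a `spectra_set` (its grid must equal the training grid) or
#'   a matrix with the training column dimension.
#' @param type `"response"` (continuous prediction), `"class"`, or `"both"`
#'   (data.frame with both).
#' @param ... unused.
#' @return Numeric vector, character vector, or data.frame according to
#'   `type`.
#' @export
predict.osc_plsda <- function(object, newdata,
                              type = c("response", "class", "both"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "spectra_set")) {
    if (!is.null(object$grid) &&
        (length(newdata$grid) != length(object$grid) ||
         max(abs(newdata$grid - object$grid)) > 1e-8))
      stop("newdata grid does not match the training grid")
    newdata <- newdata$X
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_means))
    stop("newdata has ", ncol(newdata), " variables; the model was trained on ",
         length(object$x_means))
  Xc <- sweep(newdata, 2L, object$x_means)
  Xc <- osc_apply(object$osc, Xc)
  yhat <- drop(Xc %*% object$coefficients) + object$y_mean
  cls <- decode_classes(yhat, object$class_codes, object$threshold)
  switch(type,
         response = yhat,
         class = cls,
         both = data.frame(y_continuous = yhat, y_class = cls,
                           stringsAsFactors = FALSE))
}

#' @export
coef.osc_plsda <- function(object, ...) object$coefficients

#' @export
fitted.osc_plsda <- function(object, ...) object$fitted

#' @export
residuals.osc_plsda <- function(object, ...) object$y - object$fitted

#' @export
print.osc_plsda <- function(x, ...) {
  cat("OSC-PLS-DA model\n")
  cat(sprintf("  %d samples x %d variables; %d OSC component(s), %d latent variable(s)\n",
              length(x$y), length(x$coefficients), x$n_osc, x$n_lv))
  cat(sprintf("  classes: %s (codes %s; threshold %.2f)\n",
              paste(names(x$class_codes), collapse = " vs "),
              paste(x$class_codes, collapse = "/"), x$threshold))
  cat(sprintf("  cumulative X-variance explained: %.1f%%; Y-variance: %.1f%%\n",
              100 * sum(x$explained_x), 100 * sum(x$explained_y)))
  invisible(x)
}

#' @export
summary.osc_plsda <- function(object, ...) {
  pred <- decode_classes(object$fitted, object$class_codes, object$threshold)
  truth <- ifelse(object$y < object$threshold,
                  names(object$class_codes)[which.min(object$class_codes)],
                  names(object$class_codes)[which.max(object$class_codes)])
  out <- list(
    model = object,
    lv_table = data.frame(
      LV = seq_len(object$n_lv),
      x_variance = object$explained_x,
      x_cumulative = cumsum(object$explained_x),
      y_variance = object$explained_y,
      y_cumulative = cumsum(object$explained_y)),
    train_confusion = table(truth = truth, predicted = pred),
    train_rmse = sqrt(mean((object$y - object$fitted)^2)))
  class(out) <- "summary.osc_plsda"
  out
}

#' @export
print.summary.osc_plsda <- function(x, ...) {
  print(x$model)
  cat("\nPer-LV explained variance (fractions):\n")
  print(x$lv_table, row.names = FALSE, digits = 3)
  cat(sprintf("\nTraining RMSE (coded-Y units): %.4f\n", x$train_rmse))
  cat("Training confusion:\n")
  print(x$train_confusion)
  invisible(x)
}

#' Plot an OSC-PLS-DA model
#'
#' `which = "scores"` draws the score plot of two latent variables with
#' per-LV explained X-variance in the axis labels; `which = "coefficients"`
#' draws the regression vector against wavenumber.
#'
#' @param x an `"osc_plsda"` fit.
#' @param which `"scores"` or `"coefficients"`.
#' @param lv length-2 vector of LV indices for the score plot.
#' @param ... passed to the underlying plot call.
#' @export
plot.osc_plsda <- function(x, which = c("scores", "coefficients"),
                           lv = c(1L, 2L), ...) {
  which <- match.arg(which)
  if (which == "scores") {
    lv <- lv[lv <= x$n_lv]
    if (length(lv) < 2L) stop("need two latent variables for a score plot")
    cls <- factor(x$labels)
    graphics::plot(x$scores[, lv[1L]], x$scores[, lv[2L]],
                   col = as.integer(cls), pch = as.integer(cls),
                   xlab = sprintf("LV%d (%.1f%% X-var)", lv[1L],
                                  100 * x$explained_x[lv[1L]]),
                   ylab = sprintf("LV%d (%.1f%% X-var)", lv[2L],
                                  100 * x$explained_x[lv[2L]]), ...)
    graphics::legend("topright", legend = levels(cls),
                     col = seq_along(levels(cls)), pch = seq_along(levels(cls)))
  } else {
    graphics::plot(x$wavenumber, x$coefficients, type = "l",
                   xlab = "wavenumber (cm-1)", ylab = "regression coefficient",
                   ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Ranked discriminant bands from the regression vector
#'
#' Finds the local extrema of the absolute regression vector, ranks them by
#' magnitude, and annotates each with the nearest entry of the reference band
#' table within a tolerance window. On second-derivative spectra one band
#' produces a cluster of extrema (the centre plus dispersive flanks spanning
#' roughly three half-widths), so extrema closer than `min_sep` to a
#' higher-ranked one are treated as the same spectral feature and dropped.
#' The top-ranked features are the wavenumbers that drive the
#' discrimination.
#'
#' Band attribution is only as interpretable as the regression vector
#' itself: with many latent variables the coefficients mix signal with
#' within-class variance directions. For reading off discriminant bands,
#' fit with the OSC component(s) plus a single predictive latent variable
#' (`n_lv = 1`), whose regression vector is the class-covariance direction
#' — the usual practice for orthogonally-filtered discriminant models.
#'
#' @param m an `"osc_plsda"` fit.
#' @param top_k number of features to report (default 10).
#' @param bands annotation table, default [band_assignments()].
#' @param tol annotation tolerance in cm^-1 (default 8).
#' @param min_sep minimum separation between reported features in cm^-1
#'   (default 30, about three default band half-widths).
#' @return A data.frame with columns `rank`, `wavenumber`, `coefficient`,
#'   `band`, `mode`, `assignment` (NA where no table entry lies within
#'   `tol`).
#' @export
regression_vector_report <- function(m, top_k = 10L, bands = band_assignments(),
                                     tol = 8, min_sep = 30) {
  stopifnot(inherits(m, "osc_plsda"))
  b <- abs(m$coefficients)
  wn <- m$wavenumber
  n <- length(b)
  # strict local maxima of |b| (plateaus excluded => flat vectors yield none)
  is_ext <- c(FALSE, b[2:(n - 1)] > b[1:(n - 2)] & b[2:(n - 1)] > b[3:n], FALSE)
  idx <- which(is_ext)
  if (!length(idx))
    return(data.frame(rank = integer(0), wavenumber = numeric(0),
                      coefficient = numeric(0), band = numeric(0),
                      mode = character(0), assignment = character(0),
                      stringsAsFactors = FALSE))
  idx <- idx[order(b[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in idx) {
    if (!length(kept) || all(abs(wn[i] - wn[kept]) >= min_sep))
      kept <- c(kept, i)
    if (length(kept) >= top_k) break
  }
  idx <- kept
  ann <- lapply(wn[idx], function(w) {
    d <- abs(bands$position - w)
    j <- which(d <= tol)
    if (!length(j))
      return(list(band = NA_real_, mode = NA_character_, assignment = NA_character_))
    j <- j[order(d[j], bands$source[j] != "regression")][1L]  # nearest; prefer
    list(band = bands$position[j], mode = bands$mode[j],     # discriminant table
         assignment = bands$assignment[j])
  })
  data.frame(rank = seq_along(idx), wavenumber = wn[idx],
             coefficient = unname(m$coefficients[idx]),
             band = vapply(ann, `[[`, 0, "band"),
             mode = vapply(ann, `[[`, "", "mode"),
             assignment = vapply(ann, `[[`, "", "assignment"),
             stringsAsFactors = FALSE)
}

#' Serialize a fitted model to JSON
#'
#' Writes all model vectors and metadata as one JSON document (vectors as
#' arrays), round-trippable enough for audit and external tooling.
#'
#' @param m an `"osc_plsda"` fit.
#' @param path output file path.
#' @export
write_model_json <- function(m, path) {
  stopifnot(inherits(m, "osc_plsda"))
  obj <- list(
    type = "osc_plsda", n_lv = m$n_lv, n_osc = m$n_osc,
    class_codes = as.list(m$class_codes), threshold = m$threshold,
    wavenumber = m$wavenumber, coefficients = unname(m$coefficients),
    x_means = unname(m$x_means), y_mean = m$y_mean,
    explained_x = m$explained_x, explained_y = m$explained_y,
    osc = lapply(m$osc$components, function(cmp)
      list(w = cmp$w, p = cmp$p)),
    weights = apply(m$weights, 2L, identity, simplify = FALSE),
    loadings = apply(m$loadings, 2L, identity, simplify = FALSE),
    y_loadings = m$y_loadings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
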