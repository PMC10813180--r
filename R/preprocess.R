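# Spectral preprocessing: rubberband baseline, normalization, Savitzky-Golay
# second derivative, region selection, mean-centering, difference spectra.

# Andrew's monotone-chain lower convex hull; returns vertex indices in
# increasing x order. x strictly increasing.
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      o <- hull[k - 1L]; a <- hull[k]
      # pop a if (o, a, i) is not a strict right-of/convex-down turn
      cr <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cr <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    hull[k] <- i
  }
  hull[seq_len(k)]
}

#' Rubberband (convex-hull) baseline correction
#'
#' Estimates a smooth fluorescence background as the piecewise-linear
#' interpolation of the lower convex hull of the (wavenumber, intensity)
#' points — the "rubberband" stretched under the spectrum — and subtracts it.
#' The corrected spectrum is zero at every hull vertex (in particular both
#' endpoints) and non-negative everywhere.
#'
#' @param s a `spectrum` (length >= 3).
#' @return A list with components `baseline` and `corrected`, both `spectrum`
#'   objects on the input grid.
#' @export
rubberband_baseline <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (length(s$wavenumber) < 3L) stop("rubberband needs at least 3 points")
  idx <- lower_hull_idx(s$wavenumber, s$intensity)
  base <- stats::approx(s$wavenumber[idx], s$intensity[idx],
                        xout = s$wavenumber, method = "linear",
                        ties = "ordered")$y
  corr <- pmax(s$intensity - base, 0)
  corr[idx] <- 0
  list(baseline = spectrum(s$wavenumber, base, s$sample_id, s$replicate, s$label),
       corrected = spectrum(s$wavenumber, corr, s$sample_id, s$replicate, s$label))
}

#' Rubberband-correct every spectrum in a set
#' @param set a `spectra_set`.
#' @return The corrected `spectra_set`.
#' @export
rubberband_correct <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  X <- t(apply(set$X, 1L, function(y) {
    idx <- lower_hull_idx(set$grid, y)
    base <- stats::approx(set$grid[idx], y[idx], xout = set$grid,
                          ties = "ordered")$y
    out <- pmax(y - base, 0)
    out[idx] <- 0
    out
  }))
  spectra_set(set$grid, X, set$sample_id, set$replicate, set$label)
}

#' Normalize a spectrum
#'
#' `vector`: unit Euclidean norm; `area`: unit trapezoid integral of the
#' absolute intensity over the wavenumber axis; `max`: maximum intensity 1;
#' `none`: identity.
#'
#' @param s a `spectrum`.
#' @param method one of `"vector"`, `"area"`, `"max"`, `"none"`.
#' @return The normalized `spectrum`.
#' @export
normalize_spectrum <- function(s, method = c("vector", "area", "max", "none")) {
  stopifnot(inherits(s, "spectrum"))
  s$intensity <- normalize_vec(s$intensity, s$wavenumber, match.arg(method))
  s
}

normalize_vec <- function(y, x, method) {
  if (method == "none") return(y)
  nrm <- switch(method,
    vector = sqrt(sum(y^2)),
    area = sum(diff(x) * (abs(y)[-length(y)] + abs(y)[-1L]) / 2),
    max = max(y))
  if (!is.finite(nrm) || nrm <= 0)
    stop("cannot normalize: ", method, " norm is zero or non-finite")
  y / nrm
}

#' Normalize every spectrum in a set
#' @param set a `spectra_set`.
#' @param method see [normalize_spectrum()].
#' @return A `spectra_set`.
#' @export
normalize_set <- function(set, method = c("vector", "area", "max", "none")) {
  method <- match.arg(method)
  X <- t(apply(set$X, 1L, normalize_vec, x = set$grid, method = method))
  spectra_set(set$grid, X, set$sample_id, set$replicate, set$label)
}

sg_check <- function(n, window, polyorder, spacing) {
  if (window %% 2L == 0L) stop("sg window must be odd")
  if (window < polyorder + 2L) stop("sg window must be >= polyorder + 2")
  if (window > n) stop("sg window exceeds spectrum length")
  if (max(abs(diff(spacing))) > 1e-8 * mean(spacing))
    stop("non-uniform wavenumber grid: resample before the SG derivative")
}

sg_d2_coef <- function(window, polyorder) {
  co <- unclass(signal::sgolay(p = polyorder, n = window, m = 2L))
  co[(window + 1L) %/% 2L, ]
}

#' Savitzky-Golay second derivative
#'
#' Fits a degree-`polyorder` polynomial by least squares in a sliding window
#' of `window` points and returns its second derivative at the window centre,
#' scaled by the grid spacing^-2 so values are per-(cm^-1)^2. Edge points
#' without a full window — `(window-1)/2` per side — are dropped rather than
#' padded, so the output axis is shorter than the input.
#'
#' @param s a `spectrum` on a uniform grid.
#' @param window odd window length in points (default 25).
#' @param polyorder polynomial degree, 2-4 (default 3).
#' @return A `spectrum` of interior-point second derivatives.
#' @export
sg_second_derivative <- function(s, window = 25L, polyorder = 3L) {
  stopifnot(inherits(s, "spectrum"))
  sg_check(length(s$wavenumber), window, polyorder, diff(s$wavenumber))
  h <- mean(diff(s$wavenumber))
  d2 <- sg_apply(s$intensity, sg_d2_coef(window, polyorder)) / h^2
  half <- (window - 1L) %/% 2L
  keep <- (half + 1L):(length(s$wavenumber) - half)
  spectrum(s$wavenumber[keep], d2, s$sample_id, s$replicate, s$label)
}

# centered FIR application; returns length(y) - window + 1 values
sg_apply <- function(y, coef) {
  w <- length(coef)
  E <- stats::embed(y, w)       # row t = y[t+w-1], ..., y[t]
  as.numeric(E %*% rev(coef))
}

#' Savitzky-Golay second derivative of every spectrum in a set
#' @param set a `spectra_set` on a uniform grid.
#' @inheritParams sg_second_derivative
#' @return A `spectra_set` on the truncated interior grid.
#' @export
sg_second_derivative_set <- function(set, window = 25L, polyorder = 3L) {
  stopifnot(inherits(set, "spectra_set"))
  sg_check(length(set$grid), window, polyorder, diff(set$grid))
  h <- mean(diff(set$grid))
  coef <- sg_d2_coef(window, polyorder)
  D <- t(apply(set$X, 1L, sg_apply, coef = coef)) / h^2
  half <- (window - 1L) %/% 2L
  keep <- (half + 1L):(length(set$grid) - half)
  spectra_set(set$grid[keep], D, set$sample_id, set$replicate, set$label)
}

#' Restrict a spectrum to a wavenumber region
#'
#' Keeps points with `lo <= wavenumber <= hi` (closed interval).
#'
#' @param s a `spectrum` or `spectra_set`.
#' @param lo,hi region bounds in cm^-1.
#' @return Object of the same class on the restricted axis.
#' @export
select_region <- function(s, lo, hi) {
  if (lo > hi) stop("region_lo must be <= region_hi")
  if (inherits(s, "spectra_set")) {
    keep <- s$grid >= lo & s$grid <= hi
    if (!any(keep)) stop("region [", lo, ", ", hi, "] selects no points")
    return(spectra_set(s$grid[keep], s$X[, keep, drop = FALSE], s$sample_id,
                       s$replicate, s$label))
  }
  stopifnot(inherits(s, "spectrum"))
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  if (!any(keep)) stop("region [", lo, ", ", hi, "] selects no points")
  out <- s
  out$wavenumber <- s$wavenumber[keep]
  out$intensity <- s$intensity[keep]
  if (length(out$wavenumber) >= 3L)
    out <- spectrum(out$wavenumber, out$intensity, s$sample_id, s$replicate,
                    s$label)
  out
}

#' Spectral region presets
#'
#' Two fingerprint-region presets are shipped: `"model"` (750-1750 cm^-1, the
#' region under which the discriminant model is built) and `"abstract"`
#' (750-1720 cm^-1, a slightly narrower variant also quoted for this
#' workflow). The two differ only in the upper bound; `"model"` is the
#' package default.
#'
#' @return Named list of `c(lo, hi)` bounds.
#' @export
region_presets <- function() {
  list(model = c(750, 1750), abstract = c(750, 1720))
}

#' Mean-center the columns of a matrix
#'
#' @param X numeric matrix with at least 2 rows.
#' @return List with `Xc` (centered matrix) and `column_means` (to be reused
#'   on test data).
#' @export
mean_center <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("mean_center needs at least 2 rows")
  mu <- colMeans(X)
  list(Xc = sweep(X, 2L, mu), column_means = mu)
}

#' Difference of two mean spectra
#'
#' Pointwise `a - b` on a shared grid, e.g. the mean patient-class spectrum
#' minus the mean healthy-control spectrum, used to locate the bands whose
#' intensity differs between cohorts.
#'
#' @param a,b `spectrum` objects on identical grids.
#' @return A `spectrum` of differences.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (length(a$wavenumber) != length(b$wavenumber) ||
      max(abs(a$wavenumber - b$wavenumber)) > 1e-8)
    stop("difference_spectrum: grids do not match")
  spectrum(a$wavenumber, a$intensity - b$intensity,
           sample_id = paste0(a$sample_id, "-", b$sample_id))
}

#' Mean spectrum of a class
#' @param set a `spectra_set`.
#' @param label class whose rows are averaged.
#' @return A `spectrum`.
#' @export
class_mean_spectrum <- function(set, label) {
  rows <- set$label == label
  if (!any(rows)) stop("no spectra with label ", label)
  spectrum(set$grid, colMeans(set$X[rows, , drop = FALSE]),
           sample_id = paste0("mean_", label), label = label)
}

#' Preprocessing configuration
#'
#' Bundles the tunable preprocessing choices: region bounds, Savitzky-Golay
#' window/order, normalization method, and whether/when the rubberband
#' baseline is applied. The fixed pipeline order is: baseline (per replicate)
#' -> replicate averaging -> normalization -> region selection -> SG second
#' derivative; mean-centering happens inside model fitting so that test
#' spectra are centered with training means.
#'
#' @param region_lo,region_hi region bounds in cm^-1 (default 750-1750).
#' @param sg_window odd SG window in points (default 25).
#' @param sg_polyorder SG polynomial degree, 2-4 (default 3).
#' @param normalization `"vector"` (default), `"area"`, `"max"` or `"none"`.
#' @param do_baseline apply rubberband baseline correction (default TRUE).
#' @param baseline_before_averaging baseline-correct each replicate before
#'   averaging (default TRUE) or the averaged spectrum after.
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(region_lo = 750, region_hi = 1750,
                              sg_window = 25L, sg_polyorder = 3L,
                              normalization = c("vector", "area", "max", "none"),
                              do_baseline = TRUE,
                              baseline_before_averaging = TRUE) {
  normalization <- match.arg(normalization)
  if (region_lo >= region_hi) stop("region_lo must be < region_hi")
  if (sg_window %% 2L == 0L) stop("sg_window must be odd")
  if (!sg_polyorder %in% 2:4) stop("sg_polyorder must be 2, 3 or 4")
  if (sg_window < sg_polyorder + 2L) stop("sg_window must be >= sg_polyorder + 2")
  structure(list(region_lo = region_lo, region_hi = region_hi,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 normalization = normalization, do_baseline = do_baseline,
                 baseline_before_averaging = baseline_before_averaging),
            class = "preprocess_config")
}

#' Run the full preprocessing chain on a replicate-level set
#'
#' Applies, in order: rubberband baseline correction (per replicate by
#' default), replicate averaging, normalization, region selection and the
#' Savitzky-Golay second derivative. The steps actually applied are recorded
#' in the `"provenance"` attribute of the result.
#'
#' @param set a `spectra_set`, typically with replicate rows.
#' @param config a [preprocess_config()].
#' @param average average replicates (default TRUE; set FALSE if `set` is
#'   already one row per sample).
#' @return The preprocessed `spectra_set` (one row per sample), with a
#'   `provenance` attribute listing the applied steps.
#' @export
preprocess_set <- function(set, config = preprocess_config(), average = TRUE) {
  stopifnot(inherits(set, "spectra_set"), inherits(config, "preprocess_config"))
  steps <- character(0)
  if (config$do_baseline && config$baseline_before_averaging) {
    set <- rubberband_correct(set); steps <- c(steps, "rubberband")
  }
  if (average) { set <- average_replicates(set); steps <- c(steps, "average_replicates") }
  if (config$do_baseline && !config$baseline_before_averaging) {
    set <- rubberband_correct(set); steps <- c(steps, "rubberband")
  }
  if (config$normalization != "none") {
    set <- normalize_set(set, config$normalization)
    steps <- c(steps, paste0("normalize:", config$normalization))
  }
  set <- select_region(set, config$region_lo, config$region_hi)
  steps <- c(steps, sprintf("region:%g-%g", config$region_lo, config$region_hi))
  set <- sg_second_derivative_set(set, config$sg_window, config$sg_polyorder)
  steps <- c(steps, sprintf("sg2:%d,%d", config$sg_window, config$sg_polyorder))
  attr(set, "provenance") <- list(steps = steps, config = unclass(config))
  set
}
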