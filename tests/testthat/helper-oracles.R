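# Independent oracles used to cross-check the implementation. These are
# deliberately naive (brute force / closed form) and share no code with R/.

# Lower convex envelope by exhaustive pair search: the envelope at x is the
# pointwise maximum of all chords that lie on or below every data point.
# O(n^3); for small n only.
oracle_lower_envelope <- function(x, y) {
  n <- length(x)
  env <- rep(-Inf, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sl <- (y[j] - y[i]) / (x[j] - x[i])
    line <- y[i] + sl * (x - x[i])
    if (all(line <= y + 1e-9)) env <- pmax(env, line)
  }
  env
}

# AUC as the Mann-Whitney pair-counting probability, ties counted one half.
oracle_auc_paircount <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Per-window Savitzky-Golay oracle: refit the window polynomial with lm and
# read off the analytic second derivative at the centre.
oracle_sg2 <- function(x, y, window, polyorder) {
  half <- (window - 1) %/% 2
  n <- length(x)
  idx <- (half + 1):(n - half)
  vapply(idx, function(i) {
    sel <- (i - half):(i + half)
    dx <- x[sel] - x[i]
    fit <- lm(y[sel] ~ poly(dx, degree = polyorder, raw = TRUE))
    2 * coef(fit)[[3]]
  }, 0)
}

# Independently coded leave-one-out loop: refit and predict fold by fold.
oracle_loocv_secv <- function(X, y, n_lv, n_osc) {
  n <- nrow(X)
  yhat <- vapply(seq_len(n), function(i) {
    fit <- osc_plsda(X[-i, , drop = FALSE], y[-i], n_lv = n_lv, n_osc = n_osc)
    predict(fit, X[i, , drop = FALSE], type = "response")
  }, 0)
  y_coded <- ifelse(y == "FM", 1, 2)
  list(secv = sqrt(mean((y_coded - yhat)^2)), yhat = yhat)
}

# Direct access to the confusion/rate arithmetic on given (y, yhat) pairs.
new_validation_report_for_test <- function(y, yhat) {
  sersdx:::new_validation_report("external", y, yhat,
                                 c(FM = 1, NONFM = 2), 1.5)
}

# Small labelled two-cloud matrix for model tests.
make_clouds <- function(n_per = 10, p = 5, sep = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  list(X = X, y = rep(c("FM", "NONFM"), each = n_per))
}

# Scaled-down synthetic run shared by several tests: generate, preprocess,
# split with the standard design, fit with screening off unless asked.
desk_cohort <- function(seed, effect_scale = 0.5, bands = default_band_table()) {
  cfg <- synthetic_config(seed = seed, effect_scale = effect_scale,
                          bands = bands)
  preprocess_set(generate_cohort(cfg))
}
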