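centered <- function(X) sweep(X, 2, colMeans(X))

test_that("OSC scores are exactly Y-orthogonal and X reconstructs", {
  set.seed(31)
  X <- centered(matrix(rnorm(20 * 8), 20, 8))
  y <- rep(c(1, 2), each = 10)
  fit <- osc_fit(X, y, 1)
  t1 <- fit$model$components[[1]]$t
  expect_lt(abs(cor(t1, y)), 1e-6)
  recon <- fit$X + tcrossprod(t1, fit$model$components[[1]]$p)
  expect_equal(recon, X, tolerance = 1e-10)
  # two components deflate sequentially and both stay orthogonal
  fit2 <- osc_fit(X, y, 2)
  for (cmp in fit2$model$components) expect_lt(abs(cor(cmp$t, y)), 1e-6)
  recon2 <- fit2$X
  for (cmp in rev(fit2$model$components))
    recon2 <- recon2 + tcrossprod(cmp$t, cmp$p)
  expect_equal(recon2, X, tolerance = 1e-10)
})

test_that("OSC with zero components is a no-op and rank limits error", {
  X <- centered(matrix(rnorm(12 * 4), 12, 4))
  y <- rep(c(1, 2), 6)
  expect_identical(osc_fit(X, y, 0)$X, X)
  lowrank <- centered(tcrossprod(rnorm(12), rnorm(4)))   # rank 1 centered
  expect_error(osc_fit(lowrank, y, 3), "rank")
  expect_error(osc_fit(X + 1, y, 1), "centered")
})

test_that("OSC recovers a planted Y-orthogonal high-variance direction", {
  set.seed(32)
  n <- 6; p <- 4
  y <- rep(c(1, 2), each = 3)
  yc <- y - mean(y)
  dir_y <- rnorm(p); dir_conf <- rnorm(p)
  dir_conf <- dir_conf - dir_y * sum(dir_conf * dir_y) / sum(dir_y^2)
  t_conf <- rnorm(n); t_conf <- t_conf - mean(t_conf)
  t_conf <- t_conf - yc * sum(t_conf * yc) / sum(yc^2)   # Y-orthogonal scores
  X <- tcrossprod(yc, dir_y) + 10 * tcrossprod(t_conf, dir_conf) +
    0.01 * matrix(rnorm(n * p), n, p)
  X <- centered(X)
  fit <- osc_fit(X, y, 1)
  w <- fit$model$components[[1]]$w
  cosine <- abs(sum(w * dir_conf)) / sqrt(sum(dir_conf^2))
  expect_gt(cosine, 0.99)
})

test_that("osc_apply reproduces the training deflation and is row-wise", {
  set.seed(33)
  X <- centered(matrix(rnorm(16 * 6), 16, 6))
  y <- rep(c(1, 2), 8)
  fit <- osc_fit(X, y, 1)
  expect_equal(osc_apply(fit$model, X), fit$X, tolerance = 1e-10)
  expect_equal(osc_apply(fit$model, matrix(0, 3, 6)), matrix(0, 3, 6))
  # a test row equal to a training row deflates identically
  expect_equal(drop(osc_apply(fit$model, X[4, , drop = FALSE])),
               fit$X[4, ], tolerance = 1e-12)
  expect_error(osc_apply(fit$model, matrix(0, 2, 5)), "dimension")
})

test_that("one-LV PLS regression vector is collinear with X'y", {
  set.seed(34)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- rep(c("FM", "NONFM"), each = 15)
  fit <- osc_plsda(X, y, n_lv = 1, n_osc = 0)
  v <- drop(crossprod(centered(X), ifelse(y == "FM", 1, 2)))
  b <- unname(coef(fit))
  cosine <- abs(sum(v * b)) / sqrt(sum(v^2) * sum(b^2))
  expect_gt(cosine, 1 - 1e-10)
})

test_that("duplicated X columns get identical regression coefficients", {
  set.seed(35)
  X <- matrix(rnorm(20 * 5), 20, 5)
  X <- cbind(X, X[, 2])
  fit <- osc_plsda(X, rep(c("FM", "NONFM"), 10), n_lv = 3, n_osc = 0)
  expect_equal(unname(coef(fit)[2]), unname(coef(fit)[6]), tolerance = 1e-10)
})

test_that("PLS scores are orthogonal with valid explained-variance fractions", {
  cl <- make_clouds(n_per = 15, p = 8, sep = 1, seed = 36)
  fit <- osc_plsda(cl$X, cl$y, n_lv = 5, n_osc = 1)
  G <- crossprod(fit$scores)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  expect_true(all(fit$explained_x >= 0 & fit$explained_x <= 1))
  expect_true(all(fit$explained_y >= 0 & fit$explained_y <= 1))
  expect_lte(sum(fit$explained_x), 1 + 1e-10)
})

test_that("well-separated clouds classify perfectly in training", {
  cl <- make_clouds(n_per = 10, p = 5, sep = 10, seed = 37)
  fit <- osc_plsda(cl$X, cl$y, n_lv = 2, n_osc = 1)
  expect_identical(predict(fit, cl$X, type = "class"), cl$y)
  both <- predict(fit, cl$X, type = "both")
  expect_named(both, c("y_continuous", "y_class"))
})

test_that("rank and degeneracy limits raise errors", {
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- rep(c("FM", "NONFM"), 4)
  expect_error(osc_plsda(X, y, n_lv = 5, n_osc = 0), "exceeds")
  expect_error(osc_plsda(X, rep("FM", 8), n_lv = 1), "one class")
})

test_that("a row at the training X-mean predicts the training Y-mean", {
  cl <- make_clouds(n_per = 12, p = 6, sep = 2, seed = 38)
  fit <- osc_plsda(cl$X, cl$y, n_lv = 3, n_osc = 1)
  mu <- matrix(colMeans(cl$X), 1)
  expect_equal(predict(fit, mu, type = "response"), mean(fit$y),
               tolerance = 1e-10)
})

test_that("predictions are invariant to global rescaling under vector norm", {
  raw <- generate_cohort(synthetic_config(n_fm = 12, n_nonfm = 12, n_nc = 0,
                                          seed = 39))
  scaled <- spectra_set(raw$grid, 3.7 * raw$X, raw$sample_id, raw$replicate,
                        raw$label)
  p1 <- preprocess_set(raw)
  p2 <- preprocess_set(scaled)
  fit1 <- osc_plsda(p1, n_lv = 3, n_osc = 1)
  fit2 <- osc_plsda(p2, n_lv = 3, n_osc = 1)
  expect_equal(predict(fit1, p1, type = "response"),
               predict(fit2, p2, type = "response"), tolerance = 1e-8)
})

test_that("grid mismatches are refused at prediction time", {
  co <- preprocess_set(generate_cohort(synthetic_config(
    n_fm = 6, n_nonfm = 6, n_nc = 0, seed = 40)))
  fit <- osc_plsda(co, n_lv = 2)
  off <- spectra_set(co$grid + 2, co$X, co$sample_id, co$replicate, co$label)
  expect_error(predict(fit, off), "grid")
  expect_error(predict(fit, co$X[, -1]), "variables")
})

test_that("regression-vector report ranks planted bands and annotates them", {
  bands <- default_band_table()
  bands$class_effect <- ifelse(bands$position %in% c(991, 1222, 1582), 1, 0)
  pre <- desk_cohort(seed = 41, effect_scale = 0.5, bands = bands)
  # band attribution reads the OSC-filtered predictive component (n_lv = 1):
  # its regression vector is the class-covariance direction
  model <- osc_plsda(pre[pre$label != "NC"], n_lv = 1, n_osc = 1)
  rep5 <- regression_vector_report(model, top_k = 5)
  for (b in c(991, 1222, 1582))
    expect_true(any(abs(rep5$wavenumber - b) <= 12),
                label = sprintf("band %d in top-5", b))
})

test_that("report annotation picks the discriminant-table entry within tolerance", {
  wn <- seq(1200, 1248, 2)
  b <- exp(-(wn - 1224)^2 / 18)             # single extremum at 1224
  fake <- structure(list(coefficients = stats::setNames(b, wn),
                         wavenumber = wn), class = "osc_plsda")
  rep1 <- regression_vector_report(fake, top_k = 3, tol = 8)
  expect_equal(rep1$band[1], 1222)
  expect_equal(rep1$mode[1], "C-H stretching")
  expect_equal(rep1$assignment[1], "Phe and Tyr")
  # flat vector: no extrema
  flat <- structure(list(coefficients = stats::setNames(rep(1, 25), wn),
                         wavenumber = wn), class = "osc_plsda")
  expect_equal(nrow(regression_vector_report(flat)), 0L)
})

test_that("model JSON serialization writes the full parameter set", {
  cl <- make_clouds(n_per = 8, p = 4, sep = 3, seed = 42)
  fit <- osc_plsda(cl$X, cl$y, n_lv = 2, n_osc = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, f)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(doc$n_lv, 2)
  expect_equal(doc$coefficients, unname(coef(fit)), tolerance = 1e-12)
  expect_equal(doc$osc$w[[1]], fit$osc$components[[1]]$w, tolerance = 1e-12)
})

test_that("removing one OSC component does not hurt cross-validated error on average", {
  # Y-correlated structure plus a strong Y-orthogonal confounder: the OSC
  # filter should, averaged over seeds, leave SECV no worse than without it
  se0 <- se1 <- numeric(8)
  for (seed in 1:8) {
    set.seed(200 + seed)
    n <- 16; p <- 12
    y <- rep(c("FM", "NONFM"), each = n / 2)
    yc <- ifelse(y == "FM", 1, 2); yc <- yc - mean(yc)
    conf_t <- rnorm(n); conf_t <- conf_t - mean(conf_t)
    conf_t <- conf_t - yc * sum(conf_t * yc) / sum(yc^2)
    X <- tcrossprod(yc, rnorm(p)) + 6 * tcrossprod(conf_t, rnorm(p)) +
      0.3 * matrix(rnorm(n * p), n, p)
    se0[seed] <- loocv(X, y, n_lv = 1, n_osc = 0)$se
    se1[seed] <- loocv(X, y, n_lv = 1, n_osc = 1)$se
  }
  expect_lte(mean(se1), mean(se0) + 0.01)
})

test_that("the NIPALS regression vector matches an independent PLS implementation", {
  cl <- make_clouds(n_per = 12, p = 9, sep = 1.5, seed = 43)
  colnames(cl$X) <- paste0("V", seq_len(ncol(cl$X)))
  ycode <- ifelse(cl$y == "FM", 1, 2)
  fit <- osc_plsda(cl$X, cl$y, n_lv = 4, n_osc = 0)
  ref <- suppressMessages(mixOmics::pls(cl$X, ycode, ncomp = 4,
                                        mode = "regression", scale = FALSE))
  bref <- predict(ref, cl$X)$B.hat[, 1, 4]
  b <- unname(coef(fit))
  expect_equal(b / sqrt(sum(b^2)), unname(bref / sqrt(sum(bref^2))),
               tolerance = 1e-8)
})
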