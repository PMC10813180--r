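test_that("ROC handles separation, ties and the worked pair-count example", {
  r <- roc_auc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1.0)
  expect_false(r$flipped)
  expect_equal(roc_auc(rep(0.3, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  # scores (0.1, 0.4 | 0.35, 0.8): pairs (0.35,0.1)+, (0.35,0.4)-, (0.8,*)+
  ex <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(ex$auc, 0.75)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoid ROC integration equals Mann-Whitney pair counting", {
  set.seed(51)
  for (rep in 1:200) {
    n <- sample(4:20, 1)
    lab <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    sc <- sample(round(runif(n, 0, 1), sample(1:3, 1)))  # induces ties
    o <- oracle_auc_paircount(sc, lab)
    # pair counting under the auto-orientation: flipping scores gives 1 - o
    expect_equal(roc_auc(sc, lab)$auc, max(o, 1 - o), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random instances", {
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    lab <- c(TRUE, FALSE, runif(n - 2) > 0.4)
    sc <- round(rnorm(n), 2)
    ours <- roc_auc(sc, lab)
    ref <- suppressMessages(pROC::auc(pROC::roc(lab, sc, direction = "<",
                                                quiet = TRUE)))
    expect_equal(ours$auc, max(as.numeric(ref), 1 - as.numeric(ref)),
                 tolerance = 1e-12)
  }
})

test_that("orientation auto-flip is recorded", {
  r <- roc_auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE) == FALSE)
  expect_true(r$flipped)
  expect_equal(r$auc, 1.0)
})

test_that("LOOCV matches the independently coded fold loop on small toys", {
  set.seed(53)
  for (rep in 1:3) {
    n <- sample(c(8, 10), 1)
    X <- matrix(rnorm(n * 4), n, 4)
    y <- rep(c("FM", "NONFM"), n / 2)
    got <- loocv(X, y, n_lv = 2, n_osc = 0)
    want <- oracle_loocv_secv(X, y, n_lv = 2, n_osc = 0)
    expect_equal(got$se, want$secv, tolerance = 1e-10)
    expect_equal(got$y_pred, want$yhat, tolerance = 1e-10)
  }
  # with the OSC step in the folds too
  X <- matrix(rnorm(10 * 6), 10, 6)
  y <- rep(c("FM", "NONFM"), 5)
  expect_equal(loocv(X, y, n_lv = 2, n_osc = 1)$se,
               oracle_loocv_secv(X, y, 2, 1)$secv, tolerance = 1e-10)
})

test_that("LOOCV refuses folds that lose a class", {
  X <- matrix(rnorm(4 * 3), 4, 3)
  expect_error(loocv(X, c("FM", "NONFM", "NONFM", "NONFM"), n_lv = 1),
               "loses one class")
})

test_that("a perfectly separable cohort cross-validates at 100/100/100", {
  cl <- make_clouds(n_per = 8, p = 6, sep = 10, seed = 54)
  r <- loocv(cl$X, cl$y, n_lv = 2, n_osc = 1)
  expect_equal(r$accuracy, 100)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$auc, 1.0)
  expect_gte(r$se, 0)
})

test_that("external validation computes SEP, rates and checks ID overlap", {
  cl <- make_clouds(n_per = 10, p = 5, sep = 6, seed = 55)
  fit <- osc_plsda(cl$X, cl$y, n_lv = 2, n_osc = 1)
  # test = training set: SEP equals the training RMSE
  r <- external_validate(fit, cl$X, cl$y)
  expect_equal(r$se, sqrt(mean((fit$y - fit$fitted)^2)), tolerance = 1e-12)
  expect_equal(sum(r$confusion), 20)
  # ID overlap is refused when both sides carry IDs
  g <- seq(600, 640, 2)
  tr <- spectra_set(g, matrix(rnorm(6 * 21), 6), sample_id = sprintf("S%d", 1:6),
                    label = rep(c("FM", "NONFM"), 3))
  fit2 <- osc_plsda(tr, n_lv = 1, n_osc = 0)
  expect_error(external_validate(fit2, tr), "overlaps")
})

test_that("confusion arithmetic reproduces the worked rate examples", {
  # TP=15, FN=0, FP=0, TN=13 -> 100/100/100
  y <- c(rep(1, 15), rep(2, 13))
  yhat <- c(rep(1.1, 15), rep(1.9, 13))
  fit <- structure(list(class_codes = c(FM = 1, NONFM = 2), threshold = 1.5,
                        x_means = numeric(2), y_mean = 1.5,
                        osc = structure(list(components = list()), class = "osc_model"),
                        coefficients = numeric(2), sample_id = NULL, grid = NULL),
                   class = "osc_plsda")
  r <- new_validation_report_for_test(y, yhat)
  expect_equal(unname(r$confusion), c(15, 0, 0, 13))
  expect_equal(r$accuracy, 100)
  # TP=14, FN=1, FP=0, TN=13 -> sens 93.33, spec 100, acc 96.43
  yhat2 <- yhat; yhat2[1] <- 1.9
  r2 <- new_validation_report_for_test(y, yhat2)
  expect_equal(unname(r2$confusion), c(14, 1, 0, 13))
  expect_equal(r2$sensitivity, 93.33, tolerance = 1e-3)
  expect_equal(r2$specificity, 100)
  expect_equal(r2$accuracy, 96.43, tolerance = 1e-3)
})

test_that("sensitivity and specificity swap under class exchange", {
  set.seed(56)
  X <- matrix(rnorm(24 * 6), 24, 6)
  X[1:12, 1] <- X[1:12, 1] + 1.2
  y <- rep(c("FM", "NONFM"), each = 12)
  y_sw <- rep(c("NONFM", "FM"), each = 12)
  r1 <- loocv(X, y, n_lv = 2, n_osc = 0)
  r2 <- loocv(X, y_sw, n_lv = 2, n_osc = 0)
  expect_equal(r1$sensitivity, r2$specificity, tolerance = 1e-10)
  expect_equal(r1$specificity, r2$sensitivity, tolerance = 1e-10)
  expect_equal(r1$accuracy, r2$accuracy, tolerance = 1e-10)
})

test_that("duplicated samples share leverages; a spike sample is flagged", {
  set.seed(57)
  X <- matrix(rnorm(12 * 8), 12, 8)
  X[11, ] <- X[3, ]; X[12, ] <- X[3, ]
  y <- rep(c("FM", "NONFM"), 6)
  y[c(3, 11, 12)] <- "FM"
  fit <- osc_plsda(X, y, n_lv = 2, n_osc = 0)
  fl <- detect_outliers(fit)
  expect_equal(fl$leverage[3], fl$leverage[11], tolerance = 1e-10)
  expect_equal(fl$leverage[3], fl$leverage[12], tolerance = 1e-10)
  expect_true(all(fl$leverage > 0 & fl$leverage <= 1 + 1e-12))

  # a 20-sigma spike artifact across the discriminant band carries the
  # maximum (externally studentized) residual and exceeds the residual cut;
  # its leverage stays bounded because vector normalization keeps every
  # sample near the unit sphere, so it is a residual outlier, not a
  # leverage point
  pre <- desk_cohort(seed = 58)
  cal <- split_dataset(pre, seed = 58)$calibration
  spike_row <- 17L
  win <- which(abs(cal$grid - 1222) <= 8)
  cal$X[spike_row, win] <- cal$X[spike_row, win] +
    20 * apply(cal$X[, win, drop = FALSE], 2, stats::sd)
  fit2 <- osc_plsda(cal, n_lv = 7, n_osc = 1)
  fl2 <- detect_outliers(fit2)
  expect_equal(which.max(abs(fl2$studentized_residual)), spike_row)
  expect_gt(abs(fl2$studentized_residual[spike_row]), fl2$resid_cut)
  # the calibration-residual variant misses it: the model absorbs the spike
  fl3 <- detect_outliers(fit2, residuals = "calibration")
  expect_lt(abs(fl3$studentized_residual[spike_row]), fl2$resid_cut)
})

test_that("flag removal is capped and ordered by residual magnitude", {
  pre <- desk_cohort(seed = 59)
  cal <- pre[pre$label != "NC"]
  fit <- osc_plsda(cal, n_lv = 7, n_osc = 1)
  fl <- detect_outliers(fit)
  fl$flagged <- rep(TRUE, length(fl$flagged))      # force many flags
  out <- remove_flagged(cal, fl, max_frac = 0.03)
  cap <- floor(0.03 * n_spectra(cal))
  expect_equal(n_spectra(cal) - n_spectra(out), cap)
  worst <- cal$sample_id[order(abs(fl$studentized_residual),
                               decreasing = TRUE)][seq_len(cap)]
  expect_setequal(attr(out, "removed"), worst)
})

test_that("report JSON serialization round-trips the headline metrics", {
  cl <- make_clouds(n_per = 8, p = 5, sep = 6, seed = 60)
  r <- loocv(cl$X, cl$y, n_lv = 2, n_osc = 0)
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(r, f)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(doc$se, r$se, tolerance = 1e-12)
  expect_equal(doc$accuracy, r$accuracy)
  expect_equal(doc$confusion$TP + doc$confusion$FN +
               doc$confusion$FP + doc$confusion$TN, r$n)
})

test_that("the SECV profile of nested models matches one-size-at-a-time LOOCV", {
  set.seed(61)
  X <- matrix(rnorm(14 * 8), 14, 8)
  X[1:7, 2] <- X[1:7, 2] + 1.5
  y <- rep(c("FM", "NONFM"), each = 7)
  prof <- select_n_lv(X, y, n_lv_max = 3, n_osc = 1)
  for (k in 1:3)
    expect_equal(prof$secv[k], loocv(X, y, n_lv = k, n_osc = 1)$se,
                 tolerance = 1e-10)
  expect_true(prof$best %in% 1:3)
})
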