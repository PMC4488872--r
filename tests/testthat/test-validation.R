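test_that("the factor cap is one tenth of the sample count with floor one", {
  expect_equal(max_factors(39), 3L)
  expect_equal(max_factors(24), 2L)
  expect_equal(max_factors(5), 1L)
  expect_equal(max_factors(10), 1L)
  expect_equal(max_factors(40), 4L)
})

test_that("LOO predicts each sample exactly once per factor count", {
  s <- random_spectra(12, 20, seed = 3)
  y <- rnorm(12)
  cv <- loo_crossvalidate("plsr", s$absorbance, y, 2)
  expect_equal(dim(cv$predictions), c(12, 2))
  expect_false(anyNA(cv$predictions))
  expect_equal(cv$n_folds, 12)
})

test_that("a noise-free rank-1 calibration cross-validates to ~zero SECV", {
  set.seed(17)
  shape <- rnorm(30)
  y <- runif(12)
  X <- 0.2 + outer(y, shape)
  cv <- loo_crossvalidate("plsr", X, y, 1)
  expect_lt(cv$per_factor_secv[1], 1e-8)
})

test_that("integrated LOO equals an independent brute-force refit loop", {
  set.seed(20)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- rnorm(20)
  for (kind in c("plsr", "pcr")) {
    cv <- loo_crossvalidate(kind, X, y, 2)
    expect_equal(cv$per_factor_secv, brute_force_loo_secv(kind, X, y, 2),
                 tolerance = 1e-10)
  }
  cv_osc <- loo_crossvalidate("plsr", X, y, 2,
                              pretreatment = list(osc_components = 1))
  expect_equal(cv_osc$per_factor_secv,
               brute_force_loo_secv("plsr", X, y, 2, osc_components = 1),
               tolerance = 1e-10)
})

test_that("group hold-out reduces to LOO and pools batch structure", {
  set.seed(27)
  X <- matrix(rnorm(14 * 25), 14, 25)
  y <- rnorm(14)
  loo <- loo_crossvalidate("plsr", X, y, 1)
  as_groups <- group_holdout_validate("plsr", X, y, groups = paste0("g", 1:14),
                                      k = 1)
  expect_equal(as_groups$predictions, loo$predictions, tolerance = 1e-12)
  two <- group_holdout_validate("plsr", X, y,
                                groups = rep(c("a", "b"), each = 7), k = 1)
  expect_equal(two$n_folds, 2)
  expect_error(group_holdout_validate("plsr", X, y, groups = rep("a", 14), k = 1),
               class = "aquaphot_parameter_error")

  # batch-confounded responses: leaving whole batches out is harder than LOO
  batch <- rep(c("b1", "b2", "b3"), c(5, 5, 4))
  yb <- y + 3 * as.numeric(factor(batch))
  Xb <- X + outer(as.numeric(factor(batch)), rnorm(25))
  secv_group <- min(group_holdout_validate("plsr", Xb, yb, batch, 1)$per_factor_secv)
  secv_loo <- min(loo_crossvalidate("plsr", Xb, yb, 1)$per_factor_secv)
  expect_gte(secv_group, secv_loo)
})

test_that("calibration metrics follow their defining formulas", {
  y <- c(1, 2, 3, 4)
  fit <- y + c(1, -1, 1, -1)
  res <- calibration_metrics(y, fit, fit, k = 1)
  expect_equal(res$sec, sqrt(4 / 2))
  expect_equal(res$secv, 1)
  perfect <- calibration_metrics(y, y, y, k = 1)
  expect_equal(perfect$r_cal, 1)
  expect_equal(perfect$sec, 0)
  expect_error(calibration_metrics(rep(2, 4), y, y, k = 1),
               class = "aquaphot_degenerate_error")
  expect_error(calibration_metrics(y, fit, fit, k = 3),
               class = "aquaphot_parameter_error")
})

test_that("metrics are invariant to sample permutation", {
  set.seed(40)
  y <- rnorm(15); cal <- y + rnorm(15, sd = 0.2); cv <- y + rnorm(15, sd = 0.4)
  perm <- sample(15)
  a <- calibration_metrics(y, cal, cv, 2)
  b <- calibration_metrics(y[perm], cal[perm], cv[perm], 2)
  expect_equal(a$r_cal, b$r_cal)
  expect_equal(a$sec, b$sec)
  expect_equal(a$secv, b$secv)
})

test_that("SEC does not exceed SECV on average over replicates", {
  diffs <- vapply(1:50, function(seed) {
    set.seed(seed)
    shape <- rnorm(30)
    y <- runif(15)
    X <- outer(y, shape) + matrix(rnorm(15 * 30, sd = 0.3), 15, 30)
    cv <- loo_crossvalidate("plsr", X, y, 1)
    cen <- fit_centering(X, y)
    ac <- apply_centering(cen, X, y)
    model <- fit_plsr(ac$X, ac$y, 1, centering = cen)
    met <- calibration_metrics(y, predict_regression(model, X),
                               cv$predictions[, 1], 1)
    met$secv - met$sec
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("factor selection takes the SECV argmin with ties to fewer factors", {
  expect_equal(select_factors(c(3, 1, 2)), 2L)
  expect_equal(select_factors(c(1, 1, 1)), 1L)
  expect_equal(select_factors(c(5, 4, 3)), 3L)
  expect_equal(select_factors(c(5, 4, 3), k_max = 2), 2L)
})

test_that("classification summaries score strictly", {
  truth <- rep(c("a", "b"), each = 8)
  pred <- truth
  pred[c(1, 9)] <- c("b", NA)
  attr(pred, "classes") <- c("a", "b")
  summ <- misclassification_summary(truth, pred)
  expect_equal(summ$ratio_correct, 14 / 16)
  expect_equal(summ$n_unassigned, 1)
  all_na <- rep(NA_character_, 16)
  expect_equal(misclassification_summary(truth, all_na)$ratio_correct, 0)
  expect_equal(misclassification_summary(truth, truth)$ratio_correct, 1)
  bad <- truth; bad[1] <- "zz"
  expect_error(misclassification_summary(bad, pred),
               class = "aquaphot_label_error")
})
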