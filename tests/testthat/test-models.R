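test_that("PCA recovers rank-1 structure and matches an SVD oracle", {
  set.seed(12)
  t1 <- rnorm(10); p1 <- rnorm(6)
  X <- outer(t1, p1)
  Xc <- sweep(X, 2, colMeans(X))
  pca <- fit_pca(Xc, 1)
  expect_equal(pca$explained_variance[1], 1, tolerance = 1e-10)

  Xc2 <- scale(matrix(rnorm(20 * 50), 20, 50), scale = FALSE)
  pca2 <- fit_pca(Xc2, 4)
  sv <- svd(Xc2)
  for (j in 1:4) {
    v <- sv$v[, j]
    sgn <- sign(v[which.max(abs(v))])
    expect_equal(pca2$x_loadings[, j], sgn * v, tolerance = 1e-8)
    expect_equal(pca2$scores[, j], sgn * sv$u[, j] * sv$d[j], tolerance = 1e-8)
    expect_gt(pca2$x_loadings[which.max(abs(pca2$x_loadings[, j])), j], 0)
  }
  G <- crossprod(pca2$x_loadings)
  expect_equal(G, diag(4), tolerance = 1e-8)
  expect_true(all(diff(pca2$explained_variance) <= 1e-12))
  expect_error(fit_pca(Xc2, 25), class = "aquaphot_parameter_error")
})

test_that("one-factor PLS1 equals the closed form b proportional to X'y", {
  set.seed(4)
  Xc <- scale(matrix(rnorm(12 * 30), 12, 30), scale = FALSE)
  yc <- rnorm(12); yc <- yc - mean(yc)
  model <- fit_plsr(Xc, yc, 1)
  b_closed <- crossprod(Xc, yc)
  b_closed <- b_closed * (sum(model$regression_vector * b_closed) / sum(b_closed^2))
  expect_equal(model$regression_vector, as.numeric(b_closed), tolerance = 1e-10)
})

test_that("PLSR and PCR at full rank reproduce least-squares predictions", {
  set.seed(15)
  X <- matrix(rnorm(15 * 8), 15, 8)
  y <- rnorm(15)
  cen <- fit_centering(X, y)
  ac <- apply_centering(cen, X, y)
  k <- qr(ac$X)$rank
  oracle <- ols_oracle_predict(ac$X, ac$y, ac$X) + cen$y_mean
  plsr <- fit_plsr(ac$X, ac$y, k, centering = cen)
  pcr <- fit_pcr(ac$X, ac$y, k, centering = cen)
  expect_equal(predict_regression(plsr, X), oracle, tolerance = 1e-6)
  expect_equal(predict_regression(pcr, X), oracle, tolerance = 1e-6)
})

test_that("an exact single-direction calibration has zero residuals", {
  set.seed(9)
  t1 <- rnorm(10); p1 <- rnorm(20)
  X <- outer(t1, p1)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- 2 * (t1 - mean(t1)) * sqrt(sum(p1^2))
  model <- fit_plsr(Xc, yc, 1)
  expect_lt(sum((yc - as.numeric(Xc %*% model$regression_vector))^2), 1e-12)
  # PCR and PLSR coincide when X has a single nonzero singular value
  pcr <- fit_pcr(Xc, yc, 1)
  expect_equal(as.numeric(Xc %*% pcr$regression_vector),
               as.numeric(Xc %*% model$regression_vector), tolerance = 1e-8)
})

test_that("PCR shrinks to the mean when y is orthogonal to the scores", {
  set.seed(21)
  U <- qr.Q(qr(matrix(rnorm(12 * 12), 12)))
  D <- c(10, 5, rep(1e-8, 10))
  V <- qr.Q(qr(matrix(rnorm(30 * 12), 30)))
  Xc <- U %*% diag(D) %*% t(V)
  Xc <- sweep(Xc, 2, colMeans(Xc))
  pca <- fit_pca(Xc, 2)
  yc <- rnorm(12)
  yc <- residuals(lm(yc ~ pca$scores))      # orthogonal to the top-2 scores
  yc <- yc - mean(yc)
  pcr <- fit_pcr(Xc, yc, 2)
  expect_lt(sqrt(sum(pcr$regression_vector^2)), 1e-6)
  expect_lt(max(abs(as.numeric(Xc %*% pcr$regression_vector))), 1e-6)
})

test_that("prediction replays centering and OSC and is exact when noise-free", {
  sc <- confounded_scene(5)
  cen <- fit_centering(sc$X, sc$y)
  ac <- apply_centering(cen, sc$X, sc$y)
  osc <- fit_osc(ac$X, ac$y, 1)
  Xo <- apply_osc(osc, ac$X)
  model <- fit_plsr(Xo, ac$y, 2, centering = cen, osc = osc)
  stored_fit <- as.numeric(Xo %*% model$regression_vector) + cen$y_mean
  expect_equal(predict_regression(model, sc$X), stored_fit, tolerance = 1e-10)
  mean_row <- matrix(colMeans(sc$X), 1)
  expect_equal(predict_regression(model, mean_row), cen$y_mean,
               tolerance = 1e-8)

  set.seed(77)        # noise-free linear simulation: near-perfect recovery
  shape <- exp(-0.5 * ((seq(1300, by = 0.5, length.out = 150) - 1340) / 5)^2)
  y2 <- runif(25)
  X2 <- 0.4 + outer(y2, shape)
  cen2 <- fit_centering(X2, y2)
  ac2 <- apply_centering(cen2, X2, y2)
  m2 <- fit_plsr(ac2$X, ac2$y, 1, centering = cen2)
  expect_gt(cor(predict_regression(m2, X2), y2), 0.999999)
  expect_error(predict_regression(m2, X2[, 1:10]),
               class = "aquaphot_shape_error")
})

test_that("PLS-DA codes two classes and classifies around the 0.5 threshold", {
  set.seed(30)
  m <- 40
  shape <- rnorm(m)
  n_per <- 10
  X <- rbind(matrix(rnorm(n_per * m, sd = 0.05), n_per, m),
             outer(rep(1, n_per), shape) + matrix(rnorm(n_per * m, sd = 0.05),
                                                  n_per, m))
  labels <- rep(c("ctrl", "treated"), each = n_per)
  y_dummy <- as.numeric(factor(labels)) - 1
  expect_equal(mean(y_dummy), 0.5)       # balanced coding centers at +/- 0.5
  cen <- fit_centering(X)
  Xc <- apply_centering(cen, X)
  model <- fit_plsda(Xc, labels, 1)
  expect_equal(model$classes, c("ctrl", "treated"))
  pred <- classify_plsda(model, Xc)
  expect_equal(pred, labels)
  dup <- Xc[n_per + 1, , drop = FALSE]   # duplicate of a treated sample
  expect_equal(classify_plsda(model, dup), "treated")
  expect_error(fit_plsda(Xc, rep(c("a", "b", "c"), length.out = 2 * n_per), 1),
               class = "aquaphot_parameter_error")
  expect_error(fit_plsda(Xc, rep("a", 2 * n_per), 1),
               class = "aquaphot_degenerate_error")
})

test_that("well-separated classes give zero cross-validated misclassifications", {
  set.seed(55)
  m <- 30; n_per <- 12
  mu <- rnorm(m)
  X <- rbind(matrix(rnorm(n_per * m, sd = 0.1), n_per, m),
             outer(rep(1, n_per), mu) + matrix(rnorm(n_per * m, sd = 0.1),
                                               n_per, m))
  labels <- rep(c("a", "b"), each = n_per)
  cv <- loo_crossvalidate("plsda", X, labels, 1)
  pred <- ifelse(cv$predictions[, 1] > 0.5, cv$classes[2], cv$classes[1])
  expect_equal(mean(pred == labels), 1)
})

test_that("PLSR residual norm is non-increasing in the factor count", {
  set.seed(61)
  Xc <- scale(matrix(rnorm(20 * 40), 20, 40), scale = FALSE)
  yc <- rnorm(20); yc <- yc - mean(yc)
  model <- fit_plsr(Xc, yc, 5)
  rss <- vapply(1:5, function(k)
    sum((yc - as.numeric(Xc %*% model$coef_per_factor[, k]))^2), numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("models serialize to JSON and predict identically after reload", {
  sc <- confounded_scene(8)
  cen <- fit_centering(sc$X, sc$y)
  ac <- apply_centering(cen, sc$X, sc$y)
  osc <- fit_osc(ac$X, ac$y, 1)
  model <- fit_plsr(apply_osc(osc, ac$X), ac$y, 2, centering = cen, osc = osc)
  path <- withr::local_tempfile(fileext = ".json")
  serialize_latent_model(model, path)
  back <- read_latent_model(path)
  expect_equal(predict_regression(back, sc$X),
               predict_regression(model, sc$X), tolerance = 1e-12)
})
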