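# Independent oracles used to check the package's own implementations.
# These deliberately avoid the package's code paths.

# random spectra-like set on a regular grid
random_spectra <- function(n, m, seed, lo = 1300, step = 0.5) {
  set.seed(seed)
  wl <- lo + step * (seq_len(m) - 1)
  spectra_set(matrix(rnorm(n * m), n, m), wl,
              data.frame(sample_id = sprintf("R%02d", seq_len(n))))
}

# Moore-Penrose least-squares predictions, via base svd only
ols_oracle_predict <- function(Xc, yc, X_new_c) {
  sv <- svd(Xc)
  keep <- sv$d > sv$d[1] * 1e-12
  beta <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], yc) / sv$d[keep])
  as.numeric(X_new_c %*% beta)
}

# windowed mean with symmetric reflection padding, written index by index
boxcar_oracle <- function(x, window) {
  h <- (window - 1) / 2
  m <- length(x)
  out <- numeric(m)
  at <- function(i) {            # reflect about the end points
    if (i < 1) return(x[2 - i])
    if (i > m) return(x[2 * m - i])
    x[i]
  }
  for (i in seq_len(m)) {
    acc <- 0
    for (j in (i - h):(i + h)) acc <- acc + at(j)
    out[i] <- acc / window
  }
  out
}

# brute-force leave-one-out SECV: an explicit refit loop over folds using
# the public single-model functions, independent of the integrated CV engine
brute_force_loo_secv <- function(kind, X, y, k_max, osc_components = 0) {
  n <- nrow(X)
  preds <- matrix(NA_real_, n, k_max)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    cen <- fit_centering(Xtr, ytr)
    ac <- apply_centering(cen, Xtr, ytr)
    Xc <- ac$X; yc <- ac$y
    osc <- NULL
    if (osc_components > 0) {
      osc <- fit_osc(Xc, yc, osc_components)
      Xc <- apply_osc(osc, Xc)
    }
    for (k in seq_len(k_max)) {
      model <- if (kind == "plsr") fit_plsr(Xc, yc, k, centering = cen, osc = osc)
               else fit_pcr(Xc, yc, k, centering = cen, osc = osc)
      preds[i, k] <- predict_regression(model, X[i, , drop = FALSE])
    }
  }
  sqrt(colSums((y - preds)^2) / n)
}

# small confounded calibration scene shared by OSC tests: band-shaped
# response signal plus an independent confounder component and noise
confounded_scene <- function(seed, n = 30, m = 120, conf_scale = 5) {
  set.seed(seed)
  wl <- seq(1300, by = 0.5, length.out = m)
  sig_shape <- exp(-0.5 * ((wl - 1330) / 4)^2)
  conf_shape <- exp(-0.5 * ((wl - 1350) / 6)^2)
  y <- runif(n, 0, 1)
  d <- rnorm(n)
  X <- outer(y, sig_shape) + conf_scale * outer(d, conf_shape) +
    matrix(rnorm(n * m, sd = 0.01), n, m)
  list(X = X, y = y, wl = wl, conf_shape = conf_shape, d = d)
}
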