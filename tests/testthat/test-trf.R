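# TRF estimation: lagged designs against a double-loop oracle, ridge
# solutions against the closed-form normal equations, kernel recovery,
# decoder behavior, leave-one-out folds, and the window statistics.

test_that("lag matrix equals the explicit double-loop construction", {
  set.seed(51)
  x <- matrix(rnorm(40), 20, 2)
  lags_ms <- c(0, 10, 20)
  fs <- 100
  got <- lag_matrix(x, lags_ms, fs)
  oracle <- matrix(0, 20, 6)
  col <- 0
  for (f in 1:2) for (l in c(0, 1, 2)) {
    col <- col + 1
    for (t in 1:20) if (t - l >= 1) oracle[t, col] <- x[t - l, f]
  }
  expect_equal(got, oracle)

  # single zero lag is the identity copy; impulses shift per column
  expect_equal(lag_matrix(x[, 1], 0, fs), x[, 1, drop = FALSE])
  imp <- c(1, numeric(9))
  li <- lag_matrix(imp, c(0, 10, 20), fs)
  expect_equal(which(li[, 1] != 0), 1L)
  expect_equal(which(li[, 2] != 0), 2L)
  expect_equal(which(li[, 3] != 0), 3L)
  # future direction shifts the other way
  lf <- lag_matrix(imp, c(0, 10), fs, direction = "future")
  expect_equal(lf[, 2], c(numeric(10))) # impulse at t=1 has no future copy
  expect_error(lag_matrix(imp, 150, fs), "smaller than the series")
  expect_error(lag_matrix(imp, -10, fs), "nonnegative")
  expect_error(lag_matrix(imp, 3.3, fs), "integer multiples")
})

test_that("encoder ridge solution equals the normal-equations oracle", {
  set.seed(52)
  fs <- 50
  env <- rnorm(50)
  y <- rnorm(50)
  lags_ms <- seq(0, 80, by = 20)
  for (ridge in c(0, 3)) {
    enc <- fit_encoder(env, rbind(y), lags_ms = lags_ms, ridge = ridge, fs = fs)
    X <- lag_matrix(env, lags_ms, fs)
    Xc <- scale(X, scale = FALSE)
    yc <- y - mean(y)
    oracle <- solve(crossprod(Xc) + ridge * diag(ncol(X)), crossprod(Xc, yc))
    expect_equal(as.numeric(enc$weights), as.numeric(oracle), tolerance = 1e-10)
  }
  # shrinkage limit
  enc_inf <- fit_encoder(env, rbind(y), lags_ms = lags_ms, ridge = 1e12, fs = fs)
  expect_lt(max(abs(enc_inf$weights)), 1e-6)
  expect_error(fit_encoder(rep(1, 50), rbind(y), lags_ms = lags_ms, fs = fs),
               "zero-variance")
})

test_that("noiseless known-kernel responses are recovered nearly exactly", {
  fs <- 250
  lags_ms <- seq(0, 400, by = 4)
  env <- make_envelope(20, fs, seed = 53)
  k_true <- exp(-(lags_ms - 120)^2 / 5000) * sin(2 * pi * 5 * lags_ms / 1000)
  y <- as.numeric(lag_matrix(env$values, lags_ms, fs) %*% k_true)
  enc <- fit_encoder(env, rbind(y), lags_ms = lags_ms, ridge = 1e-8)
  expect_gte(cor(as.numeric(enc$weights), k_true), 0.99)
})

test_that("decoder matches its oracle, and reconstructs identity channels", {
  set.seed(54)
  fs <- 50
  roi <- matrix(rnorm(120), 3, 40) # 3 ROIs x 40 samples
  env <- rnorm(40)
  lags_ms <- c(0, 20, 40)
  dec <- fit_decoder(roi, env, lags_ms = lags_ms, ridge = 2, fs = fs)
  X <- lag_matrix(t(roi), lags_ms, fs, direction = "future")
  Xc <- scale(X, scale = FALSE)
  oracle <- solve(crossprod(Xc) + 2 * diag(ncol(X)),
                  crossprod(Xc, env - mean(env)))
  expect_equal(as.numeric(t(dec$weights)), as.numeric(oracle), tolerance = 1e-10)

  # a single ROI equal to the envelope with lag grid {0} reconstructs r = 1
  dec1 <- fit_decoder(rbind(env), env, lags_ms = 0, ridge = 0, fs = fs)
  expect_equal(cor(predict_decoder(dec1, rbind(env)), env), 1, tolerance = 1e-10)

  # nested-model property: the all-ROI OLS decoder fits training data at
  # least as well as any single-ROI decoder
  mse <- function(d, r) mean((predict_decoder(d, r) - env)^2)
  full <- fit_decoder(roi, env, lags_ms = lags_ms, ridge = 0, fs = fs)
  for (r in 1:3) {
    single <- fit_decoder(roi[r, , drop = FALSE], env, lags_ms = lags_ms,
                          ridge = 0, fs = fs)
    expect_lte(mse(full, roi), mse(single, roi[r, , drop = FALSE]) + 1e-10)
  }
})

test_that("leave-one-out decoding: fold structure, copies, and the null", {
  fs <- 250
  # exact copies of one high-SNR trial -> no generalization gap
  env <- make_envelope(4, fs, seed = 55)
  kern <- exp(-(seq(0, 200, by = 4) - 80)^2 / 2000)
  y <- as.numeric(lag_matrix(env$values, seq(0, 200, by = 4), fs) %*% kern)
  roi <- rbind(y, env$values) # second ROI carries the envelope directly
  trials <- rep(list(list(envelope = env, roi = roi)), 3)
  res <- loo_crossval(trials, lags_ms = seq(0, 200, by = 40), fs = fs)
  expect_equal(nrow(res), 3)
  expect_true(all(res$r >= 0.99))
  expect_equal(res$z, atanh(res$r))

  # 24 trials -> 24 folds each trained on 23 (structure only, tiny data)
  tiny <- lapply(1:24, function(i) {
    e <- make_envelope(0.5, fs, seed = 200 + i)
    list(envelope = e, roi = rbind(e$values + rnorm(125, 0, 3)))
  })
  res24 <- loo_crossval(tiny, lags_ms = c(0, 40), fs = fs,
                        ridge_grid = 1)
  expect_equal(res24$trial, 1:24)
  expect_true(all(!is.na(res24$r)))

  # envelope-unrelated ROI noise: mean r indistinguishable from zero
  set.seed(56)
  null_trials <- lapply(1:4, function(i) {
    list(envelope = make_envelope(10, fs, seed = 300 + i),
         roi = matrix(rnorm(2 * 2500), 2, 2500))
  })
  null_res <- loo_crossval(null_trials, lags_ms = seq(0, 200, by = 40),
                           fs = fs, ridge_grid = 1)
  expect_lt(abs(mean(null_res$r)), 0.05)
  expect_error(loo_crossval(null_trials[1], fs = fs), "at least 2")
})

test_that("Fisher z is atanh with domain checking", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("window statistics match the textbook paired t and handle degeneracy", {
  # hand-computed 5-pair toy: diffs (-1,-2,-1,0,-1), mean -1, sd sqrt(0.5)
  a <- c(1, 2, 0, 1, 2)
  b <- c(2, 4, 1, 1, 3)
  res <- compare_trf_windows(a, b, window_ms = c(0, 100))
  expect_equal(res$t, -3.1622777, tolerance = 1e-6)
  expect_equal(res$cohen_d, -1.4142136, tolerance = 1e-6)
  expect_equal(res$p, 0.0341094, tolerance = 1e-5)
  expect_equal(res$df, 4)

  # identical sets -> t = 0, d = 0; constant nonzero shift -> degenerate
  same <- compare_trf_windows(a, a, window_ms = c(0, 100))
  expect_equal(same$t, 0)
  expect_equal(same$cohen_d, 0)
  expect_error(compare_trf_windows(a, a + 2, window_ms = c(0, 100)),
               "degenerate")

  # matrix input averages within the window; window must sit in the grid
  lags <- seq(0, 800, by = 100)
  ma <- matrix(seq_len(18), 2, 9)
  expect_error(compare_trf_windows(ma, ma, window_ms = c(700, 900),
                                   lags_ms = lags), "outside the lag grid")
  mres <- compare_trf_windows(ma, ma, window_ms = c(0, 200), lags_ms = lags)
  expect_equal(mres$t, 0)
})
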