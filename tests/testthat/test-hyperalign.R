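# MCCA: covariance assembly against loop oracles, the generalized
# eigenproblem against a classical two-set CCA oracle and known identities,
# and the denoising/averaging behavior the alignment is for.

test_that("between-set covariance equals the brute-force centered sum", {
  set.seed(21)
  x <- matrix(rnorm(6), 3, 2)
  y <- matrix(rnorm(6), 3, 2)
  oracle <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    oracle[a, b] <- sum((x[, a] - mean(x[, a])) * (y[, b] - mean(y[, b])))
  }
  expect_equal(between_set_covariance(x, y), oracle)

  # self-covariance is symmetric PSD; constant columns give zeros
  v <- between_set_covariance(x, x)
  expect_equal(v, t(v))
  expect_true(all(eigen(v, symmetric = TRUE)$values > -1e-12))
  xc <- cbind(rep(2, 3), x[, 1])
  expect_equal(between_set_covariance(xc, y)[1, ], c(0, 0))
  expect_error(between_set_covariance(x, y[1:2, ]), "time dimension")
})

test_that("identical datasets give a leading canonical correlation of 1", {
  set.seed(22)
  x <- matrix(rnorm(200), 50, 4)
  for (i in c(2, 3, 5)) {
    m <- fit_mcca(rep(list(x), i))
    expect_equal(m$canonical_correlations[1], 1, tolerance = 1e-6)
  }
})

test_that("two-set MCCA matches the classical CCA oracle", {
  set.seed(23)
  x <- matrix(rnorm(150), 50, 3)
  y <- 0.5 * x + matrix(rnorm(150), 50, 3)
  m <- fit_mcca(list(x, y), ridge = 1e-10)
  expect_equal(m$canonical_correlations[1], cca2_oracle(x, y),
               tolerance = 1e-6)
})

test_that("independent noise gives a small leading correlation at long T", {
  set.seed(24)
  sets <- lapply(1:3, function(i) matrix(rnorm(10000 * 4), 10000, 4))
  m <- fit_mcca(sets)
  expect_lt(m$canonical_correlations[1], 0.2)
})

test_that("eigenpairs satisfy the generalized residual bound and ordering", {
  st <- small_study()
  sets <- lapply(1:4, function(s) {
    do.call(rbind, lapply(1:6, function(tr) t(st$eeg$data[s, tr, , ])))
  })
  m <- fit_mcca(sets, keep_matrices = TRUE)
  expect_true(all(diff(m$canonical_correlations) < 1e-10))
  W <- do.call(rbind, lapply(seq_along(m$projections), function(i) {
    m$projections[[i]]
  }))
  for (k in seq_len(m$default_k)) {
    w <- W[, k]
    resid <- sqrt(sum((m$B %*% w - m$eigenvalues[k] * (m$R %*% w))^2))
    expect_lt(resid / sqrt(sum((m$B %*% w)^2)), 1e-8)
  }
  expect_error(fit_mcca(list(sets[[1]])), "at least 2")
})

test_that("full-rank truncation reconstructs a subject's data exactly", {
  set.seed(25)
  x <- matrix(rnorm(300), 100, 3)
  y <- 0.8 * x + 0.2 * matrix(rnorm(300), 100, 3)
  m <- fit_mcca(list(x, y))
  rec <- mcca_reconstruct(m, x, 1, n_components = 3)
  expect_equal(rec, x, tolerance = 1e-8)
  expect_error(mcca_reconstruct(m, x, 1, n_components = 10), "exceeds")
})

test_that("hyperaligned averaging beats single subjects on shared signal and
           suppresses independent noise like 1/sqrt(I)", {
  gt <- make_ground_truth(n_roi = 8, n_channels = 8, n_sources = 32,
                          n_communities = 2, n_subjects = 6,
                          misalignment = 0.3, seed = 31)
  envs <- lapply(1:4, function(i) make_envelope(4, 250, seed = 30 + i))
  eeg <- simulate_study(gt, envs, n_trials_per_condition = 2, snr_db = 0,
                        seed = 32, keep_parts = TRUE)
  sets <- lapply(1:6, function(s) {
    do.call(rbind, lapply(1:4, function(tr) t(eeg$data[s, tr, , ])))
  })
  m <- fit_mcca(sets)
  truth <- eeg$signal[1, 1, , ] # identity-free: misalignment rotates, but
  den <- denoise_and_average(m, eeg, 1)
  # compare correlation with the montage-space truth of subject 1
  avg_cor <- cor(as.numeric(den), as.numeric(truth))
  single_cors <- sapply(1:6, function(s) {
    cor(as.numeric(eeg$data[s, 1, , ]), as.numeric(eeg$signal[s, 1, , ]))
  })
  expect_gt(avg_cor, max(single_cors))

  # independent-noise-only data: averaging shrinks RMS by about 1/sqrt(I)
  noise_eeg <- eeg
  noise_eeg$data <- eeg$noise
  avg <- naive_average(noise_eeg, 1)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(avg), mean(apply(eeg$noise[, 1, , ], 1, rms)) / sqrt(6) * 1.5)
})

test_that("aligned (component-space) averaging undoes misalignment that the
           naive average cannot", {
  # strong signal, substantially rotated caps: the naive average attenuates
  # the shared signal, the canonical-space average re-aligns it first
  gt <- make_ground_truth(n_roi = 8, n_channels = 16, n_sources = 32,
                          n_communities = 2, n_subjects = 8,
                          misalignment = 1.2, seed = 33)
  envs <- lapply(1:4, function(i) make_envelope(4, 250, seed = 40 + i))
  eeg <- simulate_study(gt, envs, n_trials_per_condition = 2, snr_db = 0,
                        seed = 34, keep_parts = TRUE)
  m <- fit_mcca_eeg(eeg)
  # montage-space truth: the unrotated forward projection
  kern <- gt$kernels$A
  env <- envs[[1]]$values
  X <- lag_matrix(env, gt$lag_grid_ms, 250)
  roi_sig <- t(X %*% t(kern))
  truth <- gt$leadfield %*% roi_sig[gt$parcellation, ]
  score <- function(est) {
    # best linear match to the truth, channel by channel is too strict under
    # re-mixing; compare via canonical correlation of the two multichannel
    # series' principal subspaces -- here simply the correlation of the
    # leading principal component time courses
    pc <- function(x) prcomp(t(x))$x[, 1]
    abs(cor(pc(est), pc(truth)))
  }
  aligned <- denoise_and_average(m, eeg, 1, space = "component")
  naive <- naive_average(eeg, 1)
  expect_gt(score(aligned), score(naive))
})

test_that("naive averaging is the elementwise mean over subjects", {
  st <- small_study()
  oracle <- matrix(0, 10, 1000)
  for (s in 1:4) oracle <- oracle + st$eeg$data[s, 2, , ]
  expect_equal(naive_average(st$eeg, 2), oracle / 4)
  # identical subjects -> any subject; opposite signs -> zero
  two <- st$eeg
  two$data <- two$data[c(1, 1), , , , drop = FALSE]
  expect_equal(naive_average(two, 1), st$eeg$data[1, 1, , ])
  two$data[2, , , ] <- -two$data[1, , , ]
  expect_equal(naive_average(two, 1), matrix(0, 10, 1000))
  expect_error(naive_average(st$eeg, 99), "out of range")
})
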