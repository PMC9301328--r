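# The simulator must produce exactly the statistical structure downstream
# stages assume: seeded determinism, band-limited nonnegative envelopes,
# planted within- vs between-community kernel similarity, bounded subject
# mixings, and background-plus-sensor noise calibrated to the requested
# stimulus-locked SNR.

test_that("envelopes have the right length, sign, determinism and band limit", {
  env <- make_envelope(60, 250, seed = 7)
  expect_length(env$values, 15000)
  expect_true(all(env$values >= 0))
  expect_identical(env$values, make_envelope(60, 250, seed = 7)$values)
  expect_false(identical(env$values, make_envelope(60, 250, seed = 8)$values))

  # periodogram: power above 20 Hz (excluding DC) below 1% of total
  v <- env$values - mean(env$values)
  spec <- Mod(fft(v))^2
  freqs <- (seq_along(v) - 1) / length(v) * 250
  freqs <- pmin(freqs, 250 - freqs)
  expect_lt(sum(spec[freqs > 20]) / sum(spec), 0.01)

  expect_error(make_envelope(-1, 250), "positive")
  expect_error(make_envelope(10, 0), "positive")
  expect_error(make_envelope(10, 12, modulation_band_hz = c(2, 8)), "twice")
})

test_that("envelope extraction tracks amplitude modulation", {
  fs_a <- 16000
  t <- seq(0, 2, length.out = 2 * fs_a)
  # constant-amplitude tone -> near-constant envelope after the filter
  # transient
  tone <- sin(2 * pi * 1000 * t)
  env <- extract_envelope(tone, fs_a, target_fs = 250)
  steady <- env$values[100:(length(env$values) - 50)]
  expect_lt(sd(steady) / mean(steady), 0.05)

  # 4 Hz AM tone -> envelope spectrum peaks at 4 Hz
  am <- (1 + 0.9 * sin(2 * pi * 4 * t)) * sin(2 * pi * 1000 * t)
  env4 <- extract_envelope(am, fs_a, target_fs = 250)
  v <- env4$values[51:450] - mean(env4$values[51:450])
  spec <- Mod(fft(v))^2
  freqs <- (seq_along(v) - 1) / length(v) * 250
  peak <- freqs[freqs > 0.5 & freqs < 125][which.max(spec[freqs > 0.5 & freqs < 125])]
  expect_equal(peak, 4, tolerance = 0.2)

  expect_warning(z <- extract_envelope(numeric(1600), 16000, target_fs = 250),
                 "silent")
  expect_true(all(z$values == 0))
  expect_error(extract_envelope(tone, 8000), "twice")
})

test_that("planted kernels are more similar within than between communities", {
  for (seed in c(1, 23, 404)) {
    gt <- make_ground_truth(n_roi = 16, n_channels = 12, n_sources = 64,
                            n_communities = 4, n_subjects = 2, seed = seed)
    for (cond in c("A", "B")) {
      C <- cor(t(gt$kernels[[cond]]))
      same <- outer(gt$community_labels[[cond]], gt$community_labels[[cond]], `==`)
      expect_gt(mean(C[same & upper.tri(C)]), mean(C[!same & upper.tri(C)]))
    }
  }
})

test_that("ground-truth geometry respects its invariants", {
  gt <- make_ground_truth(n_roi = 10, n_channels = 8, n_sources = 45,
                          n_communities = 3, n_subjects = 3,
                          misalignment = 0.4, max_condition_number = 50,
                          seed = 2)
  # every source in exactly one ROI, every ROI nonempty
  expect_length(gt$parcellation, 45)
  expect_setequal(unique(gt$parcellation), 1:10)
  # lead-field condition number within the configured bound
  d <- svd(gt$leadfield)$d
  expect_lte(max(d) / min(d), 50 * (1 + 1e-10))
  # subject mixing deviation bounded by the misalignment level, near-orthogonal
  for (Tm in gt$subject_transforms) {
    expect_lte(norm(Tm - diag(8), type = "2"), 0.4 + 1e-10)
    expect_lt(max(abs(crossprod(Tm) - diag(8))), 1e-8)
  }
  # zero misalignment -> exact identity
  gt0 <- make_ground_truth(n_roi = 10, n_channels = 8, n_sources = 45,
                           n_communities = 3, n_subjects = 2,
                           misalignment = 0, seed = 2)
  expect_identical(gt0$subject_transforms[[1]], diag(8))

  expect_error(make_ground_truth(n_roi = 4, n_sources = 2), "at least")
  expect_error(make_ground_truth(n_roi = 3, n_communities = 5), "at least")
})

test_that("simulated study has the full-study layout and balanced conditions", {
  st <- small_study()
  d <- dim(st$eeg$data)
  expect_equal(d, c(4, 6, 10, 1000))
  expect_equal(as.vector(table(st$eeg$condition_labels)), c(3L, 3L))
  # determinism: same seed, same bits
  eeg2 <- simulate_study(st$gt, st$envs, n_trials_per_condition = 3,
                         snr_db = 0, seed = 12)
  expect_identical(st$eeg$data, eeg2$data)
  expect_error(simulate_study(st$gt, st$envs[1:3], n_trials_per_condition = 3),
               "one envelope per trial")
})

test_that("noiseless limit reproduces the forward model exactly", {
  gt <- make_ground_truth(n_roi = 6, n_channels = 5, n_sources = 18,
                          n_communities = 2, n_subjects = 2,
                          misalignment = 0, seed = 3)
  envs <- lapply(1:2, function(i) make_envelope(2, 250, seed = i))
  eeg <- simulate_study(gt, envs, n_trials_per_condition = 1, snr_db = Inf,
                        seed = 4)
  env <- envs[[1]]$values
  kern <- gt$kernels$A
  n_t <- length(env)
  # brute-force causal convolution per ROI
  roi_sig <- t(sapply(seq_len(nrow(kern)), function(r) {
    sapply(seq_len(n_t), function(t) {
      taus <- seq_len(min(t, ncol(kern)))
      sum(kern[r, taus] * env[t - taus + 1])
    })
  }))
  expected <- gt$leadfield %*% roi_sig[gt$parcellation, ]
  expect_equal(eeg$data[1, 1, , ], expected, tolerance = 1e-10)
  expect_equal(eeg$data[2, 1, , ], expected, tolerance = 1e-10)
})

test_that("empirical signal-to-total-noise ratio matches the request within 1 dB", {
  gt <- make_ground_truth(n_roi = 8, n_channels = 6, n_sources = 24,
                          n_communities = 2, n_subjects = 2, seed = 5)
  envs <- lapply(1:4, function(i) make_envelope(3, 250, seed = 10 + i))
  for (snr in c(-5, 0, 10)) {
    eeg <- simulate_study(gt, envs, n_trials_per_condition = 2, snr_db = snr,
                          seed = 6, keep_parts = TRUE)
    emp <- 10 * log10(mean(eeg$signal^2) / mean(eeg$noise^2))
    expect_lt(abs(emp - snr), 1)
  }
})
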