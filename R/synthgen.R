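# Seeded forward simulation of a multi-subject natural-listening EEG study:
# band-limited stimulus envelopes, planted per-ROI response kernels with
# community structure, a smooth synthetic lead field, near-orthogonal
# per-subject channel mixings, and 1/f-shaped sensor noise.

#' Generate a band-limited stimulus envelope
#'
#' Produces a nonnegative, band-limited amplitude-modulation signal standing
#' in for the broadband envelope of a spoken story.  Speech envelopes carry
#' most of their power in the syllabic 2-8 Hz range, which is the default
#' modulation band.
#'
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling rate in Hz; must exceed twice the upper modulation
#'   frequency.
#' @param modulation_band_hz length-2 numeric, modulation band in Hz.
#' @param seed integer seed; the same seed gives a bitwise-identical envelope.
#' @return an object of class `envelope`: list with `values` (nonnegative,
#'   unit-variance before offsetting), `fs`, `duration`.
#' @export
#' @examples
#' env <- make_envelope(2, 250, seed = 1)
#' length(env$values) # 500
make_envelope <- function(duration_s, fs, modulation_band_hz = c(2, 8),
                          seed = 1) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_invalid("duration_s must be positive, got %s", format(duration_s))
  }
  if (!is.numeric(fs) || fs <= 0) {
    stop_invalid("fs must be positive, got %s", format(fs))
  }
  if (fs <= 2 * max(modulation_band_hz)) {
    stop_invalid("fs (%g Hz) must exceed twice the upper modulation frequency (%g Hz)",
                 fs, max(modulation_band_hz))
  }
  n <- round(fs * duration_s)
  values <- with_seed(seed, {
    x <- stats::rnorm(n)
    bp <- fft_bandpass(x, fs, modulation_band_hz[1], modulation_band_hz[2])
    bp <- bp / stats::sd(bp)
    bp - min(bp) # nonnegative; only adds a DC offset
  })
  structure(list(values = values, fs = fs, duration = duration_s),
            class = "envelope")
}

#' Extract a broadband envelope from an audio waveform
#'
#' Gammatone-filterbank decomposition with ERB-spaced center frequencies,
#' power-law compression of the band magnitudes, band averaging, low-pass
#' filtering and decimation to the neural sampling rate.
#'
#' @param audio numeric waveform.
#' @param audio_fs audio sampling rate in Hz; must be at least twice the top
#'   filterbank frequency.
#' @param n_bands number of gammatone bands (default 16).
#' @param power_exponent compression exponent applied to band magnitudes
#'   (default 0.6).
#' @param target_fs output sampling rate in Hz.
#' @param band_range_hz filterbank frequency range (default 50 Hz to 8 kHz).
#' @return an `envelope` at `target_fs`.
#' @export
extract_envelope <- function(audio, audio_fs, n_bands = 16,
                             power_exponent = 0.6, target_fs = 250,
                             band_range_hz = c(50, 8000)) {
  if (audio_fs < 2 * band_range_hz[2]) {
    stop_invalid("audio_fs (%g) must be at least twice the top filterbank frequency (%g)",
                 audio_fs, band_range_hz[2])
  }
  n <- length(audio)
  if (all(audio == 0)) {
    warning("silent (all-zero) audio: returning an all-zero envelope")
    m <- round(n / audio_fs * target_fs)
    return(structure(list(values = numeric(m), fs = target_fs,
                          duration = n / audio_fs), class = "envelope"))
  }
  cfs <- erb_centers(band_range_hz[1], band_range_hz[2], n_bands)
  band_env <- matrix(0, n, n_bands)
  for (b in seq_len(n_bands)) {
    y <- gammatone_filter(audio, audio_fs, cfs[b])
    band_env[, b] <- abs(y)^power_exponent
  }
  env <- rowMeans(band_env)
  # anti-alias low-pass, then resample onto the target grid
  env <- fft_bandpass(env, audio_fs, 0, 0.4 * target_fs, transition = 0.1 * target_fs)
  m <- round(n / audio_fs * target_fs)
  t_out <- (seq_len(m) - 1) / target_fs
  t_in <- (seq_len(n) - 1) / audio_fs
  values <- stats::approx(t_in, env, xout = t_out, rule = 2)$y
  values[values < 0] <- 0
  structure(list(values = values, fs = target_fs, duration = n / audio_fs),
            class = "envelope")
}

# ERB-rate spaced center frequencies (Glasberg & Moore scale)
erb_centers <- function(f_lo, f_hi, n) {
  erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
  erb_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437
  erb_inv(seq(erb(f_lo), erb(f_hi), length.out = n))
}

# 4th-order gammatone band-pass by FFT convolution with the impulse response
gammatone_filter <- function(x, fs, cf) {
  b <- 1.019 * 24.7 * (4.37 * cf / 1000 + 1) # ERB bandwidth
  ir_len <- min(length(x), max(64L, round(0.05 * fs)))
  t <- (seq_len(ir_len) - 1) / fs
  ir <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  ir <- ir / sqrt(sum(ir^2))
  n_fft <- stats::nextn(length(x) + ir_len - 1, 2)
  X <- stats::fft(c(x, numeric(n_fft - length(x))))
  H <- stats::fft(c(ir, numeric(n_fft - ir_len)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / n_fft
  y[seq_along(x)]
}

#' Generate the planted ground truth of a synthetic listening study
#'
#' Builds everything the forward simulation and the parameter-recovery tests
#' need: a source-to-ROI parcellation, per-ROI temporal response kernels with
#' planted community structure (ROIs in a community share a damped-oscillation
#' template with a community-specific latency and polarity, plus small ROI
#' jitter), a second condition whose structure differs, a smooth random lead
#' field with bounded condition number, and near-orthogonal per-subject
#' channel mixings.
#'
#' Communities are assigned as spatially contiguous ROI blocks and the lead
#' field is spatially smooth over a 2-D source sheet, so inverse-solution
#' leakage predominantly mixes kernels belonging to the same community --
#' the regime in which region-level kernel recovery is meaningful.
#'
#' @param n_roi number of ROIs (default 68, a Desikan-Killiany-sized atlas).
#' @param n_channels number of EEG channels (default 122, a 128-electrode
#'   montage minus non-EEG channels).
#' @param n_sources number of cortical sources (default 500); must be at
#'   least `n_roi`.
#' @param n_communities number of planted communities (>= 2, default 4);
#'   must not exceed `n_roi`.
#' @param lag_grid_ms kernel lag grid in ms (default 0-800 ms at 4 ms).
#' @param misalignment rotation angle (radians) of each subject's orthogonal
#'   channel mixing, applied in every plane of a random per-subject basis;
#'   the operator-norm deviation from the identity is `2 sin(angle/2) <=
#'   angle` (0 = perfectly matched caps).
#' @param n_subjects number of subjects to draw mixings for (default 21).
#' @param condition_b `"redraw"` re-draws community labels and templates for
#'   condition B; `"windowed"` keeps condition A's kernels and adds a
#'   condition difference confined to `difference_window_ms`.
#' @param difference_window_ms lag window (ms) of the planted condition
#'   difference when `condition_b = "windowed"`.
#' @param max_condition_number upper bound enforced on the lead-field
#'   condition number (default 50).
#' @param seed integer seed.
#' @return an object of class `ground_truth`; see fields in the source.
#' @export
make_ground_truth <- function(n_roi = 68, n_channels = 122, n_sources = 500,
                              n_communities = 4,
                              lag_grid_ms = seq(0, 800, by = 4),
                              misalignment = 1.2, n_subjects = 21,
                              condition_b = c("redraw", "windowed"),
                              difference_window_ms = c(300, 450),
                              max_condition_number = 50, seed = 1) {
  condition_b <- match.arg(condition_b)
  if (n_sources < n_roi) {
    stop_invalid("n_sources (%d) must be at least n_roi (%d)", n_sources, n_roi)
  }
  if (n_communities < 2) stop_invalid("n_communities must be at least 2")
  if (n_roi < n_communities) {
    stop_invalid("n_roi (%d) must be at least n_communities (%d)",
                 n_roi, n_communities)
  }

  # contiguous, as-even-as-possible partition of sources into ROIs
  parcellation <- sort(rep_len(seq_len(n_roi), n_sources))

  labels_a <- contiguous_blocks(n_roi, n_communities,
                               seed = derive_seed(seed, "labels_a"))
  kern_a <- community_kernels(labels_a, lag_grid_ms,
                              seed = derive_seed(seed, "kern_a"))
  if (condition_b == "redraw") {
    labels_b <- contiguous_blocks(n_roi, n_communities,
                                 seed = derive_seed(seed, "labels_b"))
    kern_b <- community_kernels(labels_b, lag_grid_ms,
                                seed = derive_seed(seed, "kern_b"))
  } else {
    labels_b <- labels_a
    kern_b <- windowed_difference(kern_a, lag_grid_ms, difference_window_ms,
                                  labels_a, seed = derive_seed(seed, "kern_b"))
  }

  leadfield <- smooth_leadfield(n_channels, n_sources, max_condition_number,
                                seed = derive_seed(seed, "leadfield"))
  transforms <- lapply(seq_len(n_subjects), function(i) {
    near_identity_rotation(n_channels, misalignment,
                           seed = derive_seed(seed, paste0("transform", i)))
  })

  structure(list(
    n_roi = n_roi,
    n_channels = n_channels,
    n_sources = n_sources,
    n_communities = n_communities,
    community_labels = list(A = labels_a, B = labels_b),
    kernels = list(A = kern_a, B = kern_b),
    lag_grid_ms = lag_grid_ms,
    leadfield = leadfield,
    parcellation = parcellation,
    subject_transforms = transforms,
    misalignment = misalignment,
    condition_b = condition_b,
    difference_window_ms = difference_window_ms,
    seeds = c(master = as.integer(seed))
  ), class = "ground_truth")
}

# random contiguous blocks: cut points drawn uniformly, every block nonempty
contiguous_blocks <- function(n_roi, k, seed) {
  with_seed(seed, {
    cuts <- sort(sample(seq_len(n_roi - 1), k - 1))
    labels <- findInterval(seq_len(n_roi), c(0, cuts)) # 1..k contiguous
    labels
  })
}

# damped-oscillation community templates with ROI-level jitter
community_kernels <- function(labels, lag_grid_ms, seed,
                              jitter_sd = 0.15) {
  k <- max(labels)
  n_roi <- length(labels)
  with_seed(seed, {
    templates <- vapply(seq_len(k), function(c) {
      latency <- stats::runif(1, 60, 380)      # ms
      freq <- stats::runif(1, 3, 7)            # Hz
      decay <- stats::runif(1, 100, 200)       # ms
      pol <- sample(c(-1, 1), 1)
      tau <- lag_grid_ms - latency
      k_c <- ifelse(tau >= 0,
                    pol * exp(-tau / decay) * sin(2 * pi * freq * tau / 1000),
                    0)
      k_c / max(abs(k_c))
    }, numeric(length(lag_grid_ms)))
    kern <- t(templates)[labels, , drop = FALSE] # ROI x lag
    # small smooth ROI-specific jitter so within-community kernels are not
    # exactly identical
    for (r in seq_len(n_roi)) {
      jit <- fft_bandpass(stats::rnorm(length(lag_grid_ms)), 250, 0, 10)
      kern[r, ] <- kern[r, ] * (1 + stats::rnorm(1, 0, jitter_sd / 2)) +
        jitter_sd * stats::sd(kern[r, ]) * jit / stats::sd(jit)
    }
    rownames(kern) <- paste0("ROI", seq_len(n_roi))
    kern
  })
}

# condition difference confined to one lag window (Hann-tapered bump)
windowed_difference <- function(kern, lag_grid_ms, window_ms, labels, seed) {
  idx <- lag_grid_ms >= window_ms[1] & lag_grid_ms <= window_ms[2]
  taper <- numeric(length(lag_grid_ms))
  m <- sum(idx)
  taper[idx] <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))
  with_seed(seed, {
    out <- kern
    scale <- apply(abs(kern), 1, max)
    signs <- sample(c(-1, 1), max(labels), replace = TRUE)
    freq <- stats::runif(max(labels), 3, 7)
    for (r in seq_len(nrow(kern))) {
      c_r <- labels[r]
      bump <- taper * sin(2 * pi * freq[c_r] * lag_grid_ms / 1000)
      out[r, ] <- kern[r, ] + signs[c_r] * 0.9 * scale[r] * bump
    }
    out
  })
}

# smooth random gain maps over a 2-D source sheet, condition number clipped
smooth_leadfield <- function(n_channels, n_sources, max_cond, seed) {
  nx <- ceiling(sqrt(n_sources))
  ny <- ceiling(n_sources / nx)
  with_seed(seed, {
    L <- matrix(0, n_channels, n_sources)
    sigma <- 1.5 # smoothing radius in grid units: local, but not so broad
                 # that neighboring ROIs become indistinguishable
    gx <- outer(seq_len(nx), seq_len(nx),
                function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
    gy <- outer(seq_len(ny), seq_len(ny),
                function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
    for (ch in seq_len(n_channels)) {
      field <- matrix(stats::rnorm(nx * ny), nx, ny)
      sm <- gx %*% field %*% gy
      v <- as.vector(sm)[seq_len(n_sources)]
      L[ch, ] <- v / stats::sd(v)
    }
    s <- svd(L)
    d <- pmax(s$d, max(s$d) / max_cond)
    L <- s$u %*% (d * t(s$v))
    L / sqrt(mean(L^2))
  })
}

# orthogonal channel mixing rotating every 2-D plane of a random basis by
# `angle` radians: |T - I|_2 = 2 sin(angle/2) <= angle, so the deviation is
# bounded by the misalignment level, and the parameter is the actual
# rotation angle rather than a bound only the worst plane attains
near_identity_rotation <- function(n, angle, seed) {
  if (angle == 0) return(diag(n))
  with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
    r <- diag(n)
    co <- cos(angle)
    si <- sin(angle)
    for (b in seq_len(n %/% 2)) {
      i <- 2 * b - 1
      r[i, i] <- co; r[i + 1, i + 1] <- co
      r[i, i + 1] <- -si; r[i + 1, i] <- si
    }
    q %*% r %*% t(q)
  })
}

#' Simulate the multi-subject EEG of the listening study
#'
#' Source activity per trial is the planted per-ROI kernel convolved with the
#' trial's stimulus envelope -- identical across subjects, the generative
#' premise behind cross-subject additive averaging.  On top of it each
#' subject gets two independent noise terms, matching how real EEG fails:
#'
#' * **background source activity**: 1/f-plus-white noise at every source,
#'   independent across subjects and sources, projected through the same
#'   lead field and channel mixing as the signal.  Because it occupies the
#'   same sensor subspace as the signal, pooling channels cannot average it
#'   away -- only cross-subject averaging can.
#' * **sensor noise**: 1/f-plus-white noise per channel, spatially white.
#'
#' `snr_db` is the variance ratio, per subject and trial, of the
#' stimulus-locked signal to the *total* noise (background plus sensor) at
#' the sensors -- the quantity speech-tracking studies mean by SNR;
#' `noise_mix` fixes how the noise variance is split between the background
#' (default 3/4) and sensor (1/4) terms.  The calibration is exact per
#' subject-trial.  `snr_db = Inf` is the fully noiseless sentinel: both
#' noise terms are dropped and the EEG equals the mixed forward projection
#' exactly.
#'
#' @param ground_truth a [make_ground_truth()] object.
#' @param envelopes list of [make_envelope()] objects, one per trial; all at
#'   the same `fs` and length.  Trials `1..n` are condition A, the rest
#'   condition B.
#' @param n_subjects number of subjects (default: all mixings in
#'   `ground_truth`).
#' @param n_trials_per_condition trials per condition; `length(envelopes)`
#'   must equal twice this.
#' @param snr_db stimulus-locked signal to total noise ratio in dB; `Inf`
#'   means noiseless.
#' @param noise_mix fraction of the noise variance carried by background
#'   source activity (in `[0, 1]`, default 0.75); the rest is sensor noise.
#' @param seed integer seed.
#' @param keep_parts if `TRUE`, also return the stimulus-locked signal and
#'   the total-noise arrays (memory-heavy; meant for small diagnostic runs).
#' @return object of class `multisubject_eeg`: `data` is a
#'   subject x trial x channel x time array, plus `fs`, `condition_labels`,
#'   `subject_ids`.
#' @export
simulate_study <- function(ground_truth, envelopes,
                           n_subjects = length(ground_truth$subject_transforms),
                           n_trials_per_condition = length(envelopes) / 2,
                           snr_db = -25, noise_mix = 0.75, seed = 1,
                           keep_parts = FALSE) {
  if (!is.numeric(noise_mix) || noise_mix < 0 || noise_mix > 1) {
    stop_invalid("noise_mix must lie in [0, 1], got %s", format(noise_mix))
  }
  gt <- ground_truth
  n_trials <- 2 * n_trials_per_condition
  if (length(envelopes) != n_trials) {
    stop_invalid("need one envelope per trial: %d envelopes for %d trials",
                 length(envelopes), n_trials)
  }
  if (!is.finite(snr_db) && !identical(snr_db, Inf)) {
    stop_invalid("snr_db must be finite (or Inf for the noiseless limit)")
  }
  if (n_subjects > length(gt$subject_transforms)) {
    stop_invalid("ground truth only has %d subject transforms",
                 length(gt$subject_transforms))
  }
  fs <- envelopes[[1]]$fs
  lag_step <- gt$lag_grid_ms[2] - gt$lag_grid_ms[1]
  if (abs(lag_step - 1000 / fs) > 1e-9) {
    stop_invalid("kernel lag grid step (%g ms) must match the envelope sampling step (%g ms)",
                 lag_step, 1000 / fs)
  }
  n_t <- length(envelopes[[1]]$values)
  condition_labels <- rep(c("A", "B"), each = n_trials_per_condition)

  data <- array(0, dim = c(n_subjects, n_trials, gt$n_channels, n_t))
  signal_arr <- if (keep_parts) array(0, dim = dim(data)) else NULL
  noise_arr <- if (keep_parts) array(0, dim = dim(data)) else NULL

  for (tr in seq_len(n_trials)) {
    env <- envelopes[[tr]]$values
    if (length(env) != n_t) stop_invalid("all envelopes must share one length")
    kern <- gt$kernels[[condition_labels[tr]]]
    roi_sig <- convolve_kernels(kern, env) # ROI x time
    src <- roi_sig[gt$parcellation, , drop = FALSE] # sources x time
    base <- gt$leadfield %*% src # channels x time (montage space)
    noiseless <- identical(snr_db, Inf)
    for (s in seq_len(n_subjects)) {
      sig <- gt$subject_transforms[[s]] %*% base
      if (noiseless) {
        noise <- 0
      } else {
        target_var <- mean(sig^2) / 10^(snr_db / 10)
        noise <- 0
        if (noise_mix > 0) {
          bg <- with_seed(derive_seed(seed, sprintf("src%03d_%03d", s, tr)), {
            t(pink_white_noise_mat(n_t, gt$n_sources, fs))
          })
          bg <- gt$subject_transforms[[s]] %*% (gt$leadfield %*% bg)
          noise <- bg * sqrt(noise_mix * target_var / mean(bg^2))
        }
        if (noise_mix < 1) {
          sen <- with_seed(derive_seed(seed, sprintf("sen%03d_%03d", s, tr)), {
            t(pink_white_noise_mat(n_t, gt$n_channels, fs))
          })
          noise <- noise +
            sen * sqrt((1 - noise_mix) * target_var / mean(sen^2))
        }
      }
      data[s, tr, , ] <- sig + noise
      if (keep_parts) {
        signal_arr[s, tr, , ] <- as.matrix(sig)
        noise_arr[s, tr, , ] <- if (noiseless) 0 else noise
      }
    }
  }

  out <- structure(list(
    data = data, fs = fs, condition_labels = condition_labels,
    subject_ids = paste0("S", sprintf("%02d", seq_len(n_subjects))),
    snr_db = snr_db, seed = as.integer(seed)
  ), class = "multisubject_eeg")
  if (keep_parts) {
    out$signal <- signal_arr
    out$noise <- noise_arr
  }
  out
}

# causal convolution of each ROI kernel with the envelope (zero initial state)
convolve_kernels <- function(kern, env) {
  n_t <- length(env)
  n_lag <- ncol(kern)
  n_fft <- stats::nextn(n_t + n_lag - 1, 2)
  E <- stats::fft(c(env, numeric(n_fft - n_t)))
  out <- matrix(0, nrow(kern), n_t)
  for (r in seq_len(nrow(kern))) {
    K <- stats::fft(c(kern[r, ], numeric(n_fft - n_lag)))
    y <- Re(stats::fft(E * K, inverse = TRUE)) / n_fft
    out[r, ] <- y[seq_len(n_t)]
  }
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Planted ground truth: %d ROIs / %d sources / %d channels, %d communities\n",
    x$n_roi, x$n_sources, x$n_channels, x$n_communities))
  cat(sprintf("  condition B: %s; misalignment bound %.2f; %d subject mixings\n",
              x$condition_b, x$misalignment, length(x$subject_transforms)))
  invisible(x)
}

#' @export
print.multisubject_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Multi-subject EEG: %d subjects x %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], d[4], x$fs))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s=%d", names(table(x$condition_labels)),
                            table(x$condition_labels)), collapse = ", ")))
  invisible(x)
}
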