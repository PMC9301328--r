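#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, and restores the state, so
#' seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stream-specific child seed from a master seed
#'
#' Deterministic integer mixing kept below 2^31 so derived seeds are valid R
#' integer seeds.
#'
#' @param seed master seed.
#' @param k stream index (any integer, or a short string which is hashed).
#' @return integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, k) {
  if (is.character(k)) {
    k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
  }
  # multiplicative mixing in double precision; exact below 2^53
  v <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k) * 16807 + 11
  as.integer(v %% 2147483629)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Brick-wall FFT band-pass filter with raised-cosine edges
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param lower,upper band edges (Hz); `lower = 0` gives a low-pass.
#' @param transition width of the raised-cosine roll-off (Hz).
#' @return filtered vector, same length.
#' @keywords internal
#' @noRd
fft_bandpass <- function(x, fs, lower, upper, transition = 0.5) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs) # two-sided spectrum, mirrored
  gain <- rep(1, n)
  if (lower > 0) {
    lo <- lower - transition / 2
    hi <- lower + transition / 2
    ramp <- (freqs - lo) / (hi - lo)
    gain <- gain * pmin(1, pmax(0, ramp))
  }
  if (is.finite(upper) && upper < fs / 2) {
    lo <- upper - transition / 2
    hi <- upper + transition / 2
    ramp <- (hi - freqs) / (hi - lo)
    gain <- gain * pmin(1, pmax(0, ramp))
  }
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Generate 1/f-shaped ("pink") noise plus a white floor
#'
#' Spectral amplitude proportional to 1/sqrt(f) mixed with an equal-variance
#' white component, normalized to unit variance per column.  The matrix
#' version generates `k` independent columns in two FFT passes.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param k number of independent columns (matrix version).
#' @return numeric vector (or n x k matrix) with unit column variance.
#' @keywords internal
#' @noRd
pink_white_noise <- function(n, fs) {
  drop(pink_white_noise_mat(n, 1, fs))
}

pink_white_noise_mat <- function(n, k, fs) {
  white <- matrix(stats::rnorm(n * k), n, k)
  spec <- stats::mvfft(matrix(stats::rnorm(n * k), n, k))
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)
  shape <- 1 / sqrt(pmax(freqs, fs / n)) # avoid the DC singularity
  shape[1] <- 0
  pink <- Re(stats::mvfft(spec * shape, inverse = TRUE)) / n
  # global (not per-column) normalization: downstream calibration rescales
  # total variance anyway, and one pass over the array is twice as fast
  z <- pink / sqrt(mean(pink^2)) + white
  z / sqrt(mean(z^2))
}

#' Adjusted Rand index between two labelings
#'
#' Standard Hubert-Arabie adjusted Rand index, used for parameter-recovery
#' checks against planted community structure.
#'
#' @param a,b label vectors over the same items.
#' @return numeric in `[-1, 1]`; 1 means identical partitions up to renaming.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop_invalid("labelings must cover the same items (%d vs %d)",
                 length(a), length(b))
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# relabel a partition to contiguous ids 1..k in order of first appearance
relabel_partition <- function(labels) {
  match(labels, unique(labels))
}
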