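# Independent oracles used across the suite.  These deliberately use
# brute-force formulations (loops, enumeration, closed forms) and never call
# the code paths they check.

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_id) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (id in seq_len(next_id)) {
      recurse(c(labels, id), max(next_id, id + 1))
    }
  }
  recurse(integer(0), 1)
  out
}

# signed modularity by the direct definitional formula, elementwise loops
modularity_signed_oracle <- function(W, labels, gamma = 1) {
  n <- nrow(W)
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  vp <- sum(Wp); vn <- sum(Wn)
  q_part <- function(Ws, v) {
    if (v == 0) return(0)
    k <- rowSums(Ws)
    q <- 0
    for (i in 1:n) for (j in 1:n) {
      if (labels[i] == labels[j]) {
        q <- q + (Ws[i, j] - gamma * k[i] * k[j] / v) / v
      }
    }
    q
  }
  q_part(Wp, vp) - vn / (vp + vn) * q_part(Wn, vn)
}

# classical two-set CCA leading correlation via the SVD of the whitened
# cross-covariance
cca2_oracle <- function(x, y) {
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  sxx <- crossprod(xc); syy <- crossprod(yc); sxy <- crossprod(xc, yc)
  ex <- eigen(sxx, symmetric = TRUE)
  ey <- eigen(syy, symmetric = TRUE)
  wx <- ex$vectors %*% diag(1 / sqrt(ex$values)) %*% t(ex$vectors)
  wy <- ey$vectors %*% diag(1 / sqrt(ey$values)) %*% t(ey$vectors)
  svd(wx %*% sxy %*% wy)$d[1]
}

# VI by direct counting over the co-membership confusion table
vi_oracle <- function(p1, p2) {
  n <- length(p1)
  u1 <- unique(p1); u2 <- unique(p2)
  h <- function(p, u) {
    -sum(sapply(u, function(a) {
      f <- sum(p == a) / n
      f * log(f)
    }))
  }
  i_xy <- 0
  for (a in u1) for (b in u2) {
    nij <- sum(p1 == a & p2 == b)
    if (nij > 0) {
      i_xy <- i_xy + nij / n * log((nij / n) / ((sum(p1 == a) / n) * (sum(p2 == b) / n)))
    }
  }
  h(p1, u1) + h(p2, u2) - 2 * i_xy
}

# small study fixture shared across tests (memoized: built once per session)
.fixture_env <- new.env()

small_study <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  gt <- make_ground_truth(n_roi = 12, n_channels = 10, n_sources = 48,
                          n_communities = 3, n_subjects = 4,
                          misalignment = 0.3, seed = 11)
  envs <- lapply(1:6, function(i) make_envelope(4, 250, seed = 100 + i))
  eeg <- simulate_study(gt, envs, n_trials_per_condition = 3, snr_db = 0,
                        seed = 12)
  .fixture_env$small <- list(gt = gt, envs = envs, eeg = eeg)
  .fixture_env$small
}
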