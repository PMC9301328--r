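# Multi-set CCA across subjects, canonical-component denoising, and
# cross-subject additive averaging.
#
# The model: find per-subject projection vectors w_i maximizing the summed
# between-set correlation rho = (1/(N-1)) * sum_{i != j} w_i' V_ij w_j /
# sum_i w_i' V_ii w_i with N the number of sets, which reduces to the
# generalized eigenproblem B w = lambda R w with B holding the between-set
# covariance blocks (zero diagonal) and R the block-diagonal within-set
# covariances.

#' Centered cross-covariance between two datasets
#'
#' Computes `t(X - colMeans(X)) %*% (Y - colMeans(Y))`.  With `Y = X` this is
#' the within-set covariance block.
#'
#' @param x,y time x channel matrices with equal numbers of rows.
#' @return channels(x) x channels(y) matrix.
#' @export
between_set_covariance <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) {
    stop_invalid("datasets must share the time dimension (%d vs %d rows)",
                 nrow(x), nrow(y))
  }
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  crossprod(xc, yc)
}

#' Fit multi-set canonical correlation analysis across subjects
#'
#' Assembles the between-set block matrix `B` (off-diagonal cross-covariance
#' blocks, zero diagonal) and the block-diagonal within-set matrix `R`
#' (ridge-stabilized), solves the generalized symmetric eigenproblem
#' `B w = lambda R w` via Cholesky whitening, and splits each eigenvector
#' into per-subject projection blocks.  The summed canonical correlation of
#' each component is `rho = lambda / (I - 1)`, which equals 1 for identical
#' datasets and is bounded by [0, 1] for the leading components.
#'
#' @param datasets list of >= 2 time x channel matrices with equal row
#'   counts; channel counts may differ between subjects.
#' @param ridge relative ridge added to each within-set block
#'   (`ridge * mean(diag(V_ii))`, default 1e-6) to stabilize near-singular
#'   finite-sample covariances.
#' @param keep_matrices store `B` and stabilized `R` in the model (used by
#'   residual diagnostics; default `FALSE`).
#' @return object of class `mcca_model` with per-subject `projections`,
#'   `eigenvalues` (descending), `canonical_correlations`, `channel_means`,
#'   `n_subjects`, `normalizer`, and `default_k` (smallest component count
#'   carrying 90% of the positive eigenvalue mass).
#' @export
fit_mcca <- function(datasets, ridge = 1e-6, keep_matrices = FALSE) {
  if (!is.list(datasets) || length(datasets) < 2) {
    stop_invalid("fit_mcca needs at least 2 datasets, got %d",
                 if (is.list(datasets)) length(datasets) else 1L)
  }
  datasets <- lapply(datasets, as.matrix)
  n_time <- unique(vapply(datasets, nrow, integer(1)))
  if (length(n_time) != 1) {
    stop_invalid("all datasets must share the time dimension")
  }
  means <- lapply(datasets, colMeans)
  V <- assemble_covariance(function(i) {
    sweep(datasets[[i]], 2, means[[i]])
  }, length(datasets), vapply(datasets, ncol, integer(1)))
  solve_mcca(V, vapply(datasets, ncol, integer(1)), means, ridge,
             keep_matrices)
}

#' Fit MCCA directly from a multi-subject EEG container
#'
#' Identical model to [fit_mcca()] on the per-subject trial-concatenated
#' data, but the covariance blocks are assembled from per-subject matrices
#' held on a decimated time grid, so no full concatenated copy of the data
#' set is ever materialized.  Preferred for full-size studies.
#'
#' Covariance estimation does not need every sample: EEG at 250 Hz is
#' heavily oversampled relative to the 1-40 Hz content, so the time axis is
#' subsampled to at most `max_samples` points per subject (stride chosen
#' accordingly; `Inf` disables subsampling).  The projections are unchanged
#' up to estimation noise while assembly cost and memory drop by the stride
#' factor.
#'
#' @param eeg a [simulate_study()] container.
#' @param trials trial indices to concatenate (default all).
#' @param max_samples cap on time samples per subject used for covariance
#'   assembly (default 20000).
#' @inheritParams fit_mcca
#' @return an `mcca_model`, as from [fit_mcca()].
#' @export
fit_mcca_eeg <- function(eeg, trials = NULL, ridge = 1e-6,
                         max_samples = 20000, keep_matrices = FALSE) {
  d <- dim(eeg$data)
  if (d[1] < 2) stop_invalid("fit_mcca_eeg needs at least 2 subjects, got %d", d[1])
  if (is.null(trials)) trials <- seq_len(d[2])
  n_total <- length(trials) * d[4]
  stride <- max(1L, ceiling(n_total / max_samples))
  keep_t <- seq(1L, d[4], by = stride)
  # one pass: per-subject centered matrices on the decimated grid
  centered <- vector("list", d[1])
  means <- vector("list", d[1])
  for (s in seq_len(d[1])) {
    x <- matrix(0, length(trials) * length(keep_t), d[3])
    for (k in seq_along(trials)) {
      rows <- ((k - 1) * length(keep_t) + 1):(k * length(keep_t))
      x[rows, ] <- t(eeg$data[s, trials[k], , keep_t])
    }
    means[[s]] <- colMeans(x)
    centered[[s]] <- sweep(x, 2, means[[s]])
  }
  V <- assemble_covariance(function(i) centered[[i]], d[1], rep(d[3], d[1]))
  solve_mcca(V, rep(d[3], d[1]), means, ridge, keep_matrices)
}

# pairwise assembly of the stacked covariance matrix; get_centered(i) must
# return subject i's centered time x channel matrix
assemble_covariance <- function(get_centered, n_set, n_chan) {
  offsets <- c(0, cumsum(n_chan))
  V <- matrix(0, sum(n_chan), sum(n_chan))
  for (i in seq_len(n_set)) {
    xi <- get_centered(i)
    ri <- (offsets[i] + 1):offsets[i + 1]
    V[ri, ri] <- crossprod(xi)
    if (i < n_set) {
      for (j in (i + 1):n_set) {
        xj <- get_centered(j)
        rj <- (offsets[j] + 1):offsets[j + 1]
        Vij <- crossprod(xi, xj)
        V[ri, rj] <- Vij
        V[rj, ri] <- t(Vij)
      }
    }
  }
  V
}

solve_mcca <- function(V, n_chan, means, ridge, keep_matrices) {
  n_set <- length(n_chan)
  blocks <- split(seq_len(sum(n_chan)), rep(seq_len(n_set), n_chan))

  R <- matrix(0, sum(n_chan), sum(n_chan))
  for (i in seq_len(n_set)) {
    Vii <- V[blocks[[i]], blocks[[i]], drop = FALSE]
    R[blocks[[i]], blocks[[i]]] <- Vii + diag(ridge * mean(diag(Vii)),
                                              n_chan[i])
  }
  B <- V
  for (i in seq_len(n_set)) B[blocks[[i]], blocks[[i]]] <- 0

  # whiten with the block-diagonal Cholesky factor; fall back with guidance
  K <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(K)) {
    stop("within-set covariance is rank-deficient even after stabilization; ",
         "raise the `ridge` argument of fit_mcca()", call. = FALSE)
  }
  Kinv <- backsolve(K, diag(nrow(K)))
  S <- crossprod(Kinv, B %*% Kinv)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  W <- Kinv %*% eig$vectors # generalized eigenvectors, R-orthonormal
  lambda <- eig$values      # already descending

  rho <- lambda / (n_set - 1)
  # default truncation: 90% of the positive eigenvalue mass, capped at half
  # the smallest montage -- retaining a full channel rank would make the
  # back-projection the identity and denoise nothing
  pos <- pmax(lambda, 0)
  default_k <- min(which(cumsum(pos) >= 0.9 * sum(pos))[1],
                   max(1L, floor(min(n_chan) / 2)))

  projections <- lapply(seq_len(n_set), function(i) {
    W[blocks[[i]], , drop = FALSE]
  })

  structure(list(
    projections = projections,
    eigenvalues = lambda,
    canonical_correlations = rho,
    n_subjects = n_set,
    normalizer = n_set,
    channel_means = means,
    ridge = ridge,
    default_k = default_k,
    B = if (keep_matrices) B else NULL,
    R = if (keep_matrices) R else NULL
  ), class = "mcca_model")
}

#' @export
print.mcca_model <- function(x, ...) {
  cat(sprintf("MCCA model: %d subjects, %d components (default truncation %d)\n",
              x$n_subjects, length(x$eigenvalues), x$default_k))
  cat("  leading canonical correlations:",
      paste(sprintf("%.3f", utils::head(x$canonical_correlations, 5)),
            collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct one subject's data from truncated canonical components
#'
#' Projects the subject's (time x channel) data onto its leading
#' `n_components` MCCA projections and back-projects into that subject's
#' channel space via the Moore-Penrose pseudoinverse of the truncated
#' projection matrix.  With a full-rank square projection this is the
#' identity map.
#'
#' @param model a [fit_mcca()] model.
#' @param x time x channel matrix for this subject.
#' @param subject subject index into the model.
#' @param n_components number of retained components.
#' @return time x channel reconstruction.
#' @export
mcca_reconstruct <- function(model, x, subject, n_components) {
  w <- model$projections[[subject]]
  if (n_components > ncol(w)) {
    stop_invalid("n_components (%d) exceeds the model component count (%d)",
                 n_components, ncol(w))
  }
  wk <- w[, seq_len(n_components), drop = FALSE]
  xc <- sweep(as.matrix(x), 2, model$channel_means[[subject]])
  z <- xc %*% wk
  rec <- z %*% MASS::ginv(wk)
  sweep(rec, 2, model$channel_means[[subject]], "+")
}

#' Denoise one trial by canonical truncation and average across subjects
#'
#' Two averaging spaces are implemented; both return a denoised trial on the
#' common montage:
#'
#' * `"electrode"`: each subject's trial is reconstructed from its leading
#'   `n_components` canonical components ([mcca_reconstruct()]) and the
#'   reconstructions are averaged in electrode space.  Simple, but the
#'   averaged signal carries the same mean-misalignment attenuation as the
#'   naive average (the per-subject projections cannot undo a rotation that
#'   happens before averaging).
#' * `"component"` (the aligned average): each subject's trial is projected
#'   onto its own canonical components, whose scores are aligned across
#'   subjects by construction, the scores are averaged, and the average is
#'   back-projected to the montage through the pseudoinverse of the
#'   subject-averaged projection.  Signal adds coherently regardless of the
#'   misalignment, which is the point of hyperaligning before averaging.
#'
#' @param model a [fit_mcca()] model fit on these subjects.
#' @param eeg a [simulate_study()] container (or any object with a
#'   subject x trial x channel x time `data` array).
#' @param trial trial index.
#' @param n_components retained components (default: the model's 90%
#'   eigenvalue-mass truncation).
#' @param space `"electrode"` or `"component"`.
#' @return channel x time matrix on the common montage.
#' @export
denoise_and_average <- function(model, eeg, trial,
                                n_components = model$default_k,
                                space = c("electrode", "component")) {
  space <- match.arg(space)
  d <- dim(eeg$data)
  if (trial < 1 || trial > d[2]) {
    stop_invalid("trial index %d out of range 1..%d", trial, d[2])
  }
  if (n_components > length(model$eigenvalues)) {
    stop_invalid("n_components (%d) exceeds the model component count (%d)",
                 n_components, length(model$eigenvalues))
  }
  n_sub <- d[1]
  if (space == "electrode") {
    acc <- 0
    for (s in seq_len(n_sub)) {
      x <- t(eeg$data[s, trial, , ]) # time x channel
      acc <- acc + mcca_reconstruct(model, x, s, n_components)
    }
    t(acc / n_sub) # channel x time
  } else {
    ks <- seq_len(n_components)
    acc <- 0
    xbar <- 0
    mbar <- 0
    for (s in seq_len(n_sub)) {
      wk <- model$projections[[s]][, ks, drop = FALSE]
      xc <- sweep(t(eeg$data[s, trial, , ]), 2, model$channel_means[[s]])
      acc <- acc + xc %*% wk
      xbar <- xbar + xc
      mbar <- mbar + model$channel_means[[s]]
    }
    zbar <- acc / n_sub
    xbar <- xbar / n_sub
    # montage patterns by regressing the naive electrode average onto the
    # aligned scores: the output is the naive average restricted to the
    # cross-subject-aligned subspace, on the correct montage geometry
    G <- crossprod(zbar)
    A <- solve(G + diag(1e-8 * mean(diag(G)), ncol(zbar)),
               crossprod(zbar, xbar))
    t(sweep(zbar %*% A, 2, mbar / n_sub, "+"))
  }
}

#' Plain additive average of one trial across subjects
#'
#' The comparison baseline: the elementwise mean over subjects with no
#' alignment.
#'
#' @inheritParams denoise_and_average
#' @return channel x time matrix.
#' @export
naive_average <- function(eeg, trial) {
  d <- dim(eeg$data)
  if (trial < 1 || trial > d[2]) {
    stop_invalid("trial index %d out of range 1..%d", trial, d[2])
  }
  out <- matrix(0, d[3], d[4])
  for (s in seq_len(d[1])) out <- out + eeg$data[s, trial, , ]
  out / d[1]
}
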