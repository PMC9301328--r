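# Temporal response functions: lagged design matrices, per-ROI ridge
# encoders, multivariate stimulus-reconstruction decoders, leave-one-out
# evaluation, and TRF window statistics.
#
# The encoder models each ROI as a linear time-invariant response to the
# speech envelope, x(t, ROI) = sum_tau r(tau, ROI) s(t - tau) with tau on a
# 0-800 ms grid.  The decoder inverts the system, reconstructing s(t) from
# all ROIs jointly; because the neural response lags the stimulus, the
# decoder consumes anti-causal lags x(t + tau).

#' Build a lagged (Toeplitz) design matrix
#'
#' Lagged copies of each input feature, zero-padded at the trial boundary.
#' Columns are ordered feature-major: all lags of feature 1, then feature 2,
#' each with lags ascending.  `direction = "past"` uses x(t - tau) (encoder
#' convention); `"future"` uses x(t + tau) (decoder convention).
#'
#' @param series numeric vector or time x feature matrix.
#' @param lags_ms nonnegative lags in ms; each must be an integer number of
#'   samples at `fs`.
#' @param fs sampling rate (Hz).
#' @param direction `"past"` or `"future"`.
#' @return time x (features * lags) matrix.
#' @export
lag_matrix <- function(series, lags_ms, fs, direction = c("past", "future")) {
  direction <- match.arg(direction)
  x <- as.matrix(series)
  n_t <- nrow(x)
  if (any(lags_ms < 0)) stop_invalid("lags must be nonnegative")
  lag_smp <- lags_ms * fs / 1000
  if (any(abs(lag_smp - round(lag_smp)) > 1e-6)) {
    stop_invalid("lags must be integer multiples of the sampling step (%g ms)",
                 1000 / fs)
  }
  lag_smp <- as.integer(round(lag_smp))
  if (any(lag_smp >= n_t)) {
    stop_invalid("largest lag (%d samples) must be smaller than the series length (%d)",
                 max(lag_smp), n_t)
  }
  n_f <- ncol(x)
  out <- matrix(0, n_t, n_f * length(lag_smp))
  col <- 0L
  for (f in seq_len(n_f)) {
    for (l in lag_smp) {
      col <- col + 1L
      if (l == 0L) {
        out[, col] <- x[, f]
      } else if (direction == "past") {
        out[(l + 1L):n_t, col] <- x[seq_len(n_t - l), f]
      } else {
        out[seq_len(n_t - l), col] <- x[(l + 1L):n_t, f]
      }
    }
  }
  out
}

default_lags <- function(fs, from_ms = 0, to_ms = 800) {
  seq(from_ms, to_ms, by = 1000 / fs)
}

#' Fit forward (encoder) temporal response functions
#'
#' Per-ROI ridge regression of the neural signal on the lagged stimulus
#' envelope; `ridge = 0` is ordinary least squares.  Predictors and targets
#' are centered; intercepts are returned unpenalized.
#'
#' @param envelope [make_envelope()] object or numeric vector at the neural
#'   sampling rate.
#' @param roi_series [aggregate_roi()] object, or an ROI x time matrix.
#' @param lags_ms lag grid in ms (default 0-800 ms at the sampling step).
#' @param ridge nonnegative ridge penalty (raw scale).
#' @param fs sampling rate, required when both inputs are bare numerics.
#' @return object of class `trf_model`: `weights` (ROI x lag), `lags_ms`,
#'   `ridge`, `intercepts`, `fs`.
#' @export
fit_encoder <- function(envelope, roi_series, lags_ms = NULL, ridge = 0,
                        fs = NULL) {
  env <- if (inherits(envelope, "envelope")) envelope$values else as.numeric(envelope)
  if (inherits(envelope, "envelope")) fs <- envelope$fs
  y <- roi_values(roi_series)
  if (is.null(fs)) fs <- attr(roi_series, "fs") %||%
      (if (inherits(roi_series, "roi_series")) roi_series$fs else NULL)
  if (is.null(fs) || is.na(fs)) stop_invalid("sampling rate fs is required")
  if (is.null(lags_ms)) lags_ms <- default_lags(fs)
  if (ncol(y) != length(env)) {
    stop_invalid("envelope (%d samples) and ROI series (%d) must share length",
                 length(env), ncol(y))
  }
  if (stats::sd(env) == 0) {
    stop("zero-variance envelope: encoder fit failed", call. = FALSE)
  }
  X <- lag_matrix(env, lags_ms, fs, direction = "past")
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  Yt <- t(y) # time x ROI
  ym <- colMeans(Yt)
  Yc <- sweep(Yt, 2, ym)
  G <- crossprod(Xc) + diag(ridge, ncol(Xc))
  W <- solve(G, crossprod(Xc, Yc)) # lags x ROI
  weights <- t(W)
  rownames(weights) <- rownames(y)
  colnames(weights) <- paste0("lag", lags_ms)
  structure(list(weights = weights, lags_ms = lags_ms, ridge = ridge,
                 intercepts = as.numeric(ym - xm %*% W), fs = fs),
            class = "trf_model")
}

roi_values <- function(x) {
  if (inherits(x, "roi_series")) x$values else as.matrix(x)
}

#' Predict ROI responses from an encoder
#'
#' @param model a [fit_encoder()] model.
#' @param envelope envelope object or numeric vector.
#' @return ROI x time matrix of predicted responses.
#' @export
predict_encoder <- function(model, envelope) {
  env <- if (inherits(envelope, "envelope")) envelope$values else as.numeric(envelope)
  X <- lag_matrix(env, model$lags_ms, model$fs, direction = "past")
  t(X %*% t(model$weights) + rep(model$intercepts, each = nrow(X)))
}

#' Fit a backward (decoder) stimulus-reconstruction model
#'
#' One multivariate ridge regression of the envelope on the anti-causally
#' lagged signals of all ROIs jointly (the double sum over regions and lags),
#' minimizing the mean squared reconstruction error.
#'
#' @param roi_series [aggregate_roi()] object or ROI x time matrix.
#' @param envelope envelope object or numeric vector.
#' @param lags_ms lag grid in ms (default 0-800 ms at the sampling step).
#' @param ridge nonnegative ridge penalty (raw scale).
#' @param fs sampling rate if not carried by the inputs.
#' @return object of class `trf_decoder`: `weights` (ROI x lag), `lags_ms`,
#'   `ridge`, `intercept`, `fs`.
#' @export
fit_decoder <- function(roi_series, envelope, lags_ms = NULL, ridge = 0,
                        fs = NULL) {
  env <- if (inherits(envelope, "envelope")) envelope$values else as.numeric(envelope)
  if (inherits(envelope, "envelope")) fs <- envelope$fs
  y <- roi_values(roi_series)
  if (is.null(fs)) fs <- if (inherits(roi_series, "roi_series")) roi_series$fs else NULL
  if (is.null(fs) || is.na(fs)) stop_invalid("sampling rate fs is required")
  if (is.null(lags_ms)) lags_ms <- default_lags(fs)
  if (ncol(y) != length(env)) {
    stop_invalid("ROI series (%d samples) and envelope (%d) must share length",
                 ncol(y), length(env))
  }
  if (all(apply(y, 1, stats::sd) == 0)) {
    stop("zero-variance neural signal: decoder fit failed", call. = FALSE)
  }
  X <- lag_matrix(t(y), lags_ms, fs, direction = "future")
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  yc <- env - mean(env)
  G <- crossprod(Xc) + diag(ridge, ncol(Xc))
  w <- solve(G, crossprod(Xc, yc))
  weights <- matrix(w, nrow = nrow(y), byrow = TRUE) # feature-major columns
  rownames(weights) <- rownames(y)
  colnames(weights) <- paste0("lag", lags_ms)
  structure(list(weights = weights, lags_ms = lags_ms, ridge = ridge,
                 intercept = mean(env) - as.numeric(xm %*% w), fs = fs),
            class = "trf_decoder")
}

#' Reconstruct a stimulus envelope with a decoder
#'
#' @param decoder a [fit_decoder()] model.
#' @param roi_series ROI x time matrix or `roi_series` object.
#' @return numeric reconstructed envelope.
#' @export
predict_decoder <- function(decoder, roi_series) {
  y <- roi_values(roi_series)
  X <- lag_matrix(t(y), decoder$lags_ms, decoder$fs, direction = "future")
  as.numeric(X %*% as.numeric(t(decoder$weights))) + decoder$intercept
}

#' Leave-one-out stimulus-reconstruction cross-validation
#'
#' For each fold, a decoder is fit on the concatenation of all other trials
#' (per-trial centering, no cross-trial leakage in the lagged designs), the
#' ridge is chosen from `ridge_grid` by mean reconstruction correlation over
#' inner folds of the training trials, and the held-out trial's Pearson r and
#' Fisher z are reported.  Implemented with per-trial Gram accumulation so
#' each fold is a single regularized solve.
#'
#' @param trials list of trials, each a list with elements `envelope`
#'   (envelope object or numeric) and `roi` (`roi_series` or ROI x time
#'   matrix).
#' @param lags_ms decoder lag grid in ms.
#' @param ridge_grid relative ridge grid; each value is scaled by
#'   `mean(diag(Gram)) / ncol(X)` of the training fold (trace
#'   normalization).  A length-1 grid skips inner tuning.
#' @param fs sampling rate if not carried by the inputs.
#' @param inner_folds number of inner folds for ridge selection (default 3).
#' @return data.frame of class `prediction_result` with columns `trial`,
#'   `r`, `z`, `ridge`; constant test envelopes give `NA` with a warning.
#' @export
loo_crossval <- function(trials, lags_ms = NULL, ridge_grid = 10^c(-4, -2, 0, 2),
                         fs = NULL, inner_folds = 3) {
  n <- length(trials)
  if (n < 2) stop_invalid("leave-one-out needs at least 2 trials, got %d", n)
  get_env <- function(tr) {
    if (inherits(tr$envelope, "envelope")) tr$envelope$values else as.numeric(tr$envelope)
  }
  if (is.null(fs)) {
    e1 <- trials[[1]]$envelope
    fs <- if (inherits(e1, "envelope")) e1$fs else
      if (inherits(trials[[1]]$roi, "roi_series")) trials[[1]]$roi$fs else NULL
  }
  if (is.null(fs) || is.na(fs)) stop_invalid("sampling rate fs is required")
  if (is.null(lags_ms)) lags_ms <- default_lags(fs)

  # per-trial centered lagged designs and Gram pieces
  grams <- vector("list", n)
  xtys <- vector("list", n)
  designs <- vector("list", n)
  envs <- vector("list", n)
  p <- NULL
  for (k in seq_len(n)) {
    y <- roi_values(trials[[k]]$roi)
    e <- get_env(trials[[k]])
    X <- lag_matrix(t(y), lags_ms, fs, direction = "future")
    X <- sweep(X, 2, colMeans(X))
    e <- e - mean(e)
    p <- ncol(X)
    grams[[k]] <- crossprod(X)
    xtys[[k]] <- crossprod(X, e)
    designs[[k]] <- X
    envs[[k]] <- e
  }
  G_all <- Reduce(`+`, grams)
  g_all <- Reduce(`+`, xtys)

  inner_groups <- function(train_idx) {
    nf <- min(inner_folds, length(train_idx))
    split(train_idx, rep_len(seq_len(nf), length(train_idx)))
  }
  fold_r <- function(w, idx) {
    mean(vapply(idx, function(k) {
      pred <- designs[[k]] %*% w
      if (stats::sd(envs[[k]]) == 0 || stats::sd(pred) == 0) return(NA_real_)
      stats::cor(pred, envs[[k]])
    }, numeric(1)), na.rm = TRUE)
  }

  res <- data.frame(trial = seq_len(n), r = NA_real_, z = NA_real_,
                    ridge = NA_real_)
  for (j in seq_len(n)) {
    train_idx <- setdiff(seq_len(n), j)
    G_tr <- G_all - grams[[j]]
    g_tr <- g_all - xtys[[j]]
    scale <- mean(diag(G_tr)) # trace normalization
    lam <- ridge_grid * scale
    best <- lam[1]
    if (length(lam) > 1) {
      groups <- inner_groups(train_idx)
      score <- vapply(lam, function(l) {
        mean(vapply(groups, function(g) {
          G_in <- G_tr - Reduce(`+`, grams[g])
          g_in <- g_tr - Reduce(`+`, xtys[g])
          w <- solve(G_in + diag(l, p), g_in)
          fold_r(w, g)
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      best <- lam[which.max(score)] # which.max: ties -> smallest ridge
    }
    w <- solve(G_tr + diag(best, p), g_tr)
    if (stats::sd(envs[[j]]) == 0) {
      warning(sprintf("test trial %d has a constant envelope; r recorded as NA", j))
      next
    }
    r <- stats::cor(designs[[j]] %*% w, envs[[j]])
    res$r[j] <- r
    res$z[j] <- atanh(r)
    res$ridge[j] <- best / scale
  }
  class(res) <- c("prediction_result", "data.frame")
  res
}

#' Fisher z transform of a correlation coefficient
#'
#' Variance-stabilizing `atanh(r)`, used before averaging or testing
#' correlations.
#'
#' @param r correlation(s) with `|r| < 1`.
#' @return z value(s).
#' @export
#' @examples
#' fisher_z(0.5) # 0.5493
fisher_z <- function(r) {
  if (any(!is.na(r) & abs(r) >= 1)) {
    stop_invalid("fisher_z requires |r| < 1")
  }
  atanh(r)
}

#' Paired comparison of TRF amplitude within a lag window
#'
#' Mean signed TRF amplitude inside `window_ms` is computed for each paired
#' observation (e.g. per subject or per trial) in the two sets, then a paired
#' t-test and Cohen's d (mean difference over the SD of differences) are
#' returned.  Identical sets give `t = 0, d = 0`; a nonzero constant shift
#' with zero within-pair variance is a degenerate-variance error.
#'
#' @param trf_set_a,trf_set_b paired numeric matrices (observations x lags)
#'   or vectors of per-observation window amplitudes.
#' @param window_ms length-2 window inside the lag grid.
#' @param lags_ms lag grid matching the matrix columns (required for matrix
#'   input).
#' @return list with `t`, `p`, `cohen_d`, `df`, `mean_diff`.
#' @export
compare_trf_windows <- function(trf_set_a, trf_set_b, window_ms,
                                lags_ms = NULL) {
  window_amp <- function(x) {
    if (is.matrix(x)) {
      if (is.null(lags_ms)) stop_invalid("lags_ms is required for matrix input")
      if (window_ms[1] < min(lags_ms) || window_ms[2] > max(lags_ms)) {
        stop_invalid("window [%g, %g] ms is outside the lag grid [%g, %g] ms",
                     window_ms[1], window_ms[2], min(lags_ms), max(lags_ms))
      }
      idx <- lags_ms >= window_ms[1] & lags_ms <= window_ms[2]
      rowMeans(x[, idx, drop = FALSE])
    } else {
      as.numeric(x)
    }
  }
  a <- window_amp(trf_set_a)
  b <- window_amp(trf_set_b)
  if (length(a) != length(b)) {
    stop_invalid("paired sets must have equal size (%d vs %d)",
                 length(a), length(b))
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, cohen_d = 0, df = length(d) - 1, mean_diff = 0))
    }
    stop("degenerate within-pair variance: all differences are identical ",
         "and nonzero", call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       cohen_d = mean(d) / stats::sd(d),
       df = unname(tt$parameter), mean_diff = mean(d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
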