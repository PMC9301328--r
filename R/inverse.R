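# Standardized minimum-norm (sLORETA) source reconstruction and ROI
# aggregation, for fixed-orientation sources.

#' Build an sLORETA inverse operator
#'
#' Minimum-norm kernel `T = L' (L L' + a I)^-1` with `a` expressed as a
#' fraction of the mean eigenvalue of the sensor covariance `L L'`
#' (equivalently its mean diagonal trace share), standardized per source by
#' the diagonal of the resolution matrix `T L`.  For fixed-orientation
#' sources the standardization factors are scalars, and the standardized
#' estimate has zero localization error for noiseless point sources.
#'
#' @param leadfield channels x sources gain matrix.
#' @param alpha regularization as a fraction of the mean eigenvalue of
#'   `L L'` (> 0; default 0.05).
#' @return object of class `inverse_operator` with `kernel`
#'   (sources x channels), `standardization` (per-source positive scale),
#'   `alpha`, `alpha_abs`.
#' @export
make_inverse_operator <- function(leadfield, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0) {
    stop_invalid("alpha must be positive, got %s", format(alpha))
  }
  L <- as.matrix(leadfield)
  G <- tcrossprod(L)
  alpha_abs <- alpha * mean(diag(G))
  M <- G + diag(alpha_abs, nrow(G))
  kernel <- t(solve(M, L)) # L' M^-1, sources x channels
  res_diag <- rowSums(kernel * t(L)) # diag(T L)
  if (any(res_diag <= 0)) {
    stop("resolution matrix has non-positive diagonal entries; ",
         "the lead field is degenerate", call. = FALSE)
  }
  structure(list(kernel = kernel,
                 standardization = sqrt(res_diag),
                 alpha = alpha, alpha_abs = alpha_abs,
                 n_channels = ncol(kernel), n_sources = nrow(kernel)),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("sLORETA inverse operator: %d sources x %d channels, alpha = %g (abs %.3g)\n",
              x$n_sources, x$n_channels, x$alpha, x$alpha_abs))
  invisible(x)
}

#' Apply an inverse operator to sensor data
#'
#' Standardized source estimates `diag(1/s) T x`; linear in the input.
#'
#' @param op an [make_inverse_operator()] object.
#' @param eeg_trial channels x time matrix.
#' @return sources x time matrix of standardized source activity.
#' @export
apply_inverse <- function(op, eeg_trial) {
  x <- as.matrix(eeg_trial)
  if (nrow(x) != op$n_channels) {
    stop_invalid("channel count (%d) does not match the operator (%d)",
                 nrow(x), op$n_channels)
  }
  (op$kernel %*% x) / op$standardization
}

#' Aggregate source activity into ROI time series
#'
#' Per-ROI mean across member sources at every time point, the plain-average
#' aggregation of a labeled parcellation (no sign flipping by default; set
#' `sign_flip = TRUE` to align each source with its ROI's first principal
#' direction before averaging).
#'
#' @param source_activity sources x time matrix.
#' @param parcellation integer vector mapping each source to an ROI id; every
#'   ROI between 1 and `max(parcellation)` must be nonempty.
#' @param fs sampling rate carried into the result (Hz), optional.
#' @param sign_flip flip the sign of sources anti-correlated with their ROI
#'   mean before averaging (default `FALSE`).
#' @return object of class `roi_series`: `values` (ROI x time), `roi_ids`,
#'   `fs`.
#' @export
aggregate_roi <- function(source_activity, parcellation, fs = NA_real_,
                          sign_flip = FALSE) {
  s <- as.matrix(source_activity)
  parcellation <- as.integer(parcellation)
  if (length(parcellation) != nrow(s)) {
    stop_invalid("parcellation labels %d sources but activity has %d rows",
                 length(parcellation), nrow(s))
  }
  n_roi <- max(parcellation)
  counts <- tabulate(parcellation, n_roi)
  if (any(counts == 0)) {
    stop_invalid("parcellation has empty ROI(s): %s",
                 paste(which(counts == 0), collapse = ", "))
  }
  if (sign_flip) {
    for (r in seq_len(n_roi)) {
      idx <- which(parcellation == r)
      if (length(idx) > 1) {
        m <- colMeans(s[idx, , drop = FALSE])
        flip <- vapply(idx, function(i) {
          cc <- suppressWarnings(stats::cor(s[i, ], m))
          !is.na(cc) && cc < 0
        }, logical(1))
        s[idx[flip], ] <- -s[idx[flip], ]
      }
    }
  }
  values <- rowsum(s, parcellation) / counts
  rownames(values) <- paste0("ROI", seq_len(n_roi))
  structure(list(values = values, roi_ids = seq_len(n_roi), fs = fs),
            class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("ROI time series: %d ROIs x %d samples @ %s Hz\n",
              nrow(x$values), ncol(x$values),
              if (is.na(x$fs)) "?" else format(x$fs)))
  invisible(x)
}
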