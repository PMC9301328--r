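# Condition-separability evaluation: network vectorization, 2-D embedding
# (PCA / exact t-SNE / classical MDS), k-means with best-permutation F1, and
# TRF time-window clustering.

#' Vectorize a symmetric connectivity matrix
#'
#' Upper triangle excluding the diagonal, row-major order, so a 68 x 68
#' network becomes a 2,278-dimensional feature vector.
#'
#' @param connectivity `connectivity_matrix` or symmetric matrix (asymmetry
#'   beyond 1e-10 is an error).
#' @return numeric vector of length `n(n-1)/2`.
#' @export
vectorize_network <- function(connectivity) {
  C <- conn_values(connectivity)
  if (max(abs(C - t(C)), na.rm = TRUE) > 1e-10) {
    stop_invalid("matrix is not symmetric within 1e-10")
  }
  t(C)[lower.tri(C)] # row-major upper triangle
}

#' Rebuild a symmetric matrix from its vectorized upper triangle
#'
#' Inverse of [vectorize_network()]; the diagonal is set to 1.
#'
#' @param v vector of length `n(n-1)/2`.
#' @param n matrix dimension.
#' @return n x n symmetric matrix.
#' @export
unvectorize_network <- function(v, n) {
  if (length(v) != edge_count(n)) {
    stop_invalid("vector length %d does not match n = %d (expected %d)",
                 length(v), n, edge_count(n))
  }
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v # fills column-major lower = row-major upper transposed
  m <- t(m)
  m <- m + t(m)
  diag(m) <- 1
  m
}

#' Embed trial feature vectors in two dimensions
#'
#' `"pca"` (deterministic, the default): scores on the top-2 principal
#' components with a sign convention fixed by the largest-magnitude loading.
#' `"tsne"`: exact (dense) t-distributed stochastic neighbor embedding,
#' deterministic given `seed`.  `"mds"`: classical metric MDS.
#'
#' @param features trials x features numeric matrix.
#' @param method `"pca"`, `"tsne"`, or `"mds"`.
#' @param seed integer seed (t-SNE initialization).
#' @param perplexity t-SNE perplexity; must be below the number of trials.
#' @return trials x 2 coordinate matrix.
#' @export
embed_2d <- function(features, method = c("pca", "tsne", "mds"), seed = 1,
                     perplexity = 10) {
  method <- match.arg(method)
  x <- as.matrix(features)
  n <- nrow(x)
  if (method == "tsne" && n < 5) {
    stop_invalid("t-SNE needs at least 5 trials, got %d", n)
  }
  if (method == "tsne" && perplexity >= n) {
    stop_invalid("perplexity (%g) must be below the number of trials (%d)",
                 perplexity, n)
  }
  switch(method,
    pca = {
      xc <- sweep(x, 2, colMeans(x))
      sv <- svd(xc, nu = 2, nv = 2)
      scores <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
      for (j in 1:2) { # sign convention: largest-|.| loading positive
        v <- sv$v[, j]
        if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
      }
      scores
    },
    mds = stats::cmdscale(stats::dist(x), k = 2),
    tsne = tsne_exact(x, perplexity = perplexity, seed = seed)
  )
}

# Exact (dense) t-SNE; fine for the tens-of-trials problems used here.
tsne_exact <- function(x, perplexity = 10, seed = 1, n_iter = 500,
                       eta = 100, early_exaggeration = 4) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  # per-point precision by binary search on the perplexity
  P <- matrix(0, n, n)
  log_perp <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p[] <- 1 / length(p) else p <- p / sp
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - log_perp) < 1e-5) break
      if (h > log_perp) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    for (it in seq_len(n_iter)) {
      Pe <- if (it <= 100) P * early_exaggeration else P
      num <- 1 / (1 + as.matrix(stats::dist(y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% y
      momentum <- if (it < 250) 0.5 else 0.8
      inc <- momentum * inc - eta * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    y
  })
}

#' Mean best-permutation F1 of repeated k-means against known labels
#'
#' Runs `n_reps` k-means clusterings with random initial centers on the
#' embedded coordinates, scores each against the true binary labels with the
#' F1 of the cluster-to-label assignment maximizing F1, and returns the mean.
#' Chance level of this best-permutation score is above 0.5 and is calibrated
#' empirically rather than assumed.
#'
#' @param embedded trials x d coordinate matrix.
#' @param true_labels binary condition labels (two classes).
#' @param k number of clusters (default 2; only 2 is supported).
#' @param n_reps k-means repetitions (default 1000).
#' @param seed integer seed.
#' @return mean F1 over repetitions.
#' @export
kmeans_f1 <- function(embedded, true_labels, k = 2, n_reps = 1000, seed = 1) {
  x <- as.matrix(embedded)
  labs <- as.factor(true_labels)
  if (nlevels(labs) < 2) stop_invalid("true_labels must contain two classes")
  if (nlevels(labs) != 2 || k != 2) {
    stop_invalid("kmeans_f1 supports the two-condition case only")
  }
  if (length(labs) != nrow(x)) {
    stop_invalid("labels (%d) do not match the embedding rows (%d)",
                 length(labs), nrow(x))
  }
  truth <- as.integer(labs) # 1/2
  with_seed(seed, {
    f1s <- vapply(seq_len(n_reps), function(rep) {
      km <- tryCatch(
        stats::kmeans(x, centers = k, iter.max = 100, nstart = 1),
        error = function(e) NULL)
      if (is.null(km)) return(NA_real_)
      best_permutation_f1(km$cluster, truth)
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  })
}

# F1 = 2TP / (2TP + FP + FN), maximized over the two cluster-to-label maps
best_permutation_f1 <- function(cluster, truth) {
  f1_of <- function(pred) {
    tp <- sum(pred == 1 & truth == 1)
    fp <- sum(pred == 1 & truth == 2)
    fn <- sum(pred == 2 & truth == 1)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  max(f1_of(cluster), f1_of(3L - cluster))
}

#' Condition separability of TRF amplitudes per time window
#'
#' For each lag window, per-trial features are the per-ROI mean TRF
#' amplitudes in the window; the features are embedded in 2-D and scored by
#' [kmeans_f1()] against the condition labels.
#'
#' @param trf_trials list of per-trial ROI x lag TRF weight matrices (or
#'   `trf_model` objects).
#' @param condition_labels per-trial condition labels (two classes).
#' @param lags_ms lag grid matching the TRF columns.
#' @param windows_ms list of length-2 windows (default the 0-150, 150-300,
#'   300-450, 450-600 ms grid).
#' @param method,seed,perplexity,n_reps passed to [embed_2d()] and
#'   [kmeans_f1()].
#' @return named numeric vector of F1 values, one per window.
#' @export
window_cluster <- function(trf_trials, condition_labels, lags_ms = NULL,
                           windows_ms = list(c(0, 150), c(150, 300),
                                             c(300, 450), c(450, 600)),
                           method = "pca", seed = 1, perplexity = 10,
                           n_reps = 1000) {
  mats <- lapply(trf_trials, function(m) {
    if (inherits(m, "trf_model")) m$weights else as.matrix(m)
  })
  if (is.null(lags_ms)) {
    lags_ms <- trf_trials[[1]]$lags_ms
    if (is.null(lags_ms)) stop_invalid("lags_ms is required")
  }
  for (w in windows_ms) {
    if (w[1] < min(lags_ms) || w[2] > max(lags_ms)) {
      stop_invalid("window [%g, %g] ms is outside the lag grid", w[1], w[2])
    }
  }
  out <- vapply(seq_along(windows_ms), function(wi) {
    w <- windows_ms[[wi]]
    idx <- lags_ms >= w[1] & lags_ms <= w[2]
    feats <- t(vapply(mats, function(m) rowMeans(m[, idx, drop = FALSE]),
                      numeric(nrow(mats[[1]]))))
    emb <- embed_2d(feats, method = method, seed = derive_seed(seed, wi),
                    perplexity = perplexity)
    kmeans_f1(emb, condition_labels, n_reps = n_reps,
              seed = derive_seed(seed, 1000 + wi))
  }, numeric(1))
  names(out) <- vapply(windows_ms, function(w) sprintf("%g-%g ms", w[1], w[2]),
                       character(1))
  out
}

#' Correlation between two ROIs' TRF lag-courses over a lag range
#'
#' The inter-regional coupling statistic: Pearson correlation between two
#' TRF kernels restricted to `lag_range_ms`.
#'
#' @param trf_a,trf_b numeric kernels on a shared lag grid.
#' @param lags_ms the lag grid.
#' @param lag_range_ms length-2 range (default: the full grid).
#' @return Pearson r, or `NA` with a warning for degenerate variance.
#' @export
coupling_correlation <- function(trf_a, trf_b, lags_ms,
                                 lag_range_ms = range(lags_ms)) {
  if (length(trf_a) != length(lags_ms) || length(trf_b) != length(lags_ms)) {
    stop_invalid("kernels must share the lag grid")
  }
  idx <- lags_ms >= lag_range_ms[1] & lags_ms <= lag_range_ms[2]
  a <- trf_a[idx]
  b <- trf_b[idx]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("degenerate variance in a TRF lag-course; coupling is NA")
    return(NA_real_)
  }
  stats::cor(a, b)
}
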