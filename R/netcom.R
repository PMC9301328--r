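# TRF-correlation brain networks: Pearson connectivity between ROI kernels,
# density thresholding with sign retention, and community detection by
# Louvain optimization of the asymmetric signed modularity
# Q = Q+ - (v-/(v+ + v-)) Q-, where Q+/Q- are Newman modularities of the
# positive/negative subnetworks and v+/v- their total weights.

#' TRF-correlation connectivity matrix
#'
#' Pairwise Pearson correlation between the ROIs' TRF lag-courses over the
#' full lag grid.  Zero-variance rows get missing correlations (with a
#' warning); more than 10% degenerate rows is an error.
#'
#' @param trf_model a [fit_encoder()] model, or an ROI x lag weight matrix.
#' @return object of class `connectivity_matrix`: symmetric `values` with
#'   unit diagonal, `roi_ids`.
#' @export
trf_connectivity <- function(trf_model) {
  w <- if (inherits(trf_model, "trf_model")) trf_model$weights else as.matrix(trf_model)
  if (nrow(w) < 2) stop_invalid("connectivity needs at least 2 ROIs")
  if (ncol(w) < 3) stop_invalid("connectivity needs at least 3 lag points")
  sds <- apply(w, 1, stats::sd)
  degenerate <- sds == 0
  if (mean(degenerate) > 0.1) {
    stop_invalid("more than 10%% of TRF rows have zero variance (%d of %d)",
                 sum(degenerate), nrow(w))
  }
  if (any(degenerate)) {
    warning(sprintf("%d zero-variance TRF row(s); correlations set to NA",
                    sum(degenerate)))
  }
  values <- suppressWarnings(stats::cor(t(w)))
  values[degenerate, ] <- NA_real_
  values[, degenerate] <- NA_real_
  diag(values) <- 1
  structure(list(values = values,
                 roi_ids = rownames(w) %||% paste0("ROI", seq_len(nrow(w)))),
            class = "connectivity_matrix")
}

conn_values <- function(x) {
  if (inherits(x, "connectivity_matrix")) x$values else as.matrix(x)
}

#' Number of undirected edges of a complete graph
#'
#' `n (n - 1) / 2`; a 68-node network has 2,278 pairwise links.
#'
#' @param n_nodes node count (>= 2).
#' @return edge count.
#' @export
#' @examples
#' edge_count(68) # 2278
edge_count <- function(n_nodes) {
  if (!is.numeric(n_nodes) || n_nodes < 2) {
    stop_invalid("edge_count needs at least 2 nodes")
  }
  n_nodes * (n_nodes - 1) / 2
}

#' Threshold a connectivity matrix to a target edge density
#'
#' Keeps the `ceiling(t * E)` upper-triangle edges of largest absolute
#' weight (`E = n(n-1)/2`), zeroing the rest; signs are retained, or mapped
#' to +/-1 when `binarize = TRUE`.  Ties at the cutoff are broken by (row,
#' column) lexicographic order, so the result is deterministic.
#'
#' @param connectivity `connectivity_matrix` or symmetric matrix.
#' @param t target density in (0, 1].
#' @param binarize replace retained weights by their sign (default `FALSE`).
#' @return object of class `thresholded_graph`: sparse signed `values`
#'   (dense storage, zero diagonal), `density`, `binarized`, `n_edges`.
#' @export
threshold_density <- function(connectivity, t, binarize = FALSE) {
  if (!is.numeric(t) || t <= 0 || t > 1) {
    stop_invalid("density t must lie in (0, 1], got %s", format(t))
  }
  C <- conn_values(connectivity)
  n <- nrow(C)
  m <- ceiling(t * edge_count(n))
  ut <- which(upper.tri(C), arr.ind = TRUE)
  vals <- C[ut]
  ord <- order(-abs(vals), ut[, 1], ut[, 2], na.last = TRUE)
  keep <- ord[seq_len(m)]
  W <- matrix(0, n, n, dimnames = dimnames(C))
  kept_vals <- vals[keep]
  kept_vals[is.na(kept_vals)] <- 0
  if (binarize) kept_vals <- sign(kept_vals)
  W[ut[keep, , drop = FALSE]] <- kept_vals
  W <- W + t(W)
  structure(list(values = W, density = t, binarized = binarize, n_edges = m),
            class = "thresholded_graph")
}

graph_values <- function(x) {
  if (inherits(x, "thresholded_graph")) x$values else as.matrix(x)
}

#' Signed modularity of a partition
#'
#' `Q = Q+ - (v- / (v+ + v-)) Q-`, the asymmetric signed quality index:
#' positive within-community weight is rewarded at full strength while
#' negative within-community weight is penalized in proportion to its share
#' of total weight.  `Q+`/`Q-` are Newman-style modularities of the positive
#' and negative subnetworks with resolution `gamma` scaling the null term.
#'
#' @param graph `thresholded_graph` or symmetric weight matrix (zero
#'   diagonal).
#' @param partition integer community labels covering all nodes.
#' @param gamma resolution parameter (default 1).
#' @return scalar Q.
#' @export
modularity_signed <- function(graph, partition, gamma = 1) {
  W <- graph_values(graph)
  n <- nrow(W)
  if (length(partition) != n) {
    stop_invalid("partition labels %d nodes but the graph has %d",
                 length(partition), n)
  }
  Wp <- pmax(W, 0)
  Wn <- -pmin(W, 0)
  vp <- sum(Wp)
  vn <- sum(Wn)
  if (vp + vn == 0) stop_invalid("graph has zero total weight")
  part_q <- function(Ws, v) {
    if (v == 0) return(0)
    k <- rowSums(Ws)
    q <- 0
    for (c in unique(partition)) {
      idx <- partition == c
      q <- q + sum(Ws[idx, idx]) / v - gamma * (sum(k[idx]) / v)^2
    }
    q
  }
  part_q(Wp, vp) - vn / (vp + vn) * part_q(Wn, vn)
}

# modularity matrix M such that Q = sum_ij M_ij [c_i == c_j]
signed_modularity_matrix <- function(W, gamma) {
  Wp <- pmax(W, 0)
  Wn <- -pmin(W, 0)
  vp <- sum(Wp)
  vn <- sum(Wn)
  if (vp + vn == 0) stop_invalid("graph has zero total weight")
  M <- matrix(0, nrow(W), ncol(W))
  if (vp > 0) {
    kp <- rowSums(Wp)
    M <- M + Wp / vp - gamma * tcrossprod(kp) / vp^2
  }
  if (vn > 0) {
    kn <- rowSums(Wn)
    M <- M - vn / (vp + vn) * (Wn / vn - gamma * tcrossprod(kn) / vn^2)
  }
  (M + t(M)) / 2
}

# one greedy Louvain pass on a (possibly aggregated) modularity matrix
louvain_on_matrix <- function(M) {
  n <- nrow(M)
  labels <- seq_len(n)
  improved_any <- FALSE
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      li <- labels[i]
      # gain of joining community c: 2 * sum_{j in c, j != i} M_ij
      s <- rowsum(M[i, -i, drop = TRUE],
                  labels[-i]) # sum of M[i, j] by community, excluding i
      cand <- as.integer(rownames(s))
      gain <- 2 * s[, 1]
      stay <- if (li %in% cand) gain[match(li, cand)] else 0
      best <- which.max(gain)
      if (gain[best] > stay + 1e-12 && cand[best] != li) {
        labels[i] <- cand[best]
        improved <- TRUE
        improved_any <- TRUE
      }
    }
    if (!improved) break
  }
  list(labels = relabel_partition(labels), improved = improved_any)
}

louvain_once <- function(M) {
  n <- nrow(M)
  node_labels <- seq_len(n)
  Mcur <- M
  repeat {
    res <- louvain_on_matrix(Mcur)
    labels <- res$labels
    if (!res$improved || length(unique(labels)) == nrow(Mcur)) {
      node_labels <- labels[node_labels]
      break
    }
    node_labels <- labels[node_labels]
    # aggregate communities into super-nodes
    k <- max(labels)
    agg <- matrix(0, k, k)
    for (a in seq_len(k)) {
      ia <- labels == a
      for (b in seq_len(k)) {
        agg[a, b] <- sum(Mcur[ia, labels == b, drop = FALSE])
      }
    }
    if (k == 1) break
    Mcur <- agg
  }
  relabel_partition(node_labels)
}

#' Detect communities by signed-modularity Louvain optimization
#'
#' Greedy Louvain optimization of the asymmetric signed modularity with
#' `n_runs` random restarts (randomized node sweep order); the best-Q
#' partition is returned, and never one worse than the single-community
#' baseline.  Deterministic given `seed`.
#'
#' @param graph `thresholded_graph` or symmetric weight matrix.
#' @param gamma resolution parameter (default 1).
#' @param n_runs random restarts (default 100).
#' @param seed integer seed.
#' @return object of class `partition`: `labels` (contiguous ids from 1),
#'   `n_communities`, `quality` (Q of the returned labels), `gamma`.
#' @export
detect_communities <- function(graph, gamma = 1, n_runs = 100, seed = 1) {
  if (n_runs < 1) stop_invalid("n_runs must be at least 1")
  W <- graph_values(graph)
  if (nrow(W) == 0 || all(W == 0)) {
    stop_invalid("empty graph: nothing to partition")
  }
  M <- signed_modularity_matrix(W, gamma)
  best_labels <- rep(1L, nrow(W))
  best_q <- modularity_signed(W, best_labels, gamma) # single-community baseline
  with_seed(seed, {
    for (run in seq_len(n_runs)) {
      labels <- louvain_once(M)
      q <- modularity_signed(W, labels, gamma)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_labels <- labels
      }
    }
  })
  structure(list(labels = relabel_partition(best_labels),
                 n_communities = length(unique(best_labels)),
                 quality = best_q, gamma = gamma),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d communities over %d nodes, Q = %.4f (gamma %g)\n",
              x$n_communities, length(x$labels), x$quality, x$gamma))
  invisible(x)
}

#' Fisher-z average of per-trial connectivity matrices
#'
#' Condition-level network: mean of `atanh`-transformed trial matrices,
#' mapped back through `tanh`.  Correlations at +/-1 are clipped just inside
#' the open interval before transforming.
#'
#' @param matrices list of `connectivity_matrix` objects or matrices.
#' @return `connectivity_matrix`.
#' @export
average_connectivity <- function(matrices) {
  vals <- lapply(matrices, conn_values)
  z <- lapply(vals, function(v) atanh(pmin(pmax(v, -1 + 1e-12), 1 - 1e-12)))
  avg <- tanh(Reduce(`+`, z) / length(z))
  diag(avg) <- 1
  structure(list(values = avg,
                 roi_ids = rownames(avg) %||% paste0("ROI", seq_len(nrow(avg)))),
            class = "connectivity_matrix")
}
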