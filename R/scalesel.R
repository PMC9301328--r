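# Multi-scale selection: variation of information between partitions,
# density scanning, and the joint (partition-stability + separability)
# scale-selection rule.

#' Variation of information between two partitions
#'
#' Plug-in estimate from the co-membership confusion table, in nats:
#' `VI = H(X) + H(Y) - 2 I(X;Y)`, computed in the numerically exact form
#' `sum_ij p_ij [log(p_i / p_ij) + log(p_j / p_ij)]` whose terms are each
#' nonnegative, so identical partitions give exactly zero.
#'
#' @param p1,p2 label vectors (or `partition` objects) over the same node
#'   set.
#' @return object of class `partition_comparison`: list with `H_X`, `H_Y`,
#'   `I_XY`, `VI` (all in nats).
#' @export
#' @examples
#' variation_of_information(c(1, 1, 2, 2), c(1, 1, 2, 2))$VI # 0
variation_of_information <- function(p1, p2) {
  if (inherits(p1, "partition")) p1 <- p1$labels
  if (inherits(p2, "partition")) p2 <- p2$labels
  if (length(p1) != length(p2)) {
    stop_invalid("partitions must cover the same node set (%d vs %d nodes)",
                 length(p1), length(p2))
  }
  n <- length(p1)
  tab <- table(p1, p2)
  pij <- unname(unclass(tab / n))
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  h1 <- -sum(pi_ * log(pi_))
  h2 <- -sum(p_j * log(p_j))
  vi <- 0
  for (a in seq_along(pi_)) {
    for (b in seq_along(p_j)) {
      if (pij[a, b] > 0) {
        vi <- vi + pij[a, b] * (log(pi_[a] / pij[a, b]) +
                                log(p_j[b] / pij[a, b]))
      }
    }
  }
  structure(list(H_X = h1, H_Y = h2, I_XY = (h1 + h2 - vi) / 2, VI = vi),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf("VI = %.4f nats (H_X %.4f, H_Y %.4f, I %.4f)\n",
              x$VI, x$H_X, x$H_Y, x$I_XY))
  invisible(x)
}

#' Scan a density grid: threshold, detect, track Q and partition stability
#'
#' For every density in `t_grid` the connectivity matrix is thresholded,
#' communities are detected by signed-modularity Louvain, and the modularity
#' `Q_d` and partition are recorded.  The VI curve holds the variation of
#' information between the partitions at consecutive densities (length
#' `length(t_grid) - 1`): low VI marks a range of scales over which the
#' community structure is stable.
#'
#' @param connectivity `connectivity_matrix` or symmetric matrix.
#' @param t_grid density grid in (0, 1] (default 0.01-0.50, step 0.01).
#' @param gamma resolution parameter (default 1).
#' @param n_runs Louvain restarts per density (default 100).
#' @param seed integer seed; each density gets a derived seed.
#' @return object of class `density_scan`: `densities`, `partitions` (list),
#'   `Q_d`, `n_communities`, `VI` (consecutive), and an empty `F1` slot a
#'   caller can fill from a separability analysis.
#' @export
scan_densities <- function(connectivity, t_grid = seq(0.01, 0.5, by = 0.01),
                           gamma = 1, n_runs = 100, seed = 1) {
  if (any(t_grid <= 0 | t_grid > 1)) {
    stop_invalid("all densities must lie in (0, 1]")
  }
  nt <- length(t_grid)
  partitions <- vector("list", nt)
  qd <- numeric(nt)
  ncom <- integer(nt)
  for (k in seq_len(nt)) {
    part <- tryCatch({
      g <- threshold_density(connectivity, t_grid[k])
      detect_communities(g, gamma = gamma, n_runs = n_runs,
                         seed = derive_seed(seed, k))
    }, error = function(e) {
      stop(sprintf("density scan failed at t = %g: %s", t_grid[k],
                   conditionMessage(e)), call. = FALSE)
    })
    partitions[[k]] <- part$labels
    qd[k] <- part$quality
    ncom[k] <- part$n_communities
  }
  vi <- vapply(seq_len(nt - 1), function(k) {
    variation_of_information(partitions[[k]], partitions[[k + 1]])$VI
  }, numeric(1))
  structure(list(densities = t_grid, partitions = partitions, Q_d = qd,
                 n_communities = ncom, VI = vi, F1 = NULL, gamma = gamma),
            class = "density_scan")
}

#' @export
print.density_scan <- function(x, ...) {
  cat(sprintf("Density scan: %d densities in [%g, %g], Q_d in [%.3f, %.3f]\n",
              length(x$densities), min(x$densities), max(x$densities),
              min(x$Q_d), max(x$Q_d)))
  invisible(x)
}

#' Select the optimal network scale from a density scan
#'
#' Joint rule: among the densities whose condition-separability F1 is within
#' `f1_tol` of the maximum, return the one minimizing the partition-
#' instability VI; ties go to the smallest density.  Each density's VI value
#' is the variation of information to the preceding density's partition (the
#' first density inherits the first curve value).  An empty feasible set
#' falls back to the global VI minimum with a warning.
#'
#' @param scan a [scan_densities()] result.
#' @param f1_curve per-density F1 values aligned with `scan$densities`
#'   (default: the scan's `F1` slot; `NULL` makes every density feasible).
#' @param f1_tol tolerance below the F1 maximum (default 0.02).
#' @return list with `density`, `index`, `vi`, `f1`, `partition`, `Q`.
#' @export
select_scale <- function(scan, f1_curve = scan$F1, f1_tol = 0.02) {
  nd <- length(scan$densities)
  if (!is.null(f1_curve) && length(f1_curve) != nd) {
    stop_invalid("f1_curve (%d values) is not aligned with the scan (%d densities)",
                 length(f1_curve), nd)
  }
  vi_at <- c(scan$VI[1], scan$VI) # VI to the preceding density
  feasible <- if (is.null(f1_curve)) {
    rep(TRUE, nd)
  } else if (all(is.na(f1_curve))) {
    rep(FALSE, nd) # empty feasible set -> fallback below
  } else {
    !is.na(f1_curve) & f1_curve >= max(f1_curve, na.rm = TRUE) - f1_tol
  }
  if (!any(feasible)) {
    warning("no density satisfies the F1 condition; falling back to the global VI minimum")
    feasible <- rep(TRUE, nd)
  }
  idx_f <- which(feasible)
  best <- idx_f[which.min(vi_at[idx_f])] # which.min: ties -> smallest density
  list(density = scan$densities[best], index = best, vi = vi_at[best],
       f1 = if (is.null(f1_curve)) NA_real_ else f1_curve[best],
       partition = scan$partitions[[best]], Q = scan$Q_d[best])
}
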