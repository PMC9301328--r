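# Network construction and community detection: Pearson connectivity
# against the textbook formula, deterministic density thresholding against a
# sort-and-slice oracle, and the signed modularity / Louvain pair against
# exhaustive partition enumeration.

test_that("TRF connectivity equals the textbook Pearson formula on a toy", {
  set.seed(61)
  w <- matrix(rnorm(4 * 10), 4, 10)
  C <- trf_connectivity(w)$values
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:4) for (j in 1:4) {
    if (i != j) expect_equal(C[i, j], pearson(w[i, ], w[j, ]), tolerance = 1e-12)
  }
  expect_equal(diag(C), rep(1, 4))

  # identical rows -> all 1; negated row -> -1
  same <- trf_connectivity(matrix(rep(w[1, ], 3), 3, byrow = TRUE) +
                             0)$values
  expect_true(all(abs(same - 1) < 1e-12))
  opp <- trf_connectivity(rbind(w[1, ], -w[1, ]))$values
  expect_equal(opp[1, 2], -1)

  expect_warning(trf_connectivity(rbind(matrix(rnorm(190), 19, 10),
                                        numeric(10))), "zero-variance")
  expect_error(trf_connectivity(rbind(w[1:2, ], numeric(10))), "10%")
  expect_error(trf_connectivity(w[1, , drop = FALSE]), "at least 2")
  expect_error(trf_connectivity(w[, 1:2]), "at least 3")
})

test_that("edge counts follow n(n-1)/2", {
  expect_equal(edge_count(68), 2278)
  expect_equal(edge_count(2), 1)
  expect_equal(edge_count(10), nrow(t(combn(10, 2)))) # enumeration
  expect_error(edge_count(1), "at least 2")
})

test_that("density thresholding keeps exactly the strongest edges, signed", {
  set.seed(62)
  C <- matrix(rnorm(64), 8, 8)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  g <- threshold_density(C, 0.3)
  m <- ceiling(0.3 * 28)
  expect_equal(sum(g$values[upper.tri(g$values)] != 0), m)
  expect_equal(g$values, t(g$values))
  # retained set equals the sort-and-slice oracle
  ut <- which(upper.tri(C), arr.ind = TRUE)
  ord <- order(-abs(C[ut]))
  oracle_kept <- ut[ord[1:m], ]
  kept <- which(upper.tri(C) & g$values != 0, arr.ind = TRUE)
  expect_setequal(paste(kept[, 1], kept[, 2]),
                  paste(oracle_kept[, 1], oracle_kept[, 2]))
  # signs preserved; binarize maps to +-1
  expect_true(all(sign(g$values[g$values != 0]) ==
                    sign(C[g$values != 0])))
  gb <- threshold_density(C, 0.3, binarize = TRUE)
  expect_setequal(unique(gb$values[gb$values != 0]), c(-1, 1))

  # full density keeps everything; 0.14 on 68 nodes keeps 319 edges
  expect_equal(threshold_density(C, 1)$n_edges, 28)
  C68 <- matrix(rnorm(68^2), 68); C68 <- (C68 + t(C68)) / 2; diag(C68) <- 1
  expect_equal(threshold_density(C68, 0.14)$n_edges, 319)
  expect_error(threshold_density(C, 0), "density")
  expect_error(threshold_density(C, 1.2), "density")
})

test_that("signed modularity matches Newman identities and the enumeration oracle", {
  # all-positive complete graph, one community -> exactly 0
  K <- matrix(1, 5, 5); diag(K) <- 0
  expect_equal(modularity_signed(K, rep(1, 5)), 0)
  # two disconnected positive cliques, correct split -> 0.5
  W <- matrix(0, 8, 8); W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  expect_equal(modularity_signed(W, rep(1:2, each = 4)), 0.5)
  expect_error(modularity_signed(matrix(0, 3, 3), rep(1, 3)), "zero total")

  # exhaustive oracle equivalence on a 6-node signed toy, all 203 partitions
  set.seed(63)
  S <- matrix(rnorm(36), 6, 6); S <- (S + t(S)) / 2; diag(S) <- 0
  for (labels in all_partitions(6)) {
    expect_equal(modularity_signed(S, labels),
                 modularity_signed_oracle(S, labels), tolerance = 1e-9)
  }
})

test_that("Louvain recovers unambiguous and planted signed structure", {
  W <- matrix(0, 8, 8); W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  for (seed in 1:3) {
    p <- detect_communities(W, n_runs = 5, seed = seed)
    expect_equal(adjusted_rand_index(p$labels, rep(1:2, each = 4)), 1)
    expect_equal(p$quality, 0.5)
  }

  # planted 4-block signed matrix: within +0.8, between -0.2
  lab <- rep(1:4, each = 10)
  Wb <- ifelse(outer(lab, lab, `==`), 0.8, -0.2)
  diag(Wb) <- 0
  p4 <- detect_communities(Wb, n_runs = 20, seed = 64)
  expect_equal(adjusted_rand_index(p4$labels, lab), 1)

  # returned Q is self-consistent and never below the single-community Q
  expect_equal(p4$quality, modularity_signed(Wb, p4$labels))
  set.seed(65)
  for (i in 1:5) {
    R <- matrix(rnorm(49), 7, 7); R <- (R + t(R)) / 2; diag(R) <- 0
    p <- detect_communities(R, n_runs = 10, seed = i)
    expect_gte(p$quality, modularity_signed(R, rep(1, 7)) - 1e-12)
    expect_equal(p$quality, modularity_signed(R, p$labels))
    # determinism given seed
    p2 <- detect_communities(R, n_runs = 10, seed = i)
    expect_identical(p$labels, p2$labels)
  }
  expect_error(detect_communities(matrix(0, 4, 4)), "empty graph")
  expect_error(detect_communities(Wb, n_runs = 0), "n_runs")
})

test_that("Fisher-z averaging of trial networks stays a valid correlation matrix", {
  set.seed(66)
  mats <- lapply(1:5, function(i) {
    m <- cor(matrix(rnorm(80), 10, 8))
    m
  })
  avg <- average_connectivity(mats)$values
  expect_equal(avg, t(avg))
  expect_true(all(avg >= -1 & avg <= 1))
  expect_equal(diag(avg), rep(1, 8))
  # averaging identical matrices is the identity operation
  same <- average_connectivity(mats[c(1, 1, 1)])$values
  expect_equal(same, mats[[1]], tolerance = 1e-8)
})
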