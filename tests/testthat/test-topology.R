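sym_weight_matrix <- function(n, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(n * n), n)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- list(sprintf("R%03d", 1:n), sprintf("R%03d", 1:n))
  W
}

test_that("sparsity grid defaults give 36 ordered thresholds", {
  g <- sparsity_grid()
  expect_length(g, 36)
  expect_equal(g[1], 0.05)
  expect_equal(g[36], 0.4)
  expect_true(all(diff(g) > 0))
  expect_error(sparsity_grid(start = 0.5, stop = 0.4), "start")
})

test_that("thresholding keeps exactly floor(S * N(N-1)/2) edges", {
  W5 <- sym_weight_matrix(5, 1)
  A <- threshold_by_sparsity(W5, 0.4)
  expect_equal(sum(A) / 2, 4)          # floor(0.4 * 10)
  W116 <- sym_weight_matrix(116, 2)
  A116 <- threshold_by_sparsity(W116, 0.05)
  # brute-force count oracle
  expect_equal(sum(A116) / 2, floor(0.05 * 116 * 115 / 2))
  expect_equal(sum(A116) / 2, 333)
  # saturation
  Afull <- threshold_by_sparsity(W5, 1)
  expect_equal(sum(Afull) / 2, 10)
  expect_equal(attr(Afull, "sparsity"), 1)
  expect_error(threshold_by_sparsity(W5, 0.01), "zero edges")
})

test_that("thresholding keeps the strongest edges with deterministic ties", {
  W <- sym_weight_matrix(6, 3)
  A <- threshold_by_sparsity(W, 0.2)   # 3 edges
  kept <- W[upper.tri(W)][A[upper.tri(A)] == 1]
  dropped <- W[upper.tri(W)][A[upper.tri(A)] == 0]
  expect_gte(min(kept), max(dropped))
  # exact ties resolve identically across calls
  Wt <- matrix(0.5, 4, 4); diag(Wt) <- 1
  expect_identical(threshold_by_sparsity(Wt, 0.5),
                   threshold_by_sparsity(Wt, 0.5))
})

test_that("global metrics match hand-enumerated small graphs", {
  K4 <- matrix(1, 4, 4) - diag(4)
  m <- clustering_and_paths(K4)
  expect_equal(m[c("Cp", "Lp", "Eg", "Eloc")],
               list(Cp = 1, Lp = 1, Eg = 1, Eloc = 1))
  # path graph 1-2-3: six ordered pairs, distances 1,1,1,1,2,2
  P3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  m <- clustering_and_paths(P3)
  expect_equal(m$Eg, 5 / 6)
  expect_equal(m$Lp, 6 / 5)
  expect_equal(m$Cp, 0)
  # star K1,4: no triangles; center adjacent to all
  S5 <- matrix(0, 5, 5); S5[1, 2:5] <- 1; S5 <- S5 + t(S5)
  m <- clustering_and_paths(S5)
  expect_equal(m$Cp, 0)
  expect_equal(m$nodal_efficiency[1], 1)
  expect_error(clustering_and_paths(rbind(c(0, 1), c(1, 0))), "3 nodes")
})

test_that("betweenness matches closed forms and the enumeration oracle", {
  S6 <- matrix(0, 6, 6); S6[1, 2:6] <- 1; S6 <- S6 + t(S6)
  expect_equal(betweenness_nodes(S6), c(10, 0, 0, 0, 0, 0))  # (5*4)/2
  K5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(betweenness_nodes(K5), rep(0, 5))
  ring6 <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring6[i, j] <- ring6[j, i] <- 1 }
  expect_equal(betweenness_nodes(ring6), rep(2, 6))
  expect_equal(betweenness_nodes(ring6), oracle_betweenness(ring6))
})

test_that("all graph metrics agree with the Floyd-Warshall oracle", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    A <- random_graph(n, p = runif(1, 0.25, 0.7))
    if (sum(A) < 2) next
    got <- clustering_and_paths(A)
    want <- oracle_global_metrics(A)
    expect_equal(got$Cp, want$Cp, tolerance = 1e-12)
    expect_equal(got$Eg, want$Eg, tolerance = 1e-12)
    expect_equal(got$Lp, want$Lp, tolerance = 1e-12)
    expect_equal(got$Eloc, want$Eloc, tolerance = 1e-12)
    expect_equal(got$nodal_efficiency, unname(want$nodal_efficiency),
                 tolerance = 1e-12)
    expect_equal(got$degree, unname(want$degree))
    expect_equal(betweenness_nodes(A), oracle_betweenness(A),
                 tolerance = 1e-9)
  }
})

test_that("rewired nulls preserve the degree sequence", {
  set.seed(44)
  A <- random_graph(20, 0.3)
  B <- rewired_null(A, seed = 9)
  expect_equal(rowSums(B), rowSums(A))
  expect_equal(sort(unique(as.vector(B))), c(0, 1))
  # complete graph admits no legal swap
  K6 <- matrix(1, 6, 6) - diag(6)
  expect_equal(unclass(rewired_null(K6, seed = 1)), unclass(K6),
               ignore_attr = TRUE)
})

test_that("lattice clustering exceeds its rewired nulls", {
  # ring lattice N=50, each node connected to 4 nearest neighbors
  n <- 50
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in 1:2) {
    j <- (i + s - 1) %% n + 1
    A[i, j] <- A[j, i] <- 1
  }
  cp_lattice <- clustering_and_paths(A)$Cp
  set.seed(7)
  cps <- replicate(20, clustering_and_paths(rewired_null(A))$Cp)
  expect_gt(cp_lattice, mean(cps))
})

test_that("small-world coefficients behave on reference graphs", {
  K6 <- matrix(1, 6, 6) - diag(6)
  sw <- small_world(K6, n_null = 5, seed = 2)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
  # Watts-Strogatz ring (N=100, k=6, p=0.05) is small-world: gamma > 1
  set.seed(10)
  g <- igraph::sample_smallworld(1, 100, 3, 0.05)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  sw <- small_world(A, n_null = 20, seed = 3)
  expect_gt(sw$gamma, 1)
  expect_equal(sw$sigma, sw$gamma / sw$lambda)
})

test_that("metric curves cover the grid with nested edge sets", {
  W <- sym_weight_matrix(20, 5)
  cv <- suppressMessages(metric_curves(W, n_null = 0))
  expect_equal(nrow(cv$global), 36)
  expect_equal(nrow(cv$nodal), 36 * 20)
  # nestedness: edges at S' < S are a subset of edges at S
  A1 <- threshold_by_sparsity(W, 0.1)
  A2 <- threshold_by_sparsity(W, 0.3)
  expect_true(all(A2[A1 == 1] == 1))
  # corollary: every node's degree curve is non-decreasing in S
  for (r in unique(cv$nodal$region)) {
    expect_true(all(diff(cv$nodal$degree[cv$nodal$region == r]) >= 0))
  }
})

test_that("AUC matches closed forms and the summation oracle", {
  g <- sparsity_grid()
  expect_equal(auc_trapz(rep(2, 36), g), 0.7, tolerance = 1e-12)
  expect_equal(auc_trapz(seq(0, 1, length.out = 36), g), 0.175,
               tolerance = 1e-12)
  set.seed(8)
  y <- rnorm(36)
  expect_equal(auc_trapz(y, g), oracle_trapz(y, as.numeric(g)),
               tolerance = 1e-12)
  expect_error(auc_trapz(1:10, g), "length")
})
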