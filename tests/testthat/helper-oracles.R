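# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph) so metric tests are genuine cross-checks.

# All-pairs shortest paths by Floyd-Warshall on a 0/1 adjacency matrix.
fw_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      di <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], di)
    }
  }
  d
}

# Global metrics recomputed from first principles.
oracle_global_metrics <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  cc <- vapply(seq_len(n), function(i) {
    k <- deg[i]
    if (k < 2) return(0)
    nb <- which(A[i, ] > 0)
    t_i <- sum(A[nb, nb]) / 2
    2 * t_i / (k * (k - 1))
  }, numeric(1))
  d <- fw_distances(A)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  eg <- sum(inv) / (n * (n - 1))
  nodal_eff <- rowSums(inv) / (n - 1)
  eloc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    ds <- fw_distances(A[nb, nb, drop = FALSE])
    invs <- ifelse(is.finite(ds) & ds > 0, 1 / ds, 0)
    sum(invs) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  list(Cp = mean(cc), Lp = 1 / eg, Eg = eg, Eloc = mean(eloc),
       nodal_efficiency = nodal_eff, degree = deg)
}

# Betweenness by explicit enumeration of all shortest paths (DFS over
# predecessor structure); feasible for the <= 12-node graphs used in tests.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  d <- fw_distances(A)
  # shortest-path counts via DP in order of distance from the source
  count_paths <- function(s) {
    sigma <- numeric(n)
    sigma[s] <- 1
    ord <- order(d[s, ])
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      preds <- which(A[v, ] > 0 & d[s, ] == d[s, v] - 1)
      sigma[v] <- sum(sigma[preds])
    }
    sigma
  }
  sig <- t(vapply(seq_len(n), count_paths, numeric(n)))
  bet <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      if (!is.finite(d[s, t]) || d[s, t] < 2) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          bet[v] <- bet[v] + sig[s, v] * sig[t, v] / sig[s, t]
        }
      }
    }
  }
  bet
}

# Direct-summation divergence oracles on probability vectors.
oracle_sym_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    s <- s + p[i] * log(p[i] / q[i]) + q[i] * log(q[i] / p[i])
  }
  s
}

oracle_jsd_base2 <- function(p, q) {
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log2(q[i] / m[i])
  }
  s
}

oracle_trapz <- function(y, x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# Partial correlation via the inverse-correlation-matrix identity.
oracle_partial_r <- function(x, y, Z) {
  R <- stats::cor(cbind(x, y, Z))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Random connected-ish test graph with no isolated structure guarantees.
random_graph <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- as.integer(stats::runif(length(ut)) < p)
  A + t(A)
}

# Small synthetic subject for similarity tests.
make_subject <- function(n_regions = 6, n_vox = 80, seed = 1) {
  set.seed(seed)
  rv <- lapply(seq_len(n_regions), function(r) {
    stats::rnorm(n_vox, mean = 0.3 + 0.05 * r, sd = 0.05 + 0.005 * r)
  })
  names(rv) <- sprintf("R%03d", seq_len(n_regions))
  list(subject_id = "S001", group = "patient", region_values = rv)
}

tiny_cohort <- function(n_per_group = 4, n_regions = 6, seed = 1,
                        effect_size = 0, effect_nodes = character(),
                        voxel_range = c(60, 120)) {
  generate_cohort(cohort_config(
    n_per_group = n_per_group, n_regions = n_regions,
    voxel_range = voxel_range, n_communities = min(3, n_regions),
    effect_nodes = effect_nodes, effect_size = effect_size, seed = seed))
}
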