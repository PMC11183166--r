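#' Sparsity threshold grid
#'
#' Ordered list of sparsity thresholds used to binarize weighted similarity
#' matrices. The defaults (0.05 to 0.4 in steps of 0.01) give 36 thresholds;
#' metric curves over this grid are summarized by their area under the
#' curve rather than a single arbitrary threshold.
#'
#' @param start,stop,step grid limits and spacing; `0 < start < stop <= 1`.
#' @return numeric vector of thresholds with class `sparsity_grid`.
#' @export
sparsity_grid <- function(start = 0.05, stop = 0.4, step = 0.01) {
  stopifnot(start > 0, start < stop, stop <= 1, step > 0)
  n <- round((stop - start) / step) + 1L
  structure(start + step * (seq_len(n) - 1L), class = "sparsity_grid")
}

#' Binarize a similarity matrix at a sparsity threshold
#'
#' Sparsity `S` is the ratio of retained edges to the `N(N-1)/2` possible
#' edges. The `floor(S * N(N-1)/2)` strongest off-diagonal entries are kept
#' (ties broken by ascending region-id pair order, so thresholding is
#' deterministic) and binarized; the diagonal is excluded.
#'
#' @param W symmetric similarity matrix (diagonal ignored).
#' @param S sparsity in (0, 1].
#' @return symmetric 0/1 adjacency matrix with zero diagonal, class
#'   `binary_graph`, attribute `sparsity` = realized edge fraction.
#' @export
threshold_by_sparsity <- function(W, S) {
  stopifnot(S > 0, S <= 1)
  n <- nrow(W)
  m <- n * (n - 1L) / 2
  k <- floor(S * m)
  if (k < 1) stop("sparsity ", S, " retains zero edges for N = ", n,
                  call. = FALSE)
  iu <- which(upper.tri(W))
  wi <- W[iu]
  rows <- row(W)[iu]; cols <- col(W)[iu]
  keep <- iu[order(-wi, rows, cols)][seq_len(k)]
  A <- matrix(0L, n, n, dimnames = dimnames(W))
  A[keep] <- 1L
  A <- A + t(A)
  structure(A, class = c("binary_graph", class(A)), sparsity = k / m)
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

#' Global clustering, path-length and efficiency metrics
#'
#' Computes, on an undirected binary graph: the mean local clustering
#' coefficient `Cp` (nodes with degree < 2 contribute 0), global efficiency
#' `Eg` (mean of `1/d_ij` over ordered pairs, with `1/Inf = 0`), the
#' characteristic path length `Lp = 1/Eg` (harmonic-mean convention, finite
#' on disconnected graphs), local efficiency `Eloc` (mean over nodes of the
#' global efficiency of the subgraph induced by each node's neighbors) and
#' the nodal efficiency vector `(1/(N-1)) * sum_j 1/d_ij`.
#'
#' @param A adjacency matrix (`binary_graph` or plain 0/1 matrix), N >= 3.
#' @return list with `Cp`, `Lp`, `Eg`, `Eloc`, `nodal_efficiency`, `degree`.
#' @export
clustering_and_paths <- function(A) {
  n <- nrow(A)
  if (n < 3) stop("graph must have at least 3 nodes", call. = FALSE)
  g <- graph_from_adj(A)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  eg <- sum(inv) / (n * (n - 1))
  nodal_eff <- rowSums(inv) / (n - 1)
  eloc_i <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    ds <- igraph::distances(igraph::induced_subgraph(g, nb))
    invs <- 1 / ds
    invs[!is.finite(invs)] <- 0
    diag(invs) <- 0
    sum(invs) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  list(Cp = mean(cc), Lp = 1 / eg, Eg = eg, Eloc = mean(eloc_i),
       nodal_efficiency = unname(nodal_eff), degree = unname(deg))
}

#' Nodal shortest-path betweenness
#'
#' Unnormalized betweenness: each unordered pair of distinct endpoints
#' contributes fractional credit across its equal-length shortest paths.
#'
#' @param A adjacency matrix.
#' @return numeric vector of per-node scores.
#' @export
betweenness_nodes <- function(A) {
  unname(igraph::betweenness(graph_from_adj(A), directed = FALSE))
}

#' Degree-preserving rewired null graph
#'
#' Randomizes the edge set by attempted double-edge swaps while preserving
#' every node's degree exactly; used as the normalization reference for the
#' small-world coefficients.
#'
#' @param A adjacency matrix.
#' @param n_swap_multiple attempted swaps per edge (default 10).
#' @param seed optional seed.
#' @return rewired `binary_graph` adjacency matrix.
#' @export
rewired_null <- function(A, n_swap_multiple = 10, seed = NULL) {
  g <- graph_from_adj(A)
  m <- igraph::ecount(g)
  if (m < 2) {
    warning("graph too small to rewire; returning a copy")
    return(A)
  }
  with_seed(seed, {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swap_multiple * m))
    B <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
    dimnames(B) <- dimnames(A)
    structure(B, class = c("binary_graph", class(B)),
              sparsity = attr(A, "sparsity"))
  })
}

#' Small-world coefficients against rewired nulls
#'
#' `gamma = Cp / mean(Cp of n_null rewired graphs)`, `lambda = Lp /
#' mean(Lp of nulls)` and `sigma = gamma / lambda`. A graph is
#' small-world when `gamma > 1` with `lambda` near 1 (`sigma > 1`).
#'
#' @param A adjacency matrix.
#' @param n_null number of rewired null graphs (default 100).
#' @param seed optional seed.
#' @param n_swap_multiple attempted swaps per edge in each null.
#' @return list with `gamma`, `lambda`, `sigma`, `Cp`, `Lp`.
#' @export
small_world <- function(A, n_null = 100, seed = NULL, n_swap_multiple = 10) {
  n <- nrow(A)
  if (n < 3) stop("graph must have at least 3 nodes", call. = FALSE)
  g <- graph_from_adj(A)
  # only Cp and Lp are normalized; computing them directly avoids the
  # local-efficiency work clustering_and_paths() would also do
  cp_lp <- function(gr) {
    cp <- mean(igraph::transitivity(gr, type = "local", isolates = "zero"))
    d <- igraph::distances(gr)
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    c(cp, 1 / (sum(inv) / (n * (n - 1))))
  }
  base_v <- cp_lp(g)
  base <- list(Cp = base_v[1], Lp = base_v[2])
  with_seed(seed, {
    cps <- numeric(n_null); lps <- numeric(n_null)
    m <- igraph::ecount(g)
    for (b in seq_len(n_null)) {
      g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swap_multiple * m))
      v <- cp_lp(g2)
      cps[b] <- v[1]
      lps[b] <- v[2]
    }
    mc <- mean(cps); ml <- mean(lps)
    if (mc <= 0 || ml <= 0 || !is.finite(mc) || !is.finite(ml)) {
      stop("degenerate null means; cannot normalize", call. = FALSE)
    }
    gamma <- base$Cp / mc
    lambda <- base$Lp / ml
    list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
         Cp = base$Cp, Lp = base$Lp)
  })
}

#' Metric curves over the sparsity grid
#'
#' Thresholds a similarity matrix at every sparsity in the grid and
#' evaluates the global metrics (Cp, Lp, gamma, lambda, sigma, Eg, Eloc)
#' and nodal metrics (degree, efficiency, betweenness). Thresholds where
#' `sigma <= 1` (failing the small-world screen) are reported via a
#' message. With `n_null = 0` the normalized coefficients are skipped
#' (returned as `NA`), which is much faster when only nodal metrics or raw
#' global metrics are needed.
#'
#' @param W similarity matrix.
#' @param grid a [sparsity_grid()].
#' @param n_null rewired nulls per threshold for gamma/lambda/sigma.
#' @param seed optional seed for the null models.
#' @param n_swap_multiple attempted swaps per edge in each null.
#' @return list with `global` (data.frame: threshold + 7 metrics) and
#'   `nodal` (long data.frame: threshold, region, degree, efficiency,
#'   betweenness).
#' @export
metric_curves <- function(W, grid = sparsity_grid(), n_null = 100,
                          seed = NULL, n_swap_multiple = 10) {
  regions <- rownames(W) %||% as.character(seq_len(nrow(W)))
  res_g <- vector("list", length(grid))
  res_n <- vector("list", length(grid))
  bad_sigma <- numeric()
  with_seed(seed, {
    for (t in seq_along(grid)) {
      S <- grid[t]
      A <- threshold_by_sparsity(W, S)
      cp <- clustering_and_paths(A)
      if (n_null > 0) {
        sw <- small_world(A, n_null = n_null, seed = NULL,
                          n_swap_multiple = n_swap_multiple)
        if (is.finite(sw$sigma) && sw$sigma <= 1) bad_sigma <- c(bad_sigma, S)
      } else {
        sw <- list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
      }
      res_g[[t]] <- data.frame(
        threshold = S, Cp = cp$Cp, Lp = cp$Lp, gamma = sw$gamma,
        lambda = sw$lambda, sigma = sw$sigma, Eg = cp$Eg, Eloc = cp$Eloc)
      res_n[[t]] <- data.frame(
        threshold = S, region = regions, degree = cp$degree,
        efficiency = cp$nodal_efficiency,
        betweenness = betweenness_nodes(A), stringsAsFactors = FALSE)
    }
  })
  if (length(bad_sigma)) {
    message("small-world index sigma <= 1 at threshold(s): ",
            paste(format(bad_sigma), collapse = ", "))
  }
  list(global = do.call(rbind, res_g), nodal = do.call(rbind, res_n))
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integral of per-threshold metric values over the grid; a
#' constant curve `c` integrates to `c * (stop - start)`.
#'
#' @param values per-threshold metric values (same length as `grid`).
#' @param grid a [sparsity_grid()] (or any increasing numeric vector).
#' @return scalar AUC.
#' @export
auc_trapz <- function(values, grid) {
  if (length(values) != length(grid)) {
    stop("curve length (", length(values), ") does not match grid length (",
         length(grid), ")", call. = FALSE)
  }
  n <- length(grid)
  sum(diff(as.numeric(grid)) * (values[-1] + values[-n]) / 2)
}

#' AUC summaries of a subject's metric curves
#'
#' @param curves output of [metric_curves()].
#' @param grid the [sparsity_grid()] the curves were computed on.
#' @return list with `global` (data.frame metric/auc) and `nodal`
#'   (data.frame region/metric/auc).
#' @export
summarize_auc <- function(curves, grid = sparsity_grid()) {
  gm <- setdiff(names(curves$global), "threshold")
  global <- data.frame(
    metric = gm,
    auc = vapply(gm, function(m) auc_trapz(curves$global[[m]], grid),
                 numeric(1)),
    row.names = NULL)
  nd <- curves$nodal
  regions <- unique(nd$region)
  nm <- c("degree", "efficiency", "betweenness")
  nodal <- expand.grid(region = regions, metric = nm,
                       stringsAsFactors = FALSE)
  nodal$auc <- mapply(function(r, m) {
    auc_trapz(nd[[m]][nd$region == r], grid)
  }, nodal$region, nodal$metric)
  list(global = global, nodal = nodal)
}
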