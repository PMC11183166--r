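#' Permutation test for group differences in AUC metrics
#'
#' Builds a null distribution of group-mean differences by reassigning
#' subjects to groups without replacement. The two-tailed p-value is the
#' raw proportion of permuted `|mean(a*) - mean(b*)|` at least as large as
#' the observed `|mean(a) - mean(b)|`; the 95th percentile of the absolute
#' null distribution is also reported as the significance threshold.
#' Matrix inputs (columns = metrics) share one set of permutations.
#' For 10 or fewer total subjects with `exhaustive = "auto"`, all label
#' assignments are enumerated instead of sampled.
#'
#' @param group_a,group_b numeric vectors (one metric) or matrices with one
#'   column per metric and one row per subject; at least 2 subjects each.
#' @param n_perm number of label permutations (default 10000).
#' @param seed optional seed.
#' @param exhaustive `"auto"` (enumerate when total n <= 10), `"always"`,
#'   or `"never"`.
#' @return list of class `perm_test`: `observed` (mean difference a - b),
#'   `p_value`, `crit95`, `null_distribution` (metrics x permutations),
#'   `n_perm`, `exhaustive`.
#' @export
permutation_test_auc <- function(group_a, group_b, n_perm = 10000L,
                                 seed = NULL,
                                 exhaustive = c("auto", "never", "always")) {
  exhaustive <- match.arg(exhaustive)
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  if (ncol(a) != ncol(b)) stop("metric columns differ", call. = FALSE)
  X <- rbind(a, b)
  n1 <- nrow(a); n2 <- nrow(b); n <- n1 + n2
  observed <- colMeans(a) - colMeans(b)
  tot <- colSums(X)

  do_exhaustive <- exhaustive == "always" ||
    (exhaustive == "auto" && n <= 10)
  if (do_exhaustive) {
    combos <- utils::combn(n, n1)
    P <- matrix(0, ncol(combos), n)
    P[cbind(rep(seq_len(ncol(combos)), each = n1), as.vector(combos))] <- 1
  } else {
    P <- with_seed(seed, {
      idx <- replicate(n_perm, sample.int(n, n1))
      M <- matrix(0, n_perm, n)
      M[cbind(rep(seq_len(n_perm), each = n1), as.vector(idx))] <- 1
      M
    })
  }
  sums_a <- P %*% X                      # permutations x metrics
  null <- t(sums_a / n1 - sweep(-sums_a, 2, tot, `+`) / n2)
  np <- ncol(null)
  absnull <- abs(null)
  tol <- 1e-12
  p <- vapply(seq_len(nrow(null)), function(m) {
    mean(absnull[m, ] >= abs(observed[m]) - tol)
  }, numeric(1))
  crit <- apply(absnull, 1, stats::quantile, probs = 0.95, names = FALSE)
  structure(list(observed = observed, p_value = p, crit95 = crit,
                 null_distribution = null, n_perm = np,
                 exhaustive = do_exhaustive),
            class = "perm_test")
}

#' Benjamini-Hochberg false discovery rate decision
#'
#' Step-up BH adjustment (`adjusted p_(i) = min_{j >= i} m p_(j) / j`,
#' capped at 1) with a significance mask at level `q`.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list of class `fdr_decision`: `raw`, `adjusted`, `significant`,
#'   `q`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  structure(list(raw = p_values, adjusted = adj, significant = adj <= q,
                 q = q), class = "fdr_decision")
}

edge_index_table <- function(nodes) {
  pairs <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  data.frame(i = pairs[, 1], j = pairs[, 2])
}

# Pooled-variance two-sample t statistics for each column of X,
# group 1 = rows where lab is TRUE.
edge_t_stats <- function(X, lab) {
  n1 <- sum(lab); n2 <- sum(!lab)
  m1 <- colMeans(X[lab, , drop = FALSE])
  m2 <- colMeans(X[!lab, , drop = FALSE])
  v1 <- colSums(sweep(X[lab, , drop = FALSE], 2, m1)^2)
  v2 <- colSums(sweep(X[!lab, , drop = FALSE], 2, m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

max_component_size <- function(edges_keep, et, n_nodes) {
  if (!any(edges_keep)) return(0L)
  g <- igraph::graph_from_edgelist(
    cbind(et$i[edges_keep], et$j[edges_keep]), directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership[et$i[edges_keep]]
  max(tabulate(memb))
}

#' Network-based statistic (NBS)
#'
#' Edge-wise pooled two-sample t statistics are computed on the raw
#' similarity values of every node pair within `node_mask`; edges whose t
#' exceeds the primary threshold in the requested direction are retained,
#' and their connected components are extracted. Component size is the
#' edge count. Significance is assessed by permuting group labels,
#' re-running the whole edge-test / threshold / component procedure, and
#' recording the maximal component size of each permutation; the corrected
#' p-value of an observed component of size `k` is the raw proportion of
#' permutations whose maximum size is `>= k`.
#'
#' @param stack list of per-subject similarity matrices (or an N x N x S
#'   array), all with identical region order.
#' @param labels group factor/character vector per subject (2 levels; the
#'   first level — first-appearing value for character input — is the
#'   "positive" group of the contrast).
#' @param node_mask indices or region names restricting the analysis
#'   (default: all nodes).
#' @param primary_t primary t threshold (default 3.2, about p < 0.001
#'   uncorrected at the default cohort size).
#' @param n_perm permutations (default 5000).
#' @param direction `"greater"` keeps edges with `t >= primary_t`
#'   (group 1 > group 2); `"less"` keeps `t <= -primary_t`.
#' @param seed optional seed.
#' @return list of class `nbs_result`: `components` (each with `nodes`,
#'   `edges` data.frame, `n_edges`, `corrected_p`), `t_stats`, `null_max`,
#'   plus the settings.
#' @export
nbs <- function(stack, labels, node_mask = NULL, primary_t = 3.2,
                n_perm = 5000L, direction = c("greater", "less"),
                seed = NULL) {
  direction <- match.arg(direction)
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(s) stack[, , s])
  }
  n_sub <- length(stack)
  if (length(labels) != n_sub) stop("labels do not match stack", call. = FALSE)
  if (!is.factor(labels)) {
    labels <- factor(labels, levels = unique(as.character(labels)))
  }
  if (nlevels(labels) != 2) stop("labels must have 2 levels", call. = FALSE)
  regions <- rownames(stack[[1]]) %||% as.character(seq_len(nrow(stack[[1]])))
  if (is.null(node_mask)) node_mask <- seq_along(regions)
  if (is.character(node_mask)) node_mask <- match(node_mask, regions)
  if (!length(node_mask)) stop("node_mask is empty", call. = FALSE)
  nodes <- regions[node_mask]
  nn <- length(node_mask)

  et <- edge_index_table(nodes)
  ut <- which(upper.tri(diag(nn)))
  X <- matrix(vapply(stack, function(W) {
    Wm <- W[node_mask, node_mask, drop = FALSE]
    Wm[ut]
  }, numeric(length(ut))), nrow = length(ut))
  X <- t(X)

  lab1 <- labels == levels(labels)[1]
  sgn <- if (direction == "greater") 1 else -1
  tobs <- edge_t_stats(X, lab1)
  keep <- sgn * tobs >= primary_t

  components <- list()
  if (any(keep)) {
    g <- igraph::graph_from_edgelist(cbind(et$i[keep], et$j[keep]),
                                     directed = FALSE)
    comp <- igraph::components(g)
    memb_edge <- comp$membership[et$i[keep]]
    kept_idx <- which(keep)
    for (cid in sort(unique(memb_edge))) {
      eidx <- kept_idx[memb_edge == cid]
      comp_nodes <- sort(unique(c(et$i[eidx], et$j[eidx])))
      components[[length(components) + 1L]] <- list(
        nodes = nodes[comp_nodes],
        edges = data.frame(from = nodes[et$i[eidx]], to = nodes[et$j[eidx]],
                           t = tobs[eidx], stringsAsFactors = FALSE),
        n_edges = length(eidx))
    }
  }

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      permlab <- lab1[sample.int(n_sub)]
      tb <- edge_t_stats(X, permlab)
      max_component_size(sgn * tb >= primary_t, et, nn)
    }, integer(1))
  })
  for (ci in seq_along(components)) {
    components[[ci]]$corrected_p <-
      mean(null_max >= components[[ci]]$n_edges)
  }
  structure(list(direction = direction, primary_t = primary_t,
                 n_perm = n_perm, components = components,
                 t_stats = tobs, edge_table = et, nodes = nodes,
                 null_max = null_max),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> direction=%s, t>=%.2f, %d permutations\n",
              x$direction, x$primary_t, x$n_perm))
  if (!length(x$components)) {
    cat("  no suprathreshold components\n")
  } else {
    for (c in x$components) {
      cat(sprintf("  component: %d nodes, %d edges, corrected p = %.4f\n",
                  length(c$nodes), c$n_edges, c$corrected_p))
    }
  }
  invisible(x)
}

#' Demographic group comparison
#'
#' Two-sample (pooled-variance) t-test for age, chi-square (without
#' continuity correction) for the sex contingency table, plus descriptive
#' Shapiro-Wilk normality p-values per group for age.
#'
#' @param clinical clinical data.frame with `group`, `age`, `sex`.
#' @return data.frame with one row per variable: group summaries, test
#'   statistic, p-value and test name; Shapiro-Wilk p-values are attached
#'   as attribute `shapiro`.
#' @export
compare_demographics <- function(clinical) {
  groups <- unique(clinical$group)
  if (length(groups) != 2) stop("need exactly 2 groups", call. = FALSE)
  g1 <- clinical[clinical$group == groups[1], ]
  g2 <- clinical[clinical$group == groups[2], ]
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  tt <- stats::t.test(g1$age, g2$age, var.equal = TRUE)
  sex_tab <- table(factor(clinical$group, levels = groups),
                   factor(clinical$sex, levels = c("M", "F")))
  cs <- suppressWarnings(stats::chisq.test(sex_tab, correct = FALSE))
  fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  fmt_sex <- function(g) paste(table(factor(g$sex, c("M", "F"))),
                               collapse = ":")
  out <- data.frame(
    variable = c("age", "sex (M:F)"),
    group1 = c(fmt(g1$age), fmt_sex(g1)),
    group2 = c(fmt(g2$age), fmt_sex(g2)),
    statistic = c(unname(tt$statistic), unname(cs$statistic)),
    p_value = c(tt$p.value, if (is.nan(cs$p.value)) 1 else cs$p.value),
    test = c("two-sample t", "chi-square"),
    stringsAsFactors = FALSE)
  names(out)[2:3] <- as.character(groups)
  attr(out, "shapiro") <- c(
    stats::setNames(stats::shapiro.test(g1$age)$p.value,
                    paste0("age_", groups[1])),
    stats::setNames(stats::shapiro.test(g2$age)$p.value,
                    paste0("age_", groups[2])))
  out
}
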