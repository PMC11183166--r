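#' Discretization settings for regional probability distributions
#'
#' Each region's kernel density estimate is evaluated on a finite grid and
#' converted to a discrete probability distribution (floored and
#' renormalized) so that divergences are finite and well defined.
#'
#' @param n_points number of grid points (>= 16).
#' @param padding grid extension beyond the pooled data range, in units of
#'   the larger bandwidth of the pair.
#' @param epsilon probability floor applied after discretization; prevents
#'   infinite Kullback-Leibler terms on empty-tail bins.
#' @return a `pdf_grid_spec` list.
#' @export
pdf_grid_spec <- function(n_points = 256L, padding = 3, epsilon = 1e-10) {
  stopifnot(n_points >= 16, padding >= 0, epsilon > 0)
  structure(list(n_points = as.integer(n_points), padding = padding,
                 epsilon = epsilon), class = "pdf_grid_spec")
}

bandwidth_for <- function(values, rule = "nrd0") {
  if (is.function(rule)) return(rule(values))
  switch(rule,
         nrd0 = stats::bw.nrd0(values),
         nrd = stats::bw.nrd(values),
         stop("unknown bandwidth rule: ", rule, call. = FALSE))
}

#' Estimate a region's discretized value distribution
#'
#' Gaussian-kernel KDE (via [stats::density()]) with an automatically
#' estimated bandwidth (Silverman's rule by default), evaluated on an
#' equally spaced grid, floored at `epsilon` and renormalized to sum to 1.
#'
#' @param values numeric vector of voxel GM values (>= 10 finite values with
#'   positive spread).
#' @param bandwidth_rule `"nrd0"` (Silverman), `"nrd"` (Scott), a function
#'   of the values, or a positive number.
#' @param grid a [pdf_grid_spec()].
#' @param range optional c(lo, hi) evaluation range; defaults to the data
#'   range padded by `padding` bandwidths. Pass a pooled range to place two
#'   regions on a common grid.
#' @param region_id label used in error messages.
#' @return a `regional_pdf` list with `region_id`, `grid`, `density`
#'   (probabilities summing to 1), `bw` and `epsilon`.
#' @export
estimate_region_pdf <- function(values, bandwidth_rule = "nrd0",
                                grid = pdf_grid_spec(), range = NULL,
                                region_id = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) < 10) {
    stop("region ", region_id, ": fewer than 10 finite values", call. = FALSE)
  }
  if (max(values) - min(values) <= 0) {
    stop("region ", region_id,
         ": constant values, bandwidth undefined", call. = FALSE)
  }
  bw <- if (is.numeric(bandwidth_rule)) bandwidth_rule
        else bandwidth_for(values, bandwidth_rule)
  if (!is.finite(bw) || bw <= 0) {
    stop("region ", region_id, ": non-positive bandwidth", call. = FALSE)
  }
  if (is.null(range)) {
    range <- c(min(values) - grid$padding * bw,
               max(values) + grid$padding * bw)
  }
  dens <- stats::density(values, bw = bw, from = range[1], to = range[2],
                         n = grid$n_points)
  p <- pmax(dens$y, 0)
  p <- p / sum(p)
  p <- pmax(p, grid$epsilon)
  p <- p / sum(p)
  structure(list(region_id = region_id, grid = dens$x, density = p,
                 bw = bw, epsilon = grid$epsilon),
            class = "regional_pdf")
}

pdf_probs <- function(x) {
  if (inherits(x, "regional_pdf")) x$density
  else if (is.numeric(x)) x
  else stop("expected a regional_pdf or a probability vector", call. = FALSE)
}

check_common_grid <- function(p, q) {
  if (inherits(p, "regional_pdf") && inherits(q, "regional_pdf")) {
    if (length(p$grid) != length(q$grid) ||
        max(abs(p$grid - q$grid)) > 1e-12) {
      stop("distributions are not on a common grid", call. = FALSE)
    }
  } else if (length(pdf_probs(p)) != length(pdf_probs(q))) {
    stop("distributions are not on a common grid", call. = FALSE)
  }
}

#' Symmetric Kullback-Leibler divergence between discretized distributions
#'
#' Returns `KL(P||Q) + KL(Q||P)` with natural logarithms, summed over the
#' shared grid. Inputs must be on an identical grid (as produced by
#' [estimate_region_pdf()] with a pooled range) or plain probability
#' vectors of equal length.
#'
#' @param p,q `regional_pdf` objects or probability vectors.
#' @return non-negative scalar.
#' @export
kl_symmetric <- function(p, q) {
  check_common_grid(p, q)
  pp <- pdf_probs(p); qq <- pdf_probs(q)
  sum(pp * log(pp / qq)) + sum(qq * log(qq / pp))
}

#' Kullback-Leibler divergence-based similarity (KLDs)
#'
#' Maps the symmetric KL divergence into the similarity score
#' `exp(-kl_symmetric(p, q))`, which is 1 for identical distributions and
#' decays toward 0 as the distributions separate.
#'
#' @inheritParams kl_symmetric
#' @return similarity in (0, 1].
#' @export
klds <- function(p, q) exp(-kl_symmetric(p, q))

#' Jensen-Shannon divergence-based similarity (JSDs)
#'
#' `JSD(P, Q) = KL(P||M)/2 + KL(Q||M)/2` with `M = (P + Q)/2`, using base-2
#' logarithms so the divergence lies in [0, 1]; the similarity is
#' `1 - JSD`. Zero-probability bins contribute zero to their own KL term.
#'
#' @inheritParams kl_symmetric
#' @return similarity in [0, 1].
#' @export
jsds <- function(p, q) {
  check_common_grid(p, q)
  pp <- pdf_probs(p); qq <- pdf_probs(q)
  m <- (pp + qq) / 2
  kl2 <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  1 - (kl2(pp) + kl2(qq)) / 2
}

#' Build a subject's morphological similarity matrix
#'
#' For every unordered region pair, both regions' KDEs are evaluated on a
#' pair-specific common grid spanning the pooled value range plus
#' `padding` bandwidths, and the pair is scored with the chosen
#' divergence-based similarity. The diagonal is fixed at 1 (self-similarity
#' carries no information and is excluded from thresholding downstream).
#'
#' @param subject a subject record with `region_values` (named list of
#'   numeric vectors), as produced by [generate_cohort()] or
#'   [read_cohort_table()].
#' @param measure `"KLDs"` or `"JSDs"`.
#' @param grid a [pdf_grid_spec()].
#' @param bandwidth_rule see [estimate_region_pdf()].
#' @return symmetric N x N matrix with unit diagonal, class
#'   `similarity_matrix`, with attributes `measure`, `grid_spec`,
#'   `bandwidth_rule` and `subject_id`.
#' @export
build_similarity_matrix <- function(subject, measure = c("KLDs", "JSDs"),
                                    grid = pdf_grid_spec(),
                                    bandwidth_rule = "nrd0") {
  measure <- match.arg(measure)
  vals <- subject$region_values
  if (is.null(vals)) stop("subject has no `region_values`", call. = FALSE)
  regions <- names(vals)
  n <- length(vals)

  bad <- character()
  for (r in regions) {
    v <- vals[[r]][is.finite(vals[[r]])]
    if (length(v) < 10 || max(v) - min(v) <= 0) bad <- c(bad, r)
  }
  if (length(bad)) {
    stop("regions failing PDF preconditions (need >= 10 finite values with ",
         "positive spread): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  bw <- vapply(vals, bandwidth_for, numeric(1), rule = bandwidth_rule)
  lo <- vapply(vals, min, numeric(1))
  hi <- vapply(vals, max, numeric(1))

  sim_fun <- if (measure == "KLDs") {
    function(p, q) exp(-(sum(p * log(p / q)) + sum(q * log(q / p))))
  } else {
    function(p, q) {
      m <- (p + q) / 2
      1 - (sum(p * log2(p / m)) + sum(q * log2(q / m))) / 2
    }
  }

  np <- grid$n_points
  eps <- grid$epsilon
  W <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    vi <- vals[[i]]
    for (j in seq.int(i + 1L, n)) {
      vj <- vals[[j]]
      pad <- grid$padding * max(bw[i], bw[j])
      from <- min(lo[i], lo[j]) - pad
      to <- max(hi[i], hi[j]) + pad
      p <- stats::density(vi, bw = bw[i], from = from, to = to, n = np)$y
      q <- stats::density(vj, bw = bw[j], from = from, to = to, n = np)$y
      p <- pmax(p, 0); p <- p / sum(p); p <- pmax(p, eps); p <- p / sum(p)
      q <- pmax(q, 0); q <- q / sum(q); q <- pmax(q, eps); q <- q / sum(q)
      W[i, j] <- W[j, i] <- sim_fun(p, q)
    }
  }
  dimnames(W) <- list(regions, regions)
  structure(W, class = c("similarity_matrix", class(W)),
            measure = measure, grid_spec = grid,
            bandwidth_rule = if (is.function(bandwidth_rule)) "custom"
                             else bandwidth_rule,
            subject_id = subject$subject_id %||% NA_character_)
}

#' Build similarity matrices for every subject in a cohort
#'
#' @param cohort a `morph_cohort` or list of subject records.
#' @inheritParams build_similarity_matrix
#' @return named list of `similarity_matrix` objects.
#' @export
build_cohort_networks <- function(cohort, measure = c("KLDs", "JSDs"),
                                  grid = pdf_grid_spec(),
                                  bandwidth_rule = "nrd0") {
  measure <- match.arg(measure)
  subjects <- if (inherits(cohort, "morph_cohort")) cohort$subjects else cohort
  lapply(subjects, build_similarity_matrix, measure = measure,
         grid = grid, bandwidth_rule = bandwidth_rule)
}
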