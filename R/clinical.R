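#' Pearson partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of the
#' covariates: both variables are regressed on the covariates (with
#' intercept) and the Pearson correlation of the residuals is returned,
#' with a two-tailed p-value from the t transform on
#' `df = n - 2 - n_covariates`. Factor/character covariates (e.g. sex) are
#' expanded to indicator columns; rows with missing values are dropped
#' listwise.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame/matrix/vector of covariates.
#' @param xname,yname labels for reporting.
#' @return list of class `partial_cor`: `r`, `p`, `df`, `n`, `covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                xname = "x", yname = "y") {
  if (is.null(covariates)) {
    Z <- matrix(numeric(0), nrow = length(x), ncol = 0)
    cov_names <- character()
  } else {
    cdf <- as.data.frame(covariates)
    cov_names <- names(cdf)
    # na.pass keeps NA rows aligned so listwise deletion happens once below
    Z <- stats::model.matrix(~ ., data = cdf,
                             na.action = stats::na.pass)[, -1, drop = FALSE]
  }
  ok <- is.finite(x) & is.finite(y)
  if (ncol(Z)) ok <- ok & apply(is.finite(Z), 1, all)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n <= k + 2) stop("too few complete observations (n = ", n,
                       ", covariates = ", k, ")", call. = FALSE)
  resid_on <- function(v) {
    if (!k) return(v - mean(v))
    stats::lm.fit(cbind(1, Z), v)$residuals
  }
  rx <- resid_on(x); ry <- resid_on(y)
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1)) {
    stop("constant variable after residualization", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(x = xname, y = yname, covariates = cov_names,
                 r = r, p = p, df = df, n = n),
            class = "partial_cor")
}

#' @export
print.partial_cor <- function(x, ...) {
  cat(sprintf("partial cor %s ~ %s | %s: r = %.3f, p = %.4f (df = %d)\n",
              x$x, x$y,
              if (length(x$covariates)) paste(x$covariates, collapse = "+")
              else "(none)",
              x$r, x$p, x$df))
  invisible(x)
}

#' Associate nodal AUC metrics with clinical variables
#'
#' Pearson partial correlations between nodal AUC metrics and clinical
#' variables in the patient group, controlling for age and sex (sex enters
#' as a binary indicator). Reported p-values are uncorrected for multiple
#' comparisons, and the result table flags this.
#'
#' @param nodal_auc data.frame with columns `subject_id`, `region`,
#'   `metric`, `auc` (one row per subject x region x metric), e.g. from
#'   stacking [summarize_auc()] results.
#' @param clinical clinical data.frame (must contain `subject_id`, `group`,
#'   `age`, `sex` and the target variables).
#' @param targets data.frame with columns `region`, `metric`, `variable`.
#' @param covariates clinical columns to control for.
#' @return data.frame: region, metric, variable, r, p, n, covariates, with
#'   attribute `correction = "uncorrected"`.
#' @export
associate_metrics <- function(nodal_auc, clinical, targets,
                              covariates = c("age", "sex")) {
  patients <- clinical[clinical$group == "patient", , drop = FALSE]
  if (!nrow(patients)) stop("no patient rows in clinical table", call. = FALSE)
  out <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    reg <- targets$region[i]; met <- targets$metric[i]
    var <- targets$variable[i]
    sel <- nodal_auc$region == reg & nodal_auc$metric == met
    if (!any(sel)) {
      stop("unknown region/metric target: ", reg, " / ", met, call. = FALSE)
    }
    if (!var %in% names(patients)) {
      stop("unknown clinical variable: ", var, call. = FALSE)
    }
    sub <- nodal_auc[sel, , drop = FALSE]
    m <- match(patients$subject_id, sub$subject_id)
    x <- sub$auc[m]
    y <- patients[[var]]
    pc <- partial_correlation(x, y, patients[, covariates, drop = FALSE],
                              xname = paste(reg, met), yname = var)
    out[[i]] <- data.frame(region = reg, metric = met, variable = var,
                           r = pc$r, p = pc$p, n = pc$n,
                           covariates = paste(covariates, collapse = "+"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "correction") <- "uncorrected"
  res
}
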