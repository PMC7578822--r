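#' Pipeline factor table
#'
#' Validates a table of the five categorical pipeline design factors used by
#' the variance decomposition: mapping algorithm, mapping strategy (spliced
#' vs un-spliced), mapping reporting (single-hit vs multi-hit),
#' quantification and normalization.
#'
#' @param df Data frame with columns `mapping_algorithm`, `mapping_strategy`,
#'   `mapping_reporting`, `quantification`, `normalization` (and optionally
#'   `pipeline`).
#' @return The validated data frame with factor columns.
#' @export
pipeline_descriptors <- function(df) {
  req <- c("mapping_algorithm", "mapping_strategy", "mapping_reporting",
           "quantification", "normalization")
  if (!all(req %in% names(df)))
    stop("descriptor table needs columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df)
  for (f in req) {
    if (any(is.na(df[[f]]) | df[[f]] == ""))
      stop("factor '", f, "' has empty levels")
    df[[f]] <- factor(df[[f]])
  }
  df
}

#' ANOVA decomposition of metric variance over pipeline factors
#'
#' Fits a linear model of a per-pipeline response (a benchmark metric or a
#' prediction-performance value) on the five pipeline factors and their
#' two-way interactions, in the factors' listing order, and reports the
#' sequential (Type-I) analysis-of-variance table: per-term sum of squares,
#' degrees of freedom, F-test p-value and the percentage of the total sum of
#' squares attributed to each term.  Interaction columns aliased by the
#' partial confounding of the factors (mapping strategy and reporting are
#' attributes of the mapping algorithm) are dropped by the fit; fully
#' aliased terms appear with zero df and are listed in `dropped`.
#'
#' @param values Numeric response, one value per pipeline.
#' @param descriptors A [pipeline_descriptors()] table, rows aligned with
#'   `values`.
#' @param interactions Include all two-way interactions (default `TRUE`).
#' @return An object of class `variance_decomposition`: `table` (term, df,
#'   sum_sq, pct_ss, f_value, p_value, with a residual row), `dropped`
#'   (aliased terms) and `total_ss`.
#' @export
anova_decomposition <- function(values, descriptors, interactions = TRUE) {
  descriptors <- pipeline_descriptors(descriptors)
  if (length(values) != nrow(descriptors))
    stop("'values' and 'descriptors' lengths differ")
  fac <- c("mapping_algorithm", "mapping_strategy", "mapping_reporting",
           "quantification", "normalization")
  fac <- fac[vapply(descriptors[fac], nlevels, 1L) >= 2L]
  if (length(fac) == 0) stop("no factor with >= 2 levels")
  rhs <- paste(fac, collapse = " + ")
  if (interactions && length(fac) >= 2)
    rhs <- sprintf("(%s)^2", rhs)
  dat <- cbind(.response = values, descriptors)
  form <- stats::as.formula(paste(".response ~", rhs))
  fit <- stats::lm(form, data = dat)
  av <- stats::anova(fit)
  terms <- rownames(av)
  total_ss <- sum(av$`Sum Sq`)
  tab <- data.frame(term = terms, df = av$Df, sum_sq = av$`Sum Sq`,
                    pct_ss = if (total_ss > 0) 100 * av$`Sum Sq` / total_ss else
                      rep(0, length(terms)),
                    f_value = av$`F value`, p_value = av$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  # fully aliased terms are silently absent from the sequential table
  intended <- attr(stats::terms(form), "term.labels")
  dropped <- setdiff(intended, terms)
  structure(list(table = tab, dropped = dropped, total_ss = total_ss,
                 constant_response = stats::var(values) == 0),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance decomposition (sequential SS):\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$dropped) > 0)
    cat("aliased terms dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Robust linear regression by Huber M-estimation
#'
#' Fits `y ~ x` by iteratively reweighted least squares with the Huber psi
#' function (tuning constant 1.345 for 95% Gaussian efficiency), as in
#' `MASS::rlm`, and reports the slope, intercept and residual standard
#' error.  An exact fit (all residuals numerically zero) is returned as the
#' ordinary least-squares solution.
#'
#' @param x Explanatory numeric vector (not constant, at least 3 points).
#' @param y Response numeric vector.
#' @param tuning Huber tuning constant (default 1.345).
#' @param max_iter Maximum IRLS iterations (default 200).
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @return A list: `slope`, `intercept`, `residual_se`, `converged`.
#' @export
huber_regression <- function(x, y, tuning = 1.345, max_iter = 200, tol = 1e-8) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 paired points")
  if (stats::sd(x) == 0) stop("'x' is constant")
  ols <- stats::lm(y ~ x)
  if (max(abs(stats::residuals(ols))) < 1e-10) {
    co <- stats::coef(ols)
    return(list(slope = unname(co[2]), intercept = unname(co[1]),
                residual_se = summary(ols)$sigma, converged = TRUE))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = tuning,
                   maxit = max_iter, acc = tol)
  if (!fit$converged)
    stop(sprintf("Huber IRLS did not converge in %d iterations (last slope %.6g, intercept %.6g)",
                 max_iter, stats::coef(fit)[2], stats::coef(fit)[1]))
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       residual_se = summary(fit)$sigma, converged = TRUE)
}

#' Distribution characteristics of an expression vector
#'
#' The nine summary statistics used to profile a pipeline's expression
#' distribution: lower quartile, median, upper quartile, maximum,
#' interquartile range, standard deviation, skewness, kurtosis (excess) and
#' entropy.  Quartiles use linear interpolation (R type 7).  Entropy is the
#' Shannon entropy (bits) of a 64-bin equal-width histogram of
#' `log2(x + 1)` values, with empty bins contributing zero; a constant
#' vector has entropy 0.
#'
#' @param x Non-empty numeric vector of expression values.
#' @param bins Histogram bins for the entropy (default 64).
#' @return Named numeric vector of the nine statistics.
#' @export
distribution_profile <- function(x, bins = 64) {
  if (length(x) == 0 || !is.numeric(x)) stop("'x' must be a non-empty numeric vector")
  if (length(x) < 4)
    warning("fewer than 4 points; quartile-based fields are unstable")
  q <- quantile7(x, c(0.25, 0.5, 0.75))
  s <- stats::sd(x)
  n <- length(x)
  m <- mean(x)
  if (s > 0) {
    skew <- mean((x - m)^3) / (mean((x - m)^2))^1.5
    kurt <- mean((x - m)^4) / (mean((x - m)^2))^2 - 3
  } else skew <- kurt <- 0
  lx <- log2(x + 1)
  if (diff(range(lx)) == 0) {
    entropy <- 0
  } else {
    h <- tabulate(cut(lx, breaks = seq(min(lx), max(lx), length.out = bins + 1),
                      include.lowest = TRUE, labels = FALSE), nbins = bins)
    p <- h / sum(h)
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
  }
  c(lower_quartile = unname(q[1]), median = unname(q[2]),
    upper_quartile = unname(q[3]), maximum = max(x),
    iqr = unname(q[3] - q[1]), sd = s, skewness = skew, kurtosis = kurt,
    entropy = entropy)
}
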