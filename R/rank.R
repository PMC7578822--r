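#' The twelve benchmark metric subsets
#'
#' Ranking can use any of four combinations of the three benchmark metrics
#' (all three, or each of the three pairs) crossed with three gene-set
#' choices (all genes, low-expressing genes, or both), giving twelve subset
#' specifications of the six metric columns
#' (`accuracy_all`, ..., `reliability_low`).
#'
#' @return A named list of 12 character vectors of metric column names.
#' @export
metric_subsets <- function() {
  metrics <- c("accuracy", "precision", "reliability")
  metric_combos <- c(list(all3 = metrics),
                     stats::setNames(lapply(seq_along(metrics), function(i) metrics[-i]),
                                     paste0("drop_", metrics)))
  gene_sets <- list(all = "all", low = "low", both = c("all", "low"))
  out <- list()
  for (mc in names(metric_combos)) for (gs in names(gene_sets)) {
    cols <- as.vector(outer(metric_combos[[mc]], gene_sets[[gs]], paste, sep = "_"))
    out[[paste(mc, gs, sep = ":")]] <- cols
  }
  out
}

#' Default metric orientations
#'
#' Accuracy (log-ratio deviation) and precision (CoV) are better when
#' smaller; reliability (ICC) is better when larger.
#'
#' @param columns Metric column names.
#' @return Named character vector, `"lower"` or `"higher"`, per column.
#' @export
metric_orientation <- function(columns) {
  stats::setNames(ifelse(grepl("^reliability", columns), "higher", "lower"),
                  columns)
}

#' Average rank of pipelines over a metric subset
#'
#' Ranks pipelines within each metric column (rank 1 = best under the
#' column's orientation, ties receiving average ranks) and averages the
#' ranks over the subset's columns.
#'
#' @param metric_table Data frame with a `pipeline` column and metric
#'   columns.
#' @param subset Character vector of metric column names (one element of
#'   [metric_subsets()]).
#' @param orientation Named orientations per column; defaults to
#'   [metric_orientation()].
#' @return An object of class `ranking_result`: `table` (pipeline,
#'   per-metric ranks, `average_rank`), ordered best first.
#' @export
average_rank <- function(metric_table, subset,
                         orientation = metric_orientation(subset)) {
  stopifnot("pipeline" %in% names(metric_table))
  miss_col <- setdiff(subset, names(metric_table))
  if (length(miss_col) > 0) stop("missing metric column(s): ",
                                 paste(miss_col, collapse = ", "))
  tab <- metric_table[, c("pipeline", subset)]
  incomplete <- !stats::complete.cases(tab)
  if (any(incomplete)) {
    log_note("excluding %d pipeline(s) with missing metric values", sum(incomplete))
    tab <- tab[!incomplete, , drop = FALSE]
  }
  ranks <- sapply(subset, function(cl) {
    v <- tab[[cl]]
    if (orientation[[cl]] == "higher") v <- -v
    rank(v, ties.method = "average")
  })
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1, dimnames = list(NULL, subset))
  colnames(ranks) <- paste0("rank_", subset)
  out <- data.frame(pipeline = tab$pipeline, ranks,
                    average_rank = rowMeans(ranks),
                    stringsAsFactors = FALSE)
  out <- out[order(out$average_rank, out$pipeline), ]
  rownames(out) <- NULL
  structure(list(table = out, subset = subset), class = "ranking_result")
}

#' Select top and bottom pipelines by average rank
#'
#' Returns the best and worst `round(fraction * n)` pipelines (round
#' half-up) from a ranking; ties at either boundary are broken by
#' lexicographic pipeline ID, so the selection is deterministic.
#'
#' @param ranking A [average_rank()] result.
#' @param fraction Selection fraction in (0, 0.5] (default 0.10).
#' @return A list with character vectors `good` and `poor`.
#' @export
select_extremes <- function(ranking, fraction = 0.10) {
  stopifnot(inherits(ranking, "ranking_result"),
            fraction > 0, fraction <= 0.5)
  tab <- ranking$table
  n <- nrow(tab)
  m <- round_half_up(fraction * n)
  if (m < 1) stop("selection fraction yields an empty set for ", n, " pipelines")
  # table is ordered (average_rank, pipeline): head = best, tail = worst
  good <- tab$pipeline[seq_len(m)]
  poor_tab <- tab[order(-tab$average_rank, tab$pipeline), ]
  poor <- poor_tab$pipeline[seq_len(m)]
  list(good = good, poor = poor)
}

# exact one-sided rank-sum tail by dynamic programming over (doubled,
# integer) midranks: counts size-n1 subsets with rank sum >= observed
ranksum_tail_exact <- function(ranks2, n1, obs2) {
  n <- length(ranks2)
  total <- sum(ranks2)
  # counts[j+1, s+1] = number of subsets of size j with doubled-rank sum s
  counts <- matrix(0, nrow = n1 + 1, ncol = total + 1)
  counts[1, 1] <- 1
  for (r in ranks2) {
    for (j in min(n1, n):1) {
      shifted <- c(rep(0, r), counts[j, seq_len(total + 1 - r)])
      counts[j + 1, ] <- counts[j + 1, ] + shifted
    }
  }
  tail_count <- sum(counts[n1 + 1, seq(obs2 + 1, total + 1)])
  tail_count / choose(n, n1)
}

#' One-sided Wilcoxon rank-sum comparison
#'
#' Tests the null hypothesis that the `good` group's values are not larger
#' than the `poor` group's, against the one-sided alternative good > poor.
#' For combined sample sizes up to `exact_max` the p-value is the exact
#' permutation tail of the rank-sum distribution (midranks, so ties are
#' handled exactly); larger samples use the normal approximation with
#' continuity and tie corrections.
#'
#' @param good,poor Numeric vectors.
#' @param exact_max Largest combined size for the exact computation
#'   (default 25).
#' @return An object of class `comparison_result`: `p_value`, `statistic`
#'   (the good group's rank sum), `method` and the group summaries.
#' @export
wilcoxon_one_sided <- function(good, poor, exact_max = 25) {
  if (length(good) == 0 || length(poor) == 0) stop("both groups must be non-empty")
  n1 <- length(good); n2 <- length(poor); n <- n1 + n2
  ranks <- rank(c(good, poor))
  w <- sum(ranks[seq_len(n1)])
  if (stats::var(c(good, poor)) == 0) {
    p <- 1; method <- "degenerate"
  } else if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * ranks))
    p <- ranksum_tail_exact(ranks2, n1, as.integer(round(2 * w)))
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(ranks)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal approximation"
  }
  structure(list(p_value = p, statistic = w, method = method,
                 n_good = n1, n_poor = n2,
                 median_good = stats::median(good),
                 median_poor = stats::median(poor)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("one-sided rank-sum (good > poor), %s: W = %g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}
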