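#' Accuracy: absolute log-ratio deviation from qPCR
#'
#' For each gene, compares the RNA-seq replicate-mean expression ratio of a
#' sample pair (A/B by default) to the corresponding qPCR ratio on the log2
#' scale: `delta_k = | log2(xA/xB) - log2(qA/qB) |`.  The metric is the
#' median of the per-gene deviations.  Genes with a zero mean on either
#' platform in either sample are dropped (the count is reported).
#'
#' @param rnaseq An [expression_matrix()] for a single site (normalized
#'   expression).
#' @param qpcr A [qpcr_table()].
#' @param genes Gene IDs to evaluate (default: all shared genes).
#' @param pair The two samples whose ratio is compared (default A, B).
#' @return A list: `metric` (the median), `per_gene` (named deviations) and
#'   `n_dropped`.
#' @export
accuracy_metric <- function(rnaseq, qpcr, genes = NULL, pair = c("A", "B")) {
  stopifnot(inherits(rnaseq, "expression_matrix"), inherits(qpcr, "qpcr_table"),
            length(pair) == 2L)
  xm <- sample_means(rnaseq, pair)
  qm <- qpcr_means(qpcr)[, pair, drop = FALSE]
  if (is.null(genes)) genes <- intersect(rownames(xm), rownames(qm))
  xm <- xm[match(genes, rownames(xm)), , drop = FALSE]
  qm <- qm[match(genes, rownames(qm)), , drop = FALSE]
  ok <- rowSums(xm > 0) == 2L & rowSums(qm > 0) == 2L & !is.na(xm[, 1]) & !is.na(qm[, 1])
  n_dropped <- sum(!ok)
  if (n_dropped > 0) log_note("accuracy: dropped %d gene(s) with zero means", n_dropped)
  delta <- abs(log2(xm[ok, 1] / xm[ok, 2]) - log2(qm[ok, 1] / qm[ok, 2]))
  names(delta) <- genes[ok]
  list(metric = stats::median(delta), per_gene = delta, n_dropped = n_dropped)
}

#' Precision: coefficient of variation across replicate libraries
#'
#' Computes, for each gene and each sample, the coefficient of variation of
#' expression across the sample's replicate libraries (sample standard
#' deviation, n-1 denominator, divided by the replicate mean).  The metric
#' is the median of all CoVs across genes and samples.  Gene-sample cells
#' with a zero mean are dropped (count reported).
#'
#' @param rnaseq An [expression_matrix()] for a single site.
#' @param genes Gene IDs to evaluate (default: all).
#' @return A list: `metric`, `per_gene_sample` (genes x samples matrix of
#'   CoVs) and `n_dropped`.
#' @export
precision_metric <- function(rnaseq, genes = NULL) {
  stopifnot(inherits(rnaseq, "expression_matrix"))
  samples <- sort(unique(rnaseq$libraries$sample))
  if (is.null(genes)) genes <- rownames(rnaseq$counts)
  x <- rnaseq$counts[match(genes, rownames(rnaseq$counts)), , drop = FALSE]
  cov <- vapply(samples, function(s) {
    cols <- rnaseq$libraries$sample == s
    if (sum(cols) < 2) stop("precision needs >= 2 replicates per sample")
    sub <- x[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- sqrt(rowSums((sub - mu)^2) / (ncol(sub) - 1))
    ifelse(mu > 0, sdv / mu, NA_real_)
  }, numeric(length(genes)))
  if (is.null(dim(cov))) cov <- matrix(cov, nrow = 1, dimnames = list(NULL, samples))
  rownames(cov) <- genes
  n_dropped <- sum(is.na(cov))
  if (n_dropped > 0) log_note("precision: dropped %d gene-sample cell(s) with zero mean", n_dropped)
  list(metric = stats::median(cov, na.rm = TRUE), per_gene_sample = cov,
       n_dropped = n_dropped)
}

# vectorized one-way ANOVA mean squares for a genes x libraries matrix with
# balanced groups; returns list(bms, wms) per gene
oneway_mean_squares <- function(x, groups) {
  groups <- as.factor(groups)
  j <- nlevels(groups)
  k <- unique(table(groups))
  if (length(k) != 1L) stop("reliability requires a balanced design")
  if (j < 2 || k < 2) stop("need >= 2 groups and >= 2 replicates per group")
  grand <- rowMeans(x)
  gm <- vapply(levels(groups),
               function(g) rowMeans(x[, groups == g, drop = FALSE]),
               numeric(nrow(x)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1)
  bms <- k * rowSums((gm - grand)^2) / (j - 1)
  within_ss <- rowSums((x - gm[, as.integer(groups), drop = FALSE])^2)
  wms <- within_ss / (j * (k - 1))
  list(bms = bms, wms = wms, k = k, j = j)
}

#' Reliability: intraclass correlation ICC(1,k)
#'
#' Treats the samples as groups and the replicate libraries as observations
#' of a one-way random-effects model `Y_ij = mu + alpha_j + eps_ij` and
#' computes, per gene, `ICC(1,k) = (BMS - WMS) / BMS` from the between- and
#' within-group mean squares of a balanced one-way ANOVA.  The metric is the
#' median of per-gene ICCs.  ICC may be negative (it is not clamped); genes
#' with `BMS = 0` are undefined and dropped (count reported).
#'
#' @param rnaseq An [expression_matrix()] for a single site.
#' @param genes Gene IDs to evaluate (default: all).
#' @return A list: `metric`, `per_gene` (named ICCs) and `n_dropped`.
#' @export
reliability_metric <- function(rnaseq, genes = NULL) {
  stopifnot(inherits(rnaseq, "expression_matrix"))
  if (is.null(genes)) genes <- rownames(rnaseq$counts)
  x <- rnaseq$counts[match(genes, rownames(rnaseq$counts)), , drop = FALSE]
  ms <- oneway_mean_squares(x, rnaseq$libraries$sample)
  icc <- ifelse(ms$bms > 0, (ms$bms - ms$wms) / ms$bms, NA_real_)
  names(icc) <- genes
  n_dropped <- sum(is.na(icc))
  if (n_dropped > 0) log_note("reliability: dropped %d gene(s) with BMS = 0", n_dropped)
  list(metric = stats::median(icc, na.rm = TRUE), per_gene = icc,
       n_dropped = n_dropped)
}

#' Reproducibility: Spearman correlation of replicate libraries
#'
#' Spearman rank correlation over genes for every unordered pair of
#' replicate libraries within each sample; the metric is the median over all
#' pairs and samples.  Pairs with a constant vector are dropped.
#'
#' @inheritParams precision_metric
#' @return A list: `metric`, `per_pair` (data frame) and `n_dropped`.
#' @export
reproducibility_metric <- function(rnaseq, genes = NULL) {
  stopifnot(inherits(rnaseq, "expression_matrix"))
  if (is.null(genes)) genes <- rownames(rnaseq$counts)
  x <- rnaseq$counts[match(genes, rownames(rnaseq$counts)), , drop = FALSE]
  rows <- list(); n_dropped <- 0L
  for (s in unique(rnaseq$libraries$sample)) {
    cols <- which(rnaseq$libraries$sample == s)
    if (length(cols) < 2) stop("reproducibility needs >= 2 replicates per sample")
    for (i in seq_along(cols)) for (j in seq_along(cols)) if (i < j) {
      v1 <- x[, cols[i]]; v2 <- x[, cols[j]]
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) { n_dropped <- n_dropped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, lib1 = colnames(x)[cols[i]], lib2 = colnames(x)[cols[j]],
        rho = stats::cor(v1, v2, method = "spearman"),
        stringsAsFactors = FALSE)
    }
  }
  if (n_dropped > 0) log_note("reproducibility: dropped %d constant pair(s)", n_dropped)
  per_pair <- do.call(rbind, rows)
  list(metric = if (is.null(per_pair)) NA_real_ else stats::median(per_pair$rho),
       per_pair = per_pair, n_dropped = n_dropped)
}

#' Benchmark metric report for one pipeline
#'
#' Computes accuracy, precision and reliability (and optionally
#' reproducibility) for the reference genes and their low-expressing subset,
#' per site, and averages across sites for the summary row.  Per-site values
#' are retained in the result.
#'
#' @param rnaseq Normalized [expression_matrix()] (may span several sites).
#' @param qpcr A [qpcr_table()].
#' @param refset A [build_reference_set()] result.
#' @param reproducibility Also compute the Spearman reproducibility metric.
#' @return An object of class `metric_report`: `summary` (one-row data
#'   frame with columns `accuracy_all`, `precision_all`, `reliability_all`,
#'   `accuracy_low`, `precision_low`, `reliability_low`, ...) and `per_site`.
#' @export
benchmark_metrics <- function(rnaseq, qpcr, refset, reproducibility = FALSE) {
  stopifnot(inherits(refset, "reference_gene_set"))
  sites <- unique(rnaseq$libraries$site)
  gene_sets <- list(all = refset$all_genes, low = refset$low_expressing)
  per_site <- list()
  for (st in sites) {
    sub <- em_subset_site(rnaseq, st)
    row <- list(site = st)
    for (gs in names(gene_sets)) {
      g <- intersect(gene_sets[[gs]], rownames(sub$counts))
      row[[paste0("accuracy_", gs)]] <- accuracy_metric(sub, qpcr, g)$metric
      row[[paste0("precision_", gs)]] <- precision_metric(sub, g)$metric
      row[[paste0("reliability_", gs)]] <- reliability_metric(sub, g)$metric
      if (reproducibility)
        row[[paste0("reproducibility_", gs)]] <- reproducibility_metric(sub, g)$metric
    }
    per_site[[st]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  per_site <- do.call(rbind, c(per_site, make.row.names = FALSE))
  summary <- as.data.frame(c(list(pipeline = rnaseq$pipeline),
                             as.list(colMeans(per_site[, -1, drop = FALSE]))),
                           stringsAsFactors = FALSE)
  structure(list(summary = summary, per_site = per_site),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report (mean over sites):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
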