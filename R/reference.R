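#' Detectability filter for qPCR genes
#'
#' Retains genes quantified as non-zero in all four samples and, when Ct
#' values are available, with Ct at or below `ct_max` in all samples (a Ct of
#' 35 corresponds to detecting a single molecule, so larger values are
#' treated as undetected).  When the table carries no Ct values the Ct
#' criterion is skipped with a logged notice.
#'
#' @param qpcr A [qpcr_table()].
#' @param ct_max Maximum admissible Ct (default 35 cycles).
#' @return Character vector of retained gene IDs.
#' @export
filter_detectable <- function(qpcr, ct_max = 35) {
  stopifnot(inherits(qpcr, "qpcr_table"))
  nonzero <- apply(qpcr$q > 0, 1, all)
  if (is.null(qpcr$ct)) {
    log_note("no Ct values present; Ct <= %g criterion skipped", ct_max)
    keep <- nonzero
  } else {
    keep <- nonzero & apply(qpcr$ct <= ct_max, 1, all)
  }
  qpcr$genes[keep]
}

#' Titration-order (TO) filter
#'
#' Because C and D are mixtures of A and B, every gene must be expressed in
#' the order A >= C >= D >= B or A <= C <= D <= B.  Replicate-mean expression
#' is compared with the design's margin multipliers: the descending chain is
#' `a*qA >= b*qC  &  a*qC >= b*qD  &  a*qD >= b*qB` and the ascending chain
#' `b*qA <= a*qC  &  b*qC <= a*qD  &  b*qD <= a*qB`.  With `a = b = 1` this
#' is the strict multi-replicate ordering; the 1.15/0.85 margins absorb the
#' variability of single-replicate qPCR measurements.  By default margins
#' are applied only to single-replicate tables (multi-replicate tables use
#' the strict order).
#'
#' @param qpcr A [qpcr_table()].
#' @param design A [mixture_design()] supplying `a` and `b`.
#' @param use_margins Apply the design margins; defaults to `TRUE` for
#'   single-replicate tables, `FALSE` otherwise.
#' @return Character vector: the gene IDs in the titration-order set.
#' @export
titration_order_set <- function(qpcr, design = mixture_design(),
                                use_margins = qpcr$n_replicates == 1L) {
  stopifnot(inherits(qpcr, "qpcr_table"), inherits(design, "mixture_design"))
  m <- qpcr_means(qpcr)
  a <- if (use_margins) design$a else 1
  b <- if (use_margins) design$b else 1
  desc <- (a * m[, "A"] >= b * m[, "C"]) &
          (a * m[, "C"] >= b * m[, "D"]) &
          (a * m[, "D"] >= b * m[, "B"])
  asc  <- (b * m[, "A"] <= a * m[, "C"]) &
          (b * m[, "C"] <= a * m[, "D"]) &
          (b * m[, "D"] <= a * m[, "B"])
  qpcr$genes[desc | asc]
}

#' Expected-mixing-ratio (EMR) filter
#'
#' For each gene with non-zero replicate-mean expression in all four samples,
#' compares the observed ratio `R = C/D` with the expected ratio
#' [emr_expected()] implied by its `A/B` ratio.  The margin intervals
#' `[b*R, a*R]` and `[b*EMR, a*EMR]` must overlap, i.e. the gene passes iff
#' `EMR * b/a <= R <= EMR * a/b`.  Genes with a zero mean in any sample are
#' excluded (their ratios are undefined).
#'
#' @inheritParams titration_order_set
#' @return Character vector: the gene IDs in the EMR set.
#' @export
emr_filter <- function(qpcr, design = mixture_design()) {
  stopifnot(inherits(qpcr, "qpcr_table"), inherits(design, "mixture_design"))
  m <- qpcr_means(qpcr)
  ok <- rowSums(m > 0) == 4L
  r_cd <- m[, "C"] / m[, "D"]
  emr <- rep(NA_real_, nrow(m))
  emr[ok] <- emr_expected(m[ok, "A"] / m[ok, "B"], design$z)
  a <- design$a; b <- design$b
  pass <- ok &
    ((r_cd >= emr & b * r_cd <= a * emr) |
     (r_cd <= emr & a * r_cd >= b * emr))
  pass[is.na(pass)] <- FALSE
  qpcr$genes[pass]
}

#' Build the benchmark reference gene set
#'
#' Chains the qPCR filters into the final reference set: detectability
#' (non-zero, Ct), titration order, expected mixing ratio, and - when count
#' matrices from one or more RNA-seq pipelines are supplied - the requirement
#' that a gene be non-zero in every replicate of every sample at every site
#' of every pipeline.  The genes are first intersected with the count
#' matrices' gene universe.  From the surviving "all genes" set, the
#' `low_fraction` (default 20%) with the smallest average qPCR expression
#' over samples A-D form the low-expressing subset (size rounded half-up).
#'
#' @param qpcr A [qpcr_table()].
#' @param count_matrices List of [expression_matrix()] objects (possibly
#'   empty) whose non-zero structure constrains the set.
#' @param design A [mixture_design()].
#' @param low_fraction Fraction of reference genes in the low-expressing
#'   subset (default 0.2).
#' @param ct_max Passed to [filter_detectable()].
#'
#' @return An object of class `reference_gene_set`: gene ID vectors
#'   `detectable`, `k_to`, `k_emr`, `all_genes`, `low_expressing`, and a
#'   per-gene `provenance` factor naming the first filter that removed each
#'   discarded gene.
#' @export
build_reference_set <- function(qpcr, count_matrices = list(),
                                design = mixture_design(),
                                low_fraction = 0.2, ct_max = 35) {
  stopifnot(inherits(qpcr, "qpcr_table"))
  if (inherits(count_matrices, "expression_matrix"))
    count_matrices <- list(count_matrices)
  universe <- qpcr$genes
  prov <- stats::setNames(rep("retained", length(universe)), universe)

  if (length(count_matrices) > 0) {
    shared <- Reduce(intersect, lapply(count_matrices, function(m) rownames(m$counts)))
    in_univ <- universe %in% shared
    prov[!in_univ] <- "not in count matrices"
  } else in_univ <- rep(TRUE, length(universe))

  detectable <- filter_detectable(qpcr, ct_max)
  prov[prov == "retained" & !(universe %in% detectable)] <- "not detectable"

  k_to <- titration_order_set(qpcr, design)
  prov[prov == "retained" & !(universe %in% k_to)] <- "titration order"

  k_emr <- emr_filter(qpcr, design)
  m <- qpcr_means(qpcr)
  zero_d <- m[, "D"] == 0
  prov[prov == "retained" & zero_d] <- "undefined ratio"
  prov[prov == "retained" & !(universe %in% k_emr)] <- "mixing ratio"

  if (length(count_matrices) > 0) {
    nz <- Reduce(`&`, lapply(count_matrices, function(mm) {
      v <- apply(mm$counts[match(universe, rownames(mm$counts)), , drop = FALSE] > 0,
                 1, all)
      v[is.na(v)] <- FALSE
      v
    }))
    prov[prov == "retained" & !nz] <- "zero count in a pipeline library"
  }

  all_genes <- universe[prov == "retained"]
  if (length(all_genes) == 0) {
    first <- names(sort(table(prov[prov != "retained"]), decreasing = TRUE))[1]
    stop("reference set is empty; dominant removing filter: ", first)
  }

  avg <- rowMeans(m[match(all_genes, universe), , drop = FALSE])
  n_low <- round_half_up(low_fraction * length(all_genes))
  low <- all_genes[order(avg, all_genes)][seq_len(n_low)]

  structure(list(detectable = detectable, k_to = k_to, k_emr = k_emr,
                 all_genes = all_genes, low_expressing = low,
                 provenance = prov, design = design,
                 low_fraction = low_fraction),
            class = "reference_gene_set")
}

#' @export
print.reference_gene_set <- function(x, ...) {
  cat(sprintf(paste0("reference_gene_set: %d detectable, %d pass TO, %d pass EMR,\n",
                     "  %d reference genes, %d low-expressing\n"),
              length(x$detectable), length(x$k_to), length(x$k_emr),
              length(x$all_genes), length(x$low_expressing)))
  invisible(x)
}
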