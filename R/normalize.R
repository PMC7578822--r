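#' Present genes for normalization
#'
#' A gene is present at a site when its replicate-mean counts satisfy
#' `(mean_A > t | mean_B > t) & mean_C > t & mean_D > t` with threshold
#' `t = 1` (strict inequality).  The final present set is the intersection of
#' the per-site sets.  Only present genes contribute to normalization-factor
#' statistics; all genes are subsequently rescaled.
#'
#' @param matrix An [expression_matrix()] with samples A-D at every site.
#' @param threshold Replicate-mean count threshold (default 1).
#' @return A list with `per_site` (named list of gene ID vectors) and
#'   `intersection`.
#' @export
present_genes <- function(matrix, threshold = 1) {
  stopifnot(inherits(matrix, "expression_matrix"))
  sites <- unique(matrix$libraries$site)
  per_site <- lapply(sites, function(st) {
    m <- sample_means(em_subset_site(matrix, st))
    keep <- (m[, "A"] > threshold | m[, "B"] > threshold) &
            m[, "C"] > threshold & m[, "D"] > threshold
    rownames(m)[keep]
  })
  names(per_site) <- sites
  list(per_site = per_site, intersection = Reduce(intersect, per_site))
}

#' Trimmed mean of M-values (TMM) scaling factor
#'
#' Computes the TMM scaling factor of a target library against a reference
#' library: gene-wise log2 expression ratios (M-values) and average log2
#' abundances (A-values) of library-size-scaled counts are trimmed
#' (`trim_m` fraction on M, `trim_a` on A, both sides) and the factor is
#' 2 to the inverse-asymptotic-variance-weighted mean of the surviving
#' M-values.  When no reference is given, the library whose present-gene
#' upper quartile (of library-size-scaled counts) is closest to the mean
#' upper quartile is used.
#'
#' @param counts Genes-by-libraries numeric matrix (present genes only).
#' @param target Column index or name of the target library.
#' @param ref Optional column index or name of the reference library.
#' @param trim_m Two-sided trim fraction on M-values (default 0.30).
#' @param trim_a Two-sided trim fraction on A-values (default 0.05).
#' @return A single positive scaling factor.
#' @export
tmm_factor <- function(counts, target, ref = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (is.null(ref)) ref <- tmm_reference(counts)
  obs <- counts[, target]; rf <- counts[, ref]
  n_o <- sum(obs); n_r <- sum(rf)
  keep <- obs > 0 & rf > 0
  obs <- obs[keep]; rf <- rf[keep]
  m_val <- log2((obs / n_o) / (rf / n_r))
  a_val <- (log2(obs / n_o) + log2(rf / n_r)) / 2
  # asymptotic variance of an M-value under binomial sampling
  v <- (n_o - obs) / (n_o * obs) + (n_r - rf) / (n_r * rf)
  if (length(m_val) == 0 || max(abs(m_val)) < 1e-6) return(1)
  n <- length(m_val)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rk_m <- rank(m_val); rk_a <- rank(a_val)
  keep2 <- rk_m >= lo_m & rk_m <= hi_m & rk_a >= lo_a & rk_a <= hi_a
  if (sum(keep2) < 2) {
    warning("fewer than 2 genes left after trimming; TMM factor set to 1")
    return(1)
  }
  f <- sum(m_val[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

tmm_reference <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, quantile7, 0.75) / lib
  which.min(abs(uq - mean(uq)))
}

#' Relative log expression (RLE) scaling factor
#'
#' Defines the median pseudo-library as the gene-wise geometric mean across
#' libraries; the scaling factor of a target library is the median over
#' genes of its ratio to the pseudo-library.  Genes with a zero count in any
#' library (zero geometric mean) are excluded.
#'
#' @param counts Genes-by-libraries numeric matrix (present genes only).
#' @param target Column index or name; when `NULL` factors for all libraries
#'   are returned.
#' @return Scaling factor(s).
#' @export
rle_factor <- function(counts, target = NULL) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no genes with positive counts in all libraries; RLE undefined")
  geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  f <- apply(counts[pos, , drop = FALSE] / geo, 2, stats::median)
  if (is.null(target)) f else unname(f[target])
}

#' Normalize a count matrix
#'
#' Applies one of the six library-scaling normalizations.  Every factor
#' statistic (present-gene totals, medians, upper quartiles, mean gene
#' length, TMM/RLE factors) is computed on present genes only, within each
#' site separately; all genes are then rescaled by their library's factor.
#' The transforms, with `x` the raw count of gene `k` in library `(s,n)`,
#' `x_sn` the library's present-gene total, and site-wide averages denoted
#' by bars, are
#' \describe{
#'   \item{fpm}{`y = x * xbar / x_sn`}
#'   \item{median}{`y = x * med_bar / med_sn`}
#'   \item{uq}{`y = x * uq_bar / uq_sn` (75th percentile)}
#'   \item{fpkm}{`y = x * lbar * xbar / (x_sn * l_k)` (lengths in bases)}
#'   \item{tmm, rle}{`y = x * xbar / (x_sn * f_sn)` with [tmm_factor()] /
#'     [rle_factor()]}
#' }
#'
#' @param matrix An [expression_matrix()] of raw counts.
#' @param method One of `"fpm"`, `"median"`, `"uq"`, `"fpkm"`, `"tmm"`,
#'   `"rle"`.
#' @param lengths Named numeric vector of gene lengths in bases (required
#'   for FPKM).
#' @param threshold Present-gene threshold, passed to [present_genes()].
#' @param trim_m,trim_a TMM trim fractions.
#' @return A list: `matrix` (normalized [expression_matrix()]), `factors`
#'   (per-library data frame of scaling statistics) and `present` (the
#'   present-gene set used).
#' @export
normalize_counts <- function(matrix, method = c("fpm", "median", "uq", "fpkm",
                                                "tmm", "rle"),
                             lengths = NULL, threshold = 1,
                             trim_m = 0.30, trim_a = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "expression_matrix"))
  kp <- present_genes(matrix, threshold)$intersection
  if (length(kp) == 0) stop("present gene set is empty")
  if (method == "fpkm") {
    if (is.null(lengths)) stop("FPKM needs a 'lengths' table")
    miss <- setdiff(kp, names(lengths))
    if (length(miss) > 0) stop("lengths missing for present gene(s): ", miss[1])
  }
  out <- matrix$counts
  fac_rows <- list()
  for (st in unique(matrix$libraries$site)) {
    cols <- which(matrix$libraries$site == st)
    sub <- matrix$counts[, cols, drop = FALSE]
    pres <- sub[kp, , drop = FALSE]
    totals <- colSums(pres)
    if (any(totals == 0))
      stop("zero present-gene total in library ",
           colnames(sub)[which(totals == 0)[1]])
    xbar <- mean(totals)
    scale_fac <- switch(method,
      fpm = xbar / totals,
      fpkm = xbar / totals,
      tmm = , rle = xbar / totals,
      median = {
        med <- apply(pres, 2, stats::median)
        if (any(med == 0)) stop("zero present-gene median in library ",
                                colnames(sub)[which(med == 0)[1]])
        mean(med) / med
      },
      uq = {
        uq <- apply(pres, 2, quantile7, 0.75)
        if (any(uq == 0)) stop("zero present-gene upper quartile in library ",
                               colnames(sub)[which(uq == 0)[1]])
        mean(uq) / uq
      })
    f_rob <- rep(1, length(cols))
    if (method == "tmm") {
      rf <- tmm_reference(pres)
      f_rob <- vapply(seq_len(ncol(pres)), function(j)
        tmm_factor(pres, j, rf, trim_m, trim_a), numeric(1))
      scale_fac <- scale_fac / f_rob
    } else if (method == "rle") {
      f_rob <- rle_factor(pres)
      scale_fac <- scale_fac / f_rob
    }
    y <- sweep(sub, 2, scale_fac, `*`)
    if (method == "fpkm") {
      lbar <- mean(lengths[kp])
      lk <- lengths[rownames(sub)]
      lk[is.na(lk)] <- lbar   # genes without a length scale like average
      y <- y * (lbar / lk)
    }
    out[, cols] <- y
    fac_rows[[st]] <- data.frame(library = colnames(sub), site = st,
                                 total = totals, scale = scale_fac,
                                 robust_factor = f_rob,
                                 stringsAsFactors = FALSE)
  }
  list(matrix = expression_matrix(out, matrix$libraries, matrix$pipeline),
       factors = do.call(rbind, c(fac_rows, make.row.names = FALSE)),
       present = kp, method = method)
}
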