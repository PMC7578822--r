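#' qPCR expression table
#'
#' Linear-scale qPCR expression of K genes in the four titration samples,
#' possibly with several replicate measurements per sample, and optional
#' cycle-threshold (Ct) values.
#'
#' @param expr Either a genes-by-4 matrix (columns A, B, C, D; single
#'   replicate) or a 3-dimensional array genes x 4 samples x N replicates.
#'   Rownames are gene IDs.
#' @param ct Optional genes-by-4 matrix of Ct values (columns A..D).
#'
#' @return An object of class `qpcr_table` with elements `q` (genes x sample
#'   x replicate array), `ct`, `genes` and `n_replicates`.
#' @export
qpcr_table <- function(expr, ct = NULL) {
  samples <- c("A", "B", "C", "D")
  if (length(dim(expr)) == 2L) {
    expr <- as.matrix(expr)
    if (!all(samples %in% colnames(expr)))
      stop("'expr' needs columns A, B, C, D")
    q <- array(expr[, samples], dim = c(nrow(expr), 4L, 1L),
               dimnames = list(rownames(expr), samples, NULL))
  } else if (length(dim(expr)) == 3L) {
    q <- expr
    if (!identical(dimnames(q)[[2]], samples))
      stop("second dimension of 'expr' must be samples A, B, C, D")
  } else stop("'expr' must be a matrix or a 3-d array")
  if (is.null(dimnames(q)[[1]]) || anyDuplicated(dimnames(q)[[1]]))
    stop("gene IDs must be unique rownames")
  if (any(q < 0)) stop("qPCR expression must be non-negative")
  if (!is.null(ct)) {
    ct <- as.matrix(ct)
    if (!all(samples %in% colnames(ct))) stop("'ct' needs columns A, B, C, D")
    ct <- ct[, samples, drop = FALSE]
    rownames(ct) <- dimnames(q)[[1]]
  }
  structure(list(q = q, ct = ct, genes = dimnames(q)[[1]],
                 n_replicates = dim(q)[3]),
            class = "qpcr_table")
}

#' @export
print.qpcr_table <- function(x, ...) {
  cat(sprintf("qpcr_table: %d genes, %d replicate(s)%s\n",
              length(x$genes), x$n_replicates,
              if (is.null(x$ct)) "" else ", with Ct values"))
  invisible(x)
}

# replicate means, genes x 4 samples
qpcr_means <- function(q) {
  stopifnot(inherits(q, "qpcr_table"))
  m <- apply(q$q, c(1, 2), mean)
  dimnames(m) <- dimnames(q$q)[1:2]
  m
}

qpcr_table_from_df <- function(tab) {
  genes <- as.character(tab[[1]])
  samples <- c("A", "B", "C", "D")
  cols <- setdiff(names(tab), names(tab)[1])
  ct_cols <- paste0("Ct_", samples)
  expr_cols <- setdiff(cols, ct_cols)
  # replicate columns written as A.1, A.2, ...
  rep_of <- sub("^([ABCD])(\\.[0-9]+)?$", "\\2", expr_cols)
  samp_of <- sub("^([ABCD])(\\.[0-9]+)?$", "\\1", expr_cols)
  if (!all(samp_of %in% samples)) stop("unrecognized qPCR column(s): ",
                                       paste(expr_cols[!samp_of %in% samples], collapse = ", "))
  n_rep <- max(table(samp_of))
  q <- array(NA_real_, dim = c(length(genes), 4L, n_rep),
             dimnames = list(genes, samples, NULL))
  for (s in samples) {
    sc <- expr_cols[samp_of == s]
    sc <- sc[order(rep_of[samp_of == s])]
    for (i in seq_along(sc)) q[, s, i] <- as.numeric(tab[[sc[i]]])
  }
  if (anyNA(q)) stop("unbalanced replicate columns in qPCR table")
  ct <- NULL
  if (all(ct_cols %in% cols)) {
    ct <- as.matrix(tab[, ct_cols])
    colnames(ct) <- samples
  }
  qpcr_table(q, ct)
}

qpcr_as_df <- function(q) {
  samples <- c("A", "B", "C", "D")
  if (q$n_replicates == 1L) {
    df <- data.frame(gene = q$genes, q$q[, , 1, drop = TRUE],
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    cols <- do.call(cbind, lapply(samples, function(s) {
      m <- q$q[, s, , drop = TRUE]
      colnames(m) <- paste0(s, ".", seq_len(ncol(m)))
      m
    }))
    df <- data.frame(gene = q$genes, cols, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  if (!is.null(q$ct)) {
    ctd <- q$ct
    colnames(ctd) <- paste0("Ct_", samples)
    df <- cbind(df, ctd)
  }
  df
}

subset_qpcr <- function(q, genes) {
  keep <- match(genes, q$genes)
  qpcr_table(q$q[keep, , , drop = FALSE],
             if (is.null(q$ct)) NULL else q$ct[keep, , drop = FALSE])
}
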