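#' Expression matrix with library annotations
#'
#' Container for a gene-by-library count (or normalized expression) matrix
#' together with the per-library annotations of the titration design: which
#' sample (A, B, C or D) the library measures, its replicate number and the
#' sequencing site that produced it.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene IDs),
#'   libraries in columns (colnames = library IDs).  Values must be
#'   non-negative.
#' @param libraries Data frame with columns `library`, `sample`, `replicate`,
#'   `site`, one row per column of `counts`.
#' @param pipeline Optional pipeline identifier carried along in reports.
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, libraries, pipeline = NA_character_) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("'counts' must have unique gene IDs as rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("'counts' must have unique library IDs as colnames")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("'counts' must be finite and numeric")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative count at gene '%s', library '%s'",
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  req <- c("library", "sample", "replicate", "site")
  if (!all(req %in% names(libraries)))
    stop("'libraries' needs columns: ", paste(req, collapse = ", "))
  libraries <- as.data.frame(libraries)[, req]
  missing_lib <- setdiff(colnames(counts), libraries$library)
  if (length(missing_lib) > 0)
    stop("libraries absent from sample sheet: ", paste(missing_lib, collapse = ", "))
  extra <- setdiff(libraries$library, colnames(counts))
  if (length(extra) > 0)
    stop("sample sheet references missing library column: ",
         paste(extra, collapse = ", "))
  libraries <- libraries[match(colnames(counts), libraries$library), ]
  rownames(libraries) <- NULL
  structure(list(counts = counts, libraries = libraries, pipeline = pipeline),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$libraries$site), collapse = ", ")))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @param site Optional site label; restricts to that site's libraries.
#' @export
em_subset_site <- function(x, site) {
  stopifnot(inherits(x, "expression_matrix"))
  keep <- x$libraries$site == site
  if (!any(keep)) stop("no libraries for site '", site, "'")
  expression_matrix(x$counts[, keep, drop = FALSE],
                    x$libraries[keep, , drop = FALSE], x$pipeline)
}

# replicate-mean counts per sample for one site: genes x samples matrix
sample_means <- function(x, samples = c("A", "B", "C", "D")) {
  stopifnot(inherits(x, "expression_matrix"))
  out <- vapply(samples, function(s) {
    cols <- x$libraries$sample == s
    if (!any(cols)) stop("sample '", s, "' missing from matrix")
    rowMeans(x$counts[, cols, drop = FALSE])
  }, numeric(nrow(x$counts)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, samples))
  rownames(out) <- rownames(x$counts)
  out
}

#' Read a gene-by-library count matrix with its sample sheet
#'
#' The counts file is tab-separated with a header row of library IDs and gene
#' IDs in the first column.  The sample sheet is tab-separated with columns
#' `library`, `sample`, `replicate`, `site`.
#'
#' @param path Path to the counts TSV.
#' @param sample_sheet_path Path to the sample-sheet TSV.
#' @param pipeline Optional pipeline label attached to the result.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, sample_sheet_path, pipeline = NA_character_) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) stop("duplicate gene ID in ", path, ": ", dup[1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row %d, column '%s' of %s",
                 bad[1, 1], colnames(m)[bad[1, 2]], path))
  }
  rownames(m) <- genes
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  expression_matrix(m, sheet, pipeline)
}

#' @rdname read_counts
#' @param x An `expression_matrix` to write.
#' @export
write_counts <- function(x, path, sample_sheet_path = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path))
    utils::write.table(x$libraries, sample_sheet_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a qPCR expression table
#'
#' Tab-separated, one row per gene: `gene`, linear-scale expression columns
#' `A`, `B`, `C`, `D` (replicated measurements as `A.1`, `A.2`, ...), and
#' optional cycle-threshold columns `Ct_A` .. `Ct_D`.
#'
#' @param path File path.
#' @return A [qpcr_table()].
#' @export
read_qpcr <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  qpcr_table_from_df(tab)
}

#' @rdname read_qpcr
#' @param q A `qpcr_table`.
#' @export
write_qpcr <- function(q, path) {
  stopifnot(inherits(q, "qpcr_table"))
  df <- qpcr_as_df(q)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-length table (TSV: gene, length_bp)
#' @param path File path.
#' @return Named numeric vector of lengths in bases.
#' @export
read_lengths <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Read a survival table (TSV: patient, time, event)
#' @param path File path.
#' @return Data frame with columns `patient`, `time`, `event`.
#' @export
read_survival <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_survival(tab)
}

validate_survival <- function(tab) {
  req <- c("patient", "time", "event")
  if (!all(req %in% names(tab)))
    stop("survival table needs columns: ", paste(req, collapse = ", "))
  if (any(tab$time <= 0)) stop("survival times must be positive")
  if (!all(tab$event %in% c(0, 1))) stop("event flags must be 0/1")
  tab[, req]
}

#' Write an analysis report deterministically
#'
#' JSON reports are written with fixed field ordering and 6 significant
#' digits; TSV reports likewise.  Run metadata (package version and seed, when
#' supplied) is embedded so identical inputs reproduce byte-identical files.
#'
#' @param results A list (JSON) or data frame (TSV or JSON).
#' @param path Output file.
#' @param format `"json"` or `"tsv"`.
#' @param seed Optional seed recorded in the metadata.
#' @export
write_report <- function(results, path, format = c("json", "tsv"), seed = NULL) {
  format <- match.arg(format)
  round6 <- function(v) {
    if (is.numeric(v)) signif(v, 6)
    else if (is.list(v) && !is.data.frame(v)) lapply(v, round6)
    else if (is.data.frame(v)) { v[] <- lapply(v, function(c) if (is.numeric(c)) signif(c, 6) else c); v }
    else v
  }
  results <- round6(results)
  if (format == "tsv") {
    stopifnot(is.data.frame(results))
    utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- list(
      meta = list(package = "titrabench",
                  version = as.character(utils::packageVersion("titrabench")),
                  seed = seed),
      results = results)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}
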