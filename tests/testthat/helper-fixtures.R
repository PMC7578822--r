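# fixture builders shared across test files

# expression_matrix for one site from a genes x (samples*reps) layout
make_em <- function(counts_by_sample, n_rep = NULL, site = "S1",
                    pipeline = "test") {
  # counts_by_sample: named list sample -> genes x reps matrix
  samples <- names(counts_by_sample)
  mats <- lapply(counts_by_sample, as.matrix)
  ng <- nrow(mats[[1]])
  genes <- rownames(mats[[1]]) %||% sprintf("g%03d", seq_len(ng))
  cols <- list(); meta <- list()
  for (s in samples) {
    m <- mats[[s]]
    rownames(m) <- genes
    for (r in seq_len(ncol(m))) {
      lib <- sprintf("%s_%s_%d", site, s, r)
      cols[[lib]] <- m[, r]
      meta[[lib]] <- data.frame(library = lib, sample = s, replicate = r,
                                site = site, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- genes
  expression_matrix(counts, do.call(rbind, meta), pipeline)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# qpcr_table from a genes x 4 matrix of A,B,C,D means
make_qpcr <- function(m, ct = NULL) {
  m <- as.matrix(m)
  colnames(m) <- c("A", "B", "C", "D")
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  qpcr_table(m, ct)
}

# brute-force one-way ANOVA mean squares via explicit sums of squares
oracle_oneway <- function(y, groups) {
  groups <- as.factor(groups)
  grand <- mean(y)
  bss <- 0; wss <- 0
  for (g in levels(groups)) {
    yg <- y[groups == g]
    bss <- bss + length(yg) * (mean(yg) - grand)^2
    wss <- wss + sum((yg - mean(yg))^2)
  }
  j <- nlevels(groups); k <- length(y) / j
  list(bms = bss / (j - 1), wms = wss / (j * (k - 1)))
}

# exhaustive one-sided rank-sum p for small groups
oracle_wilcoxon <- function(good, poor) {
  n1 <- length(good); n <- n1 + length(poor)
  r <- rank(c(good, poor))
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combs], nrow = n1))
  mean(sums >= obs - 1e-9)
}
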