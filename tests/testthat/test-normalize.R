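make_site_em <- function(counts, site = "S1") {
  # counts: genes x 16 (4 samples x 4 reps)
  split_cols <- split(seq_len(16), rep(c("A", "B", "C", "D"), each = 4))
  make_em(lapply(split_cols, function(j) counts[, j, drop = FALSE]), site = site)
}

test_that("present-gene rule is (A|B) & C & D with strict > 1", {
  cases <- rbind(g1 = c(5, 0, 2, 2),     # present: A>1, C>1, D>1
                 g2 = c(5, 5, 0.5, 5),   # absent: fails C
                 g3 = c(0.5, 0.5, 2, 2), # absent: fails A|B
                 g4 = c(1, 1, 2, 2))     # absent: mean exactly 1 not > 1
  counts <- cases[, rep(1:4, each = 4)]  # identical replicates = means
  em <- make_site_em(counts)
  kp <- present_genes(em)
  expect_equal(kp$per_site$S1, "g1")
  expect_equal(kp$intersection, "g1")
})

test_that("present set intersects per-site sets", {
  c1 <- rbind(g1 = c(5, 5, 5, 5), g2 = c(5, 5, 5, 5))[, rep(1:4, each = 4)]
  c2 <- rbind(g1 = c(5, 5, 5, 5), g2 = c(5, 5, 0.5, 5))[, rep(1:4, each = 4)]
  em1 <- make_site_em(c1, "S1"); em2 <- make_site_em(c2, "S2")
  both <- expression_matrix(cbind(em1$counts, em2$counts),
                            rbind(em1$libraries, em2$libraries))
  kp <- present_genes(both)
  expect_setequal(kp$per_site$S1, c("g1", "g2"))
  expect_equal(kp$per_site$S2, "g1")
  expect_equal(kp$intersection, "g1")
})

test_that("FPM rescales by average present-gene total over library total", {
  # two libraries with present totals 100 and 300 -> xbar = 200
  counts <- cbind(c(10, 90), c(30, 270))
  rownames(counts) <- c("g1", "g2")
  em <- make_em(list(A = counts[, 1, drop = FALSE], B = counts[, 2, drop = FALSE],
                     C = counts[, 1, drop = FALSE], D = counts[, 2, drop = FALSE]))
  norm <- normalize_counts(em, "fpm")
  expect_equal(unname(norm$matrix$counts["g1", 1]), 10 * 200 / 100)
  expect_equal(unname(norm$matrix$counts["g1", 2]), 30 * 200 / 300)
})

test_that("identical libraries make every normalization the identity map", {
  set.seed(21)
  v <- rpois(30, 50) + 2
  counts <- matrix(v, 30, 16)
  rownames(counts) <- sprintf("g%02d", 1:30)
  em <- make_site_em(counts)
  lengths <- setNames(rep(1000, 30), rownames(counts))
  for (meth in c("fpm", "median", "uq", "tmm", "rle"))
    expect_equal(normalize_counts(em, meth)$matrix$counts, em$counts,
                 tolerance = 1e-12, label = meth)
  expect_equal(normalize_counts(em, "fpkm", lengths = lengths)$matrix$counts,
               em$counts, tolerance = 1e-12)
})

test_that("median and UQ normalization reproduce the site-average statistics", {
  set.seed(22)
  counts <- matrix(rpois(40 * 16, 100) + 2, 40, 16)
  rownames(counts) <- sprintf("g%02d", 1:40)
  em <- make_site_em(counts)
  kp <- present_genes(em)$intersection
  nm <- normalize_counts(em, "median")
  meds <- apply(nm$matrix$counts[kp, ], 2, median)
  xtilde <- mean(apply(counts[kp, ], 2, median))
  expect_equal(unname(meds), rep(xtilde, 16), tolerance = 1e-9)
  nu <- normalize_counts(em, "uq")
  uqs <- apply(nu$matrix$counts[kp, ], 2, quantile, 0.75, names = FALSE)
  xhat <- mean(apply(counts[kp, ], 2, quantile, 0.75, names = FALSE))
  expect_equal(unname(uqs), rep(xhat, 16), tolerance = 1e-9)
  nf <- normalize_counts(em, "fpm")
  tots <- colSums(nf$matrix$counts[kp, ])
  expect_equal(unname(tots), rep(mean(colSums(counts[kp, ])), 16),
               tolerance = 1e-9)
})

test_that("FPKM relates to FPM through the gene-length ratio", {
  set.seed(23)
  counts <- matrix(rpois(20 * 16, 80) + 2, 20, 16)
  rownames(counts) <- sprintf("g%02d", 1:20)
  em <- make_site_em(counts)
  kp <- present_genes(em)$intersection
  # choose g05's length so it equals exactly twice the present-gene average:
  # with n-1 genes of length l0, L = 2*lbar  <=>  L = 2*(n-1)*l0/(n-2)
  l0 <- 1500; n <- length(kp)
  lengths <- setNames(rep(l0, 20), rownames(counts))
  lengths["g05"] <- 2 * (n - 1) * l0 / (n - 2)
  lbar <- mean(lengths[kp])
  expect_equal(unname(lengths["g05"]), 2 * lbar, tolerance = 1e-12)
  fpkm <- normalize_counts(em, "fpkm", lengths = lengths)$matrix$counts
  fpm <- normalize_counts(em, "fpm")$matrix$counts
  expect_equal(fpkm["g05", ], fpm["g05", ] / 2, tolerance = 1e-9)
  other <- setdiff(rownames(counts), "g05")[1]
  expect_equal(fpkm[other, ], fpm[other, ] * lbar / l0, tolerance = 1e-9)
})

test_that("FPKM equals FPM when all genes share one length", {
  set.seed(24)
  counts <- matrix(rpois(15 * 16, 60) + 2, 15, 16)
  rownames(counts) <- sprintf("g%02d", 1:15)
  em <- make_site_em(counts)
  lengths <- setNames(rep(777, 15), rownames(counts))
  expect_equal(normalize_counts(em, "fpkm", lengths = lengths)$matrix$counts,
               normalize_counts(em, "fpm")$matrix$counts, tolerance = 1e-12)
})

test_that("scaling one library's counts only rescales the site average", {
  # multiplying one library by c > 0 cancels inside its own factor; the sole
  # effect is through the site-average statistic, common to all libraries
  set.seed(25)
  counts <- matrix(rpois(30 * 16, 90) + 2, 30, 16)
  rownames(counts) <- sprintf("g%02d", 1:30)
  em <- make_site_em(counts)
  scaled <- counts; scaled[, 3] <- scaled[, 3] * 7
  em2 <- make_site_em(scaled)
  for (meth in c("fpm", "median", "uq")) {
    n1 <- normalize_counts(em, meth)$matrix$counts
    n2 <- normalize_counts(em2, meth)$matrix$counts
    ratio <- n2 / n1
    expect_equal(max(ratio), min(ratio), tolerance = 1e-9, label = meth)
  }
})

test_that("TMM factor is 1 for self-comparison and scaled copies", {
  set.seed(26)
  v <- rpois(200, 100) + 1
  counts <- cbind(lib1 = v, lib2 = v * 2L, lib3 = rpois(200, 100) + 1)
  expect_equal(tmm_factor(counts, 1, ref = 1), 1)
  # doubling cancels through the library-size division
  expect_equal(tmm_factor(counts, 2, ref = 1), 1, tolerance = 1e-9)
})

test_that("TMM trims a perturbed minority back to a factor near 1", {
  set.seed(27)
  v <- rpois(500, 100) + 1
  pert <- v
  idx <- 1:10                        # 2% of genes, well inside the 30% trim
  pert[idx] <- pert[idx] * 3L
  counts <- cbind(ref = v, target = pert)
  f <- tmm_factor(counts, "target", ref = "ref")
  # brute-force oracle: trimmed weighted mean computed directly
  n_o <- sum(pert); n_r <- sum(v)
  m_val <- log2((pert / n_o) / (v / n_r))
  a_val <- (log2(pert / n_o) + log2(v / n_r)) / 2
  w <- 1 / ((n_o - pert) / (n_o * pert) + (n_r - v) / (n_r * v))
  n <- length(m_val)
  lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m_val) >= lo_m & rank(m_val) <= hi_m &
          rank(a_val) >= lo_a & rank(a_val) <= hi_a
  oracle <- 2^(sum(m_val[keep] * w[keep]) / sum(w[keep]))
  expect_equal(f, oracle, tolerance = 1e-12)
  # the perturbed minority is trimmed away; only the small library-size
  # inflation (4%) it causes remains
  expect_lt(abs(log2(f)), 0.1)
})

test_that("TMM factor ratios agree with edgeR on random counts", {
  skip_if_not_installed("edgeR")
  set.seed(28)
  counts <- matrix(rnbinom(300 * 4, mu = 200, size = 10) + 1, 300, 4)
  ours <- sapply(1:4, function(j) tmm_factor(counts, j, ref = 1))
  theirs <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = 1)
  # edgeR centres factors to geometric mean 1; ratios are invariant
  expect_equal(ours / ours[2], theirs / theirs[2], tolerance = 1e-6)
})

test_that("RLE factors follow the median-of-ratios definition", {
  v <- c(10, 20, 40, 80, 160)
  counts <- cbind(a = v, b = 3 * v)
  f <- rle_factor(counts)
  expect_equal(unname(f), c(1 / sqrt(3), sqrt(3)), tolerance = 1e-9)
  expect_equal(unname(rle_factor(cbind(only = v))), 1)
  same <- cbind(a = v, b = v, c = v)
  expect_equal(unname(rle_factor(same)), c(1, 1, 1))
})

test_that("normalization errors carry the offending library or site", {
  counts <- matrix(2, 4, 16, dimnames = list(sprintf("g%d", 1:4), NULL))
  em <- make_site_em(counts)
  em$counts[, 1] <- 0
  expect_error(normalize_counts(em, "fpm"), "S1_A_1")
  one_sample <- make_em(list(A = matrix(5, 3, 4,
                                        dimnames = list(c("g1", "g2", "g3"), NULL))))
  expect_error(present_genes(one_sample), "sample 'B' missing")
})
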