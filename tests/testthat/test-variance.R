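# balanced synthetic factorial of pipeline descriptors
make_descriptors <- function(mappers = c("aln1", "aln2"),
                             quants = c("count", "prob"),
                             norms = c("fpm", "median")) {
  grid <- expand.grid(mapping_algorithm = mappers, quantification = quants,
                      normalization = norms, stringsAsFactors = FALSE)
  grid$mapping_strategy <- ifelse(grid$mapping_algorithm == mappers[1],
                                  "spliced", "un-spliced")
  grid$mapping_reporting <- "single-hit"
  grid$pipeline <- sprintf("p%02d", seq_len(nrow(grid)))
  grid
}

test_that("sequential sums of squares conserve the total and percentages sum to 100", {
  set.seed(41)
  desc <- make_descriptors()
  y <- rnorm(nrow(desc))
  dec <- anova_decomposition(y, desc)
  expect_equal(sum(dec$table$sum_sq), dec$total_ss, tolerance = 1e-10)
  expect_equal(sum(dec$table$pct_ss), 100, tolerance = 1e-10)
  expect_equal(dec$total_ss, sum((y - mean(y))^2), tolerance = 1e-10)
})

test_that("a pure normalization effect is attributed entirely to normalization", {
  desc <- make_descriptors()
  y <- ifelse(desc$normalization == "fpm", 1, 2)
  dec <- suppressWarnings(anova_decomposition(y, desc))
  tab <- dec$table
  expect_equal(tab$sum_sq[tab$term == "normalization"], dec$total_ss,
               tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "Residuals"], 0, tolerance = 1e-10)
  other <- !(tab$term %in% c("normalization", "Residuals"))
  expect_equal(sum(tab$sum_sq[other]), 0, tolerance = 1e-10)
})

test_that("a constant response yields zero sums of squares throughout", {
  desc <- make_descriptors()
  dec <- suppressWarnings(anova_decomposition(rep(3, nrow(desc)), desc))
  expect_true(dec$constant_response)
  expect_equal(sum(dec$table$sum_sq), 0, tolerance = 1e-12)
})

test_that("type-I SS match a projection oracle on a balanced 2x2 design", {
  set.seed(42)
  desc <- make_descriptors(mappers = "aln1",
                           quants = c("count", "prob"),
                           norms = c("fpm", "median"))
  desc <- desc[rep(1:4, each = 5), ]   # 5 replicates per cell
  y <- 0.7 * (desc$quantification == "prob") +
       1.3 * (desc$normalization == "median") + rnorm(nrow(desc), 0, 0.3)
  dec <- anova_decomposition(y, desc)
  tab <- dec$table
  # balanced design: sequential SS equal explicit group-mean projections
  ss_between <- function(f) {
    gm <- tapply(y, f, mean)
    sum(table(f) * (gm - mean(y))^2)
  }
  expect_equal(tab$sum_sq[tab$term == "quantification"],
               ss_between(desc$quantification), tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "normalization"],
               ss_between(desc$normalization), tolerance = 1e-8)
  cell <- interaction(desc$quantification, desc$normalization)
  ss_cells <- ss_between(cell)
  expect_equal(tab$sum_sq[tab$term == "quantification:normalization"],
               ss_cells - ss_between(desc$quantification) -
                 ss_between(desc$normalization), tolerance = 1e-8)
})

test_that("type-I SS of the first term equals its one-way ANOVA SS", {
  set.seed(43)
  desc <- make_descriptors()
  y <- rnorm(nrow(desc))
  dec <- anova_decomposition(y, desc)
  oneway <- anova(lm(y ~ factor(desc$mapping_algorithm)))
  expect_equal(dec$table$sum_sq[dec$table$term == "mapping_algorithm"],
               oneway$`Sum Sq`[1], tolerance = 1e-10)
})

test_that("aliased interactions of confounded factors are reported as dropped", {
  set.seed(44)
  desc <- make_descriptors()   # strategy is a function of mapping_algorithm
  y <- rnorm(nrow(desc))
  dec <- anova_decomposition(y, desc)
  expect_true("mapping_algorithm:mapping_strategy" %in% dec$dropped)
  # conservation still holds with aliasing
  expect_equal(sum(dec$table$pct_ss), 100, tolerance = 1e-10)
})

test_that("Huber regression recovers exact and outlier-contaminated lines", {
  x <- 1:10
  fit <- suppressWarnings(huber_regression(x, 2 * x))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  y <- 2 * x; y[10] <- 60                       # gross outlier
  hub <- huber_regression(x, y)
  ols <- lm(y ~ x)
  expect_lt(abs(hub$slope - 2) / 2, 0.05)
  expect_gt(abs(coef(ols)[2] - 2), abs(hub$slope - 2))
  # grid-search M-estimate oracle over (slope, intercept)
  huber_rho <- function(r, k = 1.345, s) {
    a <- abs(r / s)
    sum(ifelse(a <= k, 0.5 * a^2, k * a - 0.5 * k^2))
  }
  s <- mad(residuals(MASS::rlm(y ~ x)))
  grid <- expand.grid(b = seq(1.5, 2.5, 0.005), a = seq(-2, 2, 0.05))
  loss <- mapply(function(b, a) huber_rho(y - a - b * x, s = s),
                 grid$b, grid$a)
  best <- grid[which.min(loss), ]
  expect_equal(hub$slope, best$b, tolerance = 0.02)
})

test_that("duplicating every point leaves the Huber fit unchanged", {
  set.seed(45)
  x <- runif(20); y <- 1 + 3 * x + rnorm(20, 0, 0.2)
  f1 <- huber_regression(x, y)
  f2 <- huber_regression(rep(x, 2), rep(y, 2))
  expect_equal(f2$slope, f1$slope, tolerance = 1e-6)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-6)
})

test_that("Huber fit equals OLS when all residuals are below the threshold", {
  # alternating +-c residuals: every |r| < 1.345 * 1.4826 * c, so all Huber
  # weights are 1 and the M-estimate coincides with least squares
  x <- 1:30
  y <- 2 + 0.5 * x + rep(c(-0.01, 0.01), 15)
  hub <- huber_regression(x, y)
  ols <- lm(y ~ x)
  expect_equal(hub$slope, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(hub$intercept, unname(coef(ols)[1]), tolerance = 1e-6)
})

test_that("regression input validation", {
  expect_error(huber_regression(1:2, 1:2), "3")
  expect_error(huber_regression(rep(1, 5), 1:5), "constant")
})

test_that("distribution profile returns the nine named statistics", {
  p <- distribution_profile(c(1, 2, 3, 4, 5))
  expect_named(p, c("lower_quartile", "median", "upper_quartile", "maximum",
                    "iqr", "sd", "skewness", "kurtosis", "entropy"))
  expect_equal(unname(p["median"]), 3)
  expect_equal(unname(p["maximum"]), 5)
  # type-7 quartiles against a direct sort-and-interpolate oracle
  expect_equal(unname(p["lower_quartile"]), quantile(1:5, 0.25, names = FALSE))
  expect_equal(unname(p["iqr"]),
               quantile(1:5, 0.75, names = FALSE) - quantile(1:5, 0.25, names = FALSE))
  expect_equal(unname(p["skewness"]), 0)   # symmetric
  cst <- distribution_profile(rep(4, 10))
  expect_equal(unname(cst[c("sd", "iqr", "entropy")]), c(0, 0, 0))
})
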