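#' Simulation configuration
#'
#' Parameters of the bundled mixture-design simulator.  The defaults
#' emulate the benchmark study conditions: two sequencing sites with four
#' replicate libraries for each of the four samples, single-replicate qPCR
#' with a 15% coefficient of variation, negative-binomial sequencing counts,
#' and a configurable share of "violator" genes whose mixture expression
#' ignores the titration law.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicate libraries per sample per site (default 4).
#' @param sites Site labels (default `c("BGI", "MAY")`).
#' @param qpcr_cov Relative coefficient of variation of qPCR measurements
#'   (default 0.15; 0 disables qPCR noise).
#' @param count_dispersion Negative-binomial dispersion of counts (default
#'   0.005, giving replicate CoVs of a few percent for well-expressed
#'   genes; 0 turns count noise off, yielding deterministic expected
#'   counts).
#' @param library_size_range Min/max expected fragments per library
#'   (default 0.5e6 to 2e6).
#' @param violator_fraction Share of genes violating the mixing law
#'   (default 0).
#' @param signal_genes Number of survival-informative genes (default 20).
#' @param n_patients Cohort size for clinical simulations (default 200).
#' @param effect_size Log2-scale expression shift of signal genes between
#'   risk groups, in within-group SD units (default 1).
#' @param censor_rate Approximate fraction of censored patients (default
#'   0.3; 0 disables censoring).
#' @param seed Integer seed; identical configurations reproduce identical
#'   output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000, n_replicates = 4,
                              sites = c("BGI", "MAY"), qpcr_cov = 0.15,
                              count_dispersion = 0.005,
                              library_size_range = c(5e5, 2e6),
                              violator_fraction = 0, signal_genes = 20,
                              n_patients = 200, effect_size = 1,
                              censor_rate = 0.3, seed = 1L) {
  stopifnot(n_genes >= 1, n_replicates >= 1, length(sites) >= 1,
            qpcr_cov >= 0, count_dispersion >= 0,
            length(library_size_range) == 2L,
            all(library_size_range > 0),
            library_size_range[1] <= library_size_range[2],
            violator_fraction >= 0, violator_fraction <= 1,
            signal_genes >= 0, signal_genes <= n_genes,
            n_patients >= 2, censor_rate >= 0, censor_rate < 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 sites = sites, qpcr_cov = qpcr_cov,
                 count_dispersion = count_dispersion,
                 library_size_range = library_size_range,
                 violator_fraction = violator_fraction,
                 signal_genes = as.integer(signal_genes),
                 n_patients = as.integer(n_patients),
                 effect_size = effect_size, censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# lognormal multiplier with unit mean and coefficient of variation cv
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# NB draw around mean mu with dispersion phi (var = mu + phi mu^2);
# phi = 0 turns count noise off entirely (deterministic expected counts)
draw_counts <- function(mu, phi) {
  if (phi == 0) mu
  else stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
}

#' Simulate a titration benchmark dataset
#'
#' Draws per-gene true expression for the reference samples A and B
#' (log-normal levels with a wide spread of A/B fold changes), derives the
#' mixtures C and D by [mixture_expression()], and generates (i) a
#' single-replicate qPCR table with multiplicative log-normal noise at the
#' configured CoV and (ii) site-wise count matrices whose expected counts
#' are proportional to expression times gene length, scaled to the
#' library size, with negative-binomial noise.  A configured fraction of
#' "violator" genes has its C and/or D expression multiplied by a factor
#' outside the margin band `(a/b)^2` so the EMR filter detects them in the
#' noiseless limit.
#'
#' @param config A [simulation_config()].
#' @param design A [mixture_design()].
#' @return A list: `qpcr` ([qpcr_table()]), `counts`
#'   ([expression_matrix()] over all sites), `lengths` (named vector, bp)
#'   and `truth` (list with per-gene expression, violator flags and library
#'   scaling factors).
#' @export
simulate_benchmark <- function(config = simulation_config(),
                               design = mixture_design()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("gene_%05d", seq_len(ng))

  # true expression: lognormal baseline, symmetric log2 fold changes A vs B
  base <- stats::rlnorm(ng, meanlog = 3, sdlog = 1.2)
  lfc <- stats::rnorm(ng, 0, 1.5)
  expr_a <- base * 2^(lfc / 2)
  expr_b <- base * 2^(-lfc / 2)
  mix <- mixture_expression(expr_a, expr_b, design)
  expr_c <- mix$c; expr_d <- mix$d

  n_viol <- round_half_up(config$violator_fraction * ng)
  violator <- rep(FALSE, ng)
  if (n_viol > 0) {
    idx <- sample.int(ng, n_viol)
    violator[idx] <- TRUE
    # multiply C (or divide) by a factor beyond the (a/b)^2 band so the
    # observed C/D ratio falls outside [EMR*b/a, EMR*a/b] even if the TO
    # chain happens to tolerate it
    gamma <- (design$a / design$b)^2 * stats::runif(n_viol, 1.25, 2)
    flip <- sample(c(TRUE, FALSE), n_viol, replace = TRUE)
    expr_c[idx] <- ifelse(flip, expr_c[idx] * gamma, expr_c[idx] / gamma)
  }

  expr <- cbind(A = expr_a, B = expr_b, C = expr_c, D = expr_d)
  rownames(expr) <- genes

  qpcr_expr <- expr * matrix(lnorm_noise(4 * ng, config$qpcr_cov), ng, 4)
  qpcr <- qpcr_table(qpcr_expr)

  lengths <- stats::setNames(round(stats::rlnorm(ng, log(1500), 0.6)) + 100, genes)

  samples <- c("A", "B", "C", "D")
  lib_meta <- expand.grid(replicate = seq_len(config$n_replicates),
                          sample = samples, site = config$sites,
                          stringsAsFactors = FALSE)
  lib_meta$library <- sprintf("%s_%s_%d", lib_meta$site, lib_meta$sample,
                              lib_meta$replicate)
  lib_meta <- lib_meta[, c("library", "sample", "replicate", "site")]
  lib_sizes <- stats::runif(nrow(lib_meta), config$library_size_range[1],
                            config$library_size_range[2])
  weight <- expr * lengths   # fragments scale with expression x length
  frac <- sweep(weight, 2, colSums(weight), `/`)
  counts <- matrix(0, ng, nrow(lib_meta),
                   dimnames = list(genes, lib_meta$library))
  for (i in seq_len(nrow(lib_meta))) {
    mu <- frac[, lib_meta$sample[i]] * lib_sizes[i]
    counts[, i] <- draw_counts(mu, config$count_dispersion)
  }

  truth <- list(expr_a = stats::setNames(expr_a, genes),
                expr_b = stats::setNames(expr_b, genes),
                expr = expr, violator = stats::setNames(violator, genes),
                library_sizes = stats::setNames(lib_sizes, lib_meta$library),
                design = design)
  list(qpcr = qpcr,
       counts = expression_matrix(counts, lib_meta, pipeline = "simulated"),
       lengths = lengths, truth = truth)
}

#' Simulate a clinical cohort with survival outcomes
#'
#' Draws a latent binary risk group for each patient, survival times from
#' group-specific exponential distributions (high-risk events arrive
#' earlier), independent censoring, and log-normal expression in which the
#' configured signal genes are shifted between risk groups by
#' `effect_size` within-group standard deviations on the log2 scale.
#'
#' @param config A [simulation_config()].
#' @return A list: `counts` (genes-by-patients [expression_matrix()];
#'   all libraries labelled as one pseudo-sample), `survival` (data frame
#'   `patient`, `time`, `event`), `truth` (risk group, signal genes, effect
#'   sizes).
#' @export
simulate_clinical <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  ng <- config$n_genes; np <- config$n_patients
  genes <- sprintf("gene_%05d", seq_len(ng))
  patients <- sprintf("patient_%03d", seq_len(np))

  risk <- rep(c(1L, 0L), length.out = np)[sample.int(np)]

  # lognormal (accelerated failure time) event times: median 1 y for
  # high-risk and 8 y for low-risk patients, sdlog 0.5, so the usual 2-3 y
  # dichotomization thresholds mislabel only a few percent of each group
  med <- ifelse(risk == 1L, 1, 8)
  t_event <- stats::rlnorm(np, meanlog = log(med), sdlog = 0.5)
  if (config$censor_rate > 0) {
    # independent censoring roughly calibrated to the configured fraction
    mean_event <- mean(c(1, 8)) * exp(0.5^2 / 2)
    c_rate <- config$censor_rate / (1 - config$censor_rate) / mean_event
    t_cens <- stats::rexp(np, c_rate)
  } else t_cens <- rep(Inf, np)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  time <- pmax(time, 1e-3)

  base_log <- stats::rnorm(ng, 6, 1.5)
  noise_sd <- 1
  logx <- matrix(stats::rnorm(ng * np, 0, noise_sd), ng, np) + base_log
  sig <- integer(0)
  if (config$signal_genes > 0) {
    sig <- sample.int(ng, config$signal_genes)
    shift <- config$effect_size * noise_sd *
      sample(c(-1, 1), config$signal_genes, replace = TRUE)
    logx[sig, risk == 1L] <- logx[sig, risk == 1L] + shift
  }
  expr <- 2^logx
  dimnames(expr) <- list(genes, patients)

  lib_meta <- data.frame(library = patients, sample = "tumor",
                         replicate = seq_len(np), site = "clinic",
                         stringsAsFactors = FALSE)
  truth <- list(risk = stats::setNames(risk, patients),
                signal_genes = genes[sig],
                effect_size = config$effect_size)
  list(counts = expression_matrix(expr, lib_meta, pipeline = "simulated"),
       survival = data.frame(patient = patients, time = time, event = event,
                             stringsAsFactors = FALSE),
       truth = truth)
}
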