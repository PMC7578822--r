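#' Apply a graded distortion emulating a lower-quality pipeline
#'
#' Emulates the effect of a poorer analysis pipeline on an expression
#' matrix by two multiplicative log-normal perturbations on the log2 scale:
#' a per-gene (optionally per-sample) bias, constant across replicate
#' libraries, which shifts log ratios and so degrades accuracy; and a
#' per-cell noise term that inflates replicate variation, degrading
#' precision, reliability and any downstream prediction.  `severity` 0
#' returns the matrix unchanged.
#'
#' @param matrix An [expression_matrix()].
#' @param severity Distortion severity in \[0, 1\].
#' @param bias_sd Per-gene-per-sample log2 bias SD at severity 1
#'   (default 0.8).
#' @param noise_sd Per-cell log2 noise SD at severity 1 (default 0.4).
#' @param seed Seed controlling the perturbation draws.
#' @return The distorted [expression_matrix()].
#' @export
distort_pipeline <- function(matrix, severity, bias_sd = 0.8, noise_sd = 0.4,
                             seed = 1L) {
  stopifnot(inherits(matrix, "expression_matrix"),
            severity >= 0, severity <= 1)
  if (severity == 0) return(matrix)
  set.seed(seed)
  x <- matrix$counts
  samples <- unique(matrix$libraries$sample)
  bias <- matrix(stats::rnorm(nrow(x) * length(samples), 0,
                              bias_sd * severity),
                 nrow(x), length(samples), dimnames = list(NULL, samples))
  per_lib_bias <- bias[, matrix$libraries$sample, drop = FALSE]
  noise <- matrix(stats::rnorm(length(x), 0, noise_sd * severity),
                  nrow(x), ncol(x))
  out <- x * 2^(per_lib_bias + noise)
  expression_matrix(out, matrix$libraries,
                    pipeline = sprintf("%s_distorted_%.3f",
                                       matrix$pipeline %||% "pipeline", severity))
}

#' Benchmark-guided pipeline selection, end to end on simulated data
#'
#' Builds a panel of synthetic "pipelines" as increasing distortions of one
#' simulated benchmark dataset and one simulated clinical cohort, then runs
#' the full two-phase evaluation: (1) reference-set construction from the
#' simulated qPCR table and benchmark metrics (accuracy, precision,
#' reliability on all and low-expressing genes) per pipeline; (2) average-
#' rank pipeline ranking, top/bottom-decile selection, nested
#' cross-validation AUC of the selected pipelines on the clinical cohort,
#' and a one-sided Wilcoxon rank-sum comparison of good versus poor
#' pipelines' AUCs.
#'
#' @param n_pipelines Panel size (default 40).
#' @param bench_config [simulation_config()] for the benchmark dataset.
#' @param clin_config [simulation_config()] for the clinical cohort
#'   (defaults: 200 patients, 20 signal genes).
#' @param cv A [cv_spec()] for the nested cross-validation.
#' @param fraction Selection fraction for the extremes (default 0.10).
#' @param subset Metric columns used for ranking (default: all three
#'   metrics on both gene sets).
#' @param clin_noise_sd Per-cell clinical log2 noise SD at severity 1
#'   (default 2.5).
#' @param seed Master seed.
#' @return A list: `metric_table`, `ranking`, `selection`, `auc_table`
#'   (pipeline, severity, mean AUC for the selected pipelines),
#'   `comparison` (the [wilcoxon_one_sided()] result) and `truth`
#'   (severities).
#' @export
phase2_experiment <- function(n_pipelines = 40,
                              bench_config = simulation_config(n_genes = 600,
                                                               seed = 101L),
                              clin_config = simulation_config(n_genes = 300,
                                                              n_patients = 200,
                                                              signal_genes = 20,
                                                              seed = 202L),
                              cv = cv_spec(outer_folds = 5, inner_folds = 3,
                                           iterations = 2,
                                           feature_sizes = c(5, 10, 20)),
                              fraction = 0.10,
                              subset = metric_subsets()[["all3:both"]],
                              clin_noise_sd = 2.5,
                              seed = 1L) {
  bench <- simulate_benchmark(bench_config)
  clin <- simulate_clinical(clin_config)
  refset <- build_reference_set(bench$qpcr, list(bench$counts),
                                design = mixture_design())
  severities <- seq(0, 1, length.out = n_pipelines)
  ids <- sprintf("pipe_%02d", seq_len(n_pipelines))

  metric_rows <- vector("list", n_pipelines)
  for (i in seq_len(n_pipelines)) {
    dist_bench <- distort_pipeline(bench$counts, severities[i],
                                   seed = seed + 1000L + i)
    dist_bench$pipeline <- ids[i]
    norm <- normalize_counts(dist_bench, "fpm")
    mrep <- suppressMessages(benchmark_metrics(norm$matrix, bench$qpcr, refset))
    metric_rows[[i]] <- mrep$summary
  }
  metric_table <- do.call(rbind, metric_rows)

  ranking <- average_rank(metric_table, subset)
  selection <- select_extremes(ranking, fraction)

  labels_all <- dichotomize_survival(clin$survival, threshold = 3)
  evaluate <- function(pid) {
    sev <- severities[match(pid, ids)]
    dist_clin <- distort_pipeline(clin$counts, sev, bias_sd = 0,
                                  noise_sd = clin_noise_sd,
                                  seed = seed + 2000L + match(pid, ids))
    feats <- t(dist_clin$counts[, names(labels_all$labels), drop = FALSE])
    res <- nested_cv(feats, labels_all$labels, spec = cv)
    data.frame(pipeline = pid, severity = sev, mean_auc = res$mean_auc,
               mean_mcc = res$mean_mcc, stringsAsFactors = FALSE)
  }
  auc_table <- do.call(rbind, lapply(c(selection$good, selection$poor), evaluate))
  good_auc <- auc_table$mean_auc[auc_table$pipeline %in% selection$good]
  poor_auc <- auc_table$mean_auc[auc_table$pipeline %in% selection$poor]
  comparison <- wilcoxon_one_sided(good_auc, poor_auc)

  list(metric_table = metric_table, ranking = ranking, selection = selection,
       auc_table = auc_table, comparison = comparison,
       truth = data.frame(pipeline = ids, severity = severities,
                          stringsAsFactors = FALSE))
}
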