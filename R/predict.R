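#' Dichotomize survival outcomes at a time threshold
#'
#' High-risk patients experienced the event at or before the threshold;
#' low-risk patients experienced it after the threshold or were censored
#' with follow-up reaching the threshold.  Patients censored before the
#' threshold are excluded: their class at the threshold is unknowable.
#'
#' @param table Survival data frame (`patient`, `time`, `event`).
#' @param threshold Survival-time threshold in the table's time units
#'   (years); the study convention is 2 years for event-free survival and
#'   3 years for overall survival.
#' @return A list: `labels` (named 0/1 vector, 1 = high risk), `excluded`
#'   (patient IDs censored before the threshold).
#' @export
dichotomize_survival <- function(table, threshold) {
  table <- validate_survival(table)
  stopifnot(threshold > 0)
  high <- table$event == 1 & table$time <= threshold
  low <- (table$event == 1 & table$time > threshold) |
         (table$event == 0 & table$time >= threshold)
  excluded <- table$patient[!high & !low]
  if (length(excluded) > 0)
    log_note("dichotomize: excluded %d patient(s) censored before the threshold",
             length(excluded))
  keep <- high | low
  if (!any(keep)) stop("no patients remain after exclusion")
  list(labels = stats::setNames(as.integer(high[keep]), table$patient[keep]),
       excluded = excluded)
}

# equal-frequency discretization into `bins` levels (ties share a level)
discretize_ef <- function(v, bins = 3) {
  if (stats::sd(v) == 0) return(rep(1L, length(v)))
  br <- unique(quantile7(v, seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(rep(1L, length(v)))
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

# mutual information (nats) of two integer-coded vectors via joint counts:
# MI = H(a) + H(b) - H(a,b)
mutual_info <- function(a, b) {
  mi_int(as.integer(factor(a)), as.integer(factor(b)))
}

# core MI on 1-based integer codes
mi_int <- function(a, b) {
  na <- max(a); nb <- max(b)
  n <- length(a)
  ent <- function(cnt) {
    cnt <- cnt[cnt > 0]
    log(n) - sum(cnt * log(cnt)) / n
  }
  ent(tabulate(a, na)) + ent(tabulate(b, nb)) -
    ent(tabulate((a - 1L) * nb + b, na * nb))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy mRMR in the difference form: features (columns) are discretized
#' into three equal-frequency bins and selected one at a time to maximize
#' mutual information with the label minus the mean mutual information with
#' the already-selected features.  Deterministic: ties go to the
#' lower column index.
#'
#' @param features Samples-by-features numeric matrix.
#' @param labels Binary (or discrete) label vector.
#' @param n_features Number of features to return.
#' @return Integer vector of selected column indices, in selection order.
#' @export
mrmr_select <- function(features, labels, n_features) {
  features <- as.matrix(features)
  stopifnot(n_features >= 1, n_features <= ncol(features),
            nrow(features) == length(labels))
  disc <- apply(features, 2, discretize_ef)
  if (is.null(dim(disc))) disc <- matrix(disc, ncol = ncol(features))
  storage.mode(disc) <- "integer"
  lab_int <- as.integer(factor(labels))
  relevance <- apply(disc, 2, mi_int, b = lab_int)
  selected <- integer(0)
  redundancy_sum <- rep(0, ncol(features))
  candidates <- rep(TRUE, ncol(features))
  for (step in seq_len(n_features)) {
    score <- relevance - if (step == 1) 0 else redundancy_sum / (step - 1)
    score[!candidates] <- -Inf
    pick <- unname(which.max(score))
    selected <- c(selected, pick)
    candidates[pick] <- FALSE
    if (step < n_features)
      redundancy_sum[candidates] <- redundancy_sum[candidates] +
        apply(disc[, candidates, drop = FALSE], 2, mi_int, b = disc[, pick])
  }
  selected
}

#' Area under the ROC curve
#'
#' The probability that a random positive's score exceeds a random
#' negative's, with ties counting one half (the Mann-Whitney statistic
#' divided by the number of positive-negative pairs).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; returns 0 when
#' any factor of the denominator is zero.
#'
#' @param pred Predicted binary labels, or the TP count when the four
#'   confusion counts are given directly.
#' @param truth True binary labels (omit when giving counts).
#' @param fp,tn,fn Confusion counts (count form only).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(pred, truth = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(truth)) {
    tp <- pred
  } else {
    pred <- as.integer(pred); truth <- as.integer(truth)
    tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
    tn <- sum(pred == 0 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  }
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
           sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
}

#' Classifier plug-ins for nested cross-validation
#'
#' Returns a classifier object with a `fit(x, y)` / `score(model, x)`
#' contract (scores are class-1 probabilities).  Available classifiers:
#' logistic regression (`glm`), support vector machine with probability
#' output (`e1071::svm`, radial kernel) and gradient-boosted stumps
#' (`xgboost`, the adaptive-boosting role).  Hyperparameters are fixed
#' small defaults recorded in the returned object.
#'
#' @param name One of `"logistic"`, `"svm"`, `"boosting"`.
#' @return A list with `name`, `params`, `fit` and `score`.
#' @export
make_classifier <- function(name = c("logistic", "svm", "boosting")) {
  name <- match.arg(name)
  switch(name,
    logistic = list(
      name = name, params = list(),
      fit = function(x, y)
        suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                        family = stats::binomial())),
      score = function(model, x) {
        eta <- drop(cbind(1, x) %*% model$coefficients)
        eta[is.na(eta)] <- 0
        stats::plogis(eta)
      }),
    svm = list(
      name = name, params = list(kernel = "radial", cost = 1),
      fit = function(x, y)
        e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                   cost = 1, probability = TRUE, scale = TRUE),
      score = function(model, x) {
        pr <- attr(stats::predict(model, x, probability = TRUE), "probabilities")
        pr[, "1"]
      }),
    boosting = list(
      name = name, params = list(nrounds = 50, max_depth = 1, eta = 0.3),
      fit = function(x, y)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 1,
                        eta = 0.3, nthread = 1),
          data = xgboost::xgb.DMatrix(x, label = y), nrounds = 50,
          verbose = 0),
      score = function(model, x)
        stats::predict(model, xgboost::xgb.DMatrix(x))))
}

#' Nested cross-validation specification
#'
#' @param outer_folds Outer folds (default 5).
#' @param inner_folds Inner (model-optimizing) folds (default 3).
#' @param iterations Repetitions of the whole procedure (default 10).
#' @param feature_sizes Candidate mRMR feature counts (default
#'   `seq(5, 40, 5)`).
#' @param seed Base seed; each iteration refolds with `seed + iteration`.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(outer_folds = 5, inner_folds = 3, iterations = 10,
                    feature_sizes = seq(5, 40, by = 5), seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, iterations >= 1,
            all(diff(feature_sizes) > 0), all(feature_sizes >= 1))
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 iterations = as.integer(iterations),
                 feature_sizes = as.integer(feature_sizes),
                 seed = as.integer(seed)),
            class = "cv_spec")
}

# stratified fold assignment; guarantees both classes in every training set
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Nested cross-validation of gene-expression outcome prediction
#'
#' Runs the two-level cross-validation harness: within each outer training
#' fold, inner cross-validation over the candidate mRMR feature sizes picks
#' the size with the best mean inner AUC; the final model is retrained on
#' the full outer training fold with that size and scored on the held-out
#' fold.  Pooled held-out predictions give one AUC and MCC per iteration.
#' Features are `log2(x + 1)`-transformed expression values.
#'
#' @param features Samples-by-genes numeric matrix (raw scale; transformed
#'   internally).
#' @param labels Binary outcome labels (1 = high risk).
#' @param spec A [cv_spec()].
#' @param classifier A [make_classifier()] object (default logistic).
#' @param log_transform Apply `log2(x + 1)` before selection (default TRUE).
#' @return An object of class `prediction_result`: `per_iteration` (data
#'   frame with AUC and MCC), `mean_auc`, `mean_mcc`, and pooled
#'   `predictions` of the last iteration.
#' @export
nested_cv <- function(features, labels, spec = cv_spec(),
                      classifier = make_classifier("logistic"),
                      log_transform = TRUE) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), all(labels %in% 0:1))
  if (log_transform) features <- log2(features + 1)
  sizes <- spec$feature_sizes[spec$feature_sizes <= ncol(features)]
  if (length(sizes) == 0) sizes <- ncol(features)
  rows <- list(); last_pred <- NULL
  for (it in seq_len(spec$iterations)) {
    set.seed(spec$seed + it)
    outer <- stratified_folds(labels, spec$outer_folds)
    scores <- rep(NA_real_, length(labels))
    for (fo in seq_len(spec$outer_folds)) {
      tr <- which(outer != fo); te <- which(outer == fo)
      if (length(unique(labels[tr])) < 2) next
      best_size <- sizes[1]
      if (length(sizes) > 1) {
        inner <- stratified_folds(labels[tr], spec$inner_folds)
        # greedy mRMR orderings are nested, so one ordering per inner fold
        # serves every candidate size as a prefix
        inner_auc <- matrix(NA_real_, spec$inner_folds, length(sizes))
        for (fi in seq_len(spec$inner_folds)) {
          itr <- tr[inner != fi]; ite <- tr[inner == fi]
          if (length(unique(labels[itr])) < 2 ||
              length(unique(labels[ite])) < 2) next
          order_full <- mrmr_select(features[itr, , drop = FALSE], labels[itr],
                                    max(sizes))
          for (si in seq_along(sizes)) {
            sel <- order_full[seq_len(sizes[si])]
            mod <- classifier$fit(features[itr, sel, drop = FALSE], labels[itr])
            inner_auc[fi, si] <- auc(
              classifier$score(mod, features[ite, sel, drop = FALSE]),
              labels[ite])
          }
        }
        best_size <- sizes[which.max(colMeans(inner_auc, na.rm = TRUE))]
      }
      sel <- mrmr_select(features[tr, , drop = FALSE], labels[tr], best_size)
      mod <- classifier$fit(features[tr, sel, drop = FALSE], labels[tr])
      scores[te] <- classifier$score(mod, features[te, sel, drop = FALSE])
    }
    ok <- !is.na(scores)
    pred_label <- as.integer(scores[ok] >= 0.5)
    rows[[it]] <- data.frame(iteration = it,
                             classifier = classifier$name,
                             auc = auc(scores[ok], labels[ok]),
                             mcc = mcc(pred_label, labels[ok]))
    last_pred <- data.frame(index = which(ok), score = scores[ok],
                            label = labels[ok], predicted = pred_label)
  }
  per_iteration <- do.call(rbind, rows)
  structure(list(per_iteration = per_iteration,
                 mean_auc = mean(per_iteration$auc),
                 mean_mcc = mean(per_iteration$mcc),
                 predictions = last_pred),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("nested CV (%d iteration(s), %s): mean AUC = %.3f, mean MCC = %.3f\n",
              nrow(x$per_iteration), x$per_iteration$classifier[1],
              x$mean_auc, x$mean_mcc))
  invisible(x)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return A list: `time` (event times), `surv` (survival probabilities)
#'   and `surv_fn`, a right-continuous step function `S(t)`.
#' @export
km_estimator <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  tt <- fit$time[keep]; ss <- fit$surv[keep]
  surv_fn <- if (length(tt) == 0) function(t) rep(1, length(t))
             else stats::stepfun(tt, c(1, ss), right = FALSE)
  list(time = tt, surv = ss, surv_fn = surv_fn)
}

#' Two-tailed log-rank test
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance, referred to a chi-square distribution with one degree of
#' freedom.  With no events at all the statistic is 0 and p = 1.
#'
#' @param time1,event1 Follow-up and event indicator of group 1.
#' @param time2,event2 Follow-up and event indicator of group 2.
#' @return A list: `statistic` (chi-square), `p_value`.
#' @export
logrank_test <- function(time1, event1, time2, event2) {
  if (length(time1) == 0 || length(time2) == 0)
    stop("both groups must be non-empty")
  if (sum(event1) + sum(event2) == 0)
    return(list(statistic = 0, p_value = 1))
  grp <- c(rep(1L, length(time1)), rep(2L, length(time2)))
  sd <- survival::survdiff(survival::Surv(c(time1, time2),
                                          c(event1, event2)) ~ grp)
  stat <- sd$chisq
  if (!is.finite(stat)) stat <- 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Success rate of patient stratification
#'
#' The fraction of prediction runs whose predicted risk groups separate
#' significantly in Kaplan-Meier analysis (two-tailed log-rank p < 0.05).
#'
#' @param p_values Log-rank p-values across runs.
#' @param alpha Significance level (default 0.05).
#' @return Fraction in \[0, 1\].
#' @export
stratification_success_rate <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("empty p-value list")
  stopifnot(all(p_values > 0), all(p_values <= 1))
  mean(p_values < alpha)
}
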