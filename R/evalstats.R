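# Evaluation statistics: segmentation overlap, rank-based ROC metrics,
# operating-point selection with threshold transfer, bootstrap confidence
# intervals, and the nonparametric cohort-comparison tests.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Per-case prediction scores paired with true labels
#'
#' The container handed from the classifiers to every evaluation routine:
#' one predicted probability per case, with its patient id and true label.
#'
#' @param patient_id character vector of case identifiers.
#' @param score numeric vector of predicted probabilities in \[0, 1\].
#' @param label integer vector of true binary labels (0/1).
#' @return A `score_set` data frame with columns `patient_id`, `score`, `label`.
#' @export
score_set <- function(patient_id, score, label) {
  stopifnot(length(patient_id) == length(score), length(score) == length(label))
  if (any(!is.finite(score)) || any(score < 0 | score > 1))
    stop("scores must be probabilities in [0, 1]")
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) stop("labels must be binary 0/1")
  structure(data.frame(patient_id = as.character(patient_id),
                       score = as.numeric(score), label = label,
                       stringsAsFactors = FALSE),
            class = c("score_set", "data.frame"))
}

as_score_label <- function(scores, labels) {
  if (inherits(scores, "score_set") && missing(labels))
    return(list(score = scores$score, label = scores$label))
  list(score = as.numeric(scores), label = as.integer(labels))
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 TP / (2 TP + FP + FN)`. Two empty masks agree perfectly (Dice 1);
#' an empty prediction against a nonempty reference scores 0.
#'
#' @param pred,gt binary masks (`binary_mask` objects or 0/1 arrays) on the
#'   same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(pred, gt) {
  p <- mask_data(pred); g <- mask_data(gt)
  if (!identical(dim(p), dim(g))) stop("mask grids do not match")
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  if (tp + fp + fn == 0) return(1.0)
  2 * tp / (2 * tp + fp + fn)
}

mask_data <- function(m) {
  d <- if (inherits(m, "binary_mask")) m$data else m
  if (!all(d %in% c(0, 1))) stop("mask values must be in {0, 1}")
  d
}

#' Rank-based area under the ROC curve
#'
#' The Wilcoxon/Mann-Whitney estimator: positives' rank sum (midranks for
#' ties, scores sorted ascending) minus `M(M+1)/2`, divided by `M * N`.
#' Equals the probability that a random positive outranks a random negative
#' (ties counting one half).
#'
#' @param scores numeric scores, or a [score_set].
#' @param labels binary labels (omit when `scores` is a score_set).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  sl <- as_score_label(scores, labels)
  M <- sum(sl$label == 1L); N <- sum(sl$label == 0L)
  if (M < 1L || N < 1L) stop("AUC undefined: both classes must be present")
  r <- rank(sl$score, ties.method = "average")
  (sum(r[sl$label == 1L]) - M * (M + 1) / 2) / (M * N)
}

#' Confusion counts at a threshold
#'
#' A case is called positive iff `score >= threshold` (fixed convention,
#' shared with threshold transfer to external cohorts).
#'
#' @inheritParams auc_rank
#' @param threshold decision threshold.
#' @return list with integers `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  sl <- as_score_label(scores, labels)
  if (length(sl$score) == 0L) stop("empty score set")
  pos <- sl$score >= threshold
  list(TP = sum(pos & sl$label == 1L), FP = sum(pos & sl$label == 0L),
       FN = sum(!pos & sl$label == 1L), TN = sum(!pos & sl$label == 0L))
}

#' Threshold-based classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`,
#' NPV `TN/(TN+FN)` and `F1 = TP / (TP + (FP+FN)/2)`. A zero denominator
#' yields `NA` with a warning rather than a silent 0.
#'
#' @inheritParams confusion_counts
#' @return list with the five metrics and the `counts`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  cc <- confusion_counts(scores, labels, threshold)
  safe_ratio <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); return(NA_real_) }
    num / den
  }
  list(sensitivity = safe_ratio(cc$TP, cc$TP + cc$FN, "sensitivity"),
       specificity = safe_ratio(cc$TN, cc$TN + cc$FP, "specificity"),
       ppv = safe_ratio(cc$TP, cc$TP + cc$FP, "PPV"),
       npv = safe_ratio(cc$TN, cc$TN + cc$FN, "NPV"),
       f1 = safe_ratio(cc$TP, cc$TP + 0.5 * (cc$FP + cc$FN), "F1"),
       counts = cc)
}

#' Operating point by the maximum Youden index
#'
#' Scans all unique observed scores as candidate thresholds and returns the
#' one maximising `J = sensitivity + specificity - 1`; ties are broken by
#' the smallest threshold. The returned threshold is meant to be transferred
#' unchanged to external cohorts.
#'
#' @inheritParams auc_rank
#' @return list with `threshold` and `youden_J`.
#' @export
youden_threshold <- function(scores, labels) {
  sl <- as_score_label(scores, labels)
  if (sum(sl$label == 1L) < 1L || sum(sl$label == 0L) < 1L)
    stop("Youden index undefined: both classes must be present")
  cand <- sort(unique(sl$score))
  J <- vapply(cand, function(t) {
    cc <- confusion_counts(sl$score, sl$label, t)
    cc$TP / (cc$TP + cc$FN) + cc$TN / (cc$TN + cc$FP) - 1
  }, numeric(1))
  best <- which.max(J)  # which.max returns the first (smallest threshold) tie
  list(threshold = cand[best], youden_J = J[best])
}

#' Percentile bootstrap confidence interval for a score-set metric
#'
#' Case-level resampling with replacement, non-stratified. Resamples on
#' which the metric is not computable (for example a single-class draw for
#' AUC) are redrawn and counted in the `n_redrawn` attribute.
#'
#' @param metric function of `(scores, labels)` returning a scalar.
#' @inheritParams auc_rank
#' @param n_boot number of bootstrap replications (default 10000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lo, hi)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(metric, scores, labels, n_boot = 10000L, seed = 1L,
                         conf = 0.95) {
  sl <- as_score_label(scores, labels)
  n <- length(sl$score)
  if (n < 2L) stop("need at least 2 cases to bootstrap")
  with_seed(seed, {
    stats <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      val <- NA_real_
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(suppressWarnings(metric(sl$score[idx], sl$label[idx])),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        redrawn <- redrawn + 1L
      }
      if (!is.finite(val)) stop("metric not computable on any resample")
      stats[b] <- val
    }
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(stats, c(alpha, 1 - alpha), type = 7))
    attr(ci, "n_redrawn") <- redrawn
    ci
  })
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value; used for the
#' cohort-characteristics comparisons in the summary table.
#'
#' @param groups list of (at least two) numeric samples.
#' @return list with `H` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration for small samples without ties, tie-corrected normal
#' approximation otherwise; `U` counts pairs where `x` exceeds `y`.
#'
#' @param x,y numeric samples.
#' @return list with `U` and `p_value`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  exact <- length(x) <= 20L && length(y) <= 20L && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Empirical ROC curve
#'
#' The monotone staircase of (FPR, TPR) points obtained by sweeping the
#' decision threshold over the unique observed scores, from (0, 0) to
#' (1, 1); its trapezoidal area equals [auc_rank].
#'
#' @inheritParams auc_rank
#' @return data frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_curve <- function(scores, labels) {
  sl <- as_score_label(scores, labels)
  M <- sum(sl$label == 1L); N <- sum(sl$label == 0L)
  if (M < 1L || N < 1L) stop("ROC undefined: both classes must be present")
  ord <- order(sl$score, decreasing = TRUE)
  s <- sl$score[ord]; l <- sl$label[ord]
  keep <- rev(!duplicated(rev(s)))  # last index of each tied block
  tpr <- cumsum(l == 1L)[keep] / M
  fpr <- cumsum(l == 0L)[keep] / N
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
             threshold = c(Inf, s[keep]))
}

#' Trapezoidal area under an ROC curve
#' @param roc data frame from [roc_curve].
#' @return area in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Full metric report with bootstrap confidence intervals
#'
#' AUC plus the five threshold metrics, each with a percentile bootstrap
#' 95% CI, at a fixed operating threshold (typically transferred from the
#' internal-validation Youden point).
#'
#' @param scores a [score_set].
#' @param threshold operating threshold.
#' @param n_boot bootstrap replications (default 10000).
#' @param seed integer seed for the bootstrap.
#' @return a `metric_report` list: one `c(point, lo, hi)` per metric, plus
#'   `threshold` and `n_boot`.
#' @export
metric_report <- function(scores, threshold, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(scores, "score_set"))
  mk <- function(point_fn, sub_seed) {
    pt <- suppressWarnings(point_fn(scores$score, scores$label))
    if (!is.finite(pt)) return(c(point = NA_real_, lo = NA_real_, hi = NA_real_))
    ci <- bootstrap_ci(point_fn, scores$score, scores$label,
                       n_boot = n_boot, seed = seed + sub_seed)
    c(point = pt, lo = ci[1], hi = ci[2])
  }
  metr <- function(name) function(s, l) confusion_metrics(s, l, threshold)[[name]]
  rep <- list(auc = mk(auc_rank, 0L),
              sensitivity = mk(metr("sensitivity"), 1L),
              specificity = mk(metr("specificity"), 2L),
              ppv = mk(metr("ppv"), 3L),
              npv = mk(metr("npv"), 4L),
              f1 = mk(metr("f1"), 5L),
              threshold = threshold, n_boot = n_boot, n = nrow(scores))
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric report (n = %d, threshold = %.4f, %d bootstrap reps)\n",
              x$n, x$threshold, x$n_boot))
  for (m in c("auc", "sensitivity", "specificity", "ppv", "npv", "f1"))
    cat(sprintf("  %-12s %.2f (%.2f-%.2f)\n", m,
                x[[m]]["point"], x[[m]]["lo"], x[[m]]["hi"]))
  invisible(x)
}

#' Multivariable clinical logistic-regression baseline
#'
#' Fits a maximum-likelihood logistic model of a binary target on the
#' clinical covariates (age, sex, cT, cN) of the development cohort and
#' scores the external cohort. Perfect separation is reported as an error
#' rather than silently fitted.
#'
#' @param dev_cases,ext_cases lists of `case_record` objects.
#' @param covariates character vector of covariate names.
#' @param target `"emvi"` or `"cr"`.
#' @return list with the fitted `model` and a [score_set] for `ext_cases`.
#' @export
clinical_lr <- function(dev_cases, ext_cases,
                        covariates = c("age", "sex", "cT", "cN"),
                        target = c("emvi", "cr")) {
  target <- match.arg(target)
  df <- function(cases) {
    d <- data.frame(
      patient_id = vapply(cases, function(x) x$patient_id, ""),
      age = vapply(cases, function(x) x$age, 1),
      sex = factor(vapply(cases, function(x) x$sex, ""), levels = c("F", "M")),
      cT = factor(vapply(cases, function(x) x$cT, ""), levels = c("1-2", "3", "4")),
      cN = factor(vapply(cases, function(x) x$cN, ""), levels = c("0", "1", "2")),
      emvi = vapply(cases, function(x) x$emvi_label, 1L),
      cr = vapply(cases, function(x) x$cr_label, 1L))
    if (anyNA(d[covariates])) stop("missing covariate values")
    d
  }
  dev <- df(dev_cases); ext <- df(ext_cases)
  # covariates constant in the development data carry no information and
  # would break the factor contrasts; drop them (intercept-only is valid)
  usable <- covariates[vapply(covariates, function(cv)
    length(unique(dev[[cv]][!is.na(dev[[cv]])])) >= 2L, logical(1))]
  form <- stats::as.formula(paste(target, "~",
    if (length(usable) > 0) paste(usable, collapse = " + ") else "1"))
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = dev, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  fitted_p <- stats::fitted(fit)
  if (sep_warned || !fit$converged ||
      (length(usable) > 0 && all(fitted_p < 1e-6 | fitted_p > 1 - 1e-6)))
    stop("perfect or quasi-perfect separation in clinical logistic regression")
  p <- predict(fit, newdata = ext, type = "response")
  list(model = fit,
       scores = score_set(ext$patient_id, pmin(pmax(p, 0), 1), ext[[target]]))
}
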