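#' Empirical ROC curve
#'
#' Builds the empirical receiver-operating-characteristic curve of a
#' continuous score against a binary group label.  Tied scores are treated
#' as a single threshold step, so the curve passes through one point per
#' distinct score value plus the two trivial corners (0,0) and (1,1).  The
#' area under the curve is computed by the trapezoidal rule, which for the
#' empirical curve equals the Mann-Whitney concordance statistic
#' (concordant pairs plus half the ties over all positive-negative pairs).
#'
#' @param scores Numeric vector, one score per subject.
#' @param labels Group label per subject (factor or character); exactly two
#'   classes must be present.
#' @param positive_label The class called "positive" (diseased per the
#'   marker's convention).
#' @param direction `"greater"` if larger scores indicate the positive
#'   class, `"less"` otherwise.
#' @return An object of class `roc_result`: a list with `points` (data frame
#'   of cutoff, fpr, tpr — cutoffs are midpoints between adjacent distinct
#'   scores, with infinite end cutoffs), `auc`, `youden_cutoff`, `youden_j`,
#'   `positive_label`, `direction`, `n_pos`, `n_neg`.
#' @examples
#' roc <- empirical_roc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
#'                      c("PD", "PD", "PD", "CBS", "CBS", "CBS"),
#'                      positive_label = "PD")
#' roc$auc  # 8/9
#' @export
empirical_roc <- function(scores, labels, positive_label,
                          direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores)))
    stop("empirical_roc(): scores must be finite", call. = FALSE)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L || !positive_label %in% classes)
    stop("empirical_roc(): need exactly two classes including the positive label (degenerate ROC)",
         call. = FALSE)
  is_pos <- labels == positive_label
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)

  # orient so that larger oriented score means positive
  s <- if (direction == "greater") scores else -scores
  u <- sort(unique(s))
  # candidate thresholds: midpoints between adjacent distinct scores + ends
  thr <- c(Inf, rev((u[-1] + u[-length(u)]) / 2), -Inf)
  tpr <- vapply(thr, function(t) mean(s[is_pos] > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!is_pos] > t), numeric(1))
  cutoff <- if (direction == "greater") thr else -thr
  points <- data.frame(cutoff = cutoff, fpr = fpr, tpr = tpr)

  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  j <- tpr - fpr
  # tie-break among equal-J thresholds: highest specificity (lowest fpr)
  best <- which(j == max(j))
  best <- best[which.min(fpr[best])]
  res <- structure(list(points = points, auc = auc,
                        youden_cutoff = cutoff[best], youden_j = j[best],
                        positive_label = positive_label, direction = direction,
                        n_pos = n_pos, n_neg = n_neg),
                   class = "roc_result")
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> positive = %s (direction %s), n = %d/%d\n",
              x$positive_label, x$direction, x$n_pos, x$n_neg))
  cat(sprintf("  AUC = %.3f; Youden cutoff = %.4g (J = %.3f)\n",
              x$auc, x$youden_cutoff, x$youden_j))
  invisible(x)
}

#' Youden optimal cutoff of a ROC curve
#'
#' Returns the threshold maximising Youden's J = sensitivity + specificity
#' - 1 over the observed threshold set of an empirical ROC.  Where several
#' thresholds attain the maximal J, the one with the higher specificity is
#' reported; the cutoff value is the midpoint between the adjacent distinct
#' observed scores.
#'
#' @param roc An object from [empirical_roc()].
#' @return A list with `cutoff` and `youden_j`.
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  list(cutoff = roc$youden_cutoff, youden_j = roc$youden_j)
}

#' Binormal area under the ROC curve
#'
#' Closed-form AUC under the assumption that the score is Gaussian within
#' each class: \eqn{\Phi(|\mu_+ - \mu_-| / \sqrt{\sigma_+^2 + \sigma_-^2})}.
#' Useful as a consistency bridge between published group means/SDs and a
#' published AUC when per-subject scores are unavailable.
#'
#' @param mean_pos,sd_pos Mean and SD of the positive class.
#' @param mean_neg,sd_neg Mean and SD of the negative class.
#' @return AUC in \eqn{[0.5, 1]}.
#' @examples
#' binormal_auc(0.86, 0.36, 0.10, 0.32)  # ~0.94
#' @export
binormal_auc <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  if (sd_pos < 0 || sd_neg < 0)
    stop("binormal_auc(): SDs must be non-negative", call. = FALSE)
  s <- sqrt(sd_pos^2 + sd_neg^2)
  if (s == 0) {
    if (mean_pos == mean_neg)
      stop("binormal_auc(): undefined for identical degenerate distributions",
           call. = FALSE)
    return(1)
  }
  stats::pnorm(abs(mean_pos - mean_neg) / s)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact two-sided confidence interval for a binomial proportion from the
#' Beta-distribution quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#' Coverage is at least the nominal level (the interval is conservative).
#'
#' @param successes,n Observed successes and number of trials.
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)` of proportions.
#' @examples
#' exact_binomial_ci(12, 14)  # 0.572, 0.982
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95) {
  if (!is.finite(successes) || !is.finite(n) || n < 1 ||
      successes < 0 || successes > n ||
      successes != round(successes) || n != round(n))
    stop("exact_binomial_ci(): need integer counts with 0 <= successes <= n, n >= 1",
         call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("exact_binomial_ci(): level must be in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Classification metrics at a fixed cutoff
#'
#' Dichotomises the score at the cutoff (strict comparison in the stated
#' direction: a subject is called positive when its score is strictly
#' greater — or strictly less — than the cutoff) and tabulates the
#' confusion counts against the true labels.  Sensitivity and specificity
#' carry exact Clopper-Pearson 95% confidence intervals.
#'
#' @inheritParams empirical_roc
#' @param cutoff Decision threshold on the score scale.
#' @param level Confidence level for the exact intervals.
#' @return An object of class `binary_metrics`: counts `tp`, `fn`, `tn`,
#'   `fp`; `sensitivity`, `specificity`; `sens_ci`, `spec_ci`; plus the rule
#'   (`cutoff`, `direction`, `positive_label`).
#' @export
evaluate_rule <- function(scores, labels, cutoff,
                          direction = c("greater", "less"),
                          positive_label, level = 0.95) {
  direction <- match.arg(direction)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L || !positive_label %in% classes)
    stop("evaluate_rule(): need exactly two classes including the positive label",
         call. = FALSE)
  if (any(!is.finite(scores)))
    stop("evaluate_rule(): scores must be finite", call. = FALSE)
  called_pos <- if (direction == "greater") scores > cutoff else scores < cutoff
  is_pos <- labels == positive_label
  tp <- sum(called_pos & is_pos); fn <- sum(!called_pos & is_pos)
  tn <- sum(!called_pos & !is_pos); fp <- sum(called_pos & !is_pos)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec,
                 sens_ci = exact_binomial_ci(tp, tp + fn, level),
                 spec_ci = exact_binomial_ci(tn, tn + fp, level),
                 cutoff = cutoff, direction = direction,
                 positive_label = positive_label, level = level),
            class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, ...) {
  cat(sprintf("<binary_metrics> positive = %s, score %s %.4g\n",
              x$positive_label, if (x$direction == "greater") ">" else "<",
              x$cutoff))
  cat(sprintf("  tp=%d fn=%d tn=%d fp=%d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %.1f%% (%d%% CI %.1f-%.1f)\n",
              100 * x$sensitivity, round(100 * x$level),
              100 * x$sens_ci[1], 100 * x$sens_ci[2]))
  cat(sprintf("  specificity %.1f%% (%d%% CI %.1f-%.1f)\n",
              100 * x$specificity, round(100 * x$level),
              100 * x$spec_ci[1], 100 * x$spec_ci[2]))
  invisible(x)
}

#' Rule combining the two asymmetry indices
#'
#' Describes how the blink-reflex and MRI asymmetry indices are combined
#' into one classifier.  Two modes are supported: `"logistic_score"`
#' (default) fits a logistic regression of diagnosis on the two indices and
#' classifies on the fitted score, the practice of standard ROC software;
#' `"sequential_rule"` applies the two published cutoffs in sequence (call
#' PD when the blink-reflex index exceeds its cutoff; otherwise call CBS
#' when the MRI index exceeds its cutoff; otherwise call PD, the
#' doubly-negative cell).
#'
#' @param r2brrc_cutoff Cutoff on the blink-reflex asymmetry index
#'   (default 0.75; PD above).
#' @param mri_cutoff Cutoff on the MRI asymmetry index (default 0.014; CBS
#'   above).
#' @param mode `"logistic_score"` or `"sequential_rule"`.
#' @return An object of class `combined_rule`.
#' @export
combined_rule <- function(r2brrc_cutoff = 0.75, mri_cutoff = 0.014,
                          mode = c("logistic_score", "sequential_rule")) {
  mode <- match.arg(mode)
  if (r2brrc_cutoff < 0 || r2brrc_cutoff > 1 || mri_cutoff < 0 || mri_cutoff > 1)
    stop("combined_rule(): cutoffs must lie in [0, 1]", call. = FALSE)
  structure(list(r2brrc_cutoff = r2brrc_cutoff, mri_cutoff = mri_cutoff,
                 mode = mode),
            class = "combined_rule")
}

#' Classify patients from the two asymmetry indices combined
#'
#' Applies a [combined_rule] to per-patient blink-reflex and MRI asymmetry
#' indices.  In `logistic_score` mode a logistic regression of the group on
#' the two indices is fitted; complete separation (all fitted probabilities
#' at 0/1 by class) is detected and flagged rather than reported as an
#' ordinary converged fit, but the boundary fit's linear predictor is kept
#' as the combined score, since it ranks the classes perfectly by
#' construction.  In `sequential_rule` mode labels come from the two-cutoff
#' decision tree and the score is the rule's signed margin.
#'
#' @param ai_r2brrc,ai_mri Numeric vectors of the two asymmetry indices,
#'   one value per patient.
#' @param labels True group per patient (needed to fit the logistic score);
#'   in `sequential_rule` mode it may be omitted.
#' @param rule A [combined_rule]; default `combined_rule()`.
#' @param pd_label,cbs_label The two group labels (defaults `"PD"`,
#'   `"CBS"`); `pd_label` is the positive class of the combined score.
#' @return A list with `labels` (predicted group per patient), `score`
#'   (combined score, larger = more PD-like), `mode`, `separation`
#'   (logical flag), and `fit` (the glm object, logistic mode only).
#' @export
combined_classify <- function(ai_r2brrc, ai_mri, labels = NULL,
                              rule = combined_rule(),
                              pd_label = "PD", cbs_label = "CBS") {
  stopifnot(inherits(rule, "combined_rule"),
            length(ai_r2brrc) == length(ai_mri))
  if (any(!is.finite(ai_r2brrc)) || any(!is.finite(ai_mri)))
    stop("combined_classify(): both asymmetry indices must be present and finite for every patient",
         call. = FALSE)
  n <- length(ai_r2brrc)
  if (rule$mode == "sequential_rule") {
    lab <- ifelse(ai_r2brrc > rule$r2brrc_cutoff, pd_label,
                  ifelse(ai_mri > rule$mri_cutoff, cbs_label, pd_label))
    # signed margin: positive toward PD, from whichever branch decided
    score <- ifelse(ai_r2brrc > rule$r2brrc_cutoff,
                    ai_r2brrc - rule$r2brrc_cutoff,
                    rule$mri_cutoff - ai_mri)
    return(list(labels = lab, score = score, mode = rule$mode,
                separation = NA, fit = NULL))
  }
  if (is.null(labels))
    stop("combined_classify(): logistic_score mode needs the true labels to fit the score",
         call. = FALSE)
  labels <- as.character(labels)
  if (!all(labels %in% c(pd_label, cbs_label)))
    stop("combined_classify(): labels must be one of the two group labels",
         call. = FALSE)
  y <- as.integer(labels == pd_label)
  dat <- data.frame(y = y, ai_r2brrc = ai_r2brrc, ai_mri = ai_mri)
  fit <- suppressWarnings(stats::glm(y ~ ai_r2brrc + ai_mri,
                                     family = stats::binomial(), data = dat))
  p <- stats::fitted(fit)
  eps <- 1e-6
  separation <- all(p[y == 1] > 1 - eps) && all(p[y == 0] < eps)
  score <- as.numeric(stats::predict(fit, type = "link"))
  roc <- empirical_roc(score, labels, positive_label = pd_label,
                       direction = "greater")
  lab <- ifelse(score > roc$youden_cutoff, pd_label, cbs_label)
  list(labels = lab, score = score, mode = rule$mode,
       separation = separation, fit = fit)
}
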