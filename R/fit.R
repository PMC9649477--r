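#' Fit the asymmetry-index diagnostic classifier
#'
#' The central model of the package: given per-patient asymmetry indices
#' and the diagnostic group, fits the single-index ROC classifiers (one
#' per marker on the right-hand side of the formula, each with its
#' empirical ROC, Youden optimal cutoff and confusion metrics with exact
#' binomial confidence intervals) and, when two or more markers are
#' given, the combined classifier of [combined_classify()].
#'
#' Each marker is oriented automatically: its "positive" class is the
#' group with the larger marker mean and the decision direction is
#' "greater".  For the study's two markers this reproduces the published
#' conventions (blink-reflex asymmetry higher in PD, MRI asymmetry higher
#' in CBS).  Fixed cutoffs — e.g. previously published ones — can be
#' supplied per marker and are evaluated alongside the in-sample Youden
#' cutoffs.
#'
#' @param formula Model formula, `group ~ marker1 + marker2 + ...`.
#' @param data Data frame holding the group column and the markers, e.g.
#'   an [ai_table()].
#' @param positive Positive class of the *combined* classifier
#'   (default `"PD"`).
#' @param cutoffs Optional named numeric vector of fixed cutoffs, names
#'   matching marker columns.
#' @param combine A [combined_rule()] describing the combination mode;
#'   `NULL` for single markers.
#' @param level Confidence level of the exact binomial intervals.
#' @return An object of class `dx_fit` with `print()`, `summary()`,
#'   `coef()`, `predict()` and `plot()` methods.
#' @examples
#' fit <- dx_fit(group ~ ai_r2brrc_100 + ai_mri, data = ai_table(fixture_cohort()),
#'               cutoffs = c(ai_r2brrc_100 = 0.75, ai_mri = 0.014))
#' summary(fit)
#' @export
dx_fit <- function(formula, data, positive = "PD", cutoffs = NULL,
                   combine = combined_rule(), level = 0.95) {
  mf <- stats::model.frame(formula, data)
  labels <- as.character(mf[[1L]])
  markers <- names(mf)[-1L]
  if (length(markers) < 1L)
    stop("dx_fit(): formula needs at least one marker on the right-hand side",
         call. = FALSE)
  classes <- unique(labels)
  if (length(classes) != 2L || !positive %in% classes)
    stop("dx_fit(): need exactly two groups including the positive label",
         call. = FALSE)
  negative <- setdiff(classes, positive)

  marker_fits <- lapply(markers, function(m) {
    x <- mf[[m]]
    means <- tapply(x, labels, mean)
    marker_pos <- names(means)[which.max(means)]
    roc <- empirical_roc(x, labels, positive_label = marker_pos,
                         direction = "greater")
    yc <- youden_optimal_cutoff(roc)
    out <- list(marker = m, positive = marker_pos, roc = roc,
                youden = yc,
                metrics_youden = evaluate_rule(x, labels, yc$cutoff,
                                               direction = "greater",
                                               positive_label = marker_pos,
                                               level = level),
                metrics_fixed = NULL, fixed_cutoff = NA_real_)
    if (!is.null(cutoffs) && m %in% names(cutoffs)) {
      out$fixed_cutoff <- cutoffs[[m]]
      out$metrics_fixed <- evaluate_rule(x, labels, cutoffs[[m]],
                                         direction = "greater",
                                         positive_label = marker_pos,
                                         level = level)
    }
    out
  })
  names(marker_fits) <- markers

  combined <- NULL
  if (length(markers) >= 2L && !is.null(combine)) {
    cc <- combined_classify(mf[[markers[1L]]], mf[[markers[2L]]],
                            labels = labels, rule = combine,
                            pd_label = positive, cbs_label = negative)
    roc <- empirical_roc(cc$score, labels, positive_label = positive,
                         direction = "greater")
    metrics <- evaluate_rule(cc$score, labels, roc$youden_cutoff,
                             direction = "greater",
                             positive_label = positive, level = level)
    combined <- list(rule = combine, result = cc, roc = roc,
                     metrics = metrics,
                     accuracy = mean(cc$labels == labels))
  }

  structure(list(call = match.call(), formula = formula,
                 markers = markers, marker_fits = marker_fits,
                 combined = combined, positive = positive,
                 negative = negative, level = level,
                 data = mf, n = nrow(mf)),
            class = "dx_fit")
}

fmt_pct_ci <- function(p, ci) {
  sprintf("%.1f%% (%.1f-%.1f)", 100 * p, 100 * ci[1], 100 * ci[2])
}

#' @export
print.dx_fit <- function(x, ...) {
  cat("Asymmetry-index diagnostic classifier\n")
  cat(sprintf("  %d patients (%s positive vs %s); markers: %s\n",
              x$n, x$positive, x$negative, paste(x$markers, collapse = ", ")))
  for (mf in x$marker_fits)
    cat(sprintf("  %s: AUC %.2f, Youden cutoff %.3g (positive = %s)\n",
                mf$marker, mf$roc$auc, mf$youden$cutoff, mf$positive))
  if (!is.null(x$combined))
    cat(sprintf("  combined (%s): AUC %.2f, accuracy %.1f%%%s\n",
                x$combined$rule$mode, x$combined$roc$auc,
                100 * x$combined$accuracy,
                if (isTRUE(x$combined$result$separation))
                  " [complete separation]" else ""))
  invisible(x)
}

#' @describeIn dx_fit Marker-by-marker performance table (AUC, cutoffs,
#'   sensitivity and specificity with exact confidence intervals).
#' @param object,x A `dx_fit` object.
#' @param ... Unused.
#' @export
summary.dx_fit <- function(object, ...) {
  row_of <- function(name, cutoff, roc, m) {
    data.frame(marker = name, positive = m$positive_label,
               auc = roc$auc, cutoff = cutoff,
               sensitivity = m$sensitivity,
               sens_lower = unname(m$sens_ci[1]), sens_upper = unname(m$sens_ci[2]),
               specificity = m$specificity,
               spec_lower = unname(m$spec_ci[1]), spec_upper = unname(m$spec_ci[2]),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (mf in object$marker_fits) {
    rows[[length(rows) + 1L]] <-
      row_of(paste0(mf$marker, " @youden"), mf$youden$cutoff, mf$roc,
             mf$metrics_youden)
    if (!is.null(mf$metrics_fixed))
      rows[[length(rows) + 1L]] <-
        row_of(paste0(mf$marker, " @", format(mf$fixed_cutoff)),
               mf$fixed_cutoff, mf$roc, mf$metrics_fixed)
  }
  if (!is.null(object$combined))
    rows[[length(rows) + 1L]] <-
      row_of(sprintf("combined (%s)", object$combined$rule$mode),
             object$combined$metrics$cutoff, object$combined$roc,
             object$combined$metrics)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.dx_fit", "data.frame")
  out
}

#' @export
print.summary.dx_fit <- function(x, ...) {
  df <- as.data.frame(x)
  df$auc <- round(df$auc, 3)
  df$cutoff <- signif(df$cutoff, 4)
  df$sensitivity <- fmt_pct_ci_col(df$sensitivity, df$sens_lower, df$sens_upper)
  df$specificity <- fmt_pct_ci_col(df$specificity, df$spec_lower, df$spec_upper)
  print(df[, c("marker", "positive", "auc", "cutoff",
               "sensitivity", "specificity")], right = FALSE)
  invisible(x)
}

fmt_pct_ci_col <- function(p, lo, hi)
  sprintf("%.1f%% (%.1f-%.1f)", 100 * p, 100 * lo, 100 * hi)

#' @describeIn dx_fit Decision cutoffs, one per marker (the fixed cutoff
#'   where one was supplied, otherwise the in-sample Youden cutoff); the
#'   logistic coefficients of the combined score, when present, are
#'   attached as attribute `"logistic"`.
#' @export
coef.dx_fit <- function(object, ...) {
  out <- vapply(object$marker_fits, function(mf)
    if (is.na(mf$fixed_cutoff)) mf$youden$cutoff else mf$fixed_cutoff,
    numeric(1))
  if (!is.null(object$combined) && !is.null(object$combined$result$fit))
    attr(out, "logistic") <- stats::coef(object$combined$result$fit)
  out
}

#' @describeIn dx_fit Predict group labels (`type = "label"`) or the
#'   combined score (`type = "score"`) for new patients; `newdata` needs
#'   the marker columns.  Single-marker fits classify by the fitted
#'   marker rule.
#' @param newdata Data frame of marker values; defaults to the training
#'   data.
#' @param type `"label"` or `"score"`.
#' @export
predict.dx_fit <- function(object, newdata = NULL, type = c("label", "score"),
                           ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  miss <- setdiff(object$markers, names(newdata))
  if (length(miss) > 0L)
    stop(sprintf("predict.dx_fit(): newdata lacks marker column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (is.null(object$combined)) {
    mf <- object$marker_fits[[1L]]
    x <- newdata[[mf$marker]]
    cutoff <- if (is.na(mf$fixed_cutoff)) mf$youden$cutoff else mf$fixed_cutoff
    score <- x - cutoff
    pos <- x > cutoff
    lab <- ifelse(pos, mf$positive,
                  setdiff(c(object$positive, object$negative), mf$positive))
    if (type == "score") return(score)
    return(lab)
  }
  comb <- object$combined
  if (comb$rule$mode == "logistic_score") {
    nd <- data.frame(ai_r2brrc = newdata[[object$markers[1L]]],
                     ai_mri = newdata[[object$markers[2L]]])
    score <- as.numeric(stats::predict(comb$result$fit, newdata = nd,
                                       type = "link"))
    if (type == "score") return(score)
    ifelse(score > comb$roc$youden_cutoff, object$positive, object$negative)
  } else {
    cc <- combined_classify(newdata[[object$markers[1L]]],
                            newdata[[object$markers[2L]]],
                            rule = comb$rule, pd_label = object$positive,
                            cbs_label = object$negative)
    if (type == "score") cc$score else cc$labels
  }
}

#' @describeIn dx_fit Plot the empirical ROC curves of every marker and
#'   of the combined score (base graphics).
#' @export
plot.dx_fit <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "n",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = "Asymmetry-index ROC curves", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  cols <- c("#1b6ca8", "#c0392b", "#148f5b", "#8e44ad")
  leg <- character(0); lcol <- character(0)
  i <- 0L
  for (mf in x$marker_fits) {
    i <- i + 1L
    with(mf$roc$points, graphics::lines(fpr, tpr, type = "s",
                                        col = cols[(i - 1L) %% 4L + 1L],
                                        lwd = 2))
    leg <- c(leg, sprintf("%s (AUC %.2f)", mf$marker, mf$roc$auc))
    lcol <- c(lcol, cols[(i - 1L) %% 4L + 1L])
  }
  if (!is.null(x$combined)) {
    i <- i + 1L
    with(x$combined$roc$points,
         graphics::lines(fpr, tpr, type = "s",
                         col = cols[(i - 1L) %% 4L + 1L], lwd = 2, lty = 2))
    leg <- c(leg, sprintf("combined (AUC %.2f)", x$combined$roc$auc))
    lcol <- c(lcol, cols[(i - 1L) %% 4L + 1L])
  }
  graphics::legend("bottomright", legend = leg, col = lcol, lwd = 2, bty = "n")
  invisible(x)
}
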