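## Group-comparison statistics for the cohort tables: two-sample t tests
## (raw data or published summaries), Mann-Whitney, chi-square/Fisher on
## proportions, and age-adjusted logistic regression.

#' Summary of one variable in one group
#'
#' @param n Sample size (>= 2).
#' @param mean,sd Sample mean and standard deviation.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (!is.finite(n) || n < 2 || !is.finite(mean) || !is.finite(sd) || sd < 0)
    stop("group_summary(): need n >= 2, finite mean, sd >= 0", call. = FALSE)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x)) return(group_summary(length(x), mean(x), stats::sd(x)))
  stop("expected a numeric vector or a group_summary()", call. = FALSE)
}

test_report <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s: statistic = %.4g%s, p = %.4g\n",
              x$method, x$statistic,
              if (is.null(x$df) || is.na(x$df)) "" else sprintf(", df = %.2f", x$df),
              x$p_value))
  invisible(x)
}

#' Two-sample t test from raw data or group summaries
#'
#' Student (pooled-variance) or Welch (Satterthwaite) two-sided t test.
#' Either group may be given as a raw numeric vector or as a
#' [group_summary()] — the latter allows testing against published
#' means +/- SDs; a raw vector gives identical results to its own summary.
#'
#' @param a,b Raw numeric vectors or [group_summary()] objects.
#' @param variant `"welch"` (default) or `"student"`.
#' @return A `test_report` with `statistic`, `df`, `p_value`, `method`.
#' @examples
#' two_sample_t(group_summary(14, 0.86, 0.36), group_summary(10, 0.10, 0.32))
#' @export
two_sample_t <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  a <- as_group_summary(a); b <- as_group_summary(b)
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  if (variant == "welch") {
    se2 <- va + vb
    if (se2 <= 0) stop("two_sample_t(): zero variance in both groups", call. = FALSE)
    stat <- (a$mean - b$mean) / sqrt(se2)
    df <- se2^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    method <- "welch_t"
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    if (sp2 <= 0) stop("two_sample_t(): zero pooled variance", call. = FALSE)
    stat <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
    method <- "student_t"
  }
  test_report(stat, df, 2 * stats::pt(-abs(stat), df), method)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided Mann-Whitney test; the p-value is exact (full enumeration of
#' the rank distribution) for small untied samples and uses the normal
#' approximation with tie correction otherwise.  When every value is tied
#' across both groups, p = 1 is returned rather than an error.
#'
#' @param a,b Raw numeric vectors (n >= 1 each).
#' @return A `test_report`; `statistic` is the U statistic of group `a`,
#'   which relates to the empirical ROC area as `AUC = U / (n_a * n_b)`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (length(unique(c(a, b))) == 1L)
    return(test_report(length(a) * length(b) / 2, NA_real_, 1,
                       "mann_whitney"))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = FALSE))
  test_report(unname(wt$statistic), NA_real_, wt$p.value, "mann_whitney")
}

#' Compare two proportions (chi-square or Fisher)
#'
#' @param x1,n1,x2,n2 Successes and totals in the two groups.
#' @param method `"chi_square"` (default, without continuity correction)
#'   or `"fisher_exact"`.
#' @return A `test_report`.
#' @export
proportion_test <- function(x1, n1, x2, n2,
                            method = c("chi_square", "fisher_exact")) {
  method <- match.arg(method)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2)
  if (any(tab < 0)) stop("proportion_test(): invalid counts", call. = FALSE)
  if (method == "chi_square") {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    test_report(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                "chi_square")
  } else {
    ht <- stats::fisher.test(tab)
    test_report(unname(ht$estimate), NA_real_, ht$p.value, "fisher_exact")
  }
}

#' Age-adjusted logistic regression of diagnosis on an asymmetry index
#'
#' Fits `I(group == positive) ~ index + age` by maximum likelihood
#' (iteratively reweighted least squares via [stats::glm()]) and reports
#' the coefficient table with Wald z p-values.  Complete or
#' quasi-complete separation — fitted probabilities polarised to 0/1 by
#' class — is detected and flagged: Wald statistics are meaningless there
#' and the fit should not be read as converged.
#'
#' @param group Group label per patient.
#' @param index Asymmetry-index value per patient.
#' @param age Age per patient (the adjustment covariate); `NULL` drops it.
#' @param positive Label modelled as outcome 1 (default `"PD"`).
#' @return An object of class `adjusted_logistic`: list with
#'   `coefficients` (data frame: estimate, std_error, z, p_value),
#'   `separation` flag, and the underlying `fit`.
#' @export
fit_logistic_adjusted <- function(group, index, age = NULL, positive = "PD") {
  group <- as.character(group)
  if (length(unique(group)) != 2L || !positive %in% group)
    stop("fit_logistic_adjusted(): need two classes including the positive label",
         call. = FALSE)
  y <- as.integer(group == positive)
  dat <- data.frame(y = y, index = index)
  form <- y ~ index
  if (!is.null(age)) { dat$age <- age; form <- y ~ index + age }
  if (any(!is.finite(as.matrix(dat))))
    stop("fit_logistic_adjusted(): predictors must be finite", call. = FALSE)
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = dat))
  p <- stats::fitted(fit)
  eps <- 1e-6
  separation <- all(p[y == 1] > 1 - eps) && all(p[y == 0] < eps)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      std_error = sm[, 2], z = sm[, 3], p_value = sm[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, separation = separation, fit = fit,
                 positive = positive),
            class = "adjusted_logistic")
}

#' @export
print.adjusted_logistic <- function(x, ...) {
  cat(sprintf("<adjusted_logistic> outcome positive = %s%s\n", x$positive,
              if (x$separation) " [COMPLETE SEPARATION - Wald inference invalid]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Group-comparison table for a cohort
#'
#' Reproduces the shape of a clinical baseline-characteristics table:
#' per-group n,
#' mean and SD for each quantitative variable with Welch t, Student t and
#' Mann-Whitney p-values side by side (which test a given variable
#' received in the original analysis is not knowable, so all are
#' reported), and chi-square p-values for the categorical variables.
#'
#' @param cohort A `cohort_dataset`.
#' @param variables Quantitative columns to compare (searched in both the
#'   demographics and metrics tables).
#' @return Data frame, one row per variable.
#' @export
compare_groups <- function(cohort,
                           variables = c("age", "disease_duration",
                                         "updrs_me", "hy_stage",
                                         "ai_r2brrc_100", "ai_r2brrc_150",
                                         "ai_r2brrc_200", "total_gm_volume",
                                         "ai_mri")) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  full <- merge(cohort$patients,
                cohort$metrics[, setdiff(names(cohort$metrics),
                                         c("group", "mas_side"))],
                by = "patient_id")
  rows <- lapply(variables, function(v) {
    if (!v %in% names(full)) return(NULL)
    a <- full[[v]][full$group == "PD"]
    b <- full[[v]][full$group == "CBS"]
    data.frame(variable = v,
               pd_mean = mean(a), pd_sd = stats::sd(a),
               cbs_mean = mean(b), cbs_sd = stats::sd(b),
               p_welch = two_sample_t(a, b, "welch")$p_value,
               p_student = two_sample_t(a, b, "student")$p_value,
               p_mann_whitney = mann_whitney(a, b)$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
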