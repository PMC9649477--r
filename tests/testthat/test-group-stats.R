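test_that("t tests from summaries match hand arithmetic and published bridge", {
  same <- group_summary(10, 5, 2)
  r <- two_sample_t(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # published group summaries at ISI 100: t ~ 5.44 (Welch)
  r2 <- two_sample_t(group_summary(14, 0.86, 0.36), group_summary(10, 0.10, 0.32))
  expect_equal(r2$statistic, 0.76 / sqrt(0.36^2 / 14 + 0.32^2 / 10))
  expect_equal(round(r2$statistic, 2), 5.44)
  expect_lt(r2$p_value, 0.001)
})

test_that("raw-data path equals the summary path and stats::t.test", {
  set.seed(20)
  for (i in 1:10) {
    a <- rnorm(sample(5:15, 1), 1, 2); b <- rnorm(sample(5:15, 1))
    for (variant in c("welch", "student")) {
      raw <- two_sample_t(a, b, variant)
      summ <- two_sample_t(group_summary(length(a), mean(a), sd(a)),
                           group_summary(length(b), mean(b), sd(b)), variant)
      expect_equal(raw$statistic, summ$statistic)
      expect_equal(raw$p_value, summ$p_value)
      ref <- t.test(a, b, var.equal = (variant == "student"))
      expect_equal(raw$statistic, unname(ref$statistic))
      expect_equal(raw$df, unname(ref$parameter))
      expect_equal(raw$p_value, ref$p.value)
    }
    # sign flips under group exchange, p invariant
    fl <- two_sample_t(b, a)
    expect_equal(fl$statistic, -two_sample_t(a, b)$statistic)
    expect_equal(fl$p_value, two_sample_t(a, b)$p_value)
  }
})

test_that("Mann-Whitney is exact for small samples and ties give p = 1", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)        # U of the first group
  expect_equal(r$p_value, 2 / choose(4, 2))
  expect_equal(mann_whitney(c(5, 5, 5), c(5, 5))$p_value, 1)
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1)
})

test_that("exact Mann-Whitney p matches full permutation enumeration", {
  set.seed(30)
  for (i in 1:10) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- sample(1:100, na + nb)       # untied
    a <- x[1:na]; b <- x[-(1:na)]
    got <- mann_whitney(a, b)
    # enumerate all group assignments of the combined sample
    u_stat <- function(aa, bb) sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
    u_obs <- u_stat(a, b)
    combos <- utils::combn(na + nb, na)
    us <- apply(combos, 2, function(idx) u_stat(x[idx], x[-idx]))
    mu <- na * nb / 2
    p_exact <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    expect_equal(got$statistic, u_obs)
    expect_equal(got$p_value, p_exact)
  }
})

test_that("U statistic and empirical ROC area obey AUC = U / (nA nB)", {
  set.seed(31)
  for (i in 1:10) {
    a <- round(rnorm(8), 1); b <- round(rnorm(6, 1), 1)
    u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    roc <- empirical_roc(c(a, b), rep(c("A", "B"), c(8, 6)), "A")
    expect_equal(roc$auc, u / (8 * 6))
  }
})

test_that("proportion tests agree with base R on 2x2 tables", {
  ours <- proportion_test(7, 14, 7, 10)
  ref <- suppressWarnings(chisq.test(matrix(c(7, 7, 7, 3), 2), correct = FALSE))
  expect_equal(ours$p_value, ref$p.value)
  f <- proportion_test(7, 14, 7, 10, method = "fisher_exact")
  expect_equal(f$p_value, fisher.test(matrix(c(7, 7, 7, 3), 2))$p.value)
})

test_that("logistic fit maximises the likelihood against a coefficient grid", {
  set.seed(32)
  group <- c("PD", "PD", "PD", "CBS", "CBS", "CBS")
  index <- c(0.9, 0.6, 0.4, 0.5, 0.2, 0.1)
  fit <- fit_logistic_adjusted(group, index)
  expect_false(fit$separation)
  y <- as.integer(group == "PD")
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * index
    sum(y * eta - log1p(exp(eta)))
  }
  co <- fit$coefficients$estimate
  ll_hat <- loglik(co[1], co[2])
  for (b0 in seq(-6, 6, length.out = 25))
    for (b1 in seq(-10, 10, length.out = 25))
      expect_gte(ll_hat + 1e-8, loglik(b0, b1))
})

test_that("logistic fit flags separation and handles null predictors", {
  # a predictor independent of the outcome rejects at the nominal rate only
  set.seed(40)
  rej <- replicate(200, {
    grp <- rep(c("PD", "CBS"), each = 15)
    f <- fit_logistic_adjusted(grp, rnorm(30))
    f$coefficients$p_value[f$coefficients$term == "index"] < 0.05
  })
  expect_lt(mean(rej), 0.12)
  # a constant predictor is aliased with the intercept and drops out
  f0 <- fit_logistic_adjusted(rep(c("PD", "CBS"), each = 6), rep(0.5, 12))
  expect_false("index" %in% f0$coefficients$term)
  # fixture: near-complete separation on the blink-reflex index plus age
  tab <- ai_table(fixture_cohort())
  ages <- fixture_cohort()$patients$age
  f1 <- fit_logistic_adjusted(tab$group, tab$ai_r2brrc_100, ages)
  f2 <- fit_logistic_adjusted(tab$group, tab$ai_r2brrc_100 - 20 * tab$ai_mri, ages)
  expect_true(f1$separation || f2$separation)
  expect_true(f2$separation)
})

test_that("logistic p-values are invariant to affine predictor rescaling", {
  set.seed(33)
  grp <- sample(c("PD", "CBS"), 40, replace = TRUE)
  grp[1:2] <- c("PD", "CBS")
  x <- rnorm(40) + (grp == "PD")
  age <- rnorm(40, 65, 8)
  p1 <- fit_logistic_adjusted(grp, x, age)$coefficients$p_value
  p2 <- fit_logistic_adjusted(grp, 10 * x - 3, age)$coefficients$p_value
  expect_equal(p1[-1], p2[-1], tolerance = 1e-6)
})

test_that("compare_groups reports the published-table shape", {
  tab <- compare_groups(fixture_cohort())
  expect_true(all(c("variable", "pd_mean", "cbs_mean", "p_welch",
                    "p_student", "p_mann_whitney") %in% names(tab)))
  expect_true("ai_r2brrc_100" %in% tab$variable)
  row <- tab[tab$variable == "age", ]
  expect_equal(row$pd_mean, mean(fixture_cohort()$patients$age[1:14]))
  expect_true(all(tab$p_welch >= 0 & tab$p_welch <= 1))
})
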