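test_that("empirical ROC handles separation, ties and the worked pair count", {
  # perfect separation
  roc <- empirical_roc(c(3, 4, 5, 1, 2), c("P", "P", "P", "N", "N"), "P")
  expect_equal(roc$auc, 1)
  expect_equal(roc$youden_j, 1)
  expect_equal(roc$youden_cutoff, 2.5)   # midpoint of the separating gap
  # uninformative marker: all scores identical
  roc2 <- empirical_roc(rep(1, 6), rep(c("P", "N"), 3), "P")
  expect_equal(roc2$auc, 0.5)
  expect_equal(roc2$youden_j, 0)
  # worked example: 8 concordant of 9 pairs
  roc3 <- empirical_roc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                        c("P", "P", "P", "N", "N", "N"), "P")
  expect_equal(roc3$auc, 8 / 9)
  expect_error(empirical_roc(1:3, c("P", "P", "P"), "P"), "degenerate")
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    scores <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
    labels <- sample(c("P", "N"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    p <- empirical_roc(scores, labels, "P")$points
    expect_equal(c(p$fpr[1], p$tpr[1]), c(0, 0))
    expect_equal(c(p$fpr[nrow(p)], p$tpr[nrow(p)]), c(1, 1))
    expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
  }
})

test_that("trapezoidal AUC equals exhaustive pair counting on random sets", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    scores <- round(rnorm(n), sample(0:2, 1))
    labels <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    dir <- sample(c("greater", "less"), 1)
    roc <- empirical_roc(scores, labels, "A", direction = dir)
    expect_equal(roc$auc, oracle_auc(scores, labels, "A", dir))
  }
})

test_that("implementation AUC agrees with an established ROC library", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:10) {
    n <- 40
    labels <- sample(c("P", "N"), n, replace = TRUE, prob = c(.4, .6))
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + (labels == "P")
    ours <- empirical_roc(scores, labels, "P")$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("N", "P"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(ours, ref)
  }
})

test_that("Youden cutoff equals exhaustive threshold search with the stated tie-break", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(5:25, 1)
    scores <- round(rnorm(n), sample(0:1, 1))
    labels <- sample(c("P", "N"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    roc <- empirical_roc(scores, labels, "P")
    got <- youden_optimal_cutoff(roc)
    want <- oracle_youden(scores, labels, "P")
    expect_equal(got$youden_j, want$youden_j)
    expect_equal(got$cutoff, want$cutoff)
  }
})

test_that("binormal AUC matches the normal-CDF identity and published bridge", {
  expect_equal(binormal_auc(0, 1, 0, 1), 0.5)
  expect_equal(binormal_auc(5, 2, 5, 3), 0.5)
  expect_equal(binormal_auc(1, 1, 0, 1), pnorm(1 / sqrt(2)))
  expect_equal(round(binormal_auc(1, 1, 0, 1), 4), 0.7602)
  # symmetric in the group order (absolute mean difference)
  expect_equal(binormal_auc(0, 1, 1, 1), binormal_auc(1, 1, 0, 1))
  expect_error(binormal_auc(1, 0, 1, 0), "undefined")
  expect_equal(binormal_auc(2, 0, 1, 0), 1)
})

test_that("exact binomial interval matches closed forms and binom.test", {
  expect_equal(unname(exact_binomial_ci(10, 10)),
               c(0.025^(1 / 10), 1))
  expect_equal(unname(exact_binomial_ci(0, 7)), c(0, 1 - 0.025^(1 / 7)))
  # independent oracle: base R's exact test interval
  set.seed(4)
  for (i in 1:30) {
    n <- sample(1:50, 1); x <- sample(0:n, 1)
    expect_equal(unname(exact_binomial_ci(x, n)),
                 as.numeric(binom.test(x, n)$conf.int), tolerance = 1e-12)
  }
  expect_error(exact_binomial_ci(5, 4), "<= n")
  expect_error(exact_binomial_ci(2.5, 10), "integer")
})

test_that("exact interval coverage is at least nominal across binomial rates", {
  set.seed(5)
  n <- 25
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    x <- rbinom(1000, n, p)
    ci <- vapply(x, function(xx) exact_binomial_ci(xx, n), numeric(2))
    cover <- mean(ci[1, ] <= p & p <= ci[2, ])
    expect_gte(cover, 0.95 - 3 * sqrt(0.05 * 0.95 / 1000))
  }
})

test_that("evaluate_rule counts by strict comparison and attaches exact CIs", {
  sc <- c(1, 2, 3, 4); lb <- c("N", "N", "P", "P")
  m <- evaluate_rule(sc, lb, 2, "greater", "P")
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(2, 0, 2, 0))
  # cutoff at an observed value: strict '>' excludes it
  m2 <- evaluate_rule(sc, lb, 3, "greater", "P")
  expect_equal(c(m2$tp, m2$fn), c(1, 1))
  # cutoff below the minimum calls everything positive
  m3 <- evaluate_rule(sc, lb, 0, "greater", "P")
  expect_equal(c(m3$sensitivity, m3$specificity), c(1, 0))
  # direction "less" mirrors sensitivity and specificity
  m4 <- evaluate_rule(sc, lb, 3, "less", "N")
  expect_equal(m4$tp, 2)
  expect_equal(unname(m$sens_ci), as.numeric(binom.test(2, 2)$conf.int))
})

test_that("direction flip with label swap leaves the discrimination coherent", {
  set.seed(6)
  scores <- rnorm(30); labels <- sample(c("P", "N"), 30, replace = TRUE)
  labels[1:2] <- c("P", "N")
  a <- empirical_roc(scores, labels, "P", "greater")
  b <- empirical_roc(scores, labels, "N", "less")
  expect_equal(a$auc, b$auc)
  # with no score exactly at the cutoff, sensitivity and specificity swap
  m_a <- evaluate_rule(scores, labels, 0.2, "greater", "P")
  m_b <- evaluate_rule(scores, labels, 0.2, "less", "N")
  expect_equal(m_b$specificity, m_a$sensitivity)
  expect_equal(m_b$sensitivity, m_a$specificity)
})
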