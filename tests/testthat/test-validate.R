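test_that("binomial CI constructions match their closed forms", {
  # exact interval at full concordance: lower = (alpha/2)^(1/n)
  ci <- binomial_ci(505, 505, "clopper_pearson")
  expect_equal(ci[1], 0.025^(1 / 505))
  expect_equal(ci[1], 0.9927, tolerance = 1e-4)
  expect_equal(ci[2], 1)

  # Wilson score interval, x = 5, n = 10
  w <- binomial_ci(5, 10, "wilson")
  expect_equal(w, c(0.2366, 0.7634), tolerance = 1e-4)

  # boundary conventions: upper = 1 at x = n, lower = 0 at x = 0
  for (m in c("clopper_pearson", "wilson", "jeffreys", "agresti_coull")) {
    expect_equal(binomial_ci(10, 10, m)[2], 1)
    expect_equal(binomial_ci(0, 10, m)[1], 0)
  }
  expect_error(binomial_ci(5, 0), "n must be")
  expect_error(binomial_ci(11, 10), "x must")
})

test_that("exact interval agrees with the base binom.test oracle", {
  for (n in c(10, 25, 505)) {
    for (x in unique(c(0, 1, floor(n / 2), n - 1, n))) {
      expect_equal(unname(binomial_ci(x, n, "clopper_pearson")),
                   as.numeric(stats::binom.test(x, n)$conf.int),
                   tolerance = 1e-10, label = sprintf("x=%d n=%d", x, n))
    }
  }
})

test_that("99% intervals contain 95% intervals for every method", {
  grid <- expand.grid(x = c(0, 3, 7, 10), n = 10)
  for (m in c("clopper_pearson", "wilson", "jeffreys", "agresti_coull")) {
    for (i in seq_len(nrow(grid))) {
      ci95 <- binomial_ci(grid$x[i], grid$n[i], m, 0.95)
      ci99 <- binomial_ci(grid$x[i], grid$n[i], m, 0.99)
      expect_lte(ci99[1], ci95[1])
      expect_gte(ci99[2], ci95[2])
    }
  }
})

test_that("Clopper-Pearson coverage is at least nominal on small grids", {
  # exhaustive: for each n and p, coverage = sum of binomial probabilities
  # of the x whose interval contains p
  for (n in c(5, 12, 30)) {
    cis <- t(vapply(0:n, function(x) binomial_ci(x, n, "clopper_pearson"),
                    c(0, 0)))
    for (p in seq(0.05, 0.95, by = 0.09)) {
      covered <- cis[, 1] <= p & p <= cis[, 2]
      coverage <- sum(stats::dbinom(0:n, n, p)[covered])
      expect_gte(coverage, 0.95 - 1e-12)
    }
  }
})

test_that("confusion matrices reduce calls to a binary task", {
  calls <- data.frame(
    sample_id = c("a", "b", "c", "d", "e"),
    call_class = c("T21", "T21", "EUPLOID_FEMALE", "EUPLOID_MALE", "X0"),
    base_class = NA_character_, stringsAsFactors = FALSE)
  truth <- data.frame(
    sample_id = c("a", "b", "c", "d", "e"),
    true_karyotype = c("47,XX,+21", "47,XY,+21", "46,XX", "46,XY", "45,X"),
    stringsAsFactors = FALSE)
  cm <- confusion(calls, truth, "T21")
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 0, tn = 3, fn = 0))
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, nrow(truth))

  # a missed T21 becomes a false negative
  calls$call_class[1] <- "EUPLOID_FEMALE"
  expect_equal(confusion(calls, truth, "T21")$fn, 1)

  # mosaic of the class counts as positive when asked
  calls$call_class[1] <- "MOSAIC"; calls$base_class[1] <- "T21"
  expect_equal(confusion(calls, truth, "T21", count_mosaic = TRUE)$tp, 2)
  expect_equal(confusion(calls, truth, "T21", count_mosaic = FALSE)$fn, 1)

  expect_error(confusion(calls, truth[1:3, ], "T21"), "sample_id")
  expect_error(confusion(calls, truth, "T99"), "unknown abnormality")
})

test_that("performance reports proportions with the chosen CI convention", {
  cm <- structure(list(tp = 65, fp = 0, tn = 440, fn = 0),
                  class = "confusion_matrix")
  pf <- performance(cm, "clopper_pearson", "all_observations")
  expect_equal(pf$sensitivity, 1)
  expect_equal(pf$sens_ci[1], 0.025^(1 / 505))
  expect_equal(pf$spec_ci[1], 0.025^(1 / 505))  # same n under the convention
  pf2 <- performance(cm, "clopper_pearson", "standard")
  expect_equal(pf2$sens_ci[1], 0.025^(1 / 65))

  cm2 <- structure(list(tp = 9, fp = 0, tn = 0, fn = 1),
                   class = "confusion_matrix")
  pf3 <- performance(cm2, denominator_convention = "standard")
  expect_equal(pf3$sensitivity, 0.9)
  expect_identical(pf3$spec_flag, "UNDEFINED")
  expect_true(is.na(pf3$specificity))
})

test_that("Mann-Whitney exact path matches closed cases and the base oracle", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_identical(res$method, "exact")

  # identical groups: U = n^2/2, p ~ 1 (tie-corrected approximation)
  res2 <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res2$U, 8)
  expect_gt(res2$p_value, 0.9)

  # exact path vs wilcox.test for all group sizes up to 6
  set.seed(99)
  for (m in 2:6) for (n in 2:6) {
    a <- sample(seq_len(100), m); b <- sample(setdiff(seq_len(100), a), n)
    ours <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_identical(ours$method, "exact")
    expect_equal(ours$U, unname(ref$statistic), label = sprintf("m=%d n=%d", m, n))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12,
                 label = sprintf("m=%d n=%d", m, n))
  }

  # large-sample path agrees with the corrected normal approximation
  set.seed(100)
  a <- rnorm(40); b <- rnorm(45, mean = 0.5)
  ours <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_identical(ours$method, "normal")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("cohort percentages round half-up to two decimals", {
  s <- cohort_summary(c(T21 = 65, SCA = 13, zero = 0), 125)
  expect_equal(s$percent[s$class == "T21"], 52.00)
  expect_equal(s$percent[s$class == "SCA"], 10.40)
  expect_equal(s$percent[s$class == "zero"], 0)
  expect_equal(cohort_summary(c(older = 172), 505)$percent, 34.06)
  expect_equal(cohort_summary(c(abnormal = 125), 505)$percent, 24.75)
  expect_error(cohort_summary(c(a = 10), 5), "exceeds")
  expect_error(cohort_summary(c(a = 1), 0), "denominator")
})
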