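quant_from_lambda <- function(lambda, n_valid = 20000) {
  # invert the estimator: choose positives giving this lambda (approx)
  n_neg <- round(n_valid * exp(-lambda))
  estimate_lambda(n_valid - n_neg, n_valid)
}

test_that("chromosomal ratio divides occupancies and brackets with its CI", {
  qa <- estimate_lambda(10000, 20000)
  qb <- estimate_lambda(10000, 20000)
  r <- compute_ratio(qa, qb, "r13")
  expect_equal(r$value, 1.0)
  expect_lte(r$ci95[1], r$value); expect_gte(r$ci95[2], r$value)

  qt <- quant_from_lambda(1.0397)
  qr <- quant_from_lambda(0.6931)
  r2 <- compute_ratio(qt, qr)
  expect_equal(r2$value, 1.5, tolerance = 2e-3)

  q0 <- estimate_lambda(0, 20000)
  expect_error(compute_ratio(qa, q0, "r13"), "absent")
})

test_that("ratios are invariant under common loading scale", {
  for (scale in c(0.5, 1, 1.8)) {
    qt <- quant_from_lambda(0.6 * scale)
    qr <- quant_from_lambda(0.4 * scale)
    expect_equal(compute_ratio(qt, qr)$value, 1.5, tolerance = 0.02)
  }
})

test_that("sex call uses the Y-presence floor", {
  th <- default_thresholds()
  qX <- quant_from_lambda(0.7)
  expect_identical(sex_call(qX, estimate_lambda(0, 20000), th), "female")
  expect_identical(sex_call(qX, quant_from_lambda(0.69), th), "male")
  # stray false-positive wells below the floor stay female
  expect_identical(sex_call(qX, quant_from_lambda(0.003), th), "female")
  expect_identical(sex_call(estimate_lambda(0, 20000),
                            estimate_lambda(0, 20000), th), "indeterminate")
})

test_that("interval verdicts separate clinical euploid and trisomic ratios", {
  th <- default_thresholds()
  # values observed for aneuploid and euploid groups
  expect_identical(classify_ratio(1.495, name = "r13", thresholds = th), "aneuploid")
  expect_identical(classify_ratio(1.018, name = "r13", thresholds = th), "euploid")
  expect_identical(classify_ratio(1.30, name = "r13", thresholds = th), "intermediate")
  expect_identical(classify_ratio(0.522, sex = "female", name = "rX18",
                                  thresholds = th), "aneuploid")
  expect_identical(classify_ratio(0.975, sex = "female", name = "rX18",
                                  thresholds = th), "euploid")
  # 18/X needs sex-specific intervals
  expect_identical(classify_ratio(1.507, sex = "female", name = "r18X",
                                  thresholds = th), "aneuploid")
  expect_identical(classify_ratio(1.965, sex = "male", name = "r18X",
                                  thresholds = th), "euploid")
  expect_identical(classify_ratio(2.870, sex = "male", name = "r18X",
                                  thresholds = th), "aneuploid")
  expect_error(classify_ratio(1.5, name = "r18X", thresholds = th), "sex")
})

test_that("decision table recovers every vocabulary state from ideal ratios", {
  vocab <- state_vocabulary()
  for (k in names(vocab)) {
    st <- parse_karyotype(k)
    cc <- vapply(c("13", "18", "21", "X", "Y"), function(ch)
      dpcrscreen:::effective_copies(st, ch), 0)
    sex <- if (cc["Y"] > 0) "male" else "female"
    ratios <- ideal_ratios(cc["13"], cc["18"], cc["21"], cc["X"], cc["Y"])
    if (sex == "female") ratios$rXY <- NULL
    call <- integrate_calls(ratios, sex)
    expect_identical(call$call_class, unname(vocab[k]), label = k)
  }
})

test_that("triploid female is the documented blind spot", {
  # 69,XXX: every ratio sits at its euploid value, Y absent
  call <- integrate_calls(ideal_ratios(3, 3, 3, 3, 0), "female")
  expect_identical(call$call_class, "EUPLOID_FEMALE")
  expect_identical(expected_call("69,XXX"), "EUPLOID_FEMALE")
})

test_that("specific integration patterns match the design table", {
  # T18 female: r18X ~1.5, Y absent
  expect_identical(
    integrate_calls(list(r13 = 1.0, r21 = 1.0, r18X = 1.5, rX18 = 1 / 1.5),
                    "female")$call_class, "T18")
  # male triploidy: autosomes balanced, r18X ~1.5, X/Y ~2
  expect_identical(
    integrate_calls(list(r13 = 1.0, r21 = 1.0, r18X = 1.5, rX18 = 2 / 3,
                         rXY = 2.0), "male")$call_class, "TRIPLOID_MALE")
  # XXXY: r18X ~2/3, X/Y ~3
  expect_identical(
    integrate_calls(list(r13 = 1.0, r21 = 1.0, r18X = 2 / 3, rX18 = 1.5,
                         rXY = 3.0), "male")$call_class, "XXXY")
  # conflicting abnormal evidence on both duplexes is indeterminate
  expect_identical(
    integrate_calls(list(r13 = 1.5, r21 = 2 / 3, r18X = 1.5, rX18 = 2 / 3),
                    "female")$call_class, "INDETERMINATE")
  # QC failure forces indeterminate
  expect_identical(
    integrate_calls(ideal_ratios(), "female", qc = "LOW_QC")$call_class,
    "INDETERMINATE")
})

test_that("mosaic fraction inverts the mixture model", {
  expect_equal(mosaic_fraction(1.0, "T21"), 0)
  expect_equal(mosaic_fraction(1.5, "T21"), 1)
  expect_equal(mosaic_fraction(1.25, "T21"), 0.5)
  expect_equal(mosaic_fraction(0.75, "X0"), 0.5)
  expect_equal(mosaic_fraction(2.0, "T13"), 1)  # clamped
  expect_error(mosaic_fraction(1.2, "XXY"), "mosaic model")
})

test_that("intermediate ratios flag mosaics or reject by policy", {
  ratios <- list(r13 = 1 / 1.30, r21 = 1.30, r18X = 1.0, rX18 = 1.0)
  call <- integrate_calls(ratios, "female")
  expect_identical(call$call_class, "MOSAIC")
  expect_identical(call$base_class, "T21")
  expect_equal(call$mosaic_fraction, 2 * (1.30 - 1))
  call2 <- integrate_calls(ratios, "female", default_thresholds("reject"))
  expect_identical(call2$call_class, "INDETERMINATE")
  # X0 mosaic from an intermediate X/18 ratio (f = 0.44 -> rX18 = 0.78)
  rx <- list(r13 = 1.0, r21 = 1.0, r18X = 1 / 0.78, rX18 = 0.78)
  call3 <- integrate_calls(rx, "female")
  expect_identical(call3$call_class, "MOSAIC")
  expect_identical(call3$base_class, "X0")
  expect_equal(call3$mosaic_fraction, 2 * (1 - 0.78))
})

test_that("classification is deterministic for identical inputs", {
  pc <- partition_counts(20000, 4000, 3000, 800, 12200)
  panel <- default_panel()
  q1 <- lapply(panel$reactions, function(r) quantify_reaction(pc, r))
  q2 <- lapply(panel$reactions, function(r) quantify_reaction(pc, r))
  expect_identical(call_sample(q1, panel), call_sample(q2, panel))
})
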