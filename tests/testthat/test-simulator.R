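test_that("karyotype strings parse to copy-number states", {
  expect_equal(parse_karyotype("46,XX")$copy_numbers,
               c("13" = 2, "18" = 2, "21" = 2, "X" = 2, "Y" = 0))
  expect_equal(parse_karyotype("47,XY,+21")$copy_numbers[["21"]], 3)
  expect_equal(parse_karyotype("45,X")$copy_numbers[["X"]], 1)
  expect_equal(parse_karyotype("48,XXXY")$copy_numbers[["X"]], 3)
  tri <- parse_karyotype("69,XXY")$copy_numbers
  expect_equal(unname(tri[c("13", "18", "21", "X", "Y")]), c(3, 3, 3, 2, 1))
  mos <- parse_karyotype("47,XX,+21[40]/46,XX[60]")
  expect_equal(dpcrscreen:::effective_copies(mos, "21"), 2.4)
  expect_error(parse_karyotype("46"), "parse")
  expect_error(parse_karyotype("46,XX,+7"), "token")
  expect_error(parse_karyotype("46,XX[50]/46,XY"), "percentage")
})

test_that("effective lambda scales with copy number, mixture and efficiency", {
  p <- sim_params(lambda_base = 0.8)
  expect_equal(effective_lambda(parse_karyotype("46,XX"), "13", p), 0.8)
  expect_equal(effective_lambda(parse_karyotype("47,XX,+21"), "21", p), 1.2)
  expect_equal(effective_lambda(parse_karyotype("46,XY"), "Y", p), 0.4)
  mos <- parse_karyotype("47,XX,+21[50]/46,XX[50]")
  expect_equal(effective_lambda(mos, "21", p), 1.0)
  a <- assay("13", "VIC", efficiency = 1.1)
  expect_equal(effective_lambda(parse_karyotype("46,XX"), "13", p, a), 0.88)
})

test_that("a zero-template chip is all negative", {
  p <- sim_params(lambda_base = 0, false_positive_rate = 0,
                  invalid_fraction = 0, seed = 5)
  cts <- simulate_chip(parse_karyotype("46,XX"), default_panel()$reactions$R1, p)
  expect_equal(cts$n_negative, p$n_partitions)
  expect_equal(cts$n_fam_only + cts$n_vic_only + cts$n_double, 0)
})

test_that("simulation is reproducible under a fixed seed", {
  p <- sim_params(seed = 42)
  r1 <- default_panel()$reactions$R1
  st <- parse_karyotype("47,XY,+21")
  expect_identical(simulate_chip(st, r1, p), simulate_chip(st, r1, p))
  sim_a <- simulate_cohort(c("46,XX" = 3, "47,XY,+21" = 2), p)
  sim_b <- simulate_cohort(c("46,XX" = 3, "47,XY,+21" = 2), p)
  expect_identical(sim_a, sim_b)
  sim_c <- simulate_cohort(c("46,XX" = 3, "47,XY,+21" = 2), sim_params(seed = 43))
  expect_false(identical(sim_a$counts, sim_c$counts))
  expect_equal(dim(sim_a$counts), dim(sim_c$counts))
})

test_that("cohort bookkeeping: one chip per reaction per sample", {
  sim <- simulate_cohort(c("46,XX" = 2), sim_params(seed = 1))
  expect_equal(nrow(sim$counts), 6)
  expect_equal(nrow(sim$truth), 2)
  expect_setequal(unique(sim$counts$reaction_id), c("R1", "R2", "R3"))
  expect_true(all(sim$counts$n_fam_only + sim$counts$n_vic_only +
                    sim$counts$n_double + sim$counts$n_negative ==
                    sim$counts$n_valid))
})

test_that("estimator recovers the true occupancy without noise", {
  r1 <- default_panel()$reactions$R1
  set.seed(7)
  for (lb in c(0.2, 0.8, 1.5)) {
    p <- sim_params(lambda_base = lb, invalid_fraction = 0,
                    per_molecule_detection_prob = 1, false_positive_rate = 0)
    lam <- replicate(500, {
      cts <- simulate_chip(parse_karyotype("46,XX"), r1, p, seed = NULL)
      estimate_lambda(channel_positives(cts, "FAM"), cts$n_valid)$lambda_hat
    })
    expect_lt(abs(mean(lam) - lb) / lb, 0.01)
  }
})

test_that("simulated aneuploid chips recover the expected ratios", {
  panel <- default_panel()
  p <- sim_params(invalid_fraction = 0, per_molecule_detection_prob = 1,
                  false_positive_rate = 0)
  mean_ratio <- function(karyo, reaction, target, reference, n = 150) {
    st <- parse_karyotype(karyo)
    mean(replicate(n, {
      cts <- simulate_chip(st, reaction, p, seed = NULL)
      q <- quantify_reaction(cts, reaction)
      q[[target]]$lambda_hat / q[[reference]]$lambda_hat
    }))
  }
  set.seed(11)
  expect_equal(mean_ratio("47,XX,+13", panel$reactions$R1, "13", "21"), 1.5,
               tolerance = 0.01)
  expect_equal(mean_ratio("47,XX,+18", panel$reactions$R2, "18", "X"), 1.5,
               tolerance = 0.01)
  expect_equal(mean_ratio("45,X", panel$reactions$R2, "X", "18"), 0.5,
               tolerance = 0.02)
  expect_equal(mean_ratio("47,XY,+18", panel$reactions$R2, "18", "X"), 3.0,
               tolerance = 0.02 * 3)
})

test_that("mosaic ratios follow (2 + f)/2 and the estimate is monotone in f", {
  r1 <- default_panel()$reactions$R1
  p <- sim_params(invalid_fraction = 0, per_molecule_detection_prob = 1,
                  false_positive_rate = 0)
  f_grid <- seq(0.1, 0.9, by = 0.1)
  set.seed(13)
  est <- vapply(f_grid, function(f) {
    karyo <- sprintf("47,XX,+21[%d]/46,XX[%d]", round(100 * f),
                     100 - round(100 * f))
    st <- parse_karyotype(karyo)
    r <- replicate(60, {
      cts <- simulate_chip(st, r1, p, seed = NULL)
      q <- quantify_reaction(cts, r1)
      q[["21"]]$lambda_hat / q[["13"]]$lambda_hat
    })
    mean(r)
  }, 0)
  expect_equal(est, (2 + f_grid) / 2, tolerance = 0.01)
  f_hat <- vapply(est, mosaic_fraction, 0, base_class = "T21")
  expect_gte(suppressWarnings(cor(f_hat, f_grid, method = "spearman")), 0.95)
})

test_that("expected_call maps cohort truths consistently", {
  vocab <- state_vocabulary()
  for (k in names(vocab)) expect_identical(expected_call(k), unname(vocab[k]))
  # 60% trisomic cells put the ratio in the intermediate zone -> mosaic
  expect_identical(expected_call("47,XX,+21[60]/46,XX[40]"), "MOSAIC")
  # high-fraction mosaics are indistinguishable from full trisomy
  expect_identical(expected_call("47,XX,+21[90]/46,XX[10]"), "T21")
})
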