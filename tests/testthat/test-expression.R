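test_that("the efficiency-corrected ratio obeys its closed form", {
  ## no CT difference anywhere: ratio exactly 1
  expect_identical(
    pfaffl_ratio(20, 20, c(18, 22), c(18, 22), 1.9, c(1.85, 1.92)), 1)

  ## single reference, perfect doubling, target one cycle earlier: ratio 2
  expect_equal(pfaffl_ratio(19, 20, 20, 20, 2, 2), 2)

  ## survey values: ADS in young vs old leaves against actin/CPR/PAL
  ratio <- pfaffl_ratio(22.2, 29.9,
                        c(22.3, 21.0, 20.0), c(23.4, 19.9, 21.3),
                        1.88, c(1.91, 1.90, 1.87))
  direct <- 1.88^(29.9 - 22.2) /
    (1.91^(23.4 - 22.3) * 1.90^(19.9 - 21.0) * 1.87^(21.3 - 20.0))^(1 / 3)
  expect_equal(ratio, direct, tolerance = 1e-12)
  expect_equal(ratio, 98.26107, tolerance = 1e-5)
})

test_that("ratio is reciprocal under group swap and monotone in target CT", {
  r1 <- pfaffl_ratio(21, 24, c(20, 20), c(21, 19), 1.9, c(1.85, 1.92))
  r2 <- pfaffl_ratio(24, 21, c(21, 19), c(20, 20), 1.9, c(1.85, 1.92))
  expect_equal(r1 * r2, 1, tolerance = 1e-12)

  cts <- seq(18, 26, by = 0.5)
  ratios <- vapply(cts, function(ct)
    pfaffl_ratio(ct, 22, 20, 20, 1.9, 1.9), numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("with all efficiencies at 2 the ratio equals 2^-ddCt", {
  ct <- artemisia_fixture("ct_means")
  for (tt in c("flower_buds", "young_leaves", "stems")) {
    g <- "CPS"
    r <- pfaffl_ratio(
      ct$ct[ct$gene == g & ct$tissue == tt],
      ct$ct[ct$gene == g & ct$tissue == "old_leaves"],
      ct$ct[ct$gene == "actin" & ct$tissue == tt],
      ct$ct[ct$gene == "actin" & ct$tissue == "old_leaves"],
      2, 2)
    dd <- delta_delta_ct(ct, g, tt, "actin", g, "old_leaves")
    expect_equal(r, dd$amount, tolerance = 1e-12)
  }
})

test_that("degenerate reference input is rejected", {
  expect_error(pfaffl_ratio(20, 20, numeric(0), numeric(0), 1.9, numeric(0)),
               class = "qpcrflux_normalization_error")
  expect_error(pfaffl_ratio(20, 20, 20, 20, 2.5, 2),
               class = "qpcrflux_parameter_error")
  expect_error(pfaffl_ratio(NA, 20, 20, 20, 1.9, 1.9),
               class = "qpcrflux_parameter_error")
})

test_that("randomization p-values behave at the null and under strong effects", {
  refs <- matrix(20 + rnorm(18, 0, 0.1), ncol = 2)
  ## identical groups: nothing to detect
  p_null <- randomization_test(rep(25, 9), rep(25, 9),
                               refs[1:9, , drop = FALSE] * 0 + 20,
                               refs[1:9, , drop = FALSE] * 0 + 20,
                               1.9, c(1.9, 1.9), n_iter = 500, seed = 1)
  expect_gt(p_null, 0.9)

  ## 8-fold change, tight noise: strongly significant
  d <- two_tissue_design(
    fold_changes = tibble::tibble(gene = "T1", tissue = "treated",
                                  fold_change = 8),
    tech_sd = 0.1, bio_sd = 0.1
  )
  tab <- simulate_ct_table(d, uniform_efficiencies(d$genes), seed = 5)
  res <- relative_expression(tab, uniform_efficiencies(d$genes),
                             c("R1", "R2", "R3"), "control",
                             n_iter = 2000, n_boot = 0, seed = 5)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$ratio, 4)
  expect_lt(res$ratio, 16)

  ## fixed seed reproduces the p-value exactly
  res2 <- relative_expression(tab, uniform_efficiencies(d$genes),
                              c("R1", "R2", "R3"), "control",
                              n_iter = 2000, n_boot = 0, seed = 5)
  expect_identical(res$p_value, res2$p_value)
})

test_that("too few replicates skips the test with a warning", {
  expect_warning(
    p <- randomization_test(25, c(25, 25), matrix(20), matrix(c(20, 20)),
                            1.9, 1.9),
    "skipped")
  expect_true(is.na(p))
})

test_that("bootstrap intervals collapse under zero noise and contain the ratio", {
  t_s <- rep(24, 6); t_c <- rep(25, 6)
  refs <- matrix(20, 6, 2)
  ci <- bootstrap_interval(t_s, t_c, refs, refs, 2, c(2, 2),
                           n_boot = 200, seed = 1)
  expect_equal(unname(ci[["ci_low"]]), 2)
  expect_equal(unname(ci[["ci_high"]]), 2)

  set.seed(9)
  t_s <- 24 + rnorm(6, 0, 0.3); t_c <- 25 + rnorm(6, 0, 0.3)
  refs_s <- matrix(20 + rnorm(12, 0, 0.3), 6)
  refs_c <- matrix(20 + rnorm(12, 0, 0.3), 6)
  point <- pfaffl_ratio(mean(t_s), mean(t_c), colMeans(refs_s),
                        colMeans(refs_c), 1.9, c(1.9, 1.9))
  ci <- bootstrap_interval(t_s, t_c, refs_s, refs_c, 1.9, c(1.9, 1.9),
                           n_boot = 500, seed = 2)
  expect_lte(ci[["ci_low"]], point)
  expect_gte(ci[["ci_high"]], point)

  ci_again <- bootstrap_interval(t_s, t_c, refs_s, refs_c, 1.9, c(1.9, 1.9),
                                 n_boot = 500, seed = 2)
  expect_identical(ci, ci_again)
})

test_that("bootstrap intervals cover the true ratio at roughly nominal rate", {
  covered <- 0
  n_sim <- 60
  true_fold <- 4
  for (s in seq_len(n_sim)) {
    d <- two_tissue_design(
      fold_changes = tibble::tibble(gene = "T1", tissue = "treated",
                                    fold_change = true_fold),
      tech_sd = 0.2, bio_sd = 0
    )
    tab <- simulate_ct_table(d, uniform_efficiencies(d$genes), seed = s)
    res <- relative_expression(tab, uniform_efficiencies(d$genes),
                               c("R1", "R2", "R3"), "control",
                               n_iter = 0, n_boot = 400, seed = s)
    if (res$ci_low <= true_fold && res$ci_high >= true_fold) {
      covered <- covered + 1
    }
  }
  expect_gte(covered / n_sim, 0.9)
})

test_that("expression tables carry metadata and plot on a log scale", {
  d <- two_tissue_design()
  tab <- simulate_ct_table(d, uniform_efficiencies(d$genes), seed = 3)
  res <- relative_expression(tab, uniform_efficiencies(d$genes),
                             c("R1", "R2", "R3"), "control",
                             n_iter = 100, n_boot = 100, seed = 3)
  expect_s3_class(res, "expression_ratios")
  expect_equal(res$n_sample, 9)
  expect_equal(res$control, "control")
  expect_s3_class(autoplot(res), "ggplot")

  ## optional BH adjustment adds a column without touching raw p
  res_bh <- relative_expression(tab, uniform_efficiencies(d$genes),
                                c("R1", "R2", "R3"), "control",
                                n_iter = 100, n_boot = 0, seed = 3,
                                p_adjust = "BH")
  expect_true("p_adj" %in% names(res_bh))
})
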