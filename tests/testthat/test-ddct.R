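ct_fix <- artemisia_fixture("ct_means")
kin_fix <- artemisia_fixture("kinetics")

test_that("ddCt amounts reproduce the flower-bud turnover table", {
  ## target = calibrator: exactly 1
  self <- delta_delta_ct(ct_fix, "RED1", "flower_buds", "actin",
                         "RED1", "flower_buds")
  expect_identical(self$ddct, 0)
  expect_identical(self$amount, 1)

  ads <- delta_delta_ct(ct_fix, "ADS", "flower_buds", "actin",
                        "RED1", "flower_buds")
  expect_equal(ads$ddct, -8.4, tolerance = 1e-12)
  expect_equal(round(ads$amount), 338)

  fds <- delta_delta_ct(ct_fix, "FDS", "flower_buds", "actin",
                        "RED1", "flower_buds")
  expect_equal(fds$ddct, -7.1, tolerance = 1e-12)
  expect_equal(round(fds$amount), 137)

  aldh <- delta_delta_ct(ct_fix, "ALDH1", "flower_buds", "actin",
                         "RED1", "flower_buds")
  expect_equal(aldh$ddct, -5.9, tolerance = 1e-12)
  expect_equal(round(aldh$amount), 60)
})

test_that("tissue-resolved amounts against the stem calibrator match the survey", {
  am <- amount_matrix(ct_fix,
                      genes = c("ADS", "CPS", "GAS", "ECS", "SQS"),
                      tissues = c("flower_buds", "young_leaves",
                                  "old_leaves", "stems"),
                      reference_gene = "actin",
                      calibrator_gene = "GAS", calibrator_tissue = "stems",
                      rounding = "report")
  get <- function(g, t) am$amount[am$gene == g & am$tissue == t]
  printed <- list(
    ADS = c(flower_buds = 8780, young_leaves = 6654, old_leaves = 69,
            stems = 18),
    CPS = c(flower_buds = 360, young_leaves = 170, old_leaves = 24,
            stems = 15),
    GAS = c(flower_buds = 56, young_leaves = 890, old_leaves = 11,
            stems = 1),
    ECS = c(flower_buds = 315, young_leaves = 590, old_leaves = 43000,
            stems = 34),
    SQS = c(flower_buds = 830, young_leaves = 340, old_leaves = 1780,
            stems = 550)
  )
  for (g in names(printed)) {
    for (t in names(printed[[g]])) {
      expect_equal(get(g, t), printed[[g]][[t]], tolerance = 0.01,
                   label = sprintf("%s / %s", g, t))
    }
  }
  expect_identical(get("GAS", "stems"), 1)  # calibrator cell

  ## full precision agrees with the closed form cell-wise
  exact <- amount_matrix(ct_fix, genes = "ADS", tissues = "stems",
                         reference_gene = "actin",
                         calibrator_gene = "GAS",
                         calibrator_tissue = "stems")
  expect_equal(exact$amount, 2^-((30.0 - 21.6) - (34.2 - 21.6)),
               tolerance = 1e-12)
})

test_that("the DBR2-specific primer row does not reproduce the printed value", {
  ## the printed ddCt of -7.9 is a documented discrepancy: the
  ## DBR2-specific CT row gives -11.8, while -7.9 matches the combined
  ## DBR2 + OPR3-like amplicon row instead
  spec <- delta_delta_ct(ct_fix, "DBR2", "flower_buds", "actin",
                         "RED1", "flower_buds")
  expect_equal(spec$ddct, -11.8, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(spec$ddct, -7.9, tolerance = 0.01)))

  combined <- delta_delta_ct(ct_fix, "DBR2_OPR3", "flower_buds", "actin",
                             "RED1", "flower_buds")
  expect_equal(combined$ddct, -7.9, tolerance = 1e-12)
  expect_equal(round(combined$amount), 239)
})

test_that("chain consistency: re-normalizing amounts swaps calibrators exactly", {
  am1 <- amount_matrix(ct_fix, genes = c("ADS", "ECS", "SQS"),
                       tissues = c("flower_buds", "old_leaves"),
                       reference_gene = "actin",
                       calibrator_gene = "GAS", calibrator_tissue = "stems")
  am2 <- amount_matrix(ct_fix, genes = c("ADS", "ECS", "SQS"),
                       tissues = c("flower_buds", "old_leaves"),
                       reference_gene = "actin",
                       calibrator_gene = "RED1",
                       calibrator_tissue = "flower_buds")
  ratio1 <- am1$amount / am1$amount[am1$gene == "ADS" &
                                      am1$tissue == "flower_buds"]
  ratio2 <- am2$amount / am2$amount[am2$gene == "ADS" &
                                      am2$tissue == "flower_buds"]
  expect_equal(ratio1, ratio2, tolerance = 1e-12)
})

test_that("missing CT values propagate as flagged gaps", {
  nd <- delta_delta_ct(ct_fix, "ADS", "roots", "actin",
                       "RED1", "flower_buds")
  expect_false(nd$defined)
  expect_true(is.na(nd$amount))
  expect_error(delta_delta_ct(ct_fix, "XYZ", "roots", "actin",
                              "RED1", "flower_buds"),
               class = "qpcrflux_lookup_error")
})

test_that("turnover scores multiply amount, kcat and stoichiometry", {
  am4 <- amount_matrix(ct_fix,
                       genes = c("FDS", "ADS", "DBR2", "ALDH1", "RED1"),
                       tissues = "flower_buds", reference_gene = "actin",
                       calibrator_gene = "RED1",
                       calibrator_tissue = "flower_buds")
  tp <- turnover_potential(am4, kin_fix, rounding = "report")
  get <- function(enz, sub) {
    tp$relative_turnover[tp$enzyme == enz & tp$substrate == sub]
  }
  expect_equal(get("FDS1", "IDP"), 96)          # 137 x 0.7
  expect_equal(get("ADS", "FDP"), 1.4)          # 338 x 0.004
  expect_equal(get("ALDH1", "DHAA"), 462)       # 60 x 7.7
  expect_equal(get("ALDH1", "AA"), 90)          # 60 x 1.5
  expect_equal(get("RED1", "DHAA"), 0.3)        # 1 x 0.28
  ## FDS1/GDP has no kcat: excluded with a flag
  expect_true(is.na(get("FDS1", "GDP")))
  expect_true(tp$excluded[tp$substrate == "GDP"])

  ## zero kcat gives zero turnover
  kin0 <- tibble::tibble(enzyme = "Z", gene = "ADS", substrate = "s",
                         km_uM = 1, kcat_per_s = 0, stoichiometry = 1L)
  tp0 <- turnover_potential(am4, kin0)
  expect_equal(tp0$relative_turnover, 0)
})

test_that("competition ratios include substrate stoichiometry", {
  amounts <- amount_matrix(ct_fix, genes = c("ADS", "SQS"),
                           tissues = c("flower_buds", "young_leaves"),
                           reference_gene = "actin",
                           calibrator_gene = "GAS",
                           calibrator_tissue = "stems")
  tp <- turnover_potential(amounts, kin_fix)
  row <- function(enz, t) tp[tp$enzyme == enz & tp$tissue == t, ]

  same <- competition_ratio(row("SQS", "young_leaves"),
                            row("SQS", "young_leaves"))
  expect_identical(same, 1)

  yl <- competition_ratio(row("SQS", "young_leaves"),
                          row("ADS", "young_leaves"))
  expect_equal(yl, (2^-(-8.4) * 1 * 2) / (2^-(-12.7) * 0.004),
               tolerance = 1e-12)
  expect_equal(yl, 25.4, tolerance = 0.01)

  fb <- competition_ratio(row("SQS", "flower_buds"),
                          row("ADS", "flower_buds"))
  expect_equal(fb, 47.4, tolerance = 0.01)

  expect_error(competition_ratio(row("SQS", "young_leaves"),
                                 row("ADS", "flower_buds")),
               class = "qpcrflux_parameter_error")
  zero <- row("ADS", "young_leaves")
  zero$relative_turnover <- 0
  expect_warning(cr <- competition_ratio(row("SQS", "young_leaves"), zero),
                 "undefined")
  expect_true(is.na(cr))
})
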