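test_that("hazard quotient arithmetic and boundaries", {
  expect_equal(hazard_quotient(0.3, 0, 0.3, 0.024), 1)
  # additivity over routes
  full <- hazard_quotient(0.2, 0.05, 0.5, 0.1)
  expect_equal(full, hazard_quotient(0.2, 0, 0.5, 0.1) + hazard_quotient(0, 0.05, 0.5, 0.1))
  expect_error(hazard_quotient(0.1, 0.1, NA, 0.1), class = "wetrisk_validation_error")

  # adults exposed to the urban mean arsenic level, point parameters
  reg <- test_registry()
  r <- point_realization(reg$exposure$adults, "noncancer")
  hq_as <- hazard_quotient(cdi_ingestion(2.70, r), cdi_dermal(2.70, 1e-3, r),
                           0.3, 0.123)
  expect_equal(hq_as, 0.2458783161, tolerance = 1e-8)
})

test_that("hazard index sums quotients and is permutation-invariant", {
  expect_equal(total_hazard_index(rep(1 / 6, 6)), 1)
  set.seed(2)
  hq <- stats::runif(6)
  expect_equal(total_hazard_index(hq), total_hazard_index(rev(hq)))

  # the six adult-urban point-parameter quotients sum to ~0.33 (the
  # published simulation mean 0.46 is not recoverable from the printed
  # equations and parameters; see the methods vignette)
  reg <- test_registry()
  risk <- assess_risk(group_mean_conc(reg), reg, populations = "adults")
  thi_urban <- dplyr::filter(risk$totals, group == "urban")$thi
  expect_equal(thi_urban, 0.3285733495, tolerance = 1e-8)
  by_metal <- dplyr::filter(risk$by_metal, group == "urban")
  expect_equal(sum(by_metal$hq), thi_urban)
})

test_that("cancer risk requires slope factors and matches hand chains", {
  reg <- test_registry()
  r <- point_realization(reg$exposure$adults, "cancer")
  cr_as <- cancer_risk(cdi_ingestion(4.15, r), cdi_dermal(4.15, 1e-3, r),
                       1.5e-3, 3.66e-3)
  expect_equal(cr_as, 6.316787208e-5, tolerance = 1e-8)
  expect_equal(cancer_risk(0, 0, 1.5e-3, 3.66e-3), 0)
  expect_error(cancer_risk(0.1, 0.1, NA, NA), class = "wetrisk_validation_error")
})

test_that("total cancer risk reproduces the published rural point values", {
  reg <- test_registry()
  risk <- assess_risk(group_mean_conc(reg), reg)
  tot <- risk$totals
  tcr_ad <- dplyr::filter(tot, population == "adults", group == "rural")$tcr
  tcr_ch <- dplyr::filter(tot, population == "children", group == "rural")$tcr
  expect_equal(tcr_ad, 7.164594436e-5, tolerance = 1e-8)
  expect_equal(tcr_ch, 1.526432194e-5, tolerance = 1e-8)
  expect_equal(dplyr::filter(tot, population == "adults", group == "rural")$tcr_class,
               "low risk")
  # single-metal total equals that metal's risk
  expect_equal(total_cancer_risk(4.2e-6), 4.2e-6)
  # per-metal risks sum to the total
  bm <- dplyr::filter(risk$by_metal, population == "adults", group == "rural")
  expect_equal(sum(bm$cr, na.rm = TRUE), tcr_ad)
  # metals without slope factors are skipped, not imputed
  expect_true(all(is.na(bm$cr[bm$metal %in% c("Hg", "Cu", "Zn", "Pb")])))
  expect_setequal(risk$skipped$cancer, c("Hg", "Cu", "Zn", "Pb"))
})

test_that("adult/child risk ratio follows the closed-form intake ratio", {
  # ingestion-route intake ratio (1.95*26/70)/(1.25*2.5/20) = 4.635;
  # the dermal route shifts the full TCR ratio only slightly
  reg <- test_registry()
  risk <- assess_risk(group_mean_conc(reg), reg)
  tot <- risk$totals
  ratio <- dplyr::filter(tot, population == "adults", group == "rural")$tcr /
    dplyr::filter(tot, population == "children", group == "rural")$tcr
  expect_equal(ratio, (1.95 * 26 / 70) / (1.25 * 2.5 / 20), tolerance = 0.02)
})

test_that("risks are linear in concentration", {
  reg <- test_registry()
  conc <- group_mean_conc(reg)
  doubled <- dplyr::mutate(conc, concentration = 2 * concentration)
  r1 <- assess_risk(conc, reg)$totals
  r2 <- assess_risk(doubled, reg)$totals
  expect_equal(r2$thi, 2 * r1$thi)
  expect_equal(r2$tcr, 2 * r1$tcr)
})

test_that("contribution shares are percentages summing to 100", {
  expect_equal(contribution_shares(c(3, 1)), c(75, 25))
  set.seed(4)
  v <- stats::runif(5)
  expect_equal(sum(contribution_shares(v)), 100)
  expect_warning(out <- contribution_shares(c(0, 0)), "undefined")
  expect_true(all(is.na(out)))

  # arsenic dominates the adult rural cancer risk (~88%), cadmium the rest
  reg <- test_registry()
  bm <- assess_risk(group_mean_conc(reg), reg, populations = "adults")$by_metal |>
    dplyr::filter(group == "rural", !is.na(cr))
  shares <- contribution_shares(bm$cr)
  expect_equal(shares[bm$metal == "As"], 88.17, tolerance = 0.01)
  expect_equal(bm$cr_share, shares)
})
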