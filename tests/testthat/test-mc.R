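point_specs_registry <- function(reg) {
  for (pop in names(reg$exposure)) {
    p <- reg$exposure[[pop]]
    p$ir <- dist_spec("point", value = dist_point(p$ir))
    p$ef <- dist_spec("point", value = dist_point(p$ef))
    p$bw <- dist_spec("point", value = dist_point(p$bw))
    reg$exposure[[pop]] <- p
  }
  reg
}

test_that("parameter sampling follows the exposure specifications", {
  reg <- test_registry()
  set.seed(31)
  d <- wetrisk:::draw_parameters(reg$exposure$adults, 1e5)
  expect_lt(abs(mean(d$ef) - 296.6666667), 3 * 41.29837 / sqrt(1e5))
  expect_lt(abs(mean(d$ir) - 1.95), 3 * 0.3 / sqrt(1e5))
  expect_equal(sd(d$ir), 0.3, tolerance = 0.05)
  expect_true(all(d$ir > 0) && all(d$bw > 0))
  expect_true(all(d$ef <= 366))

  # a fully degenerate profile yields the same realization every draw
  preg <- point_specs_registry(reg)
  r <- sample_realization(preg$exposure$children, n = 10, assessment = "cancer")
  expect_equal(r$ir, rep(1.25, 10))
  expect_equal(r$ef, rep(350, 10))
  expect_equal(r$at, rep(25550, 10))
})

test_that("runs are reproducible and group streams are independent", {
  reg <- test_registry()
  mc1 <- run_mc(reg, n_iterations = 300, seed = 5)
  mc2 <- run_mc(reg, n_iterations = 300, seed = 5)
  expect_identical(mc1$draws, mc2$draws)
  expect_error(run_mc(reg, n_iterations = 300), "seed",
               class = "wetrisk_validation_error")
  expect_error(run_mc(reg, n_iterations = 50, seed = 5),
               class = "wetrisk_validation_error")
  expect_error(run_mc(reg, n_iterations = 300, seed = 5,
                      concentration_mode = "empirical"),
               class = "wetrisk_validation_error")

  # dropping a group leaves the other group's draws untouched
  rural_only <- run_mc(reg, groups = "rural", n_iterations = 300, seed = 5)
  expect_equal(dplyr::filter(mc1$draws, group == "rural"), rural_only$draws)
})

test_that("degenerate simulation equals the deterministic point assessment", {
  reg <- point_specs_registry(test_registry())
  mc <- run_mc(reg, n_iterations = 200, seed = 3, concentration_mode = "fixed")
  oracle <- assess_risk(group_mean_conc(reg), reg)$totals
  for (i in seq_len(nrow(oracle))) {
    d <- dplyr::filter(mc$draws, group == oracle$group[i],
                       population == oracle$population[i])
    expect_equal(unique(d$thi), oracle$thi[i], tolerance = 1e-12)
    expect_equal(unique(d$tcr), oracle$tcr[i], tolerance = 1e-12)
  }
})

test_that("per-iteration totals conserve their per-metal parts exactly", {
  mc <- run_mc(test_registry(), groups = "urban", n_iterations = 500, seed = 13)
  d <- mc$draws
  hq_cols <- grep("^hq_", names(d), value = TRUE)
  cr_cols <- grep("^cr_", names(d), value = TRUE)
  expect_equal(d$thi, rowSums(d[hq_cols]), tolerance = 1e-14)
  expect_equal(d$tcr, rowSums(d[cr_cols]), tolerance = 1e-14)
})

test_that("simulation means track analytic expectations for linear outputs", {
  reg <- test_registry()
  # hold BW at its point value: the cancer risk is then multilinear in the
  # independent sampled inputs, so E[TCR] factorizes exactly
  preg <- reg
  preg$exposure$adults$bw <- dist_spec("point", value = 70)
  mc <- run_mc(preg, groups = "rural", populations = "adults",
               n_iterations = 1e4, seed = 21)
  d <- mc$draws

  expected_tcr <- local({
    r <- exposure_realization(ir = 1.95, ef = (180 + 350 + 360) / 3, ed = 26,
                              bw = 70, at = 25550, sa = 18182, t_event = 1, ev = 1)
    cancer_risk(cdi_ingestion(4.15, r), cdi_dermal(4.15, 1e-3, r), 1.5e-3, 3.66e-3) +
      cancer_risk(cdi_ingestion(0.14, r), cdi_dermal(0.14, 1e-3, r), 6.1e-3, 3.8e-4)
  })
  se <- sd(d$tcr) / sqrt(nrow(d))
  expect_lt(abs(mean(d$tcr) - expected_tcr), 3 * se)

  # EF-only uncertainty: linearity in EF makes the mean exactly the
  # point value rescaled by mean(EF)/mode(EF)
  preg2 <- point_specs_registry(reg)
  preg2$exposure$adults$ef <- reg$exposure$adults$ef
  mc2 <- run_mc(preg2, groups = "rural", populations = "adults",
                n_iterations = 1e4, seed = 22, concentration_mode = "fixed")
  point_tcr <- dplyr::filter(assess_risk(group_mean_conc(reg), reg)$totals,
                             population == "adults", group == "rural")$tcr
  se2 <- sd(mc2$draws$tcr) / sqrt(nrow(mc2$draws))
  expect_lt(abs(mean(mc2$draws$tcr) - point_tcr * 296.6666667 / 350), 3 * se2)

  # with full default uncertainty the mean stays within 10% of the point
  # estimate (concentration linearity; BW nonlinearity is negligible)
  mc3 <- run_mc(reg, groups = "rural", populations = "adults",
                n_iterations = 1e4, seed = 23, fix_ef = TRUE)
  expect_equal(mean(mc3$draws$tcr), point_tcr, tolerance = 0.1)
  expect_true(all(mc3$draws$ef == 350))
})

test_that("summaries have ordered percentiles and matching draws", {
  mc <- shared_big_mc()
  s <- mc$summary
  expect_true(all(s$p5 <= s$p25 & s$p25 <= s$p50 &
                    s$p50 <= s$p75 & s$p75 <= s$p95))
  row <- dplyr::filter(s, group == "rural", population == "adults", output == "tcr")
  d <- dplyr::filter(mc$draws, group == "rural", population == "adults")
  expect_equal(row$mean, mean(d$tcr))
  expect_equal(row$p50, stats::median(d$tcr))
})

test_that("exceedance probability and cumulative frequency are complements", {
  expect_equal(exceedance_probability(c(0.5, 1.5, 2.5, 3.5), 1), 0.75)
  expect_equal(cumulative_frequency(c(0.5, 1.5, 2.5, 3.5), 1), 0.25)
  expect_equal(exceedance_probability(c(0.1, 0.2), 5), 0)
  set.seed(17)
  z <- stats::rnorm(1e4)
  expect_lt(abs(exceedance_probability(z, 0) - 0.5), 3 * 0.5 / sqrt(1e4))
  for (thr in c(-1, 0, 2)) {
    expect_equal(exceedance_probability(z, thr) + cumulative_frequency(z, thr), 1)
  }
})
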