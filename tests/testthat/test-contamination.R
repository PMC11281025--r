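test_that("single-factor index is the concentration/threshold ratio", {
  expect_equal(single_pollution_index(0.88, 0.05), 17.60)
  expect_equal(single_pollution_index(2.18, 10), 0.218)
  expect_equal(single_pollution_index(0, 7), 0)
  expect_error(single_pollution_index(1, 0), class = "wetrisk_validation_error")
  expect_error(single_pollution_index(-1, 1), class = "wetrisk_validation_error")
})

test_that("composite index matches the published group averages", {
  expect_equal(nemerow_index(c(3.21, 0.05, 0.04, 0.09, 0.12, 0.02)),
               2.307621731, tolerance = 1e-8)
  expect_equal(nemerow_index(c(4.98, 0.08, 0.06, 0.18, 0.22, 0.03)),
               3.58162149, tolerance = 1e-8)
  # equal indices collapse to the common value (max = mean)
  expect_equal(nemerow_index(rep(1.7, 6)), 1.7)
  expect_error(nemerow_index(numeric(0)), class = "wetrisk_validation_error")
  expect_error(nemerow_index(c(1, -1)), class = "wetrisk_validation_error")
})

test_that("composite index lies between the mean and max of its inputs", {
  set.seed(11)
  for (i in 1:50) {
    p <- stats::runif(6, 0, 20)
    npi <- nemerow_index(p)
    expect_gte(npi, mean(p) - 1e-12)
    expect_lte(npi, max(p) + 1e-12)
  }
})

test_that("per-sample assessment agrees with hand arithmetic", {
  reg <- test_registry()
  s <- toy_samples(Hg = c(0.10, 0.30), As = c(25, 100), group = "toy")
  res <- assess_contamination(s, reg)
  thr <- stats::setNames(reg$metals$class2_threshold, reg$metals$metal)
  for (i in 1:2) {
    p <- c(s$Hg[i], s$As[i], 1, 1, 1, 1) / thr[c("Hg", "As", "Cu", "Zn", "Pb", "Cd")]
    expect_equal(res$sample_npi$npi[res$sample_npi$sample_id == s$sample_id[i]],
                 sqrt((max(p)^2 + mean(p)^2) / 2))
  }
})

test_that("group indices from mean concentrations equal means of per-sample indices", {
  reg <- test_registry()
  s <- generate_samples(reg, seed = 6)
  res <- assess_contamination(s, reg)
  direct <- res$sample_indices |>
    dplyr::group_by(group, metal) |>
    dplyr::summarise(p_i = mean(p_i), .groups = "drop")
  j <- dplyr::inner_join(direct, res$group_indices, by = c("group", "metal"))
  expect_equal(j$p_i.x, j$p_i.y, tolerance = 1e-12)
})

test_that("indices are scale-equivariant and monotone", {
  reg <- test_registry()
  s <- generate_samples(reg, groups = "urban", seed = 9)
  res <- assess_contamination(s, reg)

  k <- 3.7
  reg_k <- reg
  reg_k$metals$class2_threshold <- reg$metals$class2_threshold * k
  s_k <- dplyr::mutate(s, dplyr::across(dplyr::all_of(reg$metals$metal), ~ .x * k))
  res_k <- assess_contamination(s_k, reg_k)
  expect_equal(res_k$sample_indices$p_i, res$sample_indices$p_i, tolerance = 1e-12)
  expect_equal(res_k$group_npi$npi, res$group_npi$npi, tolerance = 1e-12)

  # raising any single concentration never lowers the composite index
  s_up <- s
  s_up$Pb[3] <- s_up$Pb[3] * 10
  res_up <- assess_contamination(s_up, reg)
  expect_true(all(res_up$sample_npi$npi >= res$sample_npi$npi - 1e-12))
})

test_that("boundary and error behaviour of the assessment", {
  reg <- test_registry()
  at_threshold <- toy_samples(
    Hg = 0.05, As = 50, Cu = 1000, Zn = 1000, Pb = 10, Cd = 5)
  res <- assess_contamination(at_threshold, reg)
  expect_true(all(res$sample_indices$p_i == 1))
  expect_equal(unique(res$sample_npi$npi), 1)
  expect_equal(as.character(unique(res$sample_npi$class)), "slight contamination")

  expect_error(assess_contamination(dplyr::select(at_threshold, -Cd), reg),
               "Cd", class = "wetrisk_validation_error")
})
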