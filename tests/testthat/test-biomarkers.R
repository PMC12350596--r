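# Per-patient derived quantities: formula values, invariances, monotonicity,
# and the group-direction sanity check on a large synthetic cohort.

test_that("ECV formula values and error cases", {
  expect_equal(compute_ecv(35.6, 120, 40), 17.8)
  expect_equal(compute_ecv(120, 120, 1e-12 + 1e-9), 100, tolerance = 1e-6)
  expect_equal(compute_ecv(0, 120, 40), 0)
  expect_error(compute_ecv(35, -5, 40), class = "hepafunc_spec_error")
  expect_error(compute_ecv(35, 120, 0), class = "hepafunc_spec_error")
  expect_error(compute_ecv(35, 120, 100), class = "hepafunc_spec_error")
})

test_that("IWR formula values, sign behavior and error cases", {
  expect_equal(compute_iwr(63.7, 35.6), (63.7 - 35.6) / 63.7 * 100)
  expect_equal(compute_iwr(50, 50), 0)
  expect_equal(compute_iwr(40, 50), -25)
  expect_error(compute_iwr(0, 10), class = "hepafunc_spec_error")
  expect_error(compute_iwr(-5, 10), class = "hepafunc_spec_error")
})

test_that("ECV and IWR are invariant to a common enhancement rescaling", {
  for (c_scale in c(0.5, 2, 17)) {
    expect_equal(compute_ecv(35.6 * c_scale, 120 * c_scale, 40),
                 compute_ecv(35.6, 120, 40))
    expect_equal(compute_iwr(63.7 * c_scale, 35.6 * c_scale),
                 compute_iwr(63.7, 35.6))
  }
})

test_that("IWR is monotone decreasing in DP enhancement; ECV monotone in its arguments", {
  dp <- seq(-10, 60, by = 5)
  expect_true(all(diff(compute_iwr(63.7, dp)) < 0))
  expect_true(all(diff(compute_ecv(dp, 120, 40)) > 0))
  hct <- seq(20, 55, by = 5)
  expect_true(all(diff(compute_ecv(35.6, 120, hct)) < 0))
})

test_that("Mosteller BSA and volume normalization", {
  expect_equal(compute_bsa(90, 160), 2)
  expect_equal(compute_bsa(36, 100), 1)
  expect_equal(compute_bsa(60, 160), sqrt(9600 / 3600))
  expect_error(compute_bsa(-1, 160), class = "hepafunc_spec_error")
  expect_equal(normalize_volume(1634, 2), 817)
  expect_equal(normalize_volume(123.4, 1), 123.4)
  expect_equal(normalize_volume(0, 1.7), 0)
  expect_error(normalize_volume(100, 0), class = "hepafunc_spec_error")
})

test_that("MELD formula with and without clinical clamping", {
  expect_equal(compute_meld(1, 1, 1), 6.43)
  expect_equal(compute_meld(2, 3, 1.5),
               9.57 * log(2) + 3.78 * log(3) + 11.2 * log(1.5) + 6.43)
  expect_equal(compute_meld(1, 1, exp(1)), 11.2 + 6.43)
  expect_error(compute_meld(0, 1, 1), class = "hepafunc_spec_error")
  # clamping floors sub-normal inputs at 1
  expect_equal(compute_meld(0.5, 0.5, 0.9, clamp = TRUE), 6.43)
})

test_that("scintigraphy indices from TACs, with interpolation fallback", {
  flat <- tibble::tibble(time = c(0, 3, 15), counts = c(100, 100, 100))
  expect_equal(compute_hh15(flat), 1)
  two <- tibble::tibble(time = c(3, 15), counts = c(1000, 610))
  expect_equal(compute_hh15(two), 0.61)
  zero15 <- tibble::tibble(time = c(3, 15), counts = c(1000, 0))
  expect_equal(compute_hh15(zero15), 0)
  liver <- tibble::tibble(time = c(3, 15), counts = c(40, 92))
  heart <- tibble::tibble(time = c(3, 15), counts = c(1000, 8))
  expect_equal(compute_lhl15(liver, heart), 0.92)
  expect_equal(compute_lhl15(tibble::tibble(time = c(3, 15), counts = c(0, 0)),
                             two), 0)
  expect_equal(compute_lhl15(liver,
                             tibble::tibble(time = c(3, 15), counts = c(9, 0))),
               1)
  # no sample at 15 min: linear interpolation between 14 and 16
  interp <- tibble::tibble(time = c(0, 3, 14, 16), counts = c(90, 80, 60, 40))
  expect_equal(compute_hh15(interp), 50 / 80)
  expect_error(compute_hh15(tibble::tibble(time = c(3, 10), counts = c(1, 1))),
               class = "hepafunc_spec_error")
  expect_error(compute_hh15(tibble::tibble(time = c(3, 15), counts = c(0, 1))),
               class = "hepafunc_spec_error")
})

test_that("group-wise biomarker directions match the dysfunction physiology", {
  spec <- cohort_spec(n_low = 5000, n_high = 5000)
  coh <- add_biomarkers(sample_cohort(spec, seed = 13, tacs = FALSE))
  lo <- coh[coh$group == "low", ]
  hi <- coh[coh$group == "high", ]
  # severe dysfunction: lower IWR, LV/BSA, LHL15; higher ECV, SpV/BSA, HH15
  expect_lt(mean(hi$iwr), mean(lo$iwr))
  expect_lt(mean(hi$lv_bsa), mean(lo$lv_bsa))
  expect_lt(mean(hi$lhl15), mean(lo$lhl15))
  expect_gt(mean(hi$ecv), mean(lo$ecv))
  expect_gt(mean(hi$spv_bsa), mean(lo$spv_bsa))
  expect_gt(mean(hi$hh15), mean(lo$hh15))
})
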