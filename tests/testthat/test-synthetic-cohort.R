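# Synthetic cohort generator: spec validation, marginal and copula recovery,
# measurement-mode inversion, TAC construction, determinism.

test_that("invalid specs are rejected with the offending field named", {
  expect_error(cohort_spec(n_low = 0), "n_low", class = "hepafunc_spec_error")
  expect_error(cohort_spec(n_high = -1), "n_high",
               class = "hepafunc_spec_error")
  gp <- default_group_params()
  gp$sd_low[2] <- -1
  expect_error(cohort_spec(group_params = gp), "sd",
               class = "hepafunc_spec_error")
  gp <- default_group_params()
  gp$lo[1] <- gp$hi[1]
  expect_error(cohort_spec(group_params = gp), "truncation",
               class = "hepafunc_spec_error")
  gp <- default_group_params()
  gp$copula_r[3] <- 1.2
  expect_error(cohort_spec(group_params = gp), "copula_r",
               class = "hepafunc_spec_error")
})

test_that("default spec yields 96 low + 22 high subjects, consistently labeled", {
  coh <- sample_cohort(default_spec, seed = 1)
  expect_equal(nrow(coh), 118)
  expect_equal(sum(coh$group == "low"), 96)
  expect_equal(sum(coh$group == "high"), 22)
  expect_true(all((coh$icg_r15 >= 20) == (coh$group == "high")))
})

test_that("identical spec and seed give bit-identical cohorts", {
  a <- sample_cohort(default_spec, seed = 42)
  b <- sample_cohort(default_spec, seed = 42)
  expect_identical(a, b)
  c <- sample_cohort(default_spec, seed = 43)
  expect_false(identical(a$iwr, c$iwr))
})

test_that("zero-SD spec degenerates to exact group means", {
  gp <- default_group_params()
  gp$sd_low <- 0
  gp$sd_high <- 0
  spec0 <- cohort_spec(n_low = 5, n_high = 3, group_params = gp)
  coh <- sample_cohort(spec0, seed = 1, tacs = FALSE)
  for (i in seq_len(nrow(gp))) {
    v <- gp$variable[i]
    expect_equal(unique(coh[[v]][coh$group == "low"]), gp$mean_low[i],
                 info = v)
    expect_equal(unique(coh[[v]][coh$group == "high"]), gp$mean_high[i],
                 info = v)
  }
})

test_that("large-sample group moments match the configured normals (wide bounds)", {
  spec <- wide_spec(n_low = 5000, n_high = 5000)
  coh <- sample_cohort(spec, seed = 7, tacs = FALSE)
  hi <- coh[coh$group == "high", ]
  expect_lt(abs(mean(hi$iwr) - 18.8), 0.5)
  expect_lt(abs(sd(hi$iwr) - 20.2), 0.5)
  # every variable within 3 standard errors of its configured group moments
  gp <- spec$group_params
  for (i in seq_len(nrow(gp))) {
    for (g in c("low", "high")) {
      x <- coh[[gp$variable[i]]][coh$group == g]
      m <- if (g == "low") gp$mean_low[i] else gp$mean_high[i]
      s <- if (g == "low") gp$sd_low[i] else gp$sd_high[i]
      expect_lt(abs(mean(x) - m), 3 * s / sqrt(length(x)) + 1e-9,
                label = sprintf("mean of %s (%s)", gp$variable[i], g))
      expect_lt(abs(sd(x) - s), 3 * s / sqrt(2 * (length(x) - 1)) + 1e-9,
                label = sprintf("sd of %s (%s)", gp$variable[i], g))
    }
  }
})

test_that("sample Spearman correlations with ICG-R15 recover the configured values", {
  spec <- cohort_spec(n_low = 8136, n_high = 1864)
  coh <- sample_cohort(spec, seed = 11, tacs = FALSE)
  gp <- spec$group_params
  for (i in seq_len(nrow(gp))) {
    if (is.na(gp$copula_r[i])) next
    r <- cor(coh$icg_r15, coh[[gp$variable[i]]], method = "spearman")
    expect_lt(abs(r - gp$copula_r[i]), 0.05, label = gp$variable[i])
  }
})

test_that("measurement inversion reproduces drawn biomarkers", {
  coh <- sample_cohort(default_spec, seed = 3, tacs = FALSE)
  panel <- add_biomarkers(coh)
  expect_lt(max(abs(panel$iwr - coh$iwr)), 1e-9)
  expect_lt(max(abs(panel$hh15 - coh$hh15)), 1e-9)
  expect_lt(max(abs(panel$lhl15 - coh$lhl15)), 1e-9)
  expect_lt(max(abs(panel$lv_bsa - coh$lv_bsa)), 1e-9)
  expect_lt(max(abs(panel$spv_bsa - coh$spv_bsa)), 1e-9)
  # emergent ECV stays in a plausible band around the configured group means
  expect_lt(abs(mean(panel$ecv[coh$group == "low"]) - 29.4), 5)
  expect_lt(abs(mean(panel$ecv[coh$group == "high"]) - 34.8), 5)
})

test_that("zero washout leaves delayed-phase attenuation at the PVP level", {
  rec <- tibble::tibble(attn_liver_pre = 50, enh_pvp = 60, iwr = 0,
                        attn_aorta_pre = 45, aortic_enh_dp = 75)
  out <- records_to_measurements(rec)
  expect_equal(out$attn_liver_dp - out$attn_liver_pre,
               out$attn_liver_pvp - out$attn_liver_pre)
})

test_that("drawn IWR of 44.11% with 63.7 HU PVP enhancement gives 35.6 HU at DP", {
  rec <- tibble::tibble(attn_liver_pre = 55, enh_pvp = 63.7,
                        iwr = (63.7 - 35.6) / 63.7 * 100,
                        attn_aorta_pre = 45, aortic_enh_dp = 75)
  out <- records_to_measurements(rec)
  expect_equal(out$attn_liver_dp - out$attn_liver_pre, 35.6, tolerance = 1e-12)
})

test_that("infeasible washout targets are rejected", {
  rec <- tibble::tibble(attn_liver_pre = 50, enh_pvp = 60, iwr = 100,
                        attn_aorta_pre = 45, aortic_enh_dp = 75)
  expect_error(records_to_measurements(rec), "infeasible",
               class = "hepafunc_spec_error")
})

test_that("TAC construction hits the target indices exactly", {
  tac <- generate_tac(0.61, 0.92)
  expect_lt(abs(compute_hh15(tac$heart) - 0.61), 1e-9)
  expect_lt(abs(compute_lhl15(tac$liver, tac$heart) - 0.92), 1e-9)

  flat <- generate_tac(1.0, 0.5)
  expect_true(all(abs(flat$heart$counts - flat$heart$counts[1]) < 1e-9))

  half <- generate_tac(0.5, 0.5)
  h <- function(t) half$heart$counts[half$heart$time == t]
  expect_equal(h(15), h(3) / 2)

  expect_error(generate_tac(0, 0.5), class = "hepafunc_spec_error")
  expect_error(generate_tac(1.2, 0.5), class = "hepafunc_spec_error")
  expect_error(generate_tac(0.6, 1), class = "hepafunc_spec_error")
  expect_error(generate_tac(0.6, 0.5, times = 5:20),
               class = "hepafunc_spec_error")
})

test_that("round-trip over many seeded records is exact to 1e-9", {
  spec <- cohort_spec(n_low = 800, n_high = 200)
  coh <- sample_cohort(spec, seed = 9, tacs = FALSE)
  panel <- add_biomarkers(coh)
  expect_lt(max(abs(panel$iwr - coh$iwr)), 1e-9)
  expect_lt(max(abs(panel$hh15 - coh$hh15)), 1e-9)
  expect_lt(max(abs(panel$lhl15 - coh$lhl15)), 1e-9)
})
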