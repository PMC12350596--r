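# Cohort sampling: latent-severity Gaussian copula over group-conditional
# truncated-normal marginals, plus inversion of the drawn biomarkers into raw
# measurement-level fields (ROI attenuations, TAC counts, volumes, labs).

#' Draw a synthetic patient cohort
#'
#' Samples `n_low + n_high` patients from a [cohort_spec()]. Each subject gets
#' (a) a *drawn parameter panel* — ICG-R15, IWR, ECV, LV/BSA, SpV/BSA, HH15,
#' LHL15, hepatic PVP/DP enhancements, age — from the group-conditional
#' truncated normals coupled through the latent-severity copula, and (b) *raw
#' measurement fields* (per-phase ROI attenuations, aortic attenuations,
#' organ volumes, heart/liver time--activity counts, hematocrit,
#' anthropometrics, labs) constructed so that recomputing IWR, HH15, LHL15,
#' LV/BSA and SpV/BSA from the measurements reproduces the drawn values
#' exactly. The delayed-phase hepatic enhancement implied by the measurements
#' is `enh_pvp * (1 - iwr/100)`; ECV recomputed from measurements is therefore
#' emergent (driven by the derived DP enhancement, hematocrit, and a drawn
#' aortic enhancement), not forced to the drawn `ecv` column.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`. Identical spec + seed
#'   gives bit-identical cohorts.
#' @param tacs If `TRUE`, attach full heart/liver time--activity curves as
#'   list-columns (`heart_tac`, `liver_tac`); the flat count columns
#'   `heart_c3`, `heart_c15`, `liver_c3`, `liver_c15` are always present.
#' @return A tibble (class `hepafunc_cohort`), one row per patient.
#' @export
#' @examples
#' coh <- sample_cohort(cohort_spec(), seed = 1)
#' dplyr::count(coh, group)
sample_cohort <- function(spec, seed = spec$seed, tacs = TRUE) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec", class = "hepafunc_spec_error")
  }
  check_number(seed, "seed")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  n <- spec$n_low + spec$n_high
  p0 <- spec$n_low / n
  group <- rep(c("low", "high"), c(spec$n_low, spec$n_high))
  is_low <- group == "low"
  gp <- spec$group_params
  aux <- spec$aux

  # latent severity: within-group uniform v, overall CDF position fz
  v <- runif(n)
  t_lat <- qnorm(v)
  fz <- ifelse(is_low, p0 * v, p0 + (1 - p0) * v)
  icg <- icg_quantile(fz, spec$icg_params, p0)

  draw_var <- function(i, eps = rnorm(n)) {
    rho <- gp$rho_w[i]
    u <- pnorm(rho * t_lat + sqrt(max(0, 1 - rho^2)) * eps)
    x <- numeric(n)
    x[is_low] <- qtnorm(u[is_low], gp$mean_low[i], gp$sd_low[i],
                        gp$lo[i], gp$hi[i])
    x[!is_low] <- qtnorm(u[!is_low], gp$mean_high[i], gp$sd_high[i],
                         gp$lo[i], gp$hi[i])
    x
  }
  panel <- setNames(
    lapply(seq_len(nrow(gp)), draw_var),
    gp$variable
  )

  # infeasible washout (IWR >= 100 would need non-positive DP attenuation
  # with positive PVP enhancement): reject and redraw, capped
  i_iwr <- match("iwr", gp$variable)
  attempts <- 0L
  while (any(bad <- panel$iwr >= 100 & panel$enh_pvp > 0)) {
    attempts <- attempts + 1L
    if (attempts > 1000L) {
      abort("could not draw feasible IWR (< 100%) after 1000 attempts",
            class = "hepafunc_draw_error")
    }
    redraw <- draw_var(i_iwr)
    panel$iwr[bad] <- redraw[bad]
  }

  rt <- function(p) rtnorm(n, p["mean"], p["sd"], p["lo"], p["hi"])
  hct <- rt(aux$hct)
  height <- rt(aux$height)
  bmi <- ifelse(is_low, rtnorm(n, aux$bmi_low["mean"], aux$bmi_low["sd"],
                               aux$bmi_low["lo"], aux$bmi_low["hi"]),
                rtnorm(n, aux$bmi_high["mean"], aux$bmi_high["sd"],
                       aux$bmi_high["lo"], aux$bmi_high["hi"]))
  weight <- bmi * (height / 100)^2
  bsa <- compute_bsa(weight, height)
  sex <- ifelse(runif(n) < ifelse(is_low, aux$p_male_low, aux$p_male_high),
                "M", "F")

  cohort <- tibble(
    id = sprintf("P%03d", seq_len(n)),
    group = group, icg_r15 = icg, age = panel$age, sex = sex,
    height = height, weight = weight, hct = hct,
    iwr = panel$iwr, ecv = panel$ecv,
    lv_bsa = panel$lv_bsa, spv_bsa = panel$spv_bsa,
    hh15 = panel$hh15, lhl15 = panel$lhl15,
    enh_pvp = panel$enh_pvp, enh_dp = panel$enh_dp,
    lv = panel$lv_bsa * bsa, spv = panel$spv_bsa * bsa,
    cr = rt(aux$cr), tbil = rt(aux$tbil), inr = rt(aux$inr),
    attn_liver_pre = rt(aux$attn_liver_pre),
    attn_aorta_pre = rt(aux$attn_aorta_pre),
    aortic_enh_dp = rt(aux$aortic_enh_dp)
  )
  cohort <- records_to_measurements(cohort)

  # scintigraphy counts from the closed-form TAC model
  tac_pts <- tac_points(cohort$hh15, cohort$lhl15)
  cohort <- bind_cols(cohort, tac_pts)
  if (tacs) {
    curves <- map2(cohort$hh15, cohort$lhl15, generate_tac)
    cohort$heart_tac <- map(curves, "heart")
    cohort$liver_tac <- map(curves, "liver")
  }

  # second-reader re-measurements: additive HU noise on ROI means
  for (f in c("attn_liver_pre", "attn_liver_pvp", "attn_liver_dp",
              "attn_aorta_pre", "attn_aorta_dp")) {
    cohort[[paste0("reader2_", f)]] <-
      cohort[[f]] + rnorm(n, 0, spec$reader_noise_sd)
  }

  class(cohort) <- c("hepafunc_cohort", class(cohort))
  attr(cohort, "seed") <- as.integer(seed)
  cohort
}

#' Invert drawn washout targets into raw attenuation fields
#'
#' Given records carrying a pre-contrast liver attenuation, a drawn hepatic
#' PVP enhancement, a drawn IWR, a pre-contrast aortic attenuation and a drawn
#' aortic DP enhancement, sets the contrast-enhanced attenuation fields so
#' that the delayed-phase hepatic enhancement equals
#' `enh_pvp * (1 - iwr/100)`; recomputing IWR from the measurements then
#' reproduces the drawn value to machine precision.
#'
#' @param records Tibble with columns `attn_liver_pre`, `enh_pvp`, `iwr`,
#'   `attn_aorta_pre`, `aortic_enh_dp`.
#' @return `records` with `attn_liver_pvp`, `attn_liver_dp`, `attn_aorta_dp`
#'   set.
#' @export
records_to_measurements <- function(records) {
  need <- c("attn_liver_pre", "enh_pvp", "iwr", "attn_aorta_pre",
            "aortic_enh_dp")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(paste("records are missing columns:",
                paste(missing, collapse = ", ")),
          class = "hepafunc_input_error")
  }
  if (any(records$enh_pvp <= 0)) {
    abort_field("enh_pvp", "drawn hepatic PVP enhancement must be > 0")
  }
  if (any(records$iwr >= 100)) {
    abort_field("iwr", "IWR >= 100% is infeasible with positive PVP enhancement")
  }
  dplyr::mutate(
    records,
    attn_liver_pvp = .data$attn_liver_pre + .data$enh_pvp,
    attn_liver_dp = .data$attn_liver_pre + .data$enh_pvp * (1 - .data$iwr / 100),
    attn_aorta_dp = .data$attn_aorta_pre + .data$aortic_enh_dp
  )
}

# Closed-form TAC sample points at 3 and 15 min (vectorized); same model as
# generate_tac().
tac_points <- function(hh15, lhl15, h0 = 1e5, k_liver = 0.3) {
  lambda <- -log(hh15) / 12
  h3 <- h0 * exp(-3 * lambda)
  h15 <- hh15 * h3
  l15 <- lhl15 / (1 - lhl15) * h15
  shape <- function(t) (1 - exp(-k_liver * t)) / (1 - exp(-k_liver * 15))
  tibble(heart_c3 = h3, heart_c15 = h15,
         liver_c3 = l15 * shape(3), liver_c15 = l15)
}

#' Generate heart and liver time--activity curves with exact target indices
#'
#' The heart (blood pool) curve is a mono-exponential clearance
#' `H(t) = H0 * exp(-lambda * t)` with `lambda = -log(hh15)/12`, so that
#' `H(15)/H(3) = hh15` exactly. The liver uptake curve is a saturating
#' exponential scaled so that `L(15)/(L(15) + H(15)) = lhl15` exactly.
#'
#' @param hh15 Target blood clearance index, in (0, 1].
#' @param lhl15 Target liver receptor index, in (0, 1).
#' @param times Sampling grid in minutes; must cover 3 and 15 min.
#' @param h0 Heart counts at t = 0.
#' @param k_liver Liver uptake rate constant (1/min).
#' @return List of two tibbles (`heart`, `liver`) with columns `time`,
#'   `counts`.
#' @export
#' @examples
#' tac <- generate_tac(0.61, 0.92)
#' compute_hh15(tac$heart)
generate_tac <- function(hh15, lhl15, times = 0:16, h0 = 1e5, k_liver = 0.3) {
  check_number(hh15, "hh15")
  check_number(lhl15, "lhl15")
  if (hh15 <= 0 || hh15 > 1) abort_field("hh15", "must be in (0, 1]")
  if (lhl15 <= 0 || lhl15 >= 1) abort_field("lhl15", "must be in (0, 1)")
  if (min(times) > 3 || max(times) < 15) {
    abort_field("times", "grid must cover 3 and 15 min")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort_field("times", "time stamps must be strictly increasing")
  }
  lambda <- -log(hh15) / 12
  heart <- h0 * exp(-lambda * times)
  h15 <- h0 * exp(-15 * lambda)
  l15 <- lhl15 / (1 - lhl15) * h15
  liver <- l15 * (1 - exp(-k_liver * times)) / (1 - exp(-k_liver * 15))
  list(heart = tibble(time = times, counts = heart),
       liver = tibble(time = times, counts = liver))
}
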