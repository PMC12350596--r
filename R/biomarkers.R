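# Per-patient derived quantities: iodine-uptake biomarkers, BSA-normalized
# volumetry, scintigraphy indices, and the MELD score. All computations are
# vectorized over patients.

#' Hepatic extracellular volume fraction (ECV)
#'
#' `ECV = hepatic DP enhancement * (100 - Hct) / aortic DP enhancement`,
#' in percent. Rises with fibrosis as the extracellular matrix expands.
#'
#' @param hep_enh_dp Hepatic delayed-phase enhancement (HU).
#' @param aortic_enh_dp Aortic delayed-phase enhancement (HU); must be > 0.
#' @param hct Hematocrit in percent, in (0, 100).
#' @return ECV in percent.
#' @export
#' @examples
#' compute_ecv(35.6, 120, 40)
compute_ecv <- function(hep_enh_dp, aortic_enh_dp, hct) {
  if (any(!is.finite(aortic_enh_dp)) || any(aortic_enh_dp <= 0)) {
    abort_field("aortic_enh_dp",
                "blood-pool enhancement must be a positive number")
  }
  if (any(hct <= 0 | hct >= 100)) {
    abort_field("hct", "hematocrit must be in (0, 100) percent")
  }
  hep_enh_dp * (100 - hct) / aortic_enh_dp
}

#' Iodine washout rate (IWR)
#'
#' `IWR = (PVP enhancement - DP enhancement) / PVP enhancement * 100`, in
#' percent. Falls with liver dysfunction; negative values (delayed-phase
#' retention exceeding the portal-venous peak) are physically meaningful.
#'
#' @param hep_enh_pvp Hepatic portal-venous-phase enhancement (HU); must be
#'   > 0.
#' @param hep_enh_dp Hepatic delayed-phase enhancement (HU).
#' @return IWR in percent.
#' @export
#' @examples
#' compute_iwr(63.7, 35.6)
compute_iwr <- function(hep_enh_pvp, hep_enh_dp) {
  if (any(!is.finite(hep_enh_pvp)) || any(hep_enh_pvp <= 0)) {
    abort_field("hep_enh_pvp", "PVP enhancement must be a positive number")
  }
  (hep_enh_pvp - hep_enh_dp) / hep_enh_pvp * 100
}

#' Mosteller body surface area
#'
#' `BSA = sqrt(weight[kg] * height[cm] / 3600)` in m^2.
#'
#' @param weight Body weight (kg), > 0.
#' @param height Height (cm), > 0.
#' @return BSA in m^2.
#' @export
#' @examples
#' compute_bsa(90, 160)
compute_bsa <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    abort_field("weight/height", "must be positive")
  }
  sqrt(weight * height / 3600)
}

#' Normalize an organ volume by body surface area
#'
#' @param vol Volume (mL).
#' @param bsa Body surface area (m^2), > 0.
#' @return Volume index in mL/m^2.
#' @export
normalize_volume <- function(vol, bsa) {
  if (any(bsa <= 0)) abort_field("bsa", "must be positive")
  vol / bsa
}

#' MELD score
#'
#' `9.57 ln(Cr) + 3.78 ln(T-bil) + 11.2 ln(INR) + 6.43`. By default inputs
#' are used as-is (the bare formula); `clamp = TRUE` applies the standard
#' clinical floor of 1.0 to each input before taking logs.
#'
#' @param cr Serum creatinine (mg/dL), > 0.
#' @param tbil Total bilirubin (mg/dL), > 0.
#' @param inr Prothrombin time INR, > 0.
#' @param clamp Clamp inputs below 1.0 up to 1.0 (off by default).
#' @return MELD score.
#' @export
#' @examples
#' compute_meld(1, 1, 1)
compute_meld <- function(cr, tbil, inr, clamp = FALSE) {
  if (any(cr <= 0) || any(tbil <= 0) || any(inr <= 0)) {
    abort_field("cr/tbil/inr", "must be positive")
  }
  if (clamp) {
    cr <- pmax(cr, 1); tbil <- pmax(tbil, 1); inr <- pmax(inr, 1)
  }
  9.57 * log(cr) + 3.78 * log(tbil) + 11.2 * log(inr) + 6.43
}

# counts at an exact time point, by lookup or linear interpolation
tac_at <- function(tac, t) {
  if (!all(c("time", "counts") %in% names(tac))) {
    abort_field("tac", "needs `time` and `counts` columns")
  }
  if (is.unsorted(tac$time, strictly = TRUE)) {
    abort_field("tac", "time stamps must be strictly increasing")
  }
  hit <- which(tac$time == t)
  if (length(hit)) return(tac$counts[hit[1]])
  if (t < min(tac$time) || t > max(tac$time)) {
    abort_field("tac", sprintf("time grid does not cover %g min", t))
  }
  approx(tac$time, tac$counts, xout = t)$y
}

#' Blood clearance index HH15
#'
#' Heart ROI counts at 15 min divided by heart counts at 3 min. Values at
#' 3/15 min are exact samples when present, else linearly interpolated.
#' Rises with liver dysfunction.
#'
#' @param heart_tac Tibble with `time` (min, strictly increasing) and
#'   `counts` (>= 0).
#' @return HH15 ratio.
#' @export
#' @examples
#' compute_hh15(generate_tac(0.61, 0.92)$heart)
compute_hh15 <- function(heart_tac) {
  h3 <- tac_at(heart_tac, 3)
  if (h3 <= 0) abort_field("heart_tac", "heart counts at 3 min must be > 0")
  tac_at(heart_tac, 15) / h3
}

#' Liver receptor index LHL15
#'
#' Liver ROI counts at 15 min divided by the sum of liver and heart counts at
#' 15 min. Falls with liver dysfunction.
#'
#' @param liver_tac,heart_tac Tibbles with `time` (min) and `counts`.
#' @return LHL15 ratio in `[0, 1]`.
#' @export
compute_lhl15 <- function(liver_tac, heart_tac) {
  l15 <- tac_at(liver_tac, 15)
  h15 <- tac_at(heart_tac, 15)
  if (l15 + h15 <= 0) {
    abort_field("tac", "liver + heart counts at 15 min must be > 0")
  }
  l15 / (l15 + h15)
}

#' Compute the full biomarker panel from raw measurement fields
#'
#' Recomputes every derived quantity from a cohort's raw measurement columns:
#' enhancements from the per-phase attenuations, ECV, IWR, Mosteller BSA,
#' LV/BSA and SpV/BSA from the organ volumes, HH15 and LHL15 from the count
#' columns, and MELD from the labs. Existing columns with the same names
#' (e.g. the drawn parameter panel of [sample_cohort()]) are overwritten by
#' the recomputed, measurement-derived values.
#'
#' @param cohort Tibble with columns `attn_liver_pre`, `attn_liver_pvp`,
#'   `attn_liver_dp`, `attn_aorta_pre`, `attn_aorta_dp`, `hct`, `height`,
#'   `weight`, `lv`, `spv`, `heart_c3`, `heart_c15`, `liver_c15`, `cr`,
#'   `tbil`, `inr`.
#' @return The cohort with recomputed columns `enh_pvp`, `enh_dp`,
#'   `aortic_enh_dp`, `ecv`, `iwr`, `bsa`, `lv_bsa`, `spv_bsa`, `hh15`,
#'   `lhl15`, `meld`.
#' @export
#' @examples
#' coh <- sample_cohort(cohort_spec(), seed = 1)
#' panel <- add_biomarkers(coh)
#' all.equal(panel$iwr, coh$iwr)
add_biomarkers <- function(cohort) {
  need <- c("attn_liver_pre", "attn_liver_pvp", "attn_liver_dp",
            "attn_aorta_pre", "attn_aorta_dp", "hct", "height", "weight",
            "lv", "spv", "heart_c3", "heart_c15", "liver_c15",
            "cr", "tbil", "inr")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    abort(paste("cohort is missing columns:", paste(missing, collapse = ", ")),
          class = "hepafunc_input_error")
  }
  cohort |>
    mutate(
      enh_pvp = enhancement(.data$attn_liver_pvp, .data$attn_liver_pre),
      enh_dp = enhancement(.data$attn_liver_dp, .data$attn_liver_pre),
      aortic_enh_dp = enhancement(.data$attn_aorta_dp, .data$attn_aorta_pre),
      ecv = compute_ecv(.data$enh_dp, .data$aortic_enh_dp, .data$hct),
      iwr = compute_iwr(.data$enh_pvp, .data$enh_dp),
      bsa = compute_bsa(.data$weight, .data$height),
      lv_bsa = normalize_volume(.data$lv, .data$bsa),
      spv_bsa = normalize_volume(.data$spv, .data$bsa),
      hh15 = .data$heart_c15 / .data$heart_c3,
      lhl15 = .data$liver_c15 / (.data$liver_c15 + .data$heart_c15),
      meld = compute_meld(.data$cr, .data$tbil, .data$inr)
    )
}
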