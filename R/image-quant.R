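# ROI-based attenuation measurement and mask volumetry.
#
# Conventions: voxel indices are 1-based in R but physical coordinates follow
# a 0-based convention — the center of voxel i lies at (i - 0.5) * spacing.
# ROIs are 2-D discs on a single axial slice; a voxel belongs to the disc if
# its center falls inside the circle.

#' Build a set of circular ROIs
#'
#' @param liver Tibble (or data frame) with one row per hepatic ROI and
#'   columns `cx`, `cy` (voxel indices of the center), `slice` (axial index),
#'   `radius_mm`. Four hepatic ROIs (anterior/posterior/medial/lateral) are
#'   the standard layout.
#' @param aorta Single-row tibble with the same columns for the aortic ROI,
#'   or `NULL`.
#' @param nominal_area_mm2 Nominal per-ROI area (mm^2); each ROI's area must
#'   be within 20% of it.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(liver, aorta = NULL, nominal_area_mm2 = 250) {
  liver <- as_tibble(liver)
  need <- c("cx", "cy", "slice", "radius_mm")
  if (!all(need %in% names(liver))) {
    abort_field("liver", paste("needs columns", paste(need, collapse = ", ")))
  }
  if (!is.null(aorta)) {
    aorta <- as_tibble(aorta)
    if (!all(need %in% names(aorta))) {
      abort_field("aorta", paste("needs columns", paste(need, collapse = ", ")))
    }
  }
  structure(list(liver = liver, aorta = aorta,
                 nominal_area_mm2 = nominal_area_mm2),
            class = "roi_set")
}

# logical in-disc mask for one ROI on its slice; returns index matrix
roi_voxels <- function(roi, grid, spacing) {
  if (roi$slice < 1 || roi$slice > grid[3]) {
    abort_field("slice", "ROI slice outside the grid")
  }
  r_vox_x <- roi$radius_mm / spacing[1]
  r_vox_y <- roi$radius_mm / spacing[2]
  ix <- seq_len(grid[1])
  iy <- seq_len(grid[2])
  d2 <- outer(((ix - roi$cx) / r_vox_x)^2, ((iy - roi$cy) / r_vox_y)^2, `+`)
  which(d2 <= 1, arr.ind = TRUE)
}

#' Mean attenuation within one ROI
#'
#' @param volume 3-D intensity array (HU).
#' @param roi One-row data frame with `cx`, `cy`, `slice`, `radius_mm`.
#' @param spacing Voxel spacing (mm).
#' @param mask Optional logical array; if given, every ROI voxel must fall
#'   inside it (e.g. the organ label mask), else an error.
#' @return Mean HU over the disc's voxels.
#' @export
measure_roi_mean <- function(volume, roi, spacing, mask = NULL) {
  grid <- dim(volume)
  vox <- roi_voxels(roi, grid, spacing)
  if (nrow(vox) == 0) abort("ROI contains no voxels")
  if (any(vox[, 1] < 1 | vox[, 1] > grid[1] | vox[, 2] < 1 | vox[, 2] > grid[2])) {
    abort("ROI extends outside the grid")
  }
  idx <- cbind(vox, roi$slice)
  if (!is.null(mask) && !all(mask[idx])) {
    abort("ROI overlaps voxels outside the target organ mask",
          class = "hepafunc_roi_error")
  }
  mean(volume[idx])
}

#' Mean hepatic attenuation from four ROIs
#'
#' The per-phase hepatic attenuation is the unweighted mean of the four
#' per-ROI mean intensities (robust to unequal voxel counts across ROIs); set
#' `pooled = TRUE` to average all ROI voxels jointly instead.
#'
#' @param volume 3-D intensity array (HU).
#' @param rois A [roi_set()].
#' @param spacing Voxel spacing (mm).
#' @param mask Optional logical liver mask each hepatic ROI must lie inside.
#' @param pooled Pool voxels across ROIs instead of averaging ROI means.
#' @return Mean hepatic attenuation (HU).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' rs <- auto_place_rois(ph$labels, ph$organ_levels, ph$spacing)
#' measure_hepatic_mean(ph$phases$pre, rs, ph$spacing)
measure_hepatic_mean <- function(volume, rois, spacing, mask = NULL,
                                 pooled = FALSE) {
  if (!inherits(rois, "roi_set")) abort("`rois` must be a roi_set")
  if (nrow(rois$liver) != 4) {
    abort_field("rois", "hepatic measurement requires exactly four liver ROIs")
  }
  per_roi <- vapply(seq_len(4), function(i) {
    measure_roi_mean(volume, rois$liver[i, ], spacing, mask)
  }, numeric(1))
  if (!pooled) return(mean(per_roi))
  counts <- vapply(seq_len(4), function(i) {
    nrow(roi_voxels(rois$liver[i, ], dim(volume), spacing))
  }, numeric(1))
  sum(per_roi * counts) / sum(counts)
}

#' Contrast enhancement
#'
#' Enhancement is the contrast-enhanced attenuation minus the pre-contrast
#' attenuation; it may be negative.
#'
#' @param post_hu,pre_hu Attenuations (HU); vectorized.
#' @return `post_hu - pre_hu` (HU).
#' @export
#' @examples
#' enhancement(100, 40)
enhancement <- function(post_hu, pre_hu) {
  if (!is.numeric(post_hu) || !is.numeric(pre_hu)) {
    abort("attenuations must be numeric")
  }
  post_hu - pre_hu
}

#' Volume of a voxel mask
#'
#' @param mask Logical (or 0/1) array.
#' @param spacing Voxel spacing (mm), all > 0.
#' @return Volume in mL.
#' @export
#' @examples
#' mask_volume(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
mask_volume <- function(mask, spacing) {
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort_field("spacing", "must be a positive mm triple")
  }
  sum(mask != 0) * prod(spacing) / 1000
}

# 2-D erosion of a logical slice by one voxel (4-neighbourhood), applied
# `steps` times.
erode_slice <- function(m, steps = 2L) {
  for (i in seq_len(steps)) {
    shifted <- m
    shifted <- shifted & rbind(FALSE, m[-nrow(m), ])
    shifted <- shifted & rbind(m[-1, ], FALSE)
    shifted <- shifted & cbind(FALSE, m[, -ncol(m)])
    shifted <- shifted & cbind(m[, -1], FALSE)
    m <- shifted
  }
  m
}

#' Deterministic automatic ROI placement
#'
#' Stand-in for manual ROI placement: on the mid-liver axial slice (median
#' liver voxel index), the liver cross-section is eroded by 2 voxels and
#' split into quadrants about its centroid; one disc ROI of the nominal area
#' is placed at each quadrant centroid. The aortic ROI sits at the aorta
#' centroid of the same slice. Placement is fully deterministic.
#'
#' @param labels Integer label array from [generate_phantom()] (or any
#'   labeled segmentation).
#' @param organ_levels Named integer vector with at least `liver` and
#'   `aorta` labels.
#' @param spacing Voxel spacing (mm).
#' @param nominal_area_mm2 Target ROI area; the disc radius is
#'   `sqrt(area/pi)`.
#' @return A [roi_set()] whose ROIs all lie inside their eroded organ masks.
#' @export
auto_place_rois <- function(labels, organ_levels, spacing,
                            nominal_area_mm2 = 250) {
  for (org in c("liver", "aorta")) {
    if (!org %in% names(organ_levels)) {
      abort_field("organ_levels", paste("missing label for", org))
    }
  }
  radius_mm <- sqrt(nominal_area_mm2 / pi)
  liver_mask <- labels == organ_levels[["liver"]]
  zs <- which(apply(liver_mask, 3, any))
  if (length(zs) == 0) abort("liver mask is empty", class = "hepafunc_roi_error")
  slice <- zs[ceiling(length(zs) / 2)]
  sl <- liver_mask[, , slice]
  er <- erode_slice(sl, 2L)
  if (!any(er)) {
    abort("liver too small after erosion; reduce nominal_area_mm2",
          class = "hepafunc_roi_error")
  }
  idx <- which(er, arr.ind = TRUE)
  cx0 <- mean(idx[, 1])
  cy0 <- mean(idx[, 2])
  quads <- list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  liver_rois <- map(quads, function(q) {
    sel <- idx[sign(idx[, 1] - cx0) %in% c(0, q[1]) &
               sign(idx[, 2] - cy0) %in% c(0, q[2]), , drop = FALSE]
    if (nrow(sel) == 0) {
      abort("liver quadrant empty; reduce nominal_area_mm2",
            class = "hepafunc_roi_error")
    }
    tibble(cx = mean(sel[, 1]), cy = mean(sel[, 2]), slice = slice,
           radius_mm = radius_mm)
  }) |> list_rbind()
  # containment check against the eroded mask
  er3 <- array(FALSE, dim = dim(labels))
  er3[, , slice] <- er
  for (i in seq_len(4)) {
    vox <- roi_voxels(liver_rois[i, ], dim(labels), spacing)
    if (!all(er3[cbind(vox, slice)])) {
      abort("ROI does not fit inside the eroded liver; reduce nominal_area_mm2",
            class = "hepafunc_roi_error")
    }
  }
  aorta_mask <- labels == organ_levels[["aorta"]]
  asl <- aorta_mask[, , slice]
  if (!any(asl)) {
    abort("aorta not present on the mid-liver slice", class = "hepafunc_roi_error")
  }
  aidx <- which(asl, arr.ind = TRUE)
  # the aorta is narrow: shrink the aortic ROI to fit if needed
  a_radius <- min(radius_mm,
                  0.7 * min(diff(range(aidx[, 1])) * spacing[1],
                            diff(range(aidx[, 2])) * spacing[2]) / 2)
  aorta_roi <- tibble(cx = mean(aidx[, 1]), cy = mean(aidx[, 2]),
                      slice = slice, radius_mm = a_radius)
  roi_set(liver_rois, aorta_roi, nominal_area_mm2)
}
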