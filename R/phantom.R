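# Voxel phantoms: ellipsoidal organs with per-phase mean intensities, used as
# deterministic fixtures for the ROI-measurement and volumetry stages.

#' Specify a multiphase voxel phantom
#'
#' @param grid Integer triple, grid shape in voxels.
#' @param spacing Numeric triple, voxel spacing in mm (> 0).
#' @param organs Named list of organs; each organ is a list with `center`
#'   (mm), `radii` (mm), and `phases` — a named numeric vector of mean
#'   intensities (HU) per phase (e.g. `c(pre = 55, pvp = 118.7, dp = 90.6)`).
#'   All organs must share the same phase names.
#' @param background Background intensity (HU) per phase; recycled to the
#'   phase names.
#' @param noise_sd Additive Gaussian noise SD (HU) applied to every voxel.
#' @param seed Integer seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' ps <- phantom_spec()
#' names(ps$organs)
phantom_spec <- function(grid = c(96, 96, 48),
                         spacing = c(2, 2, 2),
                         organs = default_phantom_organs(),
                         background = -100,
                         noise_sd = 0,
                         seed = 1L) {
  if (length(grid) != 3 || any(grid < 1)) {
    abort_field("grid", "must be a positive integer triple")
  }
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort_field("spacing", "must be a positive mm triple")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  phases <- names(organs[[1]]$phases)
  extent <- grid * spacing
  for (nm in names(organs)) {
    o <- organs[[nm]]
    if (!setequal(names(o$phases), phases)) {
      abort_field(nm, "all organs must share the same phase names")
    }
    if (any(o$center - o$radii < 0) || any(o$center + o$radii > extent)) {
      abort_field(nm, "organ ellipsoid must lie inside the grid")
    }
  }
  structure(
    list(grid = as.integer(grid), spacing = as.numeric(spacing),
         organs = organs, phases = phases,
         background = setNames(rep_len(background, length(phases)), phases),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default phantom organ layout
#'
#' Liver, spleen and aorta ellipsoids sized and positioned so that the liver
#' hosts four 250 mm^2 ROIs after 2-voxel erosion, with phase intensities
#' matching the preserved-function group means (liver pre-contrast 55 HU,
#' PVP enhancement 63.7 HU, DP enhancement 35.6 HU; aortic DP enhancement
#' 75 HU).
#'
#' @return Named list of organ definitions for [phantom_spec()].
#' @export
default_phantom_organs <- function() {
  list(
    liver = list(center = c(70, 96, 48), radii = c(60, 50, 40),
                 phases = c(pre = 55, pvp = 118.7, dp = 90.6)),
    spleen = list(center = c(160, 60, 48), radii = c(25, 30, 35),
                  phases = c(pre = 50, pvp = 110, dp = 85)),
    aorta = list(center = c(160, 150, 48), radii = c(12, 12, 40),
                 phases = c(pre = 45, pvp = 250, dp = 120))
  )
}

#' Rasterize a phantom into per-phase intensity volumes and a label mask
#'
#' Voxels whose centers fall inside an organ's ellipsoid take that organ's
#' phase mean plus `N(0, noise_sd)` noise; all other voxels take the
#' background value. Organ labels are consecutive integers in the order of
#' `pspec$organs` (background = 0). Overlapping ellipsoids are a validation
#' error.
#'
#' @param pspec A [phantom_spec()].
#' @return List with `phases` (named list of 3-D arrays, HU), `labels` (3-D
#'   integer array), `organ_levels` (named integer vector), and `spacing`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' mask_volume(ph$labels == ph$organ_levels["liver"], ph$spacing)
generate_phantom <- function(pspec) {
  if (!inherits(pspec, "phantom_spec")) {
    abort("`pspec` must be a phantom_spec", class = "hepafunc_spec_error")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(pspec$seed)

  g <- pspec$grid
  sp <- pspec$spacing
  # physical coordinates of voxel centers: (index - 0.5) * spacing with
  # 1-based indices, i.e. 0-based index * spacing + half a voxel
  ax <- lapply(1:3, function(d) ((seq_len(g[d]) - 0.5) * sp[d]))
  labels <- array(0L, dim = g)
  organ_levels <- setNames(seq_along(pspec$organs), names(pspec$organs))
  for (nm in names(pspec$organs)) {
    o <- pspec$organs[[nm]]
    dx2 <- ((ax[[1]] - o$center[1]) / o$radii[1])^2
    dy2 <- ((ax[[2]] - o$center[2]) / o$radii[2])^2
    dz2 <- ((ax[[3]] - o$center[3]) / o$radii[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    if (any(labels[inside] != 0L)) {
      abort_field(nm, "organ ellipsoids must not overlap")
    }
    labels[inside] <- organ_levels[[nm]]
  }
  phases <- lapply(pspec$phases, function(ph) {
    vol <- array(pspec$background[[ph]], dim = g)
    for (nm in names(pspec$organs)) {
      vol[labels == organ_levels[[nm]]] <- pspec$organs[[nm]]$phases[[ph]]
    }
    if (pspec$noise_sd > 0) {
      vol <- vol + array(rnorm(prod(g), 0, pspec$noise_sd), dim = g)
    }
    vol
  })
  names(phases) <- pspec$phases
  list(phases = phases, labels = labels, organ_levels = organ_levels,
       spacing = sp)
}

#' Write a rasterized phantom to NIfTI files
#'
#' One `.nii.gz` per phase plus a `labels.nii.gz`, with voxel spacing in the
#' header. Requires the RNifti package.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("writing NIfTI requires the RNifti package")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  as_img <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- phantom$spacing
    img
  }
  paths <- character(0)
  for (ph in names(phantom$phases)) {
    p <- file.path(dir, paste0(ph, ".nii.gz"))
    RNifti::writeNifti(as_img(phantom$phases[[ph]]), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "labels.nii.gz")
  RNifti::writeNifti(as_img(phantom$labels + 0), p)
  invisible(c(paths, p))
}
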