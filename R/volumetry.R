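# Hemispheric and lesion volumetry with and without vasogenic-edema
# correction, and midline-shift quantification.
#
# Volumes follow the planimetric rule: region area per slice summed over
# slices and multiplied by the slice thickness, i.e. voxel count times
# in_plane_spacing^2 * (slice_thickness + slice_gap).
#
# With HVc / HVi the contralateral / ipsilateral hemisphere volumes and LV
# the lesion volume (all mm^3):
#   %HLVuc = LV / ((HVc + HVi) / 2) * 100
#   %HLVec = (HVc^2 + LV*(HVc + HVi) - HVi^2) / (HVc*(HVc + HVi)) * 100
# The edema-corrected form is algebraically 100 * (LV - (HVi - HVc)) / HVc:
# the space-occupying swelling HVi - HVc is subtracted from the lesion and
# the result expressed against the unaffected hemisphere. Both forms are
# evaluated and cross-checked at run time.
#
# Midline shift: MLS = (A - B) / 2 from the cortex-to-third-ventricle
# distances measured on the ipsilateral (A) and contralateral (B) side, at
# the slice of maximum lateral ventricle displacement.

#' Physical volume of a labelled region
#'
#' @param mask A [label_mask()].
#' @param region Region name in the mask legend (hierarchical: the
#'   ipsilateral hemisphere includes the lesion, see [region_mask()]).
#' @param geometry A [voxel_geometry()]; defaults to the mask's own.
#' @return Volume in mm^3.
#' @examples
#' # 1000 voxels at 0.2 mm in-plane and 2 mm slices -> 80 mm^3
#' @export
region_volume <- function(mask, region, geometry = mask$geometry) {
  stopifnot(inherits(mask, "label_mask"))
  if (is.null(geometry)) {
    abort("No voxel geometry available: supply `geometry` or attach one to the mask.",
          class = "strokevol_validation_error")
  }
  codes <- region_label_codes(mask$legend, region)
  sum(mask$labels %in% codes) * voxel_volume(geometry)
}

#' Percent hemispheric lesion volume, uncorrected
#'
#' Lesion volume expressed against the mean hemispheric volume:
#' `%HLVuc = LV / ((HVc + HVi) / 2) * 100`.
#'
#' @param lv Lesion volume, mm^3.
#' @param hv_c Contralateral hemisphere volume, mm^3.
#' @param hv_i Ipsilateral hemisphere volume, mm^3.
#' @return Percent (vectorized).
#' @export
percent_hlv_uncorrected <- function(lv, hv_c, hv_i) {
  if (any(hv_c + hv_i <= 0)) {
    abort("Hemisphere volumes must not both be zero.",
          class = "strokevol_validation_error")
  }
  if (any(lv < 0 | hv_c < 0 | hv_i < 0)) {
    abort("Volumes must be non-negative.", class = "strokevol_validation_error")
  }
  100 * lv / ((hv_c + hv_i) / 2)
}

#' Percent hemispheric lesion volume, edema-corrected
#'
#' Corrects the lesion volume for the space-occupying effect of vasogenic
#' edema: `%HLVec = (HVc^2 + LV*(HVc + HVi) - HVi^2) / (HVc*(HVc + HVi)) *
#' 100`, algebraically equal to `100 * (LV - (HVi - HVc)) / HVc`. Both forms
#' are computed and verified to agree to 1e-9 relative as an internal
#' consistency check. When ipsilateral swelling exceeds the lesion volume the
#' result is negative; it is reported as-is with a warning, never clipped.
#'
#' @inheritParams percent_hlv_uncorrected
#' @return Percent (vectorized); negative when swelling exceeds the lesion.
#' @export
percent_hlv_edema_corrected <- function(lv, hv_c, hv_i) {
  if (any(hv_c <= 0)) {
    abort("Contralateral hemisphere volume must be positive.",
          class = "strokevol_validation_error")
  }
  if (any(lv < 0 | hv_i < 0)) {
    abort("Volumes must be non-negative.", class = "strokevol_validation_error")
  }
  printed <- 100 * (hv_c^2 + lv * (hv_c + hv_i) - hv_i^2) /
    (hv_c * (hv_c + hv_i))
  equivalent <- 100 * (lv - (hv_i - hv_c)) / hv_c
  scale <- pmax(abs(printed), abs(equivalent), 1)
  if (any(abs(printed - equivalent) / scale > 1e-9)) {
    abort("Edema-corrected lesion-volume forms disagree beyond tolerance (internal error).",
          class = "strokevol_internal_error")
  }
  if (any(printed < 0)) {
    warn(paste0("Edema-corrected lesion volume is negative for ",
                sum(printed < 0),
                " case(s): swelling exceeds lesion volume. Reported unclipped."))
  }
  printed
}

#' Midline shift from bilateral landmark distances
#'
#' Computes `MLS = (A - B) / 2` on every slice and returns the slice of
#' maximum lateral displacement of the third ventricle (ties broken toward
#' the lowest slice index).
#'
#' @param landmarks Tibble with columns `slice_index`, `a_mm` (ipsilateral
#'   cortex-to-ventricle distance) and `b_mm` (contralateral), as from
#'   [read_landmarks()].
#' @return A one-row tibble: `a_mm`, `b_mm`, `mls_mm`, `slice_index`.
#' @examples
#' midline_shift(tibble::tibble(slice_index = 3L, a_mm = 3, b_mm = 2))
#' @export
midline_shift <- function(landmarks) {
  required <- c("slice_index", "a_mm", "b_mm")
  if (!all(required %in% names(landmarks))) {
    abort("Landmarks need columns slice_index, a_mm, b_mm.",
          class = "strokevol_validation_error")
  }
  if (nrow(landmarks) == 0L) {
    abort("Cannot compute midline shift from zero landmark records.",
          class = "strokevol_validation_error")
  }
  mls <- (landmarks$a_mm - landmarks$b_mm) / 2
  ord <- order(-mls, landmarks$slice_index)
  k <- ord[1L]
  tibble::tibble(a_mm = landmarks$a_mm[k], b_mm = landmarks$b_mm[k],
                 mls_mm = mls[k], slice_index = as.integer(landmarks$slice_index[k]))
}

#' Full volumetry for one animal
#'
#' Composes [region_volume()] on the contralateral hemisphere, ipsilateral
#' hemisphere and lesion, applies both percent-hemispheric-lesion-volume
#' formulas, and quantifies the midline shift from the landmark records.
#'
#' @param mask A [label_mask()] containing both hemispheres (and lesion).
#' @param geometry A [voxel_geometry()]; defaults to the mask's own.
#' @param landmarks Landmark tibble for [midline_shift()], or `NULL` to skip
#'   (midline columns are then NA).
#' @return A one-row tibble: `hv_c`, `hv_i`, `lv` (mm^3), `pct_hlv_uc`,
#'   `pct_hlv_ec` (percent), `swelling_mm3` (`hv_i - hv_c`), `a_mm`, `b_mm`,
#'   `mls_mm`, `mls_slice`.
#' @export
volumetry_for_animal <- function(mask, geometry = mask$geometry,
                                 landmarks = NULL) {
  hv_c <- region_volume(mask, "hemisphere_contra", geometry)
  hv_i <- region_volume(mask, "hemisphere_ipsi", geometry)
  lv <- region_volume(mask, "lesion", geometry)
  if (hv_c <= 0 || hv_i <= 0) {
    abort("Mask must contain both hemispheres.",
          class = "strokevol_validation_error")
  }
  if (lv > hv_i) {
    abort("Lesion volume exceeds the ipsilateral hemisphere volume.",
          class = "strokevol_validation_error")
  }
  res <- tibble::tibble(
    hv_c = hv_c, hv_i = hv_i, lv = lv,
    pct_hlv_uc = percent_hlv_uncorrected(lv, hv_c, hv_i),
    pct_hlv_ec = percent_hlv_edema_corrected(lv, hv_c, hv_i),
    swelling_mm3 = hv_i - hv_c)
  if (!is.null(landmarks) && nrow(landmarks) > 0L) {
    mls <- midline_shift(landmarks)
    res$a_mm <- mls$a_mm
    res$b_mm <- mls$b_mm
    res$mls_mm <- mls$mls_mm
    res$mls_slice <- mls$slice_index
  } else {
    res$a_mm <- NA_real_
    res$b_mm <- NA_real_
    res$mls_mm <- NA_real_
    res$mls_slice <- NA_integer_
  }
  res
}

#' Derive midline-shift landmarks from a third-ventricle mask
#'
#' Convenience for synthetic phantoms: on every slice where the third
#' ventricle is present, takes the ventricle's centroid x position and the
#' outer brain borders along x, and converts them to the bilateral
#' cortex-to-ventricle distances A (ipsilateral) and B (contralateral).
#' Outer borders are taken at the voxel edges (half a voxel beyond the most
#' extreme labelled voxel centre). Manually measured landmarks take
#' precedence over this derivation in any real analysis.
#'
#' @param mask A [label_mask()] with `third_ventricle` and hemisphere labels.
#' @param geometry A [voxel_geometry()]; defaults to the mask's own.
#' @return Landmark tibble (`slice_index`, `a_mm`, `b_mm`).
#' @export
landmarks_from_ventricle <- function(mask, geometry = mask$geometry) {
  stopifnot(inherits(mask, "label_mask"))
  if (is.null(geometry)) {
    abort("No voxel geometry available.", class = "strokevol_validation_error")
  }
  dx <- geometry$in_plane_spacing
  vent <- region_voxels(mask, "third_ventricle")
  if (nrow(vent) == 0L) {
    abort("Mask has no third-ventricle voxels.",
          class = "strokevol_validation_error")
  }
  brain_codes <- unname(mask$legend[intersect(
    c("hemisphere_contra", "hemisphere_ipsi", "lesion", "roi_ischemic",
      "roi_contralateral", "third_ventricle"), names(mask$legend))])
  brain <- which(array(mask$labels %in% brain_codes, dim(mask$labels)),
                 arr.ind = TRUE)
  purrr::map_dfr(sort(unique(vent[, "slice"])), function(k) {
    vx <- mean(vent[vent[, "slice"] == k, "x"])
    bx <- brain[brain[, 3L] == k, 1L]
    tibble::tibble(
      slice_index = as.integer(k),
      a_mm = (max(bx) + 0.5 - vx) * dx,
      b_mm = (vx - (min(bx) - 0.5)) * dx)
  })
}
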