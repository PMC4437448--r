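# Containers and file I/O for the pipeline inputs: multi-echo image stacks
# (NIfTI + JSON echo-time sidecar), integer label masks, landmark tables and
# cohort manifests (TSV).

#' Canonical region legend for label masks
#'
#' Maps region names to the label integers used in mask volumes. Labels are
#' mutually exclusive on disk; region extraction is hierarchical: the
#' ipsilateral hemisphere includes the lesion and ischemic-core ROI labels,
#' the contralateral hemisphere includes the mirrored ROI label, and the
#' lesion includes its core ROI. The third ventricle is a midline structure
#' belonging to neither hemisphere.
#'
#' @return A named integer vector (name -> label).
#' @export
default_legend <- function() {
  c(hemisphere_contra = 1L, hemisphere_ipsi = 2L, lesion = 3L,
    roi_ischemic = 4L, roi_contralateral = 5L, third_ventricle = 6L)
}

# label codes that compose each named region (hierarchical semantics)
region_label_codes <- function(legend, region) {
  if (!region %in% names(legend)) {
    abort(paste0("Unknown region '", region, "'; legend defines: ",
                 paste(names(legend), collapse = ", ")),
          class = "strokevol_validation_error")
  }
  members <- switch(region,
    hemisphere_ipsi = c("hemisphere_ipsi", "lesion", "roi_ischemic"),
    hemisphere_contra = c("hemisphere_contra", "roi_contralateral"),
    lesion = c("lesion", "roi_ischemic"),
    region
  )
  unname(legend[intersect(members, names(legend))])
}

#' Multi-echo image stack
#'
#' Bundles a 4-D magnitude image (x, y, slice, echo), the echo times of the
#' CPMG train, and the voxel geometry. Magnitude images are non-negative by
#' definition; echo times must be strictly increasing and positive.
#'
#' @param voxels 4-D non-negative numeric array (x, y, slice, echo).
#' @param echo_times Echo times in ms, one per echo; strictly increasing.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `echo_train_image`.
#' @export
echo_train_image <- function(voxels, echo_times, geometry) {
  dims <- dim(voxels)
  if (is.null(dims) || length(dims) != 4L) {
    abort("`voxels` must be a 4-D array (x, y, slice, echo).",
          class = "strokevol_format_error")
  }
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) != dims[4L]) {
    abort(sprintf(
      "Echo count mismatch: image has %d echoes but metadata lists %d echo times.",
      dims[4L], length(echo_times)), class = "strokevol_validation_error")
  }
  if (any(!is.finite(echo_times)) || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0)) {
    abort("`echo_times` must be strictly increasing and positive (ms).",
          class = "strokevol_validation_error")
  }
  if (min(voxels) < 0) {
    abort("Magnitude image voxels must be non-negative.",
          class = "strokevol_validation_error")
  }
  stopifnot(inherits(geometry, "voxel_geometry"))
  structure(list(voxels = voxels, echo_times = echo_times, geometry = geometry),
            class = "echo_train_image")
}

#' @export
print.echo_train_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<echo_train_image> %d x %d x %d slices, %d echoes (TE %.3g-%.3g ms)\n",
    d[1], d[2], d[3], d[4], min(x$echo_times), max(x$echo_times)))
  invisible(x)
}

#' Integer label mask
#'
#' A 3-D integer volume labelling hemispheres, lesion, relaxometry ROIs and
#' the third ventricle (see [default_legend()]). Validation enforces that
#' every nonzero label is declared in the legend and that lesion voxels lie
#' on the ipsilateral side of the midline.
#'
#' @param labels 3-D integer array (x, y, slice).
#' @param legend Named integer vector mapping region names to labels.
#' @param geometry Optional [voxel_geometry()] carried for volumetry.
#' @param midline_x Midline position in voxel coordinates (1-based, may be
#'   fractional). Defaults to the volume centre `(nx + 1) / 2`. The
#'   ipsilateral hemisphere is the `x > midline_x` side (the right-hemisphere
#'   occlusion convention).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, legend = default_legend(), geometry = NULL,
                       midline_x = NULL) {
  dims <- dim(labels)
  if (is.null(dims) || length(dims) != 3L) {
    abort("`labels` must be a 3-D array (x, y, slice).",
          class = "strokevol_format_error")
  }
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  unknown <- setdiff(present, c(0L, unname(legend)))
  if (length(unknown) > 0L) {
    abort(paste0("Mask contains labels absent from the legend: ",
                 paste(unknown, collapse = ", ")),
          class = "strokevol_validation_error")
  }
  if (is.null(midline_x)) midline_x <- (dims[1L] + 1) / 2

  lesion_codes <- unname(legend[intersect(c("lesion", "roi_ischemic"), names(legend))])
  if (length(lesion_codes) > 0L) {
    lesion_x <- which(array(labels %in% lesion_codes, dim = dims),
                      arr.ind = TRUE)[, 1L]
    if (length(lesion_x) > 0L && any(lesion_x < midline_x)) {
      abort(sprintf(
        "%d lesion voxel(s) lie on the contralateral side of the midline (x = %.2f).",
        sum(lesion_x < midline_x), midline_x),
        class = "strokevol_validation_error")
    }
  }
  structure(list(labels = labels, legend = legend, geometry = geometry,
                 midline_x = midline_x),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_mask> %d x %d x %d slices, midline x = %.2f\n",
              d[1], d[2], d[3], x$midline_x))
  counts <- table(factor(as.vector(x$labels), levels = unname(x$legend),
                         labels = names(x$legend)))
  for (nm in names(counts)) cat(sprintf("  %-18s %d voxels\n", nm, counts[[nm]]))
  invisible(x)
}

#' Logical mask of a named region
#'
#' Region extraction is hierarchical: `hemisphere_ipsi` includes lesion and
#' ischemic-core labels, `lesion` includes its core ROI.
#'
#' @param mask A [label_mask()].
#' @param region Region name present in the mask legend.
#' @return Logical 3-D array.
#' @export
region_mask <- function(mask, region) {
  stopifnot(inherits(mask, "label_mask"))
  codes <- region_label_codes(mask$legend, region)
  array(mask$labels %in% codes, dim = dim(mask$labels))
}

#' Voxel indices of a named region
#'
#' @inheritParams region_mask
#' @return Integer matrix with columns `x`, `y`, `slice` (1-based indices).
#' @export
region_voxels <- function(mask, region) {
  stopifnot(inherits(mask, "label_mask"))
  codes <- region_label_codes(mask$legend, region)
  idx <- which(array(mask$labels %in% codes, dim = dim(mask$labels)),
               arr.ind = TRUE)
  colnames(idx) <- c("x", "y", "slice")
  idx
}

#' Read a multi-echo image stack
#'
#' Reads a 4-D NIfTI volume plus its JSON sidecar carrying the echo times
#' and slice geometry, and returns a validated [echo_train_image()].
#'
#' @param image_path Path to the 4-D NIfTI image.
#' @param meta_path Path to the JSON sidecar with fields `echo_times_ms`,
#'   `in_plane_spacing_mm`, `slice_thickness_mm` and optional
#'   `slice_gap_mm` (default 0).
#' @return An [echo_train_image()].
#' @export
read_echo_train <- function(image_path, meta_path) {
  nii <- read_nifti(image_path)
  if (length(dim(nii$data)) != 4L) {
    abort(sprintf("Expected a 4-D echo-train image, got %d dimensions: %s",
                  length(dim(nii$data)), image_path),
          class = "strokevol_format_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("echo_times_ms", "in_plane_spacing_mm", "slice_thickness_mm")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    abort(paste0("Echo metadata missing fields: ", paste(missing, collapse = ", ")),
          class = "strokevol_validation_error")
  }
  geometry <- voxel_geometry(meta$in_plane_spacing_mm, meta$slice_thickness_mm,
                             meta$slice_gap_mm %||% 0)
  echo_train_image(nii$data, meta$echo_times_ms, geometry)
}

#' Write a multi-echo image stack
#'
#' Writes the 4-D volume as float64 NIfTI (bit-exact round trips) and the
#' echo times / geometry as a JSON sidecar.
#'
#' @param image An [echo_train_image()].
#' @param image_path Output NIfTI path.
#' @param meta_path Output JSON sidecar path.
#' @return `image_path`, invisibly.
#' @export
write_echo_train <- function(image, image_path, meta_path) {
  stopifnot(inherits(image, "echo_train_image"))
  geo <- image$geometry
  write_nifti(image$voxels, image_path,
              pixdim = c(geo$in_plane_spacing, geo$in_plane_spacing,
                         geo$slice_thickness + geo$slice_gap, 1))
  jsonlite::write_json(
    list(echo_times_ms = image$echo_times,
         in_plane_spacing_mm = geo$in_plane_spacing,
         slice_thickness_mm = geo$slice_thickness,
         slice_gap_mm = geo$slice_gap),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' Read a label mask
#'
#' @param mask_path Path to a 3-D integer NIfTI volume.
#' @param legend Named integer vector (see [default_legend()]).
#' @param geometry Optional [voxel_geometry()] to attach.
#' @param midline_x Optional midline voxel coordinate for validation; default
#'   is the volume centre.
#' @return A validated [label_mask()].
#' @export
read_label_mask <- function(mask_path, legend = default_legend(),
                            geometry = NULL, midline_x = NULL) {
  nii <- read_nifti(mask_path)
  if (length(dim(nii$data)) != 3L) {
    abort(sprintf("Expected a 3-D mask, got %d dimensions: %s",
                  length(dim(nii$data)), mask_path),
          class = "strokevol_format_error")
  }
  if (max(abs(nii$data - round(nii$data))) > 0) {
    abort(paste0("Mask volume contains non-integer values: ", mask_path),
          class = "strokevol_validation_error")
  }
  label_mask(array(as.integer(round(nii$data)), dim = dim(nii$data)),
             legend = legend, geometry = geometry, midline_x = midline_x)
}

#' Write a label mask
#'
#' @param mask A [label_mask()].
#' @param mask_path Output NIfTI path (stored as int16).
#' @return `mask_path`, invisibly.
#' @export
write_label_mask <- function(mask, mask_path) {
  stopifnot(inherits(mask, "label_mask"))
  pix <- if (!is.null(mask$geometry)) {
    c(mask$geometry$in_plane_spacing, mask$geometry$in_plane_spacing,
      mask$geometry$slice_thickness + mask$geometry$slice_gap)
  } else NULL
  write_nifti(mask$labels, mask_path, pixdim = pix, datatype = 4L)
  invisible(mask_path)
}

#' Read midline-shift landmarks
#'
#' Landmarks are per-slice distances from the outer cortical border to the
#' middle of the third ventricle, measured from the ipsilateral (`a_mm`) and
#' contralateral (`b_mm`) side.
#'
#' @param landmark_path TSV with columns `slice_index`, `a_mm`, `b_mm`.
#' @return A tibble with those columns; zero rows for an empty file.
#' @export
read_landmarks <- function(landmark_path) {
  empty <- tibble::tibble(slice_index = integer(), a_mm = numeric(),
                          b_mm = numeric())
  if (!file.exists(landmark_path)) {
    abort(paste0("Landmark file not found: ", landmark_path),
          class = "strokevol_io_error")
  }
  if (file.size(landmark_path) == 0) return(empty)
  lm <- readr::read_tsv(landmark_path, show_col_types = FALSE,
                        col_types = readr::cols(
                          slice_index = readr::col_integer(),
                          a_mm = readr::col_double(),
                          b_mm = readr::col_double()))
  if (nrow(lm) == 0L) return(empty)
  if (any(!is.finite(lm$a_mm)) || any(!is.finite(lm$b_mm)) ||
      any(lm$a_mm <= 0) || any(lm$b_mm <= 0)) {
    abort("Landmark distances A and B must be positive (mm).",
          class = "strokevol_validation_error")
  }
  lm
}

#' Write midline-shift landmarks
#'
#' @param landmarks Tibble with columns `slice_index`, `a_mm`, `b_mm`.
#' @param landmark_path Output TSV path.
#' @return `landmark_path`, invisibly.
#' @export
write_landmarks <- function(landmarks, landmark_path) {
  readr::write_tsv(landmarks[, c("slice_index", "a_mm", "b_mm")], landmark_path)
  invisible(landmark_path)
}

#' Read a cohort manifest
#'
#' The manifest maps each animal to its group and input files.
#'
#' @param manifest_path TSV with columns `animal_id`, `group`, `image_path`,
#'   `meta_path`, `mask_path`, `landmark_path`. Relative paths are resolved
#'   against the manifest's directory.
#' @return A tibble, one row per animal.
#' @export
read_manifest <- function(manifest_path) {
  mf <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  required <- c("animal_id", "group", "image_path", "meta_path",
                "mask_path", "landmark_path")
  missing <- setdiff(required, names(mf))
  if (length(missing) > 0L) {
    abort(paste0("Manifest missing columns: ", paste(missing, collapse = ", ")),
          class = "strokevol_validation_error")
  }
  if (anyDuplicated(mf$animal_id)) {
    abort("Manifest animal_id values must be unique.",
          class = "strokevol_validation_error")
  }
  groups <- unique(mf$group)
  if (length(groups) != 2L || any(table(mf$group) < 1L)) {
    abort("Manifest must contain exactly two non-empty groups.",
          class = "strokevol_validation_error")
  }
  root <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  dplyr::mutate(mf, dplyr::across(dplyr::ends_with("_path"), resolve))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
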