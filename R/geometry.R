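#' Voxel geometry of a multi-slice acquisition
#'
#' Records the physical sampling of a multi-slice MR image: isotropic
#' in-plane spacing, slice thickness and inter-slice gap (all mm). The slice
#' axis is always the third array dimension. The per-voxel volume used by all
#' volumetry is `in_plane_spacing^2 * (slice_thickness + slice_gap)`, which
#' reduces to the classical "area summed over slices times slice thickness"
#' rule for contiguous (gap 0) protocols.
#'
#' @param in_plane_spacing Voxel edge length along x and y, mm. Must be > 0.
#' @param slice_thickness Slice thickness, mm. Must be > 0.
#' @param slice_gap Gap between adjacent slices, mm. Must be >= 0. Default 0
#'   (contiguous slices, the usual rodent CPMG protocol).
#'
#' @return An object of class `voxel_geometry`.
#' @examples
#' geo <- voxel_geometry(37 / 128, 2)
#' voxel_volume(geo)
#' @export
voxel_geometry <- function(in_plane_spacing, slice_thickness, slice_gap = 0) {
  if (!is.numeric(in_plane_spacing) || length(in_plane_spacing) != 1L ||
      !is.finite(in_plane_spacing) || in_plane_spacing <= 0) {
    abort("`in_plane_spacing` must be a single positive number (mm).",
          class = "strokevol_geometry_error")
  }
  if (!is.numeric(slice_thickness) || length(slice_thickness) != 1L ||
      !is.finite(slice_thickness) || slice_thickness <= 0) {
    abort("`slice_thickness` must be a single positive number (mm).",
          class = "strokevol_geometry_error")
  }
  if (!is.numeric(slice_gap) || length(slice_gap) != 1L ||
      !is.finite(slice_gap) || slice_gap < 0) {
    abort("`slice_gap` must be a single non-negative number (mm).",
          class = "strokevol_geometry_error")
  }
  structure(
    list(
      in_plane_spacing = as.numeric(in_plane_spacing),
      slice_thickness = as.numeric(slice_thickness),
      slice_gap = as.numeric(slice_gap)
    ),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "<voxel_geometry> %.4g x %.4g mm in-plane, %.4g mm slices (gap %.4g mm)\n",
    x$in_plane_spacing, x$in_plane_spacing, x$slice_thickness, x$slice_gap
  ))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param geometry A [voxel_geometry()].
#' @return Volume in mm^3.
#' @export
voxel_volume <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$in_plane_spacing^2 * (geometry$slice_thickness + geometry$slice_gap)
}
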