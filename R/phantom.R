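# Synthetic multi-slice multi-echo rat-brain phantoms with known ground
# truth.
#
# Geometry (per slice, identical across slices): two half-ellipse
# hemispheres anchored at a midline that is displaced toward the
# contralateral (left) side. The contralateral in-plane semi-axis is a_c,
# the ipsilateral one a_i = a_c * (1 + s) so that HVi = HVc * (1 + s)
# (swelling factor s). The third ventricle is a small ellipse on the
# displaced midline, so the cortex-to-ventricle distances are A ~ a_i
# (ipsilateral) and B ~ a_c, giving a true midline shift
# MLS = (A - B) / 2 = (a_i - a_c) / 2 by construction.
#
# The lesion is a contiguous cortical+striatal region: the k nearest
# ipsilateral voxels (physical distance) to a lateral focus point, with k
# chosen to hit the requested fraction of the ipsilateral hemisphere
# exactly (to one voxel). The ischemic-core ROI is the inner 30% of that
# ordering, i.e. an eroded lesion core well away from the midline.
#
# Signal: S(TE) = S0 * exp(-TE / T2) per voxel with region T2/S0; optional
# Gaussian or Rician noise with sigma = s0_tissue / snr (first-echo tissue
# SNR). Identical seeds give bit-identical phantoms.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic phantom
#'
#' Defaults emulate the rodent CPMG stroke protocol this package targets:
#' 8 contiguous coronal slices of 2 mm, 37 x 37 mm field of view, 12 echoes
#' at TE 18-216 ms (delta TE 18 ms). The in-plane matrix defaults to
#' 128 x 128 (desk-scale runtime; the geometry is resolution-independent)
#' with spacing `fov / matrix`. Tissue T2/S0 values are typical of rat brain
#' at 7 T; the lesion carries an elevated T2 (vasogenic edema).
#'
#' @param matrix In-plane matrix size (voxels per side).
#' @param n_slices Number of slices.
#' @param fov In-plane field of view, mm.
#' @param slice_thickness,slice_gap Slice geometry, mm.
#' @param echo_times Echo times, ms.
#' @param hemisphere_volume Target contralateral hemisphere volume, mm^3.
#' @param hemisphere_aspect Dorsoventral over mediolateral semi-axis ratio
#'   of each hemisphere half-ellipse.
#' @param lesion_fraction Lesion volume as a fraction of the ipsilateral
#'   hemisphere, in `[0, 1)`.
#' @param swelling_factor s >= 0 with `HVi = HVc * (1 + s)`.
#' @param midline_displacement Midline displacement toward the contralateral
#'   side, mm; `NULL` (default) uses `a * s / 2`, proportional to swelling.
#' @param t2_tissue,t2_lesion,t2_csf T2 values, ms (within [1, 1000]).
#' @param s0_tissue,s0_lesion,s0_csf Proton-density signal amplitudes.
#' @param noise_model `"none"`, `"gaussian"` or `"rician"`.
#' @param snr First-echo tissue signal-to-noise ratio (`sigma =
#'   s0_tissue / snr`).
#' @param seed RNG seed for the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix = 128L, n_slices = 8L, fov = 37,
                         slice_thickness = 2, slice_gap = 0,
                         echo_times = seq(18, 216, by = 18),
                         hemisphere_volume = 550, hemisphere_aspect = 0.73,
                         lesion_fraction = 0.2, swelling_factor = 0.1,
                         midline_displacement = NULL,
                         t2_tissue = 50, t2_lesion = 70, t2_csf = 150,
                         s0_tissue = 1000, s0_lesion = 1050, s0_csf = 1400,
                         noise_model = c("rician", "gaussian", "none"),
                         snr = 50, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (lesion_fraction < 0 || lesion_fraction >= 1) {
    abort("`lesion_fraction` must be in [0, 1).",
          class = "strokevol_validation_error")
  }
  if (swelling_factor < 0) {
    abort("`swelling_factor` must be >= 0.", class = "strokevol_validation_error")
  }
  t2s <- c(t2_tissue, t2_lesion, t2_csf)
  if (any(t2s < 1 | t2s > 1000)) {
    abort("T2 values must lie within [1, 1000] ms.",
          class = "strokevol_validation_error")
  }
  structure(
    list(matrix = as.integer(matrix), n_slices = as.integer(n_slices),
         fov = fov, slice_thickness = slice_thickness, slice_gap = slice_gap,
         echo_times = as.numeric(echo_times),
         hemisphere_volume = hemisphere_volume,
         hemisphere_aspect = hemisphere_aspect,
         lesion_fraction = lesion_fraction, swelling_factor = swelling_factor,
         midline_displacement = midline_displacement,
         t2_tissue = t2_tissue, t2_lesion = t2_lesion, t2_csf = t2_csf,
         s0_tissue = s0_tissue, s0_lesion = s0_lesion, s0_csf = s0_csf,
         noise_model = noise_model, snr = snr, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Generate one synthetic phantom
#'
#' Draws the two-hemisphere geometry described in [phantom_spec()], renders
#' the multi-echo signal, and returns the image together with its ground
#' truth. True volumes are defined as the voxel-counted volumes of the
#' generated masks (the masks are what any downstream volumetry consumes),
#' so volumetric recovery from the truth masks is exact; the nominal
#' continuum parameters are reported alongside.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (an [echo_train_image()]) and `truth`, an
#'   object of class `phantom_truth` holding the [label_mask()], the T2 and
#'   S0 fields, derived landmark records, and a one-row `truth` tibble
#'   (`true_hv_c`, `true_hv_i`, `true_lv`, `true_mls`, `true_delta_t2`,
#'   achieved lesion fraction and swelling, midline position).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$matrix
  ny <- spec$matrix
  ns <- spec$n_slices
  dx <- spec$fov / spec$matrix
  dz <- spec$slice_thickness + spec$slice_gap
  geometry <- voxel_geometry(dx, spec$slice_thickness, spec$slice_gap)

  # hemisphere semi-axes from the target contralateral volume
  slice_area <- spec$hemisphere_volume / (ns * dz)
  a <- sqrt(2 * slice_area / (pi * spec$hemisphere_aspect))
  b <- spec$hemisphere_aspect * a
  s <- spec$swelling_factor
  d <- spec$midline_displacement %||% (a * s / 2)
  a_c <- a - d
  a_i <- a_c * (1 + s)
  if (a_c <= 0 || (-d - a_c) < -spec$fov / 2 || (-d + a_i) > spec$fov / 2 ||
      b > spec$fov / 2) {
    abort("Phantom geometry does not fit the field of view.",
          class = "strokevol_validation_error")
  }

  xc <- (seq_len(nx) - (nx + 1) / 2) * dx
  yc <- (seq_len(ny) - (ny + 1) / 2) * dx
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  m <- -d  # midline x position, mm (displaced toward the contralateral side)

  legend <- default_legend()
  slice_lab <- matrix(0L, nx, ny)
  contra <- X < m & ((X - m) / a_c)^2 + (Y / b)^2 <= 1
  ipsi <- X > m & ((X - m) / a_i)^2 + (Y / b)^2 <= 1
  slice_lab[contra] <- legend[["hemisphere_contra"]]
  slice_lab[ipsi] <- legend[["hemisphere_ipsi"]]
  # ventricle semi-axes floored at ~half a voxel so the midline structure
  # survives coarse matrices
  vent_a <- max(0.35, 0.55 * dx)
  vent_b <- max(1.3, 0.55 * dx)
  vent <- ((X - m) / vent_a)^2 + (Y / vent_b)^2 <= 1 & (contra | ipsi)
  slice_lab[vent] <- legend[["third_ventricle"]]

  labels <- array(rep(slice_lab, ns), dim = c(nx, ny, ns))

  # lesion: k nearest ipsilateral voxels to a lateral cortical/striatal focus
  ipsi_idx <- which(labels == legend[["hemisphere_ipsi"]], arr.ind = TRUE)
  n_ipsi_total <- nrow(ipsi_idx)
  k_lesion <- round(spec$lesion_fraction * n_ipsi_total)
  if (k_lesion > 0L) {
    zc <- (seq_len(ns) - (ns + 1) / 2) * dz
    focus <- c(m + 0.65 * a_i, -0.15 * b, 0)
    dist2 <- (xc[ipsi_idx[, 1L]] - focus[1])^2 +
      (yc[ipsi_idx[, 2L]] - focus[2])^2 +
      ((zc[ipsi_idx[, 3L]] - focus[3]) / 2)^2  # axially elongated lesion
    ord <- order(dist2)
    lesion_rows <- ipsi_idx[ord[seq_len(k_lesion)], , drop = FALSE]
    labels[lesion_rows] <- legend[["lesion"]]
    k_roi <- max(1L, round(0.3 * k_lesion))
    roi_rows <- ipsi_idx[ord[seq_len(k_roi)], , drop = FALSE]
    labels[roi_rows] <- legend[["roi_ischemic"]]
  }

  midline_vox <- m / dx + (nx + 1) / 2
  mask <- label_mask(labels, legend = legend, geometry = geometry,
                     midline_x = midline_vox)

  # T2 / S0 fields (background: S0 = 0, T2 irrelevant)
  t2_field <- array(Inf, dim = dim(labels))
  s0_field <- array(0, dim = dim(labels))
  tissue <- labels %in% legend[c("hemisphere_contra", "hemisphere_ipsi")]
  lesion_all <- labels %in% legend[c("lesion", "roi_ischemic")]
  csf <- labels == legend[["third_ventricle"]]
  t2_field[tissue] <- spec$t2_tissue
  s0_field[tissue] <- spec$s0_tissue
  t2_field[lesion_all] <- spec$t2_lesion
  s0_field[lesion_all] <- spec$s0_lesion
  t2_field[csf] <- spec$t2_csf
  s0_field[csf] <- spec$s0_csf

  te <- spec$echo_times
  decay <- exp(outer(-1 / as.vector(t2_field), te))
  signal <- as.vector(s0_field) * decay
  if (spec$noise_model != "none") {
    sigma <- spec$s0_tissue / spec$snr
    signal <- with_seed(spec$seed, {
      n <- length(signal)
      if (spec$noise_model == "rician") {
        sqrt((signal + sigma * rnorm(n))^2 + (sigma * rnorm(n))^2)
      } else {
        pmax(signal + sigma * rnorm(n), 0)
      }
    })
  }
  image <- echo_train_image(array(signal, dim = c(nx, ny, ns, length(te))),
                            te, geometry)

  vv <- voxel_volume(geometry)
  n_contra <- sum(labels == legend[["hemisphere_contra"]])
  n_ipsi <- sum(labels %in% legend[c("hemisphere_ipsi", "lesion", "roi_ischemic")])
  n_lesion <- sum(labels %in% legend[c("lesion", "roi_ischemic")])
  landmarks <- landmarks_from_ventricle(mask, geometry)
  truth_row <- tibble::tibble(
    true_hv_c = n_contra * vv, true_hv_i = n_ipsi * vv,
    true_lv = n_lesion * vv,
    true_pct_hlv_uc = percent_hlv_uncorrected(n_lesion * vv, n_contra * vv,
                                              n_ipsi * vv),
    true_pct_hlv_ec = suppressWarnings(
      percent_hlv_edema_corrected(n_lesion * vv, n_contra * vv, n_ipsi * vv)),
    true_mls = (a_i - a_c) / 2,
    true_delta_t2 = spec$t2_lesion - spec$t2_tissue,
    lesion_fraction_achieved = n_lesion / n_ipsi,
    swelling_achieved = n_ipsi / n_contra - 1,
    midline_x_vox = midline_vox,
    lesion_fraction_nominal = spec$lesion_fraction,
    swelling_factor_nominal = spec$swelling_factor,
    t2_tissue = spec$t2_tissue, t2_lesion = spec$t2_lesion)

  truth <- structure(
    list(mask = mask, t2_field = t2_field, s0_field = s0_field,
         landmarks = landmarks, truth = truth_row, spec = spec),
    class = "phantom_truth")
  list(image = image, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "<phantom_truth> HVc %.1f / HVi %.1f / LV %.1f mm^3, MLS %.2f mm, dT2 %.1f ms\n",
    tr$true_hv_c, tr$true_hv_i, tr$true_lv, tr$true_mls, tr$true_delta_t2))
  invisible(x)
}

#' Perturb a mask boundary
#'
#' Optional tracing-variability operator: dilates (`k > 0`) or erodes
#' (`k < 0`) the lesion boundary by `|k|` voxels in-plane. Dilation converts
#' adjacent ipsilateral-hemisphere voxels to lesion; erosion relabels the
#' lesion rim back to hemisphere (the ischemic-core ROI label is preserved).
#'
#' @param mask A [label_mask()].
#' @param k Signed boundary offset in voxels.
#' @return A perturbed [label_mask()].
#' @export
perturb_mask <- function(mask, k) {
  stopifnot(inherits(mask, "label_mask"))
  if (k == 0) return(mask)
  legend <- mask$legend
  labels <- mask$labels
  lesion_code <- legend[["lesion"]]
  hemi_code <- legend[["hemisphere_ipsi"]]
  roi_code <- legend[["roi_ischemic"]]
  shift <- function(arr, di, dj) {
    out <- array(FALSE, dim(arr))
    nx <- dim(arr)[1]; ny <- dim(arr)[2]
    src_i <- seq_len(nx) - di; src_j <- seq_len(ny) - dj
    ok_i <- src_i >= 1 & src_i <= nx; ok_j <- src_j >= 1 & src_j <= ny
    out[ok_i, ok_j, ] <- arr[src_i[ok_i], src_j[ok_j], , drop = FALSE]
    out
  }
  for (step in seq_len(abs(k))) {
    lesion <- labels == lesion_code | labels == roi_code
    nb <- shift(lesion, 1, 0) | shift(lesion, -1, 0) |
      shift(lesion, 0, 1) | shift(lesion, 0, -1)
    if (k > 0) {
      grow <- nb & labels == hemi_code
      labels[grow] <- lesion_code
    } else {
      interior <- shift(lesion, 1, 0) & shift(lesion, -1, 0) &
        shift(lesion, 0, 1) & shift(lesion, 0, -1)
      rim <- (labels == lesion_code) & !interior
      labels[rim] <- hemi_code
    }
  }
  label_mask(labels, legend = legend, geometry = mask$geometry,
             midline_x = mask$midline_x)
}
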