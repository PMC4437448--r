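# Mono-exponential T2 relaxometry from CPMG echo trains.
#
# Model: S(TE) = S0 * exp(-TE / T2) on magnitude images, no constant offset.
# Two estimators:
#   log_linear — weighted linear regression of ln S on TE with weights S^2
#     (the classical variance-stabilizing weights for log-transformed
#     exponential decays); closed form, fully vectorized over voxels.
#   nonlinear — iterative least squares on the native signal scale,
#     initialized from the log-linear solution (BFGS on (log S0, log T2),
#     an unconstrained parametrization that keeps both positive).
# Echoes at or below the noise floor are dropped per voxel; fewer than 3
# usable echoes, a non-decaying slope, an out-of-bounds T2 or a native-scale
# R^2 outside [0, 1] mark the voxel invalid.

# Core fitting on a voxels-x-echoes signal matrix. Single-voxel and whole-map
# entry points share this arithmetic path exactly, so a map equals a
# voxel-by-voxel loop bit for bit.
t2_fit_matrix <- function(S, te, method = "log_linear", noise_floor = 0,
                          t2_min = 1, t2_max = 1000) {
  stopifnot(is.matrix(S), ncol(S) == length(te))
  usable <- S > noise_floor
  n_use <- rowSums(usable)

  w <- (S * S) * usable
  y <- log(pmax(S, .Machine$double.xmin))
  y[!usable] <- 0
  sw <- rowSums(w)
  swx <- drop(w %*% te)
  swxx <- drop(w %*% (te * te))
  wy <- w * y
  swy <- rowSums(wy)
  swxy <- drop(wy %*% te)

  denom <- sw * swxx - swx * swx
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swy - slope * swx) / sw
  t2 <- -1 / slope
  s0 <- exp(intercept)

  valid <- n_use >= 3L & is.finite(slope) & slope < 0 &
    is.finite(s0) & s0 > 0 & t2 >= t2_min & t2 <= t2_max

  if (method == "nonlinear") {
    for (i in which(valid)) {
      us <- usable[i, ]
      si <- S[i, us]
      ti <- te[us]
      par <- c(log(s0[i]), log(t2[i]))
      fn <- function(p) {
        pred <- exp(p[1] - ti * exp(-p[2]))
        sum((si - pred)^2)
      }
      gr <- function(p) {
        pred <- exp(p[1] - ti * exp(-p[2]))
        r <- pred - si
        c(2 * sum(r * pred), 2 * sum(r * pred * ti * exp(-p[2])))
      }
      opt <- tryCatch(optim(par, fn, gr, method = "BFGS"),
                      error = function(e) NULL)
      if (!is.null(opt)) {
        s0[i] <- exp(opt$par[1])
        t2[i] <- exp(opt$par[2])
      }
    }
    valid <- valid & t2 >= t2_min & t2 <= t2_max
  }

  # R^2 on the native signal scale for both methods (comparability)
  pred <- exp(outer(-1 / t2, te) + log(s0))
  res <- S - pred
  res[!usable] <- 0
  ss_res <- rowSums(res * res)
  ybar <- rowSums(S * usable) / pmax(n_use, 1L)
  tot <- S - ybar
  tot[!usable] <- 0
  ss_tot <- rowSums(tot * tot)
  r2 <- 1 - ss_res / ss_tot
  valid <- valid & is.finite(r2) & r2 >= 0

  t2[!valid] <- NA_real_
  s0[!valid] <- NA_real_
  r2[!valid] <- NA_real_
  list(t2 = t2, s0 = s0, r_squared = r2, valid = valid, n_echoes_used = n_use)
}

#' Fit the mono-exponential decay of a single voxel
#'
#' Estimates `S(TE) = S0 * exp(-TE / T2)` from one echo-train signal.
#'
#' @param signal Non-negative signal values, one per echo.
#' @param echo_times Echo times in ms, strictly increasing.
#' @param method `"log_linear"` (weighted linear regression of `ln S` on TE,
#'   weights = squared signal) or `"nonlinear"` (iterative least squares on
#'   the native scale, initialized from the log-linear solution).
#' @param noise_floor Echoes at or below this signal level are dropped.
#' @param t2_min,t2_max Physical plausibility bounds on T2 (ms); fits outside
#'   are marked invalid rather than clipped.
#' @return A one-row tibble: `t2` (ms), `s0`, `r_squared` (native-scale),
#'   `valid`, `n_echoes_used`. Degenerate input (e.g. all-zero signal) gives
#'   `valid = FALSE`, never an error.
#' @examples
#' te <- seq(18, 216, by = 18)
#' fit_t2_voxel(1000 * exp(-te / 50), te)
#' @export
fit_t2_voxel <- function(signal, echo_times,
                         method = c("log_linear", "nonlinear"),
                         noise_floor = 0, t2_min = 1, t2_max = 1000) {
  method <- match.arg(method)
  echo_times <- as.numeric(echo_times)
  if (length(signal) != length(echo_times)) {
    abort("`signal` and `echo_times` must have the same length.",
          class = "strokevol_validation_error")
  }
  fit <- t2_fit_matrix(matrix(as.numeric(signal), nrow = 1L), echo_times,
                       method = method, noise_floor = noise_floor,
                       t2_min = t2_min, t2_max = t2_max)
  tibble::tibble(t2 = fit$t2, s0 = fit$s0, r_squared = fit$r_squared,
                 valid = fit$valid, n_echoes_used = fit$n_echoes_used)
}

#' Fit a whole-volume T2 map
#'
#' Applies [fit_t2_voxel()]'s estimator to every voxel of a multi-echo
#' stack (vectorized; numerically identical to a voxel-by-voxel loop).
#'
#' @param image An [echo_train_image()].
#' @inheritParams fit_t2_voxel
#' @param noise_floor Absolute signal threshold below which echoes are
#'   dropped. Alternatively supply `noise_sd` (background noise SD) and the
#'   floor becomes `noise_k * noise_sd`.
#' @param noise_sd,noise_k Background-noise based floor (default `noise_k` 3).
#' @return A `t2_map` object: 3-D arrays `t2`, `s0`, `r_squared` (NA where
#'   invalid), logical `valid`, plus geometry and fit settings.
#' @export
fit_t2_map <- function(image, method = c("log_linear", "nonlinear"),
                       noise_floor = NULL, noise_sd = NULL, noise_k = 3,
                       t2_min = 1, t2_max = 1000) {
  stopifnot(inherits(image, "echo_train_image"))
  method <- match.arg(method)
  if (is.null(noise_floor)) {
    noise_floor <- if (!is.null(noise_sd)) noise_k * noise_sd else 0
  }
  dims <- dim(image$voxels)
  S <- matrix(image$voxels, nrow = prod(dims[1:3]), ncol = dims[4L])
  fit <- t2_fit_matrix(S, image$echo_times, method = method,
                       noise_floor = noise_floor, t2_min = t2_min,
                       t2_max = t2_max)
  sp <- dims[1:3]
  structure(
    list(t2 = array(fit$t2, sp), s0 = array(fit$s0, sp),
         r_squared = array(fit$r_squared, sp), valid = array(fit$valid, sp),
         n_echoes_used = array(fit$n_echoes_used, sp),
         geometry = image$geometry, echo_times = image$echo_times,
         method = method, noise_floor = noise_floor,
         t2_bounds = c(t2_min, t2_max)),
    class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  d <- dim(x$t2)
  nv <- sum(x$valid)
  cat(sprintf("<t2_map> %d x %d x %d (%s fit), %d valid voxels (%.1f%%)\n",
              d[1], d[2], d[3], x$method, nv, 100 * nv / length(x$valid)))
  if (nv > 0) {
    cat(sprintf("  T2 median %.1f ms [%.1f, %.1f]\n",
                stats::median(x$t2[x$valid]), min(x$t2[x$valid]),
                max(x$t2[x$valid])))
  }
  invisible(x)
}

#' Write a T2 map as NIfTI volumes
#'
#' Writes `<prefix>_t2.nii`, `<prefix>_s0.nii`, `<prefix>_rsq.nii` (float64,
#' NA stored as -1) and `<prefix>_valid.nii` (int16 0/1).
#'
#' @param map A `t2_map`.
#' @param prefix Output path prefix.
#' @return The four paths, invisibly.
#' @export
write_t2_map <- function(map, prefix) {
  stopifnot(inherits(map, "t2_map"))
  geo <- map$geometry
  pix <- c(geo$in_plane_spacing, geo$in_plane_spacing,
           geo$slice_thickness + geo$slice_gap)
  subst <- function(a) { a[is.na(a)] <- -1; a }
  paths <- paste0(prefix, c("_t2.nii", "_s0.nii", "_rsq.nii", "_valid.nii"))
  write_nifti(subst(map$t2), paths[1], pixdim = pix)
  write_nifti(subst(map$s0), paths[2], pixdim = pix)
  write_nifti(subst(map$r_squared), paths[3], pixdim = pix)
  write_nifti(array(as.integer(map$valid), dim(map$valid)), paths[4],
              pixdim = pix, datatype = 4L)
  invisible(paths)
}

#' Mirror a voxel set across the midline
#'
#' Reflects a region of interest across the sagittal plane `x = midline_x`
#' to obtain the "corresponding position on the contralateral hemisphere".
#' Reflected voxels falling outside the image are clipped; a reflection that
#' lands entirely outside is an error.
#'
#' @param roi Integer matrix of voxel indices with columns `x`, `y`, `slice`
#'   (as from [region_voxels()]); must lie entirely on one side of the
#'   midline.
#' @param midline_x Midline position in voxel coordinates (may be
#'   fractional).
#' @param nx Image extent along x (voxels), used for bounds clipping.
#' @return Integer matrix of mirrored voxel indices.
#' @export
mirror_roi <- function(roi, midline_x, nx) {
  roi <- as.matrix(roi)
  if (nrow(roi) == 0L) {
    abort("Cannot mirror an empty ROI.", class = "strokevol_validation_error")
  }
  x <- roi[, 1L]
  if (!(all(x > midline_x) || all(x < midline_x))) {
    abort("ROI must lie entirely on one side of the midline before mirroring.",
          class = "strokevol_validation_error")
  }
  xm <- as.integer(round(2 * midline_x - x))
  keep <- xm >= 1L & xm <= nx
  if (!any(keep)) {
    abort("Mirrored ROI falls entirely outside the image.",
          class = "strokevol_validation_error")
  }
  out <- roi[keep, , drop = FALSE]
  out[, 1L] <- xm[keep]
  out
}

#' ROI T2 relaxation times and the ipsilateral-contralateral difference
#'
#' Pools the ischemic-core ROI voxels across all lesion-bearing slices,
#' mirrors the ROI across the midline to define the contralateral reference,
#' and returns the mean T2 of each side (valid voxels only) together with
#' their difference, the vasogenic-edema readout.
#'
#' @param map A `t2_map` from [fit_t2_map()].
#' @param roi Either a [label_mask()] containing a `roi_ischemic` region or
#'   an integer voxel-index matrix (columns `x`, `y`, `slice`).
#' @param midline_x Midline voxel coordinate; defaults to the mask's midline
#'   (or the volume centre when a bare voxel matrix is given).
#' @return A one-row tibble: `t2_ipsi`, `t2_contra`, `delta_t2` (ms, equal to
#'   `t2_ipsi - t2_contra`), `n_voxels_ipsi`, `n_voxels_contra` (valid-voxel
#'   counts).
#' @export
roi_delta_t2 <- function(map, roi, midline_x = NULL) {
  stopifnot(inherits(map, "t2_map"))
  dims <- dim(map$t2)
  if (inherits(roi, "label_mask")) {
    if (is.null(midline_x)) midline_x <- roi$midline_x
    roi <- region_voxels(roi, "roi_ischemic")
  } else {
    roi <- as.matrix(roi)
  }
  if (is.null(midline_x)) midline_x <- (dims[1L] + 1) / 2
  if (nrow(roi) == 0L) {
    abort("Ischemic ROI is empty.", class = "strokevol_validation_error")
  }
  contra <- mirror_roi(roi, midline_x, dims[1L])

  lin <- function(v) v[, 1L] + (v[, 2L] - 1L) * dims[1L] +
    (v[, 3L] - 1L) * dims[1L] * dims[2L]
  side_mean <- function(vox, side) {
    idx <- lin(vox)
    ok <- map$valid[idx]
    if (!any(ok)) {
      abort(paste0("No valid T2 fits in the ", side, " ROI."),
            class = "strokevol_validation_error")
    }
    c(mean(map$t2[idx][ok]), sum(ok))
  }
  ipsi <- side_mean(roi, "ipsilateral")
  contra_m <- side_mean(contra, "contralateral")
  tibble::tibble(
    t2_ipsi = ipsi[1], t2_contra = contra_m[1],
    delta_t2 = ipsi[1] - contra_m[1],
    n_voxels_ipsi = as.integer(ipsi[2]),
    n_voxels_contra = as.integer(contra_m[2]))
}
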