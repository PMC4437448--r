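# broom-style tidiers for the voxel containers.

#' Tidy a T2 map into a long voxel table
#'
#' @param x A `t2_map` from [fit_t2_map()].
#' @param valid_only Keep only voxels with a valid fit (default `TRUE`).
#' @param ... Unused.
#' @return Tibble with `x`, `y`, `slice`, `t2`, `s0`, `r_squared`, `valid`.
#' @exportS3Method generics::tidy
tidy.t2_map <- function(x, valid_only = TRUE, ...) {
  map <- x
  d <- dim(map$t2)
  out <- tibble::tibble(
    x = rep(seq_len(d[1]), times = d[2] * d[3]),
    y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    slice = rep(seq_len(d[3]), each = d[1] * d[2]),
    t2 = as.vector(map$t2), s0 = as.vector(map$s0),
    r_squared = as.vector(map$r_squared), valid = as.vector(map$valid))
  if (valid_only) out <- dplyr::filter(out, .data$valid)
  out
}

#' One-row summary of a T2 map fit
#'
#' @param x A `t2_map`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `n_voxels`, `n_valid`, `frac_valid`,
#'   `t2_median`, `r_squared_median` (valid voxels).
#' @exportS3Method generics::glance
glance.t2_map <- function(x, ...) {
  ok <- x$valid
  tibble::tibble(
    method = x$method,
    n_voxels = length(ok), n_valid = sum(ok),
    frac_valid = mean(ok),
    t2_median = if (any(ok)) stats::median(x$t2[ok]) else NA_real_,
    r_squared_median = if (any(ok)) stats::median(x$r_squared[ok]) else NA_real_)
}

#' Region voxel counts and volumes of a label mask
#'
#' @param x A [label_mask()].
#' @param ... Unused.
#' @return Tibble with `region`, `n_voxels`, `volume_mm3` (NA without
#'   geometry). Counts use the hierarchical region semantics of
#'   [region_mask()].
#' @exportS3Method generics::tidy
tidy.label_mask <- function(x, ...) {
  vv <- if (!is.null(x$geometry)) voxel_volume(x$geometry) else NA_real_
  purrr::map(names(x$legend), function(r) {
    n <- sum(x$labels %in% region_label_codes(x$legend, r))
    tibble::tibble(region = r, n_voxels = n, volume_mm3 = n * vv)
  }) |> purrr::list_rbind()
}
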