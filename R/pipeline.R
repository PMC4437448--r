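# End-to-end per-animal and per-cohort analysis: T2 mapping + ROI delta-T2,
# volumetry with edema correction, midline shift, one tidy row per animal.

#' Analyze one animal
#'
#' Runs the full single-animal pipeline: fits the T2 map, extracts the
#' ischemic-core vs mirrored-contralateral T2 relaxation times, computes
#' hemispheric/lesion volumetry with and without edema correction, and the
#' midline shift from the landmark records.
#'
#' @param image An [echo_train_image()].
#' @param mask A [label_mask()] with hemispheres, lesion and ischemic ROI.
#' @param landmarks Landmark tibble (see [read_landmarks()]), or `NULL` to
#'   skip midline-shift quantification.
#' @param method T2 fitting method, see [fit_t2_map()].
#' @param midline_x Midline voxel coordinate used to mirror the ROI;
#'   defaults to the mask's midline.
#' @param ... Further arguments passed to [fit_t2_map()].
#' @return A one-row tibble with the volumetry columns of
#'   [volumetry_for_animal()] plus `t2_ipsi`, `t2_contra`, `delta_t2`,
#'   `n_voxels_ipsi`, `n_voxels_contra`.
#' @export
analyze_animal <- function(image, mask, landmarks = NULL,
                           method = c("log_linear", "nonlinear"),
                           midline_x = NULL, ...) {
  method <- match.arg(method)
  vol <- volumetry_for_animal(mask, landmarks = landmarks)
  map <- fit_t2_map(image, method = method, ...)
  t2res <- roi_delta_t2(map, mask, midline_x = midline_x)
  dplyr::bind_cols(vol, t2res)
}

#' Analyze a whole cohort
#'
#' Applies [analyze_animal()] to every animal of a cohort and returns the
#' per-animal results table that [compare_cohort()] consumes. Accepts either
#' a manifest tibble (file-based cohort, see [read_manifest()]) or the
#' in-memory result of [generate_cohort()].
#'
#' @param cohort A manifest tibble or an in-memory cohort list with a
#'   `phantoms` element.
#' @param ... Passed to [analyze_animal()] (e.g. `method`).
#' @return Tibble with one row per animal: `animal_id`, `group`, then all
#'   [analyze_animal()] columns.
#' @export
analyze_cohort <- function(cohort, ...) {
  if (is.data.frame(cohort)) {
    rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
      r <- cohort[i, ]
      image <- read_echo_train(r$image_path, r$meta_path)
      mask <- read_label_mask(r$mask_path, geometry = image$geometry)
      landmarks <- read_landmarks(r$landmark_path)
      dplyr::bind_cols(
        tibble::tibble(animal_id = r$animal_id, group = r$group),
        analyze_animal(image, mask, landmarks, ...))
    })
  } else if (is.list(cohort) && !is.null(cohort$phantoms)) {
    rows <- purrr::imap(cohort$phantoms, function(ph, id) {
      grp <- cohort$params$group[match(id, cohort$params$animal_id)]
      dplyr::bind_cols(
        tibble::tibble(animal_id = id, group = grp),
        analyze_animal(ph$image, ph$truth$mask, ph$truth$landmarks, ...))
    })
  } else {
    abort("`cohort` must be a manifest tibble or an in-memory generated cohort.",
          class = "strokevol_validation_error")
  }
  purrr::list_rbind(unname(rows))
}
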