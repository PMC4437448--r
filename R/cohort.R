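# Whole-cohort simulation: two treatment groups with per-animal phantom
# parameters drawn from truncated-normal group distributions, written to
# disk via the io layer (NIfTI + TSV) or kept in memory.

#' Specification of a simulated two-group cohort
#'
#' @param n_per_group Animals per group (>= 2; default 8, the usual MCAO
#'   study size).
#' @param group_params Named list of exactly two groups. Each group is a
#'   list with elements `lesion_fraction`, `swelling_factor` and `delta_t2`,
#'   each a `c(mean, sd)` pair. `delta_t2` is the lesion-minus-tissue T2
#'   elevation in ms (the phantom's `t2_lesion` becomes
#'   `t2_tissue + delta_t2`). Draws are truncated to valid ranges
#'   (`lesion_fraction` in \[0.02, 0.6\], `swelling_factor` in \[0, 0.35\],
#'   `delta_t2` in \[1, 80\] ms).
#' @param base A [phantom_spec()] used as the template for every animal.
#' @param master_seed Integer seed; per-animal seeds are derived from it
#'   deterministically, so identical master seeds give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 8L,
                        group_params = list(
                          treatment = list(lesion_fraction = c(0.33, 0.15),
                                           swelling_factor = c(0.09, 0.05),
                                           delta_t2 = c(19.5, 9.7)),
                          control = list(lesion_fraction = c(0.17, 0.09),
                                         swelling_factor = c(0.035, 0.02),
                                         delta_t2 = c(9.2, 5.2))),
                        base = phantom_spec(), master_seed = 1L) {
  if (n_per_group < 2L) {
    abort("`n_per_group` must be >= 2.", class = "strokevol_validation_error")
  }
  if (length(group_params) != 2L || is.null(names(group_params))) {
    abort("`group_params` must name exactly two groups.",
          class = "strokevol_validation_error")
  }
  for (g in group_params) {
    if (!all(c("lesion_fraction", "swelling_factor", "delta_t2") %in% names(g))) {
      abort("Each group needs lesion_fraction, swelling_factor and delta_t2 as c(mean, sd).",
            class = "strokevol_validation_error")
    }
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 group_params = group_params, base = base,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Paper-like cohort preset
#'
#' A convenience [cohort_spec()] qualitatively emulating a two-arm MCAO MRI
#' study: n = 8 per group, 12-echo train at TE 18-216 ms, 8 slices of 2 mm,
#' and a treatment arm with larger lesion fraction, more swelling and a
#' higher lesion T2 elevation than the control arm. The group means/SDs are
#' plausible-scale choices, not estimates of any real cohort.
#'
#' @param master_seed Integer master seed.
#' @param ... Overrides passed to [phantom_spec()] for the template phantom.
#' @return A `cohort_spec`.
#' @export
paperlike_cohort_defaults <- function(master_seed = 1L, ...) {
  cohort_spec(n_per_group = 8L, base = phantom_spec(...),
              master_seed = master_seed)
}

# deterministic per-animal seed from the master seed (exact in doubles,
# result < 2^31)
derive_seed <- function(master_seed, index) {
  m <- 2147483629
  h <- ((as.double(master_seed) %% m) * 65537 + index * 104729) %% m
  as.integer(h)
}

rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd <= 0) return(min(max(mean, lower), upper))
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' Draw per-animal phantom parameters for a cohort
#'
#' Samples each animal's lesion fraction, swelling factor and lesion T2
#' elevation from its group's truncated-normal distribution. Deterministic
#' in `master_seed`.
#'
#' @param cohort A [cohort_spec()].
#' @return Tibble with one row per animal: `animal_id`, `group`, `seed`,
#'   `lesion_fraction`, `swelling_factor`, `delta_t2`.
#' @export
draw_cohort_params <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  groups <- names(cohort$group_params)
  with_seed(cohort$master_seed, {
    idx <- 0L
    purrr::map(groups, function(g) {
      par <- cohort$group_params[[g]]
      purrr::map(seq_len(cohort$n_per_group), function(i) {
        idx <<- idx + 1L
        tibble::tibble(
          animal_id = sprintf("%s_%02d", g, i),
          group = g,
          seed = derive_seed(cohort$master_seed, idx),
          lesion_fraction = rtruncnorm1(par$lesion_fraction[1],
                                        par$lesion_fraction[2], 0.02, 0.6),
          swelling_factor = rtruncnorm1(par$swelling_factor[1],
                                        par$swelling_factor[2], 0, 0.35),
          delta_t2 = rtruncnorm1(par$delta_t2[1], par$delta_t2[2], 1, 80))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
}

#' Generate a whole synthetic cohort
#'
#' Draws per-animal parameters with [draw_cohort_params()], renders each
#' phantom, and either returns everything in memory or writes the standard
#' file layout (per-animal NIfTI image + JSON sidecar, NIfTI mask, landmark
#' TSV, plus `manifest.tsv` and `truth.tsv`) under `out_dir`.
#'
#' @param cohort A [cohort_spec()].
#' @param out_dir Output directory, or `NULL` (default) to keep the cohort
#'   in memory.
#' @return A list with `params` (the drawn parameter tibble), `truth` (one
#'   row per animal: drawn parameters joined with the phantom truth), and
#'   either `phantoms` (named list of [generate_phantom()] results; in-memory
#'   mode) or `manifest` (tibble of file paths, also written as
#'   `manifest.tsv`).
#' @export
generate_cohort <- function(cohort, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  params <- draw_cohort_params(cohort)
  write_files <- !is.null(out_dir)
  if (write_files) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  phantoms <- list()
  truth_rows <- list()
  manifest_rows <- list()
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    spec <- cohort$base
    spec$lesion_fraction <- p$lesion_fraction
    spec$swelling_factor <- p$swelling_factor
    spec$midline_displacement <- NULL
    spec$t2_lesion <- spec$t2_tissue + p$delta_t2
    spec$seed <- p$seed
    ph <- generate_phantom(spec)
    truth_rows[[i]] <- dplyr::bind_cols(p, ph$truth$truth)
    if (write_files) {
      stem <- file.path(out_dir, p$animal_id)
      write_echo_train(ph$image, paste0(stem, ".nii"), paste0(stem, ".json"))
      write_label_mask(ph$truth$mask, paste0(stem, "_mask.nii"))
      write_landmarks(ph$truth$landmarks, paste0(stem, "_landmarks.tsv"))
      manifest_rows[[i]] <- tibble::tibble(
        animal_id = p$animal_id, group = p$group,
        image_path = paste0(p$animal_id, ".nii"),
        meta_path = paste0(p$animal_id, ".json"),
        mask_path = paste0(p$animal_id, "_mask.nii"),
        landmark_path = paste0(p$animal_id, "_landmarks.tsv"))
    } else {
      phantoms[[p$animal_id]] <- ph
    }
  }
  truth <- purrr::list_rbind(truth_rows)
  out <- list(params = params, truth = truth)
  if (write_files) {
    manifest <- purrr::list_rbind(manifest_rows)
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
    out$manifest <- read_manifest(file.path(out_dir, "manifest.tsv"))
  } else {
    out$phantoms <- phantoms
  }
  out
}
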