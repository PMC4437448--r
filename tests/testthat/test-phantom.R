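# Synthetic phantom and cohort generation: geometry, determinism, truth
# bookkeeping.

test_that("zero swelling gives symmetric hemispheres and no midline shift", {
  ph <- generate_phantom(phantom_spec(matrix = 64L, n_slices = 4L,
                                      noise_model = "none",
                                      swelling_factor = 0))
  tr <- ph$truth$truth
  vv <- voxel_volume(ph$truth$mask$geometry)
  expect_lt(abs(tr$true_hv_i - tr$true_hv_c), max(vv, 0.02 * tr$true_hv_c))
  expect_equal(tr$true_mls, 0)
  mls <- midline_shift(ph$truth$landmarks)
  expect_lt(abs(mls$mls_mm), ph$truth$mask$geometry$in_plane_spacing)
})

test_that("noiseless decay is exactly mono-exponential everywhere", {
  ph <- small_phantom()
  te <- ph$image$echo_times
  idx <- region_voxels(ph$truth$mask, "lesion")[1, ]
  sig <- ph$image$voxels[idx[1], idx[2], idx[3], ]
  t2 <- ph$truth$t2_field[idx[1], idx[2], idx[3]]
  s0 <- ph$truth$s0_field[idx[1], idx[2], idx[3]]
  expect_equal(sig, s0 * exp(-te / t2), tolerance = 1e-12)
  # background voxels carry zero signal
  bg <- which(ph$truth$mask$labels == 0L, arr.ind = TRUE)[1, ]
  expect_equal(ph$image$voxels[bg[1], bg[2], bg[3], ], rep(0, length(te)))
})

test_that("lesion fraction and swelling are hit within voxelization error", {
  ph <- generate_phantom(phantom_spec(lesion_fraction = 0.25,
                                      swelling_factor = 0.12,
                                      noise_model = "none"))
  tr <- ph$truth$truth
  expect_lt(abs(tr$lesion_fraction_achieved - 0.25) / 0.25, 0.02)
  expect_lt(abs(tr$swelling_achieved - 0.12), 0.025)
  # lesion is a subset of the ipsilateral hemisphere by construction
  lesion <- region_mask(ph$truth$mask, "lesion")
  ipsi <- region_mask(ph$truth$mask, "hemisphere_ipsi")
  expect_true(all(ipsi[lesion]))
})

test_that("identical seeds give bit-identical phantoms; different seeds differ", {
  spec <- phantom_spec(matrix = 32L, n_slices = 2L, seed = 9L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$truth$mask$labels, b$truth$mask$labels)
  spec$seed <- 10L
  c <- generate_phantom(spec)
  expect_false(identical(a$image$voxels, c$image$voxels))
})

test_that("infeasible geometry is rejected", {
  expect_error(phantom_spec(lesion_fraction = 1.2),
               class = "strokevol_validation_error")
  expect_error(phantom_spec(t2_lesion = 2000),
               class = "strokevol_validation_error")
  expect_error(
    generate_phantom(phantom_spec(fov = 10, hemisphere_volume = 550)),
    class = "strokevol_validation_error")
})

test_that("mask perturbation dilates and erodes the lesion boundary", {
  ph <- small_phantom(lesion_fraction = 0.15)
  n0 <- sum(region_mask(ph$truth$mask, "lesion"))
  grown <- perturb_mask(ph$truth$mask, 1)
  shrunk <- perturb_mask(ph$truth$mask, -1)
  expect_gt(sum(region_mask(grown, "lesion")), n0)
  expect_lt(sum(region_mask(shrunk, "lesion")), n0)
  # hemispheric envelope unchanged
  expect_equal(sum(region_mask(grown, "hemisphere_ipsi")),
               sum(region_mask(ph$truth$mask, "hemisphere_ipsi")))
})

test_that("cohort draws are deterministic and respect group distributions", {
  spec <- cohort_spec(n_per_group = 4L,
                      base = phantom_spec(matrix = 32L, n_slices = 2L),
                      master_seed = 123L)
  p1 <- draw_cohort_params(spec)
  p2 <- draw_cohort_params(spec)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 8)
  expect_true(all(table(p1$group) == 4))
  expect_false(anyDuplicated(p1$animal_id) > 0)

  # degenerate SDs: all animals in a group identical
  degen <- cohort_spec(
    n_per_group = 3L,
    group_params = list(
      treatment = list(lesion_fraction = c(0.3, 0), swelling_factor = c(0.1, 0),
                       delta_t2 = c(20, 0)),
      control = list(lesion_fraction = c(0.15, 0), swelling_factor = c(0.05, 0),
                     delta_t2 = c(9, 0))),
    base = phantom_spec(matrix = 32L, n_slices = 2L))
  pd <- draw_cohort_params(degen)
  expect_equal(length(unique(pd$lesion_fraction[pd$group == "treatment"])), 1)

  # law of large numbers: sample mean within 3 SE of the group mean
  big <- cohort_spec(n_per_group = 100L, master_seed = 7L)
  pb <- draw_cohort_params(big)
  trt <- pb$lesion_fraction[pb$group == "treatment"]
  expect_lt(abs(mean(trt) - 0.33), 3 * 0.15 / sqrt(100) + 0.02)
})

test_that("cohort file round trip: write, read manifest, reanalyze", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_per_group = 2L,
                      base = phantom_spec(matrix = 32L, n_slices = 2L,
                                          noise_model = "none"),
                      master_seed = 5L)
  gen <- generate_cohort(spec, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_equal(nrow(gen$manifest), 4)

  # identical master seed -> identical truth table
  dir2 <- withr::local_tempdir()
  gen2 <- generate_cohort(spec, out_dir = dir2)
  expect_equal(as.data.frame(gen$truth), as.data.frame(gen2$truth))

  res <- analyze_cohort(gen$manifest)
  expect_equal(nrow(res), 4)
  joined <- dplyr::left_join(res, gen$truth, by = "animal_id")
  expect_equal(joined$hv_c, joined$true_hv_c)
  expect_equal(joined$lv, joined$true_lv)
})

test_that("paper-like preset encodes the acquisition and study design", {
  spec <- paperlike_cohort_defaults()
  expect_equal(spec$n_per_group, 8L)
  expect_equal(spec$base$echo_times, seq(18, 216, by = 18))
  expect_equal(spec$base$n_slices, 8L)
  expect_equal(spec$base$slice_thickness, 2)
  expect_equal(spec$base$slice_gap, 0)
  trt <- spec$group_params$treatment
  ctl <- spec$group_params$control
  expect_gt(trt$lesion_fraction[1], ctl$lesion_fraction[1])
  expect_gt(trt$swelling_factor[1], ctl$swelling_factor[1])
  expect_gt(trt$delta_t2[1], ctl$delta_t2[1])
})
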