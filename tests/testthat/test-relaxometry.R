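# Mono-exponential T2 fitting, ROI mirroring and the ipsi-contra delta-T2.

test_that("both fit methods recover noiseless decays to machine precision", {
  te <- paper_echo_times
  for (method in c("log_linear", "nonlinear")) {
    fit <- fit_t2_voxel(1000 * exp(-te / 50), te, method = method)
    expect_true(fit$valid)
    expect_equal(fit$t2, 50, tolerance = 1e-9)
    expect_equal(fit$s0, 1000, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
  # sweep of T2 values: relative error < 1e-6 (noiseless recovery property)
  for (t2 in c(20, 40, 65, 90, 200)) {
    for (method in c("log_linear", "nonlinear")) {
      fit <- fit_t2_voxel(800 * exp(-te / t2), te, method = method)
      expect_lt(abs(fit$t2 - t2) / t2, 1e-6)
    }
  }
})

test_that("degenerate signals give valid = FALSE, not errors", {
  te <- paper_echo_times
  expect_false(fit_t2_voxel(rep(0, 12), te)$valid)
  expect_false(fit_t2_voxel(rep(5, 12), te, noise_floor = 10)$valid)
  # two usable echoes only
  sig <- c(100, 50, rep(0, 10))
  expect_false(fit_t2_voxel(sig, te)$valid)
  # increasing signal (non-physical, positive slope)
  expect_false(fit_t2_voxel(seq(100, 1200, length.out = 12), te)$valid)
  # T2 outside the plausibility bounds
  expect_false(fit_t2_voxel(1000 * exp(-te / 5000), te)$valid)
})

test_that("log-linear estimate equals the closed-form weighted regression", {
  te <- paper_echo_times
  # fixed perturbation, not tuned: deterministic noise vector
  withr::with_seed(42, noise <- rnorm(12, sd = 5))
  sig <- pmax(800 * exp(-te / 65) + noise, 1)
  fit <- fit_t2_voxel(sig, te, method = "log_linear")
  # independent oracle: weighted least squares of ln S on TE via lm's QR path
  oracle <- stats::lm(log(sig) ~ te, weights = sig^2)
  expect_equal(fit$t2, -1 / unname(coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(fit$s0, exp(unname(coef(oracle)[1])), tolerance = 1e-10)
})

test_that("fit_t2_map equals the voxel-by-voxel loop exactly", {
  withr::with_seed(7, {
    te <- paper_echo_times
    dims <- c(8L, 8L, 2L)
    t2s <- array(runif(prod(dims), 30, 90), dims)
    s0s <- array(runif(prod(dims), 500, 1500), dims)
    vox <- array(0, c(dims, 12L))
    for (e in seq_len(12L)) vox[, , , e] <- s0s * exp(-te[e] / t2s)
    vox <- vox * array(exp(rnorm(length(vox), sd = 0.01)), dim(vox))
  })
  img <- echo_train_image(vox, te, voxel_geometry(0.3, 2))
  map <- fit_t2_map(img, method = "log_linear")
  for (i in sample(prod(dims), 20)) {
    idx <- arrayInd(i, dims)
    ref <- fit_t2_voxel(vox[idx[1], idx[2], idx[3], ], te)
    expect_identical(map$t2[i], ref$t2)
    expect_identical(map$s0[i], ref$s0)
    expect_identical(map$r_squared[i], ref$r_squared)
  }
  # uniform phantom: map constant at truth; background all invalid
  uni <- array(0, c(4, 4, 2, 12))
  for (e in seq_len(12)) uni[2:3, 2:3, , e] <- 700 * exp(-te[e] / 55)
  umap <- fit_t2_map(echo_train_image(uni, te, voxel_geometry(0.3, 2)))
  expect_equal(unname(umap$t2[2:3, 2:3, ]), array(55, c(2, 2, 2)),
               tolerance = 1e-9)
  expect_false(any(umap$valid[1, , ]))
})

test_that("mirror_roi reflects, is an involution, and checks its preconditions", {
  roi <- cbind(x = 21L, y = 5L, slice = 1L)
  mirrored <- mirror_roi(roi, midline_x = 16, nx = 32L)
  expect_equal(mirrored[, "x"], c(x = 11L))  # 16 + 5 -> 16 - 5

  withr::with_seed(3, {
    roi2 <- cbind(x = sample(20:30, 8, replace = TRUE),
                  y = sample(1:10, 8, replace = TRUE),
                  slice = sample(1:3, 8, replace = TRUE))
  })
  twice <- mirror_roi(mirror_roi(roi2, 16, 40L), 16, 40L)
  expect_equal(unname(twice[order(twice[, 1], twice[, 2], twice[, 3]), ]),
               unname(roi2[order(roi2[, 1], roi2[, 2], roi2[, 3]), ]))
  # fully in-bounds reflection preserves the voxel count
  expect_equal(nrow(mirror_roi(roi2, 16, 40L)), nrow(roi2))

  straddle <- cbind(x = c(10L, 20L), y = 1L, slice = 1L)
  expect_error(mirror_roi(straddle, 16, 32L),
               class = "strokevol_validation_error")
  outside <- cbind(x = 30L, y = 1L, slice = 1L)
  expect_error(mirror_roi(outside, 2, 8L),
               class = "strokevol_validation_error")
})

test_that("roi_delta_t2 measures the ipsi-contra difference and is antisymmetric", {
  ph <- small_phantom()
  map <- fit_t2_map(ph$image)
  res <- roi_delta_t2(map, ph$truth$mask)
  expect_equal(res$delta_t2, res$t2_ipsi - res$t2_contra)
  expect_equal(res$delta_t2, ph$truth$truth$true_delta_t2, tolerance = 1e-6)
  expect_gt(res$n_voxels_ipsi, 0)

  # symmetric input: identical tissue both sides -> delta 0
  sym <- generate_phantom(phantom_spec(matrix = 48L, n_slices = 4L,
                                       noise_model = "none",
                                       t2_lesion = 50, s0_lesion = 1000))
  sym_map <- fit_t2_map(sym$image)
  expect_equal(roi_delta_t2(sym_map, sym$truth$mask)$delta_t2, 0,
               tolerance = 1e-9)

  # antisymmetry: mirroring the ROI to the other side flips the sign
  roi <- region_voxels(ph$truth$mask, "roi_ischemic")
  mid <- ph$truth$mask$midline_x
  swapped <- roi_delta_t2(map, mirror_roi(roi, mid, dim(map$t2)[1]),
                          midline_x = mid)
  expect_equal(swapped$delta_t2, -res$delta_t2, tolerance = 1e-9)
})

test_that("noisy-phantom delta-T2 lands within 2 ms of truth across seeds", {
  errs <- vapply(1:8, function(s) {
    ph <- generate_phantom(phantom_spec(matrix = 48L, n_slices = 4L,
                                        noise_model = "rician", snr = 50,
                                        seed = s))
    map <- fit_t2_map(ph$image, noise_floor = 60)
    roi_delta_t2(map, ph$truth$mask)$delta_t2 - ph$truth$truth$true_delta_t2
  }, numeric(1))
  expect_lt(max(abs(errs)), 2)
})
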