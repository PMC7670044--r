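test_that("seed extraction averages the clipped voxel neighborhood", {
  grid <- voxel_grid(c(6, 6, 6))
  im <- structure(list(values = array(5, c(4, 2, grid$n_voxels)),
                       conditions = c("A", "B"), subjects = 1:4,
                       grid = grid),
                  class = "condition_images")
  # constant image -> seed value is the constant
  sa <- extract_seed_values(im, seed_spec(c(0, 0, 0)))
  expect_true(all(sa$values == 5))
  # interior seed: full 27-voxel cube
  ctr <- vox_to_mm(grid, c(3, 3, 3))[1, ]
  expect_length(extract_seed_values(im, seed_spec(ctr))$voxels, 27)
  # corner seed: clipped to 8 voxels, matching explicit index enumeration
  corner_mm <- vox_to_mm(grid, c(0, 0, 0))[1, ]
  nb <- seed_neighborhood(grid, corner_mm, 1)
  expect_length(nb, 8)
  ijk <- expand.grid(0:1, 0:1, 0:1)
  expect_equal(sort(nb),
               sort(1 + ijk[, 1] + 6 * (ijk[, 2] + 6 * ijk[, 3])))
  # seed centers outside the volume are rejected
  expect_error(seed_neighborhood(grid, c(100, 0, 0)), "outside")
})

test_that("timeseries seed extraction averages window peak timepoints", {
  grid <- voxel_grid(c(4, 4, 4))
  # subjects x conditions x 8 timepoints x voxels; value = timepoint index
  ts <- array(rep(1:8, each = 2 * 2), c(2, 2, 8, grid$n_voxels))
  for (t in 1:8) ts[, , t, ] <- t
  sa <- extract_seed_values(ts, seed_spec(c(0, 0, 0)), grid = grid,
                            peak_timepoints = 3:5)
  expect_true(all(sa$values == 4))
  expect_equal(sa$provenance, "timeseries")
})

test_that("correlation maps match a brute-force Pearson oracle", {
  im <- noise_images(n_subjects = 12, n_voxels = 30, seed = 7)
  grid <- im$grid
  sa <- extract_seed_values(im, seed_spec(vox_to_mm(grid, c(5, 0, 0))[1, ]))
  cm <- seed_correlation_maps(sa, im)
  for (ci in 1:2) for (v in seq_len(30)) {
    expect_equal(unname(cm[ci, v]),
                 cor(unname(sa$values[, ci]), im$values[, ci, v]),
                 tolerance = 1e-12)
  }
  expect_true(all(cm >= -1 & cm <= 1))
  # a voxel identical to the seed value correlates exactly 1
  im2 <- im
  im2$values[, 1, 3] <- sa$values[, 1]
  cm2 <- seed_correlation_maps(sa, im2)
  expect_equal(unname(cm2[1, 3]), 1, tolerance = 1e-12)
  # fewer than 3 subjects is an error
  im3 <- im
  im3$values <- im$values[1:2, , , drop = FALSE]
  expect_error(seed_correlation_maps(sa$values[1:2, , drop = FALSE], im3),
               "3 subjects")
})

test_that("zero-variance voxels give r = 0 with a warning", {
  im <- noise_images(n_subjects = 10, n_voxels = 10, seed = 8)
  im$values[, , 4] <- 1
  sa <- extract_seed_values(im, seed_spec(vox_to_mm(im$grid, c(0, 0, 0))[1, ]))
  expect_warning(cm <- seed_correlation_maps(sa, im), "zero-variance")
  expect_equal(unname(cm[, 4]), c(0, 0))
})

test_that("correlation maps are invariant to affine rescaling of the seed", {
  im <- noise_images(n_subjects = 15, n_voxels = 20, seed = 9)
  sa <- extract_seed_values(im, seed_spec(vox_to_mm(im$grid, c(2, 0, 0))[1, ]))
  cm1 <- seed_correlation_maps(sa, im)
  sa2 <- sa
  sa2$values <- 3.2 * sa$values + 17
  cm2 <- seed_correlation_maps(sa2, im)
  expect_equal(cm1, cm2, tolerance = 1e-12)
})

test_that("seed-PLS SVD follows the shared conventions", {
  # identical correlation rows -> rank 1, uniform task saliences
  cm <- matrix(rep(seq(-0.5, 0.5, length.out = 20), each = 3), 3, 20)
  rownames(cm) <- c("A", "B", "C")
  res <- seed_pls_svd(cm)
  expect_length(res$singular_values, 1)
  expect_equal(abs(res$task_saliences[, 1]), rep(1, 3) / sqrt(3),
               tolerance = 1e-10)
  # zero matrix -> no LVs; energy identity on a random matrix
  expect_length(seed_pls_svd(matrix(0, 2, 5))$singular_values, 0)
  set.seed(10)
  cm <- matrix(runif(4 * 30, -1, 1), 4, 30,
               dimnames = list(letters[1:4], NULL))
  res <- seed_pls_svd(cm)
  expect_equal(sum(res$singular_values^2), sum(cm^2), tolerance = 1e-10)
})

test_that("condition-specific coupling dominates the first seed LV", {
  grid <- voxel_grid(c(8, 8, 8))
  set.seed(11)
  coupled <- sample(seq_len(grid$n_voxels), 30)
  m <- planted_model(grid,
                     couplings = list(list(center_mm = c(0, 0, 0),
                                           coupled = coupled,
                                           r = c(0.8, 0), amplitude = 1)),
                     subject_sd = 0.1, noise_sd = 0.2)
  im <- simulate_condition_images(14, c("target", "nontarget"), m, seed = 12)
  res <- seed_pls(im, seed_spec(c(0, 0, 0)),
                  cfg = resampling_config(n_perm = 50, n_boot = 50,
                                          seed = 13))
  # LV1 task salience loads on the coupled (target) condition
  expect_gt(abs(res$task_saliences[1, 1]), abs(res$task_saliences[2, 1]))
  # the coupled voxels are flagged reliable by the bootstrap ratio
  expect_gt(mean(abs(res$bsr[coupled, 1]) > 3), 0.8)
  # and uncoupled voxels mostly are not
  others <- setdiff(seq_len(grid$n_voxels), c(coupled, res$seed$voxels))
  expect_lt(mean(abs(res$bsr[others, 1]) > 3), 0.2)
})
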