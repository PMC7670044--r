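test_that("noise-free planted LV gives exactly rank-1 centered means", {
  grid <- voxel_grid(c(5, 5, 5))
  u <- gaussian_blob(grid, c(0, 0, 0))
  m <- planted_model(grid,
                     lvs = list(list(amplitude = 2,
                                     task_profile = c(1, -1),
                                     spatial_map = u)),
                     subject_sd = 0, noise_sd = 0)
  im <- simulate_condition_images(6, c("A", "B"), m, seed = 1)
  M <- mean_center(build_datamat(im))
  d <- svd(M)$d
  expect_gt(d[1], 0)
  expect_lt(d[2] / d[1], 1e-12)
  # the centered rows are +- a/2 * v * u up to the planted normalization
  expect_equal(abs(M[1, ]), 2 * u / sqrt(2) / 2 * 2, tolerance = 1e-12)
})

test_that("null model has no condition structure", {
  im <- noise_images(n_subjects = 30, seed = 2)
  M <- mean_center(build_datamat(im))
  # condition means equal in expectation; singular values at noise floor
  expect_lt(svd(M)$d[1], 1.5)
  expect_lt(max(abs(colMeans(im$values[, 1, ]) - colMeans(im$values[, 2, ]))),
            1.5)
})

test_that("planted seed coupling yields the requested cross-subject correlation", {
  grid <- voxel_grid(c(8, 8, 8))
  set.seed(3)
  coupled <- sample(seq_len(grid$n_voxels), 25)
  m <- planted_model(grid,
                     couplings = list(list(center_mm = c(0, 0, 0),
                                           coupled = coupled,
                                           r = c(0.9, 0), amplitude = 1)),
                     subject_sd = 0.1, noise_sd = 0.2)
  im <- simulate_condition_images(200, c("A", "B"), m, seed = 4)
  sa <- extract_seed_values(im, seed_spec(c(0, 0, 0)))
  # the generator compensates its own noise, so the realized correlation
  # matches the requested r (bivariate-normal closed form, Monte Carlo)
  r_emp <- mean(vapply(coupled, function(v)
    cor(sa$values[, "A"], im$values[, "A", v]), numeric(1)))
  expect_lt(abs(r_emp - 0.9), 0.05)
  # uncoupled condition shows no correlation beyond sampling noise
  r_null <- mean(vapply(coupled, function(v)
    cor(sa$values[, "B"], im$values[, "B", v]), numeric(1)))
  expect_lt(abs(r_null), 0.1)
})

test_that("coupled voxels outside the grid are rejected", {
  grid <- voxel_grid(c(4, 4, 4))
  expect_error(planted_model(grid,
                             couplings = list(list(center_mm = c(0, 0, 0),
                                                   coupled = c(1, 65),
                                                   r = 0.5))),
               "outside")
})

test_that("condition selection builds the repetition and targetness sets", {
  grid <- voxel_grid(c(3, 3, 3))
  m <- planted_model(grid, subject_sd = 0, noise_sd = 0)
  im <- simulate_condition_images(4, standard_conditions(), m, seed = 5)
  # make values identifiable: value = condition index
  for (ci in 1:6) im$values[, ci, ] <- ci
  rep2 <- select_conditions(im, "repetition")
  expect_equal(rep2$conditions, c("hit_3x", "hit_1x"))
  expect_equal(unique(as.vector(rep2$values[, "hit_3x", ])), (1 + 4) / 2)
  expect_equal(unique(as.vector(rep2$values[, "hit_1x", ])), (2 + 5) / 2)
  tar2 <- select_conditions(im, "targetness")
  expect_equal(tar2$conditions, c("target", "nontarget"))
  expect_equal(unique(as.vector(tar2$values[, "target", ])), (2 + 6) / 2)
  expect_equal(unique(as.vector(tar2$values[, "nontarget", ])), (5 + 3) / 2)
  tar4 <- select_conditions(im, "targetness", "unpooled")
  expect_equal(dim(tar4$values)[2], 4L)
  expect_equal(attr(tar4, "grouping"), list(target = 1:2, nontarget = 3:4))
  expect_error(select_conditions(subset_conditions(im, "inc_old_cr"),
                                 "repetition"), "missing")
})

test_that("voxel grid affine round-trips and blobs are unit norm", {
  grid <- voxel_grid(c(10, 12, 8), voxel_mm = 2)
  ijk <- rbind(c(0, 0, 0), c(9, 11, 7), c(4, 5, 3))
  expect_equal(mm_to_vox(grid, vox_to_mm(grid, ijk)), ijk,
               tolerance = 1e-12, ignore_attr = TRUE)
  u <- gaussian_blob(grid, c(1, 1, 1), fwhm_mm = 6)
  expect_equal(sum(u^2), 1, tolerance = 1e-12)
  expect_equal(length(u), grid$n_voxels)
})
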