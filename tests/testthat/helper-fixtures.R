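# small design for fast structural tests: 2 runs x (4 1x + 4 3x + 8 new),
# pool of 32 words in 8 lists of 4
small_params <- function(n_subjects = 3L) {
  design_params(n_subjects = n_subjects, pool_size = 32L, n_lists = 8L,
                n_runs = 2L, n_1x = 4L, n_3x = 4L, n_new = 8L, n_null = 2L)
}

# condition images with a single planted LV and no couplings
planted_images <- function(n_subjects = 14, amplitude = 3, noise_sd = 0.2,
                           subject_sd = 0.1, conditions = c("A", "B"),
                           grid = voxel_grid(c(6, 6, 6)), seed = 1,
                           task_profile = NULL,
                           blob_center = c(2, 2, 2)) {
  if (is.null(task_profile)) {
    task_profile <- rep(0, length(conditions))
    task_profile[1] <- 1
    task_profile[2] <- -1
  }
  u <- gaussian_blob(grid, blob_center)
  m <- planted_model(grid,
                     lvs = list(list(amplitude = amplitude,
                                     task_profile = task_profile,
                                     spatial_map = u)),
                     subject_sd = subject_sd, noise_sd = noise_sd)
  im <- simulate_condition_images(n_subjects, conditions, m, seed = seed)
  attr(im, "u_true") <- u
  attr(im, "v_true") <- task_profile / sqrt(sum(task_profile^2))
  im
}

# pure-noise images (no planted structure)
noise_images <- function(n_subjects = 14, conditions = c("A", "B"),
                         n_voxels = 40, seed = 1) {
  grid <- voxel_grid(c(n_voxels, 1, 1))
  m <- planted_model(grid, subject_sd = 0.1, noise_sd = 1)
  simulate_condition_images(n_subjects, conditions, m, seed = seed)
}
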