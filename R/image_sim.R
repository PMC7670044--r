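#' Voxel grid with an affine index-to-mm mapping
#'
#' A regular 3-D grid with an invertible affine mapping 0-based voxel
#' indices (i, j, k) to mm coordinates in RAS+ convention. The default
#' affine is isotropic scaling plus an offset that centers the grid on the
#' origin, giving a synthetic MNI-like space.
#'
#' @param dim length-3 integer grid shape (nx, ny, nz).
#' @param voxel_mm isotropic voxel size in mm.
#' @param origin_mm mm coordinate of voxel (0,0,0); default centers the grid.
#' @return An object of class \code{voxel_grid}: list with \code{dim},
#'   \code{affine} (4 x 4), \code{voxel_mm} and \code{n_voxels}.
#' @export
voxel_grid <- function(dim = c(10L, 10L, 10L), voxel_mm = 2,
                       origin_mm = -voxel_mm * (dim - 1) / 2) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L), voxel_mm > 0)
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- origin_mm
  structure(list(dim = dim, affine = affine, voxel_mm = voxel_mm,
                 n_voxels = prod(dim)),
            class = "voxel_grid")
}

#' Convert voxel indices to mm coordinates (and back)
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @param ijk matrix (or vector) of 0-based voxel indices, one row per voxel.
#' @return A matrix of mm coordinates, one row per voxel.
#' @export
vox_to_mm <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' @rdname vox_to_mm
#' @param mm matrix (or vector) of mm coordinates.
#' @return For \code{mm_to_vox}, a matrix of (possibly fractional) 0-based
#'   voxel indices.
#' @export
mm_to_vox <- function(grid, mm) {
  mm <- matrix(mm, ncol = 3)
  t(solve(grid$affine) %*% rbind(t(mm), 1))[, 1:3, drop = FALSE]
}

# linear voxel index (1-based, column-major i fastest) <-> 0-based ijk
vox_linear <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  1L + ijk[, 1] + grid$dim[1] * (ijk[, 2] + grid$dim[2] * ijk[, 3])
}
linear_vox <- function(grid, idx) {
  arrayInd(idx, grid$dim) - 1L
}

#' Gaussian blob rasterized on a grid
#'
#' Isotropic Gaussian of the given FWHM centered at \code{center_mm},
#' evaluated at every voxel center and normalized to unit Euclidean norm.
#' Used as a planted spatial salience map with a well-defined local maximum.
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @param center_mm length-3 mm center.
#' @param fwhm_mm full width at half maximum in mm.
#' @return Numeric vector of length \code{grid$n_voxels}, unit norm.
#' @export
gaussian_blob <- function(grid, center_mm, fwhm_mm = 6) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  ijk <- linear_vox(grid, seq_len(grid$n_voxels))
  mm <- vox_to_mm(grid, ijk)
  d2 <- rowSums(sweep(mm, 2, center_mm)^2)
  u <- exp(-d2 / (2 * sigma^2))
  u / sqrt(sum(u^2))
}

#' Planted generative model for condition-level images
#'
#' Describes the ground truth behind a simulated subjects x conditions x
#' voxels data set: a grand-mean map, planted latent variables (each an
#' amplitude, a unit-norm task profile over conditions and a unit-norm
#' spatial map), optional seed couplings (a latent per-subject factor
#' injected into a seed neighborhood and, attenuated by a per-condition
#' correlation, into a coupled voxel set), voxelwise subject offsets shared
#' across conditions, and white Gaussian noise.
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @param grand_mean scalar or length-V vector baseline.
#' @param lvs list of planted LVs, each a list with \code{amplitude},
#'   \code{task_profile} (length k, normalized internally) and
#'   \code{spatial_map} (length V, normalized internally).
#' @param couplings list of planted seed couplings, each a list with
#'   \code{center_mm}, \code{coupled} (linear voxel indices),
#'   \code{r} (per-condition correlation, recycled over conditions),
#'   \code{amplitude} (SD of the latent factor's contribution) and
#'   optionally \code{neighborhood} (radius in voxels, default 1).
#' @param subject_sd SD of voxelwise subject offsets.
#' @param noise_sd SD of i.i.d. Gaussian noise.
#' @return An object of class \code{planted_model}.
#' @export
planted_model <- function(grid, grand_mean = 0, lvs = list(),
                          couplings = list(), subject_sd = 0.1,
                          noise_sd = 0.2) {
  norm1 <- function(x) {
    n <- sqrt(sum(x^2))
    if (n == 0) stop("planted vectors must be nonzero", call. = FALSE)
    x / n
  }
  lvs <- lapply(lvs, function(l) {
    stopifnot(l$amplitude >= 0)
    l$task_profile <- norm1(l$task_profile)
    l$spatial_map <- norm1(l$spatial_map)
    if (length(l$spatial_map) != grid$n_voxels)
      stop("spatial map length must match the grid", call. = FALSE)
    l
  })
  couplings <- lapply(couplings, function(cp) {
    if (any(abs(cp$r) > 1)) stop("|r| must be <= 1", call. = FALSE)
    if (is.null(cp$amplitude)) cp$amplitude <- 1
    if (is.null(cp$neighborhood)) cp$neighborhood <- 1L
    if (any(cp$coupled < 1 | cp$coupled > grid$n_voxels))
      stop("coupled voxels outside grid", call. = FALSE)
    cp
  })
  structure(list(grid = grid, grand_mean = grand_mean, lvs = lvs,
                 couplings = couplings, subject_sd = subject_sd,
                 noise_sd = noise_sd),
            class = "planted_model")
}

#' Simulate condition-level images for a cohort
#'
#' Generates \code{values[s, c, v] = grand_mean[v] + sum_l a_l v_l[c] u_l[v]
#' + subject_offset[s, v] + coupling terms + noise}. For each planted
#' coupling, a standard-normal latent factor \code{z[s, c]} is added (times
#' the coupling amplitude) to the seed neighborhood, and the correlated
#' factor \code{r_c z[s, c] + sqrt(1 - r_c^2) w[s, c]} to each coupled
#' voxel, planting a cross-subject seed-voxel correlation of about
#' \code{r_c} within condition \code{c}.
#'
#' @param n_subjects number of subjects.
#' @param conditions character vector of condition labels.
#' @param model a \code{\link{planted_model}}.
#' @param seed optional integer seed.
#' @return An object of class \code{condition_images}: list with
#'   \code{values} (array subjects x conditions x voxels), \code{conditions},
#'   \code{subjects}, \code{grid}.
#' @export
simulate_condition_images <- function(n_subjects, conditions, model,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- model$grid
  k <- length(conditions); V <- grid$n_voxels
  stopifnot(anyDuplicated(conditions) == 0L)
  X <- array(0, dim = c(n_subjects, k, V),
             dimnames = list(NULL, conditions, NULL))
  base <- rep_len(model$grand_mean, V)
  for (s in seq_len(n_subjects)) X[s, , ] <- rep(base, each = k)

  for (l in model$lvs) {
    if (length(l$task_profile) != k)
      stop("planted task profile length must equal the condition count",
           call. = FALSE)
    contrib <- l$amplitude * outer(l$task_profile, l$spatial_map)
    for (s in seq_len(n_subjects)) X[s, , ] <- X[s, , ] + contrib
  }

  if (model$subject_sd > 0) {
    off <- matrix(stats::rnorm(n_subjects * V, 0, model$subject_sd),
                  n_subjects, V)
    for (s in seq_len(n_subjects)) X[s, , ] <- X[s, , ] +
        rep(off[s, ], each = k)
  }

  for (cp in model$couplings) {
    nb <- seed_neighborhood(grid, cp$center_mm, cp$neighborhood)
    r <- rep_len(cp$r, k)
    # compensate for the attenuation from measurement noise and subject
    # offsets so the realized cross-subject correlation between the seed
    # neighborhood average and a coupled voxel is r, not a diluted value
    s2 <- model$noise_sd^2 + model$subject_sd^2
    a2 <- cp$amplitude^2
    infl <- sqrt((a2 + s2) * (a2 + s2 / length(nb))) / a2
    r_adj <- r * infl
    if (any(abs(r_adj) > 1)) {
      warning("coupling r not attainable at this noise level; clamped",
              call. = FALSE)
      r_adj <- pmin(pmax(r_adj, -1), 1)
    }
    z <- matrix(stats::rnorm(n_subjects * k), n_subjects, k)
    w <- matrix(stats::rnorm(n_subjects * k), n_subjects, k)
    zc <- sweep(z, 2, r_adj, `*`) + sweep(w, 2, sqrt(1 - r_adj^2), `*`)
    for (s in seq_len(n_subjects)) {
      X[s, , nb] <- X[s, , nb] + cp$amplitude * z[s, ]
      X[s, , cp$coupled] <- X[s, , cp$coupled] + cp$amplitude * zc[s, ]
    }
  }

  if (model$noise_sd > 0)
    X <- X + array(stats::rnorm(length(X), 0, model$noise_sd), dim = dim(X))

  structure(list(values = X, conditions = conditions,
                 subjects = seq_len(n_subjects), grid = grid),
            class = "condition_images")
}

#' Standard six trial types of the payoff design
#'
#' The modeled conditions: 3x hits, 1x hits and correct rejections, crossed
#' with incentivize-old and incentivize-new runs.
#' @return Character vector of length 6.
#' @export
standard_conditions <- function() {
  c("inc_old_3x_hit", "inc_old_1x_hit", "inc_old_cr",
    "inc_new_3x_hit", "inc_new_1x_hit", "inc_new_cr")
}

#' Restrict a condition image set to a subset of conditions
#'
#' @param images a \code{condition_images}.
#' @param conditions conditions to keep, in the requested order.
#' @return A \code{condition_images}.
#' @export
subset_conditions <- function(images, conditions) {
  idx <- match(conditions, images$conditions)
  if (anyNA(idx))
    stop("conditions missing: ",
         paste(conditions[is.na(idx)], collapse = ", "), call. = FALSE)
  structure(list(values = images$values[, idx, , drop = FALSE],
                 conditions = conditions, subjects = images$subjects,
                 grid = images$grid),
            class = "condition_images")
}

avg_conditions <- function(images, groups) {
  # average named condition subsets into new conditions
  X <- images$values
  out <- array(0, dim = c(dim(X)[1], length(groups), dim(X)[3]),
               dimnames = list(NULL, names(groups), NULL))
  for (g in seq_along(groups)) {
    idx <- match(groups[[g]], images$conditions)
    if (anyNA(idx)) stop("conditions missing: ",
                         paste(groups[[g]][is.na(idx)], collapse = ", "),
                         call. = FALSE)
    sub <- X[, idx, , drop = FALSE]
    out[, g, ] <- apply(sub, c(1, 3), mean)
  }
  structure(list(values = out, conditions = names(groups),
                 subjects = images$subjects, grid = images$grid),
            class = "condition_images")
}

#' Select and group conditions for the repetition or targetness analysis
#'
#' The repetition analysis contrasts 3x hits with 1x hits (pooled over run
#' types by default). The targetness analysis contrasts detection of memory
#' targets (1x hits in incentivize-old runs and correct rejections in
#' incentivize-new runs) with non-targets (1x hits in incentivize-new runs
#' and correct rejections in incentivize-old runs); only 1x hits enter
#' because their mnemonic status is most sensitive to the payoff
#' manipulation.
#'
#' @param images a \code{condition_images} with the six standard conditions.
#' @param analysis \code{"repetition"} or \code{"targetness"}.
#' @param pooling \code{"pooled"} (2 conditions) or \code{"unpooled"}
#'   (4 conditions with a \code{grouping} attribute).
#' @return A \code{condition_images} restricted/averaged to the analysis
#'   conditions.
#' @export
select_conditions <- function(images,
                              analysis = c("repetition", "targetness"),
                              pooling = c("pooled", "unpooled")) {
  analysis <- match.arg(analysis)
  pooling <- match.arg(pooling)
  if (analysis == "repetition") {
    if (pooling == "pooled") {
      out <- avg_conditions(images, list(
        hit_3x = c("inc_old_3x_hit", "inc_new_3x_hit"),
        hit_1x = c("inc_old_1x_hit", "inc_new_1x_hit")))
    } else {
      out <- avg_conditions(images, list(
        inc_old_3x_hit = "inc_old_3x_hit", inc_new_3x_hit = "inc_new_3x_hit",
        inc_old_1x_hit = "inc_old_1x_hit", inc_new_1x_hit = "inc_new_1x_hit"))
      attr(out, "grouping") <- list(hit_3x = 1:2, hit_1x = 3:4)
    }
  } else {
    if (pooling == "pooled") {
      out <- avg_conditions(images, list(
        target = c("inc_old_1x_hit", "inc_new_cr"),
        nontarget = c("inc_new_1x_hit", "inc_old_cr")))
    } else {
      out <- avg_conditions(images, list(
        inc_old_1x_hit = "inc_old_1x_hit", inc_new_cr = "inc_new_cr",
        inc_new_1x_hit = "inc_new_1x_hit", inc_old_cr = "inc_old_cr"))
      attr(out, "grouping") <- list(target = 1:2, nontarget = 3:4)
    }
  }
  out
}
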