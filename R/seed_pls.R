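#' Seed region specification
#'
#' A seed is a voxel neighborhood centered on an mm coordinate: the center
#' voxel plus \code{neighborhood} voxels in each direction (the default of
#' one gives a 3 x 3 x 3 cube of up to 27 voxels, clipped at the volume
#' edge).
#'
#' @param center_mm length-3 mm coordinate of the seed center (e.g. the
#'   left anterior hippocampus at (-30, -10, -20) in MNI space).
#' @param neighborhood radius in voxels.
#' @param label optional seed label.
#' @return An object of class \code{seed_spec}.
#' @export
seed_spec <- function(center_mm, neighborhood = 1L, label = "seed") {
  stopifnot(length(center_mm) == 3, neighborhood >= 0)
  structure(list(center_mm = as.numeric(center_mm),
                 neighborhood = as.integer(neighborhood), label = label),
            class = "seed_spec")
}

#' Linear voxel indices of a seed neighborhood
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @param center_mm mm coordinate of the center.
#' @param neighborhood radius in voxels; the cube is clipped at grid edges.
#' @return Integer vector of 1-based linear voxel indices.
#' @export
seed_neighborhood <- function(grid, center_mm, neighborhood = 1L) {
  ctr <- round(mm_to_vox(grid, center_mm))[1, ]
  if (any(ctr < 0) || any(ctr >= grid$dim))
    stop("seed center maps outside the grid", call. = FALSE)
  rng <- lapply(1:3, function(a)
    max(0, ctr[a] - neighborhood):min(grid$dim[a] - 1, ctr[a] + neighborhood))
  ijk <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  sort(vox_linear(grid, ijk))
}

#' Extract per subject x condition seed activity
#'
#' In beta mode (the default input path), the seed value is the mean of the
#' condition beta image over the seed neighborhood. In timeseries mode the
#' value is additionally averaged over the peak and adjacent timepoints of
#' an 8-TR peristimulus window (default TRs 2-4, i.e. 4-8 s post onset,
#' bracketing the canonical HRF peak).
#'
#' @param images a \code{condition_images} (beta mode), or an array
#'   subjects x conditions x timepoints x voxels (timeseries mode, with
#'   \code{grid} supplied).
#' @param spec a \code{\link{seed_spec}}.
#' @param grid required in timeseries mode.
#' @param peak_timepoints 1-based indices of the window timepoints averaged
#'   in timeseries mode.
#' @return An object of class \code{seed_activity}: list with \code{values}
#'   (subjects x conditions matrix), \code{spec}, \code{voxels},
#'   \code{provenance}.
#' @export
extract_seed_values <- function(images, spec, grid = NULL,
                                peak_timepoints = 3:5) {
  if (inherits(images, "condition_images")) {
    nb <- seed_neighborhood(images$grid, spec$center_mm, spec$neighborhood)
    vals <- apply(images$values[, , nb, drop = FALSE], c(1, 2), mean)
    return(structure(list(values = vals, spec = spec, voxels = nb,
                          provenance = "betas"),
                     class = "seed_activity"))
  }
  stopifnot(length(dim(images)) == 4, !is.null(grid))
  nb <- seed_neighborhood(grid, spec$center_mm, spec$neighborhood)
  win <- images[, , peak_timepoints, nb, drop = FALSE]
  vals <- apply(win, c(1, 2), mean)
  structure(list(values = vals, spec = spec, voxels = nb,
                 provenance = "timeseries"),
            class = "seed_activity")
}

#' Cross-subject seed-voxel correlation maps per condition
#'
#' For every condition, correlates the seed activity with every voxel's
#' value across subjects (Pearson), producing a k x V correlation matrix.
#' Voxels with zero variance across subjects get r = 0 with a warning.
#'
#' @param seed a \code{seed_activity} (or a subjects x conditions matrix).
#' @param images a \code{condition_images}.
#' @param conditions subset of conditions to include (default all).
#' @return k x V matrix of correlations (rownames = conditions).
#' @export
seed_correlation_maps <- function(seed, images, conditions = NULL) {
  sv <- if (inherits(seed, "seed_activity")) seed$values else seed
  if (is.null(conditions)) conditions <- images$conditions
  ci <- match(conditions, images$conditions)
  if (anyNA(ci)) stop("conditions not present in the images", call. = FALSE)
  n <- dim(images$values)[1]
  if (n < 3) stop("need at least 3 subjects for correlations", call. = FALSE)
  V <- dim(images$values)[3]
  out <- matrix(NA_real_, length(conditions), V,
                dimnames = list(conditions, NULL))
  zero_var <- FALSE
  for (j in seq_along(ci)) {
    Y <- images$values[, ci[j], ]           # n x V
    s <- sv[, ci[j]]
    sc <- s - mean(s)
    Yc <- sweep(Y, 2, colMeans(Y))
    denom <- sqrt(sum(sc^2)) * sqrt(colSums(Yc^2))
    r <- as.numeric(crossprod(sc, Yc))
    bad <- denom == 0
    r[!bad] <- r[!bad] / denom[!bad]
    if (any(bad)) { r[bad] <- 0; zero_var <- TRUE }
    out[j, ] <- r
  }
  if (zero_var)
    warning("zero-variance voxels (or seed): correlations set to 0",
            call. = FALSE)
  out
}

#' SVD of a stacked seed-correlation matrix
#'
#' Decomposes the conditions x voxels correlation matrix into latent
#' variables with the same conventions as the task-PLS SVD (ordering,
#' deterministic sign, unit-norm saliences). The matrix is not mean-centered:
#' the LVs describe the shared and condition-dependent structure of the
#' seed's functional connectivity.
#'
#' @param cm k x V correlation matrix from
#'   \code{\link{seed_correlation_maps}}.
#' @return A \code{pls_result}.
#' @export
seed_pls_svd <- function(cm) {
  pls_svd(cm)
}

#' Seed PLS with permutation and bootstrap inference
#'
#' Full functional-connectivity PLS: extract seed values, build the
#' cross-subject correlation matrix over the selected conditions, decompose
#' with SVD, then assess LVs by permutation (condition labels shuffled
#' within subject; seed values and correlation maps recomputed each time)
#' and voxel saliences by bootstrap over subjects (the correlation matrix
#' is recomputed for every resample).
#'
#' @param images a \code{condition_images}.
#' @param spec a \code{\link{seed_spec}}.
#' @param conditions conditions entering the analysis (default all).
#' @param cfg a \code{\link{resampling_config}}.
#' @param fisher_z apply Fisher's z transform to correlations before the
#'   SVD (default FALSE, matching common toolbox behavior).
#' @return A \code{pls_result} augmented with \code{perm_p}, \code{bsr},
#'   \code{boot_se}, \code{seed} and \code{corr_matrix}.
#' @export
seed_pls <- function(images, spec, conditions = NULL,
                     cfg = resampling_config(), fisher_z = FALSE) {
  if (is.null(conditions)) conditions <- images$conditions
  sa <- extract_seed_values(images, spec)
  cm <- seed_correlation_maps(sa, images, conditions)
  if (fisher_z) cm <- atanh(pmin(pmax(cm, -1 + 1e-12), 1 - 1e-12))
  res <- seed_pls_svd(cm)
  # restrict the bundle to the analysis conditions so the resampling
  # engines relabel/resample exactly what entered the decomposition
  bundle <- list(images = subset_conditions(images, conditions), spec = spec,
                 conditions = conditions, fisher_z = fisher_z)
  res$perm_p <- permutation_test(bundle, analysis = "seed", cfg = cfg)
  rel <- bootstrap_reliability(bundle, analysis = "seed", cfg = cfg,
                               original = res)
  res$boot_se <- rel$se
  res$bsr <- rel$bsr
  res$seed <- sa
  res$corr_matrix <- cm
  res
}

# recompute the seed correlation matrix for a subject subset / condition
# relabeling; used by the resampling engines
seed_corr_for <- function(bundle, subject_idx = NULL, relabel = NULL) {
  im <- bundle$images
  X <- im$values
  if (!is.null(relabel)) {
    # relabel[s, ] is a permutation of condition indices for subject s
    for (s in seq_len(dim(X)[1])) X[s, , ] <- X[s, relabel[s, ], ]
  }
  if (!is.null(subject_idx)) X <- X[subject_idx, , , drop = FALSE]
  im2 <- structure(list(values = X, conditions = im$conditions,
                        subjects = seq_len(dim(X)[1]), grid = im$grid),
                   class = "condition_images")
  sa <- extract_seed_values(im2, bundle$spec)
  cm <- seed_correlation_maps(sa, im2, bundle$conditions)
  if (isTRUE(bundle$fisher_z))
    cm <- atanh(pmin(pmax(cm, -1 + 1e-12), 1 - 1e-12))
  cm
}
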