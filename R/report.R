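#' Local-maximum peaks of a bootstrap-ratio map
#'
#' Finds voxels whose |bsr| exceeds the threshold and is a local maximum in
#' its 26-voxel neighborhood, then greedily keeps peaks in decreasing |bsr|
#' order with a minimum mm separation; ties are broken by lexicographic
#' (linear) voxel index. Positive and negative saliences are both reported,
#' with a sign column.
#'
#' @param bsr numeric vector of bootstrap ratios in grid linear order.
#' @param grid a \code{\link{voxel_grid}}.
#' @param threshold peak inclusion threshold on |bsr|.
#' @param min_sep_mm minimum separation between reported peaks in mm.
#' @param lv_index LV index recorded in the table.
#' @return A data frame with columns \code{x}, \code{y}, \code{z} (mm),
#'   \code{bsr}, \code{lv_index}, \code{sign}; zero rows when nothing
#'   exceeds the threshold.
#' @export
find_peaks <- function(bsr, grid, threshold = 3, min_sep_mm = 10,
                       lv_index = 1L) {
  stopifnot(length(bsr) == grid$n_voxels)
  a <- abs(bsr)
  cand <- which(a > threshold)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      bsr = numeric(0), lv_index = integer(0),
                      sign = character(0))
  if (length(cand) == 0L) return(empty)
  arr <- array(a, dim = grid$dim)
  is_peak <- vapply(cand, function(idx) {
    ijk <- linear_vox(grid, idx)[1, ] + 1L    # 1-based for array indexing
    rng <- lapply(1:3, function(d)
      max(1L, ijk[d] - 1L):min(grid$dim[d], ijk[d] + 1L))
    arr[ijk[1], ijk[2], ijk[3]] >= max(arr[rng[[1]], rng[[2]], rng[[3]]])
  }, logical(1))
  cand <- cand[is_peak]
  if (length(cand) == 0L) return(empty)
  # greedy selection by decreasing |bsr|, ties by lexicographic voxel index
  ord <- order(-a[cand], cand)
  cand <- cand[ord]
  mm <- vox_to_mm(grid, linear_vox(grid, cand))
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d <- sqrt(rowSums(sweep(mm[keep, , drop = FALSE], 2, mm[i, ])^2))
    if (all(d >= min_sep_mm)) keep[i] <- TRUE
  }
  sel <- which(keep)
  data.frame(x = mm[sel, 1], y = mm[sel, 2], z = mm[sel, 3],
             bsr = bsr[cand[sel]], lv_index = lv_index,
             sign = ifelse(bsr[cand[sel]] > 0, "positive", "negative"))
}

#' Write a voxel map as NIfTI-1
#'
#' @param map numeric vector in grid linear order.
#' @param grid a \code{\link{voxel_grid}}.
#' @param path output file path (\code{.nii} / \code{.nii.gz}).
#' @return Invisibly, \code{path}.
#' @export
write_map_nifti <- function(map, grid, path) {
  arr <- array(map, dim = grid$dim)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(grid$voxel_mm, 3)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel map from NIfTI-1
#'
#' @param path NIfTI file path.
#' @return A list with \code{map} (numeric vector, grid linear order) and
#'   \code{grid} (a \code{\link{voxel_grid}} rebuilt from the header).
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), code = NULL)
  dim <- dim(img)[1:3]
  grid <- voxel_grid(dim, voxel_mm = abs(affine[1, 1]),
                     origin_mm = affine[1:3, 4])
  grid$affine <- unclass(affine)[1:4, 1:4]
  list(map = as.numeric(img), grid = grid)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Orchestrates: behavioral simulation and scoring, condition-image
#' simulation, the selected PLS analysis (repetition, targetness, or seed)
#' with permutation and bootstrap inference, peak extraction, and output of
#' TSV tables, NIfTI maps and a JSON manifest recording seeds and
#' parameters. Deterministic for a fixed configuration.
#'
#' @param out_dir output directory.
#' @param analysis \code{"repetition"}, \code{"targetness"} or
#'   \code{"seed"}.
#' @param params a \code{\link{design_params}}.
#' @param sdt an \code{\link{sdt_params}}.
#' @param model a \code{\link{planted_model}} (defaults to a small planted
#'   repetition pattern on a 10 x 10 x 10 grid).
#' @param seed_region a \code{\link{seed_spec}} (seed analysis only).
#' @param cfg a \code{\link{resampling_config}}.
#' @param master_seed integer master seed; per-stage seeds are derived from
#'   it by fixed offsets.
#' @return Invisibly, a list with the main in-memory results
#'   (\code{responses}, \code{rates}, \code{sdt}, \code{anova},
#'   \code{pls}, \code{peaks}, \code{manifest}).
#' @export
run_pipeline <- function(out_dir,
                         analysis = c("repetition", "targetness", "seed"),
                         params = design_params(),
                         sdt = sdt_params(),
                         model = NULL,
                         seed_region = seed_spec(c(0, 0, 0)),
                         cfg = resampling_config(n_perm = 100L, n_boot = 50L),
                         master_seed = 1L) {
  analysis <- match.arg(analysis)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(offset) (master_seed + offset) %% .Machine$integer.max

  # behavior
  responses <- simulate_responses(sdt = sdt, params = params,
                                  seed = stage_seed(1))
  rates <- score_responses(responses)
  sdt_tab <- sdt_summary(rates)
  acc <- rates; acc$value <- acc$rate
  anova_tab <- rm_anova_2way(acc)
  write_tsv(responses, file.path(out_dir, "responses.tsv"))
  write_tsv(rates, file.path(out_dir, "rates.tsv"))
  write_tsv(sdt_tab, file.path(out_dir, "sdt_summary.tsv"))
  write_tsv(anova_tab, file.path(out_dir, "anova.tsv"))

  # images
  if (is.null(model)) {
    grid <- voxel_grid()
    model <- planted_model(
      grid,
      lvs = list(list(amplitude = 3,
                      task_profile = c(1, 1, -1, 1, 1, -1) / sqrt(6),
                      spatial_map = gaussian_blob(grid, c(4, 4, 4)))),
      subject_sd = 0.1, noise_sd = 0.2)
  }
  images <- simulate_condition_images(params$n_subjects,
                                      standard_conditions(), model,
                                      seed = stage_seed(2))
  cfg$seed <- stage_seed(3)

  if (analysis == "seed") {
    res <- seed_pls(images, seed_region, cfg = cfg)
  } else {
    sel <- select_conditions(images, analysis)
    res <- task_pls(sel, cfg = cfg)
  }

  lv_tab <- data.frame(lv = seq_along(res$singular_values),
                       singular_value = res$singular_values,
                       pct_covariance = res$pct_covariance,
                       perm_p = res$perm_p,
                       significant = res$perm_p < cfg$alpha)
  write_tsv(lv_tab, file.path(out_dir, "latent_variables.tsv"))
  write_tsv(data.frame(condition = res$conditions,
                       salience = res$task_saliences[, 1]),
            file.path(out_dir, "task_saliences_lv1.tsv"))
  grid <- images$grid
  write_map_nifti(res$voxel_saliences[, 1], grid,
                  file.path(out_dir, "salience_lv1.nii.gz"))
  write_map_nifti(res$bsr[, 1], grid, file.path(out_dir, "bsr_lv1.nii.gz"))
  peaks <- find_peaks(res$bsr[, 1], grid, threshold = cfg$bsr_threshold)
  write_tsv(peaks, file.path(out_dir, "peaks_lv1.tsv"))

  manifest <- list(analysis = analysis, master_seed = master_seed,
                   stage_seeds = list(behavior = stage_seed(1),
                                      images = stage_seed(2),
                                      resampling = stage_seed(3)),
                   n_subjects = params$n_subjects,
                   conditions = res$conditions,
                   n_perm = cfg$n_perm, n_boot = cfg$n_boot,
                   bsr_threshold = cfg$bsr_threshold,
                   package_version = as.character(utils::packageVersion("plsmem")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(responses = responses, rates = rates, sdt = sdt_tab,
                 anova = anova_tab, pls = res, peaks = peaks,
                 manifest = manifest))
}
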