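#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF is the difference of two gamma densities (response
#' peaking near 5 s and a later undershoot, shape/rate 6/1 and 16/1, with
#' undershoot ratio 1/6), normalized to unit peak amplitude. The kernel is
#' returned both at scan resolution (one sample per TR, length
#' \code{duration/TR}) and at a fine microtime grid used for convolution.
#'
#' @param TR repetition time in seconds.
#' @param duration kernel support in seconds.
#' @param dt microtime resolution in seconds (default TR/16).
#' @return An object of class \code{hrf_model}: list with \code{TR},
#'   \code{duration}, \code{kernel} (sampled at TR, unit peak),
#'   \code{fine_kernel}, \code{dt}, \code{fine_times}.
#' @export
canonical_hrf <- function(TR = 2, duration = 32, dt = TR / 16) {
  if (TR <= 0) stop("TR must be positive", call. = FALSE)
  if (duration < TR) stop("duration must be at least one TR", call. = FALSE)
  h <- function(t) {
    stats::dgamma(t, shape = 6, rate = 1) -
      stats::dgamma(t, shape = 16, rate = 1) / 6
  }
  ft <- seq(0, duration - dt, by = dt)
  fk <- h(ft)
  peak <- max(fk)
  fk <- fk / peak
  st <- seq(0, duration - TR, by = TR)
  k <- h(st) / peak
  k <- k / max(abs(c(k, 1e-300)))        # unit peak at scan resolution too
  structure(list(TR = TR, duration = duration, kernel = k,
                 fine_kernel = fk, dt = dt, fine_times = ft),
            class = "hrf_model")
}

#' Build a GLM design matrix from run events
#'
#' Each modeled trial type gets one regressor: a boxcar over
#' [onset, onset + duration) on the microtime grid, convolved with the
#' canonical HRF and sampled at scan times. An intercept column is always
#' appended, an optional linear drift column by default.
#'
#' @param events data frame with \code{onset_ms}, \code{duration_ms} and a
#'   condition column named by \code{condition_col}.
#' @param n_scans number of scans in the run.
#' @param hrf an \code{\link{canonical_hrf}} model.
#' @param condition_col name of the column labelling trial types.
#' @param conditions regressor order; defaults to the sorted unique labels.
#'   Conditions with no events yield an all-zero regressor.
#' @param drift add a linear drift regressor (default TRUE).
#' @return A list with the \code{n_scans x n_regressors} matrix \code{X},
#'   \code{regressor_names}, \code{conditions} and \code{TR}.
#' @export
build_design_matrix <- function(events, n_scans, hrf = canonical_hrf(),
                                condition_col = "item_type",
                                conditions = NULL, drift = TRUE) {
  run_dur <- n_scans * hrf$TR
  onset_s <- events$onset_ms / 1000
  dur_s <- events$duration_ms / 1000
  if (any(onset_s >= run_dur))
    stop("event onsets beyond the scanned run duration", call. = FALSE)
  if (is.null(conditions)) conditions <- sort(unique(events[[condition_col]]))
  dt <- hrf$dt
  n_fine <- ceiling(run_dur / dt)
  scan_idx <- round(seq(0, n_scans - 1) * hrf$TR / dt) + 1L

  X <- matrix(0, n_scans, length(conditions))
  for (j in seq_along(conditions)) {
    sel <- events[[condition_col]] == conditions[j]
    box <- numeric(n_fine)
    for (i in which(sel)) {
      from <- floor(onset_s[i] / dt) + 1L
      to <- min(n_fine, ceiling((onset_s[i] + dur_s[i]) / dt))
      box[from:to] <- box[from:to] + 1
    }
    # dt-scaled discrete convolution approximates the continuous one, so
    # regressor amplitude does not depend on the microtime resolution
    conv <- dt * stats::convolve(box, rev(hrf$fine_kernel),
                                 type = "open")[seq_len(n_fine)]
    X[, j] <- conv[scan_idx]
  }
  names <- conditions
  X <- cbind(X, 1)
  names <- c(names, "intercept")
  if (drift) {
    X <- cbind(X, seq_len(n_scans) - (n_scans + 1) / 2)
    names <- c(names, "drift")
  }
  colnames(X) <- names
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning("design matrix is rank deficient", call. = FALSE)
  list(X = X, regressor_names = names, conditions = conditions, TR = hrf$TR)
}

#' Simulate a BOLD run from a design matrix and true betas
#'
#' @param X design matrix (\code{n_scans x n_regressors}) or the list from
#'   \code{\link{build_design_matrix}}.
#' @param betas \code{n_regressors x n_voxels} matrix of true effects.
#' @param noise_sd SD of additive white Gaussian noise.
#' @return \code{n_scans x n_voxels} matrix of simulated BOLD values.
#' @export
simulate_bold <- function(X, betas, noise_sd = 0) {
  if (is.list(X)) X <- X$X
  stopifnot(ncol(X) == nrow(betas))
  Y <- X %*% betas
  if (noise_sd > 0) Y <- Y + matrix(stats::rnorm(length(Y), 0, noise_sd),
                                    nrow(Y), ncol(Y))
  Y
}

#' Ordinary least-squares beta estimation per voxel
#'
#' @param Y \code{n_scans x n_voxels} BOLD matrix.
#' @param X design matrix or \code{\link{build_design_matrix}} output.
#' @return \code{n_regressors x n_voxels} matrix of estimated betas.
#' @export
estimate_betas <- function(Y, X) {
  if (is.list(X)) X <- X$X
  stopifnot(nrow(Y) == nrow(X), nrow(X) > ncol(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient; cannot estimate betas",
         call. = FALSE)
  qr.coef(qrX, Y)
}

#' Condition beta images from multi-run time series
#'
#' Fits the GLM run by run and averages each condition's betas across runs,
#' yielding one beta image per condition.
#'
#' @param runs list of \code{n_scans x n_voxels} BOLD matrices.
#' @param designs list of \code{\link{build_design_matrix}} outputs, one per
#'   run (conditions may differ across runs).
#' @param conditions conditions to report; defaults to the union over runs.
#' @return \code{n_conditions x n_voxels} matrix of run-averaged betas
#'   (rownames = conditions). Conditions absent from a run are averaged
#'   over the runs that contain them.
#' @export
glm_condition_betas <- function(runs, designs, conditions = NULL) {
  stopifnot(length(runs) == length(designs))
  if (is.null(conditions))
    conditions <- unique(unlist(lapply(designs, `[[`, "conditions")))
  V <- ncol(runs[[1]])
  acc <- matrix(0, length(conditions), V,
                dimnames = list(conditions, NULL))
  cnt <- integer(length(conditions))
  for (r in seq_along(runs)) {
    B <- estimate_betas(runs[[r]], designs[[r]])
    present <- intersect(conditions, designs[[r]]$conditions)
    idx <- match(present, conditions)
    acc[idx, ] <- acc[idx, ] + B[present, , drop = FALSE]
    cnt[idx] <- cnt[idx] + 1L
  }
  if (any(cnt == 0L))
    stop("conditions never observed in any run: ",
         paste(conditions[cnt == 0L], collapse = ", "), call. = FALSE)
  acc / cnt
}
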