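#' Stack condition images into a single data matrix
#'
#' Rows are (condition, subject) pairs in condition-block order (all
#' subjects of condition 1, then condition 2, ...); columns are voxels in
#' the grid's linear order. The row-to-(condition, subject) mapping is
#' retained so brain scores can be attributed.
#'
#' @param images a \code{condition_images}.
#' @return An object of class \code{pls_datamat}: list with \code{X}
#'   ((k n) x V matrix), \code{k}, \code{n}, \code{conditions},
#'   \code{subjects}, \code{row_condition}, \code{row_subject}, \code{grid}.
#' @export
build_datamat <- function(images) {
  A <- images$values
  if (anyNA(A)) stop("missing subject x condition cells", call. = FALSE)
  n <- dim(A)[1]; k <- dim(A)[2]; V <- dim(A)[3]
  X <- matrix(NA_real_, k * n, V)
  for (c in seq_len(k))
    X[(c - 1) * n + seq_len(n), ] <- A[, c, ]
  structure(list(X = X, k = k, n = n, conditions = images$conditions,
                 subjects = images$subjects,
                 row_condition = rep(seq_len(k), each = n),
                 row_subject = rep(seq_len(n), times = k),
                 grid = images$grid),
            class = "pls_datamat")
}

#' Mean-centered condition matrix
#'
#' Averages the stacked data within condition and subtracts the grand mean
#' over conditions, giving the k x V matrix whose SVD defines the task-PLS
#' latent variables. Columns of the result sum to zero.
#'
#' @param dm a \code{pls_datamat}.
#' @return k x V numeric matrix (rownames = conditions).
#' @export
mean_center <- function(dm) {
  M <- matrix(NA_real_, dm$k, ncol(dm$X), dimnames = list(dm$conditions, NULL))
  for (c in seq_len(dm$k))
    M[c, ] <- colMeans(dm$X[dm$row_condition == c, , drop = FALSE])
  sweep(M, 2, colMeans(M))
}

# deterministic sign convention: flip each LV so the voxel salience with the
# largest magnitude is positive
apply_sign_convention <- function(sv) {
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$voxel[, j]))
    if (sv$voxel[i, j] < 0) {
      sv$voxel[, j] <- -sv$voxel[, j]
      sv$task[, j] <- -sv$task[, j]
    }
  }
  sv
}

pls_core_svd <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, .Machine$double.eps)
  r <- sum(keep)
  list(d = s$d[keep], task = s$u[, keep, drop = FALSE],
       voxel = s$v[, keep, drop = FALSE], rank = r)
}

#' Singular value decomposition of a condition x voxel matrix
#'
#' Decomposes the mean-centered condition matrix (or a seed-correlation
#' matrix) into latent variables: each LV carries a singular value (the
#' covariance it accounts for), a unit-norm task-salience profile over
#' conditions, and a unit-norm voxel-salience image. LVs are ordered by
#' decreasing singular value; numerically zero LVs are dropped; each LV's
#' sign is fixed so its largest-magnitude voxel salience is positive.
#'
#' @param M k x V matrix.
#' @return An object of class \code{pls_result}: list with
#'   \code{singular_values}, \code{task_saliences} (k x r),
#'   \code{voxel_saliences} (V x r), \code{pct_covariance}, \code{conditions}.
#' @export
pls_svd <- function(M) {
  stopifnot(all(is.finite(M)))
  sv <- apply_sign_convention(pls_core_svd(M))
  tot <- sum(sv$d^2)
  structure(list(singular_values = sv$d,
                 task_saliences = sv$task,
                 voxel_saliences = sv$voxel,
                 pct_covariance = if (tot > 0) 100 * sv$d^2 / tot else
                   numeric(length(sv$d)),
                 conditions = rownames(M)),
            class = "pls_result")
}

#' Brain scores: projection of each subject-condition image onto an LV
#'
#' \code{score[s, c] = sum_v X[c, s, v] u[v]}, the dot product of a
#' subject's condition image with the LV's voxel saliences; summarizes how
#' strongly each subject expresses the LV's pattern in each condition.
#'
#' @param dm a \code{pls_datamat}.
#' @param lv a \code{pls_result}.
#' @param lv_index which LV to project on.
#' @return n x k matrix of brain scores (columns = conditions).
#' @export
compute_brain_scores <- function(dm, lv, lv_index = 1L) {
  u <- lv$voxel_saliences[, lv_index]
  if (length(u) != ncol(dm$X)) stop("voxel dimension mismatch", call. = FALSE)
  sc <- dm$X %*% u
  matrix(sc, dm$n, dm$k, dimnames = list(NULL, dm$conditions))
}

#' Mean-centered task PLS with permutation and bootstrap inference
#'
#' Runs the full task-PLS analysis on a set of condition images: stack,
#' mean-center, SVD, brain scores, permutation p-values per LV
#' (condition labels shuffled within subject) and bootstrap voxel-salience
#' reliability (subjects resampled with replacement; bootstrap ratio =
#' salience x singular value / bootstrap SE).
#'
#' @param images a \code{condition_images}.
#' @param cfg a \code{\link{resampling_config}}.
#' @return A \code{pls_result} augmented with \code{brain_scores} (list per
#'   LV), \code{perm_p}, \code{bsr} (V x r matrix), \code{boot_se},
#'   \code{datamat}.
#' @export
task_pls <- function(images, cfg = resampling_config()) {
  dm <- build_datamat(images)
  res <- pls_svd(mean_center(dm))
  res$brain_scores <- lapply(seq_along(res$singular_values),
                             function(j) compute_brain_scores(dm, res, j))
  res$perm_p <- permutation_test(dm, analysis = "task", cfg = cfg)
  rel <- bootstrap_reliability(dm, analysis = "task", cfg = cfg,
                               original = res)
  res$boot_se <- rel$se
  res$bsr <- rel$bsr
  res$datamat <- dm
  res
}
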