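#' Resampling configuration
#'
#' Defaults follow common practice for PLS inference: 500 permutations for
#' LV significance, 100 bootstrap resamples of subjects for salience
#' standard errors, and a bootstrap-ratio threshold of 3 (approximately a
#' z score at p < 0.001).
#'
#' @param n_perm number of permutations.
#' @param n_boot number of bootstrap resamples.
#' @param alpha LV significance level for the permutation test.
#' @param bsr_threshold reliability threshold on |bootstrap ratio|.
#' @param seed optional integer seed controlling both resampling streams
#'   (the permutation and bootstrap streams use fixed offsets from it).
#' @return An object of class \code{resampling_config}.
#' @export
resampling_config <- function(n_perm = 500L, n_boot = 100L, alpha = 0.05,
                              bsr_threshold = 3, seed = NULL) {
  stopifnot(n_perm >= 1, n_boot >= 1, alpha > 0, alpha < 1,
            bsr_threshold > 0)
  structure(list(n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 alpha = alpha, bsr_threshold = bsr_threshold, seed = seed),
            class = "resampling_config")
}

# singular values of the mean-centered condition matrix for a permuted /
# resampled view of a task datamat
task_singular_values <- function(dm, relabel = NULL, subject_idx = NULL,
                                 n_keep) {
  k <- dm$k; n <- dm$n
  subj <- if (is.null(subject_idx)) seq_len(n) else subject_idx
  M <- matrix(0, k, ncol(dm$X))
  for (c in seq_len(k)) {
    rows <- if (is.null(relabel)) (c - 1L) * n + subj else
      (relabel[subj, c] - 1L) * n + subj
    M[c, ] <- colMeans(dm$X[rows, , drop = FALSE])
  }
  M <- sweep(M, 2, colMeans(M))
  svd(M, nu = 0, nv = 0)$d[seq_len(n_keep)]
}

task_svd_for <- function(dm, subject_idx) {
  k <- dm$k
  M <- matrix(0, k, ncol(dm$X))
  for (c in seq_len(k)) {
    rows <- (c - 1L) * dm$n + subject_idx
    M[c, ] <- colMeans(dm$X[rows, , drop = FALSE])
  }
  M <- sweep(M, 2, colMeans(M))
  svd(M)
}

# within-subject relabeling matrix: row s holds a permutation of 1..k
relabel_within_subject <- function(n, k) {
  t(replicate(n, sample.int(k)))
}

#' Permutation test of latent-variable significance
#'
#' Re-derives the LVs after randomly reordering the rows of the data
#' matrix and compares the permuted singular values with the observed
#' ones, rank for rank. By default condition labels are shuffled within
#' subject (subjects are the exchangeable blocks); fully unrestricted row
#' permutation is available. p-values use add-one smoothing,
#' \eqn{p = (r + 1) / (n_{perm} + 1)}, so the smallest attainable p is
#' \eqn{1 / (n_{perm} + 1)}.
#'
#' @param x for \code{analysis = "task"}, a \code{pls_datamat}; for
#'   \code{"seed"}, a list with \code{images} (restricted to the analysis
#'   conditions), \code{spec}, \code{conditions}, \code{fisher_z}.
#' @param analysis \code{"task"} or \code{"seed"}.
#' @param cfg a \code{\link{resampling_config}}.
#' @param scheme \code{"within_subject"} (default) or \code{"unrestricted"}.
#' @return Numeric vector of permutation p-values, one per LV.
#' @export
permutation_test <- function(x, analysis = c("task", "seed"),
                             cfg = resampling_config(),
                             scheme = c("within_subject", "unrestricted")) {
  analysis <- match.arg(analysis)
  scheme <- match.arg(scheme)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (analysis == "task") {
    dm <- x
    k <- dm$k; n <- dm$n
    obs <- task_singular_values(dm, n_keep = min(k, ncol(dm$X)))
    obs <- obs[obs > 1e-10 * max(obs, .Machine$double.eps)]
    n_keep <- length(obs)
    exceed <- integer(n_keep)
    for (p in seq_len(cfg$n_perm)) {
      d <- if (scheme == "within_subject") {
        task_singular_values(dm, relabel = relabel_within_subject(n, k),
                             n_keep = n_keep)
      } else {
        perm <- sample.int(k * n)
        M <- matrix(0, k, ncol(dm$X))
        for (c in seq_len(k))
          M[c, ] <- colMeans(dm$X[perm[dm$row_condition == c], ,
                                  drop = FALSE])
        M <- sweep(M, 2, colMeans(M))
        svd(M, nu = 0, nv = 0)$d[seq_len(n_keep)]
      }
      exceed <- exceed + (d >= obs)
    }
    return((exceed + 1) / (cfg$n_perm + 1))
  }
  # seed analysis: shuffle condition labels within subject, recompute the
  # seed values and correlation matrix each time
  bundle <- x
  k <- length(bundle$conditions)
  n <- dim(bundle$images$values)[1]
  obs <- svd(seed_corr_for(bundle), nu = 0, nv = 0)$d
  obs <- obs[obs > 1e-12 * max(obs)]
  n_keep <- length(obs)
  exceed <- integer(n_keep)
  for (p in seq_len(cfg$n_perm)) {
    relabel <- relabel_within_subject(n, k)
    d <- svd(seed_corr_for(bundle, relabel = relabel), nu = 0, nv = 0)$d
    exceed <- exceed + (d[seq_len(n_keep)] >= obs)
  }
  (exceed + 1) / (cfg$n_perm + 1)
}

# orthogonal Procrustes rotation R minimizing ||U0 - Ub R||_F
procrustes_rotation <- function(Ub, U0) {
  s <- svd(crossprod(Ub, U0))
  s$u %*% t(s$v)
}

#' Bootstrap reliability of voxel saliences
#'
#' Resamples subjects with replacement, recomputes the analysis (the
#' mean-centered SVD for task PLS; the seed correlation matrix and its SVD
#' for seed PLS), aligns each replicate's saliences to the original LVs by
#' an orthogonal Procrustes rotation of the task-salience basis (resolving
#' sign/rotation indeterminacy), and estimates the per-voxel standard error
#' of the singular-value-scaled saliences. The bootstrap ratio is the
#' original scaled salience divided by its bootstrap SE and is treated as
#' approximately a z score.
#'
#' Degenerate resamples containing a single unique subject are redrawn (and
#' counted in the \code{n_redrawn} attribute). Voxels with zero bootstrap SE
#' get a signed infinite bootstrap ratio and are reported via a message.
#'
#' @inheritParams permutation_test
#' @param original the \code{pls_result} of the observed data.
#' @return A list with \code{se} (V x r), \code{bsr} (V x r), and
#'   \code{salience_scaled} (V x r, the original saliences scaled by their
#'   singular values).
#' @export
bootstrap_reliability <- function(x, analysis = c("task", "seed"),
                                  cfg = resampling_config(), original) {
  analysis <- match.arg(analysis)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  r <- length(original$singular_values)
  U0 <- original$task_saliences
  V0s <- original$voxel_saliences %*% diag(original$singular_values, r)
  n <- if (analysis == "task") x$n else dim(x$images$values)[1]

  reps <- array(NA_real_, dim = c(nrow(V0s), r, cfg$n_boot))
  n_redrawn <- 0L
  for (b in seq_len(cfg$n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) > 1L) break
      n_redrawn <- n_redrawn + 1L
    }
    s <- if (analysis == "task") task_svd_for(x, idx) else
      svd(seed_corr_for(x, subject_idx = idx))
    Ub <- s$u[, seq_len(r), drop = FALSE]
    Vb <- s$v[, seq_len(r), drop = FALSE]
    R <- procrustes_rotation(Ub, U0)
    reps[, , b] <- (Vb %*% diag(s$d[seq_len(r)], r)) %*% R
  }
  se <- apply(reps, c(1, 2), stats::sd)
  bsr <- V0s / se
  zero <- se == 0
  if (any(zero)) {
    message(sum(zero), " voxel salience(s) had zero bootstrap SE; ",
            "bootstrap ratio set to signed Inf")
    bsr[zero] <- sign(V0s[zero]) * Inf
  }
  out <- list(se = se, bsr = bsr, salience_scaled = V0s)
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Threshold a bootstrap-ratio map
#'
#' @param bsr numeric vector (or matrix) of bootstrap ratios.
#' @param threshold reliability threshold (default 3).
#' @return A list of logical masks: \code{mask} (|bsr| above threshold),
#'   \code{positive}, \code{negative}.
#' @export
threshold_bsr <- function(bsr, threshold = 3) {
  list(mask = abs(bsr) > threshold,
       positive = bsr > threshold,
       negative = bsr < -threshold)
}
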