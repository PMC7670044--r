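#' Signal-detection response model parameters
#'
#' Parameterizes the simulated observer in one of two ways:
#' \describe{
#'   \item{rate}{a probability of responding "old" for every
#'     (run type x item type) cell, with between-subject heterogeneity as a
#'     Gaussian jitter on the probit scale;}
#'   \item{sdt}{an equal-variance Gaussian signal-detection model: old
#'     items evoke memory strength \eqn{N(d', 1)}, new items \eqn{N(0, 1)},
#'     and the observer responds "old" when strength exceeds
#'     \eqn{\lambda = d'_{ref}/2 + c}, so that \eqn{c = 0} is the unbiased
#'     point; the criterion \eqn{c} shifts with the payoff scheme.}
#' }
#' Defaults are calibrated to the group mean hit/CR rates and correct-response
#' times of a 14-subject payoff-manipulation recognition study
#' (incentivize-old: hits 0.74 (1x), 0.93 (3x), CRs 0.71;
#' incentivize-new: hits 0.63 (1x), 0.86 (3x), CRs 0.83).
#'
#' @param parameterization \code{"rate"} or \code{"sdt"}.
#' @param p_old 2 x 3 matrix of P(respond "old"), rows
#'   \code{incentivize-old}/\code{incentivize-new}, columns
#'   \code{1x}/\code{3x}/\code{new} (rate parameterization).
#' @param d_prime 2 x 2 matrix of sensitivities, rows as above, columns
#'   \code{1x}/\code{3x} (sdt parameterization).
#' @param criterion length-2 vector of criterion locations c per run type;
#'   negative values are liberal (more "old" responses).
#' @param subject_sd_probit between-subject SD of the probit-transformed
#'   cell probabilities (rate parameterization).
#' @param subject_sd_dprime,subject_sd_c between-subject SDs of d' and c
#'   (sdt parameterization).
#' @param rt_mean_ms 2 x 3 matrix of mean response times (ms) per cell.
#' @param rt_sdlog log-scale SD of the lognormal RT distribution.
#' @return An object of class \code{sdt_params}.
#' @export
sdt_params <- function(parameterization = c("rate", "sdt"),
                       p_old = rbind(`incentivize-old` = c(0.74, 0.93, 0.29),
                                     `incentivize-new` = c(0.63, 0.86, 0.17)),
                       d_prime = rbind(`incentivize-old` = c(1.19, 2.03),
                                       `incentivize-new` = c(1.29, 2.03)),
                       criterion = c(`incentivize-old` = -0.22,
                                     `incentivize-new` = 0.16),
                       subject_sd_probit = 0.25,
                       subject_sd_dprime = 0.35,
                       subject_sd_c = 0.20,
                       rt_mean_ms = rbind(`incentivize-old` = c(1271, 1089, 1424),
                                          `incentivize-new` = c(1383, 1165, 1371)),
                       rt_sdlog = 0.3) {
  parameterization <- match.arg(parameterization)
  colnames(p_old) <- c("1x", "3x", "new")
  colnames(rt_mean_ms) <- c("1x", "3x", "new")
  colnames(d_prime) <- c("1x", "3x")
  if (any(p_old < 0 | p_old > 1))
    stop("response probabilities must lie in [0, 1]", call. = FALSE)
  if (rt_sdlog <= 0) stop("rt_sdlog must be positive", call. = FALSE)
  structure(list(parameterization = parameterization, p_old = p_old,
                 d_prime = d_prime, criterion = criterion,
                 subject_sd_probit = subject_sd_probit,
                 subject_sd_dprime = subject_sd_dprime,
                 subject_sd_c = subject_sd_c,
                 rt_mean_ms = rt_mean_ms, rt_sdlog = rt_sdlog),
            class = "sdt_params")
}

run_types <- c("incentivize-old", "incentivize-new")
item_types <- c("1x", "3x", "new")

#' Simulate recognition responses for a cohort
#'
#' Generates one experiment design per subject (fresh randomization of run
#' order, word allocation and jitter per subject, counterbalanced study
#' status across subjects) and draws old/new responses and response times
#' trial by trial from the signal-detection model in \code{sdt}. Null
#' trials elicit a key press but no memory decision and are excluded from
#' the returned table.
#'
#' @param design either a single \code{experiment_design} (used for all
#'   subjects) or \code{NULL} to generate one per subject from \code{pool}
#'   and \code{params}.
#' @param sdt an \code{\link{sdt_params}} object.
#' @param params a \code{\link{design_params}} object (cohort size etc.).
#' @param pool optional word pool; generated from \code{params} if missing.
#' @param seed integer seed for the whole cohort simulation.
#' @return A data frame (one row per non-null test trial) with columns
#'   \code{subject}, \code{run}, \code{run_type}, \code{trial},
#'   \code{item_type}, \code{word}, \code{response} ("old"/"new"),
#'   \code{correct} (logical), \code{rt_ms}.
#' @export
simulate_responses <- function(design = NULL, sdt = sdt_params(),
                               params = design_params(), pool = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool)) pool <- generate_word_pool(params)
  out <- vector("list", params$n_subjects)
  for (s in seq_len(params$n_subjects)) {
    des <- if (is.null(design)) {
      generate_design(pool, params, counterbalance_id = s)
    } else design
    out[[s]] <- simulate_subject(des, sdt, subject = s)
  }
  do.call(rbind, out)
}

# per-subject cell probabilities of an "old" response, 2x3 matrix
subject_p_old <- function(sdt) {
  if (sdt$parameterization == "rate") {
    # latent probit mean scaled by sqrt(1 + sd^2) so that the population
    # mean of pnorm(z) equals the requested cell probability exactly
    # (E[pnorm(m + sd Z)] = pnorm(m / sqrt(1 + sd^2)))
    sd <- sdt$subject_sd_probit
    z <- stats::qnorm(sdt$p_old) * sqrt(1 + sd^2) +
      matrix(stats::rnorm(6, 0, sd), 2, 3)
    p <- stats::pnorm(z)
    dimnames(p) <- dimnames(sdt$p_old)
    return(p)
  }
  # sdt parameterization: subject-level d' and c, lambda = d'_ref/2 + c
  dp <- sdt$d_prime + matrix(stats::rnorm(4, 0, sdt$subject_sd_dprime), 2, 2)
  dp <- pmax(dp, 0)
  cc <- sdt$criterion + stats::rnorm(2, 0, sdt$subject_sd_c)
  p <- matrix(NA_real_, 2, 3, dimnames = list(run_types, item_types))
  for (r in 1:2) {
    d_ref <- mean(dp[r, ])          # reference sensitivity for the criterion
    lambda <- d_ref / 2 + cc[r]
    p[r, "1x"] <- stats::pnorm(dp[r, "1x"] - lambda)
    p[r, "3x"] <- stats::pnorm(dp[r, "3x"] - lambda)
    p[r, "new"] <- stats::pnorm(-lambda)
  }
  p
}

simulate_subject <- function(design, sdt, subject) {
  p <- subject_p_old(sdt)
  rows <- vector("list", length(design$runs))
  for (r in seq_along(design$runs)) {
    ev <- design$runs[[r]]
    ev <- ev[ev$item_type != "null", ]
    rt_label <- design$run_type[r]
    p_old_trial <- p[rt_label, ev$item_type]
    resp <- ifelse(stats::runif(nrow(ev)) < p_old_trial, "old", "new")
    correct <- ifelse(ev$item_type == "new", resp == "new", resp == "old")
    mu <- log(sdt$rt_mean_ms[rt_label, ev$item_type]) - sdt$rt_sdlog^2 / 2
    rt <- stats::rlnorm(nrow(ev), meanlog = mu, sdlog = sdt$rt_sdlog)
    rows[[r]] <- data.frame(subject = subject, run = r, run_type = rt_label,
                            trial = ev$trial, item_type = ev$item_type,
                            word = ev$word, response = resp,
                            correct = correct, rt_ms = rt,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
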