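#' Per-cell accuracy rates and correct-response times
#'
#' Aggregates a trial-level response table into one row per
#' subject x run type x item type, with the proportion of correct responses
#' (hit rate for old items, correct-rejection rate for new items), the trial
#' count and the mean response time over correct trials only.
#'
#' @param responses a response table from \code{\link{simulate_responses}}.
#' @return A data frame with columns \code{subject}, \code{run_type},
#'   \code{item_type}, \code{n_trials}, \code{n_correct}, \code{rate},
#'   \code{mean_rt_correct_ms}.
#' @export
score_responses <- function(responses) {
  if (nrow(responses) == 0L) stop("empty response table", call. = FALSE)
  key <- interaction(responses$subject, responses$run_type,
                     responses$item_type, drop = FALSE)
  cells <- expand.grid(subject = sort(unique(responses$subject)),
                       run_type = run_types, item_type = item_types,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- tapply(responses$correct, key, length)
  nc <- tapply(responses$correct, key, sum)
  rt <- tapply(ifelse(responses$correct, responses$rt_ms, NA_real_), key,
               mean, na.rm = TRUE)
  k <- paste(cells$subject, cells$run_type, cells$item_type, sep = ".")
  cells$n_trials <- as.integer(n[k])
  if (anyNA(cells$n_trials))
    stop("zero trials in at least one subject x run_type x item_type cell",
         call. = FALSE)
  cells$n_correct <- as.integer(nc[k])
  cells$rate <- cells$n_correct / cells$n_trials
  cells$mean_rt_correct_ms <- as.numeric(rt[k])
  cells[order(cells$subject, cells$run_type, cells$item_type), ,
        drop = FALSE] -> cells
  rownames(cells) <- NULL
  cells
}

#' Pool hit rates over 1x and 3x items
#'
#' Trial-weighted pooled hit rate; reduces to the plain mean when the trial
#' counts are equal (as in the standard design, 16 of each per run).
#'
#' @param rate_1x,rate_3x hit rates for once- and thrice-studied items.
#' @param n_1x,n_3x trial counts behind each rate.
#' @return The pooled rate.
#' @export
collapse_hit_rate <- function(rate_1x, rate_3x, n_1x = 1, n_3x = 1) {
  (rate_1x * n_1x + rate_3x * n_3x) / (n_1x + n_3x)
}

#' Signal-detection sensitivity and criterion
#'
#' Computes \eqn{d' = z(H) - z(F)} and the criterion location
#' \eqn{c = -0.5[z(H) + z(F)]} (negative = liberal) from a hit rate and a
#' false-alarm rate under the equal-variance Gaussian model. Rates of
#' exactly 0 or 1 are replaced by \eqn{1/(2N)} and \eqn{1 - 1/(2N)}
#' before the inverse-normal transform.
#'
#' The sign convention for \eqn{c} is exposed because the two conventions
#' both circulate: \code{"standard"} returns \eqn{-0.5[z(H)+z(F)]}, under
#' which a liberal observer (high H and F) gets negative \eqn{c};
#' \code{"literal"} returns \eqn{+0.5[z(H)+z(F)]}.
#'
#' @param H hit rate in [0, 1].
#' @param F_ false-alarm rate in [0, 1].
#' @param n_old,n_new numbers of old and new trials (used by the
#'   extreme-rate correction).
#' @param sign_convention \code{"standard"} (default) or \code{"literal"}.
#' @return A list with \code{d_prime}, \code{c}, and the corrected
#'   \code{H} and \code{F} actually used.
#' @export
sdt_measures <- function(H, F_, n_old = Inf, n_new = Inf,
                         sign_convention = c("standard", "literal")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(H >= 0, H <= 1, F_ >= 0, F_ <= 1)
  clamp <- function(p, n) {
    lo <- if (is.finite(n)) 1 / (2 * n) else .Machine$double.eps
    pmin(pmax(p, lo), 1 - lo)
  }
  H <- clamp(H, n_old); F_ <- clamp(F_, n_new)
  zH <- stats::qnorm(H); zF <- stats::qnorm(F_)
  cc <- 0.5 * (zH + zF)
  if (sign_convention == "standard") cc <- -cc
  list(d_prime = zH - zF, c = cc, H = H, F = F_)
}

#' Per-subject SDT summary from a rate table
#'
#' Collapses the 1x and 3x hit rates (trial-weighted), converts the
#' correct-rejection rate to a false-alarm rate, and computes \eqn{d'} and
#' \eqn{c} for every subject x run type.
#'
#' @param rates output of \code{\link{score_responses}}.
#' @inheritParams sdt_measures
#' @return A data frame with one row per subject x run type and columns
#'   \code{H}, \code{F}, \code{d_prime}, \code{c}.
#' @export
sdt_summary <- function(rates, sign_convention = c("standard", "literal")) {
  sign_convention <- match.arg(sign_convention)
  out <- list()
  for (s in unique(rates$subject)) for (rt in run_types) {
    cell <- rates[rates$subject == s & rates$run_type == rt, ]
    r1 <- cell[cell$item_type == "1x", ]
    r3 <- cell[cell$item_type == "3x", ]
    rn <- cell[cell$item_type == "new", ]
    H <- collapse_hit_rate(r1$rate, r3$rate, r1$n_trials, r3$n_trials)
    F_ <- 1 - rn$rate
    m <- sdt_measures(H, F_, n_old = r1$n_trials + r3$n_trials,
                      n_new = rn$n_trials, sign_convention = sign_convention)
    out[[length(out) + 1L]] <- data.frame(subject = s, run_type = rt,
                                          H = m$H, F = m$F,
                                          d_prime = m$d_prime, c = m$c)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired t test with Cohen's dz
#'
#' @param a,b paired per-subject values of equal length.
#' @return A list with \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{dz} (= mean difference / SD of differences = t / sqrt(n)) and
#'   \code{mean_diff}.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of paired differences", call. = FALSE)
  n <- length(d)
  tt <- mean(d) / (sdd / sqrt(n))
  list(t = tt, df = n - 1L, p = 2 * stats::pt(-abs(tt), n - 1),
       dz = mean(d) / sdd, mean_diff = mean(d))
}

#' Two one-sided tests (TOST) for paired equivalence
#'
#' Tests whether a standardized paired effect \code{dz} lies within
#' \code{(-bound, +bound)}: the lower test uses
#' \eqn{t_L = (dz + bound)\sqrt{n}} against \eqn{H_0: dz \le -bound} and the
#' upper test \eqn{t_U = (dz - bound)\sqrt{n}} against
#' \eqn{H_0: dz \ge bound}, each one-sided with \eqn{n - 1} degrees of
#' freedom. Equivalence is declared when both reject; the binding test is
#' the one with the larger p-value.
#'
#' @param dz observed standardized effect (Cohen's dz).
#' @param n number of pairs.
#' @param bound positive equivalence bound in dz units.
#' @param alpha equivalence test level.
#' @return A list with the two t statistics and one-sided p-values, the
#'   binding statistic \code{t_binding} (reported as a magnitude) and
#'   \code{p_binding}, \code{df}, and the logical \code{equivalent}.
#' @export
tost_paired <- function(dz, n, bound = 0.5, alpha = 0.05) {
  stopifnot(n >= 2, bound > 0)
  df <- n - 1
  t_lower <- (dz + bound) * sqrt(n)
  t_upper <- (dz - bound) * sqrt(n)
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  binding <- if (p_lower >= p_upper) "lower" else "upper"
  list(dz = dz, n = n, bound = bound, df = df,
       t_lower = t_lower, t_upper = t_upper,
       p_lower = p_lower, p_upper = p_upper,
       t_binding = abs(if (binding == "lower") t_lower else t_upper),
       p_binding = max(p_lower, p_upper),
       equivalent = max(p_lower, p_upper) < alpha)
}

#' Two-way repeated-measures ANOVA
#'
#' Classical within-subject sums-of-squares partition for a complete
#' balanced subject x A x B table with one observation per cell. Each
#' effect is tested against its interaction with subjects; partial
#' eta-squared is \eqn{SS_{effect} / (SS_{effect} + SS_{error})}. No
#' sphericity correction is applied.
#'
#' @param data data frame with columns \code{subject}, \code{value} and the
#'   two factor columns named in \code{factors}.
#' @param factors length-2 character vector naming the within-subject
#'   factor columns (e.g. \code{c("item_type", "run_type")}).
#' @return A data frame with one row per effect (A, B, A:B) and columns
#'   \code{effect}, \code{df_num}, \code{df_den}, \code{ss}, \code{ss_error},
#'   \code{F}, \code{p}, \code{partial_eta_sq}; the total and subject SS are
#'   attached as attributes \code{ss_total} and \code{ss_subject}.
#' @export
rm_anova_2way <- function(data, factors = c("item_type", "run_type")) {
  A <- factor(data[[factors[1]]]); B <- factor(data[[factors[2]]])
  S <- factor(data$subject); y <- data$value
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  if (length(y) != a * b * n || anyNA(y) ||
      any(table(A, B, S) != 1))
    stop("need a complete balanced table with one value per cell",
         call. = FALSE)
  gm <- mean(y)
  ss <- function(means, mult) mult * sum((means - gm)^2)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mS <- tapply(y, S, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAS <- tapply(y, list(A, S), mean)
  mBS <- tapply(y, list(B, S), mean)
  ss_A <- ss(mA, b * n); ss_B <- ss(mB, a * n); ss_S <- ss(mS, a * b)
  ss_AB <- ss(mAB, n) - ss_A - ss_B
  ss_AS <- ss(mAS, b) - ss_A - ss_S
  ss_BS <- ss(mBS, a) - ss_B - ss_S
  ss_tot <- sum((y - gm)^2)
  ss_ABS <- ss_tot - ss_A - ss_B - ss_S - ss_AB - ss_AS - ss_BS
  eff <- data.frame(
    effect = c(factors[1], factors[2], paste(factors, collapse = ":")),
    df_num = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df_den = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    ss = c(ss_A, ss_B, ss_AB),
    ss_error = c(ss_AS, ss_BS, ss_ABS))
  eff$F <- (eff$ss / eff$df_num) / (eff$ss_error / eff$df_den)
  eff$p <- stats::pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$partial_eta_sq <- eff$ss / (eff$ss + eff$ss_error)
  attr(eff, "ss_total") <- ss_tot
  attr(eff, "ss_subject") <- ss_S
  eff
}
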