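test_that("score_responses produces one row per cell with correct rates", {
  p <- design_params()
  resp <- simulate_responses(sdt = sdt_params(), params = p, seed = 3)
  rates <- score_responses(resp)
  expect_equal(nrow(rates), 14 * 2 * 3)
  expect_true(all(rates$rate >= 0 & rates$rate <= 1))
  expect_true(all(rates$n_trials > 0))
  # all-correct table gives rate 1 everywhere
  resp2 <- resp
  resp2$correct <- TRUE
  expect_true(all(score_responses(resp2)$rate == 1))
  # RT averages use correct trials only
  one <- resp[resp$subject == 1 & resp$run_type == resp$run_type[1] &
                resp$item_type == resp$item_type[1], ]
  r1 <- score_responses(resp)
  cell <- r1[r1$subject == 1 & r1$run_type == one$run_type[1] &
               r1$item_type == one$item_type[1], ]
  expect_equal(cell$mean_rt_correct_ms, mean(one$rt_ms[one$correct]))
})

test_that("sdt_measures matches the inverse-normal oracle and conventions", {
  # symmetric rates: no sensitivity, no bias
  m <- sdt_measures(0.5, 0.5)
  expect_equal(m$d_prime, 0)
  expect_equal(m$c, 0)
  # z(0.7) = -z(0.3) -> c = 0 by symmetry
  expect_equal(sdt_measures(0.7, 0.3)$c, 0)
  # collapsed group means: oracle = qnorm arithmetic
  m <- sdt_measures(0.835, 0.29)
  expect_equal(m$d_prime, qnorm(0.835) - qnorm(0.29), tolerance = 1e-12)
  expect_equal(m$c, -0.5 * (qnorm(0.835) + qnorm(0.29)), tolerance = 1e-12)
  expect_equal(m$d_prime, 1.5274986, tolerance = 1e-6)
  expect_equal(m$c, -0.2103646, tolerance = 1e-6)
  # literal sign convention flips c only
  expect_equal(sdt_measures(0.835, 0.29, sign_convention = "literal")$c,
               -m$c)
  # extreme rates clamped by the 1/(2N) rule
  m <- sdt_measures(1, 0, n_old = 64, n_new = 128)
  expect_equal(m$H, 1 - 1 / 128)
  expect_equal(m$F, 1 / 256)
  expect_true(is.finite(m$d_prime) && is.finite(m$c))
})

test_that("d' and c transform exactly under (H,F) -> (1-F, 1-H)", {
  for (hf in list(c(0.9, 0.2), c(0.6, 0.4), c(0.835, 0.29))) {
    a <- sdt_measures(hf[1], hf[2])
    b <- sdt_measures(1 - hf[2], 1 - hf[1])
    expect_equal(b$d_prime, a$d_prime, tolerance = 1e-12)
    expect_equal(b$c, -a$c, tolerance = 1e-12)
  }
})

test_that("collapse_hit_rate pools by trial counts", {
  expect_equal(collapse_hit_rate(0.74, 0.93), 0.835)
  expect_equal(collapse_hit_rate(1, 1), 1)
  expect_equal(collapse_hit_rate(0.6, 0.8, 10, 30), 0.75)
})

test_that("paired t and Cohen's dz agree with hand computation", {
  b <- c(0, 0, 0)
  a <- c(1, 2, 3)
  r <- paired_t(a, b)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  expect_equal(r$dz, r$t / sqrt(3), tolerance = 1e-12)
  # centered differences give t = 0
  r0 <- paired_t(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(r0$t, 0)
  expect_equal(r0$dz, 0)
  # dz = t / sqrt(n) identity on arbitrary input
  set.seed(1)
  x <- rnorm(14); y <- rnorm(14)
  r <- paired_t(x, y)
  expect_lt(abs(r$dz - r$t / sqrt(14)), 1e-12)
  # matches stats::t.test
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  expect_error(paired_t(c(1, 1, 1), c(1, 1, 1)), "zero variance")
})

test_that("TOST equivalence reproduces the worked sensitivity example", {
  r5 <- tost_paired(-0.26, 14, bound = 0.50)
  expect_equal(r5$df, 13)
  expect_equal(r5$t_binding, (-0.26 + 0.5) * sqrt(14), tolerance = 1e-12)
  expect_equal(r5$t_binding, 0.89, tolerance = 0.02)
  expect_false(r5$equivalent)
  r8 <- tost_paired(-0.26, 14, bound = 0.80)
  expect_equal(r8$t_binding, 2.01, tolerance = 0.02)
  expect_true(r8$equivalent)
  expect_lt(r8$p_binding, 0.05)
})

test_that("TOST is symmetric at dz = 0 and monotone in the bound", {
  r <- tost_paired(0, 14, bound = 0.5)
  expect_equal(r$t_lower, -r$t_upper, tolerance = 1e-12)
  expect_equal(r$t_lower, 0.5 * sqrt(14), tolerance = 1e-12)
  # binding p strictly decreases as the bound widens
  bounds <- seq(0.3, 1.2, by = 0.1)
  ps <- vapply(bounds, function(b) tost_paired(-0.26, 14, b)$p_binding,
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("repeated-measures ANOVA partitions sums of squares correctly", {
  set.seed(10)
  n <- 14
  g <- expand.grid(subject = 1:n, item_type = c("1x", "3x", "new"),
                   run_type = c("io", "in"), stringsAsFactors = FALSE)
  g$value <- rnorm(nrow(g))
  tab <- rm_anova_2way(g)
  expect_equal(tab$df_num, c(2, 1, 2))
  expect_equal(tab$df_den, c(26, 13, 26))
  # SS partition closes
  total <- sum(tab$ss) + sum(tab$ss_error) + attr(tab, "ss_subject")
  expect_equal(total, attr(tab, "ss_total"), tolerance = 1e-9)
  # cross-check against the aov within-subject error stratification
  g$subject <- factor(g$subject)
  fit <- summary(aov(value ~ item_type * run_type +
                       Error(subject / (item_type * run_type)), data = g))
  f_item <- fit[["Error: subject:item_type"]][[1]]["item_type", "F value"]
  f_run <- fit[["Error: subject:run_type"]][[1]]["run_type", "F value"]
  f_int <- fit[["Error: subject:item_type:run_type"]][[1]][
    "item_type:run_type", "F value"]
  expect_equal(tab$F, unname(c(f_item, f_run, f_int)), tolerance = 1e-8)
  expect_true(all(tab$partial_eta_sq >= 0 & tab$partial_eta_sq <= 1))
})

test_that("ANOVA degenerate and planted-effect cases behave", {
  g <- expand.grid(subject = 1:6, item_type = c("a", "b", "c"),
                   run_type = c("x", "y"), stringsAsFactors = FALSE)
  g$value <- 1
  tab <- rm_anova_2way(g)
  expect_equal(tab$ss, c(0, 0, 0))
  # additive item effect, no noise: interaction SS exactly 0, item SS > 0
  g$value <- c(a = 0, b = 1, c = 2)[g$item_type]
  tab <- rm_anova_2way(g)
  expect_gt(tab$ss[1], 0)
  expect_equal(tab$ss[3], 0, tolerance = 1e-12)
  expect_equal(tab$ss_error, c(0, 0, 0), tolerance = 1e-12)
  # incomplete tables are rejected
  expect_error(rm_anova_2way(g[-1, ]), "balanced")
})

test_that("estimated criterion tracks the payoff manipulation", {
  # cohorts simulated with distinct criteria per run type recover the
  # ordering c(incentivize-old) < c(incentivize-new)
  p <- design_params()
  resp <- simulate_responses(sdt = sdt_params(), params = p, seed = 77)
  s <- sdt_summary(score_responses(resp))
  c_old <- s$c[s$run_type == "incentivize-old"]
  c_new <- s$c[s$run_type == "incentivize-new"]
  expect_lt(mean(c_old), mean(c_new))
  expect_lt(paired_t(c_old, c_new)$p, 0.05)
})
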