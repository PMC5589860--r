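test_that("RT outlier rule matches direct recomputation and boundary cases", {
  mk <- function(rts) data.frame(subject = 1, stim = "GO",
                                 response = 1, rt_ms = rts)
  # 5-point set: membership decided by recomputing the rule by hand
  rts <- c(300, 310, 320, 330, 900)
  keep_oracle <- abs(rts - mean(rts)) <= 2 * sd(rts)
  out <- reject_rt_outliers(mk(rts))
  expect_equal(out$rt_ms, rts[keep_oracle])
  expect_equal(attr(out, "removed_fraction"), mean(!keep_oracle))
  # constant RTs: SD = 0, strict inequality keeps everything
  out2 <- reject_rt_outliers(mk(rep(250, 6)))
  expect_equal(nrow(out2), 6)
  expect_error(reject_rt_outliers(mk(300)), "at least 2")
  # typical simulated subject loses roughly the documented ~4-5%
  cfg <- task_config()
  log <- simulate_behavior(generate_schedule(cfg, 1),
                           subject_profile("SI", rt_mean = 350), cfg, 2)
  log$subject <- 1
  frac <- attr(reject_rt_outliers(log), "removed_fraction")
  expect_gt(frac, 0.015); expect_lt(frac, 0.09)
})

test_that("signal-detection scores follow the printed formulas", {
  # quantile oracle: d' = z(0.95) - z(0.20), C = (z(0.95) + z(0.20)) / 2
  s <- sdt_scores(0.95, 0.20, 120, 120)
  expect_equal(s$d_prime, qnorm(0.95) - qnorm(0.20), tolerance = 1e-12)
  expect_equal(s$c_criterion, (qnorm(0.95) + qnorm(0.20)) / 2,
               tolerance = 1e-12)
  expect_equal(sdt_scores(0.5, 0.5, 10, 10)$d_prime, 0)
  expect_equal(sdt_scores(0.5, 0.5, 10, 10)$c_criterion, 0)
  # boundary correction: 0 of 120 -> 1/240
  s0 <- sdt_scores(1, 0, 120, 120)
  expect_equal(s0$fa_rate, 1 / 240)
  expect_equal(s0$hit_rate, 1 - 1 / 240)
  # sign switch negates C only
  expect_equal(sdt_scores(0.9, 0.1, 50, 50, "standard")$c_criterion,
               -sdt_scores(0.9, 0.1, 50, 50, "printed")$c_criterion)
  # antisymmetry: swapping hit and fa negates d'
  expect_equal(sdt_scores(0.8, 0.3, 40, 40)$d_prime,
               -sdt_scores(0.3, 0.8, 40, 40)$d_prime)
})

test_that("t tests match hand computation and stats::t.test", {
  # hand example: sp = 1, se = sqrt(2/10)
  t1 <- pooled_t(1, 1, 10, 0, 1, 10)
  expect_equal(t1$t, 1 / sqrt(0.2), tolerance = 1e-12)
  expect_equal(t1$df, 18)
  expect_equal(t1$cohens_d, 1)
  # identical summaries
  t0 <- pooled_t(5, 2, 8, 5, 2, 8)
  expect_equal(t0$t, 0); expect_equal(t0$p, 1)
  # raw-sample interface against stats::t.test
  set.seed(3)
  x <- rnorm(14, 1); y <- rnorm(11)
  expect_equal(pooled_t(x, y)$t,
               unname(t.test(x, y, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  w <- welch_t(x, y)
  ref <- t.test(x, y)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  # equal variances and n: welch == pooled; and satterthwaite df bound
  expect_equal(welch_t(3, 2, 9, 1, 2, 9)$t, pooled_t(3, 2, 9, 1, 2, 9)$t)
  expect_equal(welch_t(3, 2, 9, 1, 2, 9)$df, 16)
  for (i in 1:20) {
    set.seed(i)
    a <- abs(rnorm(2, 2)); n <- sample(3:20, 2)
    expect_lte(welch_t(0, a[1], n[1], 1, a[2], n[2])$df, n[1] + n[2] - 2)
  }
  # degenerate: zero variance
  expect_equal(pooled_t(1, 0, 5, 1, 0, 5)$t, 0)
  expect_true(is.infinite(pooled_t(2, 0, 5, 1, 0, 5)$t))
})

test_that("mixed 2x2 ANOVA matches the GLM oracle to 1e-10", {
  for (i in 1:20) {
    set.seed(i)
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    g <- c(rep("SI", n1), rep("II", n2))
    y1 <- rnorm(n1 + n2, sd = runif(1, 0.5, 3))
    y2 <- rnorm(n1 + n2, mean = runif(1, -1, 1))
    res <- mixed_anova_2x2(y1, y2, g)
    or <- oracle_mixed_2x2(y1, y2, g)
    expect_equal(res$between$F, or$between, tolerance = 1e-10)
    expect_equal(res$within$F, or$within, tolerance = 1e-10)
    expect_equal(res$interaction$F, or$interaction, tolerance = 1e-10)
    # classical identity: interaction F = squared pooled t on differences
    d <- y2 - y1
    expect_equal(res$interaction$F, pooled_t(d[g == "SI"], d[g == "II"])$t^2,
                 tolerance = 1e-10)
  }
  # degenerate cases
  allsame <- mixed_anova_2x2(rep(2, 8), rep(2, 8), rep(c("A", "B"), 4))
  expect_equal(allsame$between$F, 0)
  expect_equal(allsame$interaction$F, 0)
  const_d <- mixed_anova_2x2(rnorm(8), rnorm(8) * 0 + 5 + rnorm(8) * 0,
                             rep(c("A", "B"), 4))
  y1 <- rnorm(8); y2 <- y1 + 3   # constant within-difference
  r <- mixed_anova_2x2(y1, y2, rep(c("A", "B"), 4))
  expect_equal(r$interaction$F, 0)
  expect_error(mixed_anova_2x2(1:4, 1:4, c("A", "A", "A", "B")), "at least 2")
})

test_that("Levene test matches the deviation-ANOVA oracle and is monotone", {
  set.seed(5)
  x <- list(rnorm(12), rnorm(15, sd = 2.5))
  lv <- levene_test(x)
  or <- oracle_levene(x)
  expect_equal(lv$F, or$F, tolerance = 1e-10)
  expect_equal(lv$p, or$p, tolerance = 1e-10)
  # identical groups -> F = 0
  expect_equal(levene_test(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  # scaling one group by growing factors decreases p monotonically
  set.seed(6)
  base <- rnorm(20); other <- rnorm(20)
  ps <- vapply(c(1, 2, 4, 8), function(k)
    levene_test(list(base, other * k))$p, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("Holm step-down and SAT correlations behave", {
  # step-down by hand: 0.001 <= 0.05/4, but 0.02 > 0.05/3 stops the descent
  expect_equal(holm_significant(c(0.001, 0.02, 0.03, 0.8), 0.05),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(holm_significant(c(0.8, 0.01, 0.001, 0.012), 0.05),
               c(FALSE, TRUE, TRUE, TRUE))
  # agreement with p.adjust on random families
  for (i in 1:10) {
    set.seed(i); p <- runif(6)^2
    expect_equal(holm_significant(p, 0.05),
                 unname(p.adjust(p, "holm") <= 0.05))
  }
  # perfectly anticorrelated toy data
  df <- data.frame(group = "SI", session = "BEG",
                   rt_mean = 1:6, fa_rate = 6:1)
  expect_equal(sat_correlations(df)$r, -1)
  # family-wise error under independence (Holm over 4 cells)
  set.seed(11)
  fw <- vapply(1:2000, function(i) {
    d <- data.frame(group = rep(c("SI", "II"), each = 16),
                    session = rep(rep(c("BEG", "END"), each = 8), 2),
                    rt_mean = rnorm(32), fa_rate = rnorm(32))
    any(sat_correlations(d)$holm_significant)
  }, TRUE)
  expect_lte(mean(fw), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
})

test_that("Lilliefors-style KS test is calibrated and rejects non-normal data", {
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 3")
  null100 <- lilliefors_null(100, n_mc = 1500)
  expect_true(all(null100 >= 0 & null100 <= 1))
  set.seed(21)
  p_norm <- vapply(1:1000, function(i)
    ks_normality(rnorm(100), null = null100)$p, 0)
  expect_gte(mean(p_norm > 0.05), 0.94)
  p_unif <- vapply(1:200, function(i)
    ks_normality(runif(100), null = null100)$p, 0)
  expect_gt(mean(p_unif < 0.05), 0.5)
})

test_that("behavioral summaries aggregate the requested blocks", {
  cfg <- task_config(n_blocks = 2, trials_per_block = 40, go_per_block = 20,
                     nogo_per_block = 20)
  log <- simulate_behavior(generate_schedule(cfg, 3),
                           subject_profile("SI", fa_prob = 0.3), cfg, 4)
  log$subject <- 1; log$group <- "SI"
  s <- summarize_behavior(log, blocks = 1, session = "BEG")
  d1 <- log[log$block == 1, ]
  expect_equal(s$fa_rate, sum(d1$outcome == "FA") / 20)
  expect_equal(s$hit_rate, sum(d1$outcome == "HIT") / 20)
  expect_equal(s$rt_mean, mean(d1$rt_ms[d1$outcome == "HIT"]))
  expect_error(summarize_behavior(log, blocks = 99), "no trials")
  go_only <- log[log$stim == "GO", ]
  expect_error(summarize_behavior(go_only, blocks = 1), "no NoGo trials")
})
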