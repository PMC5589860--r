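#' Reject reaction-time outliers
#'
#' Removes responded Go trials whose RT deviates by strictly more than two
#' standard deviations from the subject's mean RT. Mean and SD are computed
#' per subject over responded Go trials only; false-alarm responses and
#' non-responded trials are never removed. The removed fraction (relative to
#' responded Go trials) is attached as attribute `"removed_fraction"`.
#'
#' @param log a trial log data frame with columns `subject`, `stim`
#'   (`"GO"`/`"NOGO"`), `response` (0/1), `rt_ms`
#' @param n_sd deviation threshold in SD units
#' @return the filtered trial log
#' @export
reject_rt_outliers <- function(log, n_sd = 2) {
  stopifnot(all(c("subject", "stim", "response", "rt_ms") %in% names(log)))
  go_resp <- log$stim == "GO" & log$response == 1 & !is.na(log$rt_ms)
  if (sum(go_resp) < 2) stop("need at least 2 responded Go trials")
  drop <- rep(FALSE, nrow(log))
  for (s in unique(log$subject)) {
    i <- which(go_resp & log$subject == s)
    if (length(i) < 2) next
    m <- mean(log$rt_ms[i]); sd_ <- stats::sd(log$rt_ms[i])
    drop[i] <- abs(log$rt_ms[i] - m) > n_sd * sd_
  }
  if (all(drop[go_resp])) stop("outlier rule removed every responded Go trial")
  out <- log[!drop, , drop = FALSE]
  attr(out, "removed_fraction") <- sum(drop) / sum(go_resp)
  out
}

#' Signal-detection scores for Go/NoGo performance
#'
#' Sensitivity `d' = z(hit) - z(fa)` and response criterion
#' `C = (z(hit) + z(fa)) / 2` (as printed in the source formula; the
#' conventional criterion is its negation, available via `c_sign`).
#' Rates of exactly 0 are replaced by `1/(2N)` and rates of exactly 1 by
#' `1 - 1/(2N)`, with `N` the trial count of the corresponding stimulus class
#' (the Macmillan-Creelman correction).
#'
#' @param hit_rate,fa_rate observed proportions in `[0, 1]`
#' @param n_go,n_nogo trial counts used for the boundary correction
#' @param c_sign `"printed"` keeps `C = (z(h)+z(f))/2` exactly as printed
#'   above; `"standard"` negates it (the conventional bias sign)
#' @return list with `d_prime`, `c_criterion`, and the corrected rates
#' @export
sdt_scores <- function(hit_rate, fa_rate, n_go, n_nogo,
                       c_sign = c("printed", "standard")) {
  c_sign <- match.arg(c_sign)
  stopifnot(n_go > 0, n_nogo > 0, hit_rate >= 0, hit_rate <= 1,
            fa_rate >= 0, fa_rate <= 1)
  fix <- function(p, n) {
    if (p == 0) 1 / (2 * n) else if (p == 1) 1 - 1 / (2 * n) else p
  }
  h <- fix(hit_rate, n_go); f <- fix(fa_rate, n_nogo)
  zh <- stats::qnorm(h); zf <- stats::qnorm(f)
  cc <- (zh + zf) / 2
  if (c_sign == "standard") cc <- -cc
  list(d_prime = zh - zf, c_criterion = cc, hit_rate = h, fa_rate = f)
}

#' Per-subject behavioral summary over a block selection
#'
#' Aggregates a trial log over the given blocks: mean RT over responded Go
#' trials (hits), `fa_rate = FA / (FA + CR)`, `hit_rate = HIT / (HIT + MISS)`,
#' plus signal-detection scores from the (boundary-corrected) rates. Raw
#' (uncorrected) rates are reported; the correction only enters `d_prime` and
#' `c_criterion`.
#'
#' @param log a (typically outlier-filtered) trial log for one or more
#'   subjects, with columns `subject`, `group`, `block`, `stim`, `response`,
#'   `rt_ms`, `outcome`
#' @param blocks block numbers to aggregate over
#' @param session label stored in the output (e.g. `"BEG"`)
#' @inheritParams sdt_scores
#' @return data frame, one row per subject
#' @export
summarize_behavior <- function(log, blocks, session = NA_character_,
                               c_sign = c("printed", "standard")) {
  c_sign <- match.arg(c_sign)
  sel <- log[log$block %in% blocks, , drop = FALSE]
  if (!nrow(sel)) stop("no trials in the selected blocks")
  subjects <- unique(log$subject)
  rows <- lapply(subjects, function(s) {
    d <- sel[sel$subject == s, , drop = FALSE]
    n_nogo <- sum(d$stim == "NOGO")
    if (n_nogo == 0) stop("no NoGo trials in the selection for subject ", s)
    n_go <- sum(d$stim == "GO")
    hits <- d$stim == "GO" & d$response == 1
    fa <- sum(d$outcome == "FA"); cr <- sum(d$outcome == "CR")
    hit <- sum(d$outcome == "HIT"); miss <- sum(d$outcome == "MISS")
    hit_rate <- hit / (hit + miss)
    fa_rate <- fa / (fa + cr)
    sc <- sdt_scores(hit_rate, fa_rate, n_go, n_nogo, c_sign)
    data.frame(subject = s,
               group = if ("group" %in% names(d)) d$group[1] else NA,
               session = session,
               rt_mean = mean(d$rt_ms[hits]),
               fa_rate = fa_rate, hit_rate = hit_rate,
               d_prime = sc$d_prime, c_criterion = sc$c_criterion,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.t_result <- function(t, df, p, d, variant) {
  structure(list(t = t, df = df, p = p, cohens_d = d, variant = variant),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t = %.3f, df = %.2f, p = %.4f, d = %.2f\n",
              x$variant, x$t, x$df, x$p, x$cohens_d))
  invisible(x)
}

.summary_args <- function(mean1, sd1, n1, mean2, sd2, n2) {
  # raw-sample calling convention: pooled_t(x, y)
  if (length(mean1) > 1 || length(sd1) > 1) {
    x <- mean1; y <- sd1
    list(m1 = mean(x), s1 = stats::sd(x), n1 = length(x),
         m2 = mean(y), s2 = stats::sd(y), n2 = length(y))
  } else {
    list(m1 = mean1, s1 = sd1, n1 = n1, m2 = mean2, s2 = sd2, n2 = n2)
  }
}

#' Two-sample t tests from summaries or raw samples
#'
#' `pooled_t()` is the classical equal-variance two-tailed test
#' (`df = n1 + n2 - 2`); `welch_t()` uses the unequal-variance statistic with
#' Satterthwaite degrees of freedom. Both accept either
#' `(mean1, sd1, n1, mean2, sd2, n2)` or two raw sample vectors
#' `pooled_t(x, y)`. Cohen's d is the mean difference over the pooled SD.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (or `mean1` = sample 1,
#'   `sd1` = sample 2)
#' @return a `t_test_result` list: `t`, `df`, `p`, `cohens_d`, `variant`
#' @export
pooled_t <- function(mean1, sd1, n1 = NULL, mean2 = NULL, sd2 = NULL, n2 = NULL) {
  a <- .summary_args(mean1, sd1, n1, mean2, sd2, n2)
  stopifnot(a$n1 >= 2, a$n2 >= 2)
  sp2 <- ((a$n1 - 1) * a$s1^2 + (a$n2 - 1) * a$s2^2) / (a$n1 + a$n2 - 2)
  df <- a$n1 + a$n2 - 2
  diff <- a$m1 - a$m2
  if (sp2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    t <- diff / sqrt(sp2 * (1 / a$n1 + 1 / a$n2))
  }
  d <- if (sp2 == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else diff / sqrt(sp2)
  .t_result(t, df, 2 * stats::pt(-abs(t), df), d, "pooled")
}

#' @rdname pooled_t
#' @export
welch_t <- function(mean1, sd1, n1 = NULL, mean2 = NULL, sd2 = NULL, n2 = NULL) {
  a <- .summary_args(mean1, sd1, n1, mean2, sd2, n2)
  stopifnot(a$n1 >= 2, a$n2 >= 2)
  v1 <- a$s1^2 / a$n1; v2 <- a$s2^2 / a$n2
  diff <- a$m1 - a$m2
  if (v1 + v2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    df <- a$n1 + a$n2 - 2
  } else {
    t <- diff / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (a$n1 - 1) + v2^2 / (a$n2 - 1))
  }
  sp2 <- ((a$n1 - 1) * a$s1^2 + (a$n2 - 1) * a$s2^2) / (a$n1 + a$n2 - 2)
  d <- if (sp2 == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else diff / sqrt(sp2)
  .t_result(t, df, 2 * stats::pt(-abs(t), df), d, "welch")
}

#' 2 x 2 mixed (split-plot) ANOVA
#'
#' One between-subject factor with two groups and one within-subject factor
#' with two levels, every subject measured at both levels. Effects are the
#' Type-III (unweighted-marginal-means) sums of squares, which coincide with
#' the classical decomposition for balanced groups. With two within levels
#' sphericity holds trivially. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with the matching error stratum.
#'
#' @param y1,y2 numeric vectors: each subject's value at within-level 1 and 2
#' @param group two-level factor/vector of group membership, same length
#' @return list of per-effect results (`between`, `within`, `interaction`),
#'   each with `F`, `df_num`, `df_den`, `p`, `partial_eta_sq`
#' @export
mixed_anova_2x2 <- function(y1, y2, group) {
  stopifnot(length(y1) == length(y2), length(group) == length(y1),
            !anyNA(y1), !anyNA(y2))
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required")
  n <- tabulate(g)
  if (any(n < 2)) stop("at least 2 subjects per group required")
  N <- sum(n)
  m <- (y1 + y2) / 2
  d <- y2 - y1
  ih <- 1 / n[1] + 1 / n[2]

  am <- tapply(m, g, mean)
  ad <- tapply(d, g, mean)
  ss_group <- 2 * (am[1] - am[2])^2 / ih
  ss_subj <- 2 * sum((m - am[g])^2)
  ss_sess <- 2 * mean(ad)^2 / ih            # = (sum(ad)/2)^2 * 4 / ih / 2
  ss_int <- (ad[1] - ad[2])^2 / ih / 2
  ss_werr <- sum((d - ad[g])^2) / 2

  df_den <- N - 2
  eff <- function(ss, ss_err) {
    Fv <- if (ss_err == 0) {
      if (ss == 0) 0 else Inf
    } else (ss / 1) / (ss_err / df_den)
    p <- if (is.infinite(Fv)) 0 else stats::pf(Fv, 1, df_den, lower.tail = FALSE)
    pes <- if (ss + ss_err == 0) 0 else ss / (ss + ss_err)
    list(F = unname(Fv), df_num = 1, df_den = df_den, p = unname(p),
         partial_eta_sq = unname(pes))
  }
  list(between = eff(unname(ss_group), ss_subj),
       within = eff(unname(ss_sess), ss_werr),
       interaction = eff(unname(ss_int), ss_werr))
}

#' Levene's test for homogeneity of variance (mean-centered)
#'
#' One-way ANOVA on the absolute deviations of each observation from its group
#' mean.
#'
#' @param samples list of numeric vectors, one per group
#' @return list with `F`, `df1`, `df2`, `p`
#' @export
levene_test <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(vapply(samples, length, 1L) < 2)) stop("each group needs >= 2 values")
  z <- lapply(samples, function(x) abs(x - mean(x)))
  g <- factor(rep(seq_along(z), vapply(z, length, 1L)))
  zz <- unlist(z)
  k <- length(z); N <- length(zz)
  gm <- tapply(zz, g, mean); grand <- mean(zz)
  ssb <- sum(tabulate(g) * (gm - grand)^2)
  ssw <- sum((zz - gm[g])^2)
  df1 <- k - 1; df2 <- N - k
  Fv <- if (ssw == 0) { if (ssb == 0) 0 else Inf } else (ssb / df1) / (ssw / df2)
  p <- if (is.infinite(Fv)) 0 else stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, df1 = df1, df2 = df2, p = p)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p vector of raw p-values
#' @param alpha family-wise error level
#' @return logical vector: which hypotheses are rejected
#' @export
holm_significant <- function(p, alpha = 0.05) {
  k <- length(p)
  o <- order(p)
  keep <- logical(k)
  for (i in seq_len(k)) {
    if (p[o[i]] <= alpha / (k - i + 1)) keep[o[i]] <- TRUE else break
  }
  keep
}

#' Speed-accuracy tradeoff correlations
#'
#' Pearson correlation between mean RT and false-alarm rate across subjects,
#' computed within each group x session cell, with a Holm-Bonferroni
#' correction over the resulting family of tests.
#'
#' @param summaries output of [summarize_behavior()] rows for all cells
#'   (columns `group`, `session`, `rt_mean`, `fa_rate`)
#' @param alpha family-wise level for the Holm correction
#' @return data frame with one row per group x session cell: `r`, `p`,
#'   `holm_significant`
#' @export
sat_correlations <- function(summaries, alpha = 0.05) {
  cells <- unique(summaries[, c("group", "session")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    d <- summaries[summaries$group == cells$group[i] &
                     summaries$session == cells$session[i], ]
    if (nrow(d) < 3) stop("need >= 3 subjects per cell for a correlation")
    if (stats::sd(d$rt_mean) == 0 || stats::sd(d$fa_rate) == 0)
      return(data.frame(group = cells$group[i], session = cells$session[i],
                        r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(d$rt_mean, d$fa_rate, method = "pearson")
    data.frame(group = cells$group[i], session = cells$session[i],
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$holm_significant <- NA
  ok <- !is.na(out$p)
  out$holm_significant[ok] <- holm_significant(out$p[ok], alpha)
  out
}

#' Null distribution of the Lilliefors statistic
#'
#' Monte-Carlo sample of the one-sample Kolmogorov-Smirnov statistic against
#' a normal distribution with parameters estimated from the data. Reusable
#' across calls to [ks_normality()] for the same sample size.
#'
#' @param n sample size
#' @param n_mc number of Monte-Carlo replicates
#' @return numeric vector of null statistics
#' @export
lilliefors_null <- function(n, n_mc = 2000) {
  vapply(seq_len(n_mc), function(i) .lilliefors_stat(stats::rnorm(n)), 0)
}

.lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  u <- stats::pnorm(z)
  i <- seq_len(n)
  max(i / n - u, u - (i - 1) / n)
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' The test statistic compares the empirical CDF with a normal CDF whose mean
#' and SD are estimated from the sample; because of the estimation the
#' standard KS p-value would be anticonservative, so the p-value is obtained
#' from a Monte-Carlo null distribution (Lilliefors-style).
#'
#' @param x numeric sample, `length(x) >= 3`, non-constant
#' @param null optional precomputed [lilliefors_null()] sample for `length(x)`
#' @param n_mc Monte-Carlo replicates when `null` is not supplied
#' @return list with statistic `D` and `p`
#' @export
ks_normality <- function(x, null = NULL, n_mc = 2000) {
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant sample")
  D <- .lilliefors_stat(x)
  if (is.null(null)) null <- lilliefors_null(length(x), n_mc)
  list(D = D, p = (sum(null >= D) + 1) / (length(null) + 1))
}
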