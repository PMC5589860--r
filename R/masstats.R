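# Vectorized 2x2 mixed ANOVA over many measurement points.
# Y1, Y2: subjects x points matrices (within-level 1 and 2); group: 2 levels.
# Closed forms mirror mixed_anova_2x2() exactly (Type-III, 1-df effects).
.mixed_map <- function(Y1, Y2, group) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2, nrow(Y1) == length(group),
            all(dim(Y1) == dim(Y2)))
  n <- tabulate(g); N <- sum(n)
  if (any(n < 2)) stop("at least 2 subjects per group required")
  ih <- 1 / n[1] + 1 / n[2]
  G <- stats::model.matrix(~ g - 1)               # N x 2 indicator
  M <- (Y1 + Y2) / 2
  D <- Y2 - Y1
  gm <- crossprod(G, M) / n                       # 2 x P group means of M
  gd <- crossprod(G, D) / n
  ss_group <- 2 * (gm[1, ] - gm[2, ])^2 / ih
  ss_subj <- 2 * (colSums(M^2) - n[1] * gm[1, ]^2 - n[2] * gm[2, ]^2)
  ss_sess <- 2 * ((gd[1, ] + gd[2, ]) / 2)^2 / ih
  ss_int <- (gd[1, ] - gd[2, ])^2 / ih / 2
  ss_werr <- (colSums(D^2) - n[1] * gd[1, ]^2 - n[2] * gd[2, ]^2) / 2
  df_den <- N - 2
  safe_f <- function(ss, err) {
    Fv <- ss / (err / df_den)
    Fv[err <= 0] <- ifelse(ss[err <= 0] <= 0, 0, Inf)
    Fv[Fv < 0] <- 0                               # guard tiny negatives
    Fv
  }
  f_int <- safe_f(ss_int, ss_werr)
  f_between <- safe_f(ss_group, ss_subj)
  f_within <- safe_f(ss_sess, ss_werr)
  pv <- function(Fv) stats::pf(Fv, 1, df_den, lower.tail = FALSE)
  list(F_interaction = f_int, p_interaction = pv(f_int),
       F_between = f_between, p_between = pv(f_between),
       F_within = f_within, p_within = pv(f_within),
       df_den = df_den)
}

#' Electrode x time mass-univariate mixed ANOVA
#'
#' Runs the 2 x 2 mixed ANOVA (one two-level between-subject factor, one
#' two-level within-subject factor) independently at every electrode and
#' time frame of a set of subject ERPs, and returns the interaction F and p
#' maps (between/within main-effect maps are attached for completeness).
#' Each point reproduces [mixed_anova_2x2()] exactly.
#'
#' @param Y1,Y2 subjects x electrodes x samples arrays: each subject's ERP at
#'   within-level 1 (e.g. HIT, or BEG) and 2 (CR, or END)
#' @param group group label per subject (two levels)
#' @param fs sampling rate in Hz (for ms conversion in period detection)
#' @param window epoch window in ms
#' @param design free-text tag stored in the result
#' @return object of class `stat_map` with `f_map` and `p_map`
#'   (electrodes x samples), plus metadata
#' @export
pointwise_interaction <- function(Y1, Y2, group, fs, window,
                                  design = "group-x-stimulus") {
  stopifnot(length(dim(Y1)) == 3, all(dim(Y1) == dim(Y2)))
  ns <- dim(Y1)[1]; ne <- dim(Y1)[2]; nt <- dim(Y1)[3]
  res <- .mixed_map(matrix(Y1, ns), matrix(Y2, ns), group)
  shape <- function(v) matrix(v, ne, nt)
  structure(list(f_map = shape(res$F_interaction),
                 p_map = shape(res$p_interaction),
                 f_between = shape(res$F_between),
                 p_between = shape(res$p_between),
                 f_within = shape(res$F_within),
                 p_within = shape(res$p_within),
                 df = c(1, res$df_den),
                 design = design, fs = fs, window = window,
                 n_electrodes = ne, n_samples = nt),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s: %d electrodes x %d samples, F(%d, %d)\n",
              x$design, x$n_electrodes, x$n_samples, x$df[1], x$df[2]))
  invisible(x)
}

# marked-sample indicator: for each time frame, is the count of significant
# electrodes at least ceiling(frac * n_electrodes)?
.marked_samples <- function(p_map, electrode_frac, alpha) {
  need <- ceiling(electrode_frac * nrow(p_map))
  colSums(p_map < alpha) >= need
}

.max_run <- function(marked) {
  if (!any(marked)) return(0L)
  r <- rle(marked)
  max(r$lengths[r$values])
}

#' Detect sustained interaction periods
#'
#' A time frame is *marked* when at least `ceiling(electrode_frac * n)`
#' electrodes are significant at `alpha` (with 64 electrodes and a fraction
#' of 0.10 the count threshold is 7). Maximal runs of marked frames lasting
#' at least `min_frames` frames are reported as sustained periods; the
#' default of 11 contiguous frames corresponds to about 10.7 ms at 1024 Hz.
#'
#' @param map a [pointwise_interaction()] result
#' @param electrode_frac minimum fraction of significant electrodes
#' @param min_frames minimum run length in frames
#' @param alpha point-wise significance threshold
#' @return data frame of periods: `start_ms`, `end_ms` (sample-center times),
#'   `frames`, `peak_electrode_fraction`
#' @export
find_sustained_periods <- function(map, electrode_frac = 0.10,
                                   min_frames = 11, alpha = 0.05) {
  stopifnot(inherits(map, "stat_map"))
  marked <- .marked_samples(map$p_map, electrode_frac, alpha)
  t_ms <- sample_times(map$fs, map$window, map$n_samples)
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_frames
  out <- data.frame(start_ms = t_ms[starts[keep]],
                    end_ms = t_ms[ends[keep]],
                    frames = r$lengths[keep])
  frac <- colSums(map$p_map < alpha) / map$n_electrodes
  out$peak_electrode_fraction <- vapply(which(keep), function(i) {
    max(frac[starts[i]:ends[i]])
  }, 0)
  out
}

#' Permutation calibration of the duration criterion
#'
#' Estimates how many contiguous marked frames arise by chance under the
#' null of no group effect: group labels are permuted between subjects
#' (respecting the within-subject pairing), the marked-frame sequence is
#' recomputed, and the maximum run length recorded. The returned duration
#' criterion is the 95th percentile of the null maximum run lengths plus one
#' frame (ties at the percentile round up, conservatively).
#'
#' @inheritParams pointwise_interaction
#' @param n_perm number of label permutations
#' @param alpha point-wise threshold
#' @param electrode_frac minimum fraction of significant electrodes
#' @param seed optional RNG seed for reproducibility
#' @return list with `min_frames` (the calibrated criterion) and
#'   `null_max_runs` (the permutation distribution)
#' @export
permutation_duration_threshold <- function(Y1, Y2, group, n_perm = 1000,
                                           alpha = 0.05, electrode_frac = 0.10,
                                           seed = NULL) {
  if (n_perm < 100) warning("fewer than 100 permutations; criterion unstable")
  if (!is.null(seed)) set.seed(seed)
  ns <- dim(Y1)[1]; ne <- dim(Y1)[2]; nt <- dim(Y1)[3]
  g <- factor(group)
  stopifnot(nlevels(g) == 2, length(group) == ns)
  n <- tabulate(g); N <- sum(n)
  ih <- 1 / n[1] + 1 / n[2]
  df_den <- N - 2
  # only the interaction F is needed per permutation, and only its
  # comparison against the fixed critical value
  D <- matrix(Y2, ns) - matrix(Y1, ns)
  d2 <- colSums(D^2)
  cs <- colSums(D)
  f_crit <- stats::qf(1 - alpha, 1, df_den)
  need <- ceiling(electrode_frac * ne)
  is_first <- as.integer(g) == 1L
  runs <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- sample(is_first)
    s1 <- crossprod(perm, D)[1, ]
    gd1 <- s1 / n[1]
    gd2 <- (cs - s1) / n[2]
    ss_int <- (gd1 - gd2)^2 / ih / 2
    ss_werr <- (d2 - n[1] * gd1^2 - n[2] * gd2^2) / 2
    f <- ss_int / (ss_werr / df_den)
    marked <- colSums(matrix(f > f_crit, ne)) >= need
    runs[i] <- .max_run(marked)
  }
  q <- sort(runs)[ceiling(0.95 * n_perm)]
  list(min_frames = as.integer(q) + 1L, null_max_runs = runs)
}
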