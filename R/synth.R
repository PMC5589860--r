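#' Task configuration for the Go/NoGo session
#'
#' Defaults encode the study design being emulated: 12 blocks of 60 trials
#' (30 Go / 30 NoGo in random order), an adaptive response-time threshold
#' (RTt) starting at 380 ms and then set to 90% of the previous block's mean
#' Go RT, 1500-1900 ms fixation, 500 ms stimulus, 1000 ms blank.
#'
#' @param n_blocks,trials_per_block,go_per_block,nogo_per_block counts
#' @param initial_rtt first-block response-time threshold, ms
#' @param rtt_fraction RTt as a fraction of the previous block's mean Go RT
#' @param fixation_range,stim_duration,blank_duration trial timing, ms
#' @return a `task_config` list
#' @export
task_config <- function(n_blocks = 12, trials_per_block = 60,
                        go_per_block = 30, nogo_per_block = 30,
                        initial_rtt = 380, rtt_fraction = 0.9,
                        fixation_range = c(1500, 1900),
                        stim_duration = 500, blank_duration = 1000) {
  if (go_per_block + nogo_per_block != trials_per_block)
    stop("go_per_block + nogo_per_block must equal trials_per_block")
  if (rtt_fraction <= 0 || rtt_fraction >= 1)
    stop("rtt_fraction must be in (0, 1)")
  structure(list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 go_per_block = go_per_block, nogo_per_block = nogo_per_block,
                 initial_rtt = initial_rtt, rtt_fraction = rtt_fraction,
                 fixation_range = fixation_range,
                 stim_duration = stim_duration,
                 blank_duration = blank_duration),
            class = "task_config")
}

#' Behavioral profile of a simulated subject
#'
#' Go RTs follow an ex-Gaussian model (Gaussian of mean
#' `rt_mean - rt_tau` and SD `rt_sd`, plus an exponential tail of mean
#' `rt_tau`), truncated at a 100 ms floor, with a linear practice drift of
#' `practice_rt_drift` ms per block. `rt_mean` is the expected RT in block 1.
#' NoGo trials produce false alarms with probability `fa_prob`; Go trials
#' are missed with probability `miss_prob`.
#'
#' @param group `"SI"` (standard instructions) or `"II"` (implementation
#'   intentions)
#' @param rt_mean,rt_sd,rt_tau ex-Gaussian parameters, ms
#' @param fa_prob,miss_prob outcome probabilities
#' @param practice_rt_drift RT change per block, ms
#' @return a `subject_profile` list
#' @export
subject_profile <- function(group = c("SI", "II"), rt_mean = 340, rt_sd = 20,
                            rt_tau = 55, fa_prob = 0.2, miss_prob = 0.02,
                            practice_rt_drift = 0) {
  group <- match.arg(group)
  stopifnot(rt_sd > 0, rt_tau >= 0,
            fa_prob >= 0, fa_prob <= 1, miss_prob >= 0, miss_prob <= 1)
  structure(list(group = group, rt_mean = rt_mean, rt_sd = rt_sd,
                 rt_tau = rt_tau, fa_prob = fa_prob, miss_prob = miss_prob,
                 practice_rt_drift = practice_rt_drift),
            class = "subject_profile")
}

#' Default group-level parameter distributions
#'
#' Group means are set so that the beginning-of-session (blocks 1-4)
#' aggregates land near the magnitudes the analysis is designed around:
#' SI false-alarm rate about 23%, II about 16%; SI mean Go RT about 337 ms,
#' II about 357 ms; with the faster group drifting more with practice.
#' `rt_mean_sd` and `fa_sd` are between-subject SDs used when drawing
#' subject-level parameters. The RT targets are post-outlier-rejection
#' means; trimming an ex-Gaussian at 2 SD removes mostly the right tail and
#' lowers the mean by about 8.5 ms (simulated analytically for
#' `rt_sd = 20`, `rt_tau = 55`), so that offset is folded into the raw
#' `rt_mean` defaults below.
#'
#' @return list with one parameter list per group
#' @export
group_profiles <- function() {
  list(
    SI = list(group = "SI", rt_mean = 350.9, rt_sd = 20, rt_tau = 55,
              fa_prob = 0.231, miss_prob = 0.02, practice_rt_drift = -3.5,
              rt_mean_sd = 28, fa_sd = 0.113),
    II = list(group = "II", rt_mean = 367.4, rt_sd = 20, rt_tau = 55,
              fa_prob = 0.158, miss_prob = 0.02, practice_rt_drift = -0.9,
              rt_mean_sd = 28, fa_sd = 0.068))
}

#' Generate a randomized block/trial schedule
#'
#' Each block holds exactly `go_per_block` Go and `nogo_per_block` NoGo
#' trials in seeded random order. Blocks come in pairs sharing a NoGo
#' criterion, alternating letter-based and color-based every two blocks;
#' the assignment of the concrete letter/color tokens to block pairs is a
#' seeded per-subject permutation (the tokens never enter the analysis, so
#' only the criterion label is recorded).
#'
#' @param config a [task_config()]
#' @param seed integer RNG seed
#' @return data frame (`task_schedule`): `block`, `trial`, `stim`,
#'   `criterion`
#' @export
generate_schedule <- function(config = task_config(), seed = 1) {
  stopifnot(inherits(config, "task_config"))
  set.seed(seed)
  if (config$n_blocks == 0)
    return(data.frame(block = integer(0), trial = integer(0),
                      stim = character(0), criterion = character(0)))
  n_pairs <- ceiling(config$n_blocks / 2)
  crit_pair <- rep(c("letter", "color"), length.out = n_pairs)
  # per-subject permutation of the letter tokens among letter pairs and the
  # color tokens among color pairs (token identity is not recorded)
  invisible(sample(sum(crit_pair == "letter")))
  invisible(sample(sum(crit_pair == "color")))
  rows <- lapply(seq_len(config$n_blocks), function(b) {
    stim <- sample(c(rep("GO", config$go_per_block),
                     rep("NOGO", config$nogo_per_block)))
    data.frame(block = b, trial = seq_along(stim), stim = stim,
               criterion = crit_pair[ceiling(b / 2)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# one ex-Gaussian RT draw vector, truncated at the 100 ms floor
.rt_draw <- function(n, mu, sd, tau) {
  rt <- stats::rnorm(n, mu, sd) + if (tau > 0) stats::rexp(n, 1 / tau) else 0
  pmax(rt, 100)
}

#' Simulate one subject's behavioral trial log
#'
#' Go trials receive ex-Gaussian RTs (mean drifting by `practice_rt_drift`
#' per block) and misses with `miss_prob`; NoGo trials receive false alarms
#' with `fa_prob`, with FA RTs drawn from the same RT model minus 30 ms.
#' The per-block RTt sequence follows the adaptive rule: block 1 uses
#' `initial_rtt`, every later block uses `rtt_fraction` times the mean
#' responded-Go RT of the preceding block. Trials with `rt > RTt` are
#' flagged `too_late` (they remain hits).
#'
#' @param schedule a [generate_schedule()] result
#' @param profile a [subject_profile()]
#' @param config the matching [task_config()]
#' @param seed integer RNG seed
#' @return data frame (`trial_log`): `block`, `trial`, `stim`, `response`,
#'   `rt_ms`, `outcome`, `rtt_ms`, `too_late`
#' @export
simulate_behavior <- function(schedule, profile, config = task_config(),
                              seed = 1) {
  stopifnot(inherits(profile, "subject_profile"))
  set.seed(seed)
  out <- schedule
  out$response <- 0L; out$rt_ms <- NA_real_
  out$outcome <- NA_character_; out$rtt_ms <- NA_real_; out$too_late <- 0L
  rtt <- config$initial_rtt
  for (b in unique(schedule$block)) {
    i <- which(schedule$block == b)
    mu_b <- profile$rt_mean - profile$rt_tau +
      profile$practice_rt_drift * (b - 1)
    go <- i[schedule$stim[i] == "GO"]
    nogo <- i[schedule$stim[i] == "NOGO"]
    miss <- stats::runif(length(go)) < profile$miss_prob
    out$response[go[!miss]] <- 1L
    out$rt_ms[go[!miss]] <- .rt_draw(sum(!miss), mu_b, profile$rt_sd,
                                     profile$rt_tau)
    out$outcome[go] <- ifelse(miss, "MISS", "HIT")
    fa <- stats::runif(length(nogo)) < profile$fa_prob
    out$response[nogo[fa]] <- 1L
    out$rt_ms[nogo[fa]] <- .rt_draw(sum(fa), mu_b - 30, profile$rt_sd,
                                    profile$rt_tau)
    out$outcome[nogo] <- ifelse(fa, "FA", "CR")
    out$rtt_ms[i] <- rtt
    out$too_late[i] <- as.integer(!is.na(out$rt_ms[i]) & out$rt_ms[i] > rtt)
    go_rts <- out$rt_ms[go[!miss]]
    if (length(go_rts)) rtt <- config$rtt_fraction * mean(go_rts)
  }
  out
}

.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + i * 7919) %% 2147483629)
}

#' Simulate a full two-group study
#'
#' Draws subject-level parameters around the group means (`rt_mean` normal
#' with SD `rt_mean_sd`; `fa_prob` normal with SD `fa_sd`, truncated to
#' `[0.005, 0.95]`) and simulates each subject's schedule and trial log.
#'
#' @param n_si,n_ii group sizes
#' @param profiles per-group parameter lists as from [group_profiles()]
#' @param config a [task_config()]
#' @param seed integer RNG seed; every subject's schedule and log get a
#'   derived seed
#' @return data frame (`study_log`) with `subject` and `group` columns
#'   prepended to the per-trial columns
#' @export
simulate_group_study <- function(n_si = 15, n_ii = 17,
                                 profiles = group_profiles(),
                                 config = task_config(), seed = 1) {
  if (n_si <= 0 || n_ii <= 0) stop("group sizes must be positive")
  set.seed(seed)
  groups <- c(rep("SI", n_si), rep("II", n_ii))
  subj_profiles <- lapply(seq_along(groups), function(s) {
    p <- profiles[[groups[s]]]
    rt <- stats::rnorm(1, p$rt_mean, p$rt_mean_sd)
    fa <- min(0.95, max(0.005, stats::rnorm(1, p$fa_prob, p$fa_sd)))
    subject_profile(p$group, rt_mean = rt, rt_sd = p$rt_sd, rt_tau = p$rt_tau,
                    fa_prob = fa, miss_prob = p$miss_prob,
                    practice_rt_drift = p$practice_rt_drift)
  })
  logs <- lapply(seq_along(groups), function(s) {
    sched <- generate_schedule(config, .derive_seed(seed, 2 * s))
    log <- simulate_behavior(sched, subj_profiles[[s]], config,
                             .derive_seed(seed, 2 * s + 1))
    cbind(data.frame(subject = s, group = groups[s],
                     stringsAsFactors = FALSE), log)
  })
  out <- do.call(rbind, logs)
  attr(out, "profiles") <- subj_profiles
  out
}

#' Read / write trial logs as TSV
#'
#' Columns: `subject`, `group`, `block`, `trial`, `stim`, `response`,
#' `rt_ms`, `outcome`, `rtt_ms`, `too_late` (plus any extras present).
#'
#' @param log a study/trial log data frame
#' @param path file path
#' @export
write_trial_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' EEG simulation configuration
#'
#' The signal model for every correct-trial epoch is: canonical components
#' (an N2-like fronto-central negativity near 200 ms and a P3-like
#' centro-parietal positivity near 350 ms, slightly larger for correct
#' rejections, with subject-level amplitude jitter), plus a planted
#' condition/group-specific source pattern active during `effect_window`,
#' plus spatially correlated 1/f^`pink_exponent` noise (random source-grid
#' dipoles projected through the lead field, band-shaped by a 40 Hz
#' second-order low-pass so that synthetic epochs mimic already-filtered
#' recordings) and white sensor noise.
#'
#' `effect_amplitude` is calibrated at the scalp: the planted interaction
#' pattern is scaled so its peak scalp deflection equals this many
#' microvolts (window-averaged, the 4 uV default plants a ~1.7 uV mean
#' effect at the peak electrode, a robust group-level ERP modulation).
#'
#' @param fs sampling rate, Hz
#' @param window epoch window, ms
#' @param noise_sd white sensor-noise SD per sample, uV
#' @param pink_sd spatially correlated 1/f noise SD per channel, uV
#' @param pink_exponent spectral slope of the correlated noise
#' @param lp_shape corner frequency (Hz) of the band-shaping low-pass
#'   applied to the correlated noise spectrum (`NULL` to disable)
#' @param n_noise_dipoles number of random noise dipoles per subject
#' @param effect_window ms pair; must lie inside `window`
#' @param effect_nodes indices of planted source nodes (`NULL`: a compact
#'   superficial right parieto-occipital patch is chosen from the grid)
#' @param effect_amplitude peak scalp amplitude of the planted effect, uV
#' @param effect_cell list with `group` and `condition`: the design cell
#'   that receives the planted effect
#' @param effect_blocks blocks in which the effect is active (`NULL` = all)
#' @param n2_amp,p3_amp canonical component amplitudes, uV
#' @param amp_jitter_sd between-subject SD of the canonical amplitude
#'   multipliers
#' @param artifact_prob per-epoch probability of a > 80 uV transient
#' @param bad_channel_prob per-subject probability of one corrupted channel
#' @return an `eeg_sim_config` list
#' @export
eeg_sim_config <- function(fs = 1024, window = c(-100, 500), noise_sd = 3,
                           pink_sd = 7, pink_exponent = 1, lp_shape = 40,
                           n_noise_dipoles = 40,
                           effect_window = c(218, 245), effect_nodes = NULL,
                           effect_amplitude = 4,
                           effect_cell = list(group = "II", condition = "CR"),
                           effect_blocks = NULL,
                           n2_amp = 4, p3_amp = 6, amp_jitter_sd = 0.2,
                           artifact_prob = 0.2, bad_channel_prob = 0.03) {
  stopifnot(fs > 0, effect_window[1] >= window[1],
            effect_window[2] <= window[2],
            artifact_prob >= 0, artifact_prob <= 1,
            bad_channel_prob >= 0, bad_channel_prob <= 1)
  structure(as.list(environment()), class = "eeg_sim_config")
}

# spectral amplitude profile for the correlated noise
.noise_amps <- function(nf, fs, n_samples, exponent, lp_shape) {
  f_hz <- (seq_len(nf)) * fs / n_samples
  a <- f_hz^(-exponent / 2)
  if (!is.null(lp_shape)) a <- a / sqrt(1 + (f_hz / lp_shape)^4)
  a
}

# n_series x n_samples matrix of zero-mean unit-variance colored noise
.colored_noise <- function(n_series, n_samples, amps) {
  nf <- length(amps)
  a <- amps * n_samples / (2 * sqrt(sum(amps^2)))
  C <- matrix(0 + 0i, n_samples, n_series)
  G <- matrix(stats::rnorm(nf * n_series), nf) +
    1i * matrix(stats::rnorm(nf * n_series), nf)
  C[2:(nf + 1), ] <- G * a
  C[n_samples:(n_samples - nf + 1), ] <- Conj(C[2:(nf + 1), ])
  t(Re(stats::mvfft(C, inverse = TRUE)) / n_samples)
}

# nearest grid node to a direction (unit vector) at a target radius
.nearest_node <- function(space, direction, radius_frac = 0.93) {
  target <- direction / sqrt(sum(direction^2)) * radius_frac * space$outer_r
  which.min(colSums((t(space$nodes) - target)^2))
}

# normalized scalp pattern (peak |.| = 1) of radial dipoles at `nodes`
.node_pattern <- function(lf, space, nodes) {
  o <- space$nodes[nodes, , drop = FALSE]
  o <- o / sqrt(rowSums(o^2))
  topo <- lf$G$x[, nodes, drop = FALSE] %*% o[, 1] +
    lf$G$y[, nodes, drop = FALSE] %*% o[, 2] +
    lf$G$z[, nodes, drop = FALSE] %*% o[, 3]
  topo <- as.numeric(topo)
  topo / max(abs(topo))
}

# electrode mixing matrix for random noise dipoles: column k is the scalp
# pattern of a unit dipole at node k with the given orientation, scaled so
# the summed field has RMS `sd_target` per channel
.noise_mixing <- function(lf, nodes, orient, sd_target) {
  B <- lf$G$x[, nodes, drop = FALSE] * rep(orient[, 1], each = lf$n_electrodes) +
    lf$G$y[, nodes, drop = FALSE] * rep(orient[, 2], each = lf$n_electrodes) +
    lf$G$z[, nodes, drop = FALSE] * rep(orient[, 3], each = lf$n_electrodes)
  B <- B %*% diag(1 / sqrt(colMeans(B^2)), length(nodes))
  B * (sd_target / sqrt(length(nodes)))
}

#' Default planted effect nodes
#'
#' A compact patch (nodes within `patch_radius` mm of a superficial right
#' parieto-occipital seed) standing in for the posterior sources the
#' analysis is meant to recover.
#'
#' @param space a [build_source_grid()] result
#' @param patch_radius patch radius in mm
#' @return integer node indices
#' @export
default_effect_nodes <- function(space, patch_radius = 10) {
  seed_node <- .nearest_node(space, c(0.35, -0.6, 0.72))
  center <- space$nodes[seed_node, ]
  which(sqrt(colSums((t(space$nodes) - center)^2)) <= patch_radius)
}

#' Simulate one subject's EEG epochs
#'
#' Produces one epoch per correct trial (HIT and CR), per the signal model
#' documented in [eeg_sim_config()]. With probability `artifact_prob` an
#' epoch receives a 120 uV transient (guaranteeing downstream rejection at
#' the 80 uV criterion) and with probability `bad_channel_prob` one channel
#' carries heavy noise in every epoch (reported in the `bad_channels`
#' field for interpolation).
#'
#' @param sub_log one subject's trial log (columns `block`, `stim`,
#'   `response`, `outcome`)
#' @param group the subject's group label
#' @param lf a [compute_lead_field()]
#' @param space the matching [build_source_grid()]
#' @param cfg an [eeg_sim_config()]
#' @param seed integer RNG seed
#' @param blocks blocks to simulate (default: all in the log)
#' @return list with [epoch_set()]s `HIT` and `CR` and `bad_channels`
#' @export
simulate_subject_eeg <- function(sub_log, group, lf, space, cfg, seed = 1,
                                 blocks = NULL) {
  stopifnot(inherits(cfg, "eeg_sim_config"), inherits(lf, "lead_field"))
  set.seed(seed)
  if (is.null(blocks)) blocks <- unique(sub_log$block)
  log <- sub_log[sub_log$block %in% blocks &
                   sub_log$outcome %in% c("HIT", "CR"), , drop = FALSE]
  ne <- lf$n_electrodes
  n_s <- floor((cfg$window[2] - cfg$window[1]) * cfg$fs / 1000)
  t_ms <- sample_times(cfg$fs, cfg$window, n_s)

  effect_nodes <- cfg$effect_nodes
  if (is.null(effect_nodes)) effect_nodes <- default_effect_nodes(space)
  if (any(effect_nodes < 1 | effect_nodes > lf$n_nodes))
    stop("effect_nodes outside the source space")

  n2_topo <- .node_pattern(lf, space, .nearest_node(space, c(0, 0.30, 0.95)))
  p3_topo <- .node_pattern(lf, space, .nearest_node(space, c(0, -0.45, 0.89)))
  eff_topo <- .node_pattern(lf, space, effect_nodes) * cfg$effect_amplitude
  n2_w <- -exp(-(t_ms - 200)^2 / (2 * 25^2))
  p3_w <- exp(-(t_ms - 350)^2 / (2 * 45^2))
  in_win <- t_ms >= cfg$effect_window[1] & t_ms <= cfg$effect_window[2]
  eff_w <- numeric(n_s)
  if (any(in_win)) {
    u <- seq(0, 1, length.out = sum(in_win))
    eff_w[in_win] <- 0.5 - 0.5 * cos(2 * pi * u)   # Hann window
  }

  amp_n2 <- max(0, stats::rnorm(1, 1, cfg$amp_jitter_sd))
  amp_p3 <- max(0, stats::rnorm(1, 1, cfg$amp_jitter_sd))

  noise_nodes <- sample(lf$n_nodes, cfg$n_noise_dipoles, replace = TRUE)
  orient <- matrix(stats::rnorm(3 * cfg$n_noise_dipoles), ncol = 3)
  orient <- orient / sqrt(rowSums(orient^2))
  B <- .noise_mixing(lf, noise_nodes, orient, cfg$pink_sd)

  amps <- .noise_amps(floor((n_s - 1) / 2), cfg$fs, n_s,
                      cfg$pink_exponent, cfg$lp_shape)
  bad_channels <- integer(0)
  if (stats::runif(1) < cfg$bad_channel_prob)
    bad_channels <- sample(ne, 1)

  make_cond <- function(cond) {
    sel <- which(log$outcome == if (cond == "HIT") "HIT" else "CR")
    dat <- array(0, c(ne, n_s, length(sel)))
    base_scale <- if (cond == "CR") c(1.3, 1.15) else c(1, 1)
    clean <- outer(n2_topo, n2_w) * (cfg$n2_amp * amp_n2 * base_scale[1]) +
      outer(p3_topo, p3_w) * (cfg$p3_amp * amp_p3 * base_scale[2])
    for (j in seq_along(sel)) {
      trial <- log[sel[j], ]
      ep <- clean
      has_effect <- group == cfg$effect_cell$group &&
        cond == cfg$effect_cell$condition &&
        (is.null(cfg$effect_blocks) || trial$block %in% cfg$effect_blocks)
      if (has_effect) ep <- ep + outer(eff_topo, eff_w)
      ep <- ep + B %*% .colored_noise(cfg$n_noise_dipoles, n_s, amps) +
        matrix(stats::rnorm(ne * n_s, 0, cfg$noise_sd), ne)
      if (length(bad_channels))
        ep[bad_channels, ] <- ep[bad_channels, ] +
          stats::rnorm(n_s, 0, 60)
      if (stats::runif(1) < cfg$artifact_prob) {
        ch <- sample(ne, 1); t0 <- sample(n_s - 4, 1)
        ep[ch, t0 + 0:4] <- ep[ch, t0 + 0:4] +
          sample(c(-1, 1), 1) * 120 * c(0.25, 0.75, 1, 0.75, 0.25)
      }
      dat[, , j] <- ep
    }
    epoch_set(dat, cfg$fs, cfg$window, blocks = log$block[sel],
              condition = cond)
  }
  list(HIT = make_cond("HIT"), CR = make_cond("CR"),
       bad_channels = bad_channels)
}

#' Simulate EEG for every subject of a study
#'
#' Convenience wrapper over [simulate_subject_eeg()]; note the memory cost
#' at full scale (all epochs of all subjects are returned). Pipelines that
#' only need ERPs should simulate and average per subject instead.
#'
#' @param study a [simulate_group_study()] log
#' @inheritParams simulate_subject_eeg
#' @return list (one element per subject) of [simulate_subject_eeg()] results
#' @export
simulate_eeg <- function(study, lf, space, cfg, seed = 1, blocks = NULL) {
  subjects <- unique(study$subject)
  stats::setNames(lapply(subjects, function(s) {
    sub <- study[study$subject == s, ]
    simulate_subject_eeg(sub, sub$group[1], lf, space, cfg,
                         seed = .derive_seed(seed, 100 + s), blocks = blocks)
  }), paste0("S", subjects))
}

#' Subject-level null ERPs for calibration experiments
#'
#' Generates subject-by-condition ERPs directly at the ERP level: canonical
#' components (with subject amplitude jitter, identical across groups, i.e.
#' a group-null) plus correlated 1/f noise and white noise scaled by
#' `1/sqrt(n_epochs)`, exactly the spectrum an average of `n_epochs` noise
#' epochs would have. This makes large null-calibration simulations (e.g.
#' family-wise error rates of the sensor-space procedure) affordable
#' without simulating individual epochs.
#'
#' @param n1,n2 subjects per group
#' @param lf,space head model
#' @param cfg an [eeg_sim_config()] (the planted effect is ignored)
#' @param n_epochs nominal epoch count per ERP
#' @param seed integer RNG seed
#' @return list with arrays `Y1`, `Y2` (subjects x electrodes x samples) and
#'   `group`
#' @export
simulate_null_erps <- function(n1, n2, lf, space, cfg, n_epochs = 90,
                               seed = 1) {
  set.seed(seed)
  ne <- lf$n_electrodes
  n_s <- floor((cfg$window[2] - cfg$window[1]) * cfg$fs / 1000)
  t_ms <- sample_times(cfg$fs, cfg$window, n_s)
  n2_topo <- .node_pattern(lf, space, .nearest_node(space, c(0, 0.30, 0.95)))
  p3_topo <- .node_pattern(lf, space, .nearest_node(space, c(0, -0.45, 0.89)))
  n2_w <- -exp(-(t_ms - 200)^2 / (2 * 25^2))
  p3_w <- exp(-(t_ms - 350)^2 / (2 * 45^2))
  amps <- .noise_amps(floor((n_s - 1) / 2), cfg$fs, n_s,
                      cfg$pink_exponent, cfg$lp_shape)
  ns <- n1 + n2
  group <- c(rep("SI", n1), rep("II", n2))
  Y1 <- array(0, c(ns, ne, n_s)); Y2 <- array(0, c(ns, ne, n_s))
  scl <- 1 / sqrt(n_epochs)
  for (s in seq_len(ns)) {
    a_n2 <- max(0, stats::rnorm(1, 1, cfg$amp_jitter_sd))
    a_p3 <- max(0, stats::rnorm(1, 1, cfg$amp_jitter_sd))
    noise_nodes <- sample(lf$n_nodes, cfg$n_noise_dipoles, replace = TRUE)
    orient <- matrix(stats::rnorm(3 * cfg$n_noise_dipoles), ncol = 3)
    orient <- orient / sqrt(rowSums(orient^2))
    B <- .noise_mixing(lf, noise_nodes, orient, cfg$pink_sd * scl)
    for (lev in 1:2) {
      cscale <- if (lev == 2) c(1.3, 1.15) else c(1, 1)
      e <- outer(n2_topo, n2_w) * (cfg$n2_amp * a_n2 * cscale[1]) +
        outer(p3_topo, p3_w) * (cfg$p3_amp * a_p3 * cscale[2]) +
        B %*% .colored_noise(cfg$n_noise_dipoles, n_s, amps) +
        matrix(stats::rnorm(ne * n_s, 0, cfg$noise_sd * scl), ne)
      if (lev == 1) Y1[s, , ] <- e else Y2[s, , ] <- e
    }
  }
  list(Y1 = Y1, Y2 = Y2, group = group)
}
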