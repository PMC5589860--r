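# Shared fixtures, built once per test run and cached.
# Heavy geometry (full-resolution grid + lead field + LAURA operator) is
# reused across test files; smaller stand-ins keep unit tests fast.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fix_montage <- function() fixture("montage", function() make_montage_64())

# full default grid (~3000 nodes, 6 mm)
fix_space <- function() fixture("space", function() build_source_grid())

# coarse 12-mm grid for cheap unit tests
fix_space_coarse <- function() fixture("space_coarse", function()
  build_source_grid(spacing = 12, target_n = NULL))

fix_leadfield <- function() fixture("leadfield", function()
  compute_lead_field(fix_space(), fix_montage()))

fix_laura <- function() fixture("laura", function()
  build_laura_operator(fix_leadfield(), fix_space()))

# small ERP-design dataset generator (subjects x electrodes x samples)
make_toy_design <- function(ns = 12, ne = 8, nt = 20, seed = 1,
                            effect = 0, effect_idx = NULL) {
  set.seed(seed)
  group <- rep(c("SI", "II"), length.out = ns)
  Y1 <- array(rnorm(ns * ne * nt), c(ns, ne, nt))
  Y2 <- array(rnorm(ns * ne * nt), c(ns, ne, nt))
  if (effect != 0 && !is.null(effect_idx)) {
    for (s in which(group == "II"))
      Y2[s, effect_idx$electrodes, effect_idx$samples] <-
        Y2[s, effect_idx$electrodes, effect_idx$samples] + effect
  }
  list(Y1 = Y1, Y2 = Y2, group = group)
}

# end-to-end Group x Stimulus recovery driver: full subject counts and
# per-trial SNR at the generator defaults, sampling rate reduced (the
# duration criterion scales with fs through its ~10.7 ms definition) and
# only the four BEG blocks simulated, to keep 20-seed batteries inside the
# test-time budget.
run_gxs_recovery <- function(seed, hm, fs = 256) {
  cfg <- run_config(eeg = list(fs = fs))
  study <- simulate_group_study(cfg$n_si, cfg$n_ii, cfg$profiles, cfg$task,
                                seed = enigo:::.derive_seed(seed, 1))
  subjects <- unique(study$subject)
  group <- vapply(subjects, function(s) study$group[study$subject == s][1], "")
  erps <- lapply(seq_along(subjects), function(i) {
    sub <- study[study$subject == subjects[i], ]
    eeg <- simulate_subject_eeg(sub, group[i], hm$lf, hm$space, cfg$eeg,
                                seed = enigo:::.derive_seed(seed, 500 + i),
                                blocks = 1:4)
    m <- suppressWarnings(match_trial_counts(eeg$HIT, eeg$CR))
    out <- lapply(m, function(set) {
      e <- average_erp(
        suppressWarnings(reject_artifacts(set, exclude_channels = eeg$bad_channels)))
      if (length(eeg$bad_channels))
        e <- interpolate_bad_channels(e, hm$lf$montage, eeg$bad_channels)
      e
    })
    names(out) <- c("HIT", "CR")
    out
  })
  ne <- hm$lf$n_electrodes
  nt <- floor(600 * fs / 1000)
  Y1 <- array(0, c(length(erps), ne, nt)); Y2 <- Y1
  for (i in seq_along(erps)) {
    Y1[i, , ] <- erps[[i]]$HIT$data
    Y2[i, , ] <- erps[[i]]$CR$data
  }
  map <- pointwise_interaction(Y1, Y2, group, fs = fs, window = c(-100, 500))
  min_frames <- max(2L, as.integer(ceiling(cfg$erp$min_duration_ms * fs / 1000)))
  periods <- find_sustained_periods(map, 0.10, min_frames, 0.05)
  hits <- which(periods$start_ms <= 245 & periods$end_ms >= 218)
  planted <- default_effect_nodes(hm$space)
  cluster_ok <- FALSE
  for (i in hits) {
    per <- c(periods$start_ms[i], periods$end_ms[i])
    topo <- function(cond) t(vapply(erps, function(e)
      average_erp_period(e[[cond]], per), numeric(ne)))
    D1 <- t(apply(topo("HIT"), 1, function(v) apply_inverse(hm$op, v)$density))
    D2 <- t(apply(topo("CR"), 1, function(v) apply_inverse(hm$op, v)$density))
    smap <- nodewise_interaction(D1, D2, group)
    cl <- find_clusters(smap, hm$space, alpha = 0.05, k_e = 15, radius = 8.5)
    if (any(vapply(cl, function(x) any(x$nodes %in% planted), TRUE)))
      cluster_ok <- TRUE
  }
  list(period_ok = length(hits) > 0, cluster_ok = cluster_ok)
}
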