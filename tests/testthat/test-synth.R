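test_that("schedules have exact block composition and alternating criteria", {
  cfg <- task_config()
  s <- generate_schedule(cfg, seed = 11)
  expect_equal(length(unique(s$block)), 12)
  comp <- tapply(s$stim, s$block, function(x) c(sum(x == "GO"), sum(x == "NOGO")))
  for (b in comp) expect_equal(unname(b), c(30, 30))
  crit <- tapply(s$criterion, s$block, function(x) unique(x))
  expect_equal(as.vector(unlist(crit)),
               rep(rep(c("letter", "color"), each = 2), 3))
  # determinism and empty case
  expect_identical(s, generate_schedule(cfg, seed = 11))
  expect_false(identical(s$stim, generate_schedule(cfg, seed = 12)$stim))
  empty <- generate_schedule(task_config(n_blocks = 0), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(task_config(go_per_block = 31), "must equal")
})

test_that("RTt sequence follows the adaptive 90% rule exactly", {
  cfg <- task_config()
  sched <- generate_schedule(cfg, seed = 2)
  prof <- subject_profile("SI", rt_mean = 350, practice_rt_drift = -3)
  log <- simulate_behavior(sched, prof, cfg, seed = 3)
  rtt <- tapply(log$rtt_ms, log$block, function(x) unique(x))
  expect_equal(unname(rtt[[1]]), 380)
  for (b in 2:12) {
    prev <- log[log$block == b - 1 & log$stim == "GO" & log$response == 1, ]
    expect_equal(unname(rtt[[b]]), 0.9 * mean(prev$rt_ms))
  }
  # too-late flags consistent with the emitted threshold
  responded <- !is.na(log$rt_ms)
  expect_equal(log$too_late[responded],
               as.integer(log$rt_ms[responded] > log$rtt_ms[responded]))
})

test_that("degenerate outcome probabilities behave", {
  cfg <- task_config()
  sched <- generate_schedule(cfg, seed = 4)
  log0 <- simulate_behavior(sched, subject_profile("SI", fa_prob = 0),
                            cfg, seed = 5)
  expect_equal(sum(log0$outcome == "FA"), 0)
  log1 <- simulate_behavior(sched, subject_profile("SI", fa_prob = 1,
                                                   miss_prob = 1), cfg, seed = 5)
  expect_equal(sum(log1$outcome == "CR"), 0)
  expect_equal(sum(log1$outcome == "HIT"), 0)
})

test_that("study simulation is deterministic and hits the stated group magnitudes", {
  study <- simulate_group_study(seed = 9)
  expect_identical(study, simulate_group_study(seed = 9))
  expect_equal(length(unique(study$subject)), 32)
  expect_equal(nrow(study), 32 * 720)
  # magnitude checks across a few studies (stochastic, wide bands)
  fa_diff <- rt_si <- numeric(6)
  for (i in 1:6) {
    st <- simulate_group_study(seed = 100 + i)
    f <- reject_rt_outliers(st)
    beg <- summarize_behavior(f, 1:4, "BEG")
    fa_diff[i] <- mean(beg$fa_rate[beg$group == "SI"]) -
      mean(beg$fa_rate[beg$group == "II"])
    rt_si[i] <- mean(beg$rt_mean[beg$group == "SI"])
  }
  expect_gt(mean(fa_diff), 0.02)   # SI makes more false alarms
  expect_lt(abs(mean(rt_si) - 337), 25)
})

test_that("group-null profiles give nominal t-test type-I error", {
  # scaled down for runtime (smaller blocks/groups); the type-I property is
  # size-free. 2000 studies, band 0.05 +/- 0.01 per the calibration target.
  cfg <- task_config(n_blocks = 4, trials_per_block = 10, go_per_block = 5,
                     nogo_per_block = 5)
  prof <- group_profiles()
  prof$II <- prof$SI; prof$II$group <- "II"   # identical groups
  rej <- logical(2000)
  for (i in seq_len(2000)) {
    st <- simulate_group_study(n_si = 6, n_ii = 6, profiles = prof,
                               config = cfg, seed = i)
    beg <- summarize_behavior(st, 1:4, "BEG")
    tt <- pooled_t(beg$rt_mean[beg$group == "SI"],
                   beg$rt_mean[beg$group == "II"])
    rej[i] <- tt$p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("trial log round-trips through TSV", {
  study <- simulate_group_study(n_si = 2, n_ii = 2, seed = 3,
                                config = task_config(n_blocks = 2,
                                                     trials_per_block = 10,
                                                     go_per_block = 5,
                                                     nogo_per_block = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_log(study, path)
  back <- read_trial_log(path)
  expect_equal(back$rt_ms, study$rt_ms)
  expect_equal(back$outcome, study$outcome)
})

test_that("EEG epochs carry the planted effect and respect degenerate configs", {
  space <- fix_space_coarse()
  lf <- fixture("lf_coarse", function()
    compute_lead_field(fix_space_coarse(), fix_montage()))
  cfg <- task_config(n_blocks = 2, trials_per_block = 10, go_per_block = 5,
                     nogo_per_block = 5)
  sched <- generate_schedule(cfg, 1)
  log <- simulate_behavior(sched, subject_profile("II", fa_prob = 0.2), cfg, 2)

  # zero amplitude + zero noise: identical across groups, zero variance
  base <- eeg_sim_config(fs = 128, noise_sd = 0, pink_sd = 0,
                         effect_amplitude = 0, artifact_prob = 0,
                         bad_channel_prob = 0, amp_jitter_sd = 0)
  a <- simulate_subject_eeg(log, "II", lf, space, base, seed = 7)
  b <- simulate_subject_eeg(log, "SI", lf, space, base, seed = 7)
  expect_equal(a$CR$data, b$CR$data)
  expect_equal(a$CR$data[, , 1], a$CR$data[, , 2])

  # planted effect appears only in the configured cell and window
  eff <- eeg_sim_config(fs = 128, noise_sd = 0, pink_sd = 0,
                        effect_amplitude = 4, artifact_prob = 0,
                        bad_channel_prob = 0, amp_jitter_sd = 0)
  a2 <- simulate_subject_eeg(log, "II", lf, space, eff, seed = 7)
  dif <- a2$CR$data[, , 1] - a$CR$data[, , 1]
  t_ms <- sample_times(128, c(-100, 500))
  expect_equal(max(abs(dif)), 4, tolerance = 1e-6)
  expect_true(all(abs(dif[, t_ms < 218 | t_ms > 245]) < 1e-9))
  expect_equal(a2$HIT$data, a$HIT$data)   # HIT cell unaffected

  # artifact_prob = 1: every epoch rejected downstream
  art <- eeg_sim_config(fs = 128, artifact_prob = 1, bad_channel_prob = 0)
  a3 <- simulate_subject_eeg(log, "SI", lf, space, art, seed = 8)
  expect_warning(kept <- reject_artifacts(a3$HIT), "all epochs rejected")
  expect_equal(dim(kept$data)[3], 0)

  # out-of-range effect nodes error
  bad_cfg <- eeg_sim_config(fs = 128, effect_nodes = nrow(space$nodes) + 5L)
  expect_error(simulate_subject_eeg(log, "II", lf, space, bad_cfg, seed = 1),
               "outside the source space")

  # determinism
  expect_equal(simulate_subject_eeg(log, "II", lf, space, eff, seed = 9),
               simulate_subject_eeg(log, "II", lf, space, eff, seed = 9))
})
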