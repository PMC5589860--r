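#' Full-run configuration
#'
#' Nested per-module configuration for [run_all()]. All defaults equal the
#' design the package emulates: 15 + 17 subjects, 12 blocks of 60 trials,
#' 1024 Hz / 64 channels, BEG = blocks 1-4, END = blocks 9-12, a 10%
#' electrode / ~10.7 ms duration criterion at the sensor level, and a
#' `k_E = 15` cluster-extent criterion at 8.5 mm connectivity in source
#' space. Any field can be overridden via `...` (nested lists are merged).
#'
#' @param ... named overrides, e.g. `n_si = 8`,
#'   `eeg = list(fs = 256)`
#' @return a `run_config` list
#' @export
run_config <- function(...) {
  base <- list(
    n_si = 15, n_ii = 17,
    task = task_config(),
    profiles = group_profiles(),
    eeg = eeg_sim_config(),
    headmodel = list(head_radius = 85, spacing = 6, shell = c(0.35, 0.80),
                     target_n = 3005),
    beg_blocks = 1:4, end_blocks = 9:12,
    erp = list(electrode_frac = 0.10, min_duration_ms = 11 * 1000 / 1024,
               alpha = 0.05, calibrate = FALSE, n_perm = 1000),
    source = list(lambda_snr = 3, k_e = 15, radius = 8.5, alpha = 0.05),
    artifact_threshold = 80,
    baseline = FALSE,
    sdt_c_sign = "printed")
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(base[[nm]]) && is.list(dots[[nm]]) &&
        !inherits(base[[nm]], c("task_config", "eeg_sim_config"))) {
      base[[nm]] <- utils::modifyList(base[[nm]], dots[[nm]])
    } else if (inherits(base[[nm]], c("task_config", "eeg_sim_config")) &&
               is.list(dots[[nm]]) && is.null(attr(dots[[nm]], "class"))) {
      args <- utils::modifyList(unclass(base[[nm]]), dots[[nm]])
      base[[nm]] <- do.call(if (nm == "task") task_config else eeg_sim_config,
                            args)
    } else {
      base[[nm]] <- dots[[nm]]
    }
  }
  structure(base, class = "run_config")
}

#' Build the head model bundle for a run configuration
#'
#' Deterministic given the configuration: source grid, synthetic montage,
#' three-shell lead field and LAURA inverse operator.
#'
#' @param config a [run_config()]
#' @return list with `space`, `montage`, `lf`, `op`
#' @export
build_head_model <- function(config = run_config()) {
  hm <- config$headmodel
  space <- build_source_grid(hm$head_radius, hm$spacing, hm$shell, hm$target_n)
  mont <- make_montage_64(hm$head_radius)
  lf <- compute_lead_field(space, mont)
  op <- build_laura_operator(lf, space, lambda_snr = config$source$lambda_snr)
  list(space = space, montage = mont, lf = lf, op = op)
}

#' Epoch-count control ANOVA
#'
#' Applies the same 2 x 2 mixed design used for the ERP voltages to the
#' number of epochs retained per condition, to verify that trial-count
#' differences cannot drive the voltage effects.
#'
#' @param counts1,counts2 per-subject epoch counts at the two within levels
#' @param group group label per subject
#' @return a [mixed_anova_2x2()] result
#' @export
epoch_count_control <- function(counts1, counts2, group) {
  mixed_anova_2x2(as.numeric(counts1), as.numeric(counts2), group)
}

# behavioral battery on one study log
.behavior_report <- function(study, config) {
  filtered <- reject_rt_outliers(study)
  beg <- summarize_behavior(filtered, config$beg_blocks, "BEG",
                            c_sign = config$sdt_c_sign)
  end <- summarize_behavior(filtered, config$end_blocks, "END",
                            c_sign = config$sdt_c_sign)
  summaries <- rbind(beg, end)
  si <- beg$group == "SI"

  immediate <- lapply(
    c(rt_mean = "rt_mean", fa_rate = "fa_rate",
      d_prime = "d_prime", c_criterion = "c_criterion"),
    function(v) {
      lev <- levene_test(list(beg[[v]][si], beg[[v]][!si]))
      tt <- if (lev$p < 0.05) welch_t(beg[[v]][si], beg[[v]][!si])
      else pooled_t(beg[[v]][si], beg[[v]][!si])
      list(levene = lev, t_test = unclass(tt))
    })

  practice <- lapply(
    c(rt_mean = "rt_mean", fa_rate = "fa_rate",
      d_prime = "d_prime", c_criterion = "c_criterion"),
    function(v) mixed_anova_2x2(beg[[v]], end[[v]], beg$group))

  list(removed_rt_fraction = attr(filtered, "removed_fraction"),
       summaries = summaries,
       immediate = immediate,
       practice = practice,
       sat = sat_correlations(summaries))
}

# per-subject ERP construction: simulate epochs, match HIT/CR per block
# within each session, reject artifacts, average, interpolate bad channels
.subject_erps <- function(sub_log, group, lf, space, config, seed) {
  eeg <- simulate_subject_eeg(sub_log, group, lf, space, config$eeg,
                              seed = seed,
                              blocks = c(config$beg_blocks, config$end_blocks))
  out <- list(); counts <- list()
  for (ses in c("BEG", "END")) {
    blocks <- if (ses == "BEG") config$beg_blocks else config$end_blocks
    hit <- subset_epochs(eeg$HIT, which(eeg$HIT$blocks %in% blocks))
    cr <- subset_epochs(eeg$CR, which(eeg$CR$blocks %in% blocks))
    m <- match_trial_counts(hit, cr)
    for (cond in c("HIT", "CR")) {
      set <- if (cond == "HIT") m[[1]] else m[[2]]
      set <- reject_artifacts(set, config$artifact_threshold,
                              exclude_channels = eeg$bad_channels)
      e <- average_erp(set)
      if (config$baseline) {
        pre <- sample_times(e$fs, e$window, ncol(e$data)) < 0
        if (any(pre)) e$data <- e$data - rowMeans(e$data[, pre, drop = FALSE])
      }
      if (length(eeg$bad_channels))
        e <- interpolate_bad_channels(e, lf$montage, eeg$bad_channels)
      key <- paste(cond, ses, sep = ".")
      e$condition <- key
      out[[key]] <- e
      counts[[key]] <- e$n_epochs
    }
  }
  list(erps = out, counts = counts, bad_channels = eeg$bad_channels)
}

.erp_array <- function(subject_erps, key) {
  d <- dim(subject_erps[[1]]$erps[[key]]$data)
  Y <- array(0, c(length(subject_erps), d[1], d[2]))
  for (s in seq_along(subject_erps)) Y[s, , ] <- subject_erps[[s]]$erps[[key]]$data
  Y
}

# source analysis of one sensor-space period for one 2x2 design
.period_sources <- function(period, keys, subject_erps, group, op, space,
                            config, design) {
  topo <- function(key) t(vapply(subject_erps, function(se)
    average_erp_period(se$erps[[key]], c(period$start_ms, period$end_ms)),
    numeric(op$n_electrodes)))
  D <- lapply(keys, function(key) {
    tp <- topo(key)
    t(apply(tp, 1, function(v) apply_inverse(op, v)$density))
  })
  smap <- nodewise_interaction(D[[1]], D[[2]], group, design = design)
  clusters <- find_clusters(smap, space, alpha = config$source$alpha,
                            k_e = config$source$k_e,
                            radius = config$source$radius,
                            densities = stats::setNames(D, keys))
  list(period = period, stat_map = smap, clusters = clusters)
}

#' Run the complete simulate-and-analyze pipeline
#'
#' Stages: (1) simulate the two-group behavioral study; (2) behavioral
#' battery (RT outlier rejection, BEG/END summaries, signal-detection
#' scores, t tests with Levene-guarded Welch correction, 2 x 2 mixed
#' ANOVAs, speed-accuracy correlations); (3) build the spherical head model
#' and LAURA inverse; (4) simulate, match, artifact-reject and average each
#' subject's EEG into HIT/CR x BEG/END ERPs; (5) epoch-count control
#' ANOVAs; (6) electrode x time interaction maps and sustained-period
#' detection for the Group x Stimulus (BEG) and Group x Session (CR)
#' designs; (7) LAURA source estimation and cluster-extent statistics over
#' every detected sensor period. Detected sensor periods automatically
#' become the source-analysis periods.
#'
#' @param config a [run_config()]
#' @param seed integer seed; propagated (derived) to every stochastic stage
#' @param out_dir if non-`NULL`, writes `report.json`, `report.md` and the
#'   study log there
#' @param headmodel optional prebuilt head model from [build_head_model()];
#'   building grid, lead field and inverse operator is deterministic and
#'   relatively slow, so batch callers should reuse one
#' @return a report list with elements `behavior`, `epoch_counts`,
#'   `sensor`, `sources`, `config_digest`
#' @export
run_all <- function(config = run_config(), seed = 1, out_dir = NULL,
                    headmodel = NULL) {
  stopifnot(inherits(config, "run_config"))
  study <- simulate_group_study(config$n_si, config$n_ii, config$profiles,
                                config$task, seed = .derive_seed(seed, 1))
  behavior <- .behavior_report(study, config)

  if (is.null(headmodel)) headmodel <- build_head_model(config)
  space <- headmodel$space; lf <- headmodel$lf; op <- headmodel$op

  subjects <- unique(study$subject)
  group <- vapply(subjects, function(s) study$group[study$subject == s][1], "")
  subject_erps <- lapply(seq_along(subjects), function(i) {
    sub <- study[study$subject == subjects[i], ]
    .subject_erps(sub, group[i], lf, space, config,
                  seed = .derive_seed(seed, 500 + i))
  })

  counts <- function(key) vapply(subject_erps, function(x) x$counts[[key]], 0)
  epoch_counts <- list(
    group_x_stimulus = epoch_count_control(counts("HIT.BEG"), counts("CR.BEG"),
                                           group),
    group_x_session = epoch_count_control(counts("CR.BEG"), counts("CR.END"),
                                          group),
    table = data.frame(subject = subjects, group = group,
                       hit_beg = counts("HIT.BEG"), cr_beg = counts("CR.BEG"),
                       hit_end = counts("HIT.END"), cr_end = counts("CR.END")))

  fs <- config$eeg$fs
  min_frames <- max(2L, as.integer(ceiling(config$erp$min_duration_ms * fs / 1000)))
  designs <- list(
    group_x_stimulus = list(keys = c("HIT.BEG", "CR.BEG"),
                            design = "group-x-stimulus"),
    group_x_session = list(keys = c("CR.BEG", "CR.END"),
                           design = "group-x-session"))
  sensor <- list(); sources <- list()
  for (nm in names(designs)) {
    keys <- designs[[nm]]$keys
    Y1 <- .erp_array(subject_erps, keys[1])
    Y2 <- .erp_array(subject_erps, keys[2])
    map <- pointwise_interaction(Y1, Y2, group, fs = fs,
                                 window = config$eeg$window,
                                 design = designs[[nm]]$design)
    mf <- min_frames
    calib <- NULL
    if (isTRUE(config$erp$calibrate)) {
      calib <- permutation_duration_threshold(
        Y1, Y2, group, n_perm = config$erp$n_perm, alpha = config$erp$alpha,
        electrode_frac = config$erp$electrode_frac,
        seed = .derive_seed(seed, 900 + match(nm, names(designs))))
      mf <- calib$min_frames
    }
    periods <- find_sustained_periods(map, config$erp$electrode_frac,
                                      mf, config$erp$alpha)
    sensor[[nm]] <- list(periods = periods, min_frames = mf,
                         calibration = calib, stat_map = map)
    sources[[nm]] <- lapply(seq_len(nrow(periods)), function(i)
      .period_sources(periods[i, ], keys, subject_erps, group, op, space,
                      config, designs[[nm]]$design))
  }

  report <- list(behavior = behavior, epoch_counts = epoch_counts,
                 sensor = sensor, sources = sources,
                 seed = seed,
                 config_digest = list(n_si = config$n_si, n_ii = config$n_ii,
                                      fs = fs, min_frames = min_frames,
                                      k_e = config$source$k_e))
  if (!is.null(out_dir)) .write_report(report, study, out_dir)
  report
}

# serializable view of the report (drops the large stat maps)
.report_json <- function(report) {
  slim <- report
  for (nm in names(slim$sensor)) {
    slim$sensor[[nm]]$stat_map <- NULL
    slim$sensor[[nm]]$calibration <- NULL
  }
  for (nm in names(slim$sources)) {
    slim$sources[[nm]] <- lapply(slim$sources[[nm]], function(ps) {
      list(period = ps$period,
           clusters = lapply(ps$clusters, function(cl)
             cl[c("size", "peak_node", "peak_coord", "peak_f", "cell_means")]))
    })
  }
  slim
}

.write_report <- function(report, study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trial_log(study, file.path(out_dir, "study.tsv"))
  jsonlite::write_json(.report_json(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  md <- c("# Pipeline report", "",
          sprintf("Seed: %d", report$seed), "",
          "## Sustained sensor periods", "")
  for (nm in names(report$sensor)) {
    p <- report$sensor[[nm]]$periods
    md <- c(md, sprintf("### %s", nm),
            if (nrow(p)) apply(p, 1, function(r)
              sprintf("- %.1f to %.1f ms (%d frames)",
                      as.numeric(r["start_ms"]), as.numeric(r["end_ms"]),
                      as.integer(r["frames"])))
            else "- none", "")
  }
  md <- c(md, "## Source clusters", "")
  for (nm in names(report$sources)) {
    md <- c(md, sprintf("### %s", nm))
    ps <- report$sources[[nm]]
    if (!length(ps)) md <- c(md, "- no periods")
    for (x in ps) {
      if (!length(x$clusters)) md <- c(md, "- no clusters")
      for (cl in x$clusters)
        md <- c(md, sprintf("- k = %d, peak node %d at (%.0f, %.0f, %.0f) mm",
                            cl$size, cl$peak_node, cl$peak_coord[1],
                            cl$peak_coord[2], cl$peak_coord[3]))
    }
    md <- c(md, "")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
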