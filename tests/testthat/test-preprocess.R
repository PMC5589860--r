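test_that("Butterworth sections have the designed magnitude response", {
  fs <- 1024
  mag <- function(coef, f) {
    z <- exp(-2i * pi * f / fs)
    abs(sum(coef$b * z^(0:2)) / sum(coef$a * z^(0:2)))
  }
  lp <- butter2(40, fs, "low")
  # prewarped -3 dB point lands exactly on the cutoff (single pass)
  expect_equal(mag(lp, 40), 1 / sqrt(2), tolerance = 1e-10)
  expect_gt(mag(lp, 5), 0.99)
  expect_lt(mag(lp, 200), 0.05)
  hp <- butter2(0.1, fs, "high")
  expect_equal(mag(hp, 0.1), 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(mag(hp, 0), 0, tolerance = 1e-12)
  notch <- butter2(50, fs, "stop", bw = 4)
  expect_lt(mag(notch, 50), 1e-10)
  expect_gt(mag(notch, 30), 0.95)

  # single-pass time-domain attenuation at cutoff ~ 1/sqrt(2)
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 40 * t)
  y <- apply_filter(x, lp)
  mid <- (length(t) %/% 4):(3 * length(t) %/% 4)
  ratio <- max(abs(y[mid])) / max(abs(x[mid]))
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.01)
  # forward-backward squares the response (~1/2 at cutoff)
  y2 <- filtfilt2(x, lp)
  expect_equal(max(abs(y2[mid])), 0.5, tolerance = 0.01)
})

test_that("filter_continuous removes DC and mains, preserves latency", {
  fs <- 512
  n <- fs * 2
  const <- matrix(10, 2, n)
  out <- filter_continuous(const, fs)
  expect_lt(max(abs(out)), 1e-8)
  # 50 Hz residual < 5%
  t <- (0:(n - 1)) / fs
  mains <- matrix(sin(2 * pi * 50 * t), 1)
  outm <- filter_continuous(mains, fs, hp = NULL, lp = NULL, notch = 50)
  mid <- (n %/% 4):(3 * n %/% 4)
  expect_lt(max(abs(outm[mid])) / 1, 0.05)
  expect_error(filter_continuous(const, fs = 60, lp = 40), "twice the low-pass")

  # zero-phase: a broadband pulse keeps its peak latency within 1 sample
  pulse <- matrix(0, 1, n); pulse[1, 300] <- 1
  outp <- filter_continuous(pulse, fs, hp = NULL, notch = NULL)
  expect_lte(abs(which.max(outp[1, ]) - 300), 1)

  # linearity: filtering commutes with averaging
  set.seed(1)
  a <- matrix(rnorm(2 * n), 2)
  b <- matrix(rnorm(2 * n), 2)
  f_avg <- filter_continuous((a + b) / 2, fs)
  avg_f <- (filter_continuous(a, fs) + filter_continuous(b, fs)) / 2
  expect_lt(max(abs(f_avg - avg_f)) / max(abs(f_avg)), 1e-8)
})

test_that("event relabeling keeps only correct trials", {
  log <- data.frame(stim = c("GO", "GO", "NOGO", "NOGO"),
                    response = c(1, 0, 1, 0))
  out <- relabel_events(log)
  expect_equal(out$label, c("HIT", "CR"))
  expect_equal(out$stim, c("GO", "NOGO"))
})

test_that("epoch windows follow the half-open sample convention", {
  fs <- 1024
  x <- matrix(rnorm(3 * 5000), 3)
  ep <- epoch_signal(x, events = c(1500, 2500), fs = fs)
  expect_equal(dim(ep$data), c(3, 614, 2))
  ep2 <- epoch_signal(x, events = 1500, fs = 1000)
  expect_equal(dim(ep2$data)[2], 600)
  # stimulus-onset sample is included and aligned
  o0 <- round(-100 * fs / 1000)
  expect_equal(ep$data[, , 1], x[, 1500 + o0 + 0:613])
  # zero events and edge events
  ep0 <- epoch_signal(x, events = integer(0), fs = fs)
  expect_equal(dim(ep0$data)[3], 0)
  expect_warning(ep_edge <- epoch_signal(x, events = c(10, 1500), fs = fs),
                 "too close")
  expect_equal(dim(ep_edge$data)[3], 1)
  # baseline option zeroes the pre-stimulus mean
  epb <- epoch_signal(x, events = 1500, fs = fs, baseline = TRUE)
  pre <- sample_times(fs, c(-100, 500)) < 0
  expect_equal(rowMeans(epb$data[, pre, 1]), rep(0, 3), tolerance = 1e-12)
})

test_that("trial-count matching truncates to the smaller condition per block", {
  mk <- function(n_per_block, blocks, cond) {
    all_blocks <- rep(blocks, n_per_block)
    epoch_set(array(seq_along(all_blocks), c(1, 1, length(all_blocks))),
              fs = 100, window = c(0, 10), blocks = all_blocks,
              condition = cond)
  }
  hit <- mk(c(28, 10), 1:2, "HIT")
  cr <- mk(c(25, 10), 1:2, "CR")
  m <- match_trial_counts(hit, cr)
  expect_equal(sum(m[[1]]$blocks == 1), 25)
  expect_equal(sum(m[[2]]$blocks == 1), 25)
  # the first n in presentation order are kept
  expect_equal(as.numeric(m[[1]]$data[1, 1, m[[1]]$blocks == 1]), 1:25)
  # equal counts unchanged
  expect_equal(sum(m[[1]]$blocks == 2), 10)
  # zero-count block empties both sides
  hit0 <- mk(c(5, 0), 1:2, "HIT")
  cr0 <- mk(c(5, 3), 1:2, "CR")
  expect_warning(m0 <- match_trial_counts(hit0, cr0), "zero epochs")
  expect_equal(sum(m0[[2]]$blocks == 2), 0)
  expect_equal(sum(m0[[1]]$blocks == 1), 5)
})

test_that("artifact rejection uses a strict 80 uV boundary", {
  dat <- array(0, c(2, 10, 3))
  dat[1, 5, 1] <- 81       # rejected
  dat[2, 3, 2] <- 80       # kept: boundary is strict
  dat[1, 1, 3] <- -80.5    # rejected (negative side)
  set <- epoch_set(dat, 100, c(0, 100))
  out <- reject_artifacts(set, 80)
  expect_equal(dim(out$data)[3], 1)
  expect_equal(attr(out, "n_rejected"), 2)
  expect_true(max(abs(out$data)) <= 80)
  # excluded channels are ignored by the criterion (both offending samples
  # sit on channel 1, so every epoch survives)
  out2 <- reject_artifacts(set, 80, exclude_channels = 1)
  expect_equal(dim(out2$data)[3], 3)
})

test_that("ERP averaging matches direct means and symmetry", {
  set.seed(2)
  one <- array(rnorm(4 * 10), c(4, 10, 1))
  s1 <- epoch_set(one, 100, c(0, 100))
  expect_equal(average_erp(s1)$data, one[, , 1])
  v <- matrix(rnorm(40), 4)
  pm <- epoch_set(array(c(v, -v), c(4, 10, 2)), 100, c(0, 100))
  expect_equal(average_erp(pm)$data, matrix(0, 4, 10))
  expect_equal(average_erp(pm)$n_epochs, 2)
  empty <- epoch_set(array(0, c(4, 10, 0)), 100, c(0, 100))
  expect_error(average_erp(empty), "empty")
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  m <- fix_montage()
  pos <- m$positions / 85
  # low-degree harmonic field: constant + dipolar + quadrupolar terms
  field <- 1.5 + 2.4 * pos[, 3] - 1.1 * pos[, 2] + 0.8 * pos[, 1] * pos[, 2]
  for (bad in c(3, 17, 33, 52)) {
    est <- interpolate_bad_channels(matrix(field, ncol = 1), m, bad)
    expect_lt(abs(est[bad, 1] - field[bad]) / sd(field), 0.05)
  }
  # constants reproduced exactly; empty bad set is the identity
  cst <- interpolate_bad_channels(matrix(rep(7.3, 64), ncol = 1), m, 20)
  expect_equal(cst[20, 1], 7.3, tolerance = 1e-8)
  e <- erp(matrix(field, ncol = 1), 100, c(0, 10), n_epochs = 1)
  expect_identical(interpolate_bad_channels(e, m, integer(0)), e)
  expect_error(interpolate_bad_channels(e, m, 1:20), "too many")
  # works on erp objects and labels
  e2 <- interpolate_bad_channels(e, m, m$labels[5])
  expect_lt(abs(e2$data[5, 1] - field[5]) / sd(field), 0.05)
})
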