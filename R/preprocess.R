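#' Epoch and ERP containers
#'
#' An `epoch_set` wraps a channels x samples x epochs array (microvolts) with
#' sampling rate, peri-stimulus window and per-epoch block labels. An `erp`
#' holds the channels x samples trial average plus the epoch count that went
#' into it. The sample convention is half-open: sample `j` (1-based) covers
#' `[window[1] + (j-1)/fs, window[1] + j/fs)` in ms and its center is
#' `window[1] + (j - 0.5) * 1000 / fs`.
#'
#' @param data channels x samples x epochs array (or channels x samples
#'   matrix for `erp`)
#' @param fs sampling rate, Hz
#' @param window peri-stimulus window in ms, `c(start, stop)`, half-open
#' @param blocks integer block label per epoch (optional)
#' @param condition condition tag, e.g. `"HIT"`
#' @param n_epochs number of epochs averaged into the ERP
#' @return an `epoch_set` / `erp` object
#' @export
epoch_set <- function(data, fs, window, blocks = NULL, condition = NA_character_) {
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3, fs > 0, length(window) == 2)
  n <- dim(data)[3]
  if (!is.null(blocks)) stopifnot(length(blocks) == n)
  structure(list(data = data, fs = fs, window = window,
                 blocks = blocks, condition = condition),
            class = "epoch_set")
}

#' @rdname epoch_set
#' @export
erp <- function(data, fs, window, n_epochs, condition = NA_character_) {
  stopifnot(is.matrix(data), fs > 0, n_epochs >= 1)
  structure(list(data = data, fs = fs, window = window,
                 n_epochs = n_epochs, condition = condition),
            class = "erp")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d ch x %d samples x %d epochs, %g Hz, [%g, %g) ms, %s\n",
              d[1], d[2], d[3], x$fs, x$window[1], x$window[2], x$condition))
  invisible(x)
}

#' @export
print.erp <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<erp> %d ch x %d samples (%d epochs), %g Hz, [%g, %g) ms, %s\n",
              d[1], d[2], x$n_epochs, x$fs, x$window[1], x$window[2], x$condition))
  invisible(x)
}

#' Sample-center times of an epoch window
#'
#' The epoch's first sample sits at offset `round(window[1] * fs / 1000)`
#' samples from the stimulus (the [epoch_signal()] convention), so center
#' times are aligned to the actual sample grid rather than to the nominal
#' window start; at 1024 Hz the (-100, 500) ms window starts at -99.61 ms
#' and the 218-245 ms period covers exactly 28 frames.
#'
#' @param fs sampling rate in Hz
#' @param window window in ms
#' @param n_samples number of samples (defaults to the half-open count)
#' @return numeric vector of per-sample center times in ms
#' @export
sample_times <- function(fs, window, n_samples = NULL) {
  if (is.null(n_samples))
    n_samples <- floor((window[2] - window[1]) * fs / 1000)
  t0 <- round(window[1] * fs / 1000) / fs * 1000
  t0 + (seq_len(n_samples) - 0.5) * 1000 / fs
}

# ---- second-order Butterworth sections -------------------------------------

#' Second-order Butterworth / notch coefficients (bilinear transform)
#'
#' Returns normalized digital filter coefficients `b` (numerator) and `a`
#' (denominator, `a[1] = 1`). Cutoffs are prewarped so the -3 dB point of the
#' low/high-pass lands exactly on `fc`.
#'
#' @param fc cutoff (or center, for the notch) frequency in Hz
#' @param fs sampling rate in Hz
#' @param type `"low"`, `"high"`, or `"stop"`
#' @param bw stop-band width in Hz (notch only)
#' @return list with `b` and `a`
#' @export
butter2 <- function(fc, fs, type = c("low", "high", "stop"), bw = 4) {
  type <- match.arg(type)
  stopifnot(fc > 0, fc < fs / 2)
  if (type %in% c("low", "high")) {
    K <- tan(pi * fc / fs)
    norm <- 1 + sqrt(2) * K + K^2
    a <- c(1, 2 * (K^2 - 1) / norm, (1 - sqrt(2) * K + K^2) / norm)
    b <- if (type == "low") c(K^2, 2 * K^2, K^2) / norm
    else c(1, -2, 1) / norm
  } else {
    w0 <- 2 * pi * fc / fs
    q <- fc / bw
    al <- sin(w0) / (2 * q)
    b <- c(1, -2 * cos(w0), 1) / (1 + al)
    a <- c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
  }
  list(b = b, a = a)
}

#' Apply an IIR filter (single pass or zero-phase)
#'
#' `apply_filter()` runs the direct-form difference equation once (causal).
#' `filtfilt2()` applies it forward and backward for zero phase, with odd
#' reflection padding at both ends to suppress edge transients; effective
#' magnitude response is squared.
#'
#' @param x numeric vector
#' @param coef list with `b`, `a` from [butter2()]
#' @return filtered vector, same length
#' @export
apply_filter <- function(x, coef) {
  b <- coef$b; a <- coef$a
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  z <- stats::filter(xp, b, method = "convolution", sides = 1)
  z <- as.numeric(z)[nb:length(xp)]
  if (length(a) > 1) {
    z <- stats::filter(z, -a[-1], method = "recursive")
  }
  as.numeric(z)
}

#' @rdname apply_filter
#' @param padlen reflection padding length in samples
#' @export
filtfilt2 <- function(x, coef, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1, 3 * (length(coef$a) + length(coef$b)))
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- apply_filter(c(pre, x, post), coef)
  y <- rev(apply_filter(rev(y), coef))
  y[(padlen + 1):(padlen + n)]
}

#' Band-limit continuous multichannel EEG
#'
#' Per-channel DC removal followed by zero-phase second-order Butterworth
#' high-pass and low-pass filtering and a second-order band-stop notch
#' (width `notch_bw` Hz centered on `notch`). Pass `NULL` to skip a stage.
#'
#' @param x channels x samples matrix (microvolts)
#' @param fs sampling rate in Hz; must exceed twice the low-pass cutoff
#' @param hp,lp,notch high-pass, low-pass and notch frequencies in Hz
#' @param notch_bw notch width in Hz
#' @return filtered matrix of the same shape
#' @export
filter_continuous <- function(x, fs, hp = 0.1, lp = 40, notch = 50,
                              notch_bw = 4) {
  x <- as.matrix(x)
  if (!is.null(lp) && fs <= 2 * lp)
    stop("sampling rate must exceed twice the low-pass cutoff")
  if (!is.null(notch) && notch >= fs / 2) notch <- NULL  # nothing to remove
  x <- x - rowMeans(x)
  stages <- list()
  if (!is.null(hp)) stages <- c(stages, list(butter2(hp, fs, "high")))
  if (!is.null(lp)) stages <- c(stages, list(butter2(lp, fs, "low")))
  if (!is.null(notch)) stages <- c(stages, list(butter2(notch, fs, "stop", bw = notch_bw)))
  for (st in stages) {
    x <- t(apply(x, 1, filtfilt2, coef = st))
  }
  x
}

#' Relabel stimulus events by behavioral outcome
#'
#' Tags each trial as `HIT` (responded Go) or `CR` (withheld NoGo) and drops
#' incorrect trials (misses, false alarms), which do not enter the ERPs.
#'
#' @param log trial log data frame with `stim`, `response` (and any
#'   alignment columns such as `block`, `onset_sample`)
#' @return the correct-trial subset with a `label` column
#' @export
relabel_events <- function(log) {
  stopifnot(all(c("stim", "response") %in% names(log)))
  lab <- ifelse(log$stim == "GO" & log$response == 1, "HIT",
                ifelse(log$stim == "NOGO" & log$response == 0, "CR", NA))
  out <- log[!is.na(lab), , drop = FALSE]
  out$label <- lab[!is.na(lab)]
  out
}

#' Cut peri-stimulus epochs out of a continuous recording
#'
#' Half-open window: the epoch contains `floor(span * fs / 1000)` samples,
#' the first at offset `round(window[1] * fs / 1000)` relative to the event
#' sample; the stimulus-onset sample is included. Events too close to the
#' recording edge are dropped with a warning.
#'
#' @param x channels x samples matrix
#' @param events integer vector of stimulus-onset sample indices (1-based)
#' @param fs sampling rate, Hz
#' @param window epoch window in ms
#' @param baseline subtract the mean of the pre-stimulus samples per channel?
#' @param blocks optional block label per event
#' @return an [epoch_set()]
#' @export
epoch_signal <- function(x, events, fs, window = c(-100, 500),
                         baseline = FALSE, blocks = NULL) {
  x <- as.matrix(x)
  n_s <- floor((window[2] - window[1]) * fs / 1000)
  o0 <- round(window[1] * fs / 1000)
  ok <- events + o0 >= 1 & events + o0 + n_s - 1 <= ncol(x)
  if (any(!ok)) warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  events <- events[ok]
  if (!is.null(blocks)) blocks <- blocks[ok]
  out <- array(0, c(nrow(x), n_s, length(events)))
  for (i in seq_along(events)) {
    idx <- events[i] + o0 + 0:(n_s - 1)
    out[, , i] <- x[, idx, drop = FALSE]
  }
  if (baseline && length(events)) {
    pre <- sample_times(fs, window, n_s) < 0
    if (any(pre)) {
      for (i in seq_along(events))
        out[, , i] <- out[, , i] - rowMeans(out[, pre, i, drop = FALSE])
    }
  }
  epoch_set(out, fs, window, blocks = blocks)
}

#' Match trial counts across two conditions, block by block
#'
#' Within each block both conditions are truncated to the smaller available
#' count, keeping the first `n` epochs of the larger condition in
#' presentation order. Blocks with a zero count in either condition pass
#' through empty with a warning.
#'
#' @param a,b two [epoch_set()]s with per-epoch `blocks` labels
#' @return list of the two truncated epoch sets
#' @export
match_trial_counts <- function(a, b) {
  stopifnot(inherits(a, "epoch_set"), inherits(b, "epoch_set"),
            !is.null(a$blocks), !is.null(b$blocks))
  blocks <- sort(unique(c(a$blocks, b$blocks)))
  keep_a <- integer(0); keep_b <- integer(0)
  for (bl in blocks) {
    ia <- which(a$blocks == bl); ib <- which(b$blocks == bl)
    n <- min(length(ia), length(ib))
    if (n == 0 && (length(ia) > 0 || length(ib) > 0))
      warning("block ", bl, " has zero epochs in one condition; both emptied")
    keep_a <- c(keep_a, ia[seq_len(n)])
    keep_b <- c(keep_b, ib[seq_len(n)])
  }
  list(subset_epochs(a, keep_a), subset_epochs(b, keep_b))
}

#' Subset an epoch set by epoch index
#' @param set an [epoch_set()]
#' @param idx epoch indices to keep
#' @export
subset_epochs <- function(set, idx) {
  epoch_set(set$data[, , idx, drop = FALSE], set$fs, set$window,
            blocks = set$blocks[idx], condition = set$condition)
}

#' Amplitude-threshold artifact rejection
#'
#' An epoch is rejected iff any sample at any channel exceeds the threshold
#' in absolute value (strictly: `|v| > threshold`); a sample at exactly the
#' threshold is kept. Channels already known to be bad (destined for
#' interpolation) can be excluded from the criterion, otherwise a single
#' corrupted electrode would reject every epoch.
#'
#' @param set an [epoch_set()] in microvolts
#' @param threshold rejection threshold in microvolts
#' @param exclude_channels channel indices ignored by the criterion
#' @return the surviving [epoch_set()], with attribute `"n_rejected"`
#' @export
reject_artifacts <- function(set, threshold = 80, exclude_channels = NULL) {
  stopifnot(inherits(set, "epoch_set"))
  n <- dim(set$data)[3]
  use <- setdiff(seq_len(dim(set$data)[1]), exclude_channels)
  keep <- vapply(seq_len(n), function(i)
    max(abs(set$data[use, , i])) <= threshold, TRUE)
  if (!any(keep) && n > 0)
    warning("all epochs rejected at ", threshold, " uV")
  out <- subset_epochs(set, which(keep))
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Average epochs into an ERP
#' @param set an [epoch_set()] with at least one epoch
#' @return an [erp()]
#' @export
average_erp <- function(set) {
  stopifnot(inherits(set, "epoch_set"))
  n <- dim(set$data)[3]
  if (n < 1) stop("cannot average an empty epoch set")
  erp(rowMeans(set$data, dims = 2), set$fs, set$window, n_epochs = n,
      condition = set$condition)
}

# Perrin-style spherical-spline kernel: g(x) = 1/(4*pi) *
# sum_{k=1..n_terms} (2k+1) / (k(k+1))^m * P_k(x)
.spline_g <- function(x, m = 4, n_terms = 7) {
  pkm1 <- rep(1, length(x)); pk <- x
  acc <- (2 * 1 + 1) / (1 * 2)^m * pk
  for (k in 2:n_terms) {
    pk1 <- ((2 * k - 1) * x * pk - (k - 1) * pkm1) / k
    pkm1 <- pk; pk <- pk1
    acc <- acc + (2 * k + 1) / (k * (k + 1))^m * pk
  }
  acc / (4 * pi)
}

#' Interpolate bad channels with spherical splines
#'
#' Perrin-style spherical-spline interpolation (order `m = 4`, Legendre
#' expansion truncated at `n_terms` terms): spline weights are fitted on the
#' good channels (with the usual zero-sum constraint plus a constant term,
#' so constant fields are reproduced exactly) and evaluated at the bad
#' electrode positions, per time sample.
#'
#' @param e an [erp()] (also accepts a plain channels x samples matrix)
#' @param m_ont a [montage()] giving all channel positions
#' @param bad channel indices or labels to replace
#' @param m spline order
#' @param n_terms Legendre truncation
#' @param lambda small ridge added to the spline matrix diagonal; with 64
#'   electrodes the 7-term expansion is borderline rank-deficient and the
#'   usual stabilization is a tiny regularizer
#' @param max_bad_frac error if more than this fraction of channels is bad
#' @return object of the same type with bad channels replaced
#' @export
interpolate_bad_channels <- function(e, m_ont, bad, m = 4, n_terms = 7,
                                     lambda = 1e-6, max_bad_frac = 0.10) {
  is_erp <- inherits(e, "erp")
  dat <- if (is_erp) e$data else as.matrix(e)
  stopifnot(inherits(m_ont, "montage"), nrow(dat) == length(m_ont$labels))
  if (is.character(bad)) bad <- match(bad, m_ont$labels)
  bad <- sort(unique(as.integer(bad)))
  if (!length(bad)) return(e)
  if (length(bad) > max_bad_frac * nrow(dat))
    stop("too many bad channels (", length(bad), ") to interpolate")
  pos <- m_ont$positions / sqrt(rowSums(m_ont$positions^2))
  good <- setdiff(seq_len(nrow(dat)), bad)
  clamp <- function(x) { x[x > 1] <- 1; x[x < -1] <- -1; x }
  Gg <- .spline_g(clamp(pos[good, ] %*% t(pos[good, ])), m, n_terms)
  ng <- length(good)
  diag(Gg) <- diag(Gg) + lambda
  A <- rbind(cbind(Gg, 1), c(rep(1, ng), 0))
  rhs <- rbind(dat[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)                      # (ng+1) x samples
  Gb <- .spline_g(clamp(pos[bad, , drop = FALSE] %*% t(pos[good, ])),
                  m, n_terms)
  interp <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], length(bad), ncol(dat), byrow = TRUE)
  dat[bad, ] <- interp
  if (is_erp) { e$data <- dat; e } else dat
}
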