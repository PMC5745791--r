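#' Filter specification
#'
#' @param kind "bandpass" or "notch".
#' @param band for bandpass a `(low, high)` Hz pair; for notch the notch
#'   frequency in Hz.
#' @param order Butterworth order (bandpass); the notch is a 2nd-order IIR.
#' @param phase "causal" (forward only, usable online) or "zero_phase"
#'   (forward-backward, effective order doubled, offline only).
#' @param q quality factor of the notch (default 35).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "notch"), band, order = 4,
                        phase = c("causal", "zero_phase"), q = 35) {
  kind <- match.arg(kind)
  phase <- match.arg(phase)
  if (kind == "bandpass") {
    if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2])
      stop("bandpass `band` must satisfy 0 < low < high")
  } else {
    if (length(band) != 1 || band <= 0) stop("notch `band` must be a single positive frequency")
  }
  structure(list(kind = kind, band = band, order = order, phase = phase, q = q),
            class = "filter_spec")
}

# second-order IIR notch (biquad) at f0 Hz with quality factor Q
design_notch <- function(f0, q, srate) {
  w0 <- 2 * pi * f0 / srate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

design_filter <- function(spec, srate) {
  if (spec$kind == "notch") {
    if (spec$band >= srate / 2) stop("notch frequency at or above Nyquist")
    return(design_notch(spec$band, spec$q, srate))
  }
  if (spec$band[2] >= srate / 2)
    stop("bandpass upper edge ", spec$band[2],
         " Hz at or above Nyquist (", srate / 2, " Hz)")
  signal::butter(spec$order, spec$band / (srate / 2), type = "pass")
}

filter_channel <- function(filt, x, phase) {
  if (phase == "zero_phase") as.numeric(signal::filtfilt(filt, x))
  else as.numeric(signal::filter(filt, x))
}

#' Butterworth / notch filtering of a recording
#'
#' IIR filtering applied independently per channel.  Zero-phase filtering
#' runs the filter forward and backward (no group delay, effective order
#' doubled); causal filtering runs forward only and matches what an online
#' system can compute.  Events are preserved.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [filter_spec()].
#' @return The filtered [eeg_recording()].
#' @export
butter_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  filt <- design_filter(spec, rec$srate)
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- filter_channel(filt, rec$data[ch, ], spec$phase)
  out
}

#' 5-point Laplacian derivation
#'
#' Output is the center channel minus the mean of its four orthogonal
#' neighbours, samplewise; enhances focal activity under the center electrode
#' and cancels signals common to all five sites.
#'
#' @param rec an [eeg_recording()].
#' @param center center channel label.
#' @param neighbours four neighbour channel labels.
#' @return A single-channel [eeg_recording()] labelled `center`.
#' @export
laplacian <- function(rec, center, neighbours) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(neighbours) != 4) stop("exactly four neighbours required")
  ci <- channel_index(rec, center)
  ni <- channel_index(rec, neighbours)
  d <- rec$data[ci, , drop = FALSE] - colMeans(rec$data[ni, , drop = FALSE])
  eeg_recording(matrix(d, nrow = 1), rec$srate, center, rec$events)
}

#' Cue-locked segmentation
#'
#' Cuts one trial per matching cue event, spanning `window` seconds around
#' the cue (t = 0 at the cue sample).  Trials whose window would extend past
#' the recording are dropped with a warning.
#'
#' @param rec an [eeg_recording()] with events.
#' @param cue_codes event codes treated as cues; the code becomes the trial
#'   label.  Default: all event codes present.
#' @param window `(start, stop)` in seconds relative to the cue.
#' @return A [trial_set()].
#' @export
segment <- function(rec, cue_codes = NULL, window = c(-3, 5)) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2,
            window[1] < window[2])
  ev <- rec$events
  if (!is.null(cue_codes)) ev <- ev[ev$code %in% cue_codes, , drop = FALSE]
  fs <- rec$srate
  n_win <- round((window[2] - window[1]) * fs)
  time <- window[1] + (seq_len(n_win) - 1) / fs
  off0 <- round(window[1] * fs)
  n <- ncol(rec$data)
  starts <- ev$sample + off0
  ok <- starts >= 1L & (starts + n_win - 1L) <= n
  if (any(!ok))
    warning(sum(!ok), " trial(s) dropped: cue window extends past the recording")
  ev <- ev[ok, , drop = FALSE]
  starts <- starts[ok]
  dat <- array(0, c(nrow(ev), nrow(rec$data), n_win))
  for (i in seq_len(nrow(ev)))
    dat[i, , ] <- rec$data[, starts[i] + seq_len(n_win) - 1L]
  trial_set(dat, time, fs, rec$channels, ev$code)
}

#' Statistical rejection of artifact-contaminated trials
#'
#' Single-pass screening on the currently kept trials using three criteria:
#' (1) absolute amplitude above `amp_limit` microvolts on any channel,
#' (2) abnormal joint probability: the per-trial Gaussian log-likelihood
#' (per-channel fits across all trials, summed over channels and samples)
#' deviating from its across-trial mean by more than `sd_mult` standard
#' deviations (two-sided), and (3) abnormal kurtosis, screened the same way.
#' All criteria are evaluated on the original set; rejected trials are only
#' flagged in `kept_mask`, never removed from the array.
#'
#' @param ts a [trial_set()] with at least 5 kept trials.
#' @param amp_limit amplitude threshold in microvolts (default 100).
#' @param sd_mult threshold in across-trial standard deviations (default 4).
#' @return The `trial_set` with an updated `kept` mask and an attribute
#'   `rejection` (data frame of per-trial flags).
#' @export
reject_outlier_trials <- function(ts, amp_limit = 100, sd_mult = 4) {
  stopifnot(inherits(ts, "trial_set"))
  idx <- which(ts$kept)
  if (length(idx) < 5) {
    warning("fewer than 5 kept trials; rejection skipped")
    return(ts)
  }
  dat <- ts$data[idx, , , drop = FALSE]
  nt <- length(idx)
  # criterion 1: amplitude
  amp_bad <- apply(abs(dat), 1, max) > amp_limit
  # criterion 2: joint log-probability under per-channel Gaussian fits
  ch_mean <- apply(dat, 2, mean)
  ch_sd <- apply(dat, 2, stats::sd)
  ch_sd[ch_sd == 0] <- 1
  loglik <- vapply(seq_len(nt), function(i) {
    z <- (dat[i, , ] - ch_mean) / ch_sd
    -0.5 * sum(z^2) - length(z) * 0.5 * log(2 * pi) - dim(dat)[3] * sum(log(ch_sd))
  }, numeric(1))
  jp_bad <- abs(zscore(loglik)) > sd_mult
  # criterion 3: kurtosis (mean over channels of per-channel trial kurtosis)
  kur <- vapply(seq_len(nt), function(i) {
    x <- matrix(dat[i, , ], nrow = dim(dat)[2])
    mean(apply(x, 1, kurtosis))
  }, numeric(1))
  kur_bad <- abs(zscore(kur)) > sd_mult
  bad <- amp_bad | jp_bad | kur_bad
  out <- ts
  out$kept[idx[bad]] <- FALSE
  attr(out, "rejection") <- data.frame(trial = idx, amplitude = amp_bad,
                                       joint_prob = jp_bad, kurtosis = kur_bad)
  out
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

kurtosis <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) return(0)
  mean((x - m)^4) / v^2 - 3
}

#' Normalize channels by their resting-state variance
#'
#' Divides each channel by the standard deviation of the same channel in a
#' resting recording, reducing the influence of high-variance channels and
#' supporting session-to-session transfer of calibration data.
#'
#' @param rec recording (or `trial_set`) to normalize.
#' @param resting resting [eeg_recording()] over the same montage.
#' @return `rec` with each channel divided by its resting SD.
#' @export
variance_normalize <- function(rec, resting) {
  stopifnot(inherits(resting, "eeg_recording"))
  sds <- apply(resting$data, 1, stats::sd)
  if (any(sds == 0))
    stop("zero resting variance on channel(s): ",
         paste(resting$channels[sds == 0], collapse = ", "))
  if (inherits(rec, "eeg_recording")) {
    if (!identical(rec$channels, resting$channels))
      stop("channel sets of recording and resting segment differ")
    rec$data <- rec$data / sds
    return(rec)
  }
  if (inherits(rec, "trial_set")) {
    if (!identical(rec$channels, resting$channels))
      stop("channel sets of trial set and resting segment differ")
    rec$data <- sweep(rec$data, 2, sds, "/")
    return(rec)
  }
  stop("`rec` must be an eeg_recording or trial_set")
}
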