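#' Labelled synthetic or recorded session
#'
#' A continuous recording together with its cue labels, an optional
#' artifact-free resting span (sample indices) and a ground-truth table of
#' injected artifact intervals.
#'
#' @param recording an [eeg_recording()].
#' @param labels class label per cue event.
#' @param rest two-element integer vector `(start, stop)` in samples, or NULL.
#' @param artifacts data frame `kind`, `start`, `stop` (seconds).
#' @return An object of class `labelled_session`.
#' @export
labelled_session <- function(recording, labels, rest = NULL,
                             artifacts = data.frame(kind = character(0),
                                                    start = numeric(0),
                                                    stop = numeric(0))) {
  stopifnot(inherits(recording, "eeg_recording"))
  labels <- as.character(labels)
  n_cues <- nrow(recording$events)
  if (n_cues != length(labels))
    stop("number of cue events (", n_cues, ") must equal number of labels (",
         length(labels), ")")
  if (!is.null(rest)) {
    rest <- as.integer(rest)
    stopifnot(length(rest) == 2, rest[1] >= 1, rest[2] <= ncol(recording$data),
              rest[1] < rest[2])
  }
  structure(list(recording = recording, labels = labels, rest = rest,
                 artifacts = artifacts),
            class = "labelled_session")
}

#' @export
print.labelled_session <- function(x, ...) {
  cat(sprintf("<labelled_session> %.1f s, %d cues, %s resting span, %d artifacts\n",
              rec_duration(x$recording), length(x$labels),
              if (is.null(x$rest)) "no" else
                sprintf("%.1f s", diff(x$rest) / x$recording$srate),
              nrow(x$artifacts)))
  invisible(x)
}

#' Resting segment of a session as a recording
#' @param session a `labelled_session` with a resting span.
#' @return An [eeg_recording()] holding only the resting samples.
#' @export
resting_segment <- function(session) {
  if (is.null(session$rest)) stop("session has no resting segment")
  rec <- session$recording
  eeg_recording(rec$data[, session$rest[1]:session$rest[2], drop = FALSE],
                rec$srate, rec$channels)
}

# 1/f^slope power-spectrum shaped Gaussian noise, unit variance
pink_noise <- function(n, slope, srate) {
  if (slope == 0) return(stats::rnorm(n))
  w <- stats::fft(stats::rnorm(n))
  f <- seq(0, srate, length.out = n + 1)[seq_len(n)]
  f[f > srate / 2] <- srate - f[f > srate / 2]      # mirror for real output
  f[1] <- f[2]                                      # avoid the DC pole
  shaped <- w * f^(-slope / 2)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# band-limited unit-variance Gaussian noise (4th order zero-phase Butterworth)
band_noise <- function(n, f_lo, f_hi, srate) {
  bf <- signal::butter(4, c(f_lo, f_hi) / (srate / 2), type = "pass")
  pad <- min(n, max(256L, round(srate)))
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * pad))
  x <- x[pad + seq_len(n)]
  x / stats::sd(x)
}

# multiplicative amplitude envelope: gain g over [start_s, stop_s] with
# raised-cosine ramps of `ramp` seconds at both boundaries
apply_gain_window <- function(env, start_s, stop_s, gain, ramp, srate) {
  n <- length(env)
  i0 <- max(1L, floor(start_s * srate) + 1L)
  i1 <- min(n, ceiling(stop_s * srate))
  if (i0 > i1) return(env)
  nr <- min(round(ramp * srate), floor((i1 - i0 + 1L) / 2))
  g <- rep(gain, i1 - i0 + 1L)
  if (nr > 0) {
    ramp_up <- 1 + (gain - 1) * (1 - cos(pi * seq_len(nr) / nr)) / 2
    g[seq_len(nr)] <- ramp_up
    g[(length(g) - nr + 1L):length(g)] <- rev(ramp_up)
  }
  env[i0:i1] <- env[i0:i1] * g
  env
}

# core generator: continuous EEG of n samples whose source envelopes follow a
# modulation schedule (data.frame: class, start, stop in seconds)
synth_eeg <- function(config, n, schedule = NULL) {
  nc <- length(config$channels)
  data <- matrix(0, nc, n)
  if (config$noise_sd > 0) {
    for (ch in seq_len(nc))
      data[ch, ] <- config$noise_sd *
        pink_noise(n, config$background_slope, config$srate)
  }
  if (nrow(config$sources) > 0) {
    for (s in seq_len(nrow(config$sources))) {
      src <- config$sources[s, ]
      x <- src$amp * band_noise(n, src$f_lo, src$f_hi, config$srate)
      env <- rep(1, n)
      if (!is.null(schedule) && nrow(schedule) > 0) {
        for (w in seq_len(nrow(schedule))) {
          d <- config$erd_depth[[schedule$class[w]]]
          depth <- if (!is.null(d) && src$name %in% names(d)) d[[src$name]] else 0
          if (depth != 0)
            env <- apply_gain_window(env, schedule$start[w], schedule$stop[w],
                                     sqrt(1 + depth), config$ramp, config$srate)
        }
      }
      data <- data + outer(config$mixing[s, ], x * env)
    }
  }
  data
}

#' Generate stationary resting EEG
#'
#' Background plus unmodulated oscillatory sources; no class-dependent power
#' changes.  Blink and step artifacts are added at the Poisson rates in
#' `config$artifact_rates`.
#'
#' @param config a [sim_config()].
#' @param duration length in seconds (> 0).
#' @return An [eeg_recording()] with `duration * srate` samples.
#' @export
generate_resting <- function(config, duration) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a single positive number of seconds")
  n <- round(duration * config$srate)
  with_seed(config$seed, {
    rec <- eeg_recording(synth_eeg(config, n), config$srate, config$channels)
    add_random_artifacts(rec, config, from = 0, to = duration)
  })
}

# Poisson-count artifact placement over [from, to) seconds (uses current RNG)
add_random_artifacts <- function(rec, config, from, to) {
  rate <- config$artifact_rates
  span <- to - from
  n_blink <- if (isTRUE(rate[["blinks_per_min"]] > 0))
    stats::rpois(1, rate[["blinks_per_min"]] * span / 60) else 0L
  n_step <- if (isTRUE(rate[["steps_per_min"]] > 0))
    stats::rpois(1, rate[["steps_per_min"]] * span / 60) else 0L
  if (n_blink + n_step == 0L) return(rec)
  blink_t <- sort(stats::runif(n_blink, from + 0.5, to - 0.5))
  step_t <- sort(stats::runif(n_step, from + 0.5, to - 0.5))
  inject_artifacts(rec, blink_times = blink_t, step_times = step_t,
                   blink_amplitude = config$blink_amplitude)
}

#' Generate a cue-based calibration session
#'
#' Follows the Graz-style paradigm: a resting segment at the start of the
#' session, then `trials_per_class` cues per class in pseudorandomized order.
#' The fixation cross precedes each cue by `paradigm$pre` seconds, imagery
#' lasts `paradigm$imagery` seconds from the cue, and inter-trial breaks are
#' drawn uniformly from `paradigm$iti`.  During each imagery window the power
#' of the cued class's sources is scaled by `1 + erd_depth`.
#'
#' @param config a [sim_config()].
#' @param trials_per_class number of trials per class (>= 1).
#' @param paradigm a [paradigm_spec()].
#' @return A [labelled_session()]; cue events carry the class as `code`.
#' @export
generate_calibration_session <- function(config, trials_per_class,
                                         paradigm = paradigm_spec()) {
  stopifnot(inherits(config, "sim_config"), inherits(paradigm, "paradigm_spec"))
  if (trials_per_class < 1) stop("`trials_per_class` must be >= 1")
  classes <- config$classes
  n_trials <- trials_per_class * length(classes)
  with_seed(config$seed, {
    labels <- sample(rep(classes, times = trials_per_class))
    itis <- stats::runif(n_trials, paradigm$iti[1], paradigm$iti[2])
    slot <- paradigm$pre + paradigm$imagery
    cue_t <- paradigm$rest_duration + paradigm$pre +
      c(0, cumsum(slot + itis[-n_trials]))
    duration <- paradigm$rest_duration + n_trials * slot + sum(itis) + 2
    n <- round(duration * config$srate)
    schedule <- data.frame(class = labels, start = cue_t,
                           stop = cue_t + paradigm$imagery,
                           stringsAsFactors = FALSE)
    data <- synth_eeg(config, n, schedule)
    events <- data.frame(sample = round(cue_t * config$srate) + 1L,
                         code = labels, stringsAsFactors = FALSE)
    rec <- eeg_recording(data, config$srate, config$channels, events)
    rest <- if (paradigm$rest_duration > 0)
      c(1L, round(paradigm$rest_duration * config$srate)) else NULL
    # keep the resting span clean: artifacts only after it
    rec <- add_random_artifacts(rec, config,
                                from = paradigm$rest_duration, to = duration)
    arts <- attr(rec, "artifacts")
    if (is.null(arts))
      arts <- data.frame(kind = character(0), start = numeric(0),
                         stop = numeric(0))
    labelled_session(rec, labels, rest = rest, artifacts = arts)
  })
}

#' Generate the EEG stream of a training race
#'
#' Emulates the in-game training paradigm: on each action pad the simulated
#' pilot performs the pad's mental task for the first half of the pad
#' traversal and relaxes for the second half; rest pads carry no modulation.
#' One pad-onset event (coded with the pad class) is emitted per pad.
#'
#' @param config a [sim_config()].
#' @param track a [race_track()]; pad classes must be in `config$classes`.
#' @param pad_duration nominal pad traversal time in seconds (default 10:
#'   5 s task + 5 s break).
#' @param rest_duration optional resting lead-in before the first pad, seconds.
#' @return A [labelled_session()] with one label per pad.
#' @export
generate_race_stream <- function(config, track, pad_duration = 10,
                                 rest_duration = 0) {
  stopifnot(inherits(config, "sim_config"))
  pads <- track$pads
  if (length(pads) == 0) stop("`track` must contain at least one pad")
  unknown <- setdiff(unique(pads), config$classes)
  if (length(unknown))
    stop("track pads not in config classes: ", paste(unknown, collapse = ", "))
  task_dur <- pad_duration / 2
  onset_t <- rest_duration + (seq_along(pads) - 1) * pad_duration
  duration <- rest_duration + length(pads) * pad_duration
  with_seed(config$seed, {
    active <- pads != "REST"
    schedule <- data.frame(class = pads[active], start = onset_t[active],
                           stop = onset_t[active] + task_dur,
                           stringsAsFactors = FALSE)
    n <- round(duration * config$srate)
    data <- synth_eeg(config, n, schedule)
    events <- data.frame(sample = round(onset_t * config$srate) + 1L,
                         code = pads, stringsAsFactors = FALSE)
    rec <- eeg_recording(data, config$srate, config$channels, events)
    rest <- if (rest_duration > 0)
      c(1L, round(rest_duration * config$srate)) else NULL
    labelled_session(rec, pads, rest = rest)
  })
}

#' Inject blink and step artifacts with ground truth
#'
#' Blinks are low-frequency (< 10 Hz) Gaussian-envelope transients with a
#' frontal-dominant topography maximal at the blink channel (AFz by default);
#' steps are sustained baseline shifts on the chosen channels.  Ground-truth
#' intervals are recorded in the returned object's `artifacts` table.
#'
#' @param x a [labelled_session()] or [eeg_recording()].
#' @param blink_times blink center times in seconds.
#' @param step_times step onset times in seconds.
#' @param blink_amplitude blink peak amplitude at the blink channel, microvolts.
#' @param blink_channel channel carrying the blink maximum (default "AFz").
#' @param step_amplitude baseline shift in microvolts.
#' @param step_channels channels receiving the shift (default: first channel).
#' @return Same class as `x`, with artifacts added and ground truth attached.
#' @export
inject_artifacts <- function(x, blink_times = numeric(0),
                             step_times = numeric(0),
                             blink_amplitude = 200,
                             blink_channel = "AFz",
                             step_amplitude = 50,
                             step_channels = NULL) {
  rec <- if (inherits(x, "labelled_session")) x$recording else x
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- rec_duration(rec)
  if (length(blink_times) && (any(blink_times < 0) || any(blink_times > dur)))
    stop("blink times outside the recording span [0, ", round(dur, 2), "] s")
  if (length(step_times) && (any(step_times < 0) || any(step_times > dur)))
    stop("step times outside the recording span [0, ", round(dur, 2), "] s")
  fs <- rec$srate
  n <- ncol(rec$data)
  arts <- data.frame(kind = character(0), start = numeric(0), stop = numeric(0))
  if (length(blink_times)) {
    topo <- blink_topography(rec$channels, blink_channel)
    half <- round(0.3 * fs)
    tt <- (-half:half) / fs
    shape <- exp(-tt^2 / (2 * 0.08^2))      # ~2 Hz-wide Gaussian transient
    for (t0 in blink_times) {
      c0 <- round(t0 * fs) + 1L
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1L & idx <= n
      rec$data[, idx[ok]] <- rec$data[, idx[ok]] +
        blink_amplitude * outer(topo, shape[ok])
      arts <- rbind(arts, data.frame(kind = "blink", start = t0 - 0.3,
                                     stop = t0 + 0.3))
    }
  }
  if (length(step_times)) {
    if (is.null(step_channels)) step_channels <- rec$channels[1]
    ci <- channel_index(rec, step_channels)
    for (t0 in step_times) {
      c0 <- round(t0 * fs) + 1L
      rec$data[ci, c0:n] <- rec$data[ci, c0:n] + step_amplitude
      arts <- rbind(arts, data.frame(kind = "step", start = t0, stop = t0 + 0.5))
    }
  }
  if (inherits(x, "labelled_session")) {
    labelled_session(rec, x$labels, rest = x$rest,
                     artifacts = rbind(x$artifacts, arts))
  } else {
    attr(rec, "artifacts") <- rbind(attr(x, "artifacts"), arts)
    rec
  }
}

blink_topography <- function(channels, blink_channel) {
  if (!blink_channel %in% channels)
    stop("blink channel ", blink_channel, " not in montage")
  topo <- rep(0.05, length(channels))
  frontal <- grepl("^(AF|F|Fp)", channels)
  topo[frontal] <- 0.4
  topo[channels == blink_channel] <- 1
  topo
}
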