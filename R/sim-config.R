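#' Default 32-channel montage
#'
#' Sensorimotor centers C3, Cz and C4 each carry four orthogonal close-spaced
#' neighbours (2.5 cm, suffixes `_a`/`_p`/`_l`/`_r` for anterior, posterior,
#' left, right) to support 5-point Laplacian derivations, plus AFz and a set
#' of frontal, fronto-central, centro-parietal, parietal and occipital sites.
#'
#' @return Character vector of 32 channel labels.
#' @export
default_montage <- function() {
  laplacian_block <- function(center) c(center, paste0(center, c("_a", "_p", "_l", "_r")))
  c(laplacian_block("C3"), laplacian_block("Cz"), laplacian_block("C4"),
    "AFz",
    "F3", "Fz", "F4", "FC1", "FC2", "FC5", "FC6",
    "CP1", "CP2", "P3", "Pz", "P4", "PO3", "PO4", "O1", "O2")
}

#' Neighbour labels of a Laplacian center in the default montage
#' @param center one of "C3", "Cz", "C4".
#' @return Character vector of the four orthogonal neighbour labels.
#' @export
laplacian_neighbours <- function(center) paste0(center, c("_a", "_p", "_l", "_r"))

# preferred focal channel for each mental-imagery class; right-hand MI
# desynchronizes the contralateral (left) hand area, feet MI the vertex,
# mental subtraction the parietal midline, auditory imagery fronto-temporal
class_focus <- c(HAND = "C3", FEET = "Cz", SUB = "Pz", AUD = "F4",
                 WORD = "F3", SPATNAV = "P3", ROT = "P4", REST = NA)

#' Default oscillatory source table for a class set
#'
#' One mu-band (10 +/- 2 Hz) and one beta-band (22 +/- 4 Hz) source per
#' non-rest class, centered on a class-specific scalp site.  Source amplitude
#' is the RMS contribution (microvolts) at the strongest channel.
#'
#' @param classes character vector of class identifiers.
#' @param channels montage the sources must project into.
#' @return data frame with columns `name`, `class`, `center`, `f_lo`, `f_hi`,
#'   `amp`.
#' @export
default_sources <- function(classes, channels = default_montage()) {
  cls <- setdiff(classes, "REST")
  pick_center <- function(k, taken) {
    pref <- class_focus[k]
    if (!is.na(pref) && !is.null(pref) && pref %in% channels && !(pref %in% taken))
      return(unname(pref))
    setdiff(channels, taken)[1]
  }
  rows <- list()
  taken <- character(0)
  for (k in cls) {
    center <- pick_center(k, taken)
    if (is.na(center)) stop("not enough channels to place a source for class ", k)
    taken <- c(taken, center)
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(tolower(k), c("_mu", "_beta")), class = k, center = center,
      f_lo = c(8, 18), f_hi = c(12, 26), amp = c(10, 6),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Default scalp mixing for a source table
#'
#' Each source projects with weight 1 to its center channel and 0.4 to the
#' center's close neighbours (same-prefix `_a`/`_p`/`_l`/`_r` labels) when
#' those exist in the montage; a linear instantaneous mixing model.
#'
#' @param sources source table as from [default_sources()].
#' @param channels montage labels.
#' @return Matrix, sources x channels, with source names as row names.
#' @export
default_mixing <- function(sources, channels) {
  M <- matrix(0, nrow(sources), length(channels),
              dimnames = list(sources$name, channels))
  for (i in seq_len(nrow(sources))) {
    center <- sources$center[i]
    M[i, center] <- 1
    nb <- paste0(center, c("_a", "_p", "_l", "_r"))
    nb <- nb[nb %in% channels]
    M[i, nb] <- 0.4
  }
  M
}

#' Default per-class desynchronization depths
#'
#' Fractional band-power change of each source while its class is being
#' imagined: -0.5 for mu sources and -0.3 for beta sources of the imagined
#' class, 0 for every other source.  Values must stay above -1 (power cannot
#' become negative).
#'
#' @param sources source table.
#' @param classes class identifiers.
#' @return Named list: class -> named numeric vector over source names.
#' @export
default_erd_depth <- function(sources, classes) {
  out <- lapply(classes, function(k) {
    own <- sources$class == k
    d <- numeric(sum(own))
    if (any(own)) {
      d <- ifelse(grepl("_mu$", sources$name[own]), -0.5, -0.3)
      names(d) <- sources$name[own]
    }
    d
  })
  names(out) <- classes
  out
}

#' Simulation configuration for synthetic sensorimotor-rhythm EEG
#'
#' Describes the generative model: a 1/f-shaped background noise floor on
#' every channel plus band-limited oscillatory sources mixed linearly onto the
#' scalp.  During imagery of class `k`, the power of each source is scaled by
#' `1 + erd_depth[[k]][source]` (negative values model event-related
#' desynchronization), with a raised-cosine amplitude ramp at window
#' boundaries to avoid spectral splatter.
#'
#' @param srate sampling rate in Hz (default 512).
#' @param channels ordered channel labels (default [default_montage()]).
#' @param classes ordered class identifiers (default HAND, FEET, SUB, REST).
#' @param sources source table; see [default_sources()].
#' @param mixing sources x channels projection matrix; see [default_mixing()].
#' @param erd_depth class -> per-source fractional power change; values > -1.
#' @param background_slope exponent of the 1/f background power spectrum.
#' @param noise_sd background noise standard deviation per channel, microvolts.
#' @param artifact_rates named numeric, `blinks_per_min` and `steps_per_min`.
#' @param blink_amplitude peak amplitude of generated blinks at AFz, microvolts.
#' @param ramp envelope ramp duration at modulation boundaries, seconds.
#' @param seed integer seed; identical seeds give bit-identical signals.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(srate = 512,
                       channels = default_montage(),
                       classes = c("HAND", "FEET", "SUB", "REST"),
                       sources = default_sources(classes, channels),
                       mixing = default_mixing(sources, channels),
                       erd_depth = default_erd_depth(sources, classes),
                       background_slope = 1,
                       noise_sd = 5,
                       artifact_rates = c(blinks_per_min = 0, steps_per_min = 0),
                       blink_amplitude = 150,
                       ramp = 0.25,
                       seed = 1L) {
  if (srate <= 0) stop("`srate` must be positive")
  channels <- as.character(channels)
  if (nrow(sources) > 0) {
    if (nrow(mixing) != nrow(sources))
      stop("`mixing` must have one row per source")
    if (ncol(mixing) != length(channels))
      stop("`mixing` must have one column per channel")
    if (any(sources$f_hi >= srate / 2))
      stop("source bands must lie below the Nyquist frequency")
  }
  if (!all(names(erd_depth) %in% classes))
    stop("erd_depth refers to unknown classes: ",
         paste(setdiff(names(erd_depth), classes), collapse = ", "))
  for (k in names(erd_depth)) {
    d <- erd_depth[[k]]
    if (length(d) && any(d <= -1))
      stop("erd_depth values must be > -1 (power cannot become negative)")
    if (length(d) && !all(names(d) %in% sources$name))
      stop("erd_depth for class ", k, " names unknown sources")
  }
  rownames(mixing) <- sources$name
  colnames(mixing) <- channels
  structure(
    list(srate = srate, channels = channels, classes = classes,
         sources = sources, mixing = mixing, erd_depth = erd_depth,
         background_slope = background_slope, noise_sd = noise_sd,
         artifact_rates = artifact_rates, blink_amplitude = blink_amplitude,
         ramp = ramp, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d channels @ %g Hz, classes %s, %d sources, seed %d\n",
              length(x$channels), x$srate, paste(x$classes, collapse = "/"),
              nrow(x$sources), x$seed))
  invisible(x)
}

#' Graz-style calibration paradigm timing
#'
#' Fixation cross at second -3, visual cue at second 0, imagery period of
#' `imagery` seconds, then an inter-trial break drawn uniformly from
#' `iti` (seconds).  A resting segment of `rest_duration` seconds is recorded
#' at the start of the session for variance normalization and artifact-gate
#' statistics.
#'
#' @param pre seconds of fixation before the cue.
#' @param imagery imagery period length in seconds.
#' @param iti two-element range of the inter-trial break, seconds.
#' @param rest_duration resting segment recorded at session start, seconds.
#' @return A list of class `paradigm_spec`.
#' @export
paradigm_spec <- function(pre = 3, imagery = 5, iti = c(2, 3),
                          rest_duration = 30) {
  stopifnot(pre > 0, imagery > 0, length(iti) == 2, iti[1] <= iti[2],
            rest_duration >= 0)
  structure(list(pre = pre, imagery = imagery, iti = iti,
                 rest_duration = rest_duration),
            class = "paradigm_spec")
}
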