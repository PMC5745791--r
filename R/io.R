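#' Write a recording to EDF
#'
#' European Data Format: ASCII header plus 16-bit integer data records of one
#' second each.  Channels are scaled to their physical range (microvolts) and
#' quantized to the 16-bit digital range; the final record is zero-padded
#' when the duration is not a whole number of seconds.  Events are not part
#' of EDF proper - use [write_events_tsv()] for the sidecar.
#'
#' @param rec an [eeg_recording()]; the sampling rate must be an integer.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$srate
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  X <- if (pad > 0) cbind(rec$data, matrix(0, ns, pad)) else rec$data
  phys_max <- pmax(apply(abs(X), 1, max), 1)
  phys_min <- -phys_max
  dig_min <- -32768; dig_max <- 32767
  fixed <- function(x, width) {
    s <- sprintf("%-*s", width, as.character(x))
    substr(s, 1, width)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(fixed(x, width), con, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in rec$channels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(phys_min[i], digits = 6), 8)
  for (i in seq_len(ns)) wr(format(phys_max[i], digits = 6), 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * fs + seq_len(fs)
    for (ch in seq_len(ns)) {
      dig <- round((X[ch, cols] - phys_min[ch]) * scale[ch] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports the continuous-signal EDF layout written by [write_edf()]: equal
#' sampling rate across channels, one-second records.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] (without events; see [read_events_tsv()]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    s <- readChar(con, width, useBytes = TRUE)
    if (nchar(s, type = "bytes") < width)
      stop("malformed EDF header at byte offset ", seek(con))
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") stop("unsupported EDF version field: ", version)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF: bad signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("per-channel sampling rates differ; not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * spr[1] + seq_len(spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      if (length(dig) < spr[ch]) stop("malformed EDF: truncated data record ", r)
      data[ch, cols] <- phys_min[ch] + (dig - dig_min[ch]) *
        (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
    }
  }
  eeg_recording(data, fs, labels)
}

#' Write / read the event sidecar (TSV)
#'
#' Tab-separated columns `sample`, `code` (1-based sample indices).
#'
#' @param events event data frame.
#' @param path file path.
#' @return `write_events_tsv`: invisibly `path`; `read_events_tsv`: the
#'   event data frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(sample = "integer", code = "character"),
                          stringsAsFactors = FALSE)
  validate_events(ev)
}

#' Save / load a labelled session in the package container (RDS)
#'
#' @param session a [labelled_session()].
#' @param path file path.
#' @return `write_session`: invisibly `path`; `read_session`: the session.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "labelled_session"))
  saveRDS(session, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  s <- readRDS(path)
  if (!inherits(s, "labelled_session")) stop("not a labelled_session file")
  s
}

#' Ordered store of training sessions for calibration transfer
#'
#' @param ... [labelled_session()] objects, oldest first.
#' @return An object of class `session_store`.
#' @export
session_store <- function(...) {
  sessions <- list(...)
  if (length(sessions) == 1 && is.list(sessions[[1]]) &&
      !inherits(sessions[[1]], "labelled_session"))
    sessions <- sessions[[1]]
  for (s in sessions) stopifnot(inherits(s, "labelled_session"))
  if (length(sessions) > 1) {
    ref <- sessions[[1]]$recording$channels
    for (s in sessions[-1])
      if (!identical(s$recording$channels, ref))
        stop("sessions with different montages cannot share a store")
  }
  structure(list(sessions = sessions), class = "session_store")
}

# normalize a session against its own resting span and epoch it
session_trials <- function(session, window, cue_codes = NULL) {
  rec <- session$recording
  if (!is.null(session$rest))
    rec <- variance_normalize(rec, resting_segment(session))
  segment(rec, cue_codes = cue_codes, window = window)
}

#' Assemble a calibration trial set with session-to-session transfer
#'
#' Takes the last `n_old` trials per class of the most recent stored session
#' and the first `n_new` trials per class of the current session; both
#' sessions are variance-normalized against their own resting segments
#' before merging, counteracting session-to-session amplitude drift.  With
#' the 30 + 30 protocol only 30 new trials per class need recording instead
#' of a full 50, a 40% reduction in recorded calibration trials.
#'
#' @param store a [session_store()] (may be empty).
#' @param current the current [labelled_session()].
#' @param n_old trials per class taken from the previous session.
#' @param n_new trials per class taken from the current session.
#' @param window epoching window in seconds around the cue.
#' @return A [trial_set()] with `n_old + n_new` trials per class (current
#'   only, with a warning, when the store is empty).
#' @export
assemble_calibration <- function(store, current, n_old = 30, n_new = 30,
                                 window = c(-3, 5)) {
  stopifnot(inherits(store, "session_store"),
            inherits(current, "labelled_session"))
  cur_ts <- session_trials(current, window)
  cur_sel <- select_tpc(cur_ts, n_new, from_end = FALSE)
  if (!length(store$sessions)) {
    warning("no previous session in store; using current session only")
    return(cur_sel)
  }
  prev <- store$sessions[[length(store$sessions)]]
  if (!identical(prev$recording$channels, current$recording$channels))
    stop("montage of current session differs from the store")
  prev_ts <- session_trials(prev, window)
  prev_sel <- select_tpc(prev_ts, n_old, from_end = TRUE)
  bind_trials(prev_sel, cur_sel)
}

select_tpc <- function(ts, n_per_class, from_end = FALSE) {
  if (n_per_class == 0)
    return(subset_trials(ts, integer(0)))
  idx <- integer(0)
  for (k in unique(ts$labels)) {
    ki <- which(ts$labels == k)
    if (length(ki) < n_per_class)
      stop("class ", k, " has only ", length(ki), " trials; ",
           n_per_class, " requested")
    take <- if (from_end) utils::tail(ki, n_per_class)
            else utils::head(ki, n_per_class)
    idx <- c(idx, take)
  }
  subset_trials(ts, sort(idx))
}

#' Reduction in newly recorded calibration trials under transfer
#'
#' @param n_new newly recorded trials per class under the transfer protocol.
#' @param n_full trials per class of a full (no-transfer) calibration.
#' @return Fractional reduction, e.g. 0.4 for 30 new instead of 50.
#' @export
calibration_savings <- function(n_new = 30, n_full = 50) {
  stopifnot(n_full > 0, n_new >= 0, n_new <= n_full)
  1 - n_new / n_full
}

#' Load and validate a YAML run configuration
#'
#' Recognized keys: `montage`, `srate`, `classes`, `bands`, `filters`,
#' `cv` (`repeats`, `folds`), `thresholds`, `seed`, `paths`.  Unknown keys
#' are rejected, and band edges are checked against the Nyquist frequency at
#' load time rather than mid-run.
#'
#' @param path YAML file path.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("montage", "srate", "classes", "bands", "filters", "cv",
               "thresholds", "seed", "paths")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$srate) && cfg$srate <= 0) stop("srate must be positive")
  if (!is.null(cfg$bands)) {
    for (b in cfg$bands) {
      if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2])
        stop("each band must be an increasing positive (low, high) pair")
      if (!is.null(cfg$srate) && b[2] >= cfg$srate / 2)
        stop("band edge ", b[2], " Hz at or above Nyquist (",
             cfg$srate / 2, " Hz)")
    }
  }
  if (!is.null(cfg$cv) && !all(c("repeats", "folds") %in% names(cfg$cv)))
    stop("cv needs `repeats` and `folds`")
  structure(cfg, class = "run_config")
}

#' Write a cross-validation result to JSON
#' @param cv a `cv_result`.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_cv_json <- function(cv, path) {
  out <- list(scheme = unname(cv$scheme),
              peak = as.list(cv$peak),
              trial_accuracy = cv$trial_accuracy,
              chance_upper = cv$chance$upper,
              classes = cv$classes,
              curve = cv$curve,
              confusion = as.data.frame(cv$confusion))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
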