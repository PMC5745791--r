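#' Continuous multichannel EEG recording
#'
#' Bundles a channels-by-samples signal matrix (microvolts) with its sampling
#' rate, ordered channel labels and an event table.  Events mark cue onsets,
#' pad onsets or other triggers as `(sample, code)` pairs; `sample` is 1-based.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param srate sampling rate in Hz (> 0).
#' @param channels character vector of channel labels, one per row of `data`.
#' @param events data frame with integer column `sample` and character column
#'   `code` (optionally more columns).  Rows must be sorted by `sample`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channels, events = empty_events()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a single positive number")
  channels <- as.character(channels)
  if (nrow(data) != length(channels))
    stop("`data` must have one row per channel label (",
         nrow(data), " rows vs ", length(channels), " labels)")
  if (anyDuplicated(channels))
    stop("duplicated channel labels: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  events <- validate_events(events, n_samples = ncol(data))
  rownames(data) <- channels
  structure(
    list(data = data, srate = srate, channels = channels, events = events),
    class = "eeg_recording"
  )
}

empty_events <- function() {
  data.frame(sample = integer(0), code = character(0),
             stringsAsFactors = FALSE)
}

validate_events <- function(events, n_samples = Inf) {
  if (is.null(events)) return(empty_events())
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events) == 0L) {
    if (!all(c("sample", "code") %in% names(events))) return(empty_events())
    return(events)
  }
  if (!all(c("sample", "code") %in% names(events)))
    stop("`events` needs columns `sample` and `code`")
  events$sample <- as.integer(events$sample)
  events$code <- as.character(events$code)
  if (is.unsorted(events$sample, strictly = FALSE))
    stop("event samples must be non-decreasing")
  if (any(events$sample < 1L) || any(events$sample > n_samples))
    stop("event samples outside the recording")
  rownames(events) <- NULL
  events
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$srate,
              ncol(x$data) / x$srate, nrow(x$events)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)

rec_duration <- function(rec) ncol(rec$data) / rec$srate

channel_index <- function(rec, label) {
  idx <- match(label, rec$channels)
  if (anyNA(idx))
    stop("channel(s) not found: ", paste(label[is.na(idx)], collapse = ", "))
  idx
}

#' Cue-locked trial set
#'
#' Three-dimensional array of epoched EEG (`trials x channels x samples`) with
#' a time axis in seconds relative to the cue, one class label per trial and a
#' logical mask flagging trials retained after artifact rejection.
#'
#' @param data numeric array, trials x channels x samples.
#' @param time numeric vector of times (s) relative to the cue, one per sample.
#' @param srate sampling rate in Hz.
#' @param channels channel labels.
#' @param labels character vector of class labels, one per trial.
#' @param kept logical vector, one per trial; defaults to all `TRUE`.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, time, srate, channels, labels,
                      kept = rep(TRUE, dim(data)[1])) {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[3] != length(time))
    stop("time axis length must equal the sample dimension")
  if (dim(data)[2] != length(channels))
    stop("channel labels must match the channel dimension")
  labels <- as.character(labels)
  if (dim(data)[1] != length(labels))
    stop("one label per trial required")
  if (length(kept) != length(labels)) stop("`kept` must have one flag per trial")
  structure(
    list(data = data, time = time, srate = srate,
         channels = as.character(channels), labels = labels,
         kept = as.logical(kept)),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  tab <- table(x$labels[x$kept])
  cat(sprintf("<trial_set> %d trials (%d kept) x %d channels x %d samples @ %g Hz\n",
              length(x$labels), sum(x$kept), dim(x$data)[2], dim(x$data)[3],
              x$srate))
  cat("  t in [", sprintf("%.3f", min(x$time)), ",",
      sprintf("%.3f", max(x$time)), "] s; classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$data)

#' Number of trials currently kept
#' @param ts a `trial_set`.
#' @return Integer count of retained trials.
#' @export
n_kept <- function(ts) sum(ts$kept)

#' Drop trials flagged as rejected
#'
#' @param ts a `trial_set`.
#' @return A `trial_set` containing only the kept trials.
#' @export
kept_trials <- function(ts) {
  keep <- which(ts$kept)
  trial_set(ts$data[keep, , , drop = FALSE], ts$time, ts$srate, ts$channels,
            ts$labels[keep])
}

#' Subset a trial set by trial index
#' @param ts a `trial_set`.
#' @param i integer or logical trial index.
#' @return The subsetted `trial_set`.
#' @export
subset_trials <- function(ts, i) {
  trial_set(ts$data[i, , , drop = FALSE], ts$time, ts$srate, ts$channels,
            ts$labels[i], kept = ts$kept[i])
}

#' Concatenate trial sets with identical geometry
#' @param ... `trial_set` objects sharing time axis, rate and channels.
#' @return The combined `trial_set`.
#' @export
bind_trials <- function(...) {
  sets <- list(...)
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!isTRUE(all.equal(s$time, ref$time)) || s$srate != ref$srate ||
        !identical(s$channels, ref$channels))
      stop("trial sets differ in time axis, rate or montage")
  }
  dat <- do.call(abind3, lapply(sets, `[[`, "data"))
  trial_set(dat, ref$time, ref$srate, ref$channels,
            unlist(lapply(sets, `[[`, "labels")),
            kept = unlist(lapply(sets, `[[`, "kept")))
}

# bind 3-D arrays along the first (trial) dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# run a block with a local RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
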