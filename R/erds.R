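#' Frequency grid for ERD/ERS maps
#'
#' 2 Hz-wide bands stepped by 1 Hz covering `range`; returned as a two-column
#' matrix of band edges whose centers form the map's frequency axis.
#'
#' @param range `(low, high)` Hz limits of the grid (default 2-40).
#' @param width band width in Hz.
#' @param step band step in Hz.
#' @return Matrix with columns `lo`, `hi`.
#' @export
erds_bands <- function(range = c(2, 40), width = 2, step = 1) {
  centers <- seq(range[1] + width / 2, range[2] - width / 2, by = step)
  cbind(lo = centers - width / 2, hi = centers + width / 2)
}

# smoothed per-trial band power: trials x channels x bands x times (decimated)
erds_trial_power <- function(ts, bands, smooth, decim, channel_idx,
                             filter_order = 4) {
  fs <- ts$srate
  nt <- dim(ts$data)[1]
  n_s <- dim(ts$data)[3]
  # the first half second of each epoch is dominated by the causal filter's
  # settling and the smoother's half-window: exclude it from the map
  edge <- min(n_s - 1L, round(max(0.5, smooth / 2) * fs))
  t_idx <- seq(edge + 1L, n_s, by = decim)
  win <- max(1L, round(smooth * fs))
  ma <- rep(1 / win, win)
  out <- array(NA_real_, c(nt, length(channel_idx), nrow(bands),
                           length(t_idx)))
  for (b in seq_len(nrow(bands))) {
    bf <- signal::butter(filter_order, c(bands[b, 1], bands[b, 2]) / (fs / 2),
                         type = "pass")
    for (ci in seq_along(channel_idx)) {
      ch <- channel_idx[ci]
      pad <- min(n_s, round(fs))         # reflection pad absorbs the ring-in
      for (i in seq_len(nt)) {
        xr <- ts$data[i, ch, ]
        x <- as.numeric(signal::filter(bf, c(rev(xr[seq_len(pad)]), xr)))
        x <- x[pad + seq_len(n_s)]
        p <- as.numeric(stats::filter(x^2, ma, sides = 2))
        p[is.na(p)] <- x[is.na(p)]^2     # edges: raw instantaneous power
        out[i, ci, b, ] <- p[t_idx]
      }
    }
  }
  attr(out, "t_idx") <- t_idx
  out
}

#' Event-related (de)synchronization map
#'
#' For every frequency bin the trials are causally band-filtered, squared,
#' smoothed with a moving average and averaged across trials; the map value is
#' the percent power change `100 * (A - R) / R` relative to the mean power `R`
#' in a pre-cue reference interval.  Negative values are ERD (power decrease),
#' positive values ERS.
#'
#' @param ts a [trial_set()] (rejected trials are ignored).
#' @param bands band-edge matrix as from [erds_bands()].
#' @param reference `(start, stop)` of the reference interval in seconds,
#'   entirely before the cue (t < 0).
#' @param channels channel labels to map (default: all).
#' @param smooth moving-average length in seconds (default 0.25).
#' @param decim keep every `decim`-th time sample in the map (default 16).
#' @return An object of class `erds_map` with fields `values`
#'   (channels x frequencies x times, percent), `freq`, `time`, `channels`,
#'   `reference`, and a NULL `sig_mask` until [bootstrap_significance()] runs.
#' @export
compute_erds <- function(ts, bands = erds_bands(), reference = c(-2, -1),
                         channels = NULL, smooth = 0.25, decim = 16) {
  stopifnot(inherits(ts, "trial_set"))
  if (reference[2] > 0)
    stop("reference interval must end before the cue (t <= 0)")
  if (reference[1] < min(ts$time) || reference[2] > max(ts$time))
    stop("reference interval outside the trial window")
  ts <- kept_trials(ts)
  channel_idx <- if (is.null(channels)) seq_along(ts$channels)
                 else channel_index(ts, channels)
  pw <- erds_trial_power(ts, bands, smooth, decim, channel_idx)
  t_idx <- attr(pw, "t_idx")
  tt <- ts$time[t_idx]
  ref_cols <- which(tt >= reference[1] & tt <= reference[2])
  if (!length(ref_cols)) stop("no map samples inside the reference interval")
  # R: per channel x band mean power over reference interval and trials
  R <- apply(pw[, , , ref_cols, drop = FALSE], c(2, 3), mean)
  A <- apply(pw, c(2, 3, 4), mean)
  vals <- 100 * sweep(sweep(A, c(1, 2), R, "-"), c(1, 2), R, "/")
  structure(
    list(values = vals, freq = rowMeans(bands), time = tt,
         channels = ts$channels[channel_idx], bands = bands,
         reference = reference, sig_mask = NULL, alpha = NULL,
         smooth = smooth, decim = decim, n_trials = dim(ts$data)[1]),
    class = "erds_map"
  )
}

#' @export
print.erds_map <- function(x, ...) {
  cat(sprintf("<erds_map> %d channels x %d freqs (%.0f-%.0f Hz) x %d times, ref [%g, %g] s%s\n",
              length(x$channels), length(x$freq), min(x$freq), max(x$freq),
              length(x$time), x$reference[1], x$reference[2],
              if (is.null(x$sig_mask)) "" else
                sprintf(", %.1f%% bins significant (alpha=%g)",
                        100 * mean(x$sig_mask), x$alpha)))
  invisible(x)
}

#' t-percentile bootstrap significance mask for an ERD/ERS map
#'
#' Per map bin, the across-trial mean percent power change is bootstrapped by
#' resampling trials with replacement; a studentized (t-percentile) interval
#' at level `1 - alpha` is formed and the bin is marked significant iff the
#' interval excludes zero.
#'
#' @param map an `erds_map` from [compute_erds()].
#' @param ts the [trial_set()] the map was computed from.
#' @param alpha significance level in (0, 1] (default 0.05).
#' @param n_boot number of bootstrap resamples (>= 200; default 1000).
#' @param seed RNG seed for the resampling.
#' @return The `erds_map` with `sig_mask` and `alpha` filled in.
#' @export
bootstrap_significance <- function(map, ts, alpha = 0.05, n_boot = 1000,
                                   seed = 1) {
  stopifnot(inherits(map, "erds_map"), inherits(ts, "trial_set"))
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]")
  if (n_boot < 200) stop("`n_boot` must be at least 200")
  ts <- kept_trials(ts)
  channel_idx <- channel_index(ts, map$channels)
  pw <- erds_trial_power(ts, map$bands, map$smooth, map$decim, channel_idx)
  tt <- ts$time[attr(pw, "t_idx")]
  ref_cols <- which(tt >= map$reference[1] & tt <= map$reference[2])
  nt <- dim(pw)[1]
  R <- apply(pw[, , , ref_cols, drop = FALSE], c(2, 3), mean)
  # per-trial percent change relative to the grand reference
  E <- 100 * sweep(sweep(pw, c(2, 3), R, "-"), c(2, 3), R, "/")
  dimE <- dim(E)
  n_bins <- prod(dimE[-1])
  Em <- matrix(E, nrow = nt, ncol = n_bins)
  mu <- colMeans(Em)
  se <- apply(Em, 2, stats::sd) / sqrt(nt)
  tstat <- matrix(NA_real_, n_boot, n_bins)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nt, nt, replace = TRUE)
      Eb <- Em[idx, , drop = FALSE]
      mb <- colMeans(Eb)
      sb <- sqrt(pmax(colMeans(Eb^2) - mb^2, 0) * nt / (nt - 1)) / sqrt(nt)
      sb[sb == 0] <- .Machine$double.eps
      tstat[b, ] <- (mb - mu) / sb
    }
  })
  qlo <- apply(tstat, 2, stats::quantile, probs = alpha / 2, names = FALSE)
  qhi <- apply(tstat, 2, stats::quantile, probs = 1 - alpha / 2, names = FALSE)
  lo <- mu - qhi * se
  hi <- mu - qlo * se
  sig <- lo > 0 | hi < 0
  out <- map
  out$sig_mask <- array(sig, dimE[-1])
  out$alpha <- alpha
  out
}

#' Plot an ERD/ERS map
#'
#' Time-frequency image per channel; with a significance mask present,
#' non-significant bins are blanked, mirroring the usual presentation.
#'
#' @param x an `erds_map`.
#' @param channel channel label to plot (default: first mapped channel).
#' @param zlim color limits in percent (default symmetric at 100).
#' @param ... unused.
#' @return Invisibly, the plotted matrix.
#' @export
plot.erds_map <- function(x, channel = x$channels[1], zlim = c(-100, 100), ...) {
  ci <- match(channel, x$channels)
  if (is.na(ci)) stop("channel not in map: ", channel)
  m <- x$values[ci, , ]
  if (!is.null(x$sig_mask)) m[!x$sig_mask[ci, , ]] <- NA
  m <- pmin(pmax(m, zlim[1]), zlim[2])
  pal <- grDevices::hcl.colors(64, "Blue-Red 3", rev = TRUE)
  graphics::image(x$time, x$freq, t(m), col = pal, zlim = zlim,
                  xlab = "time relative to cue (s)", ylab = "frequency (Hz)",
                  main = sprintf("ERD/ERS at %s (%% of reference)", channel))
  graphics::abline(v = 0, lty = 2)
  invisible(m)
}
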