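#' Online decision configuration
#'
#' A command is emitted at each decision tick when the trailing
#' `averaging_window` mean of some class probability exceeds that class's
#' threshold; among classes above threshold the highest mean wins, exact ties
#' emit nothing.  Predictions of `rest_class` are translated to "none"
#' (no command is sent to the game for the rest condition).
#'
#' @param thresholds named numeric vector, class -> probability in `[0, 1]`
#'   (values above 1 make a class unreachable).
#' @param averaging_window trailing probability-averaging window, seconds.
#' @param emit_rate decisions per second (default 16).
#' @param rest_class class translated to "none", or NA to disable.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(thresholds, averaging_window = 1, emit_rate = 16,
                            rest_class = "REST") {
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds))))
    stop("`thresholds` must be a named vector (class -> probability)")
  if (any(thresholds < 0)) stop("thresholds must be >= 0")
  if (averaging_window <= 0) stop("`averaging_window` must be positive")
  structure(list(thresholds = thresholds,
                 averaging_window = averaging_window,
                 emit_rate = emit_rate, rest_class = rest_class),
            class = "decision_config")
}

#' Estimate classifier bias from cross-validated class probabilities
#'
#' Runs repeated stratified CV (default 5 x 5) with in-fold CSP and sLDA
#' fitting and collects the out-of-fold class probabilities at the training
#' latencies.  The per-true-class mean and variance of the probabilities
#' expose any bias of the classifier towards specific classes; the suggested
#' per-class threshold is the mean probability the class receives on
#' off-class trials plus two standard deviations (a reproducible starting
#' point for manual tuning).
#'
#' @param ts a [trial_set()].
#' @param classes classes to include (default: all present).
#' @param spec a [pipeline_spec()].
#' @param scheme CV `(repeats, folds)`, default `c(5, 5)`.
#' @param seed fold seed.
#' @param resting optional resting recording for `spec$normalize`.
#' @return An object of class `bias_estimate`: `prob_mean` and `prob_var`
#'   (true class x predicted class), `suggested_thresholds`.
#' @export
estimate_bias <- function(ts, classes = NULL, spec = pipeline_spec(),
                          scheme = c(5, 5), seed = 1, resting = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  if (isTRUE(spec$fit_on_full))
    stop("refusing to fit feature models on the full data set")
  ts <- kept_trials(ts)
  if (is.null(classes)) classes <- sort(unique(ts$labels))
  ts <- subset_trials(ts, ts$labels %in% classes)
  repeats <- scheme[1]; folds <- scheme[2]
  if (any(table(ts$labels) < folds))
    stop("every class needs at least `folds` trials")
  probs <- NULL
  truth <- character(0)
  for (r in seq_len(repeats)) {
    fold_id <- with_seed(seed + r - 1L, stratified_folds(ts$labels, folds))
    for (f in seq_len(folds)) {
      tr <- subset_trials(ts, fold_id != f)
      te <- subset_trials(ts, fold_id == f)
      fit <- fit_pipeline(tr, classes, spec, resting)
      tf <- extract_features(fit$extractor, te)
      obs <- features_at(tf, spec$train_times)
      pp <- predict(fit$model, obs$X, type = "prob")
      probs <- rbind(probs, pp)
      truth <- c(truth, obs$y)
    }
  }
  prob_mean <- t(vapply(classes, function(k)
    colMeans(probs[truth == k, , drop = FALSE]), numeric(length(classes))))
  prob_var <- t(vapply(classes, function(k)
    apply(probs[truth == k, , drop = FALSE], 2, stats::var),
    numeric(length(classes))))
  dimnames(prob_mean) <- dimnames(prob_var) <- list(true = classes,
                                                    predicted = classes)
  thr <- vapply(classes, function(k) {
    off <- probs[truth != k, k]
    min(0.99, mean(off) + 2 * stats::sd(off))
  }, numeric(1))
  structure(list(prob_mean = prob_mean, prob_var = prob_var,
                 suggested_thresholds = thr, classes = classes,
                 scheme = scheme),
            class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf("<bias_estimate> %dx%d CV; suggested thresholds: %s\n",
              x$scheme[1], x$scheme[2],
              paste(sprintf("%s=%.2f", x$classes, x$suggested_thresholds),
                    collapse = ", ")))
  invisible(x)
}

#' Thresholded command decisions from a class-probability stream
#'
#' Averages each class probability over the trailing window, and at every
#' decision tick emits the command of the highest averaged probability among
#' classes exceeding their thresholds (exact ties or no class above threshold
#' emit "none").  While the artifact gate is blocking, the output is forced to
#' "none" and flagged as gated.  Decisions at time `t` use only samples at or
#' before `t`.
#'
#' @param probs samples x classes probability matrix (rows sum to 1),
#'   column names are the classes.
#' @param cfg a [decision_config()].
#' @param srate sample rate of the probability stream, Hz.
#' @param blocked optional logical vector (per sample) from the artifact gate.
#' @return A `command_stream` data frame: `time`, `command`, `gated`.
#' @export
decide <- function(probs, cfg, srate, blocked = NULL) {
  stopifnot(inherits(cfg, "decision_config"))
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) stop("`probs` must have class column names")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  classes <- colnames(probs)
  thr <- cfg$thresholds[classes]
  if (anyNA(thr)) stop("thresholds missing for class(es): ",
                       paste(classes[is.na(thr)], collapse = ", "))
  win <- max(1L, round(cfg$averaging_window * srate))
  avg <- apply(probs, 2, trailing_mean, win = win)
  step <- max(1L, round(srate / cfg$emit_rate))
  ticks <- seq(step, nrow(probs), by = step)
  if (is.null(blocked)) blocked <- rep(FALSE, nrow(probs))
  cmd <- character(length(ticks))
  gated <- logical(length(ticks))
  for (i in seq_along(ticks)) {
    s <- ticks[i]
    if (blocked[s]) { cmd[i] <- "none"; gated[i] <- TRUE; next }
    a <- avg[s, ]
    cand <- which(a > thr)
    if (!length(cand)) { cmd[i] <- "none"; next }
    best <- max(a[cand])
    winners <- cand[a[cand] == best]
    if (length(winners) != 1L) { cmd[i] <- "none"; next }
    lab <- classes[winners]
    cmd[i] <- if (!is.na(cfg$rest_class) && lab == cfg$rest_class) "none" else lab
  }
  structure(data.frame(time = ticks / srate, command = cmd, gated = gated,
                       stringsAsFactors = FALSE),
            class = c("command_stream", "data.frame"),
            tick = step / srate)
}

# logical run-length encoding of blocked samples into time intervals
blocked_intervals <- function(blocked, srate) {
  r <- rle(blocked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  data.frame(start = (starts[on] - 1) / srate, stop = ends[on] / srate)
}

#' Initialize blink-detector statistics from resting EEG
#'
#' The detector tracks 1-10 Hz band power at a frontal electrode in a sliding
#' window; the blocking threshold is the resting mean power plus `k` resting
#' standard deviations.
#'
#' @param resting resting [eeg_recording()].
#' @param channel frontal electrode (default "AFz").
#' @param band detection band in Hz.
#' @param window power-averaging window in seconds (default 0.25).
#' @param k threshold in resting SDs (default 3).
#' @param filter_order causal Butterworth order.
#' @return An object of class `blink_state`.
#' @export
blink_state <- function(resting, channel = "AFz", band = c(1, 10),
                        window = 0.25, k = 3, filter_order = 4) {
  stopifnot(inherits(resting, "eeg_recording"))
  ci <- channel_index(resting, channel)
  p <- blink_power(resting$data[ci, ], band, window, resting$srate, filter_order)
  if (stats::sd(p) == 0)
    stop("zero variance of resting band power at ", channel)
  structure(list(channel = channel, band = band, window = window, k = k,
                 filter_order = filter_order, srate = resting$srate,
                 mean = mean(p), sd = stats::sd(p)),
            class = "blink_state")
}

blink_power <- function(x, band, window, srate, filter_order) {
  bf <- signal::butter(filter_order, band / (srate / 2), type = "pass")
  xf <- as.numeric(signal::filter(bf, x))
  trailing_mean(xf^2, max(1L, round(window * srate)))
}

#' Blink artifact gate
#'
#' Blocks decision output while the sliding-window 1-10 Hz band power at the
#' frontal electrode exceeds the resting mean plus `k` resting SDs.
#'
#' @param rec ongoing [eeg_recording()] (same montage and rate as resting).
#' @param state a [blink_state()].
#' @return List: `blocked` (logical per sample), `intervals` (data frame
#'   `start`, `stop` in seconds), `power`, `state`.
#' @export
blink_gate <- function(rec, state) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(state, "blink_state"))
  if (rec$srate != state$srate) stop("sample-rate mismatch with resting stats")
  ci <- channel_index(rec, state$channel)
  p <- blink_power(rec$data[ci, ], state$band, state$window, rec$srate,
                   state$filter_order)
  blocked <- p > state$mean + state$k * state$sd
  list(blocked = blocked, intervals = blocked_intervals(blocked, rec$srate),
       power = p, state = state)
}

#' Fit per-channel autoregressive models on resting EEG
#'
#' Order-10 AR coefficients per channel via the autocorrelation (Yule-Walker)
#' method, with the one-step prediction-error SD; the basis of the
#' prediction-error artifact gate.
#'
#' @param resting resting [eeg_recording()] with at least `100 * order`
#'   samples.
#' @param order AR model order (default 10).
#' @return An object of class `ar_model`: `coef` (channels x order),
#'   `sd` (per channel), `order`, `channels`, `srate`.
#' @export
ar_fit <- function(resting, order = 10) {
  stopifnot(inherits(resting, "eeg_recording"))
  n <- ncol(resting$data)
  if (n < 100 * order)
    stop("resting segment too short: need at least ", 100 * order, " samples")
  coefs <- matrix(NA_real_, nrow(resting$data), order)
  sds <- numeric(nrow(resting$data))
  for (ch in seq_len(nrow(resting$data))) {
    fit <- stats::ar.yw(resting$data[ch, ], aic = FALSE, order.max = order,
                        demean = TRUE)
    coefs[ch, ] <- fit$ar
    sds[ch] <- sqrt(fit$var.pred)
  }
  rownames(coefs) <- resting$channels
  structure(list(coef = coefs, sd = sds, order = order,
                 channels = resting$channels, srate = resting$srate),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> order %d, %d channels, error SD %.2f-%.2f uV\n",
              x$order, length(x$channels), min(x$sd), max(x$sd)))
  invisible(x)
}

#' Autoregressive prediction-error artifact gate
#'
#' Each channel's next sample is linearly predicted from the previous `order`
#' samples using the resting AR coefficients (an inverse FIR filter); output
#' is blocked whenever any channel's prediction error exceeds `k` times its
#' error SD.  On unblocked samples the error SD (and, slowly, the
#' coefficients) are adapted by exponential forgetting with time constant
#' `adapt` seconds to track slow drifts of the EEG statistics.
#'
#' @param rec ongoing [eeg_recording()] over the fitted montage.
#' @param model an [ar_model()].
#' @param k blocking threshold in error SDs (default 3).
#' @param adapt forgetting time constant in seconds (default 30); `Inf`
#'   disables adaptation.
#' @return List: `blocked`, `intervals`, `errors` (channels x samples),
#'   `model` (adapted).
#' @export
ar_gate <- function(rec, model, k = 3, adapt = 30) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(model, "ar_model"))
  if (!identical(rec$channels, model$channels))
    stop("channel set differs from the fitted AR model")
  X <- rec$data
  nc <- nrow(X); n <- ncol(X); p <- model$order
  A <- model$coef
  v <- model$sd^2
  lambda <- if (is.finite(adapt)) exp(-1 / (adapt * rec$srate)) else 1
  blocked <- rep(FALSE, n)
  errors <- matrix(0, nc, n)
  if (n <= p) return(list(blocked = blocked,
                          intervals = blocked_intervals(blocked, rec$srate),
                          errors = errors, model = model))
  for (t in (p + 1):n) {
    past <- X[, (t - 1):(t - p), drop = FALSE]     # lag 1..p, channels x p
    pred <- rowSums(A * past)
    e <- X[, t] - pred
    errors[, t] <- e
    if (any(abs(e) > k * sqrt(v))) {
      blocked[t] <- TRUE
    } else if (lambda < 1) {
      v <- lambda * v + (1 - lambda) * e^2
      # normalized LMS coefficient update on clean samples
      nrm <- rowSums(past^2) + 1e-12
      A <- A + (1 - lambda) * (e / nrm) * past
    }
  }
  out_model <- model
  out_model$coef <- A
  out_model$sd <- sqrt(v)
  list(blocked = blocked, intervals = blocked_intervals(blocked, rec$srate),
       errors = errors, model = out_model)
}

#' Combine gate outputs
#' @param ... logical per-sample blocked vectors of equal length.
#' @return Logical vector, TRUE where any gate blocks.
#' @export
combine_gates <- function(...) Reduce(`|`, list(...))
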