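#' Train an online decoder from a calibration trial set
#'
#' Fits the CSP band-power extractor and sLDA classifier on the full
#' calibration set, then estimates classifier bias via repeated
#' cross-validation and derives per-class decision thresholds from the
#' out-of-fold probability statistics.
#'
#' @param ts calibration [trial_set()].
#' @param classes classes to decode (default: all present).
#' @param spec a [pipeline_spec()].
#' @param resting resting [eeg_recording()] for variance normalization and
#'   the artifact gates (required when `spec$normalize` is TRUE).
#' @param bias_scheme CV scheme for [estimate_bias()] (default `c(5, 5)`).
#' @param seed seed for the bias CV folds.
#' @param thresholds manual per-class thresholds overriding the suggestion.
#' @return An object of class `bci_decoder`: `extractor`, `model`,
#'   `thresholds`, `bias`, `spec`, `classes`.
#' @export
train_decoder <- function(ts, classes = NULL, spec = pipeline_spec(),
                          resting = NULL, bias_scheme = c(5, 5), seed = 1,
                          thresholds = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  ts <- kept_trials(ts)
  if (is.null(classes)) classes <- sort(unique(ts$labels))
  if (isTRUE(spec$normalize) && is.null(resting))
    stop("`spec$normalize` requires a resting recording")
  fit <- fit_pipeline(ts, classes, spec, resting)
  bias <- estimate_bias(ts, classes, spec, scheme = bias_scheme, seed = seed,
                        resting = resting)
  if (is.null(thresholds)) thresholds <- bias$suggested_thresholds
  structure(list(extractor = fit$extractor, model = fit$model,
                 thresholds = thresholds, bias = bias, spec = spec,
                 classes = classes),
            class = "bci_decoder")
}

#' @export
print.bci_decoder <- function(x, ...) {
  cat(sprintf("<bci_decoder> %s; %d features; thresholds %s\n",
              paste(x$classes, collapse = "/"), feature_dim(x$extractor),
              paste(sprintf("%.2f", x$thresholds), collapse = "/")))
  invisible(x)
}

#' Decode a continuous EEG stream into a command stream
#'
#' Runs the decoder's feature extraction and sLDA over the stream sample by
#' sample, averages the class probabilities over the trailing second and
#' applies the class-specific thresholds; optionally the blink and AR
#' prediction-error gates block output over contaminated intervals.
#'
#' @param decoder a `bci_decoder`.
#' @param rec the ongoing [eeg_recording()].
#' @param gates optional list with components `blink` (a [blink_state()])
#'   and/or `ar` (an [ar_model()]); their blocked samples are OR-combined.
#' @param emit_rate decisions per second.
#' @return A `command_stream` data frame (`time`, `command`, `gated`) with
#'   the per-sample probability matrix attached as attribute `probs`.
#' @export
decode_stream <- function(decoder, rec, gates = NULL, emit_rate = 16) {
  stopifnot(inherits(decoder, "bci_decoder"), inherits(rec, "eeg_recording"))
  fm <- extract_features(decoder$extractor, rec)
  probs <- predict(decoder$model, fm$values, type = "prob")
  blocked <- rep(FALSE, nrow(probs))
  if (!is.null(gates$blink))
    blocked <- blocked | blink_gate(rec, gates$blink)$blocked
  if (!is.null(gates$ar))
    blocked <- blocked | ar_gate(rec, gates$ar)$blocked
  cfg <- decision_config(decoder$thresholds,
                         averaging_window = decoder$spec$window,
                         emit_rate = emit_rate,
                         rest_class = if ("REST" %in% decoder$classes)
                           "REST" else NA)
  cs <- decide(probs, cfg, srate = rec$srate, blocked = blocked)
  attr(cs, "probs") <- probs
  cs
}

#' Simulate one closed-loop race with a trained decoder
#'
#' Generates the training-paradigm EEG stream for the track (task imagery on
#' the first half of each pad, relaxation on the second), decodes it into
#' commands and replays those commands through the race dynamics.
#'
#' @param decoder a `bci_decoder`.
#' @param track a [race_track()].
#' @param cfg a [race_config()].
#' @param sim a [sim_config()] describing the simulated pilot; its `seed`
#'   determines the EEG realization.
#' @param gates optional gates as in [decode_stream()].
#' @param pad_duration nominal seconds per pad in the generated stream.
#' @return A `race_result` with the command stream attached as `commands`.
#' @export
simulate_race <- function(decoder, track, cfg, sim, gates = NULL,
                          pad_duration = track$pad_length / cfg$base_speed) {
  stream <- generate_race_stream(sim, track, pad_duration = pad_duration)
  cs <- decode_stream(decoder, stream$recording, gates = gates,
                      emit_rate = 1 / cfg$tick)
  res <- run_race(track, cfg, cs)
  res$commands <- cs
  res
}
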