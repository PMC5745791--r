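# shared small-scale fixtures: a 6-channel montage at 128 Hz keeps the suite
# fast while exercising the full pipeline geometry

test_montage <- function() c("C3", "Cz", "C4", "Pz", "AFz", "O1")

quick_config <- function(seed = 7, srate = 128, noise_sd = 3,
                         channels = test_montage(),
                         classes = c("HAND", "FEET", "SUB", "REST"), ...) {
  sim_config(srate = srate, channels = channels, classes = classes,
             noise_sd = noise_sd, seed = seed, ...)
}

quick_session <- function(tpc = 8, seed = 7, rest = 30, ...) {
  cfg <- quick_config(seed = seed, ...)
  generate_calibration_session(cfg, tpc,
                               paradigm_spec(rest_duration = rest))
}

quick_trials <- function(tpc = 8, seed = 7, ...) {
  segment(quick_session(tpc = tpc, seed = seed, ...)$recording,
          window = c(-3, 5))
}

quick_spec <- function(bands = list(c(8, 16), c(16, 30)), ...) {
  pipeline_spec(bands = bands, eval_step = 32, ...)
}

# white-noise trial set with known geometry (no class structure)
noise_trials <- function(n_trials = 20, n_ch = 2, n_s = 256, srate = 128,
                         labels = rep(c("A", "B"), length.out = n_trials),
                         seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  set.seed(seed)
  trial_set(array(rnorm(n_trials * n_ch * n_s), c(n_trials, n_ch, n_s)),
            time = seq(-1, by = 1 / srate, length.out = n_s),
            srate = srate, channels = paste0("ch", seq_len(n_ch)),
            labels = labels)
}

# log-log periodogram slope over a frequency range (Welch-style smoothing)
psd_slope <- function(x, srate, f_range = c(2, 40)) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = srate), spans = c(25, 25),
                          plot = FALSE, detrend = TRUE)
  keep <- sp$freq >= f_range[1] & sp$freq <= f_range[2]
  -unname(stats::coef(stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2])
}

# mean band power (zero-phase bandpass, variance) over sample windows
band_power_in <- function(x, srate, band, windows) {
  bf <- signal::butter(4, band / (srate / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, x))
  mean(vapply(seq_len(nrow(windows)), function(i)
    stats::var(xf[windows[i, 1]:windows[i, 2]]), numeric(1)))
}
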