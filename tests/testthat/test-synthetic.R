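test_that("generators are bit-identical under a fixed seed", {
  cfg <- quick_config(seed = 42)
  expect_identical(generate_resting(cfg, 5)$data, generate_resting(cfg, 5)$data)
  s1 <- generate_calibration_session(cfg, 2, paradigm_spec(rest_duration = 5))
  s2 <- generate_calibration_session(cfg, 2, paradigm_spec(rest_duration = 5))
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$labels, s2$labels)
  cfg2 <- quick_config(seed = 43)
  expect_false(identical(generate_resting(cfg2, 5)$data,
                         generate_resting(cfg, 5)$data))
})

test_that("degenerate config (no noise, no sources) yields silence", {
  src <- data.frame(name = character(0), class = character(0),
                    center = character(0), f_lo = numeric(0),
                    f_hi = numeric(0), amp = numeric(0))
  cfg <- sim_config(srate = 128, channels = c("C3", "AFz"),
                    classes = c("HAND", "REST"), sources = src,
                    mixing = matrix(0, 0, 2), erd_depth = list(),
                    noise_sd = 0, seed = 1)
  rec <- generate_resting(cfg, 2)
  expect_equal(dim(rec$data), c(2, 256))
  expect_true(all(rec$data == 0))
})

test_that("resting spectrum follows the configured 1/f slope", {
  cfg <- quick_config(seed = 3)
  rec <- generate_resting(cfg, 60)
  # O1 carries no oscillatory source in this montage: pure background there
  slope <- psd_slope(rec$data["O1", ], cfg$srate, c(2, 40))
  expect_lt(abs(slope - cfg$background_slope), 0.2 * cfg$background_slope)
})

test_that("non-positive resting duration is rejected", {
  expect_error(generate_resting(quick_config(), 0), "positive")
  expect_error(generate_resting(quick_config(), -3), "positive")
})

test_that("calibration sessions have exact counts and Graz timing", {
  cfg <- quick_config(seed = 11)
  ses <- generate_calibration_session(cfg, 10, paradigm_spec(rest_duration = 10))
  ev <- ses$recording$events
  expect_equal(nrow(ev), 40)                       # 10 TPC x 4 classes
  expect_equal(as.vector(table(ses$labels)), rep(10, 4))
  expect_true(all(diff(ev$sample) > 0))            # strictly increasing cues
  # cue spacing: pre(3) + imagery(5) + iti in [2, 3] seconds
  gaps <- diff(ev$sample) / cfg$srate
  expect_true(all(gaps >= 10 - 1e-6 & gaps <= 11 + 1e-6))
  expect_identical(ev$code, ses$labels)
})

test_that("per-class counts match the request across seeds", {
  for (seed in 1:3) {
    ses <- quick_session(tpc = 3, seed = seed, rest = 2)
    expect_equal(as.vector(table(ses$labels)), rep(3, 4))
  }
})

test_that("injected ERD scales imagery band power by 1 + depth", {
  # one mu source projecting to C4 only, HAND depth -0.5 in its band
  src <- data.frame(name = "hand_mu", class = "HAND", center = "C4",
                    f_lo = 10, f_hi = 14, amp = 10)
  mix <- matrix(0, 1, 3, dimnames = list("hand_mu", c("C3", "C4", "AFz")))
  mix[1, "C4"] <- 1
  cfg <- sim_config(srate = 128, channels = c("C3", "C4", "AFz"),
                    classes = c("HAND", "REST"), sources = src, mixing = mix,
                    erd_depth = list(HAND = c(hand_mu = -0.5),
                                     REST = numeric(0)),
                    noise_sd = 0.5, seed = 5)
  ses <- generate_calibration_session(cfg, 12, paradigm_spec(rest_duration = 5))
  fs <- cfg$srate
  cues <- ses$recording$events$sample
  hand <- ses$labels == "HAND"
  # avoid the 250 ms envelope ramps at the imagery boundaries
  imag <- cbind(cues[hand] + round(0.5 * fs), cues[hand] + round(4.5 * fs))
  base <- cbind(cues[hand] - round(2.5 * fs), cues[hand] - round(0.5 * fs))
  x <- ses$recording$data["C4", ]
  ratio <- band_power_in(x, fs, c(8, 16), imag) /
    band_power_in(x, fs, c(8, 16), base)
  expect_lt(abs(ratio - 0.5), 0.1)
  # REST trials keep baseline power
  rest_im <- cbind(cues[!hand] + round(0.5 * fs), cues[!hand] + round(4.5 * fs))
  rest_ba <- cbind(cues[!hand] - round(2.5 * fs), cues[!hand] - round(0.5 * fs))
  ratio_rest <- band_power_in(x, fs, c(8, 16), rest_im) /
    band_power_in(x, fs, c(8, 16), rest_ba)
  expect_lt(abs(ratio_rest - 1), 0.25)
})

test_that("zero ERD depth removes class differences in band power", {
  cfg <- quick_config(seed = 9)
  cfg$erd_depth <- lapply(cfg$erd_depth, function(d) { d[] <- 0; d })
  ses <- generate_calibration_session(cfg, 10, paradigm_spec(rest_duration = 2))
  fs <- cfg$srate
  cues <- ses$recording$events$sample
  pw <- vapply(seq_along(cues), function(i)
    band_power_in(ses$recording$data["C3", ], fs, c(8, 16),
                  cbind(cues[i] + round(0.5 * fs), cues[i] + round(4.5 * fs))),
    numeric(1))
  pvals <- sapply(utils::combn(unique(ses$labels), 2, simplify = FALSE),
                  function(pr) stats::t.test(pw[ses$labels == pr[1]],
                                             pw[ses$labels == pr[2]])$p.value)
  expect_true(all(pvals > 0.01))
})

test_that("race streams follow pad semantics", {
  cfg <- quick_config(seed = 21)
  track <- race_track(c("HAND", "REST", "FEET", "SUB"))
  ses <- generate_race_stream(cfg, track, pad_duration = 10)
  ev <- ses$recording$events
  expect_equal(nrow(ev), 4)
  expect_true(all(diff(ev$sample) > 0))
  expect_identical(ev$code, track$pads)
  fs <- cfg$srate
  # HAND pad (pad 1): first 5 s shows ERD at C3, second 5 s does not
  x <- ses$recording$data["C3", ]
  p_task <- band_power_in(x, fs, c(8, 16),
                          cbind(round(0.5 * fs), round(4.5 * fs)))
  p_break <- band_power_in(x, fs, c(8, 16),
                           cbind(round(5.5 * fs), round(9.5 * fs)))
  expect_lt(p_task / p_break, 0.75)
  # REST pad (pad 2, 10-20 s): no modulation between the two halves
  p_r1 <- band_power_in(x, fs, c(8, 16),
                        cbind(round(10.5 * fs), round(14.5 * fs)))
  p_r2 <- band_power_in(x, fs, c(8, 16),
                        cbind(round(15.5 * fs), round(19.5 * fs)))
  expect_lt(abs(p_r1 / p_r2 - 1), 0.35)
})

test_that("unknown pad classes are rejected", {
  cfg <- quick_config()
  expect_error(generate_race_stream(cfg, race_track(c("HAND", "TONGUE"))),
               "TONGUE")
})

test_that("doubling a source's mixing weights doubles its contribution", {
  src <- data.frame(name = "s1", class = "HAND", center = "C3",
                    f_lo = 9, f_hi = 13, amp = 5)
  mk <- function(w) {
    mix <- matrix(w * c(1, 0.4, 0), 1, 3,
                  dimnames = list("s1", c("C3", "Cz", "AFz")))
    sim_config(srate = 128, channels = c("C3", "Cz", "AFz"),
               classes = c("HAND", "REST"), sources = src, mixing = mix,
               erd_depth = list(HAND = c(s1 = -0.5), REST = numeric(0)),
               noise_sd = 0, seed = 2)
  }
  r1 <- generate_resting(mk(1), 10)
  r2 <- generate_resting(mk(2), 10)
  rms <- function(m) sqrt(mean(m^2))
  expect_lt(abs(rms(r2$data) / rms(r1$data) - 2), 0.02)
})

test_that("artifact injection adds detectable blinks with ground truth", {
  cfg <- quick_config(seed = 31, noise_sd = 3)
  rec <- generate_resting(cfg, 30)
  same <- inject_artifacts(rec)
  expect_identical(same$data, rec$data)                  # empty lists: identity
  zero <- inject_artifacts(rec, blink_times = 10, blink_amplitude = 0)
  expect_equal(zero$data, rec$data, tolerance = 1e-12)
  out <- inject_artifacts(rec, blink_times = 10, blink_amplitude = 200)
  arts <- attr(out, "artifacts")
  expect_equal(arts$kind, "blink")
  fs <- cfg$srate
  bf <- signal::butter(4, c(1, 10) / (fs / 2), type = "pass")
  p <- as.numeric(signal::filtfilt(bf, out$data["AFz", ]))^2
  base_idx <- c(seq_len(8 * fs), (12 * fs):(30 * fs))
  win <- (round(9.75 * fs)):(round(10.25 * fs))
  expect_gt(mean(p[win]), mean(p[base_idx]) + 3 * stats::sd(p[base_idx]))
})

test_that("out-of-range artifact times are rejected", {
  rec <- generate_resting(quick_config(), 5)
  expect_error(inject_artifacts(rec, blink_times = 100), "span")
  expect_error(inject_artifacts(rec, step_times = -1), "span")
})

test_that("step artifacts shift the baseline of chosen channels", {
  cfg <- quick_config(seed = 8, noise_sd = 1)
  rec <- generate_resting(cfg, 10)
  out <- inject_artifacts(rec, step_times = 5, step_amplitude = 50,
                          step_channels = "Cz")
  fs <- cfg$srate
  shift <- mean(out$data["Cz", (6 * fs):(10 * fs)]) -
    mean(out$data["Cz", 1:(4 * fs)])
  expect_lt(abs(shift - 50), 2)
  expect_equal(out$data["C3", ], rec$data["C3", ])       # other channels untouched
})
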