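make_rec <- function(data, srate = 128, channels = paste0("ch", seq_len(nrow(data))),
                     events = NULL) {
  eeg_recording(data, srate, channels, events)
}

test_that("the 50 Hz notch removes a 50 Hz tone", {
  fs <- 512
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- make_rec(matrix(sin(2 * pi * 50 * t), 1), srate = fs)
  out <- butter_filter(rec, filter_spec("notch", 50, phase = "causal"))
  steady <- out$data[1, (2 * fs):(10 * fs)]          # skip the ring-in
  expect_lt(sqrt(mean(steady^2)) / sqrt(1 / 2), 0.01)
})

test_that("causal bandpass gains match the Butterworth response", {
  fs <- 512
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 10 * t)
  rec <- make_rec(matrix(tone, 1), srate = fs)
  inband <- butter_filter(rec, filter_spec("bandpass", c(8, 16), 4, "causal"))
  gain <- sqrt(mean(inband$data[1, (2 * fs):(10 * fs)]^2) / 0.5)
  expect_gte(gain, 0.9)
  expect_lte(gain, 1.0 + 1e-6)
  outband <- butter_filter(rec, filter_spec("bandpass", c(16, 30), 4, "causal"))
  atten <- sqrt(mean(outband$data[1, (2 * fs):(10 * fs)]^2) / 0.5)
  expect_lt(20 * log10(atten), -20)
})

test_that("filters are linear and map zero to zero", {
  fs <- 128
  set.seed(4)
  x <- rnorm(fs * 4); y <- rnorm(fs * 4)
  spec <- filter_spec("bandpass", c(8, 16), 4, "causal")
  f <- function(v) butter_filter(make_rec(matrix(v, 1), fs), spec)$data[1, ]
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-9)
  expect_true(all(f(rep(0, fs * 4)) == 0))
})

test_that("zero-phase filtering leaves a band-centred tone undelayed", {
  fs <- 256
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 12 * t) * exp(-((t - 4) / 1.5)^2)
  out <- butter_filter(make_rec(matrix(tone, 1), fs),
                       filter_spec("bandpass", c(8, 16), 4, "zero_phase"))
  cc <- stats::ccf(out$data[1, ], tone, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("bands beyond Nyquist are rejected", {
  rec <- make_rec(matrix(rnorm(256), 1), srate = 128)
  expect_error(butter_filter(rec, filter_spec("bandpass", c(8, 70), 4)),
               "Nyquist")
})

test_that("laplacian derivation implements center minus neighbour mean", {
  fs <- 64
  n <- 64
  base <- matrix(rnorm(5 * n), 5)
  chans <- c("C3", "C3_a", "C3_p", "C3_l", "C3_r")
  # neighbours identical to center: common-mode fully rejected
  rec <- make_rec(matrix(rep(base[1, ], 5), 5, byrow = TRUE), fs, chans)
  lap <- laplacian(rec, "C3", chans[-1])
  expect_true(all(abs(lap$data) < 1e-12))
  # constant channels: 4 - mean(2,2,2,2) = 2
  rec2 <- make_rec(rbind(rep(4, n), matrix(2, 4, n)), fs, chans)
  expect_true(all(laplacian(rec2, "C3", chans[-1])$data == 2))
  expect_error(laplacian(rec2, "C3", c("C3_a", "C3_p", "C3_l", "nope")),
               "not found")
})

test_that("laplacian passes focal sources and cancels common sources", {
  src <- data.frame(name = c("focal", "broad"), class = c("HAND", "FEET"),
                    center = c("C3", "C3"), f_lo = c(9, 18), f_hi = c(13, 24),
                    amp = c(5, 5))
  chans <- c("C3", "C3_a", "C3_p", "C3_l", "C3_r")
  mix <- rbind(focal = c(1, 0, 0, 0, 0), broad = rep(1, 5))
  colnames(mix) <- chans
  cfg <- sim_config(srate = 128, channels = chans,
                    classes = c("HAND", "FEET", "REST"), sources = src,
                    mixing = mix,
                    erd_depth = list(HAND = c(focal = -0.5)),
                    noise_sd = 0, seed = 6)
  rec <- generate_resting(cfg, 10)
  lap <- laplacian(rec, "C3", chans[-1])
  # reconstruct the focal source alone for comparison
  cfg_focal <- cfg
  cfg_focal$mixing["broad", ] <- 0
  focal_only <- generate_resting(cfg_focal, 10)
  expect_equal(lap$data[1, ], focal_only$data["C3", ], tolerance = 1e-9)
})

test_that("segmentation is cue-locked with exact geometry", {
  fs <- 512
  n <- 40 * round(10.5 * fs)
  set.seed(2)
  cues <- round(seq(4 * fs, n - 6 * fs, length.out = 40))
  rec <- make_rec(matrix(rnorm(3 * n), 3), fs, c("C3", "Cz", "C4"),
                  events = data.frame(sample = cues,
                                      code = rep(c("HAND", "FEET"), 20)))
  ts <- segment(rec, window = c(-3, 5))
  expect_equal(dim(ts$data), c(40, 3, 4096))
  expect_equal(ts$time[1], -3)
  expect_equal(sum(ts$time < 0), 3 * fs)
  # the sample at t = 0 is the cue sample
  i0 <- which.min(abs(ts$time))
  expect_equal(ts$data[1, , i0], unname(rec$data[, cues[1]]))
  expect_identical(ts$labels, rec$events$code)
})

test_that("segmentation boundary cases are handled", {
  fs <- 128
  rec <- make_rec(matrix(rnorm(2 * 10 * fs), 2), fs,
                  c("a", "b"),
                  events = data.frame(sample = c(100L, 640L),
                                      code = c("X", "X")))
  expect_warning(ts <- segment(rec, window = c(-3, 5)), "dropped")
  expect_equal(dim(ts$data)[1], 1)
  empty <- segment(make_rec(matrix(rnorm(2 * fs), 1), fs, "a"),
                   window = c(-0.5, 0.5))
  expect_equal(dim(empty$data)[1], 0)
})

test_that("segmenting adjacent windows preserves samples bit-exactly", {
  fs <- 64
  n <- 8 * fs
  x <- matrix(rnorm(2 * n), 2)
  starts <- seq(1L, n, by = 2 * fs)
  rec <- make_rec(x, fs, c("a", "b"),
                  events = data.frame(sample = starts, code = "w"))
  ts <- segment(rec, window = c(0, 2))
  recon <- do.call(cbind, lapply(seq_len(dim(ts$data)[1]), function(i)
    matrix(ts$data[i, , ], nrow = 2)))
  expect_identical(recon, unname(x))
})

test_that("outlier rejection flags exactly the contaminated trials", {
  set.seed(10)
  nt <- 20
  dat <- array(rnorm(nt * 2 * 128, sd = 5), c(nt, 2, 128))
  ts <- trial_set(dat, seq(0, by = 1 / 128, length.out = 128), 128,
                  c("a", "b"), rep(c("X", "Y"), nt / 2))
  clean <- reject_outlier_trials(ts)
  expect_true(all(clean$kept))
  dat2 <- dat
  dat2[7, 1, 50] <- 150                     # amplitude criterion
  ts2 <- trial_set(dat2, ts$time, 128, ts$channels, ts$labels)
  rej <- reject_outlier_trials(ts2)
  expect_identical(which(!rej$kept), 7L)
})

test_that("rejection fraction tracks the contamination rate", {
  set.seed(12)
  nt <- 30
  dat <- array(rnorm(nt * 3 * 256, sd = 8), c(nt, 3, 256))
  bad <- c(4, 13, 27)                        # 10% contaminated
  for (i in bad) dat[i, 1, 100:110] <- 300
  ts <- trial_set(dat, seq(0, by = 1 / 128, length.out = 256), 128,
                  c("a", "b", "c"), rep("X", nt))
  rej <- reject_outlier_trials(ts)
  expect_identical(which(!rej$kept), as.integer(bad))
  expect_equal(mean(!rej$kept), 0.1)
})

test_that("rejection refuses tiny sets and never guts clean data", {
  ts_small <- noise_trials(n_trials = 4)
  expect_warning(out <- reject_outlier_trials(ts_small), "fewer than 5")
  expect_identical(out$kept, ts_small$kept)
  ts_sim <- quick_trials(tpc = 6, seed = 17)
  rej <- reject_outlier_trials(ts_sim)
  expect_lte(mean(!rej$kept), 0.5)           # guard: at most half removed
})

test_that("variance normalization rescales by resting SD", {
  cfg <- quick_config(seed = 13)
  rest <- generate_resting(cfg, 20)
  task <- generate_resting(quick_config(seed = 14), 10)
  norm <- variance_normalize(task, rest)
  # resting normalized against itself has unit channel SDs
  self <- variance_normalize(rest, rest)
  expect_equal(unname(apply(self$data, 1, sd)), rep(1, 6), tolerance = 1e-9)
  # scaling a channel in both rest and task leaves the output invariant
  rest2 <- rest; task2 <- task
  rest2$data[2, ] <- rest2$data[2, ] * 10
  task2$data[2, ] <- task2$data[2, ] * 10
  norm2 <- variance_normalize(task2, rest2)
  expect_equal(norm2$data, norm$data, tolerance = 1e-12)
  # unit resting SD: identity
  unit <- rest
  unit$data <- matrix(rnorm(ncol(rest$data) * 6), 6)
  unit$data <- unit$data / apply(unit$data, 1, sd)
  expect_equal(variance_normalize(task, unit)$data, task$data,
               tolerance = 1e-12)
  flat <- rest
  flat$data[3, ] <- 0
  expect_error(variance_normalize(task, flat), "C4")
})
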