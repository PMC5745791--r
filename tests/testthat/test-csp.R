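# trial set with prescribed per-class source variances through a known mixing
mixed_trials <- function(A, var_a, var_b, n_per_class = 12, n_s = 256,
                         srate = 128, noise = 0.3, seed = 1) {
  set.seed(seed)
  n_src <- nrow(A); n_ch <- ncol(A)
  nt <- 2 * n_per_class
  dat <- array(0, c(nt, n_ch, n_s))
  labels <- rep(c("A", "B"), each = n_per_class)
  for (i in seq_len(nt)) {
    v <- if (labels[i] == "A") var_a else var_b
    S <- matrix(rnorm(n_src * n_s, sd = sqrt(v)), n_src)
    dat[i, , ] <- t(A) %*% S + noise * matrix(rnorm(n_ch * n_s), n_ch)
  }
  trial_set(dat, seq(1, by = 1 / srate, length.out = n_s), srate,
            paste0("ch", seq_len(n_ch)), labels)
}

test_that("identical class covariances give eigenvalues of one half", {
  ts <- noise_trials(n_trials = 16, n_ch = 4, n_s = 256,
                     labels = rep(c("A", "B"), 8), seed = 2)
  ts$time <- seq(1, by = 1 / 128, length.out = 256)
  # same data for both classes: duplicate trials under both labels
  dat <- ts$data[rep(1:8, 2), , ]
  ts2 <- trial_set(dat, ts$time, 128, ts$channels,
                   rep(c("A", "B"), each = 8))
  m <- fit_csp(ts2, c("A", "B"), fit_window = c(1, 2.9), shrinkage = 0)
  expect_equal(m$eigenvalues, rep(0.5, 4), tolerance = 1e-6)
})

test_that("CSP recovers the discriminative source's unmixing filter", {
  A <- rbind(c(1, 0.5, 0.2, 0.1),     # source 1: class-dependent power
             c(0.1, 0.3, 0.9, 0.4))   # source 2: constant power
  ts <- mixed_trials(A, var_a = c(9, 1), var_b = c(0.05, 1), seed = 3)
  m <- fit_csp(ts, c("A", "B"), fit_window = c(1, 2.9), shrinkage = 0,
               trace_norm = FALSE)
  expect_gt(m$eigenvalues[1], 0.9)
  # oracle: row of the mixing pseudoinverse that extracts source 1
  W_oracle <- solve(A %*% t(A)) %*% A    # pinv(t(A)), rows unmix sources
  cor1 <- abs(stats::cor(m$filters[, 1], W_oracle[1, ]))
  expect_gt(cor1, 0.95)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))   # sorted descending
  expect_true(all(m$eigenvalues >= -1e-9 & m$eigenvalues <= 1 + 1e-9))
})

test_that("full shrinkage collapses the eigenvalues to the trace ratio", {
  A <- diag(3)
  ts <- mixed_trials(A, var_a = c(4, 1, 1), var_b = c(1, 1, 4), seed = 4)
  m <- fit_csp(ts, c("A", "B"), fit_window = c(1, 2.9), shrinkage = 1)
  # trace-normalized covariances have unit trace: ratio is exactly 1/2
  expect_equal(m$eigenvalues, rep(0.5, 3), tolerance = 1e-9)
})

test_that("eigenvalues are invariant to invertible channel mixing", {
  A <- rbind(c(1, 0.4, 0.1), c(0.2, 1, 0.3))
  ts <- mixed_trials(A, var_a = c(4, 1), var_b = c(0.5, 1), seed = 5)
  m1 <- fit_csp(ts, c("A", "B"), fit_window = c(1, 2.9), shrinkage = 0,
                trace_norm = FALSE)
  M <- matrix(c(1, 0.3, -0.2, 0.5, 1.2, 0.1, 0, -0.4, 0.9), 3, 3)
  ts2 <- ts
  for (i in seq_len(dim(ts$data)[1]))
    ts2$data[i, , ] <- M %*% matrix(ts$data[i, , ], nrow = 3)
  m2 <- fit_csp(ts2, c("A", "B"), fit_window = c(1, 2.9), shrinkage = 0,
                trace_norm = FALSE)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-6)
})

test_that("singular covariances without shrinkage are refused", {
  ts <- noise_trials(n_trials = 12, n_ch = 3, n_s = 128,
                     labels = rep(c("A", "B"), 6), seed = 6)
  ts$time <- seq(1, by = 1 / 128, length.out = 128)
  ts$data[, 3, ] <- ts$data[, 2, ]       # duplicated channel: rank deficient
  expect_error(fit_csp(ts, c("A", "B"), c(1, 1.9), shrinkage = 0),
               "shrinkage")
  m <- fit_csp(ts, c("A", "B"), c(1, 1.9), shrinkage = 0.1)
  expect_s3_class(m, "csp_model")
})

test_that("feature dimension follows pairs x 4 filters x bands", {
  ts4 <- quick_trials(tpc = 5, seed = 19)
  ex48 <- build_extractor(ts4, bands = list(c(8, 16), c(16, 30)),
                          fit_window = c(1, 3), shrinkage = 0.2)
  expect_equal(feature_dim(ex48), 48)      # 6 pairs x 4 filters x 2 bands
  ex24 <- build_extractor(ts4, bands = list(c(6, 35)),
                          fit_window = c(1, 3), shrinkage = 0.2)
  expect_equal(feature_dim(ex24), 24)      # 6 pairs x 4 filters x 1 band
  cfg3 <- quick_config(seed = 20, classes = c("HAND", "FEET", "REST"))
  ses3 <- generate_calibration_session(cfg3, 5, paradigm_spec(rest_duration = 2))
  ts3 <- segment(ses3$recording, window = c(-3, 5))
  ex12 <- build_extractor(ts3, bands = list(c(6, 35)),
                          fit_window = c(1, 3), shrinkage = 0.2)
  expect_equal(feature_dim(ex12), 12)      # 3 pairs x 4 filters x 1 band
  expect_error(build_extractor(subset_trials(ts4, ts4$labels == "HAND"),
                               bands = list(c(8, 16))), "2 classes")
})

test_that("log band power scales as the log of squared amplitude", {
  ts <- quick_trials(tpc = 5, seed = 22)
  ex <- build_extractor(ts, bands = list(c(8, 16)), fit_window = c(1, 3),
                        shrinkage = 0.2)
  rec <- generate_resting(quick_config(seed = 23), 6)
  f1 <- extract_features(ex, rec)
  rec2 <- rec
  rec2$data <- rec2$data * 2
  f2 <- extract_features(ex, rec2)
  after <- !f1$burn_in
  expect_equal(f2$values[after, ] - f1$values[after, ],
               matrix(log(4), sum(after), ncol(f1$values)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("extracted features match brute-force windowed variance", {
  ts <- quick_trials(tpc = 5, seed = 25)
  ex <- build_extractor(ts, bands = list(c(8, 16)), fit_window = c(1, 3),
                        shrinkage = 0.2)
  rec <- generate_resting(quick_config(seed = 26), 4)
  fm <- extract_features(ex, rec)
  fs <- rec$srate
  # oracle: filter, project, and average squares by explicit windows
  bf <- signal::butter(4, c(8, 16) / (fs / 2), type = "pass")
  Xf <- t(apply(rec$data, 1, function(x) as.numeric(signal::filter(bf, x))))
  if (!is.null(ex$scales[[1]])) Xf <- Xf / ex$scales[[1]]
  m <- ex$models[[1]]
  y <- as.numeric(crossprod(m$filters[, m$selected[1], drop = FALSE], Xf))
  win <- fs
  for (s in c(10L, 100L, 300L, 500L)) {
    lo <- max(1L, s - win + 1L)
    expect_equal(unname(fm$values[s, 1]), log(mean(y[lo:s]^2)),
                 tolerance = 1e-9)
  }
  expect_true(all(fm$burn_in == (fm$time < 1)))
  expect_true(all(is.finite(fm$values)))
})

test_that("unit-variance white noise through an identity filter logs near zero", {
  m <- structure(list(pair = c("A", "B"), band = c(0.5, 63), filters = matrix(1),
                      eigenvalues = 1, selected = 1L, shrinkage = c(0, 0),
                      channels = "ch1"), class = "csp_model")
  ex <- structure(list(classes = c("A", "B"), bands = list(c(0.5, 63)),
                       models = list(m), scales = list(NULL), channels = "ch1",
                       srate = 128, filter_order = 4, window = 1,
                       log_floor = 1e-12, fit_window = c(0, 1)),
                  class = "feature_extractor")
  set.seed(9)
  rec <- eeg_recording(matrix(rnorm(128 * 20), 1), 128, "ch1")
  fm <- extract_features(ex, rec)
  expect_lt(abs(mean(fm$values[!fm$burn_in, 1])), 0.1)
})

test_that("channel mismatches are reported with the differing labels", {
  ts <- quick_trials(tpc = 5, seed = 27)
  ex <- build_extractor(ts, bands = list(c(8, 16)), fit_window = c(1, 3),
                        shrinkage = 0.2)
  rec <- generate_resting(quick_config(seed = 28, channels = c("C3", "Cz"),
                                       classes = c("HAND", "REST")), 2)
  expect_error(extract_features(ex, rec), "missing")
})

test_that("class means separate in feature space for deep ERD", {
  ts <- quick_trials(tpc = 8, seed = 29)
  ex <- build_extractor(ts, bands = list(c(8, 16), c(16, 30)),
                        fit_window = c(1, 3))
  tf <- extract_features(ex, ts)
  obs <- features_at(tf, 2.5)
  classes <- sort(unique(obs$y))
  sep <- FALSE
  for (j in seq_len(ncol(obs$X))) {
    mu <- tapply(obs$X[, j], obs$y, mean)
    s <- sqrt(mean(tapply(obs$X[, j], obs$y, var)))
    if (max(mu) - min(mu) > 2 * s) sep <- TRUE
  }
  expect_true(sep)
})
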