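#' Fit shrinkage-regularized Common Spatial Patterns for one class pair
#'
#' Class-wise average covariance matrices (per-trial covariances normalized by
#' trace) are shrunk toward a scaled identity,
#' `S_hat = (1 - gamma) S + gamma (tr(S)/C) I`, and the spatial filters solve
#' the generalized eigenproblem on `(S_hat_A, S_hat_A + S_hat_B)`.
#' Eigenvalues are class-A variance ratios in `[0, 1]`, sorted descending; the
#' retained projections are the two largest- and two smallest-eigenvalue
#' filters, which carry the most discriminative band-power information.
#'
#' @param ts a [trial_set()] (already band-filtered).
#' @param pair character vector of two class labels `(A, B)`.
#' @param fit_window `(start, stop)` seconds of the trial used for covariance
#'   estimation (default 1-3 s after the cue).
#' @param shrinkage numeric intensity in `[0, 1]`, or `"auto"` for the
#'   analytic Ledoit-Wolf-style estimate from the trial covariances.
#' @param band optional `(low, high)` Hz annotation stored in the model.
#' @param trace_norm normalize each trial covariance by its trace before
#'   averaging (standard CSP practice; default TRUE).  With it disabled and
#'   `shrinkage = 0` the eigenvalues are exactly invariant to invertible
#'   channel mixings.
#' @return An object of class `csp_model` with fields `filters` (channels x
#'   channels, one filter per column), `eigenvalues`, `selected`, `shrinkage`
#'   (per class), `pair`, `band`, `channels`.
#' @export
fit_csp <- function(ts, pair, fit_window = c(1, 3), shrinkage = "auto",
                    band = NULL, trace_norm = TRUE) {
  stopifnot(inherits(ts, "trial_set"), length(pair) == 2)
  ts <- kept_trials(ts)
  cols <- which(ts$time >= fit_window[1] & ts$time < fit_window[2])
  if (length(cols) < dim(ts$data)[2])
    stop("fit window too short for covariance estimation")
  covs <- function(klass) {
    idx <- which(ts$labels == klass)
    if (length(idx) < 4)
      stop("class ", klass, " has fewer than 4 trials")
    lapply(idx, function(i) {
      X <- matrix(ts$data[i, , cols], nrow = dim(ts$data)[2])
      X <- X - rowMeans(X)
      C <- tcrossprod(X) / ncol(X)
      if (trace_norm) C / sum(diag(C)) else C
    })
  }
  ca <- covs(pair[1])
  cb <- covs(pair[2])
  shrink <- function(cl) {
    S <- Reduce(`+`, cl) / length(cl)
    g <- if (identical(shrinkage, "auto")) lw_gamma(cl, S) else shrinkage
    p <- nrow(S)
    list(S = (1 - g) * S + g * (sum(diag(S)) / p) * diag(p), gamma = g)
  }
  sa <- shrink(ca)
  sb <- shrink(cb)
  Csum <- sa$S + sb$S
  ec <- eigen(Csum, symmetric = TRUE)
  tol <- max(ec$values) * 1e-10
  if (any(ec$values < tol))
    stop("combined class covariance is singular; use shrinkage > 0")
  W <- ec$vectors %*% diag(1 / sqrt(ec$values), nrow(Csum)) %*% t(ec$vectors)
  es <- eigen(W %*% sa$S %*% W, symmetric = TRUE)
  filters <- W %*% es$vectors            # columns: descending class-A ratio
  # deterministic sign: largest-magnitude coefficient positive
  for (j in seq_len(ncol(filters))) {
    k <- which.max(abs(filters[, j]))
    if (filters[k, j] < 0) filters[, j] <- -filters[, j]
  }
  p <- ncol(filters)
  structure(
    list(pair = pair, band = band, filters = filters,
         eigenvalues = es$values, selected = unique(c(1, 2, p - 1, p)),
         shrinkage = c(sa$gamma, sb$gamma), channels = ts$channels),
    class = "csp_model"
  )
}

# analytic shrinkage intensity toward the scaled-identity target, estimated
# from the dispersion of per-trial covariance matrices around their mean
lw_gamma <- function(cov_list, S = NULL) {
  n <- length(cov_list)
  if (n < 2) return(0)
  if (is.null(S)) S <- Reduce(`+`, cov_list) / n
  p <- nrow(S)
  target <- (sum(diag(S)) / p) * diag(p)
  var_mean <- Reduce(`+`, lapply(cov_list, function(C) (C - S)^2)) /
    (n * (n - 1))
  denom <- sum((S - target)^2)
  if (denom <= 0) return(0)
  min(1, max(0, sum(var_mean) / denom))
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %s vs %s%s: %d filters, selected [%s], gamma = %.3f/%.3f\n",
              x$pair[1], x$pair[2],
              if (is.null(x$band)) "" else
                sprintf(" (%g-%g Hz)", x$band[1], x$band[2]),
              ncol(x$filters), paste(x$selected, collapse = ","),
              x$shrinkage[1], x$shrinkage[2]))
  invisible(x)
}

# causal band filtering of every trial in a set
band_filter_trials <- function(ts, band, order = 4) {
  bf <- signal::butter(order, band / (ts$srate / 2), type = "pass")
  out <- ts
  for (i in seq_len(dim(ts$data)[1]))
    for (ch in seq_len(dim(ts$data)[2]))
      out$data[i, ch, ] <- as.numeric(signal::filter(bf, ts$data[i, ch, ]))
  out
}

#' Build a one-vs-one CSP band-power feature extractor
#'
#' For every frequency band the trials are causally band-filtered, optionally
#' normalized by the band-filtered resting variance of each channel, and one
#' [fit_csp()] model is fitted per unordered class pair.  With `k` classes,
#' `b` bands and 4 retained filters per model the feature dimension is
#' `choose(k, 2) * 4 * b` - e.g. 48 for 4 classes and 2 bands, 24 for
#' 4 classes and 1 band, 12 for 3 classes and 1 band.
#'
#' @param ts a [trial_set()] of broadband (unfiltered) trials.
#' @param classes classes to model (default: all labels present).
#' @param bands list of `(low, high)` Hz pairs.
#' @param fit_window seconds of each trial used for CSP covariance fitting.
#' @param shrinkage per-model CSP shrinkage (`"auto"` or numeric).
#' @param resting optional resting [eeg_recording()]; when given, channels are
#'   divided by their band-filtered resting standard deviation before CSP
#'   (and the same scaling is applied at extraction time).
#' @param filter_order causal Butterworth order for the band filters.
#' @param window band-power moving-average window in seconds (default 1).
#' @param log_floor lower clamp applied before the log (default 1e-12).
#' @return An object of class `feature_extractor`.
#' @export
build_extractor <- function(ts, classes = NULL, bands = list(c(8, 16), c(16, 30)),
                            fit_window = c(1, 3), shrinkage = "auto",
                            resting = NULL, filter_order = 4, window = 1,
                            log_floor = 1e-12) {
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(classes)) classes <- sort(unique(ts$labels[ts$kept]))
  if (length(classes) < 2) stop("at least 2 classes required")
  if (!is.list(bands)) bands <- list(bands)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- list()
  scales <- list()
  for (b in seq_along(bands)) {
    tsf <- band_filter_trials(ts, bands[[b]], filter_order)
    sc <- NULL
    if (!is.null(resting)) {
      rf <- butter_filter(resting, filter_spec("bandpass", bands[[b]],
                                               filter_order, "causal"))
      sc <- apply(rf$data, 1, stats::sd)
      if (any(sc == 0))
        stop("zero band-filtered resting variance on channel(s): ",
             paste(resting$channels[sc == 0], collapse = ", "))
      tsf$data <- sweep(tsf$data, 2, sc, "/")
    }
    scales[b] <- list(sc)     # keep NULL slots (no normalization)
    for (pr in pairs) {
      m <- fit_csp(tsf, pr, fit_window, shrinkage, band = bands[[b]])
      models[[length(models) + 1L]] <- m
    }
  }
  structure(
    list(classes = classes, bands = bands, models = models,
         scales = scales, channels = ts$channels, srate = ts$srate,
         filter_order = filter_order, window = window, log_floor = log_floor,
         fit_window = fit_window),
    class = "feature_extractor"
  )
}

#' Feature dimension of an extractor
#' @param extractor a `feature_extractor`.
#' @return Integer: number of log band-power features it emits.
#' @export
feature_dim <- function(extractor) {
  sum(vapply(extractor$models, function(m) length(m$selected), integer(1)))
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor> %d classes x %d bands -> %d models, %d features\n",
              length(x$classes), length(x$bands), length(x$models),
              feature_dim(x)))
  invisible(x)
}

# causal trailing moving average with growing window during burn-in
trailing_mean <- function(x, win) {
  cs <- cumsum(x)
  n <- length(x)
  out <- numeric(n)
  i <- seq_len(n)
  lead <- i <= win
  out[lead] <- cs[lead] / i[lead]
  if (win < n)
    out[!lead] <- (cs[i[!lead]] - cs[i[!lead] - win]) / win
  out
}

# features for one channels x samples matrix -> samples x features
extract_matrix <- function(extractor, X) {
  fs <- extractor$srate
  win <- max(1L, round(extractor$window * fs))
  n <- ncol(X)
  feats <- vector("list", length(extractor$models))
  names_out <- character(0)
  b_of_model <- rep(seq_along(extractor$bands),
                    each = length(extractor$models) / length(extractor$bands))
  Xf_by_band <- lapply(seq_along(extractor$bands), function(b) {
    bf <- signal::butter(extractor$filter_order,
                         extractor$bands[[b]] / (fs / 2), type = "pass")
    Xf <- X
    for (ch in seq_len(nrow(X)))
      Xf[ch, ] <- as.numeric(signal::filter(bf, X[ch, ]))
    if (!is.null(extractor$scales[[b]])) Xf <- Xf / extractor$scales[[b]]
    Xf
  })
  for (mi in seq_along(extractor$models)) {
    m <- extractor$models[[mi]]
    Xf <- Xf_by_band[[b_of_model[mi]]]
    Wsel <- m$filters[, m$selected, drop = FALSE]
    Y <- crossprod(Wsel, Xf)              # selected x samples
    F <- matrix(0, n, ncol(Wsel))
    for (j in seq_len(ncol(Wsel)))
      F[, j] <- log(pmax(trailing_mean(Y[j, ]^2, win), extractor$log_floor))
    feats[[mi]] <- F
    names_out <- c(names_out,
                   sprintf("%s.%s_b%d_f%d", m$pair[1], m$pair[2],
                           b_of_model[mi], m$selected))
  }
  out <- do.call(cbind, feats)
  colnames(out) <- names_out
  out
}

#' Extract log band-power features
#'
#' Per retained CSP filter: project, square, causal moving average over the
#' trailing window (step one sample; during the first window the average
#' grows with the data seen so far and is flagged as burn-in), then natural
#' log with a small floor.
#'
#' @param extractor a `feature_extractor` from [build_extractor()].
#' @param x an [eeg_recording()] or [trial_set()] over the training montage.
#' @return For a recording: a `feature_matrix` (list with `values`
#'   samples x features, `time`, `burn_in`).  For a trial set: a
#'   `trial_features` object (`values` trials x features x samples, `time`,
#'   `labels`).
#' @export
extract_features <- function(extractor, x) {
  stopifnot(inherits(extractor, "feature_extractor"))
  chans <- if (inherits(x, "eeg_recording") || inherits(x, "trial_set"))
    x$channels else stop("`x` must be an eeg_recording or trial_set")
  if (!identical(chans, extractor$channels)) {
    miss <- setdiff(extractor$channels, chans)
    extra <- setdiff(chans, extractor$channels)
    stop("channel set differs from training montage",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  if (inherits(x, "eeg_recording")) {
    vals <- extract_matrix(extractor, x$data)
    tt <- (seq_len(ncol(x$data)) - 1) / x$srate
    return(structure(list(values = vals, time = tt,
                          burn_in = tt < extractor$window),
                     class = "feature_matrix"))
  }
  nt <- dim(x$data)[1]
  first <- extract_matrix(extractor, matrix(x$data[1, , ], nrow = dim(x$data)[2]))
  vals <- array(NA_real_, c(nt, ncol(first), dim(x$data)[3]),
                dimnames = list(NULL, colnames(first), NULL))
  vals[1, , ] <- t(first)
  if (nt > 1) {
    for (i in 2:nt)
      vals[i, , ] <- t(extract_matrix(extractor,
                                      matrix(x$data[i, , ], nrow = dim(x$data)[2])))
  }
  structure(list(values = vals, time = x$time, labels = x$labels,
                 kept = x$kept),
            class = "trial_features")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features (%.1f s, %.0f%% burn-in)\n",
              nrow(x$values), ncol(x$values), max(x$time),
              100 * mean(x$burn_in)))
  invisible(x)
}

#' @export
print.trial_features <- function(x, ...) {
  cat(sprintf("<trial_features> %d trials x %d features x %d samples\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}

#' Feature observations at fixed times within each trial
#'
#' Pools the per-trial feature vectors at the requested latencies into a flat
#' observation matrix (one row per trial x time point), the usual way
#' classifier training samples are assembled from calibration trials.
#'
#' @param tf a `trial_features` object.
#' @param times latencies in seconds (relative to the cue).
#' @return List with `X` (observations x features), `y` (labels), `trial`
#'   (source trial index), `t` (source latency).
#' @export
features_at <- function(tf, times) {
  stopifnot(inherits(tf, "trial_features"))
  cols <- vapply(times, function(t0) which.min(abs(tf$time - t0)), integer(1))
  keep <- which(tf$kept)
  X <- do.call(rbind, lapply(cols, function(cc)
    matrix(tf$values[keep, , cc, drop = FALSE],
           nrow = length(keep), ncol = dim(tf$values)[2],
           dimnames = list(NULL, dimnames(tf$values)[[2]]))))
  y <- rep(tf$labels[keep], times = length(cols))
  list(X = X, y = y,
       trial = rep(keep, times = length(cols)),
       t = rep(tf$time[cols], each = length(keep)))
}
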