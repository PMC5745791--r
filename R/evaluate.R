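#' Decoding pipeline specification
#'
#' Bundles every tunable of the offline/online decoding chain: analysis
#' bands, causal band-filter order, the CSP covariance window, shrinkage
#' settings, the classifier training latencies, and the time step at which
#' accuracy-over-time curves are evaluated.
#'
#' @param bands list of `(low, high)` Hz pairs (default 8-16 and 16-30 Hz).
#' @param filter_order causal Butterworth order for band filtering.
#' @param fit_window `(start, stop)` seconds after the cue for CSP fitting.
#' @param csp_shrinkage CSP shrinkage intensity or `"auto"`.
#' @param lda_shrinkage sLDA shrinkage intensity or `"auto"`.
#' @param train_times classifier training latencies in seconds after the cue.
#' @param window band-power moving-average window, seconds.
#' @param log_floor clamp under the log band power.
#' @param eval_step evaluate accuracy every `eval_step` samples.
#' @param normalize divide channels by band-filtered resting variance
#'   (requires a resting recording wherever the spec is used).
#' @param fit_on_full never set this: fitting feature models on the full data
#'   set before cross-validation leaks test information and is refused.
#' @return An object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(bands = list(c(8, 16), c(16, 30)), filter_order = 4,
                          fit_window = c(1, 3), csp_shrinkage = "auto",
                          lda_shrinkage = "auto", train_times = 2.5,
                          window = 1, log_floor = 1e-12, eval_step = 16,
                          normalize = FALSE, fit_on_full = FALSE) {
  if (!is.list(bands)) bands <- list(bands)
  structure(list(bands = bands, filter_order = filter_order,
                 fit_window = fit_window, csp_shrinkage = csp_shrinkage,
                 lda_shrinkage = lda_shrinkage, train_times = train_times,
                 window = window, log_floor = log_floor,
                 eval_step = eval_step, normalize = normalize,
                 fit_on_full = fit_on_full),
            class = "pipeline_spec")
}

# fit extractor + classifier on a trial set (training folds only)
fit_pipeline <- function(train_ts, classes, spec, resting = NULL) {
  extractor <- build_extractor(
    train_ts, classes = classes, bands = spec$bands,
    fit_window = spec$fit_window, shrinkage = spec$csp_shrinkage,
    resting = if (isTRUE(spec$normalize)) resting else NULL,
    filter_order = spec$filter_order, window = spec$window,
    log_floor = spec$log_floor)
  tf <- extract_features(extractor, train_ts)
  obs <- features_at(tf, spec$train_times)
  model <- fit_slda(obs$X, obs$y, spec$lda_shrinkage)
  list(extractor = extractor, model = model)
}

# stratified fold assignment: integer fold id per trial
stratified_folds <- function(labels, folds) {
  out <- integer(length(labels))
  for (k in unique(labels)) {
    idx <- which(labels == k)
    out[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  out
}

#' Repeated stratified cross-validation of the full decoding chain
#'
#' CSP fitting and sLDA training happen strictly inside training folds;
#' per-time-point accuracy, trial-majority accuracy over `eval_window` and a
#' row-normalized confusion matrix are computed on the held-out folds.  With
#' `scheme = c(10, 5)` this yields 50 fold-specific results whose mean and
#' standard deviation form the accuracy curve.
#'
#' @param ts a [trial_set()]; only kept trials are used.
#' @param classes classes to include (default: all present).
#' @param spec a [pipeline_spec()]; must not request fitting on full data.
#' @param scheme `(repeats, folds)`.
#' @param eval_window `(start, stop)` seconds for trial-majority evaluation.
#' @param seed fold assignment seed; repeat `r` uses `seed + r - 1`.
#' @param resting optional resting recording for `spec$normalize`.
#' @param alpha significance level of the chance-level bound.
#' @return An object of class `cv_result`: `curve` (data frame `time`,
#'   `accuracy`, `sd`), `peak`, `trial_accuracy`, `confusion`, `chance`,
#'   `scheme`, `fold_curves`.
#' @export
crossvalidate <- function(ts, classes = NULL, spec = pipeline_spec(),
                          scheme = c(10, 5), eval_window = c(1, 4), seed = 1,
                          resting = NULL, alpha = 0.05) {
  stopifnot(inherits(ts, "trial_set"), inherits(spec, "pipeline_spec"))
  if (isTRUE(spec$fit_on_full))
    stop("refusing to fit feature models on the full data set: ",
         "that leaks test-fold information into training")
  ts <- kept_trials(ts)
  if (is.null(classes)) classes <- sort(unique(ts$labels))
  ts <- subset_trials(ts, ts$labels %in% classes)
  counts <- table(ts$labels)
  repeats <- scheme[1]; folds <- scheme[2]
  if (any(counts < folds))
    stop("every class needs at least `folds` trials")
  eval_idx <- seq(1L, dim(ts$data)[3], by = spec$eval_step)
  eval_t <- ts$time[eval_idx]
  fold_curves <- matrix(NA_real_, repeats * folds, length(eval_idx))
  maj_correct <- logical(0)
  maj_pred <- character(0)
  maj_truth <- character(0)
  win_cols <- which(eval_t >= eval_window[1] & eval_t <= eval_window[2])
  fi <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- with_seed(seed + r - 1L, stratified_folds(ts$labels, folds))
    for (f in seq_len(folds)) {
      fi <- fi + 1L
      tr <- subset_trials(ts, fold_id != f)
      te <- subset_trials(ts, fold_id == f)
      fit <- fit_pipeline(tr, classes, spec, resting)
      tf <- extract_features(fit$extractor, te)
      nt <- dim(tf$values)[1]
      pred <- matrix(NA_character_, nt, length(eval_idx))
      for (ti in seq_along(eval_idx)) {
        X <- matrix(tf$values[, , eval_idx[ti]], nrow = nt)
        pred[, ti] <- predict(fit$model, X)
      }
      fold_curves[fi, ] <- colMeans(pred == te$labels)
      pw <- pred[, win_cols, drop = FALSE]
      hits <- rowSums(pw == te$labels)
      maj_correct <- c(maj_correct, hits > ncol(pw) / 2)
      maj_pred <- c(maj_pred, apply(pw, 1, modal_label))
      maj_truth <- c(maj_truth, te$labels)
    }
  }
  curve <- data.frame(time = eval_t, accuracy = colMeans(fold_curves),
                      sd = apply(fold_curves, 2, stats::sd))
  pk <- which.max(curve$accuracy)
  structure(
    list(curve = curve,
         peak = c(time = curve$time[pk], accuracy = curve$accuracy[pk],
                  sd = curve$sd[pk]),
         trial_accuracy = mean(maj_correct),
         confusion = confusion_rownorm(maj_pred, maj_truth, classes),
         chance = chance_level(dim(ts$data)[1], length(classes), alpha),
         scheme = c(repeats = repeats, folds = folds),
         fold_curves = fold_curves, eval_window = eval_window,
         classes = classes, n_trials = dim(ts$data)[1]),
    class = "cv_result"
  )
}

modal_label <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)]
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %dx%d CV, %d trials, %d classes\n",
              x$scheme[1], x$scheme[2], x$n_trials, length(x$classes)))
  cat(sprintf("  peak accuracy %.1f%% (SD %.1f) at %.2f s; trial-majority %.1f%%; chance bound %.1f%%\n",
              100 * x$peak["accuracy"], 100 * x$peak["sd"], x$peak["time"],
              100 * x$trial_accuracy, 100 * x$chance$upper))
  invisible(x)
}

#' Plot a cross-validation accuracy curve
#' @param x a `cv_result`.
#' @param ... unused.
#' @return Invisibly `x`.
#' @export
plot.cv_result <- function(x, ...) {
  graphics::plot(x$curve$time, 100 * x$curve$accuracy, type = "l", lwd = 2,
                 ylim = c(0, 100), xlab = "time relative to cue (s)",
                 ylab = "accuracy (%)", main = "Cross-validated accuracy")
  graphics::polygon(c(x$curve$time, rev(x$curve$time)),
                    100 * c(x$curve$accuracy - x$curve$sd,
                            rev(x$curve$accuracy + x$curve$sd)),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::abline(h = 100 * x$chance$upper, col = "red", lty = 2)
  graphics::abline(h = 100 / length(x$classes), col = "grey", lty = 3)
  invisible(x)
}

#' Trial-majority accuracy
#'
#' A trial counts as correct iff strictly more than half of its in-window
#' sample predictions equal the true class; ties count as incorrect.
#'
#' @param predictions character matrix, trials x evaluated time points.
#' @param truth true class per trial.
#' @return Fraction of correct trials.
#' @export
trial_majority_accuracy <- function(predictions, truth) {
  predictions <- as.matrix(predictions)
  if (ncol(predictions) == 0) stop("evaluation window is empty")
  stopifnot(nrow(predictions) == length(truth))
  hits <- rowSums(predictions == truth)
  mean(hits > ncol(predictions) / 2)
}

#' Row-normalized confusion matrix in percent
#'
#' Rows are true classes, columns predicted classes; each row sums to 100
#' (rows without trials are zero, with a warning).
#'
#' @param predictions predicted class per trial.
#' @param truth true class per trial.
#' @param classes class order of the matrix (default: sorted union).
#' @return Numeric matrix, percent.
#' @export
confusion_rownorm <- function(predictions, truth, classes = NULL) {
  stopifnot(length(predictions) == length(truth))
  if (is.null(classes)) classes <- sort(unique(c(predictions, truth)))
  m <- table(factor(truth, classes), factor(predictions, classes))
  tot <- rowSums(m)
  if (any(tot == 0))
    warning("no trials for class(es): ",
            paste(classes[tot == 0], collapse = ", "))
  out <- 100 * sweep(unclass(m), 1, pmax(tot, 1), "/")
  dimnames(out) <- list(true = classes, predicted = classes)
  out
}

#' Adjusted-Wald (Agresti-Coull) chance-level bound
#'
#' Upper bound of the adjusted-Wald confidence interval for the accuracy of a
#' random classifier (success probability `1/n_classes`) over `n_trials`
#' trials; accuracies above this bound are better than chance at level
#' `alpha`.
#'
#' @param n_trials number of evaluated trials (>= 1).
#' @param n_classes number of classes.
#' @param alpha significance level in (0, 1).
#' @return An object of class `chance_level` with field `upper` (accuracy
#'   scale, 0-1).
#' @export
chance_level <- function(n_trials, n_classes, alpha = 0.05) {
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  p0 <- 1 / n_classes
  z <- stats::qnorm(1 - alpha / 2)
  n_adj <- n_trials + z^2
  p_adj <- (n_trials * p0 + z^2 / 2) / n_adj
  upper <- p_adj + z * sqrt(p_adj * (1 - p_adj) / n_adj)
  structure(list(n_trials = n_trials, n_classes = n_classes, alpha = alpha,
                 upper = min(upper, 1)),
            class = "chance_level")
}

#' @export
print.chance_level <- function(x, ...) {
  cat(sprintf("<chance_level> %.1f%% (n = %d, %d classes, alpha = %g)\n",
              100 * x$upper, x$n_trials, x$n_classes, x$alpha))
  invisible(x)
}

#' Rank all k-task combinations of a task pool by discriminability
#'
#' Runs [crossvalidate()] for every `k`-subset of `task_pool` (70 subsets for
#' a pool of 8 and `k = 4`) and tabulates peak accuracy with its SD and the
#' median accuracy over `median_window`, sorted by peak accuracy.
#'
#' @param ts a [trial_set()] containing trials of every pool task.
#' @param task_pool character vector of candidate tasks.
#' @param k combination size (default 4).
#' @param spec a [pipeline_spec()].
#' @param scheme CV `(repeats, folds)`.
#' @param median_window seconds over which the median accuracy is taken.
#' @param seed RNG seed passed to every [crossvalidate()] call.
#' @param resting optional resting recording for normalization.
#' @return data frame: `combination`, `peak_pct`, `peak_sd_pct`,
#'   `median_pct`, `median_sd_pct`, `peak_time`, sorted by `peak_pct`.
#' @export
rank_combinations <- function(ts, task_pool, k = 4, spec = pipeline_spec(),
                              scheme = c(10, 5), median_window = c(1, 4),
                              seed = 1, resting = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  missing_cls <- setdiff(task_pool, unique(ts$labels))
  if (length(missing_cls))
    stop("pool classes absent from trial set: ",
         paste(missing_cls, collapse = ", "))
  combos <- utils::combn(task_pool, k, simplify = FALSE)
  rows <- lapply(combos, function(cls) {
    cv <- crossvalidate(ts, classes = cls, spec = spec, scheme = scheme,
                        eval_window = median_window, seed = seed,
                        resting = resting)
    wc <- cv$curve$time >= median_window[1] & cv$curve$time <= median_window[2]
    fold_medians <- apply(cv$fold_curves[, wc, drop = FALSE], 1, stats::median)
    data.frame(combination = paste(cls, collapse = "-"),
               peak_pct = 100 * cv$peak[["accuracy"]],
               peak_sd_pct = 100 * cv$peak[["sd"]],
               median_pct = 100 * stats::median(fold_medians),
               median_sd_pct = 100 * stats::sd(fold_medians),
               peak_time = cv$peak[["time"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak_pct), ]
  rownames(out) <- NULL
  out
}
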