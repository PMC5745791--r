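#' Fit a shrinkage linear discriminant analysis classifier
#'
#' Linear discriminant analysis with the pooled within-class covariance shrunk
#' toward a scaled identity, `S_hat = (1 - gamma) S + gamma (tr(S)/p) I`,
#' stabilizing the estimate when the feature dimension approaches the number
#' of observations.  Class priors are equal (balanced calibration designs);
#' posterior probabilities are the softmax of the linear discriminant scores.
#'
#' @param X observations x features numeric matrix.
#' @param labels class label per observation (>= 2 classes, each >= 2 rows).
#' @param shrinkage numeric intensity in `[0, 1]` or `"auto"` for the
#'   analytic Ledoit-Wolf estimate on the pooled centered observations.
#' @return An object of class `slda_model` with fields `classes`, `means`,
#'   `cov` (shrunk pooled covariance), `weights`, `bias`, `shrinkage`.
#' @export
fit_slda <- function(X, labels, shrinkage = "auto") {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("at least two classes required")
  counts <- table(labels)
  if (any(counts < 2)) stop("every class needs at least 2 observations")
  p <- ncol(X)
  means <- t(vapply(classes, function(k) colMeans(X[labels == k, , drop = FALSE]),
                    numeric(p)))
  centered <- X - means[match(labels, classes), , drop = FALSE]
  n <- nrow(X)
  S <- crossprod(centered) / (n - length(classes))
  gamma <- if (identical(shrinkage, "auto")) lw_gamma_obs(centered) else shrinkage
  Sh <- (1 - gamma) * S + gamma * (sum(diag(S)) / p) * diag(p)
  Sinv <- tryCatch(solve(Sh), error = function(e)
    stop("shrunk covariance is singular; increase shrinkage"))
  W <- Sinv %*% t(means)                      # features x classes
  b <- -0.5 * colSums(t(means) * W)           # per-class bias, equal priors
  structure(
    list(classes = classes, means = means, cov = Sh, weights = W, bias = b,
         shrinkage = gamma, features = colnames(X)),
    class = "slda_model"
  )
}

# Ledoit-Wolf style analytic shrinkage toward nu*I for centered observations
lw_gamma_obs <- function(Z) {
  n <- nrow(Z)
  p <- ncol(Z)
  if (n < 2) return(0)
  S <- crossprod(Z) / n
  nu <- sum(diag(S)) / p
  # dispersion of per-observation outer products around S
  num <- 0
  for (i in seq_len(n)) {
    zi <- Z[i, ]
    num <- num + sum((tcrossprod(zi) - S)^2)
  }
  num <- num / n^2
  den <- sum((S - nu * diag(p))^2)
  if (den <= 0) return(0)
  min(1, max(0, num / den))
}

#' @export
print.slda_model <- function(x, ...) {
  cat(sprintf("<slda_model> %d classes (%s), %d features, gamma = %.3f\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              nrow(x$weights), x$shrinkage))
  invisible(x)
}

#' Predict classes or posterior probabilities from an sLDA model
#'
#' @param object an `slda_model`.
#' @param newdata observations x features matrix (same feature order as
#'   training).
#' @param type `"class"` for hard labels, `"prob"` for posterior
#'   probabilities, `"score"` for raw discriminant scores.
#' @param ... unused.
#' @return Character vector, or a matrix observations x classes.
#' @export
predict.slda_model <- function(object, newdata, type = c("class", "prob", "score"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  scores <- sweep(newdata %*% object$weights, 2, object$bias, "+")
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  if (type == "class") return(object$classes[max.col(scores, ties.method = "first")])
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  e / rowSums(e)
}
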