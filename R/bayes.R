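# Binary Bayesian classifier over Gaussian-smoothed class-conditional
# descriptor histograms. For each descriptor, training values are rescaled
# to [0, 1] over the training range and accumulated into fixed equal-width
# bins separately for actives and inactives; each histogram is convolved
# with a Gaussian kernel (smoothing width sigma, in normalized-range units)
# to avoid sensitivity to bin boundaries, floored, and renormalized to a
# probability mass function. Prediction combines the per-descriptor
# likelihoods naively (independence) with the class priors; descriptors
# whose two class histograms coincide contribute nothing and effectively
# drop out.

#' Fit the binary Bayesian QSAR classifier
#'
#' @param X Numeric training matrix (compounds x descriptors).
#' @param labels Logical vector, `TRUE` = active. Both classes must be
#'   present.
#' @param bins Number of histogram bins over the normalized range
#'   (default 25).
#' @param sigma Gaussian smoothing width in normalized-range units
#'   (default 0.25).
#' @param floor Probability floor added to every bin before renormalization
#'   (default 1e-9).
#' @return A `bq_bayes` model.
#' @export
fit_binary_bayes <- function(X, labels, bins = 25L, sigma = 0.25, floor = 1e-9) {
  X <- as.matrix(X); labels <- as.logical(labels)
  stopifnot(nrow(X) == length(labels))
  if (anyNA(labels) || anyNA(X)) stop("missing values in training data", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("single-class training data: both actives and inactives required",
         call. = FALSE)
  bins <- as.integer(bins)
  p <- ncol(X)
  rmin <- apply(X, 2, min); rmax <- apply(X, 2, max)
  centers <- (seq_len(bins) - 0.5) / bins
  K <- exp(-outer(centers, centers, "-")^2 / (2 * sigma^2))
  lik <- function(x, rows) {
    h <- numeric(bins)
    if (rmax[x] > rmin[x]) {
      xn <- (X[rows, x] - rmin[x]) / (rmax[x] - rmin[x])
      idx <- pmin(bins, pmax(1L, floor(xn * bins) + 1L))
      h <- tabulate(idx, nbins = bins)
    } else h[] <- 1  # degenerate column: uniform, drops out
    sm <- as.numeric(K %*% h) + floor
    sm / sum(sm)
  }
  lik_a <- vapply(seq_len(p), lik, numeric(bins), rows = which(labels))
  lik_i <- vapply(seq_len(p), lik, numeric(bins), rows = which(!labels))
  structure(list(lik_active = lik_a, lik_inactive = lik_i,
                 rmin = rmin, rmax = rmax, bins = bins, sigma = sigma,
                 prior_active = mean(labels), threshold = 0.5,
                 names = colnames(X)),
            class = "bq_bayes")
}

#' Predicted probability of activity
#'
#' Naive-Bayes combination of the smoothed per-descriptor likelihoods with
#' the class priors, normalized over the two classes. Descriptor values
#' outside the training range are clamped to the boundary bin.
#'
#' @param model A `bq_bayes` model.
#' @param X Numeric matrix (or vector for one compound) with the model's
#'   descriptors.
#' @return Numeric vector of P(active), one per row.
#' @export
predict_bayes <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  bins <- model$bins
  p <- ncol(X)
  la0 <- log(model$prior_active); li0 <- log(1 - model$prior_active)
  vapply(seq_len(nrow(X)), function(r) {
    la <- la0; li <- li0
    for (j in seq_len(p)) {
      rng <- model$rmax[j] - model$rmin[j]
      xn <- if (rng > 0) (X[r, j] - model$rmin[j]) / rng else 0.5
      xn <- min(max(xn, 0), 1)
      b <- min(bins, max(1L, floor(xn * bins) + 1L))
      la <- la + log(model$lik_active[b, j])
      li <- li + log(model$lik_inactive[b, j])
    }
    mx <- max(la, li)
    exp(la - mx) / (exp(la - mx) + exp(li - mx))
  }, 0)
}

#' @export
predict.bq_bayes <- function(object, newdata, ...) predict_bayes(object, newdata)

#' @export
print.bq_bayes <- function(x, ...) {
  cat(sprintf("<bq_bayes: %d descriptors, %d bins, sigma %.2f, prior(active) %.3f>\n",
              ncol(x$lik_active), x$bins, x$sigma, x$prior_active))
  invisible(x)
}
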