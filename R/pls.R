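# Partial least squares (PLS1, NIPALS) with a condition-number limit on the
# principal-component transform of the descriptor correlation matrix:
# eigendirections whose eigenvalue ratio to the largest exceeds the limit are
# discarded before latent-variable extraction, so collinear descriptor
# blocks cannot destabilize the fit.

#' Fit a PLS regression model
#'
#' Descriptors are autoscaled, projected onto the principal components of
#' the correlation matrix that pass the condition limit
#' (`lambda_max / lambda <= cond_limit`), and a PLS1 model is extracted by
#' NIPALS. Components are added until the residual activity variance is
#' exhausted (relative to the magnitude of `y`, so an essentially constant
#' response retains no components) or the component limit is reached.
#'
#' @param X Numeric training matrix (compounds x descriptors).
#' @param y Numeric response (log10 IC50 by pipeline convention).
#' @param ncomp Component limit; `Inf` (default) means no limit on the
#'   degree of fit.
#' @param cond_limit Maximum condition number of the principal-component
#'   transform (default 1e6).
#' @return A `bq_pls` model for use with `predict()`.
#' @export
fit_pls <- function(X, y, ncomp = Inf, cond_limit = 1e6) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 3L) stop("need at least 3 training rows", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response: nothing to regress", call. = FALSE)
  if (cond_limit <= 0) stop("condition limit must be positive", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- which(scl > 1e-12)
  if (!length(keep)) stop("all descriptor columns constant", call. = FALSE)
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  S <- stats::cor(Z)
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  ok <- lam > 0 & (lam[1] / pmax(lam, .Machine$double.xmin)) <= cond_limit
  V <- eg$vectors[, ok, drop = FALSE]
  T0 <- Z %*% V
  ybar <- mean(y)
  yres <- y - ybar
  ss_tot <- sum(y^2)           # uncentered: sets the "essentially constant" scale
  Xa <- T0
  m <- ncol(T0)
  amax <- min(m, nrow(X) - 1L, ncomp)
  W <- P <- matrix(0, m, 0); qv <- numeric(0)
  a <- 0L
  while (a < amax) {
    if (sum(yres^2) <= 1e-16 * ss_tot) break
    w <- crossprod(Xa, yres)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12 * sqrt(sum(Xa^2) + 1) * sqrt(sum(yres^2) + 1)) break
    w <- w / wn
    tt <- Xa %*% w
    tsq <- sum(tt^2)
    if (tsq < 1e-24) break
    p <- crossprod(Xa, tt) / tsq
    q <- sum(yres * tt) / tsq
    Xa <- Xa - tt %*% t(p)
    yres <- yres - q * tt
    W <- cbind(W, w); P <- cbind(P, p); qv <- c(qv, q)
    a <- a + 1L
  }
  beta_pc <- if (a > 0L) W %*% solve(crossprod(P, W), qv) else matrix(0, m, 1)
  beta_z <- V %*% beta_pc
  structure(list(center = ctr[keep], scale = scl[keep], cols = keep,
                 beta = drop(beta_z), intercept = ybar,
                 ncomp_used = a, n_pc = ncol(V), cond_limit = cond_limit),
            class = "bq_pls")
}

#' Predict from a PLS model
#' @param object A `bq_pls` model.
#' @param newdata Numeric matrix with the training descriptor columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.bq_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Z <- sweep(sweep(newdata[, object$cols, drop = FALSE], 2, object$center),
             2, object$scale, "/")
  drop(Z %*% object$beta) + object$intercept
}
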