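make_lib <- function(ic50, cell = "NCI-H446") {
  n <- length(ic50)
  mols <- lapply(seq_len(n), function(i) {
    m <- mol_ethane(); m$id <- sprintf("m%02d", i); m
  })
  act <- matrix(ic50, ncol = 1, dimnames = list(sprintf("m%02d", seq_len(n)), cell))
  join_library(mols, act)
}

test_that("binarization labels potency against the positive-control cutoff", {
  lib <- make_lib(c(5.0, 9.13, 20, NA))
  bl <- binarize(lib, "NCI-H446", 9.13)
  expect_identical(unname(bl$labels[1:3]), c(TRUE, TRUE, FALSE))  # boundary = active
  expect_true(is.na(bl$labels[4]))
  expect_identical(bl$excluded, "m04")
  expect_warning(binarize(make_lib(c(20, 30)), "NCI-H446", 9.13), "single-class")
  expect_error(binarize(lib, "NCI-H446", -1), "positive")
  expect_error(binarize(lib, "nope", 1), "unknown cell line")
})

test_that("lowering the cutoff never converts an inactive to active", {
  set.seed(31)
  ic <- 10^rnorm(40, 1, 0.5)
  lib <- make_lib(ic)
  cuts <- sort(10^runif(10, 0, 2))
  prev <- suppressWarnings(binarize(lib, "NCI-H446", cuts[1])$labels)
  for (ct in cuts[-1]) {
    cur <- suppressWarnings(binarize(lib, "NCI-H446", ct)$labels)
    expect_true(all(cur[prev]))  # once active at a lower cutoff, still active
    prev <- cur
  }
})

test_that("PLS reproduces noiseless linear data and truncates wisely", {
  set.seed(5)
  X <- matrix(rnorm(150), 30, 5)
  y <- 2 * X[, 1] - X[, 2]
  fit <- fit_pls(X, y)
  expect_lt(max(abs(predict(fit, X) - y)), 1e-9)
  # essentially constant response retains no latent components
  y2 <- 5 + rnorm(30, 0, 1e-9)
  fit2 <- fit_pls(X, y2)
  expect_lte(fit2$ncomp_used, 1L)
  expect_lt(max(abs(predict(fit2, X) - mean(y2))), 1e-6)
  # duplicated (collinear) columns engage the condition-number truncation
  Xc <- cbind(X, X[, 1])
  fitc <- fit_pls(Xc, y, cond_limit = 1e6)
  expect_lt(fitc$n_pc, ncol(Xc))
  expect_lt(max(abs(predict(fitc, Xc) - y)), 1e-6)
  expect_error(fit_pls(X, rep(1, 30)), "constant")
})

test_that("condition-limit truncation matches a direct eigen-analysis", {
  set.seed(6)
  X <- matrix(rnorm(120), 30, 4)
  X <- cbind(X, X[, 1] + 1e-5 * rnorm(30))
  lam <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  for (cl in c(1e2, 1e6, 1e10)) {
    expected <- sum(lam[1] / lam <= cl & lam > 0)
    expect_equal(fit_pls(X, rnorm(30), cond_limit = cl)$n_pc, expected)
  }
})

test_that("leave-one-out cross validation behaves at its limits", {
  set.seed(8)
  X <- matrix(rnorm(150), 30, 5)
  y <- X %*% c(1, -2, 0.5, 0, 1)
  cv <- loo_cv(function(a, b) fit_pls(a, b), X, as.numeric(y))
  expect_gt(cor(as.numeric(cv), as.numeric(y))^2, 0.999)
  # response independent of descriptors: no apparent predictivity
  ynoise <- rnorm(30)
  cvn <- loo_cv(function(a, b) fit_pls(a, b), X, ynoise)
  expect_lt(cor(as.numeric(cvn), ynoise)^2, 0.3)
  # perfectly separable two-class problem: LOO accuracy 1
  Xs <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2), matrix(rnorm(20, 5, 0.2), 10, 2))
  lab <- rep(c(TRUE, FALSE), each = 10)
  cvb <- loo_cv(function(a, b) fit_binary_bayes(a, b), Xs, lab,
                predict_fun = function(m, x) predict_bayes(m, x) > 0.5)
  expect_equal(mean(as.logical(cvb) == lab), 1)
})

test_that("SVR fits tight noiseless data and degrades gracefully", {
  set.seed(10)
  X <- matrix(rnorm(100), 20, 5)
  y <- as.numeric(X %*% c(2, -1, 0, 1, 0.5))
  fit <- fit_svr(X, y, svr_config(cost = 100, epsilon = 0.01))
  expect_gt(cor(predict(fit, X), y)^2, 0.99)
  expect_identical(predict(fit, X), predict(fit_svr(X, y, svr_config(cost = 100, epsilon = 0.01)), X))
  const <- fit_svr(X, rep(3, 20))
  expect_equal(predict(const, X), rep(3, 20))
})

test_that("SVM separates separable and kernel-separable patterns", {
  Xs <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2), matrix(rnorm(20, 4, 0.2), 10, 2))
  lab <- rep(c(TRUE, FALSE), each = 10)
  fit <- fit_svm(Xs, lab)
  expect_equal(mean(predict(fit, Xs) == lab), 1)
  # XOR needs the RBF kernel
  Xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  Xx <- Xx[rep(1:4, each = 3), ] + matrix(rnorm(24, 0, 0.02), 12, 2)
  labx <- rep(c(TRUE, TRUE, FALSE, FALSE), each = 3)
  fx <- fit_svm(Xx, labx, svm_config(cost = 100, gamma = 2))
  expect_equal(mean(predict(fx, Xx) == labx), 1)
  expect_error(fit_svm(Xs, rep(TRUE, 20)), "single-class")
})

test_that("the smoothed Bayes histograms are proper distributions", {
  set.seed(12)
  X <- matrix(runif(60), 20, 3)
  lab <- rep(c(TRUE, FALSE), 10)
  m <- fit_binary_bayes(X, lab)
  expect_true(all(abs(colSums(m$lik_active) - 1) < 1e-12))
  expect_true(all(abs(colSums(m$lik_inactive) - 1) < 1e-12))
  expect_true(all(m$lik_active > 0))
  expect_error(fit_binary_bayes(X, rep(TRUE, 20)), "single-class")
})

test_that("uninformative descriptors leave the posterior at the prior", {
  # both classes share the same descriptor values exactly
  base <- matrix(runif(15), 5, 3)
  X <- rbind(base, base)
  lab <- rep(c(TRUE, FALSE), each = 5)
  m <- fit_binary_bayes(X, lab)
  q <- matrix(runif(12), 4, 3)
  expect_equal(predict_bayes(m, q), rep(0.5, 4), tolerance = 1e-9)
  # unbalanced priors shine through unchanged
  X2 <- rbind(base, base, base)
  lab2 <- c(rep(TRUE, 5), rep(FALSE, 10))
  m2 <- fit_binary_bayes(X2, lab2)
  expect_equal(predict_bayes(m2, q), rep(1 / 3, 4), tolerance = 1e-9)
})

test_that("well-separated one-descriptor classes give confident posteriors", {
  X <- matrix(c(1.0, 1.1, 1.2, 2.9, 3.0, 3.2), ncol = 1)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  m <- fit_binary_bayes(X, lab)
  expect_gt(predict_bayes(m, matrix(1.05)), 0.9)
  expect_lt(predict_bayes(m, matrix(3.1)), 0.1)
})

test_that("the two-class posterior is normalized and matches the brute-force oracle", {
  set.seed(77)
  for (k in 1:30) {
    n <- sample(4:8, 1); p <- sample(1:3, 1)
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    X <- matrix(rnorm(n * p), n, p)
    xq <- rnorm(p) * 1.2
    m <- fit_binary_bayes(X, lab)
    pa <- predict_bayes(m, matrix(xq, 1))
    expect_equal(pa, naive_bayes_oracle(X, lab, xq), tolerance = 1e-9)
    # complement symmetry: swapping the class labels complements the posterior
    pi <- predict_bayes(fit_binary_bayes(X, !lab), matrix(xq, 1))
    expect_equal(pa + pi, 1, tolerance = 1e-12)
  }
})

test_that("evaluation reports carry the three accuracy modes with integer counts", {
  set.seed(15)
  X <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2), matrix(rnorm(40, 5, 0.3), 20, 2))
  lab <- rep(c(TRUE, FALSE), each = 20)
  split <- structure(list(train = seq(1, 40, 2), test = seq(2, 40, 2),
                          scheme = "diverse", frac = 0.5), class = "bq_split")
  rep_c <- evaluate_classification(X, lab, split, function(a, b) fit_binary_bayes(a, b))
  expect_equal(rep_c$At, 1); expect_equal(rep_c$Av, 1); expect_equal(rep_c$Ap, 1)
  expect_identical(rep_c$counts$Ap[["d"]], 20L)

  y <- as.numeric(X %*% c(1, 0.5)) + rnorm(40, 0, 0.1)
  rep_r <- evaluate_regression(X, y, split, function(a, b) fit_pls(a, b))
  fit <- fit_pls(X[split$train, ], y[split$train])
  expect_equal(rep_r$r2, cor(y[split$test], predict(fit, X[split$test, ]))^2,
               tolerance = 1e-12)
  expect_error(evaluate_regression(X, rep(NA_real_, 40), split,
                                   function(a, b) fit_pls(a, b)))
})
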