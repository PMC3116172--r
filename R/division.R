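# Training/testing division: greedy max-min diversity ranking, applied
# globally or within descriptor-based clusters.

#' Rank compounds by greedy max-min diversity
#'
#' The start entry is ranked first; each subsequent rank goes to the
#' unranked compound whose minimum Euclidean distance to all already-ranked
#' compounds is largest. Ties are broken toward the lowest original index so
#' the ranking is fully deterministic.
#'
#' @param X Numeric matrix (compounds x normalized descriptors).
#' @param start Index of the reference compound ranked first (default 1,
#'   the first entry in file order).
#' @return A `bq_ranking`: list with `order` (a permutation of row indices),
#'   `start`, and `metric`.
#' @export
rank_diverse <- function(X, start = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1L) stop("empty matrix", call. = FALSE)
  if (anyNA(X)) stop("NaN/NA in descriptor matrix", call. = FALSE)
  start <- as.integer(start)
  if (start < 1L || start > n) stop("invalid start index", call. = FALSE)
  ord <- integer(n)
  ord[1L] <- start
  if (n > 1L) {
    # running minimum distance from each unranked row to the ranked set
    mind <- sqrt(rowSums(sweep(X, 2, X[start, ])^2))
    mind[start] <- -Inf
    for (k in 2L:n) {
      nxt <- which.max(mind)  # which.max takes the first (lowest-index) tie
      ord[k] <- nxt
      d <- sqrt(rowSums(sweep(X, 2, X[nxt, ])^2))
      mind <- pmin(mind, d)
      mind[nxt] <- -Inf
    }
  }
  structure(list(order = ord, start = start, metric = "euclidean"),
            class = "bq_ranking")
}

# round-half-up of frac*n, capped so both partitions are non-empty
.train_size <- function(n, frac) {
  k <- floor(frac * n + 0.5)
  min(max(k, 1L), n - 1L)
}

#' Split a diversity ranking into training and testing sets
#'
#' The first `floor(frac * N + 0.5)` entries of the diversity order (capped
#' so the test set keeps at least one compound) form the training set; the
#' remainder is the test set.
#'
#' @param ranking A `bq_ranking` from [rank_diverse()].
#' @param frac Training fraction, strictly between 0 and 1 (default 0.65).
#' @return A `bq_split`: list with `train`, `test` (original row indices),
#'   `scheme`, `frac`.
#' @export
split_by_rank <- function(ranking, frac = 0.65) {
  stopifnot(inherits(ranking, "bq_ranking"))
  if (!(frac > 0 && frac < 1)) stop("frac must be in (0, 1)", call. = FALSE)
  n <- length(ranking$order)
  if (n < 2L) stop("need at least 2 compounds to split", call. = FALSE)
  k <- .train_size(n, frac)
  structure(list(train = sort(ranking$order[seq_len(k)]),
                 test = sort(ranking$order[(k + 1L):n]),
                 scheme = "diverse", frac = frac),
            class = "bq_split")
}

#' @export
print.bq_split <- function(x, ...) {
  cat(sprintf("<bq_split [%s]: train %d / test %d>\n",
              x$scheme, length(x$train), length(x$test)))
  invisible(x)
}

#' Cluster compounds in descriptor space
#'
#' Seeded k-means on the normalized descriptor matrix. If the data have
#' fewer distinct rows than `k`, or a cluster comes back empty, clusters are
#' repaired by splitting the largest cluster at its farthest-from-center
#' point, so exactly `k` non-empty clusters with contiguous ids are always
#' returned.
#'
#' @param X Numeric matrix (compounds x normalized descriptors).
#' @param k Number of clusters (2 <= k <= N).
#' @param seed Integer seed making the clustering deterministic.
#' @return A `bq_clustering`: list with `labels` (1..k per compound), `k`,
#'   `seed`, `method`.
#' @export
cluster_compounds <- function(X, k, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k cannot exceed the number of compounds", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  uniq <- unique(X)
  k0 <- min(k, nrow(uniq))
  set.seed(as.integer(seed))
  labels <- if (k0 < 2L) rep(1L, n) else {
    km <- stats::kmeans(X, centers = k0, nstart = 10L, iter.max = 100L)
    as.integer(km$cluster)
  }
  # repair: grow to exactly k non-empty clusters
  while (length(unique(labels)) < k) {
    sizes <- table(labels)
    big <- as.integer(names(sizes)[which.max(sizes)])
    members <- which(labels == big)
    ctr <- colMeans(X[members, , drop = FALSE])
    d <- sqrt(rowSums(sweep(X[members, , drop = FALSE], 2, ctr)^2))
    labels[members[which.max(d)]] <- max(labels) + 1L
  }
  labels <- as.integer(factor(labels))  # contiguous ids
  structure(list(labels = labels, k = k, seed = as.integer(seed),
                 method = "kmeans"), class = "bq_clustering")
}

#' Per-cluster diverse split
#'
#' Runs the max-min diversity ranking and the 65/35-style split inside each
#' cluster (round-half-up per cluster; every cluster of size >= 2 keeps at
#' least one test compound; singleton clusters go to training), then unions
#' the per-cluster parts.
#'
#' @param X Numeric matrix (compounds x normalized descriptors).
#' @param k Number of clusters (ignored when `clustering` is supplied).
#' @param frac Training fraction (default 0.65).
#' @param seed Seed for the clustering step.
#' @param clustering Optional precomputed `bq_clustering` (or an integer
#'   label vector) to split on instead of running k-means.
#' @return A `bq_split` with scheme `"cluster_diverse"` and the clustering
#'   attached as `$clustering`.
#' @export
cluster_diverse_split <- function(X, k = NULL, frac = 0.65, seed = 1L,
                                  clustering = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(clustering)) {
    if (is.null(k)) k <- max(2L, as.integer(round(n / 20)))
    clustering <- cluster_compounds(X, k, seed)
  }
  labels <- if (inherits(clustering, "bq_clustering")) clustering$labels
            else as.integer(clustering)
  stopifnot(length(labels) == n)
  train <- integer(); test <- integer()
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    if (length(members) == 1L) { train <- c(train, members); next }
    rk <- rank_diverse(X[members, , drop = FALSE], start = 1L)
    ktrain <- .train_size(length(members), frac)
    train <- c(train, members[rk$order[seq_len(ktrain)]])
    test <- c(test, members[rk$order[(ktrain + 1L):length(members)]])
  }
  if (!length(test))
    stop("cluster-diverse split produced an empty test set", call. = FALSE)
  structure(list(train = sort(train), test = sort(test),
                 scheme = "cluster_diverse", frac = frac,
                 clustering = clustering),
            class = "bq_split")
}

#' Save a split as CSV (id, rank, cluster, partition)
#' @param split A `bq_split`.
#' @param ids Compound ids in row order.
#' @param ranking Optional `bq_ranking` for the rank column.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_split <- function(split, ids, path, ranking = NULL) {
  n <- length(ids)
  part <- rep("test", n); part[split$train] <- "train"
  rk <- rep(NA_integer_, n)
  if (!is.null(ranking)) rk[ranking$order] <- seq_len(n)
  cl <- if (!is.null(split$clustering)) split$clustering$labels else NA_integer_
  df <- data.frame(id = ids, rank = rk, cluster = cl, partition = part)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
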