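#' k-means clustering of samples on the meta-kernel's row profiles
#'
#' Each sample is represented by its length-n row of the fused
#' meta-kernel (its similarity profile), and Lloyd's k-means is run with
#' k-means++ initialization per restart; the restart with the smallest
#' within-cluster sum of squares E is kept. Iterations stop when the
#' maximum centroid shift drops below `1e-8` or after 300 iterations. An
#' empty cluster is repaired by re-seeding its centroid at the sample
#' farthest from its assigned centroid. Labels are canonicalized by
#' first occurrence, so output is deterministic given `(seed,
#' n_restarts)`.
#'
#' @param K `meta_kernel` (or any numeric matrix whose rows are sample
#'   profiles).
#' @param k Number of clusters, in `1..n`.
#' @param seed Integer seed governing all restarts; default 42.
#' @param n_restarts Number of k-means++ restarts; default 50.
#' @return A `cluster_assignment` list: `labels` (integers in 1..k),
#'   `k`, `objective` (E), `seed`, `n_restarts`.
#' @export
kernel_rows_kmeans <- function(K, k, seed = 42L, n_restarts = 50L) {
  X <- unclass(as.matrix(K))
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1 || k > n) stop("k must be in 1..n")
  if (!is.null(seed)) set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_once(X, k)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  labels <- canonicalize_labels(best$labels)
  structure(
    list(labels = labels, k = k, objective = best$objective,
         seed = seed, n_restarts = as.integer(n_restarts)),
    class = "cluster_assignment"
  )
}

lloyd_once <- function(X, k, max_iter = 300L, tol = 1e-8) {
  n <- nrow(X)
  C <- X[kmeanspp_init(X, k), , drop = FALSE]
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, C)
    labels <- max.col(-d2, ties.method = "first")
    shift <- 0
    for (j in seq_len(k)) {
      members <- which(labels == j)
      if (!length(members)) {
        # re-seed the empty centroid at the sample farthest from its
        # current centroid (standard repair)
        message("k-means: repaired an empty cluster")
        far <- which.max(d2[cbind(seq_len(n), labels)])
        C_new <- X[far, ]
        labels[far] <- j
        members <- far
      } else {
        C_new <- colMeans(X[members, , drop = FALSE])
      }
      shift <- max(shift, sqrt(sum((C_new - C[j, ])^2)))
      C[j, ] <- C_new
    }
    if (shift < tol) break
  }
  obj <- wcss(X, labels, k)
  list(labels = labels, objective = obj)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, each
# further center with probability proportional to squared distance to
# the nearest chosen center
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k == 1) return(centers)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ], `-`)^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j], ], `-`)^2))
  }
  centers
}

dist2_to_centers <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
  pmax(d2, 0)
}

wcss <- function(X, labels, k) {
  obj <- 0
  for (j in seq_len(k)) {
    members <- which(labels == j)
    if (length(members)) {
      mu <- colMeans(X[members, , drop = FALSE])
      obj <- obj + sum(sweep(X[members, , drop = FALSE], 2, mu, `-`)^2)
    }
  }
  obj
}

# relabel so cluster IDs appear in order of first occurrence
canonicalize_labels <- function(labels) {
  first <- unique(labels)
  match(labels, first)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d, n = %d, E = %.4f (seed %s, %d restarts)\n",
              x$k, length(x$labels), x$objective,
              as.character(x$seed), x$n_restarts))
  cat("cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}
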