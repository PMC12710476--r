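#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions
#' (up to label permutation), approximately 0 for independent random
#' labelings.
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @return A number in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  res <- mclust::adjustedRandIndex(labels_a, labels_b)
  if (is.nan(res)) {
    # degenerate partitions (all singletons / one cluster): the pair
    # counts carry no information; identical partitions still agree fully
    same <- identical(match(labels_a, unique(labels_a)),
                      match(labels_b, unique(labels_b)))
    res <- if (same) 1 else 0
  }
  res
}

# kernel-induced squared distance: d^2 = K_ii + K_jj - 2 K_ij
kernel_distance <- function(K) {
  K <- unclass(as.matrix(K))
  dk <- diag(K)
  d2 <- outer(dk, dk, `+`) - 2 * K
  d <- sqrt(pmax(d2, 0))
  diag(d) <- 0
  d
}

#' Mean silhouette width under the kernel-induced distance
#'
#' Uses the distance \eqn{d_{ij} = \sqrt{\max(0, K_{ii} + K_{jj} -
#' 2K_{ij})}} implied by the meta-kernel (the feature-space distance of
#' the kernel embedding). Set `distance = "rows"` to use Euclidean
#' distance between the kernel's row profiles instead.
#'
#' @param K `meta_kernel` (or similarity matrix).
#' @param labels Cluster labels (>= 2 nonempty clusters).
#' @param distance `"kernel"` (default) or `"rows"`.
#' @return Mean silhouette width in [-1, 1].
#' @export
silhouette_score <- function(K, labels, distance = c("kernel", "rows")) {
  distance <- match.arg(distance)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("need >= 2 clusters")
  if (all(tabulate(labels) <= 1)) stop("all clusters are singletons")
  d <- if (distance == "kernel") kernel_distance(K)
       else as.matrix(stats::dist(unclass(as.matrix(K))))
  sil <- cluster::silhouette(labels, dmatrix = d)
  mean(sil[, "sil_width"])
}

#' Davies-Bouldin index on the meta-kernel's row profiles
#'
#' \deqn{DBI = \frac{1}{k} \sum_i \max_{j \ne i}
#'   \frac{S_i + S_j}{M_{ij}},}
#' where \eqn{S_i} is the mean Euclidean distance of cluster `i`'s
#' members to its centroid and \eqn{M_{ij}} the distance between
#' centroids. Lower is better; 0 for point-mass clusters at distinct
#' locations.
#'
#' @param features Numeric matrix of per-sample feature vectors (for
#'   iMKL, the rows of the meta-kernel).
#' @param labels Cluster labels (>= 2 nonempty clusters).
#' @return Nonnegative real.
#' @export
davies_bouldin <- function(features, labels) {
  X <- unclass(as.matrix(features))
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("need >= 2 clusters")
  cent <- t(vapply(seq_len(k), function(j)
    colMeans(X[labels == j, , drop = FALSE]), numeric(ncol(X))))
  scatter <- vapply(seq_len(k), function(j) {
    xs <- X[labels == j, , drop = FALSE]
    mean(sqrt(rowSums(sweep(xs, 2, cent[j, ], `-`)^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cent))
  ratios <- outer(scatter, scatter, `+`) / M
  diag(ratios) <- -Inf
  mean(apply(ratios, 1, max))
}

#' Log-rank test for survival differences between clusters
#'
#' Standard (k-1)-degree-of-freedom log-rank chi-square comparing the
#' survival distributions of the k groups, with the usual discrete-time
#' handling of tied event times (via [survival::survdiff()]).
#'
#' @param surv A [survival_table()] (columns `time`, `event`).
#' @param labels Group label per row of `surv` (>= 2 groups).
#' @return List with `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank_test <- function(surv, labels) {
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(surv)) stop("length mismatch")
  if (length(unique(labels)) < 2) stop("need >= 2 groups")
  if (sum(surv$event) < 1) stop("no events observed; all times censored")
  fit <- survival::survdiff(
    survival::Surv(surv$time, surv$event) ~ labels,
    data = data.frame(labels = labels))
  df <- length(unique(labels)) - 1L
  stat <- fit$chisq
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Resampling stability of the subtyping pipeline
#'
#' Repeatedly subsamples patients (or features within each layer)
#' without replacement, reruns the full iMKL pipeline at each candidate
#' number of clusters, and records a quality metric per repeat — the
#' harness behind stability curves across k (e.g. 50% of patients, 100
#' repeats, k in 2..5). Per-repeat seeds are derived deterministically
#' from `seed` (`seed + rep`); the pipeline's own k-means seed comes
#' from `config`, so `fraction = 1` reproduces the full-data result in
#' every repeat.
#'
#' @param datasets List of aligned [omics_dataset()] objects.
#' @param config An [imkl_config()]; its `k` is overridden by
#'   `k_values`.
#' @param truth_labels True subtype per sample (required for metric
#'   `"ari_vs_truth"`).
#' @param surv A [survival_table()] aligned with the samples (required
#'   for metric `"logrank_p"`).
#' @param axis Resample `"samples"` or `"features"`.
#' @param fraction Fraction kept, in (0, 1].
#' @param n_reps Number of repeats.
#' @param k_values Candidate cluster numbers.
#' @param metric `"ari_vs_truth"` or `"logrank_p"`.
#' @param seed Base seed for the subsampling.
#' @return A `stability_report` list: `values` (`n_reps x
#'   length(k_values)` matrix), plus the settings.
#' @export
stability_resample <- function(datasets, config = imkl_config(),
                               truth_labels = NULL, surv = NULL,
                               axis = c("samples", "features"),
                               fraction = 0.5, n_reps = 20L,
                               k_values = 2:5,
                               metric = c("ari_vs_truth", "logrank_p"),
                               seed = 1L) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (metric == "ari_vs_truth" && is.null(truth_labels))
    stop("metric 'ari_vs_truth' requires truth_labels")
  if (metric == "logrank_p" && is.null(surv))
    stop("metric 'logrank_p' requires a survival table")
  n <- nrow(datasets[[1]]$values)
  vals <- matrix(NA_real_, n_reps, length(k_values),
                 dimnames = list(NULL, paste0("k", k_values)))
  for (rep_i in seq_len(n_reps)) {
    set.seed(as.integer(seed) + rep_i)
    if (axis == "samples") {
      m <- floor(fraction * n)
      keep <- if (m == n) seq_len(n) else sort(sample.int(n, m))
      ds <- lapply(datasets, function(d)
        omics_dataset(d$values[keep, , drop = FALSE],
                      d$sample_ids[keep], d$layer_name))
    } else {
      keep <- seq_len(n)
      ds <- lapply(datasets, function(d) {
        p <- ncol(d$values)
        pm <- floor(fraction * p)
        cols <- if (pm == p) seq_len(p) else sort(sample.int(p, pm))
        omics_dataset(d$values[, cols, drop = FALSE],
                      d$sample_ids, d$layer_name)
      })
    }
    if (nrow(ds[[1]]$values) < (config$k_eps %||% default_k_eps(nrow(ds[[1]]$values))) + 1)
      stop("subsample too small for kernel construction")
    for (ki in seq_along(k_values)) {
      cfg <- config
      cfg$k <- k_values[ki]
      fit <- imkl_fit(ds, cfg)
      vals[rep_i, ki] <- switch(
        metric,
        ari_vs_truth = adjusted_rand_index(fit$assignment$labels,
                                           truth_labels[keep]),
        logrank_p = {
          sv <- surv[match(ds[[1]]$sample_ids, surv$sample_id), , drop = FALSE]
          logrank_test(sv, fit$assignment$labels)$p_value
        })
    }
  }
  structure(list(values = vals, axis = axis, fraction = fraction,
                 n_reps = as.integer(n_reps), k_values = k_values,
                 metric = metric, seed = as.integer(seed)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s, fraction %.2f, %d reps, metric %s\n",
              x$axis, x$fraction, x$n_reps, x$metric))
  print(round(apply(x$values, 2, stats::median), 4))
  invisible(x)
}
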