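# hand contingency-table ARI for a frozen small case:
# (1,1,2,2) vs (1,2,1,2): all four cells of the 2x2 table equal 1, so
# sum_ij C(n_ij,2) = 0, sum_a C(2,2) = 2 = sum_b, E = 2*2/C(4,2) = 2/3,
# ARI = (0 - 2/3)/((2 + 2)/2 - 2/3) = -0.5
test_that("adjusted Rand index matches hand computation and invariances", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c("a", "a", "b"), c(5, 5, 9)), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")

  # independent random labelings: mean ARI ~ 0
  set.seed(1)
  m <- mean(replicate(500, adjusted_rand_index(sample(1:3, 40, TRUE),
                                               sample(1:3, 40, TRUE))))
  expect_lt(abs(m), 0.02)
})

test_that("silhouette separates well-structured clusters and not noise", {
  K <- block_matrix(2, 10, within = 0.999, between = 1e-4)
  truth <- rep(1:2, each = 10)
  expect_gt(silhouette_score(K, truth), 0.9)

  # homogeneous data with random labels: |silhouette| near 0
  set.seed(2)
  vals <- replicate(20, {
    Kr <- unclass(rand_kernel(30, seed = sample.int(1e6, 1)))
    silhouette_score(Kr, sample(1:2, 30, TRUE))
  })
  expect_lt(abs(mean(vals)), 0.1)

  # equidistant configuration: a = b so silhouette is 0
  Keq <- matrix(0.5, 4, 4); diag(Keq) <- 1
  expect_equal(silhouette_score(Keq, c(1, 1, 2, 2)), 0)

  expect_error(silhouette_score(K, rep(1, 20)), "2 clusters")
})

# textbook Davies-Bouldin computed with explicit loops
naive_dbi <- function(X, labels) {
  ks <- sort(unique(labels))
  cent <- lapply(ks, function(c) colMeans(X[labels == c, , drop = FALSE]))
  S <- sapply(ks, function(c) {
    xs <- X[labels == c, , drop = FALSE]
    mean(sqrt(rowSums(sweep(xs, 2, cent[[which(ks == c)]])^2)))
  })
  total <- 0
  for (a in seq_along(ks)) {
    worst <- -Inf
    for (b in seq_along(ks)) {
      if (a != b) {
        M <- sqrt(sum((cent[[a]] - cent[[b]])^2))
        worst <- max(worst, (S[a] + S[b]) / M)
      }
    }
    total <- total + worst
  }
  total / length(ks)
}

test_that("Davies-Bouldin matches the textbook formula and orders solutions", {
  # point-mass clusters at distinct locations: DBI = 0
  X0 <- rbind(matrix(0, 5, 2), matrix(5, 5, 2))
  expect_equal(davies_bouldin(X0, rep(1:2, each = 5)), 0)

  set.seed(3)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2))
  lab <- rep(1:2, each = 10)
  expect_equal(davies_bouldin(X, lab), naive_dbi(X, lab), tolerance = 1e-9)

  # merging two separated clusters against a third inflates DBI
  X3 <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
              matrix(rnorm(20, 5, 0.3), 10, 2),
              matrix(rnorm(20, 10, 0.3), 10, 2))
  good <- rep(1:3, each = 10)
  merged <- c(rep(1, 20), rep(2, 10))
  expect_gt(davies_bouldin(X3, merged), davies_bouldin(X3, good))

  expect_error(davies_bouldin(X, rep(1, 20)), "2 clusters")
})

# direct observed-minus-expected log-rank computation for two groups
naive_logrank <- function(time, event, group) {
  tt <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in tt) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    U <- U + d1 - d_t * n1 / n_t
    if (n_t > 1)
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  U^2 / V
}

test_that("log-rank test matches the O-E oracle and handles identical groups", {
  # identical survival experience in both groups: statistic 0, p exactly 1
  tm <- c(1, 2, 3, 4, 5); ev <- c(1, 1, 0, 1, 1)
  surv <- survival_table(sprintf("s%d", 1:10), c(tm, tm), c(ev, ev))
  res <- logrank_test(surv, rep(1:2, each = 5))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  # ten-sample two-group fixture vs hand computation
  time <- c(3, 5, 7, 2, 18, 11, 4, 1, 8, 12)
  event <- c(1, 1, 1, 0, 1, 1, 1, 1, 0, 1)
  group <- c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  sv <- survival_table(sprintf("p%d", 1:10), time, event)
  res2 <- logrank_test(sv, group)
  expect_equal(res2$statistic, naive_logrank(time, event, group),
               tolerance = 1e-9)
  expect_identical(res2$df, 1L)

  expect_error(logrank_test(survival_table("a", 1, 0), 1), "2 groups")
  all_cens <- survival_table(sprintf("s%d", 1:4), 1:4, rep(0L, 4))
  expect_error(logrank_test(all_cens, c(1, 1, 2, 2)), "censored")
})

test_that("stability harness is deterministic and respects subsample sizes", {
  g <- generate_multiomics(synthetic_spec(n = 60, k_true = 3, seed = 3))
  ds <- align_and_standardize(g$datasets)
  cfg <- imkl_config(n_restarts = 5)

  r1 <- stability_resample(ds, cfg, truth_labels = g$truth$labels,
                           axis = "samples", fraction = 0.5, n_reps = 3,
                           k_values = c(2, 3), seed = 7)
  r2 <- stability_resample(ds, cfg, truth_labels = g$truth$labels,
                           axis = "samples", fraction = 0.5, n_reps = 3,
                           k_values = c(2, 3), seed = 7)
  expect_identical(r1$values, r2$values)
  expect_equal(dim(r1$values), c(3L, 2L))

  # feature subsampling keeps floor(0.8 * p) features per layer
  r3 <- stability_resample(ds, cfg, truth_labels = g$truth$labels,
                           axis = "features", fraction = 0.8, n_reps = 2,
                           k_values = 3, seed = 8)
  expect_true(all(is.finite(r3$values)))

  expect_error(stability_resample(ds, cfg, truth_labels = g$truth$labels,
                                  fraction = 0), "fraction")
  expect_error(stability_resample(ds, cfg, metric = "ari_vs_truth"),
               "truth_labels")
})

test_that("stability with log-rank metric consumes the survival table", {
  spec <- synthetic_spec(n = 60, k_true = 2, seed = 4,
                         layers = replicate(2, list(p = 40L,
                                                    p_informative = 20L,
                                                    delta = 3, sigma = 1),
                                            simplify = FALSE),
                         survival = list(baseline_hazard = 0.1,
                                         hazard_ratios = c(1, 5),
                                         censoring_rate = 0))
  g <- generate_multiomics(spec)
  ds <- align_and_standardize(g$datasets)
  r <- stability_resample(ds, imkl_config(n_restarts = 5),
                          surv = g$truth$survival_table,
                          axis = "samples", fraction = 1, n_reps = 2,
                          k_values = 2, metric = "logrank_p", seed = 2)
  expect_true(all(r$values >= 0 & r$values <= 1))
  # strong hazard contrast on recovered clusters: small p
  expect_lt(max(r$values), 0.01)
})
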