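# brute-force per-row top-k neighbour scan
brute_knn_edges <- function(K, k) {
  n <- nrow(K)
  adj <- matrix(FALSE, n, n)
  for (i in 1:n) {
    s <- unclass(K)[i, ]; s[i] <- -Inf
    top <- integer(0)
    for (step in seq_len(k)) {
      cand <- which(s == max(s))
      pick <- min(cand)
      top <- c(top, pick); s[pick] <- -Inf
    }
    adj[i, top] <- TRUE
  }
  adj <- adj | t(adj)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# literal ordered-pair quadruple-loop cost
naive_cost <- function(kernels, W) {
  L <- length(kernels); n <- nrow(W)
  S <- matrix(0, L, L)
  for (l in 1:L) for (lp in 1:L) {
    acc <- 0
    for (i in 1:n) for (j in 1:n) {
      if (W[i, j] > 0) {
        dl <- kernels[[l]][, i] - kernels[[l]][, j]
        dlp <- kernels[[lp]][, i] - kernels[[lp]][, j]
        acc <- acc + W[i, j] * sum(dl * dlp)
      }
    }
    S[l, lp] <- acc
  }
  S
}

test_that("k-NN graph edges match a brute-force scan and edge cases", {
  K <- rand_kernel(8, seed = 7)
  e <- knn_graph_edges(K, 2)
  expect_equal(unname(e), unname(brute_knn_edges(K, 2)))

  # complete graph at k = n - 1
  expect_equal(nrow(knn_graph_edges(K, 7)), choose(8, 2))

  # block similarity keeps all edges within blocks
  Kb <- block_matrix(2, 6, within = 0.9, between = 1e-8)
  eb <- knn_graph_edges(Kb, 3)
  lab <- rep(1:2, each = 6)
  expect_true(all(lab[eb[, 1]] == lab[eb[, 2]]))

  expect_error(knn_graph_edges(K, 8), "k_graph")
})

test_that("co-occurrence counts edge membership across kernels", {
  e1 <- cbind(i = c(1L, 2L), j = c(2L, 3L))
  W <- cooccurrence(list(e1, e1, e1), 4)
  expect_equal(W[1, 2], 3L)
  expect_equal(W[2, 1], 3L)
  expect_equal(W[1, 3], 0L)
  expect_equal(unname(diag(W)), rep(0L, 4))

  disjoint <- list(cbind(1L, 2L), cbind(3L, 4L))
  expect_true(all(cooccurrence(disjoint, 4) %in% 0:1))

  # random edge sets equal direct per-pair counting
  set.seed(5)
  sets <- lapply(1:3, function(s) {
    pairs <- t(combn(6, 2))
    pairs[sort(sample(nrow(pairs), 5)), , drop = FALSE]
  })
  W2 <- cooccurrence(sets, 6)
  for (i in 1:5) for (j in (i + 1):6) {
    cnt <- sum(vapply(sets, function(e)
      any(e[, 1] == i & e[, 2] == j), logical(1)))
    expect_equal(W2[i, j], cnt)
  }

  expect_error(cooccurrence(list(cbind(1L, 9L)), 4), "out of range")
})

test_that("cost matrix equals the naive quadruple-loop oracle", {
  for (s in 1:5) {
    marg <- lapply(1:3, function(m) rand_kernel(5, seed = s * 10 + m,
                                                layer_index = m))
    W <- cooccurrence(lapply(marg, knn_graph_edges, k_graph = 2), 5)

    # literal formula on the raw kernels
    S_raw <- build_cost_matrix(marg, W, normalize = FALSE)
    expect_equal(unclass(S_raw), naive_cost(lapply(marg, unclass), W),
                 ignore_attr = TRUE, tolerance = 1e-9)

    # normalized variant: same formula on independently centered kernels
    center <- function(K) {
      K <- unclass(K)
      Kc <- sweep(sweep(K, 1, rowMeans(K)), 2, colMeans(K)) + mean(K)
      Kc / sqrt(sum(Kc^2))
    }
    S_norm <- build_cost_matrix(marg, W, normalize = TRUE)
    expect_equal(unclass(S_norm), naive_cost(lapply(marg, center), W),
                 ignore_attr = TRUE, tolerance = 1e-9)

    # Gram structure: symmetric PSD
    ev <- eigen(unclass(S_norm), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
})

test_that("identical kernels give a rank-one cost matrix", {
  K <- rand_kernel(6, seed = 2)
  kernels <- list(K, K, K)
  attr(kernels[[2]], "layers") <- 2L
  attr(kernels[[3]], "layers") <- 3L
  W <- cooccurrence(lapply(kernels, knn_graph_edges, k_graph = 2), 6)
  S <- build_cost_matrix(kernels, W)
  expect_lt(max(abs(S - S[1, 1])), 1e-9 * max(1, abs(S[1, 1])))
  expect_gte(S[1, 1], 0)
})

test_that("simplex QP recovers closed-form and symmetric solutions", {
  b <- solve_simplex_qp(diag(c(1, 4)))
  expect_equal(as.numeric(b), c(0.8, 0.2), tolerance = 1e-9)

  for (L in c(2, 5, 7)) {
    u <- solve_simplex_qp(diag(L))
    expect_equal(as.numeric(u), rep(1 / L, L), tolerance = 1e-9)
  }

  # invariants: simplex membership, no worse than vertices or uniform
  set.seed(8)
  for (rep in 1:10) {
    A <- matrix(rnorm(9), 3, 3)
    S <- crossprod(A)
    beta <- as.numeric(solve_simplex_qp(S))
    expect_true(all(beta >= -1e-10))
    expect_equal(sum(beta), 1, tolerance = 1e-8)
    obj <- drop(t(beta) %*% S %*% beta)
    expect_lte(obj, min(diag(S)) + 1e-9)
    unif <- rep(1 / 3, 3)
    expect_lte(obj, drop(t(unif) %*% S %*% unif) + 1e-9)
  }
})

test_that("QP argmin is invariant to positive scaling of the cost", {
  set.seed(9)
  A <- matrix(rnorm(16), 4, 4)
  S <- crossprod(A)
  b1 <- as.numeric(solve_simplex_qp(S))
  b2 <- as.numeric(solve_simplex_qp(17.3 * S))
  expect_equal(b1, b2, tolerance = 1e-8)
  # and deterministic across repeated calls
  expect_identical(b1, as.numeric(solve_simplex_qp(S)))
})

test_that("fusion forms the convex combination and validates weights", {
  basis <- build_kernel_basis(
    lapply(1:2, function(m) rand_kernel(9, seed = m + 40, layer_index = m)))
  onehot <- c(0, 1, 0)
  Kf <- fuse(basis, onehot)
  expect_equal(unclass(Kf), unclass(basis$K2), ignore_attr = TRUE)

  beta <- c(0.5, 0.3, 0.2)
  Kf2 <- fuse(basis, beta)
  expect_equal(unname(diag(Kf2)), rep(1, 9))
  ub <- pmax(unclass(basis[[1]]), unclass(basis[[2]]), unclass(basis[[3]]))
  expect_true(all(unclass(Kf2) <= ub + 1e-15))
  expect_lt(max(abs(unclass(Kf2) -
    (0.5 * unclass(basis[[1]]) + 0.3 * unclass(basis[[2]]) +
     0.2 * unclass(basis[[3]])))), 1e-12)

  expect_error(fuse(basis, c(0.5, 0.6, 0.2)), "simplex")
  expect_error(fuse(basis, c(1, 0)), "length")
})

test_that("structured consensus outweighs an unrelated noise kernel", {
  # three kernels sharing block structure plus one from pure noise
  set.seed(10)
  kerns <- c(lapply(1:3, function(m)
    clustered_kernel(60, 3, delta = 2.5, seed = m, layer_index = m)$kernel),
    list(rand_kernel(60, p = 30, seed = 99, layer_index = 4L)))
  names(kerns) <- c("inf1", "inf2", "inf3", "noise")
  W <- cooccurrence(lapply(kerns, knn_graph_edges, k_graph = 5), 60)
  beta <- as.numeric(solve_simplex_qp(build_cost_matrix(kerns, W)))
  expect_lt(beta[4], mean(beta[1:3]))
})
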