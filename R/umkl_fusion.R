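#' k-nearest-neighbour graph edges of a similarity kernel
#'
#' Sample `j` is linked to `i` if `j` is among the `k_graph` most similar
#' samples to `i` (descending similarity, self excluded, ties broken by
#' lower sample index) or vice versa; edges are undirected
#' (OR-symmetrization, which keeps the downstream topology matrix
#' symmetric).
#'
#' @param K A `similarity_kernel` (or symmetric matrix).
#' @param k_graph Number of neighbours per sample, in `1..n-1`.
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per
#'   undirected edge, ordered by (i, j).
#' @export
knn_graph_edges <- function(K, k_graph = 5L) {
  K <- unclass(as.matrix(K))
  n <- nrow(K)
  k_graph <- as.integer(k_graph)
  if (k_graph < 1 || k_graph > n - 1)
    stop("k_graph must be in 1..n-1")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    s <- K[i, ]
    s[i] <- -Inf
    nb <- order(-s)[seq_len(k_graph)]  # stable order: ties -> lower index
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(edges) <- c("i", "j")
  edges
}

#' Edge co-occurrence (topology) matrix across kernels
#'
#' Counts, for every sample pair, in how many of the per-kernel k-NN
#' graphs the pair appears as an edge. This consensus topology drives the
#' kernel-weight optimization: pairs that are neighbours in many kernels
#' should stay close under the fused kernel.
#'
#' @param edge_sets List of edge matrices as returned by
#'   [knn_graph_edges()], all over the same `n` samples.
#' @param n Number of samples.
#' @return A symmetric `n x n` integer matrix of class `topology_matrix`
#'   with zero diagonal; entries bounded by `length(edge_sets)`.
#' @export
cooccurrence <- function(edge_sets, n) {
  W <- matrix(0L, n, n)
  for (e in edge_sets) {
    if (nrow(e) && (max(e) > n || min(e) < 1))
      stop("edge index out of range")
    for (r in seq_len(nrow(e))) {
      i <- e[r, 1]; j <- e[r, 2]
      W[i, j] <- W[i, j] + 1L
      W[j, i] <- W[j, i] + 1L
    }
  }
  structure(W, class = c("topology_matrix", "matrix", "array"))
}

#' Topology-preservation cost matrix for kernel-weight learning
#'
#' Entry (l, l') is
#' \deqn{S_{ll'} = \sum_{i,j=1}^n W_{ij}\,\langle \Delta_i^l - \Delta_j^l,\;
#'   \Delta_i^{l'} - \Delta_j^{l'}\rangle,}
#' where \eqn{\Delta_i^l} is column `i` of kernel `l` (the sample's
#' similarity profile) and `W` the edge co-occurrence matrix. `S` is a
#' Gram matrix of weighted profile-difference vectors, hence symmetric
#' PSD; the fused-kernel objective \eqn{\sum_{ij} W_{ij}\|\Delta_i(\beta)
#' - \Delta_j(\beta)\|^2} equals \eqn{\beta^T S \beta} by bilinearity.
#'
#' The sum runs over ordered pairs; since `W` is symmetric with zero
#' diagonal this is computed as twice the sum over unordered pairs with
#' `W_ij > 0`, vectorized in edge chunks.
#'
#' With `normalize = TRUE` (the default) each kernel is double-centered
#' and scaled to unit Frobenius norm before the profile differences are
#' taken. This puts heterogeneous kernels on a comparable energy scale:
#' without it the quadratic objective is dominated by each kernel's
#' overall entry magnitude, and a structureless near-constant kernel —
#' whose profiles barely vary — receives the lowest cost and hence the
#' largest weight, inverting the intended "more weight to more
#' informative kernels" behaviour. Normalization only affects the
#' learned weights; fusion always combines the raw kernels.
#'
#' @param basis A [build_kernel_basis()] result (or list of kernels).
#' @param W Topology matrix from [cooccurrence()].
#' @param normalize Center/scale kernels before computing the cost
#'   (default `TRUE`); `FALSE` applies the formula to the raw kernels.
#' @param chunk Number of edges per vectorized block (memory control).
#' @return A symmetric PSD `L x L` matrix of class `cost_matrix`, with
#'   kernel names as dimnames.
#' @export
build_cost_matrix <- function(basis, W, normalize = TRUE, chunk = 2000L) {
  L <- length(basis)
  n <- nrow(W)
  if (any(vapply(basis, nrow, 1L) != n)) stop("kernel/topology dimension mismatch")
  basis <- if (normalize) lapply(basis, center_scale_kernel)
           else lapply(basis, unclass)
  idx <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
  S <- matrix(0, L, L)
  if (nrow(idx)) {
    w <- W[idx]
    starts <- seq(1L, nrow(idx), by = chunk)
    for (s0 in starts) {
      s1 <- min(s0 + chunk - 1L, nrow(idx))
      ii <- idx[s0:s1, 1]; jj <- idx[s0:s1, 2]
      sw <- sqrt(w[s0:s1])
      V <- vapply(basis, function(K) {
        K <- unclass(K)
        d <- K[, ii, drop = FALSE] - K[, jj, drop = FALSE]
        as.vector(sweep(d, 2, sw, `*`))
      }, numeric(n * length(ii)))
      S <- S + crossprod(V)
    }
  }
  S <- 2 * S           # ordered-pair convention
  S <- (S + t(S)) / 2
  dimnames(S) <- list(names(basis), names(basis))
  structure(S, class = c("cost_matrix", "matrix", "array"))
}

# double-center a kernel and scale to unit Frobenius norm, so kernels
# compete in the weight-learning QP on topology rather than magnitude
center_scale_kernel <- function(K) {
  K <- unclass(K)
  n <- nrow(K)
  rm_ <- rowMeans(K)
  Kc <- K - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(K)
  nrm <- sqrt(sum(Kc^2))
  if (nrm < .Machine$double.eps) return(Kc)
  Kc / nrm
}

#' Minimize a quadratic form over the probability simplex
#'
#' Solves \eqn{\min_\beta \beta^T S \beta} subject to \eqn{\beta_l \ge 0,
#' \sum_l \beta_l = 1}. The simplex constraint fixes the L1 norm at 1,
#' which induces sparsity in the resulting weights. For moderate `L`
#' (<= 16) the exact minimizer is found by enumerating active sets and
#' solving the equality-constrained KKT system on each face; a projected
#' accelerated-gradient polish guards against singular faces and handles
#' larger `L`. Deterministic for a given `S`.
#'
#' @param S Symmetric PSD cost matrix (tiny negative eigenvalues are
#'   tolerated). On solver failure the uniform vector is returned with a
#'   warning, never silently.
#' @return A `weight_vector`: numeric vector `beta` on the simplex, named
#'   by `dimnames(S)` if present.
#' @export
solve_simplex_qp <- function(S) {
  S <- unclass(as.matrix(S))
  L <- nrow(S)
  if (L != ncol(S) || max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be symmetric")
  S <- (S + t(S)) / 2
  nms <- rownames(S)
  obj <- function(b) drop(crossprod(b, S %*% b))

  best <- rep(1 / L, L)
  best_obj <- obj(best)
  consider <- function(b) {
    if (all(b >= -1e-10) && abs(sum(b) - 1) < 1e-8) {
      b <- pmax(b, 0); b <- b / sum(b)
      o <- obj(b)
      if (o < best_obj - 1e-12 * max(1, abs(best_obj))) {
        best <<- b; best_obj <<- o
      }
    }
  }

  if (L <= 16) {
    # exact: the minimizer lies on some face; on each face it solves
    # [2 S_AA, 1; 1', 0] (beta, nu) = (0, 1)
    for (size in seq_len(L)) {
      for (A in utils::combn(L, size, simplify = FALSE)) {
        if (size == 1) {
          b <- numeric(L); b[A] <- 1
          consider(b)
        } else {
          M <- rbind(cbind(2 * S[A, A, drop = FALSE], 1), c(rep(1, size), 0))
          sol <- tryCatch(solve(M, c(rep(0, size), 1)), error = function(e) NULL)
          if (!is.null(sol)) {
            b <- numeric(L); b[A] <- sol[seq_len(size)]
            consider(b)
          }
        }
      }
    }
  } else {
    for (l in seq_len(L)) {   # vertices as candidate starts
      b <- numeric(L); b[l] <- 1
      consider(b)
    }
  }

  # FISTA polish from the current best (also the sole solver for L > 16)
  b <- projected_gradient_simplex(S, best, iters = 5000L)
  consider(b)

  if (!all(is.finite(best))) {
    warning("simplex QP solver failed; falling back to uniform weights")
    best <- rep(1 / L, L)
  }
  structure(as.numeric(best), names = nms,
            class = "weight_vector")
}

projected_gradient_simplex <- function(S, b0, iters = 5000L) {
  lip <- max(abs(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  if (lip <= 0) return(b0)
  step <- 1 / (2 * lip)
  b <- b0; y <- b0; t0 <- 1
  for (it in seq_len(iters)) {
    g <- 2 * (S %*% y)
    b_new <- project_simplex(as.numeric(y - step * g))
    t1 <- (1 + sqrt(1 + 4 * t0^2)) / 2
    y <- b_new + ((t0 - 1) / t1) * (b_new - b)
    if (max(abs(b_new - b)) < 1e-14) { b <- b_new; break }
    b <- b_new; t0 <- t1
  }
  b
}

# Euclidean projection onto the probability simplex (Duchi et al.)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> kernel weights (simplex):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Fuse a kernel basis into the meta-kernel
#'
#' \deqn{K_{final} = \sum_l \beta_l K^l} — the convex combination of the
#' basis kernels under the learned weights. Inherits symmetry, unit
#' diagonal and PSD-ness from the basis.
#'
#' @param basis A `kernel_basis`.
#' @param weights A `weight_vector` (or numeric simplex vector) of
#'   matching length.
#' @return A `meta_kernel`: the fused `n x n` matrix with the weights
#'   attached as attribute `"weights"`.
#' @export
fuse <- function(basis, weights) {
  beta <- as.numeric(weights)
  if (length(beta) != length(basis)) stop("length(weights) != length(basis)")
  if (any(beta < -1e-8) || abs(sum(beta) - 1) > 1e-8)
    stop("weights must lie on the probability simplex")
  Kf <- Reduce(`+`, Map(function(K, b) b * unclass(K), basis, beta))
  structure(Kf,
            weights = structure(beta, names = names(basis),
                                class = "weight_vector"),
            class = c("meta_kernel", "matrix", "array"))
}

#' @export
print.meta_kernel <- function(x, ...) {
  cat(sprintf("<meta_kernel> n = %d, fused from %d kernels\n",
              nrow(x), length(attr(x, "weights"))))
  invisible(x)
}
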