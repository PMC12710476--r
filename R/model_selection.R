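#' Similarity Laplacian of a meta-kernel
#'
#' Normalized symmetric graph Laplacian
#' \deqn{L_{sym} = I - D^{-1/2} K D^{-1/2}, \quad D = \mathrm{diag}(K\,\mathbf{1}),}
#' whose spectrum lies in [0, 2] and whose zero-eigenvalue multiplicity
#' equals the number of connected components of the similarity graph —
#' the basis of the eigengap heuristic. The unnormalized variant
#' `D - K` is also available.
#'
#' @param K Symmetric matrix with nonnegative entries (typically a
#'   `meta_kernel`).
#' @param variant `"normalized"` (default) or `"unnormalized"`.
#' @return Symmetric `n x n` Laplacian matrix.
#' @export
similarity_laplacian <- function(K, variant = c("normalized", "unnormalized")) {
  variant <- match.arg(variant)
  K <- unclass(as.matrix(K))
  if (any(K < 0)) stop("K must have nonnegative entries")
  d <- rowSums(K)
  zero <- which(d <= 0)
  if (length(zero)) {
    nm <- rownames(K)[zero[1]] %||% as.character(zero[1])
    stop("isolated sample with zero similarity row sum: ", nm)
  }
  if (variant == "unnormalized") {
    Lp <- diag(d) - K
  } else {
    inv_sqrt <- 1 / sqrt(d)
    Lp <- diag(nrow(K)) - (inv_sqrt * K) * rep(inv_sqrt, each = nrow(K))
  }
  (Lp + t(Lp)) / 2
}

#' Select the number of clusters by the Laplacian eigengap
#'
#' Computes the ascending eigenvalues \eqn{\lambda_1 \le \dots \le
#' \lambda_n} of the similarity Laplacian and the gaps
#' \eqn{eigengap(k) = \lambda_{k+1} - \lambda_k}; the selected number of
#' clusters is \eqn{C^* = \arg\max_{2 \le k \le k_{max}} eigengap(k)},
#' with ties broken toward the smallest k (parsimony).
#'
#' @param K Symmetric nonnegative similarity matrix (`meta_kernel`).
#' @param k_max Largest candidate k; default `min(10, n - 1)`.
#' @param variant Laplacian variant, see [similarity_laplacian()].
#' @return An `eigengap_profile` list: `eigenvalues` (ascending), `gaps`
#'   (for k = 1..k_max), `selected_k`, `k_max`, `variant`.
#' @export
eigengap_select <- function(K, k_max = NULL,
                            variant = c("normalized", "unnormalized")) {
  variant <- match.arg(variant)
  n <- nrow(K)
  if (is.null(k_max)) k_max <- min(10L, n - 1L)
  k_max <- as.integer(k_max)
  if (k_max < 2 || k_max > n - 1) stop("k_max must be in 2..n-1")
  Lp <- similarity_laplacian(K, variant)
  lam <- sort(eigen(Lp, symmetric = TRUE, only.values = TRUE)$values)
  gaps <- lam[2:(k_max + 1)] - lam[1:k_max]
  cand <- gaps[2:k_max]                 # k = 2..k_max
  selected_k <- which.max(cand) + 1L    # which.max: first max -> smallest k
  structure(
    list(eigenvalues = lam, gaps = gaps, selected_k = selected_k,
         k_max = k_max, variant = variant),
    class = "eigengap_profile"
  )
}

#' @export
print.eigengap_profile <- function(x, ...) {
  cat(sprintf("<eigengap_profile> selected k = %d (k_max = %d, %s Laplacian)\n",
              x$selected_k, x$k_max, x$variant))
  cat("gaps:", paste(sprintf("k=%d: %.4f", seq_along(x$gaps), x$gaps),
                     collapse = "  "), "\n")
  invisible(x)
}
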