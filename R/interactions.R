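#' Hadamard (element-wise) product of similarity kernels
#'
#' The Schur product theorem guarantees the element-wise product of PSD
#' kernels is PSD, and unit diagonals are preserved, so the product is a
#' valid similarity kernel. It represents the interaction structure of
#' the omics layers involved: samples are similar under the product only
#' if they are similar in every factor.
#'
#' @param kernels List of >= 2 `similarity_kernel` objects with identical
#'   dimensions and pairwise-disjoint layer subsets.
#' @return A `similarity_kernel` with `kind = "interaction"` and
#'   `layers` = the union of the inputs' layers.
#' @export
hadamard_product <- function(kernels) {
  if (length(kernels) < 2) stop("need at least 2 kernels")
  n <- nrow(kernels[[1]])
  layer_sets <- lapply(kernels, attr, "layers")
  if (any(vapply(kernels, nrow, 1L) != n) ||
      any(vapply(kernels, ncol, 1L) != n))
    stop("kernel dimension mismatch")
  all_layers <- unlist(layer_sets)
  if (anyDuplicated(all_layers))
    stop("overlapping layer subsets in Hadamard product")
  prod <- Reduce(`*`, lapply(kernels, unclass))
  new_similarity_kernel(prod, layers = all_layers, kind = "interaction",
                        sample_ids = rownames(kernels[[1]]))
}

#' Build the full kernel basis (marginals plus interaction kernels)
#'
#' For `M` marginal kernels, forms the Hadamard interaction kernel of
#' every layer subset of size `2..max_order` and returns all kernels in a
#' deterministic order: marginals first (by layer index), then pairwise
#' subsets in lexicographic order, then larger subsets. With
#' `max_order = M` the basis has `L = 2^M - 1` members (e.g. `L = 7` for
#' three omics layers: K1, K2, K3, K1x2, K1x3, K2x3, K1x2x3).
#'
#' @param marginals List of M >= 1 marginal `similarity_kernel` objects.
#' @param max_order Largest subset size to include; default `M`. Capping
#'   at 2 avoids the `2^M` blow-up for many-layer inputs.
#' @return A `kernel_basis`: a named list of `similarity_kernel` objects
#'   with names like `"K1"`, `"K2x3"`, `"K1x2x3"`.
#' @export
build_kernel_basis <- function(marginals, max_order = length(marginals)) {
  M <- length(marginals)
  if (M < 1) stop("need at least one marginal kernel")
  if (max_order < 1 || max_order > M)
    stop("max_order must be in 1..M")
  n <- vapply(marginals, nrow, 1L)
  if (length(unique(n)) != 1) stop("marginal kernels have mismatched n")
  kernels <- list()
  for (s in seq_len(max_order)) {
    subsets <- utils::combn(M, s, simplify = FALSE)
    for (sub in subsets) {
      k <- if (s == 1) marginals[[sub]] else hadamard_product(marginals[sub])
      kernels[[kernel_name(sub)]] <- k
    }
  }
  structure(kernels, class = "kernel_basis")
}

kernel_name <- function(layers) paste0("K", paste(layers, collapse = "x"))

#' @export
print.kernel_basis <- function(x, ...) {
  cat(sprintf("<kernel_basis> L = %d kernels (n = %d): %s\n",
              length(x), nrow(x[[1]]), paste(names(x), collapse = ", ")))
  invisible(x)
}
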