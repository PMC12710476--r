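#' Configuration for an iMKL run
#'
#' Collects every tunable of the pipeline with its default. Numeric
#' defaults: `mu = 0.5` and `k_eps = min(20, max(floor(n/10), 3))`
#' follow the conventional ranges of the scaled exponential kernel
#' family; `k_graph = 5` neighbours define the per-kernel topology
#' graph; `k_max = min(10, n-1)` bounds the eigengap search; 50 k-means
#' restarts from seed 42.
#'
#' @param mu Kernel bandwidth (> 0).
#' @param k_eps Neighbourhood size for the kernel's local scale;
#'   `NULL` = auto from n.
#' @param max_order Largest interaction order; `NULL` = number of
#'   layers. Forced to 1 by `marginal_only`.
#' @param k_graph k-NN graph size for the topology matrix.
#' @param k Fixed number of clusters; `NULL` = select by eigengap.
#' @param k_max Upper bound of the eigengap search; `NULL` = auto.
#' @param laplacian `"normalized"` or `"unnormalized"`.
#' @param n_restarts k-means restarts.
#' @param seed Base seed for k-means initialization.
#' @param standardize Z-score features during alignment.
#' @param marginal_only If `TRUE`, use only the marginal kernels
#'   (`max_order = 1`) — the plain UMKL baseline without interactions.
#' @return An `imkl_config` list.
#' @export
imkl_config <- function(mu = 0.5, k_eps = NULL, max_order = NULL,
                        k_graph = 5L, k = NULL, k_max = NULL,
                        laplacian = c("normalized", "unnormalized"),
                        n_restarts = 50L, seed = 42L,
                        standardize = TRUE, marginal_only = FALSE) {
  laplacian <- match.arg(laplacian)
  if (mu <= 0) stop("mu must be > 0")
  structure(list(mu = mu, k_eps = k_eps, max_order = max_order,
                 k_graph = as.integer(k_graph), k = k, k_max = k_max,
                 laplacian = laplacian, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), standardize = standardize,
                 marginal_only = isTRUE(marginal_only)),
            class = "imkl_config")
}

#' Run the iMKL pipeline on aligned omics layers
#'
#' Executes the full method: (i) per-layer scaled exponential similarity
#' kernels; (ii) Hadamard interaction kernels over layer subsets; (iii)
#' simplex-constrained topology-preservation weights and fusion into the
#' meta-kernel; (iv) eigengap selection of the number of subtypes and
#' k-means on the meta-kernel rows.
#'
#' @param datasets List of aligned [omics_dataset()] objects sharing the
#'   same sample ordering (see [align_and_standardize()]).
#' @param config An [imkl_config()].
#' @return An `imkl_result` list: `assignment` (`cluster_assignment`),
#'   `weights` (`weight_vector`), `eigengap` (`eigengap_profile` or
#'   `NULL` when `k` was fixed), `meta_kernel`, `basis_names`,
#'   `sample_ids`, `config`.
#' @export
imkl_fit <- function(datasets, config = imkl_config()) {
  stopifnot(length(datasets) >= 1)
  ids <- datasets[[1]]$sample_ids
  for (d in datasets)
    if (!identical(d$sample_ids, ids))
      stop("datasets are not aligned; run align_and_standardize() first")
  n <- length(ids)
  k_eps <- config$k_eps %||% default_k_eps(n)
  if (k_eps >= n)
    stop("k_eps must be smaller than the number of samples")
  M <- length(datasets)
  max_order <- if (config$marginal_only) 1L else (config$max_order %||% M)
  max_order <- min(max_order, M)

  marginals <- marginal_kernels(datasets, mu = config$mu, k_eps = k_eps)
  basis <- build_kernel_basis(marginals, max_order = max_order)
  edge_sets <- lapply(basis, knn_graph_edges, k_graph = config$k_graph)
  W <- cooccurrence(edge_sets, n)
  S <- build_cost_matrix(basis, W)
  beta <- solve_simplex_qp(S)
  Kf <- fuse(basis, beta)

  profile <- NULL
  if (is.null(config$k)) {
    profile <- eigengap_select(Kf, k_max = config$k_max,
                               variant = config$laplacian)
    k <- profile$selected_k
  } else {
    k <- as.integer(config$k)
  }
  assignment <- kernel_rows_kmeans(Kf, k, seed = config$seed,
                                   n_restarts = config$n_restarts)
  structure(list(assignment = assignment, weights = beta,
                 eigengap = profile, meta_kernel = Kf,
                 basis_names = names(basis), sample_ids = ids,
                 config = config),
            class = "imkl_result")
}

#' @export
print.imkl_result <- function(x, ...) {
  cat(sprintf("<imkl_result> n = %d, k = %d%s\n",
              length(x$sample_ids), x$assignment$k,
              if (is.null(x$eigengap)) " (fixed)" else " (eigengap)"))
  print(x$weights)
  invisible(x)
}

#' Run iMKL from files to files
#'
#' File-level orchestration: reads the omics matrices, aligns and
#' standardizes them, fits iMKL, and writes `clusters.tsv` (sample_id,
#' cluster), `weights.tsv` (kernel, beta), `eigengap.tsv` (k, lambda,
#' gap), optionally `meta_kernel.tsv` and per-layer `aligned_<layer>.tsv`,
#' and `run.log` with every resolved parameter. On error, partial
#' outputs are removed.
#'
#' @param layer_paths Character vector of delimited-text matrix paths.
#' @param layer_names Layer labels (default `layer1..M`).
#' @param out_dir Output directory (created if missing).
#' @param orientation Matrix orientation, see [read_omics_matrix()].
#' @param impute Missing-value policy, see [align_and_standardize()].
#' @param config An [imkl_config()].
#' @param save_kernels Write the fused meta-kernel as TSV.
#' @param save_aligned Write the aligned, standardized layers as TSV.
#' @return The `imkl_result`, invisibly.
#' @export
run_imkl <- function(layer_paths, layer_names = NULL, out_dir = ".",
                     orientation = "samples_in_rows",
                     impute = "reject",
                     config = imkl_config(),
                     save_kernels = FALSE, save_aligned = FALSE) {
  if (is.null(layer_names))
    layer_names <- paste0("layer", seq_along(layer_paths))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    stop(e)
  }
  tryCatch({
    datasets <- Map(read_omics_matrix, layer_paths, layer_names,
                    MoreArgs = list(orientation = orientation))
    datasets <- align_and_standardize(datasets, impute = impute,
                                      standardize = config$standardize)
    fit <- imkl_fit(datasets, config)

    path <- function(f) { p <- file.path(out_dir, f); written <<- c(written, p); p }
    utils::write.table(
      data.frame(sample_id = fit$sample_ids,
                 cluster = fit$assignment$labels),
      path("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(kernel = fit$basis_names, beta = as.numeric(fit$weights)),
      path("weights.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fit$eigengap)) {
      pr <- fit$eigengap
      utils::write.table(
        data.frame(k = seq_along(pr$gaps),
                   lambda = pr$eigenvalues[seq_along(pr$gaps)],
                   gap = pr$gaps),
        path("eigengap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (save_kernels)
      write_matrix_tsv(unclass(fit$meta_kernel), fit$sample_ids,
                       path("meta_kernel.tsv"))
    if (save_aligned)
      for (d in datasets)
        write_matrix_tsv(d$values, d$sample_ids,
                         path(sprintf("aligned_%s.tsv", d$layer_name)))
    log_lines <- c(
      sprintf("imkl run: %d layers, n = %d", length(datasets),
              length(fit$sample_ids)),
      sprintf("selected k = %d%s", fit$assignment$k,
              if (is.null(config$k)) " (eigengap)" else " (fixed)"),
      sprintf("weights: %s",
              paste(sprintf("%s=%.4f", fit$basis_names,
                            as.numeric(fit$weights)), collapse = " ")),
      sprintf("config: mu=%g k_eps=%s max_order=%s k_graph=%d k_max=%s laplacian=%s restarts=%d seed=%d standardize=%s marginal_only=%s",
              config$mu, config$k_eps %||% "auto",
              config$max_order %||% "auto", config$k_graph,
              config$k_max %||% "auto", config$laplacian,
              config$n_restarts, config$seed, config$standardize,
              config$marginal_only))
    writeLines(log_lines, path("run.log"))
    invisible(fit)
  }, error = on_fail)
}

write_matrix_tsv <- function(mat, ids, path) {
  df <- data.frame(sample_id = ids, mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
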