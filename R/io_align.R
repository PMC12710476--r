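#' Construct an omics dataset
#'
#' An `omics_dataset` is one omics layer: an `n x p` numeric matrix of
#' continuous measurements (samples in rows) with unique sample identifiers
#' and a layer name (e.g. `"miRNA"`, `"mRNA"`, `"methylation"`).
#'
#' @param values Numeric matrix, samples in rows.
#' @param sample_ids Character vector of unique sample identifiers, one per row.
#' @param layer_name Single string labelling the layer.
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(values, sample_ids, layer_name) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample IDs: ", paste(unique(dup), collapse = ", "))
  rownames(values) <- sample_ids
  structure(
    list(layer_name = as.character(layer_name)[1],
         sample_ids = sample_ids,
         values = values),
    class = "omics_dataset"
  )
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset> layer '%s': %d samples x %d features\n",
              x$layer_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) dim(x$values)

# tab if the header line contains a tab, else comma
detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an omics matrix from delimited text
#'
#' Reads a TSV/CSV matrix with one ID header row and one ID column and
#' returns it in samples-in-rows orientation. The delimiter is
#' auto-detected from the header line (tab if present, else comma).
#'
#' @param path Path to a delimited text file.
#' @param layer_name Label for the layer.
#' @param orientation `"samples_in_rows"` (IDs in the first column) or
#'   `"samples_in_columns"` (IDs in the header row).
#' @return An [omics_dataset()].
#' @export
read_omics_matrix <- function(path, layer_name,
                              orientation = c("samples_in_rows",
                                              "samples_in_columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("cannot read file: ", path)
  sep <- detect_delim(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 2) stop("file has no data columns: ", path)
  ids_col <- as.character(tab[[1]])
  mat <- tab[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    col <- mat[[j]]
    if (is.character(col) || is.factor(col)) {
      num <- suppressWarnings(as.numeric(as.character(col)))
      bad <- which(is.na(num) & !is.na(col) &
                     !(trimws(as.character(col)) %in% c("NA", "")))
      if (length(bad))
        stop(sprintf("non-numeric cell in '%s' at row %d, column '%s': '%s'",
                     path, bad[1], colnames(mat)[j], col[bad[1]]))
      mat[[j]] <- num
    }
  }
  mat <- as.matrix(mat)
  if (orientation == "samples_in_rows") {
    sample_ids <- ids_col
    feature_ids <- colnames(mat)
  } else {
    sample_ids <- colnames(mat)
    feature_ids <- ids_col
    mat <- t(mat)
  }
  colnames(mat) <- feature_ids
  omics_dataset(mat, sample_ids, layer_name)
}

#' Read a survival table
#'
#' Expects three delimited columns: sample ID, follow-up time
#' (nonnegative, study time units) and event indicator (1 = event,
#' 0 = censored).
#'
#' @param path Path to a delimited text file with a header.
#' @return A `data.frame` of class `survival_table` with columns
#'   `sample_id`, `time`, `event`.
#' @export
read_survival_table <- function(path) {
  sep <- detect_delim(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("survival table needs 3 columns (id, time, event)")
  survival_table(tab[[1]], tab[[2]], tab[[3]])
}

#' @rdname read_survival_table
#' @param sample_ids,time,event Vectors of equal length.
#' @export
survival_table <- function(sample_ids, time, event) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be >= 0")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  out <- data.frame(sample_id = as.character(sample_ids),
                    time = time, event = event,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Align samples across omics layers and standardize features
#'
#' Restricts every layer to the sorted intersection of sample IDs
#' (deterministic ordering, independent of input file order), optionally
#' mean-imputes missing values, drops zero-variance features, and
#' z-scores each retained feature to mean 0 / sd 1. Scaling matters
#' because the Euclidean-distance kernel downstream is scale-sensitive.
#'
#' @param datasets List of [omics_dataset()] objects (>= 2).
#' @param impute `"reject"` (error on any missing value, the default) or
#'   `"feature_mean"` (impute per-feature means over retained samples).
#' @param standardize Logical; set `FALSE` to skip z-scoring (features
#'   are still aligned and zero-variance features still dropped).
#' @return List of aligned `omics_dataset` objects sharing an identical
#'   sample ordering.
#' @export
align_and_standardize <- function(datasets,
                                  impute = c("reject", "feature_mean"),
                                  standardize = TRUE) {
  impute <- match.arg(impute)
  if (length(datasets) < 2) stop("need at least 2 omics layers")
  ids <- Reduce(intersect, lapply(datasets, function(d) d$sample_ids))
  ids <- sort(ids)
  if (length(ids) < 3)
    stop("sample intersection across layers has fewer than 3 samples")
  lapply(datasets, function(d) {
    x <- d$values[ids, , drop = FALSE]
    if (anyNA(x)) {
      if (impute == "reject") {
        idx <- which(is.na(x), arr.ind = TRUE)[1, ]
        stop(sprintf(
          "missing value in layer '%s', sample '%s', feature '%s'",
          d$layer_name, rownames(x)[idx[1]],
          colnames(x)[idx[2]] %||% as.character(idx[2])))
      }
      mu <- colMeans(x, na.rm = TRUE)
      for (j in which(colSums(is.na(x)) > 0))
        x[is.na(x[, j]), j] <- mu[j]
    }
    if (any(!is.finite(x)))
      stop(sprintf("non-finite value in layer '%s'", d$layer_name))
    sds <- apply(x, 2, stats::sd)
    keep <- is.finite(sds) & sds > 0
    if (!all(keep))
      message(sprintf("layer '%s': dropped %d zero-variance feature(s)",
                      d$layer_name, sum(!keep)))
    x <- x[, keep, drop = FALSE]
    if (ncol(x) == 0)
      stop(sprintf("layer '%s': all features dropped", d$layer_name))
    if (standardize)
      x <- scale(x)[, , drop = FALSE]
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    omics_dataset(x, ids, d$layer_name)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
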