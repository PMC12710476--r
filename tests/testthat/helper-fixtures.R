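# deterministic fixtures shared across test files

rand_dataset <- function(n, p, seed, layer = "x") {
  set.seed(seed)
  omics_dataset(matrix(rnorm(n * p), n, p),
                sprintf("s%03d", seq_len(n)), layer)
}

# a valid marginal kernel from random data
rand_kernel <- function(n, p = 8, seed = 1, layer_index = 1L) {
  scaled_exponential_kernel(pairwise_euclidean(rand_dataset(n, p, seed)),
                            layer_index = layer_index)
}

# plain block-structured similarity matrix (b equal blocks)
block_matrix <- function(b, block_size, within = 1, between = 1e-6) {
  n <- b * block_size
  lab <- rep(seq_len(b), each = block_size)
  K <- matrix(between, n, n)
  K[outer(lab, lab, "==")] <- within
  diag(K) <- 1
  K
}

# marginal kernels from clearly clustered Gaussian data
clustered_kernel <- function(n, k, delta, p = 30, seed = 1, layer_index = 1L) {
  set.seed(seed)
  lab <- rep(seq_len(k), length.out = n)
  pat <- matrix(sign(rnorm(k * p)), k, p)
  X <- matrix(rnorm(n * p), n, p) + delta * pat[lab, ]
  list(kernel = scaled_exponential_kernel(
         pairwise_euclidean(omics_dataset(X, sprintf("s%03d", 1:n), "x")),
         layer_index = layer_index),
       labels = lab)
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
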