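#' Specify a synthetic multi-omics study
#'
#' Describes a generated multi-layer continuous dataset with planted
#' subtype structure. The Gaussian layers stand in for log-scale
#' expression and M-value methylation matrices; only the cluster
#' structure the method consumes is emulated, not platform noise.
#'
#' Two signal modes:
#' \describe{
#'   \item{`marginal`}{each layer's informative features of subtype `c`
#'     are mean-shifted by `delta * v_c`, where `v_c` is a fixed
#'     subtype-specific pattern of +-1 signs; every layer carries the
#'     subtype signal.}
#'   \item{`interaction_xor`}{(requires `k_true = 2`, `M >= 2`) samples
#'     carry independent balanced latent binary blocks `a` (layer 1) and
#'     `b` (layer 2); layer 1's informative features shift by `a *
#'     delta`, layer 2's by `b * delta`, remaining layers are pure
#'     noise, and the true subtype is `xor(a, b)` — so no single layer's
#'     marginal structure aligns with the subtype, only cross-layer
#'     interaction does.}
#' }
#'
#' @param n Number of samples.
#' @param k_true True number of subtypes (>= 2).
#' @param layers List of per-layer settings, each a list with elements
#'   `p` (features), `p_informative`, `delta` (mean shift in noise-sd
#'   units) and `sigma` (noise sd). Default: three layers of 100
#'   features, 20% informative, `delta = 2`, `sigma = 1`.
#' @param mode `"marginal"` or `"interaction_xor"`.
#' @param survival Optional list with `baseline_hazard`, `hazard_ratios`
#'   (one per subtype) and `censoring_rate` (target fraction in [0, 1)).
#' @param seed Integer seed; identical specs + seeds give bit-identical
#'   data.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 150L, k_true = 3L,
                           layers = NULL,
                           mode = c("marginal", "interaction_xor"),
                           survival = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(layers))
    layers <- replicate(3, list(p = 100L, p_informative = 20L,
                                delta = 2, sigma = 1), simplify = FALSE)
  n <- as.integer(n); k_true <- as.integer(k_true)
  if (n < k_true || k_true < 2) stop("need n >= k_true >= 2")
  for (ly in layers) {
    if (ly$p_informative < 0 || ly$p_informative > ly$p)
      stop("p_informative must be in 0..p")
    if (ly$sigma <= 0) stop("sigma must be > 0")
  }
  if (mode == "interaction_xor") {
    if (k_true != 2) stop("interaction_xor mode requires k_true = 2")
    if (length(layers) < 2) stop("interaction_xor mode requires M >= 2 layers")
  }
  if (!is.null(survival)) {
    if (length(survival$hazard_ratios) != k_true)
      stop("need one hazard ratio per subtype")
    if (any(survival$hazard_ratios <= 0) || survival$baseline_hazard <= 0)
      stop("hazards must be positive")
    cr <- survival$censoring_rate %||% 0
    if (cr < 0 || cr >= 1) stop("censoring_rate must be in [0, 1)")
  }
  structure(list(n = n, k_true = k_true, layers = layers, mode = mode,
                 survival = survival, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic multi-omics dataset with known subtypes
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `datasets` (list of [omics_dataset()]) and
#'   `truth` (list with `labels`, `latent_blocks` — an `n x 2` 0/1
#'   matrix in `interaction_xor` mode, `NULL` otherwise — and
#'   `survival_table` or `NULL`).
#' @export
generate_multiomics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n; k <- spec$k_true; M <- length(spec$layers)
  ids <- sprintf("S%04d", seq_len(n))
  latent_blocks <- NULL

  if (spec$mode == "marginal") {
    labels <- sample(rep(seq_len(k), length.out = n))
    shift_scale <- NULL
  } else {
    a <- sample(rep(0:1, length.out = n))
    b <- sample(rep(0:1, length.out = n))
    labels <- as.integer(xor(a == 1, b == 1)) + 1L
    latent_blocks <- cbind(a = a, b = b)
    # layer 1 sees only a, layer 2 only b, further layers see nothing
    shift_scale <- c(list(a, b),
                     replicate(max(0, M - 2), rep(0, n), simplify = FALSE))
  }

  datasets <- vector("list", M)
  for (m in seq_len(M)) {
    ly <- spec$layers[[m]]
    p <- as.integer(ly$p); pi_ <- as.integer(ly$p_informative)
    x <- matrix(stats::rnorm(n * p, sd = ly$sigma), n, p)
    if (pi_ > 0) {
      if (spec$mode == "marginal") {
        v <- distinct_sign_patterns(k, pi_)
        x[, seq_len(pi_)] <- x[, seq_len(pi_)] + ly$delta * v[labels, , drop = FALSE]
      } else {
        x[, seq_len(pi_)] <- x[, seq_len(pi_)] +
          ly$delta * matrix(shift_scale[[m]], n, pi_)
      }
    }
    colnames(x) <- sprintf("f%d_%03d", m, seq_len(p))
    datasets[[m]] <- omics_dataset(x, ids, paste0("layer", m))
  }

  surv <- NULL
  if (!is.null(spec$survival)) {
    sv <- spec$survival
    surv <- generate_survival(labels,
                              baseline_hazard = sv$baseline_hazard,
                              hazard_ratios = sv$hazard_ratios,
                              censoring_rate = sv$censoring_rate %||% 0,
                              seed = spec$seed + 10000L,
                              sample_ids = ids)
  }
  list(datasets = datasets,
       truth = list(labels = labels, latent_blocks = latent_blocks,
                    survival_table = surv))
}

# k distinct rows of +-1 signs of length p (resample collisions)
distinct_sign_patterns <- function(k, p) {
  v <- matrix(sign(stats::rnorm(k * p)), k, p)
  v[v == 0] <- 1
  if (p >= 2) {
    for (tries in 1:100) {
      key <- apply(v, 1, paste, collapse = "")
      dup <- which(duplicated(key))
      if (!length(dup)) break
      v[dup, ] <- sign(stats::rnorm(length(dup) * p))
      v[v == 0] <- 1
    }
  }
  v
}

#' Generate cluster-dependent survival times
#'
#' Event times are exponential with hazard `baseline_hazard *
#' hazard_ratios[cluster]`. Censoring times are independent
#' `Uniform(0, u)` with `u` calibrated (by root finding on the expected
#' censoring fraction of the exponential/uniform mixture) so the
#' empirical censoring fraction approximates `censoring_rate`.
#'
#' @param labels Integer cluster label per sample.
#' @param baseline_hazard Positive baseline hazard per unit time.
#' @param hazard_ratios Positive hazard ratio per cluster.
#' @param censoring_rate Target censored fraction in [0, 1); 0 gives
#'   fully observed event times.
#' @param seed Integer seed.
#' @param sample_ids Optional IDs; defaults to `S0001...`.
#' @return A [survival_table()].
#' @export
generate_survival <- function(labels, baseline_hazard = 0.1,
                              hazard_ratios = NULL, censoring_rate = 0,
                              seed = 1L, sample_ids = NULL) {
  labels <- as.integer(labels)
  k <- max(labels)
  if (is.null(hazard_ratios)) hazard_ratios <- rep(1, k)
  if (length(hazard_ratios) < k)
    stop("need one hazard ratio per cluster")
  if (any(hazard_ratios <= 0) || baseline_hazard <= 0)
    stop("hazards must be positive")
  n <- length(labels)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  set.seed(as.integer(seed))
  rate <- baseline_hazard * hazard_ratios[labels]
  event_time <- stats::rexp(n, rate = rate)
  if (censoring_rate <= 0)
    return(survival_table(sample_ids, event_time, rep(1L, n)))
  # P(censored | rate r, C ~ U(0,u)) = (1 - exp(-r u)) / (r u)
  cens_frac <- function(u) mean((1 - exp(-rate * u)) / (rate * u))
  lo <- 1e-8 / max(rate); hi <- 1
  while (cens_frac(hi) > censoring_rate && hi < 1e12) hi <- hi * 2
  u <- stats::uniroot(function(x) cens_frac(x) - censoring_rate,
                      lower = lo, upper = hi, tol = 1e-10)$root
  cens_time <- stats::runif(n, 0, u)
  time <- pmin(event_time, cens_time)
  event <- as.integer(event_time <= cens_time)
  survival_table(sample_ids, time, event)
}
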