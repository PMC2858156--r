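#' Simulation configuration
#'
#' Parameters of the in-silico benchmark generator: sparse stable linear
#' networks and noisy steady-state responses to single-gene unit
#' perturbations.
#'
#' @param n_genes number of genes N.
#' @param avg_in_degree expected number of off-diagonal regulators per gene
#'   (each off-diagonal edge is present independently with probability
#'   `avg_in_degree / (n_genes - 1)`).
#' @param weight_low,weight_high bounds of the uniform distribution of edge
#'   magnitudes before sign assignment and stability rescaling.
#' @param noise_sd measurement-noise standard deviation expressed as a
#'   fraction of the root-mean-square of the noise-free expression signal;
#'   0 disables noise.
#' @param n_experiments number of single-gene perturbation experiments
#'   (experiment l perturbs gene l); must not exceed `n_genes`.  Default:
#'   one experiment per gene.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes, avg_in_degree = 10, weight_low = 0.5,
                       weight_high = 1, noise_sd = 0.1,
                       n_experiments = n_genes, seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_experiments <- as.integer(n_experiments)
  if (is.na(n_genes) || n_genes < 2L) stop("n_genes must be at least 2")
  if (avg_in_degree < 0 || avg_in_degree > n_genes - 1L)
    stop("avg_in_degree must lie in [0, n_genes - 1]")
  if (weight_low <= 0 || weight_high < weight_low)
    stop("need 0 < weight_low <= weight_high")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.na(n_experiments) || n_experiments < 1L ||
      n_experiments > n_genes)
    stop("n_experiments must lie in [1, n_genes]")
  structure(list(n_genes = n_genes, avg_in_degree = avg_in_degree,
                 weight_low = weight_low, weight_high = weight_high,
                 noise_sd = noise_sd, n_experiments = n_experiments,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random sparse stable linear network
#'
#' Each off-diagonal influence (i, j) is present independently with
#' probability `avg_in_degree / (n_genes - 1)`; present edges get a
#' magnitude uniform in `[weight_low, weight_high]` and an equiprobable
#' sign.  The diagonal (self-degradation) is fixed at -1, and each row's
#' off-diagonal entries are rescaled, when needed, so their absolute sum is
#' at most 0.9: strict diagonal dominance guarantees the matrix is
#' invertible and the steady state stable.
#'
#' @param config a [sim_config()].
#' @return A [gene_network()] whose weight matrix is the generating
#'   influence matrix A (including the -1 diagonal).
#' @export
random_network <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  n <- config$n_genes
  set.seed(config$seed)
  p <- config$avg_in_degree / (n - 1)
  mask <- matrix(stats::runif(n * n) < p, n, n)
  diag(mask) <- FALSE
  m <- sum(mask)
  a <- matrix(0, n, n)
  if (m > 0) {
    mag <- stats::runif(m, config$weight_low, config$weight_high)
    sgn <- ifelse(stats::runif(m) < 0.5, -1, 1)
    a[mask] <- mag * sgn
  }
  rs <- rowSums(abs(a))
  scale <- ifelse(rs > 0.9, 0.9 / rs, 1)
  a <- a * scale  # vector recycling scales row i by scale[i]
  diag(a) <- -1
  gene_network(a, paste0("g", seq_len(n)))
}

#' Simulate noisy steady-state responses to single-gene perturbations
#'
#' Builds the canonical perturbation design (experiment l applies a unit
#' perturbation to gene l) and solves the steady-state condition
#' `A x_l + p_l = 0` for each experiment, i.e. `X = -A^{-1} P`.  Zero-mean
#' Gaussian noise with standard deviation `noise_sd` times the root mean
#' square of the noise-free signal is then added entrywise.
#'
#' @param A a [gene_network()] holding the generating influence matrix
#'   (invertible; guaranteed for [random_network()] output).
#' @param config the [sim_config()] used to generate `A` (supplies
#'   `n_experiments`, `noise_sd` and the seed for the noise draw).
#' @return A list with elements `expression` ([expression_matrix()]) and
#'   `perturbation` ([perturbation_design()], canonical).
#' @export
steady_state_data <- function(A, config) {
  if (!inherits(A, "gene_network")) stop("A must be a gene_network")
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  n <- length(A$gene_ids)
  if (n != config$n_genes)
    stop("network size does not match config$n_genes")
  m <- config$n_experiments
  P <- matrix(0, n, m)
  P[cbind(seq_len(m), seq_len(m))] <- 1
  W <- as.matrix(A$weights)
  X0 <- tryCatch(solve(W, -P),
                 error = function(e)
                   stop("generating network matrix is singular: ",
                        conditionMessage(e)))
  X <- X0
  if (config$noise_sd > 0) {
    set.seed(config$seed + 1000003L)  # independent of the topology draw
    rms <- sqrt(mean(X0^2))
    X <- X0 + matrix(stats::rnorm(n * m, sd = config$noise_sd * rms), n, m)
  }
  exp_ids <- paste0("e", seq_len(m))
  list(expression = expression_matrix(X, A$gene_ids, exp_ids),
       perturbation = perturbation_design(P, A$gene_ids, exp_ids))
}
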