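#' Inference configuration
#'
#' @param k positive integer, maximum number of ingoing edges per gene (the
#'   sparsity bound of the per-gene regression).
#' @param beam_width positive integer, number of candidate regulator sets
#'   retained at each growth step of the greedy search; defaults to `k`.
#' @param workers positive integer, number of parallel worker processes for
#'   the gene loop.  Results are identical for every worker count.
#' @param allow_self logical; whether a gene may be selected as its own
#'   regulator.  The default `TRUE` matches the model, whose degradation
#'   term is a self-influence; self-edges compete for the k slots like any
#'   other regulator.
#' @return An object of class `nir_config`.
#' @export
nir_config <- function(k, beam_width = k, workers = 1L, allow_self = TRUE) {
  k <- as.integer(k)
  beam_width <- as.integer(beam_width)
  workers <- as.integer(workers)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a positive integer")
  if (length(beam_width) != 1L || is.na(beam_width) || beam_width < 1L)
    stop("beam_width must be a positive integer")
  if (length(workers) != 1L || is.na(workers) || workers < 1L)
    stop("workers must be a positive integer")
  structure(list(k = k, beam_width = beam_width, workers = workers,
                 allow_self = isTRUE(allow_self)),
            class = "nir_config")
}

candidate_pool <- function(n, gene, allow_self) {
  if (allow_self) seq_len(n) else setdiff(seq_len(n), gene)
}

check_k_vs_pool <- function(k, pool_size) {
  if (k > pool_size)
    stop("k (", k, ") exceeds the number of candidate regulators (",
         pool_size, "); lower k or enlarge the gene set")
  invisible(TRUE)
}

#' Greedy beam search for the best k-regulator set of one gene
#'
#' Implements the forward-selection heuristic: step 1 fits every
#' single-regressor model and keeps the `beam_width` best by residual sum of
#' squares; each later step extends every surviving set with every unused
#' candidate, merges duplicate sets arising from different parents,
#' evaluates each via [subset_least_squares()], and again keeps the
#' `beam_width` best.  After step `k` the size-k set with minimal rss wins;
#' rss ties (within 1e-12 relative) go to the lexicographically smallest
#' subset so results are deterministic.  Singular candidate sets are
#' excluded from the beam.
#'
#' @param gene target gene index (1-based).
#' @param G a [compute_gram()] result.
#' @param proj the [response_projection()] for `gene`.
#' @param config an [nir_config()].
#' @return An object of class `subset_solution` (fields `gene`, `subset`,
#'   `coefficients`, `rss`, and `n_evals`, the number of candidate
#'   evaluations performed) or, when every size-k candidate is singular, an
#'   object of class `gene_failure` with an empty subset.
#' @export
greedy_gene_regression <- function(gene, G, proj, config) {
  if (!inherits(G, "gram_matrix")) stop("G must be a gram_matrix")
  if (!inherits(proj, "response_projection"))
    stop("proj must be a response_projection")
  if (!inherits(config, "nir_config")) stop("config must be an nir_config")
  n <- length(G$gene_ids)
  gene <- as.integer(gene)
  if (gene < 1L || gene > n) stop("gene index out of range: ", gene)
  pool <- candidate_pool(n, gene, config$allow_self)
  check_k_vs_pool(config$k, length(pool))
  res <- cpp_greedy_gene(G$values, proj$xty, proj$yty, pool - 1L,
                         config$k, config$beam_width)
  if (isTRUE(res$failed)) {
    return(structure(list(gene = gene, subset = integer(0),
                          coefficients = numeric(0), rss = NA_real_,
                          n_evals = res$n_evals),
                     class = "gene_failure"))
  }
  structure(list(gene = gene, subset = as.integer(res$subset),
                 coefficients = as.numeric(res$coefficients),
                 rss = res$rss, n_evals = res$n_evals),
            class = "subset_solution")
}

#' Infer a gene regulatory network from perturbation steady-state data
#'
#' Runs the full pipeline: computes the Gram matrix once, then for each
#' gene projects the response (`y = -p_i`) and runs the greedy beam search
#' for its best set of at most `k` regulators.  The fitted coefficients are
#' the signed edge weights `a_ij` of regulator j on target i.  Coefficients
#' that are numerically zero relative to the gene's largest coefficient
#' (factor 1e-8) are dropped, so on noise-free data the recovered in-degree
#' equals the true one even when `k` exceeds it.
#'
#' Genes for which every size-k candidate set is singular are reported with
#' an empty regulator set in the `failures` attribute of the result rather
#' than aborting the run.  The result is independent of `config$workers`.
#'
#' @param X an [expression_matrix()].
#' @param P the matched [perturbation_design()].
#' @param config an [nir_config()].
#' @return A [gene_network()]; attribute `failures` holds the gene ids (if
#'   any) whose regression failed.
#' @examples
#' cfg <- sim_config(n_genes = 12, avg_in_degree = 2, noise_sd = 0, seed = 1)
#' truth <- random_network(cfg)
#' dat <- steady_state_data(truth, cfg)
#' net <- infer_network(dat$expression, dat$perturbation, nir_config(k = 4))
#' @export
infer_network <- function(X, P, config) {
  check_matched_pair(X, P)
  if (!inherits(config, "nir_config")) stop("config must be an nir_config")
  n <- length(X$gene_ids)
  check_k_vs_pool(config$k, if (config$allow_self) n else n - 1L)
  G <- compute_gram(X)
  task <- function(i) {
    proj <- response_projection(X, P, i)
    greedy_gene_regression(i, G, proj, config)
  }
  results <- run_parallel(seq_len(n), config$workers, task)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  failures <- character(0)
  for (r in results) {
    if (inherits(r, "gene_failure")) {
      failures <- c(failures, X$gene_ids[r$gene])
      next
    }
    b <- r$coefficients
    keep <- abs(b) > 1e-8 * max(abs(b))  # drop numerically-zero slots
    if (!any(keep)) next
    ii <- c(ii, rep.int(r$gene, sum(keep)))
    jj <- c(jj, r$subset[keep])
    ww <- c(ww, b[keep])
  }
  w <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n),
                            dimnames = list(X$gene_ids, X$gene_ids))
  net <- gene_network(w, X$gene_ids)
  attr(net, "failures") <- failures
  net
}

#' Run a per-gene task across a pool of worker processes
#'
#' Partitions the gene list into near-equal contiguous blocks, one per
#' worker, evaluates `per_gene_task` on every gene, and reassembles results
#' in the original gene order.  The genes are independent (no inter-gene
#' communication), so the output is invariant to `worker_count`; a plain
#' serial loop is used when `worker_count` is 1 or process forking is not
#' available.
#'
#' @param genes vector of gene indices.
#' @param worker_count positive integer.
#' @param per_gene_task function of one gene index.
#' @return A list of per-gene results in the order of `genes`.
#' @export
run_parallel <- function(genes, worker_count, per_gene_task) {
  worker_count <- as.integer(worker_count)
  if (length(worker_count) != 1L || is.na(worker_count) || worker_count < 1L)
    stop("worker_count must be a positive integer")
  n <- length(genes)
  if (n == 0L) return(list())
  w <- min(worker_count, n)
  sizes <- rep.int(n %/% w, w)
  extra <- n %% w
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  blocks <- split(genes, factor(rep.int(seq_len(w), sizes),
                                levels = seq_len(w)))
  run_block <- function(b) {
    lapply(b, function(g) {
      tryCatch(per_gene_task(g),
               error = function(e) structure(
                 list(gene = g, message = conditionMessage(e)),
                 class = "nir_worker_error"))
    })
  }
  out <- if (w > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(blocks, run_block, mc.cores = w)
  } else {
    lapply(blocks, run_block)
  }
  for (b in out) {
    if (inherits(b, "try-error"))
      stop("a worker process failed: ", as.character(b))
  }
  res <- unlist(out, recursive = FALSE, use.names = FALSE)
  for (r in res) {
    if (inherits(r, "nir_worker_error"))
      stop("worker failed on gene ", r$gene, ": ", r$message)
  }
  res
}
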