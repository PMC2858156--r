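#' Precompute the Gram matrix of gene expression profiles
#'
#' Computes `G = X X'`, the N x N matrix of inner products of gene profiles
#' across experiments, once per data set.  Every candidate subset regression
#' afterwards only extracts a small symmetric submatrix of `G`, so the
#' per-candidate cost no longer depends on the number of experiments.
#'
#' @param X an [expression_matrix()].
#' @return An object of class `gram_matrix` with fields `gene_ids` and
#'   `values` (symmetric positive semidefinite N x N matrix).
#' @export
compute_gram <- function(X) {
  if (!inherits(X, "expression_matrix"))
    stop("X must be an expression_matrix")
  G <- tcrossprod(X$values)
  G <- (G + t(G)) / 2  # enforce exact symmetry
  structure(list(gene_ids = X$gene_ids, values = G), class = "gram_matrix")
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat("gram_matrix:", length(x$gene_ids), "x", length(x$gene_ids), "\n")
  invisible(x)
}

#' Project the regression response for one target gene
#'
#' At steady state the model reads `A x + p = 0`, so the response regressed
#' on the transcript profiles for target gene i is `y = -p_i` (the i-th row
#' of the perturbation design, sign-flipped) and the fitted coefficients are
#' the influences `a_ij` directly.  This operation reduces the response to
#' the two Gram-side quantities the subset solver needs: `xty = X y'` and
#' `yty = y y'`.  When the design is canonical (one unit perturbation per
#' experiment) `xty` is just the sign-flipped sum of the expression columns
#' of the experiments that perturb the gene, avoiding the matrix product.
#'
#' @param X an [expression_matrix()].
#' @param P the matched [perturbation_design()].
#' @param gene target gene index (1-based).
#' @return An object of class `response_projection` with fields `xty`
#'   (length N), `yty` (scalar >= 0) and `gene`.
#' @export
response_projection <- function(X, P, gene) {
  check_matched_pair(X, P)
  n <- length(X$gene_ids)
  gene <- as.integer(gene)
  if (length(gene) != 1L || is.na(gene) || gene < 1L || gene > n)
    stop("gene index out of range: ", gene)
  p <- P$values[gene, ]
  if (isTRUE(P$canonical)) {
    hit <- which(p != 0)
    xty <- if (length(hit) == 0) numeric(n) else
      unname(-rowSums(X$values[, hit, drop = FALSE]))
    yty <- as.numeric(length(hit))  # unit magnitudes
  } else {
    y <- -p
    xty <- as.vector(X$values %*% y)
    yty <- sum(y * y)
  }
  structure(list(xty = xty, yty = yty, gene = gene),
            class = "response_projection")
}

#' Least-squares fit of one regulator subset via the Gram matrix
#'
#' Extracts the symmetric submatrix `G_S` for the regulator subset, solves
#' the normal equations `G_S b = (X y')_S` by Cholesky factorization (no
#' matrix inversion, no re-touching of the expression data), and evaluates
#' the residual sum of squares algebraically as `rss = y y' - b' (X y')_S`,
#' clamped at 0.
#'
#' @param G a [compute_gram()] result.
#' @param proj a [response_projection()] for the target gene.
#' @param subset non-empty, strictly increasing vector of regulator indices
#'   (1-based).
#' @return An object of class `subset_solution` with fields `subset`,
#'   `coefficients` and `rss` — or, when `G_S` is not positive definite
#'   (linearly dependent regressors), an object of class
#'   `singular_candidate` carrying the offending subset.
#' @export
subset_least_squares <- function(G, proj, subset) {
  if (!inherits(G, "gram_matrix")) stop("G must be a gram_matrix")
  if (!inherits(proj, "response_projection"))
    stop("proj must be a response_projection")
  subset <- as.integer(subset)
  n <- length(G$gene_ids)
  if (length(subset) == 0L) stop("subset must be non-empty")
  if (anyNA(subset) || any(subset < 1L) || any(subset > n))
    stop("subset indices out of range")
  if (is.unsorted(subset, strictly = TRUE))
    stop("subset must be strictly increasing")
  res <- cpp_subset_solve(G$values, proj$xty, proj$yty, subset - 1L)
  if (isTRUE(res$singular))
    return(structure(list(subset = subset), class = "singular_candidate"))
  structure(list(subset = subset,
                 coefficients = as.numeric(res$coefficients),
                 rss = res$rss),
            class = "subset_solution")
}

#' @export
print.subset_solution <- function(x, ...) {
  cat("subset_solution: regulators {", paste(x$subset, collapse = ", "),
      "}, rss =", format(x$rss), "\n")
  invisible(x)
}

#' @export
print.singular_candidate <- function(x, ...) {
  cat("singular_candidate: regulators {", paste(x$subset, collapse = ", "),
      "} are linearly dependent\n")
  invisible(x)
}
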