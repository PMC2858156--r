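#' Construct an expression deviation matrix
#'
#' Container for the regressor data of the network model: an N genes x
#' M experiments matrix of transcript-level expression deviations from the
#' unperturbed steady state.  Rows are genes (the candidate regulators),
#' columns are perturbation experiments.
#'
#' @param values numeric matrix, N genes x M experiments, all finite.
#' @param gene_ids character vector of N unique gene identifiers; defaults
#'   to the rownames of `values`.
#' @param experiment_ids character vector of M unique experiment
#'   identifiers; defaults to the colnames of `values`.
#' @return An object of class `expression_matrix` with fields `gene_ids`,
#'   `experiment_ids` and `values`.
#' @examples
#' X <- expression_matrix(diag(2), c("g1", "g2"), c("e1", "e2"))
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              experiment_ids = colnames(values)) {
  lab <- check_labeled_matrix(values, gene_ids, experiment_ids,
                              min_rows = 2L, what = "expression matrix")
  structure(list(gene_ids = lab$gene_ids,
                 experiment_ids = lab$experiment_ids,
                 values = lab$values),
            class = "expression_matrix")
}

#' Construct a perturbation design matrix
#'
#' Container for the response data: the N x M matrix of applied perturbation
#' magnitudes, entry (i, l) being the perturbation applied to gene i in
#' experiment l.  The design is flagged `canonical` when every experiment
#' perturbs exactly one gene with magnitude 1, which enables a shortcut in
#' [response_projection()].
#'
#' @inheritParams expression_matrix
#' @return An object of class `perturbation_design` with fields `gene_ids`,
#'   `experiment_ids`, `values` and logical `canonical` (auto-detected).
#' @examples
#' P <- perturbation_design(diag(2), c("g1", "g2"), c("e1", "e2"))
#' P$canonical  # TRUE: one unit perturbation per experiment
#' @export
perturbation_design <- function(values,
                                gene_ids = rownames(values),
                                experiment_ids = colnames(values)) {
  lab <- check_labeled_matrix(values, gene_ids, experiment_ids,
                              min_rows = 2L, what = "perturbation design")
  nz_per_exp <- colSums(lab$values != 0)
  canonical <- all(nz_per_exp == 1) && all(lab$values %in% c(0, 1))
  structure(list(gene_ids = lab$gene_ids,
                 experiment_ids = lab$experiment_ids,
                 values = lab$values,
                 canonical = canonical),
            class = "perturbation_design")
}

#' Construct a gene regulatory network
#'
#' A signed, weighted, directed network over a fixed gene set.  Entry
#' (i, j) of `weights` is the influence of regulator gene j on target gene
#' i; zero entries are absent edges and are stored sparsely.
#'
#' @param weights square numeric matrix (dense or `Matrix` sparse), N x N;
#'   all entries finite.
#' @param gene_ids character vector of N unique gene identifiers; defaults
#'   to the rownames of `weights`.
#' @return An object of class `gene_network` with fields `gene_ids` and
#'   `weights` (a `dgCMatrix` with explicit zeros dropped).
#' @examples
#' w <- matrix(0, 2, 2); w[1, 2] <- -0.5
#' net <- gene_network(w, c("g1", "g2"))  # g2 represses g1
#' @export
gene_network <- function(weights, gene_ids = rownames(weights)) {
  if (is.null(gene_ids)) stop("gene_ids are required for a gene_network")
  gene_ids <- as.character(gene_ids)
  if (nrow(weights) != ncol(weights))
    stop("network weight matrix must be square")
  if (length(gene_ids) != nrow(weights))
    stop("gene_ids length does not match the weight matrix dimension")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene label: ", gene_ids[duplicated(gene_ids)][1])
  w <- methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (any(!is.finite(w@x))) stop("network weights must all be finite")
  w <- Matrix::drop0(w)
  dimnames(w) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, weights = w), class = "gene_network")
}

# Shared validation for labeled numeric matrices.
check_labeled_matrix <- function(values, gene_ids, experiment_ids,
                                 min_rows, what) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop(what, ": values must be numeric")
  if (nrow(values) < min_rows)
    stop(what, ": need at least ", min_rows, " genes, got ", nrow(values))
  if (ncol(values) < 1L) stop(what, ": need at least 1 experiment")
  if (any(!is.finite(values))) stop(what, ": all values must be finite")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(experiment_ids))
    experiment_ids <- paste0("e", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  experiment_ids <- as.character(experiment_ids)
  if (length(gene_ids) != nrow(values))
    stop(what, ": gene_ids length does not match the number of rows")
  if (length(experiment_ids) != ncol(values))
    stop(what, ": experiment_ids length does not match the number of columns")
  if (anyDuplicated(gene_ids))
    stop(what, ": duplicate gene label: ", gene_ids[duplicated(gene_ids)][1])
  if (anyDuplicated(experiment_ids))
    stop(what, ": duplicate experiment label: ",
         experiment_ids[duplicated(experiment_ids)][1])
  dimnames(values) <- list(gene_ids, experiment_ids)
  list(values = values, gene_ids = gene_ids, experiment_ids = experiment_ids)
}

check_matched_pair <- function(X, P) {
  if (!inherits(X, "expression_matrix"))
    stop("X must be an expression_matrix")
  if (!inherits(P, "perturbation_design"))
    stop("P must be a perturbation_design")
  if (!identical(X$gene_ids, P$gene_ids))
    stop("expression and perturbation gene labels differ")
  if (!identical(X$experiment_ids, P$experiment_ids))
    stop("expression and perturbation experiment labels differ")
  invisible(TRUE)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", length(x$gene_ids), "genes x",
      length(x$experiment_ids), "experiments\n")
  invisible(x)
}

#' @export
print.perturbation_design <- function(x, ...) {
  cat("perturbation_design:", length(x$gene_ids), "genes x",
      length(x$experiment_ids), "experiments",
      if (x$canonical) "(canonical single-gene unit perturbations)" else "",
      "\n")
  invisible(x)
}

#' @export
print.gene_network <- function(x, ...) {
  n_edges <- length(x$weights@x)
  cat("gene_network:", length(x$gene_ids), "genes,", n_edges,
      "weighted directed edges\n")
  invisible(x)
}
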