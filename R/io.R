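#' Read a labeled expression or perturbation matrix from TSV
#'
#' The expected layout is the usual expression-table convention: a header
#' row of experiment labels (first cell is a corner label and is ignored),
#' one row per gene with the gene label in the first column, tab-delimited,
#' numeric body.
#'
#' @param path path to a TSV file.
#' @param kind `"expression"` or `"perturbation"`; selects the returned
#'   class.  For a perturbation design the canonical single-gene
#'   unit-perturbation flag is auto-detected.
#' @return An [expression_matrix()] or [perturbation_design()].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, kind = c("expression", "perturbation")) {
  kind <- match.arg(kind)
  tab <- read_labeled_tsv(path)
  if (kind == "expression") {
    expression_matrix(tab$values, tab$row_ids, tab$col_ids)
  } else {
    perturbation_design(tab$values, tab$row_ids, tab$col_ids)
  }
}

#' Write a labeled matrix to TSV
#'
#' Inverse of [read_matrix()]: header row of experiment labels (corner cell
#' `gene_id`), one row per gene.  Values are serialized with 17 significant
#' digits so that a read/write round trip reproduces every double exactly.
#'
#' @param x an [expression_matrix()] or [perturbation_design()].
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  if (!inherits(x, c("expression_matrix", "perturbation_design")))
    stop("x must be an expression_matrix or perturbation_design")
  write_labeled_tsv(x$values, x$gene_ids, x$experiment_ids, "gene_id", path)
}

#' Write a gene network to TSV
#'
#' Two formats are supported.  `edge_list` emits one line per edge with
#' columns `regulator`, `target`, `weight` (an entry (i, j) of the weight
#' matrix, the influence of regulator j on target i, is written as the line
#' `j  i  w`), preceded by a `# genes:` comment line carrying the full gene
#' universe so that isolated genes survive a round trip.  `adjacency` emits
#' the full labeled N x N matrix.  Weights carry 17 significant digits so
#' [read_network()] reproduces them exactly.
#'
#' @param net a [gene_network()].
#' @param path output path.
#' @param format `"edge_list"` or `"adjacency"`.
#' @seealso [read_network()]
#' @export
write_network <- function(net, path, format = c("edge_list", "adjacency")) {
  format <- match.arg(format)
  if (!inherits(net, "gene_network")) stop("net must be a gene_network")
  if (format == "adjacency") {
    write_labeled_tsv(as.matrix(net$weights), net$gene_ids, net$gene_ids,
                      "gene_id", path)
    return(invisible(NULL))
  }
  tri <- Matrix::summary(net$weights)
  ord <- order(tri$j, tri$i)
  lines <- c(
    paste(c("# genes:", net$gene_ids), collapse = "\t"),
    "regulator\ttarget\tweight",
    if (nrow(tri) > 0)
      paste(net$gene_ids[tri$j[ord]], net$gene_ids[tri$i[ord]],
            sprintf("%.17g", tri$x[ord]), sep = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(NULL)
}

#' Read a gene network from TSV
#'
#' @param path path written by [write_network()] (or any TSV in the same
#'   layout).
#' @param format `"edge_list"` or `"adjacency"`.
#' @param gene_ids optional character vector fixing the gene universe of an
#'   edge list.  When absent, the `# genes:` comment line is used if
#'   present, otherwise the universe is the labels seen in the file, in
#'   order of first appearance.
#' @return A [gene_network()].
#' @export
read_network <- function(path, format = c("edge_list", "adjacency"),
                         gene_ids = NULL) {
  format <- match.arg(format)
  if (format == "adjacency") {
    tab <- read_labeled_tsv(path)
    return(gene_network(tab$values, tab$row_ids))
  }
  lines <- readLines(path)
  if (length(lines) > 0 && startsWith(lines[1], "# genes:")) {
    ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
    if (is.null(gene_ids)) gene_ids <- ids
    lines <- lines[-1]
  }
  if (length(lines) == 0 || lines[1] != "regulator\ttarget\tweight")
    stop("edge list in '", path,
         "' lacks the 'regulator\ttarget\tweight' header")
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0)
    stop("edge list in '", path, "': line ", bad[1] + 2L,
         " does not have 3 fields")
  reg <- vapply(parts, `[[`, "", 1L)
  tgt <- vapply(parts, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w))
    stop("edge list in '", path, "': non-numeric weight on line ",
         which(is.na(w))[1] + 2L)
  if (is.null(gene_ids)) gene_ids <- unique(c(rbind(reg, tgt)))
  jj <- match(reg, gene_ids)
  ii <- match(tgt, gene_ids)
  if (anyNA(jj) || anyNA(ii))
    stop("edge list in '", path, "' names genes outside the gene universe: ",
         paste(unique(c(reg[is.na(jj)], tgt[is.na(ii)])), collapse = ", "))
  if (anyDuplicated(paste(ii, jj)))
    stop("edge list in '", path, "' repeats an edge")
  n <- length(gene_ids)
  w_mat <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n),
                                dimnames = list(gene_ids, gene_ids))
  gene_network(w_mat, gene_ids)
}

# -- internal TSV helpers ----------------------------------------------------

read_labeled_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) < 2L) stop("'", path, "' has no data rows")
  if (length(unique(nf)) != 1L) {
    r <- which(nf != nf[1])[1]
    stop("ragged TSV in '", path, "': row ", r, " has ", nf[r],
         " fields, expected ", nf[1])
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  if (anyDuplicated(row_ids))
    stop("'", path, "': duplicate row label: ",
         row_ids[duplicated(row_ids)][1])
  if (anyDuplicated(col_ids))
    stop("'", path, "': duplicate column label: ",
         col_ids[duplicated(col_ids)][1])
  body <- as.matrix(df[, -1L, drop = FALSE])
  values <- suppressWarnings(
    matrix(as.numeric(body), nrow = nrow(body), ncol = ncol(body)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("'", path, "': non-numeric cell at row '", row_ids[bad[1]],
         "', column '", col_ids[bad[2]], "'")
  }
  dimnames(values) <- list(row_ids, col_ids)
  list(values = values, row_ids = row_ids, col_ids = col_ids)
}

write_labeled_tsv <- function(values, row_ids, col_ids, corner, path) {
  header <- paste(c(corner, col_ids), collapse = "\t")
  rows <- vapply(seq_along(row_ids), function(i) {
    paste(c(row_ids[i], sprintf("%.17g", values[i, ])), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(NULL)
}
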