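#' Extract the edge set of a network under a comparison mode
#'
#' Converts a weighted network into the set of edges used for accuracy
#' scoring.  `directed` yields ordered (regulator, target) pairs;
#' `signed` additionally tags each pair with the sign of its weight;
#' `undirected` collapses orientation, so a pair connected in either (or
#' both) directions contributes a single element.  Self-loops are dropped
#' unless `include_self` is set: the model's diagonal is structural
#' self-degradation and would inflate accuracy.
#'
#' @param net a [gene_network()].
#' @param mode `"directed"`, `"undirected"` or `"signed"`.
#' @param include_self logical, keep self-loops (default `FALSE`).
#' @return Character vector of unique edge keys (`"j->i"`, `"j->i:+"`, or
#'   `"a--b"` with the unordered pair in gene-index order).
#' @export
edge_set <- function(net, mode = c("directed", "undirected", "signed"),
                     include_self = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(net, "gene_network")) stop("net must be a gene_network")
  tri <- Matrix::summary(net$weights)
  i <- tri$i; j <- tri$j; x <- tri$x
  if (!include_self) {
    keep <- i != j
    i <- i[keep]; j <- j[keep]; x <- x[keep]
  }
  if (length(i) == 0L) return(character(0))
  ids <- net$gene_ids
  keys <- switch(mode,
    directed = paste0(ids[j], "->", ids[i]),
    signed = paste0(ids[j], "->", ids[i], ":", ifelse(x > 0, "+", "-")),
    undirected = paste0(ids[pmin(i, j)], "--", ids[pmax(i, j)]))
  unique(keys)
}

eval_report <- function(tp, fp, fn, mode) {
  structure(list(
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    mode = mode), class = "eval_report")
}

#' Score an inferred network against the known truth
#'
#' Counts true positives, false positives and false negatives over the
#' mode's edge sets and reports the positive predictive value
#' `PPV = TP / (TP + FP)` and sensitivity `Se = TP / (TP + FN)`.  Ratios
#' with a zero denominator are reported as `NA`, never as 0.
#'
#' @param inferred,truth [gene_network()] objects over identical gene ids.
#' @param mode `"directed"`, `"undirected"` or `"signed"` (in signed mode
#'   an edge counts as a true positive only if orientation and sign both
#'   match).
#' @param include_self logical, score self-loops too (default `FALSE`).
#' @return An object of class `eval_report` with fields `tp`, `fp`, `fn`,
#'   `ppv`, `se`, `mode`.
#' @export
ppv_se <- function(inferred, truth,
                   mode = c("directed", "undirected", "signed"),
                   include_self = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(inferred, "gene_network") || !inherits(truth, "gene_network"))
    stop("inferred and truth must be gene_network objects")
  if (!identical(inferred$gene_ids, truth$gene_ids))
    stop("inferred and truth networks have different gene ids")
  a <- edge_set(inferred, mode, include_self)
  b <- edge_set(truth, mode, include_self)
  eval_report(tp = length(intersect(a, b)),
              fp = length(setdiff(a, b)),
              fn = length(setdiff(b, a)),
              mode = mode)
}

#' Score a uniform random edge predictor against the truth
#'
#' Samples `n_edges` distinct edges uniformly without replacement from the
#' mode's edge universe and scores them against the true network with the
#' same machinery as [ppv_se()].  The expected PPV of this baseline is the
#' edge density of the truth.
#'
#' @param n_genes number of genes (must match `truth`).
#' @param n_edges number of edges to predict.
#' @param truth the true [gene_network()].
#' @param mode `"directed"`, `"undirected"` or `"signed"`.
#' @param seed integer seed.
#' @param include_self logical, include self-loops in the universe.
#' @return An object of class `eval_report`.
#' @export
random_baseline <- function(n_genes, n_edges, truth,
                            mode = c("directed", "undirected", "signed"),
                            seed = 1L, include_self = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(truth, "gene_network")) stop("truth must be a gene_network")
  n <- as.integer(n_genes)
  if (n != length(truth$gene_ids))
    stop("n_genes does not match the truth network")
  ids <- truth$gene_ids
  jj <- rep(seq_len(n), each = n)
  ii <- rep(seq_len(n), times = n)
  if (!include_self) {
    keep <- ii != jj
    ii <- ii[keep]; jj <- jj[keep]
  }
  universe <- switch(mode,
    directed = paste0(ids[jj], "->", ids[ii]),
    signed = c(paste0(ids[jj], "->", ids[ii], ":+"),
               paste0(ids[jj], "->", ids[ii], ":-")),
    undirected = unique(paste0(ids[pmin(ii, jj)], "--", ids[pmax(ii, jj)])))
  if (n_edges > length(universe))
    stop("n_edges (", n_edges, ") exceeds the number of possible edges (",
         length(universe), ")")
  set.seed(seed)
  pred <- universe[sample.int(length(universe), n_edges)]
  b <- edge_set(truth, mode, include_self)
  eval_report(tp = length(intersect(pred, b)),
              fp = length(setdiff(pred, b)),
              fn = length(setdiff(b, pred)),
              mode = mode)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s): TP=%d FP=%d FN=%d  PPV=%s  Se=%s\n",
              x$mode, x$tp, x$fp, x$fn,
              ifelse(is.na(x$ppv), "undefined", sprintf("%.3f", x$ppv)),
              ifelse(is.na(x$se), "undefined", sprintf("%.3f", x$se))))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(mode = x$mode, tp = x$tp, fp = x$fp, fn = x$fn,
             ppv = x$ppv, se = x$se, stringsAsFactors = FALSE)
}
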