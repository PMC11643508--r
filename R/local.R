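# Local simpliciality: ego-hypergraphs, nodal measures, simplicial
# assortativity on the unweighted pairwise projection, and cross-measure
# correlations.

#' Ego-hypergraph of a node
#'
#' The subhypergraph induced on a node's neighborhood: with
#' \eqn{n(v) = \{u : u, v \in e \in E\}} and \eqn{\hat V = \{v\} \cup n(v)},
#' the ego edge set is \eqn{\hat E = \{e \in E : e \subseteq \hat V\}}. Note
#' that \eqn{\hat E} may contain edges that do not touch `v` itself — any
#' edge lying fully inside the neighborhood qualifies.
#'
#' @param h A [hypergraph()].
#' @param v A node label; must be in the node set of `h`.
#' @return A [hypergraph()] on \eqn{\hat V} with edge set \eqn{\hat E} and a
#'   `"center"` attribute naming `v`. An isolated node yields a single-node,
#'   zero-edge hypergraph.
#' @export
ego_hypergraph <- function(h, v) {
  stopifnot(is_hypergraph(h))
  v <- as.character(v)
  stopifnot(length(v) == 1L)
  if (!v %in% h$nodes) stop(sprintf("node '%s' is not in the hypergraph", v))
  touching <- vapply(h$edges, function(e) v %in% e, logical(1L))
  vhat <- unique(c(v, unlist(h$edges[touching], use.names = FALSE)))
  inside <- vapply(h$edges, function(e) all(e %in% vhat), logical(1L))
  out <- hypergraph(h$edges[inside], nodes = vhat)
  attr(out, "center") <- v
  out
}

#' Nodal simpliciality
#'
#' The simpliciality of a node is a chosen global measure evaluated on its
#' ego-hypergraph. A node whose ego-hypergraph is empty (isolated node) or
#' contains only minimal faces has undefined nodal simpliciality (`NA`).
#'
#' @param h A [hypergraph()]; preprocessed internally.
#' @param measure One of `"sf"`, `"es"`, `"fes"`.
#' @param restriction A [size_restriction()].
#' @return A named numeric vector over the nodes of `h` (the original node
#'   set, so nodes removed by preprocessing report `NA`).
#' @export
nodal_simpliciality <- function(h, measure = c("sf", "es", "fes"),
                                restriction = size_restriction()) {
  stopifnot(is_hypergraph(h))
  measure <- match.arg(measure)
  restriction <- .check_restriction(restriction)
  hp <- preprocess(h, restriction)
  fun <- switch(measure,
    sf = simplicial_fraction,
    es = edit_simpliciality,
    fes = face_edit_simpliciality
  )
  vals <- stats::setNames(rep(NA_real_, length(h$nodes)), h$nodes)
  for (v in hp$nodes) {
    vals[[v]] <- fun(ego_hypergraph(hp, v), restriction)
  }
  vals
}

#' Per-node simpliciality table
#'
#' All three nodal measures at once, as a data frame with one row per node
#' and an `undefined_reason` column (empty string where every measure is
#' defined). This is the numeric content behind local-simpliciality maps
#' and histograms.
#'
#' @inheritParams nodal_simpliciality
#' @return A `data.frame` with columns `node`, `sf`, `es`, `fes`,
#'   `undefined_reason`.
#' @export
nodal_simpliciality_table <- function(h, restriction = size_restriction()) {
  stopifnot(is_hypergraph(h))
  restriction <- .check_restriction(restriction)
  hp <- preprocess(h, restriction)
  out <- data.frame(
    node = h$nodes,
    sf = NA_real_, es = NA_real_, fes = NA_real_,
    undefined_reason = "", stringsAsFactors = FALSE
  )
  rownames(out) <- h$nodes
  for (v in h$nodes) {
    if (!v %in% hp$nodes) {
      out[v, "undefined_reason"] <- "isolated_after_preprocessing"
      next
    }
    rep <- simpliciality_report(ego_hypergraph(hp, v), restriction)
    out[v, c("sf", "es", "fes")] <- c(rep$sf, rep$es, rep$fes)
    if (length(rep$undefined)) {
      out[v, "undefined_reason"] <- paste(
        unique(rep$undefined), collapse = ";"
      )
    }
  }
  rownames(out) <- NULL
  out
}

#' Unweighted pairwise projection adjacency
#'
#' The symmetric 0/1 adjacency relation of the hypergraph's pairwise
#' projection: \eqn{A_{ij} = 1} iff \eqn{i \neq j} and nodes `i` and `j`
#' share at least one hyperedge, i.e. \eqn{[B B^T]_{ij} > 0} off the
#' diagonal for the node-edge incidence matrix \eqn{B}.
#'
#' @param h A [hypergraph()].
#' @return A sparse symmetric logical adjacency matrix (class from the
#'   Matrix package) with zero diagonal and node labels as dimnames.
#' @export
projection_adjacency <- function(h) {
  stopifnot(is_hypergraph(h))
  n <- length(h$nodes)
  if (n == 0L || length(h$edges) == 0L) {
    return(Matrix::sparseMatrix(
      i = integer(0L), j = integer(0L), dims = c(n, n),
      dimnames = list(h$nodes, h$nodes)
    ))
  }
  sz <- lengths(h$edges)
  B <- Matrix::sparseMatrix(
    i = match(unlist(h$edges, use.names = FALSE), h$nodes),
    j = rep.int(seq_along(h$edges), sz),
    x = 1,
    dims = c(n, length(h$edges)),
    dimnames = list(h$nodes, NULL)
  )
  A <- Matrix::tcrossprod(B) > 0
  Matrix::diag(A) <- FALSE
  Matrix::drop0(A)
}

#' Simplicial assortativity
#'
#' The Pearson correlation of nodal simpliciality across pairs of nodes
#' connected by at least one hyperedge, computed over the ordered adjacent
#' pairs of the unweighted pairwise projection — i.e. the assortativity
#' coefficient of the nodal values on the projection graph. Pairs with an
#' undefined endpoint are dropped. `NA` when fewer than two usable pairs
#' remain or the endpoint values have zero variance.
#'
#' For tractability on large data this is conventionally computed on the
#' hypergraph filtered to interactions of sizes two and three
#' (`restriction = size_restriction(max_size = 3)`).
#'
#' @inheritParams nodal_simpliciality
#' @return A correlation in `[-1, 1]`, or `NA`.
#' @export
simplicial_assortativity <- function(h, measure = c("sf", "es", "fes"),
                                     restriction = size_restriction()) {
  stopifnot(is_hypergraph(h))
  measure <- match.arg(measure)
  restriction <- .check_restriction(restriction)
  hp <- preprocess(h, restriction)
  if (num_edges(hp) == 0L) return(NA_real_)
  sigma <- nodal_simpliciality(hp, measure, restriction)
  A <- methods::as(projection_adjacency(hp), "TsparseMatrix")
  i <- A@i + 1L
  j <- A@j + 1L
  upper <- i < j
  i <- i[upper]
  j <- j[upper]
  si <- sigma[hp$nodes[i]]
  sj <- sigma[hp$nodes[j]]
  ok <- !is.na(si) & !is.na(sj)
  si <- si[ok]
  sj <- sj[ok]
  if (length(si) < 2L) return(NA_real_)
  # ordered pairs: each unordered pair contributes (si, sj) and (sj, si)
  x <- c(si, sj)
  y <- c(sj, si)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Correlation between two measure vectors
#'
#' Product-moment (Pearson) or rank (Spearman) correlation with a two-sided
#' significance test, used to compare simpliciality measures across datasets
#' or across nodes. Zero-variance input yields `NA`.
#'
#' @param values_a,values_b Equal-length numeric vectors (length >= 3 after
#'   dropping pairs with missing entries).
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `estimate`, `p_value`, `method`, and `n` (pairs
#'   used).
#' @export
measure_correlations <- function(values_a, values_b,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(values_a) == length(values_b))
  ok <- !is.na(values_a) & !is.na(values_b)
  a <- as.numeric(values_a[ok])
  b <- as.numeric(values_b[ok])
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(estimate = NA_real_, p_value = NA_real_, method = method,
                n = length(a)))
  }
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = method, exact = FALSE)
  )
  list(
    estimate = unname(ct$estimate),
    p_value = ct$p.value,
    method = method,
    n = length(a)
  )
}
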