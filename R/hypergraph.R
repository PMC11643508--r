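# Core data model: simple hypergraphs stored as canonical edges.
#
# An edge is kept as a sorted (C-locale radix order), duplicate-free character
# vector of node labels; its identity is the key obtained by joining the
# sorted labels with an unprintable separator. All set-membership tests on
# edges go through these keys, so a lookup is a hashed string comparison.

.EDGE_SEP <- "\x1f"

.canon_edge <- function(e) {
  sort(unique(as.character(e)), method = "radix")
}

.edge_key <- function(e) paste(e, collapse = .EDGE_SEP)

.edge_keys <- function(edges) {
  vapply(edges, .edge_key, character(1L), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a simple hypergraph from raw edges
#'
#' Canonicalizes a collection of raw hyperedges into a simple hypergraph
#' \eqn{H = (V, E)}: node labels within an edge are deduplicated, duplicate
#' edges are collapsed (no multi-hyperedges), and the node set is the union
#' of the edge members plus any extra labels passed via `nodes` (which may
#' therefore contain isolated nodes).
#'
#' @param edges A list (or other sequence) of node-label vectors, one per
#'   hyperedge. Labels may be integers or strings; they are compared by
#'   equality after coercion to character.
#' @param nodes Optional additional node labels to include in the node set.
#' @return An object of class `"hypergraph"`: a list with components
#'   `nodes` (sorted character vector), `edges` (list of canonical edges,
#'   ordered by size then lexicographically), and `keys` (edge identity
#'   strings, parallel to `edges`).
#' @examples
#' h <- hypergraph(list(c(1, 2), c(2, 1), c(1, 1, 2, 3)))
#' num_edges(h) # 2: {1,2} and {1,2,3}
#' @export
hypergraph <- function(edges = list(), nodes = NULL) {
  if (is.null(edges)) edges <- list()
  stopifnot(is.list(edges) || is.vector(edges))
  edges <- lapply(edges, .canon_edge)
  edges <- edges[lengths(edges) > 0L]
  keys <- .edge_keys(edges)
  dup <- duplicated(keys)
  edges <- edges[!dup]
  keys <- keys[!dup]
  ord <- order(lengths(edges), keys, method = "radix")
  edges <- edges[ord]
  keys <- keys[ord]
  nodes <- sort(
    unique(c(
      as.character(nodes %||% character(0L)),
      unlist(edges, use.names = FALSE)
    )),
    method = "radix"
  )
  structure(
    list(nodes = nodes, edges = edges, keys = keys),
    class = "hypergraph"
  )
}

#' @rdname hypergraph
#' @param x Object to test or print.
#' @export
is_hypergraph <- function(x) inherits(x, "hypergraph")

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf(
    "Hypergraph with %d nodes and %d hyperedges\n",
    length(x$nodes), length(x$edges)
  ))
  if (length(x$edges)) {
    sz <- lengths(x$edges)
    cat(sprintf(
      "  edge sizes: min %d, mean %.2f, max %d\n",
      min(sz), mean(sz), max(sz)
    ))
  }
  invisible(x)
}

#' Basic hypergraph summaries
#'
#' @param h A [hypergraph()].
#' @return `num_nodes()` and `num_edges()` return integer counts;
#'   `edge_sizes()` the integer sizes of all edges; `degrees()` a named
#'   integer vector with the number of incident edges per node (isolated
#'   nodes have degree 0).
#' @export
num_nodes <- function(h) {
  stopifnot(is_hypergraph(h))
  length(h$nodes)
}

#' @rdname num_nodes
#' @export
num_edges <- function(h) {
  stopifnot(is_hypergraph(h))
  length(h$edges)
}

#' @rdname num_nodes
#' @export
edge_sizes <- function(h) {
  stopifnot(is_hypergraph(h))
  lengths(h$edges)
}

#' @rdname num_nodes
#' @export
degrees <- function(h) {
  stopifnot(is_hypergraph(h))
  d <- stats::setNames(integer(length(h$nodes)), h$nodes)
  if (length(h$edges)) {
    tab <- table(unlist(h$edges, use.names = FALSE))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Size restriction for downward closure
#'
#' Downward closure in its strict form requires every subset of an edge —
#' including singletons and the empty set — to be present, which is
#' unreasonably strict for most interaction data (proximity or email data
#' never contain singleton interactions by construction). A size restriction
#' relaxes closure to a set of allowed subface sizes \eqn{K}; all shipped
#' analyses default to \eqn{K = \{2, \dots, 11\}}, excluding singletons and
#' the empty set and capping edges at size 11 for computational tractability
#' (an edge of size \eqn{m} has \eqn{2^m} subsets).
#'
#' @param min_size Smallest allowed subface size (default 2, excluding
#'   singletons). Ignored when `sizes` is given.
#' @param max_size Largest allowed size; edges larger than this are dropped
#'   by [preprocess()], never truncated. Defaults to 11, or to `max(sizes)`
#'   when `sizes` is given.
#' @param sizes Optional explicit integer set \eqn{K} of allowed sizes,
#'   overriding `min_size:max_size`. Include 1 for the stricter convention
#'   where singletons count (e.g. co-authorship data with single-author
#'   papers).
#' @return An object of class `"size_restriction"` with components `sizes`
#'   (sorted integer vector \eqn{K}) and `max_size`.
#' @examples
#' size_restriction()            # K = {2, ..., 11}
#' size_restriction(max_size = 3) # K = {2, 3}, used for assortativity tables
#' @export
size_restriction <- function(min_size = 2L, max_size = 11L, sizes = NULL) {
  if (is.null(sizes)) {
    min_size <- as.integer(min_size)
    max_size <- as.integer(max_size)
    stopifnot(length(min_size) == 1L, length(max_size) == 1L,
              min_size >= 1L, max_size >= min_size)
    sizes <- seq.int(min_size, max_size)
  } else {
    sizes <- sort(unique(as.integer(sizes)))
    stopifnot(length(sizes) >= 1L, all(sizes >= 1L))
    if (missing(max_size)) max_size <- max(11L, sizes)
    max_size <- as.integer(max_size)
    stopifnot(max_size >= max(sizes))
  }
  structure(
    list(sizes = sizes, max_size = max_size),
    class = "size_restriction"
  )
}

#' @export
print.size_restriction <- function(x, ...) {
  cat(sprintf(
    "Size restriction: K = {%s}, max edge size %d\n",
    paste(x$sizes, collapse = ", "), x$max_size
  ))
  invisible(x)
}

.check_restriction <- function(restriction) {
  stopifnot(inherits(restriction, "size_restriction"))
  restriction
}

#' Preprocess a hypergraph for simpliciality analysis
#'
#' Applies the standard cleaning used before any measure is computed: edges
#' smaller than `min(K)` (singletons under the default restriction) are
#' removed, edges larger than `max_size` are removed (dropped, not
#' truncated), and nodes left without any incident edge are removed. The cap
#' is applied first, then isolated nodes are pruned.
#'
#' @param h A [hypergraph()].
#' @param restriction A [size_restriction()].
#' @return A preprocessed [hypergraph()] (possibly empty).
#' @export
preprocess <- function(h, restriction = size_restriction()) {
  stopifnot(is_hypergraph(h))
  restriction <- .check_restriction(restriction)
  sz <- lengths(h$edges)
  keep <- sz >= min(restriction$sizes) & sz <= restriction$max_size
  hypergraph(h$edges[keep])
}

# Logical vector flagging maximal edges (not strictly contained in another
# edge). Containment is only tested against larger edges incident to the
# least-frequent member node, so the scan is near-linear on sparse data; the
# all-pairs oracle lives in the test suite.
.maximal_flags <- function(h) {
  m <- length(h$edges)
  if (m == 0L) return(logical(0L))
  sizes <- lengths(h$edges)
  inc <- split(
    rep.int(seq_len(m), sizes),
    unlist(h$edges, use.names = FALSE)
  )
  node_deg <- lengths(inc)
  flags <- rep(TRUE, m)
  for (i in seq_len(m)) {
    e <- h$edges[[i]]
    pivot <- e[which.min(node_deg[e])]
    cand <- inc[[pivot]]
    cand <- cand[sizes[cand] > sizes[i]]
    for (j in cand) {
      if (all(e %in% h$edges[[j]])) {
        flags[i] <- FALSE
        break
      }
    }
  }
  flags
}

#' Maximal hyperedges
#'
#' A hyperedge is maximal when it is not strictly contained in any other
#' hyperedge. The maximal edges form an antichain under set inclusion, and
#' every edge of the hypergraph is contained in at least one maximal edge.
#'
#' @param h A [hypergraph()].
#' @return A list of canonical edges (character vectors), in the
#'   hypergraph's edge order.
#' @examples
#' maximal_edges(hypergraph(list(1:2, 1:3))) # only {1,2,3}
#' @export
maximal_edges <- function(h) {
  stopifnot(is_hypergraph(h))
  h$edges[.maximal_flags(h)]
}

#' Size-restricted power set of an edge
#'
#' All subsets of an edge whose size lies in the allowed set \eqn{K}
#' (intersected with `1:|e|`); the edge itself is included exactly when its
#' own size is in \eqn{K}. For \eqn{K = \{2, \dots, n-1\}} an edge of size
#' \eqn{n} has \eqn{2^n - n - 2} such subfaces.
#'
#' @param e An edge (vector of node labels).
#' @param restriction A [size_restriction()]. Edges above `max_size` are an
#'   error: large edges must be filtered out with [preprocess()] first.
#' @return A list of canonical edges.
#' @export
restricted_powerset <- function(e, restriction = size_restriction()) {
  restriction <- .check_restriction(restriction)
  e <- .canon_edge(e)
  n <- length(e)
  if (n > restriction$max_size) {
    stop(sprintf(
      "edge of size %d exceeds max_size = %d; filter large edges with preprocess() first",
      n, restriction$max_size
    ))
  }
  sizes <- restriction$sizes[restriction$sizes <= n]
  out <- vector("list", 0L)
  for (m in sizes) {
    if (m == n) {
      out <- c(out, list(e))
    } else {
      out <- c(out, utils::combn(e, m, simplify = FALSE))
    }
  }
  out
}

#' Minimal faces of a hypergraph
#'
#' The minimal faces are the edges of size `min(K)` (size-2 edges under the
#' default restriction). Under a size restriction they are always simplices
#' — there are no smaller allowed edges for them to include — so the global
#' measures exclude them from the sets of potential simplices.
#'
#' @inheritParams preprocess
#' @return A list of canonical edges (possibly empty).
#' @export
minimal_faces <- function(h, restriction = size_restriction()) {
  stopifnot(is_hypergraph(h))
  restriction <- .check_restriction(restriction)
  h$edges[lengths(h$edges) == min(restriction$sizes)]
}

# is_simplex on an edge known (by index) to be in h.
.is_simplex_idx <- function(h, i, restriction) {
  subs <- restricted_powerset(h$edges[[i]], restriction)
  all(.edge_keys(subs) %in% h$keys)
}

#' Test whether an edge of a hypergraph is a simplex
#'
#' An edge is a simplex when every member of its size-restricted power set
#' is itself an edge of the hypergraph (downward closure at this edge).
#' Minimal-size edges are trivially simplices.
#'
#' @param e An edge; must be an edge of `h`.
#' @inheritParams preprocess
#' @return `TRUE` or `FALSE`.
#' @export
is_simplex <- function(e, h, restriction = size_restriction()) {
  stopifnot(is_hypergraph(h))
  restriction <- .check_restriction(restriction)
  key <- .edge_key(.canon_edge(e))
  i <- match(key, h$keys)
  if (is.na(i)) stop("e is not an edge of the hypergraph")
  .is_simplex_idx(h, i, restriction)
}

#' Induced (size-restricted) simplicial complex
#'
#' The minimal simplicial complex containing the hypergraph: the union of
#' the size-restricted power sets of all maximal edges. Applying the
#' operation to its own output is the identity (idempotence).
#'
#' @inheritParams preprocess
#' @return A [hypergraph()] whose edge set is the induced complex
#'   \eqn{C = \cup_{\tilde e} P_K(\tilde e)}; the node set is carried over.
#' @export
induced_simplicial_complex <- function(h, restriction = size_restriction()) {
  stopifnot(is_hypergraph(h))
  restriction <- .check_restriction(restriction)
  maxed <- maximal_edges(h)
  faces <- unlist(
    lapply(maxed, restricted_powerset, restriction = restriction),
    recursive = FALSE
  )
  hypergraph(faces, nodes = h$nodes)
}
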