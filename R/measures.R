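# Global simpliciality measures.
#
# All three measures quantify how close a hypergraph is to downward closure,
# using the size-restricted power set P_K and excluding minimal faces (edges
# of size min(K)) from the sets of potential simplices: under the size
# restriction a minimal face is trivially a simplex, so counting it would
# inflate every measure.
#
# Degenerate denominators yield NA with a reason recorded in the report,
# never a silent 0 or 1: the simpliciality of an empty hypergraph is
# undefined.

# Shared workhorse: computes every count and per-face quantity once.
# Measures operate on the preprocessed hypergraph (sizes within
# [min K, max_size], no isolated nodes); preprocess() is a fixed point on
# already-clean input so applying it here is harmless.
.global_counts <- function(h, restriction) {
  h <- preprocess(h, restriction)
  kmin <- min(restriction$sizes)
  sizes <- lengths(h$edges)
  flags <- .maximal_flags(h)

  # --- simplicial fraction: candidates are non-minimal edges
  sf_cand <- which(sizes > kmin)
  n_sf_cand <- length(sf_cand)
  n_simplices <- if (n_sf_cand) {
    sum(vapply(sf_cand, function(i) .is_simplex_idx(h, i, restriction),
               logical(1L)))
  } else 0L

  # --- edit simpliciality: maximal edges that are not minimal faces,
  # the induced restricted complex over them, and the edges inside it
  mt <- which(flags & sizes > kmin)
  n_maximal_nonminimal <- length(mt)
  per_face <- NULL
  if (n_maximal_nonminimal) {
    face_keys <- lapply(mt, function(i) {
      .edge_keys(restricted_powerset(h$edges[[i]], restriction))
    })
    complex_keys <- unique(unlist(face_keys, use.names = FALSE))
    n_complex <- length(complex_keys)
    n_edges_in_complex <- sum(h$keys %in% complex_keys)
    # --- face edit simpliciality terms over the same face set
    d_fes <- integer(n_maximal_nonminimal)
    p_size <- integer(n_maximal_nonminimal)
    for (t in seq_along(mt)) {
      keys_t <- face_keys[[t]]
      p_size[t] <- length(keys_t)
      d_fes[t] <- p_size[t] - sum(keys_t %in% h$keys)
    }
    per_face <- data.frame(
      edge = vapply(mt, function(i) paste(h$edges[[i]], collapse = ","),
                    character(1L)),
      size = sizes[mt],
      powerset_size = p_size,
      face_edit_distance = d_fes,
      stringsAsFactors = FALSE
    )
  } else {
    n_complex <- 0L
    n_edges_in_complex <- 0L
  }

  list(
    h = h,
    n_edges = length(h$edges),
    n_maximal = sum(flags),
    n_sf_candidates = n_sf_cand,
    n_simplices = as.integer(n_simplices),
    n_maximal_nonminimal = n_maximal_nonminimal,
    n_complex = n_complex,
    n_edges_in_complex = n_edges_in_complex,
    per_face = per_face
  )
}

.sf_from_counts <- function(cnt) {
  if (cnt$n_sf_candidates == 0L) NA_real_
  else cnt$n_simplices / cnt$n_sf_candidates
}

.es_from_counts <- function(cnt) {
  denom <- cnt$n_complex - cnt$n_maximal_nonminimal
  if (denom <= 0L) NA_real_
  else (cnt$n_edges_in_complex - cnt$n_maximal_nonminimal) / denom
}

.fes_terms_from_counts <- function(cnt) {
  pf <- cnt$per_face
  if (is.null(pf) || nrow(pf) == 0L) return(NULL)
  data.frame(pf, normalized_distance = ifelse(
    pf$powerset_size > 1L,
    pf$face_edit_distance / (pf$powerset_size - 1L),
    0
  ))
}

.fes_from_counts <- function(cnt) {
  terms <- .fes_terms_from_counts(cnt)
  if (is.null(terms)) NA_real_ else mean(1 - terms$normalized_distance)
}

#' Simplicial fraction
#'
#' The fraction of hyperedges that are simplices,
#' \eqn{\sigma_{SF} = |S| / |E|}, where both the simplex set \eqn{S} and the
#' edge count exclude minimal faces (edges of size `min(K)`), which are
#' trivially simplices under the size restriction. Undefined (`NA`) when no
#' non-minimal edge exists.
#'
#' @param h A [hypergraph()]; it is preprocessed internally with
#'   `restriction` before measuring.
#' @param restriction A [size_restriction()].
#' @return A fraction in `[0, 1]`, or `NA` when undefined.
#' @examples
#' h <- hypergraph(list(1:3, c(1, 2), c(1, 3), c(2, 3)))
#' simplicial_fraction(h) # 1: the triangle has all three pairs
#' @export
simplicial_fraction <- function(h, restriction = size_restriction()) {
  restriction <- .check_restriction(restriction)
  .sf_from_counts(.global_counts(h, restriction))
}

#' Edit simpliciality
#'
#' The fraction of the induced simplicial complex already present,
#' \eqn{\sigma_{ES} = (|E| - |\tilde E|) / (|C| - |\tilde E|)}: the
#' complement of the fraction of edges that must be added to reach downward
#' closure. Maximal edges that are also minimal faces are excluded from the
#' maximal set, from the induced complex \eqn{C}, and from the edge count
#' (only edges lying inside the reduced complex are counted), which keeps
#' the ratio in `[0, 1]`. Undefined (`NA`) when every maximal edge is a
#' minimal face.
#'
#' @inheritParams simplicial_fraction
#' @return A fraction in `[0, 1]`, or `NA` when undefined.
#' @examples
#' edit_simpliciality(hypergraph(list(1:3, 1:2))) # 1/3
#' @export
edit_simpliciality <- function(h, restriction = size_restriction()) {
  restriction <- .check_restriction(restriction)
  .es_from_counts(.global_counts(h, restriction))
}

#' Simplicial edit distance
#'
#' The number of edges that must be added to reach the induced (restricted)
#' simplicial complex, \eqn{d_{ES} = |C| - |E|}, or its normalized form
#' \eqn{d_{NES} = 1 - \sigma_{ES}}.
#'
#' @inheritParams simplicial_fraction
#' @param normalized If `TRUE`, return \eqn{1 - \sigma_{ES}} (undefined
#'   exactly when the edit simpliciality is); otherwise the raw count.
#' @return A nonnegative number (or `NA` for the undefined normalized case).
#' @export
simplicial_edit_distance <- function(h, restriction = size_restriction(),
                                     normalized = FALSE) {
  restriction <- .check_restriction(restriction)
  cnt <- .global_counts(h, restriction)
  if (normalized) {
    es <- .es_from_counts(cnt)
    if (is.na(es)) NA_real_ else 1 - es
  } else {
    cnt$n_complex - cnt$n_edges_in_complex
  }
}

#' Face edit distance of a single edge
#'
#' The number of subfaces that must be added to make edge `e` a simplex:
#' \eqn{d_{FES}(e) = |P_K(e)| - |\{f \in E : f \subseteq e, |f| \in K\}|}.
#' Both counts include `e` itself when its size is in \eqn{K}. A simplex has
#' distance 0; an edge with no subfaces present has distance
#' \eqn{|P_K(e)| - 1}, i.e. normalized face edit distance 1.
#'
#' @param e An edge; must be an edge of `h`.
#' @inheritParams simplicial_fraction
#' @return A nonnegative integer.
#' @export
face_edit_distance <- function(e, h, restriction = size_restriction()) {
  stopifnot(is_hypergraph(h))
  restriction <- .check_restriction(restriction)
  e <- .canon_edge(e)
  if (!.edge_key(e) %in% h$keys) stop("e is not an edge of the hypergraph")
  keys <- .edge_keys(restricted_powerset(e, restriction))
  length(keys) - sum(keys %in% h$keys)
}

#' Face edit simpliciality
#'
#' The mean per-face completeness of subfaces over the maximal edges that
#' are not minimal faces:
#' \eqn{\sigma_{FES} = |F|^{-1} \sum_{e \in F} (1 - d_{FES}(e) / (|P_K(e)| - 1))}.
#' The per-face normalization removes the dominance of large edges that
#' drives the edit simpliciality towards zero. Undefined (`NA`) when the
#' face set is empty.
#'
#' @inheritParams simplicial_fraction
#' @return A fraction in `[0, 1]`, or `NA` when undefined.
#' @examples
#' face_edit_simpliciality(hypergraph(list(1:3, 1:2))) # 1/3
#' @export
face_edit_simpliciality <- function(h, restriction = size_restriction()) {
  restriction <- .check_restriction(restriction)
  .fes_from_counts(.global_counts(h, restriction))
}

#' Mean (normalized) face edit distance
#'
#' Aggregates of the per-face edit distances over the maximal edges that are
#' not minimal faces: the mean raw count \eqn{\bar d_{FES}} and the mean
#' normalized distance \eqn{\bar d_{NFES} = 1 - \sigma_{FES}}.
#'
#' @inheritParams simplicial_fraction
#' @param normalized If `TRUE`, return the mean normalized distance.
#' @return A nonnegative number, or `NA` when the face set is empty.
#' @export
mean_face_edit_distance <- function(h, restriction = size_restriction(),
                                    normalized = FALSE) {
  restriction <- .check_restriction(restriction)
  terms <- .fes_terms_from_counts(.global_counts(h, restriction))
  if (is.null(terms)) return(NA_real_)
  if (normalized) mean(terms$normalized_distance)
  else mean(terms$face_edit_distance)
}

#' Full simpliciality report
#'
#' Computes all global measures in one pass, sharing the maximal-edge scan
#' and the power-set enumeration, and records the counts entering each
#' measure so discrepancies between conventions are diagnosable. Undefined
#' measures are flagged with a reason, never silently set to 0 or 1.
#'
#' @inheritParams simplicial_fraction
#' @return An object of class `"simpliciality_report"`: a list with the
#'   measure values (`sf`, `es`, `fes`), the distance variants
#'   (`es_distance`, `es_distance_normalized`, `mean_face_edit_distance`,
#'   `mean_normalized_face_edit_distance`), a `counts` list
#'   (`n_edges`, `n_maximal`, `n_sf_candidates`, `n_simplices`,
#'   `n_maximal_nonminimal`, `n_complex`, `n_edges_in_complex`), and an
#'   `undefined` named character vector of reason codes for `NA` measures.
#' @examples
#' simpliciality_report(hypergraph(list(1:3, c(1, 2), c(1, 3), c(2, 3))))
#' @export
simpliciality_report <- function(h, restriction = size_restriction()) {
  stopifnot(is_hypergraph(h))
  restriction <- .check_restriction(restriction)
  cnt <- .global_counts(h, restriction)
  sf <- .sf_from_counts(cnt)
  es <- .es_from_counts(cnt)
  fes <- .fes_from_counts(cnt)
  terms <- .fes_terms_from_counts(cnt)

  undefined <- character(0L)
  if (cnt$n_edges == 0L) {
    undefined <- c(
      sf = "empty_hypergraph", es = "empty_hypergraph",
      fes = "empty_hypergraph"
    )
  } else {
    if (is.na(sf)) undefined["sf"] <- "no_candidate_simplices"
    if (is.na(es)) undefined["es"] <- "degenerate_denominator"
    if (is.na(fes)) undefined["fes"] <- "no_nonminimal_maximal_faces"
  }

  structure(
    list(
      sf = sf,
      es = es,
      fes = fes,
      es_distance = cnt$n_complex - cnt$n_edges_in_complex,
      es_distance_normalized = if (is.na(es)) NA_real_ else 1 - es,
      mean_face_edit_distance =
        if (is.null(terms)) NA_real_ else mean(terms$face_edit_distance),
      mean_normalized_face_edit_distance =
        if (is.na(fes)) NA_real_ else 1 - fes,
      counts = cnt[c(
        "n_edges", "n_maximal", "n_sf_candidates", "n_simplices",
        "n_maximal_nonminimal", "n_complex", "n_edges_in_complex"
      )],
      restriction = restriction,
      undefined = undefined
    ),
    class = "simpliciality_report"
  )
}

#' @export
print.simpliciality_report <- function(x, digits = 4, ...) {
  fmt <- function(v) {
    if (is.na(v)) "undefined" else formatC(v, digits = digits, format = "g")
  }
  cat("Simpliciality report\n")
  cat(sprintf("  simplicial fraction (SF):      %s\n", fmt(x$sf)))
  cat(sprintf("  edit simpliciality (ES):       %s\n", fmt(x$es)))
  cat(sprintf("  face edit simpliciality (FES): %s\n", fmt(x$fes)))
  cat(sprintf(
    "  edit distance d_ES = %d (normalized %s)\n",
    x$es_distance, fmt(x$es_distance_normalized)
  ))
  with(x$counts, cat(sprintf(
    "  counts: |E| = %d, |E~| = %d (non-minimal %d), |C| = %d, |S| = %d/%d\n",
    n_edges, n_maximal, n_maximal_nonminimal, n_complex,
    n_simplices, n_sf_candidates
  )))
  if (length(x$undefined)) {
    cat(sprintf(
      "  undefined: %s\n",
      paste(sprintf("%s (%s)", names(x$undefined), x$undefined),
            collapse = ", ")
    ))
  }
  invisible(x)
}

#' Summary row for a hypergraph
#'
#' One data-frame row with the structural properties and the three global
#' measures, in the column layout used by the `compute` CLI subcommand:
#' dataset name, `n_nodes`, `n_edges`, mean degree, mean edge size, `sf`,
#' `es`, `fes`. Counts describe the preprocessed hypergraph.
#'
#' @inheritParams simplicial_fraction
#' @param name Dataset label for the first column.
#' @return A one-row `data.frame`.
#' @export
summary_row <- function(h, restriction = size_restriction(),
                        name = "hypergraph") {
  stopifnot(is_hypergraph(h))
  restriction <- .check_restriction(restriction)
  hp <- preprocess(h, restriction)
  rep <- simpliciality_report(hp, restriction)
  data.frame(
    dataset = name,
    n_nodes = num_nodes(hp),
    n_edges = num_edges(hp),
    mean_degree = if (num_nodes(hp)) mean(degrees(hp)) else NA_real_,
    mean_edge_size = if (num_edges(hp)) mean(edge_sizes(hp)) else NA_real_,
    sf = rep$sf,
    es = rep$es,
    fes = rep$fes,
    stringsAsFactors = FALSE
  )
}
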