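# Brute-force oracles, written independently of the package internals:
# subsets are enumerated by bitmask, containment by all-pairs scan, and
# every measure follows its definition literally. Fractions are carried as
# integer numerator/denominator pairs so agreement can be checked exactly.

okey <- function(e) paste(sort(as.character(e)), collapse = "|")

# all non-empty subsets of a vector, by bitmask
oracle_subsets <- function(e) {
  n <- length(e)
  out <- vector("list", 2^n - 1)
  for (mask in seq_len(2^n - 1)) {
    out[[mask]] <- e[bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1)) > 0]
  }
  out
}

# Full measure computation from definitions. `edges`: list of node-label
# vectors; K: integer vector of allowed sizes (max size = max(K) cap).
oracle_measures <- function(edges, K = 2:11) {
  edges <- unique(lapply(edges, function(e) sort(unique(as.character(e)))))
  sz <- sapply(edges, length)
  if (length(edges) == 0 || !any(sz >= min(K) & sz <= max(K))) {
    empty <- list(num = NA, den = NA, value = NA_real_)
    return(list(sf = empty, es = empty, fes = list(value = NA_real_),
                fes_pairs = NULL,
                d_es = 0L, d_nes = NA_real_))
  }
  edges <- edges[sz >= min(K) & sz <= max(K)]
  sz <- sapply(edges, length)
  keys <- sapply(edges, okey)
  m <- length(edges)

  # maximal edges: all-pairs strict containment
  is_max <- rep(TRUE, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j && sz[j] > sz[i] && all(edges[[i]] %in% edges[[j]])) {
        is_max[i] <- FALSE
        break
      }
    }
  }

  # simplex test from the definition
  edge_is_simplex <- function(e) {
    subs <- oracle_subsets(e)
    subs <- subs[sapply(subs, length) %in% K]
    all(sapply(subs, okey) %in% keys)
  }

  # SF: candidates and simplices both exclude minimal faces
  cand <- which(sz > min(K))
  sf <- if (length(cand) == 0) {
    list(num = NA, den = NA, value = NA_real_)
  } else {
    nS <- sum(sapply(cand, function(i) edge_is_simplex(edges[[i]])))
    list(num = nS, den = length(cand), value = nS / length(cand))
  }

  # ES: maximal edges that are not minimal faces; C' over them; E' = E ∩ C'
  mt <- which(is_max & sz > min(K))
  if (length(mt) == 0) {
    es <- list(num = NA, den = NA, value = NA_real_)
    d_es <- 0L
    d_nes <- NA_real_
    fes <- list(value = NA_real_)
    fes_pairs <- NULL
  } else {
    ckeys <- unique(unlist(lapply(mt, function(i) {
      subs <- oracle_subsets(edges[[i]])
      subs <- subs[sapply(subs, length) %in% K]
      sapply(subs, okey)
    })))
    nC <- length(ckeys)
    nE <- sum(keys %in% ckeys)
    nM <- length(mt)
    es <- if (nC == nM) list(num = NA, den = NA, value = NA_real_)
          else list(num = nE - nM, den = nC - nM,
                    value = (nE - nM) / (nC - nM))
    d_es <- nC - nE
    d_nes <- if (is.na(es$value)) NA_real_ else 1 - es$value

    # FES over the same face set: per-face (distance, powerset size) pairs
    fes_pairs <- t(sapply(mt, function(i) {
      subs <- oracle_subsets(edges[[i]])
      subs <- subs[sapply(subs, length) %in% K]
      p <- length(subs)
      d <- p - sum(sapply(subs, okey) %in% keys)
      c(d = d, p = p)
    }))
    fes <- list(value = mean(1 - fes_pairs[, "d"] / (fes_pairs[, "p"] - 1)))
  }

  list(sf = sf, es = es, fes = fes, fes_pairs = fes_pairs,
       d_es = d_es, d_nes = d_nes)
}

# random simple hypergraph for fuzzing
random_hypergraph <- function(n_nodes = NULL, n_edges = NULL,
                              max_edge_size = 6) {
  if (is.null(n_nodes)) n_nodes <- sample(4:12, 1)
  if (is.null(n_edges)) n_edges <- sample(1:40, 1)
  edges <- lapply(seq_len(n_edges), function(i) {
    s <- sample(2:min(max_edge_size, n_nodes), 1)
    sample(as.character(seq_len(n_nodes)), s)
  })
  hypergraph(edges)
}

default_K <- function() size_restriction()

# add one absent proper subface of an existing non-minimal maximal edge;
# returns NULL when the hypergraph has no such missing subface
add_missing_subface <- function(h, restriction = size_restriction()) {
  maxed <- maximal_edges(h)
  maxed <- maxed[lengths(maxed) > min(restriction$sizes)]
  for (e in maxed) {
    subs <- restricted_powerset(e, restriction)
    subs <- subs[lengths(subs) < length(e)]
    missing <- subs[!sapply(subs, okey) %in% sapply(h$edges, okey)]
    if (length(missing)) {
      return(hypergraph(c(h$edges, missing[1]), nodes = h$nodes))
    }
  }
  NULL
}

# exact-agreement assertion between package measures and the oracle
expect_matches_oracle <- function(h, restriction = size_restriction()) {
  orc <- oracle_measures(h$edges, K = restriction$sizes)
  sf <- simplicial_fraction(h, restriction)
  es <- edit_simpliciality(h, restriction)
  fes <- face_edit_simpliciality(h, restriction)
  if (is.na(orc$sf$value)) expect_true(is.na(sf)) else
    expect_identical(sf, orc$sf$num / orc$sf$den)
  if (is.na(orc$es$value)) expect_true(is.na(es)) else
    expect_identical(es, orc$es$num / orc$es$den)
  if (is.na(orc$fes$value)) {
    expect_true(is.na(fes))
  } else {
    expect_equal(fes, orc$fes$value)
    # exact rational content: the per-face (distance, powerset-size) pairs
    impl <- simpliciality:::.global_counts(h, restriction)$per_face
    impl_pairs <- impl[order(impl$face_edit_distance, impl$powerset_size),
                       c("face_edit_distance", "powerset_size")]
    orc_pairs <- orc$fes_pairs[order(orc$fes_pairs[, "d"],
                                     orc$fes_pairs[, "p"]), , drop = FALSE]
    expect_identical(unname(as.integer(impl_pairs$face_edit_distance)),
                     unname(as.integer(orc_pairs[, "d"])))
    expect_identical(unname(as.integer(impl_pairs$powerset_size)),
                     unname(as.integer(orc_pairs[, "p"])))
  }
  invisible(list(sf = sf, es = es, fes = fes, oracle = orc))
}
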