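test_that("construction canonicalizes edges with set semantics", {
  h <- hypergraph(list(c(1, 2), c(2, 1), c(1, 1, 2, 3)))
  expect_setequal(sapply(h$edges, paste, collapse = ","), c("1,2", "1,2,3"))
  expect_identical(h$nodes, c("1", "2", "3"))

  expect_identical(num_edges(hypergraph(list())), 0L)
  expect_identical(num_nodes(hypergraph(list())), 0L)

  # isolated nodes may be declared explicitly
  h2 <- hypergraph(list(c("a", "b")), nodes = c("a", "b", "z"))
  expect_true("z" %in% h2$nodes)
  expect_identical(unname(degrees(h2)["z"]), 0L)
})

test_that("duplicate collapsing matches brute-force set deduplication", {
  set.seed(41)
  raw <- lapply(1:100, function(i) {
    sample(as.character(1:8), sample(2:4, 1), replace = TRUE)
  })
  raw <- c(raw, raw[sample(100, 30)]) # inject exact duplicates
  h <- hypergraph(raw)
  distinct <- unique(sapply(raw, function(e) {
    paste(sort(unique(e)), collapse = "|")
  }))
  expect_identical(num_edges(h), length(distinct))
})

test_that("preprocess removes singletons, oversized edges, isolated nodes", {
  h <- hypergraph(list("1", c("1", "2"), as.character(1:12)))
  p <- preprocess(h, size_restriction(max_size = 11))
  expect_identical(lapply(p$edges, identity), list(c("1", "2")))
  expect_identical(p$nodes, c("1", "2"))

  # fixed point on clean input
  clean <- hypergraph(list(1:3, c(1, 2)))
  expect_identical(preprocess(clean), clean)

  # random hypergraph with planted violations vs an independent filter pass
  set.seed(7)
  raw <- c(
    lapply(1:30, function(i) sample(as.character(1:15), sample(1:13, 1))),
    list("99", as.character(1:12))
  )
  h <- hypergraph(raw)
  p <- preprocess(h, size_restriction(min_size = 2, max_size = 11))
  surviving <- Filter(function(e) length(e) >= 2 && length(e) <= 11, h$edges)
  expect_setequal(
    sapply(p$edges, paste, collapse = "|"),
    sapply(surviving, paste, collapse = "|")
  )
  expect_setequal(p$nodes, unique(unlist(surviving)))
})

test_that("maximal edges are exactly the non-included edges", {
  expect_identical(
    maximal_edges(hypergraph(list(1:2, 1:3))),
    list(as.character(1:3))
  )
  h <- hypergraph(list(c(1, 2), c(3, 4)))
  expect_length(maximal_edges(h), 2L)

  # against the O(|E|^2) all-pairs containment oracle
  set.seed(11)
  for (rep in 1:5) {
    h <- random_hypergraph(n_nodes = 12, n_edges = 200, max_edge_size = 6)
    got <- sapply(maximal_edges(h), paste, collapse = "|")
    edges <- h$edges
    want <- sapply(
      Filter(function(e) {
        !any(sapply(edges, function(f) {
          length(f) > length(e) && all(e %in% f)
        }))
      }, edges),
      paste, collapse = "|"
    )
    expect_setequal(got, want)
  }
})

test_that("maximal edge set is an antichain covering every edge", {
  set.seed(13)
  for (rep in 1:10) {
    h <- random_hypergraph()
    maxed <- maximal_edges(h)
    for (i in seq_along(maxed)) {
      for (j in seq_along(maxed)) {
        if (i != j) expect_false(all(maxed[[i]] %in% maxed[[j]]))
      }
    }
    for (e in h$edges) {
      expect_true(any(sapply(maxed, function(f) all(e %in% f))))
    }
  }
})

test_that("restricted power set enumerates subsets with sizes in K", {
  e <- as.character(1:3)
  got <- restricted_powerset(e, size_restriction(sizes = 2))
  expect_setequal(
    sapply(got, paste, collapse = ","),
    c("1,2", "1,3", "2,3")
  )

  # size-4 edge, K = {2,3}: 2^4 - 4 - 2 = 10 subfaces
  expect_length(
    restricted_powerset(as.character(1:4), size_restriction(sizes = 2:3)),
    10L
  )

  # exhaustive enumeration for a size-3 edge, K = {2,3}
  all_subs <- oracle_subsets(as.character(1:3))
  all_subs <- all_subs[sapply(all_subs, length) %in% 2:3]
  got <- restricted_powerset(as.character(1:3), size_restriction(sizes = 2:3))
  expect_setequal(sapply(got, okey), sapply(all_subs, okey))
  expect_length(got, 4L)

  expect_error(
    restricted_powerset(as.character(1:12), size_restriction(max_size = 11)),
    "max_size"
  )
})

test_that("restricted power set size obeys the binomial identity", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:9, 1)
    K <- sort(sample(1:11, sample(1:4, 1)))
    r <- size_restriction(sizes = K, max_size = 11)
    got <- length(restricted_powerset(as.character(seq_len(n)), r))
    want <- sum(choose(n, K[K <= n]))
    expect_identical(got, as.integer(want))
  }
})

test_that("minimal faces are the edges of size min(K)", {
  h <- hypergraph(list(c(1, 2), c(3, 4), 1:3))
  expect_setequal(
    sapply(minimal_faces(h), paste, collapse = ","),
    c("1,2", "3,4")
  )
  h2 <- hypergraph(list(1:3, 1:4))
  expect_length(minimal_faces(h2), 0L)

  set.seed(19)
  h3 <- random_hypergraph()
  expect_setequal(
    sapply(minimal_faces(h3), okey),
    sapply(Filter(function(e) length(e) == 2, h3$edges), okey)
  )
})

test_that("is_simplex checks restricted downward closure", {
  closed <- hypergraph(list(1:3, c(1, 2), c(1, 3), c(2, 3)))
  expect_true(is_simplex(1:3, closed))
  open <- hypergraph(list(1:3, c(1, 2)))
  expect_false(is_simplex(1:3, open))
  expect_error(is_simplex(c(7, 8), open), "not an edge")

  # exhaustive subset-membership oracle on random edges
  set.seed(23)
  for (rep in 1:20) {
    h <- random_hypergraph(n_nodes = 8, n_edges = 25, max_edge_size = 5)
    for (i in seq_along(h$edges)) {
      e <- h$edges[[i]]
      subs <- oracle_subsets(e)
      subs <- subs[sapply(subs, length) %in% 2:11]
      want <- all(sapply(subs, okey) %in% sapply(h$edges, okey))
      expect_identical(is_simplex(e, h), want)
    }
  }
})

test_that("induced simplicial complex closes the maximal edges", {
  r23 <- size_restriction(sizes = 2:3)
  C <- induced_simplicial_complex(hypergraph(list(1:3, c(1, 2))), r23)
  expect_setequal(
    sapply(C$edges, paste, collapse = ","),
    c("1,2,3", "1,2", "1,3", "2,3")
  )

  # fixed point on a complex, and |C| = 8 for two bare disjoint triangles
  closed <- hypergraph(list(1:3, c(1, 2), c(1, 3), c(2, 3)))
  expect_identical(induced_simplicial_complex(closed, r23)$keys, closed$keys)
  expect_identical(
    num_edges(induced_simplicial_complex(hypergraph(list(1:3, 4:6)), r23)),
    8L
  )
})

test_that("induced simplicial complex is idempotent", {
  set.seed(29)
  for (rep in 1:10) {
    h <- preprocess(random_hypergraph())
    C <- induced_simplicial_complex(h)
    expect_identical(induced_simplicial_complex(C)$keys, C$keys)
  }
})
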