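# Global measures on worked toy hypergraphs and against the brute-force
# oracle; invariants (range, closure, monotonicity, internal consistency).

toy_open <- hypergraph(list(1:3, c(1, 2)))
toy_two <- hypergraph(list(1:3, 4:6, c(1, 2), c(1, 3), c(2, 3)))
toy_closed <- hypergraph(list(1:3, c(1, 2), c(1, 3), c(2, 3)))

test_that("simplicial fraction on worked toys", {
  expect_identical(simplicial_fraction(toy_closed), 1)
  expect_identical(simplicial_fraction(toy_open), 0)
  expect_identical(simplicial_fraction(toy_two), 1 / 2)
  expect_true(is.na(simplicial_fraction(hypergraph(list()))))
  # only minimal faces: no candidate simplices
  expect_true(is.na(simplicial_fraction(hypergraph(list(c(1, 2), c(3, 4))))))
})

test_that("edit simpliciality on worked toys", {
  expect_identical(edit_simpliciality(toy_closed), 1)
  expect_identical(edit_simpliciality(toy_open), 1 / 3)
  expect_identical(edit_simpliciality(toy_two), 1 / 2)
  # sole maximal edge is a minimal face: degenerate denominator
  expect_true(is.na(edit_simpliciality(hypergraph(list(c(1, 2))))))
  expect_true(is.na(edit_simpliciality(hypergraph(list()))))
})

test_that("simplicial edit distance and its normalized form", {
  expect_identical(simplicial_edit_distance(toy_closed), 0L)
  expect_identical(simplicial_edit_distance(toy_open), 2L)
  expect_equal(simplicial_edit_distance(toy_open, normalized = TRUE), 2 / 3)

  set.seed(31)
  for (rep in 1:10) {
    h <- random_hypergraph()
    es <- edit_simpliciality(h)
    dn <- simplicial_edit_distance(h, normalized = TRUE)
    if (is.na(es)) expect_true(is.na(dn)) else expect_equal(dn + es, 1)
  }
})

test_that("face edit distance counts missing subfaces", {
  r23 <- size_restriction(sizes = 2:3)
  expect_identical(face_edit_distance(1:3, toy_open, r23), 2L)
  expect_identical(face_edit_distance(1:3, toy_closed), 0L)
  expect_error(face_edit_distance(c(8, 9), toy_open), "not an edge")

  # an edge with no subfaces present has normalized distance exactly 1
  bare <- hypergraph(list(1:4))
  d <- face_edit_distance(1:4, bare)
  p <- length(restricted_powerset(as.character(1:4)))
  expect_identical(d, p - 1L)
  expect_identical(mean_face_edit_distance(bare, normalized = TRUE), 1)
})

test_that("face edit simpliciality on worked toys", {
  expect_identical(face_edit_simpliciality(toy_closed), 1)
  expect_equal(face_edit_simpliciality(toy_open), 1 / 3)
  expect_equal(face_edit_simpliciality(toy_two), 1 / 2)
  expect_true(is.na(face_edit_simpliciality(hypergraph(list()))))
  expect_equal(mean_face_edit_distance(toy_two), 3 / 2) # (3 + 0) / 2
})

test_that("full report agrees with the individual operations", {
  set.seed(37)
  for (rep in 1:15) {
    h <- random_hypergraph()
    rep_ <- simpliciality_report(h)
    expect_identical(rep_$sf, simplicial_fraction(h))
    expect_identical(rep_$es, edit_simpliciality(h))
    expect_identical(rep_$fes, face_edit_simpliciality(h))
    expect_identical(rep_$es_distance, simplicial_edit_distance(h))
    expect_identical(
      rep_$mean_face_edit_distance, mean_face_edit_distance(h)
    )
    if (!is.na(rep_$es)) {
      expect_equal(rep_$es_distance_normalized, 1 - rep_$es)
    }
    if (!is.na(rep_$fes)) {
      expect_equal(rep_$mean_normalized_face_edit_distance, 1 - rep_$fes)
    }
  }
})

test_that("undefined measures are flagged with reasons, never 0 or 1", {
  rep_empty <- simpliciality_report(hypergraph(list()))
  expect_true(all(is.na(c(rep_empty$sf, rep_empty$es, rep_empty$fes))))
  expect_identical(unname(rep_empty$undefined["sf"]), "empty_hypergraph")

  rep_min <- simpliciality_report(hypergraph(list(c(1, 2), c(3, 4))))
  expect_identical(unname(rep_min$undefined["sf"]), "no_candidate_simplices")
  expect_identical(unname(rep_min$undefined["es"]), "degenerate_denominator")
})

test_that("measures match the brute-force oracle on random hypergraphs", {
  set.seed(43)
  for (rep in 1:60) {
    expect_matches_oracle(random_hypergraph())
  }
  # also under a non-default restriction (sizes 2-3, as for assortativity)
  r23 <- size_restriction(max_size = 3)
  for (rep in 1:20) {
    expect_matches_oracle(random_hypergraph(max_edge_size = 5), r23)
  }
})

test_that("a hypergraph equal to its induced complex scores 1 everywhere", {
  set.seed(47)
  for (rep in 1:10) {
    h <- preprocess(random_hypergraph())
    if (num_edges(h) == 0) next
    C <- induced_simplicial_complex(h)
    rep_ <- simpliciality_report(C)
    if (!is.na(rep_$sf)) expect_identical(rep_$sf, 1)
    if (!is.na(rep_$es)) expect_identical(rep_$es, 1)
    if (!is.na(rep_$fes)) expect_identical(rep_$fes, 1)
  }
})

test_that("adding a missing subface raises ES strictly, never lowers FES", {
  set.seed(53)
  tested <- 0
  while (tested < 25) {
    h <- preprocess(random_hypergraph())
    h2 <- add_missing_subface(h)
    if (is.null(h2)) next
    tested <- tested + 1
    es1 <- edit_simpliciality(h)
    es2 <- edit_simpliciality(h2)
    if (!is.na(es1) && !is.na(es2)) expect_gt(es2, es1)
    fes1 <- face_edit_simpliciality(h)
    fes2 <- face_edit_simpliciality(h2)
    if (!is.na(fes1) && !is.na(fes2)) expect_gte(fes2, fes1)
  }
})

test_that("defined measures always lie in [0, 1]", {
  set.seed(59)
  for (rep in 1:40) {
    h <- random_hypergraph()
    vals <- c(simplicial_fraction(h), edit_simpliciality(h),
              face_edit_simpliciality(h))
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("summary row mirrors the structural properties", {
  row <- summary_row(toy_two, name = "toy")
  expect_identical(row$dataset, "toy")
  expect_identical(row$n_nodes, 6L)
  expect_identical(row$n_edges, 5L)
  expect_equal(row$mean_edge_size, 12 / 5)
  expect_equal(row$mean_degree, 2)
  expect_equal(unlist(row[c("sf", "es", "fes")], use.names = FALSE),
               c(0.5, 0.5, 0.5))
})
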