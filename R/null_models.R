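# Randomized baselines: a degree- and size-preserving configuration model
# sampled by bipartite double edge swaps, a bipartite Chung-Lu sampler, and
# an ensemble harness that scores samples with the full measure report.

#' Degree and edge-size sequences
#'
#' The sufficient statistics fitted by both null models: per-node incident
#' edge counts and the multiset of edge sizes. The bipartite handshake
#' `sum(degrees) == sum(sizes)` always holds for sequences extracted from a
#' hypergraph.
#'
#' @param h A [hypergraph()].
#' @return An object of class `"degree_size_sequences"`: a list with
#'   `degrees` (named integer vector) and `sizes` (integer vector).
#' @export
degree_size_sequences <- function(h) {
  stopifnot(is_hypergraph(h))
  structure(
    list(degrees = degrees(h), sizes = as.integer(edge_sizes(h))),
    class = "degree_size_sequences"
  )
}

#' @export
print.degree_size_sequences <- function(x, ...) {
  cat(sprintf(
    "Degree/size sequences: %d nodes (degree sum %d), %d edges (size sum %d)\n",
    length(x$degrees), sum(x$degrees), length(x$sizes), sum(x$sizes)
  ))
  invisible(x)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Configuration-model sample via bipartite double edge swaps
#'
#' Randomizes a hypergraph while preserving the node degree sequence and
#' the edge size sequence exactly. Each swap picks two (node, edge)
#' incidences uniformly at random and exchanges their node endpoints; a
#' swap that would place a repeated node inside an edge or create a
#' duplicate edge is rejected and retried. `n_swaps` counts accepted swaps;
#' a safety cap of `max(100 * |E|, 10 * n_swaps)` attempts guards against
#' inputs with no admissible swap.
#'
#' @param h A preprocessed [hypergraph()].
#' @param n_swaps Number of accepted swaps; defaults to `10 * |E|`, after
#'   which the chain is conventionally taken as mixed.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards. Identical seeds give identical samples.
#' @return A [hypergraph()] with the same degree and size sequences.
#' @export
configuration_model_sample <- function(h, n_swaps = NULL, seed = NULL) {
  stopifnot(is_hypergraph(h))
  m <- length(h$edges)
  if (is.null(n_swaps)) n_swaps <- 10L * m
  stopifnot(n_swaps >= 0)
  if (m < 2L) {
    warning("hypergraph has fewer than 2 edges; returning an identical copy")
    return(hypergraph(h$edges, nodes = h$nodes))
  }
  if (n_swaps == 0L) return(hypergraph(h$edges, nodes = h$nodes))

  .with_seed(seed, {
    edges <- h$edges
    sz <- lengths(edges)
    inc_edge <- rep.int(seq_len(m), sz)
    inc_node <- unlist(edges, use.names = FALSE)
    n_inc <- length(inc_node)
    keyenv <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(m)) assign(.edge_key(edges[[i]]), i, envir = keyenv)

    accepted <- 0L
    attempts <- 0L
    cap <- max(100 * m, 10 * n_swaps)
    while (accepted < n_swaps && attempts < cap) {
      attempts <- attempts + 1L
      ab <- sample.int(n_inc, 2L)
      e1 <- inc_edge[ab[1L]]
      e2 <- inc_edge[ab[2L]]
      u <- inc_node[ab[1L]]
      w <- inc_node[ab[2L]]
      if (e1 == e2 || u == w) next
      if (w %in% edges[[e1]] || u %in% edges[[e2]]) next
      new1 <- .canon_edge(c(setdiff(edges[[e1]], u), w))
      new2 <- .canon_edge(c(setdiff(edges[[e2]], w), u))
      k1 <- .edge_key(new1)
      k2 <- .edge_key(new2)
      if (k1 == k2) next
      hit1 <- get0(k1, envir = keyenv, inherits = FALSE)
      if (!is.null(hit1) && hit1 != e1 && hit1 != e2) next
      hit2 <- get0(k2, envir = keyenv, inherits = FALSE)
      if (!is.null(hit2) && hit2 != e1 && hit2 != e2) next
      rm(list = c(.edge_key(edges[[e1]]), .edge_key(edges[[e2]])),
         envir = keyenv)
      assign(k1, e1, envir = keyenv)
      assign(k2, e2, envir = keyenv)
      edges[[e1]] <- new1
      edges[[e2]] <- new2
      inc_node[ab[1L]] <- w
      inc_node[ab[2L]] <- u
      accepted <- accepted + 1L
    }
    if (accepted < n_swaps) {
      warning(sprintf(
        "attempt cap reached: %d of %d swaps accepted", accepted, n_swaps
      ))
    }
    out <- hypergraph(edges, nodes = h$nodes)
    attr(out, "accepted_swaps") <- accepted
    attr(out, "attempts") <- attempts
    out
  })
}

#' Bipartite Chung-Lu sample
#'
#' Samples a hypergraph in which node `i` joins an edge of size `s` with
#' probability `min(1, k_i * s / sum(k))`, so degrees and sizes match the
#' target sequences in expectation (not exactly). Each edge is filled with
#' the efficient geometric-skipping construction over nodes sorted by
#' weight, so the cost is proportional to the realized incidences rather
#' than `|V| * |E|`. Duplicate sampled edges are collapsed to keep the
#' simple-hypergraph contract; the number collapsed is recorded in the
#' `"duplicates_collapsed"` attribute.
#'
#' @param sequences A [degree_size_sequences()] object (or a list with
#'   `degrees` and `sizes`). The bipartite handshake
#'   `sum(degrees) == sum(sizes)` must hold.
#' @param seed Optional integer seed.
#' @return A [hypergraph()] on the nodes named in `degrees`; empty sampled
#'   edges are dropped.
#' @export
chung_lu_sample <- function(sequences, seed = NULL) {
  stopifnot(is.list(sequences), !is.null(sequences$degrees),
            !is.null(sequences$sizes))
  k <- sequences$degrees
  sizes <- as.integer(sequences$sizes)
  if (is.null(names(k))) names(k) <- as.character(seq_along(k))
  if (sum(k) != sum(sizes)) {
    stop("inconsistent sequences: sum of degrees must equal sum of sizes")
  }
  S <- sum(k)
  if (S == 0) return(hypergraph(list(), nodes = names(k)))
  ord <- order(-as.numeric(k))
  w <- as.numeric(k)[ord]
  labels <- names(k)[ord]
  n <- length(w)

  .with_seed(seed, {
    raw <- vector("list", length(sizes))
    for (jj in seq_along(sizes)) {
      s <- sizes[jj]
      members <- character(0L)
      i <- 1L
      p <- 1
      while (i <= n) {
        if (p < 1) {
          if (p <= 0) break
          i <- i + floor(log(stats::runif(1)) / log1p(-p))
          if (i > n) break
        }
        q <- min(1, w[i] * s / S)
        if (stats::runif(1) < q / p) members <- c(members, labels[i])
        p <- q
        i <- i + 1L
      }
      raw[[jj]] <- members
    }
    raw <- raw[lengths(raw) > 0L]
    out <- hypergraph(raw, nodes = names(k))
    attr(out, "duplicates_collapsed") <- length(raw) - length(out$edges)
    out
  })
}

#' Null-model ensemble of simpliciality values
#'
#' Fits a null model to a hypergraph, draws `n_samples` realizations, and
#' scores each with [simpliciality_report()] after preprocessing each
#' sample identically to the empirical data. One master seed spawns the
#' per-sample seeds deterministically, so ensembles are reproducible and
#' order-invariant. Undefined per-sample measures are dropped from the
#' summaries with a recorded count.
#'
#' @param h A [hypergraph()] (the empirical data; preprocessed internally).
#' @param model `"configuration"` (exact degree/size sequences, double edge
#'   swaps), `"chung_lu"` (sequences matched in expectation), or
#'   `"external"` (score user-supplied samples, e.g. from a bipartite
#'   stochastic block model sampled with outside tooling).
#' @param n_samples Number of realizations (the conventional ensemble size
#'   for dataset baselining is 1000).
#' @param restriction A [size_restriction()] applied to the empirical data
#'   and to every sample.
#' @param seed Optional master seed.
#' @param n_swaps Accepted-swap count per configuration-model sample;
#'   defaults to `10 * |E|`.
#' @param samples For `model = "external"`: a list of [hypergraph()]s or of
#'   file paths readable by [read_hypergraph()].
#' @param external_format Format passed to [read_hypergraph()] for external
#'   sample paths.
#' @return An object of class `"simpliciality_ensemble"`: a list with the
#'   `empirical` report, a per-sample data frame `samples` (columns `sample`,
#'   `sf`, `es`, `fes`, `es_distance`), and a `summary` data frame (mean,
#'   sd, quantiles, number of undefined samples per measure).
#' @export
ensemble_simpliciality <- function(h,
                                   model = c("configuration", "chung_lu",
                                             "external"),
                                   n_samples = 1000L,
                                   restriction = size_restriction(),
                                   seed = NULL,
                                   n_swaps = NULL,
                                   samples = NULL,
                                   external_format = "edgelist") {
  stopifnot(is_hypergraph(h))
  model <- match.arg(model)
  restriction <- .check_restriction(restriction)
  hp <- preprocess(h, restriction)
  empirical <- simpliciality_report(hp, restriction)

  if (model == "external") {
    if (is.null(samples)) stop("model = 'external' requires `samples`")
    sample_list <- lapply(samples, function(s) {
      if (is_hypergraph(s)) s else read_hypergraph(s, external_format)
    })
    n_samples <- length(sample_list)
    sample_seeds <- rep(NA_integer_, n_samples)
  } else {
    n_samples <- as.integer(n_samples)
    stopifnot(n_samples >= 1L)
    sample_seeds <- .with_seed(seed,
      sample.int(.Machine$integer.max - 1L, n_samples)
    )
    seqs <- if (model == "chung_lu") degree_size_sequences(hp) else NULL
    sample_list <- lapply(seq_len(n_samples), function(i) {
      switch(model,
        configuration = configuration_model_sample(
          hp, n_swaps = n_swaps, seed = sample_seeds[i]
        ),
        chung_lu = chung_lu_sample(seqs, seed = sample_seeds[i])
      )
    })
  }

  rows <- lapply(seq_along(sample_list), function(i) {
    rep <- simpliciality_report(
      preprocess(sample_list[[i]], restriction), restriction
    )
    data.frame(
      sample = i, sf = rep$sf, es = rep$es, fes = rep$fes,
      es_distance = rep$es_distance
    )
  })
  df <- do.call(rbind, rows)

  summarize <- function(v) {
    ok <- v[!is.na(v)]
    if (!length(ok)) {
      return(c(mean = NA, sd = NA, q025 = NA, q25 = NA, median = NA,
               q75 = NA, q975 = NA, n_undefined = sum(is.na(v))))
    }
    q <- stats::quantile(ok, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    c(mean = mean(ok), sd = stats::sd(ok), q025 = q[1], q25 = q[2],
      median = q[3], q75 = q[4], q975 = q[5], n_undefined = sum(is.na(v)))
  }
  summ <- as.data.frame(t(vapply(
    df[c("sf", "es", "fes")], summarize, numeric(8L)
  )))
  summ <- cbind(measure = rownames(summ), summ)
  rownames(summ) <- NULL

  structure(
    list(
      model = model, n_samples = n_samples, seed = seed,
      restriction = restriction, empirical = empirical,
      samples = df, summary = summ
    ),
    class = "simpliciality_ensemble"
  )
}

#' @export
print.simpliciality_ensemble <- function(x, ...) {
  cat(sprintf(
    "Simpliciality ensemble: model = %s, %d samples\n", x$model, x$n_samples
  ))
  emp <- c(sf = x$empirical$sf, es = x$empirical$es, fes = x$empirical$fes)
  for (i in seq_len(nrow(x$summary))) {
    m <- x$summary$measure[i]
    cat(sprintf(
      "  %-3s empirical %s | ensemble mean %s (sd %s, %d undefined)\n",
      m,
      formatC(emp[[m]], digits = 3, format = "g"),
      formatC(x$summary$mean[i], digits = 3, format = "g"),
      formatC(x$summary$sd[i], digits = 3, format = "g"),
      as.integer(x$summary$n_undefined[i])
    ))
  }
  invisible(x)
}
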