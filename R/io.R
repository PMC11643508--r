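# Readers and writers for the three supported hypergraph formats:
#   edgelist  — one edge per line, labels separated by commas or whitespace;
#               blank lines and '#' comments ignored
#   bipartite — two columns (node-label, edge-id); edges grouped on edge-id
#   json      — the JSON hypergraph dialect of the public xgi-data
#               repository ("node-data" / "edge-dict"), with a tolerant
#               fallback to a plain {"nodes": [...], "edges": {...}} layout

.split_tokens <- function(line) {
  toks <- strsplit(trimws(line), "[,[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}

.read_content_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_content <- nzchar(trimws(lines)) & !grepl("^[[:space:]]*#", lines)
  list(lines = lines, content = which(is_content))
}

#' Read a hypergraph from a file
#'
#' @param path Path to the input file.
#' @param format One of `"edgelist"`, `"bipartite"`, `"json"`.
#' @return A canonical simple [hypergraph()]. Parse statistics (lines read,
#'   duplicate edges collapsed) are attached as the `"parse_stats"`
#'   attribute.
#' @export
read_hypergraph <- function(path,
                            format = c("edgelist", "bipartite", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  switch(format,
    edgelist = .read_edgelist(path),
    bipartite = .read_bipartite(path),
    json = .read_xgi_json(path)
  )
}

.read_edgelist <- function(path) {
  parsed <- .read_content_lines(path)
  raw <- vector("list", length(parsed$content))
  for (idx in seq_along(parsed$content)) {
    ln <- parsed$content[idx]
    toks <- .split_tokens(parsed$lines[ln])
    if (!length(toks)) {
      stop(sprintf("%s:%d: malformed edge line: %s",
                   path, ln, parsed$lines[ln]))
    }
    raw[[idx]] <- toks
  }
  .finish_read(raw, length(parsed$lines))
}

.read_bipartite <- function(path) {
  parsed <- .read_content_lines(path)
  node <- character(length(parsed$content))
  eid <- character(length(parsed$content))
  for (idx in seq_along(parsed$content)) {
    ln <- parsed$content[idx]
    toks <- .split_tokens(parsed$lines[ln])
    if (length(toks) != 2L) {
      stop(sprintf(
        "%s:%d: expected two columns (node, edge-id), got %d",
        path, ln, length(toks)
      ))
    }
    node[idx] <- toks[1L]
    eid[idx] <- toks[2L]
  }
  raw <- unname(split(node, eid))
  .finish_read(raw, length(parsed$lines))
}

.read_xgi_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc[["edge-dict"]])) {
    raw <- lapply(doc[["edge-dict"]], function(e) {
      as.character(unlist(e, use.names = FALSE))
    })
    nodes <- if (!is.null(doc[["node-data"]])) names(doc[["node-data"]])
  } else if (!is.null(doc[["edges"]])) {
    raw <- lapply(doc[["edges"]], function(e) {
      as.character(unlist(e, use.names = FALSE))
    })
    nodes <- if (!is.null(doc[["nodes"]])) {
      as.character(unlist(doc[["nodes"]], use.names = FALSE))
    }
  } else {
    stop(sprintf("%s: no 'edge-dict' or 'edges' object found", path))
  }
  h <- hypergraph(unname(raw), nodes = nodes)
  attr(h, "parse_stats") <- list(
    lines_read = NA_integer_,
    raw_edges = length(raw),
    duplicates_collapsed = length(raw) - num_edges(h)
  )
  h
}

.finish_read <- function(raw, n_lines) {
  h <- hypergraph(raw)
  attr(h, "parse_stats") <- list(
    lines_read = n_lines,
    raw_edges = length(raw),
    duplicates_collapsed = length(raw) - num_edges(h)
  )
  h
}

#' Write a hypergraph to a file
#'
#' Writers are deterministic: edges are emitted in canonical order (by size,
#' then lexicographically) and node labels within an edge are sorted, so a
#' write–read round trip reproduces the edge set exactly in any format.
#'
#' @param h A [hypergraph()].
#' @param path Output path.
#' @param format One of `"edgelist"`, `"bipartite"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_hypergraph <- function(h, path,
                             format = c("edgelist", "bipartite", "json")) {
  stopifnot(is_hypergraph(h))
  format <- match.arg(format)
  switch(format,
    edgelist = writeLines(
      vapply(h$edges, paste, character(1L), collapse = " "), path
    ),
    bipartite = {
      eid <- sprintf("e%d", rep.int(seq_along(h$edges), lengths(h$edges)))
      writeLines(
        paste(unlist(h$edges, use.names = FALSE), eid, sep = "\t"), path
      )
    },
    json = {
      edge_dict <- stats::setNames(
        lapply(h$edges, as.list),
        sprintf("e%d", seq_along(h$edges))
      )
      node_data <- stats::setNames(
        rep(list(structure(list(), names = character(0L))),
            length(h$nodes)),
        h$nodes
      )
      doc <- list(
        `hypergraph-data` = structure(list(), names = character(0L)),
        `node-data` = node_data,
        `edge-dict` = edge_dict
      )
      jsonlite::write_json(doc, path, auto_unbox = TRUE)
    }
  )
  invisible(path)
}

#' Planted-inclusion synthetic hypergraph
#'
#' Generates a hypergraph with a controlled inclusion structure: a set of
#' "planted" edges is drawn (sizes from `size_distribution`, members uniform
#' without replacement), and then every size-restricted proper subface of
#' every planted edge is added independently with probability `q`. At
#' `q = 1` the output is downward-closed (all measures equal 1); at `q = 0`
#' with mutually non-including planted edges there are no inclusions at all
#' (all measures equal 0). Sweeping `q` traces the full simpliciality
#' spectrum.
#'
#' @param n_nodes Number of available nodes (labelled `"1"` ... `"n"`).
#' @param n_maximal_edges Number of planted edges to draw.
#' @param size_distribution Named numeric vector of probabilities; names are
#'   edge sizes (within `2:max_size` of `restriction`). Probabilities are
#'   normalized to sum to 1.
#' @param inclusion_probability Probability `q` in `[0, 1]` that each
#'   subface of a planted edge is present.
#' @param restriction A [size_restriction()] governing which subface sizes
#'   exist.
#' @param seed Optional integer seed.
#' @return A canonical simple [hypergraph()].
#' @examples
#' h <- generate_planted_inclusion(
#'   30, 8, c(`3` = 0.5, `4` = 0.5), inclusion_probability = 1, seed = 1
#' )
#' simplicial_fraction(h) # 1
#' @export
generate_planted_inclusion <- function(n_nodes,
                                       n_maximal_edges,
                                       size_distribution,
                                       inclusion_probability,
                                       restriction = size_restriction(),
                                       seed = NULL) {
  restriction <- .check_restriction(restriction)
  n_nodes <- as.integer(n_nodes)
  n_maximal_edges <- as.integer(n_maximal_edges)
  q <- inclusion_probability
  stopifnot(n_nodes >= 1L, n_maximal_edges >= 0L, q >= 0, q <= 1,
            length(size_distribution) >= 1L,
            !is.null(names(size_distribution)))
  sizes <- as.integer(names(size_distribution))
  probs <- as.numeric(size_distribution)
  stopifnot(all(probs >= 0), sum(probs) > 0)
  if (any(sizes < 2L) || any(sizes > restriction$max_size)) {
    stop("planted edge sizes must lie within 2..max_size of the restriction")
  }
  if (any(sizes > n_nodes)) {
    stop("requested edge size exceeds the number of nodes")
  }
  probs <- probs / sum(probs)
  node_labels <- as.character(seq_len(n_nodes))

  .with_seed(seed, {
    drawn_sizes <- sizes[sample.int(length(sizes), n_maximal_edges,
                                    replace = TRUE, prob = probs)]
    planted <- lapply(drawn_sizes, function(s) sample(node_labels, s))
    extra <- list()
    for (e in planted) {
      subs <- restricted_powerset(e, restriction)
      subs <- subs[lengths(subs) < length(e)]
      if (length(subs)) {
        keep <- stats::runif(length(subs)) < q
        extra <- c(extra, subs[keep])
      }
    }
    hypergraph(c(planted, extra))
  })
}
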