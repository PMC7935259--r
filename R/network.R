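#' Directed weighted circulation networks
#'
#' A circulation network is a directed, weighted graph at a chosen
#' administrative level. A node is a province or a city; an edge u -> v
#' carries the number of substandard records whose manufacturer sits in u and
#' whose distributor sits in v. Self-loops (u = v) are stored explicitly —
#' they carry the within-unit ("local circulation") mass — but are excluded
#' from degree-based topology statistics (degree, density, betweenness,
#' communities, key players); within-unit mass is reported via
#' [within_unit_fraction()] instead.
#'
#' @param edges data frame with columns `source`, `destination`, `weight`
#'   (positive integers); at most one row per ordered pair.
#' @param level `"province"` or `"city"`.
#' @param nodes optional data frame with columns `unit_id`, `name`; defaults
#'   to the units appearing in `edges` with `name = unit_id`.
#' @return an object of class `circulation_network`: list with `level`,
#'   `nodes` (tibble), `edges` (tibble) and `n_records` (total edge weight,
#'   self-loops included).
#' @export
circulation_network <- function(edges, level = c("city", "province"),
                                nodes = NULL) {
  level <- match.arg(level)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("source", "destination", "weight") %in% names(edges)))
    if (any(edges$weight <= 0) || any(edges$weight != as.integer(edges$weight)))
      stop_circnet("edge weights must be positive integers")
    if (anyDuplicated(paste(edges$source, edges$destination, sep = "\r")))
      stop_circnet("at most one edge per ordered (source, destination) pair")
    edges$weight <- as.integer(edges$weight)
  } else {
    edges <- tibble::tibble(source = character(), destination = character(),
                            weight = integer())
  }
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$source, edges$destination)))
    nodes <- tibble::tibble(unit_id = ids, name = ids)
  } else {
    nodes <- tibble::as_tibble(nodes)
    if (!"name" %in% names(nodes)) nodes$name <- nodes$unit_id
    nodes <- nodes[, c("unit_id", "name")]
    if (anyDuplicated(nodes$unit_id)) stop_circnet("duplicate node unit_id")
    ref <- unique(c(edges$source, edges$destination))
    if (!all(ref %in% nodes$unit_id))
      stop_circnet("edges reference units absent from the node table")
  }
  structure(list(level = level, nodes = nodes, edges = edges,
                 n_records = sum(edges$weight)),
            class = "circulation_network")
}

#' @export
print.circulation_network <- function(x, ...) {
  nl <- sum(x$edges$source == x$edges$destination)
  cat(sprintf("<circulation_network> level=%s, %d nodes, %d edges (%d self-loops), %d records\n",
              x$level, nrow(x$nodes), nrow(x$edges), nl, x$n_records))
  invisible(x)
}

#' Build a circulation network from geo-resolved records
#'
#' Aggregates resolved records into edge weights: edge (u -> v) weight is the
#' number of records manufactured in u and distributed in v at the requested
#' level. Records unresolved at that level are excluded with an explicit
#' count.
#'
#' @param resolutions output of [resolve_records()].
#' @param level `"province"` or `"city"`.
#' @param gaz optional [gazetteer()]; supplies node display names.
#' @return a [circulation_network()]; attribute `n_dropped` counts excluded
#'   records.
#' @export
build_network <- function(resolutions, level = c("city", "province"), gaz = NULL) {
  level <- match.arg(level)
  src <- if (level == "city") resolutions$manu_city else resolutions$manu_province
  dst <- if (level == "city") resolutions$dist_city else resolutions$dist_province
  ok <- !is.na(src) & !is.na(dst)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " record(s) excluded: unresolved at ", level, " level")
  if (!any(ok)) {
    warning("no resolvable records; returning an empty network", call. = FALSE)
    net <- circulation_network(NULL, level = level)
    attr(net, "n_dropped") <- n_dropped
    return(net)
  }
  edges <- dplyr::count(tibble::tibble(source = src[ok], destination = dst[ok]),
                        .data$source, .data$destination, name = "weight")
  nodes <- NULL
  if (!is.null(gaz)) {
    ids <- sort(unique(c(edges$source, edges$destination)))
    nm <- stats::setNames(gaz$units$name, gaz$units$unit_id)
    nodes <- tibble::tibble(unit_id = ids,
                            name = dplyr::coalesce(unname(nm[ids]), ids))
  }
  net <- circulation_network(edges, level = level, nodes = nodes)
  attr(net, "n_dropped") <- n_dropped
  net
}

#' Fraction of circulation mass that stays within a unit
#'
#' Share of total edge weight carried by self-loops, i.e. the proportion of
#' substandard records whose manufacturer and distributor lie in the same
#' province (or city).
#'
#' @param net a [circulation_network()].
#' @return a proportion in [0, 1].
#' @export
within_unit_fraction <- function(net) {
  stopifnot(inherits(net, "circulation_network"))
  total <- sum(net$edges$weight)
  if (total == 0) stop_circnet("within_unit_fraction is undefined on a network with zero weight")
  sum(net$edges$weight[net$edges$source == net$edges$destination]) / total
}

#' Heaviest circulation paths
#'
#' Ranks edges by weight (record count on the route), descending, with ties
#' broken by (source name, destination name) lexicographically.
#'
#' @param net a [circulation_network()].
#' @param k number of paths to return (the full list if fewer exist).
#' @param exclude_self_loops drop within-unit routes first (default TRUE).
#' @return tibble with `source`, `destination`, `source_name`,
#'   `destination_name`, `weight`, `rank`.
#' @export
top_paths <- function(net, k = 10L, exclude_self_loops = TRUE) {
  stopifnot(inherits(net, "circulation_network"))
  k <- assert_scalar_count(k, "k")
  e <- net$edges
  if (exclude_self_loops) e <- e[e$source != e$destination, ]
  nm <- stats::setNames(net$nodes$name, net$nodes$unit_id)
  e$source_name <- unname(nm[e$source])
  e$destination_name <- unname(nm[e$destination])
  e <- e[order(-e$weight, e$source_name, e$destination_name), ]
  e <- utils::head(e, k)
  e$rank <- seq_len(nrow(e))
  e[, c("source", "destination", "source_name", "destination_name", "weight", "rank")]
}

#' Aggregate a city-level network to province level
#'
#' Maps every city node to its parent province (per the gazetteer) and sums
#' edge weights; city pairs inside the same province become province
#' self-loops. On data where both levels are resolvable this reproduces
#' [build_network()] at province level exactly.
#'
#' @param net a city-level [circulation_network()].
#' @param gaz a [gazetteer()] covering every node of `net`.
#' @return a province-level [circulation_network()].
#' @export
aggregate_to_province <- function(net, gaz) {
  stopifnot(inherits(net, "circulation_network"), inherits(gaz, "gazetteer"))
  if (net$level != "city") stop_circnet("aggregate_to_province expects a city-level network")
  parent <- stats::setNames(gaz$units$parent_id, gaz$units$unit_id)
  if (!all(net$nodes$unit_id %in% names(parent)))
    stop_circnet("gazetteer does not cover every city node")
  e <- net$edges
  e$source <- unname(parent[e$source])
  e$destination <- unname(parent[e$destination])
  agg <- dplyr::summarise(dplyr::group_by(e, .data$source, .data$destination),
                          weight = sum(.data$weight), .groups = "drop")
  nm <- stats::setNames(gaz$units$name, gaz$units$unit_id)
  ids <- sort(unique(c(agg$source, agg$destination)))
  circulation_network(agg, level = "province",
                      nodes = tibble::tibble(unit_id = ids, name = unname(nm[ids])))
}

# ---- internal graph machinery ------------------------------------------------

# Integer-indexed directed edge structure with self-loops removed.
# Returns NULL-free list: n, edge_from, edge_to, weight (per cross edge),
# adj_out / adj_in (lists of integer vectors), eid_out (edge ids aligned with
# adj_out), node ids.
graph_index <- function(net, drop_self_loops = TRUE) {
  ids <- net$nodes$unit_id
  n <- length(ids)
  e <- net$edges
  if (drop_self_loops) e <- e[e$source != e$destination, , drop = FALSE]
  from <- match(e$source, ids)
  to <- match(e$destination, ids)
  adj_out <- vector("list", n); adj_in <- vector("list", n)
  eid_out <- vector("list", n)
  for (i in seq_len(n)) { adj_out[[i]] <- integer(0); adj_in[[i]] <- integer(0); eid_out[[i]] <- integer(0) }
  if (length(from)) {
    o <- split(seq_along(from), from)
    for (k in names(o)) {
      i <- as.integer(k)
      adj_out[[i]] <- to[o[[k]]]
      eid_out[[i]] <- o[[k]]
    }
    ii <- split(seq_along(to), to)
    for (k in names(ii)) adj_in[[as.integer(k)]] <- from[ii[[k]]]
  }
  list(n = n, ids = ids, from = from, to = to, weight = e$weight,
       adj_out = adj_out, adj_in = adj_in, eid_out = eid_out)
}

# Hop distances from a set of source indices, following edge direction
# ("out"), against it ("in"), or ignoring it ("all"). NA = unreachable.
bfs_distances <- function(g, sources, mode = c("out", "in", "all")) {
  mode <- match.arg(mode)
  adj <- switch(mode,
    out = g$adj_out,
    `in` = g$adj_in,
    all = Map(c, g$adj_out, g$adj_in))
  d <- rep(NA_integer_, g$n)
  frontier <- unique(sources)
  d[frontier] <- 0L
  lev <- 0L
  while (length(frontier)) {
    lev <- lev + 1L
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    nb <- nb[is.na(d[nb])]
    if (!length(nb)) break
    d[nb] <- lev
    frontier <- nb
  }
  d
}

# Number of weakly connected components.
weak_components <- function(g) {
  unseen <- rep(TRUE, g$n)
  comp <- 0L
  membership <- integer(g$n)
  while (any(unseen)) {
    comp <- comp + 1L
    s <- which(unseen)[1]
    d <- bfs_distances(g, s, mode = "all")
    got <- !is.na(d) & unseen
    membership[got] <- comp
    unseen[got] <- FALSE
  }
  list(count = comp, membership = membership)
}

# ---- exports ----------------------------------------------------------------

#' Convert a circulation network to an igraph object
#'
#' Convenience bridge for plotting and file export. Requires the igraph
#' package (Suggests).
#'
#' @param net a [circulation_network()].
#' @param include_self_loops keep within-unit edges (default FALSE).
#' @return an igraph directed weighted graph.
#' @export
as_igraph <- function(net, include_self_loops = FALSE) {
  stopifnot(inherits(net, "circulation_network"))
  if (!requireNamespace("igraph", quietly = TRUE))
    stop_circnet("as_igraph requires the igraph package")
  e <- net$edges
  if (!include_self_loops) e <- e[e$source != e$destination, ]
  g <- igraph::graph_from_data_frame(
    e, directed = TRUE,
    vertices = data.frame(name = net$nodes$unit_id, label = net$nodes$name))
  g
}

#' Write a network to disk
#'
#' `"edgelist"` writes a weighted edge-list CSV; `"graphml"` goes through
#' igraph; `"gexf"` writes a minimal GEXF 1.2 document (node labels and edge
#' weights).
#'
#' @param net a [circulation_network()].
#' @param path output path.
#' @param format `"edgelist"`, `"graphml"` or `"gexf"`.
#' @param include_self_loops keep within-unit edges (default TRUE for the
#'   edge list, which is the archival format; FALSE for graph formats).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml", "gexf"),
                          include_self_loops = NULL) {
  format <- match.arg(format)
  if (is.null(include_self_loops)) include_self_loops <- format == "edgelist"
  e <- net$edges
  if (!include_self_loops) e <- e[e$source != e$destination, ]
  if (format == "edgelist") {
    readr::write_csv(e, path, progress = FALSE)
  } else if (format == "graphml") {
    g <- as_igraph(net, include_self_loops = include_self_loops)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    xml_escape <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    nodes <- sprintf('      <node id="%s" label="%s" />',
                     xml_escape(net$nodes$unit_id), xml_escape(net$nodes$name))
    edges <- sprintf('      <edge id="%d" source="%s" target="%s" weight="%d" />',
                     seq_len(nrow(e)), xml_escape(e$source),
                     xml_escape(e$destination), e$weight)
    doc <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
             '  <graph defaultedgetype="directed" mode="static">',
             '    <nodes>', nodes, '    </nodes>',
             '    <edges>', edges, '    </edges>',
             '  </graph>', '</gexf>')
    writeLines(doc, path, useBytes = TRUE)
  }
  invisible(path)
}
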