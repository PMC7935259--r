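# Exact betweenness via Brandes' accumulation, written directly on the
# package's integer edge structure. Directed; endpoints excluded for node
# scores (the i != j != k constraint); ordered pairs; pairs with no connecting
# path contribute nothing. Unweighted mode measures distance in hops; the
# weighted mode treats an edge of weight w as length 1/w (heavier flows are
# "closer"), which is the non-default interpretation for flow-valued weights.

betweenness_engine <- function(net, weighted = FALSE) {
  g <- graph_index(net)
  n <- g$n
  node_bt <- numeric(n)
  edge_bt <- numeric(length(g$from))
  if (n < 2 || length(g$from) == 0)
    return(list(node = node_bt, edge = edge_bt, graph = g))
  len <- if (weighted) 1 / g$weight else rep(1, length(g$weight))

  for (s in seq_len(n)) {
    if (length(g$adj_out[[s]]) == 0) next
    if (!weighted) {
      d <- bfs_distances(g, s, mode = "out")
      d <- as.numeric(d)
    } else {
      d <- dijkstra_from(g, s, len)
    }
    reached <- !is.na(d)
    if (sum(reached) < 2) next
    # shortest-path DAG edges: d[from] + len == d[to]
    fin <- reached[g$from] & reached[g$to]
    on_dag <- fin & abs(d[g$from] + len - d[g$to]) < 1e-12
    de <- which(on_dag)
    if (!length(de)) next
    ef <- g$from[de]; et <- g$to[de]
    # sigma forward, by increasing distance level of the edge head
    sigma <- numeric(n); sigma[s] <- 1
    lev_head <- d[et]
    ord_lv <- sort(unique(lev_head))
    groups <- split(seq_along(de), factor(lev_head, levels = ord_lv))
    for (gidx in groups) {
      add <- rowsum(sigma[ef[gidx]], group = et[gidx])
      vidx <- as.integer(rownames(add))
      sigma[vidx] <- sigma[vidx] + add[, 1]
    }
    # delta backward, by decreasing level
    delta <- numeric(n)
    for (gidx in rev(groups)) {
      contrib <- sigma[ef[gidx]] / sigma[et[gidx]] * (1 + delta[et[gidx]])
      edge_bt[de[gidx]] <- edge_bt[de[gidx]] + contrib
      add <- rowsum(contrib, group = ef[gidx])
      uidx <- as.integer(rownames(add))
      delta[uidx] <- delta[uidx] + add[, 1]
    }
    delta[s] <- 0
    node_bt <- node_bt + delta
  }
  list(node = node_bt, edge = edge_bt, graph = g)
}

# Dijkstra with positive edge lengths; plain O(n^2) selection (networks here
# have at most a few hundred nodes).
dijkstra_from <- function(g, s, len) {
  n <- g$n
  d <- rep(Inf, n)
  done <- rep(FALSE, n)
  d[s] <- 0
  for (iter in seq_len(n)) {
    cand <- d
    cand[done] <- Inf
    u <- which.min(cand)
    if (is.infinite(cand[u])) break
    done[u] <- TRUE
    eids <- g$eid_out[[u]]
    if (length(eids)) {
      v <- g$to[eids]
      nd <- d[u] + len[eids]
      upd <- nd < d[v] - 1e-15
      d[v[upd]] <- nd[upd]
    }
  }
  d[is.infinite(d)] <- NA_real_
  d
}

#' Node betweenness centrality
#'
#' For every node k, the sum over ordered node pairs (i, j), i != j != k, of
#' the fraction of shortest directed i -> j paths that pass through k.
#' Self-loops are ignored. Raw scores are accompanied by percentage shares of
#' the total, the presentation used for ranked key-node tables.
#'
#' @param net a [circulation_network()] with at least 3 nodes.
#' @param weighted if TRUE, path length is the sum of reciprocal edge weights
#'   (heavy routes are short); the default FALSE counts hops, the appropriate
#'   reading when weights are flow volumes rather than distances.
#' @return tibble of class `betweenness_result` with `unit_id`, `name`,
#'   `score`, `pct`, `rank`.
#' @export
node_betweenness <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "circulation_network"))
  if (nrow(net$nodes) < 3) stop_circnet("node betweenness needs at least 3 nodes")
  res <- betweenness_engine(net, weighted)
  total <- sum(res$node)
  out <- tibble::tibble(
    unit_id = net$nodes$unit_id,
    name = net$nodes$name,
    score = res$node,
    pct = if (total > 0) 100 * res$node / total else rep(0, length(res$node))
  )
  out <- out[order(-out$score, out$name), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "scope") <- "node"
  attr(out, "weighted") <- weighted
  class(out) <- c("betweenness_result", class(out))
  out
}

#' Edge betweenness centrality
#'
#' For every directed edge, the sum over ordered node pairs (i, j), i != j, of
#' the fraction of shortest i -> j paths that traverse the edge. Percentages
#' are shares of the total edge betweenness, matching ranked key-path tables.
#'
#' @inheritParams node_betweenness
#' @return tibble of class `betweenness_result` with `source`, `destination`,
#'   names, `weight`, `score`, `pct`, `rank`.
#' @export
edge_betweenness <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "circulation_network"))
  if (nrow(net$nodes) < 3) stop_circnet("edge betweenness needs at least 3 nodes")
  res <- betweenness_engine(net, weighted)
  g <- res$graph
  nm <- stats::setNames(net$nodes$name, net$nodes$unit_id)
  out <- tibble::tibble(
    source = g$ids[g$from],
    destination = g$ids[g$to],
    source_name = unname(nm[g$ids[g$from]]),
    destination_name = unname(nm[g$ids[g$to]]),
    weight = g$weight,
    score = res$edge,
    pct = if (sum(res$edge) > 0) 100 * res$edge / sum(res$edge) else rep(0, length(res$edge))
  )
  out <- out[order(-out$score, out$source_name, out$destination_name), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "scope") <- "edge"
  attr(out, "weighted") <- weighted
  class(out) <- c("betweenness_result", class(out))
  out
}
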