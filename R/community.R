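# Louvain community detection, written on an undirected weighted view of the
# circulation network. Directed edges are symmetrized by summing the two
# directions (w_sym(u,v) = w(u,v) + w(v,u)); the modularity formula below is
# the undirected one, so this choice is stated prominently in the docs.
# Original within-unit self-loops are excluded (network policy); self-loops
# that arise from aggregating communities into super-nodes carry the internal
# community weight and do count, with the usual convention that a self-loop of
# weight s contributes 2s to its node's strength.

sym_graph <- function(net) {
  ids <- net$nodes$unit_id
  n <- length(ids)
  e <- net$edges[net$edges$source != net$edges$destination, , drop = FALSE]
  if (nrow(e) == 0)
    return(list(n = n, ids = ids, ei = integer(0), ej = integer(0),
                w = numeric(0), self = numeric(n), m = 0))
  i <- match(e$source, ids); j <- match(e$destination, ids)
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * n + hi
  agg <- rowsum(as.numeric(e$weight), group = key)
  k <- as.numeric(rownames(agg))
  lo <- (k - 1) %/% n + 1
  hi <- k - (lo - 1) * n
  level_graph(n, ids, as.integer(lo), as.integer(hi), agg[, 1], numeric(n))
}

level_graph <- function(n, ids, ei, ej, w, self) {
  list(n = n, ids = ids, ei = ei, ej = ej, w = w, self = self,
       m = sum(w) + sum(self))
}

# strength k_i = sum of incident symmetric weights + 2 * self-loop weight
strengths <- function(L) {
  k <- numeric(L$n)
  if (length(L$ei)) {
    a <- rowsum(L$w, group = L$ei); k[as.integer(rownames(a))] <- a[, 1]
    b <- rowsum(L$w, group = L$ej)
    ib <- as.integer(rownames(b)); k[ib] <- k[ib] + b[, 1]
  }
  k + 2 * L$self
}

# Q for a membership vector on a level graph.
level_modularity <- function(L, memb, resolution = 1) {
  if (L$m <= 0) stop_circnet("modularity is undefined when the graph has no (cross) edges")
  two_m <- 2 * L$m
  internal <- if (length(L$ei)) sum(L$w[memb[L$ei] == memb[L$ej]]) else 0
  win <- 2 * internal + 2 * sum(L$self)      # sum of A_ij inside communities
  k <- strengths(L)
  tot <- rowsum(k, group = memb)[, 1]
  win / two_m - resolution * sum((tot / two_m)^2)
}

#' Modularity of a partition
#'
#' Evaluates Q = (1/2m) * sum_ij [A_ij - k_i k_j / 2m] delta(c_i, c_j) on the
#' symmetrized (undirected) weighted view of the network, with within-unit
#' self-loops excluded. Q = 0 for the all-in-one-community partition; a
#' partition into singletons on a loop-free graph has Q < 0.
#'
#' @param net a [circulation_network()] with at least one cross-unit edge.
#' @param membership community ids: either a vector aligned with
#'   `net$nodes$unit_id` or a named vector keyed by unit id.
#' @param resolution resolution parameter multiplying the null-model term
#'   (default 1, the plain modularity).
#' @return the scalar Q.
#' @export
modularity_q <- function(net, membership, resolution = 1) {
  stopifnot(inherits(net, "circulation_network"))
  L <- sym_graph(net)
  memb <- align_membership(membership, L$ids)
  level_modularity(L, memb, resolution)
}

align_membership <- function(membership, ids) {
  if (!is.null(names(membership))) {
    if (!all(ids %in% names(membership)))
      stop_circnet("membership must cover every node")
    membership <- membership[ids]
  }
  if (length(membership) != length(ids))
    stop_circnet("membership must assign every node to exactly one community")
  as.integer(factor(membership))
}

#' Fast modularity gain of absorbing an isolated node
#'
#' The one-step gain formula used inside the Louvain sweep: for a node i that
#' currently sits alone in its own community, the modularity change of moving
#' it into community C is
#' `[(S_in + k_i_in)/2m - ((S_tot + k_i)/2m)^2] - [S_in/2m - (S_tot/2m)^2 - (k_i/2m)^2]`,
#' where `S_in` sums the adjacency entries inside C, `S_tot` the strengths of
#' C's members, `k_i` node i's strength and `k_i_in` node i's adjacency into C
#' — counted from both endpoints, i.e. twice the symmetric edge weight from i
#' to C, the convention under which the formula is algebraically identical to
#' the direct modularity difference.
#'
#' @param net a [circulation_network()].
#' @param membership current community assignment (see [modularity_q()]); node
#'   `node` must be a singleton in it.
#' @param node unit id of the node to move.
#' @param community community id (as used in `membership`) to move it into.
#' @param resolution resolution parameter (default 1).
#' @return the scalar gain, equal to `modularity_q(after) - modularity_q(before)`.
#' @export
delta_q <- function(net, membership, node, community, resolution = 1) {
  stopifnot(inherits(net, "circulation_network"))
  L <- sym_graph(net)
  ids <- L$ids
  raw <- membership
  if (is.null(names(raw))) names(raw) <- ids
  memb <- align_membership(membership, ids)
  v <- match(node, ids)
  if (is.na(v)) stop_circnet("unknown node: ", node)
  if (sum(memb == memb[v]) != 1L)
    stop_circnet("delta_q requires the node to be alone in its own community")
  target <- which(raw[ids] == community & seq_along(ids) != v)
  if (!length(target)) stop_circnet("candidate community is empty or unknown")

  two_m <- 2 * L$m
  k <- strengths(L)
  inC <- seq_len(L$n) %in% target
  s_in <- 2 * sum(L$w[inC[L$ei] & inC[L$ej]]) + 2 * sum(L$self[inC])
  s_tot <- sum(k[inC])
  k_i <- k[v]
  k_i_in <- 2 * sum(L$w[(L$ei == v & inC[L$ej]) | (L$ej == v & inC[L$ei])])
  ((s_in + k_i_in) / two_m - ((s_tot + k_i) / two_m)^2) -
    (s_in / two_m - (s_tot / two_m)^2 - (k_i / two_m)^2)
}

# One Louvain sweep phase on a level graph. Returns membership (1..C,
# renumbered by first appearance) and whether any node moved.
louvain_one_level <- function(L, resolution) {
  n <- L$n
  k <- strengths(L)
  two_m <- 2 * L$m
  # neighbor lists with symmetric weights
  nbr <- vector("list", n); nbw <- vector("list", n)
  for (i in seq_len(n)) { nbr[[i]] <- integer(0); nbw[[i]] <- numeric(0) }
  if (length(L$ei)) {
    for (side in 1:2) {
      a <- if (side == 1) L$ei else L$ej
      b <- if (side == 1) L$ej else L$ei
      sp <- split(seq_along(a), a)
      for (nmk in names(sp)) {
        i <- as.integer(nmk)
        nbr[[i]] <- c(nbr[[i]], b[sp[[nmk]]])
        nbw[[i]] <- c(nbw[[i]], L$w[sp[[nmk]]])
      }
    }
  }
  comm <- seq_len(n)
  comm_tot <- k
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      if (!length(nbr[[i]])) next
      old <- comm[i]
      comm_tot[old] <- comm_tot[old] - k[i]
      cc <- comm[nbr[[i]]]
      kin <- rowsum(nbw[[i]], group = cc)
      cand <- as.integer(rownames(kin))
      if (!old %in% cand) { cand <- c(cand, old); kin <- rbind(kin, 0) }
      gain <- kin[, 1] - resolution * comm_tot[cand] * k[i] / two_m
      best <- max(gain)
      pick <- min(cand[gain >= best - 1e-12])   # ties -> lowest community id
      cur <- gain[match(old, cand)]
      if (pick != old && best > cur + 1e-12) {
        comm[i] <- pick
        moved <- TRUE
        moved_any <- TRUE
      }
      comm_tot[comm[i]] <- comm_tot[comm[i]] + k[i]
    }
    if (!moved) break
  }
  list(membership = as.integer(factor(comm, levels = unique(comm[order(seq_len(n))]))) ,
       moved = moved_any)
}

# Aggregate communities into super-nodes; internal weight + member self-loops
# become the super-node's self-loop.
louvain_aggregate <- function(L, memb) {
  nc <- max(memb)
  self <- numeric(nc)
  if (length(L$self)) {
    a <- rowsum(L$self, group = memb)
    self[as.integer(rownames(a))] <- a[, 1]
  }
  if (!length(L$ei))
    return(level_graph(nc, as.character(seq_len(nc)), integer(0), integer(0),
                       numeric(0), self))
  ci <- memb[L$ei]; cj <- memb[L$ej]
  internal <- ci == cj
  if (any(internal)) {
    a <- rowsum(L$w[internal], group = ci[internal])
    idx <- as.integer(rownames(a))
    self[idx] <- self[idx] + a[, 1]
  }
  lo <- pmin(ci, cj)[!internal]; hi <- pmax(ci, cj)[!internal]
  if (length(lo)) {
    key <- (lo - 1) * nc + hi
    agg <- rowsum(L$w[!internal], group = key)
    kk <- as.numeric(rownames(agg))
    lo <- as.integer((kk - 1) %/% nc + 1)
    hi <- as.integer(kk - (lo - 1) * nc)
    level_graph(nc, as.character(seq_len(nc)), lo, hi, agg[, 1], self)
  } else {
    level_graph(nc, as.character(seq_len(nc)), integer(0), integer(0),
                numeric(0), self)
  }
}

#' Louvain community detection
#'
#' Two-phase greedy modularity maximization: (1) sweep the nodes in a seeded
#' random order, moving each to the neighboring community with the largest
#' positive modularity gain (ties broken toward the lowest community id) until
#' no move improves; (2) aggregate communities into super-nodes whose edge
#' weights are the summed weights between the original node groups, and
#' repeat both phases until the modularity stabilizes. Directed input is
#' symmetrized by summing the two edge directions; within-unit self-loops are
#' excluded.
#'
#' @param net a [circulation_network()] with at least one cross-unit edge.
#' @param seed integer seed fixing the sweep order (default 42); identical
#'   seed and input give an identical partition. The caller's RNG state is
#'   left untouched.
#' @param resolution resolution parameter (default 1).
#' @return an object of class `community_partition`: list with `membership`
#'   (named integer vector, community ids 1..C), `modularity`,
#'   `n_communities`, `levels` (per-phase memberships of the aggregated
#'   graphs), `modularity_trace` (Q after each phase) and `seed`.
#' @export
louvain <- function(net, seed = 42L, resolution = 1) {
  stopifnot(inherits(net, "circulation_network"))
  L <- sym_graph(net)
  if (L$m <= 0)
    stop_circnet("louvain needs at least one cross-unit edge (modularity undefined)")
  with_seed(seed, {
    memb_global <- seq_len(L$n)
    levels <- list()
    trace <- numeric(0)
    q_prev <- -Inf
    repeat {
      res <- louvain_one_level(L, resolution)
      memb_global <- res$membership[memb_global]
      q <- level_modularity(L, res$membership, resolution)
      levels[[length(levels) + 1]] <- res$membership
      trace <- c(trace, q)
      if (!res$moved || q <= q_prev + 1e-12) break
      q_prev <- q
      L <- louvain_aggregate(L, res$membership)
    }
    # deterministic ids: renumber by first appearance in node order
    memb_global <- as.integer(factor(memb_global, levels = unique(memb_global)))
    out <- list(
      membership = stats::setNames(memb_global, net$nodes$unit_id),
      modularity = modularity_q(net, memb_global, resolution),
      n_communities = max(memb_global),
      levels = levels,
      modularity_trace = trace,
      resolution = resolution,
      seed = seed
    )
    class(out) <- "community_partition"
    out
  })
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.4f (seed %d)\n",
              x$n_communities, x$modularity, x$seed))
  invisible(x)
}

#' Community gatekeepers
#'
#' For each community, the member with the highest node betweenness — the node
#' most often bridging shortest paths, typically the community's main link to
#' the rest of the network. Ties are broken lexicographically by name.
#'
#' @param partition a [louvain()] result (or any `community_partition`).
#' @param betweenness a [node_betweenness()] result computed on the same
#'   network.
#' @return tibble with `community`, `unit_id`, `name`, `score`, `size`.
#' @export
community_gatekeepers <- function(partition, betweenness) {
  stopifnot(inherits(partition, "community_partition"),
            inherits(betweenness, "betweenness_result"),
            attr(betweenness, "scope") == "node")
  bt <- tibble::as_tibble(betweenness)
  bt$community <- unname(partition$membership[bt$unit_id])
  if (any(is.na(bt$community)))
    stop_circnet("betweenness and partition must cover the same node set")
  bt <- bt[order(bt$community, -bt$score, bt$name), ]
  sizes <- table(bt$community)
  top <- bt[!duplicated(bt$community), c("community", "unit_id", "name", "score")]
  top$size <- as.integer(sizes[as.character(top$community)])
  top
}
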