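# Fixture builders and independent oracles used across the suite. Oracles are
# deliberately written on different machinery than the package (igraph path
# enumeration / distances, dense-matrix formulas, exhaustive search) so they
# check the implementation rather than restate it.

make_net <- function(edges, level = "city", nodes = NULL) {
  circulation_network(tibble::as_tibble(edges), level = level, nodes = nodes)
}

# Random weighted digraph (no self-loops) on n nodes; assumes the caller
# controls the RNG seed.
rand_digraph <- function(n, p = 0.35, max_w = 5L) {
  pairs <- expand.grid(source = seq_len(n), destination = seq_len(n))
  pairs <- pairs[pairs$source != pairs$destination, ]
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(length(keep), 2)] <- TRUE
  e <- pairs[keep, ]
  make_net(tibble::tibble(source = sprintf("n%02d", e$source),
                          destination = sprintf("n%02d", e$destination),
                          weight = sample.int(max_w, nrow(e), replace = TRUE)),
           nodes = tibble::tibble(unit_id = sprintf("n%02d", seq_len(n))))
}

net_to_igraph <- function(net, directed = TRUE) {
  e <- net$edges[net$edges$source != net$edges$destination, ]
  igraph::graph_from_data_frame(e, directed = directed,
                                vertices = data.frame(name = net$nodes$unit_id))
}

# Brute-force betweenness by explicit enumeration of every shortest path of
# every ordered pair (igraph's all_shortest_paths does the enumeration).
oracle_betweenness <- function(net) {
  g <- net_to_igraph(net)
  ids <- net$nodes$unit_id
  n <- length(ids)
  e <- net$edges[net$edges$source != net$edges$destination, ]
  ekey <- paste(e$source, e$destination)
  nb <- stats::setNames(numeric(n), ids)
  eb <- stats::setNames(numeric(nrow(e)), ekey)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = ids[i], to = ids[j], mode = "out",
                                 weights = NA))
    paths <- sp$vpaths %||% sp$res
    if (length(paths) == 0) next
    p_ij <- length(paths)
    for (pth in paths) {
      v <- names(pth)
      if (length(v) > 2) {
        mid <- v[-c(1, length(v))]
        nb[mid] <- nb[mid] + 1 / p_ij
      }
      ek <- paste(v[-length(v)], v[-1])
      eb[ek] <- eb[ek] + 1 / p_ij
    }
  }
  list(node = nb, edge = eb)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Direct double-sum evaluation of the modularity formula on the dense
# symmetrized adjacency matrix.
oracle_modularity <- function(net, membership, resolution = 1) {
  ids <- net$nodes$unit_id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- net$edges[net$edges$source != net$edges$destination, ]
  for (r in seq_len(nrow(e))) {
    i <- e$source[r]; j <- e$destination[r]
    A[i, j] <- A[i, j] + e$weight[r]
    A[j, i] <- A[j, i] + e$weight[r]
  }
  m2 <- sum(A)                      # = 2m
  if (m2 == 0) stop("modularity undefined")
  k <- rowSums(A)
  memb <- if (!is.null(names(membership))) membership[ids] else membership
  same <- outer(memb, memb, "==")
  sum((A - resolution * outer(k, k) / m2) * same) / m2
}

# All set partitions of n elements as restricted-growth strings (rows).
all_partitions <- function(n) {
  a <- integer(n); b <- integer(n)   # b[i] = max(a[1..i-1])
  rows <- list()
  a[] <- 1L
  repeat {
    rows[[length(rows) + 1]] <- a
    # next RGS
    i <- n
    while (i > 1) {
      bmax <- max(a[seq_len(i - 1)])
      if (a[i] <= bmax) break
      i <- i - 1
    }
    if (i == 1) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1):n] <- 1L
  }
  do.call(rbind, rows)
}

# Fast Q evaluator for exhaustive-partition search (oracle-side).
oracle_best_partition_q <- function(net) {
  ids <- net$nodes$unit_id
  n <- length(ids)
  A <- matrix(0, n, n)
  e <- net$edges[net$edges$source != net$edges$destination, ]
  si <- match(e$source, ids); di <- match(e$destination, ids)
  for (r in seq_along(si)) {
    A[si[r], di[r]] <- A[si[r], di[r]] + e$weight[r]
    A[di[r], si[r]] <- A[di[r], si[r]] + e$weight[r]
  }
  m2 <- sum(A)
  k <- rowSums(A)
  parts <- all_partitions(n)
  best <- -Inf
  for (r in seq_len(nrow(parts))) {
    m <- parts[r, ]
    internal <- sum(A[outer(m, m, "==")])
    tot <- rowsum(k, m)[, 1]
    q <- internal / m2 - sum((tot / m2)^2)
    if (q > best) best <- q
  }
  best
}

# Exhaustive within-class SSD minimization over all break placements.
oracle_jenks_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  for (cut in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bounds <- c(0, cut, n)
    s <- sum(vapply(seq_len(k), function(c)
      ssd(x[(bounds[c] + 1):bounds[c + 1]]), numeric(1)))
    if (s < best) best <- s
  }
  best
}

# Reach of a node set from igraph distances (independent of the package BFS).
oracle_reach <- function(net, S, mode = "out") {
  g <- net_to_igraph(net)
  ids <- net$nodes$unit_id
  d <- igraph::distances(g, v = S, mode = if (mode == "out") "out" else "all",
                         weights = NA)
  dmin <- apply(d, 2, min)
  r <- 1 / pmax(dmin, 1)
  r[is.infinite(dmin)] <- 0
  r[colnames(d) %in% S] <- 1
  mean(r[ids])
}

oracle_best_reach <- function(net, k, mode = "out") {
  ids <- net$nodes$unit_id
  best <- -Inf
  for (S in utils::combn(ids, k, simplify = FALSE)) {
    v <- oracle_reach(net, S, mode)
    if (v > best) best <- v
  }
  best
}

# Tiny raw record table used by the records tests.
toy_records <- function() {
  tibble::tibble(
    record_id = sprintf("R%02d", 1:5),
    status = c("qualified", "substandard", "substandard", "substandard", "qualified"),
    manufacturer_address = c("1 Mill Lane, A City, P Province",
                             "2 Mill Lane, A City, P Province",
                             "2 Mill Lane, A City, P Province",
                             "3 Mill Lane, B City, P Province",
                             "4 Mill Lane, B City, P Province"),
    distributor_address = c("9 Canal Road, B City, P Province",
                            "8 Canal Road, B City, P Province",
                            "8 Canal Road, B City, P Province",
                            "",
                            "7 Canal Road, A City, P Province"),
    sample_date = as.Date(c("2018-03-01", "2018-03-02", "2018-03-02",
                            "2018-03-04", "2018-03-05")),
    food_name = "biscuits"
  )
}

toy_gazetteer <- function() {
  gazetteer(tibble::tibble(
    unit_id = c("P", "Q", "P-A", "P-B", "Q-C"),
    name = c("P Province", "Q Province", "A City", "B City", "C City"),
    level = c("province", "province", "city", "city", "city"),
    parent_id = c(NA, NA, "P", "P", "Q")
  ))
}
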