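# Borgatti key-player (reach variant): choose a node set S maximizing the
# distance-weighted reach D_R = (1/n) * sum_i 1/d(S, i), where d(S, i) is the
# shortest hop distance from the set to node i. Members of S contribute 1 each
# (the self-distance-zero convention of the original measure) and unreachable
# nodes contribute 0, so D_R is in [0, 1] and equals 1 exactly when every node
# is in S or at distance 1 from it.

# Reciprocal-distance matrix R[s, i] = 1/max(1, d(s -> i)), 0 if unreachable,
# 1 on the diagonal. D_R(S) is then mean over i of max over s in S of R[s, i].
recip_matrix <- function(net, mode = c("out", "undirected")) {
  mode <- match.arg(mode)
  g <- graph_index(net)
  bmode <- if (mode == "out") "out" else "all"
  n <- g$n
  R <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- as.numeric(bfs_distances(g, s, mode = bmode))
    r <- 1 / d
    r[s] <- 1
    r[is.na(d)] <- 0
    R[s, ] <- r
  }
  R
}

reach_from_rows <- function(R, S) {
  if (length(S) == 1) mean(R[S, ]) else mean(apply(R[S, , drop = FALSE], 2, max))
}

#' Distance-weighted reach of a node set
#'
#' D_R = (1/n) * sum over nodes i of the reciprocal shortest distance from the
#' set S to i. Distances follow edge direction outward from S by default
#' (circulation out of the key units); `mode = "undirected"` ignores
#' direction, as the original formulation of the measure does.
#'
#' @param net a [circulation_network()].
#' @param S character vector of unit ids, non-empty, all present in the
#'   network.
#' @param mode `"out"` (default) or `"undirected"`.
#' @return D_R in [0, 1].
#' @export
distance_weighted_reach <- function(net, S, mode = c("out", "undirected")) {
  stopifnot(inherits(net, "circulation_network"))
  mode <- match.arg(mode)
  ids <- net$nodes$unit_id
  if (length(S) == 0) stop_circnet("S must be non-empty")
  idx <- match(S, ids)
  if (anyNA(idx)) stop_circnet("S contains units absent from the network: ",
                               paste(S[is.na(idx)], collapse = ", "))
  g <- graph_index(net)
  d <- as.numeric(bfs_distances(g, idx, mode = if (mode == "out") "out" else "all"))
  r <- 1 / d
  r[idx] <- 1
  r[is.na(d)] <- 0
  mean(r)
}

#' Find a key-player set of size k
#'
#' Greedy forward selection (best single node, then best addition) followed by
#' pairwise swap improvement until no swap raises the reach, repeated over
#' seeded restarts that randomize tie-breaking; the best solution found is
#' kept, so the result is never worse than the pure greedy one. Exact for the
#' small graphs used in verification; a heuristic (as the original software
#' is) in general.
#'
#' @param net a [circulation_network()].
#' @param k set size, 1 <= k <= number of nodes.
#' @param restarts number of seeded restarts (default 20).
#' @param seed integer seed (default 42); the caller's RNG state is restored.
#' @param mode `"out"` (default) or `"undirected"` distances.
#' @return an object of class `key_player_solution`: list with `set` (unit
#'   ids), `names`, `k`, `reach`, `reach_pct`, `mode`, `seed`, `trace` (one
#'   row per accepted greedy/swap decision).
#' @export
find_key_players <- function(net, k, restarts = 20L, seed = 42L,
                             mode = c("out", "undirected")) {
  stopifnot(inherits(net, "circulation_network"))
  mode <- match.arg(mode)
  k <- assert_scalar_count(k, "k")
  n <- nrow(net$nodes)
  if (k > n) stop_circnet("k must not exceed the number of nodes")
  restarts <- assert_scalar_count(restarts, "restarts")
  R <- recip_matrix(net, mode)
  ids <- net$nodes$unit_id

  with_seed(seed, {
    best_set <- NULL; best_val <- -Inf
    trace <- list()
    for (r in seq_len(restarts)) {
      # restart 1: deterministic greedy; even restarts: greedy with random
      # tie-breaking; odd restarts > 1: a random initial set, so the swap
      # phase explores basins the greedy start cannot reach
      randomize <- r > 1
      random_start <- r > 1 && r %% 2 == 1
      if (random_start) {
        S <- sample.int(n, k)
        cur <- if (k == 1) R[S, ] else apply(R[S, , drop = FALSE], 2, max)
        trace[[length(trace) + 1]] <-
          list(restart = r, action = "random-start",
               unit = paste(ids[S], collapse = "+"), reach = sum(cur) / n)
      } else {
        cur <- numeric(n)   # best reciprocal per target under current S
        S <- integer(0)
        for (step in seq_len(k)) {
          cand <- setdiff(seq_len(n), S)
          vals <- vapply(cand, function(v) sum(pmax(cur, R[v, ])), numeric(1))
          top <- vals >= max(vals) - 1e-12
          pickfrom <- cand[top]
          v <- if (randomize && length(pickfrom) > 1) sample(pickfrom, 1) else min(pickfrom)
          S <- c(S, v)
          cur <- pmax(cur, R[v, ])
          trace[[length(trace) + 1]] <-
            list(restart = r, action = "add", unit = ids[v], reach = sum(cur) / n)
        }
      }
      # pairwise swap improvement
      repeat {
        improved <- FALSE
        for (pos in seq_along(S)) {
          keep <- S[-pos]
          base <- if (length(keep)) do.call(pmax, c(lapply(keep, function(v) R[v, ]),
                                                    list(numeric(n))))
                  else numeric(n)
          cand <- setdiff(seq_len(n), S)
          if (!length(cand)) next
          vals <- vapply(cand, function(v) sum(pmax(base, R[v, ])), numeric(1))
          now <- sum(pmax(base, R[S[pos], ]))
          if (max(vals) > now + 1e-12) {
            v <- cand[which.max(vals)]
            trace[[length(trace) + 1]] <-
              list(restart = r, action = "swap", unit = ids[v],
                   out = ids[S[pos]], reach = max(vals) / n)
            S[pos] <- v
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      val <- reach_from_rows(R, S)
      key <- paste(sort(ids[S]), collapse = ",")
      if (val > best_val + 1e-12 ||
          (abs(val - best_val) <= 1e-12 &&
           !is.null(best_set) && key < paste(sort(ids[best_set]), collapse = ","))) {
        best_val <- val; best_set <- S
      }
    }
    out <- list(set = sort(ids[best_set]),
                names = net$nodes$name[match(sort(ids[best_set]), ids)],
                k = k, reach = best_val, reach_pct = 100 * best_val,
                mode = mode, seed = seed,
                trace = dplyr::bind_rows(lapply(trace, tibble::as_tibble)))
    class(out) <- "key_player_solution"
    out
  })
}

#' @export
print.key_player_solution <- function(x, ...) {
  cat(sprintf("<key_player_solution> k=%d, D_R = %.3f (%.1f%%), mode=%s\n  {%s}\n",
              x$k, x$reach, x$reach_pct, x$mode, paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Key-player profile over set sizes
#'
#' Optimizes a key set independently for every k = 1..k_max (sets need not be
#' nested; membership can churn between rows) and reports the reach achieved.
#' Also reports `full_coverage_k`: the smallest set size at which greedy
#' extension attains D_R = 1 (every node in the set or at distance 1), an
#' upper bound on the true minimum.
#'
#' @inheritParams find_key_players
#' @param k_max largest set size to profile.
#' @return tibble with `k`, `members` (comma-joined names), `reach`,
#'   `reach_pct`; attribute `full_coverage_k`.
#' @export
key_player_profile <- function(net, k_max, restarts = 20L, seed = 42L,
                               mode = c("out", "undirected")) {
  mode <- match.arg(mode)
  k_max <- assert_scalar_count(k_max, "k_max")
  n <- nrow(net$nodes)
  if (k_max > n) stop_circnet("k_max must not exceed the number of nodes")
  rows <- vector("list", k_max)
  sols <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    sol <- find_key_players(net, k, restarts = restarts, seed = seed + k, mode = mode)
    sols[[k]] <- sol
    rows[[k]] <- tibble::tibble(k = k,
                                members = paste(sol$names, collapse = ", "),
                                reach = sol$reach,
                                reach_pct = sol$reach_pct)
  }
  out <- dplyr::bind_rows(rows)

  # greedy extension to full coverage
  R <- recip_matrix(net, mode)
  ids <- net$nodes$unit_id
  S <- match(sols[[k_max]]$set, ids)
  cur <- if (length(S) == 1) R[S, ] else apply(R[S, , drop = FALSE], 2, max)
  kk <- k_max
  full_k <- if (mean(cur) >= 1 - 1e-12) {
    # already full at some k <= k_max: find the smallest profiled k with reach 1
    min(out$k[out$reach >= 1 - 1e-12])
  } else {
    while (mean(cur) < 1 - 1e-12 && kk < n) {
      cand <- setdiff(seq_len(n), S)
      vals <- vapply(cand, function(v) sum(pmax(cur, R[v, ])), numeric(1))
      v <- cand[which.max(vals)]
      S <- c(S, v); cur <- pmax(cur, R[v, ]); kk <- kk + 1
    }
    if (mean(cur) >= 1 - 1e-12) kk else NA_integer_
  }
  attr(out, "full_coverage_k") <- full_k
  out
}
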