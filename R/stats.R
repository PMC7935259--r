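#' Per-node degree, flow and ratio metrics
#'
#' Computes, for every node, the unweighted in/out degree (number of distinct
#' sending/receiving partners), the weighted in/out degree (record counts on
#' incoming/outgoing routes), their sums, the within-unit (self-loop) weight,
#' and the in/out flow ratio. Self-loops are excluded from all degree columns
#' per the network policy; their mass is kept in `self_weight`.
#'
#' The ratio defaults to the weighted convention `weighted_in / weighted_out`
#' (a node is a *net destination* when the ratio exceeds 1 and a *net source*
#' below 1); the unweighted variant `in_degree / out_degree` is returned
#' alongside as `ratio_unweighted`. Nodes with zero outgoing flow but positive
#' incoming flow get ratio `Inf`; isolated nodes get `NaN`.
#'
#' @param net a [circulation_network()].
#' @return tibble with one row per node.
#' @export
node_metrics <- function(net) {
  stopifnot(inherits(net, "circulation_network"))
  if (nrow(net$nodes) == 0) stop_circnet("node_metrics needs a non-empty network")
  ids <- net$nodes$unit_id
  e <- net$edges
  self <- e$source == e$destination
  sw <- tapply(e$weight[self], factor(e$source[self], levels = ids), sum)
  ec <- e[!self, ]
  f_src <- factor(ec$source, levels = ids)
  f_dst <- factor(ec$destination, levels = ids)
  zero <- function(x) { x[is.na(x)] <- 0; as.numeric(x) }
  out_deg <- zero(tapply(rep(1L, nrow(ec)), f_src, sum))
  in_deg <- zero(tapply(rep(1L, nrow(ec)), f_dst, sum))
  w_out <- zero(tapply(ec$weight, f_src, sum))
  w_in <- zero(tapply(ec$weight, f_dst, sum))
  tibble::tibble(
    unit_id = ids,
    name = net$nodes$name,
    in_degree = in_deg,
    out_degree = out_deg,
    degree = in_deg + out_deg,
    weighted_in = w_in,
    weighted_out = w_out,
    weighted_degree = w_in + w_out,
    self_weight = zero(sw),
    ratio = w_in / w_out,
    ratio_unweighted = in_deg / out_deg
  )
}

#' Directed network density
#'
#' Ratio of the number of distinct directed cross-node edges to the
#' `n * (n - 1)` ordered pairs that could exist. Self-loops are excluded.
#'
#' @param net a [circulation_network()].
#' @return a proportion in [0, 1].
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "circulation_network"))
  n <- nrow(net$nodes)
  if (n < 2) stop_circnet("density is undefined for networks with fewer than 2 nodes")
  e <- sum(net$edges$source != net$edges$destination)
  e / (n * (n - 1))
}

#' Whole-network summary statistics
#'
#' Size, diameter, density, component count and the degree summaries of the
#' standard network-indicator table. The diameter is the longest finite
#' directed shortest path (hop count) over reachable ordered pairs;
#' `unreachable_pairs` counts the pairs with no directed path and
#' `strongly_connected` records whether there were none. Components are
#' weakly connected components. Two mean-degree conventions are reported:
#' `mean_degree = e / n` (each edge counted once per node set, the convention
#' that reproduces printed indicator tables of this kind) and
#' `mean_degree_both_ends = 2e / n`. Mean weighted degree is total record
#' weight over n, with (`mean_weighted_degree`) and without
#' (`mean_weighted_degree_cross`) self-loop mass.
#'
#' @param net a [circulation_network()].
#' @return a list of class `network_summary`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "circulation_network"))
  n <- nrow(net$nodes)
  if (n == 0) stop_circnet("cannot summarize an empty network")
  g <- graph_index(net)
  e <- length(g$weight)

  diam <- 0L
  unreachable <- 0L
  for (s in seq_len(n)) {
    d <- bfs_distances(g, s, mode = "out")
    d[s] <- NA_integer_
    unreachable <- unreachable + sum(is.na(d))
    if (any(!is.na(d))) diam <- max(diam, max(d, na.rm = TRUE))
  }
  m <- node_metrics(net)
  rng <- function(x) sprintf("%s (%s, %s)", format(median(x)), format(min(x)), format(max(x)))
  out <- list(
    level = net$level,
    size = n,
    diameter = diam,
    unreachable_pairs = unreachable,
    strongly_connected = unreachable == 0L,
    density = if (n >= 2) network_density(net) else NA_real_,
    components = weak_components(g)$count,
    mean_degree = e / n,
    mean_degree_both_ends = 2 * e / n,
    mean_weighted_degree = net$n_records / n,
    mean_weighted_degree_cross = sum(g$weight) / n,
    median_weighted_in = median(m$weighted_in),
    range_weighted_in = range(m$weighted_in),
    median_weighted_out = median(m$weighted_out),
    range_weighted_out = range(m$weighted_out),
    median_in_degree = median(m$in_degree),
    range_in_degree = range(m$in_degree),
    median_out_degree = median(m$out_degree),
    range_out_degree = range(m$out_degree)
  )
  class(out) <- "network_summary"
  out
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> %s level\n", x$level))
  cat(sprintf("  size %d | diameter %d | density %.3f | components %d\n",
              x$size, x$diameter, x$density, x$components))
  cat(sprintf("  mean degree %.3f (e/n; both-ends %.3f) | mean weighted degree %.3f\n",
              x$mean_degree, x$mean_degree_both_ends, x$mean_weighted_degree))
  cat(sprintf("  weighted in-degree %g (%g, %g) | weighted out-degree %g (%g, %g)\n",
              x$median_weighted_in, x$range_weighted_in[1], x$range_weighted_in[2],
              x$median_weighted_out, x$range_weighted_out[1], x$range_weighted_out[2]))
  if (!x$strongly_connected)
    cat(sprintf("  (diameter over reachable pairs; %d unreachable ordered pairs)\n",
                x$unreachable_pairs))
  invisible(x)
}

#' Circulation intensity per node
#'
#' Intensity is the substandard flow through a unit per 1,000 samples taken
#' there: `in_intensity = scale * inflow / total_samples` and likewise for
#' outflow, where `total_samples` counts all sampled items (qualified plus
#' substandard) in the unit. By default the within-unit (self-loop)
#' substandard mass counts toward both the inflow and the outflow, since a
#' locally circulated record is both supplied and received by the unit; set
#' `include_self_loops = FALSE` for the cross-border-only variant.
#'
#' Nodes without a (positive) entry in `totals` are flagged `unscorable` with
#' `NA` intensities rather than silently zeroed.
#'
#' @param net a [circulation_network()].
#' @param totals data frame with columns `unit_id`, `total_samples`.
#' @param include_self_loops see above.
#' @param scale samples per reporting unit (default 1000).
#' @return the [node_metrics()] tibble plus `total_samples`, `in_intensity`,
#'   `out_intensity`, `unscorable`.
#' @export
circulation_intensity <- function(net, totals, include_self_loops = TRUE,
                                  scale = 1000) {
  m <- node_metrics(net)
  totals <- tibble::as_tibble(totals)
  stopifnot(all(c("unit_id", "total_samples") %in% names(totals)))
  m$total_samples <- totals$total_samples[match(m$unit_id, totals$unit_id)]
  m$unscorable <- is.na(m$total_samples) | m$total_samples <= 0
  if (any(m$unscorable))
    warning(sum(m$unscorable), " node(s) lack a positive sample total and are unscorable",
            call. = FALSE)
  extra <- if (include_self_loops) m$self_weight else 0
  m$in_intensity <- ifelse(m$unscorable, NA_real_,
                           scale * (m$weighted_in + extra) / m$total_samples)
  m$out_intensity <- ifelse(m$unscorable, NA_real_,
                            scale * (m$weighted_out + extra) / m$total_samples)
  m
}

#' Fisher-Jenks natural-breaks classification
#'
#' Partitions a numeric vector into `k` classes minimizing the total
#' within-class sum of squared deviations from the class means (the exact
#' dynamic-programming optimum, not the iterative approximation). Intervals
#' are half-open `[lo, hi)` with a closed last interval, where each class's
#' upper edge is the next class's minimum value.
#'
#' @param values numeric vector, at least `k` distinct values.
#' @param k number of classes (>= 2). With `k = 4` the classes are labelled
#'   `Lower`, `Low`, `High`, `Higher` in ascending order; otherwise
#'   `class_1..class_k`.
#' @return list with `breaks` (length k + 1: min, the k - 1 class lower edges,
#'   max), `classes` (ordered factor aligned with `values`), `labels`,
#'   `intervals` (printed bracket form) and `ssd` (the achieved total
#'   within-class sum of squares).
#' @export
jenks_classes <- function(values, k = 4L) {
  k <- assert_scalar_count(k, "k", min = 2L)
  if (any(is.na(values))) stop_circnet("values must not contain NA")
  x <- sort(as.numeric(values))
  n <- length(x)
  if (length(unique(x)) < k)
    stop_circnet("need at least k distinct values for k classes")

  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssq <- function(i, j) { # within-class SSD of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, n, k)   # D[j, c]: optimal SSD of x[1..j] in c classes
  B <- matrix(0L, n, k)    # argmin start index of the last class
  for (j in 1:n) { D[j, 1] <- ssq(1, j); B[j, 1] <- 1L }
  for (c in 2:k) {
    for (j in c:n) {
      best <- Inf; arg <- c
      for (i in c:j) {
        v <- D[i - 1, c - 1] + ssq(i, j)
        if (v < best - 1e-12) { best <- v; arg <- i }
      }
      D[j, c] <- best; B[j, c] <- arg
    }
  }
  starts <- integer(k)
  j <- n
  for (c in k:1) { starts[c] <- B[j, c]; j <- starts[c] - 1L }
  lowers <- x[starts]                 # minimum value of each class
  breaks <- c(x[1], lowers[-1], x[n])

  labels <- if (k == 4) c("Lower", "Low", "High", "Higher") else paste0("class_", 1:k)
  cls_idx <- findInterval(values, lowers, rightmost.closed = FALSE)
  classes <- factor(labels[cls_idx], levels = labels, ordered = TRUE)
  intervals <- sprintf("[%g,%g%s", breaks[1:k], breaks[2:(k + 1)],
                       c(rep(")", k - 1), "]"))
  list(breaks = breaks, classes = classes, labels = labels,
       intervals = intervals, ssd = D[n, k])
}

#' Assign intensity classes to node metrics
#'
#' Runs [jenks_classes()] separately on the in- and out-intensity columns of
#' scorable nodes and attaches ordered class factors.
#'
#' @param metrics output of [circulation_intensity()].
#' @param k class count (default 4).
#' @return `metrics` plus `intensity_class_in`, `intensity_class_out`;
#'   attribute `"intensity_breaks"` holds both interval tables.
#' @export
intensity_classes <- function(metrics, k = 4L) {
  ok <- !metrics$unscorable
  jin <- jenks_classes(metrics$in_intensity[ok], k)
  jout <- jenks_classes(metrics$out_intensity[ok], k)
  metrics$intensity_class_in <- factor(NA, levels = jin$labels, ordered = TRUE)
  metrics$intensity_class_out <- factor(NA, levels = jout$labels, ordered = TRUE)
  metrics$intensity_class_in[ok] <- jin$classes
  metrics$intensity_class_out[ok] <- jout$classes
  attr(metrics, "intensity_breaks") <- list(in_intensity = jin, out_intensity = jout)
  metrics
}

#' Circulation pattern quadrants
#'
#' Labels each unit by where its in- and out-intensity classes fall:
#' `A_high_both` (both in the top class), `B_net_destination` (in-intensity
#' top, out-intensity not), `C_net_source` (out-intensity top, in-intensity
#' not), `D_low_both` (both in the bottom class), otherwise `unclassified`.
#'
#' @param metrics output of [intensity_classes()].
#' @return `metrics` with a `pattern` factor column.
#' @export
classify_patterns <- function(metrics) {
  stopifnot(all(c("intensity_class_in", "intensity_class_out") %in% names(metrics)))
  lv_in <- levels(metrics$intensity_class_in)
  lv_out <- levels(metrics$intensity_class_out)
  top_in <- metrics$intensity_class_in == lv_in[length(lv_in)]
  top_out <- metrics$intensity_class_out == lv_out[length(lv_out)]
  bot_in <- metrics$intensity_class_in == lv_in[1]
  bot_out <- metrics$intensity_class_out == lv_out[1]
  pat <- dplyr::case_when(
    top_in & top_out ~ "A_high_both",
    top_in & !top_out ~ "B_net_destination",
    top_out & !top_in ~ "C_net_source",
    bot_in & bot_out ~ "D_low_both",
    .default = "unclassified"
  )
  metrics$pattern <- factor(pat, levels = c("A_high_both", "B_net_destination",
                                            "C_net_source", "D_low_both",
                                            "unclassified"))
  metrics
}
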