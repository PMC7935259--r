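test_that("node metrics separate directions, weights and self-loop mass", {
  star <- make_net(tibble::tibble(source = "c", destination = c("x", "y", "z"),
                                  weight = 1L))
  m <- node_metrics(star)
  ctr <- m[m$unit_id == "c", ]
  expect_equal(ctr$out_degree, 3)
  expect_equal(ctr$in_degree, 0)
  expect_equal(ctr$weighted_degree, 3)
  expect_equal(ctr$ratio, 0)

  net <- make_net(tibble::tibble(source = c("a", "b", "b"),
                                 destination = c("b", "a", "b"),
                                 weight = c(2L, 3L, 7L)))
  mb <- node_metrics(net)
  b <- mb[mb$unit_id == "b", ]
  expect_equal(b$weighted_in, 2)   # self-loop excluded from degrees
  expect_equal(b$weighted_out, 3)
  expect_equal(b$self_weight, 7)
  a <- mb[mb$unit_id == "a", ]
  expect_equal(a$ratio, 3 / 2)
})

test_that("zero-outflow nodes get the infinite-ratio sentinel", {
  net <- make_net(tibble::tibble(source = "a", destination = "b", weight = 5L))
  m <- node_metrics(net)
  expect_true(is.infinite(m$ratio[m$unit_id == "b"]))
})

test_that("density matches its definition on canonical graphs", {
  n3 <- expand.grid(source = c("a", "b", "c"), destination = c("a", "b", "c"),
                    stringsAsFactors = FALSE)
  n3 <- n3[n3$source != n3$destination, ]
  n3$weight <- 1L
  expect_equal(network_density(make_net(n3)), 1)
  dyad <- make_net(tibble::tibble(source = "a", destination = "b", weight = 1L))
  expect_equal(network_density(dyad), 0.5)
  single <- circulation_network(tibble::tibble(source = "a", destination = "a",
                                               weight = 1L))
  expect_error(network_density(single), "fewer than 2")
})

test_that("density equals brute-force edge enumeration on random graphs", {
  withr::local_seed(5)
  for (i in 1:10) {
    net <- rand_digraph(sample(3:9, 1))
    e <- net$edges[net$edges$source != net$edges$destination, ]
    n <- nrow(net$nodes)
    expect_equal(network_density(net), nrow(e) / (n * (n - 1)))
  }
})

test_that("summaries report diameter, components and the handshake identity", {
  path <- make_net(tibble::tibble(source = c("a", "b"), destination = c("b", "c"),
                                  weight = 1L))
  s <- summarize_network(path)
  expect_equal(s$diameter, 2L)
  expect_equal(s$components, 1L)
  expect_false(s$strongly_connected)

  dyads <- make_net(tibble::tibble(source = c("a", "c"), destination = c("b", "d"),
                                   weight = 1L))
  expect_equal(summarize_network(dyads)$components, 2L)

  withr::local_seed(17)
  for (i in 1:8) {
    net <- rand_digraph(sample(4:9, 1))
    m <- node_metrics(net)
    e <- sum(net$edges$source != net$edges$destination)
    expect_equal(sum(m$in_degree), e)
    expect_equal(sum(m$out_degree), e)
    expect_equal(sum(m$weighted_in), sum(m$weighted_out))
    s <- summarize_network(net)
    expect_equal(s$mean_degree, e / nrow(net$nodes))
    expect_equal(s$mean_degree_both_ends, 2 * e / nrow(net$nodes))
  }
})

test_that("circulation intensity is per-1000 flow over sample totals", {
  net <- make_net(tibble::tibble(source = c("a", "b"), destination = c("b", "a"),
                                 weight = c(130L, 4L)))
  totals <- tibble::tibble(unit_id = c("a", "b"), total_samples = c(500L, 2000L))
  m <- circulation_intensity(net, totals, include_self_loops = FALSE)
  expect_equal(m$in_intensity[m$unit_id == "b"], 1000 * 130 / 2000)
  expect_equal(m$out_intensity[m$unit_id == "a"], 1000 * 130 / 500)

  # self-loop mass counts toward both directions by default
  loopy <- make_net(tibble::tibble(source = c("a", "a"), destination = c("a", "b"),
                                   weight = c(10L, 5L)))
  m2 <- circulation_intensity(loopy, tibble::tibble(unit_id = c("a", "b"),
                                                    total_samples = c(1000L, 1000L)))
  expect_equal(m2$out_intensity[m2$unit_id == "a"], 1000 * 15 / 1000)
  expect_equal(m2$in_intensity[m2$unit_id == "a"], 1000 * 10 / 1000)

  # missing totals flag, never silently zero
  expect_warning(
    m3 <- circulation_intensity(net, totals[1, ]), "unscorable")
  expect_true(m3$unscorable[m3$unit_id == "b"])
  expect_true(is.na(m3$in_intensity[m3$unit_id == "b"]))
})

test_that("jenks classes split at the obvious gaps and reject bad input", {
  j <- jenks_classes(c(1, 2, 10, 11, 100, 101, 1000, 1001), k = 4)
  expect_equal(j$breaks, c(1, 10, 100, 1000, 1001))
  expect_equal(as.character(j$classes),
               rep(c("Lower", "Low", "High", "Higher"), each = 2))
  expect_equal(j$intervals[4], "[1000,1001]")
  expect_error(jenks_classes(rep(3, 10), 4), "distinct")
  expect_error(jenks_classes(c(1, 2, 3), 4), "distinct")
})

test_that("jenks matches the exhaustive break-placement oracle", {
  withr::local_seed(29)
  for (i in 1:6) {
    vals <- round(stats::rlnorm(sample(10:25, 1), meanlog = 3), 2)
    k <- sample(2:5, 1)
    if (length(unique(vals)) < k) next
    j <- jenks_classes(vals, k)
    expect_equal(j$ssd, oracle_jenks_ssd(vals, k), tolerance = 1e-10)
  }
})

test_that("pattern quadrants follow the class grid", {
  m <- tibble::tibble(
    unit_id = c("u1", "u2", "u3", "u4", "u5"),
    intensity_class_in = factor(c("Higher", "Higher", "Low", "Lower", "Lower"),
                                levels = c("Lower", "Low", "High", "Higher"),
                                ordered = TRUE),
    intensity_class_out = factor(c("Higher", "Low", "Higher", "Lower", "High"),
                                 levels = c("Lower", "Low", "High", "Higher"),
                                 ordered = TRUE))
  p <- classify_patterns(m)
  expect_equal(as.character(p$pattern),
               c("A_high_both", "B_net_destination", "C_net_source",
                 "D_low_both", "unclassified"))
})

test_that("net-destination counts are invariant under unit relabeling", {
  withr::local_seed(31)
  net <- rand_digraph(8)
  m <- node_metrics(net)
  perm <- sample(net$nodes$unit_id)
  relab <- setNames(perm, net$nodes$unit_id)
  e2 <- net$edges
  e2$source <- unname(relab[e2$source]); e2$destination <- unname(relab[e2$destination])
  m2 <- node_metrics(make_net(e2))
  expect_equal(sum(m$ratio > 1, na.rm = TRUE), sum(m2$ratio > 1, na.rm = TRUE))
})
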