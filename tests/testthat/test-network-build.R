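resolutions_from <- function(df) {
  # minimal geo_resolution-shaped tibble for build_network
  tibble::tibble(record_id = sprintf("R%03d", seq_len(nrow(df))),
                 status = "substandard", sample_date = as.Date(NA),
                 manu_province = sub("-.*", "", df$src),
                 manu_city = df$src,
                 dist_province = sub("-.*", "", df$dst),
                 dist_city = df$dst,
                 method = "gazetteer", unresolved = FALSE)
}

test_that("edge weights count records and self-loops carry local circulation", {
  res <- resolutions_from(tibble::tibble(src = c("P-A", "P-A", "P-A"),
                                         dst = c("P-B", "P-B", "P-A")))
  net <- build_network(res, level = "city")
  expect_setequal(net$nodes$unit_id, c("P-A", "P-B"))
  e <- net$edges[order(net$edges$destination), ]
  expect_equal(e$weight[e$source == "P-A" & e$destination == "P-B"], 2L)
  expect_equal(e$weight[e$source == "P-A" & e$destination == "P-A"], 1L)
  expect_equal(net$n_records, 3L)
  expect_equal(within_unit_fraction(net), 1 / 3)
})

test_that("all-local data gives a single node with one self-loop", {
  res <- resolutions_from(tibble::tibble(src = rep("P-A", 4), dst = rep("P-A", 4)))
  net <- build_network(res, level = "city")
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(within_unit_fraction(net), 1)
})

test_that("unresolved records are excluded with an explicit count", {
  res <- resolutions_from(tibble::tibble(src = c("P-A", "P-B"), dst = c("P-B", "P-A")))
  res$manu_city[2] <- NA
  res$unresolved[2] <- TRUE
  expect_message(net <- build_network(res, level = "city"), "excluded")
  expect_equal(net$n_records, 1L)
  expect_equal(attr(net, "n_dropped"), 1L)
})

test_that("top_paths ranks by weight with lexicographic tie-breaks", {
  net <- make_net(tibble::tibble(source = c("A", "B", "C"),
                                 destination = c("B", "C", "A"),
                                 weight = c(5L, 2L, 2L)))
  tp <- top_paths(net, k = 2)
  expect_equal(tp$source, c("A", "B"))
  expect_equal(tp$weight, c(5L, 2L))
  full <- top_paths(net, k = 99)
  expect_equal(nrow(full), 3L)
  expect_equal(full$source[2:3], c("B", "C"))  # tie resolved by name
})

test_that("generated data reproduces the ground-truth flow matrix exactly", {
  ds <- generate_records(generator_config(n_provinces = 5, cities_per_province = 4,
                                          samples_per_city = 150,
                                          substandard_rate = 0.2, seed = 11))
  res <- suppressMessages(resolve_records(filter_substandard(clean_records(ds$records)),
                                          ds$gazetteer))
  net <- build_network(res, level = "city", gaz = ds$gazetteer)
  got <- dplyr::arrange(net$edges, source, destination)
  want <- dplyr::arrange(ds$truth$flow_matrix, source, destination)
  expect_equal(got$source, want$source)
  expect_equal(got$destination, want$destination)
  expect_equal(got$weight, as.integer(want$weight))
  expect_equal(net$n_records, ds$truth$n_substandard)
})

test_that("the province network equals the city network aggregated by parent", {
  ds <- generate_records(generator_config(n_provinces = 6, cities_per_province = 3,
                                          samples_per_city = 120,
                                          substandard_rate = 0.15, seed = 23))
  res <- suppressMessages(resolve_records(filter_substandard(clean_records(ds$records)),
                                          ds$gazetteer))
  city <- build_network(res, level = "city", gaz = ds$gazetteer)
  prov <- build_network(res, level = "province", gaz = ds$gazetteer)
  agg <- aggregate_to_province(city, ds$gazetteer)
  e1 <- dplyr::arrange(prov$edges, source, destination)
  e2 <- dplyr::arrange(agg$edges, source, destination)
  expect_equal(e1, e2)
  # conservation at both levels
  expect_equal(city$n_records, prov$n_records)
  expect_equal(sum(city$edges$weight), nrow(res))
})

test_that("network exports write edge lists, GraphML and GEXF", {
  net <- make_net(tibble::tibble(source = c("A", "B", "A"),
                                 destination = c("B", "C", "A"),
                                 weight = c(3L, 1L, 2L)))
  el <- withr::local_tempfile(fileext = ".csv")
  write_network(net, el, "edgelist")
  expect_equal(nrow(readr::read_csv(el, show_col_types = FALSE)), 3L)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 2L)  # self-loop dropped in graph exports
  gexf <- withr::local_tempfile(fileext = ".gexf")
  write_network(net, gexf, "gexf")
  doc <- paste(readLines(gexf), collapse = "")
  expect_match(doc, "<gexf", fixed = TRUE)
  expect_match(doc, 'source="A" target="B" weight="3"', fixed = TRUE)
})

test_that("degenerate networks are rejected or warned about", {
  expect_error(circulation_network(tibble::tibble(
    source = "A", destination = "B", weight = 0)), "positive integers")
  expect_error(circulation_network(tibble::tibble(
    source = c("A", "A"), destination = c("B", "B"), weight = c(1, 2))),
    "one edge")
  res <- resolutions_from(tibble::tibble(src = "P-A", dst = "P-B"))
  res$unresolved <- TRUE; res$manu_city <- NA
  expect_warning(suppressMessages(net <- build_network(res, "city")), "empty")
  expect_equal(nrow(net$nodes), 0L)
})
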