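test_that("the generator is deterministic given a seed", {
  cfg <- generator_config(n_provinces = 3, cities_per_province = 3,
                          samples_per_city = 60, seed = 5)
  d1 <- generate_records(cfg)
  d2 <- generate_records(cfg)
  expect_identical(d1$records$records, d2$records$records)
  expect_identical(d1$truth$flow_matrix, d2$truth$flow_matrix)
  d3 <- generate_records(generator_config(n_provinces = 3, cities_per_province = 3,
                                          samples_per_city = 60, seed = 6))
  expect_false(identical(d1$records$records, d3$records$records))
})

test_that("forced regimes produce the forced networks", {
  # everything within-city -> only self-loops
  all_local <- generate_records(generator_config(
    n_provinces = 2, cities_per_province = 3, samples_per_city = 50,
    substandard_rate = 0.3, p_within_city = 1, seed = 2))
  res <- suppressMessages(resolve_records(all_local$records, all_local$gazetteer))
  net <- build_network(res[res$status == "substandard", ], "city")
  expect_equal(within_unit_fraction(net), 1)

  # no substandard records at all -> pipeline degrades gracefully
  none <- generate_records(generator_config(
    n_provinces = 2, cities_per_province = 2, samples_per_city = 30,
    substandard_rate = 0, seed = 3))
  expect_equal(none$truth$n_substandard, 0L)
  expect_warning(sub <- filter_substandard(none$records), "no substandard")
  expect_equal(sub$counts$total, 0L)
})

test_that("configured probabilities are recovered within binomial error", {
  cfg <- generator_config(n_provinces = 10, cities_per_province = 5,
                          samples_per_city = 1000, substandard_rate = 0.021,
                          seed = 8)
  ds <- generate_records(cfg)   # 50,000 records
  n_sub <- ds$truth$n_substandard
  se <- sqrt(cfg$p_within_city * (1 - cfg$p_within_city) / n_sub)
  expect_lt(abs(ds$truth$within_city_fraction - cfg$p_within_city), 3 * se)
  p_prov <- cfg$p_within_city + (1 - cfg$p_within_city) * cfg$p_within_province
  se2 <- sqrt(p_prov * (1 - p_prov) / n_sub)
  expect_lt(abs(ds$truth$within_province_fraction - p_prov), 3 * se2)
  # substandard rate itself
  se3 <- sqrt(cfg$substandard_rate * (1 - cfg$substandard_rate) / ds$records$counts$total)
  expect_lt(abs(n_sub / ds$records$counts$total - cfg$substandard_rate), 3 * se3)
})

test_that("ground-truth bookkeeping is internally consistent", {
  ds <- generate_records(generator_config(n_provinces = 4, cities_per_province = 4,
                                          samples_per_city = 200,
                                          substandard_rate = 0.1, seed = 13))
  fl <- ds$truth$flow_matrix
  expect_equal(sum(fl$weight), ds$truth$n_substandard)
  dst_sum <- tapply(fl$weight, fl$destination, sum)
  tc <- ds$truth$totals_city
  expect_equal(as.integer(dst_sum[tc$unit_id[tc$substandard > 0]]),
               tc$substandard[tc$substandard > 0])
  expect_equal(sum(tc$total_samples), ds$records$counts$total)
})

test_that("hub attraction concentrates inflow and the null case does not", {
  hubby <- generate_records(generator_config(
    n_provinces = 4, cities_per_province = 5, samples_per_city = 400,
    substandard_rate = 0.2, hub_fraction = 0.1, hub_attraction = 30,
    weight_tail = 0, seed = 21))
  tc <- hubby$truth$totals_city
  hub_mean <- mean(tc$total_samples[tc$unit_id %in% hubby$truth$hubs])
  rest_max <- max(tc$total_samples[!tc$unit_id %in% hubby$truth$hubs])
  expect_gt(hub_mean, rest_max)

  flat <- generate_records(generator_config(
    n_provinces = 4, cities_per_province = 5, samples_per_city = 400,
    substandard_rate = 0.2, hub_attraction = 1, weight_tail = 0, seed = 21))
  expect_length(flat$truth$hubs, 0)
  tcf <- flat$truth$totals_city
  # uniform destinations: spread stays within ordinary multinomial noise
  expect_lt(max(tcf$total_samples) / min(tcf$total_samples), 1.5)
})

test_that("the two-hub scenario plants dominant, recoverable hubs", {
  cfg <- generator_config(n_provinces = 4, cities_per_province = 5,
                          samples_per_city = 500, substandard_rate = 0.05,
                          seed = 37)
  ds <- plant_two_hub_scenario(cfg)
  expect_length(ds$truth$hubs, 2)
  res <- suppressMessages(resolve_records(ds$records, ds$gazetteer))
  net <- build_network(res[res$status == "substandard", ], "city")
  m <- node_metrics(net)
  hub_w <- m$weighted_degree[m$unit_id %in% ds$truth$hubs]
  non_w <- m$weighted_degree[!m$unit_id %in% ds$truth$hubs]
  expect_gt(min(hub_w), max(non_w))
  sol <- find_key_players(net, 2, restarts = 5, seed = 1)
  expect_identical(sol$set, ds$truth$hubs)
  expect_equal(sol$reach, 1)
})

test_that("impossible configurations are rejected", {
  expect_error(generator_config(n_provinces = 1, cities_per_province = 1,
                                p_within_city = 0.5), "single city")
  expect_error(generator_config(substandard_rate = 1.2), "probability")
  expect_error(generator_config(blocks = 1:3), "every province")
  expect_error(plant_two_hub_scenario(generator_config(n_provinces = 2,
                                                       cities_per_province = 2)),
               "at least 10")
})
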