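#' Configuration for the synthetic inspection-record generator
#'
#' The defaults describe the circulation regime the analysis pipeline assumes:
#' most substandard food moves locally (57.2% of routes inside one city and
#' 81.7% inside one province), destination cities receive long-tailed flow
#' volumes, and a small set of hub cities attracts disproportionate flow.
#' `p_within_province` is the probability that a route stays inside the
#' province *given* that it leaves the city; the default 0.5724 makes the
#' overall within-province share 0.572 + 0.428 x 0.5724 = 0.817.
#'
#' @param n_provinces number of provinces (default 34).
#' @param cities_per_province cities in each province; scalar or a vector of
#'   length `n_provinces` (default 11, about 361/34).
#' @param samples_per_city mean number of sampled items per city; the total
#'   sample count is `n_cities * samples_per_city` with destinations drawn by
#'   weight, so realized per-city totals vary (default 2600, which at 34 x 11
#'   cities gives a national total close to one million records).
#' @param substandard_rate probability a sampled item fails inspection
#'   (default 0.021, the retained-substandard share of a national total).
#' @param p_within_city probability the manufacturer sits in the sampling
#'   (distributor) city (default 0.572).
#' @param p_within_province probability the manufacturer sits elsewhere in the
#'   same province, given it is outside the city (default 0.5724).
#' @param hub_fraction share of cities designated hubs (default 0.03).
#' @param hub_attraction multiplicative destination weight on hub cities
#'   (default 3; 1 disables hub structure).
#' @param weight_tail Zipf exponent of the long-tailed city base weights
#'   (default 1.1; 0 gives uniform cities).
#' @param blocks optional integer vector assigning each province to a planted
#'   community block; cross-province routes then stay inside the block with
#'   probability `p_within_block`.
#' @param p_within_block see `blocks` (default 0.9).
#' @param seed integer seed fixing the whole dataset (default 42).
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_provinces = 34L,
                             cities_per_province = 11L,
                             samples_per_city = 2600L,
                             substandard_rate = 0.021,
                             p_within_city = 0.572,
                             p_within_province = 0.5724,
                             hub_fraction = 0.03,
                             hub_attraction = 3,
                             weight_tail = 1.1,
                             blocks = NULL,
                             p_within_block = 0.9,
                             seed = 42L) {
  n_provinces <- assert_scalar_count(n_provinces, "n_provinces")
  if (n_provinces > 99) stop_circnet("at most 99 provinces are supported")
  if (length(cities_per_province) == 1L)
    cities_per_province <- rep(as.integer(cities_per_province), n_provinces)
  if (length(cities_per_province) != n_provinces || any(cities_per_province < 1))
    stop_circnet("cities_per_province must be a positive scalar or a vector of length n_provinces")
  if (any(cities_per_province > 99)) stop_circnet("at most 99 cities per province")
  samples_per_city <- assert_scalar_count(samples_per_city, "samples_per_city")
  cfg <- list(
    n_provinces = n_provinces,
    cities_per_province = as.integer(cities_per_province),
    samples_per_city = samples_per_city,
    substandard_rate = assert_prob(substandard_rate, "substandard_rate"),
    p_within_city = assert_prob(p_within_city, "p_within_city"),
    p_within_province = assert_prob(p_within_province, "p_within_province"),
    hub_fraction = assert_prob(hub_fraction, "hub_fraction"),
    hub_attraction = as.numeric(hub_attraction),
    weight_tail = as.numeric(weight_tail),
    blocks = blocks,
    p_within_block = assert_prob(p_within_block, "p_within_block"),
    seed = as.integer(seed)
  )
  n_cities <- sum(cfg$cities_per_province)
  if (n_cities < 2 && cfg$p_within_city < 1)
    stop_circnet("cross-city circulation is impossible with a single city")
  if (!is.null(blocks)) {
    if (length(blocks) != n_provinces)
      stop_circnet("blocks must assign every province")
    if (length(unique(blocks)) < 2)
      stop_circnet("planted blocks need at least two distinct blocks")
  }
  if (cfg$hub_attraction < 1) stop_circnet("hub_attraction must be >= 1")
  class(cfg) <- "generator_config"
  cfg
}

# Synthetic admin units; names are synthetic on purpose (no real gazetteer is
# shipped). Centroids are laid out on a grid purely for display.
synthetic_gazetteer <- function(cfg) {
  pid <- sprintf("P%02d", seq_len(cfg$n_provinces))
  prov <- tibble::tibble(
    unit_id = pid,
    name = paste(pid, "Province"),
    level = "province",
    parent_id = NA_character_,
    lng = 75 + (seq_len(cfg$n_provinces) %% 7) * 7,
    lat = 20 + (seq_len(cfg$n_provinces) %/% 7) * 5,
    aliases = NA_character_
  )
  city <- dplyr::bind_rows(lapply(seq_len(cfg$n_provinces), function(p) {
    k <- cfg$cities_per_province[p]
    cid <- sprintf("%s-C%02d", pid[p], seq_len(k))
    tibble::tibble(unit_id = cid, name = paste(cid, "City"), level = "city",
                   parent_id = pid[p],
                   lng = prov$lng[p] + (seq_len(k) %% 4),
                   lat = prov$lat[p] + (seq_len(k) %/% 4),
                   aliases = NA_character_)
  }))
  gazetteer(dplyr::bind_rows(prov, city))
}

synthetic_address <- function(city_name, province_name, street, number) {
  sprintf("%d %s, %s, %s", number, street, city_name, province_name)
}

# Draw, for each cross-city record, a source city. Rejection sampling keeps
# everything vectorized: redraw until the constraint holds (expected a couple
# of rounds).
draw_with_constraint <- function(n, n_cities, ok_fun) {
  src <- sample.int(n_cities, n, replace = TRUE)
  bad <- !ok_fun(src)
  guard <- 0L
  while (any(bad)) {
    src[bad] <- sample.int(n_cities, sum(bad), replace = TRUE)
    bad <- !ok_fun(src)
    guard <- guard + 1L
    if (guard > 10000L) stop_circnet("constraint sampling failed to converge")
  }
  src
}

#' Generate a synthetic inspection-record dataset
#'
#' Emulates a national sampling-inspection table: each record is sampled at a
#' destination (distributor) city drawn proportionally to a Zipf-tailed base
#' weight boosted on hub cities, fails inspection with `substandard_rate`, and
#' has its manufacturer placed in the same city with `p_within_city`,
#' elsewhere in the same province with `p_within_province` (given cross-city),
#' and otherwise in a different province (respecting planted blocks when
#' configured). Addresses are templated from the synthetic gazetteer names so
#' offline geocoding round-trips exactly.
#'
#' @param cfg a [generator_config()].
#' @return a list of class `synthetic_dataset` with elements `records` (a
#'   [record_set()]), `gazetteer` (a [gazetteer()]), `truth` (ground-truth
#'   bookkeeping: substandard `flow_matrix` by city pair, per-city and
#'   per-province `totals`, `hubs`, `block_of_province`, `block_of_city`,
#'   realized within-city/within-province fractions) and `config`.
#' @export
generate_records <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  gaz <- synthetic_gazetteer(cfg)
  cities <- gaz$units[gaz$units$level == "city", ]
  provs <- gaz$units[gaz$units$level == "province", ]
  n_cities <- nrow(cities)
  prov_of <- match(cities$parent_id, provs$unit_id)

  with_seed(cfg$seed, {
    base_w <- sample(seq_len(n_cities))^(-cfg$weight_tail)
    n_hubs <- if (cfg$hub_attraction > 1) ceiling(cfg$hub_fraction * n_cities) else 0L
    hubs <- if (n_hubs > 0) sort(sample.int(n_cities, n_hubs)) else integer(0)
    dest_w <- base_w
    dest_w[hubs] <- dest_w[hubs] * cfg$hub_attraction

    N <- n_cities * cfg$samples_per_city
    dest <- sample.int(n_cities, N, replace = TRUE, prob = dest_w)
    status <- ifelse(stats::runif(N) < cfg$substandard_rate, "substandard", "qualified")

    u <- stats::runif(N)
    src <- dest
    cross_city <- u >= cfg$p_within_city
    # same province, different city (provinces with one city fall through)
    single <- (cfg$cities_per_province[prov_of] == 1L)[dest]
    v <- stats::runif(N)
    in_prov <- cross_city & !single & v < cfg$p_within_province
    if (any(in_prov)) {
      idx <- which(in_prov)
      src[idx] <- draw_with_constraint(length(idx), n_cities, function(s)
        prov_of[s] == prov_of[dest[idx]] & s != dest[idx])
    }
    out_prov <- cross_city & !in_prov
    if (any(out_prov)) {
      idx <- which(out_prov)
      if (is.null(cfg$blocks)) {
        src[idx] <- draw_with_constraint(length(idx), n_cities, function(s)
          prov_of[s] != prov_of[dest[idx]])
      } else {
        blk <- cfg$blocks
        w <- stats::runif(length(idx)) < cfg$p_within_block
        same_blk <- idx[w]; other_blk <- idx[!w]
        if (length(same_blk))
          src[same_blk] <- draw_with_constraint(length(same_blk), n_cities, function(s)
            prov_of[s] != prov_of[dest[same_blk]] &
              blk[prov_of[s]] == blk[prov_of[dest[same_blk]]])
        if (length(other_blk))
          src[other_blk] <- draw_with_constraint(length(other_blk), n_cities, function(s)
            blk[prov_of[s]] != blk[prov_of[dest[other_blk]]])
      }
    }

    streets <- c("Market Road", "Harbour Street", "Mill Lane", "Station Road",
                 "Garden Avenue", "Temple Street", "Canal Road", "Liberation Avenue")
    foods <- c("biscuits", "rice noodles", "soy sauce", "dried tofu", "peanut oil",
               "black tea", "pickled vegetables", "rice wine", "sesame paste",
               "preserved plums", "vermicelli", "chili sauce", "lotus cakes",
               "walnut milk", "mung bean cake", "fermented bean curd",
               "sunflower seeds", "hawthorn slices", "osmanthus candy", "barley flour")
    addr_for <- function(city_idx) {
      synthetic_address(cities$name[city_idx],
                        provs$name[prov_of[city_idx]],
                        sample(streets, length(city_idx), replace = TRUE),
                        sample.int(20L, length(city_idx), replace = TRUE))
    }
    dates <- seq(as.Date("2014-01-01"), as.Date("2019-06-30"), by = "day")
    records <- tibble::tibble(
      record_id = sprintf("R%07d", seq_len(N)),
      status = status,
      manufacturer_address = addr_for(src),
      distributor_address = addr_for(dest),
      sample_date = sample(dates, N, replace = TRUE),
      food_name = sample(foods, N, replace = TRUE)
    )
    rs <- record_set(records, source = "synthetic-generator")

    sub <- status == "substandard"
    flow <- dplyr::count(
      tibble::tibble(source = cities$unit_id[src[sub]],
                     destination = cities$unit_id[dest[sub]]),
      .data$source, .data$destination, name = "weight")
    totals_city <- tibble::tibble(
      unit_id = cities$unit_id,
      total_samples = as.integer(tabulate(dest, n_cities)),
      substandard = as.integer(tabulate(dest[sub], n_cities))
    )
    totals_prov <- tibble::tibble(
      unit_id = provs$unit_id,
      total_samples = as.integer(tabulate(prov_of[dest], nrow(provs))),
      substandard = as.integer(tabulate(prov_of[dest[sub]], nrow(provs)))
    )
    truth <- list(
      flow_matrix = flow,
      totals_city = totals_city,
      totals_province = totals_prov,
      hubs = cities$unit_id[hubs],
      block_of_province = if (is.null(cfg$blocks)) NULL else
        stats::setNames(cfg$blocks, provs$unit_id),
      block_of_city = if (is.null(cfg$blocks)) NULL else
        stats::setNames(cfg$blocks[prov_of], cities$unit_id),
      within_city_fraction = mean(src[sub] == dest[sub]),
      within_province_fraction = mean(prov_of[src[sub]] == prov_of[dest[sub]]),
      n_substandard = sum(sub)
    )
    structure(list(records = rs, gazetteer = gaz, truth = truth, config = cfg),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d records over %d cities (%d substandard), seed %d\n",
              x$records$counts$total, sum(x$config$cities_per_province),
              x$truth$n_substandard, x$config$seed))
  invisible(x)
}

#' Plant a two-hub scenario
#'
#' Builds a dataset in which two hub cities in different provinces originate a
#' fixed large share of all cross-city substandard flow, each covering its own
#' half of the provinces, while every other city sends cross-city flow only to
#' a small fixed neighborhood. By construction the hubs' weighted degrees
#' dominate every non-hub and the pair is the unique size-2 set reaching the
#' whole network, which is the recovery target for key-player and gatekeeper
#' checks.
#'
#' @param cfg a [generator_config()] with at least 10 cities.
#' @param hub_share share of cross-city routes that originate at a hub
#'   (default 0.6).
#' @param background_out_neighbors out-neighborhood size of non-hub cities for
#'   background cross-city flow (default 2).
#' @return a `synthetic_dataset` (see [generate_records()]); `truth$hubs`
#'   names the two planted hubs.
#' @export
plant_two_hub_scenario <- function(cfg, hub_share = 0.6,
                                   background_out_neighbors = 2L) {
  stopifnot(inherits(cfg, "generator_config"))
  gaz <- synthetic_gazetteer(cfg)
  cities <- gaz$units[gaz$units$level == "city", ]
  provs <- gaz$units[gaz$units$level == "province", ]
  n_cities <- nrow(cities)
  if (n_cities < 10) stop_circnet("the two-hub scenario needs at least 10 cities")
  if (cfg$n_provinces < 2) stop_circnet("the two-hub scenario needs at least 2 provinces")
  hub_share <- assert_prob(hub_share, "hub_share")
  prov_of <- match(cities$parent_id, provs$unit_id)

  with_seed(cfg$seed + 1L, {
    half1 <- which(prov_of <= cfg$n_provinces / 2)
    half2 <- setdiff(seq_len(n_cities), half1)
    h1 <- sample(half1, 1); h2 <- sample(half2, 1)
    halves <- list(half1, half2)
    hub_of_half <- c(h1, h2)

    N <- n_cities * cfg$samples_per_city
    dest <- sample.int(n_cities, N, replace = TRUE)
    status <- ifelse(stats::runif(N) < cfg$substandard_rate, "substandard", "qualified")
    src <- dest
    cross <- stats::runif(N) >= cfg$p_within_city
    from_hub <- cross & stats::runif(N) < hub_share
    if (any(from_hub)) {
      idx <- which(from_hub)
      half_pick <- sample.int(2L, length(idx), replace = TRUE)
      src[idx] <- hub_of_half[half_pick]
      # destination inside the originating hub's half, not the hub itself
      dest[idx] <- vapply(half_pick, function(h)
        sample(setdiff(halves[[h]], hub_of_half[h]), 1L), integer(1))
    }
    bg <- cross & !from_hub
    if (any(bg)) {
      nb <- lapply(seq_len(n_cities), function(i)
        sample(setdiff(seq_len(n_cities), c(i, h1, h2)),
               min(background_out_neighbors, n_cities - 3L)))
      idx <- which(bg)
      src[idx] <- vapply(dest[idx], function(d) {
        cand <- nb[[d]]
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      # background edges run source -> destination along each city's small
      # out-neighborhood: reverse so the chosen neighbor is the destination
      tmp <- src[idx]; src[idx] <- dest[idx]; dest[idx] <- tmp
    }
    # coverage guarantee: each hub ships one record to every city in its half
    extra_src <- c(rep(h1, length(setdiff(half1, h1))), rep(h2, length(setdiff(half2, h2))))
    extra_dst <- c(setdiff(half1, h1), setdiff(half2, h2))

    src <- c(src, extra_src); dest <- c(dest, extra_dst)
    status <- c(status, rep("substandard", length(extra_src)))

    streets <- c("Market Road", "Harbour Street", "Mill Lane", "Station Road")
    addr_for <- function(ci) synthetic_address(
      cities$name[ci], provs$name[prov_of[ci]],
      sample(streets, length(ci), replace = TRUE),
      sample.int(20L, length(ci), replace = TRUE))
    dates <- seq(as.Date("2014-01-01"), as.Date("2019-06-30"), by = "day")
    n_all <- length(src)
    rs <- record_set(tibble::tibble(
      record_id = sprintf("R%07d", seq_len(n_all)),
      status = status,
      manufacturer_address = addr_for(src),
      distributor_address = addr_for(dest),
      sample_date = sample(dates, n_all, replace = TRUE),
      food_name = sample(c("biscuits", "soy sauce", "black tea", "rice wine"),
                         n_all, replace = TRUE)
    ), source = "synthetic-two-hub")

    sub <- status == "substandard"
    flow <- dplyr::count(
      tibble::tibble(source = cities$unit_id[src[sub]],
                     destination = cities$unit_id[dest[sub]]),
      .data$source, .data$destination, name = "weight")
    truth <- list(
      flow_matrix = flow,
      totals_city = tibble::tibble(unit_id = cities$unit_id,
                                   total_samples = as.integer(tabulate(dest, n_cities)),
                                   substandard = as.integer(tabulate(dest[sub], n_cities))),
      hubs = sort(cities$unit_id[c(h1, h2)]),
      n_substandard = sum(sub)
    )
    structure(list(records = rs, gazetteer = gaz, truth = truth, config = cfg),
              class = "synthetic_dataset")
  })
}

#' Plant a block-community scenario
#'
#' Assigns provinces to `n_blocks` blocks round-robin and generates records
#' whose cross-province routes stay inside their block with the configured
#' `p_within_block`. Under a strong signal (high `p_within_block`, modest
#' within-city share) the city-level network has the planted blocks as its
#' community structure, the recovery target for the Louvain checks.
#'
#' @param cfg a [generator_config()]; its `blocks` field is overwritten.
#' @param n_blocks number of planted blocks (default 3).
#' @return a `synthetic_dataset` with `truth$block_of_city` filled in.
#' @export
plant_block_scenario <- function(cfg, n_blocks = 3L) {
  stopifnot(inherits(cfg, "generator_config"))
  n_blocks <- assert_scalar_count(n_blocks, "n_blocks", min = 2L)
  if (cfg$n_provinces < n_blocks)
    stop_circnet("need at least one province per block")
  cfg$blocks <- rep_len(seq_len(n_blocks), cfg$n_provinces)
  generate_records(cfg)
}
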