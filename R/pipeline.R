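#' Quarterly record counts
#'
#' Buckets dated records into calendar quarters and reports per-quarter totals
#' and the substandard proportion. Undated records are excluded from the table
#' and counted in the `undated` attribute (with a warning when present).
#'
#' @param rs a [record_set()].
#' @return tibble with `quarter` (e.g. `"2014Q1"`), `total`, `substandard`,
#'   `proportion`; attribute `undated`.
#' @export
quarterly_counts <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  rec <- rs$records
  dated <- !is.na(rec$sample_date)
  n_undated <- sum(!dated)
  if (n_undated > 0)
    warning(n_undated, " undated record(s) excluded from quarterly counts",
            call. = FALSE)
  if (!any(dated)) {
    warning("no dated records; quarterly table is empty", call. = FALSE)
    out <- tibble::tibble(quarter = character(), total = integer(),
                          substandard = integer(), proportion = numeric())
    attr(out, "undated") <- n_undated
    return(out)
  }
  d <- rec$sample_date[dated]
  q <- sprintf("%dQ%d", as.integer(format(d, "%Y")),
               (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L)
  out <- tibble::tibble(quarter = q, status = rec$status[dated])
  out <- dplyr::summarise(dplyr::group_by(out, .data$quarter),
                          total = dplyr::n(),
                          substandard = sum(.data$status == "substandard"),
                          .groups = "drop")
  out$proportion <- out$substandard / out$total
  out <- out[order(out$quarter), ]
  attr(out, "undated") <- n_undated
  out
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_circnet(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))))
}

#' Run the full circulation analysis
#'
#' Orchestrates the complete pipeline: clean the records, split off the
#' substandard subset, geocode both against the gazetteer, build the
#' province- and city-level circulation networks, and compute every report
#' table — network summary indicators, per-node flow metrics with
#' net-source/net-destination counts, circulation intensities with
#' natural-breaks classes and pattern quadrants, heaviest paths, edge- and
#' node-betweenness rankings, Louvain communities with their gatekeepers, and
#' the key-player reach profile — plus quarterly counts and a manifest tying
#' every headline number to the operation that produced it.
#'
#' Sample totals for the intensity denominators are taken from the full
#' cleaned record set (a unit's total is the number of samples whose
#' distributor resolves there), or from `totals` when supplied.
#'
#' @param records a raw [record_set()].
#' @param gaz a [gazetteer()].
#' @param totals optional list with elements `province` and/or `city`, each a
#'   data frame `unit_id`, `total_samples`, overriding the computed
#'   denominators.
#' @param levels which networks to build (default both).
#' @param seed integer seed used for every seeded stage (default 42).
#' @param n_classes intensity class count (default 4).
#' @param k_max largest key-player set size profiled (default 10).
#' @param restarts key-player restarts (default 20).
#' @param top_k rows kept in ranked tables (default 10).
#' @param out_dir optional directory; when given, every table is written as
#'   CSV and the manifest as JSON.
#' @return a list of class `pipeline_report`.
#' @export
run_pipeline <- function(records, gaz, totals = NULL,
                         levels = c("province", "city"),
                         seed = 42L, n_classes = 4L, k_max = 10L,
                         restarts = 20L, top_k = 10L, out_dir = NULL) {
  stopifnot(inherits(records, "record_set"), inherits(gaz, "gazetteer"))
  levels <- match.arg(levels, c("province", "city"), several.ok = TRUE)
  manifest <- list(seed = seed)

  cleaned <- pipeline_stage("clean", clean_records(records))
  manifest$cleaning <- c(list(producer = "clean_records",
                              input_records = records$counts$total,
                              retained = cleaned$counts$total),
                         cleaned$provenance$cleaning_report)

  substd <- pipeline_stage("filter", filter_substandard(cleaned))
  manifest$substandard_records <- list(producer = "filter_substandard",
                                       value = substd$counts$total)

  res_all <- pipeline_stage("geocode", resolve_records(cleaned, gaz))
  res_sub <- res_all[res_all$status == "substandard", ]
  manifest$resolution <- list(producer = "resolve_records",
                              records = nrow(res_all),
                              unresolved = sum(res_all$unresolved))

  quarterly <- pipeline_stage("quarterly", suppressWarnings(quarterly_counts(cleaned)))

  per_level <- list()
  for (lev in levels) {
    net <- pipeline_stage(paste0("build-", lev),
                          build_network(res_sub, level = lev, gaz = gaz))
    if (nrow(net$nodes) == 0) {
      per_level[[lev]] <- list(network = net)
      next
    }
    summary <- pipeline_stage(paste0("summary-", lev), summarize_network(net))
    metrics <- pipeline_stage(paste0("metrics-", lev), node_metrics(net))
    ratio_table <- list(
      net_destination = sum(metrics$ratio > 1, na.rm = TRUE),
      net_source = sum(metrics$ratio < 1, na.rm = TRUE),
      balanced = sum(metrics$ratio == 1, na.rm = TRUE)
    )
    within <- within_unit_fraction(net)
    paths <- top_paths(net, k = top_k)

    # intensity denominators: all samples (qualified + substandard) per unit
    tot <- if (!is.null(totals[[lev]])) tibble::as_tibble(totals[[lev]]) else {
      dst <- if (lev == "city") res_all$dist_city else res_all$dist_province
      cnt <- table(dst[!is.na(dst)])
      tibble::tibble(unit_id = names(cnt), total_samples = as.integer(cnt))
    }
    intensity <- pipeline_stage(paste0("intensity-", lev), {
      if (!all(c("unit_id", "total_samples") %in% names(tot)))
        stop("totals need columns unit_id and total_samples")
      m <- suppressWarnings(circulation_intensity(net, tot))
      ok <- !m$unscorable
      if (length(unique(m$in_intensity[ok])) >= n_classes &&
          length(unique(m$out_intensity[ok])) >= n_classes) {
        m <- intensity_classes(m, k = n_classes)
        classify_patterns(m)
      } else NULL
    })

    nb <- eb <- part <- gate <- NULL
    if (nrow(net$nodes) >= 3) {
      nb <- pipeline_stage(paste0("node-betweenness-", lev), node_betweenness(net))
      eb <- pipeline_stage(paste0("edge-betweenness-", lev), edge_betweenness(net))
    }
    if (sum(net$edges$source != net$edges$destination) > 0) {
      part <- pipeline_stage(paste0("communities-", lev), louvain(net, seed = seed))
      if (!is.null(nb))
        gate <- pipeline_stage(paste0("gatekeepers-", lev),
                               community_gatekeepers(part, nb))
    }
    keyp <- NULL
    if (lev == "city" && nrow(net$nodes) >= 2) {
      keyp <- pipeline_stage("keyplayers", key_player_profile(
        net, k_max = min(k_max, nrow(net$nodes)), restarts = restarts, seed = seed))
    }

    per_level[[lev]] <- list(
      network = net, summary = summary, metrics = metrics,
      ratio_table = ratio_table, within_unit_fraction = within,
      top_paths = paths, totals = tot, intensity = intensity,
      node_betweenness = nb, edge_betweenness = eb,
      communities = part, gatekeepers = gate, key_players = keyp
    )
    manifest[[lev]] <- list(
      network = list(producer = "build_network", nodes = nrow(net$nodes),
                     edges = nrow(net$edges), records = net$n_records,
                     dropped_unresolved = attr(net, "n_dropped")),
      within_unit_fraction = list(producer = "within_unit_fraction", value = within),
      density = list(producer = "network_density", value = summary$density),
      diameter = list(producer = "summarize_network", value = summary$diameter),
      components = list(producer = "summarize_network", value = summary$components),
      ratio_table = c(list(producer = "node_metrics"), ratio_table),
      communities = if (!is.null(part))
        list(producer = "louvain", n = part$n_communities,
             modularity = part$modularity, seed = seed),
      key_players = if (!is.null(keyp))
        list(producer = "key_player_profile",
             reach_pct = keyp$reach_pct,
             full_coverage_k = attr(keyp, "full_coverage_k"))
    )
  }

  report <- list(cleaned = cleaned, substandard = substd,
                 resolutions = res_sub, quarterly = quarterly,
                 levels = per_level, manifest = manifest, seed = seed)
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  records: %d cleaned, %d substandard\n",
              x$cleaned$counts$total, x$substandard$counts$total))
  for (lev in names(x$levels)) {
    pl <- x$levels[[lev]]
    if (is.null(pl$summary)) next
    cat(sprintf("  %s: %d nodes, density %.3f, within-unit %.1f%%%s\n",
                lev, pl$summary$size, pl$summary$density,
                100 * pl$within_unit_fraction,
                if (!is.null(pl$communities))
                  sprintf(", %d communities", pl$communities$n_communities) else ""))
  }
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_records(report$cleaned, file.path(out_dir, "cleaned_records.csv"))
  readr::write_csv(report$quarterly, file.path(out_dir, "quarterly_counts.csv"),
                   progress = FALSE)
  for (lev in names(report$levels)) {
    pl <- report$levels[[lev]]
    if (is.null(pl$summary)) next
    pre <- function(nm) file.path(out_dir, paste0(lev, "_", nm))
    write_network(pl$network, pre("edges.csv"), format = "edgelist")
    readr::write_csv(pl$metrics, pre("node_metrics.csv"), progress = FALSE)
    readr::write_csv(pl$top_paths, pre("top_paths.csv"), progress = FALSE)
    if (!is.null(pl$intensity))
      readr::write_csv(pl$intensity, pre("intensity.csv"), progress = FALSE)
    if (!is.null(pl$node_betweenness))
      readr::write_csv(tibble::as_tibble(pl$node_betweenness),
                       pre("node_betweenness.csv"), progress = FALSE)
    if (!is.null(pl$edge_betweenness))
      readr::write_csv(tibble::as_tibble(pl$edge_betweenness),
                       pre("edge_betweenness.csv"), progress = FALSE)
    if (!is.null(pl$communities))
      readr::write_csv(tibble::tibble(unit_id = names(pl$communities$membership),
                                      community = unname(pl$communities$membership)),
                       pre("communities.csv"), progress = FALSE)
    if (!is.null(pl$gatekeepers))
      readr::write_csv(pl$gatekeepers, pre("gatekeepers.csv"), progress = FALSE)
    if (!is.null(pl$key_players))
      readr::write_csv(pl$key_players, pre("key_players.csv"), progress = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}
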