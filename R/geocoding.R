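#' Administrative gazetteers
#'
#' A gazetteer is the offline lookup table used to resolve free-text
#' manufacturer/distributor addresses to administrative units. It holds
#' two levels of units — provinces and the cities nested inside them — with
#' one or more match keys (the unit name plus optional aliases) per unit.
#' Direct-administered municipalities are represented as both a
#' province-level and a city-level unit with the same name; match keys are
#' therefore required to be unique *within a level*, not globally.
#'
#' @param units data frame with columns `unit_id`, `name`, `level`
#'   (`"province"` or `"city"`), `parent_id` (NA for provinces), optional
#'   `lng`, `lat` (decimal degrees) and `aliases` (pipe-separated extra match
#'   keys).
#' @return an object of class `gazetteer`: list with `units` (tibble) and
#'   `keys` (tibble of match keys sorted longest-first).
#' @export
gazetteer <- function(units) {
  units <- tibble::as_tibble(units)
  for (col in c("lng", "lat")) if (!col %in% names(units)) units[[col]] <- NA_real_
  if (!"aliases" %in% names(units)) units$aliases <- NA_character_
  need <- c("unit_id", "name", "level", "parent_id")
  missing <- setdiff(need, names(units))
  if (length(missing))
    stop_circnet("gazetteer is missing columns: ", paste(missing, collapse = ", "))
  if (!all(units$level %in% c("province", "city")))
    stop_circnet("gazetteer levels must be 'province' or 'city'")
  if (anyDuplicated(units$unit_id))
    stop_circnet("gazetteer unit_id values must be unique")

  prov <- units[units$level == "province", ]
  city <- units[units$level == "city", ]
  if (!all(is.na(prov$parent_id)))
    stop_circnet("province units must have no parent")
  if (any(is.na(city$parent_id)) || !all(city$parent_id %in% prov$unit_id))
    stop_circnet("every city unit must name a province unit as parent")
  ll <- c(units$lng, units$lat)
  if (any(abs(units$lng) > 180, na.rm = TRUE) || any(abs(units$lat) > 90, na.rm = TRUE))
    stop_circnet("centroids must satisfy lng in [-180,180], lat in [-90,90]")
  dup_name <- duplicated(paste(units$level, units$parent_id, tolower(units$name)))
  if (any(dup_name))
    stop_circnet("unit names must be unique within a level under the same parent")

  keys <- lapply(seq_len(nrow(units)), function(i) {
    al <- units$aliases[i]
    extra <- if (is.na(al) || !nzchar(al)) character(0) else strsplit(al, "|", fixed = TRUE)[[1]]
    tibble::tibble(key = normalize_address(c(units$name[i], extra)),
                   unit_id = units$unit_id[i],
                   level = units$level[i])
  })
  keys <- dplyr::bind_rows(keys)
  keys <- keys[nzchar(keys$key), ]
  keys <- keys[!duplicated(paste(keys$level, tolower(keys$key), keys$unit_id)), ]
  clash <- duplicated(paste(keys$level, tolower(keys$key)))
  if (any(clash))
    stop_circnet("match keys must map to exactly one unit per level; duplicated: ",
                 paste(unique(keys$key[clash]), collapse = ", "))
  keys$nchar <- nchar(keys$key)
  keys <- keys[order(-keys$nchar, keys$key), ]

  structure(list(units = units, keys = keys), class = "gazetteer")
}

#' @export
print.gazetteer <- function(x, ...) {
  cat(sprintf("<gazetteer> %d provinces, %d cities, %d match keys\n",
              sum(x$units$level == "province"), sum(x$units$level == "city"),
              nrow(x$keys)))
  invisible(x)
}

#' Read a gazetteer from CSV
#'
#' Expected columns: `unit_id`, `name`, `level`, `parent_id`, `lng`, `lat`,
#' `aliases` (pipe-separated).
#'
#' @param path CSV file path.
#' @return a [gazetteer()].
#' @export
read_gazetteer <- function(path) {
  units <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  gazetteer(units)
}

# Vectorized core: best (longest, then leftmost) key match per address for one
# gazetteer level. Returns unit_id (NA if no match), a tie flag (two different
# units share the best match), and the number of distinct units matched at all.
match_level <- function(addresses, gaz, level) {
  keys <- gaz$keys[gaz$keys$level == level, ]
  n <- length(addresses)
  best_unit <- rep(NA_character_, n)
  best_len <- rep(-1L, n)
  best_pos <- rep(.Machine$integer.max, n)
  tie <- rep(FALSE, n)
  first_match <- rep(NA_character_, n)
  multi <- rep(FALSE, n)
  for (i in seq_len(nrow(keys))) {
    pos <- regexpr(keys$key[i], addresses, fixed = TRUE)
    hit <- pos > 0L
    if (!any(hit)) next
    len <- keys$nchar[i]
    uid <- keys$unit_id[i]
    multi[hit & !is.na(first_match) & first_match != uid] <- TRUE
    first_match[hit & is.na(first_match)] <- uid
    better <- hit & (len > best_len | (len == best_len & pos < best_pos))
    equal <- hit & len == best_len & pos == best_pos & !is.na(best_unit) &
      best_unit != uid
    tie[equal] <- TRUE
    tie[better] <- FALSE
    best_unit[better] <- uid
    best_len[better] <- len
    best_pos[better] <- pos[better]
  }
  list(unit = best_unit, tie = tie, multi = multi)
}

resolve_addresses_core <- function(addresses, gaz) {
  addresses <- normalize_address(addresses)
  city <- match_level(addresses, gaz, "city")
  prov <- match_level(addresses, gaz, "province")

  city_parent <- stats::setNames(gaz$units$parent_id, gaz$units$unit_id)
  province_id <- ifelse(is.na(city$unit), prov$unit, unname(city_parent[city$unit]))
  city_id <- city$unit
  note <- rep(NA_character_, length(addresses))
  unresolved <- is.na(city_id)
  note[unresolved & !is.na(province_id)] <- "province only"
  note[unresolved & is.na(province_id)] <- "no match"

  conflict <- city$tie |
    (prov$multi) |
    (!is.na(city_id) & !is.na(prov$unit) & prov$unit != unname(city_parent[city_id]))
  note[conflict] <- "conflict"
  city_id[conflict] <- NA_character_
  province_id[conflict] <- NA_character_
  unresolved <- is.na(city_id)

  tibble::tibble(address = addresses, province_id = province_id,
                 city_id = city_id, unresolved = unresolved, note = note)
}

#' Resolve one address to a (province, city) pair
#'
#' Finds the gazetteer match keys occurring in the address, preferring the
#' longest key and, among equal lengths, the leftmost occurrence. The province
#' is taken from the matched city's parent and must not contradict any
#' province keyword present in the address; on any conflict (tied keys naming
#' different cities, two different province keywords, or a province keyword
#' disagreeing with the city's parent) the address is returned unresolved with
#' a conflict note rather than guessed.
#'
#' @param address a single free-text address.
#' @param gaz a [gazetteer()].
#' @return one-row tibble with `province_id`, `city_id`, `unresolved`, `note`.
#' @export
#' @examples
#' gaz <- gazetteer(tibble::tibble(
#'   unit_id = c("SX", "SX-JZ"), name = c("Shanxi Province", "Jinzhong City"),
#'   level = c("province", "city"), parent_id = c(NA, "SX")))
#' resolve_address("No. 445, Financial Road, Jiexiu City, Jinzhong City, Shanxi Province", gaz)
resolve_address <- function(address, gaz) {
  stopifnot(inherits(gaz, "gazetteer"), length(address) == 1L)
  resolve_addresses_core(address, gaz)
}

#' Resolve every record's manufacturer and distributor address
#'
#' Applies [resolve_address()] (vectorized over the distinct addresses in the
#' set) to both parties of every record. Records unresolved at city level are
#' flagged, not dropped here; network construction excludes them with an
#' explicit count. An optional fallback resolver — the hook where a remote
#' geocoder can be plugged in — is consulted for addresses the gazetteer
#' cannot place, and its answers can be cached to CSV so re-runs are
#' reproducible and offline.
#'
#' @param rs a cleaned [record_set()].
#' @param gaz a [gazetteer()].
#' @param fallback optional `function(addresses)` returning a data frame with
#'   columns `address`, `province_id`, `city_id` (NA where it too fails).
#' @param cache_path optional CSV path; fallback results are read from and
#'   appended to it.
#' @return a tibble of class `geo_resolution`: one row per record with
#'   `record_id`, `status`, `manu_province`, `manu_city`, `dist_province`,
#'   `dist_city`, `method`, `unresolved` (TRUE iff either party lacks a
#'   city-level assignment).
#' @export
resolve_records <- function(rs, gaz, fallback = NULL, cache_path = NULL) {
  stopifnot(inherits(rs, "record_set"), inherits(gaz, "gazetteer"))
  rec <- rs$records
  addr <- normalize_address(c(rec$manufacturer_address, rec$distributor_address))
  uniq <- unique(addr)
  res <- resolve_addresses_core(uniq, gaz)
  res$method <- ifelse(res$unresolved, NA_character_, "gazetteer")

  if (!is.null(cache_path) && file.exists(cache_path)) {
    cache <- readr::read_csv(cache_path, show_col_types = FALSE, progress = FALSE)
    hit <- match(res$address, cache$address)
    use <- res$unresolved & !is.na(hit) & !is.na(cache$city_id[hit])
    res$province_id[use] <- cache$province_id[hit[use]]
    res$city_id[use] <- cache$city_id[hit[use]]
    res$unresolved[use] <- FALSE
    res$method[use] <- "plugin"
  }
  if (!is.null(fallback) && any(res$unresolved)) {
    ask <- res$address[res$unresolved]
    ans <- tibble::as_tibble(fallback(ask))
    idx <- match(res$address, ans$address)
    use <- res$unresolved & !is.na(idx) & !is.na(ans$city_id[idx])
    res$province_id[use] <- ans$province_id[idx[use]]
    res$city_id[use] <- ans$city_id[idx[use]]
    res$unresolved[use] <- FALSE
    res$method[use] <- "plugin"
    if (!is.null(cache_path) && any(use)) {
      add <- res[use, c("address", "province_id", "city_id")]
      if (file.exists(cache_path)) {
        old <- readr::read_csv(cache_path, show_col_types = FALSE, progress = FALSE)
        add <- dplyr::bind_rows(old, add)
        add <- add[!duplicated(add$address), ]
      }
      readr::write_csv(add, cache_path, progress = FALSE)
    }
  }

  n <- nrow(rec)
  m_idx <- match(addr[seq_len(n)], res$address)
  d_idx <- match(addr[n + seq_len(n)], res$address)
  out <- tibble::tibble(
    record_id = rec$record_id,
    status = rec$status,
    sample_date = rec$sample_date,
    manu_province = res$province_id[m_idx],
    manu_city = res$city_id[m_idx],
    dist_province = res$province_id[d_idx],
    dist_city = res$city_id[d_idx],
    method = dplyr::coalesce(res$method[m_idx], res$method[d_idx]),
    unresolved = is.na(res$city_id[m_idx]) | is.na(res$city_id[d_idx])
  )
  n_un <- sum(out$unresolved)
  message(sprintf("resolved %d/%d records at city level (%.1f%%)",
                  n - n_un, n, if (n > 0) 100 * (n - n_un) / n else 0))
  class(out) <- c("geo_resolution", class(out))
  out
}
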