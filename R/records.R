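#' Sampling-inspection record sets
#'
#' A `record_set` holds one row per sampled food item together with its
#' qualification status (`qualified` or `substandard`) and the free-text
#' addresses of the manufacturer and the distributor. It is the unit of
#' exchange between the reading, cleaning, geocoding and network-building
#' steps.
#'
#' @param records a data frame with columns `record_id`, `status`,
#'   `manufacturer_address`, `distributor_address`, `sample_date` (Date or NA)
#'   and `food_name`.
#' @param source character label naming where the rows came from.
#' @param provenance optional list of extra provenance entries (merged over
#'   the defaults).
#' @return an object of class `record_set`: a list with elements `records`
#'   (tibble), `counts` (list with `total`, `qualified`, `substandard`) and
#'   `provenance` (list; always includes `source` and `loaded_at`).
#' @export
record_set <- function(records, source = "in-memory", provenance = list()) {
  records <- tibble::as_tibble(records)
  needed <- c("record_id", "status", "manufacturer_address",
              "distributor_address", "sample_date", "food_name")
  if (!"record_id" %in% names(records))
    records$record_id <- sprintf("R%07d", seq_len(nrow(records)))
  if (!"sample_date" %in% names(records)) records$sample_date <- as.Date(NA)
  if (!"food_name" %in% names(records)) records$food_name <- NA_character_
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop_circnet("record_set is missing columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(records$status), c("qualified", "substandard"))
  if (length(bad))
    stop_circnet("status values outside {qualified, substandard}: ",
                 paste(bad, collapse = ", "))
  if (anyDuplicated(records$record_id))
    stop_circnet("record_id values must be unique within a record_set")
  records <- records[, needed]
  counts <- list(
    total = nrow(records),
    qualified = sum(records$status == "qualified"),
    substandard = sum(records$status == "substandard")
  )
  prov <- utils::modifyList(
    list(source = source, loaded_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    provenance
  )
  structure(list(records = records, counts = counts, provenance = prov),
            class = "record_set")
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("<record_set> %d records (%d qualified, %d substandard) from %s\n",
              x$counts$total, x$counts$qualified, x$counts$substandard,
              x$provenance$source))
  invisible(x)
}

#' Load sampling-inspection records from a file
#'
#' Reads a CSV, XLS or XLSX table of sampling-inspection results and maps its
#' columns onto the canonical record fields. Rows whose status cannot be
#' coerced to `qualified`/`substandard` are dropped, counted and reported in
#' the provenance rather than guessed at.
#'
#' @param path path to the source file.
#' @param column_map named character vector mapping logical field names to
#'   source column names. Must cover `status`, `manufacturer_address` and
#'   `distributor_address`; may also map `record_id`, `sample_date` and
#'   `food_name`.
#' @param format one of `"auto"`, `"csv"`, `"xls"`, `"xlsx"`. `"auto"` decides
#'   from the file extension. XLS/XLSX need the readxl package.
#' @param status_values named character vector giving the source-file spellings
#'   of the two statuses, e.g. `c(qualified = "PASS", substandard = "FAIL")`.
#'   Matching is case-insensitive after whitespace trimming.
#' @param encoding text encoding of CSV input (legacy exports are often GBK).
#' @return a [record_set()]. `provenance$coercion_failures` counts rows dropped
#'   for an unparseable status.
#' @export
load_records <- function(path,
                         column_map,
                         format = c("auto", "csv", "xls", "xlsx"),
                         status_values = c(qualified = "qualified",
                                           substandard = "substandard"),
                         encoding = "UTF-8") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_circnet("input file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", xls = "xls", xlsx = "xlsx",
                     stop_circnet("cannot infer format from extension: .", ext))
  }
  raw <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE,
                          locale = readr::locale(encoding = encoding),
                          progress = FALSE),
    xls = ,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop_circnet("reading ", format, " files requires the readxl package")
      readxl::read_excel(path)
    })

  required <- c("status", "manufacturer_address", "distributor_address")
  if (is.null(names(column_map)) || !all(required %in% names(column_map)))
    stop_circnet("column_map must name source columns for: ",
                 paste(required, collapse = ", "))
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent))
    stop_circnet("column_map names columns absent from the file: ",
                 paste(absent, collapse = ", "))

  pick <- function(field) {
    if (field %in% names(column_map)) raw[[column_map[[field]]]] else NULL
  }
  n <- nrow(raw)
  status_raw <- tolower(trimws(as.character(pick("status"))))
  lut <- stats::setNames(names(status_values), tolower(trimws(status_values)))
  status <- unname(lut[status_raw])
  ok <- !is.na(status)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(n_bad, " row(s) dropped: status not coercible to qualified/substandard")

  sample_date <- pick("sample_date")
  sample_date <- if (is.null(sample_date)) as.Date(rep(NA, n)) else
    suppressWarnings(as.Date(as.character(sample_date)))

  records <- tibble::tibble(
    record_id = {
      rid <- pick("record_id")
      if (is.null(rid)) sprintf("R%07d", seq_len(n)) else as.character(rid)
    },
    status = status,
    manufacturer_address = as.character(pick("manufacturer_address")),
    distributor_address = as.character(pick("distributor_address")),
    sample_date = sample_date,
    food_name = {
      fn <- pick("food_name")
      if (is.null(fn)) NA_character_ else as.character(fn)
    }
  )[ok, ]

  record_set(records, source = basename(path),
             provenance = list(coercion_failures = n_bad, format = format))
}

#' Clean a record set
#'
#' Applies the two preprocessing rules used throughout the pipeline: drop
#' records lacking a manufacturer or distributor address, and collapse exact
#' duplicates to a single record. Addresses are normalized (whitespace,
#' full-width characters, see [normalize_address()]) before the emptiness
#' check. A duplicate is an exact match on the tuple (status,
#' manufacturer_address, distributor_address, food_name, sample_date) after
#' normalization; the first occurrence is kept.
#'
#' The operation is idempotent and never mutates its input.
#'
#' @param rs a [record_set()].
#' @return a cleaned [record_set()]; `provenance$cleaning_report` lists how many
#'   rows each rule removed (`missing_party`, `duplicates`).
#' @export
clean_records <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  rec <- rs$records
  rec$manufacturer_address <- normalize_address(rec$manufacturer_address)
  rec$distributor_address <- normalize_address(rec$distributor_address)

  has_party <- !is.na(rec$manufacturer_address) & nzchar(rec$manufacturer_address) &
    !is.na(rec$distributor_address) & nzchar(rec$distributor_address)
  n_missing <- sum(!has_party)
  rec <- rec[has_party, ]

  key <- paste(rec$status, rec$manufacturer_address, rec$distributor_address,
               rec$food_name, rec$sample_date, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  rec <- rec[!dup, ]

  if (nrow(rec) == 0L)
    warning("cleaning removed every record", call. = FALSE)

  out <- record_set(rec, source = rs$provenance$source,
                    provenance = utils::modifyList(
                      rs$provenance,
                      list(cleaning_report = list(missing_party = n_missing,
                                                  duplicates = n_dup))))
  out
}

#' Keep only substandard records
#'
#' Subsets a cleaned record set to status `substandard`. The qualified totals
#' are preserved in the provenance so that circulation-intensity denominators
#' (qualified + substandard samples) remain available downstream.
#'
#' @param rs a [record_set()], normally the output of [clean_records()].
#' @return a [record_set()] of the substandard records;
#'   `provenance$pre_filter_counts` holds the full counts of the input.
#' @export
filter_substandard <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  keep <- rs$records$status == "substandard"
  if (!any(keep))
    warning("no substandard records present; downstream networks will be empty",
            call. = FALSE)
  record_set(rs$records[keep, ], source = rs$provenance$source,
             provenance = utils::modifyList(
               rs$provenance,
               list(pre_filter_counts = rs$counts)))
}

#' Write records to CSV in the canonical column order
#'
#' @param rs a [record_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(rs, path) {
  stopifnot(inherits(rs, "record_set"))
  readr::write_csv(rs$records, path, progress = FALSE)
  invisible(path)
}
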