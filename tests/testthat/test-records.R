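test_that("load_records reads a CSV fixture and reports every row", {
  path <- withr::local_tempfile(fileext = ".csv")
  raw <- tibble::tibble(
    id = 1:5,
    result = c("PASS", "FAIL", "pass", "FAIL", "PASS"),
    maker = paste0("addr", 1:5), seller = paste0("dest", 1:5))
  readr::write_csv(raw, path)
  rs <- load_records(path,
                     column_map = c(record_id = "id", status = "result",
                                    manufacturer_address = "maker",
                                    distributor_address = "seller"),
                     status_values = c(qualified = "PASS", substandard = "FAIL"))
  expect_s3_class(rs, "record_set")
  expect_equal(rs$counts$total, 5L)
  expect_equal(rs$counts$qualified, 3L)
  expect_equal(rs$counts$substandard, 2L)
  expect_equal(rs$counts$total, rs$counts$qualified + rs$counts$substandard)
})

test_that("load_records fails loudly on bad configuration", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(a = 1, b = "x", c = "y"), path)
  expect_error(load_records("no/such/file.csv",
                            column_map = c(status = "a",
                                           manufacturer_address = "b",
                                           distributor_address = "c")),
               "does not exist")
  expect_error(load_records(path,
                            column_map = c(status = "nope",
                                           manufacturer_address = "b",
                                           distributor_address = "c")),
               "nope")
  expect_error(load_records(path, column_map = c(status = "a")),
               "manufacturer_address")
})

test_that("unparseable statuses are dropped and counted, not guessed", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(status = c("qualified", "gibberish", "substandard"),
                                  m = c("a", "b", "c"), d = c("x", "y", "z")), path)
  expect_message(
    rs <- load_records(path, column_map = c(status = "status",
                                            manufacturer_address = "m",
                                            distributor_address = "d")),
    "dropped")
  expect_equal(rs$counts$total, 2L)
  expect_equal(rs$provenance$coercion_failures, 1L)
})

test_that("clean_records removes missing-party rows and exact duplicates with a report", {
  rs <- record_set(toy_records())
  out <- clean_records(rs)
  expect_equal(out$counts$total, 3L)
  rep <- out$provenance$cleaning_report
  expect_equal(rep$missing_party, 1L)
  expect_equal(rep$duplicates, 1L)
  # input untouched (value semantics)
  expect_equal(rs$counts$total, 5L)
})

test_that("clean_records is idempotent and the identity on already-clean data", {
  clean1 <- clean_records(record_set(toy_records()))
  clean2 <- clean_records(clean1)
  expect_equal(clean2$records, clean1$records)
  expect_equal(clean2$provenance$cleaning_report,
               list(missing_party = 0L, duplicates = 0L))
})

test_that("cleaning normalizes full-width characters before emptiness checks", {
  rec <- toy_records()[1:2, ]
  rec$distributor_address[1] <- "　　"  # ideographic spaces only -> empty
  rec$manufacturer_address[2] <- "１２ Mill Lane, A City"  # full-width digits
  out <- clean_records(record_set(rec))
  expect_equal(out$counts$total, 1L)
  expect_equal(out$records$manufacturer_address, "12 Mill Lane, A City")
})

test_that("clean_records matches an independent row-by-row filter on planted noise", {
  withr::local_seed(101)
  n <- 85
  base <- tibble::tibble(
    status = sample(c("qualified", "substandard"), n, TRUE),
    manufacturer_address = sprintf("%d High Street, City %d", sample(99, n, TRUE),
                                   sample(30, n, TRUE)),
    distributor_address = sprintf("%d Low Street, City %d", sample(99, n, TRUE),
                                  sample(30, n, TRUE)),
    sample_date = as.Date("2016-01-01") + sample(700, n, TRUE),
    food_name = sample(letters, n, TRUE)
  )
  dup <- base[sample(n, 10), ]                      # 10 planted duplicates
  miss <- base[sample(n, 5), ]
  miss$distributor_address <- c("", " ", "", "　", "")  # 5 planted missing
  shuffled <- dplyr::slice_sample(dplyr::bind_rows(base, dup, miss), prop = 1)
  shuffled$record_id <- sprintf("R%03d", seq_len(nrow(shuffled)))
  out <- clean_records(record_set(shuffled))
  # independent oracle: plain vector filter on the same rules
  o <- shuffled
  o$distributor_address <- trimws(gsub("　", " ", o$distributor_address))
  o <- o[nzchar(o$manufacturer_address) & nzchar(o$distributor_address), ]
  o <- o[!duplicated(o[, c("status", "manufacturer_address", "distributor_address",
                           "food_name", "sample_date")]), ]
  expect_equal(out$counts$total, nrow(o))
  expect_equal(out$counts$total, 85L)
})

test_that("filter_substandard keeps the failing records and the qualified totals", {
  rec <- toy_records()
  rs <- clean_records(record_set(rec))
  sub <- filter_substandard(rs)
  expect_true(all(sub$records$status == "substandard"))
  expect_equal(sub$counts$substandard, sub$counts$total)
  expect_equal(sub$provenance$pre_filter_counts$qualified, rs$counts$qualified)

  allq <- record_set(dplyr::mutate(rec, status = "qualified"))
  expect_warning(empty <- filter_substandard(allq), "no substandard")
  expect_equal(empty$counts$total, 0L)
})

test_that("record sets round-trip through the canonical CSV writer", {
  rs <- clean_records(record_set(toy_records()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rs, path)
  back <- load_records(path, column_map = c(
    record_id = "record_id", status = "status",
    manufacturer_address = "manufacturer_address",
    distributor_address = "distributor_address",
    sample_date = "sample_date", food_name = "food_name"))
  expect_equal(back$records, rs$records)
})
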