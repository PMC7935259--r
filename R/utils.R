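# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a free-text address
#'
#' Trims outer whitespace, collapses internal runs of whitespace to a single
#' space, and converts full-width ASCII forms (U+FF01--U+FF5E) and the
#' ideographic space (U+3000) to their half-width equivalents. Chinese source
#' tables routinely mix the two widths, so all emptiness checks and gazetteer
#' matching operate on the normalized form.
#'
#' @param x character vector of addresses (NA allowed).
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_address("  Ｎｏ． 445   Financial Road ")
normalize_address <- function(x) {
  if (length(x) == 0L) return(character(0L))
  full  <- intToUtf8(c(0x3000L, 0xFF01L:0xFF5EL))
  half  <- intToUtf8(c(0x20L, 0x21L:0x7EL))
  out <- chartr(full, half, enc2utf8(as.character(x)))
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_circnet <- function(...) stop(..., call. = FALSE)

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stop_circnet(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_circnet(sprintf("`%s` must be a single probability in [0, 1]", name))
  as.numeric(x)
}
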