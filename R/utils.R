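#' Normalize a gene symbol for comparison
#'
#' Symbols are stored as read but always compared after trimming
#' whitespace and upper-casing, so that mouse-style (`Src`) and
#' human-style (`SRC`) capitalization meet on common ground.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
norm_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

as_int_checked <- function(x, column) {
  suppressWarnings(out <- as.integer(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop_format("column '%s' contains non-integer values (first offending row: %d)",
                column, bad[1])
  }
  out
}
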