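#' ATC code validation and level prefixes
#'
#' A (truncated) ATC code as used throughout this package is a 5-character
#' string encoding the first four levels of the WHO Anatomical Therapeutic
#' Chemical hierarchy: one letter for the anatomical main group, two digits
#' for the therapeutic subgroup, one letter for the pharmacological subgroup
#' and one letter for the chemical subgroup (e.g. `"A02BC"`).
#'
#' @param code character vector of candidate codes.
#' @return `is_valid_atc()` returns a logical vector.
#' @examples
#' is_valid_atc(c("A02BC", "a02bc", "A02B", "V03AX"))
#' level_prefix("A02BC", 2)
#' @export
is_valid_atc <- function(code) {
  !is.na(code) & grepl("^[A-Z][0-9]{2}[A-Z][A-Z]$", code)
}

#' @rdname is_valid_atc
#' @param n hierarchy level, an integer in 1..4.
#' @return `level_prefix()` returns the first 1, 3, 4 or 5 characters of
#'   `code` for `n` = 1, 2, 3, 4 respectively.
#' @export
level_prefix <- function(code, n) {
  if (length(n) != 1L || is.na(n) || !n %in% 1:4) {
    stop("`n` must be a single integer in 1..4", call. = FALSE)
  }
  len <- c(1L, 3L, 4L, 5L)[n]
  substr(code, 1L, len)
}

## Number of characters of an ATC code that belong to levels 1..n.
level_prefix_length <- function(n) c(1L, 3L, 4L, 5L)[n]

assert_atc <- function(codes, what = "ATC code") {
  bad <- codes[!is_valid_atc(codes)]
  if (length(bad) > 0) {
    stop(sprintf("invalid %s: %s", what, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(codes)
}
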