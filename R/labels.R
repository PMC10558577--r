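#' The nine bone level implant catalogue sizes
#'
#' The classifier targets nine implant sizes: body diameters 3.3, 4.1 and
#' 4.8 mm crossed with lengths 8, 10 and 12 mm. Each size is identified by a
#' four-digit code: the first two digits are ten times the diameter, the last
#' two the length (3.3 mm / 8 mm becomes `"3308"`).
#'
#' @return A data frame with columns `code`, `diameter_mm` and `length_mm`,
#'   one row per size, ordered by ascending code.
#' @examples
#' size_labels()
#' @export
size_labels <- function() {
  grid <- expand.grid(length_mm = c(8, 10, 12), diameter_mm = c(3.3, 4.1, 4.8),
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(
    code = sprintf("%02d%02d", round(grid$diameter_mm * 10), grid$length_mm),
    diameter_mm = grid$diameter_mm,
    length_mm = grid$length_mm,
    stringsAsFactors = FALSE
  )
}

#' Decode four-digit implant size codes
#'
#' @param code Character vector of four-digit size codes (e.g. `"4110"`).
#' @return A data frame with columns `code`, `diameter_mm`, `length_mm`.
#' @examples
#' parse_size_code(c("3308", "4812"))
#' @export
parse_size_code <- function(code) {
  tab <- size_labels()
  idx <- match(code, tab$code)
  if (anyNA(idx)) {
    isz_error(sprintf("unknown size code(s): %s",
                      paste(unique(code[is.na(idx)]), collapse = ", ")),
              "implant_value_error")
  }
  tab[idx, , drop = FALSE]
}

# Internal: all nine codes in ascending order.
size_codes <- function() size_labels()$code
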