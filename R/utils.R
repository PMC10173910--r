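#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Decimal rounding where ties go up (2.675 -> 2.68 at 2 digits), as used for
#' every displayed score and percentage in this package. `base::round()` uses
#' IEC 60559 banker's rounding, which differs on exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(2.5, 2.675, -2.5), c(0, 2, 0))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just under .5 (binary
  # representation) still round up, e.g. 41.175 -> 41.18
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

is_blank <- function(x) {
  is.null(x) || length(x) == 0 || is.na(x) || !nzchar(trimws(as.character(x)))
}

# scalar text coercion used when ingesting spreadsheet cells
cell_chr <- function(x) {
  if (is_blank(x)) "" else trimws(as.character(x))
}

truthy <- function(x) {
  tolower(cell_chr(x)) %in% c("true", "yes", "1", "y")
}

VALID_NAME_RE <- "^[a-z][a-z0-9_]*$"

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

edc_error <- function(class, msg, data = list()) {
  structure(
    class = c(class, "edc_error", "error", "condition"),
    c(list(message = msg, call = NULL), data)
  )
}

#' @noRd
iso_date <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  if (any(is.na(d))) stop("invalid ISO date: ", paste(x[is.na(d)], collapse = ", "), call. = FALSE)
  d
}

# numeric if parseable, else NA (no warning)
num_or_na <- function(x) suppressWarnings(as.numeric(x))

# CSV field quoting per RFC 4180; writer must be byte-stable
csv_quote <- function(x) {
  x <- ifelse(is.na(x), "", x)
  need <- grepl('[",\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}
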