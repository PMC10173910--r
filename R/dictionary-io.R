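#' REDCap data-dictionary CSV I/O
#'
#' The on-disk dialect is the standard 18-column REDCap dictionary CSV
#' (UTF-8, comma-separated, RFC 4180 quoting, LF line endings). The writer is
#' byte-stable: the same dictionary always produces identical bytes, so
#' serialized dictionaries can be diffed and content-addressed.
#'
#' @name dictionary_io
NULL

#' Write a data dictionary as CSV
#'
#' @param dd an `edc_dictionary`.
#' @param path output path; when omitted the CSV text is returned as a
#'   character vector of lines.
#' @return the CSV lines, invisibly when written to a file.
#' @export
write_dictionary <- function(dd, path = NULL) {
  lines <- paste(csv_quote(DICTIONARY_COLUMNS), collapse = ",")
  for (row in dd$rows) {
    vals <- vapply(DICT_KEYS, function(k) cell_chr(row[[k]] %||% ""), character(1))
    lines <- c(lines, paste(csv_quote(vals), collapse = ","))
  }
  if (is.null(path)) return(lines)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(lines)
}

#' Read a data-dictionary CSV
#'
#' @param path CSV file path, or a character vector of CSV lines.
#' @param form_name optional override; defaults to the first row's form name.
#' @return an `edc_dictionary`.
#' @export
read_dictionary <- function(path, form_name = NULL) {
  df <- utils::read.csv(if (length(path) > 1L) textConnection(path) else path,
                        colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (ncol(df) != 18L || !identical(names(df)[1:2], DICTIONARY_COLUMNS[1:2]))
    stop(edc_error("edc_bad_header",
                   sprintf("expected the 18-column dictionary header, got %d column(s)", ncol(df))))
  names(df) <- DICT_KEYS
  if (any(duplicated(df$variable_name)))
    stop(edc_error("edc_duplicate_variable",
                   paste0("duplicate variable names: ",
                          paste(unique(df$variable_name[duplicated(df$variable_name)]), collapse = ", "))))
  rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  rows <- lapply(rows, function(r) stats::setNames(lapply(r, cell_chr), DICT_KEYS))
  fn <- form_name %||% if (nrow(df)) df$form_name[1L] else "form"
  # branching logic must parse in the redcap dialect (structural invariant)
  for (r in rows) {
    if (nzchar(r$branching_logic)) parse_logic(r$branching_logic, "redcap")
  }
  new_dictionary(fn, rows)
}
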