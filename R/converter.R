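#' XLSForm-to-REDCap conversion
#'
#' Turns a canonical instrument into a REDCap data dictionary: one dictionary
#' row per field, the fixed type-mapping table below, skip logic translated to
#' branching logic, and the multiple-selection naming pre-check. Conversion is
#' all-or-nothing: a failed pre-check raises before any row is produced.
#'
#' Type mapping: text->text; integer->text+integer; decimal->text+number;
#' date->text+date_ymd; datetime->text+datetime_ymd; time->text+time;
#' select_one->radio; select_multiple->checkbox; calc->calc; note->descriptive;
#' file->file.
#'
#' @name converter
NULL

#' The 18 REDCap data-dictionary column headers, in order
#' @export
DICTIONARY_COLUMNS <- c(
  "Variable / Field Name", "Form Name", "Section Header", "Field Type",
  "Field Label", "Choices, Calculations, OR Slider Labels", "Field Note",
  "Text Validation Type OR Show Slider Number", "Text Validation Min",
  "Text Validation Max", "Identifier?",
  "Branching Logic (Show field only if...)", "Required Field?",
  "Custom Alignment", "Question Number (surveys only)", "Matrix Group Name",
  "Matrix Ranking?", "Field Annotation"
)

# internal (syntactic) names for the 18 positions
DICT_KEYS <- c("variable_name", "form_name", "section_header", "field_type",
               "field_label", "choices_or_calc", "field_note", "validation_type",
               "validation_min", "validation_max", "identifier",
               "branching_logic", "required", "alignment", "question_number",
               "matrix_group", "matrix_rank", "field_annotation")

TYPE_MAPPING <- list(
  text            = list(field_type = "text", validation = ""),
  integer         = list(field_type = "text", validation = "integer"),
  decimal         = list(field_type = "text", validation = "number"),
  date            = list(field_type = "text", validation = "date_ymd"),
  datetime        = list(field_type = "text", validation = "datetime_ymd"),
  time            = list(field_type = "text", validation = "time"),
  select_one      = list(field_type = "radio", validation = ""),
  select_multiple = list(field_type = "checkbox", validation = ""),
  calc            = list(field_type = "calc", validation = ""),
  note            = list(field_type = "descriptive", validation = ""),
  file            = list(field_type = "file", validation = "")
)

new_dictionary <- function(form_name, rows = list()) {
  structure(list(form_name = form_name, rows = rows), class = "edc_dictionary")
}

#' @export
print.edc_dictionary <- function(x, ...) {
  cat(sprintf("<data dictionary '%s'> %d row(s)\n", x$form_name, length(x$rows)))
  invisible(x)
}

#' Pre-check the multiple-selection naming convention
#'
#' Data transfer relies on multiple-selection (checkbox) variables being
#' recognizable by name: every `select_multiple` field must be named with a
#' `checkbox_` prefix. Conversion refuses to start while violations exist.
#'
#' @param instr an `edc_instrument`.
#' @return character vector of violations (empty when the convention holds).
#' @export
precheck_names <- function(instr) {
  v <- character(0)
  for (f in instr$fields) {
    if (f$type == "select_multiple" && !startsWith(f$name, "checkbox_"))
      v <- c(v, sprintf("select_multiple field '%s' must be named with the 'checkbox_' prefix", f$name))
  }
  v
}

#' Render a logic tree as REDCap branching logic
#'
#' `selected(${f}, 'c')` becomes the checkbox reference `[f(c)] = '1'`;
#' `!=` becomes `<>`; constant true renders as empty text (field always
#' shown). The output re-parses in the redcap dialect to a truth-equivalent
#' tree.
#'
#' @param expr an `edc_logic` tree.
#' @return branching-logic text.
#' @export
render_branching <- function(expr) {
  if (is.null(expr)) return("")
  render_logic(expr, "redcap")
}

serialize_choices <- function(cl) {
  paste(paste0(cl$codes, ", ", cl$labels), collapse = " | ")
}

parse_choices <- function(text) {
  if (!nzchar(cell_chr(text))) return(NULL)
  parts <- strsplit(text, "\\s*\\|\\s*")[[1L]]
  codes <- character(0); labels <- character(0)
  for (p in parts) {
    m <- regexec("^\\s*([^,]+?)\\s*,\\s*(.*)$", p)[[1L]]
    g <- regmatches(p, regexec("^\\s*([^,]+?)\\s*,\\s*(.*)$", p))[[1L]]
    assert_that(length(g) == 3, paste0("malformed choices cell: ", text))
    codes <- c(codes, g[2L]); labels <- c(labels, g[3L])
  }
  list(codes = codes, labels = labels)
}

# constraint `${self} >= a and ${self} <= b` (either or both arms) -> min/max
constraint_bounds <- function(expr) {
  if (is.null(expr)) return(NULL)
  arms <- if (expr$kind == "and") expr$args else list(expr)
  mn <- NULL; mx <- NULL
  for (a in arms) {
    if (a$kind != "cmp" || a$field != "self") return(NULL)
    if (a$op == ">=") mn <- a$value
    else if (a$op == "<=") mx <- a$value
    else return(NULL)
  }
  list(min = mn, max = mx)
}

#' Map one field to its dictionary row(s)
#'
#' Checkbox fields stay a single row here; per-option column expansion is a
#' record-level concern. A `calc` field with an empty label takes its label
#' from the guidance hint (authoring tools cannot label calculated fields, so
#' the hint is the designated carrier). An own-value range constraint
#' (`. >= a and . <= b`) populates validation min/max; any other constraint
#' shape cannot be represented and is dropped with a warning.
#'
#' @param field an `edc_field`.
#' @param form_name dictionary form name.
#' @param instr owning instrument (for choice-list resolution).
#' @return list of named dictionary rows (length 1).
#' @export
map_field <- function(field, form_name, instr = NULL) {
  mp <- TYPE_MAPPING[[field$type]]
  assert_that(!is.null(mp), paste0("unmapped field type: ", field$type))
  label <- field$label
  if (field$type == "calc" && !nzchar(label) && !is.null(field$guidance_hint))
    label <- field$guidance_hint

  choices_or_calc <- ""
  if (field$type %in% c("select_one", "select_multiple")) {
    cl <- instr$choice_lists[[field$choice_list]]
    assert_that(!is.null(cl), paste0("unresolved choice list for ", field$name))
    choices_or_calc <- serialize_choices(cl)
  } else if (field$type == "calc") {
    choices_or_calc <- field$calculation %||% ""
  }

  vmin <- cell_chr(field$validation$min %||% "")
  vmax <- cell_chr(field$validation$max %||% "")
  if (!is.null(field$constraint)) {
    b <- constraint_bounds(field$constraint)
    if (is.null(b)) {
      warning(sprintf("field '%s': constraint not representable as a range; dropped", field$name),
              call. = FALSE)
    } else {
      if (!is.null(b$min)) vmin <- b$min
      if (!is.null(b$max)) vmax <- b$max
    }
  }
  validation_type <- mp$validation
  if ((nzchar(vmin) || nzchar(vmax)) && !nzchar(validation_type)) validation_type <- "number"
  if (!is.null(field$validation$kind)) validation_type <- field$validation$kind

  row <- stats::setNames(as.list(rep("", 18L)), DICT_KEYS)
  row$variable_name <- field$name
  row$form_name <- form_name
  row$field_type <- mp$field_type
  row$field_label <- label
  row$choices_or_calc <- choices_or_calc
  row$field_note <- if (field$type != "calc") field$guidance_hint %||% "" else ""
  row$validation_type <- validation_type
  row$validation_min <- vmin
  row$validation_max <- vmax
  row$identifier <- if (field$identifier) "y" else ""
  row$branching_logic <- render_branching(field$relevant)
  row$required <- if (field$required) "y" else ""
  row$field_annotation <- if (!is.null(field$tag)) field$tag$value else ""
  list(row)
}

#' Convert an instrument to a REDCap data dictionary
#'
#' Fails atomically: naming-convention or structural violations raise a
#' `PrecheckFailed`/invalid-instrument condition carrying the violation list,
#' and no partial dictionary is returned.
#'
#' @param instr an `edc_instrument`.
#' @param form_name dictionary form name; defaults to the instrument name.
#' @return an `edc_dictionary` (one row per field, field order preserved).
#' @export
convert_instrument <- function(instr, form_name = instr$name) {
  pv <- precheck_names(instr)
  if (length(pv))
    stop(edc_error("edc_precheck_failed",
                   paste0("naming pre-check failed:\n  ", paste(pv, collapse = "\n  ")),
                   data = list(violations = pv)))
  iv <- validate_instrument(instr)
  if (length(iv))
    stop(edc_error("edc_invalid_instrument",
                   paste0("invalid instrument:\n  ", paste(iv, collapse = "\n  ")),
                   data = list(violations = iv)))
  rows <- list()
  for (f in instr$fields) rows <- c(rows, map_field(f, form_name, instr))
  new_dictionary(form_name, rows)
}

#' Re-read a dictionary as an instrument
#'
#' Inverse of [convert_instrument()] on the representable subset; used by the
#' round-trip checks. Branching logic is parsed in the redcap dialect and
#' checkbox references become membership nodes.
#'
#' @param dd an `edc_dictionary`.
#' @return an `edc_instrument`.
#' @export
dictionary_to_instrument <- function(dd) {
  fields <- list()
  cls <- list()
  rev_type <- function(row) {
    ft <- row$field_type; vt <- row$validation_type
    if (ft == "radio" || ft == "dropdown") return("select_one")
    if (ft == "checkbox") return("select_multiple")
    if (ft == "calc") return("calc")
    if (ft == "descriptive") return("note")
    if (ft == "file") return("file")
    switch(vt, integer = "integer", number = "decimal", date_ymd = "date",
           datetime_ymd = "datetime", time = "time", "text")
  }
  for (row in dd$rows) {
    type <- rev_type(row)
    cl_ref <- NULL
    if (type %in% c("select_one", "select_multiple")) {
      ch <- parse_choices(row$choices_or_calc)
      assert_that(!is.null(ch), paste0("select field without choices: ", row$variable_name))
      cl_ref <- row$variable_name
      cls[[cl_ref]] <- choice_list(cl_ref, ch$codes, ch$labels)
    }
    validation <- list()
    if (nzchar(row$validation_min)) validation$min <- row$validation_min
    if (nzchar(row$validation_max)) validation$max <- row$validation_max
    tag <- NULL
    if (nzchar(row$field_annotation)) {
      tag <- if (startsWith(row$field_annotation, "#"))
        semantic_tag("hxl_hashtag", row$field_annotation)
      else semantic_tag("ontology_property", row$field_annotation)
    }
    fields[[length(fields) + 1L]] <- field_def(
      name = row$variable_name, type = type, label = row$field_label,
      choice_list = cl_ref,
      required = row$required == "y",
      relevant = parse_logic(row$branching_logic, "redcap"),
      validation = validation,
      guidance_hint = if (nzchar(row$field_note)) row$field_note,
      identifier = row$identifier == "y",
      tag = tag,
      calculation = if (row$field_type == "calc" && nzchar(row$choices_or_calc)) row$choices_or_calc
    )
  }
  instrument(dd$form_name, fields, cls)
}

#' Package a dictionary as a zip archive
#'
#' Writes `instrument.csv` inside a zip, the shape accepted by REDCap's
#' instrument upload.
#'
#' @param dd an `edc_dictionary`.
#' @param zip_path output `.zip` path.
#' @return `zip_path`, invisibly.
#' @export
dictionary_zip <- function(dd, zip_path) {
  dir <- tempfile("dict")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_dictionary(dd, file.path(dir, "instrument.csv"))
  zip_path <- normalizePath(zip_path, mustWork = FALSE)
  if (file.exists(zip_path)) unlink(zip_path)
  zip::zip(zip_path, files = "instrument.csv", root = dir, mode = "mirror")
  invisible(zip_path)
}
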