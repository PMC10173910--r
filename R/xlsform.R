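#' XLSForm workbook I/O
#'
#' Reads and writes instruments as XLSForm workbooks: a `survey` sheet (one
#' row per question), a `choices` sheet (one row per option) and a `settings`
#' sheet. A semantic-annotation column named `hxl` on the survey sheet is
#' read into an HXL [semantic_tag()]; an `annotation` column holding an
#' absolute IRI maps to an ontology-property tag.
#'
#' @name xlsform
NULL

# XLSForm type token -> canonical FieldType (select types handled separately)
XLSFORM_TYPE_MAP <- c(
  text = "text", integer = "integer", decimal = "decimal", date = "date",
  datetime = "datetime", time = "time", calculate = "calc", note = "note",
  file = "file", image = "file"
)

#' Read an XLSForm workbook into an instrument
#'
#' @param path path to an `.xlsx` workbook with `survey`, `choices` (optional
#'   when no select questions) and `settings` (optional) sheets. Legacy
#'   binary `.xls` is not supported by the bundled reader and raises an
#'   explicit unsupported-format error.
#' @return an `edc_instrument`; guaranteed to pass [validate_instrument()].
#' @export
read_xlsform <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  if (grepl("\\.xls$", path, ignore.case = TRUE))
    stop(edc_error("edc_unsupported_format",
                   "legacy binary .xls is not supported; save the form as .xlsx"))
  sheets <- readxl::excel_sheets(path)
  assert_that("survey" %in% sheets, "workbook has no 'survey' sheet")
  survey <- read_xlsx_sheet(path, "survey")
  for (col in c("type", "name", "label")) {
    if (!col %in% names(survey))
      stop(edc_error("edc_missing_column",
                     sprintf("survey sheet lacks required column '%s'", col)))
  }
  choices <- if ("choices" %in% sheets) read_xlsx_sheet(path, "choices") else
    data.frame(list_name = character(0), name = character(0), label = character(0))
  settings <- if ("settings" %in% sheets) read_xlsx_sheet(path, "settings") else NULL

  cls <- list()
  if (nrow(choices)) {
    assert_that(all(c("list_name", "name") %in% names(choices)),
                "choices sheet needs list_name and name columns")
    if (!"label" %in% names(choices)) choices$label <- choices$name
    keep <- nzchar(cell_chr_v(choices$list_name))
    choices <- choices[keep, , drop = FALSE]
    for (ln in unique(tolower(trimws(choices$list_name)))) {
      sub <- choices[tolower(trimws(choices$list_name)) == ln, , drop = FALSE]
      cls[[ln]] <- choice_list(ln, trimws(sub$name), cell_chr_v(sub$label))
    }
  }

  getcol <- function(row, col) if (col %in% names(survey)) cell_chr(survey[row, col]) else ""
  fields <- list()
  for (i in seq_len(nrow(survey))) {
    tok <- getcol(i, "type")
    if (!nzchar(tok)) next
    parts <- strsplit(tok, "\\s+")[[1L]]
    head_tok <- tolower(parts[1L])
    name <- tolower(getcol(i, "name"))
    cl_ref <- NULL
    if (head_tok %in% c("select_one", "select_multiple")) {
      if (length(parts) < 2L)
        stop(edc_error("edc_bad_type",
                       sprintf("survey row %d: '%s' needs a list name", i, head_tok)))
      type <- head_tok
      cl_ref <- tolower(parts[2L])
      if (is.null(cls[[cl_ref]]))
        stop(edc_error("edc_dangling_list",
                       sprintf("survey row %d (column 'type'): choice list '%s' not in choices sheet", i, cl_ref)))
    } else if (head_tok %in% names(XLSFORM_TYPE_MAP)) {
      type <- unname(XLSFORM_TYPE_MAP[head_tok])
    } else {
      stop(edc_error("edc_bad_type",
                     sprintf("survey row %d (column 'type'): unknown type token '%s'", i, head_tok)))
    }
    tag <- NULL
    hxl <- getcol(i, "hxl")
    ann <- getcol(i, "annotation")
    if (nzchar(hxl)) tag <- semantic_tag("hxl_hashtag", hxl)
    else if (nzchar(ann)) tag <- semantic_tag("ontology_property", ann)

    validation <- list()
    vmin <- getcol(i, "validation_min"); vmax <- getcol(i, "validation_max")
    if (nzchar(vmin)) validation$min <- vmin
    if (nzchar(vmax)) validation$max <- vmax

    fields[[length(fields) + 1L]] <- field_def(
      name = name, type = type, label = getcol(i, "label"),
      choice_list = cl_ref,
      required = truthy(getcol(i, "required")),
      relevant = getcol(i, "relevant"),
      constraint = getcol(i, "constraint"),
      validation = validation,
      guidance_hint = if (nzchar(getcol(i, "guidance_hint"))) getcol(i, "guidance_hint"),
      identifier = truthy(getcol(i, "identifier")),
      participant_id = truthy(getcol(i, "participant_id")),
      tag = tag,
      calculation = if (nzchar(getcol(i, "calculation"))) getcol(i, "calculation")
    )
  }

  form_name <- "form"
  if (!is.null(settings) && nrow(settings)) {
    if ("form_id" %in% names(settings) && nzchar(cell_chr(settings[1, "form_id"])))
      form_name <- tolower(cell_chr(settings[1, "form_id"]))
    else if ("form_title" %in% names(settings) && nzchar(cell_chr(settings[1, "form_title"])))
      form_name <- tolower(gsub("[^a-z0-9_]+", "_", tolower(cell_chr(settings[1, "form_title"]))))
  }
  instr <- instrument(form_name, fields, cls)
  viol <- validate_instrument(instr)
  if (length(viol))
    stop(edc_error("edc_invalid_instrument",
                   paste0("workbook yields an invalid instrument:\n  ",
                          paste(viol, collapse = "\n  "))))
  instr
}

cell_chr_v <- function(x) vapply(x, cell_chr, character(1), USE.NAMES = FALSE)

#' Write an instrument as an XLSForm workbook
#'
#' Inverse of [read_xlsform()] on the representable subset: re-reading the
#' written workbook reproduces every field, choice list, logic expression and
#' semantic tag.
#'
#' @param instr an `edc_instrument`.
#' @param path output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_xlsform <- function(instr, path) {
  viol <- validate_instrument(instr)
  assert_that(length(viol) == 0, paste0("refusing to write invalid instrument: ", paste(viol, collapse = "; ")))
  n <- length(instr$fields)
  col <- function(f) vapply(instr$fields, f, character(1))
  survey <- data.frame(
    type = col(function(f) {
      if (f$type %in% c("select_one", "select_multiple")) paste(f$type, f$choice_list)
      else if (f$type == "calc") "calculate"
      else f$type
    }),
    name = col(function(f) f$name),
    label = col(function(f) f$label),
    required = col(function(f) if (f$required) "true" else ""),
    relevant = col(function(f) if (is.null(f$relevant)) "" else render_logic(f$relevant, "xlsform")),
    constraint = col(function(f) render_constraint(f$constraint)),
    calculation = col(function(f) f$calculation %||% ""),
    guidance_hint = col(function(f) f$guidance_hint %||% ""),
    identifier = col(function(f) if (f$identifier) "true" else ""),
    participant_id = col(function(f) if (f$participant_id) "true" else ""),
    validation_min = col(function(f) cell_chr(f$validation$min %||% "")),
    validation_max = col(function(f) cell_chr(f$validation$max %||% "")),
    hxl = col(function(f) if (!is.null(f$tag) && f$tag$kind == "hxl_hashtag") f$tag$value else ""),
    annotation = col(function(f) if (!is.null(f$tag) && f$tag$kind == "ontology_property") f$tag$value else ""),
    stringsAsFactors = FALSE
  )
  if (n == 0) survey <- survey[0, , drop = FALSE]

  ch <- do.call(rbind, lapply(instr$choice_lists, function(cl) {
    data.frame(list_name = cl$name, name = cl$codes, label = cl$labels,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ch)) ch <- data.frame(list_name = character(0), name = character(0),
                                    label = character(0), stringsAsFactors = FALSE)
  settings <- data.frame(form_title = instr$name, form_id = instr$name,
                         stringsAsFactors = FALSE)
  write_xlsx_sheets(list(survey = survey, choices = ch, settings = settings), path)
}
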