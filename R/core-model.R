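#' Canonical instrument model
#'
#' The in-memory lingua franca between the XLSForm reader/writer, the
#' data-dictionary converter, the ontology bridge and the ETL pipeline. An
#' instrument is an ordered list of typed fields plus the named choice lists
#' they reference.
#'
#' @name core_model
NULL

#' Closed set of field types
#' @export
FIELD_TYPES <- c("text", "integer", "decimal", "date", "datetime", "time",
                 "calc", "select_one", "select_multiple", "note", "file")

#' Construct a choice list
#'
#' @param name list name (token).
#' @param codes choice codes (no whitespace, unique).
#' @param labels display labels, same length as `codes`.
#' @return an `edc_choice_list`.
#' @export
choice_list <- function(name, codes, labels = codes) {
  codes <- as.character(codes); labels <- as.character(labels)
  assert_that(length(codes) == length(labels), "codes and labels differ in length")
  assert_that(length(codes) > 0, "choice list must be non-empty")
  structure(list(name = tolower(cell_chr(name)), codes = codes, labels = labels),
            class = "edc_choice_list")
}

#' Construct a field definition
#'
#' @param name variable name; lower-cased on ingest, must match
#'   `[a-z][a-z0-9_]*`.
#' @param type one of [FIELD_TYPES].
#' @param label question label shown to the respondent.
#' @param choice_list name of the bound choice list (select types only).
#' @param required logical; answer mandatory.
#' @param relevant skip logic: an `edc_logic` tree or XLSForm expression text.
#' @param constraint value constraint: `edc_logic` tree or XLSForm text; the
#'   pattern `. >= a and . <= b` (with `.` the field itself) maps to
#'   validation min/max on conversion.
#' @param validation list with optional `kind` (one of `date_ymd`,
#'   `datetime_ymd`, `time`, `integer`, `number`), `min`, `max`.
#' @param guidance_hint collector-facing hint; for `calc` fields with an empty
#'   label it becomes the label in the REDCap dictionary.
#' @param identifier logical; field holds a personal identifier.
#' @param participant_id logical; field is the participant identifier used for
#'   record-ID resolution (at most one per instrument).
#' @param tag optional [semantic_tag()].
#' @param calculation calc-field expression text (stored verbatim).
#' @return an `edc_field`.
#' @export
field_def <- function(name, type, label = "", choice_list = NULL,
                      required = FALSE, relevant = NULL, constraint = NULL,
                      validation = list(), guidance_hint = NULL,
                      identifier = FALSE, participant_id = FALSE,
                      tag = NULL, calculation = NULL) {
  name <- tolower(cell_chr(name))
  if (is.character(relevant)) relevant <- parse_logic(relevant, "xlsform")
  if (is.character(constraint)) constraint <- parse_constraint(constraint)
  validation <- validation %||% list()
  if (!is.null(validation$min) && !is.null(validation$max)) {
    mn <- num_or_na(validation$min); mx <- num_or_na(validation$max)
    if (!is.na(mn) && !is.na(mx)) assert_that(mn <= mx, sprintf("field '%s': validation min > max", name))
    else assert_that(as.character(validation$min) <= as.character(validation$max),
                     sprintf("field '%s': validation min > max", name))
  }
  structure(list(
    name = name, type = type, label = as.character(label %||% ""),
    choice_list = if (!is.null(choice_list)) tolower(cell_chr(choice_list)),
    required = isTRUE(required), relevant = relevant, constraint = constraint,
    validation = validation, guidance_hint = guidance_hint,
    identifier = isTRUE(identifier), participant_id = isTRUE(participant_id),
    tag = tag, calculation = calculation
  ), class = "edc_field")
}

#' Parse an XLSForm constraint expression
#'
#' XLSForm constraints refer to the field's own value as `.`; the dot (when
#' not part of a numeric literal) is rewritten to the pseudo-field
#' `${self}` before parsing so the shared grammar applies.
#'
#' @param text constraint text.
#' @return an `edc_logic` tree referencing `self`.
#' @export
parse_constraint <- function(text) {
  text <- cell_chr(text)
  if (!nzchar(text)) return(NULL)
  rewritten <- gsub("(?<![0-9a-z_}$])\\.(?![0-9])", "${self}", text, perl = TRUE)
  parse_logic(rewritten, "xlsform")
}

render_constraint <- function(expr) {
  if (is.null(expr) || expr$kind == "true") return("")
  gsub("${self}", ".", render_logic(expr, "xlsform"), fixed = TRUE)
}

#' Construct a semantic tag
#'
#' A field-level annotation carrying machine-readable meaning: either an
#' ontology datatype-property IRI or an HXL hashtag.
#'
#' @param kind `"ontology_property"` or `"hxl_hashtag"`.
#' @param value absolute IRI, or hashtag starting with `#`.
#' @return an `edc_semantic_tag`.
#' @export
semantic_tag <- function(kind = c("ontology_property", "hxl_hashtag"), value) {
  kind <- match.arg(kind)
  value <- cell_chr(value)
  if (kind == "hxl_hashtag") assert_that(startsWith(value, "#"), "HXL hashtag must start with '#'")
  if (kind == "ontology_property")
    assert_that(grepl("^[a-z][a-z0-9+.-]*://", value), "ontology property must be an absolute IRI")
  structure(list(kind = kind, value = value), class = "edc_semantic_tag")
}

#' Construct an instrument
#'
#' @param name instrument/form name (token).
#' @param fields list of [field_def()] in display order.
#' @param choice_lists list of [choice_list()].
#' @return an `edc_instrument`.
#' @export
instrument <- function(name, fields = list(), choice_lists = list()) {
  cl <- choice_lists
  if (length(cl) && is.null(names(cl)))
    names(cl) <- vapply(cl, function(x) x$name, character(1))
  structure(list(name = tolower(cell_chr(name)), fields = fields, choice_lists = cl),
            class = "edc_instrument")
}

#' @export
print.edc_instrument <- function(x, ...) {
  cat(sprintf("<instrument '%s'> %d field(s), %d choice list(s)\n",
              x$name, length(x$fields), length(x$choice_lists)))
  for (f in x$fields) {
    cat(sprintf("  %-20s %-15s %s\n", f$name, f$type,
                if (nzchar(f$label)) substr(f$label, 1, 40) else ""))
  }
  invisible(x)
}

field_names <- function(instr) vapply(instr$fields, function(f) f$name, character(1))

get_field <- function(instr, name) {
  for (f in instr$fields) if (f$name == name) return(f)
  NULL
}

#' Validate an instrument against its structural invariants
#'
#' Violations are data, not errors: an empty return means the instrument is
#' well formed. Checked: field-name syntax and uniqueness, resolvable choice
#' lists on select fields, choice-code uniqueness and non-emptiness, resolvable
#' field references in `relevant` logic, at most one participant-id field,
#' HXL/IRI tag shape, and min <= max.
#'
#' @param instr an `edc_instrument`.
#' @return character vector of violation descriptions (empty if valid).
#' @export
validate_instrument <- function(instr) {
  v <- character(0)
  nms <- field_names(instr)
  dup <- unique(nms[duplicated(nms)])
  for (d in dup) v <- c(v, sprintf("duplicate field name '%s'", d))
  for (f in instr$fields) {
    if (!grepl(VALID_NAME_RE, f$name))
      v <- c(v, sprintf("field '%s': name must match %s", f$name, VALID_NAME_RE))
    if (!f$type %in% FIELD_TYPES)
      v <- c(v, sprintf("field '%s': unknown type '%s'", f$name, f$type))
    if (f$type %in% c("select_one", "select_multiple")) {
      if (is.null(f$choice_list) || is.null(instr$choice_lists[[f$choice_list]]))
        v <- c(v, sprintf("field '%s': unresolved choice list '%s'", f$name, f$choice_list %||% "<none>"))
    }
    for (expr in list(f$relevant, f$constraint)) {
      if (is.null(expr)) next
      refs <- setdiff(logic_fields(expr), "self")
      missing <- setdiff(refs, nms)
      for (m in missing)
        v <- c(v, sprintf("field '%s': logic references unknown field '%s'", f$name, m))
    }
    val <- f$validation
    if (!is.null(val$min) && !is.null(val$max)) {
      mn <- num_or_na(val$min); mx <- num_or_na(val$max)
      if (!is.na(mn) && !is.na(mx) && mn > mx)
        v <- c(v, sprintf("field '%s': validation min exceeds max", f$name))
    }
  }
  for (cl in instr$choice_lists) {
    if (any(duplicated(cl$codes)))
      v <- c(v, sprintf("choice list '%s': duplicate codes", cl$name))
    if (any(grepl("\\s", cl$codes) | !nzchar(cl$codes)))
      v <- c(v, sprintf("choice list '%s': codes must be non-empty and whitespace-free", cl$name))
  }
  pid <- vapply(instr$fields, function(f) isTRUE(f$participant_id), logical(1))
  if (sum(pid) > 1)
    v <- c(v, sprintf("multiple participant_id fields: %s", paste(nms[pid], collapse = ", ")))
  v
}

#' Construct a flat record
#'
#' One participant-event's values keyed by field name. Multiple-selection
#' answers are stored in REDCap's expanded form: one `name___code` entry per
#' option, `"1"`/`"0"`.
#'
#' @param record_id record identifier (text).
#' @param values named list or character vector of field values.
#' @param event optional event/visit name for longitudinal projects.
#' @return an `edc_flat_record`.
#' @export
flat_record <- function(record_id, values = list(), event = NULL) {
  values <- as.list(values)
  structure(list(record_id = as.character(record_id), event = event,
                 values = lapply(values, as.character)),
            class = "edc_flat_record")
}

#' @export
print.edc_flat_record <- function(x, ...) {
  cat(sprintf("<record %s%s> %d value(s)\n", x$record_id,
              if (!is.null(x$event)) paste0(" @", x$event) else "", length(x$values)))
  invisible(x)
}

# equality helper for round-trip tests: compares the representable surface.
# Choice lists are compared by content (codes + labels), not by list name —
# the dictionary rendering does not carry list names. A calc field's
# effective label is its guidance hint when the label is empty (the
# documented labeling workaround).
fields_equivalent <- function(a, b, instr_a = NULL, instr_b = NULL) {
  same_logic <- function(x, y) {
    if (is.null(x)) x <- logic_true()
    if (is.null(y)) y <- logic_true()
    logic_equal(x, y)
  }
  eff_label <- function(f) {
    if (f$type == "calc" && !nzchar(f$label) && !is.null(f$guidance_hint)) f$guidance_hint
    else f$label
  }
  choices_of <- function(f, instr) {
    if (is.null(f$choice_list) || is.null(instr)) return(NULL)
    cl <- instr$choice_lists[[f$choice_list]]
    if (is.null(cl)) NULL else list(codes = cl$codes, labels = cl$labels)
  }
  same_choices <- if (is.null(instr_a) || is.null(instr_b))
    is.null(a$choice_list) == is.null(b$choice_list)
  else identical(choices_of(a, instr_a), choices_of(b, instr_b))
  ok <- a$name == b$name && a$type == b$type && eff_label(a) == eff_label(b) &&
    same_choices && a$required == b$required &&
    same_logic(a$relevant, b$relevant) &&
    identical(cell_chr(a$validation$min %||% ""), cell_chr(b$validation$min %||% "")) &&
    identical(cell_chr(a$validation$max %||% ""), cell_chr(b$validation$max %||% ""))
  isTRUE(ok)
}

#' Are two instruments field-level equivalent?
#'
#' Order-sensitive comparison of the conversion-representable surface: name,
#' type, effective label, choice content, required flag, skip logic (by tree
#' equality) and validation bounds.
#'
#' @param a,b instruments.
#' @return logical.
#' @export
instruments_equivalent <- function(a, b) {
  length(a$fields) == length(b$fields) &&
    all(mapply(fields_equivalent, a$fields, b$fields,
               MoreArgs = list(instr_a = a, instr_b = b)))
}
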