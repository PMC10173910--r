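#' Reporting: usability scoring, registry summaries, DMP rendering, logs
#'
#' Covers the analysis-facing surfaces: scoring of the 16-item IBM Computer
#' System Usability Questionnaire (CSUQ v3), respondent breakdowns, project
#' registry summaries, data-management-plan rendering from a bundled
#' template, and the support-request / instrument-comment audit trails.
#'
#' @name reporting
NULL

CSUQ_SUBSCALES <- list(overall = 1:16, sysuse = 1:6, infoqual = 7:12, intqual = 13:15)

#' Score the CSUQ
#'
#' Input is either a respondents-by-16 matrix of ratings (each in \[1, 7\],
#' already oriented so higher is better — any reversal is the caller's
#' preprocessing) or a vector of the 16 item means. Each subscale is the
#' arithmetic mean of its items' means: Overall items 1-16, SysUse 1-6,
#' InfoQual 7-12, IntQual 13-15. Scores are reported half-up at two
#' decimals; raw values are retained in the `raw` component.
#'
#' @param x numeric matrix (n x 16) or numeric vector of 16 item means.
#' @return an `edc_csuq` list: `item_means`, `raw` (unrounded scores),
#'   `scores` (rounded to 2 decimals), `n` (respondents; `NA` for mean input).
#' @export
#' @examples
#' score_csuq(rep(7, 16))$scores
score_csuq <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    assert_that(ncol(x) == 16L, sprintf("expected 16 items, got %d", ncol(x)))
    assert_that(all(x >= 1 & x <= 7), "ratings must lie in [1, 7]")
    item_means <- colMeans(x)
    n <- nrow(x)
  } else {
    x <- as.numeric(x)
    assert_that(length(x) == 16L, sprintf("expected 16 item means, got %d", length(x)))
    assert_that(all(x >= 1 & x <= 7), "item means must lie in [1, 7]")
    item_means <- x
    n <- NA_integer_
  }
  raw <- vapply(CSUQ_SUBSCALES, function(idx) mean(item_means[idx]), numeric(1))
  structure(list(item_means = unname(item_means), raw = raw,
                 scores = round_half_up(raw, 2), n = n),
            class = "edc_csuq")
}

#' @export
print.edc_csuq <- function(x, ...) {
  cat(sprintf("CSUQ scores%s\n", if (!is.na(x$n)) sprintf(" (n = %d)", x$n) else ""))
  lbl <- c(overall = "Overall", sysuse = "SysUse", infoqual = "InfoQual", intqual = "IntQual")
  for (k in names(lbl))
    cat(sprintf("  %-9s %.2f\n", lbl[[k]], x$scores[[k]]))
  invisible(x)
}

#' Percentage breakdown of respondent categories
#'
#' Percentages are computed from the unrounded ratios and displayed half-up
#' at two decimals, so categories of 7, 9 and 1 out of 17 give 41.18, 52.94
#' and 5.88.
#'
#' @param counts named non-negative counts; total must be positive.
#' @return named numeric vector of percentages.
#' @export
respondent_breakdown <- function(counts) {
  counts <- unlist(counts)
  assert_that(all(counts >= 0), "counts must be non-negative")
  total <- sum(counts)
  assert_that(total > 0, "total count must be positive")
  round_half_up(100 * counts / total, 2)
}

#' Summarize a project registry
#'
#' @param projects data frame with columns `project`, `centers`,
#'   `instruments`, `fields`, `expected_records` (one row per project, in
#'   registration order).
#' @return an `edc_registry_summary`: the per-project rows plus a `totals`
#'   row of exact integer sums.
#' @export
summarize_registry <- function(projects) {
  needed <- c("project", "centers", "instruments", "fields", "expected_records")
  assert_that(all(needed %in% names(projects)),
              paste0("registry needs columns: ", paste(needed, collapse = ", ")))
  num_cols <- needed[-1L]
  for (cn in num_cols)
    assert_that(all(projects[[cn]] >= 0), paste0("negative count in ", cn))
  totals <- vapply(num_cols, function(cn) sum(as.integer(projects[[cn]])), integer(1))
  structure(list(projects = projects, totals = totals), class = "edc_registry_summary")
}

#' @export
print.edc_registry_summary <- function(x, ...) {
  print(x$projects, row.names = FALSE)
  cat("Totals:", paste(names(x$totals), x$totals, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

## ---- data management plan -------------------------------------------------

DMP_REQUIRED <- c("project_name", "project_number", "principal_investigator", "funding")

#' Render a data management plan
#'
#' Fills the bundled plan template (Portuguese; sections on study data and
#' resources, security and privacy, access and archiving, and ethical and
#' regulatory aspects) with project metadata. Values are inserted verbatim,
#' never interpreted. Rendering fails listing every missing required field,
#' and refuses to leave unreplaced placeholder markers behind.
#'
#' @param metadata named list; required: `project_name`, `project_number`,
#'   `principal_investigator`, `funding`. Optional placeholders render as
#'   empty text.
#' @param template path to a mustache-style template; default: the bundled
#'   one.
#' @param path optional output path for the rendered markdown.
#' @return rendered document as a single string (invisibly when written).
#' @export
fill_dmp <- function(metadata, template = NULL, path = NULL) {
  template <- template %||% system.file("templates", "dmp.md", package = "edcbridge")
  assert_that(nzchar(template) && file.exists(template), "DMP template not found")
  missing <- setdiff(DMP_REQUIRED, names(metadata)[nzchar(vapply(metadata, cell_chr, character(1)))])
  if (length(missing))
    stop(edc_error("edc_missing_field",
                   paste0("missing required DMP field(s): ", paste(missing, collapse = ", ")),
                   data = list(fields = missing)))
  tpl <- paste(readLines(template, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  wanted <- unique(regmatches(tpl, gregexpr("\\{\\{\\{[a-z_]+\\}\\}\\}", tpl))[[1L]])
  wanted <- gsub("[{}]", "", wanted)
  full <- stats::setNames(as.list(rep("", length(wanted))), wanted)
  for (k in names(metadata)) full[[k]] <- as.character(metadata[[k]])
  doc <- whisker::whisker.render(tpl, full)
  # only template-style markers count: metadata values may contain braces
  assert_that(!grepl("\\{\\{\\{[a-z_]+\\}\\}\\}", doc),
              "rendered document still contains placeholder markers")
  if (is.null(path)) return(doc)
  writeLines(doc, path, useBytes = TRUE)
  invisible(doc)
}

## ---- support requests and instrument comments ------------------------------

#' Record a support request
#'
#' Requests (record unlocking, data deletion, ...) are append-only with a
#' full audit trail of status transitions.
#'
#' @param store an `edc_store`.
#' @param project_id project the request concerns.
#' @param record_id record the request concerns.
#' @param kind `"unlock"`, `"delete"` or `"other"`.
#' @param requester who asked.
#' @param now timestamp.
#' @return request id.
#' @export
record_support_request <- function(store, project_id, record_id, kind = c("unlock", "delete", "other"),
                                   requester, now = NULL) {
  kind <- match.arg(kind)
  require_project(store, project_id)
  x1(store, "INSERT INTO support_requests (project_id, record_id, kind, requester, status, created_at)
       VALUES (?,?,?,?, 'open', ?)", project_id, record_id, kind, requester, now_ts(now))
  id <- q1(store, "SELECT last_insert_rowid() AS id")$id[1L]
  x1(store, "INSERT INTO support_audit (request_id, status, at, note) VALUES (?, 'open', ?, ?)",
     id, now_ts(now), paste0("opened by ", requester))
  id
}

#' @rdname record_support_request
#' @param request_id request to transition.
#' @param status new status (e.g. `"done"`, `"rejected"`).
#' @param note audit note.
#' @export
update_support_request <- function(store, project_id, request_id, status, note = "", now = NULL) {
  r <- q1(store, "SELECT 1 FROM support_requests WHERE project_id = ? AND request_id = ?",
          project_id, request_id)
  if (!nrow(r))
    stop(edc_error("edc_unknown_request", paste0("unknown support request: ", request_id)))
  x1(store, "UPDATE support_requests SET status = ? WHERE request_id = ?", status, request_id)
  x1(store, "INSERT INTO support_audit (request_id, status, at, note) VALUES (?,?,?,?)",
     request_id, status, now_ts(now), note)
  invisible(request_id)
}

#' @rdname record_support_request
#' @export
support_request_audit <- function(store, request_id) {
  q1(store, "SELECT * FROM support_audit WHERE request_id = ? ORDER BY id", request_id)
}

#' Comment on an instrument field
#'
#' Threads are flat: a reply references the original comment via
#' `parent_id`. History is retrievable in insertion order.
#'
#' @inheritParams record_support_request
#' @param form_name registered form being discussed.
#' @param field_name field being discussed (must exist in the form).
#' @param author,body comment author and text.
#' @param parent_id optional id of the comment being replied to.
#' @return comment id.
#' @export
add_instrument_comment <- function(store, project_id, form_name, field_name,
                                   author, body, parent_id = NULL, now = NULL) {
  dd <- get_form_dictionary(store, project_id, form_name)
  vars <- vapply(dd$rows, function(r) r$variable_name, character(1))
  assert_that(field_name %in% vars,
              sprintf("field '%s' not in form '%s'", field_name, form_name))
  if (!is.null(parent_id)) {
    p <- q1(store, "SELECT 1 FROM instrument_comments WHERE comment_id = ?", parent_id)
    if (!nrow(p))
      stop(edc_error("edc_unknown_parent", paste0("no such parent comment: ", parent_id)))
  }
  x1(store, "INSERT INTO instrument_comments
       (project_id, form_name, field_name, author, body, parent_id, created_at)
       VALUES (?,?,?,?,?,?,?)", project_id, form_name, field_name, author, body,
     parent_id %||% NA_integer_, now_ts(now))
  q1(store, "SELECT last_insert_rowid() AS id")$id[1L]
}

#' @rdname add_instrument_comment
#' @export
instrument_comments <- function(store, project_id, form_name = NULL) {
  sql <- "SELECT * FROM instrument_comments WHERE project_id = ?"
  params <- list(project_id)
  if (!is.null(form_name)) { sql <- paste(sql, "AND form_name = ?"); params <- c(params, form_name) }
  DBI::dbGetQuery(store$con, paste(sql, "ORDER BY comment_id"), params = params)
}
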