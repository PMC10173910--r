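#' Embedded project store
#'
#' An embedded SQLite database emulating the electronic-data-capture surfaces
#' the pipeline needs: project registry with API credentials, per-project form
#' registration, field-level semantic metadata, record storage with
#' checkbox-expanded values, record-ID generation, record locking, a
#' query (data-issue) lifecycle, an append-only change log, validation rules,
#' visit configuration, alert recipients and the alert/notification log.
#'
#' Tables mirror the metadata model of the emulated system:
#' `redcap_project`, `redcap_forms`, `form_metadata`,
#' `redcap_validation_rules`, `redcap_validation_issues`,
#' `redcap_visits_config`, `redcap_alerts`, `redcap_alerts_log`, plus the
#' implied `records`, `record_locks`, `change_log`, `parked_submissions`,
#' `support_requests` / `support_audit` and `instrument_comments` tables.
#'
#' @name store
NULL

#' Open (or create) a project store
#'
#' @param path SQLite file path, or `":memory:"` for an ephemeral store.
#' @return an `edc_store` handle.
#' @export
open_store <- function(path = ":memory:") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  stmts <- c(
    "CREATE TABLE IF NOT EXISTS redcap_project (
       project_id TEXT PRIMARY KEY, name TEXT, api_url TEXT,
       api_token TEXT NOT NULL CHECK(length(api_token) > 0),
       description TEXT, username TEXT, password TEXT,
       ref_date_field TEXT, record_counter INTEGER NOT NULL DEFAULT 0)",
    "CREATE TABLE IF NOT EXISTS redcap_forms (
       project_id TEXT, form_name TEXT, order_index INTEGER, is_first INTEGER,
       dictionary_csv TEXT, PRIMARY KEY (project_id, form_name))",
    "CREATE TABLE IF NOT EXISTS form_metadata (
       project_id TEXT, form_name TEXT, field_name TEXT,
       tag_kind TEXT, tag_value TEXT, identifier INTEGER DEFAULT 0,
       participant_id INTEGER DEFAULT 0,
       PRIMARY KEY (project_id, form_name, field_name))",
    "CREATE TABLE IF NOT EXISTS records (
       project_id TEXT, record_id TEXT, event TEXT DEFAULT '',
       field_name TEXT, value TEXT,
       PRIMARY KEY (project_id, record_id, event, field_name))",
    "CREATE TABLE IF NOT EXISTS record_locks (
       project_id TEXT, record_id TEXT, form_name TEXT,
       PRIMARY KEY (project_id, record_id, form_name))",
    "CREATE TABLE IF NOT EXISTS change_log (
       seq INTEGER PRIMARY KEY AUTOINCREMENT, project_id TEXT,
       record_id TEXT, form_name TEXT, timestamp TEXT, snapshot TEXT)",
    "CREATE TABLE IF NOT EXISTS redcap_validation_rules (
       rule_id TEXT, project_id TEXT, form_name TEXT, field_name TEXT,
       rule_type TEXT, min TEXT, max TEXT, pattern TEXT, format TEXT,
       PRIMARY KEY (project_id, rule_id))",
    "CREATE TABLE IF NOT EXISTS redcap_validation_issues (
       issue_id INTEGER PRIMARY KEY AUTOINCREMENT, project_id TEXT,
       record_id TEXT, field_name TEXT, rule_id TEXT, status TEXT,
       opened_at TEXT, resolved_at TEXT)",
    "CREATE TABLE IF NOT EXISTS redcap_visits_config (
       project_id TEXT, event_name TEXT, day_offset INTEGER,
       window_after INTEGER DEFAULT 0, linked_forms TEXT, order_index INTEGER,
       PRIMARY KEY (project_id, event_name))",
    "CREATE TABLE IF NOT EXISTS redcap_alerts (
       project_id TEXT, recipient TEXT, channel TEXT,
       PRIMARY KEY (project_id, recipient, channel))",
    "CREATE TABLE IF NOT EXISTS redcap_alerts_log (
       id INTEGER PRIMARY KEY AUTOINCREMENT, project_id TEXT, recipient TEXT,
       channel TEXT, reason TEXT, ref TEXT, body TEXT, sent_at TEXT)",
    "CREATE TABLE IF NOT EXISTS parked_submissions (
       id INTEGER PRIMARY KEY AUTOINCREMENT, project_id TEXT, form_name TEXT,
       payload TEXT, reason TEXT, parked_at TEXT)",
    "CREATE TABLE IF NOT EXISTS support_requests (
       request_id INTEGER PRIMARY KEY AUTOINCREMENT, project_id TEXT,
       record_id TEXT, kind TEXT, requester TEXT, status TEXT, created_at TEXT)",
    "CREATE TABLE IF NOT EXISTS support_audit (
       id INTEGER PRIMARY KEY AUTOINCREMENT, request_id INTEGER, status TEXT,
       at TEXT, note TEXT)",
    "CREATE TABLE IF NOT EXISTS instrument_comments (
       comment_id INTEGER PRIMARY KEY AUTOINCREMENT, project_id TEXT,
       form_name TEXT, field_name TEXT, author TEXT, body TEXT,
       parent_id INTEGER, created_at TEXT)"
  )
  for (s in stmts) DBI::dbExecute(con, s)
  structure(list(con = con, path = path), class = "edc_store")
}

#' @rdname open_store
#' @param store an `edc_store`.
#' @export
close_store <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.edc_store <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM redcap_project")$n
  cat(sprintf("<edc store %s> %d project(s)\n", x$path, n))
  invisible(x)
}

q1 <- function(store, sql, ...) {
  p <- list(...)
  if (length(p)) DBI::dbGetQuery(store$con, sql, params = p)
  else DBI::dbGetQuery(store$con, sql)
}
x1 <- function(store, sql, ...) {
  p <- list(...)
  if (length(p)) DBI::dbExecute(store$con, sql, params = p)
  else DBI::dbExecute(store$con, sql)
}

now_ts <- function(now = NULL) {
  if (is.null(now)) format(Sys.time(), "%Y-%m-%d %H:%M:%S") else as.character(now)
}

project_exists <- function(store, project_id) {
  nrow(q1(store, "SELECT 1 FROM redcap_project WHERE project_id = ?", project_id)) > 0
}

require_project <- function(store, project_id) {
  if (!project_exists(store, project_id))
    stop(edc_error("edc_unknown_project", paste0("unknown project: ", project_id)))
}

#' Register a project
#'
#' @param store an `edc_store`.
#' @param project_id unique project identifier.
#' @param name descriptive name.
#' @param api_url,api_token emulated API coordinates (token must be non-empty;
#'   neither carries network meaning here).
#' @param description free text.
#' @param username,password basic-auth credentials the ETL receiver checks.
#' @param ref_date_field name of the field holding each participant's
#'   reference date (inclusion/intervention day) for visit scheduling.
#' @return `project_id`, invisibly.
#' @export
register_project <- function(store, project_id, name = project_id,
                             api_url = "http://localhost/api/",
                             api_token = "token", description = "",
                             username = "etl", password = "secret",
                             ref_date_field = NULL) {
  assert_that(nzchar(cell_chr(api_token)), "api_token must be non-empty")
  assert_that(!project_exists(store, project_id),
              paste0("project already registered: ", project_id))
  x1(store, "INSERT INTO redcap_project
       (project_id, name, api_url, api_token, description, username, password, ref_date_field)
       VALUES (?,?,?,?,?,?,?,?)",
     project_id, name, api_url, api_token, description, username, password,
     ref_date_field %||% NA_character_)
  invisible(project_id)
}

#' Register a form (instrument) in a project
#'
#' @inheritParams register_project
#' @param dd the form's `edc_dictionary`.
#' @param is_first logical; the project's entry form (exactly one per
#'   project) — submissions to it may create new participants.
#' @param order_index display position; defaults to the next free slot.
#' @export
register_form <- function(store, project_id, dd, is_first = FALSE, order_index = NULL) {
  require_project(store, project_id)
  form_name <- dd$form_name
  existing <- q1(store, "SELECT form_name, is_first FROM redcap_forms WHERE project_id = ?", project_id)
  assert_that(!form_name %in% existing$form_name,
              paste0("form already registered: ", form_name))
  if (is_first)
    assert_that(!any(existing$is_first == 1), "project already has a first form")
  if (is.null(order_index)) order_index <- nrow(existing) + 1L
  csv <- paste(write_dictionary(dd), collapse = "\n")
  x1(store, "INSERT INTO redcap_forms (project_id, form_name, order_index, is_first, dictionary_csv)
       VALUES (?,?,?,?,?)", project_id, form_name, order_index, as.integer(is_first), csv)
  invisible(form_name)
}

#' Fetch a registered form's dictionary
#' @inheritParams register_form
#' @param form_name registered form name.
#' @export
get_form_dictionary <- function(store, project_id, form_name) {
  r <- q1(store, "SELECT dictionary_csv FROM redcap_forms WHERE project_id = ? AND form_name = ?",
          project_id, form_name)
  if (!nrow(r))
    stop(edc_error("edc_unknown_form", paste0("form not registered: ", form_name)))
  read_dictionary(strsplit(r$dictionary_csv[1L], "\n")[[1L]], form_name = form_name)
}

#' Record field-level metadata (semantics, identifiers, participant id)
#'
#' @inheritParams get_form_dictionary
#' @param field_name field the metadata describes.
#' @param tag optional [semantic_tag()].
#' @param identifier logical; personal identifier.
#' @param participant_id logical; at most one field per project may carry it.
#' @export
set_field_metadata <- function(store, project_id, form_name, field_name,
                               tag = NULL, identifier = FALSE, participant_id = FALSE) {
  require_project(store, project_id)
  if (participant_id) {
    other <- q1(store, "SELECT field_name FROM form_metadata
                  WHERE project_id = ? AND participant_id = 1 AND NOT (form_name = ? AND field_name = ?)",
                project_id, form_name, field_name)
    assert_that(nrow(other) == 0,
                paste0("project already has a participant_id field: ", paste(other$field_name, collapse = ", ")))
  }
  x1(store, "INSERT OR REPLACE INTO form_metadata
       (project_id, form_name, field_name, tag_kind, tag_value, identifier, participant_id)
       VALUES (?,?,?,?,?,?,?)",
     project_id, form_name, field_name,
     if (is.null(tag)) NA_character_ else tag$kind,
     if (is.null(tag)) NA_character_ else tag$value,
     as.integer(identifier), as.integer(participant_id))
  invisible(field_name)
}

participant_field <- function(store, project_id) {
  r <- q1(store, "SELECT field_name FROM form_metadata WHERE project_id = ? AND participant_id = 1",
          project_id)
  if (!nrow(r)) NULL else r$field_name[1L]
}

#' Generate the next record ID
#'
#' Strictly increasing integers rendered as text, starting at `"1"`; IDs are
#' never reused, including after record deletion.
#'
#' @inheritParams register_form
#' @return record id as text.
#' @export
next_record_id <- function(store, project_id) {
  require_project(store, project_id)
  x1(store, "UPDATE redcap_project SET record_counter = record_counter + 1 WHERE project_id = ?",
     project_id)
  n <- q1(store, "SELECT record_counter FROM redcap_project WHERE project_id = ?", project_id)
  as.character(n$record_counter[1L])
}

# field names legal for a form: dictionary variables plus checkbox expansions
form_field_universe <- function(dd) {
  out <- character(0)
  for (row in dd$rows) {
    out <- c(out, row$variable_name)
    if (row$field_type == "checkbox") {
      ch <- parse_choices(row$choices_or_calc)
      if (!is.null(ch)) out <- c(out, paste0(row$variable_name, "___", ch$codes))
    }
  }
  out
}

#' Is a record locked for a form?
#' @inheritParams get_form_dictionary
#' @param record_id record identifier.
#' @export
is_locked <- function(store, project_id, record_id, form_name) {
  nrow(q1(store, "SELECT 1 FROM record_locks WHERE project_id = ? AND record_id = ? AND form_name = ?",
          project_id, record_id, form_name)) > 0
}

#' Lock a record's form (idempotent)
#'
#' A locked record's values can never be mutated until the lock is lifted.
#'
#' @inheritParams is_locked
#' @export
lock_record <- function(store, project_id, record_id, form_name) {
  require_project(store, project_id)
  known <- q1(store, "SELECT 1 FROM records WHERE project_id = ? AND record_id = ? LIMIT 1",
              project_id, record_id)
  if (!nrow(known))
    stop(edc_error("edc_unknown_record", paste0("unknown record: ", record_id)))
  x1(store, "INSERT OR IGNORE INTO record_locks (project_id, record_id, form_name) VALUES (?,?,?)",
     project_id, record_id, form_name)
  invisible(TRUE)
}

#' @rdname lock_record
#' @export
unlock_record <- function(store, project_id, record_id, form_name) {
  x1(store, "DELETE FROM record_locks WHERE project_id = ? AND record_id = ? AND form_name = ?",
     project_id, record_id, form_name)
  invisible(TRUE)
}

#' Import a record (upsert) into the store
#'
#' Upserts by (record id, event, form). Every call that changes at least one
#' value appends one change-log entry containing exactly the changed values;
#' a no-op import appends nothing. Unknown fields and locked records raise.
#'
#' @inheritParams get_form_dictionary
#' @param rec a [flat_record()] whose value names belong to the form's
#'   dictionary (checkbox expansions `name___code` included).
#' @param now timestamp for the change-log entry (ISO text); defaults to the
#'   current time.
#' @return number of changed values, invisibly.
#' @export
import_record <- function(store, project_id, form_name, rec, now = NULL) {
  require_project(store, project_id)
  dd <- get_form_dictionary(store, project_id, form_name)
  universe <- form_field_universe(dd)
  unknown <- setdiff(names(rec$values), universe)
  if (length(unknown))
    stop(edc_error("edc_unknown_field",
                   paste0("field(s) not in form '", form_name, "': ", paste(unknown, collapse = ", "))))
  if (is_locked(store, project_id, rec$record_id, form_name))
    stop(edc_error("edc_locked_record",
                   sprintf("record %s is locked for form %s", rec$record_id, form_name)))
  ev <- rec$event %||% ""
  changed <- list()
  for (fn in names(rec$values)) {
    new <- as.character(rec$values[[fn]])
    cur <- q1(store, "SELECT value FROM records WHERE project_id = ? AND record_id = ? AND event = ? AND field_name = ?",
              project_id, rec$record_id, ev, fn)
    if (nrow(cur) && identical(cur$value[1L], new)) next
    x1(store, "INSERT OR REPLACE INTO records (project_id, record_id, event, field_name, value)
         VALUES (?,?,?,?,?)", project_id, rec$record_id, ev, fn, new)
    changed[[fn]] <- new
  }
  if (length(changed)) {
    x1(store, "INSERT INTO change_log (project_id, record_id, form_name, timestamp, snapshot)
         VALUES (?,?,?,?,?)", project_id, rec$record_id, form_name, now_ts(now),
       jsonlite::toJSON(changed, auto_unbox = TRUE))
  }
  invisible(length(changed))
}

#' Export stored records
#'
#' Always reflects current store state (never cached).
#'
#' @inheritParams get_form_dictionary
#' @param record_id optional filter.
#' @param form_name optional: restrict values to one form's field universe.
#' @param event optional event filter.
#' @return list of [flat_record()]s, ordered by record id then event.
#' @export
export_records <- function(store, project_id, record_id = NULL, form_name = NULL,
                           event = NULL) {
  require_project(store, project_id)
  sql <- "SELECT record_id, event, field_name, value FROM records WHERE project_id = ?"
  params <- list(project_id)
  if (!is.null(record_id)) { sql <- paste(sql, "AND record_id = ?"); params <- c(params, record_id) }
  if (!is.null(event)) { sql <- paste(sql, "AND event = ?"); params <- c(params, event) }
  df <- DBI::dbGetQuery(store$con, paste(sql, "ORDER BY CAST(record_id AS INTEGER), record_id, event"),
                        params = params)
  if (!is.null(form_name)) {
    universe <- form_field_universe(get_form_dictionary(store, project_id, form_name))
    df <- df[df$field_name %in% universe, , drop = FALSE]
  }
  if (!nrow(df)) return(list())
  keys <- unique(df[, c("record_id", "event")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$record_id == keys$record_id[i] & df$event == keys$event[i], , drop = FALSE]
    flat_record(keys$record_id[i],
                stats::setNames(as.list(sub$value), sub$field_name),
                event = if (nzchar(keys$event[i])) keys$event[i])
  })
}

#' The append-only change log
#' @inheritParams export_records
#' @return data frame with columns seq, project_id, record_id, form_name,
#'   timestamp, snapshot (JSON of the changed values).
#' @export
change_log <- function(store, project_id, record_id = NULL) {
  sql <- "SELECT seq, project_id, record_id, form_name, timestamp, snapshot
          FROM change_log WHERE project_id = ?"
  params <- list(project_id)
  if (!is.null(record_id)) { sql <- paste(sql, "AND record_id = ?"); params <- c(params, record_id) }
  DBI::dbGetQuery(store$con, paste(sql, "ORDER BY seq"), params = params)
}

## ---- query (issue) lifecycle ---------------------------------------------

#' Open a data query on a record's field
#'
#' At most one open issue may exist per (record, field, rule); re-opening
#' after resolution creates a fresh issue id.
#'
#' @inheritParams export_records
#' @param field_name,rule_id issue coordinates.
#' @param now open timestamp.
#' @return new issue id.
#' @export
open_query <- function(store, project_id, record_id, field_name, rule_id, now = NULL) {
  require_project(store, project_id)
  dup <- q1(store, "SELECT issue_id FROM redcap_validation_issues
              WHERE project_id = ? AND record_id = ? AND field_name = ? AND rule_id = ? AND status = 'open'",
            project_id, record_id, field_name, rule_id)
  assert_that(nrow(dup) == 0,
              sprintf("open issue already exists for (%s, %s, %s)", record_id, field_name, rule_id))
  x1(store, "INSERT INTO redcap_validation_issues
       (project_id, record_id, field_name, rule_id, status, opened_at)
       VALUES (?,?,?,?,'open',?)", project_id, record_id, field_name, rule_id, now_ts(now))
  q1(store, "SELECT last_insert_rowid() AS id")$id[1L]
}

#' Resolve an open query
#' @inheritParams open_query
#' @param issue_id the issue to resolve.
#' @export
resolve_query <- function(store, project_id, issue_id, now = NULL) {
  r <- q1(store, "SELECT status FROM redcap_validation_issues WHERE project_id = ? AND issue_id = ?",
          project_id, issue_id)
  if (!nrow(r))
    stop(edc_error("edc_unknown_issue", paste0("unknown issue: ", issue_id)))
  if (r$status[1L] != "open")
    stop(edc_error("edc_illegal_transition",
                   sprintf("issue %s is already %s", issue_id, r$status[1L])))
  x1(store, "UPDATE redcap_validation_issues SET status = 'resolved', resolved_at = ?
       WHERE project_id = ? AND issue_id = ?", now_ts(now), project_id, issue_id)
  invisible(issue_id)
}

#' List validation issues
#' @inheritParams export_records
#' @param status optional filter (`"open"` or `"resolved"`).
#' @export
list_queries <- function(store, project_id, status = NULL) {
  sql <- "SELECT issue_id, project_id, record_id, field_name, rule_id, status, opened_at, resolved_at
          FROM redcap_validation_issues WHERE project_id = ?"
  params <- list(project_id)
  if (!is.null(status)) { sql <- paste(sql, "AND status = ?"); params <- c(params, status) }
  DBI::dbGetQuery(store$con, paste(sql, "ORDER BY issue_id"), params = params)
}

## ---- quality-plane metadata ----------------------------------------------

#' Define a validation rule
#'
#' @inheritParams get_form_dictionary
#' @param rule_id unique rule identifier within the project.
#' @param field_name field the rule checks.
#' @param rule_type one of `range`, `format`, `required`, `regex`.
#' @param min,max range bounds (numbers or ISO dates, as text).
#' @param pattern regular expression for `regex` rules.
#' @param format named format for `format` rules: one of `date_ymd`,
#'   `datetime_ymd`, `time`, `integer`, `number`.
#' @export
add_validation_rule <- function(store, project_id, rule_id, form_name, field_name,
                                rule_type = c("range", "format", "required", "regex"),
                                min = NULL, max = NULL, pattern = NULL, format = NULL) {
  rule_type <- match.arg(rule_type)
  require_project(store, project_id)
  dd <- get_form_dictionary(store, project_id, form_name)
  vars <- vapply(dd$rows, function(r) r$variable_name, character(1))
  assert_that(field_name %in% vars,
              sprintf("rule %s: field '%s' not in form '%s'", rule_id, field_name, form_name))
  if (rule_type == "range") assert_that(!is.null(min) || !is.null(max), "range rule needs min and/or max")
  if (rule_type == "regex") assert_that(!is.null(pattern), "regex rule needs a pattern")
  if (rule_type == "format") assert_that(!is.null(format), "format rule needs a format name")
  x1(store, "INSERT INTO redcap_validation_rules
       (rule_id, project_id, form_name, field_name, rule_type, min, max, pattern, format)
       VALUES (?,?,?,?,?,?,?,?,?)",
     rule_id, project_id, form_name, field_name, rule_type,
     min %||% NA_character_, max %||% NA_character_,
     pattern %||% NA_character_, format %||% NA_character_)
  invisible(rule_id)
}

list_rules <- function(store, project_id) {
  q1(store, "SELECT * FROM redcap_validation_rules WHERE project_id = ? ORDER BY rule_id", project_id)
}

#' Configure a scheduled visit (event)
#'
#' @inheritParams get_form_dictionary
#' @param event_name unique event name within the project.
#' @param day_offset days after the participant's reference date (0 = the
#'   reference day itself).
#' @param window_after grace period in days after the due date before the
#'   visit counts as missed.
#' @param linked_forms forms whose presence marks the visit as carried out.
#' @param order_index panel column position.
#' @export
add_visit_config <- function(store, project_id, event_name, day_offset,
                             window_after = 0L, linked_forms = character(0),
                             order_index = NULL) {
  require_project(store, project_id)
  assert_that(day_offset >= 0, "day_offset must be >= 0")
  assert_that(window_after >= 0, "window_after must be >= 0")
  if (is.null(order_index))
    order_index <- nrow(q1(store, "SELECT 1 FROM redcap_visits_config WHERE project_id = ?", project_id)) + 1L
  x1(store, "INSERT INTO redcap_visits_config
       (project_id, event_name, day_offset, window_after, linked_forms, order_index)
       VALUES (?,?,?,?,?,?)",
     project_id, event_name, as.integer(day_offset), as.integer(window_after),
     paste(linked_forms, collapse = ","), order_index)
  invisible(event_name)
}

list_visit_configs <- function(store, project_id) {
  df <- q1(store, "SELECT * FROM redcap_visits_config WHERE project_id = ? ORDER BY order_index",
           project_id)
  df$linked_forms <- strsplit(df$linked_forms, ",", fixed = TRUE)
  df
}

#' Register an alert recipient
#' @inheritParams get_form_dictionary
#' @param recipient address (email or phone number).
#' @param channel `"email"` or `"sms"`.
#' @export
add_alert_recipient <- function(store, project_id, recipient, channel = c("email", "sms")) {
  channel <- match.arg(channel)
  require_project(store, project_id)
  x1(store, "INSERT OR IGNORE INTO redcap_alerts (project_id, recipient, channel) VALUES (?,?,?)",
     project_id, recipient, channel)
  invisible(recipient)
}

# append to the notification/alert log (transport is recording-only: nothing
# is ever sent over a network)
log_notification <- function(store, project_id, recipient, channel, reason, ref, body, now = NULL) {
  x1(store, "INSERT INTO redcap_alerts_log
       (project_id, recipient, channel, reason, ref, body, sent_at)
       VALUES (?,?,?,?,?,?,?)", project_id, recipient, channel, reason, ref, body, now_ts(now))
}

#' The notification log
#' @inheritParams get_form_dictionary
#' @param reason optional filter.
#' @export
notification_log <- function(store, project_id, reason = NULL) {
  sql <- "SELECT * FROM redcap_alerts_log WHERE project_id = ?"
  params <- list(project_id)
  if (!is.null(reason)) { sql <- paste(sql, "AND reason = ?"); params <- c(params, reason) }
  DBI::dbGetQuery(store$con, paste(sql, "ORDER BY id"), params = params)
}

# snapshot of all mutable state, for atomicity checks in tests
store_snapshot <- function(store) {
  tabs <- c("records", "change_log", "record_locks", "redcap_validation_issues",
            "redcap_alerts_log", "redcap_project")
  lapply(stats::setNames(tabs, tabs), function(t)
    DBI::dbGetQuery(store$con, paste("SELECT * FROM", t)))
}
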