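#' Data-quality engine
#'
#' Three computational submodules: rule-based validation with a query
#' lifecycle (issues open when a value breaks a rule and resolve when it is
#' fixed), longitudinal visit scheduling with a status panel, and alert
#' generation with a one-day dedupe window. Scheduling *when* the engine runs
#' belongs to cron; the library exposes single-shot entry points.
#'
#' @name quality
NULL

#' Evaluate one validation rule against a stored value
#'
#' Range rules compare numerically when both sides parse as numbers,
#' otherwise as ISO dates (text comparison, which is chronological for
#' `YYYY-MM-DD`). Empty values fail only `required` rules: absence of a
#' value is a completeness problem, not a range/format one.
#'
#' @param rule one-row data frame or list with `rule_type` and params
#'   (`min`, `max`, `pattern`, `format`, `field_name`).
#' @param value stored text value (possibly empty).
#' @return list with `pass` (logical) and `message` (non-empty on failure).
#' @export
evaluate_rule <- function(rule, value) {
  v <- cell_chr(value)
  fail <- function(msg) list(pass = FALSE, message = msg)
  pass <- list(pass = TRUE, message = "")
  blank_ok <- function() pass  # only `required` penalizes blanks
  fieldn <- rule$field_name %||% "?"
  switch(rule$rule_type,
    required = if (nzchar(v)) pass else
      fail(sprintf("field '%s' is required but empty", fieldn)),
    range = {
      if (!nzchar(v)) return(blank_ok())
      mn <- if (!is_blank(rule$min)) cell_chr(rule$min)
      mx <- if (!is_blank(rule$max)) cell_chr(rule$max)
      cmp_lt <- function(a, b) {
        na <- num_or_na(a); nb <- num_or_na(b)
        if (!is.na(na) && !is.na(nb)) na < nb else as.character(a) < as.character(b)
      }
      if (!is.null(mn) && cmp_lt(v, mn))
        return(fail(sprintf("field '%s': value %s below minimum %s", fieldn, v, mn)))
      if (!is.null(mx) && cmp_lt(mx, v))
        return(fail(sprintf("field '%s': value %s above maximum %s", fieldn, v, mx)))
      pass
    },
    regex = {
      if (!nzchar(v)) return(blank_ok())
      if (grepl(rule$pattern, v)) pass else
        fail(sprintf("field '%s': value %s does not match pattern %s", fieldn, v, rule$pattern))
    },
    format = {
      if (!nzchar(v)) return(blank_ok())
      re <- switch(cell_chr(rule$format),
        date_ymd = "^\\d{4}-\\d{2}-\\d{2}$",
        datetime_ymd = "^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}$",
        time = "^\\d{2}:\\d{2}$",
        integer = "^-?\\d+$",
        number = "^-?\\d+(\\.\\d+)?$",
        stop(edc_error("edc_bad_rule", paste0("unknown format name: ", rule$format)))
      )
      extra_ok <- TRUE
      if (cell_chr(rule$format) == "date_ymd" && grepl(re, v))
        extra_ok <- !is.na(suppressWarnings(as.Date(v, "%Y-%m-%d")))
      if (grepl(re, v) && extra_ok) pass else
        fail(sprintf("field '%s': value %s is not a valid %s", fieldn, v, rule$format))
    },
    stop(edc_error("edc_bad_rule", paste0("unknown rule type: ", rule$rule_type)))
  )
}

#' Run one validation cycle over a project
#'
#' For every (record, field, rule) whose current value fails and has no open
#' issue, a query is opened and a validation-issue notification is logged to
#' each configured recipient. Open issues whose value now passes are
#' resolved. Running again on unchanged data is a fixed point (`opened = 0`,
#' `resolved = 0`).
#'
#' @param store an `edc_store`.
#' @param project_id project to validate.
#' @param now timestamp for issues and notifications.
#' @return list with counts `opened`, `resolved`, `unchanged` (open issues
#'   still failing).
#' @export
run_validation_cycle <- function(store, project_id, now = NULL) {
  require_project(store, project_id)
  rules <- list_rules(store, project_id)
  recs <- export_records(store, project_id)
  recipients <- q1(store, "SELECT recipient, channel FROM redcap_alerts WHERE project_id = ?", project_id)
  opened <- 0L; resolved <- 0L; unchanged <- 0L

  value_of <- function(rec, field) cell_chr(rec$values[[field]] %||% "")

  open_now <- list_queries(store, project_id, status = "open")
  is_open <- function(record_id, field, rule_id) {
    any(open_now$record_id == record_id & open_now$field_name == field &
          open_now$rule_id == rule_id)
  }

  for (rec in recs) {
    for (i in seq_len(nrow(rules))) {
      rule <- as.list(rules[i, , drop = FALSE])
      res <- evaluate_rule(rule, value_of(rec, rule$field_name))
      already <- is_open(rec$record_id, rule$field_name, rule$rule_id)
      if (!res$pass && !already) {
        open_query(store, project_id, rec$record_id, rule$field_name, rule$rule_id, now = now)
        for (j in seq_len(nrow(recipients)))
          log_notification(store, project_id, recipients$recipient[j], recipients$channel[j],
                           "validation_issue",
                           paste(rec$record_id, rule$field_name, rule$rule_id, sep = ":"),
                           res$message, now = now)
        opened <- opened + 1L
      } else if (!res$pass && already) {
        unchanged <- unchanged + 1L
      } else if (res$pass && already) {
        id <- open_now$issue_id[open_now$record_id == rec$record_id &
                                  open_now$field_name == rule$field_name &
                                  open_now$rule_id == rule$rule_id][1L]
        resolve_query(store, project_id, id, now = now)
        resolved <- resolved + 1L
      }
    }
  }
  list(opened = opened, resolved = resolved, unchanged = unchanged)
}

#' Compute visit due dates from a reference date
#'
#' @param reference_date ISO date (`YYYY-MM-DD`) of inclusion/intervention.
#' @param configs data frame of visit configs (needs `event_name`,
#'   `day_offset`) in panel order, e.g. from an `edc_store`.
#' @return data frame with `event_name` and `due_date` (Date), config order
#'   preserved.
#' @export
schedule_visits <- function(reference_date, configs) {
  ref <- iso_date(reference_date)
  data.frame(event_name = configs$event_name,
             due_date = ref + as.integer(configs$day_offset),
             stringsAsFactors = FALSE)
}

#' Status of a single visit
#'
#' Present data wins; otherwise a visit past its due date plus grace window
#' is missed, and anything earlier is still pending.
#'
#' @param due_date visit due date (ISO text or Date).
#' @param window_after grace days after the due date.
#' @param has_data logical: do the visit's linked forms hold data?
#' @param today evaluation date.
#' @return `"carried_out"`, `"not_carried_out"` or `"pending"`.
#' @export
visit_status <- function(due_date, window_after, has_data, today) {
  if (isTRUE(has_data)) return("carried_out")
  if (iso_date(today) > iso_date(due_date) + as.integer(window_after)) return("not_carried_out")
  "pending"
}

# does the record hold any non-empty value for every linked form at an event?
visit_has_data <- function(store, project_id, record_id, event_name, linked_forms) {
  if (!length(linked_forms) || !nzchar(paste(linked_forms, collapse = "")))
    return(FALSE)
  present <- q1(store, "SELECT DISTINCT field_name FROM records
                  WHERE project_id = ? AND record_id = ? AND event = ? AND value <> ''",
                project_id, record_id, event_name)$field_name
  for (fm in linked_forms) {
    universe <- form_field_universe(get_form_dictionary(store, project_id, fm))
    if (!length(intersect(universe, present))) return(FALSE)
  }
  TRUE
}

#' Build the visits panel
#'
#' One row per participant, one column per configured visit, computed live
#' from the store (never cached). A participant whose reference-date field is
#' empty contributes no cells and is listed in the `missing_reference`
#' attribute instead of being silently dropped.
#'
#' @inheritParams run_validation_cycle
#' @param today evaluation date (ISO text or Date).
#' @return data frame of cells: `record_id`, `event_name`, `due_date`,
#'   `status`; participants lacking a reference date in
#'   `attr(,"missing_reference")`.
#' @export
build_visits_panel <- function(store, project_id, today) {
  require_project(store, project_id)
  cfg <- list_visit_configs(store, project_id)
  ref_field <- q1(store, "SELECT ref_date_field FROM redcap_project WHERE project_id = ?",
                  project_id)$ref_date_field[1L]
  assert_that(!is.na(ref_field) && nzchar(ref_field %||% ""),
              "project has no reference-date field configured")
  recs <- export_records(store, project_id)
  ids <- unique(vapply(recs, function(r) r$record_id, character(1)))
  cells <- list()
  missing_ref <- character(0)
  for (id in ids) {
    ref <- q1(store, "SELECT value FROM records WHERE project_id = ? AND record_id = ? AND field_name = ?
                ORDER BY event LIMIT 1", project_id, id, ref_field)
    refv <- if (nrow(ref)) cell_chr(ref$value[1L]) else ""
    due <- if (nzchar(refv))
      tryCatch(schedule_visits(refv, cfg), error = function(e) NULL)
    # an empty or unparseable reference date excludes the participant from
    # the grid but keeps them visible in the missing_reference attribute
    if (is.null(due) || !nzchar(refv)) {
      missing_ref <- c(missing_ref, id)
      next
    }
    for (i in seq_len(nrow(cfg))) {
      hd <- visit_has_data(store, project_id, id, cfg$event_name[i], cfg$linked_forms[[i]])
      cells[[length(cells) + 1L]] <- data.frame(
        record_id = id, event_name = cfg$event_name[i],
        due_date = as.character(due$due_date[i]),
        status = visit_status(due$due_date[i], cfg$window_after[i], hd, today),
        stringsAsFactors = FALSE)
    }
  }
  panel <- if (length(cells)) do.call(rbind, cells) else
    data.frame(record_id = character(0), event_name = character(0),
               due_date = character(0), status = character(0), stringsAsFactors = FALSE)
  attr(panel, "missing_reference") <- missing_ref
  panel
}

#' Write a visits panel as CSV (rows = records, columns = events)
#'
#' @param panel output of [build_visits_panel()].
#' @param path output path.
#' @export
write_panel_csv <- function(panel, path) {
  ids <- unique(panel$record_id)
  evs <- unique(panel$event_name)
  wide <- data.frame(record_id = ids, stringsAsFactors = FALSE)
  for (ev in evs)
    wide[[ev]] <- vapply(ids, function(id) {
      s <- panel$status[panel$record_id == id & panel$event_name == ev]
      if (length(s)) s[1L] else ""
    }, character(1))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Generate alerts for open queries and missed visits
#'
#' One notification per (recipient, reason instance); an identical alert
#' already logged on the same calendar day is suppressed (dedupe window), so
#' the periodic runner can fire as often as it likes without spamming.
#'
#' @inheritParams run_validation_cycle
#' @param now evaluation timestamp (`YYYY-MM-DD` or `YYYY-MM-DD HH:MM:SS`).
#' @return data frame of the notifications sent this call.
#' @export
generate_alerts <- function(store, project_id, now = NULL) {
  require_project(store, project_id)
  ts <- now_ts(now)
  day <- substr(ts, 1, 10)
  recipients <- q1(store, "SELECT recipient, channel FROM redcap_alerts WHERE project_id = ?", project_id)
  sent <- 0L
  emit <- function(recipient, channel, reason, ref, body) {
    dup <- q1(store, "SELECT 1 FROM redcap_alerts_log
                WHERE project_id = ? AND recipient = ? AND reason = ? AND ref = ?
                  AND substr(sent_at, 1, 10) = ? LIMIT 1",
              project_id, recipient, reason, ref, day)
    if (nrow(dup)) return(invisible(NULL))
    log_notification(store, project_id, recipient, channel, reason, ref, body, now = ts)
    sent <<- sent + 1L
  }
  open_q <- list_queries(store, project_id, status = "open")
  for (i in seq_len(nrow(open_q))) {
    ref <- paste0("query:", open_q$issue_id[i])
    for (j in seq_len(nrow(recipients)))
      emit(recipients$recipient[j], recipients$channel[j], "open_query", ref,
           sprintf("Query %s on record %s field %s is awaiting an answer.",
                   open_q$issue_id[i], open_q$record_id[i], open_q$field_name[i]))
  }
  cfg <- list_visit_configs(store, project_id)
  if (nrow(cfg)) {
    panel <- tryCatch(build_visits_panel(store, project_id, today = day), error = function(e) NULL)
    if (!is.null(panel)) {
      overdue <- panel[panel$status == "not_carried_out", , drop = FALSE]
      for (i in seq_len(nrow(overdue))) {
        ref <- paste0("visit:", overdue$record_id[i], ":", overdue$event_name[i])
        for (j in seq_len(nrow(recipients)))
          emit(recipients$recipient[j], recipients$channel[j], "pending_visit", ref,
               sprintf("Visit %s for record %s was due %s and has no data.",
                       overdue$event_name[i], overdue$record_id[i], overdue$due_date[i]))
      }
    }
  }
  log <- notification_log(store, project_id)
  utils::tail(log, sent)
}
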