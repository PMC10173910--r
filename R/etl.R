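#' ETL processor
#'
#' The pipeline from a field-submission payload (the JSON POSTed by the
#' collection platform's REST service) to a stored research record:
#' authenticate, clean platform metadata out of the payload, expand
#' multiple-selection answers into checkbox columns, resolve the record ID
#' from the participant identifier, import, then run the configured post-save
#' actions (duplicate check, record lock, notifications) in a fixed order.
#' The whole pipeline is transactional: any failure leaves the store exactly
#' as it was.
#'
#' @name etl
NULL

# payload keys that are platform plumbing, not data; configurable via the
# `metadata_keys` argument of parse_submission
DEFAULT_METADATA_KEYS <- c("start", "end", "today", "deviceid", "username",
                           "phonenumber", "simserial", "subscriberid")
DEFAULT_METADATA_PREFIXES <- c("_", "meta/", "formhub/")

#' Check submission credentials against a project
#'
#' Rejection is deliberately uninformative: the caller learns only that the
#' pair did not match, never which part failed.
#'
#' @param store an `edc_store`.
#' @param project_id registered project.
#' @param username,password basic-auth pair supplied with the POST.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
authenticate <- function(store, project_id, username, password) {
  require_project(store, project_id)
  r <- q1(store, "SELECT username, password FROM redcap_project WHERE project_id = ?", project_id)
  identical(cell_chr(username), r$username[1L]) && identical(cell_chr(password), r$password[1L])
}

#' Clean a submission payload
#'
#' Removes platform metadata (keys starting with `_`, `meta/`, `formhub/`,
#' and the fixed key list `start`, `end`, `today`, `deviceid`, ...), strips
#' group prefixes (`group/field` -> `field`), lower-cases names, and keeps
#' only keys that resolve to instrument fields.
#'
#' @param payload named list as posted (field answers plus platform entries).
#' @param instr the target `edc_instrument`.
#' @param metadata_keys,metadata_prefixes override the default blocklist.
#' @return named list of cleaned field values (all character).
#' @export
parse_submission <- function(payload, instr,
                             metadata_keys = DEFAULT_METADATA_KEYS,
                             metadata_prefixes = DEFAULT_METADATA_PREFIXES) {
  assert_that(length(payload) > 0, "empty payload")
  keys <- names(payload)
  keep <- !vapply(keys, function(k) {
    k %in% metadata_keys || any(startsWith(k, metadata_prefixes))
  }, logical(1))
  payload <- payload[keep]
  # strip group prefixes to terminal names
  names(payload) <- vapply(names(payload), function(k) {
    tolower(utils::tail(strsplit(k, "/", fixed = TRUE)[[1L]], 1L))
  }, character(1))
  known <- names(payload) %in% field_names(instr)
  payload <- payload[known]
  if (!length(payload))
    stop(edc_error("edc_empty_after_cleaning",
                   "payload contains no instrument data after cleaning"))
  lapply(payload, function(v) cell_chr(v))
}

#' Transform cleaned values into a flat record
#'
#' Multiple-selection answers arrive as space-separated code lists (the
#' XLSForm convention) and are expanded to one `name___code` column per
#' option, `"1"` for listed codes and `"0"` otherwise. Codes outside the
#' field's choice list are flagged in the `flags` attribute, not fatal.
#' Scalar values pass through as text.
#'
#' @param cleaned output of [parse_submission()].
#' @param instr the target `edc_instrument`.
#' @param record_id resolved record id.
#' @param event optional event name.
#' @return a [flat_record()]; unknown-code flags in `attr(,"flags")`.
#' @export
transform_record <- function(cleaned, instr, record_id = NA_character_, event = NULL) {
  unknown <- setdiff(names(cleaned), field_names(instr))
  if (length(unknown))
    stop(edc_error("edc_unknown_field",
                   paste0("unknown field(s): ", paste(unknown, collapse = ", "))))
  values <- list()
  flags <- character(0)
  for (fn in names(cleaned)) {
    f <- get_field(instr, fn)
    v <- cell_chr(cleaned[[fn]])
    if (f$type == "select_multiple") {
      cl <- instr$choice_lists[[f$choice_list]]
      picked <- if (nzchar(v)) strsplit(v, "\\s+")[[1L]] else character(0)
      bad <- setdiff(picked, cl$codes)
      if (length(bad))
        flags <- c(flags, sprintf("field '%s': code(s) not in choice list: %s",
                                  fn, paste(bad, collapse = ", ")))
      for (code in cl$codes)
        values[[paste0(fn, "___", code)]] <- if (code %in% picked) "1" else "0"
    } else {
      values[[fn]] <- v
    }
  }
  rec <- flat_record(record_id, values, event = event)
  attr(rec, "flags") <- flags
  rec
}

#' Resolve the record ID for an incoming submission
#'
#' Submissions to the project's first (entry) form may create participants: an
#' unseen participant identifier draws a fresh record ID. Submissions to any
#' other form may only attach to an existing participant, found by searching
#' the stored records for the participant-identifier field; an unknown
#' participant raises `UnresolvedParticipant` (the caller parks the
#' submission).
#'
#' @inheritParams authenticate
#' @param form_name registered form the submission targets.
#' @param participant_value value of the participant-identifier field.
#' @return list with `record_id` (text) and `created_new` (logical).
#' @export
resolve_record <- function(store, project_id, form_name, participant_value) {
  require_project(store, project_id)
  fr <- q1(store, "SELECT is_first FROM redcap_forms WHERE project_id = ? AND form_name = ?",
           project_id, form_name)
  if (!nrow(fr))
    stop(edc_error("edc_unknown_form", paste0("form not registered: ", form_name)))
  pid_field <- participant_field(store, project_id)
  assert_that(!is.null(pid_field), "no participant_id field designated in form_metadata")
  hit <- q1(store, "SELECT record_id FROM records
              WHERE project_id = ? AND field_name = ? AND value = ?
              ORDER BY CAST(record_id AS INTEGER) LIMIT 1",
            project_id, pid_field, cell_chr(participant_value))
  if (nrow(hit)) return(list(record_id = hit$record_id[1L], created_new = FALSE))
  if (fr$is_first[1L] == 1L)
    return(list(record_id = next_record_id(store, project_id), created_new = TRUE))
  stop(edc_error("edc_unresolved_participant",
                 sprintf("participant '%s' unknown and form '%s' is not the entry form",
                         participant_value, form_name)))
}

#' Default post-save settings
#'
#' @param event event name assigned to the submission (the platform payload
#'   carries none).
#' @param check_duplicate,lock,notify_team,notify_respondent toggles for the
#'   post-save actions, applied in this fixed order.
#' @param team_channel notification channel for the research team.
#' @param respondent address/identifier used to notify the respondent.
#' @export
etl_settings <- function(event = NULL, check_duplicate = TRUE, lock = FALSE,
                         notify_team = FALSE, notify_respondent = FALSE,
                         team_channel = "email", respondent = NULL) {
  list(event = event, check_duplicate = check_duplicate, lock = lock,
       notify_team = notify_team, notify_respondent = notify_respondent,
       team_channel = team_channel, respondent = respondent)
}

#' Process one submission end-to-end
#'
#' Pipeline: authenticate -> [parse_submission()] -> [transform_record()] ->
#' [resolve_record()] -> [import_record()] -> post-save actions. Duplicate
#' handling: an identical resubmission for the same (participant, form,
#' event) is flagged and skipped (idempotent); a differing resubmission is
#' imported as an update and opens a data query. Failure at any stage rolls
#' the store back; authentication is checked before anything is persisted.
#'
#' @inheritParams resolve_record
#' @param payload named list (parsed JSON) as posted.
#' @param credentials list with `username` and `password`.
#' @param settings an [etl_settings()] list.
#' @param instr instrument for the form; defaults to re-deriving it from the
#'   registered dictionary.
#' @param now timestamp for log entries.
#' @return a process outcome: list with `record_id`, `created_new`,
#'   `actions_performed`, `issues`.
#' @export
process_submission <- function(store, project_id, form_name, payload, credentials,
                               settings = etl_settings(), instr = NULL, now = NULL) {
  if (!authenticate(store, project_id, credentials$username %||% "", credentials$password %||% ""))
    stop(edc_error("edc_auth_failed", "authentication failed"))
  if (is.null(instr))
    instr <- dictionary_to_instrument(get_form_dictionary(store, project_id, form_name))

  DBI::dbExecute(store$con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(store$con, "ROLLBACK"), add = TRUE)

  outcome <- tryCatch({
    cleaned <- parse_submission(payload, instr)
    pid_field <- participant_field(store, project_id)
    assert_that(!is.null(pid_field), "no participant_id field designated in form_metadata")
    assert_that(pid_field %in% names(cleaned),
                paste0("submission lacks the participant identifier field '", pid_field, "'"))
    res <- resolve_record(store, project_id, form_name, cleaned[[pid_field]])
    rec <- transform_record(cleaned, instr, record_id = res$record_id, event = settings$event)
    actions <- character(0)
    issues <- attr(rec, "flags") %||% character(0)

    do_import <- TRUE
    if (isTRUE(settings$check_duplicate) && !res$created_new) {
      stored <- export_records(store, project_id, record_id = res$record_id,
                               form_name = form_name, event = settings$event %||% "")
      if (length(stored)) {
        old <- stored[[1L]]$values
        new <- rec$values
        same <- length(old) == length(new) && setequal(names(old), names(new)) &&
          all(vapply(names(new), function(k) identical(as.character(old[[k]]), as.character(new[[k]])), logical(1)))
        if (same) {
          actions <- c(actions, "duplicate_flagged")
          do_import <- FALSE
        } else if (length(old)) {
          # changed resubmission: import as update, but open a query for review
          qid <- open_query(store, project_id, res$record_id, pid_field,
                            "duplicate_divergence", now = now)
          issues <- c(issues, sprintf("divergent resubmission; query %s opened", qid))
        }
      }
    }
    if (do_import) import_record(store, project_id, form_name, rec, now = now)
    if (isTRUE(settings$lock) && do_import) {
      lock_record(store, project_id, res$record_id, form_name)
      actions <- c(actions, "locked")
    }
    if (isTRUE(settings$notify_team)) {
      team <- q1(store, "SELECT recipient, channel FROM redcap_alerts WHERE project_id = ?", project_id)
      for (i in seq_len(nrow(team)))
        log_notification(store, project_id, team$recipient[i], team$channel[i],
                         "submission_received",
                         paste0(form_name, ":", res$record_id),
                         sprintf("New submission for record %s (form %s)", res$record_id, form_name),
                         now = now)
      actions <- c(actions, "notified_team")
    }
    if (isTRUE(settings$notify_respondent) && !is.null(settings$respondent)) {
      log_notification(store, project_id, settings$respondent, "email",
                       "submission_receipt",
                       paste0(form_name, ":", res$record_id),
                       "Thank you, your submission was received.", now = now)
      actions <- c(actions, "notified_respondent")
    }
    list(record_id = res$record_id, created_new = res$created_new,
         actions_performed = actions, issues = issues)
  }, edc_unresolved_participant = function(e) e, error = function(e) e)

  if (inherits(outcome, "error")) {
    DBI::dbExecute(store$con, "ROLLBACK")
    ok <- TRUE  # disarm on.exit rollback (already done)
    if (inherits(outcome, "edc_unresolved_participant")) {
      # park the submission for manual resolution; this log lives outside the
      # transactional record state on purpose
      x1(store, "INSERT INTO parked_submissions (project_id, form_name, payload, reason, parked_at)
           VALUES (?,?,?,?,?)", project_id, form_name,
         as.character(jsonlite::toJSON(payload, auto_unbox = TRUE)),
         conditionMessage(outcome), now_ts(now))
    }
    stop(outcome)
  }
  DBI::dbExecute(store$con, "COMMIT")
  ok <- TRUE
  outcome
}

#' Record-change monitor (data entry trigger)
#'
#' Call when a record was edited directly in the capture system: exports the
#' record's current state and, if it differs from the last logged snapshot,
#' appends a change-log entry. A no-op edit appends nothing.
#'
#' @inheritParams resolve_record
#' @param record_id edited record.
#' @param now timestamp.
#' @return the new change-log entry (one-row data frame), or `NULL` for a
#'   no-op edit.
#' @export
on_record_changed <- function(store, project_id, record_id, form_name, now = NULL) {
  require_project(store, project_id)
  recs <- export_records(store, project_id, record_id = record_id, form_name = form_name)
  if (!length(recs))
    stop(edc_error("edc_unknown_record", paste0("unknown record: ", record_id)))
  current <- recs[[1L]]$values
  log <- change_log(store, project_id, record_id = record_id)
  log <- log[log$form_name == form_name, , drop = FALSE]
  if (nrow(log)) {
    # reconstruct last known state from the cumulative snapshots
    state <- list()
    for (i in seq_len(nrow(log))) {
      snap <- jsonlite::fromJSON(log$snapshot[i])
      for (k in names(snap)) state[[k]] <- as.character(snap[[k]])
    }
    same <- setequal(names(state), names(current)) &&
      all(vapply(names(current), function(k) identical(state[[k]], as.character(current[[k]])), logical(1)))
    if (same) return(invisible(NULL))
  }
  x1(store, "INSERT INTO change_log (project_id, record_id, form_name, timestamp, snapshot)
       VALUES (?,?,?,?,?)", project_id, record_id, form_name, now_ts(now),
     as.character(jsonlite::toJSON(current, auto_unbox = TRUE)))
  entry <- change_log(store, project_id, record_id = record_id)
  entry[nrow(entry), , drop = FALSE]
}
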