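test_that("authentication accepts only the exact pair, opaquely", {
  ts <- setup_toy_store(1)
  withr::defer(close_store(ts$store))
  expect_true(authenticate(ts$store, "p1", "etl", "secret"))
  expect_false(authenticate(ts$store, "p1", "etl", "wrong"))
  expect_false(authenticate(ts$store, "p1", "", ""))
  expect_error(authenticate(ts$store, "nope", "a", "b"), class = "edc_unknown_project")
})

test_that("payload cleaning removes platform metadata and strips group prefixes", {
  instr <- make_toy_project(1)$instrument
  cleaned <- parse_submission(list(`_id` = 5, `_uuid` = "u", `meta/instanceID` = "m",
                                   `formhub/uuid` = "f", start = "t", end = "t",
                                   age = "34"), instr)
  expect_identical(cleaned, list(age = "34"))
  cleaned2 <- parse_submission(list(`grp/sex` = "1", `deep/er/age` = "40"), instr)
  expect_identical(cleaned2, list(sex = "1", age = "40"))
  expect_error(parse_submission(list(`_id` = 1, start = "x"), instr),
               class = "edc_empty_after_cleaning")
})

test_that("checkbox answers expand by set membership; stray codes are flagged", {
  instr <- make_toy_project(1)$instrument
  rec <- transform_record(list(checkbox_symptoms = "cough fever"), instr, "1")
  expect_identical(rec$values, list(checkbox_symptoms___cough = "1",
                                    checkbox_symptoms___fever = "1",
                                    checkbox_symptoms___chills = "0"))
  rec0 <- transform_record(list(checkbox_symptoms = ""), instr, "1")
  expect_true(all(unlist(rec0$values) == "0"))
  recb <- transform_record(list(checkbox_symptoms = "cough wheeze"), instr, "1")
  expect_match(attr(recb, "flags"), "wheeze")
  expect_identical(recb$values$checkbox_symptoms___cough, "1")
  # scalar values pass through untouched
  expect_identical(transform_record(list(age = "34"), instr, "1")$values$age, "34")
  expect_error(transform_record(list(ghost = "1"), instr, "1"),
               class = "edc_unknown_field")
})

test_that("record resolution: entry form creates, later forms only look up", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  r1 <- resolve_record(st, "p1", "intake", "P-001")
  expect_identical(r1, list(record_id = "1", created_new = TRUE))
  import_record(st, "p1", "intake", flat_record("1", list(pid = "P-001")))
  expect_identical(resolve_record(st, "p1", "intake", "P-001"),
                   list(record_id = "1", created_new = FALSE))
  expect_identical(resolve_record(st, "p1", "treatment", "P-001")$record_id, "1")
  expect_error(resolve_record(st, "p1", "treatment", "P-999"),
               class = "edc_unresolved_participant")
})

test_that("full pipeline performs the configured actions in order", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  sims <- simulate_submissions(ts$fixture, 1, seed = 11, violation_rate = 0)
  out <- process_submission(st, "p1", "intake", sims$payloads[[1]], toy_creds,
                            etl_settings(event = "inclusion", lock = TRUE,
                                         notify_team = TRUE, notify_respondent = TRUE,
                                         respondent = "p@x.org"))
  expect_true(out$created_new)
  expect_identical(out$actions_performed, c("locked", "notified_team", "notified_respondent"))
  expect_true(is_locked(st, "p1", out$record_id, "intake"))
  log <- notification_log(st, "p1")
  expect_setequal(unique(log$reason), c("submission_received", "submission_receipt"))

  # end-to-end conservation: every cleaned answer appears in the export
  instr <- ts$fixture$instrument
  cleaned <- parse_submission(sims$payloads[[1]], instr)
  stored <- export_records(st, "p1", record_id = out$record_id)[[1]]$values
  for (k in names(cleaned)) {
    f <- Filter(function(g) g$name == k, instr$fields)[[1]]
    if (f$type == "select_multiple") {
      picked <- strsplit(cleaned[[k]], " +")[[1]]
      for (code in picked)
        expect_identical(stored[[paste0(k, "___", code)]], "1")
    } else {
      expect_identical(stored[[k]], cleaned[[k]])
    }
  }
})

test_that("identical resubmission is flagged, divergent one updates + opens a query", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  sims <- simulate_submissions(ts$fixture, 1, seed = 5, violation_rate = 0)
  p <- sims$payloads[[1]]
  o1 <- process_submission(st, "p1", "intake", p, toy_creds, etl_settings(event = "inclusion"))
  o2 <- process_submission(st, "p1", "intake", p, toy_creds, etl_settings(event = "inclusion"))
  expect_false(o2$created_new)
  expect_true("duplicate_flagged" %in% o2$actions_performed)
  expect_length(export_records(st, "p1"), 1)           # idempotent
  expect_identical(nrow(change_log(st, "p1")), 1L)     # no second mutation

  p$age <- as.character(as.integer(p$age) + 1L)
  o3 <- process_submission(st, "p1", "intake", p, toy_creds, etl_settings(event = "inclusion"))
  expect_false("duplicate_flagged" %in% o3$actions_performed)
  expect_match(o3$issues, "divergent")
  expect_identical(nrow(list_queries(st, "p1", status = "open")), 1L)
  expect_identical(export_records(st, "p1")[[1]]$values$age, p$age)
})

test_that("failures are atomic: store state is untouched", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  sims <- simulate_submissions(ts$fixture, 2, seed = 8, violation_rate = 0)
  process_submission(st, "p1", "intake", sims$payloads[[1]], toy_creds,
                     etl_settings(event = "inclusion"))
  snap <- edcbridge:::store_snapshot(st)

  # bad credentials abort before anything is read or persisted
  expect_error(process_submission(st, "p1", "intake", sims$payloads[[2]],
                                  list(username = "etl", password = "nope")),
               class = "edc_auth_failed")
  expect_identical(edcbridge:::store_snapshot(st), snap)

  # mid-pipeline failure (metadata-only payload) rolls back cleanly
  expect_error(process_submission(st, "p1", "intake", list(`_id` = 1, start = "x"),
                                  toy_creds, etl_settings(event = "inclusion")),
               class = "edc_empty_after_cleaning")
  expect_identical(edcbridge:::store_snapshot(st), snap)

  # unresolved participant on a non-entry form: rolled back but parked
  expect_error(process_submission(st, "p1", "followup",
                                  list(pid = "P-404", weight = "70.0"),
                                  toy_creds, etl_settings()),
               class = "edc_unresolved_participant")
  expect_identical(edcbridge:::store_snapshot(st), snap)
  parked <- DBI::dbGetQuery(st$con, "SELECT * FROM parked_submissions")
  expect_identical(nrow(parked), 1L)
})

test_that("the change monitor logs real edits and skips no-ops", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  import_record(st, "p1", "intake", flat_record("1", list(pid = "P-001", age = "40")),
                now = "2023-01-01 08:00:00")
  n0 <- nrow(change_log(st, "p1"))
  expect_null(on_record_changed(st, "p1", "1", "intake", now = "2023-01-01 09:00:00"))
  expect_identical(nrow(change_log(st, "p1")), n0)

  # direct edit outside import_record's logging path
  DBI::dbExecute(st$con, "UPDATE records SET value = '41' WHERE field_name = 'age'")
  entry <- on_record_changed(st, "p1", "1", "intake", now = "2023-01-01 10:00:00")
  expect_identical(jsonlite::fromJSON(entry$snapshot)$age, "41")
  expect_identical(nrow(change_log(st, "p1")), n0 + 1L)
  expect_error(on_record_changed(st, "p1", "404", "intake"), class = "edc_unknown_record")
})
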