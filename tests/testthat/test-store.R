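test_that("record IDs start at 1, increase strictly and are never reused", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  expect_identical(next_record_id(st, "p1"), "1")
  expect_identical(next_record_id(st, "p1"), "2")
  expect_identical(next_record_id(st, "p1"), "3")
  expect_identical(next_record_id(st, "p1"), "4")
  expect_error(next_record_id(st, "ghost"), class = "edc_unknown_project")
})

test_that("import/export round trips and upserts append to the change log", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  rec <- flat_record("1", list(pid = "P-001", age = "40", sex = "1"), event = "inclusion")
  import_record(st, "p1", "intake", rec, now = "2023-01-01 10:00:00")
  out <- export_records(st, "p1", record_id = "1")
  expect_length(out, 1)
  expect_identical(out[[1]]$values$age, "40")
  expect_identical(out[[1]]$event, "inclusion")

  # second import to the same key: one stored record, two change-log entries
  rec2 <- flat_record("1", list(age = "41"), event = "inclusion")
  import_record(st, "p1", "intake", rec2, now = "2023-01-02 10:00:00")
  expect_length(export_records(st, "p1"), 1)
  log <- change_log(st, "p1")
  expect_identical(nrow(log), 2L)
  expect_true(!is.unsorted(log$timestamp))  # ISO timestamps sort lexicographically
  # the second snapshot carries exactly the changed value
  expect_identical(jsonlite::fromJSON(log$snapshot[2]), list(age = "41"))

  # no-op import appends nothing (conservation: log length = mutating imports)
  import_record(st, "p1", "intake", rec2)
  expect_identical(nrow(change_log(st, "p1")), 2L)

  expect_error(import_record(st, "p1", "intake", flat_record("1", list(ghost = "x"))),
               "ghost", class = "edc_unknown_field")
})

test_that("locks are idempotent and locked records are immutable", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  import_record(st, "p1", "intake", flat_record("1", list(pid = "P-001", age = "40")))
  lock_record(st, "p1", "1", "intake")
  expect_true(is_locked(st, "p1", "1", "intake"))
  expect_silent(lock_record(st, "p1", "1", "intake"))
  before <- export_records(st, "p1", record_id = "1")
  expect_error(import_record(st, "p1", "intake", flat_record("1", list(age = "99"))),
               class = "edc_locked_record")
  expect_identical(export_records(st, "p1", record_id = "1"), before)
  unlock_record(st, "p1", "1", "intake")
  import_record(st, "p1", "intake", flat_record("1", list(age = "99")))
  expect_identical(export_records(st, "p1", record_id = "1")[[1]]$values$age, "99")
  expect_error(lock_record(st, "p1", "404", "intake"), class = "edc_unknown_record")
})

test_that("query lifecycle: open once, resolve once, re-open fresh", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  id1 <- open_query(st, "p1", "1", "age", "r_age_range", now = "2023-01-01 08:00:00")
  expect_error(open_query(st, "p1", "1", "age", "r_age_range"), "already")
  resolve_query(st, "p1", id1, now = "2023-01-02 08:00:00")
  q <- list_queries(st, "p1")
  expect_identical(q$status, "resolved")
  expect_false(is.na(q$resolved_at))
  expect_error(resolve_query(st, "p1", id1), class = "edc_illegal_transition")
  expect_error(resolve_query(st, "p1", 999L), class = "edc_unknown_issue")
  id2 <- open_query(st, "p1", "1", "age", "r_age_range")
  expect_gt(id2, id1)
})

test_that("open-issue uniqueness survives interleaved validation cycles", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  import_record(st, "p1", "intake",
                flat_record("1", list(pid = "P-001", age = "300", sex = "")),
                now = "2023-01-01 08:00:00")
  for (i in 1:4) run_validation_cycle(st, "p1", now = sprintf("2023-01-0%d 09:00:00", i))
  open_q <- list_queries(st, "p1", status = "open")
  key <- paste(open_q$record_id, open_q$field_name, open_q$rule_id)
  expect_false(any(duplicated(key)))
  expect_identical(nrow(open_q), 2L)  # age range + sex required
})

test_that("form registration enforces one entry form and unique forms", {
  st <- open_store()
  withr::defer(close_store(st))
  register_project(st, "p", api_token = "t")
  dd <- convert_instrument(treatment_instrument())
  register_form(st, "p", dd, is_first = TRUE)
  expect_error(register_form(st, "p", dd), "already registered")
  dd2 <- convert_instrument(instrument("other", list(field_def("x", "text"))))
  expect_error(register_form(st, "p", dd2, is_first = TRUE), "first form")
  expect_error(register_project(st, "p"), "already registered")
  expect_error(register_project(st, "p2", api_token = ""), "non-empty")
})
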