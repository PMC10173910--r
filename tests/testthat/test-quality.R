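test_that("rule evaluation matches a brute-force boundary sweep", {
  rng <- list(rule_type = "range", field_name = "age", min = "10", max = "120")
  # boundary values min-1, min, max, max+1 plus interior, against a
  # straightforward numeric check
  for (v in c(9, 10, 11, 65, 119, 120, 121)) {
    expected <- v >= 10 && v <= 120
    expect_identical(evaluate_rule(rng, as.character(v))$pass, expected, info = v)
  }
  expect_false(evaluate_rule(rng, "250")$pass)
  expect_match(evaluate_rule(rng, "250")$message, "age.*250.*120")
  # one-sided ranges
  expect_true(evaluate_rule(list(rule_type = "range", field_name = "x", min = "0", max = NULL), "5")$pass)
  # date ranges compare chronologically
  dr <- list(rule_type = "range", field_name = "d", min = "2023-01-01", max = "2023-12-31")
  expect_true(evaluate_rule(dr, "2023-06-15")$pass)
  expect_false(evaluate_rule(dr, "2024-01-01")$pass)
  # blanks only fail `required`
  expect_true(evaluate_rule(rng, "")$pass)
  expect_false(evaluate_rule(list(rule_type = "required", field_name = "sex"), "")$pass)
  expect_true(evaluate_rule(list(rule_type = "required", field_name = "sex"), "1")$pass)
})

test_that("format and regex rules check textual shape", {
  fmt <- function(f) list(rule_type = "format", field_name = "x", format = f)
  expect_true(evaluate_rule(fmt("date_ymd"), "2023-01-31")$pass)
  expect_false(evaluate_rule(fmt("date_ymd"), "31/01/2023")$pass)
  expect_false(evaluate_rule(fmt("date_ymd"), "2023-13-45")$pass)  # not a real date
  expect_true(evaluate_rule(fmt("time"), "08:30")$pass)
  expect_true(evaluate_rule(fmt("integer"), "-12")$pass)
  expect_false(evaluate_rule(fmt("integer"), "1.5")$pass)
  expect_true(evaluate_rule(fmt("number"), "1.5")$pass)
  expect_error(evaluate_rule(fmt("bogus"), "x"), class = "edc_bad_rule")
  rx <- list(rule_type = "regex", field_name = "pid", pattern = "^P-\\d{3}$")
  expect_true(evaluate_rule(rx, "P-001")$pass)
  expect_false(evaluate_rule(rx, "001")$pass)
})

test_that("validation cycles open, hold and resolve issues to a fixed point", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  import_record(st, "p1", "intake",
                flat_record("1", list(pid = "P-001", age = "250", sex = "1")),
                now = "2023-02-01 08:00:00")
  r1 <- run_validation_cycle(st, "p1", now = "2023-02-01 09:00:00")
  expect_identical(r1, list(opened = 1L, resolved = 0L, unchanged = 0L))
  # opening an issue alerts the configured recipients
  expect_identical(nrow(notification_log(st, "p1", reason = "validation_issue")), 1L)

  r2 <- run_validation_cycle(st, "p1", now = "2023-02-01 15:00:00")
  expect_identical(r2, list(opened = 0L, resolved = 0L, unchanged = 1L))

  import_record(st, "p1", "intake", flat_record("1", list(age = "50")),
                now = "2023-02-02 08:00:00")
  r3 <- run_validation_cycle(st, "p1", now = "2023-02-02 09:00:00")
  expect_identical(r3$resolved, 1L)
  expect_identical(nrow(list_queries(st, "p1", status = "open")), 0L)
})

test_that("visit schedules are plain calendar-day offsets in config order", {
  cfg <- data.frame(event_name = c("d0", "w1", "m1", "m3"),
                    day_offset = c(0L, 7L, 30L, 90L))
  sch <- schedule_visits("2023-01-01", cfg)
  expect_identical(as.character(sch$due_date),
                   c("2023-01-01", "2023-01-08", "2023-01-31", "2023-04-01"))
  expect_true(all(diff(sch$due_date) > 0))
  expect_identical(schedule_visits("2023-01-01", cfg[1, ])$due_date, as.Date("2023-01-01"))
  expect_error(schedule_visits("bogus", cfg), "invalid ISO date")
})

test_that("visit status: data wins, then the due+window cutoff", {
  expect_identical(visit_status("2020-01-01", 0, TRUE, "2019-01-01"), "carried_out")
  expect_identical(visit_status("2023-01-31", 0, FALSE, "2023-03-01"), "not_carried_out")
  expect_identical(visit_status("2023-01-31", 0, FALSE, "2023-01-31"), "pending")
  expect_identical(visit_status("2023-01-31", 7, FALSE, "2023-02-05"), "pending")
  expect_identical(visit_status("2023-01-31", 7, FALSE, "2023-02-08"), "not_carried_out")
})

test_that("the panel has participants x visits cells matching the status oracle", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  sims <- simulate_submissions(ts$fixture, 3, seed = 21, violation_rate = 0,
                               missingness = 0)
  ingest_payloads(st, sims$payloads)
  today <- "2023-02-20"
  panel <- build_visits_panel(st, "p1", today)
  cfg <- edcbridge:::list_visit_configs(st, "p1")
  expect_identical(nrow(panel), 3L * nrow(cfg))

  # pointwise agreement with the visit_status oracle
  for (i in seq_len(nrow(panel))) {
    row <- panel[i, ]
    has_data <- row$event_name == "inclusion"  # all data was ingested at inclusion
    w <- cfg$window_after[cfg$event_name == row$event_name]
    expect_identical(row$status, visit_status(row$due_date, w, has_data, today),
                     info = paste(row$record_id, row$event_name))
  }

  # a participant with data in every linked form/event shows a green row
  rid <- panel$record_id[1]
  for (ev in cfg$event_name[-1])
    import_record(st, "p1", "intake", flat_record(rid, list(weight = "70"), event = ev))
  panel2 <- build_visits_panel(st, "p1", today)
  expect_true(all(panel2$status[panel2$record_id == rid] == "carried_out"))

  # participants without a reference date are reported, not dropped silently
  import_record(st, "p1", "intake", flat_record("99", list(pid = "P-099"), event = "inclusion"))
  panel3 <- build_visits_panel(st, "p1", today)
  expect_identical(attr(panel3, "missing_reference"), "99")
  expect_identical(nrow(panel3), 3L * nrow(cfg))
})

test_that("a 21-visit configuration yields 42 cells for two participants", {
  st <- open_store()
  withr::defer(close_store(st))
  register_project(st, "piv", ref_date_field = "ref_date")
  intake <- instrument("intake", list(
    field_def("pid", "text", participant_id = TRUE),
    field_def("ref_date", "date")))
  register_form(st, "piv", convert_instrument(intake), is_first = TRUE)
  set_field_metadata(st, "piv", "intake", "pid", participant_id = TRUE)
  for (k in 1:21)
    add_visit_config(st, "piv", sprintf("v%02d", k), (k - 1L) * 7L, linked_forms = "intake")
  for (i in 1:2)
    import_record(st, "piv", "intake",
                  flat_record(as.character(i),
                              list(pid = sprintf("P-%03d", i), ref_date = "2023-01-01")))
  panel <- build_visits_panel(st, "piv", "2023-03-01")
  expect_identical(nrow(panel), 42L)
  expect_identical(length(unique(panel$event_name)), 21L)
})

test_that("alerts fire once per reason instance per day and are append-only", {
  ts <- setup_toy_store(1)
  st <- ts$store
  withr::defer(close_store(st))
  import_record(st, "p1", "intake",
                flat_record("1", list(pid = "P-001", age = "250", sex = "")),
                now = "2023-02-01 08:00:00")
  run_validation_cycle(st, "p1", now = "2023-02-01 09:00:00")  # opens 2 queries
  n_before <- nrow(notification_log(st, "p1"))

  sent <- generate_alerts(st, "p1", now = "2023-06-01 09:00:00")
  # 2 open queries x 1 recipient, plus overdue-visit alerts (ref_date missing
  # here, so only query alerts)
  expect_identical(nrow(sent), 2L)
  sent2 <- generate_alerts(st, "p1", now = "2023-06-01 18:00:00")
  expect_identical(nrow(sent2), 0L)  # same calendar day: deduped
  sent3 <- generate_alerts(st, "p1", now = "2023-06-02 09:00:00")
  expect_identical(nrow(sent3), 2L)  # next day: fires again
  log <- notification_log(st, "p1")
  expect_identical(nrow(log), n_before + 4L)
  expect_true(all(diff(log$id) > 0))

  # overdue visit produces a pending-collection alert
  import_record(st, "p1", "intake", flat_record("1", list(ref_date = "2023-01-01")),
                now = "2023-02-01 08:30:00")
  sent4 <- generate_alerts(st, "p1", now = "2023-06-03 09:00:00")
  expect_true(any(sent4$reason == "pending_visit"))
})
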