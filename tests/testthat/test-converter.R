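test_that("naming pre-check targets exactly the unprefixed checkbox fields", {
  bad <- instrument("f", list(field_def("symptoms", "select_multiple", choice_list = "l")),
                    list(l = choice_list("l", c("a", "b"))))
  v <- precheck_names(bad)
  expect_length(v, 1)
  expect_match(v, "checkbox_")

  good <- instrument("f", list(field_def("checkbox_symptoms", "select_multiple", choice_list = "l")),
                     list(l = choice_list("l", c("a", "b"))))
  expect_length(precheck_names(good), 0)
  expect_length(precheck_names(instrument("f", list(field_def("age", "integer")))), 0)
})

test_that("per-type mapping lands on the canonical dictionary types", {
  instr <- make_toy_project(1)$instrument
  dd <- convert_instrument(instr)
  row_of <- function(name) Filter(function(r) r$variable_name == name, dd$rows)[[1]]

  start <- row_of("ref_date")
  expect_identical(start$field_type, "text")
  expect_identical(start$validation_type, "date_ymd")

  expect_identical(row_of("age")$validation_type, "integer")
  expect_identical(row_of("age")$validation_min, "0")
  expect_identical(row_of("age")$validation_max, "120")
  expect_identical(row_of("weight")$validation_type, "number")
  expect_identical(row_of("visit_time")$validation_type, "time")
  expect_identical(row_of("admit_dt")$validation_type, "datetime_ymd")
  expect_identical(row_of("sex")$field_type, "radio")
  expect_identical(row_of("checkbox_symptoms")$field_type, "checkbox")
  expect_identical(row_of("height_note")$field_type, "descriptive")
  expect_identical(row_of("xray_img")$field_type, "file")

  # calc with empty label takes its label from the guidance hint
  bmi <- row_of("bmi")
  expect_identical(bmi$field_type, "calc")
  expect_identical(bmi$field_label, "Body mass index")

  # choices serialized as `code, label | code, label`, verbatim codes
  expect_identical(row_of("sex")$choices_or_calc, "1, Male | 2, Female")
  # semantic tag lands in the annotation column
  expect_identical(row_of("pid")$field_annotation, "#affected")
})

test_that("branching rendering translates membership and inequality", {
  expect_identical(render_branching(logic_cmp("sex", "=", "1")), "[sex] = '1'")
  expect_identical(render_branching(logic_sel("checkbox_symptoms", "cough")),
                   "[checkbox_symptoms(cough)] = '1'")
  expect_identical(render_branching(logic_cmp("age", "!=", "5")), "[age] <> '5'")
  expect_identical(render_branching(logic_true()), "")
  expect_identical(render_branching(NULL), "")
})

test_that("branching translation preserves truth values (property)", {
  withr::local_seed(99)
  for (rep in 1:40) {
    e <- random_expr(c("a", "b"), depth = 3L)
    back <- parse_logic(render_branching(e), "redcap")
    for (va in c("0", "1")) for (vb in c("0", "1")) {
      vals <- list(a = va, b = vb)
      expect_identical(evaluate_logic(back, vals), evaluate_logic(e, vals),
                       info = render_branching(e))
    }
  }
  # membership nodes translate through the checkbox reference syntax
  e <- logic_and(logic_sel("checkbox_s", "x"), logic_not(logic_sel("checkbox_s", "y")))
  back <- parse_logic(render_branching(e), "redcap")
  for (vx in c("0", "1")) for (vy in c("0", "1")) {
    vals <- list(checkbox_s___x = vx, checkbox_s___y = vy)
    expect_identical(evaluate_logic(back, vals), evaluate_logic(e, vals))
  }
})

test_that("conversion is total-or-nothing and preserves field order", {
  fx <- make_toy_project(2)
  dd <- convert_instrument(fx$instrument)
  expect_length(dd$rows, length(fx$instrument$fields))
  expect_identical(vapply(dd$rows, function(r) r$variable_name, character(1)),
                   vapply(fx$instrument$fields, function(f) f$name, character(1)))

  bad <- instrument("f", list(field_def("symptoms", "select_multiple", choice_list = "l")),
                    list(l = choice_list("l", c("a", "b"))))
  err <- tryCatch(convert_instrument(bad), error = identity)
  expect_s3_class(err, "edc_precheck_failed")
  expect_length(err$violations, 1)

  empty <- convert_instrument(instrument("empty"))
  expect_length(empty$rows, 0)
  hdr <- write_dictionary(empty)
  expect_length(hdr, 1)
  expect_match(hdr, "^Variable / Field Name,Form Name,")
  expect_match(hdr, "\"Choices, Calculations, OR Slider Labels\"", fixed = TRUE)
})

test_that("the canonical treatment instrument converts to its three rows", {
  dd <- convert_instrument(treatment_instrument())
  expect_length(dd$rows, 3)
  expect_identical(vapply(dd$rows, function(r) r$variable_name, character(1)),
                   c("start_date", "clinical_form", "discharg_date"))
  expect_identical(dd$rows[[1]]$validation_type, "date_ymd")
  expect_identical(dd$rows[[2]]$field_type, "radio")
  expect_identical(dd$rows[[3]]$validation_type, "date_ymd")
})

test_that("unrepresentable constraints are dropped with a warning", {
  f <- field_def("age", "integer", constraint = ". != 13")
  expect_warning(rows <- map_field(f, "f"), "not representable")
  expect_identical(rows[[1]]$validation_min, "")
})
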