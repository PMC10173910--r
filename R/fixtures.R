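#' Deterministic test-data generators
#'
#' Everything the test suite consumes is generated here, seeded and
#' byte-deterministic: a canonical treatment instrument with its ontology
#' correspondence, randomized instruments exercising every field type,
#' submission payload streams with planted rule violations (ground truth
#' returned alongside, never embedded in the data), and CSUQ rating matrices
#' constructed to hit prescribed item means.
#'
#' @name fixtures
NULL

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Base IRI of the treatment vocabulary fixture
#' @export
TREATMENT_BASE_IRI <- "http://vocab.redbox.technology/vocab/treatment"

#' The canonical treatment instrument
#'
#' Three fields: treatment start date, TB clinical form (single selection)
#' and discharge date (variable name `discharg_date`, kept verbatim as
#' published rather than corrected). Its generated ontology has one datatype
#' property per field under [TREATMENT_BASE_IRI].
#'
#' @return an `edc_instrument`.
#' @export
treatment_instrument <- function() {
  instrument(
    "treatment",
    fields = list(
      field_def("start_date", "date", "Start date"),
      field_def("clinical_form", "select_one", "TB clinical form",
                choice_list = "clinical_form"),
      field_def("discharg_date", "date", "Discharge date")
    ),
    choice_lists = list(clinical_form = choice_list(
      "clinical_form", c("1", "2"), c("Pulmonary", "Extrapulmonary")))
  )
}

#' The 16 published CSUQ item means used as scoring fixtures
#' @return numeric vector of length 16.
#' @export
csuq_item_means <- function() {
  c(6.25, 6.19, 6.44, 6.38, 6.06, 6.25,
    5.19, 5.38, 5.63, 6.00, 6.44, 5.94,
    5.94, 6.00, 5.94, 6.25)
}

#' The five-project registry fixture
#'
#' Per-project counts of research centers, instruments, fields and expected
#' records for the five deployments the framework was validated on.
#'
#' @return data frame with one row per project.
#' @export
registry_projects <- function() {
  data.frame(
    project = c("I", "II", "III", "IV", "V"),
    centers = c(3L, 12L, 10L, 3L, 5L),
    instruments = c(4L, 14L, 9L, 24L, 14L),
    fields = c(175L, 679L, 183L, 528L, 357L),
    expected_records = c(2500L, 3800L, 1020L, 1000L, 500L),
    stringsAsFactors = FALSE
  )
}

# pool of plausible clinical field stems for randomized instruments
FIXTURE_STEMS <- c("cough_weeks", "fever_onset", "weight_kg", "height_cm",
                   "smear_result", "culture_date", "hiv_status", "contact_count",
                   "treatment_phase", "adverse_event", "followup_time", "xray_dt")

#' Build a seeded toy project
#'
#' Returns the canonical treatment instrument plus a seeded randomized
#' intake instrument exercising every field type (text, integer, decimal,
#' date, datetime, time, calc, single and multiple selection, note, file),
#' the ontology generated from the treatment instrument, a four-visit
#' schedule (offsets 0, 7, 30, 90 days) and a small rule set with known
#' semantics (age range 0-120, required sex, ISO-date format on the
#' reference date).
#'
#' @param seed integer seed; identical seeds give identical fixtures.
#' @return list with `instrument` (randomized intake form), `treatment`,
#'   `ontology`, `visit_configs` (data frame), `rules` (data frame).
#' @export
make_toy_project <- function(seed = 1L) {
  with_seed(seed, {
    extra_n <- sample(2:4, 1)
    stems <- sample(FIXTURE_STEMS, extra_n)
    extra_types <- sample(c("text", "integer", "decimal", "date"), extra_n, replace = TRUE)
    extra <- Map(function(nm, ty) {
      field_def(nm, ty, label = gsub("_", " ", nm))
    }, stems, extra_types)

    fields <- c(list(
      field_def("pid", "text", "Participant identifier", participant_id = TRUE,
                identifier = TRUE, tag = semantic_tag("hxl_hashtag", "#affected")),
      field_def("ref_date", "date", "Inclusion date"),
      field_def("sex", "select_one", "Sex", choice_list = "sex", required = TRUE),
      field_def("age", "integer", "Age (years)",
                constraint = ". >= 0 and . <= 120",
                validation = list(min = "0", max = "120")),
      field_def("weight", "decimal", "Weight (kg)"),
      field_def("visit_time", "time", "Visit time"),
      field_def("admit_dt", "datetime", "Admission date/time"),
      field_def("checkbox_symptoms", "select_multiple", "Symptoms",
                choice_list = "symptoms"),
      field_def("pregnant", "select_one", "Currently pregnant?", choice_list = "yesno",
                relevant = "${sex} = '2'"),
      field_def("bmi", "calc", "", guidance_hint = "Body mass index",
                calculation = "[weight]/(([height_cm]/100)*([height_cm]/100))"),
      field_def("height_note", "note", "Measure height without shoes."),
      field_def("xray_img", "file", "Chest X-ray upload")
    ), unname(extra))

    instr <- instrument("intake", fields, list(
      sex = choice_list("sex", c("1", "2"), c("Male", "Female")),
      symptoms = choice_list("symptoms", c("cough", "fever", "chills"),
                             c("Cough", "Fever", "Chills")),
      yesno = choice_list("yesno", c("1", "0"), c("Yes", "No"))
    ))

    visit_configs <- data.frame(
      event_name = c("inclusion", "week_1", "month_1", "month_3"),
      day_offset = c(0L, 7L, 30L, 90L),
      window_after = c(0L, 0L, 0L, 0L),
      stringsAsFactors = FALSE
    )
    rules <- data.frame(
      rule_id = c("r_age_range", "r_sex_required", "r_refdate_format"),
      form_name = "intake",
      field_name = c("age", "sex", "ref_date"),
      rule_type = c("range", "required", "format"),
      min = c("0", NA, NA), max = c("120", NA, NA),
      pattern = NA_character_,
      format = c(NA, NA, "date_ymd"),
      stringsAsFactors = FALSE
    )
    list(instrument = instr,
         treatment = treatment_instrument(),
         ontology = generate_ontology(treatment_instrument(), TREATMENT_BASE_IRI, "v1"),
         visit_configs = visit_configs,
         rules = rules)
  })
}

#' Generate a fully random (but always valid) instrument
#'
#' Used by property tests: any returned instrument passes
#' [validate_instrument()] and the naming pre-check.
#'
#' @param seed integer seed.
#' @param n_fields number of randomized fields.
#' @return an `edc_instrument`.
#' @export
random_instrument <- function(seed, n_fields = 6L) {
  with_seed(seed, {
    types <- sample(FIELD_TYPES, n_fields, replace = TRUE)
    cls <- list()
    fields <- list()
    for (i in seq_len(n_fields)) {
      ty <- types[i]
      nm <- sprintf("%s_%02d", if (ty == "select_multiple") "checkbox_f" else "f", i)
      cl_ref <- NULL
      if (ty %in% c("select_one", "select_multiple")) {
        cl_ref <- paste0("list_", i)
        k <- sample(2:4, 1)
        cls[[cl_ref]] <- choice_list(cl_ref, as.character(seq_len(k)),
                                     paste("Option", seq_len(k)))
      }
      validation <- list()
      if (ty == "integer" && runif(1) < 0.5) validation <- list(min = "0", max = as.character(sample(50:200, 1)))
      relevant <- NULL
      if (i > 1 && runif(1) < 0.3) {
        j <- sample(seq_len(i - 1L), 1)
        prev <- fields[[j]]
        relevant <- if (prev$type == "select_multiple")
          logic_sel(prev$name, cls[[prev$choice_list]]$codes[1L])
        else logic_cmp(prev$name, sample(c("=", "!=", ">="), 1), "1")
      }
      fields[[i]] <- field_def(nm, ty, label = paste("Question", i),
                               choice_list = cl_ref, required = runif(1) < 0.3,
                               relevant = relevant, validation = validation,
                               calculation = if (ty == "calc") "1+1",
                               guidance_hint = if (ty == "calc") paste("Derived", i))
    }
    instrument(sprintf("form_%d", seed), fields, cls)
  })
}

#' Simulate a stream of submission payloads
#'
#' Payloads mimic the POST shape of the collection platform (metadata keys
#' `_id`, `_uuid`, `meta/instanceID`, `formhub/uuid`, `start`, `end`
#' included) against the toy intake instrument. Rule violations are planted
#' at a stated rate and the ground truth is returned alongside the data so
#' validation-recovery tests have labels the pipeline cannot see.
#'
#' @param fixture a [make_toy_project()] result.
#' @param n number of payloads (one participant each).
#' @param seed integer seed.
#' @param missingness probability that each optional field is absent.
#' @param violation_rate probability that a payload carries one planted rule
#'   violation.
#' @return list with `payloads` (list of named lists) and `truth` (data
#'   frame: `pid`, `field_name`, `rule_id` for every planted violation).
#' @export
simulate_submissions <- function(fixture, n, seed = 1L, missingness = 0.1,
                                 violation_rate = 0.2) {
  assert_that(n >= 0, "n must be >= 0")
  if (n == 0) return(list(payloads = list(), truth = data.frame(
    pid = character(0), field_name = character(0), rule_id = character(0),
    stringsAsFactors = FALSE)))
  with_seed(seed, {
    payloads <- list()
    truth <- list()
    for (i in seq_len(n)) {
      pid <- sprintf("P-%03d", i)
      p <- list(
        `_id` = i, `_uuid` = sprintf("uuid-%08d", sample.int(1e7, 1)),
        `meta/instanceID` = sprintf("uuid:%08d", sample.int(1e7, 1)),
        `formhub/uuid` = "fhub-0001",
        start = "2023-03-01T08:00:00", end = "2023-03-01T08:25:00",
        pid = pid,
        ref_date = as.character(as.Date("2023-01-01") + sample.int(60, 1)),
        sex = as.character(sample(1:2, 1)),
        age = as.character(sample(18:90, 1)),
        weight = sprintf("%.1f", runif(1, 40, 110)),
        visit_time = sprintf("%02d:%02d", sample(8:17, 1), sample(0:59, 1)),
        checkbox_symptoms = paste(sample(c("cough", "fever", "chills"),
                                         sample(0:3, 1)), collapse = " ")
      )
      # optional fields drop out uniformly at random
      for (opt in c("weight", "visit_time", "checkbox_symptoms"))
        if (runif(1) < missingness) p[[opt]] <- NULL
      if (runif(1) < violation_rate) {
        kind <- sample(c("age_range", "sex_required", "refdate_format"), 1)
        if (kind == "age_range") {
          p$age <- as.character(sample(121:300, 1))
          truth[[length(truth) + 1L]] <- data.frame(
            pid = pid, field_name = "age", rule_id = "r_age_range", stringsAsFactors = FALSE)
        } else if (kind == "sex_required") {
          p$sex <- ""
          truth[[length(truth) + 1L]] <- data.frame(
            pid = pid, field_name = "sex", rule_id = "r_sex_required", stringsAsFactors = FALSE)
        } else {
          p$ref_date <- format(as.Date(p$ref_date), "%d/%m/%Y")
          truth[[length(truth) + 1L]] <- data.frame(
            pid = pid, field_name = "ref_date", rule_id = "r_refdate_format", stringsAsFactors = FALSE)
        }
      }
      payloads[[i]] <- p
    }
    list(payloads = payloads,
         truth = if (length(truth)) do.call(rbind, truth) else data.frame(
           pid = character(0), field_name = character(0), rule_id = character(0),
           stringsAsFactors = FALSE))
  })
}

#' Construct an integer rating matrix with prescribed column means
#'
#' Builds an n-by-16 matrix of integer ratings in \[1, 7\] whose column means
#' land within 0.05 of the targets. Column sums are assigned by cumulative
#' (drift-compensated) rounding of the running target total, so prefix sums
#' — and hence subscale means — track the targets as closely as integer
#' ratings allow. Within each column the sum is spread over respondents with
#' seeded unit transfers for realism; transfers conserve the column sum.
#'
#' @param target_means numeric vector of 16 item means, each in \[1, 7\].
#' @param n number of respondents (>= 1).
#' @param seed integer seed.
#' @return n x 16 integer matrix.
#' @export
make_csuq_matrix <- function(target_means, n, seed = 1L) {
  assert_that(length(target_means) == 16L, "need exactly 16 target means")
  assert_that(all(target_means >= 1 & target_means <= 7), "targets must lie in [1, 7]")
  assert_that(n >= 1, "n must be >= 1")
  # Column sums: each must keep its own mean within 0.05 of the target; among
  # the admissible integers the one minimizing the running (cumulative) drift
  # is taken, so prefix sums — and with them subscale scores — track the
  # targets as closely as integer ratings allow.
  sums <- integer(16L)
  drift <- 0
  for (j in 1:16) {
    exact <- target_means[j] * n
    cand <- unique(c(floor(exact), ceiling(exact)))
    cand <- cand[cand >= n & cand <= 7L * n & abs(cand / n - target_means[j]) <= 0.05 + 1e-9]
    if (!length(cand))
      stop(edc_error("edc_infeasible_target",
                     sprintf("cannot hit target mean %.4f within 0.05 at n = %d (item %d)",
                             target_means[j], n, j)))
    pick <- cand[which.min(abs(drift + cand - exact))]
    drift <- drift + pick - exact
    sums[j] <- pick
  }
  with_seed(seed, {
    m <- matrix(0L, nrow = n, ncol = 16L)
    for (j in 1:16) {
      s <- sums[j]
      base <- s %/% n
      r <- s %% n
      col <- rep.int(base, n)
      if (r > 0) col[sample.int(n, r)] <- base + 1L
      # seeded +1/-1 transfers keep the sum while adding spread
      for (k in seq_len(max(1L, n %/% 3L))) {
        up <- which(col < 7L); dn <- which(col > 1L)
        if (!length(up) || !length(dn)) break
        pick_up <- up[sample.int(length(up), 1L)]
        pick_dn <- dn[sample.int(length(dn), 1L)]
        if (pick_up != pick_dn) {
          col[pick_up] <- col[pick_up] + 1L
          col[pick_dn] <- col[pick_dn] - 1L
        }
      }
      m[, j] <- col
    }
    colnames(m) <- sprintf("q%d", 1:16)
    m
  })
}

#' Emit a fixture bundle to disk
#'
#' Writes `form.xlsx` (the toy intake instrument), `onto.ttl`, one JSON
#' payload per simulated submission under `payloads/`, and `ratings.csv`.
#'
#' @param seed integer seed.
#' @param out output directory (created if absent).
#' @param n_payloads number of simulated submissions.
#' @return `out`, invisibly.
#' @export
write_fixture_bundle <- function(seed, out, n_payloads = 10L) {
  dir.create(file.path(out, "payloads"), recursive = TRUE, showWarnings = FALSE)
  fx <- make_toy_project(seed)
  write_xlsform(fx$instrument, file.path(out, "form.xlsx"))
  serialize_ontology(fx$ontology, file.path(out, "onto.ttl"))
  sims <- simulate_submissions(fx, n_payloads, seed = seed)
  for (i in seq_along(sims$payloads)) {
    jsonlite::write_json(sims$payloads[[i]],
                         file.path(out, "payloads", sprintf("payload_%03d.json", i)),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  ratings <- make_csuq_matrix(csuq_item_means(), n = 17L, seed = seed)
  utils::write.csv(as.data.frame(ratings), file.path(out, "ratings.csv"), row.names = FALSE)
  invisible(out)
}
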