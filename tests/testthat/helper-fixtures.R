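# Shared helpers: a fully wired toy project store and independent oracles.

# Build an in-memory store with the seeded toy project registered: intake as
# the entry form, treatment as a second form, rules, visits and recipients.
setup_toy_store <- function(seed = 1L, with_treatment = TRUE) {
  fx <- make_toy_project(seed)
  st <- open_store()
  register_project(st, "p1", name = "Toy project", ref_date_field = "ref_date")
  register_form(st, "p1", convert_instrument(fx$instrument), is_first = TRUE)
  if (with_treatment)
    register_form(st, "p1", convert_instrument(fx$treatment))
  followup <- instrument("followup", list(
    field_def("pid", "text", "Participant identifier"),
    field_def("weight", "decimal", "Weight (kg)")))
  register_form(st, "p1", convert_instrument(followup))
  set_field_metadata(st, "p1", "intake", "pid",
                     tag = semantic_tag("hxl_hashtag", "#affected"),
                     identifier = TRUE, participant_id = TRUE)
  add_alert_recipient(st, "p1", "dm@example.org", "email")
  for (r in seq_len(nrow(fx$rules))) {
    rr <- fx$rules[r, ]
    add_validation_rule(st, "p1", rr$rule_id, rr$form_name, rr$field_name, rr$rule_type,
                        min = if (!is.na(rr$min)) rr$min,
                        max = if (!is.na(rr$max)) rr$max,
                        format = if (!is.na(rr$format)) rr$format)
  }
  for (r in seq_len(nrow(fx$visit_configs))) {
    vc <- fx$visit_configs[r, ]
    add_visit_config(st, "p1", vc$event_name, vc$day_offset, vc$window_after,
                     linked_forms = "intake")
  }
  list(store = st, fixture = fx)
}

toy_creds <- list(username = "etl", password = "secret")

cell_chr2 <- function(x) if (is.null(x)) "" else as.character(x)

`%||%` <- function(x, y) if (is.null(x)) y else x

ingest_payloads <- function(st, payloads, event = "inclusion", ...) {
  for (p in payloads)
    process_submission(st, "p1", "intake", p, toy_creds,
                       etl_settings(event = event, ...))
  invisible(NULL)
}

# Independent brute-force logic evaluator: a deliberately different,
# recursion-by-cases implementation used to cross-check evaluate_logic().
brute_eval <- function(expr, vals) {
  k <- expr$kind
  if (k == "true") return(TRUE)
  if (k == "not") return(!brute_eval(expr$arg, vals))
  if (k == "and") {
    for (a in expr$args) if (!brute_eval(a, vals)) return(FALSE)
    return(TRUE)
  }
  if (k == "or") {
    for (a in expr$args) if (brute_eval(a, vals)) return(TRUE)
    return(FALSE)
  }
  if (k == "sel" || k == "negsel") {
    key <- paste0(expr$field, "___", expr$code)
    hit <- !is.null(vals[[key]]) && as.character(vals[[key]]) == "1"
    if (is.null(vals[[key]]) && !is.null(vals[[expr$field]]))
      hit <- expr$code %in% strsplit(as.character(vals[[expr$field]]), " +")[[1]]
    return(if (k == "sel") hit else !hit)
  }
  v <- vals[[expr$field]]
  blank <- is.null(v) || is.na(v) || !nzchar(as.character(v))
  if (expr$value == "")
    return(switch(expr$op, "=" = blank, "!=" = !blank, FALSE))
  if (blank) return(FALSE)
  v <- as.character(v)
  nv <- suppressWarnings(as.numeric(v)); nl <- suppressWarnings(as.numeric(expr$value))
  if (!is.na(nv) && !is.na(nl)) { a <- nv; b <- nl } else { a <- v; b <- expr$value }
  switch(expr$op,
         "=" = a == b, "!=" = a != b, "<" = a < b, "<=" = a <= b,
         ">" = a > b, ">=" = a >= b)
}

# random logic expression over given binary fields, depth-limited
random_expr <- function(fields, depth = 3L) {
  if (depth == 0L || stats::runif(1) < 0.4) {
    f <- sample(fields, 1)
    if (stats::runif(1) < 0.5) return(logic_cmp(f, sample(c("=", "!=", "<", "<=", ">", ">="), 1),
                                                as.character(sample(0:1, 1))))
    return(logic_cmp(f, "=", as.character(sample(0:1, 1))))
  }
  pick <- sample(c("and", "or", "not"), 1)
  if (pick == "not") return(logic_not(random_expr(fields, depth - 1L)))
  if (pick == "and") return(logic_and(random_expr(fields, depth - 1L), random_expr(fields, depth - 1L)))
  logic_or(random_expr(fields, depth - 1L), random_expr(fields, depth - 1L))
}
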