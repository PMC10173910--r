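test_that("instrument derivation maps ranges, defaults and restrictions", {
  onto <- ontology_spec("http://example.org/vocab/demo", "v1", list(
    property_def("http://example.org/vocab/demo", "start_date", range = "date"),
    property_def("http://example.org/vocab/demo", "comments"),   # no range
    property_def("http://example.org/vocab/demo", "age", range = "integer",
                 min_value = 0, max_value = 120)
  ))
  instr <- derive_instrument(onto, "demo")
  expect_identical(vapply(instr$fields, function(f) f$type, character(1)),
                   c("date", "text", "integer"))
  expect_identical(instr$fields[[3]]$validation$min, "0")
  expect_identical(instr$fields[[3]]$validation$max, "120")
  expect_identical(instr$fields[[1]]$tag$kind, "ontology_property")
  expect_identical(instr$fields[[1]]$tag$value, "http://example.org/vocab/demo/start_date")
  expect_length(validate_instrument(instr), 0)
})

test_that("ontology generation reproduces the treatment correspondences", {
  onto <- generate_ontology(treatment_instrument(), TREATMENT_BASE_IRI, "v1")
  iris <- vapply(onto$properties, function(p) p$iri, character(1))
  expect_identical(iris, paste0(TREATMENT_BASE_IRI, "/",
                                c("start_date", "clinical_form", "discharg_date")))
  expect_identical(vapply(onto$properties, function(p) p$range, character(1)),
                   c("date", "string", "date"))
  expect_error(generate_ontology(treatment_instrument(), "not an iri"), "absolute IRI")
})

test_that("generate -> derive round trip preserves names, types and bounds", {
  for (seed in c(1, 4, 9)) {
    instr <- make_toy_project(seed)$instrument
    onto <- generate_ontology(instr, "http://example.org/vocab/toy", "v1")
    back <- derive_instrument(onto, instr$name)
    expect_identical(vapply(back$fields, function(f) f$name, character(1)),
                     vapply(instr$fields, function(f) f$name, character(1)))
    for (i in seq_along(instr$fields)) {
      a <- instr$fields[[i]]; b <- back$fields[[i]]
      # non-scalar types flatten to string range, hence text on the way back
      expected_type <- if (a$type %in% c("date", "datetime", "time", "integer", "decimal"))
        a$type else "text"
      expect_identical(b$type, expected_type, info = a$name)
      expect_identical(cell_chr2(b$validation$min), cell_chr2(a$validation$min))
      expect_identical(cell_chr2(b$validation$max), cell_chr2(a$validation$max))
    }
  }
})

test_that("turtle serialization is deterministic and parses back to equality", {
  onto <- generate_ontology(make_toy_project(2)$instrument, "http://example.org/v", "v3")
  doc1 <- serialize_ontology(onto)
  doc2 <- serialize_ontology(onto)
  expect_identical(doc1, doc2)
  back <- parse_ontology(doc1)
  expect_identical(back$base_iri, onto$base_iri)
  expect_identical(back$version_label, "v3")
  expect_length(back$properties, length(onto$properties))
  for (i in seq_along(onto$properties)) {
    expect_identical(back$properties[[i]]$iri, onto$properties[[i]]$iri)
    expect_identical(back$properties[[i]]$range, onto$properties[[i]]$range)
    expect_identical(back$properties[[i]]$min_value, onto$properties[[i]]$min_value)
    expect_identical(back$properties[[i]]$max_value, onto$properties[[i]]$max_value)
  }
  # empty ontology: prefix/header lines only, no properties
  empty <- serialize_ontology(ontology_spec("http://example.org/empty"))
  expect_length(parse_ontology(empty)$properties, 0)
})

test_that("statements outside the subset are skipped with a warning", {
  doc <- paste(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "<http://x.org/v> a owl:Ontology ;",
    '    owl:versionInfo "v1" .',
    "<http://x.org/v/klass> a owl:Class .",
    "<http://x.org/v/age> a owl:DatatypeProperty ;",
    "    rdfs:range xsd:integer .",
    sep = "\n")
  expect_warning(onto <- parse_ontology(doc), "skipping")
  expect_length(onto$properties, 1)
  expect_identical(onto$properties[[1]]$local_name, "age")
})

test_that("annotation remapping rewrites, drops and reports a partition", {
  tags <- c(start_date = "http://v1.org/x/start_date",
            clinical_form = "http://v1.org/x/clinical_form",
            note = "http://v1.org/x/note")
  recs <- list(flat_record("1", list(start_date = "2023-01-01", clinical_form = "1")))

  ident <- version_mapping("v1", "v1", stats::setNames(unname(tags), tags))
  r0 <- remap_annotations(recs, tags, ident)
  expect_identical(r0$tag_map, tags)
  expect_identical(r0$report$dropped, 0L)

  vm <- version_mapping("v1", "v2", c(
    "http://v1.org/x/start_date" = "http://v2.org/x/treatment_start",
    "http://v1.org/x/clinical_form" = NA))
  r <- remap_annotations(recs, tags, vm)
  expect_identical(unname(r$tag_map["start_date"]), "http://v2.org/x/treatment_start")
  expect_false("clinical_form" %in% names(r$tag_map))   # dropped
  expect_identical(r$report, list(mapped = 1L, dropped = 1L, unmapped = 1L,
                                  unmapped_fields = "note"))
  expect_identical(r$report$mapped + r$report$dropped + r$report$unmapped, length(tags))
  # values are untouched
  expect_identical(r$records, recs)
})
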