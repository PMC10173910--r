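# edcbridge

Clinical research teams — particularly in low-resource settings such as
tuberculosis services — often collect data with a friendly offline-capable
tool (KoBoToolbox, built on the XLSForm standard) but manage it in REDCap,
whose data dictionary, branching logic, query workflow and API form the
backbone of the study database. Keeping the two in sync by hand means
designing every instrument twice, re-keying every skip-logic expression, and
manually policing data quality across longitudinal visits.

`edcbridge` is an R toolkit for that whole pipeline:

- **Form conversion.** XLSForm workbooks (survey/choices/settings sheets,
  with an optional HXL semantic-annotation column) convert to 18-column
  REDCap data-dictionary CSVs and back. Skip logic is translated between the
  XLSForm grammar (`${f} = '1'`, `selected(${f},'c')`, `and/or/not()`) and
  REDCap branching logic (`[f] = '1'`, `[f(c)] = '1'`, `<>`), preserving
  truth values — including under missing data. Multiple-selection fields
  must carry the `checkbox_` name prefix; a pre-check fails the conversion
  otherwise.
- **Ontology bridge.** Each form field corresponds to an ontology datatype
  property (IRI = base + "/" + variable name, literal range from the field
  type, min/max restrictions from validation bounds). Instruments can be
  derived from ontologies and ontologies generated from instruments, with a
  deterministic Turtle serialization and version-to-version annotation
  remapping.
- **Embedded store + ETL.** An RSQLite-backed store emulates the REDCap
  surfaces the pipeline needs (projects, forms, records, record-ID
  generation, locking, queries, change log). The ETL processor takes a
  platform submission payload (JSON), authenticates, strips platform
  metadata, expands checkbox answers to `name___code` columns, resolves the
  record ID from the participant identifier, imports atomically, and runs
  post-save actions (duplicate check, lock, notifications).
- **Data quality.** Rule-based validation (range/format/required/regex) with
  an open→resolved query lifecycle that reaches a fixed point in one cycle;
  visit calendars (due date = reference date + day offset; status
  carried_out / not_carried_out / pending); deduplicated alert generation —
  all into a recorded notification log, never a real transport.
- **Reporting.** CSUQ usability-survey scoring (Overall = items 1–16,
  SysUse = 1–6, InfoQual = 7–12, IntQual = 13–15, half-up at 2 decimals),
  respondent breakdowns, project-registry summaries, and data-management-plan
  rendering from a bundled template.
- **Fixtures.** Seed-deterministic generators for instruments, ontologies,
  submission streams with planted violations (ground truth returned
  alongside), and CSUQ matrices hitting prescribed item means within ±0.05.

## Worked example

```r
library(edcbridge)

instr <- treatment_instrument()   # canonical 3-field treatment form
instr
#> <instrument 'treatment'> 3 field(s), 1 choice list(s)
#>   start_date           date            Start date
#>   clinical_form        select_one      TB clinical form
#>   discharg_date        date            Discharge date

dd <- convert_instrument(instr)
writeLines(write_dictionary(dd)[2])
#> start_date,treatment,,text,Start date,,,date_ymd,,,,,,,,,,

generate_ontology(instr, TREATMENT_BASE_IRI, "v1")
#> <ontology http://vocab.redbox.technology/vocab/treatment (v1)> 3 properties
#>   start_date                date
#>   clinical_form             string
#>   discharg_date             date

score_csuq(csuq_item_means())
#> CSUQ scores
#>   Overall   6.02
#>   SysUse    6.26
#>   InfoQual  5.76
#>   IntQual   5.96

respondent_breakdown(c(men = 7, women = 9, not_answered = 1))
#>          men        women not_answered
#>        41.18        52.94         5.88
```

The dictionary row shows the standard type mapping (a date question becomes a
REDCap `text` field with `date_ymd` validation); the ontology properties are
the field names under the vocabulary base IRI with literal ranges; the CSUQ
scores are the subscale means of the 16 item means, rounded half-up.

## Command line

`edc_cli()` dispatches subcommands, e.g.

```sh
Rscript -e 'edcbridge::edc_cli()' convert --in form.xlsx --name intake --out dict.csv
Rscript -e 'edcbridge::edc_cli()' derive-onto --in form.xlsx --base http://example.org/vocab/x --version v1
Rscript -e 'edcbridge::edc_cli()' fixtures --seed 1 --out fixtures/
```

See `vignettes/edcbridge-methods.Rmd` for the model, its assumptions, the
numerical choices, and known limitations.
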