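---
title: "edcbridge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{edcbridge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Electronic data capture for field studies frequently splits across two
systems: an XLSForm-based collector (friendly, offline-capable, used at the
point of care) and REDCap (the managed study database, with its data
dictionary, branching logic, query resolution workflow and API). `edcbridge`
models the full round trip — instrument conversion, submission ETL, data
quality, semantic annotation — as a library with an embedded store, so every
behavior is testable on a desk without any live server.

## The canonical instrument model

All converters meet in one in-memory representation: an *instrument* is an
ordered list of typed fields (types: text, integer, decimal, date, datetime,
time, calc, select_one, select_multiple, note, file) plus named choice
lists. Fields carry labels, required flags, skip logic, value constraints,
validation bounds, personal-identifier and participant-identifier flags, and
at most one semantic tag (an ontology property IRI or an HXL hashtag).
`validate_instrument()` returns violations as data rather than raising:
structural problems in user-authored forms are findings, not crashes.

Names are normalized to lower case on ingest; labels are preserved verbatim.
Dates are naive ISO `YYYY-MM-DD`, datetimes `YYYY-MM-DD HH:MM`; no timezone
handling is attempted (field studies record local civil time).

## Logic translation and the missing-value rule

Two dialects are parsed into one expression tree: XLSForm
(`${f}`, `!=`, `selected(${f},'c')`, `not(...)`) and REDCap branching logic
(`[f]`, `<>`, `[f(c)] = '1'`). Only this subset is supported; anything else
is a parse error with a character position. Checkbox membership is a
first-class node, so `selected(${f},'c')` and `[f(c)] = '1'` are the same
tree.

**Missing values make comparisons false.** Nothing in the source material
fixes how incomplete data interacts with skip logic, so this package chooses
the conservative rule — a field whose controlling value is absent stays
hidden — and applies it uniformly. One consequence surfaced in testing:
rewriting `not(X)` for REDCap (which has no `not()`) by operator flipping is
*unsound* under this rule, because `not(a >= 0)` is true for blank `a` while
`[a] < '0'` is false. The renderer therefore emits
`([a] = '' or [a] < '0')`, and the grammar defines a comparison against the
empty literal as an emptiness test (REDCap's own `[f] = ''` idiom). The
truth-preservation property test runs every translated expression against
exhaustive assignments *including* blanks.

## Conversion choices

- Type mapping: text→text; integer→text+integer; decimal→text+number;
  date→text+date_ymd; datetime→text+datetime_ymd; time→text+time;
  select_one→radio (dropdown would be equally defensible; radio was chosen
  and is asserted in tests); select_multiple→checkbox; calc→calc;
  note→descriptive; file→file.
- Multiple-selection fields must be named `checkbox_*`; `precheck_names()`
  reports every offender and `convert_instrument()` refuses to emit anything
  while violations exist (all-or-nothing, no partial dictionaries).
- A calc field cannot be labeled in the authoring tool; its guidance hint
  becomes the dictionary label when the label is empty. Round-trip
  equivalence therefore compares *effective* labels.
- An own-value range constraint (`. >= a and . <= b`, either arm optional)
  populates validation min/max; any other constraint shape is dropped with a
  warning — it has no dictionary rendering.
- Choices serialize as `code, label | code, label`; codes and variable names
  are carried verbatim. The dictionary does not record choice-list *names*,
  so round trips compare choice content.

## The embedded store

An RSQLite database mirrors the metadata tables of the emulated system
(`redcap_project` with API credentials, `redcap_forms` with a single entry
form per project, `form_metadata` for semantics/identifiers, validation
rules/issues, visit configs, alert recipients and log) plus the implied
record, lock, change-log and support tables. Records are stored
entity-attribute-value keyed by (record, event, field), with checkbox
expansions `name___code` as ordinary columns. Record IDs are plain integers
rendered as text, strictly increasing from "1", never reused. Every
mutating import appends exactly one change-log entry holding the changed
values; a no-op import appends nothing, which makes "log length = number of
mutations" a testable conservation law.

## ETL

The pipeline is authenticate → clean → transform → resolve → import →
post-save actions, wrapped in one SQLite transaction: any stage failure
leaves the store byte-identical (tests compare full snapshots). Cleaning
removes platform metadata by blocklist (keys starting `_`, `meta/`,
`formhub/`, plus `start`, `end`, `today`, `deviceid`, ...) — the exact set
is a reconstruction and is configurable. Group prefixes (`grp/field`)
strip to terminal names. Record resolution: only the project's entry form
may create a participant; other forms look the participant identifier up in
stored data and raise `UnresolvedParticipant` otherwise, in which case the
submission is parked in a dedicated table *outside* the rolled-back
transaction (an operational log, not record state).

Duplicates are defined conservatively: identical cleaned values for the same
(participant, form, event) are flagged and skipped (so replaying a stream is
idempotent); differing values import as an update *and* open a data query
for human review. Notifications are appended to a log with a channel
(email/SMS); no transport is ever attempted.

## Data quality

- `evaluate_rule()`: ranges compare numerically when both sides parse as
  numbers, otherwise as text (chronological for ISO dates); blanks fail only
  `required` rules — absence is a completeness issue, not a range issue.
- `run_validation_cycle()` opens one query per failing (record, field, rule)
  with no open issue, alerts recipients, resolves issues whose values now
  pass, and is a fixed point on unchanged data after one cycle.
- Visits: due date = reference date + day offset (calendar days);
  `window_after` defaults to 0 — with it, "pending" covers only dates up to
  the due date plus the window. A visit is carried out when **every** linked
  form holds at least one non-empty value for the record at that event; the
  source material does not specify this, so it is an explicit per-visit
  configuration. Participants with a blank or unparseable reference date are
  listed in the panel's `missing_reference` attribute rather than dropped.
- Alerts dedupe per (recipient, reason instance, calendar day); scheduling
  *when* the engine runs is left to cron — the library exposes single-shot
  entry points.

## CSUQ scoring and synthetic ratings

Scores are means of item means: Overall 1–16, SysUse 1–6, InfoQual 7–12,
IntQual 13–15, displayed half-up at two decimals (`round_half_up()`, since
base R rounds half to even). The scorer takes already-oriented
(higher-is-better) ratings; any scale reversal is the caller's
preprocessing.

`make_csuq_matrix()` constructs integer ratings in [1, 7] whose column means
land within ±0.05 of the targets. Column sums are chosen from the
floor/ceiling of target×n, filtered to the ±0.05-admissible candidates, and
picked to minimize cumulative drift — so *prefix* sums, and hence the
subscale means, track the targets as closely as integers allow. This is why
a 17-respondent synthetic matrix reproduces all four published-scale scores
after rounding, while per-column tolerance may be infeasible below n = 10
(the generator then raises rather than silently missing).

## What the synthetic data does and does not establish

The fixture generators emulate: a realistic intake instrument exercising
every field type, platform-shaped payloads with metadata noise, uniform
missingness, planted rule violations at a stated rate (labels returned
beside the data, never embedded in it), and four-visit longitudinal
schedules. They do not emulate: real tuberculosis epidemiology, correlated
missingness, free-text noise, multi-language forms, or server failure modes.
A green suite therefore establishes the *mechanics* — conversion fidelity,
logic equivalence, conservation, idempotence, atomicity, planted-truth
recovery — not field performance at deployment scale.

## Numerical and degenerate-input choices

- Half-up rounding carries an ulp-scale epsilon so decimals stored just
  under a representational half (e.g. 41.175) round up as intended.
- Empty logic text parses to constant true (field shown unconditionally) and
  renders back to empty text.
- Empty instruments produce header-only workbooks and dictionaries.
- The dictionary CSV writer is byte-stable (fixed header, LF endings,
  RFC 4180 quoting), so serialized output can be diffed.
- Turtle serialization is deterministic (declared property order, fixed
  prefix block); parsing skips out-of-subset statements with warnings.

## Known limitations

No groups/repeats, multi-language labels, cascading selects or matrix
groups; no OWL reasoning, object properties or RDF/XML input; no live
HTTP client for either capture system (the store emulates the surfaces the
pipeline touches); no real email/SMS delivery; no timezone handling. Legacy
binary `.xls` workbooks are rejected with an explicit unsupported-format
error rather than half-read.
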