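#' Ontology bridge
#'
#' Instruments and ontologies are two renderings of the same schema: each
#' datatype property (IRI, literal range, optional min/max restrictions)
#' corresponds to one form field. This module derives instruments from
#' ontologies, generates ontologies from instruments, serializes the
#' supported subset as Turtle, and remaps annotated datasets between ontology
#' versions.
#'
#' Supported subset: `owl:DatatypeProperty` declarations with `rdfs:label`,
#' `rdfs:range` in xsd literal types, and `xsd:minInclusive` /
#' `xsd:maxInclusive` value annotations. Classes and object properties are
#' skipped with a warning on read.
#'
#' @name ontology_bridge
NULL

PROPERTY_RANGES <- c("string", "integer", "decimal", "date", "datetime", "time")

XSD_OF_RANGE <- c(string = "xsd:string", integer = "xsd:integer",
                  decimal = "xsd:decimal", date = "xsd:date",
                  datetime = "xsd:dateTime", time = "xsd:time")

RANGE_TO_FIELDTYPE <- c(string = "text", integer = "integer", decimal = "decimal",
                        date = "date", datetime = "datetime", time = "time")

# every field type maps to a literal range; non-scalar kinds flatten to string
FIELDTYPE_TO_RANGE <- c(text = "string", integer = "integer", decimal = "decimal",
                        date = "date", datetime = "datetime", time = "time",
                        calc = "string", select_one = "string",
                        select_multiple = "string", note = "string", file = "string")

#' Construct a datatype-property definition
#'
#' @param base_iri ontology base IRI (no trailing slash).
#' @param local_name property local name; must satisfy field-name rules. The
#'   property IRI is `base_iri + "/" + local_name`.
#' @param range literal range, one of `r paste(PROPERTY_RANGES, collapse=", ")`;
#'   `NULL` means unstated (derives to a text field).
#' @param min_value,max_value optional inclusive restrictions.
#' @param label optional human-readable label.
#' @return an `edc_property`.
#' @export
property_def <- function(base_iri, local_name, range = NULL, min_value = NULL,
                         max_value = NULL, label = NULL) {
  local_name <- tolower(cell_chr(local_name))
  assert_that(grepl(VALID_NAME_RE, local_name),
              paste0("property local name must match ", VALID_NAME_RE, ": ", local_name))
  if (!is.null(range))
    assert_that(range %in% PROPERTY_RANGES, paste0("unknown range: ", range))
  structure(list(iri = paste0(sub("/+$", "", base_iri), "/", local_name),
                 local_name = local_name, range = range,
                 min_value = if (!is.null(min_value)) as.character(min_value),
                 max_value = if (!is.null(max_value)) as.character(max_value),
                 label = label), class = "edc_property")
}

#' Construct an ontology specification
#'
#' @param base_iri base IRI shared by all properties.
#' @param version_label opaque version text (e.g. `"v1"`).
#' @param properties ordered list of [property_def()].
#' @return an `edc_ontology`.
#' @export
ontology_spec <- function(base_iri, version_label = "v1", properties = list()) {
  base_iri <- sub("/+$", "", cell_chr(base_iri))
  assert_that(nzchar(base_iri), "base_iri must be non-empty")
  iris <- vapply(properties, function(p) p$iri, character(1))
  assert_that(!any(duplicated(iris)), "duplicate property IRIs")
  structure(list(base_iri = base_iri, version_label = version_label,
                 properties = properties), class = "edc_ontology")
}

#' @export
print.edc_ontology <- function(x, ...) {
  cat(sprintf("<ontology %s (%s)> %d propert%s\n", x$base_iri, x$version_label,
              length(x$properties), if (length(x$properties) == 1) "y" else "ies"))
  for (p in x$properties)
    cat(sprintf("  %-25s %s\n", p$local_name, p$range %||% "(unstated)"))
  invisible(x)
}

#' Derive an instrument from an ontology
#'
#' One field per property, in property order: the field name is the property
#' local name, the type follows the literal range (unstated or unknown range
#' gives a text field), min/max restrictions become validation bounds, and
#' every field is tagged with its source property IRI.
#'
#' @param onto an `edc_ontology`.
#' @param form_name instrument name.
#' @return an `edc_instrument`.
#' @export
derive_instrument <- function(onto, form_name) {
  nms <- vapply(onto$properties, function(p) p$local_name, character(1))
  dup <- unique(nms[duplicated(nms)])
  assert_that(length(dup) == 0,
              paste0("duplicate local names after normalization: ", paste(dup, collapse = ", ")))
  fields <- lapply(onto$properties, function(p) {
    type <- if (is.null(p$range)) "text" else unname(RANGE_TO_FIELDTYPE[p$range])
    validation <- list()
    if (!is.null(p$min_value)) validation$min <- p$min_value
    if (!is.null(p$max_value)) validation$max <- p$max_value
    field_def(name = p$local_name, type = type,
              label = p$label %||% p$local_name,
              validation = validation,
              tag = semantic_tag("ontology_property", p$iri))
  })
  instrument(form_name, fields)
}

#' Generate an ontology from an instrument
#'
#' One datatype property per field, in field order: the property IRI is
#' `base_iri + "/" + field name` (the variable name verbatim), date/time and
#' numeric fields keep a typed literal range and everything else (including
#' selections) flattens to a string literal; validation bounds become
#' min/max restrictions.
#'
#' @param instr an `edc_instrument`.
#' @param base_iri ontology base IRI.
#' @param version_label opaque version text.
#' @return an `edc_ontology`.
#' @export
generate_ontology <- function(instr, base_iri, version_label = "v1") {
  assert_that(grepl("^[a-z][a-z0-9+.-]*://", base_iri), "base_iri must be an absolute IRI")
  props <- lapply(instr$fields, function(f) {
    property_def(base_iri, f$name,
                 range = unname(FIELDTYPE_TO_RANGE[f$type]),
                 min_value = f$validation$min, max_value = f$validation$max,
                 label = if (nzchar(f$label)) f$label)
  })
  ontology_spec(base_iri, version_label, props)
}

## ---- Turtle serialization -------------------------------------------------

ttl_escape <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))

#' Serialize an ontology as Turtle
#'
#' Deterministic: identical specs produce identical bytes (properties in
#' declared order, fixed prefix block).
#'
#' @param onto an `edc_ontology`.
#' @param path optional output path; when omitted the document is returned as
#'   a single string.
#' @return the Turtle document (invisibly when written to `path`).
#' @export
serialize_ontology <- function(onto, path = NULL) {
  lines <- c(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "",
    sprintf("<%s> a owl:Ontology ;", onto$base_iri),
    sprintf('    owl:versionInfo "%s" .', ttl_escape(onto$version_label)),
    ""
  )
  for (p in onto$properties) {
    body <- sprintf("<%s> a owl:DatatypeProperty", p$iri)
    if (!is.null(p$label)) body <- c(body, sprintf('    rdfs:label "%s"', ttl_escape(p$label)))
    if (!is.null(p$range)) body <- c(body, sprintf("    rdfs:range %s", XSD_OF_RANGE[p$range]))
    if (!is.null(p$min_value)) body <- c(body, sprintf('    xsd:minInclusive "%s"', ttl_escape(p$min_value)))
    if (!is.null(p$max_value)) body <- c(body, sprintf('    xsd:maxInclusive "%s"', ttl_escape(p$max_value)))
    stmt <- paste0(paste(body, collapse = " ;\n"), " .")
    lines <- c(lines, stmt, "")
  }
  doc <- paste(lines, collapse = "\n")
  if (is.null(path)) return(doc)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(doc, con, sep = "\n", useBytes = TRUE)
  invisible(doc)
}

#' Parse a Turtle document into an ontology specification
#'
#' Accepts the subset written by [serialize_ontology()] plus tolerant
#' skipping: statements about subjects that are not datatype properties or
#' the ontology header, and predicates outside the subset, are skipped with a
#' warning.
#'
#' @param doc Turtle text (single string or lines), or a file path.
#' @return an `edc_ontology`.
#' @export
parse_ontology <- function(doc) {
  if (length(doc) == 1L && file.exists(doc) && !grepl("\n", doc))
    doc <- paste(readLines(doc, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  doc <- paste(doc, collapse = "\n")
  # strip comments and prefix declarations
  lines <- strsplit(doc, "\n", fixed = TRUE)[[1L]]
  lines <- lines[!grepl("^\\s*#", lines) & !grepl("^\\s*@prefix", lines)]
  text <- paste(lines, collapse = "\n")
  # statements end in " ." ; split on a dot at end-of-statement position
  stmts <- strsplit(text, "(?<=[>\"a-zA-Z0-9])\\s*\\.\\s*(?=\\n|$)", perl = TRUE)[[1L]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]

  base_iri <- NULL; version <- "v1"; props <- list()
  for (stmt in stmts) {
    parts <- trimws(strsplit(stmt, ";", fixed = TRUE)[[1L]])
    m <- regmatches(parts[1L], regexec("^<([^>]+)>\\s+a\\s+(\\S+)$", parts[1L]))[[1L]]
    if (length(m) != 3L) {
      warning("skipping statement outside the supported subset: ", substr(stmt, 1, 60), call. = FALSE)
      next
    }
    subj <- m[2L]; klass <- m[3L]
    po <- list()
    for (p in parts[-1L]) {
      pm <- regmatches(p, regexec('^(\\S+)\\s+(.*)$', p))[[1L]]
      if (length(pm) == 3L) po[[pm[2L]]] <- pm[3L]
    }
    unquote <- function(x) {
      if (is.null(x)) return(NULL)
      x <- trimws(x)
      if (grepl('^".*"$', x)) gsub('\\\\(["\\\\])', "\\1", substr(x, 2, nchar(x) - 1L)) else x
    }
    if (klass == "owl:Ontology") {
      base_iri <- subj
      if (!is.null(po[["owl:versionInfo"]])) version <- unquote(po[["owl:versionInfo"]])
    } else if (klass == "owl:DatatypeProperty") {
      rng <- NULL
      if (!is.null(po[["rdfs:range"]])) {
        xsd <- trimws(po[["rdfs:range"]])
        hit <- names(XSD_OF_RANGE)[XSD_OF_RANGE == xsd]
        if (length(hit)) rng <- hit else
          warning("unknown range ", xsd, " on ", subj, "; treating as unstated", call. = FALSE)
      }
      local <- sub("^.*/", "", subj)
      base <- sub("/[^/]*$", "", subj)
      props[[length(props) + 1L]] <- property_def(
        base, local, range = rng,
        min_value = unquote(po[["xsd:minInclusive"]]),
        max_value = unquote(po[["xsd:maxInclusive"]]),
        label = unquote(po[["rdfs:label"]]))
    } else {
      warning("skipping non-property subject ", subj, " (", klass, ")", call. = FALSE)
    }
  }
  if (is.null(base_iri)) {
    assert_that(length(props) > 0, "document contains no supported statements")
    base_iri <- sub("/[^/]*$", "", props[[1L]]$iri)
  }
  ontology_spec(base_iri, version, props)
}

#' Read an ontology file
#'
#' Turtle (`.ttl`) is read natively. RDF/XML (`.owl`) would need an RDF
#' reader, which this package does not bundle; such files are rejected with a
#' clear message rather than mis-parsed.
#'
#' @param path file path.
#' @return an `edc_ontology`.
#' @export
read_ontology <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  if (grepl("\\.owl$", path, ignore.case = TRUE)) {
    head <- paste(readLines(path, n = 5L, warn = FALSE), collapse = "")
    if (grepl("<\\?xml|<rdf:RDF", head))
      stop(edc_error("edc_unsupported_format",
                     "RDF/XML (.owl) input needs an RDF reader; convert the file to Turtle (.ttl)"))
  }
  parse_ontology(paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n"))
}

## ---- version remapping ----------------------------------------------------

#' Construct a version mapping
#'
#' @param from_version,to_version opaque version labels; direction is given
#'   by the mapping itself, not by parsing the labels.
#' @param property_map named character vector/list: old IRI -> new IRI, or
#'   `NA` to mark the property as dropped in the target version.
#' @return an `edc_version_mapping`.
#' @export
version_mapping <- function(from_version, to_version, property_map) {
  property_map <- unlist(property_map)
  assert_that(!any(duplicated(names(property_map))), "duplicate keys in property_map")
  structure(list(from_version = from_version, to_version = to_version,
                 property_map = property_map), class = "edc_version_mapping")
}

#' Remap dataset annotations across ontology versions
#'
#' The dataset's values are never touched: only the annotation map (field
#' name -> property IRI) is rewritten. Tags whose IRI maps to `NA` are
#' dropped; tags absent from the mapping are left in place and reported as
#' unmapped (not an error — a prior property mapping is a prerequisite for a
#' complete conversion).
#'
#' @param records list of [flat_record()]s (returned untouched).
#' @param tag_map named character vector: field name -> property IRI under the
#'   source ontology version.
#' @param vm an [version_mapping()].
#' @return list with `records`, `tag_map` (rewritten) and `report` (counts:
#'   mapped, dropped, unmapped).
#' @export
remap_annotations <- function(records, tag_map, vm) {
  tag_map <- unlist(tag_map)
  out <- character(0)
  mapped <- 0L; dropped <- 0L; unmapped <- 0L
  unmapped_fields <- character(0)
  for (fn in names(tag_map)) {
    iri <- tag_map[[fn]]
    if (!iri %in% names(vm$property_map)) {
      unmapped <- unmapped + 1L
      unmapped_fields <- c(unmapped_fields, fn)
      out[fn] <- iri
    } else if (is.na(vm$property_map[[iri]])) {
      dropped <- dropped + 1L
    } else {
      mapped <- mapped + 1L
      out[fn] <- vm$property_map[[iri]]
    }
  }
  list(records = records, tag_map = out,
       report = list(mapped = mapped, dropped = dropped, unmapped = unmapped,
                     unmapped_fields = unmapped_fields))
}
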