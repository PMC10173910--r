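#' Skip-logic and branching-logic expressions
#'
#' Instruments carry conditional-display ("skip") logic. Two concrete dialects
#' are supported: the XLSForm dialect used by KoBoToolbox/ODK
#' (`${field} = '1'`, `selected(${f}, 'code')`, `and`/`or`/`not()`) and the
#' REDCap branching-logic dialect (`[field] = '1'`, checkbox references
#' `[f(code)] = '1'`, `<>` for not-equal). Both parse to the same expression
#' tree so truth values can be compared across dialects.
#'
#' Tree nodes (class `edc_logic`) are lists with a `kind`:
#' \describe{
#'   \item{`true`}{constant true — absent logic shows the field unconditionally}
#'   \item{`cmp`}{`field`, `op` (one of `=` `!=` `<` `<=` `>` `>=`), `value`}
#'   \item{`sel`}{checkbox membership: `field`, `code`}
#'   \item{`and` / `or`}{`args`, a list of subtrees}
#'   \item{`not`}{`arg`}
#' }
#'
#' @name logic
NULL

logic_node <- function(kind, ...) structure(list(kind = kind, ...), class = "edc_logic")

#' @rdname logic
#' @export
logic_true <- function() logic_node("true")

#' @rdname logic
#' @param field field name the node refers to.
#' @param op comparison operator.
#' @param value literal right-hand side (stored as text).
#' @export
logic_cmp <- function(field, op, value) {
  assert_that(op %in% c("=", "!=", "<", "<=", ">", ">="), paste0("unknown operator: ", op))
  logic_node("cmp", field = field, op = op, value = as.character(value))
}

#' @rdname logic
#' @param code choice code tested for membership.
#' @export
logic_sel <- function(field, code) logic_node("sel", field = field, code = as.character(code))

#' @rdname logic
#' @param ... subtrees.
#' @export
logic_and <- function(...) logic_node("and", args = list(...))

#' @rdname logic
#' @export
logic_or <- function(...) logic_node("or", args = list(...))

#' @rdname logic
#' @param arg subtree to negate.
#' @export
logic_not <- function(arg) logic_node("not", arg = arg)

is_logic <- function(x) inherits(x, "edc_logic")

## ---- tokenizer ------------------------------------------------------------

# Tokens: FIELD (dialect-specific), OP, LPAREN, RPAREN, COMMA, STRING, NUMBER,
# AND, OR, NOT, SELECTED. Each token records its character position for error
# reporting.
tokenize_logic <- function(text, dialect) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- substr(text, i, i)
    rest <- substr(text, i, n)
    if (grepl("^\\s", ch)) { i <- i + 1L; next }
    if (dialect == "xlsform" && startsWith(rest, "${")) {
      m <- regmatches(rest, regexpr("^\\$\\{[A-Za-z][A-Za-z0-9_]*\\}", rest))
      if (!length(m)) stop(logic_syntax_error(text, i, "malformed ${field} reference"))
      push("FIELD", tolower(substr(m, 3, nchar(m) - 1L)), i)
      i <- i + nchar(m); next
    }
    if (dialect == "redcap" && ch == "[") {
      m <- regmatches(rest, regexpr("^\\[[A-Za-z][A-Za-z0-9_]*(\\([A-Za-z0-9_]+\\))?\\]", rest))
      if (!length(m)) stop(logic_syntax_error(text, i, "malformed [field] reference"))
      inner <- substr(m, 2, nchar(m) - 1L)
      push("FIELD", tolower(inner), i)
      i <- i + nchar(m); next
    }
    opm <- regmatches(rest, regexpr("^(<=|>=|<>|!=|=|<|>)", rest))
    if (length(opm)) {
      op <- opm
      if (op == "<>") {
        if (dialect != "redcap") stop(logic_syntax_error(text, i, "'<>' is REDCap syntax"))
        op <- "!="
      } else if (op == "!=" && dialect != "xlsform") {
        stop(logic_syntax_error(text, i, "'!=' is XLSForm syntax; use '<>'"))
      }
      push("OP", op, i)
      i <- i + nchar(opm); next
    }
    if (ch == "(") { push("LPAREN", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", ")", i); i <- i + 1L; next }
    if (ch == ",") { push("COMMA", ",", i); i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      m <- regmatches(rest, regexpr(paste0("^", ch, "[^", ch, "]*", ch), rest))
      if (!length(m)) stop(logic_syntax_error(text, i, "unterminated string literal"))
      push("STRING", substr(m, 2, nchar(m) - 1L), i)
      i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^-?[0-9]+(\\.[0-9]+)?", rest))
    if (length(m)) { push("NUMBER", m, i); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(m)) {
      kw <- tolower(m)
      if (kw %in% c("and", "or", "not")) push(toupper(kw), kw, i)
      else if (kw == "selected") push("SELECTED", kw, i)
      else stop(edc_error("edc_unknown_function",
                          sprintf("unknown function or keyword '%s' at position %d", m, i)))
      i <- i + nchar(m); next
    }
    stop(logic_syntax_error(text, i, paste0("unexpected character '", ch, "'")))
  }
  toks
}

logic_syntax_error <- function(text, pos, why) {
  edc_error("edc_logic_syntax",
            sprintf("logic syntax error at position %d: %s (in %s)", pos, why, dQuote(text)))
}

#' Parse a logic expression
#'
#' @param text expression text; empty or all-whitespace text parses to the
#'   constant-true node (the field is shown unconditionally).
#' @param dialect `"xlsform"` or `"redcap"`.
#' @return an `edc_logic` tree.
#' @export
#' @examples
#' parse_logic("${sex} = '1'", "xlsform")
#' parse_logic("[checkbox_symptoms(cough)] = '1'", "redcap")
parse_logic <- function(text, dialect = c("xlsform", "redcap")) {
  dialect <- match.arg(dialect)
  text <- cell_chr(text)
  if (!nzchar(text)) return(logic_true())
  toks <- tokenize_logic(text, dialect)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L; st$text <- text; st$dialect <- dialect
  expr <- p_or(st)
  if (st$i <= length(st$toks)) {
    t <- st$toks[[st$i]]
    stop(logic_syntax_error(text, t$pos, paste0("unexpected trailing '", t$value, "'")))
  }
  expr
}

peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
advance <- function(st) { t <- st$toks[[st$i]]; st$i <- st$i + 1L; t }
expect_tok <- function(st, type, what) {
  t <- peek(st)
  if (is.null(t)) stop(logic_syntax_error(st$text, nchar(st$text) + 1L, paste0("expected ", what, ", got end of input")))
  if (t$type != type) stop(logic_syntax_error(st$text, t$pos, paste0("expected ", what, ", got '", t$value, "'")))
  advance(st)
}

p_or <- function(st) {
  args <- list(p_and(st))
  while (!is.null(t <- peek(st)) && t$type == "OR") {
    advance(st)
    args[[length(args) + 1L]] <- p_and(st)
  }
  if (length(args) == 1L) args[[1L]] else logic_node("or", args = args)
}

p_and <- function(st) {
  args <- list(p_atom(st))
  while (!is.null(t <- peek(st)) && t$type == "AND") {
    advance(st)
    args[[length(args) + 1L]] <- p_atom(st)
  }
  if (length(args) == 1L) args[[1L]] else logic_node("and", args = args)
}

p_atom <- function(st) {
  t <- peek(st)
  if (is.null(t)) stop(logic_syntax_error(st$text, nchar(st$text) + 1L, "expected expression, got end of input"))
  if (t$type == "NOT") {
    advance(st)
    expect_tok(st, "LPAREN", "'(' after not")
    inner <- p_or(st)
    expect_tok(st, "RPAREN", "')'")
    return(logic_node("not", arg = inner))
  }
  if (t$type == "LPAREN") {
    advance(st)
    inner <- p_or(st)
    expect_tok(st, "RPAREN", "')'")
    return(inner)
  }
  if (t$type == "SELECTED") {
    if (st$dialect != "xlsform") stop(logic_syntax_error(st$text, t$pos, "selected() is XLSForm syntax"))
    advance(st)
    expect_tok(st, "LPAREN", "'('")
    f <- expect_tok(st, "FIELD", "${field}")
    expect_tok(st, "COMMA", "','")
    lit <- peek(st)
    if (is.null(lit) || !lit$type %in% c("STRING", "NUMBER"))
      stop(logic_syntax_error(st$text, if (is.null(lit)) nchar(st$text) + 1L else lit$pos, "expected choice code literal"))
    advance(st)
    expect_tok(st, "RPAREN", "')'")
    return(logic_sel(f$value, lit$value))
  }
  if (t$type == "FIELD") {
    f <- advance(st)
    # REDCap checkbox reference [field(code)] = '1'  => membership node
    cbm <- regmatches(f$value, regexec("^([a-z][a-z0-9_]*)\\(([a-z0-9_]+)\\)$", f$value))[[1L]]
    op <- expect_tok(st, "OP", "comparison operator")
    lit <- peek(st)
    if (is.null(lit) || !lit$type %in% c("STRING", "NUMBER"))
      stop(logic_syntax_error(st$text, if (is.null(lit)) nchar(st$text) + 1L else lit$pos, "expected literal"))
    advance(st)
    if (length(cbm)) {
      # only `[f(c)] = '1'` / `<> '0'`-style equality maps onto membership
      if (op$value == "=" && lit$value == "1") return(logic_sel(cbm[2L], cbm[3L]))
      if (op$value == "=" && lit$value == "0") return(logic_not(logic_sel(cbm[2L], cbm[3L])))
      stop(logic_syntax_error(st$text, f$pos, "checkbox reference must compare to '1' or '0'"))
    }
    return(logic_cmp(f$value, op$value, lit$value))
  }
  stop(logic_syntax_error(st$text, t$pos, paste0("unexpected '", t$value, "'")))
}

## ---- rendering ------------------------------------------------------------

#' Render a logic tree to expression text
#'
#' Inverse of [parse_logic()]: `parse_logic(render_logic(e, d), d)` returns a
#' tree equal to `e` (constant-true renders as empty text in both dialects).
#'
#' @param expr an `edc_logic` tree.
#' @param dialect target dialect.
#' @return single character string.
#' @export
render_logic <- function(expr, dialect = c("xlsform", "redcap")) {
  dialect <- match.arg(dialect)
  render_node(expr, dialect, top = TRUE)
}

render_node <- function(e, dialect, top = FALSE) {
  assert_that(is_logic(e), "not a logic expression")
  lit <- function(v) paste0("'", v, "'")
  out <- switch(e$kind,
    true = "",
    cmp = {
      ref <- if (dialect == "xlsform") paste0("${", e$field, "}") else paste0("[", e$field, "]")
      op <- if (dialect == "redcap" && e$op == "!=") "<>" else e$op
      paste(ref, op, lit(e$value))
    },
    sel = {
      if (dialect == "xlsform") paste0("selected(${", e$field, "}, ", lit(e$code), ")")
      else paste0("[", e$field, "(", e$code, ")] = '1'")
    },
    "not" = {
      inner <- render_node(e$arg, dialect)
      if (dialect == "xlsform") paste0("not(", inner, ")")
      # redcap has no not(): push the negation inward; parenthesize because
      # the rewrite can surface an or-chain into arbitrary parent context
      else paste0("(", render_node(negate_node(e$arg), dialect), ")")
    },
    and = ,
    or = {
      parts <- vapply(e$args, function(a) {
        s <- render_node(a, dialect)
        if (a$kind %in% c("and", "or") && a$kind != e$kind) paste0("(", s, ")") else s
      }, character(1))
      joined <- paste(parts, collapse = paste0(" ", e$kind, " "))
      if (!top && e$kind == "or") joined else joined
    },
    stop("unknown node kind: ", e$kind)
  )
  out
}

# De Morgan / operator flip used when rendering `not` for REDCap. Because a
# missing value makes every comparison false, not(f op v) is true when f is
# blank — the flipped comparison alone would miss that, so an explicit
# emptiness check ([f] = '') is OR-ed in.
negate_node <- function(e) {
  switch(e$kind,
    true = logic_cmp("__never__", "=", "1"),
    cmp = {
      flip <- c("=" = "!=", "!=" = "=", "<" = ">=", "<=" = ">", ">" = "<=", ">=" = "<")
      if (e$value == "") {
        # emptiness checks are total: plain flip is exact
        logic_cmp(e$field, unname(flip[e$op]), "")
      } else {
        logic_node("or", args = list(
          logic_cmp(e$field, "=", ""),
          logic_cmp(e$field, unname(flip[e$op]), e$value)))
      }
    },
    sel = logic_node("negsel", field = e$field, code = e$code),
    "not" = e$arg,
    and = logic_node("or", args = lapply(e$args, negate_node)),
    or = logic_node("and", args = lapply(e$args, negate_node)),
    stop("cannot negate node kind: ", e$kind)
  )
}

# internal kind produced only by negate_node; rendered as `[f(c)] = '0'`
render_negsel <- function(e, dialect) {
  if (dialect == "redcap") paste0("[", e$field, "(", e$code, ")] = '0'")
  else paste0("not(selected(${", e$field, "}, '", e$code, "'))")
}

# patch render_node dispatch for negsel without enlarging the switch above
render_node_orig <- render_node
render_node <- function(e, dialect, top = FALSE) {
  if (e$kind == "negsel") return(render_negsel(e, dialect))
  render_node_orig(e, dialect, top)
}

## ---- evaluation -----------------------------------------------------------

#' Evaluate a logic tree against a flat record
#'
#' Missing or empty values make any comparison false (conservative: a field
#' whose controlling value is absent stays hidden). Values parseable as
#' numbers on both sides compare numerically; otherwise text comparison is
#' used (ISO dates therefore compare chronologically). Checkbox membership
#' reads the expanded `name___code` entry.
#'
#' @param expr an `edc_logic` tree.
#' @param rec a [flat_record()] or a plain named list/vector of values.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_logic <- function(expr, rec) {
  vals <- if (inherits(rec, "edc_flat_record")) rec$values else rec
  eval_node(expr, vals)
}

eval_node <- function(e, vals) {
  switch(e$kind,
    true = TRUE,
    cmp = {
      v <- vals[[e$field]]
      # the empty literal tests emptiness itself (REDCap's [f] = '' idiom)
      if (e$value == "")
        return(switch(e$op, "=" = is_blank(v), "!=" = !is_blank(v), FALSE))
      if (is_blank(v)) return(FALSE)
      v <- as.character(v); lit <- e$value
      nv <- num_or_na(v); nl <- num_or_na(lit)
      res <- if (!is.na(nv) && !is.na(nl)) {
        switch(e$op, "=" = nv == nl, "!=" = nv != nl, "<" = nv < nl,
               "<=" = nv <= nl, ">" = nv > nl, ">=" = nv >= nl)
      } else {
        switch(e$op, "=" = v == lit, "!=" = v != lit, "<" = v < lit,
               "<=" = v <= lit, ">" = v > lit, ">=" = v >= lit)
      }
      isTRUE(res)
    },
    sel = {
      v <- vals[[paste0(e$field, "___", e$code)]]
      if (is_blank(v)) {
        # fall back to unexpanded space-separated codes (XLSForm shape)
        raw <- vals[[e$field]]
        if (is_blank(raw)) return(FALSE)
        return(e$code %in% strsplit(as.character(raw), "\\s+")[[1L]])
      }
      as.character(v) %in% c("1", "TRUE", "true")
    },
    negsel = !eval_node(logic_sel(e$field, e$code), vals),
    "not" = !eval_node(e$arg, vals),
    and = all(vapply(e$args, eval_node, logical(1), vals = vals)),
    or = any(vapply(e$args, eval_node, logical(1), vals = vals)),
    stop("unknown node kind: ", e$kind)
  )
}

#' Field names referenced by a logic tree
#' @param expr an `edc_logic` tree.
#' @return character vector of referenced field names.
#' @export
logic_fields <- function(expr) {
  switch(expr$kind,
    true = character(0),
    cmp = expr$field,
    sel = ,
    negsel = expr$field,
    "not" = logic_fields(expr$arg),
    and = ,
    or = unique(unlist(lapply(expr$args, logic_fields))),
    character(0)
  )
}

#' @export
print.edc_logic <- function(x, ...) {
  cat("<logic> ", if (x$kind == "true") "(true)" else render_logic(x, "xlsform"), "\n", sep = "")
  invisible(x)
}

logic_equal <- function(a, b) identical(unclass_deep(a), unclass_deep(b))

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
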