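# Minimal Office Open XML spreadsheet writer.
#
# No XLSX-writing package is assumed at run time, so workbooks are emitted
# directly: a zip container with the mandatory content-types/relationship
# parts and one worksheet per sheet, all cells as inline strings. readxl (and
# Excel/LibreOffice) read the result. Only what XLSForm needs is supported:
# rectangular character data with a header row.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

col_letter <- function(j) {
  # 1 -> A, 27 -> AA; XLSForm sheets stay well under two letters but be exact
  out <- ""
  while (j > 0) {
    r <- (j - 1L) %% 26L
    out <- paste0(LETTERS[r + 1L], out)
    j <- (j - 1L) %/% 26L
  }
  out
}

sheet_xml <- function(df) {
  header <- names(df)
  mat <- rbind(header, as.matrix(df))
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    cells <- vapply(seq_len(ncol(mat)), function(j) {
      v <- mat[i, j]
      if (is.na(v) || !nzchar(v)) return("")
      sprintf('<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
              col_letter(j), i, xml_escape(v))
    }, character(1))
    sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
  }, character(1))
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

#' Write a workbook of character data frames as XLSX
#'
#' @param sheets named list of data frames (coerced to character).
#' @param path output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_xlsx_sheets <- function(sheets, path) {
  assert_that(length(sheets) > 0 && !is.null(names(sheets)), "sheets must be a named list")
  dir <- tempfile("xlsx")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  dir.create(file.path(dir, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(dir, "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "_rels"), recursive = TRUE)

  n <- length(sheets)
  overrides <- paste(sprintf(
    '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    overrides, '</Types>'), file.path(dir, "[Content_Types].xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(dir, "_rels", ".rels"))

  rels <- paste(sprintf(
    '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
    seq_len(n), seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    rels, '</Relationships>'), file.path(dir, "xl", "_rels", "workbook.xml.rels"))

  sheet_tags <- paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                              xml_escape(names(sheets)), seq_len(n), seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>', sheet_tags, '</sheets></workbook>'), file.path(dir, "xl", "workbook.xml"))

  for (i in seq_len(n)) {
    df <- as.data.frame(lapply(sheets[[i]], as.character), stringsAsFactors = FALSE,
                        check.names = FALSE)
    writeLines(sheet_xml(df), file.path(dir, "xl", "worksheets", sprintf("sheet%d.xml", i)),
               useBytes = TRUE)
  }

  files <- c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
             "xl/_rels/workbook.xml.rels",
             sprintf("xl/worksheets/sheet%d.xml", seq_len(n)))
  path <- normalizePath(path, mustWork = FALSE)
  if (file.exists(path)) unlink(path)
  zip::zip(path, files = files, root = dir, mode = "mirror")
  invisible(path)
}

# read one sheet as an all-character data frame; empty header cells dropped
read_xlsx_sheet <- function(path, sheet) {
  df <- readxl::read_excel(path, sheet = sheet, col_types = "text",
                           .name_repair = "minimal")
  df <- as.data.frame(df, stringsAsFactors = FALSE, check.names = FALSE)
  df[, nzchar(names(df)), drop = FALSE]
}
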