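# Minimal deterministic XLSX writer (OOXML worksheets with inline strings).
# Used by the synthetic-data generator; instrument files are read via readxl.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xlsx_colref <- function(j) {
  s <- ""
  while (j > 0L) {
    s <- paste0(LETTERS[(j - 1L) %% 26L + 1L], s)
    j <- (j - 1L) %/% 26L
  }
  s
}

# sheets: named list of data.frames. Character columns become inline-string
# cells, numeric columns numeric cells; NA cells are omitted. If `headers`
# is TRUE, column names are written as a leading text row.
write_xlsx_sheets <- function(sheets, path, headers = FALSE) {
  stopifnot(length(sheets) > 0L, !is.null(names(sheets)),
            all(nzchar(names(sheets))))
  if (anyDuplicated(names(sheets)))
    stop("sheet names must be unique")
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  n <- length(sheets)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
            seq_len(n)),
    '</Types>'), file.path(tmp, "[Content_Types].xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(tmp, "_rels", ".rels"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
            xml_escape(names(sheets)), seq_len(n), seq_len(n)),
    '</sheets></workbook>'), file.path(tmp, "xl", "workbook.xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
            seq_len(n), seq_len(n)),
    '</Relationships>'), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  for (i in seq_len(n)) {
    df <- sheets[[i]]
    r0 <- 0L
    rows <- character(0)
    if (isTRUE(headers) && ncol(df) > 0L) {
      cells <- sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
                       vapply(seq_len(ncol(df)), xlsx_colref, ""),
                       xml_escape(names(df)))
      rows <- sprintf('<row r="1">%s</row>', paste0(cells, collapse = ""))
      r0 <- 1L
    }
    if (nrow(df) > 0L) {
      body <- vapply(seq_len(nrow(df)), function(r) {
        cells <- character(0)
        for (j in seq_len(ncol(df))) {
          v <- df[[j]][r]
          if (is.na(v)) next
          ref <- paste0(xlsx_colref(j), r + r0)
          cells <- c(cells, if (is.numeric(v))
            sprintf('<c r="%s"><v>%s</v></c>', ref,
                    format(v, digits = 15, scientific = FALSE))
          else
            sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
                    xml_escape(as.character(v))))
        }
        sprintf('<row r="%d">%s</row>', r + r0, paste0(cells, collapse = ""))
      }, character(1))
      rows <- c(rows, body)
    }
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"><sheetData>',
      rows, '</sheetData></worksheet>'),
      file.path(tmp, "xl", "worksheets", sprintf("sheet%d.xml", i)))
  }
  # fixed timestamps so identical content gives identical bytes
  all_files <- list.files(tmp, recursive = TRUE, all.files = TRUE,
                          full.names = TRUE)
  Sys.setFileTime(all_files, as.POSIXct("2020-01-01", tz = "UTC"))
  if (file.exists(path)) unlink(path)
  # zip() resolves the archive path relative to `root`: make it absolute
  path <- file.path(normalizePath(dirname(path), mustWork = TRUE),
                    basename(path))
  zip::zip(zipfile = path,
           files = list.files(tmp, recursive = TRUE, all.files = TRUE),
           root = tmp, include_directories = FALSE)
  unlink(tmp, recursive = TRUE)
  invisible(path)
}
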