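# Spreadsheet interchange for GBA models.
#
# Canonical format: a single ODS file with one sheet per parameter matrix
# ("M", "K", "KA", "KI", "kcat", "conditions"). Alternate dialect: a CSV
# bundle, i.e. a directory holding M.csv, K.csv, ... with identical layouts.
# Every sheet has reaction (or condition) labels in the first row and
# reactant (or parameter) labels in the first column.

TAB_NAMES <- c("M", "K", "KA", "KI", "kcat", "conditions")

#' Read a GBA model from an ODS file or CSV bundle
#'
#' Parses the six standard tabs (`M`, `K`, `KA`, `KI`, `kcat`, `conditions`)
#' into a [gba_model] and a [gba_conditions] object, preserving labels and
#' ordering exactly as stored. No numeric validation is performed beyond
#' parseability; run [check_model()] next.
#'
#' @param path path to an `.ods` file, or to a directory containing
#'   `M.csv`, `K.csv`, `KA.csv`, `KI.csv`, `kcat.csv`, `conditions.csv`.
#' @param dialect `"auto"` (from the path), `"ods"`, or `"csv"`.
#'
#' @return A list with elements `model` and `conditions`.
#' @export
#' @examples
#' dir <- tempfile(); ex <- gba_example()
#' write_gba(ex$model, ex$conditions, dir, dialect = "csv")
#' identical(read_gba(dir)$model$M, ex$model$M)
read_gba <- function(path, dialect = c("auto", "ods", "csv")) {
  dialect <- resolve_dialect(match.arg(dialect), path, writing = FALSE)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  tabs <- if (dialect == "ods") ods_read_tabs(path) else csv_read_tabs(path)
  for (tab in TAB_NAMES) {
    if (is.null(tabs[[tab]]))
      stop(sprintf("missing tab: %s", tab), call. = FALSE)
  }
  tabs_to_model(tabs)
}

#' Write a GBA model to an ODS file or CSV bundle
#'
#' Numeric values are serialized with 17 significant digits, so
#' `read_gba(write_gba(...))` round-trips every double bit-exactly.
#'
#' @param model a [gba_model].
#' @param conditions a [gba_conditions].
#' @inheritParams read_gba
#' @return `path`, invisibly.
#' @export
write_gba <- function(model, conditions, path, dialect = c("auto", "ods", "csv")) {
  dialect <- resolve_dialect(match.arg(dialect), path, writing = TRUE)
  tabs <- model_to_tabs(model, conditions)
  if (dialect == "ods") ods_write_tabs(tabs, path) else csv_write_tabs(tabs, path)
  invisible(path)
}

#' Write a GBA model template
#'
#' Emits a structurally valid skeleton model -- one external substrate, a
#' transport column, a chain of enzymatic columns, and the ribosome column
#' `"r"` producing total protein `"P"` -- that users can edit in any
#' spreadsheet program. The template passes [check_model()] as written.
#'
#' @param n_reactants total number of reactant rows (external + internal,
#'   including `"P"`); at least 2.
#' @param n_reactions number of reaction columns (transport first, ribosome
#'   last); at least 2.
#' @inheritParams write_gba
#' @return `path`, invisibly.
#' @export
write_template <- function(n_reactants, n_reactions, path,
                           dialect = c("auto", "ods", "csv")) {
  tpl <- template_model(n_reactants, n_reactions)
  write_gba(tpl$model, tpl$conditions, path, dialect)
}

resolve_dialect <- function(dialect, path, writing) {
  if (dialect != "auto") return(dialect)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ods") return("ods")
  if (ext == "" || (!writing && dir.exists(path))) return("csv")
  stop(sprintf("cannot infer dialect from path %s; pass dialect = \"ods\" or \"csv\"", path),
       call. = FALSE)
}

# ---- tab <-> model mapping -------------------------------------------------

# A "tab" is a character matrix including the header row and label column;
# cell [1,1] is empty.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

matrix_to_tab <- function(X) {
  body <- matrix(fmt_num(X), nrow(X), ncol(X))
  rbind(c("", colnames(X)), cbind(rownames(X), body))
}

model_to_tabs <- function(model, conditions) {
  kcat <- rbind(kcat_f = model$kcat_f, kcat_b = model$kcat_b)
  cond <- rbind(rho = conditions$rho, conditions$a)
  rownames(cond) <- c("rho", rownames(conditions$a))
  colnames(cond) <- condition_labels(conditions)
  list(M = matrix_to_tab(model$M),
       K = matrix_to_tab(model$K),
       KA = matrix_to_tab(model$KA),
       KI = matrix_to_tab(model$KI),
       kcat = matrix_to_tab(kcat),
       conditions = matrix_to_tab(cond))
}

tab_to_matrix <- function(tab, name, strict = TRUE) {
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop(sprintf("tab %s is empty or lacks labels", name), call. = FALSE)
  rlab <- unname(as.character(tab[-1, 1]))
  clab <- unname(as.character(tab[1, -1]))
  body <- tab[-1, -1, drop = FALSE]
  num <- suppressWarnings(array(as.numeric(body), dim(body)))
  if (strict) {
    bad <- which(is.na(num) & !is.na(body) & nzchar(trimws(body)), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-parseable cell in tab %s at row %s, column %s: \"%s\"",
                   name, rlab[bad[1, 1]], clab[bad[1, 2]],
                   body[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(rlab, clab)
  num
}

tabs_to_model <- function(tabs, strict = TRUE) {
  M <- tab_to_matrix(tabs$M, "M", strict)
  K <- tab_to_matrix(tabs$K, "K", strict)
  KA <- tab_to_matrix(tabs$KA, "KA", strict)
  KI <- tab_to_matrix(tabs$KI, "KI", strict)
  kcat <- tab_to_matrix(tabs$kcat, "kcat", strict)
  cond <- tab_to_matrix(tabs$conditions, "conditions", strict)
  if (!all(c("kcat_f", "kcat_b") %in% rownames(kcat)))
    stop("tab kcat must have rows labeled kcat_f and kcat_b", call. = FALSE)
  if (rownames(cond)[1] != "rho")
    stop("tab conditions must have \"rho\" as its first row", call. = FALSE)
  model <- gba_model(M, K, KA = KA, KI = KI,
                     kcat_f = kcat["kcat_f", ], kcat_b = kcat["kcat_b", ],
                     check = FALSE)
  a <- cond[-1, , drop = FALSE]
  conditions <- gba_conditions(rho = cond["rho", ],
                               a = if (nrow(a)) a else NULL,
                               labels = colnames(cond))
  if (nrow(a)) rownames(conditions$a) <- rownames(cond)[-1]
  list(model = model, conditions = conditions)
}

# ---- CSV bundle dialect ----------------------------------------------------

csv_read_tabs <- function(dir) {
  if (!dir.exists(dir))
    stop(sprintf("CSV bundle must be a directory: %s", dir), call. = FALSE)
  tabs <- list()
  for (tab in TAB_NAMES) {
    f <- file.path(dir, paste0(tab, ".csv"))
    if (!file.exists(f)) next
    lines <- readLines(f)
    cells <- utils::read.csv(text = lines, header = FALSE,
                             colClasses = "character", check.names = FALSE)
    widths <- vapply(strsplit(lines, ",", fixed = TRUE), length, integer(1))
    if (length(unique(widths)) > 1)
      stop(sprintf("ragged matrix in tab %s: row %d has %d cells, expected %d",
                   tab, which(widths != widths[1])[1],
                   widths[widths != widths[1]][1], widths[1]), call. = FALSE)
    tabs[[tab]] <- as.matrix(cells)
  }
  tabs
}

csv_write_tabs <- function(tabs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in names(tabs)) {
    utils::write.table(tabs[[tab]], file.path(dir, paste0(tab, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(dir)
}

# ---- ODS dialect -----------------------------------------------------------

ODF_NS <- paste0(
  ' xmlns:office="urn:oasis:names:tc:opendocument:xmlns:office:1.0"',
  ' xmlns:table="urn:oasis:names:tc:opendocument:xmlns:table:1.0"',
  ' xmlns:text="urn:oasis:names:tc:opendocument:xmlns:text:1.0"')

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

ods_cell_xml <- function(value) {
  if (is.na(value) || !nzchar(value)) return("<table:table-cell/>")
  num <- suppressWarnings(as.numeric(value))
  if (!is.na(num)) {
    sprintf('<table:table-cell office:value-type="float" office:value="%s"><text:p>%s</text:p></table:table-cell>',
            value, xml_escape(value))
  } else {
    sprintf('<table:table-cell office:value-type="string"><text:p>%s</text:p></table:table-cell>',
            xml_escape(value))
  }
}

ods_write_tabs <- function(tabs, path) {
  sheets <- vapply(names(tabs), function(tab) {
    rows <- apply(tabs[[tab]], 1, function(row) {
      paste0("<table:table-row>",
             paste(vapply(row, ods_cell_xml, character(1)), collapse = ""),
             "</table:table-row>")
    })
    sprintf('<table:table table:name="%s">%s</table:table>',
            xml_escape(tab), paste(rows, collapse = ""))
  }, character(1))
  content <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<office:document-content', ODF_NS, ' office:version="1.2">',
    '<office:body><office:spreadsheet>',
    paste(sheets, collapse = ""),
    '</office:spreadsheet></office:body></office:document-content>')
  manifest <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<manifest:manifest xmlns:manifest="urn:oasis:names:tc:opendocument:xmlns:manifest:1.0" manifest:version="1.2">',
    '<manifest:file-entry manifest:full-path="/" manifest:media-type="application/vnd.oasis.opendocument.spreadsheet"/>',
    '<manifest:file-entry manifest:full-path="content.xml" manifest:media-type="text/xml"/>',
    '</manifest:manifest>')
  zip_write_stored(path, list(
    "mimetype" = charToRaw("application/vnd.oasis.opendocument.spreadsheet"),
    "META-INF/manifest.xml" = charToRaw(manifest),
    "content.xml" = charToRaw(content)))
  invisible(path)
}

ods_read_tabs <- function(path) {
  content <- zip_read_entry(path, "content.xml")
  doc <- xml2::read_xml(content)
  ns <- xml2::xml_ns(doc)
  sheets <- xml2::xml_find_all(doc, ".//table:table", ns)
  tabs <- list()
  for (sheet in sheets) {
    name <- xml2::xml_attr(sheet, "table:name", ns)
    tabs[[name]] <- ods_sheet_to_matrix(sheet, ns, name)
  }
  tabs
}

ods_sheet_to_matrix <- function(sheet, ns, name) {
  rows <- xml2::xml_find_all(sheet, ".//table:table-row", ns)
  parsed <- list()
  for (row in rows) {
    rep_row <- xml2::xml_attr(row, "table:number-rows-repeated", ns)
    rep_row <- if (is.na(rep_row)) 1L else as.integer(rep_row)
    cells <- xml2::xml_find_all(row, "./table:table-cell", ns)
    vals <- character(0)
    for (cell in cells) {
      rep_col <- xml2::xml_attr(cell, "table:number-columns-repeated", ns)
      rep_col <- if (is.na(rep_col)) 1L else as.integer(rep_col)
      value <- xml2::xml_attr(cell, "office:value", ns)
      if (is.na(value)) {
        txt <- xml2::xml_text(cell)
        value <- if (nzchar(txt)) txt else ""
      }
      # spreadsheet apps pad with thousands of repeated empty cells
      if (!nzchar(value) && rep_col > 1000L) rep_col <- 1L
      vals <- c(vals, rep(value, rep_col))
    }
    if (rep_row > 1000L && all(!nzchar(vals))) rep_row <- 1L
    parsed <- c(parsed, rep(list(vals), rep_row))
  }
  # drop trailing all-empty rows, then pad/truncate to the widest used row
  while (length(parsed) > 0 && all(!nzchar(parsed[[length(parsed)]])))
    parsed[[length(parsed)]] <- NULL
  if (length(parsed) == 0)
    stop(sprintf("tab %s is empty", name), call. = FALSE)
  width <- max(vapply(parsed, function(v) {
    used <- which(nzchar(v))
    if (length(used)) max(used) else 0L
  }, integer(1)))
  out <- matrix("", length(parsed), width)
  for (i in seq_along(parsed)) {
    v <- parsed[[i]][seq_len(min(width, length(parsed[[i]])))]
    out[i, seq_along(v)] <- v
  }
  out
}
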