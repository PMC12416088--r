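#' Read a tabular corpus (CSV, TSV or XLSX)
#'
#' A header row is required, with at least a `title` or `body`/`abstract`
#' column. An optional label column named `included` or `label`
#' (case-insensitive; `included` wins if both are present) marks prior
#' screening decisions: 1 relevant, 0 irrelevant, blank unknown.
#'
#' @param path file path.
#' @param dialect `"csv"`, `"tsv"` or `"xlsx"`; guessed from the file
#'   extension when omitted.
#' @return a [corpus()]; row order is preserved.
#' @export
read_tabular <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  dialect <- dialect %||% switch(tolower(tools::file_ext(path)),
                                 csv = "csv", tsv = "tsv", txt = "tsv",
                                 xlsx = "xlsx", "csv")
  df <- switch(dialect,
    csv = ,
    tsv = {
      sep <- if (dialect == "csv") "," else "\t"
      out <- tryCatch(
        suppressWarnings(
          data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, colClasses = "character",
                            na.strings = NULL)),
        error = function(e) abort_format(sprintf("cannot parse %s: %s", path,
                                                 conditionMessage(e))))
      out
    },
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        abort_format("reading xlsx requires the readxl package")
      as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
    },
    abort_format(sprintf("unknown dialect '%s'", dialect))
  )
  if (nrow(df) == 0L || ncol(df) == 0L)
    abort_format(sprintf("empty or header-only file: %s", path))
  corpus(df, source_format = dialect)
}

#' Read a RIS citation file
#'
#' Labels are carried in `N1` fields: a line whose value contains the
#' sentinel tag `ASReview_relevant` marks the record relevant,
#' `ASReview_irrelevant` irrelevant; records with neither are unknown.
#' Non-sentinel N1 content is kept as the record note. All other RIS fields
#' are preserved verbatim for round-tripping.
#'
#' @param path file path.
#' @return a [corpus()].
#' @export
read_ris <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  refs <- parse_ris(lines)
  if (!length(refs)) abort_format(sprintf("no RIS references in %s", path))

  rows <- lapply(seq_along(refs), function(i) {
    tags <- refs[[i]]
    get1 <- function(tag) {
      v <- vapply(tags[vapply(tags, function(t) t$tag == tag, logical(1))],
                  function(t) t$value, character(1))
      if (length(v)) v[1L] else ""
    }
    n1 <- vapply(tags[vapply(tags, function(t) t$tag == "N1", logical(1))],
                 function(t) t$value, character(1))
    label <- if (any(grepl("ASReview_relevant", n1, fixed = TRUE))) 1L
             else if (any(grepl("ASReview_irrelevant", n1, fixed = TRUE))) 0L
             else NA_integer_
    note <- paste(n1[!grepl("ASReview_(ir)?relevant", n1)], collapse = "; ")
    id <- get1("ID")
    data.frame(record_id = if (nzchar(id)) id else as.character(i - 1L),
               title = get1("TI"), body = get1("AB"),
               label = label, note = note, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  out <- corpus(df, source_format = "ris")
  out$ris_extra <- lapply(refs, function(tags)
    Filter(function(t) !(t$tag %in% c("TI", "AB", "ID", "N1", "TY", "ER")), tags))
  out$ris_type <- vapply(refs, function(tags) {
    ty <- Filter(function(t) t$tag == "TY", tags)
    if (length(ty)) ty[[1L]]$value else "JOUR"
  }, character(1))
  out
}

# RIS line format: "XX  - value". References delimited by TY ... ER.
parse_ris <- function(lines) {
  refs <- list()
  cur <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^([A-Z][A-Z0-9])  ?- ?(.*)$", ln))[[1L]]
    if (length(m) == 0L) {
      if (is.null(cur)) abort_format(sprintf("malformed RIS line: %s", ln))
      # continuation line: append to previous tag value
      k <- length(cur)
      cur[[k]]$value <- paste(cur[[k]]$value, trimws(ln))
      next
    }
    tag <- m[2L]; value <- m[3L]
    if (tag == "TY") {
      if (!is.null(cur)) abort_format("RIS reference opened before previous ER")
      cur <- list(list(tag = "TY", value = value))
    } else if (tag == "ER") {
      if (is.null(cur)) abort_format("RIS 'ER' without opening 'TY'")
      refs[[length(refs) + 1L]] <- cur
      cur <- NULL
    } else {
      if (is.null(cur)) abort_format(sprintf("RIS tag outside reference: %s", ln))
      cur[[length(cur) + 1L]] <- list(tag = tag, value = value)
    }
  }
  if (!is.null(cur)) abort_format("unterminated RIS reference (missing ER)")
  refs
}

#' Write a labeled corpus
#'
#' Writes the corpus with the supplied labels so screening can be re-imported
#' and continued later. Tabular output carries an `included` column
#' (`1`/`0`/blank); RIS output carries one `N1` sentinel line per labeled
#' record (`ASReview_relevant` / `ASReview_irrelevant`).
#'
#' @param corpus a [corpus()].
#' @param labels integer vector aligned to the corpus (1/0/NA); defaults to
#'   the corpus's own known labels.
#' @param path output file path.
#' @param format `"csv"`, `"tsv"` or `"ris"`.
#' @return `path`, invisibly.
#' @export
write_labeled <- function(corpus, labels = corpus_labels(corpus), path,
                          format = c("csv", "tsv", "ris")) {
  format <- match.arg(format)
  if (length(labels) != n_records(corpus))
    abort_validation("labels must align with the corpus")
  labels <- parse_label(labels)
  if (format %in% c("csv", "tsv")) {
    df <- data.frame(record_id = record_ids(corpus),
                     title = corpus$records$title,
                     abstract = corpus$records$body,
                     included = ifelse(is.na(labels), "", as.character(labels)),
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = if (format == "csv") "," else "\t")
  } else {
    writeLines(format_ris(corpus, labels), path)
  }
  invisible(path)
}

format_ris <- function(corpus, labels) {
  n <- n_records(corpus)
  types <- corpus$ris_type %||% rep("JOUR", n)
  extras <- corpus$ris_extra %||% rep(list(list()), n)
  out <- character(0)
  for (i in seq_len(n)) {
    lines <- c(sprintf("TY  - %s", types[i]),
               sprintf("ID  - %s", corpus$records$record_id[i]),
               sprintf("TI  - %s", corpus$records$title[i]),
               sprintf("AB  - %s", corpus$records$body[i]))
    for (t in extras[[i]]) lines <- c(lines, sprintf("%s  - %s", t$tag, t$value))
    if (nzchar(corpus$records$note[i]))
      lines <- c(lines, sprintf("N1  - %s", corpus$records$note[i]))
    if (!is.na(labels[i]))
      lines <- c(lines, sprintf("N1  - %s",
                 if (labels[i] == 1L) "ASReview_relevant" else "ASReview_irrelevant"))
    out <- c(out, lines, "ER  - ", "")
  }
  out
}
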