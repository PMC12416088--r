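#' Screening corpus
#'
#' A corpus is an ordered collection of screenable records (typically the
#' title and abstract of a reference retrieved by a systematic search). Each
#' record carries an opaque stable identifier, its text, and an optional
#' known label: `1` (relevant), `0` (irrelevant) or `NA` (unlabeled). Record
#' order is preserved exactly as read, because the top-down query strategy
#' and all tie-breaking rules are defined in terms of corpus position.
#'
#' @param records a data.frame with at least one of `title`, `body`
#'   (synonyms: `abstract`, `text`). Optional columns: `record_id`, `label`
#'   (or `included`), `tags`, `note`, `exclusion_reasons`, `discuss`.
#'   If no id column is present, 0-based positional ids are assigned; they
#'   are stable for a given file but not across edits.
#' @param source_format one of `"csv"`, `"tsv"`, `"xlsx"`, `"ris"`,
#'   `"synthetic"`, `"memory"`.
#' @return an object of class `corpus`.
#' @export
corpus <- function(records, source_format = "memory") {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  nm <- tolower(names(records))
  names(records) <- nm

  title <- if ("title" %in% nm) as.character(records[["title"]]) else rep("", nrow(records))
  body_col <- intersect(c("body", "abstract", "text"), nm)
  body <- if (length(body_col)) as.character(records[[body_col[1L]]]) else rep("", nrow(records))
  if (!("title" %in% nm) && !length(body_col))
    abort_format("corpus requires a title or body/abstract/text column")

  id_col <- intersect(c("record_id", "id"), nm)
  record_id <- if (length(id_col)) as.character(records[[id_col[1L]]])
               else as.character(seq_len(nrow(records)) - 1L)
  if (anyDuplicated(record_id))
    abort_validation("duplicate record_id values in corpus")

  # "included" wins over "label" when both are present.
  lab_col <- intersect(c("included", "label", "known_label"), nm)
  label <- if (length(lab_col)) parse_label(records[[lab_col[1L]]])
           else rep(NA_integer_, nrow(records))

  df <- data.frame(
    record_id = record_id,
    title = ifelse(is.na(title), "", title),
    body = ifelse(is.na(body), "", body),
    label = label,
    tags = chr_or(records, "tags", nrow(records)),
    note = chr_or(records, "note", nrow(records)),
    exclusion_reasons = chr_or(records, "exclusion_reasons", nrow(records)),
    discuss = lgl_or(records, "discuss", nrow(records)),
    stringsAsFactors = FALSE
  )
  structure(list(records = df, source_format = source_format),
            class = "corpus")
}

chr_or <- function(df, col, n) {
  if (col %in% names(df)) {
    x <- as.character(df[[col]])
    ifelse(is.na(x), "", x)
  } else rep("", n)
}

lgl_or <- function(df, col, n) {
  if (col %in% names(df)) {
    x <- df[[col]]
    if (is.character(x)) x <- x %in% c("1", "TRUE", "true", "yes")
    as.logical(ifelse(is.na(x), FALSE, x))
  } else rep(FALSE, n)
}

# 1 -> relevant, 0 -> irrelevant, blank/NA -> unknown.
parse_label <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(x)
  } else {
    x <- trimws(as.character(x))
    out <- ifelse(x %in% c("", "NA"), NA_integer_,
                  suppressWarnings(as.integer(x)))
  }
  bad <- !is.na(out) & !(out %in% c(0L, 1L))
  if (any(bad))
    abort_validation(sprintf("label values must be 0, 1 or blank (got %s)",
                             paste(unique(out[bad]), collapse = ", ")))
  out
}

#' @exportS3Method base::print
print.corpus <- function(x, ...) {
  lab <- corpus_labels(x)
  cat(sprintf("<corpus> %d records (%s): %d relevant, %d irrelevant, %d unlabeled\n",
              n_records(x), x$source_format,
              sum(lab == 1L, na.rm = TRUE), sum(lab == 0L, na.rm = TRUE),
              sum(is.na(lab))))
  invisible(x)
}

#' Number of records in a corpus
#' @param x a [corpus()]
#' @return integer count
#' @export
n_records <- function(x) nrow(x$records)

#' Known labels of a corpus
#' @param x a [corpus()]
#' @return integer vector in corpus order: 1 relevant, 0 irrelevant, NA unknown
#' @export
corpus_labels <- function(x) x$records$label

#' @export
as.data.frame.corpus <- function(x, ...) x$records

#' Record ids of a corpus
#' @param x a [corpus()]
#' @return character vector in corpus order
#' @export
record_ids <- function(x) x$records$record_id

record_text <- function(x) {
  paste(x$records$title, x$records$body)
}

# Content fingerprint used by the feature cache; no digest dependency, so a
# simple serialization-sum over the text fields and ids.
corpus_fingerprint <- function(x) {
  raw <- serialize(list(x$records$record_id, x$records$title, x$records$body),
                   connection = NULL, version = 2L)
  v <- as.integer(raw)
  sprintf("%d-%.0f-%.0f", length(v), sum(v),
          sum(v * (seq_along(v) %% 97L + 1L)))
}
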