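EVENT_LOG_COLUMNS <- c("row_no", "record_id", "label", "labeling_time",
                       "training_set_size", "queue_iteration", "queue_rank",
                       "model_name", "user_id", "note", "tags",
                       "exclusion_reasons", "discuss")

# Construct one event row. Allocation events (a record handed to an annotator
# but never labeled) carry label = NA and no labeling_time.
event_row <- function(row_no, record_id, label = NA_integer_,
                      labeling_time = "", training_set_size = NA_integer_,
                      queue_iteration = NA_integer_, queue_rank = NA_integer_,
                      model_name = "", user_id = "", note = "", tags = "",
                      exclusion_reasons = "", discuss = FALSE) {
  data.frame(row_no = as.integer(row_no), record_id = as.character(record_id),
             label = as.integer(label), labeling_time = labeling_time,
             training_set_size = as.integer(training_set_size),
             queue_iteration = as.integer(queue_iteration),
             queue_rank = as.integer(queue_rank),
             model_name = model_name, user_id = user_id, note = note,
             tags = tags, exclusion_reasons = exclusion_reasons,
             discuss = discuss, stringsAsFactors = FALSE)
}

empty_event_log <- function() {
  data.frame(row_no = integer(0), record_id = character(0),
             label = integer(0), labeling_time = character(0),
             training_set_size = integer(0), queue_iteration = integer(0),
             queue_rank = integer(0), model_name = character(0),
             user_id = character(0), note = character(0),
             tags = character(0), exclusion_reasons = character(0),
             discuss = logical(0), stringsAsFactors = FALSE)
}

#' Write a project event log as CSV
#'
#' One row per labeling or allocation event, in the fixed column order
#' `row_no,record_id,label,labeling_time,training_set_size,queue_iteration,`
#' `queue_rank,model_name,user_id,note,tags,exclusion_reasons,discuss`.
#' Timestamps are ISO-8601 with millisecond precision in live mode and
#' integer ticks in scripted/simulated mode.
#'
#' @param log an event-log data.frame (e.g. `$event_log` of a finished run).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  log <- as.data.frame(log)[, EVENT_LOG_COLUMNS, drop = FALSE]
  data.table::fwrite(log, path, sep = ",", na = "")
  invisible(path)
}

#' Read an event log written by [write_event_log()]
#' @param path CSV path.
#' @return event-log data.frame.
#' @export
read_event_log <- function(path) {
  df <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("record_id",
                            "labeling_time", "model_name", "user_id", "note",
                            "tags", "exclusion_reasons")),
                          na.strings = "")
  df$label <- suppressWarnings(as.integer(df$label))
  df$discuss <- as.logical(df$discuss) %in% TRUE
  for (col in c("labeling_time", "model_name", "user_id", "note", "tags",
                "exclusion_reasons"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", df[[col]])
  df[, EVENT_LOG_COLUMNS, drop = FALSE]
}

#' Replay an event log
#'
#' Recomputes the summary state of a screening project purely from its
#' logged history: how many records were labeled, how many of those were
#' relevant, how many records were allocated to an annotator but never
#' labeled, the per-agent segments (split on `model_name` change), and
#' per-user label counts. Replay is a pure function of the log; the paper
#' trail alone must reproduce the run.
#'
#' @param log event-log data.frame (or path to one).
#' @param corpus_size total number of records in the screened corpus.
#' @return a list of class `replay_summary` with elements `labeled_count`,
#'   `relevant_count`, `irrelevant_count`, `allocated_unlabeled_count`,
#'   `never_touched`, `segments` (data.frame), `per_user` (named counts).
#' @export
replay_event_log <- function(log, corpus_size) {
  if (is.character(log)) log <- read_event_log(log)
  log <- as.data.frame(log)
  if (nrow(log)) {
    if (any(diff(log$row_no) <= 0L))
      abort_integrity("row_no must be strictly increasing")
    unalloc <- is.na(log$label)
    if (any(unalloc & nzchar(log$labeling_time)))
      abort_integrity("an unlabeled (allocation) row must have no labeling_time")
    labeled <- log[!is.na(log$label), , drop = FALSE]
    if (anyDuplicated(labeled$record_id))
      abort_integrity("duplicate terminal label for a record_id")
    # training_set_size must never decrease within one model segment
    seg_id <- cumsum(c(TRUE, log$model_name[-1L] != log$model_name[-nrow(log)]))
    for (s in split(log$training_set_size, seg_id)) {
      s <- s[!is.na(s)]
      if (length(s) > 1L && any(diff(s) < 0L))
        abort_integrity("training_set_size decreases within a model segment")
    }
    seg_models <- vapply(split(log$model_name, seg_id), `[`, character(1), 1L)
    segments <- data.frame(
      segment = seq_along(seg_models), model_name = unname(seg_models),
      n_rows = as.integer(table(seg_id)),
      n_labels = vapply(split(!is.na(log$label), seg_id), sum, integer(1),
                        USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
    alloc_only <- setdiff(log$record_id[unalloc], labeled$record_id)
    per_user <- table(labeled$user_id)
  } else {
    labeled <- log
    segments <- data.frame(segment = integer(0), model_name = character(0),
                           n_rows = integer(0), n_labels = integer(0))
    alloc_only <- character(0)
    per_user <- table(character(0))
  }
  out <- list(
    labeled_count = nrow(labeled),
    relevant_count = sum(labeled$label == 1L),
    irrelevant_count = sum(labeled$label == 0L),
    allocated_unlabeled_count = length(alloc_only),
    never_touched = corpus_size - nrow(labeled) - length(alloc_only),
    segments = segments,
    per_user = per_user)
  class(out) <- "replay_summary"
  out
}

#' @exportS3Method base::print
print.replay_summary <- function(x, ...) {
  cat(sprintf(paste0("<replay_summary> labeled %d (K+=%d, K-=%d), ",
                     "allocated-unlabeled %d, untouched %d, %d segment(s)\n"),
              x$labeled_count, x$relevant_count, x$irrelevant_count,
              x$allocated_unlabeled_count, x$never_touched,
              nrow(x$segments)))
  invisible(x)
}

iso_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}
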