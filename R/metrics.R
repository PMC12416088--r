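full_ordering <- function(result) {
  stopifnot(inherits(result, "simulation_result") ||
            inherits(result, "crowd_run"))
  if (inherits(result, "simulation_result")) {
    truth <- corpus_labels(result$config$corpus)
    ids <- record_ids(result$config$corpus)
    screened <- result$results$record_id
    rest <- result$final_ranking
  } else {
    truth <- result$state$labels
    ids <- result$state$ids
    log <- result$event_log
    screened <- log$record_id[!is.na(log$label)]
    rest <- result$state$ranking[!(result$state$ranking %in% screened)]
  }
  ord <- c(screened, rest)
  data.frame(record_id = ord, label = truth[match(ord, ids)],
             screened = c(rep(TRUE, length(screened)),
                          rep(FALSE, length(rest))),
             stringsAsFactors = FALSE)
}

#' Cumulative recall curve
#'
#' Number of relevant records found as a function of records screened. The
#' screening order is extended past the stopping point by the final model's
#' ranking of the unscreened remainder, giving a curve over the whole
#' corpus.
#'
#' @param result a `simulation_result`, or an integer 0/1 vector of labels
#'   in screening order.
#' @return a `recall_curve`: list with `N`, `R`, `r` (cumulative relevant
#'   found at positions 1..N), `n_screened`.
#' @export
recall_curve <- function(result) {
  if (is.numeric(result)) {
    labels <- as.integer(result)
    n_screened <- length(labels)
  } else {
    ord <- full_ordering(result)
    labels <- ord$label
    n_screened <- sum(ord$screened)
  }
  if (anyNA(labels)) abort_validation("recall curve requires known labels")
  structure(list(N = length(labels), R = sum(labels == 1L),
                 r = cumsum(labels == 1L), n_screened = n_screened),
            class = "recall_curve")
}

#' Work saved over sampling at a recall level
#'
#' `WSS@r = (N - n_r)/N - (1 - r)` where `n_r` is the smallest number of
#' screened records at which recall reaches `r`: the screening effort saved
#' relative to exhaustive screening, discounting the `1 - r` that random
#' screening would nominally save.
#'
#' @param curve a [recall_curve()].
#' @param level target recall in (0, 1].
#' @return a fraction (can be negative for orderings worse than random).
#' @export
wss_at <- function(curve, level = 0.95) {
  if (curve$R == 0L) abort_domain("no relevant records")
  reach <- which(curve$r / curve$R >= level)
  if (!length(reach))
    abort_domain(sprintf("recall never reaches %g within the curve", level))
  n_r <- reach[1L]
  (curve$N - n_r) / curve$N - (1 - level)
}

#' Extra relevant records found at a screening fraction
#'
#' `ERF@f = r(floor(f*N))/R - f`: the proportion of relevant records found
#' after screening a fraction `f` of the corpus, minus the random-screening
#' baseline `f`.
#'
#' @param curve a [recall_curve()].
#' @param fraction screening fraction in \[0, 1\].
#' @return a fraction in \[-1, 1\].
#' @export
erf_at <- function(curve, fraction) {
  if (fraction < 0 || fraction > 1)
    abort_validation("fraction must be in [0, 1]")
  i <- floor(fraction * curve$N)
  r_i <- if (i == 0L) 0L else curve$r[i]
  r_i / curve$R - fraction
}

#' Time to discovery of one relevant record
#'
#' The fraction of the corpus that must be screened to reach the record:
#' its 1-based screening position divided by N. Records never screened use
#' their extrapolated position in the final model ranking.
#'
#' @param result a `simulation_result`.
#' @param record_id a relevant record's id.
#' @return a fraction in (0, 1].
#' @export
time_to_discovery <- function(result, record_id) {
  ord <- full_ordering(result)
  pos <- match(record_id, ord$record_id)
  if (is.na(pos)) abort_validation(sprintf("unknown record '%s'", record_id))
  if (ord$label[pos] != 1L)
    abort_domain("time to discovery is defined for relevant records only")
  pos / nrow(ord)
}

#' Average time to discovery
#'
#' Mean [time_to_discovery()] over all relevant records; tracks ranking
#' quality over the whole screening process without an arbitrary cutoff.
#'
#' @param result a `simulation_result`.
#' @return a fraction.
#' @export
atd <- function(result) {
  ord <- full_ordering(result)
  rel <- which(ord$label == 1L)
  if (!length(rel)) abort_domain("no relevant records")
  mean(rel / nrow(ord))
}

#' Normalized screening loss
#'
#' `loss = (A_perfect - A_actual) / (A_perfect - A_worst)` where `A` is the
#' area under the cumulative-relevant-found step curve over positions 1..N;
#' perfect puts all R relevant records first, worst puts them last. 0 is a
#' perfect ordering, 1 the worst possible.
#'
#' @param curve a [recall_curve()] complete to all-relevant-found or a full
#'   screen.
#' @return a fraction in \[0, 1\].
#' @export
loss_norm <- function(curve) {
  N <- curve$N; R <- curve$R
  if (R == 0L || R == N)
    abort_domain("loss is undefined for single-class corpora")
  if (curve$r[N] < R)
    abort_domain("curve must be complete (all relevant found)")
  a_actual <- sum(curve$r)
  a_perfect <- R * (R + 1) / 2 + R * (N - R)
  a_worst <- R * (R + 1) / 2
  (a_perfect - a_actual) / (a_perfect - a_worst)
}

#' Confusion counts at a screening cutoff
#'
#' Treating the first `n` screened records as predicted positive:
#' TP relevant within the cutoff, FP the rest of the cutoff, FN the
#' relevant beyond it, TN the remainder.
#'
#' @param result a `simulation_result` or [recall_curve()].
#' @param n cutoff, `1 <= n <= N`.
#' @return named integer vector `(tp, fp, tn, fn)`.
#' @export
confusion_at <- function(result, n) {
  curve <- if (inherits(result, "recall_curve")) result else recall_curve(result)
  if (n < 1L || n > curve$N) abort_validation("cutoff out of range")
  tp <- curve$r[n]
  fp <- n - tp
  fn <- curve$R - tp
  tn <- curve$N - n - fn
  c(tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
    fn = as.integer(fn))
}

#' Percent change between two mean losses
#'
#' `100 * (loss_a - loss_b) / loss_a`, rounded to one decimal: the
#' percentage reduction achieved by configuration b over configuration a.
#'
#' @param loss_a baseline mean loss (> 0).
#' @param loss_b comparison mean loss.
#' @return percent change, one decimal.
#' @export
compare_mean_losses <- function(loss_a, loss_b) {
  if (!is_scalar_number(loss_a) || loss_a <= 0)
    abort_domain("baseline loss must be > 0")
  round(100 * (loss_a - loss_b) / loss_a, 1L)
}

#' Full metrics report for a finished run
#'
#' @param result a `simulation_result`.
#' @param wss_levels recall levels for WSS.
#' @param erf_fractions screening fractions for ERF.
#' @param recall_points screening fractions at which to report recall.
#' @return a `metrics_report` list, JSON-serializable.
#' @export
screening_metrics <- function(result, wss_levels = c(0.85, 0.95),
                              erf_fractions = c(0.1, 0.5),
                              recall_points = c(0.1, 0.25, 0.5, 1.0)) {
  curve <- recall_curve(result)
  ord <- full_ordering(result)
  rel_ids <- ord$record_id[ord$label == 1L]
  report <- list(
    n_records = curve$N, n_relevant = curve$R,
    n_screened = curve$n_screened,
    recall = stats::setNames(
      vapply(recall_points, function(f) {
        i <- max(1L, floor(f * curve$N)); curve$r[i] / curve$R
      }, numeric(1)), paste0("at_", recall_points)),
    wss = stats::setNames(
      vapply(wss_levels, function(l)
        tryCatch(wss_at(curve, l), alscreen_error = function(e) NA_real_),
        numeric(1)), paste0("at_", wss_levels)),
    erf = stats::setNames(vapply(erf_fractions, erf_at, numeric(1),
                                 curve = curve),
                          paste0("at_", erf_fractions)),
    td = stats::setNames(vapply(rel_ids, time_to_discovery, numeric(1),
                                result = result), rel_ids),
    atd = atd(result),
    loss = tryCatch(loss_norm(curve), alscreen_error = function(e) NA_real_),
    confusion = as.list(confusion_at(curve, max(1L, curve$n_screened))))
  class(report) <- "metrics_report"
  report
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> N=%d R=%d screened=%d ATD=%.4f loss=%.4f\n",
              x$n_records, x$n_relevant, x$n_screened, x$atd,
              if (is.na(x$loss)) NA else x$loss))
  invisible(x)
}

#' Plot a recall curve
#'
#' Draws the achieved recall curve with random-baseline and
#' perfect-ordering reference lines.
#'
#' @param result a `simulation_result` or [recall_curve()].
#' @param path optional output file (png); plots to the active device when
#'   NULL.
#' @return invisibly, the curve.
#' @export
plot_recall <- function(result, path = NULL) {
  curve <- if (inherits(result, "recall_curve")) result else recall_curve(result)
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  i <- seq_len(curve$N)
  plot(i, curve$r / curve$R, type = "s", xlab = "records screened",
       ylab = "recall", ylim = c(0, 1), col = "steelblue", lwd = 2)
  graphics::lines(i, pmin(i, curve$R) / curve$R, lty = 2, col = "grey40")
  graphics::lines(i, i / curve$N, lty = 3, col = "grey60")
  graphics::legend("bottomright", c("achieved", "perfect", "random"),
                   lty = c(1, 2, 3), col = c("steelblue", "grey40", "grey60"),
                   bty = "n")
  invisible(curve)
}
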