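#' Simulation configuration
#'
#' A simulation re-enacts screening on a *fully labeled* corpus: the known
#' labels play the oracle, answering every query with the true label.
#'
#' @param corpus a [corpus()] with no unknown labels.
#' @param chain an [agent_chain()] (default: the tf-idf + linear-SVM
#'   default agent).
#' @param priors record ids labeled (with their true labels) before the
#'   first cycle; they count toward the minimum training set.
#' @param stop_if `"min"` (stop once every relevant record is found — the
#'   default), `"full"` (label everything), or an integer screening budget.
#' @param seed integer seed.
#' @param batch_size labels per retraining round (default 1: retrain after
#'   every label).
#' @return a `simulation_config`.
#' @export
simulation_config <- function(corpus, chain = chain_preset("default"),
                              priors = character(0), stop_if = "min",
                              seed = 1L, batch_size = 1L) {
  if (anyNA(corpus_labels(corpus)))
    abort_validation("simulation requires a fully labeled corpus")
  if (!all(priors %in% record_ids(corpus)))
    abort_validation("priors must be record ids present in the corpus")
  if (!(identical(stop_if, "min") || identical(stop_if, "full") ||
        is_scalar_number(stop_if)))
    abort_validation("stop_if must be 'min', 'full' or an integer budget")
  structure(list(corpus = corpus, chain = chain,
                 priors = unique(as.character(priors)),
                 stop_if = stop_if, seed = as.integer(seed),
                 batch_size = as.integer(batch_size)),
            class = "simulation_config")
}

#' Label prior records before the first cycle
#'
#' @param config a [simulation_config()].
#' @param ids record ids to pre-label with their true labels. Repeats are
#'   idempotent.
#' @return the updated config.
#' @export
label_priors <- function(config, ids) {
  if (!all(ids %in% record_ids(config$corpus)))
    abort_validation("unknown prior record id")
  config$priors <- unique(c(config$priors, as.character(ids)))
  config
}

#' Sample prior sets with geometric sizes
#'
#' Draws `n_sets` prior combinations: per class the set size is
#' `1 + Geometric(p)` (so always at least one relevant and one irrelevant
#' record), members uniform without replacement. Used to average
#' simulation results over prior-selection variability.
#'
#' @param corpus a fully labeled [corpus()].
#' @param n_sets number of prior sets.
#' @param seed integer seed.
#' @param p geometric success probability, default 0.5.
#' @return list of character id vectors.
#' @export
sample_priors <- function(corpus, n_sets = 10L, seed = 1L, p = 0.5) {
  lab <- corpus_labels(corpus)
  if (anyNA(lab)) abort_validation("sample_priors requires full labels")
  rel <- record_ids(corpus)[lab == 1L]
  irr <- record_ids(corpus)[lab == 0L]
  if (!length(rel) || !length(irr))
    abort_validation("both classes must be present")
  local_seed(seed, lapply(seq_len(n_sets), function(i) {
    n_rel <- min(1L + stats::rgeom(1L, p), length(rel))
    n_irr <- min(1L + stats::rgeom(1L, p), length(irr))
    c(sample(rel, n_rel), sample(irr, n_irr))
  }))
}

#' Run a full screening simulation
#'
#' The oracle answers every query with the true label; after each label (or
#' batch) the active agent retrains and re-ranks under the same policy as
#' the live task server (model-free agents rank once per segment; classifier
#' agents retrain once both classes are in the training set). By default the
#' run stops once all relevant records are found; any unscreened remainder
#' is reported in the ranking of the most recent iteration.
#'
#' @param config a [simulation_config()].
#' @param progress print the two progress counters (relevant found / total
#'   labeled)?
#' @return a `simulation_result` with `$results` (one row per labeled
#'   record, in screening order), `$final_ranking` (unscreened remainder),
#'   `$event_log` and `$config`.
#' @export
run_simulation <- function(config, progress = FALSE) {
  corpus <- config$corpus
  truth <- corpus_labels(corpus)
  ids <- record_ids(corpus)
  n <- length(ids)
  n_rel <- sum(truth == 1L)
  budget <- if (identical(config$stop_if, "min")) n
            else if (identical(config$stop_if, "full")) n
            else min(n, as.integer(config$stop_if))

  state <- screen_state(corpus, seed = config$seed)
  rows <- vector("list", n)
  nrows <- 0L
  record_row <- function(rid, lab) {
    nrows <<- nrows + 1L
    rows[[nrows]] <<- data.frame(
      order = nrows, record_id = rid, label = lab,
      training_set_size = state$ranking_train_size,
      queue_iteration = state$ranking_iteration,
      queue_rank = state$ranking_served,
      model_name = state$ranking_model, stringsAsFactors = FALSE)
  }

  # priors: labeled with true labels before the first cycle
  for (rid in config$priors) {
    lab <- truth[match(rid, ids)]
    state$ranking_served <- state$ranking_served + 1L
    state <- apply_label(state, rid, lab, user_id = "prior", time = "0")
    record_row(rid, lab)
  }

  rk <- compute_ranking(state, config$chain)
  state$n_rankings <- state$n_rankings + 1L
  state <- install_ranking(state, rk$ranking, rk$model, rk$train_size)
  seg_trained <- !is.null(config$chain$agents[[state$active_agent]]$classifier) &&
    min_training_ready(state)
  since_retrain <- 0L

  repeat {
    found <- sum(state$labels == 1L, na.rm = TRUE)
    labeled <- sum(!is.na(state$labels))
    if (progress)
      cat(sprintf("\rrelevant found: %d/%d | labeled: %d/%d",
                  found, n_rel, labeled, n))
    if (identical(config$stop_if, "min") && found == n_rel) break
    if (labeled >= budget) break
    nxt <- NA_character_
    for (rid in state$ranking)
      if (is.na(state$labels[match(rid, ids)])) { nxt <- rid; break }
    if (is.na(nxt)) break
    lab <- truth[match(nxt, ids)]
    state$ranking_served <- state$ranking_served + 1L
    state <- apply_label(state, nxt, lab, user_id = "oracle",
                         time = as.character(labeled + 1L))
    record_row(nxt, lab)
    since_retrain <- since_retrain + 1L

    decision <- evaluate_stopping(state, config$chain)
    while (decision == "handoff") {
      state <- advance_chain(state, config$chain)
      seg_trained <- FALSE
      decision <- evaluate_stopping(state, config$chain)
    }
    if (decision == "global_stop") { state$finished <- TRUE; break }

    agent <- config$chain$agents[[state$active_agent]]
    retrain <- if (is.null(agent$classifier)) !seg_trained
               else min_training_ready(state) &&
                    (agent$retrain || !seg_trained) &&
                    (since_retrain >= config$batch_size || !seg_trained)
    if (retrain) {
      rk <- compute_ranking(state, config$chain)
      state$n_rankings <- state$n_rankings + 1L
      state <- install_ranking(state, rk$ranking, rk$model, rk$train_size)
      seg_trained <- TRUE
      since_retrain <- 0L
    }
  }
  if (progress) cat("\n")

  results <- if (nrows) do.call(rbind, rows[seq_len(nrows)])
             else data.frame(order = integer(0), record_id = character(0),
                             label = integer(0))
  final_ranking <- state$ranking[state$ranking %in% ids[is.na(state$labels)]]
  structure(list(results = results, final_ranking = final_ranking,
                 event_log = state_event_log(state), state = state,
                 config = config, n_records = n, n_relevant = n_rel),
            class = "simulation_result")
}

#' @exportS3Method base::print
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> screened %d/%d records, found %d/%d relevant\n",
              nrow(x$results), x$n_records,
              sum(x$results$label == 1L), x$n_relevant))
  invisible(x)
}
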