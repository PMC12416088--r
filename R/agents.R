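#' Hand-off policy of an agent
#'
#' Decides when an agent stops and control passes to its successor.
#' `labeled_count`: after `threshold` labels under this agent.
#' `labeled_fraction`: after labels under this agent reach `threshold`
#' (a fraction) of the whole corpus. `consecutive_irrelevant`: once the
#' trailing run of irrelevant labels reaches `threshold` (the classic
#' stopping heuristic). `never`: the agent runs until the global stop.
#' Segment counters (and the trailing run) count only labels made under the
#' current agent; both reset to zero on hand-off.
#'
#' @param kind one of `"labeled_count"`, `"labeled_fraction"`,
#'   `"consecutive_irrelevant"`, `"never"`.
#' @param threshold positive number (a fraction for `labeled_fraction`).
#' @return a `handoff_policy`.
#' @export
handoff_policy <- function(kind = c("never", "labeled_count",
                                    "labeled_fraction",
                                    "consecutive_irrelevant"),
                           threshold = NULL) {
  kind <- match.arg(kind)
  if (kind != "never") {
    if (!is_scalar_number(threshold) || threshold <= 0)
      abort_validation("threshold must be > 0")
  }
  structure(list(kind = kind, threshold = threshold), class = "handoff_policy")
}

#' Agent specification
#'
#' One learner configuration: feature extractor, classifier, balancer and
#' querier, plus the hand-off policy. Only the querier is mandatory; a
#' classifier is present if and only if a vectorizer is.
#'
#' @param name display name; also the `model_name` written to the event log.
#' @param vectorizer a [vectorizer_spec()] or NULL.
#' @param classifier a [classifier_spec()] or NULL.
#' @param balancer a [balancer_spec()].
#' @param querier a [querier_spec()].
#' @param handoff a [handoff_policy()].
#' @param retrain if FALSE the task server trains this agent once per
#'   segment and never again (for expensive models).
#' @return an `agent_spec`.
#' @export
agent_spec <- function(name, vectorizer = NULL, classifier = NULL,
                       balancer = balancer_spec(), querier = querier_spec(),
                       handoff = handoff_policy("never"), retrain = TRUE) {
  if (is.null(querier)) abort_validation("the querier is mandatory for an agent")
  if (is.null(classifier) != is.null(vectorizer))
    abort_validation("classifier present if and only if vectorizer present")
  structure(list(name = name, vectorizer = vectorizer, classifier = classifier,
                 balancer = balancer, querier = querier, handoff = handoff,
                 retrain = isTRUE(retrain)),
            class = "agent_spec")
}

#' Ordered agent chain
#'
#' @param ... `agent_spec`s in hand-off order (A1 .. An). After the last
#'   agent there is no successor: its hand-off condition triggers the
#'   global stop and the export of the relevant collection.
#' @return an `agent_chain`.
#' @export
agent_chain <- function(...) {
  agents <- list(...)
  if (length(agents) == 1L && is.list(agents[[1L]]) &&
      !inherits(agents[[1L]], "agent_spec"))
    agents <- agents[[1L]]
  if (!length(agents)) abort_validation("an agent chain needs >= 1 agent")
  stopifnot(all(vapply(agents, inherits, logical(1), "agent_spec")))
  structure(list(agents = agents), class = "agent_chain")
}

#' Named chain presets
#'
#' `"default"`: one tf-idf (uni+bigram) + linear-SVM agent with balanced
#' weighting and certainty (max) querying, never hands off.
#' `"default-nb"`: same but multinomial naive Bayes.
#' `"worked-example"`: the four-agent calibration chain — random screening
#' for 100 labels, random until 5% of the corpus is labeled, then
#' tf-idf + naive Bayes and finally tf-idf + SVM, each stopping after 100
#' consecutive irrelevant labels.
#'
#' @param name preset name.
#' @param seed base seed stored in the queriers/classifiers.
#' @return an [agent_chain()].
#' @export
chain_preset <- function(name = c("default", "default-nb", "worked-example"),
                         seed = 1L) {
  name <- match.arg(name)
  tfidf <- vectorizer_spec("tfidf", c(1L, 2L))
  switch(name,
    "default" = agent_chain(agent_spec(
      "tfidf-svm", tfidf, classifier_spec("linear-svm", random_seed = seed),
      balancer_spec(), querier_spec("max", random_seed = seed))),
    "default-nb" = agent_chain(agent_spec(
      "tfidf-nb", tfidf, classifier_spec("multinomial-bayes", random_seed = seed),
      balancer_spec(), querier_spec("max", random_seed = seed))),
    "worked-example" = agent_chain(
      agent_spec("random-100", querier = querier_spec("random", random_seed = seed),
                 handoff = handoff_policy("labeled_count", 100)),
      agent_spec("random-5pct", querier = querier_spec("random", random_seed = seed),
                 handoff = handoff_policy("labeled_fraction", 0.05)),
      agent_spec("tfidf-nb", tfidf,
                 classifier_spec("multinomial-bayes", random_seed = seed),
                 balancer_spec(), querier_spec("max", random_seed = seed),
                 handoff = handoff_policy("consecutive_irrelevant", 100)),
      agent_spec("tfidf-svm", tfidf,
                 classifier_spec("linear-svm", random_seed = seed),
                 balancer_spec(), querier_spec("max", random_seed = seed),
                 handoff = handoff_policy("consecutive_irrelevant", 100))))
}

#' Live screening state
#'
#' Holds the set algebra of a project: the corpus K, the labeled sets K+
#' and K-, the unlabeled pool Ku, the current agent's batch counters
#' (k, k+, k-), the trailing-irrelevant run Dk, the ranking in force, and
#' the live allocations. `K = Ku + K+ + K-` holds after every operation.
#'
#' @param corpus a [corpus()].
#' @param seed integer base seed for every stochastic choice made on this
#'   state.
#' @return a `screen_state`.
#' @export
screen_state <- function(corpus, seed = 1L) {
  n <- n_records(corpus)
  state <- list(
    corpus = corpus,
    ids = record_ids(corpus),
    labels = rep(NA_integer_, n),
    seg_k = 0L, seg_kpos = 0L, seg_kneg = 0L, dk = 0L,
    ranking = record_ids(corpus),
    ranking_iteration = 0L, ranking_served = 0L,
    ranking_train_size = NA_integer_, ranking_model = "",
    allocations = list(),
    active_agent = 1L, finished = FALSE, stop_reason = NULL,
    user_stop = FALSE,
    seed = as.integer(seed), n_rankings = 0L,
    cache = feature_cache(),
    events = list(), next_row = 1L)
  class(state) <- "screen_state"
  state
}

#' @exportS3Method base::print
print.screen_state <- function(x, ...) {
  cat(sprintf(paste0("<screen_state> |K|=%d |K+|=%d |K-|=%d |Ku|=%d ",
                     "agent %d, k=%d, dk=%d%s\n"),
              length(x$labels), sum(x$labels == 1L, na.rm = TRUE),
              sum(x$labels == 0L, na.rm = TRUE), sum(is.na(x$labels)),
              x$active_agent, x$seg_k, x$dk,
              if (x$finished) " [finished]" else ""))
  invisible(x)
}

pool_ids_of <- function(state) state$ids[is.na(state$labels)]

allocated_ids <- function(state) {
  vapply(state$allocations, function(a) a$record_id, character(1),
         USE.NAMES = FALSE)
}

#' Is the minimum training set reached?
#'
#' @param state a [screen_state()].
#' @return TRUE iff at least one relevant and one irrelevant label exist.
#' @export
min_training_ready <- function(state) {
  sum(state$labels == 1L, na.rm = TRUE) >= 1L &&
    sum(state$labels == 0L, na.rm = TRUE) >= 1L
}

#' Evaluate hand-off and global stopping
#'
#' The global stop fires when the pool is empty, when a user stop was
#' requested, or when the active agent's hand-off condition is met with no
#' successor; a hand-off fires when the condition is met and a successor
#' exists.
#'
#' @param state a [screen_state()].
#' @param chain an [agent_chain()].
#' @return `"continue"`, `"handoff"` or `"global_stop"`.
#' @export
evaluate_stopping <- function(state, chain) {
  if (state$user_stop) return("global_stop")
  if (!any(is.na(state$labels))) return("global_stop")
  agent <- chain$agents[[state$active_agent]]
  pol <- agent$handoff
  met <- switch(pol$kind,
    never = FALSE,
    labeled_count = state$seg_k >= pol$threshold,
    labeled_fraction = state$seg_k >= pol$threshold * length(state$labels),
    consecutive_irrelevant = state$dk >= pol$threshold)
  if (!met) return("continue")
  if (state$active_agent < length(chain$agents)) "handoff" else "global_stop"
}

#' Advance the chain to the next agent
#'
#' Labels and feature caches carry over; the segment counters k, k+, k-
#' and the trailing-irrelevant run reset to zero.
#'
#' @param state a [screen_state()] for which [evaluate_stopping()] returned
#'   `"handoff"`.
#' @param chain an [agent_chain()].
#' @return the updated state.
#' @export
advance_chain <- function(state, chain) {
  if (state$active_agent >= length(chain$agents))
    stop("internal error: no successor agent to hand off to")
  state$active_agent <- state$active_agent + 1L
  state$seg_k <- 0L; state$seg_kpos <- 0L; state$seg_kneg <- 0L
  state$dk <- 0L
  state
}

# Apply one label; errors on duplicates; updates counters and appends an
# event row carrying the queue position the record was served from.
apply_label <- function(state, record_id, label, user_id = "oracle",
                        time = "", note = "", tags = "") {
  pos <- match(record_id, state$ids)
  if (is.na(pos)) abort_validation(sprintf("unknown record '%s'", record_id))
  if (!is.na(state$labels[pos]))
    abort_validation(sprintf("record '%s' is already labeled", record_id))
  label <- as.integer(label)
  if (!(label %in% c(0L, 1L))) abort_validation("label must be 0 or 1")
  state$labels[pos] <- label
  state$seg_k <- state$seg_k + 1L
  if (label == 1L) {
    state$seg_kpos <- state$seg_kpos + 1L
    state$dk <- 0L
  } else {
    state$seg_kneg <- state$seg_kneg + 1L
    state$dk <- state$dk + 1L
  }
  alloc <- state$allocations[[user_id]]
  if (!is.null(alloc) && alloc$record_id == record_id) {
    queue <- alloc   # where the record sat when it was served
    state$allocations[[user_id]] <- NULL
  } else {
    queue <- list(iteration = state$ranking_iteration,
                  rank = state$ranking_served)
  }
  # training size and model are those of the ranking in force *now*: a label
  # arriving while a newer model trains is credited to the model still
  # serving the queue, and sizes stay monotone within a model segment even
  # when an old allocation is labeled late.
  state$events[[length(state$events) + 1L]] <- event_row(
    row_no = state$next_row, record_id = record_id, label = label,
    labeling_time = as.character(time),
    training_set_size = state$ranking_train_size,
    queue_iteration = queue$iteration, queue_rank = queue$rank,
    model_name = if (nzchar(state$ranking_model)) state$ranking_model
                 else "random",
    user_id = user_id, note = note, tags = tags)
  state$next_row <- state$next_row + 1L
  state
}

# Install a freshly computed ranking (atomically replaces the one in force).
install_ranking <- function(state, ranking, model_name, train_size) {
  state$ranking <- ranking
  state$ranking_iteration <- state$ranking_iteration + 1L
  state$ranking_served <- 0L
  state$ranking_train_size <- as.integer(train_size)
  state$ranking_model <- model_name
  state
}

# Compute (but do not install) a ranking of the current pool under the
# active agent, from a snapshot of the labels. Falls back to random
# selection while the minimum training set (1 relevant + 1 irrelevant) is
# unavailable.
compute_ranking <- function(state, chain, labels = state$labels) {
  agent <- chain$agents[[state$active_agent]]
  pool <- state$ids[is.na(labels)]
  seed <- derive_seed(state$seed, state$n_rankings + 1L)
  train_size <- sum(!is.na(labels))
  trained <- !is.null(agent$classifier) &&
    sum(labels == 1L, na.rm = TRUE) >= 1L &&
    sum(labels == 0L, na.rm = TRUE) >= 1L
  if (trained) {
    fm <- feature_cache_get_or_build(state$cache, state$corpus, agent$vectorizer)
    tr_labels <- labels[!is.na(labels)]
    w <- compute_sample_weights(tr_labels, agent$balancer)
    scored <- train_and_score(fm, labels, w, agent$classifier)
    ranking <- rank_pool(scored, agent$querier, pool, seed = seed)
    model <- agent$name
  } else if (agent$querier$strategy %in% c("random", "top_down") &&
             is.null(agent$classifier)) {
    ranking <- rank_pool(NULL, agent$querier, pool, seed = seed)
    model <- if (agent$querier$strategy == "top_down") agent$name else "random"
    train_size <- NA_integer_
  } else {
    ranking <- rank_pool(NULL, querier_spec("random"), pool, seed = seed)
    model <- "random"
    train_size <- NA_integer_
  }
  list(ranking = ranking, model = model, train_size = train_size)
}

#' Run one active-learning cycle iteration
#'
#' Applies a batch of labels, evaluates hand-off/stopping, and — if the run
#' continues — retrains the active agent (when it has a classifier and the
#' minimum training set of one relevant plus one irrelevant label exists)
#' and installs a new ranking of the pool. Without a trainable model the
#' pool is ranked randomly (or top-down/randomly for model-free agents).
#'
#' @param state a [screen_state()].
#' @param chain an [agent_chain()].
#' @param labels_in data.frame with columns `record_id`, `label` (and
#'   optionally `user_id`, `time`); may have zero rows.
#' @return the updated state (`$finished` is TRUE after a global stop).
#' @export
run_cycle_iteration <- function(state, chain, labels_in = NULL) {
  if (!is.null(labels_in) && nrow(labels_in)) {
    for (i in seq_len(nrow(labels_in))) {
      state <- apply_label(state, labels_in$record_id[i], labels_in$label[i],
                           user_id = labels_in$user_id[i] %||% "oracle",
                           time = labels_in$time[i] %||% "")
    }
  }
  decision <- evaluate_stopping(state, chain)
  while (decision == "handoff") {
    state <- advance_chain(state, chain)
    decision <- evaluate_stopping(state, chain)
  }
  if (decision == "global_stop") {
    state$finished <- TRUE
    state$stop_reason <- "global_stop"
    return(state)
  }
  rk <- compute_ranking(state, chain)
  state$n_rankings <- state$n_rankings + 1L
  install_ranking(state, rk$ranking, rk$model, rk$train_size)
}

# Flush outstanding allocations to the event log as unlabeled rows
# (the Table-3 convention for records held by annotators at stop).
flush_allocations <- function(state) {
  users <- names(state$allocations)
  for (u in users[order(users)]) {
    a <- state$allocations[[u]]
    state$events[[length(state$events) + 1L]] <- event_row(
      row_no = state$next_row, record_id = a$record_id,
      queue_iteration = a$iteration, queue_rank = a$rank,
      model_name = a$model, user_id = u)
    state$next_row <- state$next_row + 1L
  }
  state
}

state_event_log <- function(state) {
  if (!length(state$events)) return(empty_event_log())
  do.call(rbind, state$events)
}
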