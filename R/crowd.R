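#' Task server configuration
#'
#' Retraining is performed by a pool of workers (default 2, mirroring CPU
#' cores): a new label triggers retraining only if a worker is free,
#' otherwise the task server waits for the next label. `retrain_duration`
#' is the simulated training time in integer ticks; 0 makes retraining
#' synchronous (completed before the next event is processed).
#'
#' @param n_workers positive integer, default 2.
#' @param retrain_duration nonnegative integer ticks, default 1.
#' @return a `task_server_config`.
#' @export
task_server_config <- function(n_workers = 2L, retrain_duration = 1L) {
  n_workers <- as.integer(n_workers)
  if (is.na(n_workers) || n_workers < 1L)
    abort_validation("n_workers must be >= 1")
  structure(list(n_workers = n_workers,
                 retrain_duration = as.numeric(retrain_duration)),
            class = "task_server_config")
}

#' Open a multi-annotator crowd session
#'
#' @param corpus a [corpus()] (labels, if present, serve as the oracle for
#'   scripted `label` actions without an explicit value).
#' @param chain an [agent_chain()].
#' @param config a [task_server_config()].
#' @param seed integer seed.
#' @param annotators character vector of registered user ids.
#' @return a `crowd_session`; pass it through [request_record()],
#'   [submit_label()], [release_record()] and [crowd_tick()].
#' @export
crowd_session <- function(corpus, chain, config = task_server_config(),
                          seed = 1L, annotators = character(0)) {
  state <- screen_state(corpus, seed = seed)
  rk <- compute_ranking(state, chain)
  state$n_rankings <- state$n_rankings + 1L
  state <- install_ranking(state, rk$ranking, rk$model, rk$train_size)
  structure(list(state = state, chain = chain, config = config,
                 annotators = annotators, jobs = list(), job_counter = 0L,
                 seg_trained = FALSE, trace = list(), finished = FALSE,
                 stop_reason = NULL),
            class = "crowd_session")
}

trace_event <- function(session, time, kind, payload = "") {
  session$trace[[length(session$trace) + 1L]] <-
    data.frame(time = as.numeric(time), kind = kind,
               payload = as.character(payload), stringsAsFactors = FALSE)
  session
}

#' Request the next record for an annotator
#'
#' Returns the highest-ranked pool record not currently allocated to
#' another annotator and records the allocation. An annotator re-requesting
#' without labeling receives their already-allocated record. Requests are
#' never blocked by training: they are answered from the ranking in force.
#'
#' @param session a [crowd_session()].
#' @param user_id annotator id.
#' @param time event time (integer tick or timestamp string).
#' @return list with updated `session` and `record_id` (NA when the pool is
#'   exhausted — the annotator should wait or stop).
#' @export
request_record <- function(session, user_id, time = 0) {
  session <- complete_due_retrains(session, time)
  if (session$finished)
    return(list(session = session, record_id = NA_character_))
  state <- session$state
  held <- state$allocations[[user_id]]
  if (!is.null(held))
    return(list(session = session, record_id = held$record_id))
  taken <- allocated_ids(state)
  nxt <- NA_character_
  for (rid in state$ranking) {
    pos <- match(rid, state$ids)
    if (is.na(state$labels[pos]) && !(rid %in% taken)) { nxt <- rid; break }
  }
  if (is.na(nxt)) return(list(session = session, record_id = NA_character_))
  state$ranking_served <- state$ranking_served + 1L
  state$allocations[[user_id]] <- list(
    record_id = nxt, iteration = state$ranking_iteration,
    rank = state$ranking_served, train_size = state$ranking_train_size,
    model = state$ranking_model)
  session$state <- state
  session <- trace_event(session, time, "request",
                         sprintf("%s:%s", user_id, nxt))
  list(session = session, record_id = nxt)
}

#' Release an allocation without labeling
#'
#' @param session a [crowd_session()].
#' @param user_id annotator id.
#' @return the updated session.
#' @export
release_record <- function(session, user_id) {
  session$state$allocations[[user_id]] <- NULL
  session
}

#' Submit a label from an annotator
#'
#' Applies the label, evaluates hand-off/stopping, and schedules a retrain
#' if a worker is free (training uses a snapshot of the labels present at
#' this instant; labels arriving during training enter the next round).
#'
#' @param session a [crowd_session()].
#' @param user_id annotator id.
#' @param record_id record to label; defaults to the user's allocation.
#' @param label 0 or 1.
#' @param time event time.
#' @param note,tags free-text annotations for the event log.
#' @return the updated session.
#' @export
submit_label <- function(session, user_id, record_id = NULL, label,
                         time = 0, note = "", tags = "") {
  session <- complete_due_retrains(session, time)
  if (session$finished) return(session)
  state <- session$state
  held <- state$allocations[[user_id]]
  if (is.null(record_id)) {
    if (is.null(held)) abort_validation(
      sprintf("user '%s' holds no allocation and gave no record_id", user_id))
    record_id <- held$record_id
  }
  owners <- names(state$allocations)[vapply(state$allocations,
              function(a) a$record_id == record_id, logical(1))]
  if (length(owners) && !(user_id %in% owners))
    abort_validation(sprintf("record '%s' is allocated to another user",
                             record_id))
  state <- apply_label(state, record_id, label, user_id = user_id,
                       time = time, note = note, tags = tags)
  session$state <- state
  session <- trace_event(session, time, "label",
                         sprintf("%s:%s=%d", user_id, record_id, label))

  decision <- evaluate_stopping(session$state, session$chain)
  while (decision == "handoff") {
    session$state <- advance_chain(session$state, session$chain)
    session$seg_trained <- FALSE
    session <- trace_event(session, time, "handoff",
                           sprintf("agent %d", session$state$active_agent))
    decision <- evaluate_stopping(session$state, session$chain)
  }
  if (decision == "global_stop") {
    session$finished <- TRUE
    session$stop_reason <- "global_stop"
    session$state$finished <- TRUE
    session$state <- flush_allocations(session$state)
    session <- trace_event(session, time, "stop")
    return(session)
  }
  maybe_schedule_retrain(session, time)
}

# Schedule a retrain if the agent wants one and a worker is free.
maybe_schedule_retrain <- function(session, time) {
  agent <- session$chain$agents[[session$state$active_agent]]
  wants <- if (is.null(agent$classifier)) {
    # model-free agents rank once per segment, no worker needed
    if (!session$seg_trained) {
      rk <- compute_ranking(session$state, session$chain)
      session$state$n_rankings <- session$state$n_rankings + 1L
      session$state <- install_ranking(session$state, rk$ranking, rk$model,
                                       rk$train_size)
      session$seg_trained <- TRUE
    }
    FALSE
  } else if (!min_training_ready(session$state)) {
    FALSE
  } else {
    agent$retrain || !session$seg_trained
  }
  if (!wants) return(session)
  if (length(session$jobs) >= session$config$n_workers)
    return(session)  # all workers occupied: wait for the next label
  session$job_counter <- session$job_counter + 1L
  job <- list(id = session$job_counter,
              labels = session$state$labels,
              agent = session$state$active_agent,
              start = as.numeric(time),
              done = as.numeric(time) + session$config$retrain_duration)
  session$jobs[[length(session$jobs) + 1L]] <- job
  session$seg_trained <- TRUE
  session <- trace_event(session, time, "retrain_start",
                         sprintf("job %d (train %d)", job$id,
                                 sum(!is.na(job$labels))))
  if (session$config$retrain_duration == 0)
    session <- complete_due_retrains(session, time)
  session
}

#' Complete a finished retrain
#'
#' Installs the new ranking atomically: live allocations are untouched and
#' annotator requests were served from the old ranking until this instant.
#'
#' @param session a [crowd_session()].
#' @param job internal job record.
#' @param time completion time.
#' @return the updated session.
#' @export
complete_retrain <- function(session, job, time) {
  session$jobs <- Filter(function(j) j$id != job$id, session$jobs)
  if (session$finished) return(session)
  st <- session$state
  saved_agent <- st$active_agent
  st$active_agent <- job$agent
  rk <- compute_ranking(st, session$chain, labels = job$labels)
  st$active_agent <- saved_agent
  st$n_rankings <- st$n_rankings + 1L
  session$state <- install_ranking(st, rk$ranking, rk$model, rk$train_size)
  trace_event(session, time, "retrain_done", sprintf("job %d", job$id))
}

# Process retrain completions due at or before `time`, in completion order.
complete_due_retrains <- function(session, time) {
  repeat {
    due <- Filter(function(j) j$done <= as.numeric(time), session$jobs)
    if (!length(due)) return(session)
    ord <- order(vapply(due, `[[`, numeric(1), "done"),
                 vapply(due, `[[`, numeric(1), "id"))
    session <- complete_retrain(session, due[[ord[1L]]],
                                due[[ord[1L]]]$done)
  }
}

#' Advance simulated time (completing due retrains)
#'
#' @param session a [crowd_session()].
#' @param time tick to advance to.
#' @return the updated session.
#' @export
crowd_tick <- function(session, time) complete_due_retrains(session, time)

#' Run a scripted crowd schedule
#'
#' Fully deterministic discrete-event replay of a multi-annotator screening
#' session. The script is a data.frame with columns `time` (integer ticks),
#' `user_id`, `action` (`"request"`, `"label"`, `"release"`) and optional
#' `label` (blank/NA means: answer with the record's known label from the
#' corpus — the scripted annotator acts as the oracle). A `label` action by
#' a user without an allocation implicitly requests first.
#'
#' @param corpus a [corpus()].
#' @param chain an [agent_chain()].
#' @param script annotator script data.frame.
#' @param config a [task_server_config()].
#' @param seed integer seed.
#' @param annotators registered user ids (defaults to those in the script).
#' @return a `crowd_run`: list with `event_log`, `state`, `trace`,
#'   `stop_reason`.
#' @export
run_crowd_schedule <- function(corpus, chain, script,
                               config = task_server_config(), seed = 1L,
                               annotators = unique(script$user_id)) {
  stopifnot(is.data.frame(script),
            all(c("time", "user_id", "action") %in% names(script)))
  if (!all(script$user_id %in% annotators))
    abort_validation("script references an unregistered user")
  script <- script[order(script$time, seq_len(nrow(script))), , drop = FALSE]
  session <- crowd_session(corpus, chain, config, seed, annotators)
  truth <- corpus_labels(corpus)
  ids <- record_ids(corpus)
  for (i in seq_len(nrow(script))) {
    if (session$finished) break
    t <- script$time[i]; u <- script$user_id[i]; act <- script$action[i]
    if (act == "request") {
      session <- request_record(session, u, t)$session
    } else if (act == "release") {
      session <- release_record(session, u)
    } else if (act == "label") {
      if (is.null(session$state$allocations[[u]])) {
        res <- request_record(session, u, t)
        session <- res$session
        if (is.na(res$record_id)) next
      }
      rid <- session$state$allocations[[u]]$record_id
      lab <- if ("label" %in% names(script)) script$label[i] else NA
      if (is.na(lab)) lab <- truth[match(rid, ids)]
      if (is.na(lab))
        abort_validation(sprintf("no scripted or known label for '%s'", rid))
      session <- submit_label(session, u, rid, lab, time = t)
    } else abort_validation(sprintf("unknown script action '%s'", act))
  }
  if (!session$finished) {
    session$stop_reason <- "script_exhausted"
    session$state <- flush_allocations(session$state)
  }
  trace <- if (length(session$trace)) do.call(rbind, session$trace)
           else data.frame(time = numeric(0), kind = character(0),
                           payload = character(0))
  structure(list(event_log = state_event_log(session$state),
                 state = session$state, trace = trace,
                 stop_reason = session$stop_reason,
                 config = config, seed = seed),
            class = "crowd_run")
}

#' @exportS3Method base::print
print.crowd_run <- function(x, ...) {
  lab <- x$state$labels
  cat(sprintf("<crowd_run> %d events, labeled %d (K+=%d), stop: %s\n",
              nrow(x$event_log), sum(!is.na(lab)),
              sum(lab == 1L, na.rm = TRUE), x$stop_reason))
  invisible(x)
}
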