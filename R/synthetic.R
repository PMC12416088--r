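#' Synthetic corpus specification
#'
#' Documents are bags of tokens drawn from two multinomial vocabularies: a
#' signal vocabulary used (with probability `separability` per token) by
#' relevant documents, and a background vocabulary used by everything else.
#' This is the simplest generative model with a tunable class separation
#' and a well-specified optimal classifier (multinomial naive Bayes), and
#' it emulates the defining trait of screening corpora: a small fraction of
#' relevant records distinguished by vocabulary.
#'
#' @param n_records corpus size.
#' @param prevalence fraction of relevant records (before noise).
#' @param vocab_size_signal,vocab_size_background vocabulary sizes.
#' @param separability probability that a relevant-document token comes
#'   from the signal vocabulary (0 = classes indistinguishable).
#' @param doc_length mean document length in tokens (Poisson, floor 4).
#' @param label_noise probability of flipping each label after generation.
#' @param seed integer seed.
#' @return a `corpus_spec`.
#' @export
corpus_spec <- function(n_records = 200L, prevalence = 0.1,
                        vocab_size_signal = 50L, vocab_size_background = 400L,
                        separability = 0.9, doc_length = 30L,
                        label_noise = 0, seed = 1L) {
  for (v in list(prevalence, separability, label_noise))
    if (!is_scalar_number(v) || v < 0 || v > 1)
      abort_validation("prevalence, separability and label_noise must be in [0, 1]")
  if (vocab_size_signal < 1L || vocab_size_background < 1L)
    abort_validation("vocabulary sizes must be >= 1")
  structure(list(n_records = as.integer(n_records), prevalence = prevalence,
                 vocab_size_signal = as.integer(vocab_size_signal),
                 vocab_size_background = as.integer(vocab_size_background),
                 separability = separability,
                 doc_length = as.integer(doc_length),
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a fully labeled synthetic corpus
#'
#' Exactly `round(prevalence * n_records)` records are relevant before
#' noise; relevant documents mix signal and background tokens per
#' `separability`, irrelevant documents use background tokens only.
#' Deterministic under the spec's seed.
#'
#' @param spec a [corpus_spec()].
#' @return a [corpus()] with all labels known.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  n <- spec$n_records
  sig <- sprintf("sig%03d", seq_len(spec$vocab_size_signal))
  bg <- sprintf("bg%04d", seq_len(spec$vocab_size_background))
  local_seed(spec$seed, {
    n_rel <- round(spec$prevalence * n)
    label <- rep(0L, n)
    label[sample.int(n, n_rel)] <- 1L
    docs <- vapply(seq_len(n), function(i) {
      len <- max(4L, stats::rpois(1L, spec$doc_length))
      from_sig <- label[i] == 1L &
        (stats::runif(len) < spec$separability)
      toks <- character(len)
      if (any(from_sig)) toks[from_sig] <- sample(sig, sum(from_sig), replace = TRUE)
      if (any(!from_sig)) toks[!from_sig] <- sample(bg, sum(!from_sig), replace = TRUE)
      paste(toks, collapse = " ")
    }, character(1))
    if (spec$label_noise > 0) {
      flip <- stats::runif(n) < spec$label_noise
      label[flip] <- 1L - label[flip]
    }
    first_space <- regexpr(" ", docs, fixed = TRUE)
    corpus(data.frame(
      record_id = sprintf("r%04d", seq_len(n)),
      title = substr(docs, 1L, ifelse(first_space > 0, first_space - 1L,
                                      nchar(docs))),
      body = docs, label = label, stringsAsFactors = FALSE),
      source_format = "synthetic")
  })
}

#' Crowd fixture specification
#'
#' Describes a reproducible multi-annotator screening scenario: a corpus,
#' an annotator script, and a three-agent chain (random start, tf-idf +
#' naive Bayes, tf-idf + linear SVM) whose final agent stops on a
#' consecutive-irrelevant run, with a given number of records still
#' allocated to annotators — but never labeled — when the stop fires.
#'
#' @param n_records corpus size (default 100).
#' @param n_annotators number of annotators (default 4).
#' @param outstanding_allocations records held by annotators at stop
#'   (default `min(3, n_annotators - 1)`; each hold needs its own
#'   annotator, and at least one annotator must keep labeling).
#' @param seed integer seed.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_records = 100L, n_annotators = 4L,
                         outstanding_allocations = min(3L, n_annotators - 1L),
                         seed = 1L) {
  n_records <- as.integer(n_records)
  n_annotators <- as.integer(n_annotators)
  outstanding_allocations <- as.integer(outstanding_allocations)
  if (outstanding_allocations >= n_records)
    abort_validation("outstanding_allocations must be < n_records")
  if (outstanding_allocations >= n_annotators && outstanding_allocations > 0L)
    abort_validation("each outstanding allocation needs its own annotator, plus one to keep labeling")
  structure(list(n_records = n_records, n_annotators = n_annotators,
                 outstanding_allocations = outstanding_allocations,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_chain <- function(final_policy, seed) {
  tfidf <- vectorizer_spec("tfidf", c(1L, 2L))
  agent_chain(
    agent_spec("random-start", querier = querier_spec("random", random_seed = seed),
               handoff = handoff_policy("labeled_count", 2)),
    agent_spec("tfidf-nb", tfidf,
               classifier_spec("multinomial-bayes", random_seed = seed),
               balancer_spec(), querier_spec("max", random_seed = seed),
               handoff = handoff_policy("labeled_count", 13)),
    agent_spec("tfidf-svm", tfidf,
               classifier_spec("linear-svm", random_seed = seed),
               balancer_spec(), querier_spec("max", random_seed = seed),
               handoff = final_policy))
}

fixture_script <- function(spec) {
  users <- sprintf("%02d", seq_len(spec$n_annotators))
  labels_needed <- spec$n_records - spec$outstanding_allocations
  # holds placed while the final agent is active; last annotator survives
  hold_users <- setdiff(users, users[length(users)])[
    seq_len(spec$outstanding_allocations)]
  hold_points <- if (spec$outstanding_allocations)
    pmax(16L, round(labels_needed *
      seq(0.6, 0.92, length.out = spec$outstanding_allocations)))
  else integer(0)
  rows <- list()
  t <- 1
  emit <- function(user, action) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time = t, user_id = user, action = action, stringsAsFactors = FALSE)
    t <<- t + 1
  }
  active <- users
  holds_done <- 0L
  for (i in seq_len(labels_needed + 10L)) {
    while (holds_done < length(hold_users) &&
           i > hold_points[holds_done + 1L]) {
      h <- hold_users[holds_done + 1L]
      emit(h, "request")
      t <- t + 1
      active <- setdiff(active, h)
      holds_done <- holds_done + 1L
    }
    u <- active[(i - 1L) %% length(active) + 1L]
    emit(u, "request")
    emit(u, "label")
  }
  do.call(rbind, rows)
}

#' Generate a worked-example crowd fixture
#'
#' Builds a labeled synthetic corpus, a deterministic annotator script and
#' the three-agent chain, calibrated so that replaying the fixture through
#' [run_crowd_schedule()] reaches the final agent's consecutive-irrelevant
#' stop with exactly `outstanding_allocations` records still allocated but
#' unlabeled — i.e. `n_records - outstanding_allocations` labeled records.
#' The consecutive-irrelevant threshold is not knowable a priori (the label
#' sequence is emergent), so it is measured on a trial replay with the stop
#' disabled and then verified by a full replay; an unreachable stop raises
#' a generation error with a diagnostic.
#'
#' @param spec a [fixture_spec()].
#' @return a `crowd_fixture`: list with `corpus`, `chain`, `script`,
#'   `config`, `threshold` (the calibrated run length) and `spec`.
#' @export
generate_crowd_fixture <- function(spec = fixture_spec()) {
  corpus <- generate_corpus(corpus_spec(
    n_records = spec$n_records, prevalence = 0.1, separability = 0.9,
    vocab_size_signal = 40L, vocab_size_background = 300L,
    doc_length = 25L, seed = derive_seed(spec$seed, 101L)))
  script <- fixture_script(spec)
  config <- task_server_config(n_workers = 2L, retrain_duration = 1L)
  labels_needed <- spec$n_records - spec$outstanding_allocations

  trial <- run_crowd_schedule(corpus, fixture_chain(handoff_policy("never"),
                                                    spec$seed),
                              script, config, seed = spec$seed)
  lab_rows <- trial$event_log[!is.na(trial$event_log$label), , drop = FALSE]
  if (nrow(lab_rows) != labels_needed)
    abort_validation(sprintf(
      "fixture generation: trial labeled %d records, expected %d",
      nrow(lab_rows), labels_needed))
  seg3 <- lab_rows$label[16:labels_needed]  # labels under the final agent
  trailing <- match(TRUE, rev(seg3) == 1L, nomatch = length(seg3) + 1L) - 1L
  if (trailing < 1L)
    abort_validation("fixture generation: final label is relevant; consecutive-irrelevant stop unreachable")
  runs <- rle(seg3)
  early <- with(runs, lengths[values == 0L])
  early <- early[-length(early)]  # all zero-runs except the trailing one
  if (length(early) && max(early) >= trailing)
    abort_validation(sprintf(
      "fixture generation: an earlier irrelevant run (%d) reaches the trailing run length (%d); stop would fire early",
      max(early), trailing))

  chain <- fixture_chain(handoff_policy("consecutive_irrelevant", trailing),
                         spec$seed)
  run <- run_crowd_schedule(corpus, chain, script, config, seed = spec$seed)
  summ <- replay_event_log(run$event_log, spec$n_records)
  if (run$stop_reason != "global_stop" ||
      summ$labeled_count != labels_needed ||
      summ$allocated_unlabeled_count != spec$outstanding_allocations)
    abort_validation(sprintf(
      "fixture verification failed: stop=%s labeled=%d allocated=%d",
      run$stop_reason, summ$labeled_count, summ$allocated_unlabeled_count))

  structure(list(corpus = corpus, chain = chain, script = script,
                 config = config, threshold = trailing, spec = spec),
            class = "crowd_fixture")
}

#' @exportS3Method base::print
print.crowd_fixture <- function(x, ...) {
  cat(sprintf(paste0("<crowd_fixture> %d records, %d annotators, %d ",
                     "outstanding at stop, final-agent run threshold %d\n"),
              x$spec$n_records, x$spec$n_annotators,
              x$spec$outstanding_allocations, x$threshold))
  invisible(x)
}
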