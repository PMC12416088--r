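two_agent_chain <- function(m = 100) {
  agent_chain(
    agent_spec("first", vectorizer_spec("tfidf", c(1, 1)),
               classifier_spec("multinomial-bayes"), balancer_spec(),
               querier_spec("max"),
               handoff = handoff_policy("consecutive_irrelevant", m)),
    agent_spec("second", querier = querier_spec("random")))
}

label_k <- function(state, ids, labels) {
  for (i in seq_along(ids)) state <- apply_label(state, ids[i], labels[i])
  state
}

test_that("min_training_ready needs one label from each class", {
  cp <- toy_corpus(letters[1:4])
  st <- screen_state(cp)
  expect_false(min_training_ready(st))
  st <- apply_label(st, "r1", 1L)
  expect_false(min_training_ready(st))
  st <- apply_label(st, "r2", 0L)
  expect_true(min_training_ready(st))
})

test_that("the trailing-irrelevant run drives hand-off", {
  cp <- toy_corpus(paste("w", 1:120))
  chain <- two_agent_chain(m = 100)
  st <- screen_state(cp)
  st <- label_k(st, paste0("r", 1:99), rep(0L, 99))
  st <- apply_label(st, "r100", 1L)   # relevant: run resets
  expect_equal(st$dk, 0L)
  expect_equal(evaluate_stopping(st, chain), "continue")
  st <- label_k(st, paste0("r", 101:119), rep(0L, 19))
  expect_equal(st$dk, 19L)
  st2 <- screen_state(cp)
  st2 <- label_k(st2, paste0("r", 1:100), rep(0L, 100))
  expect_equal(evaluate_stopping(st2, chain), "handoff")
})

test_that("an empty pool is a global stop regardless of agent policy", {
  cp <- toy_corpus(c("a", "b"))
  chain <- two_agent_chain()
  st <- label_k(screen_state(cp), c("r1", "r2"), c(1L, 0L))
  expect_equal(evaluate_stopping(st, chain), "global_stop")
})

test_that("a met hand-off with no successor is a global stop", {
  cp <- toy_corpus(paste("w", 1:10))
  chain <- agent_chain(agent_spec("only", querier = querier_spec("random"),
                                  handoff = handoff_policy("labeled_count", 3)))
  st <- label_k(screen_state(cp), paste0("r", 1:3), c(1L, 0L, 0L))
  expect_equal(evaluate_stopping(st, chain), "global_stop")
})

test_that("labeled_fraction hand-off is relative to the whole corpus", {
  cp <- toy_corpus(paste("w", 1:40))
  chain <- agent_chain(
    agent_spec("a", querier = querier_spec("random"),
               handoff = handoff_policy("labeled_fraction", 0.05)),
    agent_spec("b", querier = querier_spec("random")))
  st <- apply_label(screen_state(cp), "r1", 0L)
  expect_equal(evaluate_stopping(st, chain), "continue")
  st <- apply_label(st, "r2", 0L)   # 2/40 = 5%
  expect_equal(evaluate_stopping(st, chain), "handoff")
})

test_that("run_cycle_iteration trains once both classes exist", {
  cp <- separable_corpus(8, 3)
  chain <- two_agent_chain()
  st <- screen_state(cp)
  st <- run_cycle_iteration(st, chain,
                            data.frame(record_id = c("r1", "r4"),
                                       label = c(1L, 0L)))
  expect_equal(st$ranking_model, "first")
  expect_equal(st$ranking_train_size, 2L)
  expect_setequal(st$ranking, paste0("r", c(2, 3, 5:8)))

  # with a single class: random ranking, no training
  st2 <- run_cycle_iteration(screen_state(cp), chain,
                             data.frame(record_id = "r1", label = 1L))
  expect_equal(st2$ranking_model, "random")
  expect_true(is.na(st2$ranking_train_size))

  # empty batch: stopping re-evaluated, nothing else changes
  st3 <- run_cycle_iteration(st, chain, NULL)
  expect_equal(sum(!is.na(st3$labels)), 2L)
  expect_false(st3$finished)
})

test_that("duplicate labels are rejected", {
  st <- apply_label(screen_state(toy_corpus(c("a", "b"))), "r1", 1L)
  expect_error(apply_label(st, "r1", 0L),
               class = "alscreen_validation_error")
})

test_that("advance_chain preserves labels and resets segment counters", {
  cp <- toy_corpus(paste("w", 1:10))
  chain <- agent_chain(
    agent_spec("a", querier = querier_spec("random"),
               handoff = handoff_policy("labeled_count", 3)),
    agent_spec("b", vectorizer_spec("tfidf", c(1, 1)),
               classifier_spec("multinomial-bayes"),
               querier = querier_spec("max")))
  st <- label_k(screen_state(cp), paste0("r", 1:3), c(1L, 0L, 0L))
  expect_equal(st$dk, 2L)
  st <- advance_chain(st, chain)
  expect_equal(st$active_agent, 2L)
  expect_equal(st$seg_k, 0L)
  expect_equal(st$dk, 0L)   # judged on its own labels after hand-off
  expect_equal(sum(!is.na(st$labels)), 3L)
})

test_that("hand-off re-uses the shared feature cache", {
  cp <- separable_corpus(10, 4)
  spec <- vectorizer_spec("tfidf", c(1, 1))
  chain <- agent_chain(
    agent_spec("a", spec, classifier_spec("multinomial-bayes"),
               querier = querier_spec("max"),
               handoff = handoff_policy("labeled_count", 2)),
    agent_spec("b", spec, classifier_spec("linear-svm"),
               querier = querier_spec("max")))
  st <- run_cycle_iteration(screen_state(cp), chain,
                            data.frame(record_id = c("r1", "r5"),
                                       label = c(1L, 0L)))
  fm_before <- st$cache[[spec_key(spec)]]
  expect_false(is.null(fm_before))
  st <- run_cycle_iteration(st, chain,
                            data.frame(record_id = "r2", label = 1L))
  expect_equal(st$active_agent, 2L)
  expect_identical(st$cache[[spec_key(spec)]], fm_before)  # no re-vectorization
})

test_that("label conservation and monotonicity hold across random steps", {
  set.seed(1234)
  cp <- generate_corpus(corpus_spec(n_records = 60, prevalence = 0.2,
                                    seed = 9))
  truth <- corpus_labels(cp)
  chain <- agent_chain(
    agent_spec("rnd", querier = querier_spec("random"),
               handoff = handoff_policy("labeled_count", 10)),
    agent_spec("nb", vectorizer_spec("tfidf", c(1, 1)),
               classifier_spec("multinomial-bayes"),
               querier = querier_spec("max")))
  st <- screen_state(cp, seed = 5)
  st <- run_cycle_iteration(st, chain, NULL)
  n <- n_records(cp)
  labeled_before <- 0L
  while (!st$finished && labeled_before < n) {
    pool <- st$ids[is.na(st$labels)]
    pick <- sample(pool, min(length(pool), sample(1:3, 1)))
    batch <- data.frame(record_id = pick,
                        label = truth[match(pick, st$ids)])
    st <- run_cycle_iteration(st, chain, batch)
    labeled <- sum(!is.na(st$labels))
    expect_equal(labeled + sum(is.na(st$labels)), n)      # K = Ku + K+ + K-
    expect_gte(labeled, labeled_before)                    # monotone
    labeled_before <- labeled
  }
  expect_equal(sum(st$labels == 1L), sum(truth == 1L))
})

test_that("agent specs are validated", {
  expect_error(agent_spec("x", vectorizer = vectorizer_spec()),
               class = "alscreen_validation_error")
  expect_error(agent_spec("x", querier = NULL),
               class = "alscreen_validation_error")
  expect_error(handoff_policy("labeled_count", 0),
               class = "alscreen_validation_error")
  expect_error(agent_chain(), class = "alscreen_validation_error")
})
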