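top_down_chain <- function() {
  agent_chain(agent_spec("td", querier = querier_spec("top_down")))
}

nb_chain <- function(seed = 1L, retrain = TRUE) {
  agent_chain(agent_spec("nb", vectorizer_spec("tfidf", c(1, 1)),
                         classifier_spec("multinomial-bayes"),
                         balancer_spec(), querier_spec("max", random_seed = seed),
                         retrain = retrain))
}

test_that("annotators receive the highest-ranked unallocated record", {
  cp <- toy_corpus(c("a", "b", "c"))
  ses <- crowd_session(cp, top_down_chain())
  ra <- request_record(ses, "A", 1); ses <- ra$session
  rb <- request_record(ses, "B", 2); ses <- rb$session
  expect_equal(ra$record_id, "r1")
  expect_equal(rb$record_id, "r2")
  # idempotent re-request without labeling
  expect_equal(request_record(ses, "A", 3)$record_id, "r1")
  rc <- request_record(ses, "C", 4); ses <- rc$session
  expect_equal(rc$record_id, "r3")
  # pool exhausted: no-record signal
  expect_true(is.na(request_record(ses, "D", 5)$record_id))
})

test_that("labels from non-owners and duplicates are rejected", {
  cp <- toy_corpus(c("a", "b"))
  ses <- crowd_session(cp, top_down_chain())
  ses <- request_record(ses, "A", 1)$session
  expect_error(submit_label(ses, "B", "r1", 1L, 2),
               class = "alscreen_validation_error")
  ses <- submit_label(ses, "A", "r1", 1L, 2)
  expect_error(submit_label(ses, "A", "r1", 0L, 3),
               class = "alscreen_validation_error")
})

test_that("release returns a record to the queue", {
  cp <- toy_corpus(c("a", "b"))
  ses <- crowd_session(cp, top_down_chain())
  ses <- request_record(ses, "A", 1)$session
  ses <- release_record(ses, "A")
  expect_equal(request_record(ses, "B", 2)$record_id, "r1")
})

test_that("retraining is scheduled only when a worker is free", {
  cp <- separable_corpus(10, 4)
  cfg <- task_server_config(n_workers = 1L, retrain_duration = 100L)
  ses <- crowd_session(cp, nb_chain(), cfg)
  ses <- request_record(ses, "A", 1)$session
  ses <- submit_label(ses, "A", label = 0L, time = 1)
  ses <- request_record(ses, "A", 2)$session
  ses <- submit_label(ses, "A", label = 1L, time = 2)  # starts the retrain
  ses <- request_record(ses, "A", 3)$session
  ses <- submit_label(ses, "A", label = 1L, time = 3)  # worker busy: waits
  kinds <- vapply(ses$trace, function(e) e$kind, character(1))
  expect_equal(sum(kinds == "retrain_start"), 1L)
  # ranking in force is still the initial one (training size unknown)
  expect_equal(ses$state$ranking_iteration, 1L)
  # after the retrain completes the new ranking is installed atomically
  ses <- crowd_tick(ses, 200)
  expect_equal(ses$state$ranking_iteration, 2L)
  expect_equal(ses$state$ranking_train_size, 2L)  # snapshot at retrain start
})

test_that("labels during training are served from the old ranking", {
  cp <- separable_corpus(10, 4)
  cfg <- task_server_config(n_workers = 1L, retrain_duration = 10L)
  ses <- crowd_session(cp, nb_chain(), cfg)
  for (i in 1:2) {
    ses <- request_record(ses, "A", i)$session
    ses <- submit_label(ses, "A", label = c(1L, 0L)[i], time = i)
  }
  it_before <- ses$state$ranking_iteration
  res <- request_record(ses, "A", 3)   # during training
  expect_equal(res$session$state$ranking_iteration, it_before)
  expect_false(is.na(res$record_id))
})

test_that("crowd invariants hold over a randomized schedule", {
  set.seed(77)
  cp <- generate_corpus(corpus_spec(n_records = 50, prevalence = 0.2,
                                    seed = 21))
  users <- c("u1", "u2", "u3")
  rows <- list(); t <- 1
  for (i in 1:180) {
    u <- sample(users, 1)
    act <- sample(c("request", "label", "label"), 1)
    rows[[i]] <- data.frame(time = t, user_id = u, action = act,
                            stringsAsFactors = FALSE)
    t <- t + sample(0:2, 1)
  }
  script <- do.call(rbind, rows)
  run <- run_crowd_schedule(cp, nb_chain(), script,
                            task_server_config(n_workers = 2L,
                                               retrain_duration = 3L),
                            seed = 4)
  # no record ever allocated to two users: replay the request/label trace
  held <- list()
  for (i in seq_len(nrow(run$trace))) {
    ev <- run$trace[i, ]
    parts <- strsplit(sub("=.*", "", ev$payload), ":")[[1]]
    if (ev$kind == "request") {
      expect_false(parts[2] %in% setdiff(unlist(held), held[[parts[1]]]))
      held[[parts[1]]] <- parts[2]
    } else if (ev$kind == "label") {
      held[[parts[1]]] <- NULL
    }
  }
  # at most n_workers retrains overlap
  starts <- run$trace$time[run$trace$kind == "retrain_start"]
  dones <- run$trace$time[run$trace$kind == "retrain_done"]
  expect_equal(length(starts), length(dones))
  for (s in starts)
    expect_lte(sum(starts <= s) - sum(dones <= s), 2L)
  # the log satisfies the replay invariants
  summ <- replay_event_log(run$event_log, n_records(cp))
  expect_equal(summ$labeled_count, sum(!is.na(run$state$labels)))
})

test_that("an all-request script logs only allocation rows", {
  cp <- toy_corpus(c("a", "b", "c"))
  script <- data.frame(time = 1:2, user_id = c("A", "B"),
                       action = "request", stringsAsFactors = FALSE)
  run <- run_crowd_schedule(cp, top_down_chain(), script)
  expect_equal(nrow(run$event_log), 2L)
  expect_true(all(is.na(run$event_log$label)))
  expect_equal(run$event_log$labeling_time, c("", ""))
})

test_that("scripts referencing unknown users are rejected", {
  cp <- toy_corpus(c("a", "b"))
  script <- data.frame(time = 1, user_id = "ghost", action = "request")
  expect_error(run_crowd_schedule(cp, top_down_chain(), script,
                                  annotators = "A"),
               class = "alscreen_validation_error")
})

test_that("one scripted annotator reproduces the synchronous simulation", {
  cp <- generate_corpus(corpus_spec(n_records = 40, prevalence = 0.2,
                                    seed = 31))
  chain <- nb_chain(seed = 2L)
  n <- n_records(cp)
  script <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(time = c(2 * i - 1, 2 * i), user_id = "solo",
               action = c("request", "label"), stringsAsFactors = FALSE)))
  run <- run_crowd_schedule(cp, chain, script,
                            task_server_config(n_workers = 1L,
                                               retrain_duration = 0L),
                            seed = 6)
  sim <- run_simulation(simulation_config(cp, chain, stop_if = "full",
                                          seed = 6))
  crowd_order <- run$event_log$record_id[!is.na(run$event_log$label)]
  expect_equal(crowd_order, sim$results$record_id)
  expect_equal(run$event_log$label[!is.na(run$event_log$label)],
               sim$results$label)
})

test_that("seeded crowd runs produce byte-identical event logs", {
  fx_corpus <- generate_corpus(corpus_spec(n_records = 30, seed = 8))
  script <- do.call(rbind, lapply(1:40, function(i)
    data.frame(time = c(2 * i - 1, 2 * i),
               user_id = c("a", "b")[i %% 2 + 1],
               action = c("request", "label"), stringsAsFactors = FALSE)))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  for (f in c(f1, f2)) {
    run <- run_crowd_schedule(fx_corpus, nb_chain(seed = 3L), script,
                              task_server_config(2L, 1L), seed = 9)
    write_event_log(run$event_log, f)
  }
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
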