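test_that("read_tabular maps the included column to 1/0/unknown", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("title,abstract,included", "a,x,1", "b,y,0", "c,z,"), f)
  cp <- read_tabular(f)
  expect_s3_class(cp, "corpus")
  expect_equal(corpus_labels(cp), c(1L, 0L, NA_integer_))
  expect_equal(cp$records$title, c("a", "b", "c"))  # row order preserved

  # "label" is a documented alias, case-insensitively
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("title,abstract,Label", "a,x,1", "b,y,0", "c,z,"), f2)
  expect_equal(as.data.frame(read_tabular(f2)), as.data.frame(cp))

  # "included" wins when both columns are present with conflicting values
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("title,included,label", "a,1,0"), f3)
  expect_equal(corpus_labels(read_tabular(f3)), 1L)
})

test_that("read_tabular rejects degenerate input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(read_tabular(f), class = "alscreen_format_error")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,included", "1,1"), f2)  # no text columns
  expect_error(read_tabular(f2), class = "alscreen_format_error")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,title", "x,a", "x,b"), f3)  # duplicate ids
  expect_error(read_tabular(f3), class = "alscreen_validation_error")

  expect_error(read_tabular(file.path(tempdir(), "nope.csv")),
               class = "alscreen_format_error")
})

test_that("read_tabular reads TSV and assigns positional ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("title\tabstract", "a\tx", "b\ty"), f)
  cp <- read_tabular(f)
  expect_equal(record_ids(cp), c("0", "1"))
})

test_that("read_ris extracts sentinel labels from N1 fields", {
  f <- withr::local_tempfile(fileext = ".ris")
  writeLines(c("TY  - JOUR", "TI  - first", "AB  - text one",
               "N1  - ASReview_relevant", "ER  - ", "",
               "TY  - JOUR", "TI  - second", "AB  - text two", "ER  - "), f)
  cp <- read_ris(f)
  expect_equal(corpus_labels(cp), c(1L, NA_integer_))
  expect_equal(cp$records$title, c("first", "second"))

  # unrelated note text only: unknown label, note preserved
  f2 <- withr::local_tempfile(fileext = ".ris")
  writeLines(c("TY  - JOUR", "TI  - t", "N1  - screened by JD", "ER  - "), f2)
  cp2 <- read_ris(f2)
  expect_true(is.na(corpus_labels(cp2)))
  expect_equal(cp2$records$note, "screened by JD")
})

test_that("malformed RIS raises a format error", {
  f <- withr::local_tempfile(fileext = ".ris")
  writeLines(c("TI  - orphan field before TY"), f)
  expect_error(read_ris(f), class = "alscreen_format_error")
  f2 <- withr::local_tempfile(fileext = ".ris")
  writeLines(c("TY  - JOUR", "TI  - never closed"), f2)
  expect_error(read_ris(f2), class = "alscreen_format_error")
})

test_that("write_labeled emits the tabular included encoding", {
  cp <- toy_corpus(c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_labeled(cp, c(1L, 0L, NA), f, "csv")
  raw <- read.csv(f, colClasses = "character")
  expect_equal(raw$included, c("1", "0", ""))

  # zero labeled records: all-blank label column
  write_labeled(cp, rep(NA_integer_, 3), f, "csv")
  expect_equal(read.csv(f, colClasses = "character")$included, rep("", 3))
})

test_that("labeled round-trips are identity on id/title/body/label", {
  set.seed(42)
  n <- 10L
  cp <- toy_corpus(replicate(n, paste(sample(letters, 4), collapse = " ")))
  labels <- sample(c(0L, 1L, NA_integer_), n, replace = TRUE)
  for (fmt in c("csv", "tsv", "ris")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_labeled(cp, labels, f, fmt)
    back <- if (fmt == "ris") read_ris(f) else read_tabular(f, fmt)
    expect_equal(record_ids(back), record_ids(cp), info = fmt)
    expect_equal(back$records$title, cp$records$title, info = fmt)
    expect_equal(corpus_labels(back), labels, info = fmt)
  }
})

test_that("unknown RIS fields survive a round-trip verbatim", {
  f <- withr::local_tempfile(fileext = ".ris")
  writeLines(c("TY  - JOUR", "ID  - a1", "TI  - t", "AB  - b",
               "AU  - Someone, A.", "PY  - 2021", "ER  - "), f)
  cp <- read_ris(f)
  f2 <- withr::local_tempfile(fileext = ".ris")
  write_labeled(cp, c(1L), f2, "ris")
  out <- readLines(f2)
  expect_true("AU  - Someone, A." %in% out)
  expect_true("PY  - 2021" %in% out)
  expect_true("N1  - ASReview_relevant" %in% out)
})

test_that("event logs round-trip through CSV", {
  log <- rbind(
    event_row(1, "r1", 1L, "2025-01-23T09:32:08.460", NA, NA, NA, "random", "01"),
    event_row(2, "r2", 0L, "2025-01-23T09:32:40.130", NA, NA, NA, "random", "01"),
    event_row(3, "r3", 1L, "3", 2L, 1L, 1L, "nb", "02", note = "a note"),
    event_row(4, "r4"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log, f)
  back <- read_event_log(f)
  expect_equal(back$record_id, log$record_id)
  expect_equal(back$label, log$label)
  expect_equal(back$model_name, log$model_name)
  expect_equal(back$note, log$note)
})

test_that("replay_event_log computes counts and segments", {
  log <- rbind(
    event_row(1, "r1", 1L, "1", NA, NA, NA, "random", "01"),
    event_row(2, "r2", 0L, "2", NA, NA, NA, "random", "02"),
    event_row(3, "r3", 0L, "3", 2L, 1L, 1L, "nb", "01"),
    event_row(4, "r4", model_name = "nb"),  # allocated, never labeled
    event_row(5, "r5", 1L, "5", 3L, 2L, 1L, "nb", "02"))
  s <- replay_event_log(log, 10L)
  expect_equal(s$labeled_count, 4L)
  expect_equal(s$relevant_count, 2L)
  expect_equal(s$allocated_unlabeled_count, 1L)
  expect_equal(s$never_touched, 5L)
  expect_equal(s$segments$model_name, c("random", "nb"))
  expect_equal(s$segments$n_rows, c(2L, 3L))
  expect_equal(s$segments$n_labels, c(2L, 2L))
  expect_equal(as.integer(s$per_user[c("01", "02")]), c(2L, 2L))
  expect_equal(s$labeled_count + s$allocated_unlabeled_count + s$never_touched,
               10L)
  # pure function of the log
  expect_identical(replay_event_log(log, 10L), s)
})

test_that("replay enforces the event-row invariants", {
  s <- replay_event_log(empty_event_log(), 5L)
  expect_equal(s$labeled_count, 0L)
  expect_equal(s$allocated_unlabeled_count, 0L)
  expect_equal(s$never_touched, 5L)

  bad <- rbind(event_row(1, "r1", 1L, "1", 6L, 1L, 1L, "nb", "01"),
               event_row(2, "r2", 0L, "2", 2L, 1L, 2L, "nb", "01"))
  expect_error(replay_event_log(bad, 5L), class = "alscreen_integrity_error")

  dup <- rbind(event_row(1, "r1", 1L, "1", NA, NA, NA, "m", "01"),
               event_row(2, "r1", 0L, "2", NA, NA, NA, "m", "01"))
  expect_error(replay_event_log(dup, 5L), class = "alscreen_integrity_error")

  badtime <- event_row(1, "r1", labeling_time = "2025-01-01T00:00:00.000")
  expect_error(replay_event_log(badtime, 5L),
               class = "alscreen_integrity_error")
})

test_that("projects round-trip through the on-disk container", {
  cp <- toy_corpus(c("alpha beta", "gamma delta", "beta beta"),
                   labels = c(1L, 0L, NA))
  proj <- screen_project("demo", cp, chain_preset("worked-example", seed = 7L),
                         seed = 7L, priors = c("r1", "r2"))
  proj$event_log <- rbind(
    event_row(1, "r1", 1L, "1", NA, NA, NA, "random", "01"),
    event_row(2, "r2", 0L, "2", NA, NA, NA, "random", "01"))
  fm <- feature_cache_get_or_build(proj$cache, cp, vectorizer_spec("tfidf"))
  d <- withr::local_tempdir()
  save_project(proj, d)
  back <- load_project(d)
  expect_equal(back$metadata$name, "demo")
  expect_equal(back$seed, 7L)
  expect_equal(back$priors, c("r1", "r2"))
  expect_equal(corpus_labels(back$corpus), corpus_labels(cp))
  expect_equal(length(back$chain$agents), 4L)
  expect_equal(back$chain$agents[[3]]$classifier$algorithm, "multinomial-bayes")
  expect_equal(back$chain$agents[[3]]$handoff$kind, "consecutive_irrelevant")
  expect_equal(back$event_log$record_id, proj$event_log$record_id)
  fm2 <- feature_cache_get_or_build(back$cache, back$corpus,
                                    vectorizer_spec("tfidf"))
  expect_equal(as.matrix(fm2$matrix), as.matrix(fm$matrix))
})
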