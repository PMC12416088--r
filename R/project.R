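#' Create a screening project
#'
#' The project bundles everything needed to reconstruct a screening run:
#' metadata, the corpus, the full learner-chain configuration including
#' hyperparameters, prior record ids, the random seed, the event log, and
#' cached feature matrices.
#'
#' @param name project name.
#' @param corpus a [corpus()].
#' @param chain an [agent_chain()].
#' @param seed integer seed.
#' @param owner owner user id.
#' @param priors prior record ids.
#' @return a `screen_project`.
#' @export
screen_project <- function(name, corpus, chain = chain_preset("default"),
                           seed = 1L, owner = "owner",
                           priors = character(0)) {
  structure(list(
    metadata = list(name = name, created = iso_now(), owner = owner),
    corpus = corpus, chain = chain, priors = as.character(priors),
    seed = as.integer(seed), event_log = empty_event_log(),
    cache = feature_cache()),
    class = "screen_project")
}

agent_to_list <- function(a) {
  list(name = a$name,
       vectorizer = if (!is.null(a$vectorizer)) unclass(a$vectorizer),
       classifier = if (!is.null(a$classifier)) unclass(a$classifier),
       balancer = unclass(a$balancer), querier = unclass(a$querier),
       handoff = unclass(a$handoff), retrain = a$retrain)
}

agent_from_list <- function(l) {
  agent_spec(
    name = l$name,
    vectorizer = if (!is.null(l$vectorizer))
      vectorizer_spec(l$vectorizer$kind, unlist(l$vectorizer$ngram_range),
                      l$vectorizer$lowercase, l$vectorizer$min_token_length),
    classifier = if (!is.null(l$classifier))
      classifier_spec(l$classifier$algorithm,
                      as.list(l$classifier$hyperparameters),
                      l$classifier$random_seed),
    balancer = balancer_spec(l$balancer$kind,
                             l$balancer$relevant_weight_multiplier),
    querier = querier_spec(l$querier$strategy, l$querier$random_fraction,
                           l$querier$random_seed),
    handoff = handoff_policy(l$handoff$kind, l$handoff$threshold),
    retrain = l$retrain)
}

#' Save a project to disk
#'
#' The on-disk container is a directory holding a JSON config document
#' (metadata, learner chain with hyperparameters, priors, seed), the
#' corpus (CSV), the event log (CSV) and any cached feature matrices
#' (MatrixMarket). `load_project(save_project(p, d))` round-trips the
#' configuration and log losslessly.
#'
#' @param project a [screen_project()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_project <- function(project, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  config <- list(metadata = project$metadata,
                 seed = project$seed, priors = project$priors,
                 chain = lapply(project$chain$agents, agent_to_list))
  jsonlite::write_json(config, file.path(path, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  write_labeled(project$corpus, path = file.path(path, "corpus.csv"),
                format = "csv")
  write_event_log(project$event_log, file.path(path, "event_log.csv"))
  keys <- ls(project$cache)
  if (length(keys)) {
    dir.create(file.path(path, "features"), showWarnings = FALSE)
    for (k in keys) {
      fm <- project$cache[[k]]
      base <- file.path(path, "features", gsub("[^A-Za-z0-9_-]", "_", k))
      Matrix::writeMM(fm$matrix, paste0(base, ".mtx"))
      writeLines(fm$vocabulary, paste0(base, ".vocab"))
      jsonlite::write_json(list(spec = unclass(fm$spec),
                                fingerprint = fm$fingerprint, key = k),
                           paste0(base, ".json"), auto_unbox = TRUE,
                           digits = NA)
    }
  }
  invisible(path)
}

#' Load a project saved by [save_project()]
#' @param path project directory.
#' @return a `screen_project`.
#' @export
load_project <- function(path) {
  config <- jsonlite::read_json(file.path(path, "config.json"))
  corpus <- read_tabular(file.path(path, "corpus.csv"), "csv")
  project <- screen_project(
    name = config$metadata$name, corpus = corpus,
    chain = agent_chain(lapply(config$chain, agent_from_list)),
    seed = config$seed, owner = config$metadata$owner,
    priors = unlist(config$priors) %||% character(0))
  project$metadata$created <- config$metadata$created
  project$event_log <- read_event_log(file.path(path, "event_log.csv"))
  feat_dir <- file.path(path, "features")
  if (dir.exists(feat_dir)) {
    for (meta_file in list.files(feat_dir, "\\.json$", full.names = TRUE)) {
      meta <- jsonlite::read_json(meta_file)
      base <- sub("\\.json$", "", meta_file)
      s <- meta$spec
      fm <- structure(list(
        matrix = methods::as(Matrix::readMM(paste0(base, ".mtx")),
                             "CsparseMatrix"),
        vocabulary = readLines(paste0(base, ".vocab")),
        spec = vectorizer_spec(s$kind, unlist(s$ngram_range), s$lowercase,
                               s$min_token_length),
        fingerprint = meta$fingerprint), class = "feature_matrix")
      dimnames(fm$matrix) <- list(record_ids(corpus), fm$vocabulary)
      assign(meta$key, fm, envir = project$cache)
    }
  }
  project
}

#' @exportS3Method base::print
print.screen_project <- function(x, ...) {
  cat(sprintf("<screen_project> '%s': %d records, %d agent(s), %d event(s)\n",
              x$metadata$name, n_records(x$corpus), length(x$chain$agents),
              nrow(x$event_log)))
  invisible(x)
}
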