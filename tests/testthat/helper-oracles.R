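# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: plain loops
# and explicit arithmetic only.

# Term-count oracle: data.frame of counts per document from naive loops.
oracle_term_counts <- function(texts, ngram = 1L) {
  toks <- lapply(strsplit(tolower(texts), "[^a-z0-9]+"), function(t) t[nzchar(t)])
  grams <- lapply(toks, function(t) {
    out <- character(0)
    for (k in seq_len(ngram)) {
      if (length(t) < k) next
      for (i in seq_len(length(t) - k + 1L))
        out <- c(out, paste(t[i:(i + k - 1L)], collapse = " "))
    }
    out
  })
  vocab <- sort(unique(unlist(grams)))
  m <- matrix(0, length(texts), length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_along(grams))
    for (g in grams[[i]]) m[i, g] <- m[i, g] + 1
  m
}

# TF-IDF oracle: counts, idf = ln((1+N)/(1+df)) + 1, L2 row normalization.
oracle_tfidf <- function(texts, ngram = 1L) {
  m <- oracle_term_counts(texts, ngram)
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    df <- sum(m[, j] > 0)
    m[, j] <- m[, j] * (log((1 + n) / (1 + df)) + 1)
  }
  for (i in seq_len(n)) {
    nrm <- sqrt(sum(m[i, ]^2))
    if (nrm > 0) m[i, ] <- m[i, ] / nrm
  }
  m
}

# Laplace-smoothed multinomial Bayes posterior for the relevant class,
# from an explicit count matrix.
oracle_nb_posterior <- function(x_train, y, x_test, alpha = 1,
                                weights = rep(1, length(y))) {
  prior1 <- sum(weights[y == 1]) / sum(weights)
  prior0 <- 1 - prior1
  c1 <- colSums(x_train[y == 1, , drop = FALSE] * weights[y == 1]) + alpha
  c0 <- colSums(x_train[y == 0, , drop = FALSE] * weights[y == 0]) + alpha
  p1 <- c1 / sum(c1); p0 <- c0 / sum(c0)
  apply(x_test, 1, function(doc) {
    l1 <- log(prior1) + sum(doc * log(p1))
    l0 <- log(prior0) + sum(doc * log(p0))
    1 / (1 + exp(l0 - l1))
  })
}

# Ranking oracle: stable sort with explicit tie-break on pool position.
oracle_rank <- function(ids, key) {
  ord <- seq_along(ids)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j < length(ids)) {
      a <- ord[j]; b <- ord[j + 1L]
      if (key[a] > key[b] || (key[a] == key[b] && a > b)) {
        ord[j] <- b; ord[j + 1L] <- a
      }
    }
  }
  ids[ord]
}

toy_corpus <- function(titles, labels = rep(NA_integer_, length(titles)),
                       ids = paste0("r", seq_along(titles))) {
  corpus(data.frame(record_id = ids, title = titles,
                    abstract = rep("", length(titles)),
                    included = labels, stringsAsFactors = FALSE))
}

# A tiny linearly separable two-vocabulary corpus.
separable_corpus <- function(n = 12, n_rel = 4) {
  titles <- c(replicate(n_rel, paste(rep("alpha", 5), collapse = " ")),
              replicate(n - n_rel, paste(rep("beta", 5), collapse = " ")))
  toy_corpus(titles, labels = c(rep(1L, n_rel), rep(0L, n - n_rel)))
}

# Build a simulation_result-shaped object from an explicit screening order.
fake_result <- function(screened_labels, remaining_labels = integer(0)) {
  n <- length(screened_labels) + length(remaining_labels)
  ids <- paste0("d", seq_len(n))
  labs <- c(screened_labels, remaining_labels)
  cp <- toy_corpus(paste("w", seq_len(n)), labels = as.integer(labs),
                   ids = ids)
  ns <- length(screened_labels)
  structure(list(
    results = data.frame(order = seq_len(ns), record_id = ids[seq_len(ns)],
                         label = as.integer(screened_labels),
                         stringsAsFactors = FALSE),
    final_ranking = if (ns < n) ids[(ns + 1L):n] else character(0),
    config = list(corpus = cp), n_records = n,
    n_relevant = sum(labs == 1L)), class = "simulation_result")
}
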