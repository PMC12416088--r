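#' Vectorizer specification
#'
#' Text is tokenized by splitting on non-alphanumeric characters (lowercased
#' by default, empty tokens dropped) and turned into n-gram features. Two
#' kinds are supported: `"onehot"` (term presence, weights in \{0,1\}) and
#' `"tfidf"` (raw term counts, smoothed idf `ln((1+N)/(1+df)) + 1`, L2 row
#' normalization). The default n-gram range for tfidf is `(1,2)` — unigrams
#' plus pairs of consecutive words.
#'
#' @param kind `"tfidf"` or `"onehot"`.
#' @param ngram_range integer pair `(low, high)`, `1 <= low <= high`.
#' @param lowercase lowercase before tokenizing?
#' @param min_token_length drop tokens shorter than this.
#' @return a `vectorizer_spec`.
#' @export
vectorizer_spec <- function(kind = c("tfidf", "onehot"),
                            ngram_range = if (match.arg(kind) == "tfidf") c(1L, 2L) else c(1L, 1L),
                            lowercase = TRUE, min_token_length = 1L) {
  kind <- match.arg(kind)
  ngram_range <- as.integer(ngram_range)
  if (length(ngram_range) != 2L || ngram_range[1L] < 1L ||
      ngram_range[1L] > ngram_range[2L])
    abort_validation("ngram_range must satisfy 1 <= low <= high")
  structure(list(kind = kind, ngram_range = ngram_range,
                 lowercase = lowercase,
                 min_token_length = as.integer(min_token_length)),
            class = "vectorizer_spec")
}

tokenize <- function(text, spec) {
  if (spec$lowercase) text <- tolower(text)
  toks <- strsplit(text, "[^a-z0-9A-Z]+")
  lapply(toks, function(t) t[nchar(t) >= spec$min_token_length & nzchar(t)])
}

ngrams <- function(tokens, low, high) {
  n <- length(tokens)
  out <- character(0)
  for (k in low:high) {
    if (n < k) next
    if (k == 1L) out <- c(out, tokens)
    else {
      idx <- seq_len(n - k + 1L)
      grams <- tokens[idx]
      for (j in 1L:(k - 1L)) grams <- paste(grams, tokens[idx + j])
      out <- c(out, grams)
    }
  }
  out
}

#' Build a feature matrix from a corpus
#'
#' Deterministic for a fixed corpus and spec: the vocabulary is sorted
#' lexicographically so column order (and hence every downstream score and
#' ranking) is reproducible across runs and platforms.
#'
#' @param corpus a [corpus()].
#' @param spec a [vectorizer_spec()].
#' @return a `feature_matrix`: sparse `n_records x n_terms` weights plus
#'   `vocabulary`, `spec` and a corpus `fingerprint`. Row i corresponds to
#'   corpus record i.
#' @export
fit_transform <- function(corpus, spec = vectorizer_spec()) {
  if (n_records(corpus) == 0L) abort_validation("corpus is empty")
  toks <- tokenize(record_text(corpus), spec)
  grams <- lapply(toks, ngrams, low = spec$ngram_range[1L],
                  high = spec$ngram_range[2L])
  vocab <- sort(unique(unlist(grams)))
  if (!length(vocab))
    abort_validation("vectorization failed: all records have empty text")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_along(grams)) {
    if (!length(grams[[i]])) next
    tab <- table(grams[[i]])
    ii <- c(ii, rep(i, length(tab)))
    jj <- c(jj, match(names(tab), vocab))
    xx <- c(xx, as.numeric(tab))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(grams), length(vocab)),
                            dimnames = list(record_ids(corpus), vocab))
  if (spec$kind == "onehot") {
    m@x <- rep(1, length(m@x))
  } else {
    n <- nrow(m)
    df <- Matrix::colSums(m > 0)
    idf <- log((1 + n) / (1 + df)) + 1
    m <- m %*% Matrix::Diagonal(x = idf)
    norms <- sqrt(Matrix::rowSums(m^2))
    norms[norms == 0] <- 1
    m <- Matrix::Diagonal(x = 1 / norms) %*% m
    dimnames(m) <- list(record_ids(corpus), vocab)
  }
  structure(list(matrix = methods::as(m, "CsparseMatrix"), vocabulary = vocab,
                 spec = spec, fingerprint = corpus_fingerprint(corpus)),
            class = "feature_matrix")
}

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s, ngrams %d-%d)\n",
              nrow(x$matrix), ncol(x$matrix), x$spec$kind,
              x$spec$ngram_range[1L], x$spec$ngram_range[2L]))
  invisible(x)
}

#' Create a feature cache
#'
#' Agents sharing a vectorizer re-use each other's feature matrices; a
#' cache entry is keyed on the corpus fingerprint plus the full vectorizer
#' spec, so editing the corpus or changing any knob rebuilds while older
#' entries are kept.
#'
#' @return an environment usable with [feature_cache_get_or_build()].
#' @export
feature_cache <- function() new.env(parent = emptyenv())

spec_key <- function(spec) {
  paste(spec$kind, spec$ngram_range[1L], spec$ngram_range[2L],
        spec$lowercase, spec$min_token_length, sep = "|")
}

#' Fetch a cached feature matrix or build it
#'
#' @param cache a [feature_cache()] (or a project holding one).
#' @param corpus a [corpus()].
#' @param spec a [vectorizer_spec()].
#' @return a `feature_matrix`; bit-identical to an uncached [fit_transform()].
#' @export
feature_cache_get_or_build <- function(cache, corpus, spec) {
  if (inherits(cache, "screen_project")) cache <- cache$cache
  key <- spec_key(spec)
  fp <- corpus_fingerprint(corpus)
  hit <- cache[[key]]
  if (!is.null(hit) && hit$fingerprint == fp) return(hit)
  fm <- fit_transform(corpus, spec)
  assign(key, fm, envir = cache)
  fm
}
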