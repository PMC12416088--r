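#' Balancer specification
#'
#' The balancer counteracts the scarcity of relevant records during
#' training: with `kind = "balanced"`, class `c` gets weight
#' `multiplier_c * N / (2 * N_c)` (inverse class frequency; mean weight 1
#' when the multiplier is 1). The relevant-side multiplier is the single
#' tunable knob; `kind = "none"` gives unit weights.
#'
#' @param kind `"balanced"` or `"none"`.
#' @param relevant_weight_multiplier positive real; extra boost applied to
#'   the relevant class on top of inverse-frequency weighting.
#' @return a `balancer_spec`.
#' @export
balancer_spec <- function(kind = c("balanced", "none"),
                          relevant_weight_multiplier = 1.0) {
  kind <- match.arg(kind)
  if (!is_scalar_number(relevant_weight_multiplier) ||
      relevant_weight_multiplier <= 0)
    abort_validation("relevant_weight_multiplier must be > 0")
  structure(list(kind = kind,
                 relevant_weight_multiplier = relevant_weight_multiplier),
            class = "balancer_spec")
}

#' Per-observation sample weights for a labeled training set
#'
#' @param labels integer vector of 0/1 training labels (no NA).
#' @param balancer a [balancer_spec()].
#' @return numeric weights aligned to `labels`.
#' @export
compute_sample_weights <- function(labels, balancer = balancer_spec()) {
  labels <- as.integer(labels)
  if (anyNA(labels)) abort_validation("training labels may not be NA")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    abort_training("training requires at least one relevant and one irrelevant label")
  if (balancer$kind == "none") return(rep(1, length(labels)))
  n <- length(labels)
  w1 <- balancer$relevant_weight_multiplier * n / (2 * n1)
  w0 <- n / (2 * n0)
  ifelse(labels == 1L, w1, w0)
}

#' Classifier specification
#'
#' @param algorithm one of `"multinomial-bayes"`, `"logistic"`,
#'   `"linear-svm"`, `"random-forest"`.
#' @param hyperparameters named list; recognised knobs: `alpha` (Laplace
#'   smoothing, bayes, default 1), `lambda` (ridge penalty, logistic,
#'   default 1e-3), `cost` (squared-hinge C, linear-svm, default 1),
#'   `n_trees`/`max_depth`/`mtry` (random-forest, defaults 100/8/sqrt(p)).
#' @param random_seed integer seed used by stochastic algorithms.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("multinomial-bayes", "logistic",
                                          "linear-svm", "random-forest"),
                            hyperparameters = list(), random_seed = 1L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 random_seed = as.integer(random_seed)),
            class = "classifier_spec")
}

#' Querier specification
#'
#' @param strategy `"max"` (certainty: highest relevance score first),
#'   `"uncertainty"` (closest to the decision boundary first), `"hybrid"`
#'   (max with a fraction of random records mixed in), `"random"`, or
#'   `"top_down"` (original corpus order).
#' @param random_fraction mixing fraction for hybrid, default 0.05.
#' @param random_seed integer seed for random/hybrid draws.
#' @return a `querier_spec`.
#' @export
querier_spec <- function(strategy = c("max", "uncertainty", "hybrid",
                                      "random", "top_down"),
                         random_fraction = 0.05, random_seed = 1L) {
  strategy <- match.arg(strategy)
  if (!is_scalar_number(random_fraction) || random_fraction < 0 ||
      random_fraction > 1)
    abort_validation("random_fraction must be in [0, 1]")
  structure(list(strategy = strategy, random_fraction = random_fraction,
                 random_seed = as.integer(random_seed)),
            class = "querier_spec")
}

#' Train a classifier and score the unlabeled pool
#'
#' Trains on the rows of `features` whose label is known (0/1) and scores
#' the remaining rows. Bayes, logistic and random-forest emit probabilities
#' of relevance; the linear SVM emits decision values (its uncertainty
#' boundary is 0 rather than 0.5).
#'
#' @param features a `feature_matrix` from [fit_transform()].
#' @param labels integer vector aligned to the feature rows; NA marks pool.
#' @param weights training weights aligned to the *labeled* rows (in row
#'   order), e.g. from [compute_sample_weights()]; NULL for unit weights.
#' @param classifier a [classifier_spec()].
#' @return a `scored_pool`: named numeric `scores` over pool record ids plus
#'   `score_kind` (`"probability"` or `"decision"`).
#' @export
train_and_score <- function(features, labels, weights = NULL,
                            classifier = classifier_spec()) {
  x <- features$matrix
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    abort_validation("labels must align with feature rows")
  tr <- which(!is.na(labels))
  pool <- which(is.na(labels))
  y <- labels[tr]
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    abort_training("training requires both classes")
  w <- weights %||% rep(1, length(tr))
  if (length(w) != length(tr))
    abort_validation("weights must align with the labeled rows")
  xt <- x[tr, , drop = FALSE]
  xp <- x[pool, , drop = FALSE]
  scores <- switch(classifier$algorithm,
    "multinomial-bayes" = nb_train_score(xt, y, w, xp,
        alpha = classifier$hyperparameters$alpha %||% 1),
    "logistic" = logistic_train_score(xt, y, w, xp,
        lambda = classifier$hyperparameters$lambda %||% 1e-3),
    "linear-svm" = svm_train_score(xt, y, w, xp,
        cost = classifier$hyperparameters$cost %||% 1),
    "random-forest" = forest_train_score(xt, y, w, xp,
        hyper = classifier$hyperparameters, seed = classifier$random_seed))
  names(scores) <- rownames(x)[pool]
  structure(list(scores = scores,
                 score_kind = if (classifier$algorithm == "linear-svm")
                   "decision" else "probability",
                 algorithm = classifier$algorithm),
            class = "scored_pool")
}

# Weighted multinomial naive Bayes with Laplace smoothing. Feature values
# act as (possibly fractional) term counts; weights scale whole documents.
nb_train_score <- function(xt, y, w, xp, alpha = 1) {
  classes <- c(0L, 1L)
  logprior <- log(vapply(classes, function(c) sum(w[y == c]), numeric(1)) / sum(w))
  loglik <- vapply(classes, function(c) {
    counts <- Matrix::colSums(xt[y == c, , drop = FALSE] * w[y == c]) + alpha
    log(counts / sum(counts))
  }, numeric(ncol(xt)))
  if (is.null(dim(loglik))) loglik <- matrix(loglik, ncol = 2L)
  jll <- as.matrix(xp %*% loglik) +
    matrix(logprior, nrow(xp), 2L, byrow = TRUE)
  # normalize in log space for stable posteriors
  m <- pmax(jll[, 1L], jll[, 2L])
  p1 <- exp(jll[, 2L] - m) / (exp(jll[, 1L] - m) + exp(jll[, 2L] - m))
  as.numeric(p1)
}

# L2 (ridge) logistic regression via glmnet at one fixed lambda.
logistic_train_score <- function(xt, y, w, xp, lambda = 1e-3) {
  pad <- ncol(xt) < 2L
  if (pad) { # glmnet needs >= 2 columns
    xt <- cbind(xt, 0)
    xp <- cbind(xp, 0)
  }
  fit <- suppressWarnings(  # small-n class warnings are expected here
    glmnet::glmnet(xt, factor(y, levels = c(0L, 1L)), weights = w,
                   family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE))
  as.numeric(stats::predict(fit, xp, type = "response"))
}

# L2-regularized squared-hinge linear SVM, minimized with L-BFGS-B.
# Objective: 0.5 ||beta||^2 + C * sum_i w_i * max(0, 1 - y_i f_i)^2.
# Exactly weight-respecting: duplicating a row equals doubling its weight.
svm_train_score <- function(xt, y, w, xp, cost = 1) {
  ys <- ifelse(y == 1L, 1, -1)
  p <- ncol(xt)
  obj <- function(par) {
    beta <- par[seq_len(p)]; b <- par[p + 1L]
    f <- as.numeric(xt %*% beta) + b
    slack <- pmax(0, 1 - ys * f)
    0.5 * sum(beta^2) + cost * sum(w * slack^2)
  }
  grad <- function(par) {
    beta <- par[seq_len(p)]; b <- par[p + 1L]
    f <- as.numeric(xt %*% beta) + b
    slack <- pmax(0, 1 - ys * f)
    coef <- -2 * cost * w * slack * ys
    g_beta <- beta + as.numeric(Matrix::crossprod(xt, coef))
    c(g_beta, sum(coef))
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 500L))
  as.numeric(xp %*% fit$par[seq_len(p)]) + fit$par[p + 1L]
}

# Bagged CART trees (gini impurity, weighted) on a dense copy of the
# features. Pure-R stand-in for a random forest: no tree package is
# available in the target environment. Adequate at desk scale.
forest_train_score <- function(xt, y, w, xp, hyper = list(), seed = 1L) {
  n_trees <- hyper$n_trees %||% 100L
  max_depth <- hyper$max_depth %||% 8L
  xt <- as.matrix(xt); xp <- as.matrix(xp)
  mtry <- hyper$mtry %||% max(1L, floor(sqrt(ncol(xt))))
  local_seed(seed, {
    preds <- vapply(seq_len(n_trees), function(t) {
      idx <- sample.int(nrow(xt), nrow(xt), replace = TRUE,
                        prob = w / sum(w))
      tree <- grow_tree(xt[idx, , drop = FALSE], y[idx], mtry, max_depth)
      predict_tree(tree, xp)
    }, numeric(nrow(xp)))
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(xp))
    rowMeans(preds)
  })
}

grow_tree <- function(x, y, mtry, depth) {
  p1 <- mean(y == 1L)
  if (depth == 0L || nrow(x) < 4L || p1 == 0 || p1 == 1)
    return(list(leaf = TRUE, p = p1))
  feats <- sample.int(ncol(x), min(mtry, ncol(x)))
  best <- NULL; best_gain <- 0
  gini <- function(q) 2 * q * (1 - q)
  g0 <- gini(p1)
  for (j in feats) {
    v <- x[, j]
    cuts <- unique(stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE))
    for (cut in cuts) {
      left <- v <= cut
      nl <- sum(left)
      if (nl == 0L || nl == nrow(x)) next
      gain <- g0 - (nl * gini(mean(y[left] == 1L)) +
                    (nrow(x) - nl) * gini(mean(y[!left] == 1L))) / nrow(x)
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(j = j, cut = cut, left = left)
      }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, p = p1))
  list(leaf = FALSE, j = best$j, cut = best$cut,
       l = grow_tree(x[best$left, , drop = FALSE], y[best$left], mtry, depth - 1L),
       r = grow_tree(x[!best$left, , drop = FALSE], y[!best$left], mtry, depth - 1L))
}

predict_tree <- function(tree, x) {
  if (tree$leaf) return(rep(tree$p, nrow(x)))
  out <- numeric(nrow(x))
  left <- x[, tree$j] <= tree$cut
  if (any(left)) out[left] <- predict_tree(tree$l, x[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_tree(tree$r, x[!left, , drop = FALSE])
  out
}

#' Rank the unlabeled pool under a query strategy
#'
#' All ties are broken by ascending corpus position, so a fixed
#' (scores, querier, seed) triple always yields the identical ranking.
#'
#' @param scored_pool a `scored_pool` from [train_and_score()], or NULL for
#'   the score-free strategies (`random`, `top_down`).
#' @param querier a [querier_spec()].
#' @param pool_ids record ids of the unlabeled pool, in corpus order.
#' @param seed integer seed for random draws (defaults to the querier's).
#' @return character vector: `pool_ids` permuted into screening order.
#' @export
rank_pool <- function(scored_pool, querier, pool_ids,
                      seed = querier$random_seed) {
  n <- length(pool_ids)
  if (n == 0L) return(character(0))
  if (querier$strategy %in% c("random", "top_down")) {
    return(switch(querier$strategy,
      top_down = pool_ids,
      random = local_seed(seed, sample(pool_ids))))
  }
  scores <- scored_pool$scores[pool_ids]
  if (anyNA(scores))
    abort_validation("scored strategies require a score for every pool record")
  boundary <- if (identical(scored_pool$score_kind, "decision")) 0 else 0.5
  base <- switch(querier$strategy,
    max = ,
    hybrid = pool_ids[order(-scores, seq_len(n))],
    uncertainty = pool_ids[order(abs(scores - boundary), seq_len(n))])
  if (querier$strategy == "hybrid" && querier$random_fraction > 0) {
    k <- ceiling(querier$random_fraction * n)
    base <- local_seed(seed, {
      promoted <- sample(pool_ids, k)
      positions <- sort(sample.int(n, k))
      rest <- base[!(base %in% promoted)]
      out <- character(n)
      out[positions] <- promoted
      out[setdiff(seq_len(n), positions)] <- rest
      out
    })
  }
  base
}
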