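#' Available learners
#'
#' The learner registry realizes the hypothesis class shared by the publisher
#' and the attacker. Registered learners:
#'
#' * `"maxent"` — a Markov sequence tagger: sparse logistic regression
#'   (glmnet) over the token feature templates plus the previous token's
#'   label, trained with gold label history and decoded in two left-to-right
#'   sweeps (a prior-label pass, then a pass fed the first pass's
#'   predictions).
#' * `"svm"` — a margin-based learner: linear-kernel support vector machine
#'   (e1071) on the static feature templates. Training is capped at
#'   `svm_cap` instances (all positives plus a seeded sample of negatives)
#'   because SVM training cost grows quadratically with the training size.
#' * `"boost"` — gradient boosting (xgboost) on the static templates.
#' * `"ensemble"` — a two-stage learner: the sequence tagger proposes
#'   positives, then a margin classifier trained on those proposals filters
#'   out false positives; a token is positive only if both stages agree.
#' * `"lookup"` — a surface-dictionary classifier that flags a surface iff
#'   its (weighted) sensitive occurrences outnumber its non-sensitive ones
#'   in training. This is the exact empirical-risk minimizer within the
#'   surface-lookup hypothesis family and is useful for fast property checks.
#'
#' All learners accept a `class_weight_ratio` giving the weight of a
#' positive-class error relative to a negative-class error (set it to L/C for
#' cost-sensitive training, 1 for plain accuracy training).
#'
#' @return Character vector of registered learner names.
#' @export
list_learners <- function() c("maxent", "svm", "boost", "ensemble", "lookup")

#' Train a binary sensitive-token classifier
#'
#' @param learner one of [list_learners()].
#' @param corpus a fully labeled [token_corpus].
#' @param class_weight_ratio positive real: misclassification weight of the
#'   positive (sensitive) class relative to the negative class.
#' @param seed integer seed; training is reproducible under a fixed seed.
#' @param config a [feature_config()].
#' @param svm_cap training-subsample cap for the margin-based learner.
#' @return A `san_classifier` handle with a [predict][predict.san_classifier]
#'   method mapping every token of a corpus to \{0, 1\}. Degenerate
#'   single-class training data yields the constant classifier of that
#'   class; when one class has a single instance, the statistical learners
#'   fall back to the surface-lookup rule.
#' @export
train_classifier <- function(learner, corpus, class_weight_ratio = 1,
                             seed = 0L, config = feature_config(),
                             svm_cap = 4000L) {
  stopifnot(learner %in% list_learners(), inherits(corpus, "token_corpus"),
            class_weight_ratio > 0)
  if (nrow(corpus) > 0 && anyNA(corpus$label))
    stop("training corpus must be fully labeled")
  y <- corpus$label
  if (nrow(corpus) == 0 || length(unique(y)) == 1L) {
    value <- if (nrow(corpus) == 0) 0L else unique(y)
    return(structure(list(learner = learner, kind = "constant",
                          value = as.integer(value), config = config,
                          train_n = nrow(corpus), train_acc = 1),
                     class = "san_classifier"))
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  # with a single instance of one class the statistical learners cannot
  # fit; fall back to the surface-lookup rule, which handles any counts
  if (min(table(y)) < 2L && !learner %in% c("lookup"))
    learner_fit <- "lookup"
  else
    learner_fit <- learner
  feats <- extract_features(corpus, config)
  fit <- switch(learner_fit,
    maxent  = .fit_maxent(feats, corpus, y, class_weight_ratio),
    svm     = .fit_svm(feats, y, class_weight_ratio, svm_cap),
    boost   = .fit_boost(feats, y, class_weight_ratio, seed),
    ensemble = .fit_ensemble(corpus, y, class_weight_ratio, seed, config,
                             svm_cap),
    lookup  = .fit_lookup(corpus, y, class_weight_ratio))
  h <- structure(c(list(learner = learner, config = config,
                        train_n = nrow(corpus)), fit),
                 class = "san_classifier")
  h$train_acc <- mean(predict(h, corpus) == y)
  h
}

#' @export
print.san_classifier <- function(x, ...) {
  cat(sprintf("<san_classifier> learner=%s kind=%s trained on n=%d",
              x$learner, x$kind, x$train_n))
  if (!is.null(x$train_acc)) cat(sprintf(" (train acc %.4f)", x$train_acc))
  cat("\n")
  invisible(x)
}

# ---- individual learners ----------------------------------------------------

.fit_maxent <- function(feats, corpus, y, ratio) {
  hist <- if (feats$config$use_history)
    history_feature(corpus$doc_id, y) else NULL
  dict <- feature_dictionary(feats, hist)
  x <- feature_matrix(feats, dict, hist)
  w <- ifelse(y == 1L, ratio, 1)
  # elastic-net path down to a small floor; the floor grows on small corpora
  # where near-separable data makes unpenalized coefficients diverge
  lambda <- sort(unique(c(0.05, 0.02, 0.002, max(5e-5, 0.5 / nrow(x)))),
                 decreasing = TRUE)
  model <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", weights = w, lambda = lambda,
                   alpha = 0.5, standardize = FALSE, maxit = 5e4,
                   thresh = 1e-6))
  list(kind = "maxent", model = model, dict = dict,
       s = min(model$lambda))
}

.fit_svm <- function(feats, y, ratio, cap) {
  dict <- feature_dictionary(feats)
  x <- feature_matrix(feats, dict)
  idx <- seq_along(y)
  if (length(idx) > cap) {
    pos <- idx[y == 1L]
    neg <- idx[y == 0L]
    take <- max(cap - length(pos), min(length(neg), 100L))
    neg <- sort(.resample(neg, min(length(neg), take)))
    idx <- sort(c(pos, neg))
  }
  cw <- c("0" = 1, "1" = ratio)
  model <- e1071::svm(x = x[idx, , drop = FALSE], y = factor(y[idx],
                      levels = c(0, 1)), kernel = "linear", cost = 1,
                      class.weights = cw, scale = FALSE)
  list(kind = "svm", model = model, dict = dict)
}

.fit_boost <- function(feats, y, ratio, seed) {
  dict <- feature_dictionary(feats)
  x <- feature_matrix(feats, dict)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  params <- list(objective = "binary:logistic", max_depth = 4L, eta = 0.3,
                 nthread = 1L, scale_pos_weight = ratio,
                 seed = as.integer(seed) %% .Machine$integer.max)
  model <- xgboost::xgb.train(params = params, data = dtrain, nrounds = 60L,
                              verbose = 0)
  list(kind = "boost", model = model, dict = dict)
}

.fit_ensemble <- function(corpus, y, ratio, seed, config, cap) {
  feats <- extract_features(corpus, config)
  stage1 <- structure(c(list(learner = "maxent", config = config,
                             train_n = nrow(corpus)),
                        .fit_maxent(feats, corpus, y, ratio)),
                      class = "san_classifier")
  p1 <- predict(stage1, corpus)
  pos <- which(p1 == 1L)
  if (length(pos) < 2L || length(unique(y[pos])) == 1L) {
    value <- if (length(pos) == 0L) 1L else as.integer(unique(y[pos])[1])
    stage2 <- structure(list(learner = "svm", kind = "constant",
                             value = value, config = config,
                             train_n = length(pos), train_acc = 1),
                        class = "san_classifier")
  } else {
    sub <- corpus[pos, , drop = FALSE]
    class(sub) <- class(corpus)
    sfeats <- extract_features(sub, config)
    stage2 <- structure(c(list(learner = "svm", config = config,
                               train_n = nrow(sub)),
                          .fit_svm(sfeats, y[pos], ratio, cap)),
                        class = "san_classifier")
  }
  list(kind = "ensemble", stage1 = stage1, stage2 = stage2)
}

.fit_lookup <- function(corpus, y, ratio) {
  pos <- tapply(y == 1L, corpus$surface, sum)
  neg <- tapply(y == 0L, corpus$surface, sum)
  flag <- names(pos)[ratio * pos > neg]
  list(kind = "lookup", surfaces = flag)
}

# ---- prediction -------------------------------------------------------------

#' Predict sensitivity labels for every token of a corpus
#'
#' @param object a `san_classifier` from [train_classifier()].
#' @param newdata a [token_corpus]; features are extracted with the
#'   configuration the classifier was trained with.
#' @param ... unused.
#' @return Integer vector of 0/1 predictions aligned with the corpus rows.
#'   Prediction is deterministic: repeated calls on identical input agree.
#' @export
predict.san_classifier <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "token_corpus"))
  n <- nrow(newdata)
  if (n == 0) return(integer(0))
  if (object$kind == "constant") return(rep(object$value, n))
  if (object$kind == "lookup")
    return(as.integer(newdata$surface %in% object$surfaces))
  if (object$kind == "ensemble") {
    p1 <- predict(object$stage1, newdata)
    out <- p1
    pos <- which(p1 == 1L)
    if (length(pos) > 0) {
      sub <- newdata[pos, , drop = FALSE]
      class(sub) <- class(newdata)
      out[pos] <- as.integer(predict(object$stage2, sub) == 1L)
    }
    return(out)
  }
  feats <- extract_features(newdata, object$config)
  if (object$kind == "maxent") {
    if (object$config$use_history) {
      # two-sweep decoding: prior-label pass, then feed its predictions back
      hist <- rep("0", n)
      hist[!duplicated(newdata$doc_id)] <- "<S>"
      x <- feature_matrix(feats, object$dict, hist)
      p <- as.integer(predict(object$model, x, s = object$s,
                              type = "response") > 0.5)
      hist <- history_feature(newdata$doc_id, p)
      x <- feature_matrix(feats, object$dict, hist)
      return(as.integer(predict(object$model, x, s = object$s,
                                type = "response") > 0.5))
    }
    x <- feature_matrix(feats, object$dict)
    return(as.integer(predict(object$model, x, s = object$s,
                              type = "response") > 0.5))
  }
  x <- feature_matrix(feats, object$dict)
  if (object$kind == "svm")
    return(as.integer(as.character(predict(object$model, x))))
  if (object$kind == "boost")
    return(as.integer(predict(object$model, xgboost::xgb.DMatrix(x)) > 0.5))
  stop("unknown classifier kind: ", object$kind)
}

#' Train every learner in a registry and keep the most accurate
#'
#' Splits the provided documents 75/25 (seeded), trains each registry
#' learner on the larger split, scores token accuracy on the holdout, picks
#' the winner (ties broken by registry order) and refits it on all provided
#' data. This realizes the "best available classifier" that both the
#' publisher's selection mode and the simulated attacker use.
#'
#' @param registry character vector of learner names (see [list_learners()]).
#' @param corpus a fully labeled [token_corpus].
#' @param seed integer seed for the split and for training.
#' @param class_weight_ratio passed to [train_classifier()].
#' @param config a [feature_config()].
#' @param holdout_fraction fraction of documents held out for scoring.
#' @return The winning `san_classifier`, with attributes `selected` (learner
#'   name) and `holdout_acc` (named accuracy vector).
#' @export
select_best <- function(registry, corpus, seed = 0L, class_weight_ratio = 1,
                        config = feature_config(),
                        holdout_fraction = 0.25) {
  stopifnot(length(registry) >= 1, all(registry %in% list_learners()))
  if (length(registry) == 1L) {
    h <- train_classifier(registry, corpus, class_weight_ratio, seed, config)
    attr(h, "selected") <- registry
    return(h)
  }
  docs <- unique(corpus$doc_id)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n_hold <- max(1L, floor(length(docs) * holdout_fraction))
  if (length(docs) == 1L) {
    # single document: fall back to a token-level split
    hold_rows <- sort(sample(nrow(corpus), max(1L, floor(nrow(corpus) *
                                                           holdout_fraction))))
  } else {
    hold_docs <- .resample(docs, n_hold)
    hold_rows <- which(corpus$doc_id %in% hold_docs)
  }
  train_c <- corpus[-hold_rows, , drop = FALSE]
  hold_c <- corpus[hold_rows, , drop = FALSE]
  class(train_c) <- class(hold_c) <- class(corpus)
  acc <- vapply(registry, function(nm) {
    h <- train_classifier(nm, train_c, class_weight_ratio, seed, config)
    mean(predict(h, hold_c) == hold_c$label)
  }, numeric(1))
  winner <- registry[which.max(acc)]   # which.max keeps the first tie
  h <- train_classifier(winner, corpus, class_weight_ratio, seed, config)
  attr(h, "selected") <- winner
  attr(h, "holdout_acc") <- acc
  h
}
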