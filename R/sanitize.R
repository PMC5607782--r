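#' Publisher-attacker game parameters
#'
#' @param L loss (in utility units) incurred by the publisher — and gained by
#'   the attacker — for each sensitive instance that is published and then
#'   exploited; must be positive.
#' @param C cost (same units) of suppressing one non-sensitive instance,
#'   i.e., the value of publishing a data token; must be positive.
#' @param B attacker inspection budget: the number of token instances the
#'   adversary can manually read and verify; non-negative integer.
#' @return A `game_params` list. Only the ratio `L/C` matters to the
#'   sanitizer's stopping rule; `B` matters to the simulated attacker and to
#'   the bound calculators.
#' @export
game_params <- function(L = 1, C = 1, B = 0L) {
  stopifnot(is.numeric(L), length(L) == 1, L > 0,
            is.numeric(C), length(C) == 1, C > 0,
            is.numeric(B), length(B) == 1, B >= 0, B == floor(B))
  structure(list(L = as.numeric(L), C = as.numeric(C), B = as.integer(B)),
            class = "game_params")
}

#' Publisher's total loss
#'
#' The worst-case loss of publishing with classifier set `H` is
#' `T(H) = L * FN(H) + C * FP(H)`: every residual sensitive instance is
#' eventually exploited at loss `L`, and every wrongly suppressed
#' non-sensitive instance costs `C` of data value.
#'
#' @param counts a [confusion_counts] of the classifier set on the data.
#' @param params a [game_params()].
#' @return The loss `L * fn + C * fp`.
#' @export
publisher_loss <- function(counts, params) {
  stopifnot(inherits(counts, "confusion_counts"),
            inherits(params, "game_params"))
  params$L * counts$fn + params$C * counts$fp
}

#' Loss change from adding a candidate classifier
#'
#' By the count decomposition identities (see [check_count_identities()]),
#' adding candidate `h` to the set `H` changes the publisher's loss by
#' `T(H + h) - T(H) = C * FP(h, D) - L * TP(h, D)` where `D` is the residual
#' (still-published) data `h` was evaluated on. The greedy loop stops as soon
#' as this is non-negative: the candidate no longer pays for itself.
#'
#' @param new_counts [confusion_counts] of the candidate on the residual
#'   training data.
#' @param params a [game_params()].
#' @return The loss change; negative means the candidate should be adopted.
#' @export
stopping_delta <- function(new_counts, params) {
  stopifnot(inherits(new_counts, "confusion_counts"),
            inherits(params, "game_params"))
  params$C * new_counts$fp - params$L * new_counts$tp
}

#' Greedy iterative sanitization
#'
#' Runs the GreedySanitize loop on a labeled training corpus: starting from
#' the empty classifier set, repeatedly (1) train a classifier on the
#' residual training instances, (2) compute its confusion counts on that
#' residual, and (3) if the loss change [stopping_delta()] is negative, adopt
#' the classifier, drop its predicted positives from the residual, and
#' repeat. The loop stops at the first candidate whose loss change is
#' non-negative; that stop-triggering candidate is *not* added to the set.
#' Removal operates on token instances: features keep their original document
#' context, instances are simply excluded from subsequent training rounds.
#'
#' Each iteration retrains from scratch with seed `seed + k` so runs are
#' reproducible. The loop always terminates after at most `n_tokens(corpus)`
#' iterations, because every continuing iteration must remove at least one
#' true positive.
#'
#' @param corpus a fully labeled [token_corpus].
#' @param learner a learner name (see [list_learners()]), or `"select"` to
#'   pick the most accurate registry learner each iteration.
#' @param params a [game_params()]; only `L` and `C` are used.
#' @param seed integer seed.
#' @param config a [feature_config()].
#' @param registry learner names used when `learner = "select"`.
#' @param verbose print per-iteration counts.
#' @return A `san_ensemble`: list with `classifiers` (the adopted handles),
#'   `iterations` (number of training rounds, including the stopping one),
#'   `history` (per-iteration data frame of counts, loss change, and residual
#'   size), `redacted` (doc_id/position of all training instances removed),
#'   `stop_candidate` (the rejected final classifier), and `params`.
#' @seealso [publish()] to apply the ensemble to a corpus.
#' @export
greedy_sanitize <- function(corpus, learner = "maxent", params = game_params(),
                            seed = 0L, config = feature_config(),
                            registry = c("maxent", "svm", "boost", "ensemble"),
                            verbose = FALSE) {
  stopifnot(inherits(corpus, "token_corpus"), inherits(params, "game_params"))
  if (nrow(corpus) > 0 && anyNA(corpus$label))
    stop("greedy_sanitize requires a fully labeled corpus")
  out <- list(classifiers = list(), iterations = 0L,
              history = data.frame(), redacted = NULL,
              stop_candidate = NULL, params = params, learner = learner,
              config = config, n = nrow(corpus))
  class(out) <- "san_ensemble"
  if (nrow(corpus) == 0) return(out)

  residual <- seq_len(nrow(corpus))
  removed <- integer(0)
  hist_rows <- list()
  k <- 0L
  repeat {
    if (length(residual) == 0L) break       # nothing left to train on
    k <- k + 1L
    d <- corpus[residual, , drop = FALSE]
    class(d) <- class(corpus)
    h <- if (identical(learner, "select"))
      select_best(registry, d, seed = seed + k, config = config)
    else
      train_classifier(learner, d, class_weight_ratio = 1, seed = seed + k,
                       config = config)
    pred <- predict(h, d)
    cc <- confusion_counts(pred, d$label)
    delta <- stopping_delta(cc, params)
    hist_rows[[k]] <- data.frame(iteration = k, tp = cc$tp, fp = cc$fp,
                                 tn = cc$tn, fn = cc$fn, delta = delta,
                                 residual_n = length(residual))
    if (verbose)
      message(sprintf("iter %d: tp=%d fp=%d tn=%d fn=%d delta=%.3f (m=%d)",
                      k, cc$tp, cc$fp, cc$tn, cc$fn, delta, length(residual)))
    if (delta >= 0) {
      out$stop_candidate <- h
      break
    }
    out$classifiers[[length(out$classifiers) + 1L]] <- h
    removed <- c(removed, residual[pred == 1L])
    residual <- residual[pred == 0L]
  }
  out$iterations <- k
  out$history <- do.call(rbind, hist_rows)
  out$redacted <- corpus[removed, c("doc_id", "position")]
  out$residual_m <- length(residual)
  out
}

#' @export
print.san_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<san_ensemble> %d classifier(s) adopted in %d ",
                     "iteration(s); %d of %d training tokens redacted\n"),
              length(x$classifiers), x$iterations, NROW(x$redacted), x$n))
  if (NROW(x$history) > 0) print(x$history, row.names = FALSE)
  invisible(x)
}

#' Apply a sanitizing ensemble to a corpus and redact its positives
#'
#' Predicts with every adopted classifier and redacts the union of their
#' predicted positives — the publishing rule `P(H) = X \ X1(H)`. The corpus
#' may be the training corpus itself or a held-out corpus (the usual
#' cross-validated evaluation applies the ensemble learned on training folds
#' to the held-out fold).
#'
#' @param corpus a [token_corpus].
#' @param ensemble a `san_ensemble` from [greedy_sanitize()].
#' @param placeholder replacement token for suppressed surfaces.
#' @return The corpus with every predicted-positive token marked redacted
#'   (surface replaced by the placeholder in any written output).
#' @export
publish <- function(corpus, ensemble, placeholder = "[NAME]") {
  stopifnot(inherits(corpus, "token_corpus"),
            inherits(ensemble, "san_ensemble"))
  if (nrow(corpus) == 0) return(corpus)
  flag <- rep(FALSE, nrow(corpus))
  for (h in ensemble$classifiers)
    flag <- flag | (predict(h, corpus) == 1L)
  corpus$redaction[flag] <- placeholder
  corpus
}
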