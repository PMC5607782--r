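#' Expected utility of classifier-prioritized inspection
#'
#' Closed-form expectation of the attacker's gain when inspecting up to `B`
#' instances ranked predicted-positives first. With budget below the number
#' of predicted positives the attacker reads a uniformly random size-`B`
#' subset of them, gaining `L * B * tp / (tp + fp)` in expectation. With
#' surplus budget every predicted positive is read (gaining `L * tp`) and the
#' remaining `B - tp - fp` inspections fall uniformly on the predicted
#' negatives, each paying off `L * fn / (fn + tn)` in expectation.
#'
#' @param counts [confusion_counts] of the attacker's classifier on the
#'   inspectable published instances.
#' @param B inspection budget (capped at the number of instances in
#'   `counts`).
#' @param L attacker gain per confirmed sensitive instance.
#' @return Expected attacker utility (utility units).
#' @export
expected_attack_utility <- function(counts, B, L = 1) {
  stopifnot(inherits(counts, "confusion_counts"), B >= 0, L > 0)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  B <- min(B, n)
  if (B <= tp + fp) {
    if (tp + fp == 0) return(0)
    return(L * B * tp / (tp + fp))
  }
  surplus <- B - tp - fp
  neg_rate <- if (fn + tn > 0) fn / (fn + tn) else 0
  L * (tp + neg_rate * surplus)
}

#' Expected utility of uniformly random inspection
#'
#' The trivial baseline attacker draws `B` instances uniformly at random from
#' the inspectable published instances; each is sensitive with probability
#' `(tp + fn) / n`, so the expected gain is `L * B * (tp + fn) / n`.
#'
#' @inheritParams expected_attack_utility
#' @return Expected baseline utility. Errors on an empty published set.
#' @export
baseline_utility <- function(counts, B, L = 1) {
  stopifnot(inherits(counts, "confusion_counts"), B >= 0, L > 0)
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0) stop("baseline utility is undefined on an empty published set")
  if (B > n) stop("budget exceeds the number of inspectable instances")
  L * B * (counts$tp + counts$fn) / n
}

#' Ratio of learned-attack to random-baseline utility
#'
#' Measures how much the attacker's classifier is worth: the expected utility
#' of prioritized inspection divided by the expected utility of uniformly
#' random inspection at the same budget. A ratio near 1 means learning adds
#' essentially nothing over random reading.
#'
#' @param x either an `attack_result` from [attack()], or a
#'   [confusion_counts] (in which case `B` and `L` must be given).
#' @param B,L budget and per-instance gain, used when `x` is a counts object.
#' @return The utility ratio. Errors when the baseline utility is zero.
#' @examples
#' cc <- confusion_counts(rep(c(1, 0), c(9, 17)),
#'                        rep(c(1, 0, 1, 0), c(3, 6, 2, 15)))
#' utility_ratio(cc, B = 20)
#' @export
utility_ratio <- function(x, B = NULL, L = 1) {
  if (inherits(x, "attack_result")) {
    if (x$utility_baseline <= 0)
      stop("utility ratio undefined: baseline utility is zero")
    return(x$utility_learned / x$utility_baseline)
  }
  stopifnot(inherits(x, "confusion_counts"), !is.null(B))
  base <- baseline_utility(x, B, L)
  if (base <= 0) stop("utility ratio undefined: baseline utility is zero")
  expected_attack_utility(x, B, L) / base
}

#' Simulate the budget-limited inspection adversary
#'
#' Plays the threat model against a published corpus: the attacker labels a
#' seeded random fraction of the published (non-redacted) instances using the
#' ground truth (its labeled holdout), trains the most accurate registry
#' classifier on that holdout, ranks the remaining instances
#' predicted-positives first (document order within each rank class), and
#' inspects the first `B`. Inspection is an oracle lookup: the attacker
#' always assesses true sensitivity correctly and gains `L` per confirmed
#' sensitive instance.
#'
#' With `train_fraction = 0` the attacker trains on all published instances
#' with their true labels — the omniscient accuracy-optimal limit — and the
#' whole published set stays inspectable. Otherwise the labeled holdout is
#' excluded from the inspectable pool (its labels are already known to the
#' attacker).
#'
#' @param published a [token_corpus] with redactions applied (see
#'   [publish()]).
#' @param truth the original fully labeled [token_corpus], aligned with
#'   `published` by (doc_id, position).
#' @param params a [game_params()]; uses `L` and `B`.
#' @param registry learner names the attacker chooses among.
#' @param train_fraction fraction of published instances in the attacker's
#'   labeled holdout, in `[0, 1)`.
#' @param seed integer seed.
#' @param score `"expectation"` scores the inspection in closed form (exact
#'   for the surplus-budget regime); `"sampled"` draws one concrete seeded
#'   inspection order (uniform within each rank class) and counts realized
#'   hits.
#' @param config a [feature_config()].
#' @return An `attack_result`: list with the attacker's classifier handle,
#'   `counts` (its confusion counts on the inspectable pool), `inspected`
#'   (doc_id/position of the inspected instances in rank order),
#'   `utility_learned`, `utility_baseline`, `ratio`, and `pool_n`.
#' @export
attack <- function(published, truth, params, registry = "maxent",
                   train_fraction = 0.5, seed = 0L,
                   score = c("expectation", "sampled"),
                   config = feature_config()) {
  score <- match.arg(score)
  stopifnot(inherits(published, "token_corpus"),
            inherits(truth, "token_corpus"),
            inherits(params, "game_params"))
  if (train_fraction < 0 || train_fraction >= 1)
    stop("train_fraction must be in [0, 1)")
  key_p <- .tok_key(published$doc_id, published$position)
  key_t <- .tok_key(truth$doc_id, truth$position)
  if (nrow(published) != nrow(truth) || !all(key_p == key_t))
    stop("published corpus does not align with the truth corpus")
  if (anyNA(truth$label)) stop("truth corpus must be fully labeled")

  open <- which(is.na(published$redaction))   # inspectable candidates
  if (length(open) == 0) stop("nothing published: empty inspectable set")
  set.seed(as.integer(seed) %% .Machine$integer.max)

  if (train_fraction > 0) {
    n_hold <- floor(train_fraction * length(open))
    if (n_hold < 1) stop("train_fraction leaves no labeled instances")
    hold <- sort(.resample(open, n_hold))
    pool <- setdiff(open, hold)
    if (length(pool) == 0) stop("train_fraction leaves nothing to inspect")
  } else {
    hold <- open
    pool <- open
  }
  train_c <- published[hold, , drop = FALSE]
  train_c$label <- truth$label[hold]
  class(train_c) <- class(published)
  h_a <- select_best(registry, train_c, seed = seed, config = config)

  pool_c <- published[pool, , drop = FALSE]
  class(pool_c) <- class(published)
  pred <- predict(h_a, pool_c)
  cc <- confusion_counts(pred, truth$label[pool])

  B <- min(params$B, length(pool))
  rank_order <- c(pool[pred == 1L], pool[pred == 0L])  # document order within
  inspected <- rank_order[seq_len(B)]
  u_base <- if (B > 0) baseline_utility(cc, B, params$L) else 0
  if (score == "expectation") {
    u_learn <- expected_attack_utility(cc, B, params$L)
  } else {
    perm <- c(.resample(pool[pred == 1L]), .resample(pool[pred == 0L]))
    inspected <- perm[seq_len(B)]
    u_learn <- params$L * sum(truth$label[inspected] == 1L)
  }
  structure(list(classifier = h_a, counts = cc,
                 inspected = truth[inspected, c("doc_id", "position")],
                 utility_learned = u_learn, utility_baseline = u_base,
                 ratio = if (u_base > 0) u_learn / u_base else NA_real_,
                 pool_n = length(pool), budget = B,
                 holdout_n = if (train_fraction > 0) length(hold) else 0L),
            class = "attack_result")
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf(paste0("<attack_result> pool=%d budget=%d tp=%d fp=%d ",
                     "U*=%.3f U0=%.3f ratio=%.3f\n"),
              x$pool_n, x$budget, x$counts$tp, x$counts$fp,
              x$utility_learned, x$utility_baseline, x$ratio))
  invisible(x)
}
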