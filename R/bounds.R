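#' Local-optimality check for a publishing strategy
#'
#' A classifier set `H` is locally optimal when adding the attacker's best
#' classifier `h_A` cannot reduce the publisher's loss. In terms of `h_A`'s
#' confusion counts on the published data this holds exactly when
#' `tp = 0` or `fp / tp >= L / C`. This is also the condition the greedy
#' sanitizer's stop-triggering candidate satisfies on the residual training
#' data.
#'
#' @param attacker_counts [confusion_counts] of `h_A` on the published set.
#' @param params a [game_params()].
#' @return `TRUE` iff the local-optimality condition holds.
#' @export
is_local_optimum <- function(attacker_counts, params) {
  stopifnot(inherits(attacker_counts, "confusion_counts"),
            inherits(params, "game_params"))
  tp <- attacker_counts$tp
  tp == 0 || attacker_counts$fp / tp >= params$L / params$C
}

#' Bound on the attacker's true positives at a local optimum
#'
#' At any locally optimal publishing strategy the attacker's classifier can
#' correctly flag at most `(C / L) * (1 - alpha) * n` sensitive instances:
#' when the loss-to-value ratio `L/C` is large, learned re-identification is
#' necessarily scarce.
#'
#' @param params a [game_params()].
#' @param alpha fraction of sensitive instances in the original data.
#' @param n total number of instances.
#' @return The bound (a real number; not floored to an integer).
#' @export
attacker_tp_bound <- function(params, alpha, n) {
  stopifnot(inherits(params, "game_params"), alpha >= 0, alpha <= 1, n >= 0)
  (params$C / params$L) * (1 - alpha) * n
}

#' Bound on the attacker's utility ratio at a local optimum
#'
#' Under the large-budget regime (`B >= tp + fp`) and the prioritization
#' condition `tp * tn >= fp * fn`, the learned-attack to random-baseline
#' utility ratio at any local optimum is at most
#' `((1 - alpha) * n + 1) / (1 + L / C)`: with high `L/C`, a classifier adds
#' little over random inspection. The caller is responsible for checking the
#' two preconditions (see [bound_report()], which flags them).
#'
#' @inheritParams attacker_tp_bound
#' @return The bound.
#' @export
attacker_ratio_bound <- function(params, alpha, n) {
  stopifnot(inherits(params, "game_params"), alpha >= 0, alpha <= 1, n >= 0)
  ((1 - alpha) * n + 1) / (1 + params$L / params$C)
}

#' Finite-sample parameters for the generalization bounds
#'
#' The finite-sample versions of the attacker bounds account for the gap
#' between the publisher's training estimate of the attacker's classifier and
#' the classifier the attacker actually learns. They depend on the
#' Vapnik-Chervonenkis dimension `vc_dim` of the shared hypothesis class, a
#' confidence level `1 - delta`, the residual training size `m` at
#' termination, and four ratio parameters tying empirical to true counts:
#' `fp_hat <= p * fn_hat`, `tp_hat >= q * pos_hat` on the training estimate,
#' and `fp_a >= s * fn_a`, `tp_a <= r * pos_a` for the attacker's classifier
#' (`pos_hat`/`pos_a` are the respective predicted-positive counts; see
#' [estimate_count_ratios()]).
#'
#' @param vc_dim integer >= 1.
#' @param delta confidence parameter in (0, 1).
#' @param m residual training-set size at termination, >= 1.
#' @param p,q,r,s positive ratio parameters as above.
#' @return A `finite_sample_params` list.
#' @export
finite_sample_params <- function(vc_dim = 1L, delta = 0.05, m = 1L,
                                 p = 1, q = 1, r = 1, s = 1) {
  stopifnot(vc_dim >= 1, delta > 0, delta < 1, m >= 1,
            p > 0, q > 0, r > 0, s > 0)
  structure(list(vc_dim = as.integer(vc_dim), delta = as.numeric(delta),
                 m = as.numeric(m), p = as.numeric(p), q = as.numeric(q),
                 r = as.numeric(r), s = as.numeric(s)),
            class = "finite_sample_params")
}

#' VC deviation term linking empirical and true error
#'
#' `lambda(delta, m) = sqrt((4 / m) * (v * log(2 e m / v) + log(4 / delta)))`
#' with natural logarithms: with probability at least `1 - delta` the true
#' error of any classifier in a VC class of dimension `v` is within `lambda`
#' of its empirical error on `m` samples. Decreasing in `m`, increasing as
#' `delta` shrinks.
#'
#' @param fsp a [finite_sample_params()] (only `vc_dim`, `delta`, `m` used).
#' @return The deviation term.
#' @export
vc_deviation <- function(fsp) {
  stopifnot(inherits(fsp, "finite_sample_params"))
  v <- fsp$vc_dim
  m <- fsp$m
  sqrt((4 / m) * (v * log(2 * exp(1) * m / v) + log(4 / fsp$delta)))
}

# shared validity check: the denominator of the finite-sample bounds
.fs_denominator <- function(fsp, params) {
  lam <- vc_deviation(fsp)
  den <- (1 + 1 / fsp$p) * fsp$q * (params$L / params$C) - lam
  if (den <= 0)
    stop("finite-sample bound invalid: the deviation term lambda = ",
         signif(lam, 4), " is not below (1 + 1/p) * q * L/C = ",
         signif((1 + 1 / fsp$p) * fsp$q * params$L / params$C, 4),
         "; increase the residual training size m")
  list(lambda = lam, den = den)
}

#' Finite-sample bound on the attacker's true positives
#'
#' Generalizes [attacker_tp_bound()] to the training-estimate setting:
#' with probability at least `1 - delta`,
#' `tp_a <= r * (1 + 1/s) * (1 - alpha) * n /
#'          ((1 + 1/p) * q * (L/C) - lambda(delta, m))`.
#' As `m` grows (`lambda -> 0`) and the ratio parameters tighten
#' (`p, s -> Inf`, `q, r -> 1`) this reduces to the asymptotic bound.
#'
#' @param fsp a [finite_sample_params()].
#' @inheritParams attacker_tp_bound
#' @return The bound. Errors when the validity condition
#'   `lambda < (1 + 1/p) * q * L/C` fails.
#' @export
attacker_tp_bound_fs <- function(fsp, params, alpha, n) {
  stopifnot(inherits(fsp, "finite_sample_params"),
            inherits(params, "game_params"), alpha >= 0, alpha <= 1, n >= 0)
  d <- .fs_denominator(fsp, params)
  fsp$r * (1 + 1 / fsp$s) * (1 - alpha) * n / d$den
}

#' Finite-sample bound on the attacker's utility ratio
#'
#' Generalizes [attacker_ratio_bound()]: with probability at least
#' `1 - delta`, under the same budget and prioritization preconditions,
#' `ratio <= ((1 - alpha) * n + 1) * r * (1 + 1/s) /
#'           (r * (1 + 1/s) + (1 + 1/p) * q * (L/C) - lambda(delta, m))`.
#'
#' @inheritParams attacker_tp_bound_fs
#' @return The bound; errors under the same validity condition as
#'   [attacker_tp_bound_fs()].
#' @export
attacker_ratio_bound_fs <- function(fsp, params, alpha, n) {
  stopifnot(inherits(fsp, "finite_sample_params"),
            inherits(params, "game_params"), alpha >= 0, alpha <= 1, n >= 0)
  d <- .fs_denominator(fsp, params)
  rs <- fsp$r * (1 + 1 / fsp$s)
  ((1 - alpha) * n + 1) * rs / (rs + d$den)
}

#' Verify the count decomposition identities for classifier sets
#'
#' For a set of classifiers `H` and a candidate `h`, the false negatives of
#' the union and the false positives of the union decompose exactly as
#' `FN(H) = FN(H + h) + TP(h, P(H))` and
#' `FP(H + h) = FP(H) + FP(h, P(H))`,
#' where `P(H)` is the data surviving every classifier in `H`. These
#' identities are what reduce the sanitizer's stopping rule to the candidate's
#' counts on the residual data. This verifier recomputes every term from the
#' raw prediction maps and reports whether both identities hold.
#'
#' @param H_predictions list of 0/1 prediction vectors, one per classifier in
#'   `H` (possibly empty), all over the same instance universe.
#' @param h_predictions 0/1 prediction vector of the candidate classifier.
#' @param labels 0/1 true labels of the universe.
#' @return `TRUE` iff both identities hold exactly.
#' @export
check_count_identities <- function(H_predictions, h_predictions, labels) {
  n <- length(labels)
  stopifnot(length(h_predictions) == n,
            all(vapply(H_predictions, length, 1L) == n),
            !anyNA(labels), !anyNA(h_predictions))
  pos_any <- function(preds) {
    out <- rep(FALSE, n)
    for (p in preds) out <- out | (p == 1L)
    out
  }
  x1_H <- pos_any(H_predictions)                 # union of predicted positives
  x1_Hh <- x1_H | (h_predictions == 1L)
  S <- labels == 1L
  fn_H <- sum(S & !x1_H)
  fn_Hh <- sum(S & !x1_Hh)
  fp_H <- sum(!S & x1_H)
  fp_Hh <- sum(!S & x1_Hh)
  in_P <- !x1_H                                  # published under H
  tp_h_P <- sum(S & in_P & h_predictions == 1L)
  fp_h_P <- sum(!S & in_P & h_predictions == 1L)
  (fn_H == fn_Hh + tp_h_P) && (fp_Hh == fp_H + fp_h_P)
}

#' Estimate the finite-sample ratio parameters from observed counts
#'
#' The ratio parameters of [finite_sample_params()] are treated as given by
#' the theory; in practice they can be estimated as the tightest values
#' consistent with observed counts: `p = fp_hat / fn_hat` and
#' `q = tp_hat / (tp_hat + fp_hat)` from the stop-triggering candidate's
#' counts on the residual training data, and `s = fp_a / fn_a`,
#' `r = tp_a / (tp_a + fp_a)` from the attacker's counts on a validation
#' split. Zero denominators yield `Inf` (for `p`, `s`) or are left at 1 (for
#' `q`, `r` when the classifier predicts no positives); the chosen estimator
#' is recorded in the result.
#'
#' @param train_counts [confusion_counts] of the stopping candidate on the
#'   residual training data.
#' @param attacker_counts [confusion_counts] of the attacker's classifier.
#' @return A [finite_sample_params()]-style list of `p`, `q`, `r`, `s` with
#'   an `estimator` attribute describing the normalizers used.
#' @export
estimate_count_ratios <- function(train_counts, attacker_counts) {
  stopifnot(inherits(train_counts, "confusion_counts"),
            inherits(attacker_counts, "confusion_counts"))
  rat <- function(a, b) if (b > 0) a / b else Inf
  prec <- function(tp, fp) if (tp + fp > 0) tp / (tp + fp) else 1
  out <- list(p = rat(train_counts$fp, train_counts$fn),
              q = prec(train_counts$tp, train_counts$fp),
              r = prec(attacker_counts$tp, attacker_counts$fp),
              s = rat(attacker_counts$fp, attacker_counts$fn))
  attr(out, "estimator") <-
    "p=fp^/fn^, q=tp^/(tp^+fp^) on residual training; r=tp/(tp+fp), s=fp/fn for the attacker"
  out
}

#' Full bound report for a sanitize-and-attack run
#'
#' Aggregates every guarantee for one run: the local-optimality flag, the
#' asymptotic true-positive and utility-ratio bounds, the VC deviation term,
#' and the finite-sample bounds (when valid), together with flags for the
#' preconditions the ratio bounds assume (prioritization condition
#' `tp * tn >= fp * fn` and budget regime `B >= tp + fp`).
#'
#' @param attacker_counts [confusion_counts] of the attacker on the
#'   published data.
#' @param params a [game_params()].
#' @param alpha,n composition of the original data.
#' @param fsp optional [finite_sample_params()]; when `NULL` the
#'   finite-sample bounds are omitted.
#' @return A `bound_report` list.
#' @export
bound_report <- function(attacker_counts, params, alpha, n, fsp = NULL) {
  stopifnot(inherits(attacker_counts, "confusion_counts"))
  cc <- attacker_counts
  rep <- list(
    local_optimum = is_local_optimum(cc, params),
    tp_bound = attacker_tp_bound(params, alpha, n),
    ratio_bound = attacker_ratio_bound(params, alpha, n),
    prioritization_ok = cc$tp * cc$tn >= cc$fp * cc$fn,
    budget_regime_ok = params$B >= cc$tp + cc$fp,
    lambda = NA_real_, lambda_valid = NA,
    fs_tp_bound = NA_real_, fs_ratio_bound = NA_real_)
  if (!is.null(fsp)) {
    rep$lambda <- vc_deviation(fsp)
    rep$lambda_valid <-
      rep$lambda < (1 + 1 / fsp$p) * fsp$q * (params$L / params$C)
    if (rep$lambda_valid) {
      rep$fs_tp_bound <- attacker_tp_bound_fs(fsp, params, alpha, n)
      rep$fs_ratio_bound <- attacker_ratio_bound_fs(fsp, params, alpha, n)
    }
    rep$fsp <- fsp
  }
  class(rep) <- "bound_report"
  rep
}

#' @export
print.bound_report <- function(x, ...) {
  cat("<bound_report>\n")
  cat(sprintf("  local optimum: %s\n", x$local_optimum))
  cat(sprintf("  attacker TP bound: %.4f; utility-ratio bound: %.4f\n",
              x$tp_bound, x$ratio_bound))
  cat(sprintf("  preconditions: prioritization %s, budget regime %s\n",
              x$prioritization_ok, x$budget_regime_ok))
  if (!is.na(x$lambda))
    cat(sprintf("  lambda=%.4f (valid: %s); fs TP bound: %.4f; fs ratio bound: %.4f\n",
                x$lambda, x$lambda_valid, x$fs_tp_bound, x$fs_ratio_bound))
  invisible(x)
}
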