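#' Publish ratio
#'
#' The data-utility metric: the fraction of original token instances that is
#' released unredacted.
#'
#' @param published a [token_corpus] with redactions applied.
#' @param original the corpus it was derived from (same token count).
#' @return `(n - #redacted) / n` in `[0, 1]`. Errors on an empty corpus.
#' @export
publish_ratio <- function(published, original = published) {
  stopifnot(inherits(published, "token_corpus"))
  if (nrow(original) == 0) stop("publish ratio undefined for an empty corpus")
  if (nrow(published) != nrow(original))
    stop("published and original corpora are not aligned")
  sum(is.na(published$redaction)) / nrow(original)
}

.experiment_defaults <- function() {
  list(corpus = list(synth = list()),
       learner = "maxent",
       registry = "maxent",
       baselines = character(0),
       loss = 10,
       cost = 1,
       budgets = integer(0),
       folds = 4L,
       train_fraction = 0.5,
       seed = 1L,
       feature = list(),
       vc_dim = NULL,
       delta = 0.05)
}

.check_config <- function(config) {
  defaults <- .experiment_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("config$", unknown[1], ": unknown key")
  if ("corpus" %in% names(config) &&
      (!is.list(config$corpus) ||
       !any(c("synth", "path") %in% names(config$corpus))))
    stop("config$corpus: must contain 'synth' (spec fields) or 'path'")
  cfg <- utils::modifyList(defaults, config)
  # the corpus source is taken as given, never merged with the default
  if ("corpus" %in% names(config)) cfg$corpus <- config$corpus
  if (!(identical(cfg$learner, "select") || cfg$learner %in% list_learners()))
    stop("config$learner: unknown learner '", cfg$learner, "'")
  bad <- setdiff(c(cfg$registry, cfg$baselines), list_learners())
  if (length(bad) > 0)
    stop("config$registry/baselines: unknown learner '", bad[1], "'")
  if (!is.numeric(cfg$loss) || any(cfg$loss <= 0))
    stop("config$loss: must be positive")
  if (!is.numeric(cfg$cost) || length(cfg$cost) != 1 || cfg$cost <= 0)
    stop("config$cost: must be a positive scalar")
  if (cfg$folds < 2) stop("config$folds: need at least 2 folds")
  if (cfg$train_fraction < 0 || cfg$train_fraction >= 1)
    stop("config$train_fraction: must be in [0, 1)")
  cfg
}

# metrics of one published fold (+ optional attack across budgets)
.eval_fold <- function(pub, test, L, C, budgets, registry, train_fraction,
                       seed, config_f) {
  ratio <- publish_ratio(pub, test)
  residual <- sum(test$label == 1L & is.na(pub$redaction))
  out <- list(publish_ratio = ratio, residual_sensitive = residual,
              attack = NULL)
  if (length(budgets) > 0 && any(is.na(pub$redaction))) {
    res <- attack(pub, test, game_params(L, C, max(budgets)),
                  registry = registry, train_fraction = train_fraction,
                  seed = seed, config = config_f)
    per_b <- lapply(budgets, function(B) {
      Bc <- min(B, res$pool_n)
      found <- expected_attack_utility(res$counts, Bc, 1)
      data.frame(budget = B,
                 identified = found,
                 identified_per_budget = if (Bc > 0) found / Bc else 0,
                 utility_ratio = if (Bc > 0 &&
                                     baseline_utility(res$counts, Bc, L) > 0)
                   utility_ratio(res$counts, Bc, L) else NA_real_)
    })
    out$attack <- do.call(rbind, per_b)
    out$attacker_counts <- res$counts
  }
  out
}

#' Run a cross-validated sanitize-and-attack experiment
#'
#' The evaluation design: documents are split into `folds` cross-validation
#' folds; for every loss value `L` in the grid and every fold, the greedy
#' sanitizer runs on the training folds, the learned classifier set is
#' applied to the held-out fold, the result is published, and the simulated
#' attacker is played against it at each budget. Cost-sensitive
#' single-classifier baselines (one classifier trained once with positive
#' class weight `L/C`) are evaluated the same way for comparison.
#'
#' @param config a named list (or path to a YAML file) with keys:
#'   `corpus` (either `list(synth = <synthetic_spec fields>)` or
#'   `list(path = <labeled corpus file>)`), `learner`, `registry`,
#'   `baselines`, `loss` (grid of L values), `cost` (C), `budgets`, `folds`,
#'   `train_fraction`, `seed`, `feature` ([feature_config()] fields),
#'   `vc_dim`/`delta` (optional, enables per-fold bound reports). Unknown
#'   keys are rejected with the offending key path.
#' @return An `experiment_report`: list with `config` (the resolved
#'   configuration), `per_fold` (one row per L x fold x method with publish
#'   ratio, residual sensitive count, iterations), `per_budget` (one row per
#'   L x fold x method x budget with the identified-per-budget curve and
#'   utility ratio), `aggregate` (fold means), and `bounds` (per L, when
#'   `vc_dim` is given).
#' @seealso [write_report()]
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .check_config(config)
  fconf <- do.call(feature_config, cfg$feature)

  corpus <- if (!is.null(cfg$corpus$synth))
    generate_corpus(do.call(synthetic_spec, cfg$corpus$synth))
  else
    read_corpus(cfg$corpus$path, labeled = TRUE)
  if (anyNA(corpus$label)) stop("experiment corpus must be fully labeled")

  docs <- unique(corpus$doc_id)
  set.seed(cfg$seed)
  fold_of <- sample(rep_len(seq_len(cfg$folds), length(docs)))
  names(fold_of) <- docs

  per_fold <- list()
  per_budget <- list()
  bounds <- list()
  for (li in seq_along(cfg$loss)) {
    L <- cfg$loss[li]
    C <- cfg$cost
    for (f in seq_len(cfg$folds)) {
      seed_f <- cfg$seed + 1009L * f + 101L * li
      train <- corpus[fold_of[corpus$doc_id] != f, , drop = FALSE]
      test <- corpus[fold_of[corpus$doc_id] == f, , drop = FALSE]
      class(train) <- class(test) <- class(corpus)

      ens <- greedy_sanitize(train, learner = cfg$learner,
                             params = game_params(L, C), seed = seed_f,
                             config = fconf, registry = cfg$registry)
      pub <- publish(test, ens)
      ev <- .eval_fold(pub, test, L, C, cfg$budgets, cfg$registry,
                       cfg$train_fraction, seed_f, fconf)
      per_fold[[length(per_fold) + 1]] <-
        data.frame(method = "greedy", L = L, fold = f,
                   publish_ratio = ev$publish_ratio,
                   residual_sensitive = ev$residual_sensitive,
                   iterations = ens$iterations)
      if (!is.null(ev$attack))
        per_budget[[length(per_budget) + 1]] <-
          cbind(method = "greedy", L = L, fold = f, ev$attack)

      if (!is.null(cfg$vc_dim) && !is.null(ev$attacker_counts)) {
        last <- ens$history[nrow(ens$history), ]
        ratios <- estimate_count_ratios(
          as_confusion_counts(last$tp, last$fp, last$tn, last$fn),
          ev$attacker_counts)
        clamp <- function(x) min(max(x, 1e-6), 1e6)
        fsp <- finite_sample_params(cfg$vc_dim, cfg$delta,
                                    max(1L, ens$residual_m),
                                    p = clamp(ratios$p), q = clamp(ratios$q),
                                    r = clamp(ratios$r), s = clamp(ratios$s))
        bounds[[length(bounds) + 1]] <-
          list(L = L, fold = f,
               report = bound_report(ev$attacker_counts,
                                     game_params(L, C, max(cfg$budgets, 0)),
                                     sensitive_fraction(test), nrow(test),
                                     fsp))
      }

      for (bl in cfg$baselines) {
        h <- train_classifier(bl, train, class_weight_ratio = L / C,
                              seed = seed_f, config = fconf)
        pub_b <- test
        pub_b$redaction[predict(h, test) == 1L] <- "[NAME]"
        ev_b <- .eval_fold(pub_b, test, L, C, cfg$budgets, cfg$registry,
                           cfg$train_fraction, seed_f, fconf)
        per_fold[[length(per_fold) + 1]] <-
          data.frame(method = paste0("cs_", bl), L = L, fold = f,
                     publish_ratio = ev_b$publish_ratio,
                     residual_sensitive = ev_b$residual_sensitive,
                     iterations = 1L)
        if (!is.null(ev_b$attack))
          per_budget[[length(per_budget) + 1]] <-
            cbind(method = paste0("cs_", bl), L = L, fold = f, ev_b$attack)
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)
  per_budget <- if (length(per_budget) > 0) do.call(rbind, per_budget)
  agg <- stats::aggregate(
    cbind(publish_ratio, residual_sensitive, iterations) ~ method + L,
    data = per_fold, FUN = mean)
  structure(list(config = cfg, per_fold = per_fold, per_budget = per_budget,
                 aggregate = agg, bounds = bounds),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' @param report an `experiment_report` (or any list of results).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$bounds <- lapply(out$bounds, function(b)
    c(b[c("L", "fold")], lapply(unclass(b$report)[
      c("local_optimum", "tp_bound", "ratio_bound", "lambda",
        "fs_tp_bound", "fs_ratio_bound")], identity)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", force = TRUE)
  invisible(path)
}
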