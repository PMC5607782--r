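test_that("publisher loss and stopping delta follow the loss model", {
  p51 <- game_params(L = 5, C = 1)
  expect_equal(publisher_loss(textsan:::as_confusion_counts(0, 0, 10, 0), p51), 0)
  # worked-example counts: L*fn + C*fp = 5*2 + 1*6
  expect_equal(publisher_loss(textsan:::as_confusion_counts(3, 6, 15, 2), p51), 16)
  expect_equal(publisher_loss(textsan:::as_confusion_counts(0, 4, 0, 3),
                              game_params(L = 1, C = 1)), 7)
  # delta = C*fp - L*tp; zero predictions stop the loop
  expect_equal(stopping_delta(textsan:::as_confusion_counts(0, 0, 9, 1), p51), 0)
  expect_equal(stopping_delta(textsan:::as_confusion_counts(3, 6, 15, 2), p51), -9)
  expect_equal(stopping_delta(textsan:::as_confusion_counts(1, 1, 0, 0),
                              game_params(L = 1, C = 10)), 9)
})

test_that("stopping delta equals the brute-force loss difference", {
  # adding candidate h to H changes the loss by C*fp - L*tp on P(H),
  # recomputed here from raw index sets
  set.seed(77)
  for (i in 1:40) {
    n <- sample(5:25, 1)
    labels <- sample(0:1, n, TRUE)
    H_preds <- replicate(sample(0:3, 1), sample(0:1, n, TRUE),
                         simplify = FALSE)
    h_pred <- sample(0:1, n, TRUE)
    L <- sample(1:10, 1); C <- sample(1:5, 1)
    sets <- oracle_ensemble_sets(H_preds, labels)
    oc <- oracle_counts(h_pred, labels, sets$published)
    delta_direct <- oracle_loss(c(H_preds, list(h_pred)), labels, L, C) -
      oracle_loss(H_preds, labels, L, C)
    delta_pkg <- stopping_delta(
      textsan:::as_confusion_counts(oc$tp, oc$fp, oc$tn, oc$fn),
      game_params(L, C))
    expect_equal(delta_pkg, delta_direct)
  }
})

test_that("a corpus with no signal publishes everything", {
  corp <- token_corpus(doc_id = rep("d", 8),
                       surface = letters[1:8], label = rep(0L, 8))
  ens <- greedy_sanitize(corp, learner = "lookup", params = game_params(5, 1))
  expect_equal(length(ens$classifiers), 0)
  pub <- publish(corp, ens)
  expect_equal(publish_ratio(pub, corp), 1)
})

test_that("an empty corpus yields an empty ensemble", {
  corp <- token_corpus(character(), character(), label = integer(0))
  ens <- greedy_sanitize(corp, learner = "lookup", params = game_params(5, 1))
  expect_equal(ens$iterations, 0)
  expect_equal(NROW(ens$redacted), 0)
})

test_that("on the separable toy the loop adopts one classifier and stops", {
  toy <- make_separable_toy()
  ens <- greedy_sanitize(toy, learner = "maxent",
                         params = game_params(L = 5, C = 1), seed = 2)
  expect_equal(length(ens$classifiers), 1)
  expect_equal(ens$iterations, 2)
  # iteration 1 found every sensitive token: the residual has none left
  expect_equal(ens$history$tp[1], sum(toy$label))
  expect_equal(ens$history$fn[2] + ens$history$tp[2], 0)
  expect_equal(ens$history$tp[2], 0)
  expect_gte(ens$history$delta[2], 0)
  # published result keeps every non-sensitive token
  pub <- publish(toy, ens)
  expect_equal(sum(!is.na(pub$redaction)), sum(toy$label))
  expect_equal(sum(pub$label == 1L & is.na(pub$redaction)), 0)
})

test_that("the loop terminates within n iterations on random corpora", {
  for (i in 1:100) {
    corp <- make_random_corpus(sample(10:60, 1), seed = 5000 + i,
                               p_sens = stats::runif(1, 0.1, 0.9))
    params <- game_params(L = sample(c(1, 2, 5, 10), 1), C = 1)
    ens <- greedy_sanitize(corp, learner = "lookup", params = params,
                           seed = i)
    expect_lte(ens$iterations, n_tokens(corp))
    # the stop-triggering candidate (when the loop did not simply run out
    # of residual data) is locally optimal on the residual data
    if (!is.null(ens$stop_candidate)) {
      last <- ens$history[nrow(ens$history), ]
      expect_true(last$tp == 0 ||
                    last$fp / last$tp >= params$L / params$C)
    }
    # loss change decomposition holds at every adopted iteration
    if (nrow(ens$history) > 1) {
      adopted <- ens$history[-nrow(ens$history), ]
      expect_true(all(adopted$delta < 0))
    }
  }
})

test_that("redaction grows weakly as iterations proceed", {
  spec <- synthetic_spec(n_docs = 40, tokens_per_doc = 60, seed = 12,
                         name_vocab_size = 50, background_vocab_size = 300)
  corp <- generate_corpus(spec)
  ens <- greedy_sanitize(corp, learner = "lookup",
                         params = game_params(L = 20, C = 1), seed = 1)
  # residual training size is non-increasing; removals equal predicted tp+fp
  expect_true(all(diff(ens$history$residual_n) <= 0))
  if (nrow(ens$history) > 1) {
    removed <- -diff(ens$history$residual_n)
    adopted <- ens$history[-nrow(ens$history), ]
    expect_equal(removed, adopted$tp + adopted$fp)
  }
})

test_that("raising L/C weakly increases suppression and lowers residual risk", {
  spec <- synthetic_spec(n_docs = 50, tokens_per_doc = 60, seed = 31,
                         name_vocab_size = 60, background_vocab_size = 300)
  corp <- generate_corpus(spec)
  lc <- c(1, 2, 5, 10, 20)
  redacted <- numeric(length(lc))
  residual <- numeric(length(lc))
  for (i in seq_along(lc)) {
    ens <- greedy_sanitize(corp, learner = "lookup",
                           params = game_params(L = lc[i], C = 1), seed = 8)
    pub <- publish(corp, ens)
    redacted[i] <- sum(!is.na(pub$redaction))
    residual[i] <- sum(pub$label == 1L & is.na(pub$redaction))
  }
  expect_true(all(diff(redacted) >= 0))
  expect_true(all(diff(residual) <= 0))
})

test_that("publishing with an empty ensemble is the identity", {
  fx <- fixture_example1()
  ens <- structure(list(classifiers = list(), iterations = 0L,
                        history = data.frame(), redacted = NULL,
                        params = game_params(), n = 26),
                   class = "san_ensemble")
  pub <- publish(fx$corpus, ens)
  expect_equal(sum(!is.na(pub$redaction)), 0)
  # redacting the fixture's 9 predicted positives publishes 17 of 26
  red <- fx$corpus[fx$predictions == 1L, c("doc_id", "position")]
  pub2 <- redact(fx$corpus, red)
  expect_equal(sum(is.na(pub2$redaction)), 17)
  expect_equal(publish_ratio(pub2, fx$corpus), 17 / 26)
  # saturation: redacting everything publishes nothing
  pub3 <- redact(fx$corpus, fx$corpus[, c("doc_id", "position")])
  expect_equal(publish_ratio(pub3, fx$corpus), 0)
})
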