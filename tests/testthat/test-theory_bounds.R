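test_that("the local-optimality characterization matches direct cases", {
  p51 <- game_params(L = 5, C = 1)
  expect_true(is_local_optimum(textsan:::as_confusion_counts(0, 9, 1, 0), p51))
  # fp/tp = 2 < 5: the attacker's classifier still pays off
  expect_false(is_local_optimum(textsan:::as_confusion_counts(3, 6, 15, 2), p51))
  # boundary: fp/tp = 2 >= L/C = 2
  expect_true(is_local_optimum(textsan:::as_confusion_counts(3, 6, 15, 2),
                               game_params(L = 2, C = 1)))
})

test_that("local-optimality agrees with the brute-force loss test", {
  # enumerate small universes through their realized count 4-tuples and
  # compare against the direct criterion T(H + h_A) - T(H) >= 0 computed
  # from raw index sets (with H empty, P(H) is the whole universe)
  g <- count_grid(12)
  for (lc in c(0.5, 1, 2, 5)) {
    params <- game_params(L = lc, C = 1)
    for (i in seq_len(nrow(g))) {
      r <- realize_counts(g$tp[i], g$fp[i], g$tn[i], g$fn[i])
      direct <- oracle_loss(list(r$pred), r$labels, lc, 1) -
        oracle_loss(list(), r$labels, lc, 1) >= 0
      chk <- is_local_optimum(
        textsan:::as_confusion_counts(g$tp[i], g$fp[i], g$tn[i], g$fn[i]),
        params)
      if (chk != direct) {
        fail(sprintf("disagreement at tp=%d fp=%d tn=%d fn=%d L/C=%g",
                     g$tp[i], g$fp[i], g$tn[i], g$fn[i], lc))
      }
    }
  }
  succeed()
})

test_that("local-optimality transfers through nonempty classifier sets", {
  # with a nonempty H the criterion applies to h_A's counts on P(H)
  set.seed(52)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    labels <- sample(0:1, n, TRUE)
    H_preds <- replicate(sample(1:3, 1), sample(0:1, n, TRUE),
                         simplify = FALSE)
    h_pred <- sample(0:1, n, TRUE)
    lc <- sample(c(1, 2, 5), 1)
    sets <- oracle_ensemble_sets(H_preds, labels)
    oc <- oracle_counts(h_pred, labels, sets$published)
    direct <- oracle_loss(c(H_preds, list(h_pred)), labels, lc, 1) -
      oracle_loss(H_preds, labels, lc, 1) >= 0
    chk <- is_local_optimum(
      textsan:::as_confusion_counts(oc$tp, oc$fp, oc$tn, oc$fn),
      game_params(L = lc, C = 1))
    expect_equal(chk, direct)
  }
})

test_that("count decomposition identities hold against the set oracle", {
  # 1000 randomized universes, up to 4 classifiers in H
  set.seed(991)
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    labels <- sample(0:1, n, TRUE)
    H_preds <- replicate(sample(0:4, 1), sample(0:1, n, TRUE),
                         simplify = FALSE)
    h_pred <- sample(0:1, n, TRUE)
    # package verifier
    if (!check_count_identities(H_preds, h_pred, labels)) {
      fail(sprintf("identity violated at case %d (n=%d)", i, n))
    }
    # independent set-oracle version of both identities
    s_H <- oracle_ensemble_sets(H_preds, labels)
    s_Hh <- oracle_ensemble_sets(c(H_preds, list(h_pred)), labels)
    oc <- oracle_counts(h_pred, labels, s_H$published)
    if (s_H$fn != s_Hh$fn + oc$tp || s_Hh$fp != s_H$fp + oc$fp) {
      fail(sprintf("oracle identity violated at case %d", i))
    }
  }
  succeed()
})

test_that("identity edge cases: empty set and duplicated classifier", {
  labels <- c(1L, 1L, 0L, 0L, 1L)
  h <- c(1L, 0L, 1L, 0L, 1L)
  # empty H: FN(H) is the total sensitive count
  expect_true(check_count_identities(list(), h, labels))
  s <- oracle_ensemble_sets(list(), labels)
  expect_equal(s$fn, 3)
  # h already in H: its positives on P(H) vanish, identities degenerate
  expect_true(check_count_identities(list(h), h, labels))
  oc <- oracle_counts(h, labels, oracle_ensemble_sets(list(h), labels)$published)
  expect_equal(oc$tp, 0)
  expect_equal(oc$fp, 0)
})

test_that("attacker true-positive bound evaluates and behaves monotonically", {
  # worked-example composition: C/L = 0.2, 21 non-sensitive of 26
  expect_equal(attacker_tp_bound(game_params(L = 5, C = 1), 5 / 26, 26), 4.2)
  expect_equal(attacker_tp_bound(game_params(L = 5, C = 1), 1, 100), 0)
  lvals <- c(1, 2, 5, 10, 100)
  b <- vapply(lvals, function(L)
    attacker_tp_bound(game_params(L = L, C = 1), 0.02, 1000), numeric(1))
  expect_true(all(diff(b) < 0))
})

test_that("utility-ratio bound evaluates at known points", {
  expect_equal(attacker_ratio_bound(game_params(L = 5, C = 1), 5 / 26, 26),
               22 / 6)
  # algebraic fixed point: L/C = (1 - alpha) n gives exactly 1
  expect_equal(attacker_ratio_bound(game_params(L = 21, C = 1), 5 / 26, 26), 1)
  # the worked-example realized ratio stays below the bound while
  # L/C <= 18.8 (22 / (1 + x) >= 1.1165 iff x <= 18.70...)
  ratio <- utility_ratio(textsan:::as_confusion_counts(3, 6, 15, 2), B = 20)
  for (lc in c(1, 5, 10, 18)) {
    expect_gte(attacker_ratio_bound(game_params(L = lc, C = 1), 5 / 26, 26),
               ratio)
  }
  expect_lt(attacker_ratio_bound(game_params(L = 19.8, C = 1), 5 / 26, 26),
            ratio)
})

test_that("the VC deviation term evaluates and is monotone", {
  fsp <- finite_sample_params(vc_dim = 1, delta = 0.05, m = 10000)
  expect_equal(vc_deviation(fsp), 0.0782, tolerance = 1e-3)
  # independently recomputed: sqrt((4/m)(v ln(2em/v) + ln(4/delta)))
  expect_equal(vc_deviation(fsp),
               sqrt((4 / 10000) * (log(2 * exp(1) * 10000) + log(80))),
               tolerance = 1e-12)
  # more data tightens the term; smaller delta loosens it
  for (m in c(50, 500, 5000)) {
    expect_gt(vc_deviation(finite_sample_params(2, 0.05, m)),
              vc_deviation(finite_sample_params(2, 0.05, 2 * m)))
  }
  expect_gt(vc_deviation(finite_sample_params(2, 0.01, 1000)),
            vc_deviation(finite_sample_params(2, 0.05, 1000)))
})

test_that("finite-sample bounds evaluate and recover the asymptotic forms", {
  params <- game_params(L = 10, C = 1)
  # frozen values computed with an independent calculator for
  # v=2, delta=0.1, m=1000, p=3, q=0.9, r=0.8, s=4, L/C=10, alpha=0.02, n=500
  fsp <- finite_sample_params(2, 0.1, 1000, p = 3, q = 0.9, r = 0.8, s = 4)
  expect_equal(vc_deviation(fsp), 0.2793162366356687, tolerance = 1e-12)
  expect_equal(attacker_tp_bound_fs(fsp, params, 0.02, 500),
               41.80643466651721, tolerance = 1e-10)
  expect_equal(attacker_ratio_bound_fs(fsp, params, 0.02, 500),
               38.59855406625891, tolerance = 1e-10)
  # validity: lambda must stay below (1 + 1/p) q L/C
  bad <- finite_sample_params(50, 0.05, 10, p = 1e6, q = 0.01)
  expect_error(attacker_tp_bound_fs(bad, game_params(L = 1, C = 1), 0.02, 100),
               "lambda")
  # asymptotic consistency: m -> Inf, p,s -> Inf, q,r -> 1
  big <- finite_sample_params(1, 0.05, 1e12, p = 1e12, q = 1, r = 1, s = 1e12)
  expect_equal(attacker_tp_bound_fs(big, params, 0.02, 500),
               attacker_tp_bound(params, 0.02, 500), tolerance = 1e-4)
  expect_equal(attacker_ratio_bound_fs(big, params, 0.02, 500),
               attacker_ratio_bound(params, 0.02, 500), tolerance = 1e-4)
  # the ratio bound falls strictly as L/C rises
  fsp2 <- finite_sample_params(3, 0.05, 2000, p = 4, q = 0.8, r = 0.9, s = 5)
  rbs <- vapply(c(2, 5, 10, 50), function(L)
    attacker_ratio_bound_fs(fsp2, game_params(L = L, C = 1), 0.02, 500),
    numeric(1))
  expect_true(all(diff(rbs) < 0))
})

test_that("lambda -> 0 limit of the finite-sample forms is exact", {
  # with the ratio parameters at their tight limits the finite-sample
  # expressions must reduce to the asymptotic bounds to within 1e-9
  params <- game_params(L = 7, C = 2)
  alpha <- 0.05; n <- 300
  fsp <- finite_sample_params(1, 0.5, 1e300, p = 1e300, q = 1, r = 1,
                              s = 1e300)
  expect_equal(attacker_tp_bound_fs(fsp, params, alpha, n),
               attacker_tp_bound(params, alpha, n), tolerance = 1e-9)
  expect_equal(attacker_ratio_bound_fs(fsp, params, alpha, n),
               attacker_ratio_bound(params, alpha, n), tolerance = 1e-9)
})

test_that("ratio estimation and the aggregated bound report are coherent", {
  train_cc <- textsan:::as_confusion_counts(8, 2, 80, 4)
  att_cc <- textsan:::as_confusion_counts(3, 6, 15, 2)
  ratios <- estimate_count_ratios(train_cc, att_cc)
  expect_equal(ratios$p, 2 / 4)
  expect_equal(ratios$q, 8 / 10)
  expect_equal(ratios$r, 3 / 9)
  expect_equal(ratios$s, 6 / 2)
  # zero denominators degrade gracefully
  r0 <- estimate_count_ratios(textsan:::as_confusion_counts(0, 0, 10, 0),
                              textsan:::as_confusion_counts(0, 0, 5, 0))
  expect_equal(r0$p, Inf)
  expect_equal(r0$q, 1)
  rep <- bound_report(att_cc, game_params(L = 2, C = 1, B = 20), 5 / 26, 26,
                      finite_sample_params(2, 0.05, 5000, 1, 1, 1, 1))
  expect_true(rep$local_optimum)       # fp/tp = 2 >= 2
  expect_true(rep$prioritization_ok)   # 45 >= 12
  expect_true(rep$budget_regime_ok)    # 20 >= 9
  expect_equal(rep$tp_bound, 10.5)
  expect_true(is.finite(rep$fs_tp_bound) || is.na(rep$fs_tp_bound))
})
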