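---
title: "Adversarial sanitization of text corpora: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial sanitization of text corpora: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Organizations that share weakly structured data — clinical notes, emails,
court records — must first remove personal identifiers. At scale this is
done with machine-learned classifiers, and learning is never perfect: some
sensitive tokens always leak. `textsan` implements a publishing strategy
that accepts a small leak but makes it *hard to find*: the publisher's goal
is not zero residual identifiers, it is that an adversary with a bounded
amount of manual reading can do little better than reading at random.

The data model is deliberately simple. A corpus is a set of $n$ token
instances $X = \{x_1,\dots,x_n\}$, each carrying a binary sensitivity label
$S(x) \in \{0,1\}$ (here: is the token a personal name). A fraction
$\alpha$ of instances is sensitive; in realistic corpora $\alpha$ is small,
on the order of 2–5%. Both sides of the game draw classifiers from a common
hypothesis class $\mathcal{H}$ — the assumption being that state-of-the-art
learners are public knowledge.

## The publisher–attacker game

The publisher chooses a *set* of classifiers $H = \{h_1,\dots,h_D\}$,
suppresses every instance any $h_i$ flags (replacing the surface with a
placeholder such as `[NAME]`), and releases the rest,
$P(H) = X \setminus X_1(H)$. Its worst-case loss is

$$T(H) = L \cdot FN(H) + C \cdot FP(H),$$

where $L$ is the cost of one leaked-and-exploited sensitive instance, $C$
the value of one wrongly suppressed ordinary token, $FN(H)$ the residual
sensitive instances in $P$, and $FP(H)$ the non-sensitive instances that
were suppressed. Only the ratio $L/C$ matters to the publisher's decisions.

The attacker receives $P$, labels a holdout of it, trains the most accurate
classifier $h_A$ available in $\mathcal{H}$, ranks the remaining instances
predicted-positives first, and manually inspects up to $B$ of them.
Inspection is assumed perfect: each inspected instance's true status is
revealed, and each confirmed sensitive instance pays the attacker $L$. Its
expected gain is compared to the trivial baseline of inspecting $B$
instances uniformly at random; the ratio $U^*_A / U_A$ of the two measures
what learning is worth to the attacker.

## The greedy sanitize loop

`greedy_sanitize()` iterates: train a classifier on the residual training
instances $D_{k-1}$, compute its confusion counts there, and stop as soon
as the loss change of adopting it,
$\Delta T = C \cdot FP(h_k, D_{k-1}) - L \cdot TP(h_k, D_{k-1})$, is
non-negative; otherwise adopt it, remove its predicted positives, and
repeat. Two consequences drive the design:

* **Termination.** Every continuing iteration must have $TP \ge 1$, so at
  most $|X|$ iterations are possible; in practice the loop ends after a
  handful, because the learnable signal is exhausted quickly.
* **Local optimality.** The stop-triggering candidate satisfies $TP = 0$ or
  $FP/TP \ge L/C$ on the residual data. At such a point the attacker's best
  classifier can identify at most $(C/L)(1-\alpha)n$ sensitive instances,
  and — when its budget covers all predicted positives and the
  prioritization condition $TP_A TN_A \ge FP_A FN_A$ holds — its utility
  ratio is capped by $((1-\alpha)n + 1)/(1 + L/C)$. The package computes
  both bounds (`attacker_tp_bound()`, `attacker_ratio_bound()`) and their
  finite-sample generalizations, which inflate the cap by a
  Vapnik–Chervonenkis deviation term
  $\lambda(\delta, m) = \sqrt{\tfrac{4}{m}\left(\upsilon \ln\tfrac{2em}{\upsilon} + \ln\tfrac{4}{\delta}\right)}$
  (natural logarithms, the standard VC convention) evaluated at the
  residual training size $m$.

Design choices where the procedure was genuinely open:

* The stopping condition is evaluated with true labels on the residual
  *training* data, using the count decomposition identities
  ($FN(H) = FN(H \cup h) + TP(h, P(H))$ and
  $FP(H \cup h) = FP(H) + FP(h, P(H))$, verified exhaustively in the test
  suite) so that only the new candidate's counts are needed.
* The stop-triggering candidate is **not** added to $H$: it is the
  certificate that no further classifier pays for itself, not a member of
  the publishing set.
* Removal operates on token instances, not on document text: a removed
  instance keeps contributing its surface to neighbors' window features,
  and is merely excluded from later training rounds. All counting in the
  game is per instance, so this is the consistent reading.
* Retraining is from scratch each round with seed `seed + k`; no warm
  starts, so runs are exactly reproducible.
* A constant-positive candidate (redact everything) needs no special case:
  its $C \cdot FP$ term already makes $\Delta T \ge 0$ unless the corpus is
  mostly sensitive.
* If the residual becomes empty before any candidate triggers the stop,
  the loop ends without a stop certificate; tests treat this exit
  separately.

## Learners

The hypothesis class is realized by a registry of five learners
(`list_learners()`), all reading the same orthographic feature templates
(surface, lowercase form, collapsed capitalization shape, digit/punctuation
flags, prefixes/suffixes up to length 3, neighbor surfaces at offsets
$-2\dots+2$ with explicit padding). Part-of-speech information is
approximated by these orthographic and affix templates rather than by an
external tagger, keeping the package self-contained; a precomputed `pos`
column is honored when present.

* `maxent` — a Markov sequence tagger: sparse elastic-net logistic
  regression over the templates plus the previous token's label, trained
  with gold history and decoded in two left-to-right sweeps (first with a
  non-sensitive prior label, then feeding back the first sweep's
  predictions). Two sweeps suffice here because name mentions are one or
  two tokens long; the history feature mainly helps tag the second token
  of a two-token name. The regularization path ends at a small floor that
  grows on small corpora, where near-separable data would otherwise drive
  unpenalized coefficients to diverge (glmnet, `maxit` capped).
* `svm` — a linear-kernel SVM with class weights. Because SVM training
  cost is quadratic in the training size, training is capped at `svm_cap`
  (default 4000) instances: all positives plus a seeded negative sample.
* `boost` — gradient boosted trees (60 rounds, depth 4) on the same
  templates.
* `ensemble` — the two-stage scheme used in de-identification practice:
  the sequence tagger proposes positives and a margin classifier trained
  on those proposals filters false positives.
* `lookup` — a surface-dictionary classifier, the exact empirical-risk
  minimizer within the surface-lookup family. It is fast and deterministic,
  which makes it the workhorse of the property-based tests.

Cost-sensitive training uses a single knob, `class_weight_ratio`: the
weight of a positive-class error relative to a negative-class error, set to
$L/C$ for the cost-sensitive baselines and 1 (plain accuracy) inside the
greedy loop. `select_best()` realizes "choose the most accurate learner":
a seeded 75/25 document split, accuracy on the holdout, ties broken by
registry order, winner refit on all provided data. The attacker uses the
same registry — common knowledge of $\mathcal{H}$ — but can be restricted
via configuration to study weaker adversaries.

The attacker's labeled holdout fraction defaults to 0.5 of the published
instances; the holdout is excluded from the inspectable pool (its labels
are already known). With `train_fraction = 0` the attacker trains on all of
$P$ with true labels — the omniscient limit used by the worked-example
fixture. Surplus-budget inspection is scored in expectation by default
(uniform within each rank class), which matches the accounting of the
closed-form analysis and makes small fixtures exact; a `sampled` mode draws
concrete seeded inspection orders, and the tests verify the two agree
within Monte-Carlo error.

## The synthetic corpus generator

Real de-identification corpora are access-restricted, so the package
evaluates on synthetic corpora designed to reproduce the *regime* the
method assumes, not natural language:

* documents are streams of function words and Zipf-weighted pseudo-words,
  including capitalized non-names (days, places, "The", pronoun "He"), so
  capitalization alone cannot identify names;
* name mentions are planted at a calibrated rate so the realized sensitive
  fraction tracks `alpha_target` (default 0.02, the scale of clinical
  corpora); mentions are one or two tokens (30% two-token), preceded by an
  honorific cue with probability `context_cue_strength`;
* a fraction `ambiguity_rate` (default 0.3) of name surface forms also
  occurs as ordinary background tokens at a matched rate, so no
  surface-only rule separates them — the "He the surname vs. He the
  pronoun" phenomenon. Uncued ambiguous mentions are genuinely
  unlearnable, which is what gives the high-but-imperfect-recall regime.

Defaults (500 documents × 200 tokens, $\alpha$ 0.02, ambiguity 0.3, cue
strength 0.7) are the package's standing study conditions; the cue strength
reflects that most name mentions in clinical text are titled. What passing
tests on this generator show is that the *loop and its guarantees* behave
as analyzed when the signal has this shape; they do not certify performance
on any particular natural-language corpus, where feature adequacy, not the
game logic, is the binding constraint.

## Evaluation harness and problem sizes

`run_experiment()` mirrors the standard evaluation design: four-fold
cross-validation *by documents* (token-level folds would leak document
context across the split), greedy sanitization on the training folds, the
learned set applied to the held-out fold, publication, then the attack at
each budget on the published fold. Cost-sensitive single-classifier
baselines (class weight $L/C$) are run on the same folds. Reports are plain
lists serializable to JSON (`write_report()`); determinism is exact given
the configuration and seed.

The shipped test-suite and acceptance studies use the default 500×200
corpus (~100k tokens) for the headline run and corpora of 1–10k tokens for
property checks — sizes chosen so the full suite completes in minutes on a
single core while keeping the headline run at the generator's standing
conditions. Exhaustive verifications (count-identity and local-optimality
oracles, attack-utility inequalities) run over all confusion-count
4-tuples summing to at most 30 and randomized universes of up to 20
instances.

## Known limitations

* Tokenization is assumed done; only one sensitive category is modeled
  (a configurable placeholder, default `[NAME]`).
* Contextual and linkage attacks — an adversary exploiting correlated
  *context* words rather than the tokens themselves — are out of scope.
* The ratio parameters $p, q, r, s$ of the finite-sample bounds are inputs
  of the theory; `estimate_count_ratios()` supplies the tightest values
  consistent with observed counts (normalizing $q$ and $r$ by predicted
  positives) and records that estimator choice, but other normalizers are
  defensible.
* The utility-ratio bound presumes the attacker's classifier has at least
  one true positive; the degenerate no-positive classifier reduces to the
  uninformative ratio of 1 and is excluded from the bound's grid checks.
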