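# Brute-force oracles and fixture builders shared across test files.
# The oracles recompute every quantity from explicit set operations on
# instance index sets, independently of the package's count arithmetic.

# confusion counts by explicit set construction
oracle_counts <- function(pred, labels, subset = seq_along(labels)) {
  S <- intersect(subset, which(labels == 1L))
  N <- intersect(subset, which(labels == 0L))
  pos <- intersect(subset, which(pred == 1L))
  list(tp = length(intersect(S, pos)),
       fp = length(intersect(N, pos)),
       tn = length(setdiff(N, pos)),
       fn = length(setdiff(S, pos)))
}

# FN(H), FP(H) and the published index set P(H) for a classifier set,
# computed from the raw definitions: X1(H) is the union of predicted
# positives, FN(H) the sensitive instances every member misses
oracle_ensemble_sets <- function(H_preds, labels) {
  n <- length(labels)
  x1 <- integer(0)
  for (p in H_preds) x1 <- union(x1, which(p == 1L))
  S <- which(labels == 1L)
  N <- which(labels == 0L)
  list(fn = length(setdiff(S, x1)),
       fp = length(intersect(N, x1)),
       published = setdiff(seq_len(n), x1))
}

# publisher loss from the raw sets
oracle_loss <- function(H_preds, labels, L, C) {
  s <- oracle_ensemble_sets(H_preds, labels)
  L * s$fn + C * s$fp
}

# 50-token corpus whose positives carry a unique suffix marker, so any
# non-trivial learner can separate it; the rule-based oracle is grepl("qq$")
make_separable_toy <- function(seed = 1) {
  set.seed(seed)
  vocab <- c("the", "dog", "ran", "fast", "home", "blue", "tree", "rock",
             "sun", "mild")
  surface <- character(0); label <- integer(0); doc <- character(0)
  for (d in 1:10) {
    s <- sample(vocab, 5, TRUE)
    l <- rep(0L, 5)
    pos <- sample(1:5, 2)
    s[pos] <- paste0("Pz", d, pos, "qq")
    l[pos] <- 1L
    surface <- c(surface, s); label <- c(label, l)
    doc <- c(doc, rep(paste0("d", d), 5))
  }
  token_corpus(doc, surface, label = label)
}

# small random labeled corpus over a limited vocabulary (labels depend
# noisily on the surface, so lookup-style learners find partial signal)
make_random_corpus <- function(n_tokens, seed, p_sens = 0.3) {
  set.seed(seed)
  vocab <- paste0("w", 1:8)
  sens_prob <- stats::setNames(stats::runif(8) < p_sens, vocab)
  surface <- sample(vocab, n_tokens, TRUE)
  label <- as.integer(ifelse(sens_prob[surface],
                             stats::runif(n_tokens) < 0.85,
                             stats::runif(n_tokens) < 0.1))
  doc <- paste0("d", ceiling(seq_len(n_tokens) / 10))
  token_corpus(doc, surface, label = label)
}

# enumerate all confusion 4-tuples (tp, fp, tn, fn) with tp+fp+tn+fn <= nmax
count_grid <- function(nmax) {
  g <- expand.grid(tp = 0:nmax, fp = 0:nmax, tn = 0:nmax, fn = 0:nmax)
  g[g$tp + g$fp + g$tn + g$fn <= nmax & g$tp + g$fp + g$tn + g$fn > 0, ]
}

# build a concrete universe + prediction vector realizing given counts
realize_counts <- function(tp, fp, tn, fn) {
  labels <- rep(c(1L, 0L, 0L, 1L), c(tp, fp, tn, fn))
  pred <- rep(c(1L, 1L, 0L, 0L), c(tp, fp, tn, fn))
  list(labels = labels, pred = pred)
}
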