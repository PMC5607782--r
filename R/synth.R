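#' Specification for a synthetic annotated corpus
#'
#' Describes a seeded generator for labeled token corpora with the
#' statistical structure the sanitizer targets: personal-name tokens are
#' rare (a small sensitive fraction `alpha_target`, matching the roughly
#' 2-5% seen in clinical and email corpora), some name surface forms are
#' ambiguous (they also occur as ordinary non-sensitive tokens, the way "He"
#' can be a surname or a pronoun), and most — but not all — name mentions are
#' preceded by an honorific cue ("Dr.", "Ms.", ...), so the signal is
#' learnable yet imperfect.
#'
#' @param n_docs number of documents.
#' @param tokens_per_doc mean document length in tokens (lengths vary ~15%
#'   around the mean).
#' @param alpha_target target sensitive-token fraction in (0, 1).
#' @param ambiguity_rate fraction of name *surface forms* that also occur as
#'   non-sensitive background tokens, in `[0, 1]`. Sensitive mentions draw an
#'   ambiguous form with this probability, and ambiguous forms are injected
#'   into the background at a matching rate, so no surface-only rule can
#'   separate them.
#' @param name_vocab_size,background_vocab_size vocabulary sizes.
#' @param context_cue_strength probability that a name mention is preceded by
#'   an honorific cue token, in `[0, 1]`.
#' @param seed integer seed; the generated corpus is a deterministic function
#'   of the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_docs = 500L, tokens_per_doc = 200L,
                           alpha_target = 0.02, ambiguity_rate = 0.3,
                           name_vocab_size = 200L,
                           background_vocab_size = 3000L,
                           context_cue_strength = 0.7, seed = 1L) {
  stopifnot(n_docs >= 1, tokens_per_doc >= 1,
            alpha_target > 0, alpha_target < 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            name_vocab_size >= 2, background_vocab_size >= 10,
            context_cue_strength >= 0, context_cue_strength <= 1)
  structure(list(n_docs = as.integer(n_docs),
                 tokens_per_doc = as.integer(tokens_per_doc),
                 alpha_target = as.numeric(alpha_target),
                 ambiguity_rate = as.numeric(ambiguity_rate),
                 name_vocab_size = as.integer(name_vocab_size),
                 background_vocab_size = as.integer(background_vocab_size),
                 context_cue_strength = as.numeric(context_cue_strength),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.cue_words <- c("Dr.", "Mr.", "Mrs.", "Ms.", "Prof.")

.function_words <- c("the", "of", "and", "to", "a", "in", "was", "for",
                     "on", "with", "as", "is", "at", "by", "that", "from",
                     "this", "be", "were", "not", "his", "her", "their",
                     "had", "has", "after", "before", "during", "no",
                     ",", ".", ";", ":")

# capitalized non-name background words: shape alone must not identify names
.capitalized_background <- c("The", "Monday", "Tuesday", "Friday", "January",
                             "March", "Hospital", "Clinic", "Center",
                             "Austin", "Boston", "Mercy", "MRI", "CT",
                             "Tylenol", "He", "She", "It", "They")

# pronounceable pseudo-word from syllables, deterministic given the RNG state
.make_words <- function(k, capitalize = FALSE) {
  onset <- c("b", "d", "f", "g", "h", "j", "k", "l", "m", "n", "p", "r",
             "s", "t", "v", "w", "z", "br", "ch", "cl", "dr", "gr", "kr",
             "pl", "sh", "st", "th", "tr")
  vowel <- c("a", "e", "i", "o", "u", "ai", "ea", "ou")
  coda <- c("", "n", "r", "s", "t", "l", "m", "ck", "rd", "nd")
  out <- character(0)
  while (length(out) < k) {
    need <- k - length(out)
    syl <- function() paste0(sample(onset, need, TRUE),
                             sample(vowel, need, TRUE))
    w <- paste0(syl(), syl(), sample(coda, need, TRUE))
    out <- unique(c(out, w))
  }
  out <- out[seq_len(k)]
  if (capitalize)
    out <- paste0(toupper(substr(out, 1, 1)), substring(out, 2))
  out
}

#' Generate a seeded synthetic labeled corpus
#'
#' Documents are streams of background tokens (function words plus a
#' Zipf-weighted pseudo-word vocabulary, including some capitalized
#' non-names) into which name mentions are planted: an optional honorific
#' cue, then one or (30% of the time) two consecutive sensitive name tokens.
#' A `ambiguity_rate` fraction of the name vocabulary also occurs,
#' capitalized and uncued, as non-sensitive background, at a rate matched to
#' its sensitive usage. The mention rate is calibrated so the realized
#' sensitive fraction tracks `alpha_target`.
#'
#' @param spec a [synthetic_spec()].
#' @return A fully labeled [token_corpus]; identical spec (including seed)
#'   yields a byte-identical corpus.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_target <- spec$n_docs * spec$tokens_per_doc
  if (spec$alpha_target * n_target < 1)
    stop("infeasible spec: alpha_target * n < 1 sensitive token expected")
  set.seed(spec$seed)

  names_vocab <- .make_words(spec$name_vocab_size, capitalize = TRUE)
  n_amb <- round(spec$ambiguity_rate * spec$name_vocab_size)
  amb_names <- names_vocab[seq_len(n_amb)]
  plain_names <- setdiff(names_vocab, amb_names)

  n_pseudo <- max(0L, spec$background_vocab_size - length(.function_words) -
                    length(.capitalized_background))
  bg_vocab <- c(.function_words, .capitalized_background,
                .make_words(n_pseudo, capitalize = FALSE))
  bg_weight <- 1 / seq_along(bg_vocab)^1.1      # Zipf-ish frequencies
  bg_weight <- bg_weight / sum(bg_weight)

  two_tok_p <- 0.3
  a <- spec$alpha_target
  cue <- spec$context_cue_strength
  # per-slot mention probability such that the expected sensitive fraction
  # (1 + two_tok_p) * pi / (1 + pi * (two_tok_p + cue)) equals alpha_target
  pi_slot <- a / (1 + two_tok_p - a * (two_tok_p + cue))
  amb_bg_p <- a * spec$ambiguity_rate           # background use of ambiguous forms

  len <- pmax(20L, round(stats::rnorm(spec$n_docs, spec$tokens_per_doc,
                                      0.15 * spec$tokens_per_doc)))
  n_slots <- sum(len)
  slot_doc <- rep(sprintf("doc%05d", seq_len(spec$n_docs)), times = len)

  u <- stats::runif(n_slots)
  is_event <- u < pi_slot
  is_amb_bg <- !is_event & (u < pi_slot + amb_bg_p) & n_amb > 0

  s1 <- character(n_slots); s2 <- rep(NA_character_, n_slots)
  s3 <- rep(NA_character_, n_slots)
  l1 <- integer(n_slots); l2 <- rep(NA_integer_, n_slots)
  l3 <- rep(NA_integer_, n_slots)

  n_bg <- sum(!is_event & !is_amb_bg)
  s1[!is_event & !is_amb_bg] <- sample(bg_vocab, n_bg, TRUE, bg_weight)
  if (any(is_amb_bg))
    s1[is_amb_bg] <- amb_names[sample.int(n_amb, sum(is_amb_bg), TRUE)]

  ev <- which(is_event)
  if (length(ev) > 0) {
    draw_name <- function(k) {
      amb <- stats::runif(k) < spec$ambiguity_rate & n_amb > 0
      out <- character(k)
      if (any(amb)) out[amb] <- amb_names[sample.int(n_amb, sum(amb), TRUE)]
      if (any(!amb)) {
        src <- if (length(plain_names) > 0) plain_names else amb_names
        out[!amb] <- src[sample.int(length(src), sum(!amb), TRUE)]
      }
      out
    }
    has_cue <- stats::runif(length(ev)) < cue
    two_tok <- stats::runif(length(ev)) < two_tok_p
    name1 <- draw_name(length(ev))
    name2 <- draw_name(length(ev))
    cue_tok <- sample(.cue_words, length(ev), TRUE)
    s1[ev] <- ifelse(has_cue, cue_tok, name1)
    l1[ev] <- ifelse(has_cue, 0L, 1L)
    s2[ev] <- ifelse(has_cue, name1, ifelse(two_tok, name2, NA))
    l2[ev] <- ifelse(has_cue, 1L, ifelse(two_tok, 1L, NA))
    s3[ev] <- ifelse(has_cue & two_tok, name2, NA)
    l3[ev] <- ifelse(has_cue & two_tok, 1L, NA)
  }

  surf_mat <- rbind(s1, s2, s3)
  lab_mat <- rbind(l1, l2, l3)
  keep <- !is.na(surf_mat)
  surface <- surf_mat[keep]                     # column-major: slot order
  label <- lab_mat[keep]
  doc_id <- rep(slot_doc, times = colSums(keep))
  token_corpus(doc_id = doc_id, surface = surface, label = label)
}

#' Worked example: a 26-token published snippet and an attacker's predictions
#'
#' A small clinical-note style fixture with 5 sensitive name tokens among 26,
#' together with a fixed attacker prediction map realizing the confusion
#' counts tp = 3, fp = 6, tn = 15, fn = 2 — including an ambiguous "He" that
#' is a surname in one place (a true positive) and a pronoun in another (a
#' false positive). With unit loss and budget 20 the expectation-scored
#' utility ratio on these counts is about 1.12 (the surplus 11 inspections
#' pay off at rate 2/17 on the predicted negatives).
#'
#' @return A list with `corpus` (a labeled [token_corpus]), `predictions`
#'   (integer vector aligned with the corpus rows), and `counts` (the
#'   resulting [confusion_counts]).
#' @examples
#' fx <- fixture_example1()
#' fx$counts
#' utility_ratio(fx$counts, B = 20)
#' @export
fixture_example1 <- function() {
  surface <- c("Dr.", "Verghese", "saw", "Ms.", "Park", "at", "Mercy",
               "Hospital", "on", "Tuesday", ".", "He", "remained", "stable",
               ";", "He", "was", "seen", "by", "White", "in", "Austin",
               "with", "nurse", "Day", ".")
  label <- integer(26)
  label[c(2, 5, 12, 20, 25)] <- 1L
  predictions <- integer(26)
  predictions[c(2, 4, 5, 7, 8, 10, 12, 16, 22)] <- 1L
  corpus <- token_corpus(doc_id = rep("doc00001", 26), surface = surface,
                         label = label)
  list(corpus = corpus, predictions = predictions,
       counts = confusion_counts(predictions, label))
}
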