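#' Feature extraction configuration
#'
#' Controls the token feature templates used by all learners. Features are
#' orthographic and contextual: the surface itself, its lowercase form, a
#' collapsed capitalization shape (e.g. `"Xx"` for `He`), digit/punctuation
#' flags, prefixes and suffixes up to `affix_max` characters, the neighboring
#' surfaces in a window of `window` tokens on each side (with explicit
#' `<BOS>`/`<EOS>` padding at document boundaries), and optionally the label
#' history of the preceding token (used by the Markov sequence tagger).
#' Part-of-speech information is approximated by these orthographic and affix
#' templates; a precomputed `pos` column on the corpus is used as an
#' additional template when `pos_column = TRUE`.
#'
#' @param window non-negative integer, neighbor offsets `-window ... +window`.
#' @param affix_max maximum prefix/suffix length (0 disables affixes).
#' @param use_history include the previous token's (predicted) label as a
#'   feature in learners that support it.
#' @param min_count features seen fewer than `min_count` times in training
#'   are dropped from the dictionary.
#' @param pos_column use a `pos` column on the corpus as a feature template.
#' @return A `feature_config` list.
#' @export
feature_config <- function(window = 2L, affix_max = 3L, use_history = TRUE,
                           min_count = 1L, pos_column = FALSE) {
  stopifnot(window >= 0, affix_max >= 0, min_count >= 1)
  structure(list(window = as.integer(window),
                 affix_max = as.integer(affix_max),
                 use_history = isTRUE(use_history),
                 min_count = as.integer(min_count),
                 pos_column = isTRUE(pos_column)),
            class = "feature_config")
}

# capitalization shape: runs of upper -> X, lower -> x, digit -> d, other -> .
.token_shape <- function(s) {
  s <- gsub("[[:upper:]]", "X", s)
  s <- gsub("[[:lower:]]", "x", s)
  s <- gsub("[[:digit:]]", "d", s)
  s <- gsub("[^Xxd]", ".", s)
  gsub("(.)\\1+", "\\1", s)
}

# neighbor surface at signed offset within the same document, padded
.neighbor <- function(surface, doc_id, offset, pad) {
  n <- length(surface)
  idx <- seq_len(n) + offset
  ok <- idx >= 1L & idx <= n
  out <- rep(pad, n)
  ok[ok] <- doc_id[idx[ok]] == doc_id[ok]
  out[ok] <- surface[idx[ok]]
  out
}

#' Extract token features
#'
#' Computes one feature bundle per token of the corpus. Extraction is a
#' deterministic function of the corpus (and configuration): the same corpus
#' yields identical features. Redacted tokens are represented by their
#' placeholder surface, which is what a data recipient would see.
#'
#' @param corpus a [token_corpus].
#' @param config a [feature_config()].
#' @return A `token_features` object: a named list of length-`n` character
#'   template vectors plus bookkeeping used to build sparse design matrices.
#' @export
extract_features <- function(corpus, config = feature_config()) {
  stopifnot(inherits(corpus, "token_corpus"))
  if (nrow(corpus) == 0) stop("corpus is empty")
  surf <- ifelse(is.na(corpus$redaction), corpus$surface, corpus$redaction)
  doc <- corpus$doc_id
  t <- list()
  t[["w"]] <- surf
  t[["wl"]] <- tolower(surf)
  t[["shape"]] <- .token_shape(surf)
  t[["digit"]] <- ifelse(grepl("[[:digit:]]", surf), "1", "0")
  t[["punct"]] <- ifelse(grepl("[[:punct:]]", surf), "1", "0")
  t[["icap"]] <- ifelse(grepl("^[[:upper:]]", surf), "1", "0")
  if (config$affix_max > 0) {
    for (k in seq_len(config$affix_max)) {
      t[[paste0("pre", k)]] <- substr(surf, 1L, k)
      t[[paste0("suf", k)]] <- substring(surf, pmax(1L, nchar(surf) - k + 1L))
    }
  }
  if (config$window > 0) {
    for (o in seq_len(config$window)) {
      t[[paste0("w-", o)]] <- .neighbor(surf, doc, -o, "<BOS>")
      t[[paste0("w+", o)]] <- .neighbor(surf, doc, +o, "<EOS>")
    }
  }
  if (config$pos_column) {
    if (is.null(corpus$pos)) stop("pos_column = TRUE but corpus has no pos column")
    t[["pos"]] <- as.character(corpus$pos)
    if (config$window > 0) {
      t[["pos-1"]] <- .neighbor(t[["pos"]], doc, -1L, "<BOS>")
      t[["pos+1"]] <- .neighbor(t[["pos"]], doc, +1L, "<EOS>")
    }
  }
  structure(list(templates = t, n = nrow(corpus), doc_id = doc,
                 config = config),
            class = "token_features")
}

# previous-token label within each document (character), "<S>" at doc start
history_feature <- function(doc_id, labels) {
  .neighbor(as.character(labels), doc_id, -1L, "<S>")
}

# flatten templates (plus optional history vector) to "name=value" strings
.feature_strings <- function(feats, history = NULL) {
  t <- feats$templates
  if (!is.null(history)) t[["hist1"]] <- history
  unlist(lapply(names(t), function(nm) paste0(nm, "=", t[[nm]])),
         use.names = FALSE)
}

# build the training dictionary: features occurring >= min_count times
feature_dictionary <- function(feats, history = NULL,
                               min_count = feats$config$min_count) {
  fs <- .feature_strings(feats, history)
  tab <- table(fs)
  sort(names(tab)[tab >= min_count])
}

# n x |dict| sparse indicator matrix; unseen features are dropped
feature_matrix <- function(feats, dict, history = NULL) {
  fs <- .feature_strings(feats, history)
  n <- feats$n
  k <- length(fs) / n
  i <- rep.int(seq_len(n), k)
  j <- match(fs, dict)
  keep <- !is.na(j)
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(n, length(dict)))
  # duplicate features within a token collapse to a single indicator
  m@x[m@x > 1] <- 1
  m
}
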