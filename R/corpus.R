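#' Token corpora
#'
#' A `token_corpus` is an ordered collection of tokenized documents, stored as
#' a data frame with one row per token instance and columns:
#'
#' * `doc_id` (character): document identifier, in file order.
#' * `position` (integer): 0-based token index within the document.
#' * `surface` (string): the token as it appears in the text.
#' * `label` (integer or `NA`): 1 if the token is a sensitive entity (e.g., a
#'   personal name), 0 otherwise; `NA` for unlabeled corpora.
#' * `redaction` (character or `NA`): the placeholder (default `"[NAME]"`)
#'   that replaced the surface when the token was suppressed before
#'   publication; `NA` for tokens published verbatim.
#'
#' The unit of sanitization is the token: multi-word names are consecutive
#' sensitive tokens, and all counting (losses, attacker utilities, publish
#' ratios) is per token instance.
#'
#' @param doc_id,surface character vectors of equal length.
#' @param position integer vector; 0-based, unique within each document. When
#'   `NULL`, positions are assigned in row order within each document.
#' @param label optional integer vector in \{0, 1\} (or `NA`).
#' @param redaction optional character vector of placeholders (`NA` = not
#'   redacted).
#' @return A `token_corpus` data frame.
#' @examples
#' corp <- token_corpus(doc_id = c("d1", "d1", "d2"),
#'                      surface = c("Dr.", "Smith", "admitted"),
#'                      label = c(0L, 1L, 0L))
#' n_tokens(corp)
#' sensitive_fraction(corp)
#' @export
token_corpus <- function(doc_id, surface, position = NULL, label = NULL,
                         redaction = NULL) {
  doc_id <- as.character(doc_id)
  surface <- as.character(surface)
  n <- length(surface)
  if (length(doc_id) != n) stop("doc_id and surface must have equal length")
  if (is.null(position)) {
    position <- stats::ave(seq_len(n), doc_id, FUN = seq_along) - 1L
  }
  position <- as.integer(position)
  if (n > 0 && any(position < 0)) stop("positions must be >= 0")
  if (anyDuplicated(paste0(doc_id, "\r", position)))
    stop("(doc_id, position) pairs must be unique")
  if (is.null(label)) label <- rep(NA_integer_, n)
  label <- as.integer(label)
  if (!all(is.na(label) | label %in% c(0L, 1L)))
    stop("labels must be 0, 1 or NA")
  if (is.null(redaction)) redaction <- rep(NA_character_, n)
  x <- data.frame(doc_id = doc_id, position = position, surface = surface,
                  label = label, redaction = as.character(redaction),
                  stringsAsFactors = FALSE)
  class(x) <- c("token_corpus", "data.frame")
  x
}

#' @rdname token_corpus
#' @param x a `token_corpus`.
#' @export
n_tokens <- function(x) nrow(x)

#' @rdname token_corpus
#' @export
sensitive_fraction <- function(x) {
  if (nrow(x) == 0) return(NA_real_)
  if (anyNA(x$label))
    stop("sensitive_fraction is defined only for fully labeled corpora")
  mean(x$label == 1L)
}

#' @export
print.token_corpus <- function(x, ...) {
  nd <- length(unique(x$doc_id))
  cat(sprintf("<token_corpus> %d tokens in %d documents", nrow(x), nd))
  if (nrow(x) > 0 && !anyNA(x$label))
    cat(sprintf("; sensitive fraction %.4f", sensitive_fraction(x)))
  nr <- sum(!is.na(x$redaction))
  if (nr > 0) cat(sprintf("; %d redacted", nr))
  cat("\n")
  invisible(x)
}

# stable key for (doc_id, position)
.tok_key <- function(doc_id, position) paste0(doc_id, "\r", position)

#' Read a token corpus from a CoNLL-style file
#'
#' The exchange format is one token per line, documents separated by blank
#' lines, UTF-8. Labeled files have two tab-separated fields,
#' `<token>\t<SENS|O>`; unlabeled (or published) files have a single field
#' per line. `SENS` maps to label 1 and `O` to label 0. In unlabeled mode a
#' surface equal to the placeholder argument is read back as a redacted token.
#'
#' @param path file path.
#' @param labeled logical; `TRUE` expects the two-column labeled dialect.
#' @param placeholder placeholder string recognized as a redaction marker when
#'   reading unlabeled files.
#' @return A [token_corpus].
#' @seealso [write_corpus()], [write_published()]
#' @export
read_corpus <- function(path, labeled = TRUE, placeholder = "[NAME]") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  # trim trailing blank lines so they do not create an empty final document
  while (length(lines) > 0 && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) == 0)
    return(token_corpus(character(), character()))
  blank <- lines == ""
  # a document starts at a non-blank line that is first or follows a blank
  doc_no <- cumsum(!blank & c(TRUE, blank[-length(blank)]))
  keep <- !blank
  content <- lines[keep]
  doc_no <- doc_no[keep]
  parts <- strsplit(content, "\t", fixed = TRUE)
  nf <- lengths(parts)
  want <- if (labeled) 2L else 1L
  bad <- which(nf != want)
  if (length(bad) > 0) {
    lineno <- which(keep)[bad[1]]
    if (length(unique(nf)) > 1)
      stop(sprintf("mixed labeled/unlabeled lines (line %d has %d field(s))",
                   lineno, nf[bad[1]]))
    stop(sprintf("line %d has %d field(s), expected %d", lineno, nf[bad[1]],
                 want))
  }
  surface <- vapply(parts, `[[`, character(1), 1L)
  if (labeled) {
    tag <- vapply(parts, `[[`, character(1), 2L)
    if (!all(tag %in% c("SENS", "O"))) {
      lineno <- which(keep)[which(!tag %in% c("SENS", "O"))[1]]
      stop(sprintf("line %d: label must be SENS or O", lineno))
    }
    label <- ifelse(tag == "SENS", 1L, 0L)
  } else {
    label <- rep(NA_integer_, length(surface))
  }
  doc_id <- sprintf("doc%05d", doc_no)
  corp <- token_corpus(doc_id = doc_id, surface = surface, label = label)
  if (!labeled) {
    red <- corp$surface == placeholder
    corp$redaction[red] <- placeholder
  }
  corp
}

#' Write a token corpus in the CoNLL-style exchange format
#'
#' @param corpus a [token_corpus].
#' @param path output file path.
#' @param labeled logical; write the two-column labeled dialect (requires all
#'   labels present) or the one-column surface dialect (redacted tokens are
#'   written as their placeholder).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, labeled = TRUE) {
  stopifnot(inherits(corpus, "token_corpus"))
  if (nrow(corpus) == 0) {
    writeLines(character(), path, useBytes = TRUE)
    return(invisible(path))
  }
  if (labeled) {
    if (anyNA(corpus$label))
      stop("cannot write labeled dialect: corpus has missing labels")
    body <- paste0(corpus$surface, "\t",
                   ifelse(corpus$label == 1L, "SENS", "O"))
  } else {
    body <- ifelse(is.na(corpus$redaction), corpus$surface, corpus$redaction)
  }
  docs <- split(body, factor(corpus$doc_id, levels = unique(corpus$doc_id)))
  out <- unlist(lapply(docs, function(d) c(d, "")), use.names = FALSE)
  out <- out[-length(out)]                      # no trailing blank separator
  writeLines(enc2utf8(out), path, useBytes = TRUE)
  invisible(path)
}

#' Redact selected tokens and write the published corpus
#'
#' Replaces the surface of every token named in `redacted_ids` with the
#' placeholder and writes the one-column published dialect. Document structure
#' and total token count are preserved: redaction is replacement, not
#' deletion, so the data recipient sees where suppression occurred.
#'
#' @param corpus a [token_corpus].
#' @param redacted_ids a data frame with columns `doc_id` and `position`
#'   naming the tokens to suppress (every pair must exist in `corpus`).
#' @param path output file path.
#' @param placeholder replacement token, default `"[NAME]"`.
#' @return `path`, invisibly.
#' @export
write_published <- function(corpus, redacted_ids, path,
                            placeholder = "[NAME]") {
  stopifnot(inherits(corpus, "token_corpus"))
  corp <- redact(corpus, redacted_ids, placeholder)
  write_corpus(corp, path, labeled = FALSE)
}

#' Mark tokens of a corpus as redacted
#'
#' @inheritParams write_published
#' @return The corpus with the named tokens' `redaction` set (surfaces are
#'   kept so that the truth corpus can still be aligned; writers and feature
#'   extraction see the placeholder).
#' @export
redact <- function(corpus, redacted_ids, placeholder = "[NAME]") {
  stopifnot(inherits(corpus, "token_corpus"))
  if (is.null(redacted_ids) || NROW(redacted_ids) == 0) return(corpus)
  key <- .tok_key(corpus$doc_id, corpus$position)
  rkey <- .tok_key(as.character(redacted_ids$doc_id),
                   as.integer(redacted_ids$position))
  hit <- match(rkey, key)
  if (anyNA(hit))
    stop("unknown (doc_id, position): ", rkey[which(is.na(hit))[1]])
  corpus$redaction[hit] <- placeholder
  corpus
}

#' Confusion counts of binary predictions
#'
#' Tallies true/false positives and negatives of a predictor against true
#' sensitivity labels over a token subset. By convention the counts on an
#' empty subset are all zero.
#'
#' @param predictions integer vector of predicted labels in \{0, 1\}.
#' @param labels integer vector of true labels in \{0, 1\}, same length.
#' @return An object of class `confusion_counts`: a list with elements `tp`,
#'   `fp`, `tn`, `fn` summing to `length(labels)`.
#' @examples
#' confusion_counts(c(1, 0, 1), c(1, 1, 0))
#' @export
confusion_counts <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (anyNA(predictions)) stop("missing prediction")
  if (anyNA(labels)) stop("missing label")
  if (!all(predictions %in% c(0L, 1L)) || !all(labels %in% c(0L, 1L)))
    stop("predictions and labels must be 0/1")
  structure(list(tp = sum(predictions == 1L & labels == 1L),
                 fp = sum(predictions == 1L & labels == 0L),
                 tn = sum(predictions == 0L & labels == 0L),
                 fn = sum(predictions == 0L & labels == 1L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

# internal constructor from bare counts (used by bound calculators and tests)
as_confusion_counts <- function(tp, fp, tn, fn) {
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 tn = as.numeric(tn), fn = as.numeric(fn)),
            class = "confusion_counts")
}
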