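#' @keywords internal
"_PACKAGE"

CUE_TYPES <- c("negation", "speculation")
SUB_CORPORA <- c("abstracts", "full_papers", "clinical", "unknown")

#' Cue annotation
#'
#' A typed cue (negation or speculation) covering a half-open, 0-based word
#' interval `[start, end)` of its sentence. `ref_id` links the cue to the
#' scope annotation carrying the same identifier.
#'
#' @param cue_type `"negation"` or `"speculation"`.
#' @param start,end Integer word indices, 0-based, half-open: the cue covers
#'   words `start, ..., end - 1`. Multi-word cues (e.g. "rather than") use
#'   `end - start > 1`.
#' @param ref_id Identifier string linking this cue to its scope.
#' @return An object of class `cue_annotation`.
#' @export
cue_annotation <- function(cue_type, start, end, ref_id) {
  cue_type <- match.arg(cue_type, CUE_TYPES)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("cue span must satisfy 0 <= start < end")
  structure(list(cue_type = cue_type, start = start, end = end,
                 ref_id = as.character(ref_id)),
            class = "cue_annotation")
}

#' Scope annotation
#'
#' A contiguous scope span linked (by `scope_id`) to the cue whose `ref_id`
#' matches. Spans are 0-based half-open word intervals.
#'
#' @param scope_id Identifier string; the linked cue's `ref_id` equals this.
#' @param start,end Integer word indices, 0-based half-open.
#' @return An object of class `scope_annotation`.
#' @export
scope_annotation <- function(scope_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("scope span must satisfy 0 <= start < end")
  structure(list(scope_id = as.character(scope_id), start = start, end = end),
            class = "scope_annotation")
}

#' Annotated sentence
#'
#' One sentence as an ordered word vector plus its cue and scope
#' annotations. All spans are 0-based half-open word intervals inside
#' `[0, length(words))`; each scope is linked to exactly one cue by
#' identifier.
#'
#' @param sentence_id Sentence identifier string.
#' @param words Character vector of words (whitespace tokens; punctuation
#'   stays attached to its word).
#' @param cues List of [cue_annotation()] objects.
#' @param scopes List of [scope_annotation()] objects.
#' @param sub_corpus One of `"abstracts"`, `"full_papers"`, `"clinical"`,
#'   `"unknown"`. Assigned per input file by the caller, not inferred.
#' @return An object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(sentence_id, words, cues = list(),
                               scopes = list(), sub_corpus = "unknown") {
  sub_corpus <- match.arg(sub_corpus, SUB_CORPORA)
  s <- structure(list(sentence_id = as.character(sentence_id),
                      words = as.character(words),
                      cues = cues, scopes = scopes, sub_corpus = sub_corpus),
                 class = "annotated_sentence")
  validate_sentence(s)
  s
}

#' Validate an annotated sentence
#'
#' Checks the structural invariants: spans inside `[0, n_words)`, unique cue
#' `ref_id`s, and a one-to-one cue/scope link for every scope.
#'
#' @param s An `annotated_sentence`.
#' @return `s`, invisibly; signals an error on violation.
#' @export
validate_sentence <- function(s) {
  stopifnot(inherits(s, "annotated_sentence"))
  n <- length(s$words)
  if (n < 1L) stop("sentence '", s$sentence_id, "' has no words")
  for (cue in s$cues)
    if (cue$end > n)
      stop("cue span [", cue$start, ",", cue$end, ") outside sentence '",
           s$sentence_id, "' of length ", n)
  for (sc in s$scopes)
    if (sc$end > n)
      stop("scope span [", sc$start, ",", sc$end, ") outside sentence '",
           s$sentence_id, "' of length ", n)
  refs <- vapply(s$cues, `[[`, "", "ref_id")
  if (anyDuplicated(refs))
    stop("duplicate cue ref_id in sentence '", s$sentence_id, "': ",
         paste(unique(refs[duplicated(refs)]), collapse = ", "))
  sids <- vapply(s$scopes, `[[`, "", "scope_id")
  for (sid in sids)
    if (sum(refs == sid) != 1L)
      stop("scope '", sid, "' in sentence '", s$sentence_id,
           "' does not link to exactly one cue")
  invisible(s)
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat("<annotated_sentence '", x$sentence_id, "' [", x$sub_corpus, "]>\n",
      sep = "")
  cat(" ", paste(x$words, collapse = " "), "\n")
  for (cue in x$cues)
    cat("  cue ", cue$ref_id, " (", cue$cue_type, "): [", cue$start, ",",
        cue$end, ") '", paste(x$words[(cue$start + 1L):cue$end],
                              collapse = " "), "'\n", sep = "")
  for (sc in x$scopes)
    cat("  scope ", sc$scope_id, ": [", sc$start, ",", sc$end, ")\n",
        sep = "")
  invisible(x)
}

# scope linked to a given cue (or NULL)
linked_scope <- function(s, cue) {
  for (sc in s$scopes) if (sc$scope_id == cue$ref_id) return(sc)
  NULL
}

#' Filter a parsed corpus
#'
#' Keeps sentences matching a sub-corpus tag and/or containing at least one
#' cue of a requested type. This is the selection step used to build the
#' super-tuning corpus from the full-papers negation sentences only.
#'
#' @param sentences List of `annotated_sentence` objects.
#' @param sub_corpus Keep only this sub-corpus; `NULL` keeps all.
#' @param cue_types Cue types that count when `require_cue` is `TRUE`.
#' @param require_cue If `TRUE`, keep only sentences with at least one cue
#'   whose type is in `cue_types`.
#' @return The filtered list, input order preserved.
#' @export
filter_sentences <- function(sentences, sub_corpus = NULL,
                             cue_types = CUE_TYPES, require_cue = FALSE) {
  if (require_cue && length(cue_types) == 0L)
    stop("cue_types must be non-empty when require_cue = TRUE")
  if (!is.null(sub_corpus)) sub_corpus <- match.arg(sub_corpus, SUB_CORPORA)
  keep <- vapply(sentences, function(s) {
    if (!is.null(sub_corpus) && s$sub_corpus != sub_corpus) return(FALSE)
    if (require_cue) {
      types <- vapply(s$cues, `[[`, "", "cue_type")
      if (!any(types %in% cue_types)) return(FALSE)
    }
    TRUE
  }, logical(1))
  sentences[keep]
}
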