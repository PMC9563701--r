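#' Token-level F1 report
#'
#' Micro-averaged per-class precision, recall and F1 over all words of a
#' corpus, plus the unweighted (macro) mean over non-padding classes.
#' The padding class never enters the report. Classes with zero support
#' and zero predictions report F1 = 0 and are flagged rather than
#' raising an error.
#'
#' @param gold,predicted Integer label vectors, or lists of per-sentence
#'   label vectors (lengths must match sentence by sentence).
#' @param classes Integer vector of all class ids in the scheme.
#' @param padding_class Class id excluded from the report (default 0).
#' @return An object of class `f1_report`: a data frame with one row per
#'   non-padding class (`class`, `precision`, `recall`, `f1`, `support`,
#'   `zero_support`) and attribute `macro_f1`.
#' @export
token_f1 <- function(gold, predicted, classes = 0:3, padding_class = 0L) {
  flatten <- function(x, nm) {
    if (!is.list(x)) return(as.integer(x))
    as.integer(unlist(x, use.names = FALSE))
  }
  if (is.list(gold) != is.list(predicted) ||
      (is.list(gold) && length(gold) != length(predicted)))
    stop("gold and predicted must have matching structure")
  if (is.list(gold)) {
    lg <- lengths(gold); lp <- lengths(predicted)
    if (any(lg != lp))
      stop("label length mismatch in sentence(s) ",
           paste(which(lg != lp), collapse = ", "))
  }
  g <- flatten(gold); p <- flatten(predicted)
  if (length(g) != length(p))
    stop("gold and predicted must have equal total length")
  eval_classes <- setdiff(as.integer(classes), as.integer(padding_class))
  rows <- lapply(eval_classes, function(cl) {
    tp <- sum(g == cl & p == cl)
    fp <- sum(g != cl & p == cl)
    fn <- sum(g == cl & p != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = tp + fn, zero_support = (tp + fn) == 0L)
  })
  rep_df <- do.call(rbind, rows)
  structure(rep_df, macro_f1 = mean(rep_df$f1),
            class = c("f1_report", "data.frame"))
}

#' @export
print.f1_report <- function(x, digits = 4, ...) {
  cat("Token-level F1 (padding class excluded):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("macro F1: %.*f\n", digits, attr(x, "macro_f1")))
  invisible(x)
}

#' Macro F1 of a report
#'
#' @param report An `f1_report` from [token_f1()].
#' @return The unweighted mean F1 over non-padding classes.
#' @export
macro_f1 <- function(report) {
  stopifnot(inherits(report, "f1_report"))
  attr(report, "macro_f1")
}

#' Exact span match proportion
#'
#' Fraction of instances whose predicted scope span equals the gold span
#' exactly (both as 0-based half-open word intervals; `NULL` predictions
#' match only `NULL` gold).
#'
#' @param gold_spans,predicted_spans Lists of length-2 integer vectors
#'   (or `NULL`), aligned by instance.
#' @return Proportion in `[0, 1]`.
#' @export
exact_span_match <- function(gold_spans, predicted_spans) {
  if (length(gold_spans) != length(predicted_spans))
    stop("gold and predicted span lists must have equal length")
  if (length(gold_spans) == 0L) return(NaN)
  hits <- vapply(seq_along(gold_spans), function(i) {
    gspan <- gold_spans[[i]]; pspan <- predicted_spans[[i]]
    if (is.null(gspan) || is.null(pspan)) return(is.null(gspan) && is.null(pspan))
    length(gspan) == length(pspan) && all(gspan == pspan)
  }, logical(1))
  mean(hits)
}

#' Write an F1 report to CSV
#'
#' @param report An `f1_report`.
#' @param path Output CSV path; the macro F1 is appended as a final row
#'   with class `"macro"`.
#' @export
write_f1_report <- function(report, path) {
  stopifnot(inherits(report, "f1_report"))
  d <- as.data.frame(report)
  d$class <- as.character(d$class)
  d <- rbind(d, data.frame(class = "macro", precision = NA, recall = NA,
                           f1 = attr(report, "macro_f1"), support = NA,
                           zero_support = NA))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write word/label predictions as a two-column CoNLL-style file
#'
#' One `word<TAB>label` line per word, sentences separated by blank
#' lines.
#'
#' @param sentences List of character vectors (words per sentence).
#' @param labels List of integer vectors aligned with `sentences`.
#' @param path Output path.
#' @export
write_conll_predictions <- function(sentences, labels, path) {
  stopifnot(length(sentences) == length(labels))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sentences)) {
    stopifnot(length(sentences[[i]]) == length(labels[[i]]))
    writeLines(paste(sentences[[i]], labels[[i]], sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a two-column CoNLL-style word/label file
#'
#' @param path Input path as written by [write_conll_predictions()].
#' @return List with `sentences` (word vectors) and `labels` (integer
#'   vectors).
#' @export
read_conll_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  block_id <- cumsum(c(TRUE, blank[-length(blank)]))
  blocks <- split(lines[!blank], block_id[!blank])
  sentences <- list(); labels <- list()
  for (b in blocks) {
    parts <- strsplit(b, "\t", fixed = TRUE)
    sentences <- c(sentences, list(vapply(parts, `[[`, "", 1L)))
    labels <- c(labels, list(as.integer(vapply(parts, `[[`, "", 2L))))
  }
  list(sentences = sentences, labels = labels)
}
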