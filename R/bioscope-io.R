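# BioScope-dialect XML: a document of <sentence id="..."> elements whose
# character content is the sentence text; <xcope id="..."> wraps a scope
# span and <cue type="negation|speculation" ref="xcope-id"> wraps the cue
# words. Words are whitespace tokens; spans are 0-based half-open word
# intervals computed while walking the element tree in document order.

#' Read a BioScope-dialect XML corpus
#'
#' Parses sentences with nested scope (`xcope`) and cue annotations into
#' [annotated_sentence()] objects. Character content is whitespace
#' tokenized; punctuation stays attached to its word. Spans are 0-based
#' half-open word intervals. A cue whose `ref` has no matching `xcope` id
#' in its sentence is an integrity error.
#'
#' @param source Path to an XML file, a literal XML string, or raw bytes.
#' @param sub_corpus Sub-corpus tag assigned to every sentence read from
#'   this source (the abstracts / full-papers split is per file).
#' @return List of `annotated_sentence` objects.
#' @export
read_bioscope <- function(source, sub_corpus = "unknown") {
  doc <- xml2::read_xml(source)
  lapply(xml2::xml_find_all(doc, ".//sentence"), function(sn) {
    env <- new.env(parent = emptyenv())
    env$words <- character(0)
    env$cues <- list()
    env$scopes <- list()
    walk_sentence_node(sn, env)
    sid <- xml2::xml_attr(sn, "id")
    if (is.na(sid)) sid <- ""
    scope_ids <- vapply(env$scopes, `[[`, "", "scope_id")
    for (cue in env$cues)
      if (!cue$ref_id %in% scope_ids)
        stop("cue ref '", cue$ref_id, "' in sentence '", sid,
             "' has no matching xcope")
    annotated_sentence(sid, env$words, env$cues, env$scopes, sub_corpus)
  })
}

walk_sentence_node <- function(node, env) {
  for (child in xml2::xml_contents(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "text") {
      toks <- split_words(xml2::xml_text(child))
      env$words <- c(env$words, toks)
    } else if (nm == "xcope") {
      start <- length(env$words)
      walk_sentence_node(child, env)
      end <- length(env$words)
      if (end > start)
        env$scopes <- c(env$scopes, list(
          scope_annotation(xml2::xml_attr(child, "id"), start, end)))
    } else if (nm == "cue") {
      start <- length(env$words)
      walk_sentence_node(child, env)
      end <- length(env$words)
      if (end > start)
        env$cues <- c(env$cues, list(
          cue_annotation(xml2::xml_attr(child, "type"), start, end,
                         xml2::xml_attr(child, "ref"))))
    } else {
      walk_sentence_node(child, env)
    }
  }
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a corpus as BioScope-dialect XML
#'
#' Serializes annotated sentences so that [read_bioscope()] reproduces
#' them exactly (words, cue types, spans, links). Annotation spans within
#' a sentence must nest or be disjoint; partially overlapping spans
#' cannot be expressed as XML nesting and raise an integrity error.
#'
#' @param sentences List of `annotated_sentence` objects.
#' @param path Output file path, or `NULL` to return the XML string only.
#' @return The XML document as a character scalar, invisibly.
#' @export
write_bioscope <- function(sentences, path = NULL) {
  body <- vapply(sentences, serialize_sentence, character(1))
  xml <- paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n<corpus>\n",
                paste0(body, collapse = ""), "</corpus>\n")
  xml2::read_xml(xml)  # self-check: emitted document must parse
  if (!is.null(path)) writeLines(xml, path, sep = "")
  invisible(xml)
}

serialize_sentence <- function(s) {
  validate_sentence(s)
  elems <- c(
    lapply(s$scopes, function(sc)
      list(kind = "xcope", start = sc$start, end = sc$end,
           open = paste0("<xcope id=\"", xml_escape(sc$scope_id), "\">"),
           close = "</xcope>")),
    lapply(s$cues, function(cue)
      list(kind = "cue", start = cue$start, end = cue$end,
           open = paste0("<cue type=\"", cue$cue_type, "\" ref=\"",
                         xml_escape(cue$ref_id), "\">"),
           close = "</cue>")))
  if (length(elems) > 1L) {
    ord <- order(vapply(elems, `[[`, 0L, "start"),
                 -vapply(elems, `[[`, 0L, "end"),
                 vapply(elems, function(e) e$kind == "cue", TRUE))
    elems <- elems[ord]
    open_ends <- integer(0)
    for (e in elems) {
      open_ends <- open_ends[open_ends > e$start]
      if (any(open_ends < e$end))
        stop("overlapping annotation spans in sentence '", s$sentence_id,
             "' cannot be serialized as nested XML")
      open_ends <- c(open_ends, e$end)
    }
  }
  paste0("<sentence id=\"", xml_escape(s$sentence_id), "\">",
         serialize_range(s$words, 0L, length(s$words), elems),
         "</sentence>\n")
}

# emit words[start, end) with the given elements (sorted for nesting)
serialize_range <- function(words, start, end, elems) {
  out <- character(0)
  pos <- start
  i <- 1L
  while (i <= length(elems)) {
    e <- elems[[i]]
    if (pos < e$start)
      out <- c(out, xml_escape(paste(words[(pos + 1L):e$start],
                                     collapse = " ")), " ")
    # children: following elements contained in [e$start, e$end)
    j <- i + 1L
    while (j <= length(elems) && elems[[j]]$start >= e$start &&
           elems[[j]]$end <= e$end) j <- j + 1L
    out <- c(out, e$open,
             serialize_range(words, e$start, e$end, elems[seq_len(j - i - 1L) + i]),
             e$close, " ")
    pos <- e$end
    i <- j
  }
  if (pos < end)
    out <- c(out, xml_escape(paste(words[(pos + 1L):end], collapse = " ")),
             " ")
  paste0(out, collapse = "")
}
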