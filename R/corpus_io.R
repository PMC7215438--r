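## CoNLL-style two-column corpus I/O and the core sentence/document containers.

#' Construct a tagged sentence
#'
#' @param tokens character vector of token surfaces (non-empty, no whitespace).
#' @param tags character vector of BIEOS tags, same length; defaults to all "O".
#' @param sentence_id opaque identifier.
#' @param validate check structural validity of the tag sequence.
#' @return object of class `tagged_sentence`: a list with `tokens`, `tags`,
#'   `sentence_id`.
#' @export
tagged_sentence <- function(tokens, tags = rep("O", length(tokens)),
                            sentence_id = NA_character_, validate = TRUE) {
  stopifnot(is.character(tokens), is.character(tags))
  if (length(tokens) != length(tags)) {
    stop("tokens and tags must have the same length")
  }
  if (any(!nzchar(tokens)) || any(grepl("[[:space:]]", tokens))) {
    stop("token surfaces must be non-empty and contain no whitespace")
  }
  if (validate && length(tags) > 0L && !is_valid_tag_sequence(tags)) {
    stop("structurally invalid BIEOS tag sequence")
  }
  structure(list(tokens = tokens, tags = tags,
                 sentence_id = as.character(sentence_id)),
            class = "tagged_sentence")
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat(sprintf("<tagged_sentence %s: %d tokens, %d entities>\n",
              x$sentence_id, length(x$tokens),
              nrow(tags_to_spans(validate_and_repair(x$tags)$tags))))
  print(rbind(token = x$tokens, tag = x$tags))
  invisible(x)
}

#' Construct a document
#'
#' @param sentences list of [tagged_sentence()] objects, source order preserved.
#' @param doc_id opaque identifier.
#' @param raw_text optional original text.
#' @return object of class `ner_document`.
#' @export
ner_document <- function(sentences, doc_id = NA_character_, raw_text = NULL) {
  stopifnot(is.list(sentences),
            all(vapply(sentences, inherits, logical(1), "tagged_sentence")))
  structure(list(sentences = sentences, doc_id = as.character(doc_id),
                 raw_text = raw_text),
            class = "ner_document")
}

#' @export
print.ner_document <- function(x, ...) {
  cat(sprintf("<ner_document %s: %d sentences, %d tokens>\n", x$doc_id,
              length(x$sentences),
              sum(vapply(x$sentences, function(s) length(s$tokens), integer(1)))))
  invisible(x)
}

#' Read a tagged corpus
#'
#' Reads a UTF-8 CoNLL-style file: one `token<TAB>tag` pair per line (any run
#' of tabs/spaces separates the columns), blank lines between sentences, and
#' `#doc <id>` comment lines starting a new document.
#'
#' @param path file path.
#' @param strict if `TRUE` (default), a structurally invalid tag sequence is an
#'   error naming the sentence and position; if `FALSE`, invalid sequences are
#'   repaired by [validate_and_repair()] and the number of repaired sentences
#'   is reported via `message()` and the `"repairs"` attribute.
#' @return list of [ner_document()] objects (attribute `repairs` when
#'   `strict = FALSE`).
#' @export
read_corpus <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)

  docs <- list()
  cur_doc_id <- "doc1"
  cur_sentences <- list()
  cur_tokens <- character(0)
  cur_tags <- character(0)
  n_repairs <- 0L
  sent_no <- 0L

  flush_sentence <- function(line_no) {
    if (length(cur_tokens) == 0L) return(invisible())
    sent_no <<- sent_no + 1L
    tags <- cur_tags
    if (!is_valid_tag_sequence(tags)) {
      if (strict) {
        changed <- which(validate_and_repair(tags)$tags != tags)
        pos <- if (length(changed)) changed[1L] else length(tags)
        stop(sprintf(
          "invalid tag sequence in sentence %d (ending before line %d), position %d",
          sent_no, line_no, pos))
      }
      rep <- validate_and_repair(tags)
      tags <- rep$tags
      n_repairs <<- n_repairs + rep$repairs
    }
    cur_sentences[[length(cur_sentences) + 1L]] <<-
      tagged_sentence(cur_tokens, tags,
                      sentence_id = sprintf("%s.s%d", cur_doc_id,
                                            length(cur_sentences) + 1L))
    cur_tokens <<- character(0)
    cur_tags <<- character(0)
  }
  flush_doc <- function(line_no) {
    flush_sentence(line_no)
    if (length(cur_sentences) > 0L) {
      docs[[length(docs) + 1L]] <<- ner_document(cur_sentences, cur_doc_id)
    }
    cur_sentences <<- list()
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    if (startsWith(line, "#doc")) {
      flush_doc(i)
      id <- trimws(sub("^#doc", "", line))
      cur_doc_id <- if (nzchar(id)) id else sprintf("doc%d", length(docs) + 1L)
      next
    }
    if (!nzchar(trimws(line))) {
      flush_sentence(i)
      next
    }
    fields <- strsplit(trimws(line), "[ \t]+")[[1L]]
    if (length(fields) != 2L) {
      stop(sprintf("parse error at line %d: expected 2 columns, got %d",
                   i, length(fields)))
    }
    cur_tokens <- c(cur_tokens, stringi::stri_trans_nfc(fields[1L]))
    cur_tags <- c(cur_tags, fields[2L])
  }
  flush_doc(length(lines) + 1L)

  if (!strict && n_repairs > 0L) {
    message(sprintf("read_corpus: repaired %d tag(s)", n_repairs))
    attr(docs, "repairs") <- n_repairs
  }
  docs
}

#' Write a tagged corpus
#'
#' Inverse of [read_corpus()]: writes `#doc <id>` headers, `token<TAB>tag`
#' lines, and a blank line after each sentence. The round trip reproduces
#' tokens and tags exactly.
#'
#' @param documents list of [ner_document()] objects.
#' @param path output file path.
#' @export
write_corpus <- function(documents, path) {
  stopifnot(is.list(documents))
  out <- character(0)
  for (doc in documents) {
    stopifnot(inherits(doc, "ner_document"))
    out <- c(out, paste("#doc", doc$doc_id))
    for (s in doc$sentences) {
      out <- c(out, paste(s$tokens, s$tags, sep = "\t"), "")
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(out) > 0) {
    writeLines(out, con, useBytes = FALSE, sep = "\n")
  }
  invisible(NULL)
}

## flatten helpers used across modules
corpus_sentences <- function(documents) {
  unlist(lapply(documents, function(d) d$sentences), recursive = FALSE)
}
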