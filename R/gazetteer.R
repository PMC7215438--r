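## Domain dictionary (gazetteer) and per-token n-gram membership features.
##
## For each token position the sentence is cut into seven context segments by
## the n-gram templates (1- to 4-grams anchored at the position); each segment
## is looked up in every dictionary category, giving a binary feature vector of
## dimension 7 * n_categories per token.

## fixed template order: offsets relative to position i (inclusive ranges)
NGRAM_TEMPLATES <- list(c(0L, 0L), c(-1L, 0L), c(0L, 1L), c(-2L, 0L),
                        c(0L, 2L), c(-3L, 0L), c(0L, 3L))

#' Construct a domain dictionary
#'
#' @param entries named list mapping category to a character vector of entity
#'   surface forms (deduplicated, NFC-normalized).
#' @return object of class `domain_dictionary` with `entries` (sorted sets)
#'   and `categories` (sorted, fixed order).
#' @export
domain_dictionary <- function(entries) {
  stopifnot(is.list(entries), length(names(entries)) == length(entries))
  cats <- sort(names(entries))
  entries <- lapply(entries[cats], function(e) {
    e <- stringi::stri_trans_nfc(trimws(e))
    sort(unique(e[nzchar(e)]))
  })
  structure(list(entries = entries, categories = cats),
            class = "domain_dictionary")
}

#' @export
print.domain_dictionary <- function(x, ...) {
  cat(sprintf("<domain_dictionary: %d categories, %d entries>\n",
              length(x$categories),
              sum(lengths(x$entries))))
  for (ct in x$categories) {
    cat(sprintf("  %s: %d entries\n", ct, length(x$entries[[ct]])))
  }
  invisible(x)
}

#' Load a domain dictionary from a text file
#'
#' One entry per UTF-8 line, either `surface` or `surface<TAB>category`
#' (default category `"body"`). Duplicates are removed, whitespace stripped,
#' empty lines ignored; the result is invariant to line order.
#'
#' @param path file path.
#' @param default_category category used for lines without one.
#' @return [domain_dictionary()].
#' @export
load_dictionary <- function(path, default_category = "body") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  surface <- vapply(parts, `[[`, character(1), 1L)
  category <- vapply(parts, function(p) {
    if (length(p) >= 2L && nzchar(trimws(p[2L]))) trimws(p[2L]) else default_category
  }, character(1))
  entries <- split(surface, category)
  domain_dictionary(entries)
}

## simple structural fingerprint, used to warn on model/dictionary mismatch
dict_fingerprint <- function(dictionary) {
  chks <- vapply(dictionary$categories, function(ct) {
    e <- dictionary$entries[[ct]]
    sum(vapply(e, function(s) sum(utf8ToInt(s) * seq_along(utf8ToInt(s))),
               numeric(1))) %% 1e9
  }, numeric(1))
  paste0(length(dictionary$categories), ":",
         paste(lengths(dictionary$entries), collapse = ","), ":",
         paste(format(chks, scientific = FALSE, trim = TRUE), collapse = ","))
}

#' N-gram context segments at a token position
#'
#' Applies the seven n-gram templates (x_i; x_{i-1}x_i; x_i x_{i+1};
#' x_{i-2}..x_i; x_i..x_{i+2}; x_{i-3}..x_i; x_i..x_{i+3}) and concatenates
#' the covered token surfaces with no joining character. A template whose
#' index range leaves the sentence yields `NA`.
#'
#' @param tokens character vector of token surfaces.
#' @param i 1-based position.
#' @return character vector of length 7 (with `NA` for out-of-range templates).
#' @export
#' @examples
#' ngram_segments(letters[1:7], 4)
ngram_segments <- function(tokens, i) {
  n <- length(tokens)
  if (i < 1L || i > n) stop(sprintf("position %d out of range [1, %d]", i, n))
  vapply(NGRAM_TEMPLATES, function(off) {
    lo <- i + off[1L]; hi <- i + off[2L]
    if (lo < 1L || hi > n) NA_character_
    else paste(tokens[lo:hi], collapse = "")
  }, character(1))
}

#' Per-token dictionary membership features
#'
#' For every token position and every dictionary category, a binary vector of
#' length 7: entry `k` is 1 iff the `k`-th template segment exists and is an
#' exact (NFC) member of that category's entry set. Layout is category-major
#' in the dictionary's fixed (sorted) category order, template-minor in the
#' fixed template order.
#'
#' @param sentence a [tagged_sentence()] or character vector of token surfaces.
#' @param dictionary a [domain_dictionary()].
#' @return numeric matrix of dimension `n_tokens x (7 * n_categories)` with
#'   attribute `"categories"`.
#' @export
dict_features <- function(sentence, dictionary) {
  tokens <- if (inherits(sentence, "tagged_sentence")) sentence$tokens else sentence
  tokens <- stringi::stri_trans_nfc(tokens)
  stopifnot(inherits(dictionary, "domain_dictionary"))
  cats <- dictionary$categories
  n <- length(tokens)
  m <- matrix(0, nrow = n, ncol = 7L * length(cats))
  for (t in seq_len(n)) {
    segs <- ngram_segments(tokens, t)
    for (ci in seq_along(cats)) {
      hit <- !is.na(segs) & segs %in% dictionary$entries[[cats[ci]]]
      m[t, (7L * (ci - 1L) + 1L):(7L * ci)] <- as.numeric(hit)
    }
  }
  attr(m, "categories") <- cats
  m
}
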