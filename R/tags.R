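## BIEOS tag scheme: parsing, validation, repair, and the span <-> tag bijection.
##
## Tags are "O" or "{B|I|E|S}-{category}". A span is a 1-based, half-open token
## interval [start, end) with a category; spans_to_tags()/tags_to_spans() are
## inverse on structurally valid inputs.

TAG_SYMBOLS <- c("B", "I", "E", "S")

#' Parse BIEOS tags into symbol and category
#'
#' @param tags character vector of tags ("O" or "B-cat", "I-cat", "E-cat", "S-cat").
#' @return data.frame with columns `symbol` ("O","B","I","E","S") and
#'   `category` (NA for "O").
#' @keywords internal
parse_tags <- function(tags) {
  stopifnot(is.character(tags))
  symbol <- ifelse(tags == "O", "O", substr(tags, 1L, 1L))
  category <- ifelse(tags == "O", NA_character_, substring(tags, 3L))
  bad <- which(tags != "O" &
                 (!symbol %in% TAG_SYMBOLS | substr(tags, 2L, 2L) != "-" |
                    !nzchar(category)))
  if (length(bad) > 0L) {
    stop(sprintf("malformed tag '%s' at position %d", tags[bad[1L]], bad[1L]))
  }
  data.frame(symbol = symbol, category = category, stringsAsFactors = FALSE)
}

#' Check structural validity of a BIEOS tag sequence
#'
#' A sequence is valid when every B-c is followed by I-c or E-c, every I-c is
#' preceded by B-c/I-c and followed by I-c/E-c, every E-c and S-c closes an
#' entity, and no entity is left open at the end of the sentence.
#'
#' @param tags character vector of tags.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_tag_sequence <- function(tags) {
  p <- parse_tags(tags)
  open_cat <- NA_character_
  for (t in seq_along(tags)) {
    sym <- p$symbol[t]; cat <- p$category[t]
    if (is.na(open_cat)) {
      if (sym %in% c("I", "E")) return(FALSE)
      if (sym == "B") open_cat <- cat
    } else {
      if (sym %in% c("O", "B", "S")) return(FALSE)
      if (!identical(cat, open_cat)) return(FALSE)
      if (sym == "E") open_cat <- NA_character_
    }
  }
  is.na(open_cat)
}

#' Repair a structurally invalid BIEOS tag sequence
#'
#' Deterministic policy: an I/E with no open entity of its category becomes B
#' when followed by I/E of the same category, otherwise S; an unclosed B/I run
#' is closed by converting its last tag to E (a lone B becomes S). Valid input
#' is returned unchanged with 0 repairs, and the repair is idempotent.
#'
#' @param tags character vector of tags drawn from the BIEOS alphabet.
#' @return list with `tags` (valid sequence) and `repairs` (count of modified
#'   positions).
#' @export
validate_and_repair <- function(tags) {
  p <- parse_tags(tags)
  sym <- p$symbol; cat <- p$category
  out <- tags
  repairs <- 0L
  open_cat <- NA_character_
  run_start <- NA_integer_

  close_run <- function(last) {
    # convert the run's last tag so the entity is closed; counts as one repair
    if (last == run_start) {
      out[run_start] <<- paste0("S-", open_cat)
    } else {
      out[last] <<- paste0("E-", open_cat)
    }
    repairs <<- repairs + 1L
    open_cat <<- NA_character_
  }

  n <- length(tags)
  for (t in seq_len(n)) {
    s <- sym[t]; ct <- cat[t]
    if (s == "O") {
      if (!is.na(open_cat)) close_run(t - 1L)
    } else if (s == "B") {
      if (!is.na(open_cat)) close_run(t - 1L)
      open_cat <- ct; run_start <- t
    } else if (s == "S") {
      if (!is.na(open_cat)) close_run(t - 1L)
    } else { # I or E
      if (!is.na(open_cat) && identical(ct, open_cat)) {
        if (s == "E") open_cat <- NA_character_
        # I continues the run
      } else {
        if (!is.na(open_cat)) close_run(t - 1L)
        follows <- t < n && sym[t + 1L] %in% c("I", "E") &&
          identical(cat[t + 1L], ct)
        if (follows) {
          out[t] <- paste0("B-", ct)
          open_cat <- ct; run_start <- t
        } else {
          out[t] <- paste0("S-", ct)
        }
        repairs <- repairs + 1L
      }
    }
  }
  if (!is.na(open_cat)) close_run(n)
  list(tags = out, repairs = repairs)
}

#' Decode a BIEOS tag sequence into entity spans
#'
#' @param x a tagged sentence (see [tagged_sentence()]) or a character vector
#'   of tags.
#' @return data.frame with columns `start` (1-based, inclusive), `end`
#'   (exclusive), `category`, sorted by `start`; zero rows for an all-"O"
#'   sentence.
#' @export
#' @examples
#' tags_to_spans(c("B-b", "I-b", "E-b", "O"))
tags_to_spans <- function(x) {
  tags <- if (inherits(x, "tagged_sentence")) x$tags else x
  if (!is_valid_tag_sequence(tags)) {
    stop("invalid BIEOS tag sequence; run validate_and_repair() first")
  }
  p <- parse_tags(tags)
  start <- integer(0); end <- integer(0); category <- character(0)
  open_start <- NA_integer_
  for (t in seq_along(tags)) {
    s <- p$symbol[t]
    if (s == "B") open_start <- t
    if (s == "E") {
      start <- c(start, open_start); end <- c(end, t + 1L)
      category <- c(category, p$category[t])
      open_start <- NA_integer_
    }
    if (s == "S") {
      start <- c(start, t); end <- c(end, t + 1L)
      category <- c(category, p$category[t])
    }
  }
  data.frame(start = start, end = end, category = category,
             stringsAsFactors = FALSE)
}

#' Encode entity spans as a BIEOS tag sequence
#'
#' @param spans data.frame with columns `start`, `end`, `category` (1-based,
#'   half-open intervals); must be non-overlapping and within `[1, length+1)`.
#' @param length sentence length in tokens.
#' @return character vector of `length` tags.
#' @export
#' @examples
#' spans_to_tags(data.frame(start = 1, end = 4, category = "b"), length = 9)
spans_to_tags <- function(spans, length) {
  stopifnot(is.data.frame(spans), length >= 0)
  tags <- rep("O", length)
  if (nrow(spans) == 0L) return(tags)
  if (any(spans$start < 1L | spans$end <= spans$start | spans$end > length + 1L)) {
    stop("span out of bounds or empty")
  }
  ord <- order(spans$start)
  spans <- spans[ord, , drop = FALSE]
  if (any(spans$start[-1L] < spans$end[-nrow(spans)])) {
    stop("overlapping spans")
  }
  for (r in seq_len(nrow(spans))) {
    s <- spans$start[r]; e <- spans$end[r] - 1L; ct <- spans$category[r]
    if (s == e) {
      tags[s] <- paste0("S-", ct)
    } else {
      tags[s] <- paste0("B-", ct)
      if (e > s + 1L) tags[(s + 1L):(e - 1L)] <- paste0("I-", ct)
      tags[e] <- paste0("E-", ct)
    }
  }
  tags
}
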