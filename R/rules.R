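## Keyword-rule pipeline for task-level extraction from clinical notes:
## sentence segmentation, candidate-sentence selection (primary tumor site /
## lesion size / metastasis site), span-level special cases, dictionary-based
## entity correction, and assembly into per-document task entities.

#' Load a rule set from YAML
#'
#' The schema holds named keyword `lexicons`, the entity categories used for
#' sites and sizes (`site_category`, `size_category`), and an ordered `rules`
#' list with `rule_id`, `target` (segmentation / primary_site / lesion_size /
#' metastasis_site / special_case / lesion_conditional), `any_of` / `all_of`
#' lexicon references, and an optional `region` policy.
#'
#' @param path YAML file path.
#' @return list of class `ruleset`.
#' @export
load_rules <- function(path) {
  rs <- yaml::read_yaml(path)
  if (is.null(rs$rules) || is.null(rs$lexicons)) {
    stop("rule file must define 'rules' and 'lexicons'")
  }
  ids <- vapply(rs$rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(ids)) stop("rule_ids must be unique")
  for (r in rs$rules) {
    for (field in c("any_of", "all_of")) {
      for (lex in r[[field]]) {
        if (is.null(rs$lexicons[[lex]])) {
          stop(sprintf("rule '%s' references unknown lexicon '%s'",
                       r$rule_id, lex))
        }
      }
    }
  }
  rs$lexicons <- lapply(rs$lexicons, as.character)
  structure(rs, class = "ruleset")
}

#' Default rule set
#'
#' The six published rules for the tumor extraction task: sentence
#' segmentation, keyword selection of primary-site / lesion-size /
#' metastasis-site candidate sentences, the lymph-node span extension, and
#' the lesion-size conditional.
#'
#' @return a `ruleset`.
#' @export
default_rules <- function() {
  load_rules(system.file("extdata", "rules_default.yaml", package = "cwdner",
                         mustWork = TRUE))
}

rule_enabled <- function(rules, target) {
  any(vapply(rules$rules, function(r) identical(r$target, target), logical(1)))
}
rule_by_target <- function(rules, target) {
  for (r in rules$rules) if (identical(r$target, target)) return(r)
  NULL
}

## case-insensitive for all-ASCII keywords, exact otherwise; returns the
## character position after the last match end, or 0L if absent
keyword_last_end <- function(text, keywords) {
  best <- 0L
  for (kw in keywords) {
    ascii <- !grepl("[^\x01-\x7f]", kw)
    hit <- gregexpr(kw, text, fixed = !ascii, ignore.case = ascii)[[1L]]
    if (hit[1L] != -1L) {
      ends <- hit + attr(hit, "match.length") - 1L
      best <- max(best, max(ends))
    }
  }
  best
}
contains_keyword <- function(text, keywords) keyword_last_end(text, keywords) > 0L

#' Segment raw text into sentences
#'
#' Splits on full-width and ASCII periods and semicolons (an ASCII period
#' flanked by digits is treated as a decimal point, not a delimiter), and
#' additionally starts a new sentence before an enumeration marker such as
#' `"2."` or `"一、"` even when the previous sentence lacks a terminator.
#' Delimiters are not included; empty segments are dropped.
#'
#' @param text raw string.
#' @return character vector of sentence strings.
#' @export
segment_sentences <- function(text) {
  if (!nzchar(text)) return(character(0))
  ## protect decimal points ("2.3cm")
  protected <- gsub("(?<=[0-9])\\.(?=[0-9])", "\x01", text, perl = TRUE)
  ## an enumeration marker ("2." not preceded by a digit, or "一、") begins a
  ## new sentence: insert a break before it and shield its period
  protected <- gsub("((?<![0-9])[0-9]+)\\.", "\x03\\1\x02", protected,
                    perl = TRUE)
  protected <- gsub("([一二三四五六七八九十]+、)",
                    "\x03\\1", protected, perl = TRUE)
  parts <- strsplit(protected, "[。；;.\x03]")[[1L]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts <- gsub("\x02", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

## tokenize a raw sentence: whitespace tokens; a whitespace-free CJK-bearing
## string falls back to one token per character
tokenize_sentence <- function(text, sentence_id = NA_character_) {
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  if (length(toks) == 1L && grepl("[^\x01-\x7f]", toks)) {
    toks <- strsplit(toks, "")[[1L]]
  }
  tagged_sentence(toks, sentence_id = sentence_id)
}

sentence_text <- function(sentence) paste(sentence$tokens, collapse = "")
span_surface <- function(sentence, start, end) {
  paste(sentence$tokens[start:(end - 1L)], collapse = "")
}

#' Select candidate sentences by keyword rules
#'
#' A sentence containing any primary-site keyword becomes a `primary_site`
#' candidate; one containing a size unit AND a density/shadow word a
#' `lesion_size` candidate; one containing a metastasis keyword a
#' `metastasis_site` candidate whose eligible region starts after the last
#' primary-site keyword when one is present. One sentence may yield several
#' candidates; selection is pure and monotone in the sentence list.
#'
#' @param sentences list of [tagged_sentence()] objects.
#' @param rules a `ruleset`.
#' @return list of candidates: each has `sentence`, `index`, `category`, and
#'   `region` (1-based half-open token interval).
#' @export
select_candidates <- function(sentences, rules) {
  lex <- rules$lexicons
  out <- list()
  push <- function(sentence, index, category, region) {
    out[[length(out) + 1L]] <<- list(sentence = sentence, index = index,
                                     category = category, region = region)
  }
  for (i in seq_along(sentences)) {
    s <- sentences[[i]]
    txt <- sentence_text(s)
    n <- length(s$tokens)
    full <- c(1L, n + 1L)
    if (rule_enabled(rules, "primary_site") &&
        contains_keyword(txt, lex$primary_keywords)) {
      push(s, i, "primary_site", full)
    }
    if (rule_enabled(rules, "lesion_size") &&
        contains_keyword(txt, lex$size_units) &&
        contains_keyword(txt, lex$density_words)) {
      push(s, i, "lesion_size", full)
    }
    if (rule_enabled(rules, "metastasis_site") &&
        contains_keyword(txt, lex$metastasis_keywords)) {
      region <- full
      pk_end <- keyword_last_end(txt, lex$primary_keywords)
      if (pk_end > 0L) {
        ## first token starting after the keyword's last character
        starts <- cumsum(c(0L, nchar(s$tokens[-n]))) + 1L
        tok0 <- which(starts > pk_end)
        region <- c(if (length(tok0)) tok0[1L] else n + 1L, n + 1L)
      }
      push(s, i, "metastasis_site", region)
    }
  }
  out
}

#' Extend incomplete part entities over a following lymph-node token
#'
#' When the extracted entity surface is in the configured incomplete-part
#' list and the next token is a lymph-node token, the span is extended to
#' include it; otherwise it is returned unchanged.
#'
#' @param span one-row data.frame (`start`, `end`, `category`).
#' @param sentence the [tagged_sentence()] the span lives in.
#' @param rules a `ruleset`.
#' @return the (possibly extended) span.
#' @export
apply_special_cases <- function(span, sentence, rules) {
  if (!rule_enabled(rules, "special_case")) return(span)
  lex <- rules$lexicons
  surf <- span_surface(sentence, span$start, span$end)
  if (surf %in% lex$incomplete_parts &&
      span$end <= length(sentence$tokens) &&
      sentence$tokens[span$end] %in% lex$lymph_tokens) {
    span$end <- span$end + 1L
  }
  span
}

#' Correct an extracted entity against the domain dictionary
#'
#' Policy: an exact dictionary member is unchanged; otherwise, if the entity
#' is a proper substring of exactly one dictionary entry that also occurs
#' contiguously in the source sentence, it is completed to that entry;
#' otherwise, if some dictionary entry is a proper substring of the entity,
#' it is trimmed to the longest such entry (prefix preferred on length ties);
#' otherwise it is unchanged. The correction is idempotent; corrections are
#' reported via `message()` when `verbose`.
#'
#' @param entity entity surface string.
#' @param dictionary a [domain_dictionary()].
#' @param sentence_text the source sentence string (enables the completion
#'   branch); `NULL` disables completion.
#' @param verbose log corrections.
#' @return corrected surface string.
#' @export
dictionary_correct <- function(entity, dictionary, sentence_text = NULL,
                               verbose = FALSE) {
  entries <- unique(unlist(dictionary$entries, use.names = FALSE))
  entity <- stringi::stri_trans_nfc(entity)
  if (entity %in% entries) return(entity)
  ## completion: unique proper superstring present in the sentence
  if (!is.null(sentence_text)) {
    supers <- entries[nchar(entries) > nchar(entity) &
                        vapply(entries, function(e)
                          grepl(entity, e, fixed = TRUE), logical(1))]
    supers <- supers[vapply(supers, function(e)
      grepl(e, sentence_text, fixed = TRUE), logical(1))]
    if (length(supers) == 1L) {
      if (verbose) message(sprintf("dictionary_correct: '%s' -> '%s' (completed)",
                                   entity, supers))
      return(supers)
    }
  }
  ## trimming: longest dictionary entry contained in the entity
  subs <- entries[nchar(entries) < nchar(entity) &
                    vapply(entries, function(e)
                      grepl(e, entity, fixed = TRUE), logical(1))]
  if (length(subs) > 0L) {
    best_len <- max(nchar(subs))
    cand <- subs[nchar(subs) == best_len]
    pref <- cand[startsWith(entity, cand)]
    pick <- if (length(pref) > 0L) pref[1L] else cand[1L]
    if (verbose) message(sprintf("dictionary_correct: '%s' -> '%s' (trimmed)",
                                 entity, pick))
    return(pick)
  }
  entity
}

#' Tagger adaptors for the extraction pipeline
#'
#' `model_tagger()` wraps a trained model into a `function(sentence) -> tags`;
#' `oracle_tagger()` returns the sentence's own (gold) tags, used to test the
#' rule pipeline in isolation from the model.
#'
#' @param model a trained `ner_model`.
#' @param dictionary the [domain_dictionary()] for its gazetteer features.
#' @return a function mapping a [tagged_sentence()] to a tag vector.
#' @export
model_tagger <- function(model, dictionary) {
  force(model); force(dictionary)
  A <- model$params$trans
  if (isTRUE(model$config$constraints_on)) {
    A <- apply_constraint_mask(A, model$constraint_mask)
  }
  function(sentence) {
    dfeat <- dict_features(sentence, dictionary)
    emis <- encoder_forward(model, sentence, dfeat)$emissions
    tags <- model$tag_alphabet[viterbi_decode(emis, A)$path]
    if (!isTRUE(model$config$constraints_on)) tags <- validate_and_repair(tags)$tags
    tags
  }
}

#' @rdname model_tagger
#' @export
oracle_tagger <- function() function(sentence) sentence$tags

#' Extract task entities from a document
#'
#' Full pipeline: sentence candidates by keyword rules, tagging within the
#' full sentence, span filtering to the candidate region, lymph-node span
#' extension, dictionary correction, and assembly. Primary-site and
#' metastasis-site entities are emitted directly; lesion-size values only
#' from lesion-size candidates that also contain a recognized primary-site
#' entity. Output is de-duplicated per document in order of first occurrence.
#'
#' @param document an [ner_document()], or a raw text string (segmented with
#'   [segment_sentences()] and tokenized by whitespace / CJK characters).
#' @param tagger a `function(sentence) -> tags` (see [model_tagger()] and
#'   [oracle_tagger()]), or a trained `ner_model`.
#' @param dictionary a [domain_dictionary()].
#' @param rules a `ruleset`; defaults to [default_rules()].
#' @return named list `primary_site`, `lesion_size`, `metastasis_site` of
#'   entity surface strings.
#' @export
extract_task_entities <- function(document, tagger, dictionary,
                                  rules = default_rules()) {
  if (is.character(document)) {
    raw <- document
    segs <- segment_sentences(raw)
    document <- ner_document(lapply(seq_along(segs), function(i)
      tokenize_sentence(segs[i], sprintf("s%d", i))), doc_id = "raw")
  }
  if (inherits(tagger, "ner_model")) tagger <- model_tagger(tagger, dictionary)

  out <- list(primary_site = character(0), lesion_size = character(0),
              metastasis_site = character(0))
  if (length(document$sentences) == 0L) return(out)

  cands <- select_candidates(document$sentences, rules)
  if (length(cands) == 0L) return(out)

  tagged <- list()  # sentence index -> spans, computed once
  spans_for <- function(idx) {
    key <- as.character(idx)
    if (is.null(tagged[[key]])) {
      tags <- tagger(document$sentences[[idx]])
      tagged[[key]] <<- tags_to_spans(validate_and_repair(tags)$tags)
    }
    tagged[[key]]
  }

  site_cat <- rules$site_category %||% "body"
  size_cat <- rules$size_category %||% "size"
  conditional <- rule_enabled(rules, "lesion_conditional")

  emit_site <- function(cand, spans) {
    s <- cand$sentence
    txt <- sentence_text(s)
    keep <- spans$category == site_cat &
      spans$start >= cand$region[1L] & spans$end <= cand$region[2L]
    vapply(which(keep), function(r) {
      sp <- apply_special_cases(spans[r, , drop = FALSE], s, rules)
      dictionary_correct(span_surface(s, sp$start, sp$end), dictionary, txt)
    }, character(1))
  }

  for (cand in cands) {
    spans <- spans_for(cand$index)
    if (cand$category %in% c("primary_site", "metastasis_site")) {
      out[[cand$category]] <- c(out[[cand$category]], emit_site(cand, spans))
    } else { # lesion_size
      has_site <- any(spans$category == site_cat)
      if (!conditional || has_site) {
        keep <- spans$category == size_cat &
          spans$start >= cand$region[1L] & spans$end <= cand$region[2L]
        vals <- vapply(which(keep), function(r)
          span_surface(cand$sentence, spans$start[r], spans$end[r]),
          character(1))
        out$lesion_size <- c(out$lesion_size, vals)
      }
    }
  }
  lapply(out, function(v) v[!duplicated(v)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate task-level extraction against gold entity maps
#'
#' Per-category strict string matching between predicted and gold entity
#' sets, pooled over documents; reports per-category and micro P/R/F and,
#' when weights are given, the weighted score.
#'
#' @param gold,pred lists (one element per document) of named lists
#'   `primary_site` / `lesion_size` / `metastasis_site` of entity strings.
#' @param weights optional named category weights (summing to 1).
#' @return list with `per_category`, `micro`, and optionally `weighted`.
#' @export
evaluate_task_extraction <- function(gold, pred, weights = NULL) {
  stopifnot(length(gold) == length(pred))
  cats <- c("primary_site", "lesion_size", "metastasis_site")
  counts <- stats::setNames(
    rep(list(c(TP = 0L, FP = 0L, FN = 0L)), length(cats)), cats)
  for (d in seq_along(gold)) {
    for (ct in cats) {
      g <- unique(gold[[d]][[ct]] %||% character(0))
      p <- unique(pred[[d]][[ct]] %||% character(0))
      tp <- length(intersect(g, p))
      counts[[ct]] <- counts[[ct]] +
        c(TP = tp, FP = length(p) - tp, FN = length(g) - tp)
    }
  }
  per_category <- lapply(counts, function(cc)
    prf(list(TP = cc[["TP"]], FP = cc[["FP"]], FN = cc[["FN"]])))
  pooled <- Reduce(`+`, counts)
  out <- list(per_category = per_category,
              micro = prf(list(TP = pooled[["TP"]], FP = pooled[["FP"]],
                               FN = pooled[["FN"]])))
  if (!is.null(weights)) out$weighted <- weighted_prf(per_category, weights)
  out
}

#' Sweep extraction quality over rule subsets
#'
#' Runs the extraction pipeline with every subset of the candidate-selection
#' and post-processing rules enabled and reports the micro F per subset —
#' a harness for studying how much each rule contributes (more rules need
#' not score higher).
#'
#' @param documents list of [ner_document()].
#' @param gold gold task-entity maps (one per document).
#' @param tagger tagger function or `ner_model`.
#' @param dictionary a [domain_dictionary()].
#' @param rules the full `ruleset` to subset.
#' @return data.frame with columns `rules` (comma-joined rule_ids) and `F`.
#' @export
rule_subset_sweep <- function(documents, gold, tagger, dictionary,
                              rules = default_rules()) {
  optional <- vapply(rules$rules, `[[`, character(1), "rule_id")
  optional <- setdiff(optional, "segmentation")
  subsets <- unlist(lapply(seq_along(optional), function(k)
    utils::combn(optional, k, simplify = FALSE)), recursive = FALSE)
  subsets <- c(list(character(0)), subsets)
  res <- lapply(subsets, function(keep) {
    sub <- rules
    sub$rules <- Filter(function(r)
      r$rule_id == "segmentation" || r$rule_id %in% keep, rules$rules)
    pred <- lapply(documents, extract_task_entities, tagger = tagger,
                   dictionary = dictionary, rules = sub)
    data.frame(rules = paste(keep, collapse = ","),
               F = unname(evaluate_task_extraction(gold, pred)$micro["F"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
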