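## Synthetic corpus and task-document generators. These emulate the corpus
## statistics the tagger assumes — short clause-like sentences, contiguous
## multi-token entities of a few categories, Zipf-like entity reuse with
## singleton and unseen entities, and keyword-bearing candidate sentences for
## the rule pipeline — without depending on any real clinical text.

#' Specification for a synthetic tagged corpus
#'
#' @param n_sentences total sentences (split 80/20 into train/test by
#'   default).
#' @param sentence_length `c(min, max)` tokens per sentence.
#' @param categories entity category names.
#' @param entity_lexicon_size entities per category.
#' @param entity_length `c(min, max)` tokens per entity.
#' @param entity_rate expected entities per sentence (Poisson, truncated to
#'   fit the sentence).
#' @param frequency_skew Zipf exponent for entity reuse (0 = uniform).
#' @param oov_entity_fraction fraction of test entity mentions drawn from a
#'   held-out, test-only part of the lexicon (exact by construction).
#' @param dict_coverage fraction of entity surface forms included in the
#'   returned dictionary (1 = oracle-complete).
#' @param filler_vocab_size number of non-entity tokens.
#' @param train_fraction train split fraction.
#' @param script `"ascii"` or `"cjk"` token surfaces.
#' @param context_markers when `TRUE`, every entity is immediately preceded
#'   by a token from a small dedicated marker vocabulary (emulating the
#'   distinctive clause patterns real mentions sit in, e.g. "seen at <site>").
#' @param seed integer seed; generation is fully deterministic.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_sentences = 500L, sentence_length = c(6L, 12L),
                        categories = "body", entity_lexicon_size = 40L,
                        entity_length = c(1L, 3L), entity_rate = 1.2,
                        frequency_skew = 1.0, oov_entity_fraction = 0.0,
                        dict_coverage = 1.0, filler_vocab_size = 60L,
                        train_fraction = 0.8, script = c("ascii", "cjk"),
                        context_markers = FALSE, seed = 1L) {
  script <- match.arg(script)
  stopifnot(sentence_length[1] <= sentence_length[2],
            entity_length[1] <= entity_length[2],
            entity_rate >= 0, oov_entity_fraction >= 0,
            oov_entity_fraction <= 1, dict_coverage >= 0, dict_coverage <= 1,
            train_fraction > 0, train_fraction < 1)
  if (entity_length[2] > sentence_length[2] - 1L) {
    stop("entity_length max must leave room for at least one filler token")
  }
  structure(as.list(environment()), class = "corpus_spec")
}

#' Separable preset corpus specification
#'
#' Entities are exactly the dictionary entries, appear in distinctive
#' contexts, and no test entity is unseen: a parameter-recovery setting a
#' correct implementation must learn to near-perfect F1 within a few epochs.
#'
#' @param seed integer seed.
#' @param n_sentences total sentences (default 250 = 200 train / 50 test).
#' @return a [corpus_spec()].
#' @export
corpus_spec_separable <- function(seed = 1L, n_sentences = 250L) {
  corpus_spec(n_sentences = n_sentences, sentence_length = c(6L, 10L),
              categories = "body", entity_lexicon_size = 15L,
              entity_length = c(1L, 3L), entity_rate = 1.5,
              frequency_skew = 0.6, oov_entity_fraction = 0,
              dict_coverage = 1, filler_vocab_size = 40L,
              context_markers = TRUE, seed = seed)
}

## deterministic unique token surfaces: 1-2 random characters plus a
## fixed-width index rendered in the alphabet (guarantees uniqueness)
make_vocab <- function(n, alphabet, min_chars = 1L, max_chars = 2L) {
  base <- length(alphabet)
  width <- max(1L, ceiling(log(n + 1) / log(base)))
  idx_str <- vapply(seq_len(n), function(i) {
    digits <- integer(width); x <- i - 1L
    for (p in width:1) { digits[p] <- x %% base; x <- x %/% base }
    paste(alphabet[digits + 1L], collapse = "")
  }, character(1))
  rand <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, sample(min_chars:max_chars, 1L), replace = TRUE),
          collapse = ""), character(1))
  paste0(rand, idx_str)
}

spec_alphabets <- function(spec) {
  if (spec$script == "ascii") {
    list(filler = letters[1:10],            # avoids keyword substrings
         entity = lapply(seq_along(spec$categories), function(i)
           letters[10 + ((i - 1) * 4 + 1):((i - 1) * 4 + 4)]))
  } else {
    cjk <- strsplit(intToUtf8(0x4E00 + 0:99), "")[[1L]]
    list(filler = cjk[1:30],
         entity = lapply(seq_along(spec$categories), function(i)
           cjk[30 + ((i - 1) * 20 + 1):((i - 1) * 20 + 20)]))
  }
}

#' Generate a synthetic tagged corpus
#'
#' Entities are drawn from per-category lexicons with the configured Zipf
#' skew; gold tags are valid BIEOS; the returned dictionary holds
#' `dict_coverage` of the entity surface forms; an exact
#' `oov_entity_fraction` of test entity mentions come from test-only surface
#' forms (feeding [stratify_by_frequency()]); generation is deterministic
#' under the spec's seed.
#'
#' @param spec a [corpus_spec()].
#' @return list with `train` and `test` (lists of [ner_document()]),
#'   `dictionary` ([domain_dictionary()]), `lexicon` (per-category surface
#'   forms), `oov_surfaces` (the test-only surface forms), and
#'   `filler_vocab`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  alph <- spec_alphabets(spec)
  fillers <- make_vocab(spec$filler_vocab_size, alph$filler)
  markers <- if (isTRUE(spec$context_markers)) {
    paste0(rep(alph$filler[1:3], each = 2), "00", alph$filler[1:6])
  } else character(0)

  ## per-category entity lexicons: each entity owns a disjoint slice of the
  ## token pool, so surface forms are unique by construction
  max_elen0 <- spec$entity_length[2]
  lexicon <- lapply(seq_along(spec$categories), function(ci) {
    pool <- make_vocab(spec$entity_lexicon_size * max_elen0,
                       alph$entity[[ci]])
    lapply(seq_len(spec$entity_lexicon_size), function(e) {
      len <- sample(spec$entity_length[1]:spec$entity_length[2], 1L)
      pool[((e - 1L) * max_elen0 + 1L):((e - 1L) * max_elen0 + len)]
    })
  })
  names(lexicon) <- spec$categories

  ## held-out (test-only) entities per category
  n_lex <- spec$entity_lexicon_size
  n_oov <- if (spec$oov_entity_fraction > 0)
    max(1L, round(spec$oov_entity_fraction * n_lex)) else 0L
  core_idx <- seq_len(n_lex - n_oov)
  oov_idx <- if (n_oov > 0) (n_lex - n_oov + 1L):n_lex else integer(0)
  zipf_w <- function(k) if (k == 0) numeric(0) else
    (seq_len(k))^(-spec$frequency_skew)

  n_train <- round(spec$train_fraction * spec$n_sentences)
  n_test <- spec$n_sentences - n_train
  max_elen <- spec$entity_length[2]

  use_markers <- isTRUE(spec$context_markers)
  draw_counts <- function(n_sent) {
    lens <- sample(spec$sentence_length[1]:spec$sentence_length[2], n_sent,
                   replace = TRUE)
    ks <- stats::rpois(n_sent, spec$entity_rate)
    ## leave room for one filler (plus one marker per entity when enabled)
    kmax <- if (use_markers) pmax(0L, (lens - 1L) %/% (max_elen + 1L))
            else pmax(0L, (lens - 1L) %/% max_elen)
    list(lens = lens, ks = pmin(ks, kmax))
  }

  build_sentence <- function(len, ents, id) {
    ## distribute entities into the sentence with filler gaps
    n_ent_tok <- sum(lengths(ents))
    n_fill <- len - n_ent_tok
    tokens <- character(0); tags <- character(0)
    k <- length(ents)
    gap_sizes <- if (k == 0) n_fill else if (use_markers) {
      ## each entity-preceding gap gets at least one slot (for its marker)
      extra <- n_fill - k
      cuts <- sort(sample(0:extra, k, replace = TRUE))
      diff(c(0, cuts, extra)) + c(rep(1L, k), 0L)
    } else {
      cuts <- sort(sample(0:n_fill, k, replace = TRUE))
      diff(c(0, cuts, n_fill))
    }
    fill_draw <- function(m) sample(fillers, m, replace = TRUE)
    for (g in seq_len(k)) {
      gap <- fill_draw(gap_sizes[g])
      if (use_markers) gap[length(gap)] <- sample(markers, 1L)
      tokens <- c(tokens, gap)
      tags <- c(tags, rep("O", gap_sizes[g]))
      etoks <- ents[[g]]$tokens
      tokens <- c(tokens, etoks)
      tags <- c(tags, spans_to_tags(
        data.frame(start = 1L, end = length(etoks) + 1L,
                   category = ents[[g]]$category), length(etoks)))
    }
    last_gap <- if (k == 0) gap_sizes else gap_sizes[k + 1L]
    tokens <- c(tokens, fill_draw(last_gap))
    tags <- c(tags, rep("O", last_gap))
    tagged_sentence(tokens, tags, sentence_id = id)
  }

  gen_split <- function(n_sent, oov_frac, prefix) {
    if (n_sent == 0) return(list())
    cnt <- draw_counts(n_sent)
    slots <- sum(cnt$ks)
    oov_slots <- logical(slots)
    if (oov_frac > 0 && slots > 0 && length(oov_idx) > 0) {
      oov_slots[sample.int(slots, round(oov_frac * slots))] <- TRUE
    }
    slot <- 0L
    sentences <- vector("list", n_sent)
    for (i in seq_len(n_sent)) {
      ents <- lapply(seq_len(cnt$ks[i]), function(j) {
        slot <<- slot + 1L
        ci <- sample(seq_along(spec$categories), 1L)
        idx <- if (oov_slots[slot]) {
          oov_idx[sample.int(length(oov_idx), 1L)]
        } else {
          core_idx[sample.int(length(core_idx), 1L,
                              prob = zipf_w(length(core_idx)))]
        }
        list(tokens = lexicon[[ci]][[idx]], category = spec$categories[ci])
      })
      sentences[[i]] <- build_sentence(cnt$lens[i], ents,
                                       sprintf("%s%d", prefix, i))
    }
    ## group into documents of up to 20 sentences
    groups <- split(sentences, ceiling(seq_along(sentences) / 20))
    lapply(seq_along(groups), function(g)
      ner_document(groups[[g]], sprintf("%s_doc%d", prefix, g)))
  }

  train <- gen_split(n_train, 0, "tr")
  test <- gen_split(n_test, spec$oov_entity_fraction, "te")

  surfaces <- lapply(lexicon, function(lx)
    vapply(lx, paste, character(1), collapse = ""))
  dict_entries <- lapply(surfaces, function(s) {
    if (spec$dict_coverage >= 1) s
    else sample(s, round(spec$dict_coverage * length(s)))
  })
  list(train = train, test = test,
       dictionary = domain_dictionary(dict_entries),
       lexicon = surfaces,
       oov_surfaces = lapply(surfaces, function(s) s[oov_idx]),
       filler_vocab = fillers)
}

#' Specification for synthetic task documents
#'
#' Documents whose sentences embed the default rule set's keyword patterns:
#' primary-site sentences carry a primary keyword, lesion-size sentences a
#' size value plus a density/shadow word (and, with probability
#' `p_lesion_has_site`, a site mention — the lesion-size conditional),
#' metastasis sentences the metastasis keyword with an optional preceding
#' primary part. Gold task entities follow the task semantics by
#' construction.
#'
#' @param n_documents number of documents.
#' @param sentences_per_doc `c(min, max)` sentences per document.
#' @param p_primary,p_lesion,p_metastasis per-sentence type probabilities
#'   (the remainder are keyword-free filler sentences).
#' @param p_lesion_has_site probability a lesion sentence mentions a site.
#' @param p_meta_has_primary probability a metastasis sentence carries a
#'   preceding primary-site part.
#' @param p_special probability a primary sentence uses the incomplete-part +
#'   lymph-node construction.
#' @param conditional enforce the lesion-size conditional in the gold.
#' @param n_sites site lexicon size.
#' @param seed integer seed.
#' @return list of class `task_doc_spec`.
#' @export
task_doc_spec <- function(n_documents = 30L, sentences_per_doc = c(3L, 6L),
                          p_primary = 0.35, p_lesion = 0.25,
                          p_metastasis = 0.25, p_lesion_has_site = 0.6,
                          p_meta_has_primary = 0.4, p_special = 0.15,
                          conditional = TRUE, n_sites = 15L, seed = 1L) {
  stopifnot(p_primary + p_lesion + p_metastasis <= 1,
            sentences_per_doc[1] <= sentences_per_doc[2])
  structure(as.list(environment()), class = "task_doc_spec")
}

#' Generate synthetic task documents with gold task entities
#'
#' @param spec a [task_doc_spec()].
#' @return list with `documents` (list of [ner_document()], gold-tagged),
#'   `gold` (per-document named lists of `primary_site` / `lesion_size` /
#'   `metastasis_site` strings), and `dictionary` (site surface forms,
#'   category `"body"`).
#' @export
generate_task_documents <- function(spec) {
  stopifnot(inherits(spec, "task_doc_spec"))
  set.seed(spec$seed)
  ## filler/site alphabets avoid 'c', 'a', 'm' so no rule keyword ("ca",
  ## "cm", "mm", "mt", ...) can arise by substring accident
  fillers <- make_vocab(30L, c("d", "e", "f", "g", "h", "i", "j", "k"))
  ## site entities: 1-2 tokens, token alphabet avoiding rule keywords
  site_pool <- make_vocab(spec$n_sites * 2L, c("q", "r", "u", "v", "x", "z"))
  sites <- lapply(seq_len(spec$n_sites), function(i)
    sample(site_pool, sample(1:2, 1L)))
  site_surf <- vapply(sites, paste, character(1), collapse = "")
  incomplete <- "mediastinum"; lymph <- "lymphnode"
  size_values <- sprintf("%d.%dcm", sample(1:9, 10, replace = TRUE),
                         sample(0:9, 10, replace = TRUE))

  draw_site <- function() sites[[sample.int(length(sites), 1L)]]
  fill <- function(m) sample(fillers, m, replace = TRUE)

  mk <- function(tokens, tags, id) tagged_sentence(tokens, tags, id)
  site_tags <- function(toks, cat = "body") {
    spans_to_tags(data.frame(start = 1L, end = length(toks) + 1L,
                             category = cat), length(toks))
  }

  docs <- vector("list", spec$n_documents)
  gold <- vector("list", spec$n_documents)
  for (d in seq_len(spec$n_documents)) {
    ns <- sample(spec$sentences_per_doc[1]:spec$sentences_per_doc[2], 1L)
    g <- list(primary_site = character(0), lesion_size = character(0),
              metastasis_site = character(0))
    sentences <- vector("list", ns)
    for (si in seq_len(ns)) {
      u <- stats::runif(1)
      id <- sprintf("d%d.s%d", d, si)
      if (u < spec$p_primary) {
        ## primary-site sentence: "<fill> <site> cancer <fill>"
        special <- stats::runif(1) < spec$p_special
        if (special) {
          toks <- c(fill(1), incomplete, lymph, "cancer", fill(2))
          tags <- c("O", "S-body", "O", "O", "O", "O")
          surf <- paste0(incomplete, lymph)
        } else {
          st <- draw_site()
          toks <- c(fill(1), st, "cancer", fill(2))
          tags <- c("O", site_tags(st), "O", "O", "O")
          surf <- paste(st, collapse = "")
        }
        g$primary_site <- c(g$primary_site, surf)
        sentences[[si]] <- mk(toks, tags, id)
      } else if (u < spec$p_primary + spec$p_lesion) {
        ## lesion-size sentence: "[site] <size> density shadow <fill>"
        has_site <- stats::runif(1) < spec$p_lesion_has_site
        sz <- sample(size_values, 1L)
        if (has_site) {
          st <- draw_site()
          toks <- c(st, sz, "shadow", fill(2))
          tags <- c(site_tags(st), "S-size", "O", "O", "O")
        } else {
          toks <- c(fill(1), sz, "shadow", fill(2))
          tags <- c("O", "S-size", "O", "O", "O")
        }
        if (has_site || !spec$conditional) {
          g$lesion_size <- c(g$lesion_size, sz)
        }
        sentences[[si]] <- mk(toks, tags, id)
      } else if (u < spec$p_primary + spec$p_lesion + spec$p_metastasis) {
        ## metastasis sentence: "[siteA cancer] metastasis siteB <fill>"
        has_primary <- stats::runif(1) < spec$p_meta_has_primary
        stB <- draw_site()
        surfB <- paste(stB, collapse = "")
        if (has_primary) {
          stA <- draw_site()
          toks <- c(stA, "cancer", "metastasis", stB, fill(1))
          tags <- c(site_tags(stA), "O", "O", site_tags(stB), "O")
          ## the sentence is also a primary-site candidate: every site span
          ## in it is emitted as primary, per the task semantics
          g$primary_site <- c(g$primary_site, paste(stA, collapse = ""), surfB)
        } else {
          toks <- c(fill(1), "metastasis", stB, fill(1))
          tags <- c("O", "O", site_tags(stB), "O")
        }
        g$metastasis_site <- c(g$metastasis_site, surfB)
        sentences[[si]] <- mk(toks, tags, id)
      } else {
        ## keyword-free filler sentence, sometimes with an unextracted site
        if (stats::runif(1) < 0.3) {
          st <- draw_site()
          toks <- c(fill(2), st, fill(1))
          tags <- c("O", "O", site_tags(st), "O")
        } else {
          toks <- fill(4)
          tags <- rep("O", 4)
        }
        sentences[[si]] <- mk(toks, tags, id)
      }
    }
    docs[[d]] <- ner_document(sentences, sprintf("taskdoc%d", d))
    gold[[d]] <- lapply(g, function(v) v[!duplicated(v)])
  }
  dict <- domain_dictionary(list(body = c(site_surf,
                                          paste0(incomplete, lymph))))
  list(documents = docs, gold = gold, dictionary = dict)
}
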