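---
title: "Hybrid clinical NER: model, design decisions, and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid clinical NER: model, design decisions, and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwdner)
```

## The problem

Clinical narratives mention anatomical sites, tumor sites and lesion sizes in
short, clause-like sentences. Two features make tagging them harder than
newswire NER: a long tail of rare and unseen entity surface forms, and task
definitions that require only a subset of the mentions in a note (the tumor's
primary site, the size of *that* lesion, the metastasis sites). `cwdner`
addresses the first with a character + word + gazetteer tagger and the second
with a keyword-rule pipeline over the tagger's output.

## Sequence model

Sentences are pre-tokenized; tags follow the BIEOS scheme
(`B-cat`/`I-cat`/`E-cat`/`S-cat`/`O`). Spans are 1-based half-open token
intervals; `spans_to_tags()` and `tags_to_spans()` are exact inverses, which
the test suite checks by exhaustive enumeration of all non-overlapping span
sets for short sentences.

Each token is represented by three streams:

1. **Characters.** A Bi-LSTM over the token's Unicode code points; the
   character representation is the concatenation of the final forward and
   final backward hidden states. Unknown characters map to a trained `<unk>`
   vector.
2. **Words.** A trainable embedding per token surface;
   `load_pretrained_embeddings()` can overwrite rows from the standard
   whitespace-separated text format. We deliberately do not ship or require
   externally pretrained vectors: they would tie results to an unavailable
   corpus.
3. **Dictionary.** For each of the seven n-gram templates anchored at the
   token (1- to 4-grams), the concatenated segment is looked up in each
   dictionary category; the resulting binary vector (7 per category,
   category-major layout) is linearly projected and passed through its own
   Bi-LSTM.

The character and word vectors are fused by a highway layer,
`t * tanh(W_k x + b_k) + (1 - t) * x` with gate `t = sigmoid(W_t x + b_t)`;
both weight matrices are square, so the fused vector keeps the concatenated
dimension and the layer can fall back to a pure carry. The fused vector,
concatenated with the dictionary vector, feeds a context Bi-LSTM whose hidden
states map linearly to emission scores. Because the published description of
the architecture can be read two ways, both wirings are implemented behind
`encoder_config(fusion_mode=)`: `"fused"` (the default; one context Bi-LSTM
over the concatenation, matching the best reported configuration) and
`"triple"` (three independent Bi-LSTMs over the character, word and
dictionary streams, concatenated before the output layer).

The CRF layer scores a tag path as boundary-augmented transitions plus
emissions, with virtual START and STOP states realized as learned boundary
transitions (the path-score sum indexes positions 0 and n+1, which must
resolve to *something*; learned boundary rows are the standard resolution).
The partition function is computed by the forward recursion entirely in log
space with a per-step log-sum-exp, numerically safe for scores up to about
1e3. Viterbi decoding breaks ties toward the lowest tag index at every
backtracking step, so decoded output is reproducible across platforms.

Emissions enter the CRF as raw linear scores, not through a softmax. A
per-position softmax would only shift each row of the emission matrix by its
own normalizer — adding a constant to one position's emissions provably
leaves decoding unchanged (a test asserts this) — so the extra nonlinearity
adds nothing to the model class while complicating gradients.

### Transition constraints

The BIEOS grammar (`B-c` must be followed by `I-c`/`E-c`, etc.) is enforced
by default as an additive mask of −10⁴ in score space on disallowed
transitions, which keeps all quantities finite and differentiable; with
constraints on, every decoded sequence is structurally valid with zero
repairs (property-tested). The mask can be switched off
(`train_config(constraints_on = FALSE)`), in which case decoded sequences
pass through a deterministic repair policy: an `I`/`E` with no open entity of
its category becomes `B` when a same-category `I`/`E` follows and `S`
otherwise, and an unclosed run is closed by converting its last tag to `E`
(lone `B` to `S`). The repair is idempotent.

One published detail could not be used as stated: the hyperparameter listing
gives a tag-index count of 4, which cannot be reconciled with five BIEOS
symbols crossed with categories. The tag alphabet is therefore derived from
the training corpus. Similarly, the worked transition-constraint example in
the source text ("I cannot be followed by E") contradicts the scheme itself;
the standard BIEOS constraint table is used.

## Training

`train_tagger()` minimizes the mean per-sentence CRF negative log-likelihood
with Adam. Defaults follow the published setting: batch size 64, learning
rate 0.005, 10 epochs, dropout 0.5 (applied to the concatenated encoder
input and to the context hidden states — the placement is not specified in
the source and these are the two standard sites), Adam optimizer. Additional
mechanics the source leaves open:

* **Batching.** Sentences are shuffled, ordered by length and sliced into
  buckets of `batch_size`; batch order is itself shuffled. Within a batch,
  sentences are processed individually and gradients summed — mathematically
  identical to padded-and-masked batching, without the padding machinery.
* **Initialization.** Embeddings start uniform in (−0.1, 0.1); LSTM input
  weights use Glorot scaling; recurrent blocks are orthogonal; forget-gate
  biases start at +1; the highway gate bias starts at −1 (carry-dominated).
  All of it is fixed by `train_config(seed=)`: identical seeds give
  bit-identical loss curves, dropout masks and data order.
* **Clipping.** Global gradient norm clipped at 5.0, a standard guard for
  LSTM training.
* **Model selection.** The checkpoint with the best dev micro entity F1 is
  returned, with per-epoch loss and dev F1 in the report.

Analytic gradients for every parameter group — embeddings, both character
LSTMs, highway, dictionary projection and LSTMs, context LSTMs, output
layer, transitions — are verified against central finite differences at
64-bit precision (relative error below 1e−4 on a three-token sentence; in
practice it sits around 1e−10).

## Evaluation

`evaluate_predictions()` implements strict entity-level scoring:
P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R), zero on zero denominators. A
prediction counts as TP only on exact (start, end, category) agreement; a
partial overlap contributes one FP *and* one FN. Weighted scoring
(`weighted_prf()`) combines per-category values with weights that must sum
to one; the shipped task weighting is primary site 0.2, lesion size 0.3,
metastasis site 0.5.

`stratify_by_frequency()` splits an entity-bearing test set by the minimum
training-set occurrence count among each sentence's entities: 0 → unknown,
1–4 → low, ≥5 → high. Two points the band definition leaves open are
resolved as: a sentence with entities in several bands goes to its rarest
entity's band, and a count of exactly five (between "fewer than five" and
"more than five") goes to high and is flagged in the log.

`inject_noise()` implements the robustness protocol: exactly
`round(ratio × n)` sentences drawn without replacement receive one word-level
edit each — insert, delete, or replace a token — at an O-tagged position
only, so gold annotations remain aligned and meaningful. A replacement is
redrawn until it differs from the original; a sentence with no editable
position is skipped with a log entry and another drawn. The sweep over
ratios 0.00–0.10 on a fixed model is the package's robustness harness.

## The rule pipeline

Rules are data, not code: `load_rules()` reads a YAML file with named keyword
lexicons and an ordered rule list, so the six shipped rules (the published
ones) can be extended without code changes — the source describes twelve but
prints only six; the remainder must be user-supplied. The shipped rules:

1. **Segmentation** on full-width/ASCII periods and semicolons, with two
   wrinkles: an ASCII period flanked by digits is a decimal point, and an
   enumeration marker ("2.", "一、") begins a new sentence even without a
   preceding terminator.
2. **Primary site**: the sentence contains a primary keyword
   (cancer / CA / MT / 癌). Latin keywords match case-insensitively, CJK
   exactly.
3. **Lesion size**: a size unit (cm/mm) AND a density/shadow word.
4. **Metastasis site**: the metastasis keyword; if a primary keyword is also
   present, the eligible region starts at the first token after that
   keyword's last character.
5. **Special case**: an extracted incomplete part (e.g. mediastinum)
   followed by a lymph-node token is extended over it.
6. **Lesion-size conditional**: size values are emitted only from lesion
   candidates that also contain a recognized primary-site entity.

Candidate regions restrict which predicted spans are *emitted*, not what the
tagger sees: the full sentence is encoded for context. Dictionary correction
("complete or trim") is operationalized as: exact members pass through;
an entity that is a proper substring of exactly one dictionary entry that
also occurs contiguously in the sentence is completed to it; otherwise, if a
dictionary entry is a proper substring of the entity, it is trimmed to the
longest such entry (prefix preferred on ties); otherwise it is unchanged.
The procedure is idempotent. `rule_subset_sweep()` measures extraction F
over every subset of the optional rules — more rules need not score higher,
and the harness makes that measurable rather than assumed.

## Synthetic study conditions

The original corpora are not redistributable, so the package's empirical
claims are made on synthetic corpora whose generator is itself first-class,
tested code. `generate_corpus()` emulates: clause-length sentences (6–12
tokens), 1–3-token contiguous entities from per-category lexicons with
unique surface forms, Zipf-skewed reuse (singletons included), an exactly
controlled fraction of test-only entity mentions, and a dictionary covering
a configurable fraction of the lexicon. Documents group 20 sentences; the
train/test split is 80/20 by sentence. Everything is deterministic under the
spec seed.

Fixed study conditions used by the tests and the acceptance script (chosen
once, at scales a single CPU handles comfortably):

* **Separable preset** (`corpus_spec_separable()`): 250 sentences
  (200 train), one category, 15 entities all present in the dictionary,
  entity rate 1.5, mild skew 0.6, no unseen test entities, and distinctive
  context markers before entities (emulating the stereotyped clause patterns
  real mentions sit in). Under the published training setting at reduced
  dimensions (word 32, char 12/8, dictionary 16, hidden 32) the tagger must
  recover this structure to test F1 ≥ 0.95 within ten epochs — the
  parameter-recovery experiment. The dictionary-on run must plateau (reach
  within 0.01 of its best F1) in no more epochs than an identical run with
  an empty dictionary, the convergence-speed claim at synthetic scale.
* **Stratification corpus**: 700 sentences, 60 entities, skew 1.3, 25%
  unseen test mentions, dictionary covering 60% — harder on purpose (no
  context markers), so recognizing an unseen entity requires character shape
  and partial dictionary evidence. The trained model's F1 must be ordered
  unknown ≤ low ≤ high. The bands are small (tens of sentences), so the
  ordering is asserted only at the fixed test seed; at other seeds the
  unknown and low bands can cross within noise, which the acceptance script
  reports but does not hide.
* **Task documents** (`generate_task_documents()`): sentences embed the
  default rule set's keyword patterns with per-type probabilities, including
  site-free lesion sentences (exercising the conditional), metastasis
  sentences with and without a preceding primary part, and the
  incomplete-part + lymph-node construction. Gold task entities are built by
  construction-time bookkeeping that mirrors the task semantics; the default
  rules plus a gold-tag oracle tagger must recover them with F = 1.

What passing these tests does and does not show: the synthetic corpora have
no segmentation errors, no nested or discontinuous entities, no spelling
variation and vocabulary-level (not morphology-level) entity cues, so
success here demonstrates correctness of the machinery and the qualitative
behaviors (dictionary features help rare entities; noise tolerance; rule
composition), not clinical-grade accuracy on real notes.

## Numerical choices and degenerate inputs

* Partition and likelihood computations run in 64-bit log space throughout;
  the constraint penalty (−1e4) is additive so gradients stay finite.
* Viterbi ties break toward the lowest tag index; `which.max` semantics make
  this platform-stable.
* Empty sentences are rejected at construction; empty corpora, empty
  dictionaries (all-zero features) and epoch-0 training (untrained model,
  empty report) are all defined and tested.
* Dictionary lookup normalizes to Unicode NFC on both sides and matches
  exactly — no fuzzy matching.
* `inject_noise()` restores the caller's RNG state, so it can be used inside
  larger seeded pipelines without disturbing them.

## Known limitations

* Word segmentation is out of scope: corpora arrive pre-tokenized (the
  whitespace/CJK fallback tokenizer in the raw-text path is a convenience,
  not a contribution).
* Training is single-threaded, pure R; it is sized for corpora of hundreds
  to a few thousand sentences, not the full published setting (word 200 /
  hidden 300 on thousands of records), though those dimensions are the
  defaults and work — slowly.
* The attention and few-shot extensions mentioned as future work in the
  source, BIO/BIOES conversion utilities, and approximate dictionary
  matching are deliberately not implemented.
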