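# cwdner — character + word + dictionary Bi-LSTM-CRF NER for clinical text

Named entity recognition in clinical narratives (body parts, tumor sites,
lesion sizes) is hard where it matters most: rare and unseen entity mentions,
ambiguous token boundaries, and task definitions that need only *some* of the
entities in a note. `cwdner` is an R implementation of a hybrid approach for
this setting, aimed at researchers in clinical text mining who want a fully
inspectable, dependency-light reference implementation:

* a **sequence tagger** that scores each token of a sentence under the BIEOS
  scheme (Begin / Inside / End / Outside / Single, suffixed with the entity
  category) and decodes whole tag paths with a linear-chain CRF;
* a **gazetteer feature module** that matches n-gram context segments of each
  token against a domain dictionary, yielding a 7-dimensional binary feature
  vector per token and category;
* a **rule pipeline** that selects candidate sentences by keywords, applies
  span-level special cases, and corrects extracted entities against the
  dictionary to produce task-level output (tumor primary site, lesion size,
  metastasis site);
* a **synthetic corpus generator** that reproduces the statistical structure
  this kind of method assumes — short clause-like sentences, Zipf-skewed
  entity reuse, unseen test entities, keyword-bearing candidate sentences —
  so every claim the package makes is testable without restricted clinical
  corpora.

## The model

Each token *x<sub>i</sub>* is represented by three streams:

* a character-level vector from a bidirectional LSTM over the token's
  characters (final forward and backward states, concatenated);
* a word embedding (trainable; pretrained vectors loadable);
* a dictionary feature vector: for the seven n-gram templates
  *x<sub>i</sub>*; *x<sub>i−1</sub>x<sub>i</sub>*; *x<sub>i</sub>x<sub>i+1</sub>*;
  *x<sub>i−2</sub>x<sub>i−1</sub>x<sub>i</sub>*; *x<sub>i</sub>x<sub>i+1</sub>x<sub>i+2</sub>*;
  *x<sub>i−3</sub>…x<sub>i</sub>*; *x<sub>i</sub>…x<sub>i+3</sub>*, a binary
  indicator of membership of the segment in the dictionary, passed through a
  projection and a Bi-LSTM.

Character and word vectors are fused by a highway layer

> t = σ(W<sub>t</sub>[w<sup>char</sup>, w<sup>word</sup>] + b<sub>t</sub>),
> w = t ⊙ tanh(W<sub>k</sub>[w<sup>char</sup>, w<sup>word</sup>] + b<sub>k</sub>) + (1 − t) ⊙ [w<sup>char</sup>, w<sup>word</sup>]

and concatenated with the dictionary vector to form e<sub>i</sub>, the input
of a context Bi-LSTM whose hidden states map linearly to per-tag emission
scores P. A transition matrix A (with virtual START/STOP states and optional
hard BIEOS constraints) defines the path score

> s(X, y) = Σ<sub>i=0..n</sub> A[y<sub>i</sub>, y<sub>i+1</sub>] + Σ<sub>i=1..n</sub> P[i, y<sub>i</sub>]

trained by maximizing log p(y|X) = s(X, y) − log Σ<sub>ỹ</sub> e<sup>s(X, ỹ)</sup>
(forward algorithm, log-space) and decoded with Viterbi. All gradients are
analytic and verified against central finite differences. Evaluation is
strict entity-level P/R/F1: a predicted span counts only when start, end and
category all match.

## Worked example

```r
library(cwdner)

## 1. simulate a corpus with known structure (200 train / 50 test sentences)
cp <- generate_corpus(corpus_spec_separable(seed = 2))

## 2. train the tagger (batch 64, Adam at 0.005, 10 epochs, dropout 0.5)
cfg <- train_config(
  seed = 42,
  encoder = encoder_config(word_dim = 32, char_dim = 12, char_hidden = 8,
                           dict_dim = 16, hidden_dim = 32, dropout = 0.5))
fit <- train_tagger(cp$train, cp$test, cp$dictionary, cfg)
round(fit$report$dev_f1, 3)
#>  [1] 0.000 0.000 0.000 0.185 0.323 0.814 0.860 0.860 0.979 1.000

## 3. strict entity-level evaluation
pred <- predict_tags(fit$model, cp$test, cp$dictionary)
evaluate_predictions(cp$test, pred)
#> <eval_report: TP 49 FP 0 FN 0>
#>   micro    P 1.0000 R 1.0000 F 1.0000
#>   body     P 1.0000 R 1.0000 F 1.0000
```

The F1 curve shows the tagger recovering the generator's structure from
scratch within ten epochs; the evaluation report counts exact span matches
(49 test entities, all found with correct boundaries and category).

Task-level extraction feeds tagged sentences through the keyword rules
(here with the gold-tag oracle in place of a model):

```r
td <- generate_task_documents(task_doc_spec(n_documents = 2, seed = 11))
extract_task_entities(td$documents[[1]], oracle_tagger(), td$dictionary)
#> $primary_site
#> [1] "xzxqruxx" "vruruvu"  "vru"      "zux"      "quzxzxq"  "vrxv"
#> $lesion_size
#> character(0)
#> $metastasis_site
#> [1] "vru"  "vrxv"
```

Lesion sizes are empty for this document because its size-bearing sentences
contain no recognized primary-site mention — the conditional rule at work.

A command-line front end over the same functions lives in `inst/cli/cwdner`
(subcommands `simulate`, `train`, `predict`, `evaluate`, `extract`).

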