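---
title: "Super-tuning sentence encoders for negation and speculation"
author: "negscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-tuning sentence encoders for negation and speculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negscope)
```

## Motivation

A biomedical sentence and its negation ("the scan shows a lesion" /
"the scan does not show a lesion") differ by one or two words, and
generic sentence embeddings place them almost on top of each other.
Systems built on such embeddings — cohort selection, information
extraction, report triage — then silently read absent findings as
present ones. `negscope` implements a three-stage remedy:

1. build a corpus of sentence pairs scored by polarity relationship;
2. *super-tune* the encoder with a Siamese cosine-similarity objective
   on those pairs;
3. fine-tune token classifiers for cue detection and scope resolution
   on top of the adjusted encoder.

This vignette is the package's account of the model, its conventions,
the tunable parameters, and what the synthetic corpus does and does not
establish.

## The pair corpus

A pair carries two sentence texts and a target score $Y \in \{-1,0,1\}$:

* **−1** — a negated sentence and its affirmative counterpart: same
  topic, opposite polarity. The embeddings should point in opposite
  directions.
* **0** — two contextually unrelated sentences: embeddings should be
  orthogonal.
* **1** — a sentence and a meaning-preserving paraphrase: embeddings
  should coincide.

`build_pairs()` applies exactly these rules; the affirmative
counterparts are an *input* (in real corpora they are authored
manually), and score-0 partners are seeded draws from an
unrelated-sentence pool. One wording ambiguity is worth recording: a
score of −1 is sometimes glossed as the similarity being "more"; we
implement the numeric target −1 (anti-alignment), which is the only
reading consistent with the cosine codomain and with the scoring table.

`augment_pairs()` multiplies the corpus: each pair is paraphrased on
both sides $k = 4$ times, children inherit the parent's score
(paraphrases preserve polarity by contract), and originals are retained
alongside the children. Retention plus deduplication is a deliberate
choice: published pair counts for this recipe are mutually inconsistent
(the same corpus is reported with two different totals, both below a
strict ×4 expansion), so the package keeps the construction that
maximizes training signal and documents the count it produces rather
than targeting either figure. `split_pairs()` partitions 0.70/0.15/0.15
by *pair family* — an augmented child always follows its parent — so
paraphrases cannot leak across splits, and `leakage_check()` verifies
that no normalized sentence text (lowercased, whitespace collapsed,
terminal punctuation stripped) is shared between the super-tuning and
fine-tuning stages.

## The Siamese objective

Both sentences pass through one shared encoder. Per-token vectors are
mean-pooled over real tokens (no padding is ever fed), giving
embeddings $u, v$. The similarity head is

$$\cos(\theta) = \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert},$$

clamped to $[-1, 1]$ against floating-point overshoot, and the loss is
the mean squared error

$$\mathrm{MSE} = \frac{1}{n}\sum_{i=1}^{n}\left(\cos(\theta)_i - Y_i\right)^2 .$$

One published rendering of this loss omits the square; since the loss
is *named* mean squared error everywhere it is used, we implement the
squared form. A zero-norm embedding is a domain error, not a silent 0:
it can only arise from a degenerate encoder and should be loud.

Training (`supertune()`) is plain minibatch gradient descent with Adam;
the gradient of the cosine head,
$\partial \cos/\partial u = v/(\lVert u\rVert \lVert v\rVert) - \cos(\theta)\, u/\lVert u\rVert^2$,
is propagated through the pooling mean into the encoder parameters.
Everything is seeded: the same configuration and seed reproduce the
loss history and the trained weights bit for bit, and `epochs = 0` is
an exact no-op (useful for before/after comparisons).
`separation_report()` computes per-pair cosine and Euclidean statistics
under two encoders and their per-class means and deltas — the
diagnostic that shows class means ordered $1 > 0 > -1$ after a
successful run.

## The reference encoder

No deep-learning framework is assumed: the package's reference encoder
(`tiny_encoder()`) is a trainable embedding table, optionally followed
by a forward Elman recurrent layer
$h_t = \tanh(x_t W_x + h_{t-1} W_h + b)$, with forward and backward
passes written out in base R. Defaults: dimension 32 (capped at 64),
Gaussian initialization (sd 0.25), seeded. The plain embedding-bag
variant suffices for super-tuning and cue detection, where a word's
identity determines its role; the recurrent variant is recommended for
scope resolution, where the label of "be" depends on the marked cue
earlier in the sentence. Larger transformer backends plug in behind the
same contract (`token_vectors()` plus the training generics); the
package deliberately treats the encoder as an interface, not a fixed
architecture.

## Label conventions

**Cue detection.** Two schemes: `bioscope4` (0 padding, 1 normal word,
2 negation cue, 3 speculation cue) and `sherlock3` (0, 1, 2 cue). Every
word inside a cue span gets the cue's class; multi-word cues ("rather
than") label each word; overlapping cues of different types on one word
are an integrity error. "This may not be a lesion" encodes as
`1 3 2 1 1 1`.

**Word/subword alignment.** `align_labels()` expands word labels onto
the token sequence: `[CLS]` and `[SEP]` get label 1, each subword
inherits its word's label, and `[PAD]` tokens (filling to `max_length`,
default 128) get label 0 — for the six-word sentence above at
`max_length = 12` this is `1 1 3 2 1 1 1 1 0 0 0 0`. Decoding
(`decode_predictions()`) takes the per-row argmax with ties resolved to
the *lowest* class index, keeps the first subword of each word, and
drops special, pad and marker positions, so the output length always
equals the word count. Over-long sentences truncate with a warning.
Encode replicates a word's label to all its subwords while decode reads
only the first — the standard convention pair, chosen because it is
deterministic and round-trip safe.

**Scope resolution.** `expand_instances()` emits one instance per cue,
wrapping the cue span in `[NEG]`/`[SPE]` markers (before the first and
after the last cue word). Labels are binary per *original* word: 1
inside the cue's linked scope, 0 outside. Following the documented
worked instances, the cue's own words are labeled 0 by default — the
scope excludes its trigger — with `exclude_cue = FALSE` available for
corpora that follow the cue-inclusive convention. Markers are atomic
vocabulary items (never subword-split), carry token label 0, are
excluded from the training objective and never appear in decoded
output. Fragmented predictions are collapsed to the longest contiguous
run of in-scope words, earliest run on ties; nothing in the task
definition addresses fragmented output, so a single deterministic rule
is applied and documented.

The classifier head is a single linear softmax over token vectors —
the task specification motivates nothing deeper — trained with
cross-entropy on word tokens only (padding, `[CLS]`/`[SEP]` and markers
excluded from the loss and from F1).

## Evaluation

`token_f1()` reports micro-averaged per-class precision/recall/F1 over
all words plus a macro mean over non-padding classes; zero-support
classes score 0 and are flagged rather than raising.
`exact_span_match()` is the stricter scope metric: the fraction of
instances whose collapsed predicted span equals gold exactly. Both are
emitted because published F1 values for these tasks rarely state the
variant; token-level F1 is the primary metric to match the transfer
learning work this approach builds on.

## The synthetic corpus

`template_bank()`/`generate_corpus()` produce BioScope-dialect XML plus
gold annotations from subject–verb–object templates ("the biopsy
reveals a lump") with negation transforms ("does not show", "reveals
no", and the multi-word "shows X rather than Y") and speculation
transforms ("may show", "suggests", "might show"). Scopes run from the
cue to sentence end, the dominant pattern in annotated corpora of this
kind. Generation is exact (requested class counts, not sampled) and
byte-reproducible per seed. The stub paraphraser substitutes synonyms
from a fixed dictionary and never touches polarity words, so
augmentation preserves scores by construction.

What the generator emulates: annotation structure (nested scope/cue
XML, per-cue columns), class balance, multi-word cues, deterministic
gold. What it does not: lexical diversity, discontiguous or
cue-medial scopes, affixal cues ("un-happy" — invisible to any
word-level scheme, a known limitation), clinical sub-corpus
conventions, and the fluency of neural paraphrasers. Green tests
therefore demonstrate that the *mechanism* — objective, gradients,
alignment, decoding — is correct, not that desk-scale models transfer
to real corpora; reproducing published corpus-level F1 requires the
original corpora and a pretrained transformer backend, both outside
this package's scope.

## Problem sizes and defaults

The shipped configuration exercises everything at desk scale, chosen so
the whole suite runs in well under a minute on one CPU core:

| parameter | default | note |
|---|---|---|
| pair corpus | 150 pairs (50/class) | separation demonstrations |
| augmentation `k` | 4 | children per pair |
| split | 0.70/0.15/0.15 | grouped by pair family |
| encoder dim | 32 | ≤ 64 by construction |
| `lr` | 2e−5 (`train_config`) | transformer-scale default; from-scratch runs of the tiny encoder use ~0.05 (Siamese) / ~0.02 (token tasks) |
| batch size | 16 | |
| epochs | 10 | super-tuning; 30 for memorization checks |
| `max_length` | 128 (32 in tests) | padded token length |
| memorization fixture | 20 sentences / 20 instances | overfit-to-1.0 capacity check |

Training-sanity expectations under these conditions: the final epoch
loss falls below the first; post-training class means order
$1 > 0 > -1$ for at least 3 of 4 seeds; cue and scope models memorize
the 20-sentence fixture to token accuracy 1.0.

## Degenerate inputs and numerical choices

Zero-norm vectors: domain error. Cosine clamped to $[-1,1]$ before the
loss. Argmax ties: lowest class. One-word sentences: paraphrase
distinctness is waived with a warning. Empty cue-type filter with
`require_cue`: argument error. Scores outside $\{-1,0,1\}$: rejected at
construction. Sentences longer than `max_length`: truncated with a
warning, labels truncated consistently. All randomness flows from
explicit seeds through a private RNG stream that restores the caller's
`.Random.seed`.
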