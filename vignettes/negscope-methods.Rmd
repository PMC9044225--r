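---
title: "Detecting negation and uncertainty in clinical text with negscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting negation and uncertainty in clinical text with negscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negscope)
```

## The problem

Clinical narrative is dense with statements about what is *not* the case
("sin dolor torácico", no chest pain) and what is merely *suspected*
("probable neumonía"). An information-extraction system that indexes
"dolor torácico" from a negated sentence inverts the clinical meaning.
Negation/uncertainty analysis decomposes into finding **cues** — the
words that trigger negation ("no", "sin", "niega", affixal forms like
"afebril") or speculation ("probable", "compatible con") — and resolving
each cue's **scope**, the text fragment whose truth value it modifies.
The scope may precede the cue, follow it, surround it, or be split into
discontinuous fragments.

`negscope` treats both subtasks as one single-stage sequence-labeling
problem. Every token of a sentence receives one of ten BIO labels —
`O`, `B-/I-NEG` (negation cue), `B-/I-NSCO` (negation scope), `B-/I-UNC`
(uncertainty cue), `B-/I-USCO` (uncertainty scope), plus a reserved `PAD`
— so a single tagger jointly recognizes cues and scopes for both
phenomena. Two tagger families are provided: a bidirectional LSTM with a
linear-chain CRF output layer, and a transformer encoder with a softmax
token-classification head over WordPiece sub-words.

## Corpus model and preprocessing

Corpora arrive as BRAT standoff pairs (`.txt` + `.ann`): entity lines
carry 0-based half-open character spans (`;`-separated for discontinuous
annotations), relation lines link each scope to its cue, attribute lines
carry the cue class (syntactic / lexical / morphological). The reader
validates every surface string against the document, segments documents
into sentences (terminator + whitespace + capital, with an abbreviation
guard; newlines always break), assigns each annotation to the sentence
holding its first fragment, and re-bases offsets to sentence-local
coordinates. When an annotation — or a cue/scope pair — crosses a
sentence boundary the sentences are merged rather than the annotation
truncated, so gold spans are never lost. Entity-type names differ across
corpus releases; per-dialect mapping tables translate them, leniently by
default for the public-corpus dialects (unknown types are flagged and
excluded) and strictly for the package's own round-trip dialect.

Tokenization is a deterministic rule (maximal letter/digit runs; every
other non-whitespace character is its own token). The rule is stated
because all token-level statistics and scores are tokenizer-relative.

Training views of a corpus follow a fixed matrix pipeline: a token matrix
`T` and label matrix `L` (one sentence per row, padded to a common length
`j`), dictionaries `DT` (tokens, with reserved ids `PAD = 0`, `UNK = 1`)
and the label alphabet, their integer codifications `T'` and `L'`, and
the one-hot array `H` of `L'`. Padding positions hold `PAD` in all five
structures, and `argmax(H) == L'` by construction.

Two labeling conventions are worth making explicit:

* **Precedence.** When one token is claimed twice, cue beats scope and
  negation beats uncertainty. Cue tokens are therefore never inside a
  scope run, mirroring the separation of cue and scope labels in the
  label alphabet.
* **Discontinuity.** BIO cannot express fragment linkage, so each
  fragment of a discontinuous annotation restarts its own `B-` run, and
  entity-level (exact-match) evaluation operates at fragment level. Since
  roughly 95% of scopes in Spanish clinical corpora are continuous, the
  impact of this convention is bounded; a stricter whole-annotation
  matching remains possible on the decoded entities for sensitivity
  analysis.

## The recurrent tagger (BiLSTM-CRF)

Tokens are embedded with pre-trained word vectors (word2vec/fastText text
format, 300-dimensional by convention; out-of-vocabulary rows are drawn
from a seeded N(0, 0.1), the `PAD` row is zero, and coverage is
reported). A forward LSTM pass produces a left-context state $f_i$ and an
independent backward pass a right-context state $b_i$; their
concatenation $h_i = [f_i; b_i]$ feeds a linear layer producing per-label
emission scores.

Because BIO labels are strongly interdependent (an `I-NSCO` cannot follow
`O`), the output layer is a linear-chain CRF. A label path $y$ over
emissions $e$ scores

$$s(x, y) = \mathrm{start}(y_1) + \sum_t e_{t,y_t}
          + \sum_t A_{y_t,y_{t+1}} + \mathrm{end}(y_n),$$

with transition matrix $A$. Training minimizes the negative
log-likelihood $\log Z - s(x, y^{gold})$, with $\log Z$ computed by the
forward algorithm in log space; decoding is exact Viterbi. Both are
verified in the test suite against brute-force enumeration of all $K^n$
paths on small instances, and the analytic gradients (forward–backward
expected counts) against finite differences.

Default hyperparameters are the published ones: learning rate 0.001,
dropout 0.5 on the encoder output, 60 epochs, hidden size 300, batch
size 512. Choices the reference description leaves open, fixed here:
Adam as the optimizer behind the stated learning rate; gradient clipping
at global norm 5 (large batches otherwise risk early divergence);
embedding rows trainable by default (configurable); Viterbi ties broken
toward the smallest label index for reproducibility. `PAD` is masked out
of both the loss and the emission scores rather than learned — learning
to label padding is vacuous, and reports treat `PAD` separately.

## The transformer tagger

Sentences are segmented by a WordPiece tokenizer (greedy
longest-match-first; continuations carry `##`; the vocabulary is built
from the training corpus with whole units for frequent words and
character fallback). `[CLS]` is prepended and `[SEP]` appended; inputs
are truncated at the configured maximum sequence length (256 sub-tokens
by default, per the published setting, with batch 64 and five epochs).

Word-level labels are expanded to sub-tokens — the first piece keeps the
word's label, continuations of a `B-X` word take `I-X`, specials take
`PAD` — and the classification head computes per-sub-token label
probabilities $P(l \mid R_i) = \mathrm{softmax}(W_o R_i + b_o)$ over the
contextual vectors $R_i$, with max-subtraction for numerical stability.
Cross-entropy is minimized over non-special positions only (special
positions receive exactly zero gradient, which the tests check).
Post-processing removes special positions and reduces each word to its
first sub-token's label; the reference description does not say how
sub-token predictions become word labels, so first-sub-token reduction is
the documented choice here, paired self-consistently with `I-X`
supervision of continuations. Truncated tails are labeled `O` and
flagged, and the output length always equals the input word count.

### The compact encoder

No deep-learning framework is part of this package's dependency set, so
both taggers are implemented natively in R on a small reverse-mode
automatic-differentiation engine written for the package (dense-matrix
tape; fused operators for softmax cross-entropy, layer normalization and
the CRF likelihood). Every operator and both full computation graphs are
gradient-checked against finite differences in the test suite.

The encoder used for desk-scale work is a compact randomly initialized
transformer honoring the same contract as a large pre-trained checkpoint
(sub-tokens in, one contextual vector per sub-token out): token
embeddings plus fixed sinusoidal position encodings, layer-normalized;
two residual blocks of multi-head scaled dot-product attention and a ReLU
feed-forward sub-layer, each followed by layer normalization; defaults
dim 32, 2 layers, 2 heads, feed-forward width 128. Three standard
design choices matter for generalization across sentence lengths on
small corpora and were adopted deliberately:

* **Sinusoidal rather than learned positions** — learned absolute
  position rows for positions absent from a small training corpus remain
  random noise at test time.
* **Relative-position attention biases** (log-bucketed signed distances,
  learned per head) — scope resolution is fundamentally about "which
  side of the cue am I on, and how far", and relative biases express this
  independently of absolute position.
* **Log-length attention scaling** — attention logits are multiplied by
  $\log(n+1)/\log 16$ so attention entropy does not grow with sequence
  length, counteracting dilution on sentences longer than those seen in
  training.

Optimization uses Adam with linear warmup over the first 10% of steps and
linear decay after, the standard fine-tuning schedule. These choices are
visible in the code and configurable; none changes the module contract.

Known limitation: with an independent softmax per position, the
transformer can emit structurally ill-formed sequences (an `I-X` with no
open run); entity decoding repairs these to `B-X` with a log record. On
sentences far beyond the training length distribution the compact
encoder can still hallucinate scope labels; the CRF-equipped recurrent
tagger, whose transition matrix hard-penalizes illegal successions, is
robust to this failure mode. Large pre-trained encoders sidestep the
issue by pre-training coverage; a compact random-init encoder cannot.

## Evaluation protocol

For a label subset (e.g. the two negation-cue labels),

$$P = \frac{\#\text{tokens correctly predicted}}{\#\text{predicted tokens}},
\qquad
R = \frac{\#\text{tokens correctly predicted}}{\#\text{tokens in the dataset}},
\qquad
F_1 = \frac{2PR}{P+R}.$$

* **Partial match** scores every token independently (a scope predicted
  2-of-3 tokens scores P = 1, R = 2/3, F1 = 0.8).
* **Exact match** scores decoded entities: a prediction counts only when
  its full token set equals an unmatched gold entity's, matched greedily
  1:1 in token order.
* **Rollups.** Task-level scores (negation/uncertainty × cue/scope) are
  the *support-weighted means of the per-label metric values* over the
  `B-`/`I-` pair — not pooled-count recomputations — because that is the
  reduction that reproduces the published task tables from the published
  per-label table; the rollup support is the sum.
* Zero-denominator metrics are reported as 0 with `defined = FALSE`
  rather than dropped, so reports are total. Human-readable tables round
  to 2 decimals; JSON keeps raw values.
* **Inter-annotator agreement** is F-measure with one annotator as
  reference (precision: fraction of the second annotator's annotations
  that agree; recall: fraction of the reference reproduced), at token and
  at entity level. Chance-corrected kappa is deliberately out of scope:
  for sparse span annotations the chance-agreement term is near zero and
  the F-measure is the field's convention.
* **Cross-validation** (for corpora without a fixed split): sentences
  are shuffled by seed into k near-equal disjoint folds; the averaged
  report is the unweighted mean of per-fold metrics, and per-fold
  reports are retained.

The open question of whether the partial-match precision denominator
should count tokens predicted outside the evaluated subset is resolved
as: only tokens predicted *with a label in the subset* count as
predicted.

## The synthetic corpus generator

Public clinical corpora cannot be redistributed with the package, so
every module is exercised on generated corpora whose *distributional*
structure mirrors the published descriptive statistics of Spanish
clinical text:

* 25.5% of sentences negated, 7.5% uncertain (independent draws);
* sentence lengths log-normal, fitted to quartiles (9, 14, 23) — the
  published mean exceeding the median indicates right skew, which the
  log-normal captures; lengths are capped at 80 tokens;
* cue inventories seeded with the documented surfaces, frequencies set
  so the five most frequent negation cues ("no", "sin", "negativo",
  "negativos", "niega") carry 87% of negation mass while the five most
  frequent uncertainty cues carry just under 48% — the concentration
  asymmetry that makes uncertainty harder to learn;
* cue class mix 85/6/9 syntactic/lexical/morphological for negation,
  2/98 syntactic/lexical for uncertainty;
* 95% continuous scopes; discontinuous scopes surround the cue (the
  canonical discontinuity in this domain) or split one side with a gap
  when a cue never takes both sides;
* per-cue scope-side distributions, right-dominant overall, left-dominant
  for postposed lexical cues like "negativo" (real per-cue side
  frequencies are not published; these defaults are configurable).

Generation is a pure function of (config, n, seed). Sentences are filler
tokens from a neutral clinical vocabulary with cue insertions and scope
spans on the sampled side(s); gold standoff records with character
offsets are emitted for every insertion. Morphological cues ("afebril")
negate affixally — the negation lives inside the cue token — so they
emit no separate scope record; a scope record overlapping its own cue
would violate the corpus model's non-overlap invariant and would be
unrepresentable under the cue-wins precedence anyway.

What the generator does *not* emulate: grammar, lexical diversity,
context-dependent cue ambiguity (real "negativo" is only sometimes a
cue), document structure, or annotation noise. Passing tests on
generated corpora therefore demonstrate mechanical correctness
(round-trips, conservation, metric identities) and *learnability* of
separable structure — not clinical-grade accuracy. Published full-corpus
scores require the real corpora plus large-scale pre-trained encoders
and are out of desk-scale reach by design.

A second configuration, `config_separable()`, makes the labeling a
deterministic function of surface and position (disjoint cue/filler
vocabularies, all scopes continuous and running to the sentence edge on
their side, one annotation per sentence). On it, a competent tagger
should approach perfect token F1; the acceptance suite trains the
recurrent tagger (hidden 32) on 200 such sentences and the compact
transformer on 300, verifying held-out token F1 of at least 0.95 and
0.90 respectively. These problem sizes — like the 2,000-sentence corpora
used for the distributional-fidelity and round-trip suites — are the
package's chosen verification scale: large enough for binomial
concentration within the asserted tolerances, small enough to run on a
laptop in minutes.

## Numerical and reproducibility choices

* All randomness flows from explicit seeds; training, generation and
  fold assignment are seed-deterministic, and the pipeline derives
  per-component sub-seeds from one global seed so components are
  independently reproducible.
* Log-space computations throughout the CRF; `-1e6` masks rather than
  `-Inf` inside trained scores to keep arithmetic finite.
* Degenerate inputs: empty annotation content parses to an empty record
  list; an empty corpus is an explicit error; a single-label CRF has
  zero loss by construction; sentences longer than the padded length are
  an error unless truncation is explicitly enabled.
* Checkpoints, dictionaries, reports and manifests are plain text
  (JSON), with full-precision numerics; every pipeline run writes a
  manifest (resolved config, input checksums, versions) sufficient to
  replay it.

## Known limitations

* Tokenization and sentence segmentation are rule-based; statistics on
  real corpora are tokenizer-relative and the distinct-cue count is
  computed on lowercased surfaces (case-sensitivity of the published
  counts is unstated).
* The entity-type names of the public releases are mapped by a
  best-effort dialect table; unknown types are excluded with a log
  record under the lenient default.
* Native-R training is CPU-bound and desk-scale; the published
  hyperparameters (hidden 300, batch 512, 60 epochs) are the defaults
  but are intended for use with the real corpora on serious hardware.
* The compact transformer's length extrapolation is imperfect (see
  above); conclusions about the two architectures' relative merits at
  desk scale should not be projected onto their full-scale counterparts.
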