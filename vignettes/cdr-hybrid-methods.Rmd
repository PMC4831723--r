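---
title: "Methods: hybrid chemical-disease relation extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid chemical-disease relation extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrhybrid)
```

## The task and its decomposition

`cdrhybrid` extracts chemical-induced disease (CID) relations at the
document level: the unit of evaluation is the triple
(document, chemical MeSH concept, disease MeSH concept). Extraction is
strictly intra-sentence — every chemical-disease mention pair sharing a
sentence is one candidate instance, and cross-sentence relations are out of
reach by construction (this shows up as an explicit `cross_sentence`
category in the error taxonomy). Document-level gold relations are
projected onto **all** co-sentential mention pairs with matching concept
IDs, the usual distant-supervision reading; this projection can mislabel
an individual mention pair whose sentence does not actually express the
relation, which is part of why three heterogeneous models are combined
rather than one.

The pipeline consumes three aligned files: a PubTator corpus (title and
abstract lines, mention lines with 0-based half-open character offsets over
`title + " " + abstract`, CID relation lines), CoNLL-style dependency
blocks (one per sentence, head indices 0-based with `-1` as root), and one
Penn-bracketed phrase tree per sentence. Sentence segmentation is taken
from the parse files and never recomputed; tokens are aligned
left-to-right against the document text, so any tokenization drift is a
hard error rather than a silent misalignment. Mentions straddling a
sentence boundary are dropped with a warning. Mentions with concept ID
`"-1"` (unnormalized) are kept as tokens but always labeled negative and
never emitted as relations: document-level evaluation operates on concept
IDs, so an unnormalizable mention cannot be scored correctly anyway.

## Syntactic views of a candidate

All tree views derive from the **shortest dependency path tree (SDPT)**:
the unique undirected path between the two entity head tokens, rooted at
their lowest common ancestor. The entity head is the span token whose
dependency head lies outside the span (rightmost if several, with a
rightmost-token fallback for pathological parses). Arcs are traversed in
both directions; the original arc direction is not preserved, only the
relation label. Children are ordered by ascending token index everywhere —
the convolution kernels are order-sensitive, so a fixed deterministic
order is required and sentence order is the natural choice.

* **SDF** rewrites each non-root SDPT node `word/POS`, reached via
  relation `r`, into the chain `r -> POS -> word`; on-path children hang
  off the relation node, so the SDPT shape is preserved at the relation
  level. The root has no incoming relation; it is labeled `ROOT` with its
  own `POS -> word` chain beneath. This keeps the root word (usually the
  governing verb, the strongest single lexical cue) visible to the kernel
  and gives the exact node-count law `|SDF| = 3 |SDPT|`, which the tests
  assert.
* **Extended SDF** additionally attaches each on-path word's off-path
  immediate dependents as extra `r -> POS -> word` chains, interleaved
  with on-path children by token index.
* **SPF** prunes the phrase tree to the leaves whose token index lies on
  the SDPT plus all their ancestral constituents, re-rooted at the lowest
  common ancestor (a single selected leaf degenerates to leaf +
  preterminal). **PT**, the path-enclosed-tree baseline, is the same prune
  over the contiguous leaf range spanned by the two entities.
* **SDP sequences** feed the neural model. `dep` order follows the path
  from the chemical head to the disease head (reading direction fixed by
  convention, configurable in spirit by swapping the heads). `seq` order
  lists the path words by token index; since dependency relations have no
  natural sentence position, each relation is placed at the midpoint of
  its arc's endpoint indices, with words preceding relations on ties. This
  midpoint rule is this package's choice; any deterministic interleaving
  would do, and the word order — the part that matters for the recurrent
  encoder — is unambiguous.

Fragmented parses (two dependency components, so no path exists) are not
fatal: such candidates keep their flat features and fall back to the plain
word sequence for the neural model, while the tree-kernel score is fixed
at the hyperplane (decision value 0, i.e. probability 0.5) so the
combination remains well defined.

## The three models

**Feature-based model.** Sparse binary features, namespaced per group:
context windows `[-3, 3]` around each entity span (word, stem, POS,
chunk; offsets relative to the span boundary, entity-interior tokens
skipped, out-of-sentence offsets emit explicit padding features), entity
head features, position (`before`/`after`), token-distance buckets with
half-open boundaries (`[0,3)` LessThree up to `[12, inf)` MoreTwelve),
three verb-zone indicators (POS prefix `VB` strictly before/between/after),
and FDF (SDPT-root position among `before`/`between`/`after` — a root
inside an entity span counts as between — plus the root's `[-1, 1]`
context). Stems come from the parse file's lemma column. The groups are
toggleable in their cumulative ablation order. Vectorization maps features
to dimensions in lexicographic order (refits are reproducible); unseen
test-time features map to nothing. The classifier is a soft-margin SVM
with kernel `(u . v + 1)^3`. Degree 3, `coef0 = 1` and `C = 1` are the
common defaults for binary NLP feature vectors; the positive-class cost is
multiplied by `j` = (#negatives / #positives) to counter class imbalance.
The polynomial Gram is cosine-normalized by default (the same
normalization as the tree kernels): raw values grow as
`(#active features)^degree`, roughly 1e5-1e7 here, and a Gram that badly
conditioned stalls the SMO solver short of fitting even separable
training data. All of these are configurable.

**Tree-kernel model.** The Collins-Duffy convolution kernel: `K(t1, t2)`
sums `Delta(n1, n2)` over node pairs, where `Delta = 0` unless the
productions match (same label, same ordered child-label sequence),
`Delta = lambda` for matching preterminal productions, and otherwise
`Delta = lambda * prod_i (sigma0 + Delta(c1i, c2i))` with `sigma0 = 0`
giving the subtree (ST) kernel and `sigma0 = 1` the subset-tree (SST)
kernel. A terminal child is part of the matched production and contributes
factor 1 in both variants. Defaults are SST with `lambda = 0.4`, the
long-standing defaults of tree-kernel SVM toolkits. Each view's kernel is
cosine-normalized **before** summation (`K' = K / sqrt(K11 K22)`), then
the SDF and SPF kernels are added with unit weights; normalizing first
keeps one view from dominating through sheer tree size. Both the kernel
recursion and the normalize-then-sum order are verified in the tests
against exhaustive fragment enumeration on all trees of at most 8 nodes,
at `lambda` 0.4 and 1.0, and Gram matrices are checked symmetric and PSD
to 1e-8. The dual problem on the precomputed Gram is solved by
`kernlab::ksvm` (SMO, tolerance 1e-3); dual coefficients, support indices
and bias are extracted so decision values are recomputed inside the
package as `f(x) = sum_i alpha_i y_i K(x_i, x) + b`, with the sign
orientation checked against the training labels at fit time.

**Neural model.** A peephole LSTM in which all three gates read the memory
cell:

```
i_t = sigma(W_i x_t + U_i h_{t-1} + v_i * c_{t-1} + b_i)
f_t = sigma(W_f x_t + U_f h_{t-1} + v_f * c_{t-1} + b_f)
c_t = f_t * c_{t-1} + i_t * tanh(W_c x_t + U_c h_{t-1} + b_c)
o_t = sigma(W_o x_t + U_o h_{t-1} + v_o * c_t + b_o)    # current cell
h_t = o_t * tanh(c_t)
```

Peephole connections are diagonal (elementwise vectors), the convention of
the architecture this gating scheme comes from. The final hidden state
feeds a logistic output unit; training minimizes cross-entropy by
mini-batch SGD (gradients averaged per batch) with optional early stopping
on a validation split, fully deterministic given the seed. Input encodings:
`WORD` (tokens from the first to the last mention, both mentions included
by default — a flag excludes them), `HEAD` (entity spans replaced by their
head token), `SDP-dep`/`SDP-seq` (path words and relations; relations use
a separate embedding table), `+POS` (POS embedding concatenated, doubling
the input width to `2d`; relation elements use a dedicated `<none>` POS).
On SDP inputs the endpoints already *are* the entity heads, so the `+HEAD`
modifier instead substitutes `<chemical>`/`<disease>` type placeholders
for the endpoint surfaces — the same generalization-over-entity-names
intent, adapted to a representation where literal head substitution would
be a no-op. Word/POS/relation embeddings are trained from random
initialization; the word table can be warm-started from a plain-text
`word v1 ... vd` embedding file. Reference widths are `d = 200` (the usual
pretrained embedding width) and `H = 100`. The CNN baseline uses window 3,
200 feature maps, `tanh`, and max-over-time pooling, with zero padding so
length-1 sequences still produce one window.

Every analytic gradient (all LSTM tensors, the CNN filters, the output
layer and all three embedding tables) is validated against central finite
differences in the tests, with relative error below 1e-4. The
finite-difference quotient uses a denominator floor of 1e-3: for
near-zero gradient entries the subtraction cancels catastrophically, so
below the floor the comparison degrades gracefully into an absolute check
at 1e-7 — still far tighter than any training-relevant scale.

## Combination, tuning, and rules

Margin decision values are mapped through the plain logistic sigmoid —
not Platt scaling — because the defining property of the 0.5 decision
boundary ("probability one half exactly on the hyperplane") holds only
for the unfitted transform. The combined score is the convex mixture
`alpha * sigma(F) + beta * sigma(K) + (1 - alpha - beta) * N`, monotone in
each component. Mention-pair probabilities aggregate to a concept pair by
**maximum**: a document asserts a relation if at least one sentence
expresses it, and the maximum preserves the 0.5 boundary semantics that a
mean would blur. Weights are tuned by grid search over the simplex
(`alpha, beta >= 0`, `alpha + beta <= 1`) with coarse step 0.1 (66 points,
computed over integers to avoid floating-point drift) and a fine 0.01 grid
within one coarse step of the optimum, scored by mean document-level F
over a k-fold split **by documents** (k = 5). Ties break toward larger
`alpha`, then larger `beta` — when the data cannot distinguish weightings,
prefer the cheaper, better-calibrated feature model. Because the grid
contains the corners (1,0), (0,1), (0,0), the tuned combination can never
score below the best individual model on the tuning folds; the paired,
exact sign-flip permutation test over fold F-scores (all `2^k`
enumerations) quantifies whether the gain is distinguishable from noise.

Post-processing only ever adds relations. Causal rules fire on
co-sentential pairs not already predicted: a trigger stem among
*related/caused/associated/induced* strictly between a chemical followed
by a disease; *during* between a disease followed by a chemical; or
chemical-disease adjacency with at most one intervening hyphen-like token
(unconstrained adjacency would fire on nearly every ordered pair).
Focused-chemical rules apply only to documents with no predicted relation:
title chemicals pair with every disease concept; failing a title chemical,
the most frequently mentioned chemical (ties to first occurrence) does.
Both rule families can raise recall and can cost precision; the tests
assert only the guaranteed direction (predicted set and recall never
shrink).

Error analysis partitions false positives by priority — missing gold
entity, then rule-introduced, then misclassification — and false negatives
by missing system entity, then no co-sentential candidate (cross-sentence),
then misclassification, with shares rounded to two decimals. The priority
order is this package's disambiguation of overlapping causes.

## The synthetic corpus generator

`generate_corpus()` emulates the full input contract — PubTator text with
exact offsets, dependency blocks, bracketed trees, document-level gold
relations — from nine sentence templates that carry their own hand-coded
parses: five positive causal patterns (trigger verbs in both entity
orders, entity adjacency, a one-chemical/three-disease enumeration) and
three negative co-occurrence patterns, with dependency paths of 2-6 nodes
and off-path dependents for the extended-SDF case. Entity slots are filled
from small chemical/disease lexicons (some multiword, spliced in with
noun-compound arcs so head finding is exercised); entities never repeat
within a document, so at `label_noise = 0` the distant-supervision
projection is exact. Documents default to 2-4 sentences (the first is the
title, so focused-chemical rules are exercised). `label_noise` flips the
document-level relation of a candidate pair, mimicking
distant-supervision noise rather than token-level corruption. Everything
is deterministic given the seed, and generated files are read back through
the package's own readers, re-validating every offset.

What passing on this generator shows — and what it does not: the corpus
has parser-perfect trees, a closed vocabulary, short sentences and
perfectly regular trigger patterns, so near-perfect F on noise-free
fixtures demonstrates that the machinery (views, kernels, optimization,
combination, rules, evaluation) is correct, not that comparable accuracy
is attainable on real abstracts with noisy parses, unseen vocabulary and
genuinely ambiguous language. Reported corpus-scale numbers from real data
are far below 1 for exactly those reasons.

## Problem sizes and numerical choices

The test suite and the acceptance script run the end-to-end experiment on
200 generated documents (120 train / 80 test; grid search 5-fold on the
training documents) with `d = 24`, `H = 16`, 40 epochs, learning rate 0.2,
batch 8 — sizes chosen so the closed template vocabulary is comfortably
covered and a full run stays in the minutes range on one CPU; the
reference defaults (`d = 200`, `H = 100`, lr 0.01) remain in
`cdr_config()` for realistic vocabularies. Other numerics: kernel Gram
PSD tolerance 1e-8; SMO tolerance 1e-3; sigmoid applied without
temperature; grid ties resolved as above; degenerate candidates (identical
entity heads) are skipped with an error at view construction; empty
documents and empty prediction sets follow the P = 0 / F = 0 conventions.

## Known limitations

Cross-sentence relations are unreachable by design. The mention-pair
labels inherit distant-supervision noise on real corpora. The tree-kernel
Gram is quadratic in the number of candidates, which is fine at corpus
scale here but the dominant cost as corpora grow; caching and the
composite weights are the available levers. The CNN baseline and the ST
kernel variant exist for comparison, not as tuned alternatives. Rule
triggers are a fixed stem list; no attempt is made to learn rule weights
or filter by MeSH hierarchy.
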