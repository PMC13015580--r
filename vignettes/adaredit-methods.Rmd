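---
title: "Predicting A-to-I editability from dsRNA structure graphs: models and methods"
author: "adaredit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting A-to-I editability from dsRNA structure graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ADAR enzymes deaminate adenosines inside double-stranded RNA, and whether a
particular adenosine is edited depends jointly on its local sequence context
(most famously, a 5' guanosine suppresses editing and a 5' uridine favours
it) and on the geometry and stability of the duplex around it (the target
adenosine is often presented in or next to a mismatch or loop). `adaredit`
predicts per-adenosine editability from exactly these two inputs: the duplex
sequence and its predicted minimum-free-energy secondary structure in
dot-bracket notation. The package does not fold RNA; it consumes dot-bracket
strings as produced by standard thermodynamic folding tools (an optional
`foldWithExternalTool()` hook is provided for convenience and never required).

Every example is one candidate adenosine inside one duplex, encoded as a
*position-centric graph*: nucleotides are nodes, and directed edges encode
both backbone adjacency and base pairing. Two candidates in the same duplex
share the topology but differ in a target flag and in signed relative-distance
features, which makes the examples distinct without leaking labels between
them.

## Models

Two architectures are implemented on a small reverse-mode automatic
differentiation engine written for this package (`R/autodiff.R`); gradient
correctness is pinned by finite-difference checks in the test suite rather
than assumed.

**Baseline.** Nodes carry 8 features: a one-hot base identity over
`A, C, G, U, N`, a binary pairing flag, the signed relative distance
`(i - target)/L`, and the target indicator. Three stacked graph-attention
layers (4 heads each; attention followed by ReLU, batch normalization and
dropout 0.2) perform message passing over backbone and pair edges plus
self-loops (added for attention stability); global mean pooling and a single
fully connected layer with a sigmoid produce the editing probability.

**Bio-aware.** Node features grow to 22 (5' and 3' neighbor one-hots,
stem length, loop length, distance to the nearest stem-loop junction, and a
pairing-energy estimate). Edges are typed (backbone, Watson-Crick pair,
wobble pair, self-loop); each type has a learned 6-dimensional embedding that
is concatenated with 10 scalar attributes and passed through a small MLP to a
16-dimensional edge representation that feeds the attention logits of all
three layers (configurable down to the first layer only — the architecture
description leaves this open, and feeding all layers is the more natural
reading of a single edge representation serving "the GAT layers"). A parallel
convolutional branch over the tokenized sequence (3-mer and 5-mer filters, 48
channels each, masked max-pooling, projection to 48 dimensions) captures
motifs independently of the graph, and an optional 4-head global attention
pooling over the post-GAT node embeddings adds a long-range context vector.
Pooled graph embedding, sequence embedding and (optionally) the context
vector are concatenated into a two-layer MLP head.

Widths the architecture description does not fix are set once: hidden width
64 (16 per head), fusion hidden width 64. Optimization is Adam
(learning rate 3e-3, weight decay 1e-5), binary cross-entropy loss,
minibatches of 8 graphs. The small batches and the relatively high learning
rate are deliberate: separating a 5' neighbor from a 3' neighbor requires the
attention logits to amplify a relative-distance gap of only 2/L, and that
amplification grows multiplicatively with optimizer steps. With conservative
settings (for example batch 32 at rate 1e-3) the model converges to a
direction-blind plateau and stays there for a hundred epochs; with the
package defaults it crosses the plateau in a few dozen epochs on the bundled
synthetic conditions. Batch normalization uses running statistics in
evaluation mode, so scoring is deterministic for fixed weights; all training
randomness (shuffles, dropout) is seeded from the model configuration.

## Pairing energies

The published description estimates pairing energy "from nearest-neighbor
thermodynamics" without giving numbers. The package uses a documented
constant table — G:C = −3, A:U = −2, G:U = −1, all else 0 (arbitrary units)
— and scales by 1/3 so features lie in [−1, 0]. Only the stability *ordering*
matters to a learner, and a fixed table keeps tests exact. Length-like
features (stem length, loop length, junction distance) are clipped at 50 nt
and scaled to [0, 1]: unbounded raw lengths destabilize attention logits.

## Threshold search and evaluation

After every epoch the model is scored on the held-out validation set over a
fixed grid of 33 thresholds from 0.10 to 0.90 (step 0.025), computing
accuracy, F1, precision, recall and specificity with the rule *positive iff
score ≥ threshold* (ties at the threshold count as positive; zero-denominator
ratios are reported as 0 so the scan is total). The returned checkpoint is
the (epoch, threshold) pair with maximal F1, earliest epoch then lowest
threshold on ties. Because that operating point is tuned on the validation
split, the package prints with every training run that these are validation
estimates, not unbiased test performance. Threshold-free AUROC (tie-corrected
Mann-Whitney) and AUPRC (step-wise precision-recall integration) are computed
alongside; the AUROC implementation is cross-checked against an independent
library in the test suite.

## Interpretability

Edge-level attention coefficients of the first layer (head-averaged,
self-loops excluded) are aggregated per position as the maximum coefficient
over incoming edges, within ±50 nt of the target (zero-padded outside the
sequence; "incident" means incoming because attention normalizes over
incoming neighbors — a flag includes outgoing edges). These 101 positional
features train a gradient-boosted tree classifier (xgboost, depth 4, 300
rounds, learning rate 0.1) on a fresh 80:20 split, as a supervised check that
attention alone carries signal; exact tree-Shapley attributions rank the
offsets, and the classifier is refit on the top 20. The attention classifier
is deliberately fit on the model's validation split, not its training split,
so the explanation is not contaminated by memorized training examples.

## In silico mutagenesis

Four perturbation analyses probe a trained model on high-confidence edited
sites (true edited labels with prediction strictly above 0.7):

* **Sequence-only mutagenesis** substitutes each base at offsets −3..+3
  (offset 0 excluded — only adenosine is biologically relevant there), leaving
  all pairing features and edges untouched, and records the mean change in
  prediction, position-mean-centred.
* **Structure-coupled mutagenesis** additionally disrupts the pair at the
  mutated position when the mutant base is no longer Watson-Crick/wobble
  valid: both endpoints' pairing flags drop to 0, both directed pair edges are
  removed, and pair energies are zeroed; a still-valid mutant keeps the pair,
  retyped with refreshed energy.
* **Positional perturbation** compares, for each offset in −40..+40, the
  prediction with the pair retained versus removed (paired minus unpaired),
  averaged over sites where that position is natively paired. Natively
  unpaired positions are skipped: forcing a pair would require inventing a
  partner the structure does not define.
* **Pair-interaction scans** at offsets −1, 0, +1 set the sequence-side base
  and its structural partner to all 16 combinations, keeping or disrupting
  the pair by validity, and report the mean prediction per combination.

All edits are local by default: stem/loop/junction annotations are *not*
recomputed after an edit, matching the perturbations' definition as local
graph edits (removal of one pairing edge). Full re-annotation of the mutated
structure is available via `reannotate = TRUE` for users who prefer
globally consistent features; whether the original analyses rescored with
re-annotated features is not documented, so the local edit — the minimal
intervention — is the default. Perturbations always operate on copies; the
purity of inputs is asserted by tests.

## The synthetic-data generator

`syntheticConfig()` defines the package's study conditions. A duplex is
generated as a left arm, a 4-8 nt hairpin linker, and an imperfect reverse
complement of the arm, with three kinds of imperfection: per-position
mismatches (10%) that survive as pairs only when the mutated base still forms
a Watson-Crick or wobble pair; symmetric internal loops (3% start rate,
2-5 nt) whose strands stay complementary but unpaired (so complementarity
does not imply pairing); and asymmetric bulges (8% start rate, 1-3 nt on one
strand) that shift the pairing register, making the partner geometry
duplex-specific rather than a fixed mirror — without them, pairing would be
recoverable from sequence positions alone and structure ablations would be
meaningless. The dot-bracket is constructed jointly with the sequence, so it
always parses and the pair table is an involution by construction — no
folding is involved.

Editing levels follow a logistic link over planted rules whose signs mirror
known ADAR biochemistry:

```
score = w0 + 5·[target unpaired] + 1·[5' base is U] − 2·[5' base is G]
           + 1·[3' base is G] + Normal(0, 0.5)
level = logistic(score)
```

with log-normal read coverage (median 200), `w0 = −3`, and base composition
A 22%, C 18%, G 32%, U 28%. The composition is part of the study design: U is
abundant so that the paired-5'U pocket described below is well populated, and
G is abundant so that the guanosine-context site population — where the
suppression rule acts and where structure, not sequence, decides the label —
is large enough to carry the structure-ablation and the mechanism analyses
(for a 5'G adenosine, pairing alone separates non-edited from edited, and for
frayed, looped or bulged positions that pairing status is invisible to
sequence inspection). Two constraints
pin the intercept and the unpaired weight. First, the deterministic rule span
must straddle both class cutoffs (non-edited: level < 1% ⇔ score < −4.6;
edited: level ≥ 15% ⇔ score ≥ −1.73) so that both classes occur at workable
rates (roughly 30% of adenosines per class under the defaults, with the
1-15% band excluded as in the real labeling rule). Second — and less
obviously — the exclusion band spans 2.87 logits, so a structural effect
smaller than that can never flip a site deterministically from one class to
the other; editability would then be almost fully recoverable from sequence
context alone, the pairing flag would be decorative, and any
structure-ablation experiment would be vacuous. The unpaired weight of 5
exceeds the gap, making pairing status a genuine label driver: for central
sequence contexts, the same adenosine is non-edited when paired and edited
when unpaired. The intercept also leaves one deliberately edited pocket among
paired adenosines — a 5' U can carry a paired site over the editing cutoff,
while the mirrored context (3' U) almost never stays in the labeled set — so
a small population of paired high-confidence edited targets exists for the
offset-0 paired-versus-unpaired perturbation, and mutating their 5' U to a G
demotes them sharply, giving the 5' G rule leverage on paired contexts
rather than being absorbed entirely by the pairing flag. Mismatch and fray
rates (6% and 18%) split the unpaired mass so that most of it is invisible
to sequence inspection: frayed, looped and bulged positions keep perfect
complementarity. Because frayed, looped and bulged positions keep perfect
strand complementarity, their pairing status cannot be reconstructed from
the sequence — exactly the property the structure-shuffle ablation measures.

Default duplex length is 40-70 nt. Two considerations fix this: the baseline
architecture ends in global mean pooling, so the target-local signal a single
node carries is diluted proportionally to 1/L, and single-CPU training cost
grows linearly with L. At 40-70 nt the planted rules are comfortably
recoverable within a 100-epoch budget on one CPU; at several hundred
nucleotides (the scale of real inverted-repeat duplexes) recovery needs far
longer training than a desk-scale test suite should spend. This is the main
respect in which the generator under-represents real data, along with: no
biased repeat-derived sequence composition, a single hairpin per duplex
rather than long multi-loop architectures, no coverage-level correlation
between neighbouring sites, and labels generated by a known rule rather than
by an enzyme. Passing the planted-rule tests therefore shows that the
pipeline can learn and explain rules of the planted kind from data of this
shape — it does not certify performance on biological data.

## Numerical choices and degenerate inputs

* Coordinates are 1-based throughout the R interface (positions in editing
  tables, target indices, pair tables), the R convention.
* DNA `T` maps silently to `U`; other foreign characters map to `N` with a
  warning; any pairing involving `N` is invalid and `N` never matches a rule.
* Pseudoknot dot-bracket dialects are rejected with an error, never silently
  dropped: nested MFE structures are the package's domain.
* A structure that pairs two bases failing Watson-Crick/wobble validity (rare
  but possible in MFE output) is kept, typed `WC_PAIR` with energy 0, and
  reported via a message — structure fidelity wins over rule purity.
* "Within 20 bases" for proximity negatives is inclusive (≤ 20); the
  densest-segment "segment" is a fixed-length sliding window (default 400 nt)
  with leftmost tie-breaking; clusters merge at gaps ≤ 1,000 bp.
* Class balancing downsamples the majority class only and precedes the 80:20
  split; validation keys overlapping training keys are removed before any
  evaluation.
* The decision rule is `score >= threshold`; metric denominators of zero
  yield 0.
* Batch normalization uses batch statistics in training and running
  statistics in evaluation; all reported scores come from evaluation mode.
* Training has no early stopping; the epoch budget is explicit
  (`modelConfig(epochs = ...)`, default 200). The bundled experiments in
  `scripts/acceptance.R` use 60 epochs for the recovery run and 30 for the
  ablation pair at reduced n — the sizes at which the planted rules are
  comfortably recovered on a single CPU.

## Known limitations

* MFE dot-bracket input only: no base-pair probability matrices, no
  ensembles, no tertiary structure, no pseudoknots.
* The graph edit model for perturbations is local; energies of neighbouring
  stacks are not re-estimated after an edit unless `reannotate = TRUE`.
* The synthetic generator is a rule-planting device, not an Alu emulator (see
  above).
* Attention weights, Shapley values and mutagenesis deltas are
  hypothesis-generating consistency checks, not causal mechanism claims.
* No pretrained weights ship with the package; models are trained from
  user-provided or generated data.
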