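---
title: "Predicting HLA class I presentation from MS elution data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting HLA class I presentation from MS elution data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hlapresent)
```

## The model and its assumptions

HLA class I molecules present 8–11mer peptides from intracellular
proteins; this length window covers ~95% of class I ligands, which is why
the package rejects anything outside it rather than padding or trimming.
The positive class is defined operationally: a peptide is "presented" if
it was eluted from HLA complexes and identified by LC-MS/MS. The negative
class is proteome-derived decoys never observed by MS. Two assumptions
follow and both matter for interpretation:

1. *MS visibility stands in for presentation.* Peptides that are
   presented but poorly ionized or below detection limits are mislabeled
   negative. The classifier therefore estimates "presented **and**
   detectable", and reported sensitivities are optimistic for the
   hard-to-detect fraction.
2. *Unobserved means negative.* Decoys are drawn from source proteins of
   observed hits, so expression of the source protein is controlled, but
   some decoys will be genuine ligands. At a ~1–2% prior this mislabeling
   is small relative to the 99:1 decoy excess in benchmarks.

The classifier itself is a small inception-style CNN, one model per
allele (the per-allele corpus sizes in `training_summary()` justify
allele-specific rather than pan-allele fitting at this data scale). The
11 × 21 one-hot input is read by three parallel branches of eight 2-D
kernels spanning 2, 3 and 4 consecutive positions and the full 21-symbol
axis, so each branch computes position-localized k-mer features; outputs
pass through Leaky ReLU, are flattened and concatenated (216 features),
then a 100-unit dense layer with inverted dropout feeds a 2-node softmax.
Because the kernels span the whole residue axis, the convolution reduces
to one matrix product per branch after an im2col expansion — fast enough
in plain vectorized R that no deep-learning framework is required, which
also makes seeded runs bit-reproducible on one device (single-threaded R
has no nondeterministic kernels; this would not hold on GPU backends).

## Encoding conventions

Columns 1–20 follow the fixed residue order `ACDEFGHIKLMNPQRSTVWY`;
column 21 is the pad `Z`. Padding is a suffix: rows beyond the peptide
length are one-hot `Z`. Suffix padding keeps the P2 anchor on a fixed
input row for every length, at the cost of moving the C-terminal anchor
row with length — which the multi-height branches are positioned to
absorb. Input is upper-cased before validation since FASTA sources vary.
Decoding is strict: any row not summing to one, or a pad row followed by
a residue row, is a malformed-matrix error rather than a silent guess.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `under`, `over` (sampling plan) | per allele | fraction / factor | corpus-specific imbalance correction; the packaged table lists values from 0.6–1 and 2–5 across 20 alleles |
| `validation_fraction` | 0.1 | fraction of non-test | early stopping needs a nontrivial held-out set; the corpus summaries give no validation size, so this is a package choice |
| `branch_kernel_heights` | 2, 3, 4 | peptide positions | multi-scale reading of 2-/3-/4-residue windows; the published architecture diagram is not recoverable, so heights are declared and configurable |
| `kernels_per_branch` | 8 | — | stated architecture value |
| `dense_units` | 100 | — | stated architecture value |
| `leaky_relu_alpha` | 0.2 | — | stated activation slope |
| `dropout_rate` | 0.4 | probability | unstated in the source; chosen as a conventional strong rate for a 100-unit layer, configurable |
| `batch_size` / `max_epochs` / `early_stopping_patience` | 128 / 200 / 10 | — | unstated; conventional values, all configurable; tests and examples reduce `max_epochs` and say so |
| Adam `learning_rate`, `beta1`, `beta2`, `epsilon` | 1e-3, 0.9, 0.999, 1e-8 | — | "standard parameters": the optimizer's canonical defaults; no schedule |
| decision `threshold` | 0.5 | probability | symmetric default on the positive-class probability; benchmarking can use percentile ranks instead for parity with external predictors |
| rank threshold | 2.0 | percentile | the conventional "top 2%" binder rule |
| `decoys_per_hit` | 99 | — | matches a ~1–2% binder prior among random fragments |
| `pseudocount` (motifs) | 0 | counts | motifs are descriptive here; smoothing only matters for log-odds use, where a pseudocount of 1 is exposed |

## Numerical and procedural choices

- **Under-sampling rounding**: `floor(under × N)` negatives, drawn
  uniformly without replacement under the seed. Floor (not round) keeps
  the count conservative and matches integer expectations in the
  packaged table.
- **Rebalancing scope**: applied to the training partition only.
  Rebalancing evaluation data would bias PPV, whose denominator depends
  on the class mix.
- **Replica bookkeeping**: over-sampled positives carry a replica index,
  and partitioning groups replicas, so "disjoint partitions" remains
  well defined after duplication.
- **Stratified splitting**: largest-remainder allocation per label
  stratum; every partition's class balance is within one record of the
  global balance, and the test partition size is exact.
- **99-decoy allocation**: 99 is not divisible by 4; the remainder goes
  to the shorter lengths, leaving the deficit on length 11
  (25/25/25/24), 11-mers being the rarest class in elution data. The
  rule is deterministic and configurable via `decoys_per_hit`.
- **Duplicate decoys**: sequence-identical decoys sampled from different
  proteins (or different hits) keep their first occurrence in seeded
  order; later ones are dropped.
- **Candidate windows**: the sliding enumeration runs from "mutation at
  the last position" to "mutation at the first position". Each length L
  gets a mutation-centered context of 2L−1 residues, so an interior
  mutation yields exactly L windows per length (38 over lengths 8–11).
  A fixed 17-mer context — the 9-mer illustration — cannot contain 10
  ten-mers or 11 eleven-mers spanning its center, which is why the
  per-length context is the default; `sliding_windows()` on a fixed
  context enumerates only the windows that truly fit. Mutations within
  L−1 residues of a terminus are clipped, never padded: padding would
  fabricate sequence.
- **Candidates identical to self-peptides elsewhere in the proteome**
  are not filtered (no self-peptide filter is part of the procedure);
  flagging is left to downstream analysis.
- **Metric degeneracies**: a zero denominator (e.g. PPV with no positive
  calls) returns `NA`, never a silent 0.
- **Percentile ranks**: `100 × (1 + #{background strictly above}) / (1 +
  B)`; the +1 smoothing keeps ranks in (0, 100] and makes a
  better-than-all-background query rank `100/(B+1)` rather than 0.
- **Anchor statistic**: Shannon information content against a uniform
  background, `IC(i) = log2(20) + Σ f log2 f`; published motif figures
  name no statistic, and IC is the standard logo height. Ties break
  toward the smaller position.
- **Property classes**: acidic {D,E}; basic {K,R,H}; hydrophobic
  {A,V,L,I,M,F,W,C}; polar {S,T,N,Q,Y}; neutral {G,P}. No published
  class list was recoverable; this conventional assignment is exported
  and overrideable.
- **Overlap rate**: Jaccard by default, overlap-over-smaller-set behind
  a flag; the published figure does not say which was used.
- **Motifs from data vs attributions**: per-allele motifs are computed
  from MS-positive peptides (the unambiguous reading); gradient-based
  input saliency of a trained model is exposed separately
  (`input_saliency()`) for the attribution reading.

## What the synthetic generators emulate — and what they do not

`synthetic_allele_spec()` states a generative world: a length
distribution over 8–11, anchor rules (position, allowed residues,
adherence probability), a background residue distribution, and an exact
imbalance ratio. The default mirrors an A*02:01-like motif — leucine at
P2 and valine/leucine at the C-terminus, adherence 0.9 — at the global
39:1 decoy:hit ratio of real corpora. The background is uniform over the
20 residues because uniformity gives clean analytic expectations for the
motif tests (every non-anchor cell is exactly 1/20); a proteome-like
frequency vector can be supplied instead.

Emulated: anchored positives, proteome-like negatives, severe class
imbalance, length mixture, seeded determinism, and (in `exclusive` mode)
constructed separability for classifier-recovery tests. Not emulated: MS
acquisition bias, residue-correlation structure of real proteins,
allele-specific length preferences beyond the stated weights, and any
binding-affinity gradient among negatives. A green recovery test
therefore establishes that the training machinery can find a planted
presentation motif under realistic imbalance — not that the model
matches any particular predictor's accuracy on real immunopeptidomes.

The classifier recovery criterion trains on the default world (2,000
positives, 39:1) with a reduced, pre-registered epoch budget
(`max_epochs = 12`, patience 3) to fit a CPU test budget; the
label-permutation null permutes the raw partition labels *before*
rebalancing, then applies the identical procedure. Permuting after
duplication would apply five gradient copies of mostly-negative labels
to every formerly-positive peptide and manufacture anti-signal — a
subtle way a "null" can leave chance level without any real effect.

## Known limitations

- Presentation ≠ immunogenicity: no T-cell-recognition modeling; many
  presented candidates will not elicit CD8+ responses.
- One model per allele: no pan-allele transfer to alleles without
  training data, and no multi-allelic deconvolution.
- No binding-affinity (IC50) regression; the output is a presentation
  probability.
- The external predictor is consumed as a rank/score table and never
  invoked; ensemble results inherit whatever biases that table carries.
- Training at the full published corpus scale (~1.9M peptides) is out of
  scope for the pure-R trainer; it is sized for the 10^4–10^5-row
  regime of per-allele desk experiments.
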