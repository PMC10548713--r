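---
title: "Predicting arginine methylation sites from sequence: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting arginine methylation sites from sequence: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylarg)
```

## The problem

Arginine methylation is a reversible post-translational modification in
which protein arginine methyltransferases transfer one or two methyl
groups onto the guanidino nitrogen of an arginine side chain. It regulates
transcription, RNA processing, signal transduction and DNA repair, and it
concentrates in glycine/arginine-rich regions. Experimental mapping of
methylation sites (mass spectrometry, methylation-specific antibodies) is
slow and expensive, so sequence-based classifiers are used to prioritize
candidate sites.

`methylarg` implements a sequence-only predictor. It deliberately avoids
evolutionary profiles, predicted structure and disorder — information that
is not always available and that depends on third-party software — and
works from the primary sequence alone.

## The peptide-window model

The unit of classification is an 11-residue peptide window centered on a
candidate arginine,

$$P_\gamma(R) = P_{-\gamma}\dots P_{-1}\,R\,P_{1}\dots P_{\gamma},
\qquad \gamma = 5,$$

labeled positive when the central R is a methylation site and negative
otherwise. The benchmark dataset is the union of the positive and negative
window sets. `gamma` is a parameter throughout (window length
$2\gamma+1$); 5 is the default.

Two boundary conventions are our own, because the window scheme alone does
not determine them:

* **Terminal windows.** An annotated site closer than $\gamma$ residues to
  a terminus is padded with the inert character `X` rather than discarded,
  preserving both the fixed dimensionality and the annotation. `X`
  contributes to no feature numerator; composition denominators keep the
  full window length, so padded windows have sub-normalized compositions.
* **Duplicate windows.** A negative window whose residue string equals any
  positive window's is dropped (a label contradiction); duplicate
  negatives are otherwise retained, so the negative pool is not silently
  shrunk.

Ambiguity codes B/Z/U/O are normalized to `X` on ingest with a warning:
the encoders define behavior only for the 20 standard residues. Input
FASTA is assumed pre-deduplicated; redundancy clustering (e.g. at 90%
identity) is out of scope and should be done upstream.

## The 434-dimensional feature vector

Each window maps to 434 named features in a fixed layout:

| block | width | positions | content |
|-------|------:|-----------|---------|
| AAC   | 20    | 1–20      | amino-acid composition $A_i = N_i / l$ |
| DPC   | 400   | 21–420    | dipeptide composition $D_i = n_i / l$ |
| ITB   | 4     | 421–424   | Shannon, Havrda–Charvát, Rényi, Arimoto entropy |
| PP    | 10    | 425–434   | ProtParam-style physicochemical descriptors |

Points where the definitions required a decision:

* **DPC denominator.** The dipeptide frequency is defined with the window
  length $l$ in the denominator even though only $l-1$ adjacent pairs
  exist, so the 400 entries of a pad-free window sum to $(l-1)/l$, not 1.
  We implement this definition exactly; a `dpc_denominator = "l-1"` switch
  is available for sensitivity checks but is not the default.
* **Entropy family.** For a window composition $p_1,\dots,p_{20}$ (with
  $0 \log 0 := 0$ and all logarithms base 2):
  $SE = -\sum_i p_i \log_2 p_i$;
  $HE = (2^{1-\alpha}-1)^{-1}\left[\sum_i p_i^\alpha - 1\right]$;
  $RE = (1-\alpha)^{-1}\log_2 \sum_i p_i^\alpha$;
  $AE = (2^{\alpha-1}-1)^{-1}\left[\left(\sum_i p_i^{1/\alpha}\right)^{\alpha}-1\right]$.
  The relative forms against a uniform background $p_0 = 1/20$, and the
  information gain $SE - \text{relative } SE$, are computed by
  `entropy_block()` and can be appended as extra columns
  (`itb_extended = TRUE`), but the standard vector carries exactly the
  four base entropies — the 4-entry block fixes the layout.
* **Entropy order.** $\alpha$ must satisfy $\alpha > 0,\ \alpha \ne 1$
  but its value is otherwise free. We pin $\alpha = 2$ (the collision
  entropy), record it in every saved model's metadata, and expose it as a
  parameter. The three generalized entropies converge to $SE$ as
  $\alpha \to 1$ for any *normalized* profile; for padded (sub-normalized)
  profiles the $\alpha \to 1$ limit diverges, which is why the continuity
  property is checked on pad-free windows only.
* **The 10-entry physicochemical block.** Nine properties are named by the
  ProtParam convention: isoelectric point, extinction coefficient,
  instability index, molecular weight, aromaticity, helix/turn/sheet
  fractions, and GRAVY. We obtain ten entries by reporting the extinction
  coefficient twice — reduced (no cystines) and oxidized (every cysteine
  pair forms a cystine, $n = \lfloor \#C/2 \rfloor$) — matching how
  ProtParam reports "extinction coefficients" in the plural. This reading
  is an interpretation and is flagged as such.
* **Physicochemical conventions.** All PP descriptors operate on the
  de-padded residue string and never consult `X`. Molecular weight is the
  sum of Expasy average residue masses plus one water. GRAVY uses the
  Kyte–Doolittle scale. The instability index is
  $\frac{10}{L}\sum_{i=1}^{L-1}\mathrm{DIWV}(A_iA_{i+1})$ over the
  bundled Guruprasad 400-entry weight table, with the conventional
  "unstable above 40" flag. The isoelectric point is found by bisecting
  the Henderson–Hasselbalch net charge over pH $\in [0, 14]$ with the
  EMBOSS pKa set (free termini included), stopping at $|Q| < 10^{-4}$ or
  a bracket narrower than 0.01 pH units. Secondary-structure fractions
  use the residue classes helix {V,I,Y,F,W,L}, turn {N,G,P,S}, sheet
  {E,M,A,L}. All constant tables ship as plain-text TSVs under
  `inst/extdata/` with cited provenance.

```{r encode}
v <- encode_window("GGGGGRGGGGG")
length(v)
round(v[c("AAC_G", "DPC_GG", "ITB_SE", "PP_GRAVY", "PP_II")], 4)
```

## Classifiers and tuning

The random forest is the default classifier, shipped with the tuned
hyperparameters: 250 trees, maximum depth 40, `log2` feature subsampling,
minimum node size to split of 3, bootstrap samples the size of the
training set. These names follow the scikit-learn convention and map onto
ranger as `num.trees`, `max.depth`, `mtry = floor(log2(p))`,
`min.node.size`, and `sample.fraction` with replacement. The forest itself
is a contract — bagged randomized trees, seedable, probability output —
satisfied by a vetted library rather than re-derived; the contribution
here is the feature system and the evaluation protocols.

`grid_search()` ships the tuning grids used to select those values: 11
tree counts $\{10, 50, 100, \dots, 500\}$ and 10 depths
$\{10, 20, \dots, 100\}$, scored by mean accuracy over a single stratified
cross-validation (the scoring metric and the non-nested structure are our
choices; ties go to the earliest-listed candidate). Four baseline
algorithms — decision tree, SVM, k-nearest neighbors (k = 5), naive
Bayes — are registered with library defaults for comparison runs; SVM
probability output is enabled so every algorithm feeds the same ROC
machinery.

## Evaluation protocols

Threshold metrics (accuracy, sensitivity, specificity, precision, F1,
MCC) are computed from the confusion counts at a 0.5 probability
threshold (configurable). A metric with a zero denominator is reported as
0 and flagged in a `degenerate` attribute rather than as `NaN`.

* **Stratified 10-fold CV** partitions each class round-robin after a
  seeded shuffle, keeping the class ratio within one sample per fold.
  Metrics are computed per fold and averaged — matching "the average of
  the ten models" — with a pooled-confusion mode behind a flag, since
  either aggregation is defensible.
* **Repeated CV** runs `repeats` independent stratified shufflings;
  repeat $r$ (0-indexed) uses seed $\text{seed} + r$, so a single repeat
  reproduces `kfold_cv()` exactly. Reported as mean ± sd per metric.
* **Imbalance protocol**: stratified 70/30 split, random under-sampling
  of the *training* portion only, test portion keeps its natural
  imbalance; reported with the precision–recall curve, whose baseline is
  the positive prevalence.
* **ROC/PR curves** sweep thresholds over the unique scores with ties
  grouped; AUC is the trapezoidal area and equals the Mann–Whitney
  pairwise statistic, which the tests verify exactly.
* **Feature ablation** re-encodes the windows with each of the 11
  default block combinations (each single block, the informative pairs
  and triples, and all four) and runs one CV per combination.

## Shapley-value explanation

No installed R package provides Shapley attributions for arbitrary
models, so the estimator is implemented here: a seeded
permutation-sampling estimator against a background set (a seeded
subsample of the training matrix, default at most 100 rows). For each
explained sample, background row and feature permutation, features flip
from background to sample value in permutation order and the output
change is credited to the flipped feature. Because every chain telescopes
from $f(b)$ to $f(x)$, the estimator satisfies local accuracy *exactly*
(up to floating point): base value plus attribution sum equals the model
output for every sample, at any number of permutations. Features equal in
sample and background are skipped — their flip cannot change the output —
which makes the estimator fast on the mostly-zero dipeptide block.
Attributions target the positive-class probability (not log-odds), which
is recorded in the output metadata. Permutation count trades variance for
time (default 4); the local-accuracy guarantee is unaffected.

`rank_features()` orders features by mean absolute attribution (ties
broken alphabetically) and tallies the top-k by block; `summary_table()`
and `autoplot()` reproduce beeswarm/bar summaries from plot-ready data.

## The synthetic benchmark generator

Real methylation benchmarks derive from curated databases and cannot be
shipped. The generator emulates their *structure*: R-centered windows of
length $2\gamma+1$, balanced or imbalanced classes (the imbalanced regime
defaults to 27 negatives per positive, the mono-methylarginine ratio),
and protein-level data in which only a fraction of arginines is
annotated. Positives carry a compositional signal chosen to mirror what
the predictor is expected to find in real data — glycine enrichment and
RG/GR adjacency around methylated arginines: with probability
`signal_strength` each flank adjacent to the central R is forced to `G`,
and each remaining flank is drawn from a G-enriched distribution (G
probability 0.3) instead of the uniform background. At
`signal_strength = 0` positives and negatives are exchangeable, giving a
null calibration.

Because the entropies are deterministic functions of composition, the
entropy-only model is *not* blind to this signal (G-enrichment lowers
window entropy); the ordering the ablation protocol relies on is that the
full feature set dominates the entropy-only block, which holds.

What the generator does **not** emulate: evolutionary conservation,
actual methyltransferase motif biology beyond the compositional proxy,
realistic proteome length distributions, or sequence redundancy. Passing
tests on synthetic data therefore demonstrate that the pipeline recovers
a planted compositional signal and that its protocols are implemented
correctly — not that the shipped defaults reach any particular accuracy
on real proteomes.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to exercise every code path at
desk scale: the planted-signal study runs 400 windows (200 per class,
strength 0.8, generator seed 42) through 10-fold CV, the null calibration
repeats it at strength 0, attribution audits explain 50–60 samples
against a 100-row background with 4 permutations, and the equation
oracles check 1000 random windows at $10^{-9}$ and 100 random confusion
matrices at $10^{-12}$. Repeated-CV stability is demonstrated with 3
repeats on 200 windows; the full 50-repeat protocol is available through
the same function. Degenerate inputs are defined, not fatal: windows with
fewer than 2 non-pad residues are rejected by the physicochemical block
with a clear error, zero-denominator metrics return flagged zeros, and
single-class inputs fail fast.

## Known limitations

* The two-extinction-coefficient reading of the 10-entry block is an
  interpretation; if the original block used a different tenth property,
  absolute feature indices 425–434 differ while the other 424 agree.
* The entropy order $\alpha$, the pKa set, and per-window pI on an
  11-mer (free termini assumed) are pinned, documented choices rather
  than community standards for this task.
* Shapley attributions for strongly correlated features (AAC_G vs
  DPC_GG) split credit between them; rankings should be read at block
  level when features are collinear.
* The predictor is trained and validated here on synthetic data only;
  applying it to real proteomes requires user-supplied annotated
  sequences and ideally upstream redundancy removal.
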