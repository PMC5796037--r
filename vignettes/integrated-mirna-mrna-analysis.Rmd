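---
title: "Methods: integrated miRNA–mRNA analysis with target-site consensus"
author: "mirpair authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA–mRNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpair)
```

## Overview and model

`mirpair` integrates three orthogonal lines of evidence to call regulatory
miRNA→mRNA pairs in tumor/normal cohorts. The underlying biological model is
miRNA-mediated repression: a miRNA loaded into the silencing complex pairs
with sites in a target's 3′UTR, lowering the target's steady-state
abundance. In expression data this predicts (i) opposite dysregulation of
the partners between tumor and normal, (ii) negative correlation of their
expression across matched samples, and (iii) a sequence-predictable binding
site. Each prediction is tested by a separate module, and only pairs passing
all of them are reported.

### Differential expression

Expression values are assumed to be on the log2 scale (normalized array
intensities or log-transformed sequencing summaries; the reader accepts any
log2 matrix and makes no distributional distinction between platforms).
Per feature, the log2 fold change is the difference of group means
(tumor − normal) and significance is a two-sample Student *t*-test with
pooled variance on `n₁ + n₂ − 2` degrees of freedom; Welch's unequal-variance
form is available behind `equal_variance = FALSE` for heteroscedastic
cohorts. Degenerate features (zero within-group variance) resolve by
convention: *t* = 0, *p* = 1 when the means agree, the *p* → 0 limit
(flagged) when they differ.

Calling uses raw *p* < α with class-specific fold-change cutoffs, strict in
both cases:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | per-feature significance level (raw *p*) |
| `lfc_mrna` | 1.0 | \|log2FC\| must exceed this for mRNA calls (2-fold) |
| `lfc_mirna` | 0.0 | miRNA calling is significance-driven (any nonzero shift) |
| `lfc_overexpression` | 0.5849 | inclusive bound for the 2-column filter; log2(1.5) |

A threshold of zero interpreted as ≥ 0 would pass every feature, so the
miRNA rule is read as a strict inequality. No multiple-testing correction is
applied per dataset by default — the consensus step, not the per-cohort
*p*-value, provides specificity — but Benjamini–Hochberg filtering is
available via `adjust = "BH"`. The overexpression filter compares exactly
two columns (mimic vs scrambled control, no replicates), with inclusive
bounds at ±0.5849; a pair of one-sided conditions with the same sign would
be vacuous, so the down-side bound is ≤ −0.5849.

### Cross-dataset consensus

A miRNA is retained iff called DE **in the same direction** in at least
`min_datasets` (default 3) cohorts. Direction consistency is required, not
merely presence in DE lists: a feature whose "up" and "down" supports both
reach the cutoff is dropped and logged, and features one cohort short of
the cutoff are written to a near-miss sidecar so the hard threshold is
auditable. mRNA cohorts from the same array platform are pooled
(column-concatenation on the intersected feature set) before DE, because a
single pooled list is both better powered and matches how array cohorts are
typically combined; per-dataset voting remains possible by calling
`consensus_mirna()` on per-cohort results. The pooled-array result is then
intersected with the sequencing cohort's result, again requiring the same
direction.

### Target-site prediction: three simplified predictors

The three predictors are deliberately simplified stand-ins that preserve
the decision axes of the standard tools (alignment quality, duplex
stability, site accessibility) while remaining fully auditable — every
score can be recomputed by hand from documented tables, and the test suite
checks each engine against brute-force enumeration.

Candidate sites come from a seed scanner: the seed is miRNA positions 2–8
(5′→3′), and the UTR is scanned for reverse-complement matches graded
8mer (rc(seed7)+A) > 7mer-m8 (rc(seed7)) > 7mer-A1 (rc(seed6)+A) > 6mer
(rc(seed6)), overlapping matches reported at the highest class only.
Intervals are 0-based half-open on the UTR 5′→3′; only the sense strand is
scanned. Each candidate is then scored on a window covering the site plus
16 nt upstream (where 3′-supplementary pairing binds) and 2 nt downstream:

- **Alignment axis.** Smith–Waterman local alignment over antiparallel
  complementarity: Watson-Crick +5, GU +2, mismatch −3, gap open −8, gap
  extend −2, with contributions opposite miRNA positions 2–8 doubled. A
  bare perfect 7mer scores 70.
- **Duplex energy axis.** Minimum free energy of the intermolecular hybrid
  without intramolecular structure, from a reduced 16-entry Watson-Crick
  nearest-neighbor stack table (keyed by the miRNA-side dinucleotide;
  GU-containing stacks take a flat wobble value; bulges/internal loops cost
  `4.0 + 1.0·nt`, capped at 8 nt per strand). The table ships as
  `extdata/stack_energies.tsv` with literature-scale magnitudes
  (−0.9 … −3.4 kcal/mol); it favors desk-scale verifiability over
  thermodynamic fidelity.
- **Accessibility axis.** ΔΔG = duplex energy − opening cost, where the
  opening cost is 1.0 kcal/mol per base pair that a maximum-base-pairing
  (Nussinov, minimum hairpin loop 3) fold of the site ± 17 nt places on the
  site. A site in an unstructured context costs nothing to open; a site
  buried in a 10-bp hairpin pays +10.

Default cutoffs (`predictor_thresholds()`): alignment ≥ 80, MFE ≤ −14
kcal/mol, ΔΔG ≤ −5 kcal/mol, minimum class 6mer. They were fixed once, at
design time, so that canonically 3′-supplemented planted sites pass all
three axes while shuffled controls essentially never do (random 20-mers
reach the alignment cutoff with probability < 1%); they are configuration,
not constants. In all-three mode a site needs all axes; union mode (any
axis) reproduces a permissive multi-tool union stage.

### Pairing and downstream stages

Pairs require opposite consensus directions, ≥ 1 consensus site (all-three
mode), and Pearson *r* < 0 with *p* < 0.05 (t-transform on *n* − 2 df) on
the matched-sample cohort. Correlation uses **tumor samples only** by
default: pooling tumor with normal samples inflates |r| mechanically through
the group-mean shift, so the tumor-only estimate is the conservative choice;
`tumor_only = FALSE` restores pooled behavior. No r-magnitude cutoff is
imposed beyond significance (`r_threshold = 0`), since any such cutoff would
be arbitrary; tightening it only ever shrinks the pair set. Pairs with sites
that fail correlation are written to a sidecar for audit.

Candidate nomination intersects the predicted target set of one focus miRNA
with the overexpression down-list, then keeps genes hitting at least one
required annotation term; a known-interaction exclusion list supports
novelty screening. Enrichment is a hypergeometric upper tail computed in
log space (the EASE variant drops one hit), with BH adjustment within each
result batch; the default background is the union of GMT members and should
be overridden with the measured universe when available. The ΔΔCt
calculator implements RQ = 2^(−ΔΔCt) from triplicate Ct means with
per-triplicate SDs.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
platform physics. Expression is Gaussian on the log2 scale for both "array"
and "sequencing" cohorts, since the analysis views both through the same
t-test/log2FC lens. Defaults (the package's reference study conditions):

- 4 array-like miRNA cohorts, 2 array-like mRNA cohorts, plus one
  matched-sample sequencing-like pair; 20 samples per group per cohort —
  comparable to mid-sized public tumor/normal series;
- 200 miRNAs / 800 mRNAs, with 60% / 30% differentially expressed (split
  evenly up/down) — large DE fractions keep the consensus and pairing
  stages well populated at desk scale;
- shift δ = 1.5 log2 units, noise σ = 0.5 (a 3σ effect, typical of clearly
  dysregulated features); planted coupling β = 0.8 with target noise σ/2 on
  the matched cohort;
- 50 planted pairs (down-miRNA → up-mRNA, mirroring a tumor-suppressor
  focus), each with one embedded site in a 600-nt UTR.

Neither the effect-size distribution nor the coupling strength is fitted to
real data — they are stated reference conditions chosen once. Planted sites
embed extended complementarity to miRNA positions 2–19 (seed + central +
3′-supplementary pairing) rather than a bare seed: a seed-only site scores
70 on the alignment axis and could never pass the documented cutoff of 80,
whereas canonically 3′-supplemented sites pass all three axes by
construction. Planted miRNAs are drawn with pairwise-distinct 6mer seeds and
embeds free of other DE miRNAs' seeds, and all background sequence
(including every non-planted UTR) is sampled free of 6mer-or-better matches
for any DE miRNA — site-level false positives are therefore attributable to
the predictors, not the generator. Because naive whole-sequence rejection is
infeasible once ~100 seeds are forbidden, backgrounds are cleaned by
bounded iterative resampling of offending 6-nt windows, which implements
the same contract.

What passing tests on these cohorts does **not** show: robustness to batch
effects, count overdispersion, probe-level artifacts, shared seed families,
competing endogenous RNA effects, or sites outside the 3′UTR — none of
which the generator emulates.

## Numerical and design choices

- All sequence arithmetic uses one alphabet (RNA, T→U on input); site lists
  are invariant under case and T/U representation.
- Writers print floats with 6 decimals and LF endings, so write→read
  round-trips are byte-stable and golden-file comparisons are meaningful;
  run manifests record per-file md5s and reruns under a fixed seed are
  byte-identical.
- The duplex DP caps bulges/internal loops at 8 nt per strand (the affine
  penalty makes longer loops non-optimal in practice and the cap keeps
  exhaustive verification feasible); the Nussinov traceback is deterministic
  (unpaired preferred on ties, then the 5′-most partner).
- Precision/recall conventions: precision is defined as 1 when nothing is
  reported, recall as 1 when nothing is planted.
- Empty groups, ragged rows, duplicate ids, inconsistent counts and
  out-of-bounds intervals raise typed errors naming the offender; readers
  never silently drop records.

## Validation and problem sizes

The shipped suite validates each engine against an independent oracle:
seed scanner vs a naive windowed scan (1000 random draws) and Biostrings
pattern matching; duplex MFE vs exhaustive enumeration of all pairings
(≤ 6 nt); Nussinov pair counts vs exhaustive fold enumeration (≤ 12 nt);
the hypergeometric tail vs exact combinatorics for every N ≤ 25; the
*t*-test vs `stats::t.test`; Pearson vs the definition and
`stats::cor.test`. Statistical calibration uses a 10,000-feature null
cohort (type-I error within [0.04, 0.06] at α = 0.05) and KS-uniformity of
null *p*-values. End-to-end recovery runs the reference conditions (50
planted pairs, seed fixed) through the full pipeline and scores the pair
table against the planted truth; these sizes keep the default suite within
a few minutes on one CPU while leaving every stage non-trivially populated.

## Known limitations

- The three predictors are decision-axis stand-ins, not reimplementations
  of miRanda/PITA/RNAhybrid; absolute scores are not comparable to those
  tools, and published site coordinates will not be reproduced exactly.
- The energy model is a reduced stack table without dangling ends, special
  hairpins or partition-function ensembles.
- Consensus requires direction consistency across cohorts; meta-analytic
  p-value combination is out of scope.
- Correlation is computed on a single matched cohort; cross-cohort
  correlation schemes for unmatched samples are not attempted.
- Enrichment results depend strongly on the background; results against the
  default (union-of-GMT) background are not comparable to tools with
  proprietary backgrounds.
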