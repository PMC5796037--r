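# mirpair

Integrated miRNA–mRNA expression analysis for tumor/normal cohorts, with a
three-predictor target-site consensus and a synthetic-cohort generator for
end-to-end validation.

## The problem

MicroRNAs repress their target mRNAs by base-pairing with sites in the
3′UTR, so a regulatory miRNA→mRNA pair in a tumor cohort should show three
convergent signals: the two partners are dysregulated in **opposite**
directions, their expression is **negatively correlated** across matched
samples, and the mRNA's 3′UTR carries a **predicted binding site** for the
miRNA. `mirpair` implements this multistep funnel as composable, testable
operations for analysts working with several expression cohorts at once
(e.g. GEO arrays plus a TCGA sequencing cohort):

1. **Per-dataset differential expression** — two-sample Student *t*-test
   (pooled variance; Welch optional) on log2 expression, with class-specific
   fold-change cutoffs: |log2FC| > 1 for mRNAs, significance-driven calling
   for miRNAs, raw *p* < 0.05.
2. **Cross-dataset consensus** — a miRNA is kept iff called in the same
   direction in ≥ 3 cohorts; mRNAs must agree between the pooled array
   cohorts and the sequencing cohort.
3. **Target-site consensus** — three independent predictors must agree on a
   candidate seed site (8mer / 7mer-m8 / 7mer-A1 / 6mer): a seed-weighted
   local complementarity alignment (miRanda-style axis), a nearest-neighbor
   duplex minimum free energy (RNAhybrid-style axis), and a site
   accessibility ΔΔG from a maximum-base-pairing fold of the local target
   structure (PITA-style axis).
4. **Inverse-correlation pairing** — Pearson *r* < 0 with *p* < 0.05 on
   matched (tumor-only by default) samples, opposite DE directions, ≥ 1
   consensus site.
5. **Candidate nomination** — predicted targets of a focus miRNA intersected
   with genes down-regulated (log2FC ≤ −0.5849 = −log2 1.5) after
   overexpressing that miRNA, then filtered by functional annotation.
6. **Enrichment** — hypergeometric over-representation (optionally DAVID's
   conservative EASE variant) with Benjamini–Hochberg adjustment, against a
   user GMT.
7. **ΔΔCt calculator** — RQ = 2^(−ΔΔCt) for qPCR validation of candidates.

Because real headline counts depend on external downloads and tool versions,
the package ships a synthetic cohort generator (`simulate_cohorts()`,
`simulate_utrs()`, `simulate_overexpression()`) that plants known DE
features and regulatory pairs — opposite shifts, negative coupling
(target = baseline − β·miRNA + ε), and embedded seed sites — so the whole
funnel can be validated against ground truth.

## Worked example

Cross-cohort consensus on the bundled table of down-regulated miRNAs from
public gastric-cancer cohorts:

```r
library(mirpair)
consensus_mirna(gc_mirna_example(c("GSE30070", "GSE23739", "TCGA_STAD")),
                min_datasets = 3)[, c("feature_id", "direction", "n_support")]
#>    feature_id direction n_support
#> 1  miR-145-5p      down         3
#> 2  miR-204-5p      down         3
#> 3  miR-26a-5p      down         3
#> 4  miR-30a-5p      down         3
#> 5  miR-342-3p      down         3
#> 6     miR-375      down         3
#> 7 miR-642a-5p      down         3
```

Seven miRNAs are down-regulated in all three cohorts of the large triple;
the `{GSE33743, GSE30070, TCGA_STAD}` triple leaves two (miR-1-3p,
miR-203a-3p).

The one-shot pipeline on a synthetic cohort (4 array miRNA cohorts + 2
array mRNA cohorts + 1 matched sequencing pair, 50 planted pairs):

```r
manifest <- run_all(pipeline_config(sim = simulation_config(rng_seed = 42L)),
                    "demo_run")
str(manifest$funnel)
#> $ n_consensus_mirnas    : int 120
#> $ n_consensus_mrnas     : int 240
#> $ n_sites               : int 50
#> $ n_pairs               : int 50
#> $ n_down_mirna_up_mrna  : int 50
#> ...
str(manifest$recovery)
#> $ precision : num 1
#> $ recall    : num 1
#> $ f1        : num 1
```

All 120 planted DE miRNAs and 240 DE mRNAs survive consensus, the predictor
consensus reports exactly the 50 planted sites, and the integrated pair
table recovers all 50 planted pairs with no false positives. The
`enrichment.tsv` output ranks the planted regulon first
(k = 50/50, hypergeometric *p* ≈ 0), and `candidates.tsv` contains exactly
the planted target of the focus miRNA. `demo_run/manifest.json` records the
funnel, the config hash and per-file md5s; rerunning with the same seed is
byte-identical.

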