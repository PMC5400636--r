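# tnbcnet

Condition-specific transcription-factor (TF) regulatory network analysis
for triple-negative breast cancer (TNBC), for computational biologists
studying how regulatory *wiring* — not just expression — distinguishes
tumor subtypes.

Triple-negative tumors lack the receptors that make other breast cancers
druggable, and expression profiling alone misses regulators whose
*activity* changes without any change in their own abundance.  `tnbcnet`
implements a network-level workflow that makes exactly those regulators
visible:

1. **Network inference.**  For each condition (normal breast `NORM`,
   non-triple-negative `nTNBC`, `TNBC`) a TF-to-gene network is inferred
   by message passing between three layers: a binary sequence-motif prior
   `M`, a TF–TF protein-interaction matrix `P`, and gene–gene
   co-expression `C`.  Starting from `W = zscore(M)`, each step blends in
   a responsibility message `R = T(P, W)` and an availability message
   `A = T(W, C)` (continuous Tanimoto kernel `T`, update rate α = 0.25):
   `W ← (1 − α) W + α (R + A)/2`.  Final weights are edge Z-scores;
   edges with BH-adjusted upper-tail p < 0.05 are significant.
2. **Regulatory patterns.**  Combining the three significance masks with
   pairwise Welch differential expression (BH FDR < 0.1) labels each edge
   *UM* (stepwise malignancy progression, edge in all three networks),
   *TNBCov* (TF overexpression driven, TF and target change only in
   TNBC), or *TNBCac* (TF activation driven: edge present **only** in the
   TNBC network, target changes only in TNBC, TF expression free).
3. **Co-regulation modules.**  TF pairs with hypergeometrically
   significant target-profile overlap merge level-wise into 3–8-TF
   modules (intersections at levels 3–4, union-merge of 4-TF gene sets
   above; Monte-Carlo nulls for ≥3-way overlaps), followed by
   network-walking extension of the core and hypergeometric gene-set
   enrichment over any GMT collection.
4. **Validation.**  Promoter-window ([−750, +250) around the TSS,
   strand-aware) ChIP-peak target calling across cell lines, and ROC/AUC
   of each TF's edge ranking against its common targets; exact
   dynamic-programming p-values for PWM promoter scanning.
5. **Stratification.**  A signature of the core targets plus their
   regulators clusters patients (k-means, k = 3 or 2); nTNBC samples
   split into *TNBC-like* and *other*, compared by Kaplan–Meier curves
   and the log-rank test.

A synthetic-data generator (`sim_config()`, `generate_truth()`,
`simulate_*()`) plants this exact structure — including a 5-TF × 35-gene
activation-driven core module wired only in TNBC — so the entire pipeline
is testable end-to-end without any external downloads.

## Worked example

```r
library(tnbcnet)
report <- run_pipeline()   # default benchmark cohort, seed 42
print(report)
```

```
Regulatory-pattern pipeline report
  significant edges: NORM=338, nTNBC=374, TNBC=587
  shared edge fraction: 0.320
  pattern edges: UM=101, TNBCov=149, TNBCac=266
  largest TNBCac module: 5 TFs, 36 shared targets (recovered 91% of planted targets)
  ChIP validation median AUC: 0.988
  TNBC-like vs other nTNBC log-rank p: 0.768
  TNBC edge-ranking AUC vs planted wiring: 0.985
```

Reading the numbers: the TNBC network carries more significant edges than
the other two because only there does the planted core module have
co-expression support; 266 edges classify as activation-driven, and
merging their TF target profiles recovers a single largest module whose
TF set (`TF01`–`TF05`) is exactly the planted one, sharing 36 targets of
which 32 (91%) are planted core targets.  Ranking each TF's Z-scores
against simulated ChIP common targets gives a median AUC of 0.988, and
the full Z-score ranking recovers the planted wiring with AUC 0.985.  The
log-rank p of 0.77 at this cohort size is expected: the 10-sample nTNBC
subgroup is below the scale at which the stratification claims are made
(see the vignette); at 550 samples per condition the split agrees with
the planted subgroup for ~98% of patients and separates survival at
p < 1e-4.

Individual stages are plain functions over plain containers —
`panda()`, `pairwise_de()`, `classify_edges()`, `find_modules()`,
`extend_core()`, `pwm_scan()`, `peak_targets()`, `rank_roc()`,
`build_signature()`, `tnbc_like_split()`, `km_curve()`, `logrank()` — and
`make_fixtures()` writes a complete plain-text input set (expression TSV,
prior/PPI TSV, BED peaks, annotation, survival table, truth JSON) for use
from any other tool.

## Documentation

The methods vignette (`vignettes/regulatory-patterns.Rmd`) documents the
model, every tunable threshold (α = 0.25; FDR 0.05 for edges and 0.1 for
DE; walking thresholds 10 and 20; common-target rule >5 cell lines;
promoter window −750/+250; PWM site p < 1e-5), the numerical choices
behind the message-passing annealing and the module merging, what the
synthetic generator does and does not emulate, and known limitations.
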