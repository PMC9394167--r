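---
title: "Profiling plasma samples with branched-selection aptamer pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling plasma samples with branched-selection aptamer pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptashape)
```

## The measurement and its statistical model

A branched selection takes a pre-trained pool of 2′F-pyrimidine-modified
RNA aptamers — each a 36-nt variable region between fixed constant
flanks — and performs one further round of selection against each
individual plasma sample, reading out the surviving pool by paired-end
sequencing. The relative abundance of an aptamer after the branched round
reflects the availability of its protein epitope in that sample, so
samples with different proteomes (here: control individuals, C;
non-muscle-invasive bladder tumors, Ta; muscle-invasive tumors, T2–T4)
produce systematically different aptamer abundance patterns.

The analysis model treats, for each aptamer $a$ and sample $s$, the
*pool fraction* $f_{as} = 100 \cdot c_{as} / N_s$ (count over total reads,
in percent), and its *relative level*
$y_{as} = f_{as} / \bar f_{a\cdot}$, the pool fraction divided by the
aptamer's mean across all samples. Dividing by the mean puts abundant and
rare aptamers on a common scale: for every aptamer the relative level
varies around 1 and group effects are expressed as fractions of the
aptamer's typical abundance.

Group effects are estimated per aptamer by ordinary least squares with
indicator coding,

$$y_{as} = \beta_0 + \beta_{\mathrm{Ta}}\,[s \in \mathrm{Ta}]
  + \beta_{\mathrm{T2T4}}\,[s \in \mathrm{T2T4}] + \varepsilon_{as},$$

once with the control group as baseline (yielding the Ta-vs-C and
T2T4-vs-C coefficients) and once re-leveled with Ta as baseline (yielding
T2T4-vs-Ta). With this coding $\beta_g$ is exactly the difference between
the group mean and the baseline mean; its standard error uses the pooled
residual variance with $n - 3$ degrees of freedom, and two-sided p-values
come from the Student's t-distribution. `fit_group_ols()` computes this in
closed form, vectorised over aptamers; it is algebraically identical to
`lm(y ~ group)` and the test suite verifies the equality against both
`lm()` and the textbook pooled two-sample t-test.

P-values are adjusted per comparison by Benjamini–Hochberg across the
tested aptamers. An aptamer is *discriminatory* when
$|\beta| > 0.5$ (tumor group vs control) or $|\beta| > 0.25$ (T2T4 vs
Ta) **and** the adjusted p-value is below 0.01. The coefficient gate is on
the magnitude, with the sign reported as depleted/increased — volcano
plots of these comparisons show both depletion and enrichment passing.
One documented ambiguity: the source protocol states the significance
gate both as an adjusted p-value of 0.01 and, elsewhere, as a false
discovery rate of 0.01%; this package follows the per-comparison
adjusted-p < 0.01 reading and exposes the gate as
`adj_p_threshold` in `pipeline_config()`.

## From reads to the frequency matrix

`fastq_to_counts()` runs the read-processing chain:

1. **Demultiplexing** by the barcode prefix of read 1, exact by default
   (`max_barcode_mismatch = 0`); with a nonzero budget, barcode sets in
   which two barcodes lie within twice the budget are rejected outright
   because assignment would be inherently ambiguous.
2. **Pair-mate joining**: read 2 is reverse-complemented and slid along
   read 1; the offset with at least `min_overlap = 10` overlapping bases
   and the fewest mismatches wins (ties toward the larger overlap), the
   pair is rejected when more than `max_mismatch_frac = 0.1` of the
   overlap mismatches, and overlap conflicts resolve toward the
   higher-quality base (ties toward read 1).
3. **Variable-region extraction** between the constant flanks, each
   located with at most one substitution; regions outside 30–42 nt
   (the design length is 36) are rejected.
4. **Dereplication** into per-sample (sequence, count) records. Identical
   read pairs are collapsed *before* joining — identical pairs merge
   identically — which makes deep error-free data cheap to process.

Counting then proceeds per sample: sequences observed fewer than
`min_count = 4` times in a sample are zeroed in that sample (the sequence
may remain present in other samples), while the per-sample *total* — the
denominator of the pool fraction — deliberately keeps all dereplicated
reads, because frequencies are fractions of everything the sample
produced, not of the retained subset.

Near-identical sequences, which stem from single-nucleotide amplification
and sequencing differences around a common ancestor, are merged by
`cluster_by_edit_distance()` under the Damerau–Levenshtein distance in
its restricted *optimal string alignment* (OSA) form: substitutions,
insertions, deletions and adjacent transpositions at unit cost, with no
substring edited twice. The restriction matters and is pinned by a test
(`d("CA","ABC") = 3` under OSA, 2 unrestricted); OSA is what most string
libraries implement under the Damerau–Levenshtein name. Clustering is
greedy and abundance-ordered: sequences are visited by decreasing total
count (ties lexicographic) and join the first existing centroid within
`cluster_max_dist = 3` (i.e. distance < 4), else found a new centroid.
This makes membership a centroid relation rather than single linkage — a
sequence 3 away from a member but 6 away from the centroid starts its own
cluster — and makes the outcome deterministic. Member counts are summed
into their centroid per sample, and clustering is applied to the
cross-sample union of sequences so every sample ends up with the same
aptamer set.

Finally `select_top_abundant()` keeps the `top_n = 1000` aptamers by mean
frequency across samples (ties lexicographic), bounding the
multiple-testing burden.

## Validation-cohort analysis

The discriminatory aptamers fitted on the training cohort are evaluated
on the validation cohort: relative levels are recomputed within that
cohort, samples are ordered by complete-linkage hierarchical clustering
on Euclidean distances (the heatmap column order; rows stay in family
order), and principal component analysis is run on three aptamer sets —
the vs-control set, the stage set, and their union — with samples as
rows, centered, unscaled (`prcomp` defaults; both flags are exposed
because the source protocol names only the function).

Only discriminatory aptamers observed in **every** cohort sample enter
this stage. The validation analysis presumes its aptamers are present in
the cohort's selections; an aptamer at its detection limit has a
quasi-binary presence/absence profile whose variance swamps the PCA with
structure unrelated to the groups.

Principal-component signs are arbitrary, so `orient_components()` fixes
them by convention: component 1 positive for the mean of cancer-labeled
samples, component 2 positive for the mean of T2T4-labeled samples.
`classify_by_sign()` then reads class from the sign: positive PC1 calls
cancer (exactly zero counts as control — the documented tie rule), and
among cancer samples positive PC2 calls late stage. Accuracy is the
exact-match fraction.

## The synthetic-data generator

`simulate_study()` generates data with the statistical structure the
analysis assumes, plus ground truth, so every stage is testable without
any external data:

* **Pool structure.** Ancestor sequences are uniform over the $4^{36}$
  sequence space; families carry i.i.d. point substitutions at
  `mutation_rate_within_family = 0.1` per nt (members typically 3–4
  substitutions from the ancestor, so families span both the read-merge
  scale and the motif-family scale). Defaults: 50 families of 4 plus 300
  singletons, 500 sequences.
* **Abundances.** Baseline pool fractions are log-normal
  (`sdlog = 2`), normalized to sum to 1. The value was calibrated once by
  Monte Carlo against the described pool shape — the top aptamer holds
  roughly a tenth of the pool (mean top share ≈ 0.12 over 20 seeds) while
  over 90% of aptamers individually stay below 1% — and is not revisited.
  A log-normal was chosen over a power law because it matches the
  "few dominant, long tail" shape with two interpretable parameters.
* **Group effects.** A planted effect multiplies an aptamer's selection
  propensity per group: a `vsC_cancer` effect multiplies both tumor
  groups; a `Ta_vs_T2T4` effect splits symmetrically about control
  (Ta × $1/\sqrt m$, T2T4 × $\sqrt m$), so stage-discriminating aptamers
  separate the stages without passing the vs-control thresholds —
  mirroring the observed disjointness of the two selection sets. Effects
  apply family-wide (same ancestor, same presumed target) and are placed
  on aptamers with baseline fraction ≥ $10^{-4}$, the detectability floor
  at the simulated depth.
* **Sampling.** For sample $s$ in group $g$, propensities
  $w_a = \mathrm{baseline}_a \times \mathrm{mult}_{ag} \times
  \varepsilon_{as}$ with $\varepsilon$ log-normal
  (`sample_noise_sigma = 0.3`, representing patient-to-patient
  variability; the source describes no noise model, so this multiplicative
  form is a package choice), then counts are
  Multinomial(`read_depth`, $w/\sum w$). The default depth of $10^5$
  reads/sample keeps simulated studies tractable; real branched
  selections average several millions of reads per sample and differ only
  through smaller sampling noise. The scaled-down depth raises the
  relative detection floor about 35-fold, which is why the presence
  filter before PCA matters more here than on real data.
* **Reads.** `write_fastq_pairs()` emits each counted molecule once as a
  pair over the amplicon `barcode + flank5 + region + flank3` (read 2
  reverse-complemented from the other end, constant Q37 qualities, an
  optional uniform substitution error to exercise the merge tolerances).
  Noise-free emission round-trips exactly through `fastq_to_counts()`.

What the simulator does *not* emulate: PCR amplification bias,
round-to-round SELEX evolution, instrument-specific quality profiles, or
any relationship between sequence content and binding. Passing tests
therefore demonstrate that the pipeline recovers the effects the model
plants under realistic pool shapes, depths and noise — not that the
biological measurement itself is reproduced.

## Numerical and design choices

* All randomness flows from single integer seeds; sub-stages use seeds
  derived deterministically from them, and two runs with the same inputs,
  configuration and seed produce byte-identical output files (numeric
  output is written at 10 significant digits).
* Ties: clustering order and top-n ranking break ties lexicographically
  by sequence; merge conflicts fall to read 1; a PCA score of exactly 0
  classifies as control/early stage.
* Sequence families among discriminatory aptamers are labeled by
  single-linkage connected components at OSA distance ≤ 8, largest family
  first (A, B, …; singletons unlabeled). This is an explicit surrogate:
  the original motif-based family assignment is not described, so any
  reconstruction is approximate. Single linkage at a permissive radius
  groups sequences sharing a mutated ancestor without claiming motif
  semantics.
* Degenerate fits (zero residual variance) report p = 0 with a flag;
  zero-mean aptamer rows are dropped from relative levels with a warning;
  zero-total samples abort normalization with the sample named.
* The regression uses one pooled three-group model (df = $n-3$),
  re-leveled for the Ta baseline, rather than three separate two-group
  fits — a single-model reading of the protocol; the two coincide in the
  coefficients and differ only in the pooled variance.

## Problem sizes used in the shipped checks

The package's own tests and the acceptance script simulate studies of 500
aptamers, 32 training samples per group, a 10/8/4 validation cohort and
$10^5$ reads/sample — the study's design at reduced depth — with 10
planted effects (multipliers 0.5 and 2). Under those conditions the
differential-enrichment stage recovers planted effects with sensitivity
≈ 1 and ≈ 0 false positives, null studies select no aptamers at the
0.01 adjusted-p gate, and sign-rule classification of the validation
cohort attains ≈ 95% (cancer vs control) and ≈ 80–85% (Ta vs T2T4)
accuracy averaged over seeds; reruns are byte-identical. A worked example
with the exact printed numbers is in the README.

## Known limitations

* The greedy centroid clustering depends on the abundance ordering;
  deterministic but not a globally optimal partition.
* Family labels are a surrogate, not motif discovery.
* The pipeline models no covariates (age, batch); the regression is
  deliberately unadjusted, matching the protocol it implements.
* With very shallow depth, min-count filtering interacts with the
  detection floor; the presence filter before PCA mitigates but does not
  remove this.
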