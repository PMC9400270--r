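---
title: "Methods: differential abundance of co-culture EV proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential abundance of co-culture EV proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evlfq)
```

## The model

`evlfq` analyzes a label-free quantification (LFQ) matrix: one row per
protein group, one column per mass-spectrometry run, over a small balanced
design — canonically three conditions (cancer monoculture KPC, stellate
monoculture PSC, and their co-culture CoC) in triplicate. The scientific
question is which proteins are secreted into extracellular vesicles *only
when the two cell types interact*: elevated in CoC, relatively low in both
monocultures.

The statistical model is deliberately classical. After preprocessing, each
protein's normalized values are treated as k independent Gaussian groups
with equal variance and tested with the one-way fixed-effects ANOVA
F statistic, df (k−1, N−k). Multiplicity over proteins is handled with the
Benjamini–Hochberg step-up procedure, and q < 0.05 gates the downstream
clustering. No moderation or variance shrinkage is applied: with thousands
of proteins and three replicates a moderated test would have more power,
but the plain ANOVA is what this pipeline is specified to do, and its
behaviour is exactly auditable against closed-form oracles.

## Preprocessing and its assumptions

**Detection filter.** A protein enters the analysis when it has at least
`min_valid` observed values in *some* condition. Two conventions coexist in
this field: "detected in at least one category" (`min_valid = 1`) and "a
complete triplicate in at least one condition" (`min_valid = 3`). Both are
one flag apart; the default is 3, the stricter rule, because imputation of
a protein never reliably observed anywhere in a condition is pure
fabrication. Per-condition identification counts are reported alongside as
a side table, and the Venn/identification accounting uses its own threshold
(`min_valid_id`, default 1) because identification totals are bookkeeping,
not inference.

**MNAR imputation.** Missing LFQ values are predominantly censored
low-abundance measurements, not random dropouts. Each missing cell is
replaced by a draw from `Normal(μ − d·σ, (w·σ)²)` where μ and σ are the
mean and sample standard deviation (n−1 denominator) of the observed log2
values in the cell's sample column, `w = 0.3` and `d = 1.8`. These two
constants are the field's standard downshifted-Gaussian parameterization;
the column-wise scope is the established convention for it (a global scope
is available via `impute_scope = "global"`). Missing cells are imputed in
row-major order from one generator seeded once per run, so a fixed seed
reproduces the imputation bit for bit.

**Width adjustment.** The normalization subtracts the median q2 and divides
positive residuals by (q3 − q2), negative residuals by (q2 − q1), forcing
the scope's quartiles to (−1, 0, +1). Quartiles use the linear-interpolation
"type 7" estimator; the convention is recorded in output provenance since
the choice is invisible in most descriptions of the method.

The *scope* of width adjustment is the one genuinely open design decision
in this pipeline, and the package resolves it empirically. Applied per
protein row — a literal reading of "all abundances for each protein were
normalized" — the transform destroys the very signal the pipeline exists to
find: for a row with 6 monoculture values near baseline and 3 co-culture
values elevated by e, the type-7 q3 falls at the low edge of the elevated
group, so (q3 − q2) ≈ e and dividing by it rescales the between-group gap
itself to ≈ 1 while the within-group noise of the lower groups is rescaled
to ≈ 1 as well; the F statistic then saturates near its null range no
matter how large e is (measured on simulated data: cluster2 discovery
drops from 100/200 to 3/200). Applied per sample column — the convention
of the Perseus software family, whose "width adjustment" vocabulary this
method shares — the transform is a monotone per-run rescaling that equalizes
asymmetric spread across runs and leaves between-condition contrasts
intact. The pipeline therefore defaults to the per-sample scope
(`normalize_scope = "sample"`); the per-protein scope remains available,
both in the pipeline and as `width_adjust(x, scope = "protein")`, and is
useful as a display transform.

**Row standardization.** Candidate tables print per-condition *averages of
row-standardized values* (mean 0, SD 1 per protein): in published tables of
this kind the three per-condition averages of every row sum to ~0, which
the asymmetric width-adjustment formula does not force but mean-centering
does. The pipeline standardizes the significant subset after width
adjustment, and clustering, profiles and candidate averages all operate on
that standardized matrix. Both the normalized and standardized matrices are
written by `run_pipeline()`.

## Clustering and candidate selection

Significant proteins are clustered with agglomerative hierarchical
clustering, Euclidean distance, average linkage, cut to exactly k clusters.
Neither the distance nor the linkage is prescribed by descriptions of this
analysis; Euclidean/average is the de-facto default for expression-profile
heatmaps, both are arguments, and the choice is recorded in provenance.
Defaults k = 4 (protein arm) and k = 5 (phospho arm) mirror the cluster
counts typical of the two data types.

Candidate selection operationalizes "overexpressed in co-culture but
relatively low in the monocultures" as a *cluster-level* contrast: the
cluster maximizing `profile(CoC) − max(profile(KPC), profile(PSC))` is
selected and all its members returned. A hard per-protein sign rule
("negative in both monocultures") is deliberately not used: genuine
candidate tables contain the occasional member with a slightly positive
monoculture average, and the cluster-level contrast tolerates that while a
sign rule would not. If no cluster has a positive CoC profile the selection
is empty with a warning. Ranking is by mean CoC abundance descending,
alphabetical tie-break on gene symbol, top n = 20 by default.

The phosphoprotein arm shares every numerical routine (same `evome()`
function, `arm = "phospho"`), differing only in the default k = 5 and in a
flag marking its candidate table as not used for target selection —
phosphoproteome cluster profiles are typically too weak to rank targets
from, and the flag preserves that caveat in the output.

## The synthetic-data generator

`simulate_lfq()` emulates the statistical structure of the real experiment
so that every stage has a recoverable ground truth: per-protein baseline
log2 intensities `N(25, 2²)` (typical LFQ intensities live around 2^25 and
span orders of magnitude), four archetype patterns shifting condition means
by ± `effect_size` (cluster1: low KPC / high PSC & CoC; cluster2: high only
CoC; cluster3: high only PSC; cluster4: low only CoC), replicate noise
`N(0, 0.5²)` (upper end of typical LFQ technical + biological CV), and
logistic missing-not-at-random dropout: `P(missing) =
plogis(−(x − midpoint)·steepness)` with default midpoint `baseline − 1.5·SD`
and steepness 1 per log2 unit, giving ~10–15% overall missingness
concentrated in low-abundance proteins — realistic for EV secretome data.
Pattern counts are deterministic: `floor(fraction · n)` per pattern in the
order given, remainder null. The default effect size 1.5 equals
3 × replicate SD.

What the generator does *not* emulate: peptide-level evidence, shared
peptides and protein-group ambiguity, correlated (batch) noise across
samples, heavy-tailed intensity error, or abundance-dependent replicate CV.
Passing recovery tests on this generator therefore demonstrates the
pipeline's correctness under its stated model, not robustness to every
pathology of real LC–MS data.

## Numerical choices and degenerate inputs

- Quartiles: type 7 everywhere. With scope sizes where quartile positions
  interpolate between order statistics that straddle the median, the
  post-adjustment quartiles are (−1, 0, 1) only to interpolation accuracy;
  at sizes where positions land on order statistics they are exact.
- Degenerate width (q3 = q2 or q2 = q1): the affected side's divisor is set
  to 1 after median subtraction, with a warning naming the scope; a
  constant scope maps to zeros.
- Constant rows in standardization: mapped to zeros with a warning.
- ANOVA degeneracies: SSW = 0 with SSB = 0 gives F = 0, p = 1; SSW = 0 with
  SSB > 0 gives p = 0 and a `degenerate` flag rather than a silent infinity.
- Zero-variance sample columns in correlation QC: `NA` with a warning, never
  silently 0.
- BH ties in p: `stats::p.adjust` step-up; ties do not affect q.
- Missing-value encoding on disk: in raw-stage tables both `0` and blank
  mean "not quantified" (the MaxQuant convention); at log2 and later stages
  only blank does, so genuine zeros survive round-trips.

## Problem sizes in the test and acceptance suites

The simulation studies run at sizes chosen to make Monte-Carlo error small
relative to the margins being tested while keeping the whole suite quick:
5,000 proteins for the null false-discovery check (binomial SE ≈ 0.3% on a
5% bound), 1,200 proteins (300 per archetype) for power and selection
recovery (SE ≈ 2% on an 80% bound), 10,000 draws for imputation
distribution recovery (SE on the mean ≈ 0.006). The power study uses the
four-archetype mixture with dropout disabled: the 80%-discovery property is
a statistical oracle for the ANOVA/BH stage, whose theoretical ceiling at
effect = 3·SD with triplicates is 83.2% at the raw 0.05 level — reachable
only when the BH threshold stays near 0.05 (few nulls among the tested
proteins) and no imputation noise intrudes. Under the generator's default
MNAR dropout the same pipeline recovers ~60% of planted co-culture proteins;
that gap is the honest cost of imputation near the detection limit, not a
defect of the test.

## Known limitations

- The ANOVA assumes equal group variances; width adjustment helps but no
  formal heteroscedasticity handling is attempted.
- BH assumes independence or positive dependence across proteins;
  co-regulated proteins violate this mildly.
- Candidate selection returns exactly one cluster; a biology where two
  clusters are co-culture-elevated would need `cluster_profiles()`
  inspection by hand.
- Reference-compendium overlaps are snapshots of user-supplied files;
  database counts are version-dependent and never asserted.
- Phosphosite-to-phosphoprotein aggregation is out of scope: the phospho
  arm consumes an already protein-level matrix.
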