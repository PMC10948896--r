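---
title: "Methods: lipid coregulation networks and cell-cycle phenotype integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid coregulation networks and cell-cycle phenotype integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidcheck)
```

# The analysis model

`lipidcheck` treats a perturbation lipidomics experiment as a matrix of
species-level abundances over samples, each sample belonging to a condition
(treatment x dose x timepoint) with a matched vehicle control at the same
timepoint. Every downstream quantity is computed from one common currency:
the log2 fold-change of a feature (lipid or gene) in a condition against its
time-matched control.

The preprocessing chain is deliberately minimal and fixed in order:

1. **Total-signal normalization** per replicate: each sample column is
   divided by its sum. The normalization target (column sum 1) is
   arbitrary — any constant cancels in the fold-change ratio — so only the
   *relative* composition of each sample matters. This assumes the measured
   species dominate the total signal and that no single species swamps it;
   compositional artifacts (a large change in one abundant species inducing
   apparent opposite changes elsewhere) are inherent to total-signal
   normalization and are not corrected.
2. **Replicate averaging** on the normalized abundance scale (arithmetic
   mean), then
3. **log2 ratio** to the control condition's average. Averaging before the
   log matches the stated order of the reference procedure; the alternative
   (log before averaging) differs by Jensen's inequality but only slightly
   at the replicate noise levels considered here.

## Coregulation network

Coregulation between two lipids is their Pearson correlation across the
treated conditions (controls are identically zero by construction and are
excluded by default). An edge connects pairs with `r >= 0.76`; the threshold
is inclusive and configurable. Pearson is the default because the reference
analyses report plain `r`; Spearman is available where monotone rather than
linear coupling is expected. Correlations over fewer than three conditions
are refused rather than fabricated.

The **leave-one-out robustness** check operationalizes "the condition that
contributed most to a correlation" as the argmin over single-condition
removals of the recomputed r. An edge is retained if that minimum still
clears the threshold. Edges supported by only three conditions cannot be
evaluated (two points always correlate at ±1) and are reported as
`insufficient` instead. Negative correlations never form edges, but the full
correlation matrix is exported so anti-correlated pairs on opposite sides of
the circle remain queryable.

## Clustering and enrichment

Fold-change profiles are clustered agglomeratively (`stats::hclust`). The
defaults — Euclidean distance on log2 fold-change rows, average linkage —
are explicit configuration, not a claim about the reference analysis, which
does not state its clustergram metric; both are arguments to
`cluster_profiles()`. Groups are renumbered by dendrogram leaf order so
group indices are stable and reportable. `k` is always a user choice (4 for
the lipid time courses, 11 for the gene clusters in the reference design);
no automatic model selection is attempted.

Enrichment of a category within a group uses the two-sided Fisher's exact
test under the *probability method*: the p-value is the total probability of
all 2x2 tables with the observed margins whose point probability does not
exceed the observed table's. This definition is stated explicitly because
two-sided Fisher tests have competing definitions (doubling the one-sided
tail gives different values); the probability method matches the common
`fishertest`-style implementations. Internally the point probabilities are
compared on exact integer numerators whenever the table total allows exact
double representation, so tie handling is exact; larger tables use
log-space densities with a 1e-7 relative tie tolerance. Fold enrichment is
`(k/n_subset)/(K/n_universe)` and is reported regardless of significance.
Raw p-values are returned; `adjust_bh()` is available for callers who test
many sets.

For gene clusters the default universe is the set of clustered genes. An
explicit universe (e.g. the whole transcriptome) may be passed instead; the
two choices answer different questions and the result object carries both
fractions so either can be quoted.

## Transcriptome and phenotype integration

Differential expression is consumed, never computed: the input is a table of
per-gene log2 fold-changes with an adjusted p-value for the selection
contrast, as produced by standard DE tools. Gene selection uses
`|log2 FC| > 1` and `FDR < 0.1` by default; the fold-change cutoff is
two-sided on purpose — strong down-regulation is as informative as strong
up-regulation. Gene/lipid condition matching is by exact condition id with
no fuzzy joining; which conditions enter the correlation is therefore an
explicit, visible choice of the caller.

Per-lipid phenotype correlations (e.g. against percent S-phase cells per
condition) produce a named vector designed to be attached to network nodes
with `overlay_values()`; lipids missing from the map become `NA`, never 0,
so "missing" and "uncorrelated" remain distinguishable.

## QIBC image quantification

The imaging pipeline mirrors standard fixed/live-cell cytometry practice:

* **Correction**: division by a mean-normalized illumination profile, then
  subtraction of a global background scalar. The background is a low
  percentile (default 1st) of the corrected image because the reference
  procedure specifies "a global background" without a formula; the
  percentile is configuration.
* **Segmentation**: global Otsu threshold on log-transformed intensities,
  connected components, area filter. The log transform keeps the Otsu split
  at the background/foreground boundary even though nuclear intensity spans
  a 2x range between G1 and G2 DNA content. There is no watershed splitting:
  the synthetic data is non-touching by construction and robustness to
  touching nuclei in real images is out of scope.
* **Ring sampling**: the cytoplasmic ring spans 0.65-3.25 µm outward from
  the nuclear boundary. Radii are converted to pixels by the configured
  pixel size (default 0.65 µm/px, consistent with a 6.5 µm camera pixel at
  10x; always override to match the instrument) and rounded half-up.
  Neighbor exclusion is deliberately strict: any pixel within the outer
  radius of a *different* nucleus is contested and dropped from both rings,
  which errs toward never sampling a neighbor's cytoplasm. Cells whose ring
  ends up empty are flagged and excluded from ratio statistics rather than
  given a default.
* **Measurements**: CDK activity = ring median / nuclear median of the
  reporter channel (dimensionless; ~0.2 in quiescence, >1 after S-phase
  commitment); DNA content = summed nuclear DNA-channel intensity
  (arbitrary units, linear in the channel gain); puncta count = number of
  above-threshold pixels inside the nucleus.
* **Gating**: DNA content is normalized so the G1 peak mode equals 1
  (leftmost density maximum at >= 25% of the global maximum — the leftmost
  rule keeps a large G2 population from being mistaken for G1). EdU-high
  cells are S phase regardless of DNA; remaining cells fall into G0/1
  (window 0.75-1.25) or G2 (1.5-2.5) or stay unclassified. The windows are
  configuration with defaults chosen to be generous around the 1 and 2
  modes; the EdU threshold defaults to Otsu on log intensities since
  EdU-positive and -negative populations are log-separated.
* **Traces**: cells are selected by CDK activity at the treatment frame
  (0.4-0.6 captures G0/G1, 1.0-1.2 S, 1.4-1.6 G2). A selected cell counts
  as committed when post-treatment activity exceeds 1.0, as entering S phase
  when the degron reporter exceeds 100 (arbitrary units of the reporter),
  and as mitotic when an annotated mitosis event follows treatment. Cell
  tracking itself is out of scope; traces arrive linked. Mitotic-defect
  *subtyping* is not algorithmized (it is a manual call in practice); a
  per-cell defect flag is passed through to summaries.

# The synthetic generators

Every generator is a pure function of its parameters and seed, and emits the
ground truth needed to score recovery without re-deriving hidden state.

**Lipidome.** Lipid `l` sits at angle `theta_l` on a circle; condition `c`
has phase `phi_c`; the log2 response is `a * cos(phi_c - theta_l)` plus
N(0, sigma) replicate noise on the log2 scale, on top of log-normal
baselines. This circular latent model is chosen because it provably induces
a circular coregulation topology with analytically known expected
correlation `cos(theta_i - theta_j)`, which makes edge-recovery tests
well-posed: the planted adjacency is exactly the pairs with
`cos(dtheta) >= 0.76`. Condition phases default to an evenly spaced grid —
the uniform deterministic design — under which the zero-noise sample
correlation *equals* `cos(dtheta)` at any condition count; a random-phase
option mimics irregular inhibitor/timepoint designs, where the sample
correlation only converges at rate `1/sqrt(n_conditions)`. Defaults (120
lipids, 12 conditions, 4 replicates, sigma = 0.2, amplitude 1 — i.e.
two-fold peak responses) reflect the reference study's scale: ~250 measured
species, a dozen inhibitor/timepoint combinations, four biological
replicates, and fold-changes of a few fold. Classes occupy angular sectors
(precursors — FA, PA, lyso-species, MG/DG, So — in one half; complex
lipids — PE, PC, TG, SM, PI, PS, Cer, ChE — in the other), with
sector-dependent double-bond distributions, so class/saturation enrichment
has planted signal.

**Time courses.** Four temporal archetypes (sustained rise/fall, transient
rise/fall, peak amplitude 2.5 log2 units over six timepoints) with
sigma = 0.25 noise; group 1 is all-saturated and each other group contains
exactly one saturated species, so the saturation enrichment of group 1 is
known (10 of 13 saturated species in a 40-lipid universe, fold ~3).

**Transcriptome.** Genes carry coupling angles `psi` in angular modules on
the lipid circle, so expected gene-lipid correlation is
`cos(psi_g - theta_l)`. The planted annotation set has 60 members but only
part of them (15 in the stress module, 3 scattered) fall inside the
differential table — as with a cross-species annotation set — because a set
fully concentrated in one small cluster would make every *other* cluster
significantly *depleted* under a two-sided test, and the generator is
designed so null clusters genuinely behave like null hypotheses. Adjusted
p-values are Beta(0.1, 5) for responsive genes and Uniform(0, 1) otherwise;
only their thresholding behavior matters.

**Phenotype.** Per-condition phenotype = `50 + 35 cos(phi_c - theta*)` plus
noise, clipped to 0-100, emulating a percent-S-phase readout driven by one
lipid module.

**Images.** Nuclei are non-overlapping disks on a jittered grid with margins
wide enough that every ring is uncontested; the DNA channel integrates to
the programmed content (1 or 2 units ± 3% jitter), the reporter channel
realizes the programmed ring/nuclear ratio in [0.3, 2.2], EdU is high in an
exact 25% of cells, and Gaussian noise (sd 3 intensity units against
nuclear signals of ~100-300) is added everywhere.

**Traces.** G1 cells pass through the 0.4-0.6 activity window at the
treatment frame; programmed S-entry cells ramp across 1.0 (slopes
0.015-0.03 per 12-min frame) with a degron ramp crossing 100 ten frames
after commitment, non-entry cells decay; G2 cells plateau at 1.4-1.6 with
programmed mitosis resets. Outcome counts are exact
(`round(fraction * n)`, shuffled) rather than Bernoulli draws, so the
programmed fraction is a property of the emitted data, not an expectation.

## What passing tests do and do not show

The generators emulate the *statistical structure* the analysis assumes —
low-dimensional coregulation, cosine coupling, log-normal noise, separable
imaging signals — not real data. In particular they do not model:
compositional normalization artifacts, missing species or
limit-of-detection censoring, isotope/adduct ambiguity, batch or drift
effects, touching or mitotic nuclei, uneven illumination residuals, or
tracking errors in live imaging. Passing recovery tests therefore
demonstrates that the implementation is faithful to its definitions and
recovers planted structure under the stated noise — not that the biological
conclusions of any particular study are reproducible from raw data.

# Numerical choices and degenerate inputs

* **Zeros before log2**: a zero condition-mean is replaced by half the
  smallest positive mean of that species across conditions, with a warning
  (standard metabolomics half-minimum imputation; keeps fold-changes
  finite). A species that is zero everywhere is an error.
* **Control columns** are set to exact zeros (not computed as `log2(x/x)`)
  so downstream control-exclusion logic can test `== 0` safely.
* **Zero-variance rows** are excluded with a warning from correlation
  stages (their correlation is undefined) and are an error under the
  correlation clustering metric, naming the row.
* **Fisher ties**: see above; exact integer comparison where representable.
* **Thresholds are inclusive** (`>= 0.76`) per the reference legend's
  explicit operator; the build is monotone in the threshold by
  construction.
* **Group numbering tie-break**: dendrogram leaf order, so labels are
  deterministic given the input and parameters and invariant (up to
  renaming) under row permutation.
* **Ring radii** round half-up to integer pixels; sub-pixel sampling is not
  attempted because the reference procedure does not state it.
* **Layout determinism**: force-directed coordinates are computed under a
  local RNG seed that does not disturb the caller's stream; disconnected
  components are laid out separately and merged without bounding-box
  overlap.

# Problem sizes

The test suite and the acceptance script run entirely on simulated data at
the reference scale: the 120-lipid / 12-condition / 4-replicate lipidome for
network recovery, 48 grid conditions at zero noise for the leave-one-out
check (where single-removal perturbations of r are O(1/n) and 100%
retention is the exact expectation), 20 seeds for clustering and enrichment
recovery, 512x512 images with 40 cells, 5000-cell gating populations, and
500-trace outcome calling. The decorrelation-convergence property uses 2000
random phases because the sampling standard deviation of r around zero is
`~1/sqrt(n)` and must sit well inside the asserted bound.

# Known limitations

Species-level identification only (no acyl-chain decomposition); no batch,
drift, or internal-standard correction; no automatic cluster-count
selection; no community detection or interactive network visualization; no
multi-frame tracking or watershed segmentation; GO-term retrieval and
DE calling are out of scope by design — both are consumed as user-supplied
tables.
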