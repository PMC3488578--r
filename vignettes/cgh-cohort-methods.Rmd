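---
title: "Methods: cohort copy-number analysis for BAC array-CGH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort copy-number analysis for BAC array-CGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghcohort)
```

## What the package computes

`cghcohort` analyzes BAC-clone array-CGH cohorts: tumor DNA and reference
DNA are co-hybridized to an array of mapped BAC clones, and each spot's
log2 ratio reflects relative copy number at the clone's genomic position.
The pipeline runs

1. **block-wise normalization** of spot log2 ratios against self-self
   hybridization statistics,
2. **Bayesian changepoint segmentation** of each sample's genome-ordered
   clone profile, with ternary gain/neutral/loss calling,
3. **cohort frequency analysis**: per-clone alteration frequencies,
   imbalance-region calling at a frequency threshold, cross-cohort
   common regions, and a signed-frequency difference statistic between
   clinical groups (tumor subtype ADC vs SCC, early vs late stage),
4. a **candidate-gene funnel** (region genes, hypergeometric gene-set
   enrichment, copy-number/expression concordance, novelty split), and
5. **validation-assay scoring** for qPCR, CISH and IHC follow-up.

A synthetic-data module generates array designs, cohorts with planted
copy-number states, expression ratios and validation measurements, so
every stage is testable against known ground truth.

## Normalization

Print blocks (sub-grids laid down by one print head) carry systematic
shifts. A self-self hybridization — reference DNA against itself — has
expected log ratio 0 everywhere, so its per-block sample mean $\mu_b$ and
SD $\sigma_b$ (computed with the $n-1$ denominator) estimate each block's
bias and noise scale. Tumor spots are standardized as
$z = (r - \mu_b)/\sigma_b$. The transform is affine per block, so spot
ordering within a block is preserved, and normalizing the self-self table
by its own statistics yields per-block mean 0 and SD 1 exactly (a test
invariant).

Numerical guards: a block needs at least 2 unflagged self-self spots, and
$\sigma_b < 10^{-6}$ raises a degenerate-block error rather than
producing unbounded z-values.

Replicate spots of a clone are collapsed by their **median** (robust to
one bad spot of a triplicate; the mean is available via `summary =
"mean"`). A clone is marked missing when fewer than 2 usable replicates
remain or when the replicate SD exceeds `max_replicate_sd` (default 1.0
on the z scale). Note that after z-normalization, single-spot noise has
SD 1 by construction, so the default cutoff sits at the center of the
replicate-SD null distribution and deliberately discards a substantial
fraction of clones (roughly 40% of triplicates at three replicates); it
is a conservative spot-quality rule, and cohort frequencies are computed
with per-clone denominators precisely so that this missingness does not
bias them. Missing clones are skipped downstream, never interpolated.

## Segmentation model

Per chromosome, over the observed clones, the normalized values
$y_1,\dots,y_n$ follow a piecewise-constant Gaussian model under a
product-partition prior:

- each of the $n-1$ between-clone gaps is independently a changepoint
  with prior probability $p_c$ (geometric segment lengths); a partition
  with $k$ changepoints has prior weight $p_c^k (1-p_c)^{n-1-k}$;
- each segment's (level, variance) has a conjugate
  Normal–Inverse-Gamma prior: level $\sim N(m_0, \sigma^2/\kappa_0)$,
  $\sigma^2 \sim \mathrm{IG}(\alpha_0, \beta_0)$, giving a closed-form
  segment marginal likelihood.

Because the posterior factorizes over segments, a forward–backward
dynamic program computes **exactly**, in $O(n^2)$: the per-clone
posterior mean, the posterior probability of a changepoint at every gap,
and the model evidence. Exactness is the point of this model choice: a
brute-force enumeration over all $2^{n-1}$ partitions
(`enumerate_posterior_oracle`, $n \le 14$) implements the identical model
independently, and the test suite requires agreement to $10^{-8}$ over
100 random profiles. The DP is the implementation; the enumeration is
never used in the pipeline.

Defaults: $p_c = 0.01$ (one changepoint expected per ~100 clones),
$m_0 = 0$ (the normalized neutral level), $\kappa_0 = 0.01$ (nearly flat
level prior; shift equivariance holds in the $\kappa_0 \to 0$ limit and
is asserted at $\kappa_0 = 10^{-8}$), $\alpha_0 = \beta_0 = 1$ (a weak
prior centered on unit variance, the scale z-normalization produces).
All are exposed.

**Reported segments vs localization.** Gaps with posterior changepoint
probability $> 0.5$ are reported as breakpoints (ties toward fewer
breakpoints). At small steps (about 3 noise SDs) the posterior spreads
changepoint mass over adjacent gaps, so individual gaps can stay below
the reporting threshold even when the breakpoint is well localized; the
posterior mode of the per-gap probabilities is the right location
estimator and is what the planted-breakpoint recovery test measures.

**Calling** is done on the *reported segments'* posterior means (not the
raw per-clone means): state +1 if the segment mean exceeds $\tau$, −1 if
below $-\tau$, else 0. The default threshold is
$\tau = 3 \times$ SD of the normalized self-self clone values
(`default_tau`), i.e. a segment must sit three noise-SDs from neutral.
Calls are emitted per clone (each clone takes its segment's state) and
aggregated into regions downstream.

## Cohort regions

Per-clone gain/loss frequencies use per-clone denominators (samples
observed at that clone). An **imbalance region** is a maximal run of
$\ge$ `min_clones` (default 2) consecutive clones whose same-direction
frequency reaches `threshold_pct`; its frequency is the run's **median**
per-clone frequency, rounded half-away-from-zero to integer percent (the
summary of a multi-clone region is a design choice; the median is robust
to single-clone dips).

Two threshold conventions coexist deliberately: region *tables* include
rows at $\ge 50\%$, while cross-cohort *commonality* requires strictly
$> 50\%$ in both cohorts before intersecting. On the shipped fixture
tables this strict rule uniquely yields the seven common regions (five
gains, two losses) that the inclusive rule would inflate via
exactly-50% rows. Intersections share chromosome and direction;
overlapping or book-ended intersections merge; the reported frequency of
a common region is the smaller of the two cohort frequencies.

The **signed-frequency difference** encodes a group entry as
$s = +f$ (gain), $-f$ (loss), $0$ (none) and reports
$D = |s_A - s_B| \in [0, 200]$. The stratified comparison splits the
cohort by subtype or stage (stages I+II = early, III+IV = late), screens
clones by per-clone $D \ge$ threshold, summarizes each group over a run
by the median signed frequency, and re-applies the threshold to the
summarized $D$. With frequencies jittered by replicate-QC missingness a
planted differential region can fragment into several reported runs;
the per-run group summaries remain close to the planted prevalences.

Coordinates are 1-based inclusive throughout; `region_size_mb` is
$(\mathrm{end}-\mathrm{start})/10^6$ to 2 decimals, and BED export
converts to 0-based half-open.

## Candidate-gene funnel

Genes map into regions by any-overlap ($\ge 1$ bp) and inherit the
region's direction. Gene-set enrichment uses the inclusive upper-tail
hypergeometric probability $P(X \ge x)$ with the **universe defaulting
to all genes in the supplied table** — the least-assuming choice when no
platform universe is given. The raw $P < \alpha$ cutoff (default 0.05)
matches common over-representation practice; Benjamini–Hochberg is
available behind `adjust = "BH"`. At $\alpha \ge 1$ the set filter is a
no-op (permissive limit). The concordance filter keeps gained genes with
tumor/normal expression ratio $> 1$ and lost genes with ratio $< 1$;
genes without expression data are dropped with a reported count. Novelty
is a caller-supplied boolean; the literature search behind it is out of
scope. Funnel monotonicity (each stage a subset of the previous) is a
test invariant.

## Validation scoring

- qPCR: $\mathrm{ratio} = E^{-(\mathrm{Ct_{target}} -
  \mathrm{Ct_{reference}})}$ with efficiency $E = 2$ by default (the
  ΔCt method; $E$ is a parameter because real assays run below 2).
- Group comparison: Welch two-sample two-tailed t test by default —
  chosen over the pooled test because equal variances cannot be assumed
  between tumor and normal ratio distributions; a paired mode exists for
  matched tumor/normal pairs, unpaired is the default.
- CISH: amplification-positive iff strictly more than 40% of $\ge 100$
  evaluated nuclei show $\ge 4$ signals; fewer nuclei is a QC error.
- IHC: overexpression iff strictly more than 50% of tumor cells stain
  positive. Both rules are strict at the boundary and monotone.
- Association with clinical parameters: Pearson chi-square without
  continuity correction (Yates behind a flag), df 1; zero margins are
  rejected.
- Percent frequencies round half-away-from-zero to whole percent.

## Synthetic-data generator

What it emulates: a targeted non-gapped BAC tiling (default clone length
150 kb) over a configurable number of regions; spotting in replicates
(3 by default) across print blocks, with clones assigned to blocks
round-robin so block effects are uncorrelated with genome position;
per-block mean shifts drawn once per design from $N(0, 0.1)$ and
noise-SD multipliers from $U(0.8, 1.2)$ — shared by all hybridizations
of a design, like a print-run effect, which is what makes
self-self-based normalization meaningful and visibly degrades naive
un-normalized calling; spot noise $N(0, \mathrm{noise\_sd} \cdot
\mathrm{mult}_b)$ with `noise_sd` defaulting to 0.2 log2 units, a
mid-range value for spotted BAC arrays (no platform estimate exists for
any specific instrument; it is a placeholder, not a measurement);
state-to-ratio map $+1 \equiv 3$ copies vs 2 ($\log_2 1.5$),
$-1 \equiv 1$ copy vs 2 ($\log_2 0.5$), attenuated by tumor purity $p$
as $\log_2((p \cdot c + (1-p) \cdot 2)/2)$ — the standard
diploid-baseline mixture model.

Cohort truth plants each region's direction in **exactly**
$\mathrm{round}(\mathrm{prevalence} \times n)$ samples, drawn without
replacement (per factor level when a region's prevalence is
subtype- or stage-specific). An exact count rather than a Binomial draw
pins the cohort alteration fraction to its specification — the property
a planted-truth generator should guarantee, and what makes
frequency-recovery tests sharp. Expression ratios match the planted
direction with probability `concordance_prob` (the total direction-match
probability) and flip otherwise. Validation measurements shift the
target Ct by $-\log_2(\mathrm{dosage})$ in amplified tumors and raise
CISH $\ge 4$-signal fractions and IHC percentages between configurable
baseline and amplified levels.

What it does **not** emulate: image-level artifacts, dye-swap or
print-tip loess structure, GC/mappability waves, subclonal mixtures of
more than two populations, copy numbers beyond one step from diploid,
and correlated replicate failures. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
performance on any particular laboratory's arrays.

## Problem sizes used by the tests and workflow

The tests and the acceptance checks run the pipeline at reduced scale —
designs of 3–10 regions × 40–50 clones (the workflow scripts use a
400-clone, 20-block design with 40 + 20 samples; the full-scale
18 × 200 = 3600-clone design is exercised for construction invariants
only). These sizes were chosen as the smallest at which every cohort
property under test (region recovery, frequency convergence,
stratified differences) is already stable; the $O(n^2)$ DP handles
thousands of clones per chromosome without difficulty.

## Known limitations

- The segmentation model is a deliberately exact stand-in for Bayesian
  changepoint regression in general: it assumes Gaussian segments with
  independent levels and geometric lengths. It reproduces the
  qualitative output the downstream stages need (+1/0/−1 per clone),
  but it is not a reimplementation of any particular published sampler.
- Whether tumor arrays should additionally be standardized by their own
  spread is left open; only self-self-based standardization is applied.
- Region frequency of a multi-clone region (median) and the common-region
  frequency (pairwise minimum) are summaries the underlying data do not
  uniquely dictate; both are documented and configurable in code.
- The candidate funnel's counts depend entirely on the supplied gene
  table, gene sets and expression resource; no external annotation is
  bundled.
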