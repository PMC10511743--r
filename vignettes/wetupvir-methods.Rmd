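---
title: "Methods: models, defaults, and design choices in wetupvir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults, and design choices in wetupvir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetupvir)
```

# The scientific setting

Seasonally dry soils hold a diverse but largely dormant reservoir of
virus-like particles. The first rain of the wet season ("wet-up")
resuscitates microbes, triggers rapid growth and mortality, and reshapes
the viral community: richness of viral operational taxonomic units
(vOTUs) drops sharply within a day while total viral biomass rises
several-fold within a week. `wetupvir` implements the computational chain
that quantifies these dynamics from tabular inputs — the outputs of read
mappers, viral predictors, density-gradient fractionation, and CRISPR
spacer searches — and a virion-based model of how much microbial death
viral lysis can explain.

This vignette documents the models and their assumptions, every default
that matters, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the methodology left
genuine choices. It states no empirical result that the package's tests
and acceptance script do not themselves compute.

# Catalog rules

A contig enters the vOTU set when **more than one** prediction tool
called it viral, and it is either predicted circular (implying a complete
genome) or at least 10 kb long. Dereplication consumes a precomputed
pairwise table (alignment itself is out of scope) and clusters
single-linkage over pairs with ANI ≥ 0.95 and aligned breadth ≥ 0.85 of
the shorter sequence; the representative is the longest member, with
length ties broken lexicographically. Single-linkage with a
longest-representative choice matches common vOTU practice; the breadth
convention (shorter-sequence denominator) is the usual one and is
documented rather than configurable. Both the consensus filter and
dereplication are idempotent, and cluster membership is independent of
pair order — properties the test suite checks directly.

# Presence, trajectories, ordination

Presence is breadth-based: a vOTU is present in a virome sample at
**80%** breadth of coverage; in SIP density fractions the cutoff relaxes
to **50%**, but detection is then required in **all three** replicate
tubes of a treatment × time. Lowering a cutoff can only add presences
(monotonicity, tested by property).

Richness and biomass trends are ordinary least squares on per-microcosm
points (plots × times, n = 18 by default), matching how the underlying
study plotted and tested them; the standard error of a time point's mean
uses the number of plots (3). Viral biomass is approximated as total
extracted virome DNA (ng per g soil) multiplied by the fraction of reads
mapping to the vOTU set.

Bray–Curtis dissimilarity is delegated to `vegan::vegdist` and classical
PCoA to `stats::cmdscale` (eigendecomposition of the double-centered
squared dissimilarities). Negative eigenvalues are reported, never
silently dropped; variance-explained fractions are taken over positive
eigenvalues only. All-zero samples have no defined Bray–Curtis distance;
they are assigned dissimilarity 1 to non-zero samples and flagged. Both
routes are cross-checked in the tests against the defining formula and a
hand eigendecomposition.

# Response categories

Persistent vOTUs (present at ≥3 time points within a plot) are
classified by explicit presence rules evaluated in fixed precedence:
ubiquitous (all six times) → early (present at 0, 3, 24 h and gone, or
drastically decreased, after) → late (absent through 24 h, present at
48 h) → 0-and-168 h (present in dry soil and at the end, plus at least
one other time) → other. The precedence makes the categories mutually
exclusive and the classification total over persistent vectors (verified
exhaustively over all 2⁶ presence vectors).

Two deliberate choices:

* "Disappear or drastically decrease" is not quantified in the source
  methodology; it is operationalized as abundance falling below
  `drastic_drop_frac` (default **0.1**) of the 0–24 h mean. Setting it to
  0 recovers literal presence/absence semantics.
* "Late" is interpreted as *first detection at 48 h* (absent through
  24 h, present at 48 h) rather than requiring presence at all of
  48/72/168 h; persistence already guarantees three detections, and this
  reading reconciles the category's two published phrasings.

The hierarchical/k-means clustering originally used to *discover* the
categories is intentionally not part of the tested surface — the package
implements the explicit rules those clusters were reported to define.

# Virus–host consensus

Spacer hits link a vOTU to a host only when the **full spacer** aligns
with **at most one mismatch and no gaps**. Multi-source predictions
(MAG spacers, unbinned-contig spacers, external spacer databases,
sequence taxonomy) are resolved by the deepest rank at which all agree —
a lowest-common-ancestor over rank prefixes — truncated there;
disagreement at the domain rank yields `"unknown"`. A single prediction
is retained unchanged. All sources carry equal weight (the methodology
implies no weighting), and `"unknown"` predictions are treated as
uninformative rather than as conflicts. The LCA is order-invariant,
idempotent, and always a prefix of every informative input — tested
against a brute-force pairwise-prefix oracle.

Lineages are semicolon-delimited, domain→species, with no gap ranks;
reconciling taxonomies (GTDB vs NCBI) is the caller's job via a
rank-name mapping upstream, and virus-taxonomy vOTUs map to hosts via a
user-supplied lookup table.

# qSIP enrichment

A genome's buoyant density centroid in one tube is the abundance-weighted
mean of fraction densities, with weights `rel_abund × dna_ng` (fractions
with zero DNA are dropped). The centroid shift from the unlabeled (¹⁶O)
to the labeled (¹⁸O) treatment converts to atom percent excess through
the standard ¹⁸O-qSIP chain with constants 1.646057 and 0.083506
(density→GC), 0.496 and 307.691 (GC→molecular weight per bp), 12.07747
(maximum mass gain under full labeling), and 0.002000429 (natural ¹⁸O
abundance). The function is strictly increasing in the labeled density,
returns 0 for no shift, and deliberately returns negative values
unclipped so the CI filter can see them.

Estimation choices, made where the methodology defers to an external
implementation:

* **Bootstrap unit: replicate tubes.** Tubes (one per field plot) are the
  independent experimental units; fractions within a tube are not.
  Resampling draws 3 labeled and 3 unlabeled tubes with replacement,
  averages centroids within treatment, and re-applies the chain.
* **n_boot = 1000, percentile CI at 90%** — neither is stated in the
  source; these are conventional values, and both are arguments.
* `W_light` is the mean over unlabeled tubes.
* A genome is estimated only when detected (50% breadth) in all three
  tubes of *both* treatments; estimates whose CI lower bound is negative
  are flagged and excluded from lineage summaries. Excluding one genome
  never changes another's estimate.

# Mortality model

Virions per gram soil follow from DNA mass and mean genome length
(Avogadro's number over 660 g·mol⁻¹·bp⁻¹), cells died from the 16S rRNA
copy loss rate divided by six copies per cell (a conservative copy
number), and the contribution is

$$\text{contribution} = 100 \cdot \frac{\text{virions}/b}{\text{loss rate} \cdot \text{days}/6}$$

for burst size $b$. **The division by burst size is deliberate and
prominent**: the source's printed equation places burst size in the
numerator, but its own reported numbers (largest contribution, 46.6%, at
burst size 1; smallest, 0.23–0.25%, at burst 200) require the inverse
relationship, and one virion per lysed cell logically implies more lysed
cells per virion observed, not fewer. The package follows the reported
monotonicity. The same source also prints a 24 h pair (17.4% at burst 1,
0.02% at burst 200) that is inconsistent with exact 200-fold linearity;
no package behavior is calibrated to it.

"Days" in the denominator defaults to cumulative days since wet-up, with
an interval option (`days = "interval"`); the cumulative series is a
literal running sum of per-time contributions even though the
denominators mix periods — as stated in the source and flagged here.
Time 0 has zero elapsed days, so its contribution is undefined and
flagged, contributing zero to the running sum. Contribution is
homogeneous of degree 1 in DNA mass and −1 in genome length and burst
size, which makes the genome-length sensitivity slope exactly −1 on the
log–log scale — an analytic anchor the acceptance report recomputes.

# The synthetic world

`generate_dataset()` emits every input table with known ground truth.
What it emulates, and the chosen defaults:

* **Design**: 3 plots × {0, 3, 24, 48, 72, 168} h viromes; metagenomes
  and SIP omit the 3 h point (SIP starts at 24 h, since isotope must be
  incorporated during incubation).
* **Richness decline 0.5**: persistent vOTUs get category presence
  templates (mix: early 0.25, late 0.10, ubiquitous 0.15, 0-and-168
  0.15, other 0.35 — chosen, not reported values); transient vOTUs are
  single detections allocated per time so mean richness interpolates
  linearly down to half its initial value.
* **Biomass fold change 5**: the source reports the increase as "at
  least fourfold", a lower bound on a noisy measurement. The latent fold
  change is therefore set *above* the bound (5) so that the realized,
  noisy series still exhibits ≥4-fold — chosen a priori as part of the
  stated world, not adjusted afterwards.
* **Abundances** are lognormal per genome × plot (CV 0.2) with temporal
  multipliers per response archetype, reproducing strong inter-sample
  heterogeneity and the less-even late community; read counts place a
  mean 35.3% of virome reads on the vOTU set (replicate-level sd 0.03 —
  the published ±7.5% spans all times, so within-time replicate spread
  is taken smaller).
* **Density profiles are Gaussian** over the fraction grid (sd
  0.012 g/mL — a typical DNA band width), centered at the GC-implied
  light density (GC ~ U(0.35, 0.65)) or at the density implied by the
  genome's true enrichment via the exact inverse of the APE chain.
  Recorded fraction densities carry measurement noise (sd 0.003 g/mL).
* **Fractions per tube: 20 over 1.61–1.81 g/mL.** This deviates from an
  earlier plan of emulating the study's 5 binned sequencing groups as 5
  fractions: numerical analysis during development showed 5-point
  quadrature of a Gaussian band biases the recovered enrichment by
  ~0.01 APE and, at the stated noise levels, leaves fewer than 95% of
  trials within the 0.05 recovery tolerance the package promises. Twenty
  fractions (typical unbinned qSIP resolution) make the quadrature error
  negligible; `n_fractions = 5` remains available to emulate binning.
* **16S loss rate 2e9 copies·g⁻¹·day⁻¹** (constant over time): the
  underlying per-time rates are not published numerically; this value is
  consistent with ~10⁹ cells per gram at six copies each and the
  reported rapid post-wet-up degradation. Only trend directions — not
  absolute contribution magnitudes — are promised by the synthetic
  world, and no test asserts a contribution magnitude.
* **Evidence tables** plant links that pass each filter and decoys that
  violate exactly one criterion each, so tests can detect any loosened
  or reordered rule.

What the generator does **not** emulate: read-level data (no FASTQ, no
assembly artifacts), sequence content, chimeras, mapping ambiguity,
compositional coupling between vOTU abundances and the unmapped
fraction, or between-plot spatial structure beyond partial pool overlap.
A green truth-recovery test therefore establishes that the decision
rules are implemented as specified — not that they are robust to every
failure mode of real sequencing data.

# Numerical choices

* All randomness derives from one integer seed via named substreams;
  equal configs give byte-identical tables.
* The CI-below-zero filter uses a 1e−9 tolerance so an exactly
  unenriched genome in a noise-free world (CI width 0 at APE 0) is not
  rejected by floating-point jitter.
* Regression on fewer than two distinct x-values is reported as
  undefined rather than an error; a constant response yields slope 0 and
  R² 0.
* Zero-total-read samples are an error naming the sample; zero
  `cells_died` and zero flanking coverage yield flagged `NA`s, not
  errors, so one degenerate time point does not kill a series.
* Coordinates are 0-based half-open where they appear (prophage BED-style
  records); the activity ratio threshold defaults to 1.65, the
  convention of coverage-ratio prophage-activity tools, since no number
  is published.
* "More than 10 kb of flanking region around the alignment" is read as
  total unaligned contig span (the `flank_len` field); a per-side
  requirement is not imposed.

# Known limitations

* The headline dataset statistics of the motivating study (26,368 vOTUs,
  richness R² = 0.28, etc.) are not recomputable without its raw reads;
  the package reproduces the *rules* and the printed worked examples,
  and recovers planted truth in the synthetic world.
* The qSIP bootstrap resamples 3 tubes per treatment — with so few
  replicates the percentile CI is coarse; the median is the robust
  quantity.
* The mortality model inherits the source's strong assumptions (every
  virion reflects a recent lysis, complete extraction, one mean genome
  length); its outputs should be read as order-of-magnitude bounds
  across the burst-size grid, and can exceed 100%.
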