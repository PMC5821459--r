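---
title: "Statistical methods for dissecting affinity-captured RNP complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for dissecting affinity-captured RNP complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnpdissect)
```

## Overview

`rnpdissect` implements the quantitative analyses used to dissect a
bait-anchored interactome measured by SILAC affinity-capture mass
spectrometry with label-swapped designs. The motivating system is a
retrotransposon ribonucleoprotein: an epitope-tagged bait (the element's
endonuclease/reverse-transcriptase protein, here called ORF2) is captured
together with a second element-encoded protein (ORF1) and a few dozen host
factors, and a series of perturbation assays asks which co-captured
proteins depend on intact RNA, which co-partition with ORF1, how catalytic
point mutations redistribute the interactome, and how fast each interactor
exchanges in vitro. Every assay reduces to arithmetic on heavy/light SILAC
ratios, so the package is organized around a shared ingestion layer and a
set of assay-specific statistics, with a synthetic-data generator that
plants known structure for validation.

All randomized procedures take explicit seeds and restore the ambient RNG
state, so every analysis is a pure function of its inputs.

## Ratio ingestion and filtering

The universal input is a tab-delimited protein-group table (the
`proteinGroups.txt` dialect; column names are remappable via
`pg_dialect()`). Standard quality filters are applied by `filter_groups()`:
potential contaminants, reversed-decoy hits, groups supported by fewer than
two razor+unique peptides (configurable), and groups without a usable ratio
are removed, each logged under exactly one reason. Ratios of zero (or
infinity), which arise from one-channel-only detections, are treated as
missing for coordinate computation — a fraction of exactly 0 or 1 would
dominate every distance statistic downstream — but they are logged rather
than silently dropped.

A heavy/light ratio r becomes a heavy *fraction* h = r/(1+r), a bijection
of (0, Inf) onto (0, 1). `condition_fraction()` resolves the label-swap
orientation declared by `label_design()`, and `merge_swap_pair()`
intersects the two mixtures of a swapped duplicate into per-protein 2-D
coordinates (one axis per mixture). Proteins quantified in only one mixture
are excluded and logged; the field has no established convention for
imputing the missing axis, and a one-armed coordinate cannot participate in
a radial or proximity statistic.

Ambiguous protein groups are collapsed to a single, consistently applied
gene symbol with the full membership kept in a side column; duplicated
symbols within one file collapse to the record with the most razor+unique
peptides (ties broken by summed intensity where available, else first
occurrence).

## RNase-sensitivity radial test

In the RNase assay the two conditions are an RNase A/T1 digestion and a
BSA mock treatment; proteins requiring intact RNA for retention are more
abundant in the BSA channel. With the control-condition fraction on both
swap axes, unchanged proteins concentrate near a common center and
RNA-dependent proteins are displaced toward (1, 1).

`rnase_radial_test()`:

1. centers the cloud on an estimate of the unchanged population
   (component-wise median by default — robust to the displaced minority;
   mean selectable);
2. computes radial distances from the center;
3. fits a location/scale law to the distances and sets the significance
   radius tau at upper-tail mass alpha (default 1e-3);
4. flags proteins strictly outside the circle (a point exactly on the
   boundary is not flagged), optionally requiring displacement into the
   control-enriched quadrant on both axes (off by default, so every point
   outside the circle is flagged).

The default law fits a normal distribution by the mean and standard
deviation of the distances, tau = mu + z(alpha) * sigma. This choice
follows the field's practice of thresholding the empirical distance
distribution directly, and it is what the package's defaults reproduce. It
is, however, *not* type-I calibrated: under isotropic Gaussian noise the
2-D radial distances are Rayleigh-distributed, and the normal fit at
alpha = 1e-3 realizes a tail mass of about 4.4e-3 (about 2.1e-2 at
alpha = 1e-2). The test suite asserts this miscalibration explicitly. For
calibrated control the `law = "rayleigh"` option estimates the Rayleigh
scale from the mean square distance and sets tau = sigma_R *
sqrt(-2 log alpha); a half-normal option is also provided. Users who need
the nominal alpha to be the realized false-positive rate should use the
Rayleigh law; users reproducing the conventional analysis should keep the
default.

A further caveat measured during validation: because mu and sigma are fit
to *all* distances, a displaced module inflates sigma and therefore tau.
With a 6-member module displaced 5 noise-SDs per axis among 150 proteins,
the per-protein recovery probability is about 0.97 rather than ~1. The
recovery assertions in the tests pool replicate simulated studies (one
study resolves recovery only to multiples of 1/6) to estimate this rate
with a sub-point standard error.

## Split-tandem partition profiles and cluster proximity

The split-tandem assay partitions the bait-captured material into an
ORF1-bound elution and an ORF1-depleted supernatant; each protein's
coordinate is its elution fraction in each swapped mixture.
`normalize_to_anchor()` rescales each axis by the affine map f(x) = ax + b
solving f(anchor) = 1 and f(median) = median: the anchor protein (ORF1)
reads exactly 1 and the population median is untouched. Affinity of the map
means medians commute with it for any sign of a, and ratios of coordinate
differences — hence relative cluster tightness — are preserved. The map is
ill-defined when the anchor sits exactly at the median; this is rejected
with an explicit error.

`cluster_proximity_pvalue()` asks how unusual the tightness of a
designated k-protein cluster is among all k-subsets of the plotted
universe. The proximity metric defaults to the cluster *diameter*
(maximum pairwise Euclidean distance), the most conservative tightness
measure and directly interpretable in coordinate units; mean pairwise
distance and minimal-enclosing-circle radius are selectable and the metric
used is recorded in the result. In exact mode all choose(n, k) subsets are
enumerated and p is the fraction with proximity less than or equal to the
observed value — ties count, and the observed subset counts itself, so
p >= 1/choose(n, k) and can never be zero. Above a configurable
enumeration cap (default 1e8 subsets) the function directs callers to
Monte-Carlo mode, which draws subsets uniformly with a recorded seed and
applies the add-one correction (1 + hits)/(1 + draws). Probabilities are
computed on the plotted (post-filter, both-mixture) universe by default,
and may be computed on raw or normalized coordinates — for the default
diameter metric the two differ only by the per-axis scale factors.

## Catalytic-mutant shift tests

Mutant-versus-wild-type captures put the wild type in the heavy channel
and the mutant in the light channel, in replicate. Per replicate,
`shift_normalize()` subtracts (h_bait - 0.5) from every protein's heavy
fraction, pinning the bait at exactly 0.5 and removing replicate-level
mixing imbalance while preserving all pairwise differences. Shifted values
may leave [0, 1]; they are used unclipped (clipping a pure translation
would bias the means the tests compare) and the affected proteins are
recorded. Relative recoveries (L/H)_i / (L/H)_bait are computed for
display; the tests run on the shifted fraction scale.

Proteins quantified in at least two replicates (configurable) are tested
against the no-change value 0.5 by a one-sample t-test and
Benjamini–Hochberg corrected across the experiment's testable family;
zero-variance proteins are flagged degenerate and excluded from the family
rather than given an arbitrary p. The endonuclease-versus-reverse-
transcriptase comparison uses Welch's unequal-variance t-test by default —
the equal-variance assumption is not justifiable for independently
prepared experiments — with a pooled option behind a flag.
`double_histogram()` bins both experiments' recoveries on shared edges
anchored at 0 (default width 2) and counts proteins whose two positions
fall on opposite sides of the bait, the "crisscross" signature of classes
moving in opposite directions under the two mutations. Mean and SD of
recoveries are emitted on the fold scale; log-scale summaries can be
derived from the per-replicate values included in the output.

## Exchange kinetics

Trajectories are heavy fractions at 0 s (untreated capture), 30 s, 5 min
and 30 min of competition with light extract; times are encoded in
seconds. Only proteins quantified at every time point are used
(`require_complete()`), since a missing cell has no neutral value on the
cosine geometry. Pairwise distances are cosine distances of the full
4-point trajectories: scale-invariant, so clustering (average-linkage,
cut to 3 groups by default, numbered most-stable first by terminal heavy
fraction) reflects decay *shape*, not amplitude. `distance_trajectory()`
implements a cumulative-prefix construction — the cosine distance of the
two proteins' trajectories truncated at each successive time point — and
labels the result as such in its metadata; per-interval and
distance-to-reference constructions are plausible alternative readings of
the same plot, and the labeling keeps the choice auditable.

## Multi-assay integration

Each experiment contributes a per-protein profile vector (its replicate or
time-point values). For every protein pair the experiments in which both
are present are concatenated and Euclidean and cosine distances computed
on the concatenation. Experiments are z-scored per column by default
before concatenation: the assays live on heterogeneous scales, and an
unstandardized concatenation would let the widest-scaled assay dominate
the Euclidean component (a raw mode is available behind a flag; the
planted-module recovery property holds in both modes at the simulated
effect sizes).

Observed Euclidean distances are min-max rescaled onto [delta, 0.9] with
delta = 1e-3: the open interval "(0, 0.9)" must exclude zero because the
combination step takes a logarithm, and delta is the configurable,
recorded realization of that exclusion. Pairs sharing no experiment get a
Euclidean component of exactly 1 — beyond the 0.9 ceiling of any observed
pair — and a cosine component of 1 so that the combined distance is
defined (the convention covers only the Euclidean component in the
original formulation; the cosine value is this package's recorded
decision). The final distance is log(E' * max(C, delta)), min-max rescaled
onto [0, 1]; being a monotone transform of the product E'C it preserves
pair rankings exactly, which the tests assert by rank correlation.
Average-linkage clustering of the final matrix, cut to five groups by
default, yields the integrated groupings; the dendrogram serializes to
Newick.

## Nuclei-pair spatial resampling test

Input is one row per nucleus: field, centroid in microns, and a
marker-positive flag. Observed distances come from mutual-nearest-neighbor
pairing among the positive nuclei of each field, so a proximal doublet
contributes exactly one distance; all-pairs and sequential-greedy rules
are available and the rule used is recorded. Fields with fewer than two
positives are skipped and logged.

The null is built per field: with x positive nuclei among n, each
resampling round draws x nuclei uniformly without replacement from the
field's n and applies the same pairing rule; distances pool across rounds
(default 1000) and fields. Per observed pair, the empirical p is the
add-one-corrected fraction of null distances at or below it, multiplied by
a Bonferroni factor (the number of observed pairs by default) and capped
at 1. The pooled observed distances are additionally compared to the
pooled null by Welch's t-test. Resampling within the observed windows
means no edge correction is applied — the null inherits exactly the
observed field geometry. The reading of "n = 1000" adopted here is 1000
resampling rounds per field (with distances pooled before the t-test),
not 1000 sampled pairs in total.

## Synthetic data: what it emulates and what it does not

The generator plants the structure each stage assumes, with mandatory
seeds: label-swapped ratio tables with logit-normal per-mixture noise
(default SD 0.15 logits, about 0.037 on the fraction scale at h = 0.5, a
typical replicate spread for SILAC AP-MS), decoy contaminant/reverse/
one-peptide rows (5 each per table), a 7-member cytoplasmic module
(bait, ORF1 and five RNA-linked partners), a 16-member nuclear module
containing a tightly co-partitioning triple, four-point exponential decay
trajectories h(t) = (1-b) exp(-kt) + b at rates 1e-4/1e-3/1e-2 per second
with truncated-normal noise (SD 0.02), mutant replicates with class
effects of +/-0.15 on the fraction scale, replicate noise 0.05, and a
replicate-level bait offset (SD 0.03) that shift normalization must
remove, and per-field spatial-Poisson nuclei (20 fields of 400 x 400
microns at 1e-4 nuclei per square micron, i.e. mean nearest-neighbor
spacing 50 microns; positive fraction 0.18 after the observed proportion
of marker-positive cells in this assay class) with planted 10-micron
daughter pairs.

Defaults are the study conditions used throughout the tests and the
acceptance script; `n_proteins = 150` reflects a post-filter bait-capture
table. The generator emulates noise *around a known truth*; it does not
emulate correlated peptide-level quantification error, ratio compression,
missingness that depends on abundance, chromatographic batch effects, or
segmentation errors upstream of the nuclei coordinates. Passing tests
therefore demonstrate that the statistics recover what they are designed
to recover under clean sampling assumptions — not that any particular
biological dataset meets those assumptions.

## Numerical choices and degenerate inputs

* Boundary conventions: radial flags use strict inequality at tau;
  proximity p-values count ties inclusively (conservative).
* The anchor map rejects anchor == median (to 1e-12); the radial threshold
  rejects zero-variance distances; cosine distance rejects zero vectors,
  and the integration layer substitutes the maximal uninformative distance
  1 for degenerate all-zero concatenations rather than erroring mid-batch.
* Agglomeration is delegated to `stats::hclust` (average linkage by
  default; the merge heights are verified against a naive cubic-time
  re-computation in the tests). Dendrograms serialize to Newick with
  branch lengths equal to merge-height differences.
* Empirical p-values are never exactly zero: exact enumeration includes
  the observed subset; resampling uses the add-one rule.
* All clamping of synthetic fractions into (0, 1) uses an epsilon of 1e-6
  so emitted ratios stay finite.

## Problem sizes used in validation

The acceptance checks run: a 5000-protein isotropic null for the radial
type-I rate; 100 replicate 150-protein studies for the planted-module
recovery rate (the rate is a per-protein probability, and a single
6-member module resolves it only to sixths); 20 random instances of exact
subset enumeration (n up to 30, k in {2, 3}) against a brute-force scan
plus Monte-Carlo agreement at 2e4 draws; 100 random anchor-normalization
instances at 1e-12; 1000 random vectors for Benjamini–Hochberg against the
quadratic definition; 200 null and 100 planted nuclei studies at 200
resampling rounds; and two full pipeline runs compared hash-for-hash.

## Known limitations

* The default radial law reproduces the conventional normal-on-distances
  threshold and is anti-conservative by about 4.4x at alpha = 1e-3 under
  an isotropic Gaussian null; the Rayleigh option is the calibrated
  alternative.
* The cluster-proximity universe, metric, and coordinate scale are all
  recorded conventions rather than uniquely determined choices; results
  should always be read together with that metadata.
* Integration treats never-co-detected pairs as maximally distant, which
  shrinks their influence on clustering but cannot invent similarity
  evidence; sparse experiment overlap degrades gracefully but not
  infinitely.
* The spatial test conditions on the observed positive counts per field
  and the observed nucleus positions; it does not model segmentation
  error or field-selection bias.
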