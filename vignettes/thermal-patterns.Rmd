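---
title: "Thermal pattern discovery in equid infrared thermography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal pattern discovery in equid infrared thermography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermopattern)
```

## The problem and the model

Infrared thermography (IRT) renders the surface temperature of an animal as
an image: each pixel of a thermogram holds a temperature in °C. In equids,
surface temperature reflects underlying circulation, muscle metabolism and
the insulating properties of skin and hair coat, which makes IRT attractive
for non-invasive veterinary screening. The question this package addresses
is how to turn such images into *reproducible, testable statements* about a
species' thermal organisation, and how to compare two species (horses and
donkeys) on that basis.

The data model is a pair of grids per animal: a thermal image (native
320 × 240) and a *class map* of the same shape assigning each pixel to one
of 15 regions of interest (ROIs) over large superficial muscles, with 0 for
unannotated background. Because visible thermal structures usually span
several muscles, the 15 ROIs are combined into ten *groups of ROIs*
(GORs) — Neck, Front quarter, Trunk, Hindquarter, Rump, Dorsal aspect,
Ventral aspect, Abdomen, Groins, Legs — which deliberately overlap (ROI 9,
for instance, sits in four GORs). A *thermal pattern* is a statistically
significant difference between the mean temperatures of two GORs.

For a species with animals $A = \{a_1,\dots,a_n\}$ and GORs
$G = \{g_1,\dots,g_{10}\}$, write $T_g^a$ for the pixel multiset of animal
$a$ in GOR $g$ and $\delta(\cdot)$ for the mean. The package computes

$$\Delta(i,j) \;=\; \delta\!\Big(\bigcup_{a\in A} T_i^a\Big) -
                    \delta\!\Big(\bigcup_{a\in A} T_j^a\Big),$$

the antisymmetric 10 × 10 matrix $M_\Delta$ of pooled mean differences.
Each pair is tested twice:

* **globally** — one test on the two pooled samples;
* **locally** — one test per animal, counting in $M_L[i,j]$ how many
  animals individually support the population-level direction.

A pattern that is globally significant *and* locally significant for every
animal is **stable**. Comparing the two species' signed matrices yields a
six-class taxonomy per GOR pair: same sign and significant in both species
(SPS) or not (SP); opposite signs with horses on the warmer side,
significant (HWS) or not (HW); opposite signs with horses colder (HCS/HC).
An individual animal's *compliance* with its species' pattern marks each
pair S when the animal's own difference matches the reference sign and is
individually significant, else NS — a useful lens on outliers such as a
long-haired (globally cold) or patchily hairless (locally warm) animal.

## The test and its sampling scheme

Pixel temperature distributions within ROIs are diverse and often
non-Gaussian, so all comparisons use the one-sided Mann–Whitney–Wilcoxon
(MWW) rank test. One-sidedness is justified because the direction is fixed
*before* testing by the observed mean difference of the compared areas; the
test then asks whether that direction is supported by the ranks.

Because compared areas have unequal pixel counts, both sides are first
brought to a common size $n = \min(|x|, |y|)$: the smaller sample is used
whole and the larger is subsampled uniformly without replacement
(`draw_test_samples()`). An alternative rule that subsamples both sides is
available behind `test_config(n_rule = "subsample_both")`. Each draw uses
its own RNG stream derived by stable hashing of the comparison's descriptor
(species, GOR pair, animal) from the base seed, so results are bit-identical
across runs and independent of evaluation order.

`mww_one_sided()` computes the U statistic with ties counted ½. For
tie-free data with combined size ≤ 12 the exact null distribution is used;
otherwise the normal approximation with tie and continuity correction. The
threshold is configurable (`exact_limit`). Degenerate input with every
value identical returns p = 0.5 flagged as a tie — a fixed convention, not
an error. Significance for pattern claims is p < 0.001; metadata
comparisons report against 10⁻⁴. **No multiple-testing correction is
applied across the 45 GOR pairs** — the fixed p < 0.001 threshold is the
method's convention, and users should read the matrices accordingly.

Two decisions deserve emphasis:

* *Local test direction.* Each animal is tested in the direction of the
  **global** sign of $\Delta(i,j)$, so an animal whose own difference is
  reversed cannot count as support for the population pattern.
* *Pooling.* Pooled samples concatenate animals proportionally to their
  pixel counts, with no per-animal reweighting, and overlapping GORs are
  **not** deduplicated — a pixel contributes to every GOR listing its ROI.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.001 | significance level for global/local/compliance tests |
| `rng_seed` | 1 | base seed; all streams derive from it |
| `n_rule` | subsample_larger | size-matching rule before each test |
| `exact_limit` | 12 | combined n at or below which the exact MWW path runs |
| `perplexity` | 5 | t-SNE perplexity (suits ~32 points) |
| `t_low`, `t_high` | 8.8, 30.65 °C | common colour range of thermal maps |

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, so the whole pipeline is testable without any external download.
A pixel is generated as

$$T = \mu' + a + o_{\mathrm{ROI}} + \varepsilon,$$

with $\mu'$ the species level, $a \sim N(0, \sigma_a^2)$ a per-animal
intercept, $o_{\mathrm{ROI}}$ a per-ROI offset resolved from per-GOR
offsets (conflicting offsets for an ROI shared by two GORs are rejected,
not averaged), and $\varepsilon$ pixel noise — Gaussian or a mean-centred
two-component mixture for multimodal ROIs. Offsets are centred by
annotated-pixel weight, so the configured species mean is exactly the
expected annotated mean. Anomalies are applied last: a uniform cold shift,
or warm patches drawn from the union of the target GORs' pixels.

The *study-like preset* fixes the conditions the analysis is exercised
under: 16 animals per species; horse annotated pixels 22.72 ± 2.46 °C and
donkey 18.88 ± 2.30 °C; Neck and Front quarter +1.5 °C; Rump and Legs
−2.5 °C (the cold-rump/warm-neck organisation seen in rested equids);
hair coat 1.78 ± 0.38 cm (horses) vs 3.39 ± 0.46 cm (donkeys) and SF-Skin
8.80 ± 0.87 mm vs 12.01 ± 0.83 mm, truncated at zero. Only pooled standard
deviations are published for the species, so the split into between-animal
and within-pixel variance is this package's choice: intercept sd 1.5 °C for
horses and 1.2 °C for donkeys (donkeys are the more uniform species), with
pixel noise balanced so the total matches the pooled sd. With
`with_outliers = TRUE` two excluded donkeys are appended: D.17, globally
4 °C colder with 7.6 cm hair (the long-haired case), and D.18 with +3.5 °C
patches over half of Rump, Legs and Hindquarter (the patchy hair-loss
case).

Geometry is a 3 × 5 grid of rectangular ROI blocks: pattern statistics
depend only on label sets, not anatomical shape. What the generator does
**not** emulate: spatial correlation within ROIs, smooth anatomical
gradients, camera noise or emissivity effects, or left/right asymmetry.
Tests passing on synthetic data therefore validate the *statistical
machinery* — they do not certify performance on real thermograms beyond the
modelled structure.

## Features, embedding, rendering

Per-animal feature vectors hold one statistic (mean, sd, skewness or excess
kurtosis — the excess convention is fixed here) per ROI; the *normalized*
variant first subtracts the animal's global annotated mean, making the
transformed annotated mean exactly zero. ROIs with too few pixels for a
statistic yield flagged missing entries, and vectors with missing entries
are excluded from embedding rather than imputed.

The 2-D embedding is exact t-SNE (per-point bandwidths by binary search to
the target perplexity, KL gradient descent with momentum and early
exaggeration), written in-package and fixed-seed reproducible. Rather than
curating a representative run from several executions, this package fixes
the seed and reports one deterministic embedding. Only neighbourhood
structure is interpretable; with ~30 points, silhouette-style separation
claims are made only on synthetic data with constructed separation (the
test configuration narrows the intercept sd to 0.8 °C to guarantee distinct
species clusters for mean features).

Rendering maps temperatures linearly onto a fixed 256-entry violet-to-red
table over a common 8.8–30.65 °C range (clamped at the ends; unannotated
pixels black), or per-animal over the record's own annotated range.
Histograms are probability-normalised by the counts/total rule (heights sum
to 1); a true density option divides by bin width as well. Boxplot
summaries use linear-interpolation quartiles with Tukey whiskers at
q1 − 1.5·IQR and q3 + 1.5·IQR clipped to the data.

## Numerical choices and degenerate inputs

* Pixel extraction order is row-major from the top-left, fixing subsampling
  reproducibility; U statistics are computed in double precision (pooled
  sample products overflow 32-bit integers).
* Empty ROIs/GORs are flagged, never fatal, except where a pooled analysis
  would be undefined; in local counts an animal with an empty GOR is
  skipped and logged, in compliance it scores NS with a logged reason.
* A zero pooled difference (measure-zero event) is tested in the
  `x_greater` direction by convention and cannot be classed as opposite
  sign.
* The class-taxonomy orientation is canonicalised on the (i < j) rendering
  of each pair so that the matrix is exactly symmetric.
* Quartile convention, tie convention (p = 0.5) and kurtosis convention are
  fixed and documented rather than configurable, to keep outputs
  comparable across runs.

## Problem sizes used in the shipped checks

The test suite exercises the pipeline at reduced geometry chosen as the
smallest scale at which every statistical property is still
well-powered: 14 × 14 px ROI blocks (48 × 80 images) for pattern and
embedding checks, and 8 × 8 px blocks (24 × 40) for the 200-replicate
type-I simulation. The acceptance script runs the full study-like scale:
native 240 × 320 thermograms, 16 + 16 animals plus the two outlier
donkeys, roughly one million annotated pixels per species.

## Known limitations

* The pooled "global" test treats pixels as exchangeable units; with
  between-animal variance the effective sample size for *species-mean*
  claims is the number of animals, not pixels. The local count matrix and
  its stability criterion are the package's answer to this — global
  significance alone should not be over-read.
* GOR overlap means the 45 pair tests are not independent, and no
  multiplicity correction is applied by design.
* t-SNE at n ≈ 32 is a visualisation aid; distances and cluster sizes in
  the embedding carry no quantitative meaning.
* The portable text format stores one image per animal; studies with
  bilateral images must choose a side or duplicate records.
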