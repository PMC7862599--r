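---
title: "Methods: 53BP1 pattern scoring, FISH genotyping, and the diagnostic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 53BP1 pattern scoring, FISH genotyping, and the diagnostic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrFoci)
```

# Overview

`ddrFoci` scores DNA-damage-response activation in lymphoid lesions from
multichannel immunofluorescence: every DAPI-segmented nucleus is assigned
one of five 53BP1 staining patterns, and the per-case fraction of abnormal
patterns (high DDR, large focus, diffuse) is the diagnostic statistic. A
companion FISH module calls t(11;18)(q21;q21) fusions and trisomy 18q21
from dual-color probe images. Because the original patient images were
never deposited, the package carries a first-class synthetic generator
that renders fields with known per-nucleus truth; every recovery claim the
test suite makes is a claim about these synthetic conditions, discussed at
the end.

# The five-class model

A nucleus is classified from three measurements: its detected focus
diameters (µm), its supra-threshold coverage, and its intensity
heterogeneity (coefficient of variation):

1. **diffuse** if coverage ≥ `diffuse_min_coverage` (default 0.4) *and*
   heterogeneity ≥ `diffuse_min_heterogeneity` (default 0.3);
2. else **largeFocus** if any focus diameter ≥ 1.0 µm;
3. else by count: **highDDR** (≥ 3), **lowDDR** (1–2), **stable** (0).

Two aspects of this rule are deliberate design choices rather than given
definitions. First, the precedence diffuse > largeFocus > counts: the five
written pattern definitions are not mutually exclusive (a nucleus can carry
three small foci *and* one large focus), and we resolve overlaps toward the
rarer, higher-grade phenotype so that the abnormal grouping is monotone —
adding a focus can never move a nucleus from abnormal back to normal (a
property the test suite checks). Second, "no or weak staining" (stable) is
operationalized purely as *zero detected foci with sub-threshold diffuse
metrics*; we add no separate absolute-intensity criterion because absolute
intensities are not comparable across staining batches.

The numeric diffuse gates are free parameters: the source definition of
the diffuse pattern ("intense and heterogeneous") is qualitative. The
defaults were chosen once from the geometry of the other classes: focal
nuclei have coverage roughly equal to their focus area fraction (a few
percent), and pure-noise nuclei at realistic photon budgets have a
coefficient of variation near 0.2, so 0.4/0.3 sit well between the
focal/noise regime and genuinely pan-nuclear staining.

# Segmentation and focus detection

Nuclei are segmented from DAPI by Otsu thresholding of the lightly
smoothed channel (Gaussian, σ = 1.5 px), hole filling, and a
distance-transform watershed to split touching nuclei (EBImage
primitives). Regions under `min_area_um2` (default 15 µm², roughly half a
small lymphocyte nucleus) and regions touching the field border are
removed — partial nuclei bias focus counts downward. Labels are renumbered
in raster order so segmentation is deterministic.

Foci are detected per field with a scale-normalized Laplacian-of-Gaussian
filter bank over eight logarithmically spaced diameters spanning 0.2–3.0
µm. Candidates are local maxima in space and scale that lie inside a
nucleus. Two contrast gates follow, both relative so that rescaling
intensities (e.g. doubling exposure) leaves detections unchanged:

- peak contrast ≥ `rel_threshold` (default 0.2) × the per-nucleus dynamic
  range (99.9th percentile − median);
- peak contrast ≥ `min_snr` (default 6) × the per-nucleus robust noise
  (MAD of the smoothed channel). This second gate exists because in a
  focus-free nucleus the "dynamic range" is pure noise and the relative
  gate alone would self-normalize noise peaks into detections.

A candidate must additionally be a near-maximum of the smoothed intensity
in its 5 × 5 neighborhood: LoG responses peak not only at blob centers
but also on the shoulders and saddles between adjacent foci, and those
spurious candidates sit below the local intensity crest. Overlapping
detections are merged strongest-first with a merge radius of the larger
blob radius, floored at `merge_min_um` (0.5 µm).

**Focus size.** The written class boundary ("size ≥ 1 µm") does not define
how size is measured. We report the area-equivalent diameter of the
half-maximum region: the connected set of pixels around the peak at or
above background + half the peak's contrast, converted to the diameter of
the circle of equal area. For a Gaussian spot this equals its full width
at half maximum, so a spot rendered with FWHM d is measured back as ≈ d
(slightly widened by the σ = 1 px measurement smoothing, a bias of ~10 %
at d = 0.5 µm and negligible at d ≥ 1 µm, well inside the tested ±20 %
band and far from the 1 µm class boundary on either side).

Coordinates are 0-based pixel indices; physical position = index ×
`pixel_size` (pixel centers). Default `pixel_size` is 0.1 µm/px, a typical
scale for high-magnification oil objectives; the source states only
"1,000-fold magnification".

**Diffuse metrics.** Coverage is the fraction of nuclear pixels at or
above a *field-level* focus intensity threshold (1st percentile + 0.2 ×
dynamic range of all nuclear pixels in the field). Anchoring the threshold
at field level rather than per nucleus is deliberate: a per-nucleus
threshold would make a focus-free noisy nucleus cover ~80 % of itself "at
threshold" by construction. Heterogeneity is sd/mean within the nucleus.

# FISH genotyping

The same blob detector runs on the green (BIRC3) and orange (MALT1)
channels (diameters 0.2–1.2 µm). Within each nucleus, green–orange pairs
are matched greedily in increasing distance order under the colocalization
radius `max_pair_distance` (default 0.6 µm ≈ one signal diameter; the
notion of a "fusion signal" is not quantified in the source). Greedy
matching is used instead of optimal assignment because real signal
configurations are sparse and separated; the test suite checks greedy
against an exhaustive maximum-matching oracle on configurations with up to
three signals per color drawn in that regime.

Per-nucleus genotypes follow the count rules: uninformative (no signals),
fusion (one *or* two fusion signals — the literal reading of the scoring
rule; the generator renders both one- and two-fusion nuclei so both
branches are exercised), trisomy 18q21 (3 orange + 2 green, no fusion),
wild (≤ 2 per color, no fusion; signal loss from nuclear truncation
tolerated), other. A slide is not scorable (NS) below `min_nuclei = 150`
informative nuclei; otherwise it is called translocation or trisomy when
the respective fraction of informative nuclei reaches
`case_fraction_threshold = 10 %`, a threshold anchored to the published
treatment of sub-10 % trisomy as equivocal ("+/−"), which the package
reports as a flag.

# Diagnostic statistics

**AUC and cutoffs.** The ROC area is computed through the Mann–Whitney
relation with ties counted ½, its confidence interval by DeLong's method
(clipped to [0, 1]; with a single observation in a class the variance is
undefined and the uninformative interval [0, 1] is reported). The original
analysis used a logistic-regression ROC; for a single monotone predictor
the ROC curve, AUC and Youden point are identical, and DeLong is the
standard nonparametric interval. The Youden cutoff maximizes
J = sensitivity + specificity − 1 over all observed scores as thresholds,
predicting positive at score ≥ threshold; ties in J break toward the
lowest threshold (maximizing sensitivity at equal J).

**Exact Wilcoxon.** Group comparisons of abnormal fractions use the exact
permutation rank-sum test with mid-ranks for ties. The two-sided p-value
is P(|S − E[S]| ≥ |s~obs~ − E[S]|) under the permutation null — the
symmetric-deviation convention; with ties the null is not symmetric and
other two-sided conventions can shift p in the third decimal. The null
distribution is computed exactly by dynamic-programming convolution over
doubled mid-ranks (so ties cost nothing), with the conventional switch to
a tie-corrected, continuity-corrected normal approximation (flagged in the
result) above a pooled size of 30.

**The MALT association.** `maltAssociation()` reproduces the published
19-case analysis from the packaged table: 6 cases above the 33.6 %
small-cell cutoff (strictly above, following the published "more than"
wording; no case sits exactly on a cutoff), their overlap with
t(11;18)(q21;q21), the low-group composition, and therapy response
excluding no-data and during-therapy cases. For the association test, the
grouping that exactly reproduces the published p-value (0.0145) is
t(11;18)-positive (6 cases) versus t(11;18)-negative (10 cases, no-signal
cases excluded) — recomputation shows the alternative reading
(any aberration incl. equivocal trisomy vs fully wild) gives p ≈ 0.001
instead. The package therefore reports the translocation contrast as the
primary association test and the aberration-vs-wild contrast as a
secondary result.

**Decision flow.** `diagnoseLesion()` is a small rule engine: follicular,
small-cell and large-cell presentations are compared against the
configurable cutoffs 27.2 / 33.6 / 22.9 % (positive at ≥ cutoff); MALT
cases are routed to the FISH call and labeled high-risk
(eradication-resistant) when the slide carries the translocation. Every
applied rule is recorded in a trace.

# The synthetic generator

**Cohort level.** Each lesion type's per-case abnormal fraction is drawn
from a distribution fitted to its published median and interquartile
range. We fit a *location-scale* Beta — shapes (a, b) plus a support
sub-interval [L, U] ⊆ [0, 100] — by multi-start Nelder–Mead least squares
on the three quantiles. A plain two-parameter Beta on [0, 100] cannot
reproduce several of the published summaries (they are skewed the "wrong"
way for a Beta at that mean; the best two-parameter fit misses the GC
quartiles by ~1.7 points and the FL1 median by 2.5), while the
four-parameter family matches all twelve summaries to better than 0.02
points. The bounded support keeps draws in [0, 100] by construction. A
zero-width summary degenerates to a point mass.

**Nucleus level.** A case's nuclei are allocated to the five classes by a
multinomial draw: abnormal probability = the case's fraction, split
(0.6, 0.3, 0.1) over (highDDR, largeFocus, diffuse), and the normal
remainder split (0.6, 0.4) over (stable, lowDDR). Only the pooled
abnormal fraction per lesion was published; the within-compartment mixes
are free parameters, set once to make high DDR the dominant abnormal
pattern and both normal classes common, and are configurable. Focus
truths keep classes visually unambiguous: small foci at 0.35–0.7 µm,
large foci at 1.25–1.8 µm — on both sides clear of the 1 µm boundary, as
in the pattern exemplars the classes are defined from.

**Rendering.** Nuclei are non-overlapping ellipses (radius 2.6–3.8 µm,
mild 0.88–1.0 ellipticity) placed by rejection sampling with a 1-pixel
gap (a crowded field raises a placement error). Foci are 2-D Gaussian
spots whose FWHM equals the true diameter, at amplitude 150 counts over a
weak pan-nuclear baseline (0.15 × amplitude) and a background of 20
counts; noise is Poisson shot noise plus Gaussian read noise (σ = 5).
This puts the peak signal-to-noise ratio near 10, the "default SNR" of
all recovery tests. Diffuse nuclei get a rank-normalized smoothed random
texture, contrast-stretched so that their supra-threshold coverage and
coefficient of variation clear the classifier gates by construction —
the generator renders the *defined* diffuse phenotype, it does not probe
the gates' sensitivity. Z-stacks are not simulated: the analysis operates
on projected images (the package still provides `projectZstack` for real
stacks), so the generator emits already-projected 2-D fields.

**FISH fields** place separated signals (≥ 1.2 µm apart) per genotype
configuration; fusion pairs are green–orange doublets within 0.15 µm.

**Problem sizes.** The recovery studies run at the scale a scoring session
would use: 300 nuclei per IF case (the number of nuclei scored per case
was not published; 300 is our default, split over fields of 64 × 64 µm at
~32 nuclei per field) and 200-nucleus FISH slides. Recovery is judged
against the *realized* per-nucleus truth of the rendered nuclei, not the
Beta-drawn case parameter: at n = 300 the multinomial draw alone wanders
±3 points around the target, which is sampling variation, not measurement
error.

# What the synthetic conditions do and do not show

The generator reproduces the statistical structure the analysis assumes —
class frequencies, focus geometry in physical units, Poisson-limited
photometry, genotype signal configurations — but not the hard parts of
real tissue: optical sectioning and defocus, autofluorescence, staining
gradients, nuclear crowding and overlap in thick sections, partial
hybridization, or the anatomical geometry of real follicles (region
labels are painted per nucleus, not grown from tissue architecture).
Passing recovery tests therefore demonstrates that the measurement chain
is correct and unbiased under its own model, and that the statistical
layer reproduces every published quantity derivable from the printed
table; it does not validate the thresholds against real biopsies. The
published cohort-level AUCs (0.942 / 0.892 / 0.859) depend on unpublished
per-case raw data and are deliberately not reproduction targets; the
synthetic follicular cohort's AUC is a property check (> 0.90), not a
reproduction.

# Other numerical choices

- Beta quantile fitting: multi-start Nelder–Mead (12 starts over support
  width and offset), objective = squared quantile error + 10^-7 ridge on
  log-shapes toward 2 (selects the tamest among near-equivalent exact
  fits); reltol 10^-14.
- Watershed tolerance 1 on the distance map; smoothing σ = 1.5 px before
  Otsu stabilizes the threshold under shot noise.
- All seeds flow through `withr::with_seed`, so generator calls are
  reproducible and leave the caller's RNG state untouched; multi-field
  simulations derive per-field sub-seeds congruentially, kept below 2^31.
- 16-bit TIFF I/O stores integer-rounded counts exactly (values clipped
  to [0, 65535]).
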