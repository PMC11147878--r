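---
title: "Multivariate localization by representational fidelity: models and methods"
author: "replocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate localization by representational fidelity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Language-responsive cortex is conventionally localized with a univariate
contrast (e.g. sentences > pseudowords), which favors regions whose mean
activation separates conditions. `replocal` implements the complementary,
more inclusive multivariate strategy: find regions whose *multivoxel
pattern geometry* is reproducible across subjects, then ask what those
patterns represent. The package covers the full chain — representational
fidelity mapping, multivariate ROI (mROI) definition,
partial-correlation representational similarity analysis (RSA) for
single-word semantics with orthographic and phonological controls, and
ROI-level sensitivity and laterality evaluation — plus a synthetic
multi-subject generator so that every stage can be validated against a
known ground truth.

# Data model

Volumes live on a `VolumeGrid` (dims, voxel size, 4x4 affine; default
3 mm isotropic). World coordinates follow RAS with negative x in the
left hemisphere, the convention of stereotaxic peak tables. A
`SubjectBetaSet` holds one beta estimate per stimulus presentation per
gray-matter voxel; rows must be in the same order for every subject. The
atom of all analyses is the `RDM`: a symmetric condition-by-condition
dissimilarity matrix with an exactly zero diagonal, vectorized by its
strictly-lower triangle in R's column order (pairs (2,1), (3,1), ...,
(n,1), (3,2), ...) — the one fixed convention every comparison uses.

# Representational fidelity (RF)

Per-word patterns are the equal-weight mean of a word's presentations
(three, in the emulated design). At each searchlight center the
neighborhood patterns give each subject an observed RDM
(dissimilarity = 1 − Pearson correlation between pattern vectors, the
dominant convention in correlation-based RSA; squared Euclidean is
available by argument). Fidelity for subject *s* is the correlation
between the subject's vectorized RDM and the elementwise mean of all
other subjects' RDMs (leave-one-out). Pearson is the default fidelity
correlation; Spearman is selectable.

The searchlight is the set of integer offsets with Euclidean norm at
most the radius. The default radius is **3.0 voxel units, a 123-voxel
sphere**: lattice enumeration gives 123 points at radius 3.0 (and 179
at 3.5), and the analysis this package re-implements is defined by its
123-voxel sphere, so the voxel count is taken as authoritative. Each
in-mask voxel serves as a center exactly once; edge neighborhoods are
truncated rather than dropped, and neighborhoods below `minMembers`
(default 10) are flagged.

The mROI is defined from the per-subject fidelity maps: Fisher
z-transform, voxelwise one-sample t against zero — one-sided, because
only *positive* cross-subject reproducibility defines a localizer —
thresholded at a deliberately inclusive voxel p < 0.05, then connected
components (26-connectivity by default; the neighborhood rule behind
extent thresholds is rarely stated, and corner-connectivity is the most
inclusive choice) smaller than 120 voxels are discarded. Caveat:
leave-one-out values are not independent across subjects, so the t-test
is a pragmatic reference distribution; a sign-flip permutation
alternative is available (`method = "signflip"`).

# Predicted RDMs and edit distances

*Semantic*: absolute pairwise differences of a rated property
(concreteness 1–5, or imageability). *Orthographic*: Levenshtein
distance over case-folded letters with unit costs (so "bullet" vs
"wallet" is 2 and "wallet" vs "jacket" is 3). *Phonological*: the same
dynamic program over phoneme symbols, but substitutions cost the
fraction of mismatching phonetic features — place and manner of
articulation for consonant pairs, height and backness for vowel pairs
(0, 0.5 or 1), 1 across classes, insertions/deletions 1. The cited
feature-based scheme does not print its weights, so the
mismatch-fraction rule over the two named features is this package's
documented choice; voicing can be added by argument. Feature-aware
costs attenuate the orthography–phonology correlation, which is what
makes it possible to include both as simultaneous controls. The feature
table ships as a TSV (ARPABET-style symbols) and can be replaced by
path.

# Partial-Spearman RSA

Betas are z-scored across stimuli within voxel (sample SD; idempotent).
At each center, the neural RDM vector is average-rank transformed, as
are the predicted target and control vectors; target and neural ranks
are residualized on the controls (least squares with intercept) and the
residuals Pearson-correlated. With no controls this is exactly
Spearman's rho; with controls it matches the recursive
partial-correlation formula, which the tests verify. A vector fully
explained by the controls has no residual association and yields 0 by
convention. Predictor pairs correlated beyond |r| = 0.7 — the
conventional multicollinearity bound for linear-model predictors — are
warned about.

Group inference: subject coefficient maps are Fisher z-transformed,
smoothed with a mask-normalized Gaussian kernel (5 mm FWHM default;
kernel weights renormalized over in-mask voxels so edge voxels are not
dragged toward zero, preserving constants exactly), and entered into a
two-tailed one-sample t-test. The transform order (z before smoothing
and t) is the variance-stabilizing standard; the literal
smooth-then-t-then-z order is available via `order = "literal"`.
Voxelwise p < 0.005, then cluster-extent correction by sign-flip
permutation: subject maps are randomly sign-flipped, the maximum
suprathreshold cluster size over both signs forms the null, and
observed clusters keep p = (1 + #{null >= size}) / (nPerm + 1). The
correction method behind the emulated analysis is unstated; sign-flip
maximum-cluster permutation is the assumption-light standard and is
seeded for reproducibility. An empty corrected mask is a valid result,
not an error.

# ROI evaluation

ROI queries take the top 20% most active voxels of the *group* map
within each ROI (k = max(1, round half-away-from-zero of
fraction·|ROI|); ties broken by ascending linear index so selection is
deterministic; group-level selection is the default because the
emulated procedure does not state group-vs-subject selection, and a
per-subject variant exists). Mean parameter estimates are compared
between ROIs with paired two-tailed t-tests, since the same subjects
contribute to every ROI. Overlap accounting reports |A|, |B|, |A∩B|,
per-hemisphere intersection counts, and percentages to one decimal.
The laterality index is LI = (V_left − V_right)/(V_left + V_right)
over hemisphere voxel counts (midline voxels excluded; undefined and
flagged when no lateralized voxels exist). Stimulus matching uses the
pooled-variance two-sample t reported as a magnitude with
df = n1 + n2 − 2; pooled (not Welch) variance reproduces the printed
statistics of the emulated stimulus table, so pooled is the
implementation.

# The synthetic generator

`synthStimuli` draws an abstract/concrete word set that mimics a
matched design: concreteness from two normals (2.45 ± 0.59 vs
4.79 ± 0.19, clipped to [1, 5] — the printed group summaries of the
emulated stimulus set, with a 2:1 abstract:concrete ratio, 128/64 by
default), log frequency, length and syllables drawn identically in both
groups. Words are random letter strings; transcriptions are random
pronounceable consonant–vowel sequences over the packaged phoneme
inventory.

`synthBetas` implements the minimal generative model under which
fidelity and RSA dissociate: each planted region carries stimulus
scores *F* — the standardized property for semantic sources, three
standardized classical-MDS coordinates of the edit-distance RDM for
phonological/orthographic sources (edit distances are not coordinates;
a low-rank embedding is needed), or a shared random vector — projected
onto voxel loadings *L* ~ N(0,1) that are **shared across subjects**
(weighted by effect size *w*). Shared loadings are what make
cross-subject fidelity positive. Nuisance structure (3 latent
dimensions at weight 0.3 by default, a modest idiosyncratic component)
is drawn per subject; presentation noise ε ~ N(0, σ²) is independent
per subject/presentation/voxel, with each of a word's three
presentations an independent replicate of the word's mean pattern. All
randomness flows from the single mandatory seed.

What it does *not* emulate: hemodynamics and temporal structure,
spatial autocorrelation of noise, anatomical variability, registration
error, and realistic lexical statistics. Passing recovery tests
therefore demonstrates correctness of the analysis chain, not
performance on real acquisitions.

## Recovery targets and the searchlight halo

A center-assigned searchlight map attributes signal to every center
whose sphere overlaps informative voxels, so a planted region of radius
r is detectable out to r + radius: the honest recovery target for a
center-indexed map is the region's *dilation by the searchlight radius*
(`detectableRegion`), restricted to the mask. Scoring against the raw
seed voxels would cap the Dice of even a perfect implementation near
2|R|/(|R| + |dilated R|). With the inclusive p < 0.05 / 120-voxel mROI
settings, the demo fixture's planted semantic region is recovered
against its detectable extent with Dice ≈ 0.67 per draw.

## Problem sizes

The shipped designs are `tiny` (4 subjects, 12³ grid, 24 words; unit
tests) and `demo` (12 subjects, 24³ grid with a ~3,700-voxel spherical
mask, 96 words, two planted ~150-voxel regions — semantic and
phonological — at effect 1.0, noise SD 0.5). These sizes keep a full
multi-seed recovery study in the minutes range on one CPU while leaving
all planted effects comfortably detectable; they are the package's
validation conditions, not tuning knobs.

# Numerical choices and degenerate inputs

- Sphere membership uses squared norms with a 1e-9 slack so exact-radius
  lattice points are included regardless of floating-point noise.
- Zero-variance voxels cannot be z-scored; they become NA and are
  dropped per-neighborhood (a center keeps its value as long as two
  usable voxels remain; otherwise it is NA and flagged).
- Zero-variance RDM vectors make correlations undefined: plain RDM
  correlations return NA; the partial correlation returns 0 when a
  vector is fully explained by the controls (no residual association).
- Paired tests guard against numerically constant differences
  (|sd| <= 1e-10 · max(1, |mean|)) instead of calling `t.test` on
  degenerate data.
- Fisher z clamps |r| at 1 − 1e-12 before `atanh`.
- Cluster labeling is an in-package BFS flood fill (no installed R
  package labels 3D components); tests cross-check it against a
  graph-components oracle.
- The compiled searchlight kernels (RcppArmadillo) are exact
  re-implementations of the R reference path (`runSearchlight` +
  `neuralRDM` + `looFidelity`/`partialSpearman`); tests assert equality
  at 1e-10.

# Known limitations

- The RF group test treats leave-one-out fidelities as independent
  across subjects; they are not. The permutation option shares the
  limitation at the exchangeability level. Both are stated choices, not
  resolved questions.
- Whether betas should be z-scored before the RF stage (they are for
  RSA) is left as a flag; the default RF input is raw per-word averages
  versus baseline.
- Partial rank correlation removes only the rank-linear component of
  the controls. Geometry related nonlinearly to a control (e.g. a
  bounded correlation-distance realization of it) leaves a small
  word-sample-dependent residual; with 96-word draws this scatter is on
  the order of ±0.01 on the coefficient scale, two orders below the
  planted effects, and centers on zero across draws.
- Euclidean-vs-correlation metric matters for low-rank planted signal:
  a 1-D property times shared loadings yields pattern distances exactly
  proportional to property distances, but a *binary* correlation-distance
  RDM in the noiseless limit. The correlation metric remains the
  default because it is the field convention and is what the RSA stage
  assumes; the generator's planted effects are chosen to be detectable
  under it.
- No crossnobis/Mahalanobis distances, noise ceilings, TFCE,
  surface-based searchlights, or single-trial estimation from time
  series.
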