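---
title: "Best-stimulus prevalence mapping of gustatory fMRI responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Best-stimulus prevalence mapping of gustatory fMRI responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tastemap)
```

## The problem

Sensory cortices tend to represent stimulus features in spatially ordered
maps (retinotopy, tonotopy, somatotopy). Whether the primary taste cortex
in the insula carries an analogous *chemotopic* layout — distinct cortical
territories preferring sweet, bitter, sour, salty, umami, or carbonation
(CO~2~) — is hard to establish with event-related fMRI: responses to
different tastants overlap heavily, overall response amplitude differs
between tastants and subjects, and the folded insular anatomy varies
across individuals.

`tastemap` implements the analysis strategy that addresses these three
obstacles, and a synthetic-data generator that lets every stage be tested
end to end without any acquisition:

1. **GLM estimation** of per-tastant response amplitudes ("beta maps") at
   every vertex of a cortical surface patch;
2. **curvature-driven inter-subject alignment** of the patches to a
   moving average template, so that homologous folds coincide before any
   averaging;
3. **best-stimulus ("prevalence") mapping**: per-vertex z-scoring of each
   taste's beta map over the insular mask, ranking of the six z-scores,
   and a winner map in which each vertex is labelled with its top-ranked
   taste — a *relative* representation that is immune to overall
   amplitude differences between tastants;
4. **group inference** (random-effects one-sample t tests with
   cluster-level family-wise-error control by sign-flip permutation) and
   **similarity statistics** quantifying how well individual maps agree
   with the group map.

## The stimulation protocol

The simulated session delivers six tastants, four times each, in four
pseudo-random six-tastant sequences. One liquid event is: a 0.5 s auditory
cue and delivery of 5 ml over 2 s, a 10 s tasting phase, a second cue and
a 3 s swallow, then 15 s rest; every tastant event is followed by a
rinse-water event with the identical phase structure. At 30 s per liquid
event this gives 48 events (24 tastant + 24 rinse), 1440 s of scanning at
TR = 2 s (720 volumes), and 240 ml of delivered liquid.
`build_schedule()` performs this arithmetic and the schedule tests pin it.

## The forward model and the generator

The generator plants a ground-truth chemotopic layout on a triangulated
rectangular strip ("the patch", default 600 vertices, 60 mm × 9 mm) whose
anterior–posterior axis is parameterized by `ap_coord` in [0, 1] and whose
signed curvature alternates sinusoidally (4 gyral/sulcal cycles),
mimicking the folding pattern that drives cortical alignment. An
elliptical interior subset is the insular mask.

Each taste receives a Gaussian amplitude bump (sd `width = 0.08` in ap
units) centred at equally spaced positions in the planted
posterior-to-anterior order *sweet, bitter, CO~2~, salt, umami, sour*.
A cross-talk fraction (`overlap = 0.3`) mixes every taste's bump into
every other taste's map, so all tastants activate the whole mask to some
degree — the overlapping-response regime the method is designed for. The
mixture is arranged so the per-vertex argmax taste is unchanged by the
mixing for any `overlap < 1`.

Per subject, BOLD at a vertex is the planted amplitude (read at the
subject's *warped* anatomical coordinate) times the canonical
double-gamma HRF convolved with the taste boxcar (delivery + tasting,
12 s), plus cue/swallow/rinse nuisance responses at 50% of the mean taste
amplitude, a slow cosine drift, and AR(1) Gaussian noise. Head-motion
parameters are simulated as bounded random walks; "excluded"-severity
subjects contain an excursion beyond the 1-voxel / 1-degree thresholds.

**Noise level.** No taste-fMRI contrast-to-noise figure is available to
copy, so the default noise sd is set analytically: `calibrate_sigma()`
chooses `sigma` so that the per-vertex CNR — peak planted amplitude over
the GLM beta standard error implied by the default design — equals 1.5, a
deliberately modest, 1.5 T-like operating point. Winner maps at a single
subject are then unreliable by construction; the pipeline must rely on
group averaging and smoothing, as the method does on real data.

What the generator does *not* emulate: physiological (cardiac/respiratory)
noise structure, susceptibility artifacts, volumetric acquisition and
projection, motion-correlated signal changes, or 2-D folding patterns
(curvature varies only along the ap axis). Passing tests therefore show
that the analysis logic is correct under its stated assumptions, not that
the pipeline is robust to every property of real data.

## GLM

`build_design_matrix()` follows the standard event-related construction:
one boxcar per taste spanning delivery + tasting (the swallow phase is
excluded by default; `include_swallow` flips this), convolved with the
canonical HRF (peak delay 6 s, undershoot delay 16 s, ratio 1/6, 32 s
support) and its temporal derivative; cue, swallow and rinse regressors;
the six motion traces; discrete-cosine drift regressors for all
frequencies below 1/128 s⁻¹ (22 columns for the default session); and an
intercept. `fit_glm()` solves ordinary least squares per vertex; the
taste beta is the canonical (non-derivative) coefficient — the derivative
is treated as a nuisance that absorbs small response-latency shifts.
OLS rather than prewhitened GLS is a known simplification; with AR(1)
noise the betas stay unbiased but their nominal standard errors are
approximate.

Beta maps are smoothed *on the surface* with `smooth_map()`, iterative
neighbour averaging whose iteration count is calibrated from the mesh
geometry so the accumulated diffusion variance matches a Gaussian kernel
of the requested FWHM (default 8 mm; the impulse-response test verifies
the calibration within 15%). Smoothing is confined to the mask: unmasked
neighbours carry no signal, and letting them bleed in systematically
attenuates boundary-adjacent clusters. Smoothing beta maps after a linear
fit rather than time series before it commutes up to boundary effects and
keeps the pipeline surface-native.

## Inter-subject alignment

Full cortex-based alignment operates on 2-D spherical hemisphere
meshes; here it is deliberately reduced to a 1-D problem: each subject's
warp is a strictly increasing piecewise-cubic (monotone Hermite) map of
the ap coordinate with anchored endpoints, estimated purely from binned
curvature profiles. This captures the tested behaviours — curvature-driven
correspondence, the moving-target average, variance reduction — at desk
scale, and is documented loudly as a simplification.

The estimation has two phases. A direct simultaneous "register everyone
to the current average" scheme proved to converge to a poor group
consensus when planted displacements approach half the folding period
(the initial average of misaligned sinusoids is attenuated and phase
mixed). Instead:

1. the most *central* subject (highest mean profile correlation with the
   others) seeds the template; the remaining subjects join one at a time
   in centrality order, each registered against the average of the
   already-aligned profiles, with a multi-start over smooth global shifts
   so nobody locks onto the wrong gyrus;
2. moving-target refinement then re-optimizes every warp against the
   dynamically updated average until the residual curvature variance
   stops improving.

Warps are optimized by coordinate descent over their control points: each
interior knot is line-searched over a bounded grid strictly between its
neighbours, so every candidate warp is monotone by construction. The
objective adds a bending-energy penalty (`smoothness = 1e-3`, chosen by
the warp-recovery experiment) to the mean squared curvature mismatch.

**Gauge.** A template-free groupwise registration cannot identify a
common warp component: composing every warp with the same map leaves all
profiles aligned. The only principled anchor is to re-centre so the
cohort-mean warp is the identity, which is done after every join and
every refinement round. Warp-recovery accuracy is therefore bounded below
by how far the true cohort-mean warp happens to sit from the identity
(about 0.01 in ap units for 8 subjects at maximum displacement 0.1); the
recovery test operates comfortably above that floor.

Aligned maps are *pulled back* to template vertices through the inverse
warp with linear interpolation along each lateral row of the strip —
never pushed forward, which would leave holes.

## Group statistics

`group_ttest()` is the random-effects one-sample t test across subjects.
`cluster_fwe()` thresholds the t map at the one-sided cluster-forming
level (`cf_p = 0.01`; the primary threshold is a free choice and is
configurable), finds connected components under mesh edge adjacency, and
corrects cluster sizes by the permutation distribution of the maximum
cluster size under random sign flips of whole subject maps — exact under
symmetric errors and free of any smoothness estimation. This replaces
random-field-theory correction deliberately.

Two numerical caveats are documented rather than hidden. First, the
maximum-cluster-*size* statistic is integer-valued; on a small unsmoothed
mesh its permutation distribution is so discrete that the achievable test
level can sit far below the nominal 0.05. The calibration experiment
(500 null cohorts of 8 subjects, 200-vertex mesh, 300 sign flips)
therefore uses spatially smoothed null maps — matching what the group
stage always receives from the pipeline — where the realized family-wise
error rate lands near 0.03–0.04. Second, with overlapping responses the
six absolute "taste vs rest" t maps share a dominant common component, so
the *location of their argmax peaks* is unstable from cohort to cohort.
That instability is precisely the argument for the relative prevalence
representation: the planted ordering is recovered robustly by the
prevalence cluster centroids, and the tests assert it there.

## Prevalence mapping

`zscore_maps()` standardizes each taste's beta map to mean 0, sd 1 over
the insular mask (tolerance 1e-9 in the tests); any positive affine
rescaling of a taste's map — scanner scaling, global responsiveness
differences — leaves the output exactly unchanged, and a property test
asserts this invariance end to end.

`rank_and_win()` sorts the six z-scores per vertex. The winner is the
rank-1 taste; exact ties are broken by the fixed canonical taste order so
the output is deterministic (ties are measure-zero on continuous data but
must not be left to sort instability). Saturation encodes the winner's
margin: `100 * (z1 - z2) / z2`, anchored so 100% means the top taste
doubles the runner-up. When the runner-up z is not positive the ratio is
undefined; saturation is then reported at the configurable cap (default
200%), which also bounds the ratio for near-zero denominators. Ranks map
to a normalized preference score `(R - rank) / (R - 1)`: 1 for the best
taste, 0 for the worst.

`exclude_taste_remap()` re-ranks over the remaining five tastes
(preference renormalized with R = 5) and labels vertices whose new margin
falls below `clarity_min` (default 5% saturation; the threshold
operationalizes "no clear prevalence" and has no published value) as
`"unassigned"`.

One subtlety discovered by the noiseless identifiability test: per-taste
z-scoring can permute winners in hairline bands at cluster boundaries
whenever the six beta distributions over the mask differ (the elliptical
mask truncates edge bumps differently from interior ones). This is a
property of the method, not an artifact — the standardized map *is* the
method's definition of preference. Ground truth for winner-map checks is
therefore the planted layout passed through the identical
standardization; on the default patch it agrees with the raw amplitude
argmax at 96% of masked vertices.

Group prevalence is computed by default from the z-scored *group-averaged*
aligned beta maps; averaging the per-subject z maps instead is available
via `group_prevalence_z(mode = "average_z")` and agrees with the default
on the planted structure.

`similarity_analysis()` quantifies individual-to-group correspondence:
Pearson correlation per taste between subject and group beta maps, and
Spearman correlation between preference maps — computed on the
concatenated normalized-preference vectors of all tastes, because the
information in a preference map lives in the ranks. P values come from a
vertex-permutation null (one-sided for positive association). The group
map includes the subject, which inflates the correlation slightly for
small cohorts; a leave-one-out variant would remove this bias and is an
acknowledged omission.

## Reproducibility and problem sizes

Every stochastic component is a pure function of an integer seed:
cohorts, noise, motion, permutations. The test-suite problem sizes are
the package's own choices for a desk-scale demonstration: 600-vertex
patches and 10-subject cohorts (two planted motion violators) for the
end-to-end layout-recovery and similarity checks; a 200-vertex mesh with
500 null cohorts for the family-wise-error calibration; 1600 vertices for
the smoothing-kernel calibration; 8 subjects at maximum displacement 0.1
for warp recovery.

## Known limitations

- No prewhitening in the GLM (OLS with AR(1) noise).
- 1-D alignment along the ap axis only; real cortex-based alignment is
  2-D and multiresolution in the folding pattern itself.
- Warp recovery is identifiable only up to the cohort-mean gauge.
- Similarity includes the subject in the group map (no leave-one-out by
  default).
- The generator omits physiological noise, motion-signal coupling, and
  volumetric projection; conclusions from passing tests are about the
  analysis logic, not scanner realism.
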