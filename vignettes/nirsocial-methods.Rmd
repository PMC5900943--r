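---
title: "Methods: simulating and analysing infant social-brain fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing infant social-brain fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`nirsocial` implements an event-related optical topography pipeline for
infant social-brain experiments: dual-wavelength light intensity is
converted to oxy- (HbO2) and deoxy-haemoglobin (HHb) concentration changes
via the modified Beer-Lambert law, trials are screened by looking time and
motion-artifact rules, channel-wise windowed peak statistics are corrected
with the Benjamini-Hochberg false discovery rate, and region-of-interest
(ROI) epoch responses are modelled with linear mixed models across outcome
groups (low-risk `LR`, high-familial-risk without later ASD `HR-noASD`,
high-risk with later ASD `HR-ASD`). A synthetic-data generator emulates the
stimulus design, hemodynamics, physiological noise, motion artifacts and
looking-time attrition of such studies, so that every stage of the analysis
can be verified by parameter recovery rather than by inspection.

## The experimental design being emulated

Three experimental conditions -- visual social videos (`V-S`), auditory
vocal with concurrent visual social (`A-V`), auditory non-vocal with
concurrent visual social (`A-NV`) -- are presented in a fixed twelve-trial
loop, with a silent static non-social reference trial (`REF`) before,
between and after the experimental trials. Experimental and reference
trials last 9--12 s (uniformly sampled by default); auditory stimuli span
exactly 8 s from trial onset. The probe consists of two temporal-frontal
arrays, 26 channels at 2 cm source-detector separation, measured at 770 and
850 nm. Channels map to three social-brain ROIs per hemisphere -- inferior
frontal gyrus (IFG), anterior middle/superior temporal gyri (aMTG-STG), and
posterior superior temporal sulcus / temporoparietal junction (pSTS-TPJ).
The channel-to-ROI map shipped as `default_probe_map()` is a synthetic
stand-in encoding the schematic arrangement (frontal channels to IFG,
anterior temporal to aMTG-STG, posterior temporal to pSTS-TPJ); a study
with a co-registered anatomical map should supply it via
`read_probe_map()`.

## Preprocessing model

Attenuation change is `-log10(I/I_ref)` per channel and wavelength, with
`I_ref` the series mean; any constant reference choice shifts the series by
a constant that later stages remove. The continuous attenuation is low-pass
filtered at 1.7 Hz before segmentation. The filter family and order are not
dictated by the analysis tradition, so the package uses a 5th-order
Butterworth applied forward-backward (zero phase), preserving response
latency for the onset-locked windows; both ends of each series are padded
with the odd reflection of the signal and each pass is referenced to its
starting level, so a constant series is reproduced exactly (unit DC gain)
and edge transients decay inside the padding.

Blocks span 4 s of the preceding reference trial, the experimental trial,
and the following reference trial, extended to at least 20 s post-onset so
that the 0--20 s epoch summary is always covered. Each block is detrended
by the line through two anchor points: (centre of the first 4 s, mean of
the first 4 s) and (centre of the last 4 s, mean of the last 4 s). This
reading makes "a linear fit between the averages" exact and testable: any
exactly linear trend is removed to numerical precision, and the procedure
is idempotent.

The modified Beer-Lambert law is solved per time point as a 2-by-2 linear
system with specific extinction coefficients (cm^-1 per uM), source-
detector separation 2 cm and an infant differential pathlength factor of
5.13 (effective pathlength 10.26 cm). The extinction table is
configuration; the shipped default is taken from standard tabulated
haemoglobin spectra, and all tests of the conversion use a forward/inverse
oracle so that correctness does not depend on the particular table.

## Rejection and inclusion rules

A trial is looking-valid only if the coded looking proportion strictly
exceeds 0.60; a proportion of exactly 0.60, or a missing code, invalidates
the trial. Channel-level intensity screening rejects a channel when its
coefficient of variation exceeds `cv_max` (default 0.10) or when the
fraction of samples deviating from a 1 s sliding median by more than
`spike_z` (default 5) robust SDs exceeds `spike_frac_max` (default 0.02).
Trial-level concentration screening flags a trial on a channel when
|dHbO2| changes by strictly more than `jump_umol` (default 1.0 uM) across
any `jump_window_s` (default 0.5 s) interval. The published accounts of the
original in-house artifact detectors do not specify their algorithms, so
these two scans are explicit, thresholded re-specifications; every
threshold is surfaced in `analysis_options()` and logged in the run
manifest. A channel is retained only with at least three valid trials in
each of the three conditions; an infant is retained only with at least
three valid trials per condition on at least one retained channel (the
order of the two rules is not dictated anywhere, and with this reading the
channel rule is the binding one); an infant with no retained IFG channel in
either hemisphere is excluded from the visual analysis only. All rules use
strict or non-strict comparisons exactly as stated, and the boundary cases
(0.59 vs 0.61 looking; 2 vs 3 trials) are asserted in the test suite.

## Response statistics

Valid trials are averaged within channels per condition on the onset-locked
grid [-4, 20] s; because trial durations vary (9--12 s), averaging past the
end of a trial deliberately includes the following reference-trial data, as
the 12--16 s analysis window extends beyond the end of the trial. Windowed
peak statistics take the signed extremum within the 8--12 s and 12--16 s
windows minus the mean over the [-4, 0) s pre-stimulus baseline; for HbO2
the extremum is the maximum and for HHb the minimum, activation being an
HbO2 increase or an HHb decrease. Channel-wise inference uses two-tailed
t-tests -- one-sample against zero for the baseline-referenced visual
peaks, paired across the two auditory conditions within infants -- with
Benjamini-Hochberg adjustment applied across channels separately within
each chromophore-by-window family (the correction family is not dictated;
per-family correction across the montage is the conservative reading that
matches how the channel tables are reported). The visual channel test is
implemented as a baseline-subtracted one-sample test against zero rather
than a paired test against a reference-period sample; the baseline
subtraction makes the two readings equivalent up to the pairing of noise,
and the one-sample form is the one the windowed-peak definition supports.

Epoch summaries average the time course within five 4-s epochs between 0
and 20 s post-onset and subtract one scalar, the mean response between 0
and 0.1 s, from all epochs; with inclusive epoch endpoints this integrates
a linear ramp exactly, which the tests exploit as a closed-form oracle. ROI
responses average epoch summaries across an infant's retained channels
within each ROI and hemisphere; the visual analysis uses IFG and pSTS-TPJ,
the auditory analysis the vocal minus non-vocal difference in aMTG-STG and
pSTS-TPJ.

## Group models

Both group analyses are linear mixed models of outcome group x ROI x
hemisphere x time epoch (8--12, 12--16 s) fitted by REML, with type-III
F-tests using the Satterthwaite degree-of-freedom approximation (the
fractional denominator df reported in this literature indicate such an
approximation; the exact software defaults of any given study are
unknowable, so coefficients and p-values are not expected to match any
particular published fit). Marginal group means and Bonferroni-adjusted
pairwise comparisons come from `emmeans`. Whether the two analysis windows
enter as a factor or are averaged is ambiguous in the tradition; they enter
as a factor here, which nests the averaged reading as a marginal mean.

The visual model uses a per-infant random intercept: the repeated measures
across ROI, hemisphere and epoch share one infant-level deviation, and a
single intercept is the smallest structure respecting that
non-independence. For the auditory difference-score model the intercept
alone is provably too small: vocal selectivity is a lateralized infant-
level trait, so individual deviations load on the left-hemisphere cells
only, and an intercept-only model misattributes that variance to the
residual and understates the standard errors of hemisphere-specific means.
The auditory model therefore adds a per-infant hemisphere random slope by
default (`random = "hemisphere"`), falling back to the intercept with a
logged note when the larger structure cannot be fitted. Parameter-recovery
simulations in the acceptance suite confirm that with this structure the
model's standard errors are calibrated (the injected values fall within 2
SE at the nominal rate).

Dimensional analysis correlates per-infant response summaries -- the
visual-social response averaged over ROIs, hemispheres and the two epochs,
and the left-hemisphere vocal minus non-vocal difference averaged over
ROIs within 12--16 s -- with the Social Responsiveness Scale total, and
partials out outcome group by residualizing both variables on group
indicators with `n - 2 - (g - 1)` degrees of freedom. Phenotype-level group
comparisons from printed summary statistics use the pooled-variance
two-sample t-test with `df = n1 + n2 - 2`; this convention exactly
reproduces the published developmental t-statistics from the published
means and SDs, which is how it was validated.

## The synthetic-data generator

Each infant's clean HbO2 series per channel is the sum over experimental
trials of the trial boxcar convolved with a single-gamma HRF (default
time-to-peak 7 s, shape 8), scaled by the amplitude-table entry for the
channel's ROI, hemisphere, condition and group plus per-infant deviations;
HHb is a scaled, sign-inverted copy (default ratio -1/3, reflecting the
much smaller HHb magnitudes in infant data). Concentrations map through the
forward modified Beer-Lambert model -- the same extinction table, 2 cm
separation and DPF 5.13 the analysis inverts -- to attenuation, and are
exponentiated onto a unit baseline intensity (the baseline is arbitrary;
attenuation changes are invariant to it). Physiological noise is additive
in concentration: cardiac (2.2 Hz, the infant heart rate), respiratory
(0.6 Hz) and vasomotor (0.1 Hz) sinusoids with random phase per channel,
plus white noise; the cardiac and respiratory terms are largely removed by
the 1.7 Hz low-pass while the 0.1 Hz term survives it and produces
realistic trial-to-trial variability. Motion artifacts are whole-head
events per experimental trial: brief triangular spikes (default 5 uM
equivalent over 0.4 s) and persistent baseline shifts (3 uM equivalent),
both of which the two-level rejection scheme is designed to catch. Looking
time per trial follows a two-component Beta mixture: attentive trials
(mean about 0.94, matching reported looking of included infants) and, with
probability 0.12, inattentive trials centred near 0.5, which drive
attrition under the 60% rule at a rate comparable to the roughly 40%
exclusion such studies report. The HRF timing defaults are conventions of
the field, not measured facts about any cohort; they are configurable.

**Amplitude reference.** The amplitude parameter needs a measurement
meaning. With `amplitude_reference = "peak"` the clean response maximum
equals the amplitude, which is the natural scale for signal-level
round-trip checks. The default, `"window_mean"`, expresses amplitudes on
the scale on which group results are reported: the value the full analysis
chain (block segmentation, linear detrend, onset baseline correction,
average of the 8--12 and 12--16 s epoch means) reads out of the clean
series. Because a realistic HRF has not returned to baseline when the next
trial's pre-stimulus window begins, consecutive trials contaminate each
other's baselines and detrend anchors; all stages are linear, so the
generator computes the 3-by-3 condition cross-measurement matrix of the
schedule and injects `solve(M) %*% target`, making the noise-free pipeline
read-out equal the target amplitudes exactly. This carry-over compensation
is what makes parameter-recovery assertions sharp; without it the recovered
group means would be biased by a few percent of the neighbouring trials'
amplitudes.

Group-level defaults encode the directions and magnitudes (in uM) that the
study design under emulation reports: visual-social amplitudes 0.45 (LR),
0.28 (HR-noASD), -0.053 (HR-ASD) in IFG and pSTS-TPJ; a non-vocal auditory
response of 0.40 in aMTG-STG and pSTS-TPJ in both hemispheres for all
groups; and a left-hemisphere-only vocal-selectivity term of +0.29 (LR),
+0.09 (HR-noASD) and -0.951 (HR-ASD) added to `A-V` trials. Per-infant
deviations have SD 0.30 uM on the visual-social amplitude and 0.60 uM on
the vocal difference, chosen so that group-level standard errors at the
emulated sample sizes (16/15/5) are of the order reported for such cohorts.
SRS totals are generated per group (means 21.57 / 21.07 / 77.8, SDs 12.2 /
11.3 / 42.8) with the standardized score equal to `coupling` times the
z-scored injected social amplitude plus independent noise, so `coupling`
(default -0.5) is the population correlation between SRS and the injected
social response; `group_only = TRUE` removes the dimensional coupling
entirely, which is the construction the partial-correlation null check
uses. Mullen composite scores are group means/SDs only.

**What the generator does not emulate.** No photon transport or layered
scalp/skull optics; no spatial correlation structure across channels beyond
shared ROI amplitudes and whole-head artifacts; no serial correlation in
the white-noise term; no eye-tracking beyond the per-trial looking
proportion; no systematic hemodynamic latency differences between groups.
Passing recovery tests therefore demonstrates that the analysis chain is
correct and calibrated for data satisfying its own assumptions, not that
those assumptions hold for any particular real cohort.

## Numerical conventions

Epoch windows use inclusive endpoints with a 1e-9 s tolerance; the
pre-stimulus baseline is [-4, 0) s (right-open). The looking rule is
strictly greater than 0.60; the concentration jump rule is strictly greater
than `jump_umol`. Zero-variance t-tests return t = 0, p = 1 for an exactly
zero effect (and p = 0 for a non-zero constant effect). A singular mixed
model fit is retained with a note -- a boundary variance estimate is a
valid REML optimum -- and only a complete failure triggers the fixed-
effects fallback. Forward/inverse consistency of the whole chain is held to
1e-6 uM at the response peak with the detrend stage disabled; the detrend
is not the identity on a clean HRF (the response has not decayed inside the
block's final anchor window), so the detrended chain is checked against the
identically detrended clean series instead, at the tolerance set by the
filter's end transient.

## Simulation sizes used by the verification suite

Monte-Carlo checks simulate at 5 Hz on a reduced six-channel montage (one
channel per ROI and hemisphere) with one stimulus loop per infant: the
statistics under study are 4-s epoch means of ROI averages, which these
choices leave unchanged while keeping each replicate cheap. Parameter
recovery uses 100 cohorts of 50/50/50 infants; null calibration uses 200
cohorts at the emulated study's 16/15/5; the dimensional-coupling check
uses cohorts of 200 infants. The defaults of `sim_config()` (26 channels,
10 Hz, 16/15/5) are what the acceptance script runs.

## Known limitations

Published fitted coefficients, F statistics and p-values of any specific
real study are not reproducible targets, because the underlying raw infant
data are not distributable; printed group means serve as simulation ground
truth instead, and the package's claims are about recovery and calibration.
The contrast coding and degree-of-freedom conventions of other software
will differ in the third decimal of F tests. The channel-to-ROI map is a
configuration stand-in. The TSV recording dialect is the package's
interchange format; native formats of specific acquisition systems are out
of scope.
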