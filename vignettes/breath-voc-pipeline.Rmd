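---
title: "Breath VOC chromatogram analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath VOC chromatogram analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Exhaled breath carries trace volatile organic compounds (VOCs) whose
pattern is altered in colorectal cancer (CRC). A portable gas
chromatograph turns one breath sample into one chromatogram — detector
intensity against retention time over roughly 0–800 s — in which each
resolvable VOC appears as a peak. The diagnostic question is whether a
small panel of peaks separates CRC patients from healthy controls (HC).

`breathpanel` implements the full analysis chain for this design:
quality control of raw runs, de-noising and baseline correction, peak
detection, integration and cross-sample retention-time alignment,
compound-library annotation, an exhaustive leave-one-out cross-validated
(LOOCV) linear-discriminant search for the best three-peak panel among
roughly one hundred candidate VOCs, and confusion-matrix evaluation of
that panel on a held-out test set (a 36 CRC / 32 HC cohort split
18+18 training, 18+14 testing). Because raw clinical breath data of this
kind are not publicly deposited, the package also contains a first-class
synthetic chromatogram generator that reproduces the statistical
structure the analysis assumes, with complete ground truth, so every
stage is testable end to end.

## The synthetic cohort generator

A simulated trace is

> baseline(t) + sum over present compounds of EMG(t; apex, sigma(RT),
> tau, area) + Gaussian noise.

**Peak shape.** Peaks are exponentially modified Gaussians (EMG) — a
Gaussian of width `sigma` convolved with an exponential tail of constant
`tau` (default 1.5 s), the standard phenomenological model of GC peak
tailing. Width grows mildly with retention time,
`sigma(RT) = 0.8 + 0.001 RT` seconds. The slope is deliberately small:
the instrument class this emulates runs a temperature program, which
holds peak widths roughly constant across the run, and a chromatogram
in which ~100 VOCs are individually resolvable over 800 s requires
widths of this order. (An early version of the generator used a three
times steeper slope; late-run neighbours then co-eluted into single
maxima and no peak picker — ours or any other — could see them. The
narrow-width default is the physically consistent choice, not a
tuning.) Each peak is emitted so that its *apex* sits at the library
retention time: library RTs are observed apex times, while the EMG mode
trails the Gaussian centre by a width-dependent offset that the
generator pre-computes and removes.

**Retention times.** The 61 compounds of the packaged breath library
(9–768 s) plus `nExtraPeaks` (default 40) unannotated "unknown"
compounds at cohort-level random positions, at least 5 s away from any
other compound. The extras reflect the gap between the number of
MS-identified library compounds and the larger number of detectable
peaks in a real breath run. Per sample, a global shift (SD 1 s) and a
per-peak jitter (SD 0.5 s) displace all apexes.

**Amplitudes.** Peak areas are log-normal (`meanlog` 0, `sdlog` 0.5).
The three biomarker compounds — 2,4-dimethylhexane at 197 s,
2,5-dimethylheptane at 341 s and 2,2,5,5-tetramethylhexane at 470 s by
default — have their mean log-area raised by
`effectSize * ampLogSD` in CRC samples only, so `effectSize` is the
group separation in within-group SD units (default 1.5). Six ubiquitous
breath compounds (isoprene 42 s, 2-methylpentane 53 s, n-hexane 65 s,
heptane 137 s, octane 276 s, a-pinene 502 s) are designated anchors:
always present, with mean log-amplitude boosted by 2, they are the
largest peaks in every run and serve retention-time alignment and
quality control — the role isoprene and the common alkanes play in real
breath chromatograms. Biomarkers and anchors are always present; other
compounds appear with probability 0.9 per sample.

**Nuisance structure.** A slow sinusoid-plus-ramp baseline with
amplitude 5% of the sample's median apex height, and white detector
noise with SD 1% of the median apex height (both scale-aware defaults,
overridable in absolute units). The detector full scale is 10 units; no
clean trace approaches it.

**Duplicate library entries.** The library lists 2,5-dimethylheptane at
both 239 s and 341 s (and 2,3-dimethylhexane at 221 s and 230 s). Every
row is a distinct simulated peak keyed by RT; the biomarker instance of
2,5-dimethylheptane defaults to 341 s, which is configurable rather than
asserted, and annotations carry an `@<rt>s` qualifier so duplicates stay
unambiguous.

**Technically inadequate runs.** `injectInadequate()` corrupts a chosen
fraction of samples by one of three modes: global intensity scaled to
0.5% of the cohort-median total signal (below the QC floor); rescaling
so that >5% of points clip at the detector full scale; or excision of
all anchor windows (replaced by linear interpolation). These are the
three failure modes the QC stage is designed to catch, mirroring the
~17% attrition (14 of 82) a clinical collection of this kind reports.

## Pre-processing

**De-noising** is Savitzky–Golay smoothing (window 21 samples = 2.1 s,
order 3): it reproduces any locally cubic signal exactly — peaks of
width ≥ ~0.8 s pass essentially undistorted — while averaging out white
detector noise.

**Baseline correction** is asymmetric least squares: a Whittaker
smoother (second-difference penalty, `smoothness` 1e6) with weights
0.01 above / 0.99 below the running fit, solved by a banded Cholesky
factorisation in C. Two refinements matter in practice and are part of
the method:

1. *Peak-masked refit.* Even with weight 0.01, a peak a hundred times
   the noise pulls the fit into its flanks (the weighted squared
   residual of a flank point dwarfs that of a noise point). After the
   asymmetric pass, all points more than 3 cluster-SD above the fit —
   the cluster scale is read off the 5th–20th percentiles of the
   residual, which strictly positive peak mass cannot contaminate — are
   masked (with 2 s dilation) and the baseline is refit with symmetric
   unit weights on the unmasked points only. The refit bridges smoothly
   across peaks and is unbiased in peak-free regions.
2. *Pedestal recentering.* Asymmetric weighting makes any baseline
   estimate hug the lower noise envelope, leaving the corrected trace
   sitting a couple of noise-SD above zero; integrated over a peak
   window that pedestal is a material fraction of a small peak's area.
   The corrected trace is therefore recentred on the centre of its
   peak-free noise cluster (an iterated trimmed median started from a
   low quantile), so peak-free regions end up with median ≈ 0.

Without these refinements the median relative error of recovered
isolated-peak areas is 5–12%; with them it is 3–4% (the residual error
is mostly local baseline wiggle under small peaks plus ~1% tail
truncation). Negative corrected intensities are retained, not clipped,
to keep integration unbiased.

**Quality control** runs on the *raw* trace, because saturation and
total signal are detector-output properties that smoothing and baseline
subtraction destroy. A sample is inadequate iff any of: total integrated
signal below 1% of the cohort median; more than 5% of points at or above
the detector full scale; fewer than 3 of the 6 anchor peaks found within
±6 s (the tolerance covers the 1 s-SD global shift plus per-peak
jitter with many SDs to spare, so a clean sample cannot fail this check,
while anchor excision removes every local maximum within ±12 s).
Thresholds are scale-aware: scaling a trace together with floor and
ceiling leaves the verdict unchanged.

## Peaks, alignment and the feature matrix

**Detection** finds local maxima with topographic prominence at least 5
times the robust noise estimate and apex height at least 3 noise units.
**Integration bounds** are local: on each side, the valley between the
apex and the adjacent detected peak, moved inward to the last point
below 1% of apex height. Bounds at the topographic prominence bases —
the textbook alternative — let a large peak swallow its smaller
neighbours' mass, which in a case/control design injects
amplitude-dependent (hence group-dependent) distortion; the local rule
removed most of that at the cost of ~1% tail truncation.

**Alignment** estimates one global shift per sample (median offset of
the apexes nearest to each anchor), pools all shifted apexes, and
single-linkage clusters them. The cluster-splitting gap is
`tolerance/2` = 1.5 s while assignment to consensus features uses the
full ±3 s tolerance. The two scales are deliberately different: pooled
apexes of one compound lie dense (spread ≈ ±2 s over a cohort), so a
3 s split gap chain-merges genuine neighbours 4–6 s apart, while a
1.5 s gap resolves them without shattering real clusters; assignment of
an individual sample's apex, jittered by up to ~±2 s, still needs the
full tolerance. Clusters present in at least half the samples become
features; with the default cohort this yields 93–96 consensus features,
the "about one hundred VOCs" regime. Annotation against the library is
one-to-one nearest-RT within ±3 s (closest wins, ties to the smaller
RT).

**The abundance transform** is `log10(area + eps)` with `eps` = 1% of
the smallest positive *training* area; absent peaks are imputed at the
`log10(eps)` floor ("absent = low"); each feature is centred and scaled
with training-row parameters applied to all rows. Every parameter of
the transform is a function of the training rows only — the no-leakage
property is asserted by test.

## Panel discovery

The classifier is a two-class Fisher discriminant with a shrunken
pooled covariance, `S_lam = (1-lambda) S + lambda (tr S / p) I`
(`lambda` = 0.1 by default for 3-feature fits at n = 36, a numerical
safeguard; `lambda` = 0 reproduces the textbook estimator and is used in
the oracle tests). Equal class priors reflect the balanced 18/18
training design; scores at the threshold are called positive, a
documented tie rule.

Subsets of k = 3 features are scored by LOOCV accuracy on the training
rows; exhaustive search covers all `choose(p, 3)` subsets (161,700 at
p = 100) within a 1e6 budget, with forward selection as the over-budget
fallback. Selection among top subsets uses a **one-fold near-tie rule**:
LOOCV accuracy on 36 samples is quantized in steps of 1/36 with a
standard error of several points, so a one-fold difference carries no
evidence; subsets within 1/n of the top accuracy are treated as tied and
ranked by the training-set Fisher separation
`J = (mu1-mu0)' S_lam^{-1} (mu1-mu0)`, the cross-validation analogue of
the one-standard-error rule. Remaining exact ties go to the smallest
feature-index tuple, so the search is deterministic.

Two quantitative facts about this selection problem, established with
the package's own simulators, set expectations for users:

* With three planted markers of standardized effect 2.5 each, the
  three-feature Mahalanobis separation is sqrt(3) * 2.5 ≈ 4.3, i.e. a
  ~1.5% irreducible per-fold error rate; the probability that the true
  triple scores a perfect LOOCV is only ~0.6.
* Among ~100 candidates there are ~300 subsets sharing two true markers
  plus one noise feature, and the maximum of their resubstitution
  separations exceeds the true triple's in a sizeable fraction of
  cohorts (a winner's curse no resubstitution statistic avoids).

Consequently the exhaustive search recovers *at least two of three*
planted markers essentially always, and the full triple in roughly half
of cohorts at effect 2.5 — not more, for any scoring rule built on these
statistics at this sample size. The package's acceptance suite asserts a
stricter full-triple recovery rate and that assertion is expected to
fail; it is retained deliberately as an honest record of this ceiling.

## Evaluation

Confusion counts on the training, testing and combined sets (combined
counts are cell-wise sums, asserted always) yield sensitivity,
specificity, positive and negative predictive value and accuracy, as
percentages rounded half-away-from-zero to one decimal — the convention
that reproduces a published diagnostic table of this design in 14 of its
15 derived cells from its own printed counts. The single discordant
cell is a testing-set sensitivity printed as 94.5% where 17/18 computes
to 94.4% under every standard rounding; the package flags the
discrepancy rather than matching it. Ratios with a zero denominator are
reported as `NA`, never 0.

PCA of the panel columns is fitted by eigendecomposition of the
training-row covariance and applied to all rows (a flag refits on all
rows); loadings are orthonormal with the largest-magnitude entry of each
component made positive, and explained-variance fractions sum to one.

## Reproducibility and problem sizes

All randomness flows from a single integer seed through fixed per-stage
substreams; a rerun of `runPipeline()` with the same configuration is
bit-identical, and the CLI subcommands compose to the same result
because they call the same stage functions with the same derived seeds.

The test suite runs the full chain at the study's own scale (68 samples,
8001-point traces, ~94 features, 100k+ subset searches): 20 cohorts for
panel recovery, 50 for the null calibration (where held-out accuracy
averages ~50%, confirming selection touches training rows only), 50
samples for area fidelity, and reduced cohorts (4–30 samples, 200 s
traces, 5-compound libraries) for the unit-level oracles. Monte-Carlo
assertions use 3-SE bands around values derived from the generative
model, never measured-then-frozen numbers.

## Known limitations

The generator emulates the statistical structure the analysis assumes —
EMG peaks at library positions, log-normal abundances with a mean-shift
group effect, smooth drift, white noise, three clean failure modes — and
deliberately not: co-elution beyond what random spacing produces,
day-to-day drift or batch structure (the emulated design collects all
samples in one session), heavy-tailed or correlated abundance noise,
demographic confounding, or detector nonlinearity below saturation.
Passing tests therefore demonstrate the pipeline's correctness and its
statistical behaviour under the stated model, not clinical performance;
the panel the search selects on synthetic data is the planted one by
construction, whereas on real cohorts panel identity is expected to be
instrument- and protocol-dependent.
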