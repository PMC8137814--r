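---
title: "Cross-brain predictive coupling: models, null construction, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-brain predictive coupling: models, null construction, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

Two people wear identical 18-channel fNIRS montages (channels 1–8 over the
prefrontal cortex, 9–18 over the temporo-parietal junction) while they
interact — the motivating setting is a teacher explaining a task to a
student. After conversion to oxyhemoglobin (HbO₂) concentration changes and
band-pass filtering, each *student* channel `j` is modelled as an affine
function of *all 18 teacher channels*,

$$ S_j(t) = \sum_{i=1}^{18} w_i\, T_i(t) + b, $$

fitted on the first 50% of the recording by either linear ε-insensitive
support vector regression (SVR) or ordinary least squares (OLS). The fitted
map is applied to the teacher's second half, and the prediction is scored
against the student's actually recorded second half by Spearman rank
correlation ρ. Significance of ρ is assessed against a moving-block
bootstrap null: the teacher's series is cut into blocks as long as its own
autocorrelation memory, the blocks are shuffled, the model is refitted and
rescored, and the one-sided p-value is the fraction of the `B` shuffled
scores exceeding the observed one. Benjamini–Hochberg FDR correction is
applied across the 18 channels of a dyad within each model family.

`fit_coupling()` returns the fitted model grid as a classed object with the
usual `print`/`coef`/`predict`/`summary`/`fitted`/`residuals` methods;
`evaluate_coupling()` runs the inference; `run_pipeline()` orchestrates a
multi-dyad batch from a single seeded configuration.

## Why this null distribution

Band-limited haemodynamic series are smooth: any two of them, even when
statistically independent, show large spurious rank correlations. An
i.i.d. permutation test ignores this and is badly anti-conservative (the
package's test suite demonstrates type-I rates above 0.15 at a nominal
0.01 on independent AR(1) dyads). The block bootstrap instead preserves
each channel's short-range dependence inside blocks while destroying the
teacher–student alignment.

The block length is estimated per dyad as the first lag at which the
per-channel sample autocorrelation of the teacher's training segment falls
inside a near-zero band (|ACF| ≤ 0.05 by default), aggregated across the
18 channels by the median, rounded up. Three choices here were genuinely
open and are fixed as follows:

* **Near-zero threshold 0.05** — a conventional near-zero band; it
  reproduces the analytic first-crossing lag 29 for an AR(1) process with
  coefficient 0.9 (`0.9^k ≤ 0.05` first at `k = 29`).
* **Median aggregation, rounded up** — a single block length per dyad is
  needed; the median is robust to one or two noisy channels, rounding up
  errs on the side of longer (safer) blocks.
* **Remainder handling** — the block rule is a division; when the block
  length does not divide the series length, trailing remainder samples are
  dropped from the shuffled series and the replicate correlation uses the
  correspondingly trimmed student test segment.

One joint permutation is applied to all 18 teacher channels, preserving the
inter-channel covariance the multivariate fit depends on; shuffling
channels independently would whiten the predictor covariance and change
what the null tests. The teacher's *whole* series is shuffled before the
50/50 split, so training and test are both resampled; the student's series
is never permuted. Within one dyad evaluation, each replicate's shuffled
teacher is shared across response channels and model families: the marginal
null of each channel is unchanged, and the expensive work (the shuffle and,
for OLS, one multi-response QR) is paid once per replicate.

The p-value is the literal ratio `#(null > observed) / B`, which can return
exactly 0; a bias-corrected `(count + 1)/(B + 1)` variant is available via
`corrected = TRUE` but is off by default to keep the reference rule. Note
the literal rule's discreteness: under exact exchangeability,
`P(p ≤ 0.01)` equals `(k+1)/(B+1)` where `k = floor(0.01 B)` — e.g. 3/201
≈ 0.0149 at `B = 200`, not 0.01. Calibration checks must be read against
that attainable level.

### What the calibration tests show — and an honest caveat

On simulated null dyads with AR(1) noise (coefficient 0.9, ~7,000 samples,
`B = 200`), the package's calibration runs measure the block bootstrap's
empirical `P(p ≤ 0.01)` in the 0.02–0.05 range (about 0.027 over ~1,800
trials) against the attainable level 0.0149, while the i.i.d. permutation
control sits near 0.15–0.2 — and the strict-calibration check in the test
suite accordingly fails its binomial band at some seeds. The block
construction therefore removes the large majority — but not all — of the
autocorrelation-induced excess. The residual inflation is a known property
of first-ACF-zero block-length selection: for smooth or oscillatory series
the first near-zero crossing *underestimates* the dependence range (an
AR(2) narrowband process has an ACF that dips through zero a quarter-cycle
in, long before its envelope has decayed), so blocks are slightly too
short and the null slightly under-disperses. Users who need strict
type-I control at extreme tails should treat p-values near the threshold
with care, raise the ACF threshold (longer blocks), or increase `B`.

## The two model families

OLS is the squared-loss optimum over the affine class, so its training MSE
is always at least as small as SVR's — a property the test suite asserts.
SVR (ε = 0.1, cost C = 1 by default, the defaults of the libsvm-based
e1071 implementation the package wraps) ignores residuals inside the
ε-tube and bounds each sample's influence by C, which regularizes the fit
when the 18 predictors are strongly collinear — as band-limited,
systemically contaminated fNIRS channels are. Under simulated collinearity
(18 channels spanned by 3 latent factors), SVR's held-out Spearman ρ beats
OLS's in well over 70% of replicates; on the training data OLS always wins.
That is the practical argument for carrying both families.

Predictors and response are standardized inside `fit_svr()` (SVR solutions
are scale-sensitive) and the weights and intercept are algebraically
un-scaled afterwards, so reported parameters and predictions are always in
the original units; `standardize = FALSE` gives the raw-scale fit.
Rank-deficient predictor matrices are a hard error naming the collinear
channels — silently pseudo-inverting would hand the bootstrap a degenerate
OLS-vs-SVR comparison. Odd-length recordings put the extra sample in the
training half (`ceiling`), a documented tie-break.

## Preprocessing

Raw two-wavelength (760/850 nm) intensities are converted by the modified
Beer–Lambert law with the *whole time series as the baseline* and
differential pathlength factors 7.25 and 6.38. The baseline is implemented
as the geometric mean intensity — equivalently the arithmetic mean in
optical-density space — which makes the conversion exactly linear and
invertible; the arithmetic-mean-intensity variant (`baseline = "mean"`)
differs only at second order in the OD excursions and is provided for
comparison. Extinction coefficients default to the Cope/Gratzer compiled
values shipped in `default_extinction()` (overridable), the source–detector
distance to 30 mm; outputs are µM. Band-pass filtering (0.01–0.2 Hz) uses
a zero-phase forward–backward Butterworth of order 3 per pass: zero phase
matters because the analysis regresses one person's series on another's,
so phase distortion would shift their temporal alignment. Because both the
filter and the 2×2 extinction solve are linear, filtering optical densities
or concentrations is mathematically identical; filtering raw intensities
before the logarithm is offered as `filter_stage = "raw"`. "Visual
inspection" of raw data is replaced by thresholded automatic QC
(saturation ≥ 5% of samples within 0.1% of the detector rail; ≥ 5%
non-finite samples; near-zero variance), for reproducibility.

## What the synthetic generator does and does not emulate

`generate_dyad()` produces ~15 min recordings at 7.81 Hz (~7,000 samples),
18 channels per subject. The teacher's channels load on a latent
event-train convolved with a canonical double-gamma haemodynamic response
(peak 6 s, undershoot 16 s, ratio 1/6) and band-limited to 0.01–0.2 Hz so
that simulated coupling survives the preprocessing filter. The student's
signal part is the teacher's noise-free part times a configurable 18×18
gain matrix (instantaneous and linear, matching the fitted model class; an
optional lag exists for robustness studies). Noise per channel combines
narrowband AR(2) surrogates for cardiac (~1.2 Hz), respiratory (~0.3 Hz),
Mayer-wave (~0.1 Hz) and slow vasomotor (~0.04 Hz) activity, a
near-unit-root AR(1) drift, and white noise; narrowband *stochastic*
processes are used instead of sinusoids so no two channels share a
deterministic waveform. With these defaults the band-passed teacher
series' first ACF zero-crossings land at ~30–45 samples, the same regime
as the 30–85-sample decorrelation lags typical of real band-passed
classroom-interaction recordings. Teacher, student and HbR
noise come from separate seeded streams, so an all-zero gain matrix yields
provably independent subjects, and identical configurations are
bitwise-reproducible.

Deliberately *not* modelled: photon transport and optode geometry, motion
artifacts, task structure beyond a stationary event train, nonlinear or
delayed neurovascular coupling, and short-channel systemic measurements.
Passing tests on this generator therefore validate the statistical
machinery — not the physiological realism of any particular dataset. HbR
is generated only as −HbO₂/3 plus noise to support the two-wavelength
optical round trip; the analysis itself uses HbO₂ only.

## Numerical choices and degenerate inputs

* The SVR/QP agreement checks run e1071 at `tolerance = 1e-8`; the default
  fitting tolerance is libsvm's 0.001.
* A constant training response returns the exact SVR optimum (zero
  weights, intercept at the constant) without invoking the solver.
* Constant series make Spearman ρ undefined: `spearman_rho()` errors, and
  `evaluate_coupling()` records NA with a reason instead of aborting the
  dyad. Replicate fit failures are recorded; more than 5% failed
  replicates abort the null.
* `block_shuffle(x, lag = n)` is the identity (one block), matching the
  block-count rule `floor(n/lag)`; `lag > n` is an error.
* The double-gamma kernel is parameterized so its first lobe peaks exactly
  at the configured time-to-peak; the undershoot shifts the global
  argmax by far less than one sample at 7.81 Hz.

## Problem sizes used by the tests and the acceptance script

The reference protocol (B = 1,000 bootstrap replicates on ~7,000-sample
recordings) is scaled in this package's checks to keep a full run on one
CPU inside minutes while leaving every statistical property intact: null
calibration uses 200 (tests) or 100 (acceptance script) independent
AR(1) dyads at full length with `B = 200`; the five-dyad batch that
exercises the complete result geometry uses 45–90-second recordings with
`B` of 100–150 (the SVR bootstrap refits dominate the cost, so the batch
trades recording length for keeping both families at all 18 channels);
detection-power and gain-ordering studies use full-length and 450-second
recordings with the OLS family, whose refits are cheap enough to run the
null at full recording length.

One scale-dependent caveat: the block bootstrap is only trustworthy when
the series contains many blocks (full-length recordings give n/lag ≈
200–300, the regime the reference protocol operates in). On the 45–90
second demonstration batches n/lag is ~20–30 and the null is visibly
anti-conservative (false-alarm rates near 10% at a nominal 1%), so those
batches exercise the pipeline's geometry, determinism and output formats —
not its calibration, which is assessed at full length.
The vignette's qualitative statements above are exactly the quantities
those runs compute — no result is quoted here that the suite does not
itself produce.

## Limitations

Besides the block-length caveat above: the 50/50 chronological split
leaves slow nonstationarities (fatigue, drift in optode contact) partly in
train and partly in test; the linear instantaneous model cannot represent
delayed or nonlinear coupling; FDR is applied per dyad × family (18
tests), matching per-dyad reporting — a global scope across dyads is
available in `run_pipeline()` via `fdr_scope = "global"`; and negative
couplings are not tested (the p-value is one-sided by construction, as in
the reference rule).
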