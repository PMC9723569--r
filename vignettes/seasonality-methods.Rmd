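---
title: "Methods: species-level seasonality in activated-sludge time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-level seasonality in activated-sludge time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasonflow)
```

## The problem

Activated-sludge (AS) bioreactors are open systems: their microbial
communities are shaped both by in-reactor growth and by continuous
immigration with the influent wastewater. Sampled every 7–10 days over
several years, species-level amplicon count tables show annual rhythms
whose amplitude and timing differ between species, even within a genus or
functional guild. `seasonflow` quantifies those rhythms per species —
significance, amplitude, peak timing, seasonal strength, cohort — and
relates them to each species' apparent net growth rate in the reactor.

## Model and procedure

### Compositional transform

Read counts are compositional and sparse. Per sample, the robust centred
log-ratio maps each positive count $x_i$ to
$\log x_i - \overline{\log x_j}$, the mean taken over the sample's taxa
with reads $> 0$; zeros stay missing rather than being imputed with a
pseudocount. The natural log is used; the log base only rescales
amplitudes and changes no p-value, peak, strength or cohort.

Two choices are exposed for the missing values that remain when a species
drops out of some samples (`species_seasonality(rclr_zero = ...)`):
`"zero"` (default) places absent taxa at the sample's geometric mean
(rclr value 0), `"interpolate"` fills them linearly along time. The
decomposition requires complete series, so one of the two must be applied;
the default is the more conservative, pulling absences toward "average",
and the alternative is kept as an explicit knob because neither convention
is canonical.

### Weekly grid

Observations are irregular (7–10-day spacing, occasional gaps), so each
series is linearly interpolated onto a 7-day grid anchored at its first
observation, never extrapolating beyond the last one. The annual cycle is
then treated as 52 weeks (364 days). The ~1.25 day/year mismatch with the
365.25-day astronomical year is far below the weekly resolution of the
analysis and is absorbed by the noise term over the 3–5-year horizons the
package targets.

### Decomposition

`stl_periodic()` performs the loess-based seasonal-trend decomposition
with a *periodic* seasonal window: each cycle-subseries (all observations
sharing a week-of-year) is replaced by its mean, so the seasonal component
is identical across years by construction. The classical low-pass stage
(two full-period moving averages, a 3-point average, then a linear loess)
is computed in closed form here: a full-period moving average of an
exactly periodic series covers each week exactly once and is therefore the
constant cycle mean, so the low-pass correction reduces to subtracting the
grand mean of the weekly means. The trend is a degree-1 loess of the
deseasonalized series with a window of 79 observations (the classical
default, the next odd integer at or above 1.5 × frequency); the remainder
is defined by subtraction, making additivity bit-exact.

Two iterations of the seasonal/trend alternation are the default, matching
the reference implementation. For inputs where the alternation converges
slowly — a pure linear ramp is the canonical case, where the first-pass
cycle means alias the ramp into a sawtooth — `tol` iterates to convergence
instead (the test suite uses `tol = 1e-9`). Robustness (outer) iterations
with bisquare weights are available but default to 0. Degenerate inputs
fail loudly: series with missing values or fewer than two full cycles are
rejected.

### Harmonic inference

The seasonal component (default) or the regularized series itself
(`fit_on = "raw"`) is fitted by OLS on $\{1, \cos(2\pi t/52),
\sin(2\pi t/52)\}$. Amplitude is the coefficient norm, phase the `atan2`
of the pair, and the p-value the joint F-test of the pair against the
intercept-only model. The distinction between the two modes matters for
calibration: the periodic seasonal component repeats by construction, so
its residuals are not independent and its p-values are anti-conservative
in a way that mirrors the procedure it implements; `"raw"` mode carries
ordinary independent-error p-values and is what the null-calibration test
exercises. The default remains `"seasonal"` because the seasonal component
is the quantity whose peak and amplitude the analysis reports.

Ties at the 1 % threshold count as significant ($p \le 0.01$). No
multiple-testing correction is applied by default, matching the per-species
raw threshold the analysis is defined with; `p.adjust` can be applied to
the returned column by users who want FDR control.

The peak week solves the fitted cosine's maximum and its 95 % CI comes
from a residual bootstrap (default 1000 draws): residuals are resampled
with replacement, the model refit (a single precomputed 3 × n projection,
so the bootstrap is one matrix product), and percentiles taken circularly —
deviations from the point estimate are mapped to the shortest arc before
quantiles, so intervals wrap the week-52/week-1 boundary correctly. A fit
with numerically zero amplitude returns the full year, flagged. The
bootstrap is the package's choice among several defensible CI
constructions; it is distribution-free and respects the circular geometry.

### Seasonal strength

$F_s = 1 - \mathrm{var}(R)/(\mathrm{var}(R) + \mathrm{var}(S))$ with
population variances of remainder and seasonal components, clipped to
$[0,1]$. Category boundaries are left-closed ($F_s \ge 0.75$ very strong,
$[0.55, 0.75)$ strong, $[0.35, 0.55)$ moderate, $[0.15, 0.35)$ weak, below
very weak): the defining inequality chains are strict on both sides and
leave exact boundary values unassigned, so a convention is required and
left-closed is used consistently.

**Known limitation — upward bias at short series.** With $y$ years of
weekly data, the periodic seasonal estimate at each week is a mean of $y$
noisy values and so absorbs roughly $\sigma^2/y$ of noise variance that
the remainder correspondingly loses. The estimator therefore overshoots
the population strength $F_s^* = (A^2/2)/(A^2/2 + \sigma^2)$ at 3 years by
roughly $(\sigma^2/y)(1 + F_s^*)/(A^2/2 + \sigma^2)$ — about $0.11$ at
signal-to-noise $A/\sigma = 2$. This is a property of the decomposition
itself (the reference implementation shows the same bias), not of this
implementation; the acceptance script measures it (`mean_abs_fs_error`)
rather than hiding it. Rankings and categories are affected far less than
absolute values, and the bias shrinks as $1/y$.

### Seasonal cohorts

Significant species are assigned to the astronomical season containing
their fitted peak day: winter Dec 21–Mar 20, spring Mar 21–Jun 21, summer
Jun 22–Sep 22, autumn Sep 23–Dec 22, all endpoints inclusive, on a fixed
365-day calendar (Feb 29 folds onto Feb 28). The winter and autumn windows
as stated overlap on Dec 21–22; `season_of_day()` resolves the overlap in
winter's favour, so autumn effectively ends Dec 20. `season_of_day()` is
the single source of truth for these windows: the synthetic generator
derives its ground-truth cohorts from the same function, so analysis and
truth cannot drift apart.

The peak day is derived from the peak week via the series start date
(week 1 = the first grid week), so cohort assignment respects the actual
calendar position of the sampling campaign.

### Growth groups

With influent biomass concentration $C_{in}$ (relative abundance × total
cells/L), reactor biomass $X$, solids retention time SRT and hydraulic
retention time HRT, the steady state of
$V\,dX/dt = Q\,C_{in} + kVX - (V/\mathrm{SRT})X$ gives

$$k = \frac{1}{\mathrm{SRT}} - \frac{C_{in}}{X\cdot\mathrm{HRT}}.$$

This simplified closed form follows from exactly three assumptions —
steady state, first-order net growth, biomass proportional to relative
abundance × total cells — and is labelled an *apparent net growth rate
(simplified steady-state)*; it is not the full regression-based estimator
of the companion immigration literature, which needs paired time-series
machinery outside this package's scope. Total cell concentrations and
SRT/HRT are required inputs, not defaults, since they are plant-specific
measurements. Per-species rates are aggregated across sampling dates by
the median (robust to outlier pairs) before classification: growing when
every per-plant rate exceeds $+\varepsilon$, disappearing below
$-\varepsilon$, surviving within $\varepsilon$, ambiguous on any
disagreement or when the species' maximum relative abundance is below
0.05 % (too few reads to classify). $\varepsilon$ defaults to
0.005 d$^{-1}$, a band of ±10 % of a typical wasting rate $1/\mathrm{SRT}
= 0.05$ d$^{-1}$ at SRT = 20 d; "close to zero" has no canonical width,
so it is a configurable parameter.

### Cross-plant comparison

Cohort agreement across plants is classified as *identical* (one distinct
seasonal cohort), *concomitant* (exactly two distinct cohorts that are
cyclically adjacent seasons: winter–spring, spring–summer, summer–autumn,
and autumn–winter, which wraps the calendar), *all-non-significant*, or
*mixed*. Adjacency is cyclic because the seasons are; whether a
winter–autumn split "counts" as neighbouring is a convention, and the
cyclic choice is the symmetric one. Non-significant labels never
contribute to adjacency but are preserved in the intersection key.
Opposite-season pairs (winter–summer, spring–autumn) can never be
identical or concomitant — a structural guarantee of the classifier, which
the tests assert over all label pairs.

## The synthetic generator

The generator emulates the study conditions the analysis is designed for:
3–5 years of sampling every 7–10 days per plant (~150 samples/plant at 3
years weekly), read depths uniform over 10 893–170 639, a small fraction
of technical replicates (5 %) and sub-10 000-read samples (2 %) to
exercise QC, hundreds of species per plant of which ~80 % carry an annual
latent cosine (log-scale amplitudes 0.5–2.5, peak days uniform), and a
cross-plant core sharing identical peak days. The latent model is
log-linear with additive Gaussian noise (per-species SD 0.2–0.6) and
multinomial read sampling at the drawn depth, chosen because the rclr of a
log-linear signal is approximately sinusoidal — the generator realises the
analysis model without being the analysis. Phases are anchored to a common
calendar epoch so shared species peak together across plants regardless of
each plant's start date.

Influent/reactor pairs are built backwards from the balance: influent
relative abundances are lognormal around per-species means (the influent
community's distribution is a stand-in, not an inference about any real
plant), the reactor abundance is solved from the steady-state equation for
the species' true $k$, and both tables receive multiplicative lognormal
noise. Species with $k \ge 1/\mathrm{SRT}$ are rejected: such species need
no immigration and the balance degenerates.

What the generator deliberately does not emulate: sequencing error and
chimeras, primer and extraction bias, temperature or other covariates,
influent chemistry, non-sinusoidal seasonality (double peaks, sharp
blooms), and abundance-dependent overdispersion beyond multinomial. A
passing test suite therefore demonstrates that the estimators recover the
truth *under the stated model*, not that real AS communities satisfy that
model.

## Problem sizes and numerical conventions

The validation suite runs at sizes chosen to give stable Monte-Carlo
estimates while staying comfortably interactive: 1000 draws for the rclr
oracle and the F-test null calibration, 500 species for peak/strength
recovery, 200 for cohort recovery and growth sign accuracy, and a full
pipeline of 4 plants × 200 species × 3 years (100-species shared core).
All simulation seeds are explicit arguments; every stochastic stage is
reproducible bit-for-bit from the configuration, and `run_all()` writes a
manifest (config echo, versions, per-stage row counts) alongside its
tables. Rarefaction (at 10 000 reads, for richness and Simpson $1-D$ only)
delegates to `vegan::rrarefy` under a local seed; diversity is computed on
raw counts *before* replicate merging because merging produces
proportion-valued tables on which count-based resampling is undefined —
the QC order is read filter → rarefied diversity → replicate merge →
species aggregation → abundance retention.
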