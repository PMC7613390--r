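---
title: "Multi-season cropland phenology from combined LAI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-season cropland phenology from combined LAI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoLAI)
```

## The problem

Irrigated delta croplands rotate two crops per year — a summer cycle (rice or
maize) and a winter cycle (wheat or berseem clover) on the same parcel.
Characterizing this system from optical satellites means recovering, per
parcel and per year, up to two complete growth cycles and their timing: start
of season (SOS), end of season (EOS), length of season (LOS = EOS − SOS) and
the seasonal integral of the LAI curve (Area, in LAI·days). A single sensor
with a 16-day revisit undersamples the short summer cycle once clouds remove
a fraction of acquisitions; combining a 5-day-revisit stream with a
16-day-revisit stream densifies the series enough for reliable multi-season
detection. `phenoLAI` implements that workflow end to end and ships a
synthetic-data generator so every stage is testable without imagery.

## Gaussian process regression

Both the spectral LAI retrieval and the temporal gap-filling use the same GPR
engine. Observations are modelled as $y = f(x) + \varepsilon$ with
$\varepsilon \sim \mathcal N(0, \sigma_n^2)$ and a zero-mean GP prior on $f$
under the anisotropic squared-exponential kernel

$$k(x_i, x_j) = \sigma_s^2 \exp\!\Big(-\tfrac12 \sum_{b=1}^{D}
  \big((x_{ib}-x_{jb})/\sigma_b\big)^2\Big),$$

where $\sigma_s^2$ is the signal variance and $\sigma_b$ the per-dimension
lengthscale; $1/\sigma_b$ measures the relevance of input $b$
(`bandRelevance()`). The predictive mean and variance at $x_*$ are the
standard conditionals
$\mu_* = k_*^\top (K + \sigma_n^2 I)^{-1} y$ and
$\sigma_*^2 = k(x_*,x_*) + \sigma_n^2 - k_*^\top (K + \sigma_n^2 I)^{-1}
k_*$. Hyperparameters are chosen by maximizing the log marginal likelihood

$$\log p(y \mid X, \theta) = -\tfrac12 y^\top (K+\sigma_n^2 I)^{-1} y
  - \tfrac12 \log |K + \sigma_n^2 I| - \tfrac{N}{2} \log 2\pi$$

(data fit, complexity penalty, constant), exposed term by term through
`gprLogMarginalLikelihood(parts = TRUE)`.

Numerical choices, all of which were open:

* **Centering.** $y$ is mean-centered before solving and the center restored
  at prediction, since the prior is zero-mean and LAI is not.
* **Optimizer.** L-BFGS-B in log-hyperparameter space with the analytic
  gradient (validated against finite differences in the tests), from a
  data-driven start (lengthscales = per-dimension input SD,
  $\sigma_s^2 = \mathrm{var}(y)$, $\sigma_n^2 = 0.1\,\mathrm{var}(y)$) plus 3
  log-uniform restarts; deterministic under a seed. Lengthscales are bounded
  to $[10^{-3}, 10^3]\times$ their start to exclude degenerate flat or spiky
  fits on short series.
* **Conditioning.** If the Cholesky factorization of $K + \sigma_n^2 I$
  fails, jitter $10^{-8}\sigma_s^2$ is added to the diagonal, escalating
  tenfold to at most $10^{-4}\sigma_s^2$, then the fit errors with a
  conditioning message.

For gap-filling the input is one-dimensional (acquisition day) and the
predictions are evaluated on a regular grid — 10-day spacing by default —
anchored at the first observation, which keeps grids reproducible and avoids
calendar-alignment ambiguity.

## Retrieval dialects

Two band dialects are supported: a 10-band set (490–2190 nm, Sentinel-2-like)
and a 6-band set (480–2200 nm, Landsat-8-like). A 10-band training table is
resampled to the 6-band sensor by selecting the six shared-wavelength columns
(`resamplePairsToL8()`); with synthetic spectra generated per band, a column
mapping is the faithful analogue of bandpass resampling. Negative predicted
LAI is clipped to zero (physical non-negativity) with the count recorded;
missing spectra propagate NA and are never imputed at the retrieval stage.

## Time-series collections

Four collections are built per parcel (`buildCollections()`):

| name | construction |
|------|--------------|
| `S30` | dense-revisit stream, Savitzky–Golay smoothed |
| `L30` | sparse-revisit stream, Savitzky–Golay smoothed |
| `SL30_SG` | date-union merge of both streams, then SG |
| `SL30_GPR` | merge, then GPR gap-fill on the regular 10-day grid |

Merging takes the union of acquisition dates; observations closer than half a
day are averaged and tagged `"both"` — collapsing duplicates is what keeps
the time axis strictly increasing, and the arithmetic mean is the natural
collapse. The merge is commutative and idempotent.

The Savitzky–Golay filter uses a window of 7 **observations** (not days) and
a quadratic, the standard span/degree choice for crop LAI series. On
irregular acquisitions fixed convolution weights do not apply, so each point
is replaced by the value of the least-squares quadratic fitted over its
7-observation window in the actual time coordinate; on evenly spaced input
this reproduces the classical filter, and a degree-2 fit reproduces quadratic
signals exactly. At the series ends the window shrinks symmetrically to the
largest odd span that fits, never below degree + 1 — shrinking avoids the
extrapolation artifacts of padded windows.

## Season detection and metrics

Candidate seasons are local maxima screened by two rules
(`detectionConfig()`):

* **prominence** ≥ `prominence_frac` × (series max − min). The published
  range for this fraction is 0.10–0.30 without a final printed value; the
  default here is 0.30, matching the stated amplitude-threshold optimum, and
  it is exposed as configuration rather than asserted as *the* upstream
  choice.
* **minimum separation** of 90 days between kept peaks; among closer peaks
  only the highest survives, and the earlier wins ties (a determinism choice
  the source is silent on). Endpoint maxima are never eligible: a cycle whose
  rise or fall lies outside the record is incomplete.

SOS and EOS are amplitude crossings located by linear interpolation between
samples (the 10-day grid needs sub-grid precision). Two conventions are
implemented:

* **seasonal** — each season's amplitude is its peak minus the mean of its
  two flanking minima; SOS is the last upward crossing of
  `left_min + 0.30 × amplitude` before the peak, EOS the first downward
  crossing of the corresponding level after it.
* **relative** — one fixed amplitude, the mean of the kept peak values minus
  the mean of their flanking minima, is applied to every season. This reading
  of "mean maximum and mean minimum" is the one that reduces exactly to the
  seasonal method when all seasons have equal amplitude; a weak season whose
  curve never reaches the fixed level is simply not detected, which is the
  method's documented failure mode under rotation systems with unequal
  amplitudes.

Seasons whose crossings would fall outside the series are discarded as
incomplete. LOS is EOS − SOS in days; for reported day-of-year statistics a
365-day year is used throughout, so a winter season with mean SOS DOY 294
and mean EOS DOY 110 in the following year has LOS 181. Area integrates the
curve above the chord joining the curve values at SOS and EOS (trapezoidal,
negative excursions floored at zero). The alternative — integrating above the
horizontal minima levels — was rejected because the chord is the only
baseline that makes the triangular worked example exact and is insensitive to
unequal flanking minima.

Seasons are classed summer when SOS falls in DOY 91–273 (April–September),
winter otherwise; the crop label comes from the planted record when one is
supplied, else from the calendar crop with the nearest preceding planting
day (circular in DOY). Winter seasons belong to the calendar year of their
SOS; their EOS is reported in the following year.

## Evaluation layer

`cropStats()` aggregates SOS/EOS/LOS per crop with wrap-aware (circular) DOY
means and SDs — the study system's winter green-ups cluster in October–
November and do not straddle the year boundary, but synthetic scenarios can,
and a silent 6-month error is the failure this prevents. Groups of one
report a missing SD, never zero. The per-collection summary is the unweighted
mean of the four per-crop SDs, rounded to whole days, matching the reporting
convention of the reference tables.

`detectionAccuracy()` compares detected seasons with a planted record.
Counting alone does not need a correspondence, but scoring synthetic truth
does, so detections are matched one-to-one to planted entries sharing parcel,
SOS-year and season class, greedily by SOS-to-planting proximity; accuracy is
the rounded percentage detected/planted, and unmatched detections are tallied
rather than dropped.

`areaLosRegression()` checks Area–LOS proportionality: Area is divided by the
mean peak LAI (putting it in days), both variables are z-scored, and OLS is
fitted — on that scale the slope equals Pearson's r, and equal-height
triangular seasons give exactly slope 1.

## What the generator emulates — and what it does not

`simulateScenario()` draws parcels under single- or double-cropping
rotations on the reference calendar (rice 15 May–10 Oct, maize 1 May–10 Aug,
wheat 10 Nov–1 May, clover 1 Oct–1 May). Each cycle is a double-logistic
pulse on a base LAI of 0.2, peak LAI ~4–5 by crop with ±0.15 parcel jitter,
green-up and senescence rates of 12 and 14 per season-span per day —
inflections at 25% and 85% of the span — normalized so the stated peak is
attained exactly. Two acquisition schedules emulate the sensor pair: 5-day
and 16-day nominal revisits with ±1-day jitter and independent cloud
dropout (20–40%); observation noise is additive Gaussian (0.2–0.3 LAI in the
bundled scenarios). Spectra for retrieval training come from a fixed
monotone exponential-saturation response per band, which makes the
retrieval's parameter recovery well-posed (the NIR response is exactly
invertible at zero noise). Multi-year truth places summer and winter peaks
more than 90 days apart by construction, so the separation rule is
satisfiable.

What this does **not** emulate: real radiative transfer (no PROSAIL),
spatially correlated cloud masks, mixed pixels and parcel-boundary effects,
atmospheric-correction residuals, or inter-annual calendar shifts. Passing
tests therefore demonstrate that the algorithms recover what the model family
can express under realistic sampling and noise — not that the retrieval
model transfers to real spectra, for which an external campaign dataset
would be required.

Problem sizes in the test-suite and acceptance computations are desk-scale by
design: 1–8 parcels, 1–2 years, 150–218 training pairs, 10–50 seeded
replicates — large enough to exercise every code path and the stated
statistical checks, small enough that the whole suite runs in minutes on one
core.

## Known limitations

* Exact GPR is $O(N^3)$; per-pixel gap-filling of large scenes is the
  workflow's computational bottleneck, as it is for any dense-GP approach.
* The homoscedastic noise model understates retrieval uncertainty where the
  reflectance–LAI response saturates (high LAI); predictive intervals there
  are optimistic.
* The relative threshold misses low-amplitude seasons by design; the
  seasonal threshold is the recommended default for rotation systems.
* Raster support is deliberately minimal (in-memory arrays, plain TIFF plus
  a JSON manifest for georeferencing); no reprojection or tiling.
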