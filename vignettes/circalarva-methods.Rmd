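---
title: "Methods: bout-based rest analysis, rhythmicity detection, and phase synchronization"
author: "circalarva"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bout-based rest analysis, rhythmicity detection, and phase synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circalarva)
```

# Scope

`circalarva` implements the computational core of a light-dependent
circadian phenotyping workflow for larval zebrafish and zebrafish cell
culture:

1. **Bout analysis** of 1-s resolution locomotor tracks: active/immobile
   classification, run-length segmentation, the sleep-like rest
   definition, and the four rest/activity architecture statistics.
2. **Rhythmicity detection** in 10-min binned activity by the
   Sokolove–Bushell chi-square periodogram, with double-plotted actogram
   matrices and per-group rhythmic ratios.
3. **Cosinor analysis** of bioluminescence and expression time courses
   (mesor, amplitude, acrophase, zero-amplitude F-test).
4. **Circular statistics** for single-cell clock phases: resultant
   length, circular mean, Rayleigh uniformity test, angular histograms.
5. **Synthetic data generators** for all three data modalities, so every
   stage can be exercised and validated end to end without recordings.

Throughout, time is kept in seconds from recording start internally, and
circadian phase is expressed in hours after light onset; recordings are
taken to start at light onset, so a track's analysis epoch in constant
darkness begins at the end of its light pulse.

# Bout analysis

A 1-s bin is *active* when its recorded distance exceeds
`movementEpsilon` (default 0 mm — immobility is literally zero recorded
distance; the parameter exists because tracker noise floors differ).
Maximal runs of equal-state bins form alternating *active bouts* and
*immobile bouts* that partition the track exactly.

An immobile bout lasting at least the rest threshold (default 60 s) is a
*rest bout*, the larval sleep-like state.  An *active period* is a
maximal interval containing no rest bout: immobile pauses shorter than
the threshold are absorbed into the surrounding activity.  Over an
analysis window the package reports, per animal:

* resting time, scaled to hours per 24-h day (`restingTime_h_per_day`);
* the number of active–rest cycles, counted as rest bouts lying fully
  inside the window (one rest terminates one cycle);
* the mean distance moved per active period and the mean active-period
  length, averaged over active periods whose full extent lies inside the
  window.

**Censoring rule.** A bout or period whose underlying extent crosses the
window boundary is excluded from per-bout means (censored durations bias
means downward) but its in-window portion still counts toward the
resting-time sum, so rest time plus active-period time always partitions
the window.  When the window coincides with the track limits, bouts
touching the ends are complete observations, not censored ones.

## The rest-threshold changepoint

The conventional 60-s threshold is motivated by a change in the pooled
immobile-bout length distribution around one minute.  The estimator
formalizes this: it fits a continuous two-segment broken line to
log10(survival) versus log10(length) of the pooled immobile-bout ECDF,
searching every observed length as a candidate breakpoint and minimizing
the total squared residual (the exhaustive search is cheap at the
relevant sizes and is its own oracle).

Three numerical choices matter:

* **Tail exclusion.** Survival points resting on fewer than 10
  exceedances are excluded.  The empirical log-survival of the few
  largest bouts always plunges below the underlying curve (the largest
  observation sits at survival 1/n regardless of the tail), which would
  otherwise fake a changepoint.
* **Validity requires both fit improvement and a slope change.**  The
  two-segment fit must improve the residual by at least 20% over a single
  line *and* the two segment slopes must differ by at least 0.25.
  The improvement rule alone is scale-unaware: an empirical survival
  curve deviates from any line by a correlated binomial wander which a
  broken line soaks up even for a single power law, so the flag would
  fire on everything.  A genuine regime change additionally shows
  distinctly different exponents.  The flag therefore detects departure
  from a single scale-free regime; a smoothly curved single-family
  distribution (e.g. exponential) can still be flagged because it, too,
  is better described by two log-log slopes than one.
* **Preconditions.** At least 50 distinct lengths spanning at least one
  decade are required; otherwise the estimator refuses and directs the
  caller to the conventional 60-s default.

The matching generator (`simulateRestBoutMixture`) draws from a
two-regime power-law survival with its kink at the requested crossover
(default slopes 0.5 and 2, crossover 60 s), because that construction's
log-log survival *is* a broken line; heavy-tailed bout-length
distributions are also what behavioral recordings typically show.  An
exponential-pause/lognormal-rest mixture is provided as an alternative
family, with its weight solved so the component survivals cross at the
target; note its log-log survival bends smoothly rather than kinking, so
changepoint recovery from it is inherently less precise.

```{r threshold-demo}
set.seed(1)
lengths <- simulateRestBoutMixture(5000, crossover = 60)
estimateRestThreshold(boutEcdf(lengths))
```

# Rhythmicity detection

Tracks are re-binned to 10-min bins (sums, exactly conserving total
distance).  For each candidate period $P$ in whole bins over 16–32 h, the
post-pulse series is folded into $K = \lfloor N/P \rfloor$ complete
cycles and

$$Q_P \;=\; \frac{K\,N'\,\sum_{h=1}^{P}(M_h-\bar M)^2}
                 {\sum_{i=1}^{N'}(x_i-\bar M)^2},\qquad N' = KP,$$

with $M_h$ the fold-position means.  Under a white-noise null $Q_P$ is
approximately $\chi^2_{P-1}$; the significance curve is the
$\chi^2_{P-1}$ quantile at $1-\alpha/m$, Bonferroni-corrected over the
$m$ scanned periods (unstated in the original workflow; conservative and
standard).  An animal is *rhythmic* when the peak exceeds its threshold
and the peak period lies in the circadian band 20–28 h — significant
peaks at the scan edges are treated as aliasing artifacts.  A
zero-variance (fully immobile) record has no defined statistic; the
pipeline reports such animals as arrhythmic rather than failing them.
A normalized Lomb–Scargle power with its exponential null is available
as an alternative statistic behind the `method` argument.

Group summaries report integer percentages of rhythmic animals per
genotype × light condition, with counts.

# Cosinor analysis and circular statistics

The single-component cosinor
$y(t) = M + A\cos\!\big(2\pi (t-\varphi)/\tau\big)$ is fit by least
squares in the linear parameterization
$(M, \beta, \gamma) = (M, A\cos 2\pi\varphi/\tau, A\sin 2\pi\varphi/\tau)$,
so $A=\sqrt{\beta^2+\gamma^2}$ and
$\varphi = (\tau/2\pi)\,\mathrm{atan2}(\gamma,\beta) \bmod \tau$.
The period is fixed at $\tau = 24$ h by default — the analyses are
anchored to the 24-h cycle after an entraining light pulse — with a
free-period grid scan as an explicit option.  Rhythm detection uses the
zero-amplitude F-test with $(2, n-3)$ degrees of freedom; cells or
courses with $p \ge \alpha$ (default 0.05, unstated in the original
workflow) are flagged arrhythmic and excluded from phase summaries, never
silently dropped.

Bioluminescence traces are detrended by subtracting a centered 24-h
moving average (one full cycle, so the average tracks the baseline, not
the rhythm; edge windows shrink one-sidedly) and normalized by the
time-mean of absolute intensity (per trace; a per-trace maximum-peak mode
is also provided).

A cell's phase is its acrophase mapped to the circle,
$2\pi\varphi/\tau$.  For a phase set the package reports the circular
mean and resultant length $R$ from the complex mean, the Rayleigh
uniformity test using Zar's approximation
$p = \exp\!\big(\sqrt{1+4n+4(n^2-R_n^2)}-(1+2n)\big)$ (its size at
$n = 24$ is within half a percentage point of nominal, and exact
permutation adds nothing at these n), and a 12-bin (2-h) angular
histogram.

# The synthetic generators

`simulateTrack` draws an alternating-renewal process at 1-s resolution:
lognormal active periods alternate with lognormal rest bouts (log-sd
0.6; families are unstated by any data source and configurable), and
within active periods, gamma per-second distances (shape 0.3,
right-skewed) are interrupted by short exponential pauses capped below
the rest threshold.  The circadian phenotype enters as a modulation of
the rest-initiation rate after the light pulse,
$1 + d\cos\!\big(2\pi(t-\varphi_0)/24\,\mathrm h\big)$, implemented by
scaling the mean of each active-period draw by the gate at its onset.
Rest initiation peaks at $\varphi_0 = 18$ h after light onset
(mid subjective night of a diurnal animal; no phase value is printed in
any source, so this is a package convention).  Before or without a light
pulse there is no modulation — dark-reared animals have dispersed
cellular clock phases and no coherent behavioral rhythm.

Presets encode three genotypes.  Their rest-bout means are solved
numerically so the *time-averaged* daily resting fraction under a 12-h
pulse hits the calibration targets 7.8 (WT), 20.5 (DKO) and 20.6 h/day
(TKO): because active periods are much shorter than 24 h the process is
locally stationary, and each time of day occupies equal time, so the
daily fraction is the uniform phase average of
$m_r / (m_r + m_a/(1+d\cos\theta))$.  Modulation depths encode the
light-history contrast (WT entrains after either pulse, depth 0.9; the
double knockout only after a 12-h pulse, depth 0.8 vs 0.05; the triple
knockout not at all, 0.05), and active-period means (15 min WT, 6 min
knockouts) are chosen at the timescale of real larval swim/rest
alternation so that rest initiations recur often enough to carry the
modulation.  The printed per-genotype cycle counts of the source
behavioral table are internally inconsistent with its mean active-period
lengths under any single definition, so cycle counts are *not*
calibration targets; the resting-time means and the qualitative
orderings are.

`simulateCells` draws damped cosine oscillators,
$b(1+st) + A(1-\delta)^{t/24}\cos(2\pi(t-\varphi_c)/\tau) + \varepsilon$,
with per-cell phases either uniform on the circle (dark condition:
cell-autonomous clocks free-run out of phase) or wrapped-normal with 1-h
spread (light-synchronized).  `simulateExpression` provides acute
(3-h-peaking) and slow (12-h-peaking) light-induction pulse shapes,
a clock-output cosine gated by a `synchronized` flag, and flat controls,
under multiplicative lognormal noise with the time-0 value renormalized
to 1.

What the generators do *not* emulate: mechanistic clock gene networks,
light responses during (rather than after) the pulse, inter-animal
parameter heterogeneity beyond sampling noise, tracker artifacts
(dropouts, reflections), and plate-position effects.  Passing tests
therefore demonstrate that the estimators recover what the generative
model encodes at realistic sizes and noise levels — not that real
recordings satisfy the model.

# Validation sizes

The test suite and acceptance script validate, among others: exact
equality of bout segmentation with a brute-force run-length encoder
(1000 random sequences up to length 10,000); a hand-derived 600-s
worked example of the rest statistics; changepoint recovery within
±15 s of a constructed 60-s crossover in 20 cohorts of 5000 bouts;
exact cosinor recovery without noise and 10%/0.5-h recovery under
σ = 0.5 noise across 50 seeds, cross-checked against a dense
grid-search oracle; periodogram size on 200 white-noise tracks and
≥ 90% power on 50 simulated wild-type tracks; Rayleigh contracts
(R = 1 synchrony, R = 0 symmetry, size under uniformity) against a
direct complex-sum oracle; and cohorts of 12 animals per genotype ×
condition for the end-to-end contrasts.  These sizes were chosen to
give stable Monte-Carlo margins at desk scale.

# Known limitations

* Table-level statistics are per animal; group inference (t-tests,
  ANOVA) is deliberately out of scope.
* The changepoint validity flag distinguishes two-regime from
  single-power-law survival; it does not certify the mixture family.
* The chi-square periodogram assumes independent bins under the null;
  strong within-day autocorrelation (long bouts) inflates its statistic,
  which is why rhythm calls are restricted to the circadian band.
* Acrophases are meaningful only relative to light onset; for DD-only
  schedules they are phases of the free-run, not of an entrained cycle.
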