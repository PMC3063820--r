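---
title: "Models and methods behind qpcrflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qpcrflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrflux)
library(dplyr)
```

`qpcrflux` implements a complete relative-quantification chain for
SYBR-green qPCR: amplification-efficiency estimation from fluorescence
curves, Grubbs screening of technical triplicates, reference-gene
stability ranking, efficiency-corrected expression ratios with
randomization inference, and 2^-ΔΔCT transcript amounts combined with
enzyme kinetics into turnover-potential scores. This vignette records the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data tests do and do not establish.

## The amplification-curve model

A simulated well follows

$$F(c) \;=\; b \;+\; \frac{A\,E^{c}}{1 + A\,E^{c}/(P-b)} \;+\;
\varepsilon_c, \qquad \varepsilon_c \sim N(0, \sigma^2),$$

with baseline $b$, plateau $P$, initial signal $A$ and per-cycle
efficiency $E \in (1, 2]$. The logistic clamp is the simplest form with a
clean log-linear phase — while $A E^c \ll P - b$,
$\log_{10}(F - b)$ grows by exactly $\log_{10} E$ per cycle — and a smooth
approach to the plateau, as real SYBR curves show. Defaults
(`curve_params()`): $b = 50$, $P = 5050$ (a 5000-unit span, typical of
RFU-scaled exports), $A = 10^{-4}$ so the half-rise sits near cycle 28 at
$E = 1.9$, 40 cycles (the standard two-step protocol length), no noise.
Melt curves, primer-dimer artifacts and plate-layout effects are out of
scope.

## Window-of-linearity efficiency estimation

`estimate_efficiency()` proceeds per well:

1. **Baseline correction.** The mean fluorescence of the
   *pre-amplification* cycles inside the import window (cycles 3–15 by
   default) is subtracted. Pre-amplification cycles are those within 5% of
   the trace range above its minimum; this guard keeps a reaction that
   amplifies early from inflating its own baseline. The spread of the
   baseline region is retained as a noise estimate.
2. **Point eligibility.** Log fits use points that are positive, exceed a
   noise floor of 5 × the baseline SD, and lie below 0.9 × the detected
   plateau. The plateau is declared only when the last four cycles are
   mutually flat within 5%; a trace that is still rising at the last cycle
   has no plateau and no upper cut.
3. **Saturation correction.** When a plateau $P$ is detected, the clamp is
   inverted before fitting: $y = \log_{10} f - \log_{10}(1 - f/P)$. Without
   this, any 4–6-point window that noise forces into the bend of the curve
   yields a slope biased low — with noise at 0.5% of the plateau the naive
   fit under-estimates $E$ by 0.1–0.2, because the usable purely
   exponential stretch between the noise floor and the clamp onset is
   shorter than four cycles. After inversion the whole rise is log-linear
   and the estimator is unbiased (mean absolute error ≈ 0.016 at that
   noise level in the test suite). Non-saturating traces are fitted on
   plain $\log_{10} f$, so the correction never touches the clean
   exponential case.
4. **Window selection.** Straight lines are fitted by least squares to all
   contiguous windows, and selection is *length-major*: the best-correlated
   6-point window wins; 5- and then 4-point windows are considered only
   when no longer window is eligible, and ties go to the earlier start.
   A pure max-$r$ rule across lengths would let short windows win
   correlation comparisons by chance under noise; the length-major rule
   removed most of the estimator variance in simulation. The fitted slope
   gives $E = 10^{\text{slope}}$; any log base yields the same $E$,
   base 10 is used for familiarity.
5. **Per-amplicon mean.** Reactions with fit correlation ≥ 0.998 (and $E$
   inside $(1, 2]$) are averaged; the count of exclusions is reported, and
   an amplicon whose reactions are all rejected is an error, not a silent
   `NaN`. Reported means are rounded to two decimals, the convention of
   primer-efficiency tables.

The noise-free recovery property (estimated $E$ equal to truth within
$10^{-6}$, regardless of baseline and initial amount) holds when the fit
window lies in the truly exponential phase, so the tests verify it on
curves whose plateau sits far above the measured range; saturating
noise-free curves are recovered to ~$10^{-3}$ after clamp inversion. The
noisy checks use saturating curves, since noise quoted as a fraction of
the plateau is only meaningful there. Bit-compatibility with any release
of instrument software or external fitting programs is a non-goal, and CT
values are treated as given inputs (the threshold convention of the
instrument is not modelled).

## Triplicate screening

`grubbs_outlier()` computes $G = \max_i |x_i - \bar x| / s$ with the
sample SD and compares it to the two-sided critical value
$G_{crit}(n, \alpha) = \frac{n-1}{\sqrt n}
\sqrt{t^2 / (n - 2 + t^2)}$, $t$ the upper $\alpha/(2n)$ t-quantile on
$n - 2$ df (checked in the tests against published Grubbs tables). The
test is single-pass at $\alpha = 0.05$: for triplets this is the
conservative choice, and at $n = 3$ the attainable maximum
$G = 2/\sqrt 3 \approx 1.1547$ barely exceeds the critical 1.1543, so a
value is removed only when the other two nearly coincide — the suite
asserts this boundary explicitly. Aggregation is the arithmetic mean of
the surviving detected values (means, not medians, to match how averaged
CT tables are reported), rounded to one decimal only at reporting.
Triplets left with fewer than two detected values become not-detected;
non-detects are always carried as missing values with a flag, never as a
sentinel CT, to avoid biasing means.

## Reference-gene stability

`rank_references()` follows the BestKeeper construction: the per-sample
index is the geometric mean of candidate CTs, and each candidate gets its
CT standard deviation, coefficient of variation and Pearson correlation
with the index. Selection uses the published rule of thumb SD < 1 cycle
plus an index-correlation floor (0.5 by default), capped at the top 3;
both are configurable. Genes with any non-detected sample are ineligible.
A constant gene has an undefined correlation; it is kept, flagged `NA`,
since zero dispersion cannot argue against it.

On the packaged survey table the ranking is instructive but
under-determined: several target genes (SQS, FDS, DXR) have raw CT
dispersion comparable to the classical reference genes, so the published
choice of references cannot be reconstructed from dispersion alone — the
original selection used replicate-level data that the printed averages no
longer contain. Selection behaviour is therefore asserted on synthetic
tables, where designated reference genes recover the top ranks in ≥ 9/10
seeds.

## Expression ratios and inference

`pfaffl_ratio()` is the efficiency-corrected ratio
$E_t^{\Delta CT_t} / \mathrm{geomean}_r\, E_r^{\Delta CT_r}$ with
$\Delta CT$ = control − sample; multi-reference normalization uses the
geometric mean of per-reference correction factors. Two structural
identities are enforced by tests: the ratio with all efficiencies at 2
equals 2^-ΔΔCT on the same inputs (the two routes are implemented
independently), and swapping sample and control inverts the ratio.

Inference treats the *well* as the exchangeable unit. Writing
$s_w = \log E_t \cdot CT_{t,w} - \frac1R \sum_r \log E_r \cdot CT_{r,w}$,
the log ratio is the difference of group means of $s_w$, so the
randomization test permutes whole replicate CT sets — each well's target
and reference CTs move together, preserving their pairing — between the
sample and control groups and reports $p = (b+1)/(n_{iter}+1)$ over 2000
iterations by default. With three biological runs of technical triplicates
per group this gives $\binom{18}{9}$ distinct reallocations and a
calibrated test; reallocating only the 3 + 3 aggregated biological means
would cap the attainable p-value at $2/\binom63 = 0.1$ and make the test
useless at routine replicate counts. The cost of the well-level unit is
that within-run correlation is treated as exchangeable noise; under the
generator's model (independent Gaussian run shifts and technical noise)
the type-I error at 0.05 stays inside the exact binomial 99% band in a
200-gene null simulation, but with strongly run-dominated real data the
user should aggregate to run means first and expect the coarser p-value
grid. Intervals come from a percentile bootstrap over wells within groups
(2000 resamples, level 0.95), widened if needed to contain the point
ratio so that degenerate resamples cannot produce an interval excluding
the estimate. No multiple-testing correction is applied by default, a
Benjamini–Hochberg option (`p_adjust = "BH"`) exists.

## 2^-ΔΔCT amounts and turnover potential

`delta_delta_ct()` fixes the amplification factor at 2 (the classical
Livak form — the packaged survey's printed amounts are exact powers of
two, confirming measured efficiencies were not used there), with the
reference gene always taken in the same tissue as the CT it normalizes.
The calibrator cell is 1 by construction and amounts are
calibrator-chain-consistent (re-normalizing to another calibrator is an
exact rescaling). Reporting mode rounds amounts to integers; turnover
scores, `amount × kcat × substrate stoichiometry`, are reported as
integers above 10 and to one decimal below, matching how such tables are
printed. The Michaelis constant is stored but unused: the score assumes
substrate saturation, where kcat alone sets conversion capacity, and
active-site number proportional to transcript level — a deliberately
crude ranking device, not a flux model. Enzymes without a published kcat
are excluded with a flag rather than scored.

One fixture row deserves a note: the DBR2-specific primer CTs give
ΔΔCT = −11.8 in flower buds, while the published table prints −7.9 — a
value that instead matches the *combined* DBR2 + OPR3-like amplicon row
exactly. The package reports what the specific primer data give and
treats the printed row as a documented discrepancy; the likely origin is
that the combined-primer measurement fed that table.

The competition ratio between two enzymes in the same tissue is the ratio
of their turnover scores, stoichiometry included — squalene synthase
consumes two farnesyl-diphosphate molecules per event, so its assumed
kcat ≈ 1 s⁻¹ counts double in the FDP budget. On the packaged survey this
evaluates to 25.4 in young leaves and 47.4 in flower buds (the published
prose rounds the latter to "about 45"; the gap comes from its use of
integer-rounded amounts).

## The synthetic-data generator

`simulate_ct_table()` draws
$CT(g, t) = CT_{base}(g) - \log_{E_g}(\text{fold change}) + u_{t,run} +
\varepsilon$, with per-run shifts $u \sim N(0, 0.2^2)$ cycles shared by a
biological run's wells, technical noise $\varepsilon \sim N(0, 0.15^2)$
cycles (routine SYBR triplicate spread), non-detects beyond CT 40 (the
protocol length), and optional outlier contamination displacing exactly
one replicate of a triplet by +5 to +10 cycles — large enough for the
Grubbs test at $n = 3$ to flag. Defaults: technical triplicates, two
biological runs, fold change 1 everywhere, reference genes validated to be
flat. What the generator does *not* emulate: plate effects, inhibition
(efficiency varying with template load), heteroscedastic CT noise at high
CT, and correlated noise between genes sharing a well position. Passing
tests therefore certify the statistical machinery under clean Gaussian
structure, not robustness to every instrument pathology.

## Problem sizes and determinism

The test suite runs desk-scale problems: 100 noisy curves for the
efficiency error bound, a 200-gene null table at 1000 randomization
iterations for calibration, 60 simulations for bootstrap coverage. Every
randomized stage takes a seed; `run_pipeline()` seeds once, records the
seed and all stage parameters in a JSON manifest, and repeated runs are
byte-identical. The acceptance script recomputes the packaged survey's
headline quantities (flower-bud amounts and turnover scores, the
stem-calibrated synthase amounts, the SQS : ADS competition ratio) from
the fixtures at run time.

## Known limitations

* CT determination from curves is not implemented; CT values are inputs.
* The turnover score ignores substrate concentration, $K_m$, translation
  efficiency and protein turnover — it ranks capacity, not flux.
* The well-level randomization unit is exact under the generator's noise
  model but approximate when run effects dominate (see above).
* The stability module implements a single (BestKeeper-style) criterion;
  pairwise-variation and model-based alternatives are out of scope.
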