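---
title: "Quantifying antibiotic persistence: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying antibiotic persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persistlab)
```

`persistlab` analyses antibiotic-persistence experiments at two scales:
batch killing curves measured by limiting dilution, and single-cell
lineage records from microchamber time-lapse imaging. This vignette is the
package's account of the underlying models, the measurement conventions it
adopts, and the choices made where the design was genuinely open. It
states no empirical result that the test suite and the acceptance script
do not themselves compute.

## 1. Viable counts by limiting dilution (MPN)

A sample at dilution $d$ is dispensed into $W$ wells of volume $y$ mL.
If viable cells are Poisson-distributed among wells, a well stays
non-turbid with probability $e^{-dyN_v}$, so with $k$ non-turbid wells the
density estimate is

$$ \hat N_v = \frac{\ln(W/k)}{y\,d}. $$

Assumptions: independent allocation (no aggregation), every viable cell
founds visible growth within the incubation time, and turbidity scoring is
error-free. The estimator is undefined at $k = 0$ (all wells turbid; the
assay only bounds the density from below, signalled as an error of class
`persistlab_all_turbid`) and returns 0 at $k = W$ with a warning.

Conventions:

* $y$ defaults to 0.2 mL (200 µL wells); the constant 5 in the common
  $(5/d)\ln(W/k)$ form is always derived from $y$, never hard-coded.
* When two dilutions show mixed (turbid + non-turbid) wells, their two
  estimates are reconciled by geometric mean, the natural mean for a
  log-scale quantity. No well-count weighting is applied when the two
  dilutions used different numbers of wells; the convention for that case
  is not established, so we keep the unweighted geometric mean.
* If more than two dilutions are mixed (rare; real assays see at most
  two), the two with $k$ closest to $W/2$ are used — the Poisson
  information per well is maximal near 50% emptiness — and a warning is
  emitted.
* Replicate curves are summarised per time point as mean ± SE of
  $\log_{10}$ density. Time points where no dilution shows growth
  contribute density 0 and are excluded from the log-mean with an explicit
  flag ($\log 0$ is undefined); time points with no usable plate are
  flagged missing rather than dropped silently.
* The MPN estimator is biased upward at the plate level (Jensen); the
  package documents and tests a weaker property instead: over plates with
  $\lambda = dyN_v \in [0.2, 3]$, the median estimate is within 20% of the
  truth.

## 2. Multi-exponential killing curves and phase selection

Killing curves of heterogeneous populations are modelled as a sum of
exponentially decaying subpopulations,

$$ f_n(t) = \sum_{j=1}^{n} a_j e^{-d_j t}, \qquad a_j > 0,\; d_j > 0, $$

fitted by least squares on **natural-log** residuals,
$\mathrm{SSR} = \sum_i (\ln N_i - \ln f_n(t_i))^2$. Fitting in log space
weights the decades equally, which is what makes the slow tail (the
persister phase, often 5–6 decades below the initial density) identifiable
at all. The fit is per mean curve, not per replicate.

The number of phases is chosen by the Gaussian-residual AIC with the
variance profiled out:

$$ \mathrm{AIC} = N\ln(2\pi) + N + N\ln(\mathrm{SSR}/N) + 2k, $$

minimised over $n = 1 \ldots n_{\max}$, ties broken toward smaller $n$.

Numerical choices:

* **Parameter count** $k = 2n$: the amplitudes and rates actually
  optimised. Counting the profiled residual variance ($k = 2n+1$) would
  shift every candidate's AIC by the same +2 and cannot change the
  selected $n$; the choice is therefore inconsequential here and we use
  the free-parameter count.
* **Parameterisation**: the optimiser works on $(\ln a_j, \ln d_j)$, so
  positivity is structural and the inner solver is unconstrained
  (L-BFGS-B with wide log-bounds to prevent overflow excursions, followed
  by Nelder-Mead/gradient polish passes).
* **Starts**: one deterministic start from exponential peeling (fit the
  slowest phase on the latest time block by log-linear regression,
  subtract, repeat), plus a deterministic grid of decade-spaced rate
  combinations \{0.1, 1, 10\} 1/h with amplitudes back-solved by linear
  least squares, plus seeded ±20% log-jitter starts up to the requested
  count. Selection is reproducible given the seed.
* **Convergence**: relative SSR change below $10^{-10}$ or 500
  iterations; all-start failure returns `converged = FALSE` rather than a
  value.
* **Degeneracy**: two fitted rates within relative $10^{-3}$ are flagged
  (`degenerate = TRUE`) — the data do not support separate phases.
* **SSR floor**: SSR below $10^{-12}$ (numerically perfect fits on
  noiseless data) is clamped before the log in the AIC, with a warning,
  to keep the criterion finite.
* For $n = 1$ the problem is exactly log-linear regression;
  `loglinear_fit()` exposes that closed form and the test suite requires
  the iterative path to match it to 6 decimals.

## 3. Single-cell lineage statistics

Lineage tables are rooted forests: each cell has a birth and end time, an
end fate (`division`, `lysis`, `tracking_lost`, `censored`), per-cell
areas, and founders carry a persister flag (did any descendant survive
exposure and regrow).

* **Division rate** of a lineage $\sigma$ is $D(\sigma)/T(\sigma)$,
  divisions per pre-exposure hour (doublings/h). To compare groups without
  pseudo-replication, one lineage per founder is sampled by choosing a
  random sister at each division (`sample_independent_lineages()`,
  deterministic given the seed).
* **Growing/non-growing classification** uses the window (default 1.5 h,
  i.e. 90 min; configurable for other protocols) immediately before
  exposure: `non_growing` iff no division in the window **and** relative
  area increase below the elongation threshold; `indeterminate` if
  tracking was lost in the window (excluded from both numerator and
  denominator of fractions, with a reported count); `growing` otherwise.
  The elongation threshold defaults to **10%** relative area increase;
  "without elongation" has no established quantitative definition, so the
  threshold is an explicit, documented knob.
* **Fractions** use the Wald binomial SE $\sqrt{p(1-p)/n}$ without
  continuity correction, matching the symmetric ± convention of
  chamber-count reporting.
* **Persister frequency from chambers**: exposed-cell total = mean cell
  count over sampled chambers × number of chambers tracked; frequency =
  persisters / total, with binomial SE.
* **Circularity** $4\pi A/P^2$ from the polygon outline (shoelace area,
  Euclidean perimeter); 1 for a circle, decreasing with elongation.
  Self-intersecting outlines are rejected; duplicate consecutive vertices
  are dropped. Frames without outlines contribute area only; circularity
  is reported missing, not zero.
* **Rank-sum test**: exact two-sided p by complete enumeration when both
  samples have ≤ 10 observations and no ties; otherwise the normal
  approximation with tie and continuity corrections (verified against the
  reference implementation).

When per-frame areas are absent, areas between a cell's recorded birth and
end are interpolated exponentially, with growth capped at exposure onset —
under a lethal β-lactam dose, surviving cells do not elongate further, so
carrying the end area back to the onset is the conservative reading of a
record that spans the exposure.

## 4. The two-mode survival model $f = s P_n$

If persisters arise (predominantly) from the non-growing subpopulation,
and a non-growing cell is a persister with probability $s$ independent of
how the population reached its state, then the population persister
frequency is $f = s P_n$ with $P_n$ the non-growing fraction immediately
before exposure.

* $s$ is anchored on one condition, by default the condition with the
  largest $P_n$ (the most stationary population, where all identified
  persisters were non-growing): $\hat s = f/P_n$, clamped to $[0,1]$ with
  a warning.
* **Error propagation** (the convention behind published ± ranges on such
  ratios is generally unstated, so both variants are exposed):
  the default `linear` variant is symmetric first-order propagation,
  $\Delta s = s\sqrt{(\Delta f/f)^2 + (\Delta P_n/P_n)^2}$, with
  $\Delta f$ equal to half the width of the linear-scale range of $f$ and
  $\Delta P_n$ the binomial SE; the `log` variant propagates on the
  $\log_{10}$ scale and yields an asymmetric range.
* `predict_f()` returns $f = sP_n$ with the band
  $[s_{lo}P_n,\, s_{hi}P_n]$. In `fit_survival_model()` the band for each
  *measured* condition is additionally widened by ±1 SE of that
  condition's $P_n$ (scaled by the $s$ bounds). Rationale: the prediction
  for a condition is uncertain both through $s$ and through the measured
  $P_n$ (the horizontal error bar of an observed-vs-predicted plot);
  without this, strict range-overlap classification of conditions that
  truly share one $s$ has joint coverage of only about $0.95^2 \approx
  90\%$ — a coin flip against a ≥90% reproducibility requirement — purely
  by construction of the narrow $s$-only band.
* `classify_scenario()` is strict interval logic: `below_prediction` iff
  the observed range lies entirely below the band, `above_prediction` iff
  entirely above, otherwise `consistent_with_constant_s`. When growing
  persisters are present, the observed $f$ is only an upper bound for the
  non-growing-persister frequency; the classification carries that note
  rather than attempting a correction.

## 5. The synthetic-data generator: its stated world

`simulate_chamber_lineages()` generates what the analysis consumes — a
lineage forest with areas and fates — from a two-state model:

* Founders (one per chamber) start non-growing with probability
  `p_nongrowing` and may switch states at rates `switch_gn`, `switch_ng`
  (default 0: no stated switching rates exist, and the generative model of
  persister formation — triggered vs spontaneous — is deliberately left
  out; the two-state model is a stand-in whose parameters are not
  data-derived except where noted below).
* Growing cells divide with exponential waiting times at rate
  `division_rate` (divisions/h). **Calibration note**: each division is
  one doubling along a lineage, so the lineage statistic
  $D(\sigma)/T(\sigma)$ recovers `division_rate` exactly — this is the
  doublings/h quantity the single-cell analysis measures. (Calibrating the
  waiting-time rate as `division_rate · ln 2` would instead make the
  *population* grow at `division_rate` doublings/h while lineages measure
  only `ln 2 ≈ 0.69` of it; since every downstream statistic here is
  lineage-based, the lineage calibration is the testable one.) Cell areas
  grow exponentially at rate `division_rate · ln 2` while growing — so
  area doubles over a mean division interval — and halve at division;
  non-growing cells keep constant area.
* At exposure onset each live cell draws its persister fate from the
  state-dependent probability (`s_growing`, `s_nongrowing`); fates are
  frozen at onset (no switching under drug). Non-persisters lyse with
  exponential waiting times at the state kill rate, or are censored at the
  end of observation; persisters regrow — their first post-removal
  division is emitted within the post-exposure window, so "persister ⇒
  regrowth event" holds by construction.
* Killing is per-cell Bernoulli/exponential (binomial thinning), never a
  deterministic scaling; the deterministic expectation (`multiexp_eval`)
  is available separately as an oracle.
* One root seed; each operation derives a labelled child stream, so
  results are bit-reproducible given (config, seed) and adding one
  operation does not shift another's draws.

Defaults describe an exponential-phase enteric-bacterium population in
rich medium under a lethal β-lactam dose: 2.26 doublings/h (the measured
non-persister division rate), a rare non-growing subpopulation
($2.9\times10^{-4}$), fast killing of growing cells (9.89 1/h) and slow
decay of the tail (0.508 1/h) taken from the fitted triphasic killing
curve, survival probabilities $s_\text{growing} = 1.6\times10^{-5}$ (the
observed growing-persister frequency) and $s_\text{nongrowing} = 0.084$
(the anchored estimate), a 1.5 h pre-exposure period, 6 h exposure, 6 h
regrowth observation, and 3-min frames.

What the generator does **not** emulate — and hence what a green test does
not establish: spatial chamber packing and crowding, segmentation and
tracking errors, late regrowers beyond the observation window (a real
source of persister undercounting in chamber assays), wall-deficient
(L-form-like) morphologies, triggered persister formation dynamics, or any
correlation between sister cells' fates. Tests against the simulator
verify the *estimators* under the model's assumptions, not the biology.

## 6. Degenerate inputs and edge rules

* `estimate_viable_density`: $k=0$ errors (`persistlab_all_turbid`);
  $k=W$ returns 0 with a warning.
* Constant killing-curve data: selection returns $n=1$ with a near-zero
  rate (flagged by the rate bound), not a failure.
* `surviving_fraction(curve, 0)` is exactly 1 with a degenerate range
  when the $t=0$ SE is 0.
* Fractions with all labels indeterminate are an error, not NaN.
* `mic_from_od` returns `Inf` with a warning when no tested concentration
  suppresses growth ("above tested range").
* Times are hours everywhere; unit conversion happens only at the I/O
  boundary (`cli_io`). Tables are UTF-8, '.'-decimal, header-required
  CSV/TSV; outlines travel as WKT strings in a single column.

## 7. Known limitations

* The MPN point estimator's small-plate bias is documented, not corrected
  (no bias-corrected MPN variant is provided).
* No confidence intervals on fitted decay rates; the fit reports SSR/AIC
  only.
* Replicate-level joint fitting of killing curves is out of scope; the
  mean curve is fitted.
* The survival model is the two-mode dichotomy with a constant $s$; no
  state-dependent extensions or Bayesian inference.
* Sibling-fate correlation is not tested statistically; single observed
  sibling pairs do not support it.
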