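---
title: "riceideo: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riceideo: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the surrogate
growth model and its assumptions, the sensitivity, optimization and
similarity layers, the synthetic data generators, and the design decisions
taken where the published description of this class of analysis is silent.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The problem

Rainfed rice production across the Casamance and Eastern Senegal region
spans a steep climate–soil gradient: a humid south (seasonal rainfall
around 917 mm, relative humidity 80%) and a drought-prone north (around
513 mm, drier and hotter air — vapor pressure deficit 1.19 kPa against
0.67 kPa in the south, as `vpd()` reproduces from the Tetens curve).
Process-based crop models encode a genotype in this setting as a small
vector of *genetic coefficients*; an *ideotype* is the coefficient vector
that maximises performance in a given environment. The package inverts the
usual simulation workflow: screen which coefficients matter, search the
coefficient space for the per-environment optimum, then rank real cultivars
by proximity to that optimum.

## 2. The surrogate growth model

`simulate_rice()` is **not** a port of any production crop model. It is a
deliberately minimal daily-loop surrogate that preserves the documented
*semantics* of the eleven coefficients — what each one controls — without
reproducing any particular model's internal equations, which are not
public in the source material for this pipeline. Its components:

* **Thermal time.** `thermal_time()` accrues `max(0, (tmin+tmax)/2 − tbase)`
  per day, `tbase = 9` °C (a conventional base temperature for rice; the
  source material states none).
* **Phenology.** The vegetative phase ends when accumulated thermal time
  reaches `photothermal_requirement()` = `P1 + P2R·max(0, daylength −
  P2O)`. A fixed panicle-development span follows (see §6 on its default),
  lengthened by `tcldp_slope = 10` GDD per °C-day of minima below `TCLDP`;
  anthesis is recorded at its end. Grain filling then lasts `P5` GDD.
* **Canopy and assimilation.** Leaves appear every `PHINT` GDD; light
  interception saturates as `1 − exp(−k_leaf · leaves)`. Daily biomass gain
  is `rue · srad · interception · stress` (g m⁻² scaled to kg ha⁻¹).
* **Water.** A single-layer bucket over the rooting depth
  (`water_balance_step()`): rain in, runoff above saturation, drainage
  above field capacity bounded by `SSKS`, transpiration `stress ×
  demand` where the stress factor ramps from 0 at wilting point to 1 once
  the readily-available fraction (`raw_frac = 0.6`) of the LL–DUL store is
  held. Demand is a radiation-based reference ET times a crop coefficient
  growing with canopy. Mass balance is exact; the test suite closes it to
  10⁻⁶ mm over 1,000 random runs.
* **Reproduction.** Tillers respond to `G3`, canopy at panicle initiation
  and vegetative water status; grain number is `G1 · tillers` discounted by
  thermal sterility (`sterility_fraction()`: linear ramps of width 5 °C
  above `THOT` on maxima and 4 °C below `TCLDF` on minima, combined as
  independent risks over anthesis ± 5 days) and by flowering-window stress.
  Grain filling is limited both by the sink (`grains · G2`) and by the
  assimilate supply during the filling window, with the supply term using
  `stress^fill_stress_exp` — reproductive processes are more
  drought-sensitive than vegetative growth.
* **Failure semantics.** A season that never reaches anthesis returns a
  flagged zero-yield result instead of raising, so the optimizer can
  penalize rather than crash.

### Constants and why they have these values

All constants live in `crop_model_config()` and are design choices of this
package, fixed once against two calibration targets: (i) realistic output
magnitudes in the wet archetype (harvest index near 0.5, water-use
efficiency within the 2–15 kg ha⁻¹ mm⁻¹ physiological band, cycles of
100–120 days), and (ii) the qualitative G×E physiology the simulator exists
to express — extended grain filling profitable under wet conditions,
drought escape under terminal water deficit.

| constant | default | unit | role |
|---|---|---|---|
| `tbase` | 9 | °C | base temperature for thermal time |
| `rue` | 1.1 | g/MJ | radiation-use efficiency |
| `k_leaf` | 0.12 | – | canopy interception per leaf |
| `base_density` | 150 | tillers/m² | pre-`G3` tiller baseline |
| `panicle_span` | 450 | GDD | panicle initiation → anthesis |
| `heat_ramp`, `cold_ramp` | 5, 4 | °C | sterility ramp widths |
| `tcldp_slope` | 10 | GDD/°C/day | cold panicle delay |
| `raw_frac` | 0.6 | – | readily available water fraction |
| `et_alpha` | 1.1 | – | radiation→reference-ET coefficient |
| `kc_min` | 0.3 | – | bare-soil crop coefficient |
| `fill_frac` | 0.85 | – | assimilate share loadable into grain |
| `fill_stress_exp` | 3 | – | drought sensitivity of grain filling |
| `max_hi` | 0.62 | – | hard harvest-index cap |
| `season_cap` | 160 | days | maximum season |
| `flower_window` | 5 | days | sterility half-window |

Two of these deserve explicit justification. The panicle span default is
450 GDD rather than a nominal 180: with realistic `P1` bounds and regional
temperatures (17–19 GDD/day) a 180-GDD span produces 50–90-day cycles, far
shorter than either wet season, so the seasonal water budget never binds
and the wet/dry contrast in optimal phenology degenerates; 450 GDD folds
the post-initiation developmental phases of CERES-type models into one span
and restores 100–120-day cycles. The grain-filling stress exponent is 3
because with a linear exponent the filling and biomass terms respond
identically to drought and the harvest index becomes insensitive to *when*
filling happens; a super-linear exponent encodes the well-established
greater drought sensitivity of reproductive processes and makes filling
into a drying soil profile genuinely costly.

## 3. Morris screening and the RSI

`build_trajectory()` implements the one-at-a-time trajectory design: k + 1
points, consecutive points differing in exactly one coefficient by ± that
coefficient's step `delta`. Two numerical choices:

* **Sign-feasible bases.** Each base coordinate is drawn uniformly from the
  sub-interval where its intended step stays within bounds (the continuous
  analogue of grid-based Morris designs), and a step that would still exit
  is reflected rather than clipped — the step magnitude is always exactly
  `delta`, which the elementary-effect normalization relies on. Plain
  uniform bases break down when `delta` exceeds half the range: an interior
  point can make *both* directions infeasible.
* **Raw effects.** The RSI uses raw output changes ΔYᵢ, with
  step-normalized effects (`dY_norm`) stored alongside. Because every
  coefficient is perturbed by its own fixed `delta`, the pooled
  normalization makes the two conventions differ only by per-coefficient
  constants; raw changes match the "change in model output" reading of the
  index.
* **Pooled maximum.** RSI divides each coefficient's mean |ΔY| by the
  maximum |ΔY| across *all* coefficients for that output. A per-coefficient
  maximum would push every consistently-acting coefficient toward 1 and
  destroy the between-coefficient contrast the index exists to show. An
  all-zero output channel yields RSI 0 for every coefficient, by
  definition.

`replicate_screening()` repeats the screening with independent seeds
(default 20 replicates) and summarises each cell by mean, sd and a
Student-t 95% half-width (reps − 1 df), with CI bounds clipped to [0, 1].
`select_targets()` ranks coefficients by max-over-outputs mean RSI, keeps
the top 8 and always drops coefficients below RSI 0.05 — in the warm
regional climates this removes the cold thresholds `TCLDP`/`TCLDF`
(minimum temperatures of 22–23 °C never reach them), which is exactly the
kind of context dependence the screening is meant to surface: the pipeline
test shows both thresholds re-entering the selection under a cooler
synthetic climate. The default bounds (`default_parameter_space()`) are
package choices drawn from published rice-calibration ranges, with `delta`
a quarter of each range; they are fully user-configurable.

## 4. The genetic algorithm

`run_ga()` is a generational GA with elitism: uniform initialization within
bounds; roulette-wheel parent selection; whole-mating arithmetic crossover
(one λ ~ U(0,1) per mating, applied coordinate-wise, so offspring stay in
the box by convexity); single-gene Gaussian mutation with probability
`Thr_mut = 0.7`, the gene picked proportionally to its sensitivity weight
and the noise sd fixed at 10% of the gene's range, clipped to bounds; the
best-so-far individual re-inserted over the worst offspring. Defaults: 40
generations × 15 individuals. Every evaluation is archived; simulator
failures score 0 rather than aborting.

One implementation decision goes beyond the textbook operator list:
selection weights are *windowed and power-scaled* (`(f − min f)²`,
configurable via `selection_window` / `selection_power`) before the
roulette draw. Raw fitness-proportional selection loses essentially all
pressure once the population plateaus — with fitness values clustered near
their optimum, every individual's relative weight approaches 1/N and the
search degenerates to a random walk; windowing plus a power of 2 is
classical fitness scaling and is what lets the default budget recover a
known 8-D optimum to within 5% of each range (the acceptance suite checks
9/10 seeds against a grid-search oracle). `roulette_select()` itself keeps
the plain proportional contract. A `mut_anneal` option (linearly shrinking
mutation) exists but defaults off: with single-gene mutation, the failure
mode is one coordinate stranded far from its optimum, and late large kicks
are what rescue it.

The fitness is `HI + WUEnorm` with WUE min-max normalized between 2 and
15 kg ha⁻¹ mm⁻¹ and clamped — both axes weighted equally, range [0, 2].
`convergence_generation()` reports the first generation reaching 95% of the
final best fitness.

## 5. Similarity analysis

Distances operate on min-max scaled coefficients over the *combined*
cultivar + ideotype set: raw coefficient scales differ by four orders of
magnitude (hundreds of GDD against hundredths of a gram), so unscaled
distances would rank by `P1` alone. Degenerate rules are explicit: constant
coefficients scale to 0; an all-zero vector has no direction, so its cosine
distance is defined as 1. Before averaging metrics into d̄ᵢⱼ, each metric
is normalized by its own maximum so Manhattan's larger magnitudes do not
dominate. Similarity is `1 − d̄ᵢⱼ/max(d̄)`; if all pairs are identical the
similarity is defined as 1 everywhere. The top-k consensus (default
`k = 4`, matching the "nearest-four" convention for connecting ideotypes to
cultivars) pools the k nearest per metric and counts appearances; ties
break by lower averaged distance, then name — documented so that rankings
are reproducible. `pca_validate()` z-scores, eigendecomposes, truncates to
positive eigenvalues, and reports nearest cultivars in the top-3 PC space
as an independent check; with all components retained, PC-space distances
equal z-scored Euclidean distances exactly (an orthogonal transform), which
the tests exploit as an oracle.

## 6. Synthetic data: what it does and does not emulate

`generate_weather()` draws Gaussian temperatures (sd 1.5 °C, `tmax ≥ tmin`
by resampling), Gaussian radiation and humidity (clipped), and rain from a
two-state wet/dry occurrence chain whose exponential intensities are
modulated by a sinusoidal seasonal envelope — monsoon onset and retreat —
and rescaled so the seasonal total matches the archetype exactly. The
envelope matters: without it the dry archetype delivers uniform rain until
an abrupt stop, no terminal-drought period overlaps grain filling, and the
drought-escape strategy has nothing to escape from. Wet-season spans are
120 days (south) and 75 days (north), from regional climatology; the
northern radiation sd is not reported and mirrors the southern value.
Soil archetypes carry the published hydraulic constants; the four
regional environments cross the two climates with soil retention levels
(`SDUL` 0.30 / 0.28 / 0.29 / 0.23) and area weights 0.30 / 0.18 / 0.21 /
0.20 (their sum, 0.89, is the covered fraction of the cultivation area).
`pedotransfer()` implements the Saxton–Rawls (2006) texture→hydraulics
regressions with tail guards enforcing SLLL < SDUL < SSAT.

What the generators do **not** emulate: spatial structure, interannual
variability, dry-season rainfall, cultivar-coefficient correlations (panels
are uniform within bounds), and any real cultivar's coefficients. A green
test therefore establishes that the *pipeline machinery* behaves as
specified on data with the right first-order statistics — not that its
outputs match any field experiment.

## 7. Numerical conventions

* Water balance closes exactly; the test tolerance of 10⁻⁶ mm absorbs only
  floating-point accumulation.
* `HI < 1` and `yield ≤ biomass` are structural (supply- and cap-limited
  filling), not clipped after the fact.
* All stochastic entry points take explicit seeds and are pure functions of
  (configuration, seed); the pipeline derives per-stage seeds from one
  master seed by fixed offsets, and identical seeds give bit-identical
  results (tested).
* Ties: target selection by declared coefficient order; top-k by averaged
  distance then name; all documented where they occur.

## 8. Known limitations

The surrogate has no nitrogen dynamics, single-layer soil, no pests, no
CO₂ response, and folds all post-initiation development into one thermal
span; its coefficient *responses* are qualitatively right (the paired-run
and monotonicity tests pin them) but its absolute outputs are not
calibrated to any dataset. Grain number here does not respond to `G2`
(sink strength affects yield only through grain mass), which differs from
richer models where grain-weight genetics also shape grain number. The GA
is a single-objective scalarization — no Pareto front — and the similarity
layer inherits whatever biases the cultivar panel carries. These are scope
boundaries, not accidents; each corresponds to an explicit non-goal of the
build.
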