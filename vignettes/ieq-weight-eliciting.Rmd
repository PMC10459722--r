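---
title: "Indirect eliciting of IEQ category weights: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect eliciting of IEQ category weights: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieqelicit)
```

## The problem

Indoor Environmental Quality (IEQ) is assessed by aggregating several
comfort categories — thermal comfort, visual comfort, acoustic comfort and
indoor air quality — into a single score per occupant and time step. The
aggregation weights are usually elicited *directly*: the occupant is asked
to compare categories pairwise (e.g. with AHP on Saaty's 1–9 scale). Direct
eliciting is cognitively demanding and often unreliable: stated judgments
can contradict how the occupant actually experiences the space.

`ieqelicit` implements the *indirect* alternative. Each occupant only rates
the overall comfort of experienced hours on a 1–5 scale. The ratings are
converted into strict preference relations between hours, and the category
weights are estimated as those under which a multi-criteria score of the
hours best reproduces the stated preferences. Two scoring engines are
supported, and classical AHP is included as the direct-eliciting benchmark.

## From sensor streams to an hourly cost panel

1. **Ingestion.** High-frequency streams (default 1 Hz) of air temperature
   (°C), relative humidity (%RH), desk illuminance (lux), pm2.5 (μg/m³) and
   A-weighted sound level (dB) are read from `timestamp,value` CSVs and
   validated against the sensors' measurement ranges. Gaps shorter than five
   minutes are linearly interpolated; longer gaps are an error, since the
   pipeline assumes continuous collection.

2. **Piecewise-linear segmentation** (`segment_series()`). Bottom-up
   merging: start from two-sample segments and repeatedly merge the adjacent
   pair whose merged least-squares fit has the smallest RMSE, stopping when
   any further merge would exceed `max_rmse` (or when `n_segments` remain).
   A final refinement sweep slides every breakpoint to the exact
   SSE-minimising split of its two adjacent segments (computed in O(1) per
   candidate via prefix sums), repeated until stable. The default threshold
   is 2% of the series range: enough to remove sampling noise without
   flattening diurnal trends. The algorithm is deterministic; increasing
   `max_rmse` never increases the segment count, because a larger threshold
   simply lets the same merge sequence continue.

3. **Hourly aggregation** (`hourly_means()`). The working day is a schedule
   of left-closed hours labelled by start hour (default 9:00–18:00 with the
   13:00 lunch hour excluded, i.e. eight time steps). Each hour's value is
   the mean of the *fitted* piecewise approximation at the original sample
   times in that hour — the smoothed signal is the quantity of interest;
   raw-sample means remain available via `use_fitted = FALSE` for
   sensitivity checks.

4. **Derived variables** (`derive_categories()`). Temperature and humidity
   are collapsed into Fanger's PMV, computed per hour and per occupant from
   a profile (clothing insulation in clo, metabolic rate in met) and
   environment defaults (mean radiant temperature 25 °C, air velocity
   0.1 m/s, external work 0). The PMV solver iterates the ISO 7730 clothing
   surface temperature balance to 1e-5 °C (error after 150 iterations) and
   is cross-checked in the test suite against an independent solution of the
   same heat balance by 1-D root finding.

5. **Cost orientation** (`to_cost_panel()`). All criteria are transformed so
   that lower is better: PMV becomes |PMV − 0|, illuminance becomes
   |illuminance − 300 lux| (the task minimum), pm2.5 and sound level pass
   through unchanged. The acceptability bounds (pm2.5 < 40 μg/m³, PMV in
   [−2, 2], noise < 87 dB) are configuration defining the transforms, never
   filters. An orientation flag prevents applying the transform twice.

## Scoring engines

Let $S_{kt}$ be the cost panel ($K$ criteria, $T$ hours) and $w$ a
nonnegative weight vector.

**TOPSIS closeness.** Each criterion is vector-normalised,
$n_{kt} = S_{kt} / \sqrt{\sum_t S_{kt}^2}$; for cost data the ideal
$a_k^+$ is the column minimum and the anti-ideal $a_k^-$ the maximum.
With weighted Euclidean distances $d_t^\pm$ to the two poles, the score is
$r_t = d_t^- / (d_t^+ + d_t^-) \in [0, 1]$, higher = better. $r_t$ is
invariant to the overall scale of $w$. A constant-zero criterion is
normalised to zero with a warning; a time step at zero distance from both
poles scores a neutral 0.5 with a warning — elicitation must tolerate
constant criteria rather than fail on them.

**PROMETHEE net flows.** For each ordered pair and criterion, the
difference in favour of $t$ (for cost data, $S_{kt'} - S_{kt}$) is mapped
through a linear preference function: 0 below zero, $d / D_k$ in between,
saturating at 1, where $D_k$ is the largest positive difference observed
for that criterion in the panel (recomputed per panel, never cached). The
printed form of the middle branch in the source material contradicts its
own boundary cases; the standard $d/D$ form, which satisfies both
boundaries, is used. Weighted preferences $s_{tt'} = \sum_k w_k\,p_{ktt'}$
aggregate into leaving (row-sum) and entering (column-sum) flows, and
$\phi_t = \phi_t^+ - \phi_t^-$. Flows are plain sums over the other
$T - 1$ steps — no $1/(T-1)$ normalisation — and always sum to zero. Net
flows are *linear* in $w$.

## The elicitation objective

Ratings (1–5, 5 = ideal) induce one strict preference per ordered pair of
hours with different ratings; ties contribute nothing. The transitive
reduction keeps the minimal subset whose closure is unchanged — for
rating-derived weak orders, exactly the pairs between adjacent distinct
levels. Reduction never changes which weight vectors achieve zero error.

Weights maximise the log-sigmoid pairwise likelihood
$$\max_{w \ge 0} \sum_{t \succ t'} \ln \frac{1}{1 + e^{-(g_t(w) - g_{t'}(w))}},$$
where $g$ is the chosen engine's score. The objective is always ≤ 0; an
empty relation set returns equal weights with a warning.

**Why the weights are optimised on the cone, not the simplex.** The
programme constrains only $w \ge 0$ and rescales to the simplex afterwards.
For TOPSIS this is equivalent to simplex optimisation (scale invariance).
For PROMETHEE the margins grow linearly with the scale of $w$, so whenever
some direction verifies every relation the likelihood can be driven to its
supremum and the returned weights reproduce the preferences exactly — this
is precisely what makes noiseless parameter recovery exact for the
outranking engine. Restricting to the simplex would instead let the
likelihood trade one small-margin relation for larger margins elsewhere,
so a satisfiable relation set could be violated at the "optimum". When the
PROMETHEE likelihood saturates, the direction is underdetermined; the tie
is broken by the largest worst-case margin (hard-margin rule) over a
candidate set containing the optimised direction, the equal-weight point
and the simplex corners.

**Optimisation.** $w = e^z$ with $z$ unconstrained (capped where the
likelihood is flat anyway), BFGS with relative tolerance 1e-8, from the
equal-weight start plus `restarts − 1` (default 19) random flat-Dirichlet
starts drawn from the mandatory seed. The TOPSIS objective is not concave,
hence the restarts; PROMETHEE's is concave in $w$. Corners and the
equal-weight point are evaluated as candidates, so the returned objective
never falls below the equal-weight objective and exact corner optima are
representable. Results are deterministic given (panel, relations, method,
seed, restarts). The contract is agreement with an exhaustive simplex grid
search (step 0.02) rather than any particular solver; with the free scale
the PROMETHEE objective may legitimately exceed the best simplex-grid
value.

**A structural note on TOPSIS.** Because $r_t \in [0, 1]$, TOPSIS margins
are bounded and there is no scale freedom, so its likelihood optimum can
violate a satisfiable relation even with noise-free ratings. This is a
property of the model, not the optimiser: the test suite verifies that the
elicited likelihood dominates the generating weights' likelihood, and the
nonzero TOPSIS reconstruction error under noiseless simulation is reported
as such by the acceptance script. The outranking engine does not share this
limitation.

## The AHP benchmark

Comparison matrices are read from CSV (fractions as `"1/3"`), validated for
positive entries, unit diagonal and reciprocity ($a_{ij} a_{ji} = 1$ within
1e-6; violations name the cells), with a warning outside the Saaty scale.
Weights are the principal right eigenvector by power iteration (tolerance
1e-12), cross-checked against a dense eigendecomposition in the tests;
$\lambda_{max}$, CI $= (\lambda_{max} - n)/(n - 1)$ and CR $=$ CI/RI are
reported, and CR > 0.1 warns but never rejects — the benchmark uses the
matrices operators actually produced, consistent or not. Geometric-mean
weights are available as a sensitivity flag. The four bundled operator
matrices are transcribed fixtures; their sub-unity entries are printed
without fraction slashes in the source tables and were restored through the
reciprocity constraint, which determines every ambiguous cell uniquely.

## Evaluation

`error_rate()` is the fraction of nonredundant relations not verified by a
score vector; a tie fails to verify a strict preference and counts as a
violation (the source material is silent; the strict reading is adopted).
It is invariant under increasing transforms of the scores.
`compare_methods()` runs the four-method design — AHP weights through
TOPSIS, AHP weights through PROMETHEE, optimised TOPSIS, optimised
PROMETHEE — per operator. `weight_correlations()` compares weight columns
across methods after dropping one category (default the noise weight):
simplex weights sum to one, so keeping all categories builds in a spurious
negative correlation. Pearson is the default coefficient; Spearman is a
flag.

## The synthetic office day

The generator exists because the monitored cohort's raw streams and hourly
ratings are unpublished; it emulates their *structure*, not their values:

* **Streams**: per-variable half-sine diurnal swing + linear drift + AR(1)
  noise at 1 Hz over the schedule span, clipped to the sensor measurement
  ranges. Defaults (e.g. temperature 22 °C baseline with a 2 °C midday
  swing; illuminance drifting from ~590 to ~480 lux; pm2.5 decaying from
  ~9.4 to ~4.6 μg/m³) were chosen once to mirror the published hourly
  panel's character — a warm drift in PMV, declining illuminance and pm2.5,
  roughly stationary noise — and are not calibrated to reproduce it.
* **Occupants**: latent flat-Dirichlet simplex weights; ratings are the
  engine's scores binned into five equal-frequency levels (all levels
  appear when T ≥ 5, maximising the number of relations and tightening
  recovery tests), then perturbed by ±1 level with probability ε.
* **Recovery experiment**: for each replicate, noise level and engine, a
  random cost panel is drawn, ratings generated from latent weights, and
  weights elicited back with the same engine; error rates are recorded for
  the optimised weights, equal weights, and a deliberately mismatched
  vector — all weight on the occupant's *least*-important category,
  emulating a confidently wrong direct statement. Panels here are drawn
  directly (lognormal columns on heterogeneous scales) rather than pushed
  through the full 1 Hz stream pipeline, which is exercised separately;
  this keeps 50-replicate Monte-Carlo runs inside a few CPU-minutes.

What passing these tests shows: the estimators recover preference structure
generated by their own model class under ordinal coarsening and moderate
rating noise. What they do not show: performance on real occupants, whose
ratings need not follow either engine, whose criteria are far more
correlated than independent synthetic columns, and whose single monitored
day yields at most ~11 nonredundant relations per person.

## Numerical choices

* PMV: saturation vapour pressure via the exponential expression of the ISO
  reference computation; convective coefficient the max of natural and
  forced terms; external work 0; values reported to 3 decimals, full
  precision internally; applicability bounds (10–30 °C, 30–70 %RH) warn
  only.
* Degenerate inputs: constant criteria warn and contribute no preference;
  zero-distance TOPSIS steps score 0.5; empty relation sets yield equal
  weights with a flag, not an error.
* Hours are `[h:00, h+1:00)` labelled by start hour; segmentation requires
  at least 4 samples and at least 2 per segment.
* Problem sizes in the default test and acceptance runs: 100 random 5×3
  oracle panels, 20 grid-search problems at T = 6, K = 3 (1,326 grid
  points), 50 recovery replicates per noise level at T = 8, K = 4 with 20
  restarts — the sizes at which the Monte-Carlo properties stabilise while
  a full run stays within a few minutes on one CPU.

## Known limitations

* One building, one day, four-category design: no adaptive comfort, no mean
  radiant temperature estimation, no draught indices.
* PROMETHEE II complete ranking only; only the linear preference function.
* No statistical testing of error-rate differences (by design, the cohorts
  are too small) and no figure rendering; exports are tidy CSVs.
* The published error-rate table for the monitored cohort cannot be
  recomputed exactly because the hourly ratings behind it are only shown
  graphically; the package reproduces the metric and the four-method
  design, not those printed cells.
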