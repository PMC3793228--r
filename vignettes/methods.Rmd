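---
title: "Methods: rate estimation, hotspot comparison and resampling in paramodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate estimation, hotspot comparison and resampling in paramodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paramodiv)
```

This vignette documents the models behind `paramodiv`, the choices we made
where more than one defensible implementation exists, and what the packaged
validation does and does not establish.

## Net diversification rates from (N, T)

The core quantity is the net diversification rate *r* = λ − μ (speciation
minus extinction, per lineage per Myr) of a clade observed only through its
standing diversity *N* and its crown age *T* in Ma. Under a constant-rate
pure-birth model the estimator is the Kendall–Moran form
*r* = [ln *N* − ln *N₀*]/*T*.

Two conventions for the initial diversity *N₀* circulate. For a clade dated
at its **crown** node, two lineages already exist at age *T*, so *N₀* = 2;
*N₀* = 1 is the **stem** convention. The packaged Páramo lineage table
reproduces its published rate columns only under the crown convention
(*Aragoa*: ln(17/2)/0.42 = 5.10, not ln 17/0.42 = 6.75), so `n0 = 2` /
`mode = "crown"` is the default everywhere, with the stem convention
selectable. When prose and numbers disagree about a convention, we follow
the numbers.

`ms_rate()` adds a relative extinction fraction ε = μ/λ ∈ [0, 1) via the
Magallón–Sanderson method of moments: solve for *r* in
E[*N*(T) | survival] = *N*. Conditioning is on the clade being observable at
all — for a stem clade, the founding lineage has extant descendants; for a
crown clade, at least one of the two crown lineages does. Both closed forms
are exercised in the test suite against bisection of the forward moment
equation (agreement to 1e−8 over random (*N*, *T*, ε)); at ε = 0 they
reduce algebraically to the pure-birth forms. Because the published
extinction-corrected tables never state which ε they used, ε is a plain
argument with default 0; {0, 0.5, 0.9} is the conventional reporting grid
for this estimator family.

These estimators assume rates constant in time and across lineages, and
complete sampling of extant diversity. They are method-of-moments point
estimates; the package deliberately fits no likelihood-based diversification
model (see Limitations).

## The rate table and hotspot summaries

`rate_table()` applies the estimator at each available crown-age bound
(minimum / mean / maximum of the dating analysis). Rates are monotone
decreasing in age, so the minimum-age column carries the numerically largest
rate; absent ages (e.g. the Jamesonia+Eriosorus record, which has only a
mean age) propagate as `NA` rather than errors.

The hotspot mean is the arithmetic mean of the *unrounded* mean-age rates —
this is what reproduces both the published Páramo mean (1.36/Myr) and its
per-area rate (38.80 × 10⁻⁶ events/Myr/km², which only matches when the
division uses the unrounded 1.3579, not 1.36). Minimum/maximum-age rates
feed only the upper/lower summary columns. Report output is rounded to two
decimals; internal arithmetic never is.

Uncertainty on each hotspot mean is a **percentile bootstrap**: resample the
lineages with replacement 1000 times and take the 2.5/97.5 percentiles of
the resampled means. With ~5–13 lineages per hotspot the percentile method
is the simplest defensible choice; BCa corrections would suggest precision
the sample sizes cannot support. The bootstrap is seeded, and the values are
sorted before resampling so the result is invariant to input row order.

`validate_hotspot_cells()` recomputes species/km² from each hotspot's own
area and species columns and compares with the published cell, flagging
differences larger than one unit in the last published decimal place. The
one-ulp band absorbs round-versus-truncate ambiguity (the Mediterranean
cell prints 0.010 where the quotient is 0.0108) while still catching cells
that are arithmetically impossible from their own rows — the Cerrado
(printed 0.060, quotient 0.006) and Cape Floristic Region (printed 0.196,
quotient 0.115) cells, which the package flags rather than reproduces.
Published speciation-density cells are judged against the rounding of the
two-decimal mean they would have been divided from.

## Fastest-lineage resampling

The comparison of hotspots by their *fastest* lineages is a two-level
Monte-Carlo procedure on a fixed per-lineage rate table:

1. **One step** (`sample_once()`): draw k = 5 lineages per hotspot without
   replacement, pool the draw (40 lineages for 8 hotspots), rank by rate,
   record which hotspot holds the top lineage and the leading-run length.
2. **One process** (`run_process()`): 1000 such steps; per hotspot, the
   proportion of steps won and the maximum leading run.
3. **Summary** (`summarize_resampling()`): 1000 independent processes;
   means and 2.5/97.5 percentile intervals of both statistics.

Three ambiguities had to be resolved:

* *"Consecutive fastest lineages from the same region"* is implemented as
  the within-step run at the top of the pooled ranking — how many of the
  highest-ranked lineages belong to the winning hotspot before another
  hotspot appears. The alternative reading (runs of wins across successive
  steps) depends on the arbitrary ordering of independent steps, so it is
  reported only as the secondary statistic `max_step_run`.
* *Without replacement* applies within a hotspot within one step; lineages
  return to the pool between steps (anything else would exhaust a 13-lineage
  hotspot long before 1000 steps).
* Ties in rate are broken lexicographically by `lineage_id` — measure-zero
  for real-valued rates, but the procedure must be reproducible. The
  1000 × 1000 scheme reuses one rate table throughout; rates are not
  re-estimated between iterations.

Reproducibility uses one root seed; iteration *i* runs on the substream
seed `(7919 · seed + i) mod (2³¹ − 1)`, so iterations are independent and
order-insensitive.

`exact_fastest_probability()` is the procedure's oracle: every k-subset of
every hotspot is enumerated, only each subset's best global rank matters,
and the joint probability factorises over hotspots. The test suite holds
the Monte-Carlo proportions to within three binomial standard errors of the
exact values (e.g. the two-hotspot configuration whose exact probability is
3/4, checked at 10⁵ steps).

## The simulators and what the tests show

`simulate_yule()` and `simulate_birth_death()` are forward Gillespie-style
simulations: exponential waiting times at rate *n*(λ + μ), uniform choice of
the affected lineage, extinct subtrees pruned and the unifurcations
collapsed so the result is the reconstructed chronogram of extant tips.
Crown start (two lineages at *t* = 0) is the default, matching the
crown-age semantics of the estimators. Conditioning on survival (≥ 2 extant
tips) is by rejection sampling — exact, and cheap at the rates used here.
With a time stop the crown age equals the stop time exactly; with a tip-count
stop the tree is sampled after one further exponential waiting time beyond
the event that created the final tip, so tip branches are positive and the
tip count is exact. Each tree records its speciation times
(`attr(tree, "event_times")`), giving an independent check that node ages
reproduce the simulation's own bookkeeping.

Validation at the defaults used in the test suite:

* Yule tip counts match the two-geometric law (mean 2e^{λt}) over 2000
  replicates within three standard errors.
* The crown pure-birth estimator is **median-consistent**: over 500 trees at
  λ = 0.5, *t* = 8, the median of the per-tree estimates sits within 10% of
  λ (and the moment estimator applied to the mean tip count within 5%).
  Individual-tree estimates scatter much more widely — by the exact
  tip-count law the median per-tree relative error at λt = 4 is ≈12% and
  that is what the suite observes — which is worth remembering when
  interpreting any single clade's rate.
* At ε = 0.5 (λ = 1, μ = 0.5, *t* = 3, 2000 conditioned replicates), the
  ε-matched crown estimator applied to the mean tip count recovers
  *r* = λ − μ within 15%.

These problem sizes (500–2000 replicates, λt ≤ 4) keep the default test run
fast while leaving the statistical checks well-powered; they are stated here
so a reader can scale them up.

`generate_lineage_table()` draws per-hotspot rates from log-normals because
observed within-hotspot rates are positive and strongly right-skewed (0.18
to 5.10 within the Páramo table alone); any positive right-skewed family
would serve. What the synthetic tables do **not** emulate: correlation
between lineages (shared phylogenetic history), uncertainty on each rate
from its crown-age interval, and the heavy discreteness of small real
tables. Passing resampling tests on synthetic tables therefore validates
the procedure's mechanics and its convergence to the enumeration oracle —
not any claim about real hotspot data.

## Chronogram handling and the Pleistocene count

Chronograms are `ape` `phylo` objects read from Newick or NEXUS; branch
lengths are taken to be Myr with no unit detection. Age-based operations
require ultrametricity within a tolerance **relative to the crown age**,
default 1e−5. The default is set above the noise floor of 6-significant-digit
branch-length serialization (which alone produces root-to-tip spreads of
~2e−6 relative on deep trees) and far below any biological signal; pass
`tol = 1e-9` for trees kept at full precision. Sub-tolerance noise is then
zeroed at the tips, so downstream counts see exact zeros. Polytomies are
allowed: every child of a polytomy inherits the polytomy's age as its
divergence age.

`count_pleistocene_tips()` operationalises "species that diverged from
their MRCA during the Pleistocene" as: tips whose **parent-node age** is
below 2.58 Ma, strictly. "Within the last 2.58 Myr" reads as strictly
younger, so ties at the boundary are excluded by default; `rule =
"inclusive"` gives the other convention, and the threshold is a parameter.
This per-tip definition (rather than, say, divergence from the nearest
conspecific after collapsing samples) is the only one that needs nothing
beyond the chronogram itself; it counts both daughters of a young split, as
the published per-lineage tallies do (e.g. 5 of 5 for *Aragoa*, whose whole
crown is younger than the cutoff).

## Degenerate inputs and numerical conventions

* `n = n0` at ε = 0 gives *r* = 0 exactly; `n < n0`, non-positive ages,
  ε ≥ 1 are argument errors naming the offending lineage where applicable.
* A single-lineage hotspot yields a degenerate bootstrap interval
  [*v*, *v*] with a warning rather than an error.
* A hotspot never fastest in a process has `max_run = 0`; per-step
  proportions sum to exactly 1 by construction.
* The Magallón–Sanderson crown discriminant is provably non-negative for
  *n* ≥ 2, ε < 1; it is guarded by an assertion, not an error path.
* Trees are written with 6 significant digits by default
  (`write_chronogram(digits =)` to change); the round-trip preserves crown
  ages and Pleistocene counts at the default tolerance.

## Limitations

* Rates are (N, T) moment estimates: no rate variation through time or
  across lineages, no diversity-dependence, no sampling-fraction
  correction. They are comparable *between* clades only under those shared
  assumptions.
* The hotspot comparison inherits whatever ascertainment produced the
  lineage sample; the package quantifies spread via the bootstrap but
  cannot correct selection toward famously fast radiations.
* Chronogram uncertainty enters only through the min/mean/max age bounds;
  posterior tree distributions are out of scope — the package consumes
  point chronograms, it does not date them.
* The cross-hotspot resampling is only as good as the per-lineage rate
  table supplied; for hotspots where only published means are available,
  the comparison operates on reconstructed or synthetic tables and should
  be labelled as such.
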