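# paramodiv

Comparative diversification analysis of the Páramo biodiversity hotspot —
the high-elevation (~2800–4700 m) tropical Andean grasslands whose flora
radiated explosively over the last few million years. The package asks, and
answers quantitatively, how fast Páramo plant lineages have diversified
relative to lineages from other fast-evolving hotspots (Mediterranean Basin,
Succulent Karoo, Hawaii, Cerrado, Cape Floristic Region, California,
Southwest Australia), and how much of that diversification is Pleistocene.

It is aimed at plant systematists and biogeographers who have clade sizes
and dated crown ages (or chronograms) in hand and want defensible
diversification-rate comparisons without fitting full likelihood models.

## What it computes

**Net diversification rates from standing diversity and crown age.** For a
clade of *N* extant species whose crown node is *T* Myr old, the pure-birth
(Kendall–Moran) estimator is

    r = [ln(N) − ln(N0)] / T

with *N0* = 2 for a crown clade (`pure_birth_rate()`). The
Magallón–Sanderson method-of-moments estimator (`ms_rate()`) generalises
this to a constant-rate birth–death process with relative extinction
fraction ε = μ/λ, by inverting the expected standing diversity conditional
on clade survival; at ε = 0 it reduces exactly to the pure-birth form.

**Hotspot comparison.** `assemble_summary()` joins per-lineage rates with
hotspot areas and species counts into per-hotspot means with 95%
percentile-bootstrap intervals (1000 resamples), species per km², and
speciation events per Myr per km². `validate_hotspot_cells()` recomputes
published per-area cells from their own raw columns and flags the ones that
are internally inconsistent.

**Fastest-lineage resampling.** `summarize_resampling()` implements the
two-level Monte-Carlo procedure — draw k = 5 lineages per hotspot without
replacement, find which hotspot holds the fastest lineage, repeat 1000
times, and repeat that whole process over 1000 independent iterations for
means and CIs of the per-hotspot probability and the leading-run statistic.
`exact_fastest_probability()` computes the same probabilities exactly by
subset enumeration, which is how the Monte-Carlo code is validated.

**Pleistocene divergence counting.** `count_pleistocene_tips()` counts, on
an ultrametric chronogram, the tips whose divergence from their parent node
is younger than 2.58 Ma.

**Simulators.** `simulate_yule()` / `simulate_birth_death()` generate
crown-start chronograms with known rates (used throughout the tests for
parameter-recovery checks), and `generate_lineage_table()` draws synthetic
per-hotspot rate tables with controlled location and spread.

The thirteen transcribed Páramo lineage records and the eight-hotspot
metadata table ship as fixtures: `paramo_lineages()`, `hotspot_metadata()`.

## Worked example

```r
library(paramodiv)

rt <- rate_table(paramo_lineages())
head(rt[, c("lineage_id", "n_species", "crown_age_mean", "rate_mean_age")], 4)
#      lineage_id n_species crown_age_mean rate_mean_age
# 1        Aragoa        17           0.42         5.095
# 2 Arcytophyllum        14          10.96         0.178
# 3      Berberis        32           3.80         0.730
# 4   Calceolaria        65           2.50         1.392

smry <- assemble_summary(rt, hotspot_metadata(), n_boot = 1000, seed = 42)
smry[, c("hotspot", "n_lineages", "mean_rate", "ci_low", "ci_high",
         "species_density", "speciation_density")]
#   hotspot n_lineages mean_rate ci_low ci_high species_density speciation_density
# 1 Paramos         13     1.358 0.6587   2.267         0.09803           3.88e-05
```

*Aragoa* (17 species, crown age 0.42 Ma) diversified at ≈5.1 speciation
events per lineage per Myr — among the fastest plant radiations known. The
13-lineage Páramo mean is 1.36 events/Myr (bootstrap 95% CI roughly
0.66–2.27; the interval is wide because one slow and two very fast lineages
dominate the spread), the hotspot holds ≈0.098 species per km², and its
per-area speciation rate is 38.8 × 10⁻⁶ events per Myr per km².

On a simulated chronogram the Pleistocene tally works the same way as on a
dated tree from BEAST:

```r
tr <- simulate_yule(0.5, stop_time = 6, seed = 7)
ct <- count_pleistocene_tips(tr)           # threshold 2.58 Ma, strict
c(tips = ct$n, pleistocene = ct$k, crown = crown_age(tr))
#        tips pleistocene       crown
#          88          84           6
```

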