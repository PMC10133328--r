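---
title: "Assessing ecosystem-service capacity and flow in managed lagoon units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing ecosystem-service capacity and flow in managed lagoon units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valliES)
```

## The study system and the question

The Venice lagoon is fringed by 31 *valli da pesca*: diked, privately
managed sub-basins historically built for capture-based extensive
aquaculture and waterfowl hunting. Each valle is run under one of five
management strategies, named for the ecosystem service (ES) its manager
maximizes: fish production (**F**), multiple services (**M**), hunting
(**H**), recreational activities (**R**), or no active management
(**N**). Because water exchange, salinity gradients and saltmarsh
maintenance inside a diked basin depend on continuous human work, the
management strategy shapes both the landscape and the services the
ecosystem can deliver.

`valliES` implements a capacity/flow assessment of nine ESs across the
three CICES categories, eight landscape indicators, and the statistical
workflow that compares the five management groups and explores
trade-offs between service categories. *Capacity* is the ecosystem's
potential to deliver a service per unit time and area; *flow* is the
amount actually reaching society. The distinction matters here: a valle
can be highly attractive for tourism (capacity) and still host zero
visitors because access is closed (flow).

The management records and classified imagery behind the real system
are private business data. The package therefore ships a
seed-deterministic synthetic-scenario generator as a first-class,
tested module: it emulates the group-conditioned structure the analysis
assumes, so the full pipeline can be exercised, tested and extended
end to end.

## Indicators

### Landscape indicators

For a four-class land-cover raster (terrestrial land, saltmarsh,
brackish water, freshwater; 25 m pixels by default) the package
computes per unit: water/total, land/total and saltmarsh/total area
ratios (water = brackish + freshwater), freshwater/brackish and
land/saltmarsh ratios, saltmarsh perimeter over saltmarsh area (km per
km²), and the Shannon diversity and evenness of the class proportions.

Numerical conventions, chosen once and logged here:

* Perimeter is raster edge counting: an edge is exposed when its
  neighbour is another class, nodata, or the grid boundary. The
  embankment is a real physical boundary, so it counts. Patch
  connectivity defaults to 4 (edge adjacency), with 8 available.
* Shannon indices use natural logarithms (base configurable); richness
  is the number of classes *present*, and the evenness of a one-class
  landscape is defined as 0 (no heterogeneity to apportion).
* Zero-denominator ratios (e.g. freshwater/brackish with no brackish)
  are flagged `NA` and excluded pairwise downstream — never coerced
  to 0, which would fabricate a signal.

### Ecosystem-service indicators

* **Climate regulation** — carbon sequestration by reed stands,
  accreting vegetated saltmarsh and seagrass meadows, with an
  epiphytic-carbonate increment on the seagrass rate; capacity and
  flow are equivalent (sequestration happens where the habitat is).
* **Water purification** — the percentage of areal nitrogen load
  removed by denitrification in the brackish basins; capacity ≡ flow.
* **Lifecycle support** — a 0–1 map-algebra attractiveness index for
  juvenile fish and migratory waterbirds (saltmarsh, freshwater,
  shrubs, herbaceous vegetation, plus a fish-suitability surface);
  flow is the sum of the min–max normalised mean sown fry biomass and
  mean censused waterbirds (a 0–2 scale).
* **Aquaculture** — capacity is the mean potential fish-biomass
  density over brackish pixels (the potential-density surface is an
  input, produced in the real study by a food-web model); flow is the
  mean yearly fish catch per hectare.
* **Waterfowl hunting** — capacity interpolates census counts by
  inverse-distance weighting (power 2 by default; the interpolator is
  a package choice, exact at census points); flow is the mean yearly
  catch from hunting registers.
* **Wild food** — capacity combines harvestable *Salicornia* biomass
  on NDVI-detected halophyte patches (annual mean NDVI within a
  closed interval, default [0.2, 0.4]) with sea-lavender honey
  (g→kg), per hectare; flow is the recorded harvest.
* **Tourism, cognitive development, birdwatching** — 0–1 weighted
  attractiveness indices over factor layers (saltmarsh presence,
  fauna, water quality, visual proximity of natural land; plus
  accessibility for the cognitive index; paths, nesting areas and
  bird probability for birdwatching); flows are visitor counts.

Attractiveness indices are rescaled so the minimum and maximum *over
the whole unit set* map to 0 and 1; rescaling each unit alone would
erase between-unit contrast, which is the signal the comparison needs.
A constant raw index maps to all zeros for the same reason.

The per-habitat process rates (carbon rates, nitrogen removal,
*Salicornia* biomass, honey yield) and the survey-derived
attractiveness weights are not settled constants; `default_rate_table()`
and `default_attractiveness_weights()` ship documented, overridable
placeholder magnitudes representative of Mediterranean transitional
waters.

## Normalisation and aggregation

Raw indicators live on wildly different scales, so each service's
capacity and flow are min–max normalised **independently** across the
31 units, then summed within each CICES category (three services per
category, so aggregates live on [0, 3]). Independent normalisation is
what allows a unit's normalised flow to exceed its normalised capacity
— the over-exploitation signal the capacity–flow difference (capacity
− flow, sign preserved) is designed to expose. Multi-year flows are
averaged over the available years first (missing years excluded, never
zero-filled), then normalised. A constant indicator vector normalises
to all zeros with a warning.

## Statistical workflow

For every indicator the groups are compared with a routed test:
Shapiro–Wilk on the pooled within-group residuals (the ANOVA normality
assumption concerns residuals, not raw pooled data — configurable) and
Bartlett's homoscedasticity test, both at α = 0.05. Only if both pass
is the parametric branch used (one-way ANOVA + Tukey HSD); otherwise
the Kruskal–Wallis H test (tie-corrected) with Dunn's post-hoc pairwise
z tests from the pooled ranks. Dunn p-values are unadjusted by default
with Holm/Bonferroni/BH available by flag — the adjustment used for the
study system's printed p-values cannot be determined without the data,
and the choice is recorded in the output metadata. Per-group
significance annotations list, for each group, the set of groups it
differs from at α. Trade-offs between categories are summarised by a
6×6 Spearman correlogram (average ranks for ties, pairwise-complete
over flagged-missing units).

The routed workflow is calibrated: under a three-group null the
Kruskal–Wallis rejection rate at α = 0.05 stays within [0.04, 0.06]
over 10,000 simulations (checked in the test suite), and with Gaussian
equal-variance groups the router takes the parametric branch in about
(1 − α)² ≈ 90% of seeds.

## The synthetic-scenario generator

`generate_scenario()` is a pure function of (configuration, seed). Its
defaults *are* the study conditions the package is tested against:

* **Fixture** — the 31 named units in their five groups
  (|F| = 4, |M| = 8, |H| = 9, |R| = 6, |N| = 4). Individual unit areas
  are not public record; the fixture carries configurable placeholder
  areas of realistic magnitude (150–1700 ha).
* **Landscapes** — seeded multi-class region growing inside an
  irregular unit footprint. Class pixel quotas are Dirichlet-sampled
  around group targets (concentration 300, i.e. ±2–3% on the major
  classes); a per-class edge-roughness parameter mixes compact BFS
  growth with Eden-style random growth. Saltmarsh is grown as a
  second-phase exact-quota overlay on the land/brackish/freshwater
  base fill: rough marsh grown jointly with the other classes strands
  enclosed pockets that inflate the marsh share well past its target,
  while the overlay keeps the quota exact with the same boundary
  raggedness. An unlucky seed placement can still strand a base class;
  generation retries within the seeded stream (up to 8 attempts) and
  keeps the composition closest to target.
* **Group conditioning** — F units are water-dominated (water/total
  ≈ 0.8), R units land-heavy (water/total ≈ 0.35), N units have no
  freshwater pools (pumping stops when management stops), and M and H
  grow many small, ragged marsh patches (high edge density) versus few
  compact ones elsewhere. Records enforce structural zeros rather than
  sampling them: F and H host no tourists, excursionists or
  birdwatchers (closed access); N has no exploitation records; R no
  provisioning records. Per-unit latent parameters (potential fish
  density, bird density, census density, denitrification fraction,
  water quality) couple the raster surfaces to the records, so
  capacity and flow are correlated within units the way bookkeeping on
  a real enterprise would make them. Wild-food harvests scale with the
  unit's own saltmarsh draw. Two designated M units carry a
  `flow_exceeds_capacity` flag: their fish-catch mean is set to 1.5×
  their potential density, and the potential itself is drawn reduced
  (0.7×) — managers spreading effort across several services maximize
  provisioning capacity less effectively — which makes their negative
  provisioning capacity–flow difference structural instead of a
  normalisation knife-edge.
* **Water purification** — a single literature removal fraction for
  all units would make the indicator constant (and normalise to
  zeros); the generator draws group-conditioned fractions (≈0.50 for
  F down to ≈0.30 for N), reflecting that managed water exchange
  sustains denitrification.
* **NDVI stack** — a toy two-band (red/NIR) annual stack in which
  *Salicornia* pixels carry mean NDVI inside the detection window and
  other covers sit outside it. This exercises the detection operators,
  not radiative transfer.

What the generator does **not** emulate: real geography and unit
shapes, seasonal and interannual trends, spatial autocorrelation of
records across neighbouring units, measurement error in censuses, or
classification error in land cover. Passing tests therefore show that
the *pipeline* recovers the structure the generator encodes — group
contrasts, the trade-off signs, the over-exploitation signature — not
that it would recover them from noisier real data.

## Problem sizes and determinism

Default runs use 25 m pixels on 31 units (about 2,400–27,000 pixels per
unit), 11 record years (2010–2020), and a three-year NDVI stack. The
replicate-based test suites use 45–60 ha units over 50 seeds, sizes at
which every group-level contrast the generator encodes is already
stable. All randomness flows from one master seed through fixed
per-unit, per-stage substreams, so any unit can be regenerated in
isolation and two runs with the same configuration and seed produce
byte-identical output tables (the only non-reproduced field is nothing:
outputs carry no timestamps, and the metadata header records seed,
config hash and package version).

## Known limitations

* Attractiveness weights and process rates are placeholders; real
  applications must supply surveyed weights and site-specific rates.
* The potential fish-biomass surface is an input; the package does not
  model food webs.
* Cultural flows are absolute visitor counts (not per-hectare), so
  large and small units are compared on totals, as the indicator
  definitions specify.
* The Dunn adjustment default ("none") mirrors the ambiguity of the
  study system's reporting; for confirmatory use, pick an adjustment
  and state it.
* With 31 units in groups of 4–9, the group comparisons have limited
  power; the workflow reports exact p-values rather than enforcing
  decisions.
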