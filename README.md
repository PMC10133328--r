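# valliES

Ecosystem-service (ES) capacity and flow assessment for the *valli da
pesca* — the 31 diked, privately managed sub-basins at the edges of the
Venice lagoon, run under five management strategies (F = fish
production, M = multiple services, H = hunting, R = recreational,
N = not managed).

The package is for landscape ecologists and ES modellers who want a
tested, reproducible implementation of the full workflow:

* a four-class land-cover raster model (terrestrial land, saltmarsh,
  brackish water, freshwater) with patch geometry (areas, connected
  components, edge-count perimeters) and NDVI-based vegetation
  detection;
* the eight landscape indicators per unit — class-area ratios,
  saltmarsh perimeter/area (km km⁻²), Shannon diversity
  H = −Σ pᵢ ln pᵢ and evenness E = H / ln S;
* nine ES capacity/flow indicators across the CICES categories:
  carbon sequestration, nitrogen removal, lifecycle-support
  attractiveness (regulating); aquaculture, waterfowl hunting by IDW
  interpolation of census points, wild food from NDVI-detected
  *Salicornia* patches plus sea-lavender honey (provisioning);
  tourism, cognitive-development and birdwatching attractiveness with
  visitor-count flows (cultural);
* min–max normalisation across units, category aggregation (sums of
  normalised indicators, range [0, 3]) and the capacity−flow
  difference, whose negative values flag over-exploitation;
* the routed group-comparison workflow — Shapiro–Wilk (on residuals)
  and Bartlett checks, then Kruskal–Wallis + Dunn post-hoc or ANOVA +
  Tukey HSD, with significance letters — and a 6×6 Spearman
  correlogram of the category aggregates.

The real management records are private business data, so a
seed-deterministic synthetic-scenario generator (seeded multi-class
region growing for landscapes, group-conditioned truncated-normal
records with structural zeros) stands in for them; it is first-class,
tested code, and `vignettes/valliES-methods.Rmd` documents exactly
which features of real data it does and does not emulate.

## Worked example

```r
library(valliES)

run <- run_pipeline(default_run_config(seed = 1), quiet = TRUE)
aggregate(run$aggregated[, c("provisioning_capacity", "provisioning_flow",
                             "cultural_flow")],
          by = list(group = run$aggregated$group), mean)
```

```
  group provisioning_capacity provisioning_flow cultural_flow
1     F                 1.502              1.19         0.000
2     H                 1.843              1.52         0.000
3     M                 1.928              1.80         0.306
4     N                 0.243              0.00         1.438
5     R                 0.255              0.00         2.845
```

Groups that maximize provisioning services (F, M, H) have the highest
provisioning aggregates and zero (F, H) or limited (M) cultural flow —
closed access converts attractiveness into no visitors — while the
recreational and abandoned units (R, N) show the mirror image. The
correlogram quantifies the trade-off:

```r
round(run$correlogram$rho[1:3, 1:3], 2)
#>                       regulating_capacity regulating_flow provisioning_capacity
#> regulating_capacity                  1.00            0.94                  0.61
#> regulating_flow                      0.94            1.00                  0.68
#> provisioning_capacity                0.61            0.68                  1.00
```

Regulating capacity and flow are almost equivalent by construction
(two of the three regulating services have capacity ≡ flow), and
provisioning capacity correlates positively with regulating capacity:
the interventions that sustain fish and game also sustain the habitats
that regulate. Group statistics come with routing diagnostics and
significance letters:

```r
subset(run$stats$omnibus, indicator == "landscape.water_total")
#>             indicator    routing shapiro_p bartlett_p statistic  value        p
#>  landscape.water_total parametric     0.075      0.629         F  213.7  1.8e-19
#>                      letters
#>  F:HMR H:FR M:FR N:R R:FHMN
```

(the water/total ratio separates R from every other group — R units
are land-dominated).

Two runs with the same configuration and seed produce byte-identical
output tables; `run_pipeline()` writes them (with a metadata header
recording seed, config hash and version) when `out_dir` is set. A thin
CLI wrapper lives at `inst/cli/valles.R`
(`Rscript valles.R run --seed 42 --out runs/s42`).

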