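# riverseason

Spatio-temporal statistics for multi-year, monthly 16S amplicon surveys of
an urban river system that receives treated wastewater. The package is
aimed at microbial ecologists asking three questions of such a design:
whether community turnover is **seasonal** and in which sample types
(river water, sediment, sewage influent, treated effluent); how far
downstream the effluent's compositional influence reaches; and whether a
dated treatment-plant **intervention** changed the downstream community,
the cultured fecal-coliform counts, or the physicochemical environment.

## What it computes

**Seasonality.** For each (site, sample type) stream, every monthly
community is compared by UniFrac distance to a fixed early-spring
*baseline* community of the same stream. Unsampled winter months
(December–February) are filled by linear-spline interpolation, the series
is decomposed by STL (seasonal–trend decomposition by loess) and
detrended (trend removed, seasonal + remainder kept), and a calendar-month
effect is tested with Friedman's two-way analysis of variance by ranks —
treatments the 12 months, blocks the (site, year) windows — with BH
correction across sample types.

**Spatial structure.** Month-matched UniFrac distances between
WRP-adjacent role pairs (effluent, upstream, immediately downstream,
further downstream), with a pre/post permutation test (999 permutations,
statistic |mean(post) − mean(pre)|, BH across pairs).

**Intervention.** A median-based bootstrap (10,000 resamples): the
coliform test contrasts pre/post sample medians against a null that pools
all timepoints; the physicochemical test works on per-timepoint
upstream–downstream differences with a within-timepoint sign-flip null
that absorbs shared seasonality. Effect sizes are plain differences of
medians in the measurement's own units.

**Seasonal log-ratio index.** ASVs are ranked by mean centered-log-ratio
difference between March and August samples; the index
`ln(Σ March-associated / Σ August-associated)` (pseudocount 1 before the
ratio) is tracked across the whole series.

All of it runs against a **synthetic-study generator**
(lognormal–multinomial counts on a random phylogeny, two regions,
exponential downstream mixing of the effluent signal, a ~20× coliform
reduction from 2016-01, measurement series with shared seasonality) whose
`truth` record lets every analysis be scored for recovery.

## Worked example

```r
library(riverseason)

cfg   <- synthetic_config(n_taxa = 40, n_sites = 4, n_years = 4,
                          reads_per_sample = 500, seed = 1)
study <- generate_study(cfg)

seasonality_analysis(study$table, study$tree, study$metadata)
#>   sample_type statistic df n_blocks  p_value p_adjusted
#> 1       water    118.06 11       12 4.44e-20   1.78e-19
#> 2    sediment      4.64 11       12 9.47e-01   9.47e-01
#> 3      sewage      9.41 11        6 5.84e-01   7.79e-01
#> 4    effluent     56.08 11        6 4.92e-08   9.84e-08
```

Water and effluent — the sample types generated with a seasonal amplitude
of 3 log units — are detected at vanishing p-values; sewage and sediment
(amplitude 0) are not. At the full default design the coliform bootstrap
reproduces the downstream decay of the intervention:

```r
cfg   <- synthetic_config(n_taxa = 60, n_sites = 6, n_years = 7,
                          reads_per_sample = 1000, seed = 20)
study <- generate_study(cfg)
coliform_analysis(study$coliform, study$metadata, n_boot = 10000, seed = 8)
#>       site_id         spatial_role abs_effect_size p_value p_adjusted
#> 1 Calumet_S02 immediate_downstream           627.4  0.0010     0.0015
#> 2 Calumet_S03   further_downstream            56.6  0.5426     0.5426
#> 3 Calumet_WRP             effluent          8064.3  0.0003     0.0006
#> 4  OBrien_S02 immediate_downstream          1233.4  0.0001     0.0006
#> 5  OBrien_S03   further_downstream           108.9  0.3334     0.4000
#> 6  OBrien_WRP             effluent         11213.6  0.0003     0.0006
```

Effluent shows an ~8,000–11,000 CFU/100 mL median reduction, the
immediately-downstream river sites a significant but much smaller one, and
sites a few miles further down no detectable change — while every
pre-intervention effluent month exceeded the 400 CFU/100 mL recreational
standard (`frac_above_400_pre = 1`).

The `analysis/` directory holds the numbered end-to-end workflow
(`01_simulate.R` … `06_seasonal_ratio.R`); each script regenerates the
study deterministically and writes its tables under `results/`.

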