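# settdensity

Composite population-density estimation for social, burrow-dwelling
species, built around the European badger (*Meles meles*). Field
ecologists and wildlife-disease managers need badger densities over
large areas, but no single method observes them: burrow systems (setts)
are countable, animals are not. `settdensity` estimates density as a
product of separately surveyable components:

```
D_Ad  = D_C × (p_SSC · ad_SSC  + p_MSC · ad_MSC  + p_MSCR · ad_MSCR)
D_Bad = D_C × (p_SSC · bad_SSC + p_MSC · bad_MSC + p_MSCR · bad_MSCR)
```

where `D_C` is the sett-cluster density per km² from line-transect
distance sampling (corrected by the proportion of suitable habitat),
`p_SSC/p_MSC/p_MSCR` are the proportions of occupied secondary, main,
and reproducing-main sett clusters, `ad_c` the mean number of adults per
cluster of category *c* (camera traps), and `bad_c` the mean total group
size (maximum of camera and genetic counts).

The package provides every stage as a pipeable, data-frame-first
function:

* **Clustering** — `cluster_setts()` groups sett records into clusters by
  single-linkage within a 500 m centroid distance; `classify_clusters()`
  assigns the MSCR > MSC > SSC > UNOCCUPIED occupancy category;
  `occupancy_proportions()` returns exact count fractions.
* **Distance sampling** — `truncate_distances()`, `fit_detection()`
  (uniform / half-normal / hazard-rate keys, cosine / polynomial /
  Hermite adjustments, CDS post-stratification and MCDS covariate
  scales), `select_model()` (AIC), `esw()`, `gof_chi2()`,
  `stratum_density()`, `bootstrap_density()` (transect-level,
  encounter-rate variance), `apply_suitable_fraction()`.
* **Group sizes** — `camera_counts()`, `count_genetic_individuals()`
  (multilocus genotype matching), `cluster_group_size()` (camera/genetic
  maximum), `site_category_means()`, `impute_group_sizes()`
  (same-landscape imputation with flags), `summarize_group_sizes()`.
* **Density** — `composite_density()`, `occupied_main_density()`,
  `estimate_density()`, `summarize_sites()`.
* **Correlates** — `spearman_cor()` (exact small-sample p),
  `bonferroni_adjust()`, `correlation_screen()`.
* **Synthetic sites** — `site_config()` / `generate_site()` simulate a
  full site survey (clustered sett placement in a suitable-habitat mask,
  gridded transects with distance-dependent detection, camera nights and
  genetic captures over a known individual roster) for validation with
  ground truth.

Fitted detection functions support `tidy()`, `glance()` and
`autoplot()`; per-site density tables have an `autoplot()` method.
The summary tables of a 13-site national badger survey in France ship
with the package (`badger_survey_sites()`, `badger_group_sizes()`) as a
complete worked example.

## Worked example

```r
library(settdensity)

sites <- badger_survey_sites()
group_sizes <- impute_group_sizes(badger_group_sizes(),
                                  sites[c("site", "site_habitat")])
dens <- estimate_density(sites, group_sizes)
dplyr::select(dens, site, d_c, d_ad, d_bad, d_occupied_main)
#> # A tibble: 13 × 5
#>    site    d_c  d_ad d_bad d_occupied_main
#>    <chr> <dbl> <dbl> <dbl>           <dbl>
#>  1 A      5.39  3.71  5.85           1.35
#>  2 B      5.5   5.97 13.3            2.63
#>  3 C      3.55  3.75  7.08           1.69
#>  4 D      5.17  7.85 11.3            1.60
#>  5 E      3.17  2.58  4.09           1.76
#>  6 F      4.75  3.79  4.22           1.30
#>  7 G      2.29  1.78  2.42           0.763
#>  8 H      6.42  4.94  6.17           2.22
#>  9 I      2.62  3.49  5.76           1.92
#> 10 J      3.59  1.66  2.56           1.12
#> 11 K      3.79  4.47  5.47           2.12
#> 12 L      1.99  1.89  2.43           1.63
#> 13 M      4.11  4.12  5.39           2.31

summarize_sites(dens)
#> # A tibble: 3 × 8
#>   metric           mean    sd   min min_site   max max_site n_sites
#>   <chr>           <dbl> <dbl> <dbl> <chr>    <dbl> <chr>      <int>
#> 1 d_ad             3.85 1.75  1.66  J         7.85 D             13
#> 2 d_bad            5.85 3.25  2.42  G        13.3  B             13
#> 3 d_occupied_main  1.72 0.520 0.763 G         2.63 B             13
```

Adult densities range from 1.66 (site J) to 7.85 per km² (site D), with
a mean of 3.85 ± 1.75 SD across sites; including cubs the mean is
5.85 ± 3.25. Occupied-main-cluster density — a proxy for the density of
resident family groups — runs from 0.76 to 2.63 per km². Adult density
tracks cluster density closely:

```r
correlation_screen(dens, "d_ad", "d_c")
#> # A tibble: 1 × 8
#>   variable   rho p_value p_adjusted     n method          cutoff significant
#>   <chr>    <dbl>   <dbl>      <dbl> <int> <chr>            <dbl> <lgl>
#> 1 d_c      0.764 0.00238    0.00238    13 t-approximation   0.05 TRUE
```

The methods vignette (`vignettes/composite-density.Rmd`) documents the
models, numerical choices and the synthetic-site generator in detail.

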