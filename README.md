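# wormassays

Quantitative analysis of *C. elegans* behavioral plate assays, for
researchers characterizing neurotransmission mutants. The package covers
the full desk side of five assays:

* **Salt chemotaxis** — predict the NaCl gradient on an assay plate from
  the drop schedule via a point-source diffusion model, simulate
  run-and-tumble worm tracks on it, and compute the assay outcome: each
  worm's mean distance from the salt peak over the final minute, with
  carry-forward imputation of detection gaps.
* **Thrashing** — count midbody bend-direction reversals per minute from
  a bend-angle series, with a hysteresis gate against noise.
* **Roaming** — count the distinct 3 × 3 mm grid squares a worm's track
  traverses, with exact segment-to-cell traversal.
* **Lawn aversion** — per-frame fraction of worms outside the bacterial
  lawn, and its plate-level summary.
* **Co-transmission mapping** — intersectional driver × reporter AND
  logic over per-neuron expression tables, with per-category and
  per-region tallies of co-transmitting neurons.

plus the **normality-gated statistics** used to compare genotypes:
Shapiro–Wilk routing to Student's *t* / one-way ANOVA + Dunnett
(parametric) or exact Mann–Whitney / Kruskal–Wallis + Dunn
(nonparametric).

## The core model

A drop of $N_i$ moles of NaCl applied to the agar $t_i$ seconds ago
contributes, at distance $r$ cm from the peak,

$$c(t_i, r) = \frac{10^6 N_i}{4 \pi d D t_i}\, e^{-r^2/(4 D t_i)} \text{ mM},$$

with $d$ the agar depth (cm) and $D = 1.590 \times 10^{-5}$ cm²/s the
NaCl diffusion coefficient; the plate concentration superposes all drops
on the 50 mM NGM baseline, $C(r) = C_o + \sum_i c(t_i, r)$. Everything
else in the package consumes this model's output or the tabular exports
of the assays (track CSVs, occupancy tables, expression TSVs).

## Worked example

```r
library(wormassays)

# Gradient at the peak and at the plate center (12.5 mm away)
predict_concentration(standard_salt_schedule(), plate_model(),
                      r_cm = c(0, 1.25))
#> [1] 85.38799 57.22996
```

The standard three-drop schedule (4, 4, 1.6 µL of 5 M NaCl at 22, 5 and
2 h before the assay) yields ~85 mM at the peak falling to ~57 mM at the
plate center — the working range of the chemotaxis assay.

```r
# Simulate one assay plate of 8 gradient-climbing worms and score it
field  <- predict_field(standard_salt_schedule(), grid_spacing_mm = 1)
tracks <- simulate_chemotaxis_tracks(field, n_worms = 8,
                                     worms = worm_params(beta = 2),
                                     seed = 1)
plate_summary(tracks)$plate
#> # A tibble: 1 × 4
#>   n_worms n_excluded mean_distance_mm sd_distance_mm
#>     <int>      <int>            <dbl>          <dbl>
#> 1       8          0             7.44           5.16
```

A plate mean around 7 mm is what a strongly chemotactic cohort looks
like; an unbiased cohort (`beta = 0`) settles near 13 mm.

```r
# Which neurons co-express the ACh and Glu vesicular transporters?
labeled_neurons(fig6_coexpression(), "unc-17", "eat-4")
#> [1] "AFDL" "AFDR" "DVA"  "M5"   "PVN"

# Compare genotypes with the routed statistics
set.seed(1)
d <- tibble::tibble(
  genotype = rep(c("wt", "mutA", "mutB"), each = 12),
  thrashes = c(rnorm(12, 95, 10), rnorm(12, 90, 10), rnorm(12, 40, 15)))
fit <- compare_groups(d, thrashes, genotype, control = "wt")
glance(fit)
#> # A tibble: 1 × 6
#>   route         method                       n_groups statistic    p.value stars
#>   <chr>         <chr>                           <int>     <dbl>      <dbl> <chr>
#> 1 nonparametric Kruskal-Wallis + Dunn (Holm)        3      24.4 0.00000512 ****
tidy(fit)
#> # A tibble: 2 × 5
#>   comparison estimate statistic    p.value stars
#>   <chr>         <dbl>     <dbl>      <dbl> <chr>
#> 1 mutA vs wt    -4.33     -1.01 0.314      NS
#> 2 mutB vs wt   -20.2      -4.69 0.00000550 ****
```

The gate detected a non-normal group, routed the comparison to
Kruskal–Wallis, and Dunn's post-hoc flags only `mutB` against wild type.
`autoplot(fit)` draws the jittered-points-with-mean ± SD panel used in
the assay figures.

See the vignette (`vignettes/worm-plate-assays.Rmd`) for the model
assumptions, parameter choices, and numerical details.

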