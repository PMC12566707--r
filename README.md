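# phyloRI

Community-level consequences of an invader expanding through a forest —
who loses, who persists, and whether the losses are mediated by soil
change — analysed from stratified vegetation surveys along an expansion
gradient. The motivating system is Moso bamboo taking over subtropical
evergreen broadleaf forest, surveyed as a space-for-time chronosequence
(bamboo-free → low mixture → high mixture → monoculture; 4 replicate
plots per stage), but the machinery is generic: any design with
plot-level invader cover in [0, 1], per-layer species records, and a
rooted, branch-length-bearing phylogeny that contains the invader.

The package computes, per plot and vegetation layer (tree / shrub /
herb):

* **Importance values** — IV = (relative density + relative dominance +
  relative frequency) / 3, in percent, summing to 100 within a layer;
* **Taxonomic α-diversity** — richness, Margalef `(S−1)/ln N`,
  Shannon–Wiener `H′ = −Σ pᵢ ln pᵢ`, Simpson in the Gini–Simpson
  complement form `1 − Σ nᵢ(nᵢ−1)/(N(N−1))`, Pielou `H′/ln S`;
* **Phylogenetic diversity and structure** — Faith's PD
  (root-inclusive), MPD/MNTD, and their taxa-labels null-model z-scores
  NRI/NTI (positive = clustering, negative = overdispersion);
* **Gradient trends** — Theil–Sen slopes with Mann–Kendall/τ_b tests
  against invader cover, Kruskal–Wallis + Dunn post hoc across stages,
  BH-FDR correction;
* **The Resistance Index**, the package's core statistic: per species,

  RIᵢ = βᵢ / D(i, invader)

  where βᵢ is the Theil–Sen slope of the species' IV against invader
  cover (IV = 0 in plots where it is absent) and D its patristic
  distance to the invader. Raw RI is z-standardized within layer;
  z ≥ +1 is Resistant, z ≤ −1 Susceptible, else Neutral;
* **Drivers** — redundancy analysis (RDA) of (Shannon, PD, NTI) on
  invader cover + soil (pH, TOC, TN, TP) with permutation tests,
  Ezekiel-adjusted R² and VIF screening, and variance partitioning into
  cover-unique / soil-unique / shared / unexplained fractions.

A synthetic-gradient generator (`gradient_config()`,
`generate_gradient()`) emulates the full study design with known ground
truth — species response archetypes, soil trending with cover, and a
phylogeny whose distances to the invader spread ≥ 4-fold per layer — so
every stage of the pipeline is testable end to end without field data.

## Worked example

```r
library(phyloRI)
library(dplyr)

dat <- generate_gradient(gradient_config(seed = 20251021))
iv  <- importance_values(dat$survey)
rs  <- resistance_scores(iv, dat$covariates, dat$tree, "invader")
rs |> filter(klass != "Neutral")
#> # A tibble: 18 × 8
#>    species    layer   beta dist_to_invader  ri_raw  ri_z klass  n_stages_present
#>  1 herb_sp10  herb  -19.0            708.  -0.0268 -2.16 Susce…                4
#>  2 herb_sp15  herb  -17.5            708.  -0.0247 -2.00 Susce…                4
#>  ...
#>  8 herb_sp02  herb    2.67            80.5  0.0331  2.62 Resis…                4
#> 16 tree_sp01  tree   -2.63            80.5 -0.0327 -1.56 Susce…                3
```

Species are scored by how steeply their importance changes along the
gradient, weighted by how close they sit to the invader on the tree:
`herb_sp02` gains only ~2.7 IV points per unit cover, but at patristic
distance 80.5 from the invader that is the strongest
proximity-weighted positive response in its layer (z = 2.62,
Resistant); `tree_sp01` declines mildly in absolute terms but, being
the invader's closest tree relative, classifies Susceptible.

Tree-layer diversity collapses along the gradient, and the decline is
carried by the joint cover–soil axis:

```r
div <- alpha_diversity(dat$survey)
ps  <- phylo_structure(dat$survey, dat$tree, n_rand = 999, seed = 20251021)
tr  <- div |>
  left_join(ps |> select(plot_id, layer, pd, nti), by = c("plot_id", "layer")) |>
  left_join(dat$covariates |> select(plot_id, cover), by = "plot_id") |>
  filter(layer == "tree")

trend_test(tr$cover, tr$shannon)
#>   slope intercept    tau s_statistic    p_value     n
#> 1 -2.25      2.51 -0.868         -99 0.00000732    16

fit <- rda_gradient(tr |> select(shannon, pd, nti),
                    dat$covariates |> select(cover, pH, TOC, TN, TP),
                    n_perm = 999, seed = 1)
fit
#> RDA: R2 = 0.570, adjusted R2 = 0.354, global p = 0.026 (n = 16, 999 permutations)
#> Axis % of constrained variance: 84.1, 15.2, 0.8

variance_partition(tr |> select(shannon, pd, nti),
                   dat$covariates$cover,
                   dat$covariates |> select(pH, TOC, TN, TP))
#>   component    fraction_total fraction_display fraction_explained
#> 1 unique_cover        0.0195           0.0195             0.0550
#> 2 unique_soil         0.00271          0.00271            0.00765
#> 3 shared              0.332            0.332              0.937
#> 4 unexplained         0.646            0.646             NA
```

Shannon diversity falls 2.25 nats per unit cover (τ = −0.87,
p < 10⁻⁵), and the variance the model does explain is almost entirely
*shared* between invader cover and the soil variables (94 % of the
explained fraction) — the generator builds soil as a function of cover,
and the partition recovers exactly that soil-mediated signature.
`run_pipeline(out_dir)` chains all of the above and writes tidy
CSV/JSON outputs plus a manifest with seeds and checksums;
`autoplot()` / `plot_*()` functions draw the IV heatmap, RI bars, RDA
triplot and VPA fractions.

See `vignettes/gradient-methods.Rmd` for the conventions the package
commits to (Simpson complement form, PD root inclusion, the
taxa-labels null model and its degeneracies, tie handling, the RI
stage filter and ddof) and for what the synthetic generator does and
does not emulate.

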