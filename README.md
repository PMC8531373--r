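# CranioNet

Distance-based population-affinity analysis for cranial measurements.

Skeletal biologists summarise fragmentary crania by a battery of
Martin-system linear measurements (mm) and ask which populations a specimen
or series resembles. CranioNet implements that workflow end to end:

* **Data model & I/O** — individual specimens with observed/estimated/missing
  flags (parenthesised values in the CSV dialect), population summary tables
  (per-measurement n / mean / SD), aggregation, and the published regression
  imputation of basion-bregma height, `M17 = 1.05 × ABH + 14.26`.
* **Affinity distances** — population mean profiles are standardized as
  `z_c = (x̄_c − g_c) / s_c` (grand means `g` over the comparative samples,
  reference SDs `s` from a single SD-donor sample), compared by Q-mode
  Pearson correlation `r` across the 13-measurement battery, and turned into
  the distance `1 − r`.
* **NeighborNet** — a full implementation of the agglomerative circular
  ordering (NJ-style two-stage selection, equal-thirds reduction) and
  non-negative least-squares estimation of the `n(n−1)/2` circular split
  weights, with SplitsTree-compatible NEXUS output and PHYLIP distance I/O.
  On additive tree metrics it provably reduces to neighbour joining, which
  the tests assert against `ape::nj`.
* **PCA** — covariance PCA of the standardized means with the Kaiser
  (eigenvalue > 1) and contribution (> 10%) retention rules, a
  positive-loading-sum sign convention so PC1 reads as overall cranial size,
  and projection of held-out (ancient) samples onto modern-fitted axes.
* **Synthetic generator** — two-cluster ("two-layer") panels with
  per-population size factors and realistic within-population SDs, so the
  whole chain is testable at desk scale without any external database.

The 13-measurement battery is `martinBattery()`: M1, M8, M9, M10, M17, M43,
M45, M46, M48, M51, M52, M54, M55.

## Worked example

Seven focal crania ship with the package (five single specimens and the
Huiyaotian/Liyupo summary samples). Here they are standardized against a
synthetic comparative panel and pushed through the network and PCA stages —
with a simulated panel the placement of the real crania is illustrative
only, but every number below is what the code prints:

```r
library(CranioNet)

imputeM17(112)          # the published worked example
#> [1] 131.86            # reported rounded as 132

fx    <- loadFocalCrania()
cfg   <- generatorConfig(seed = 2026)
panel <- generatePanel(cfg)

samples <- c(panel$samples, fx$samples,
             lapply(fx$specimens, function(s)
               aggregateSpecimens(list(s), sampleId = s@site, groupTag = "focal")))
ref      <- buildReference(c(panel$samples, list(panel$reference)), panel$reference)
profiles <- lapply(samples, standardize, ref = ref)

dm <- distanceMatrix(profiles)
dm
#> DistanceMatrix over 23 samples; off-diagonal range [0.029, 1.966]

css <- neighborNet(dm)
css
#> CircularSplitSystem: 23 taxa, 62 splits (23 trivial), RSS 3.38
#>   cycle: L1_p01 L1_p05 L1_p08 L1_p03 L1_p02 Xiaoma Bau Du Liyupo ...
writeNexusSplits(css, "network.nex")   # opens in SplitsTree 4

model <- fitPCA(profiles, fitIds = vapply(panel$samples, sampleId, ""))
model
#> PCAModel on 13 measurements, 13 components; eigenvalues 11.2, 5.07, 0.0833, 0.072 ...
#>   fitted on 16 samples; first 4 contributions (%): 67.5, 30.5, 0.5, 0.4
retainedComponents(model, "eigenvalue")
#> [1] 1 2

scores <- scoreTable(model, profiles)        # focal samples are "projected"
rankByComponent(scores, "PC1", "negative", k = 5)
#> [1] "L1_p02"      "Xiaoma"      "Mai Da Dieu" "L1_p03"      "L2_p05"
```

The `1 − r` distances behave as the method intends: off-diagonal values sit
in `[0, 2]`, the NeighborNet cycle arranges the two planted clusters as
contiguous arcs, only two PCA components carry the planted structure (size
and the cluster contrast), and the small Xiaoma cranium lands among the
most negative PC1 scores — PC1 being the size axis under the
positive-loading convention.

A pipeline front end (`cmdSimulate`, `cmdDistances`, `cmdNetwork`, `cmdPCA`,
`cmdAll`, plus the thin CLI `inst/scripts/cranionet.R`) writes all stages to
CSV/PHYLIP/NEXUS files; see the methods vignette
(`vignettes/cranionet-methods.Rmd`) for the model, parameter defaults and
design decisions.

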