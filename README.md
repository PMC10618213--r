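# phyloendemism

Spatial phylogenetics for gridded species ranges: range-weighted
phylogenetic endemism, CANAPE classification of neo-/paleo-endemism
centres, spatial-error regression of endemism drivers, permutation
comparisons between hotspot classes, and protected-area coverage
accounting — with a synthetic-data generator so the whole pipeline runs
and is testable without any external downloads.

The package is written for macroecologists and conservation
biogeographers who have (i) a rooted, dated phylogeny and (ii)
species-by-grid-cell presence–absence data on an equal-area grid, and who
want to locate and explain concentrations of range-restricted
evolutionary history.

## The metrics

**Phylogenetic endemism** (PE) of grid cell *i* weights every branch of
the phylogeny by the inverse of its geographic range:

    PE(i) = sum over branches b present in i of  L_b / R_b

where `L_b` is the branch length, a branch is "present" where at least
one of its descendant tips occurs, and `R_b` is the number of cells in
which the branch is present. Scaled PE divides by total tree length, so
cell values are proportions of the tree's evolutionary history. Summed
over all cells, unscaled PE returns exactly the total gridded branch
length — a conservation identity the test suite asserts.

**Relative phylogenetic endemism** (RPE) is the ratio of PE on the
original tree to PE on a comparison tree with identical topology whose
branches all carry the same length (total length preserved). RPE > 1
means the cell's endemic branch mass sits on long (old) branches; RPE < 1
means short (young) ones.

**CANAPE** (categorical analysis of neo- and paleo-endemism) judges both
against a tip-shuffling null: species labels are permuted across tips
(999 iterations by default), which preserves per-cell richness and
per-species range size exactly. A cell is an endemism candidate if either
PE is above the 97.5% null quantile; candidates split into *paleo* (RPE
significantly high), *neo* (RPE significantly low), and *mixed*
(neither). Hotspot = any of the three. Downstream, hotspot drivers are
fitted by OLS and by a maximum-likelihood SAR error model
`y = Xb + u, u = lambda W u + e` on k-nearest-neighbour weights, with
Moran's I diagnostics; hotspot classes are compared by Fisher–Pitman
permutation tests; and coverage by protected-area masks and top-17/30/50%
priority rankings is tabulated.

## Worked example

PE by hand on a two-species cherry — `A` confined to one cell, `B` in
two:

```r
library(phyloendemism)
tree  <- read_newick("(A:1,B:1);")
cells <- data.frame(id = c("c1", "c2"), x = 1:2, y = 0)
grid  <- build_grid(data.frame(species = c("A", "B", "B"),
                               cell    = c("c1", "c1", "c2")), cells)
phylogenetic_endemism(tree, grid, scaled = FALSE)
#>  c1  c2
#> 1.5 0.5
```

Cell `c1` holds A's whole branch (1/1) plus half of B's (1/2); summed
over cells the total is 2, the tree length.

The full pipeline on the bundled synthetic world (900-cell lattice, 122
species, planted paleo/neo/mixed refugia):

```r
report <- run_pipeline(pipeline_config(scenario = scenario_spec(), seed = 1))
report$category_percentages[, c("category", "count", "percentage")]
#>           category count percentage
#> 1              neo    14        1.6
#> 2            paleo     7        0.8
#> 3            mixed    31        3.5
#> 4  non_significant   833       94.1
#> 5          hotspot    52        5.9
#> 6      non_hotspot   833       94.1
round(c(lambda = report$driver_summary$sar_lambda,
        nagelkerke_r2 = report$driver_summary$sar_nagelkerke_r2), 3)
#>        lambda nagelkerke_r2
#>         0.883         0.664
```

The three planted refugia surface as the 52 hotspot cells; the SAR error
model absorbs the strong spatial autocorrelation that shared ranges
induce (lambda = 0.88) and beats OLS decisively by AIC. All per-stage
tables (endemism CSV, classification, driver fits, group tests, coverage)
are written when `out_dir` is set.

## Acceptance script

`scripts/acceptance.R` re-runs the complete analysis from scratch —
simulating the default scenario from the given seed, filtering the grid,
computing PE/RPE, running the 999-iteration CANAPE randomization, fitting
the driver models, the permutation comparisons, and the coverage tables —
and writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

- `R/grid_occurrence.R` — presence–absence grid, richness filter, I/O
- `R/endemism.R` — Newick I/O, branch ranges, PE / comparison-tree PE / RPE
- `R/canape.R` — tip-shuffle null, classification, summaries, overlap
- `R/drivers.R` — anomalies, standardization, VIF, OLS, kNN weights,
  SAR-error ML, Moran's I and correlogram, model selection
- `R/group_tests.R` — Fisher–Pitman two-/k-sample tests, max-T post hoc
- `R/protection.R` — protection schemes, priority masks, coverage
- `R/simulate.R` — birth–death trees, spreading-dye ranges, Gaussian
  random-field layers, protection masks, full scenario bundles
- `R/pipeline.R` — configuration and end-to-end orchestration
- `vignettes/spatial-phylogenetic-endemism.Rmd` — models, assumptions,
  calibration, and limitations
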