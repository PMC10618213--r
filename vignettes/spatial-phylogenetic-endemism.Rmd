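---
title: "Spatial phylogenetic endemism: models, null, drivers, and the synthetic world"
author: "phyloendemism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial phylogenetic endemism: models, null, drivers, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the endemism metrics and their null model, the classification rules, the
regression and permutation machinery, the synthetic world used for
testing, and every numerical choice a maintainer might want to audit.

## 1. The endemism model

Phylogenetic endemism (PE) asks how much of a phylogeny's branch length
is *endemic* to a grid cell. Each branch `b` with length `L_b` is present
in every cell occupied by at least one of its descendant tips; its
geographic range `R_b` is the number of such cells. Then

```
PE(i) = sum_{b present in i} L_b / R_b .
```

A branch confined to one cell contributes its full length there; a
cosmopolitan branch is spread thin. Two exact identities follow and are
asserted by the test suite on random instances:

* **conservation** — summed over cells, unscaled PE equals the total
  length of branches with at least one gridded descendant (each branch
  contributes `L_b/R_b` exactly `R_b` times);
* **monotonicity** — adding a presence to a cell can only increase its
  PE.

With `scaled = TRUE` (the default in the pipeline) PE is divided by the
total tree length and reads as the proportion of the tree's evolutionary
history represented in the cell; scaled PE sums to 1 over cells when all
branches are gridded.

**Relative phylogenetic endemism** (RPE) divides PE on the observed tree
by PE on a *comparison tree*: same topology and labels, every branch set
to (total length)/(number of branches). Because the comparison tree
preserves total length, the two PEs share a scale and the ratio isolates
branch-length *shape*: RPE > 1 where endemic branch mass is concentrated
on long (old) branches, RPE < 1 where it sits on short (young) ones. On a
tree whose branches are already equal, RPE is identically 1 — another
tested invariant. The normalization (equal branches summing to the
original total) is the convention of the CANAPE literature; the source
method leaves it implicit.

**Root handling.** The root carries no branch: a root (stem) edge in the
input file is ignored by all metrics, because a root branch would have
every species as a descendant and no defined complement. Zero-length
branches are legal and contribute zero. Polytomies are fully supported —
the synthetic scenario deliberately uses a root polytomy.

**Filter ordering.** Cells with fewer than five species are removed
before any metric is computed (low-richness cells carry unstable
endemism estimates; five is the conventional cut at roughly one-degree
resolution, and the threshold is an argument, not a constant). Branch
ranges are therefore computed on the *post-filter* grid. Computing them
pre-filter is equally possible by calling `endemism_metrics()` before
`filter_min_richness()` — the functions compose rather than hiding the
ordering behind a switch. The strict `>= 5` reading is used; the
threshold is configurable where a different convention is wanted.

## 2. The CANAPE null and classification

The null model shuffles species labels across tips, leaving topology and
branch lengths untouched. Since the occurrence grid is never modified,
per-cell richness and per-species range size are preserved *exactly* —
the null asks only whether the observed arrangement of branch lengths
over space is unusual, not whether richness or rarity are.

For each of 999 iterations (configurable) the three metrics are
recomputed and per-cell exceedance counts accumulated. One-tailed rates
use the permutation convention with the +1 correction:

```
p_high = (1 + #{null >= observed}) / (n_iter + 1)
```

and symmetrically for `p_low`. Ties count against significance, which is
conservative. The per-iteration work reuses one branch-incidence
structure keyed to the topology: a tip shuffle only permutes which
species feeds which tip, so each iteration is a sparse re-aggregation.
The contract that this equals naive recomputation on a relabelled tree
is tested directly.

Classification at two-tailed `alpha = 0.05` (each tail at
`alpha/2 = 0.025`, matching the "beyond the 97.5% of null values"
convention):

1. *gate*: the cell is an endemism candidate if PE on the original tree
   **or** on the comparison tree is significantly high;
2. among candidates: RPE significantly high → **paleo** (rare long
   branches), significantly low → **neo** (rare short branches),
   otherwise **mixed**.

Non-candidates are non-significant; cells dropped by the richness filter
are reported as excluded. The neo rule follows the canonical CANAPE
definition (low RPE), and candidates that pass the gate on a single PE
metric with a non-committal RPE default to mixed; a stricter variant
requiring both PE tails (`strict_both_pe = TRUE`) is available. The
"super-endemism" subcategory of the original CANAPE is not emitted.

**A granularity fact worth knowing.** Under tip shuffling, what a cell's
metrics can see is the *set* of tips carrying its species, so the finest
attainable null tail with `n` tips and a `k`-species cell is
`1/C(n, k)`. With six tips the best case is `1/C(6,3) = 0.05`: no 6-tip
instance can ever yield a significant cell at `alpha = 0.05`. The
exhaustive tests therefore pair a full 720-permutation 6-tip check
(frequencies and the all-non-significant classification) with a 9-tip
instance — enumerated exactly over the 1,260 distinct assignments of
range-equivalent species classes — in which planted paleo and neo cells
are provably significant.

## 3. Driver models

The response is `log10` of scaled PE over analysed cells; zero-PE cells
are excluded rather than offset (a cell that passed the >= 5 species
filter has positive PE, so this only matters for unfiltered input).
Predictors (current climate, past-minus-present anomaly layers,
elevation range) are z-standardized with the `n - 1` denominator so
slopes are comparable; centre/scale parameters are retained for inverse
mapping. Collinearity is screened by variance inflation factors
(`VIF_j = 1/(1 - R2_j)`), with perfectly collinear columns flagged as
infinite rather than raising.

The spatial model is the **SAR error model**
`y = X beta + u`, `u = lambda W u + eps`, fitted by profile maximum
likelihood over `lambda`. The Jacobian `log|I - lambda W|` is computed
exactly from the eigenvalues of `W` (complex pairs enter through their
moduli; the admissible interval comes from the extreme real parts, for
row-standardized weights `(1/e_min, 1)`). This eigenvalue route is exact
and cheap up to a few thousand cells, which is the package's intended
scale; larger problems would need sparse log-determinant updates that
are deliberately out of scope. `W` is k-nearest-neighbour,
row-standardized, with asymmetric neighbour relations permitted and
distance ties broken by stable site order. The neighbour count is scanned
(default over a small set) and the model chosen by AIC, since "a series
of spatial weights were tested" is all the source procedure specifies.

Reported alongside the coefficients (asymptotic normal standard errors
from the whitened GLS information, 95% confidence intervals):
log-likelihood, `AIC`/`BIC` with `p + 2` parameters (beta, lambda,
sigma^2), and the Nagelkerke pseudo-R²
`1 - exp((2/n)(ll_null - ll_model))` against the intercept-only
non-spatial model. Residuals are the *whitened* innovations
`(I - lambda W)(y - X beta)`; those are what Moran's I should find clean
when the model has absorbed the autocorrelation, and the recovery suite
checks exactly that (non-significant Moran's I in >= 90% of SAR-generated
replicates, lambda bias < 0.05, CI coverage within [90%, 99%]).

Moran's I uses the randomization-assumption variance (kurtosis-corrected
permutation moments) by default — the convention of the standard spatial
packages, and cross-checked in the tests against an independent
implementation — with the normality variance and an explicit permutation
p-value as options. `lambda_fixed = 0` reduces the SAR fit to OLS
exactly, a tested identity.

## 4. Group comparisons

Hotspot versus non-hotspot contrasts use the **Fisher–Pitman
permutation test** on raw values: the statistic is one group's sum,
referred to relabellings of the pooled sample. All `C(n, n1)` partitions
are enumerated exactly when there are at most 20,000 of them (covering
every instance up to `C(10,5)` and far beyond); otherwise Monte-Carlo
with the +1 correction. The k-sample version uses the between-group sum
of squares and reduces exactly to the two-sample test at k = 2 under
enumeration. Post-hoc pairwise comparisons are adjusted by single-step
max-T (the full label vector is permuted jointly; each pair's
standardized statistic is referred to the distribution of the maximum
across pairs), with Holm as a deterministic fallback, and summarised by
a compact letter display built on the maximal cliques of the
not-significantly-different graph. Default 10,000 permutations — the
source procedure cites both 10,000 and 100,000 in different places; the
count is a parameter.

**Limitation to keep in mind:** label permutation assumes exchangeability.
On strongly spatially autocorrelated layers the effective sample size of
a compact hotspot block is far below its cell count and the naive test
over-rejects; the test suite demonstrates calibration on weakly
autocorrelated nulls, and results on real, strongly autocorrelated layers
should be read as descriptive contrasts rather than exact tests.

## 5. Protection accounting

A protection scheme is a per-cell binary flag ("any overlap" at cell
resolution; provenance filters such as IUCN categories belong to the
mask's metadata, not to this package). Top-fraction priority masks
protect the best-ranked `ceiling(f * n)` cells of a priority layer, with
boundary ties broken by stable cell order and reported; masks from one
ranking are nested (top 17% within top 30% within top 50%), making
per-class coverage monotone along the sequence — both tested. Coverage
tables partition shared analysed cells into A-only / B-only / joint
hotspots and non-hotspots; empty classes are reported as undefined
(`NA`), never as 0%. Reported percentages round half away from zero to
one decimal (so 10.25% prints as 10.3%), with raw fractions kept
alongside; this matches how such tables are conventionally printed and is
asserted against worked examples.

## 6. The synthetic world

`scenario_spec()` states a complete world; `simulate_scenario()` renders
it deterministically from one master seed (stage seeds are drawn from
it, and byte-reproducibility is tested).

* **Phylogeny.** Background species form a birth–death clade (forward
  simulation stopping when the target tip count is reached; under pure
  birth the crown depth has the closed-form mean `(H(n) - 1)/birth`,
  which the tests check). Planted paleo endemics are pendant branches of
  the full tree depth attached at the root — maximally isolated old
  lineages. Neo endemics belong to a recent radiation (depth 0.05 of
  tree depth) on a long stem; two radiation members remain widespread so
  the stem's geographic range is wide. This last point is a real
  subtlety, found the hard way during calibration: if *all* radiation
  members are confined to the block, the stem itself becomes a
  range-restricted long branch and drags RPE up, so the block reads as
  mixed rather than neo. Mixed-block endemics are half long-pendant,
  half short-radiation species.
* **Ranges.** Spreading-dye growth (random rook-adjacent accretion from
  a seed cell) guarantees each range is one connected patch. Background
  range sizes are lognormal (`meanlog = log(0.1 * n_cells)`, `sdlog = 1`
  — heavy-tailed, verified by a KS test), with clade-clustered seed
  cells so related species co-occur regionally. Planted endemics are
  confined to their refugium block with 1–4 cells each.
* **Environment.** Each layer is white noise smoothed by a Gaussian
  kernel with sd = (correlation length)/2, so the field's correlation
  decays to 1/e at the stated length (verified empirically within 25%);
  unit variance by construction. Hotspot cells receive per-layer mean
  offsets in sd units — the defaults make hotspots climatically more
  stable (smaller absolute anomalies), topographically rougher, slightly
  warmer/wetter, more human-modified, and more exposed to future change,
  i.e. the qualitative contrasts the pipeline is meant to detect, at
  0.4–1 sd so a permutation test at ~100 cells per group has power
  above 0.9.
* **Protection.** The existing-protected-area mask covers an exact 10%
  of cells at random; the priority ranking scores standardized richness
  plus a refugium bonus plus noise, so priority masks cover planted
  diversity better than random ones (tested as an average over seeds).

**Scale.** The default world is a 30 × 30 lattice (900 cells) with 122
species. That size keeps a full 999-iteration CANAPE run at a few
seconds and the complete pipeline around twenty, so the ten-seed
end-to-end recovery experiment fits comfortably in a test run; effect
sizes are calibrated at this scale (planted categories recovered in at
least 90% of seeds, validated on a held-out seed batch).

**What a green test does *not* establish.** The generator emulates
statistical structure, not geography: cells are abstract equal-area
squares, ranges ignore climate, there is no niche evolution or
diversification–environment feedback, layers are stationary Gaussian
fields, and the protection mask is spatially random. Green tests say the
*machinery* is correct and the *procedure* can recover planted signals of
stated effect sizes — not that any real-world inference is automatic.

## 7. Numerical choices, in one place

* Standard deviations use the `n - 1` denominator throughout.
* Permutation p-values carry the +1 correction; ties count against
  significance (tie tolerance 1e-12 on metric comparisons, relative
  1e-9 on permutation statistics).
* Reported percentages round half away from zero to one decimal; raw
  fractions are never discarded.
* The SAR profile likelihood is maximized by golden-section/Brent search
  on the admissible interval shrunk by 1e-6 at each end; degenerate
  intervals and non-finite profiles raise with the offending lambda.
* RPE is `NA` (undefined), not 0 or Inf, where comparison PE is zero —
  only possible for cells with no species, which the filter removes.
* Duplicate occurrence records collapse to one presence; unknown cell
  ids are errors, not silent drops. Tree/grid species mismatches are
  intersected away with a warning, mirroring standard megatree pruning.
* All randomness flows through explicit seeds; functions given a seed
  restore the caller's RNG state.

## 8. Known limitations

* The eigenvalue log-determinant bounds practical SAR fits at a few
  thousand cells.
* SAR confidence intervals condition on the estimated lambda; coverage
  is asymptotic (empirically within [90%, 99%] at n = 500).
* The Fisher–Pitman test over-rejects under strong spatial
  autocorrelation (Section 4).
* CANAPE significance is bounded by permutation granularity for very
  small trees (Section 2).
* The comparison-tree normalization and the mixed-category edge rule
  follow the dominant convention where the source text is ambiguous;
  both are flagged as explicit arguments (`scaled`, `strict_both_pe`).
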