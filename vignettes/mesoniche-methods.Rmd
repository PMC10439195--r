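---
title: "Methods: eco-region structure and co-occurrence networks of mesopelagic plankton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eco-region structure and co-occurrence networks of mesopelagic plankton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoniche)
```

## The scientific problem

The mesopelagic zone (roughly 200–1000 m) hosts plankton communities whose
structure is far less understood than that of the sunlit epipelagic layer.
Two mesopelagic habitats are of particular interest: ordinarily oxygenated
("oxic") waters, and oxygen minimum zones (OMZs) where oxygen falls below
10 µmol/kg (suboxic) or even below 0.003 µmol/kg (anoxic, the detection
limit of the most sensitive sensors). `mesoniche` implements a complete,
testable pipeline for comparing these habitats from multi-kingdom OTU count
tables (phages, nucleo-cytoplasmic large DNA viruses, prokaryotes,
pico-eukaryotes) with station/layer/oxygen metadata:

1. **Data model and filters** (`otu_table()`, `label_sample_ecoregions()`,
   `merge_epipelagic()`, `filter_otus()`),
2. **Compositional transforms and dissimilarities** (`robust_clr()`,
   `bray_curtis()`, `aitchison_distance()`, `env_distance()`),
3. **Permutation multivariate statistics** (`nmds()`, `dispersion_test()`,
   `permanova()`, `constrained_ordination()`, `vif_scores()`,
   `marginal_terms_test()`),
4. **An OTU eco-region classifier** (`classify_otus()` built on
   `kruskal_wallis()`, `dunn_test()`, `bh_adjust()`),
5. **Signed co-occurrence networks** (`infer_network()`, `cnm_modules()`,
   `module_enrichment()`, `topology_report()`),
6. **A synthetic community generator** (`synthetic_design()`,
   `generate_community()`, `make_fixture()`) that plants known eco-region
   signatures and co-occurrence modules, so that every downstream stage has
   a ground-truth recovery test.

## Sample eco-regions and epipelagic merging

Samples are labelled from metadata alone: surface (SRF) and deep
chlorophyll maximum (DCM) samples are epipelagic (EPI); mesopelagic (MES)
samples are OMZ when the oxygen concentration measured at the sampled
depth is below `suboxic_threshold` (default 10 µmol/kg) and oxic
mesopelagic otherwise. An `anoxic` flag marks samples below
`anoxic_threshold` (default 0.003 µmol/kg). We deliberately apply the
numeric threshold strictly: a 0.83 µmol/kg sample — functionally anoxic in
the sense that aerobic metabolism cannot be sustained — is still recorded
as suboxic, because the anoxic flag encodes the measurement convention,
not a metabolic interpretation. Each MES sample is labelled independently
at its own measured oxygen value.

SRF and DCM columns are merged into a single epipelagic column per station
by summing read counts taxon-by-taxon; taxa observed in only one of the
two layers keep their counts, mesopelagic columns are untouched, and total
reads per station are conserved (a tested invariant). The merged column id
is `"<station>_EPI"` and the source sample ids are kept in a
`merged_from` metadata column.

Before network analysis, taxa are discarded only when **both** rare
(dataset-wide relative abundance below `1e-4`) and sparse (observed in
fewer than 5 samples). The conjunction matters: an OR rule would delete
abundant-but-localised taxa — exactly the OMZ specialists the analysis is
after. Relative abundance is computed dataset-wide (taxon total over grand
total); both thresholds are arguments.

## Robust CLR and dissimilarities

Counts are compositional: only relative information survives sequencing.
The robust centered log-ratio transform adds a pseudo-count of 1 and, per
sample, divides by the geometric mean computed **over observed taxa
only** (original count > 0):

$$\mathrm{rclr}(x_{ij}) = \ln\frac{x_{ij} + 1}{g_j}, \qquad
g_j = \exp\Big(\tfrac{1}{|O_j|}\sum_{i \in O_j} \ln(x_{ij}+1)\Big),$$

with $O_j$ the observed taxa of sample $j$. Restricting the geometric mean
avoids the downward bias that zero-heavy samples impose on the plain CLR.
Unobserved entries are encoded as 0 **with a boolean mask** rather than as
missing values, so dense linear algebra works downstream while mask-aware
statistics remain possible; per sample, the masked mean of the transform
is 0 to within 1e-9 (a tested invariant). Because "values greater than 0"
could also be read as "after the pseudo-count" (in which case nothing is
masked), `mask_zeros = FALSE` switches to a plain CLR of $x + 1$.

Bray–Curtis dissimilarity is undefined for negative values, so the
pipeline computes it on relative abundances and offers the Aitchison
distance (Euclidean on CLR vectors) as the CLR-space dissimilarity;
`bray_curtis()` on a CLR matrix fails loudly with a pointer to
`aitchison_distance()` rather than silently min-shifting. Environmental
distances are Euclidean on z-scored variables so each contributes on unit
scale.

## Permutation statistics

**PERMANOVA** partitions the total sum of squared dissimilarities,
$SS_T = \sum_{j<k} d_{jk}^2/n$ and
$SS_W = \sum_g \sum_{j<k \in g} d_{jk}^2/n_g$, into among- and
within-group parts, and refers pseudo-$F$ to the distribution obtained by
permuting group labels. The partition identity $SS_A + SS_W = SS_T$ is
asserted on every input. P-values use the $(1 + \#\{F^* \ge F\})/(1+B)$
estimator so that $p = 0$ is impossible; an `exact = TRUE` mode
enumerates all distinct label arrangements for small designs. When groups
separate perfectly ($SS_W = 0$) the pseudo-$F$ is reported as `Inf`
rather than a large arbitrary number. The implementation is checked
against `vegan::adonis2` in the test suite.

**Dispersion homogeneity** embeds the dissimilarity matrix via the
Gower-centered inner-product matrix and measures each sample's distance
to its group centroid,
$d^2(j, c_S) = G_{jj} - \tfrac{2}{|S|}\sum_{k\in S} G_{jk} +
\tfrac{1}{|S|^2}\sum_{k,l\in S} G_{kl}$,
which handles negative principal-coordinate eigenvalues by construction
(the "imaginary axis" contributions enter with a negative sign; residual
negative squared distances are clipped to zero). Centroids — not spatial
medians — are used. The permutation test **re-derives centroids and
distances under every relabelling**: permuting labels over the fixed
observed distances (which were computed against the original centroids)
is measurably liberal under the null, whereas the re-fit version is exact
under exchangeability; both facts are verified by simulation in the test
suite, and the observed distances coincide with
`vegan::betadisper(type = "centroid")`.

**NMDS** (best-of-restarts Kruskal stress-1, via `vegan::metaMDS` on the
supplied dissimilarities, no internal transformation) and **constrained
ordination** complete the multivariate toolbox. The default constrained
method is redundancy analysis (RDA) on CLR values: canonical
correspondence analysis requires non-negative input, so applying it to a
CLR matrix is not well defined. A `literal = TRUE` escape hatch min-shifts
the CLR matrix so the CCA route can still be exercised for comparison.
Constraints are z-scored; collinearity is screened with variance inflation
factors $1/(1-R^2_v)$ (exactly collinear variables report `Inf`), the
global test permutes sample rows of the response, and
`marginal_terms_test()` tests each variable with all others as
conditioning covariables (`by = "margin"`), making the per-variable
p-values order-independent. Marginal p-values of VIF-infinite variables
are reported as `NA` with a warning — a marginal effect of a duplicated
variable is not identifiable.

## The eco-region classifier

Per taxon, CLR abundances are compared across the three sample
eco-regions with a tie-corrected Kruskal–Wallis test (implemented from
the rank-sum formula and checked against `stats::kruskal.test` and a
permutation oracle), followed by Benjamini–Hochberg adjustment **across
taxa**. Non-significant taxa are `UBIQUITOUS`. Significant taxa proceed
to Dunn's pairwise z tests on the pooled ranks. "Election" is
operationalised as: the region with the highest mean rank, accepted only
when it differs significantly from **both** alternatives — the only
reading that yields a unique region per OTU. Taxa whose two mesopelagic
regions are mutually indistinguishable but each elevated above EPI are
`CORE_MES`. Any other significant-but-unresolvable pattern (for example
EPI highest but the mesopelagic pair unresolved against it) falls back to
`UBIQUITOUS` with a `non_resolvable` flag, avoiding silent
mis-assignment. Dunn p-values are two-sided and BH-adjusted within taxon
across the three pairs before the `alpha` comparison; both choices are
arguments (`adjust_dunn`), since reasonable analysts differ here.

Under a global null (no planted effects) the fraction of non-ubiquitous
calls stays below `alpha` plus simulation noise — the BH step across taxa
controls the false discovery rate, and the Dunn gate only tightens it.
This is verified on 200 simulated null communities.

## Co-occurrence network inference

CLR-transformed abundances are treated as approximately multivariate
Gaussian, and a signed conditional-independence network is learned
constraint-style: marginal Pearson screening with the Fisher z statistic
$\mathrm{atanh}(r)\sqrt{n - |S| - 3}$ at level `alpha`, then, level by
level, partial correlations given conditioning sets drawn from the two
endpoints' current neighbourhoods (candidates ordered by absolute
marginal correlation, then index, so inference is deterministic), up to
`max_k` variables. Removals are applied between levels (PC-stable style),
which makes the edge set invariant to taxa ordering. In *heterogeneous*
mode, one-hot indicators of per-sample covariates (here: the sample
eco-region) are permanently available as conditioning candidates, so
edges that merely reflect a shared habitat response are stripped out; the
indicators are not nodes. Edge weight is the partial correlation given
the largest conditioning set the edge survived (first subset in
deterministic order at that level); its sign is the edge sign. This is a
deliberately transparent simplification of adaptive local-to-global
learners such as FlashWeave: no adaptive CLR variants, no test switching,
no bootstrap confidence — the test suite characterises exactly what it
does (chain separation, habitat-driven edge removal, null false-discovery
budget).

**Module detection** is greedy agglomerative modularity maximisation
(Clauset–Newman–Moore): all nodes start as singletons and the connected
pair of modules with the largest gain $\Delta Q = e_{ij} - 2a_ia_j$ is
merged until no merge increases $Q$, ties broken by the smallest module-id
pair. Modularity is computed on the **unsigned** simple graph — the
greedy algorithm is sign-agnostic — while signed edge counts are reported
per module. The implementation is verified against exhaustive search over
all partitions of every ≤ 8-node fixture and against
`igraph::cluster_fast_greedy` on random graphs. Module × eco-region
enrichment uses one-sided (enrichment-direction) Fisher exact tests,
BH-adjusted across **all** tested (module, class) pairs. Topology
reports include average degree $2E/N$, mean local clustering (degree < 2
contributes 0), density, average shortest path over connected pairs only
(inferred graphs are disconnected), Freeman degree and betweenness
centralizations, and per-module modularity of the module-induced
subgraph.

## The synthetic generator: what it emulates, and what it does not

`generate_community()` draws, for taxon $t$ in sample $s$ of eco-region
$r$:

$$\lambda_{ts} = \beta_t
 + \mathit{effect} \cdot \ln 2 \cdot \mathbf{1}[t \text{ signature of } r]
 + \mathit{strength} \cdot f_{m(t),s} + \varepsilon_{ts},$$

with taxon baselines $\beta_t \sim N(0,1)$, noise
$\varepsilon \sim N(0, \sigma)$, and one standard-normal factor
$f_{m s}$ per planted module $m$ shared by its taxa within a sample
(CORE_MES signatures fire in both mesopelagic regions). Counts are drawn
**multinomially** with `depth_reads` trials from the softmax of the
column: compositional artefacts — the very thing the rCLR addresses — are
genuinely present, and zeros arise from finite sequencing depth rather
than by fiat (a `structural_zero_rate` knob exists for stress tests).
Oxygen is drawn from two regimes (OMZ: Uniform(0.5, 9) µmol/kg; oxic MES:
Uniform(40, 250)), matching the suboxic cut-off; nitrate is elevated at
depth, chlorophyll-a near-zero at depth, and particle flux is correlated
with a designated taxa subset.

Default study conditions, chosen once: 25 stations of which 13 overlay an
OMZ (the survey the package emulates sampled 13 OMZ stations), one merged
epipelagic plus one mesopelagic sample per station, library size
$2\times10^4$, signature effect $\log_2\mathrm{FC} = 2$, and latent noise
$\sigma = 0.5$ — moderate biological variability (about ±65% fold
variation around the taxon mean) under which a $\log_2$FC-2 signature is
recoverable at 8 samples per region, which is the regime the classifier
is designed for. The generator does **not** attempt realistic global
biogeography, phylogenetic correlation, taxon-specific dispersion, or
basin structure in the counts; passing recovery tests therefore show the
procedures are correct and well-calibrated under their own assumptions,
not that real mesopelagic data satisfy those assumptions.

### Calibration of the module-recovery benchmark

The module benchmark (3 planted modules × 30 taxa, factor strength 3,
50 samples) runs inference at `alpha = 0.05`, `max_k = 1`, inside a
background community of 300 taxa. Both choices follow from a small power
analysis rather than taste. First, in a single-factor module the exact
partial correlation between two members given $k$ co-members is
$\rho/(1+k\rho) \le 1/(1+k)$; the Fisher z test at $n = 50$ cannot
distinguish $1/(1+k)$ from zero for $k \ge 2$
($\mathrm{atanh}(1/3)\sqrt{44} \approx 2.3$, below even the 1% critical
value), so deep conditioning provably erases factor-built modules —
shallow conditioning is a requirement of the design, not a tuning trick.
Second, CLR closure couples the planted factors through the per-sample
geometric mean: with 90 of 120 taxa in modules, cross-module correlations
reach $|r| \approx 0.4$ and bridge the modules, while at 90 of 300 they
fall below the detection threshold. The default `max_k = 3` remains the
right setting for exploratory use on real tables, where associations are
not pure single-factor.

## Numerical conventions

- Permutation p-values use $(1+B_{\ge})/(1+B)$ everywhere; all
  permutation routines take an explicit integer seed and permute sample
  labels/rows only.
- Degenerate inputs are handled explicitly: all-tied Kruskal–Wallis input
  gives $H = 0, p = 1$; zero rank variance gives Dunn $z = 0, p = 1$;
  an all-identical dissimilarity matrix makes `dispersion_test()` report
  a `degenerate` flag with $p = 1$; perfect group separation reports
  pseudo-$F = \infty$.
- Greedy merges break exact ties on the smallest (module id, module id)
  pair; conditioning-set search order is fixed by descending absolute
  marginal correlation with index tie-break.
- Simulation scale in the shipped tests (200 null replicates for the
  classifier, 500 × 199-permutation null replicates for PERMANOVA and
  dispersion, 20 seeds for module recovery, 10 for signature recovery)
  balances Monte-Carlo error of about ±0.01 on rejection rates against
  run time; all sizes are arguments, so heavier runs are one edit away.

## Known limitations

- The network learner is a transparent PC-style approximation, not a
  reimplementation of adaptive heuristics; on data with strongly
  non-Gaussian CLR margins its tests are approximate.
- CCA on transformed (negative) data is only available through the
  explicit min-shift escape hatch, which changes the chi-square geometry
  and should be used for comparison, not inference.
- The classifier assigns exactly one call per taxon; taxa genuinely
  bimodal across basins within an eco-region are out of scope (no
  per-basin stratification).
- Average path length is computed over connected pairs, which rewards
  fragmentation; a largest-component mode would behave differently on
  very sparse graphs.
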