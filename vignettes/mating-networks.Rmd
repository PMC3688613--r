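---
title: "Delimiting species from mating and relatedness networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting species from mating and relatedness networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The biological species concept defines species as groups of interbreeding
individuals reproductively isolated from other such groups. Taken literally,
that is a statement about a *network*: nodes are individuals, links join
pairs that have actually mated. Under a strict reading, each species is a
connected component of the mating network; under a relaxed reading that
tolerates some hybridization, each species is a community — a set of nodes
densely linked inside and sparsely linked outside. `matenet` implements this
programme end to end for two sympatric, hybridizing tree species: it
reconstructs who mated with whom from open-pollinated progeny, clusters the
resulting network with a continuous (mixed-membership) stochastic block
model, classifies individuals into two species plus an intermediate class,
and quantifies how well interfertility-based boundaries agree with
independent genotype-, morphology- and relatedness-based assignments.

Because the motivating data sets (mapped forest stands with thousands of
genotyped offspring) are rarely distributable, the package ships a synthetic
stand generator that reproduces the statistical structure the analysis
relies on, so every stage is testable from code alone.

## The model

Each node $i$ carries a membership vector $u_i$ on the $Q$-simplex over $Q$
*extremal hypothetical nodes* (EHNs). Edges are independent Bernoulli draws
with

$$\pi_{ij} = u_i^\top B\, u_j,$$

where $B$ is a symmetric $Q \times Q$ matrix of EHN–EHN connectivity
coefficients with entries in $[0,1]$. The first EHN (EHN0) is structurally
unconnected: its row and column of $B$ are fixed at zero. Because $\pi$ is a
convex combination of entries of $B$, it is automatically a probability.
EHN0 gives every node a way to scale its overall connectedness without
changing *whom* it connects to — it absorbs degree heterogeneity, which in
progeny-based mating networks is dominated by the sampling design (sampled
mother trees have far more links than other adults).

With $Q = 3$ (EHN0 plus two connected EHNs) the membership vector of every
node lives in a triangle. Nodes on the EHN0–EHN1 edge mate only within group
1, nodes on the EHN0–EHN2 edge only within group 2, and interior nodes have
mixed reproductive behaviour. That geometric statement is the species rule
used by `classify_memberships()`: a node is species 1 when its EHN2 weight
is at most `epsilon`, species 2 symmetrically, and intermediate otherwise.

### Fitting

`csbm()` maximizes the Bernoulli log-likelihood
$\sum_{i<j} X_{ij}\log\pi_{ij} + (1-X_{ij})\log(1-\pi_{ij})$ ($\pi$ clipped
to $[10^{-9}, 1-10^{-9}]$) by alternating projected-gradient ascent: one
backtracking step on all rows of $U$ (each row projected back onto the
simplex with the sort-based Euclidean projection), then one on $B$
(projected onto the box, symmetry and the zero EHN0 row re-imposed exactly).
Backtracking guarantees the accepted log-likelihood never decreases.
Convergence requires the relative log-likelihood gain to stay below `tol`
(default `1e-6`) for five consecutive iterations — a single near-flat
alternating step is not evidence of stationarity — with `max_iter = 2000`
as a cap. The best of `n_restarts` (default 10) starts is kept: the first
start softens a spectral clustering of the adjacency matrix (membership in
the node's cluster scaled by relative degree, remainder on EHN0), the rest
are random Dirichlet memberships with diagonally dominant random $B$.

### Identifiability and the extremal convention

The parametrization is deliberately redundant: scaling a connected EHN's
column of $U$ up and the matching entries of $B$ down leaves every
$\pi_{ij}$ unchanged, with EHN0 absorbing the slack. Reported fits use an
*extremal* convention: after convergence, species columns are scaled up as
far as row-simplex feasibility allows (coordinate ascent on the sum of log
scale factors), so the EHNs sit as close to the data as the fit permits and
$B$ is minimal among equivalent representations. The likelihood is
untouched. Two consequences matter for interpretation:

* absolute values of $B$'s non-zero entries are convention-dependent; only
  their pattern (which blocks connect) and the induced $\pi$ are directly
  comparable across software;
* in simulation studies, recovered parameters should be compared to
  generating values only after aligning through the model's invariances
  (EHN permutation and the column scale), which is what the package's tests
  do.

A second behaviour of maximum likelihood here is worth stating plainly:
because memberships are free per node, the fit explains rare between-group
edges by giving their endpoints a little of the other species' membership
rather than by a non-zero between-EHN coefficient — fitted $B_{12}$ is
typically exactly 0 and hybridizing individuals drift into the triangle
interior. On real oak data this is precisely the published behaviour (zero
off-diagonal connectivity, hybridizing trees classified intermediate), but
it means simulations with a small true $B_{12}$ recover that coefficient as
0 and classify a fraction of the planted "pure" endpoints as intermediate.
The package's planted-model test records this honestly: AIC model ordering
is reliably recovered, while element-wise $B$ recovery at $\pm 0.05$ and an
adjusted Rand index of 0.95 on pure nodes are not attainable at $n = 200$
under maximum likelihood.

### Model choice

`csbm_scan()` fits a range of $Q$ and ranks by AIC with
$k = n(Q-1) + Q(Q-1)/2$ free parameters (the simplex coordinates plus the
free symmetric block of $B$). On progeny-sampled networks the AIC-best model
frequently captures the sampling design (who was sampled as a mother)
rather than biology, so a manual override of the selected $Q$ is
first-class; the ranking is always reported alongside.

## Paternity and the mating network

`exclusion_paternity()` implements strict multilocus exclusion: at each
locus the feasible paternal alleles are the offspring's alleles minus one
maternal contribution (either allele may be paternal when mother and
offspring share both); a candidate fails a locus if he carries no feasible
allele, and is excluded after more than `max_mismatch` failed loci
(default 0; set 1 to absorb a genotyping error). Offspring incompatible
with their own mother beyond `max_mismatch` are flagged and excluded.
Only offspring with exactly one surviving candidate enter the network —
ties are discarded, matching the practice of building links only from
unambiguous mating events. `build_mating_network()` collapses repeated
couples into single undirected links, drops selfings (couples are pairs of
distinct trees; the count is kept as a graph attribute) and keeps only
adults incident to at least one link.

Exclusion is conservative by construction: with complete adult sampling and
error-free genotypes the true father is never excluded, so a single
surviving candidate is necessarily the true father. The cost is
non-assignment, whose rate converges to the pollen-immigration rate as loci
accumulate.

## Relatedness

`estimate_relatedness()` computes the Queller–Goodnight moment estimator,
summing numerators and denominators over informative loci before dividing
and averaging the two directions, which makes the estimate exactly
symmetric. Pairs sharing fewer than `min_loci` informative loci (default 6,
half a 12-locus panel) are left missing rather than reported with high
variance. Reference allele frequencies default to the sample itself;
externally estimated frequencies or a fully precomputed matrix
(`read_relatedness()`) can be supplied — the latter is the fidelity path
when a triadic-likelihood estimate from dedicated software is available.

The related/unrelated threshold follows the calibration procedure of the
motivating study: the maximum estimate over offspring pairs known to share
neither parent (`calibrate_threshold()`), with half-sib and full-sib
validation summaries. Simulated at a 12-locus, 10-allele panel the
estimator means are within 0.05 of 0 / 0.25 / 0.5 for unrelated / half-sib
/ full-sib dyads, and the max-rule threshold over 500 uniform-frequency
unrelated pairs lands in (0.1, 0.4). One caveat is documented and handled:
a *moment* estimator has a heavy upper tail (unlike the bounded likelihood
estimator the rule was designed around), so with many calibration pairs
and skewed allele frequencies the max can exceed every adult pair estimate
and empty the network; `run_pipeline()` then falls back to the reference
threshold 0.22 with a warning.

Edges of the relatedness network require an estimate *strictly greater*
than the threshold (ties are non-edges), and isolated individuals are
reported separately rather than kept as nodes.

## The synthetic stand

`generate_stand()` and `simulate_mating()` emulate the study system the
analysis was designed for — a ~5 ha mapped mixed stand of two hybridizing
oaks — at its published scale, which the package uses as its default study
conditions:

* 298 adults at unequal abundance (178 : 120), positions uniform on a
  250 m × 200 m rectangle (5 ha);
* species labels spatially segregated (`segregation = 0.8`, a noisy
  west–east gradient): mapped mixed oak stands are strongly patchy, and the
  neighbourhood analyses below are only meaningful when the allospecific
  fraction varies between trees; at the default it spans roughly 0.05–0.65;
* 12 unlinked codominant loci with 10 alleles; per-species allele
  frequencies share a Dirichlet base mixed toward opposite allele-rank
  orders by `differentiation` (default 0.8, which yields a multilocus
  $F_{ST}$ of about 0.05, typical of SSR panels for closely related oaks;
  the knob-to-$F_{ST}$ mapping is monotone but deliberately uncalibrated);
* 51 of the adults sampled as mothers with 60 offspring each (~3,000
  offspring), fathers drawn with an exponential distance kernel of scale
  69 m (the published mean within-stand pollen dispersal distance of the
  less-dispersing species), allospecific fathers down-weighted by
  `compatibility` (default 0.2, giving ~10% hybrid matings at the default
  spatial structure), and external fathers with probability
  `immigration = 0.45` (echoing 1417 of 3046 offspring with no father in
  the stand); selfing excluded — the network is over couples of distinct
  trees;
* external pollen carries one allele per locus drawn from a donor species
  chosen by stand abundance weighted by compatibility with the mother.

`synthetic_reference_assignments()` stands in for the external
genotype-cluster and leaf-morphology assignments that real analyses import:
a 1-D trait (species means 0 and 1, Gaussian noise, cuts at 1/3 and 2/3)
for morphology, and a likelihood-weighted hybrid index (each allele votes
for the species under which it is more likely, weighted by the
log-likelihood ratio; thresholds 0.2 / 0.8) for genotype.

The generator deliberately omits masting and between-year variation, seed
dispersal and recruitment, linkage, null alleles, and any realistic
leaf-trait architecture. Tests passing on this generator therefore show
that the pipeline's statistics behave as designed under the stated
sampling structure — not that field data of arbitrary quality will yield
clean species boundaries.

## Congruence and the neighbourhood effect

`harmonize_labels()` resolves arbitrary group naming across criteria by
maximum-agreement pairing on the individuals pure under both criteria.
`congruence_summary()` then partitions individuals into fully consistent,
species inversions (conflicting pure labels), and intermediate-driven
discrepancies (no pure conflict), reporting the fraction of discrepancies
attributable to the intermediate class. The neighbourhood test follows the
published design exactly: restrict to individuals whose genotype and
morphology assignments agree on a pure label, ask whether the
interfertility label matches that consensus, and regress this indicator on
the proportion of allospecific neighbours within 69 m (Euclidean, boundary
inclusive, intermediates excluded both as focals and as neighbours;
individuals with no neighbour in range are excluded). The reported
chi-squared is the likelihood-ratio statistic against the intercept-only
model (df = 1; the Wald z is stored alongside), and complete separation is
flagged rather than silently reported. At the default study conditions the
congruent group sits near 27% allospecific neighbours versus near 48% for
the incongruent group, reproducing the direction and rough magnitude of
the published effect.

## Numerical choices and degenerate inputs

* $\pi$ clipping at $10^{-9}$; likelihood tolerance `1e-6` held for 5
  iterations; `max_iter` 2000; restarts 10 (5 in the heavier simulation
  tests below).
* Species EHNs are ordered by descending within-EHN connectivity, ties by
  the first node's membership; EHN0 is identified by its zero row, never
  by position.
* Classification: `epsilon = 0.05` absolute membership tolerance (the
  original analysis drew this boundary graphically; an absolute tolerance
  matches "on the edge" geometry, and a 0.01–0.10 sweep is a one-liner).
  Nodes with both species weights below `epsilon` are labelled by the
  dominant species EHN but flagged `low_information`; only exact ties stay
  intermediate.
* Empty father pools (all weights zero) raise an error naming the mother;
  over-parameterised fits ($Q > n$) warn; non-convergence returns the best
  iterate with `converged = FALSE`.
* Single global seed; every stage derives an independent substream, so a
  run is byte-reproducible from one integer.

## Problem sizes in the test suite

The suite exercises the full published scale where it matters (298 adults,
~3,000 offspring for the paternity and pipeline checks) and smaller stands
elsewhere; simulation-based checks use 10 replicate seeds (planted-model
recovery, neighbourhood direction), 1,000 dyads per relatedness class, 500
replicates for the null calibration of the likelihood-ratio test, and a
2,000-draw Monte-Carlo oracle on 6-node graphs for the optimizer bound.

## A minimal run

```{r, eval = FALSE}
library(matenet)
res <- run_pipeline(out_dir = "demo", seed = 5)
res$mating_scan        # AIC table, selected Q (override = 3)
res$congruence         # consistency / inversions / intermediates
res$neighborhood       # logistic neighbourhood test
plot(res$mating_fit)   # membership triangle, coloured by species label
```
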