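# matenet

Species delimitation from mating and relatedness networks.

`matenet` is for population geneticists and ecologists who want to delimit
closely related, hybridizing species by the criterion at the heart of the
biological species concept — who actually interbreeds with whom under
natural conditions — rather than by genotypic or morphological proxies. The
use case it was built around is a mapped forest stand of two sympatric oak
species in which thousands of open-pollinated offspring have been genotyped:
paternity analysis turns the progeny into a network of mating events among
adults, and clustering that network yields species boundaries, individuals
with mixed reproductive behaviour included.

## The model

Mating events are represented as an undirected, unweighted network: nodes
are adult trees, a link joins each couple that produced at least one
offspring. The network is clustered with a continuous (mixed-membership)
stochastic block model. Each node *i* has a membership vector *u<sub>i</sub>*
on the *Q*-simplex over *Q* extremal hypothetical nodes (EHNs), and edges
are independent Bernoulli draws with probability

&nbsp;&nbsp;&nbsp;&nbsp;π<sub>ij</sub> = u<sub>i</sub><sup>T</sup> B u<sub>j</sub>,

where *B* is a symmetric *Q*×*Q* matrix of EHN–EHN connectivity
coefficients. One EHN (EHN0) is structurally unconnected (its row of *B* is
zero), absorbing the large degree heterogeneity that progeny sampling
induces. Parameters are estimated by maximum likelihood (alternating
projected-gradient ascent with restarts) and the number of EHNs is chosen by
AIC, with a manual override because the AIC-best model can reflect the
sampling design rather than biology. With *Q* = 3, every individual sits in
a triangle: nodes on the EHN0–EHN1 edge are species 1, nodes on the
EHN0–EHN2 edge are species 2, interior nodes are reproductively
intermediate.

Around this core the package provides exclusion-based paternity assignment,
Queller–Goodnight pairwise relatedness with max-over-unrelated threshold
calibration and a relatedness network, congruence summaries across
delimitation criteria, a logistic-regression test of whether allospecific
neighbourhoods explain incongruent assignments, and a synthetic two-species
stand generator that reproduces the study design (298 adults on 5 ha, 51
sampled mothers, ~3,000 offspring, 12 SSR loci, pollen immigration) so the
whole pipeline runs without field data.

## Worked example

```r
library(matenet)
res <- run_pipeline(out_dir = NULL, seed = 5)
```

The pipeline simulates the default stand, reconstructs paternity, fits the
model and compares four delimitation criteria. Its components print as:

```
> res$stand
Synthetic stand: 298 adults (A: 178, B: 120) on 250 x 200 m
12 loci, 10 alleles each

> table(res$paternity$category)
  none single
  1348   1712

> res$mating_scan
C-SBM model scan
 Q      logL  df      aic converged
 2 -5076.901 297 10747.80      TRUE
 3 -4435.581 595 10061.16      TRUE
 4 -4250.843 894 10289.69      TRUE
AIC ranking (best first): 3 > 4 > 2
Selected Q = 3 (manual override)

> res$mating_fit
Continuous stochastic block model: 296 nodes, 1496 edges, Q = 3 EHNs
logL = -4435.581, AIC = 10061.161 (k = 595)
EHN connectivity matrix B:
     EHN0  EHN1  EHN2
EHN0    0 0.000 0.000
EHN1    0 0.917 0.000
EHN2    0 0.000 0.836
```

The fitted connectivity matrix is the species-delimitation result in
miniature: the two connected EHNs are strongly connected within themselves
(0.92, 0.84) and not at all with each other — two groups of interfertile
trees with almost no mating between them. Classification and congruence
with the genotype/morphology references:

```
> table(classify_memberships(res$mating_fit)$label)
intermediate           S1           S2
          40          111          145

> res$congruence
Congruence over 259 individuals:
  fully consistent: 162 (S1: 90, S2: 72)
  species inversions: 22
  intermediate-driven discrepancies: 75
  intermediate under >=1 criterion: 86
  77% of discrepancies caused by intermediates

> res$neighborhood
Neighbourhood effect on congruence (logistic regression, n = 201)
  slope = -3.704, LRT chi-sq = 21.22, df = 1, p = 4.1e-06
  mean allospecific fraction: 27% (congruent) vs 48% (incongruent)
```

Trees whose interfertility-based assignment disagrees with their
genotype/morphology consensus sit in markedly more allospecific
neighbourhoods (48% vs 27%): assignments based on who you mate with are
environment-dependent, which is exactly why they can legitimately differ
from genotype-based ones. See `vignette("mating-networks")` for the model,
its assumptions and its known limitations.

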