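---
title: "Methods: dissecting urban gene flow from genome-wide SNPs"
author: "urbanflow"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: dissecting urban gene flow from genome-wide SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanflow)
```

# The scientific problem

Container-breeding mosquitoes such as the Asian tiger mosquito disperse in
two very different ways: adults fly a few hundred metres at most, while
eggs and larvae ride human transport — ships, road traffic — across tens of
kilometres. At the scale of a single city both processes act at once, so
the genetic structure of an urban population is a superposition of weak
isolation by distance (IBD) from active flight and network-shaped signals
from passive transport. `urbanflow` implements the analysis chain needed to
separate the two from a panel of genome-wide SNPs: genotype filtering,
kinship screening, genetic and landscape distance matrices, matrix
statistics (Mantel, partial Mantel, distance-based redundancy analysis),
and — because those matrix statistics are notoriously prone to false
positives when IBD is present — a spatially explicit forward-time
simulation that measures the Type I error of every landscape model under a
null in which *only* IBD operates.

# Genotype filtering

`readGenotypeVcf()` loads biallelic SNP dosages (0/1/2 alternate-allele
copies, `NA` for missing) into a `GenotypeMatrix`, an extension of
`RangedSummarizedExperiment`: loci live in `rowRanges` with their scaffold
coordinates, individuals in `colData` with site membership and projected
coordinates in metres. The filter chain is applied in a fixed, recorded
order:

1. **Individuals** with more than 20% missing calls are removed
   (`filterIndividuals()`, strict inequality: an individual at exactly the
   threshold stays).
2. **Loci** are tested for Hardy-Weinberg equilibrium with the conditional
   exact test on genotype counts (`hweExactTest()`, no mid-p), and removed
   at `hweAlpha = 0.05`. The exact test and the alpha are configurable
   because upstream tools vary here; whatever is used is recorded in the
   `FilterReport`.
3. **Call rate**: loci called in fewer than 75% of individuals are removed.
4. **Minor allele frequency**: loci with MAF below 0.05 (computed from
   non-missing calls) are removed.
5. **Physical thinning** (`thinByDistance()`): a greedy left-to-right scan
   per scaffold keeps the first locus and drops any locus closer than
   250 kbp to the last kept one. The greedy scan is deterministic, and the
   retained set satisfies the pairwise-spacing guarantee exactly. At a
   recombination density of roughly 2.1 Mb per centimorgan this spacing
   corresponds to about eight SNPs per map unit (`snpsPerMapUnit()`), a
   density at which linkage between retained markers is negligible.

The order matters (call rate changes after removing individuals), which is
why every step appends a `FilterReport` whose counts reconcile exactly
with the matrix dimensions before and after.

# Relatedness

Full siblings in a sample distort every downstream structure statistic, so
they are found and pruned first.

**Loiselle's kinship** (`loiselleKinship()`) is a sample-frequency
referenced coefficient: per locus and allele the numerator is
$(p_i - \bar p)(p_j - \bar p) + \bar p(1-\bar p)/(n-1)$ with $p_i \in
\{0, \tfrac12, 1\}$ the within-individual allele frequency, $\bar p$ the
sample frequency and $n$ the number of sampled gene copies; the
denominator is $\bar p(1 - \bar p)$. Numerators and denominators are summed
over alleles and loci before dividing (ratio-of-sums, the convention of
the standard multilocus kinship programs), using only loci called in both
members of a pair while $\bar p$ and $n$ always come from the full sample.
Expected values are 0.25 / 0.125 / 0 for full sibs, half sibs, unrelated.

**Classification** (`classifyKinshipPairs()`) uses the midpoints between
adjacent categories' expected kinship as boundaries, derived by
`deriveKinshipThresholds()`: full-sib/half-sib at $(0.25 + 0.125)/2 =
0.1875$ and half-sib/unrelated at $(0.125 + 0.0625)/2 = 0.09375$ (the
lower anchor is the first-cousin expectation). **Pruning**
(`pruneFullSibGroups()`) builds the graph of full-sib pairs and keeps, per
connected component, the member with the least missing data (ties broken
lexicographically by id so runs are deterministic).

**Likelihood tests** (`relationshipTest()`) resolve ambiguous pairs the
way dedicated relationship-testing software does: the pair likelihood
under a category is the product over loci of $\sum_m k_m\,P(g_i, g_j \mid
m)$, where $(k_0,k_1,k_2)$ are the category's IBD-sharing coefficients and
the conditional genotype probabilities follow from Hardy-Weinberg
expansions (implemented by explicit enumeration over ordered allele
pairs, which the tests verify is a proper distribution and matches a
parental mating-table enumeration for full sibs). The null distribution of
the log-likelihood ratio is simulated under the *alternative* category;
the p-value is plus-one corrected. The default of 100 000 simulated pairs
(configurable) keeps a single test below a second at 300 loci; precision
beyond that changes nothing at the decision thresholds used here.

# Genetic distances and AMOVA

* `roussetA()` — the individual-level analogue of $F_{ST}/(1-F_{ST})$,
  computed from gene-identity probabilities as the ratio of sums over
  pairwise-complete loci of $(\hat Q_w - \hat Q_{ij})$ over
  $(1 - \hat Q_w)$, with $\hat Q_w$ the sample-average within-individual
  identity at the locus. When the denominator vanishes the value is 0 if
  the numerator vanishes too (identical homozygous pair in an invariant
  panel) and flagged `NA` otherwise.
* `neiD()` — standard between-group distance
  $-\ln(J_{xy}/\sqrt{J_x J_y})$ from gene identities averaged over shared
  loci; an unbiased small-sample variant is available behind
  `unbiased = TRUE`. Groups fixed for opposite alleles give an infinite
  distance, flagged with a warning rather than an error.
* `amova()` — one-level partition of squared pairwise distances into
  among- and within-site sums of squares, with $\eta^2 =
  SS_{among}/SS_{total}$ as the effect size and a permutation test on
  pseudo-F (group labels permuted, plus-one corrected, 999 permutations by
  default). The decomposition is exact and matches vegan's permutational
  partitioning on the same input, which the tests assert.

# Landscape variables

Each individual receives one score per transport network, all in metres
and all computed from projected coordinates:

* **Port isolation** — $\log(d_{\text{nearest port}} + 1)$. The +1 m
  offset (recorded in the documentation and harmless at city scales) makes
  a point on a port score exactly 0; natural log throughout, fixed and
  documented because monotone rescalings are not guaranteed neutral for
  the downstream matrix statistics.
* **River isolation** — same transform of the distance to the nearest
  river polyline segment.
* **Highway isolation** — $\sqrt{\text{area within 1 km not covered by
  highways}}$, with highways buffered to a nominal total width of 30 m.
  The area is integrated deterministically on a 5 m grid of cell centres
  (configurable); tests bound the discretisation error against closed
  forms and Monte-Carlo integration at well under 1%. The same operator
  applied to a railway layer is available but not part of the default
  models (it is nearly collinear with the highway layer in dense urban
  networks). More highway inside the disc can only lower the score.
* **Additive pair matrices** (`additivePairMatrix()`) — the pair value is
  the sum of the two individual scores, except that same-site pairs are
  set to 0: movement within a site requires no network transit, and the
  pair matrix models between-site connectivity only.
* **Barrier matrices** (`barrierPairMatrix()`) — sites are assigned
  integer tiers by their position relative to a barrier set (e.g. 0-2
  across two highway corridors, 0-3 across rivers); the pair value is the
  absolute tier difference, i.e. the number of barriers separating the
  pair. The tier-difference construction is this package's documented
  choice of how ordinal barrier codes become a pairwise matrix; nothing
  finer is identifiable from ordinal codes.
* **Habitat quality** — a Breteau-style container index observed at
  scattered stations is interpolated by ordinary kriging
  (`ordinaryKriging()`) with an exponential semivariogram
  $\gamma(h) = c_0 + (c - c_0)(1 - e^{-h/a})$ fitted by pair-count
  weighted least squares on 12 distance bins, solved per target on the 36
  nearest observations with the Lagrange sum-to-one constraint. Kriging is
  exact at observations when the nugget is zero; singular neighbourhoods
  fall back to a ridge-regularised solve with a warning.
  `meanWithinRadius()` then averages the kriged surface within 1 km of
  each individual.

# Matrix statistics

`mantelTest()` correlates the upper triangles of two pairwise matrices and
permutes rows/columns of one of them simultaneously; p-values are
one-tailed (greater) and plus-one corrected. `partialMantelTest()`
residualises both matrices on the conditioning matrix by ordinary least
squares over the off-diagonal entries and permutes the *residual* matrix
of the response (the residual-permutation scheme); a constant conditioning
matrix degrades gracefully to the plain test, and a response that is an
exact affine function of the conditioning matrix returns r = 0 with a
warning instead of crashing.

`pcnmBasis()` produces spatial eigenvectors (PCNM): the distance matrix is
truncated at the longest minimum-spanning-tree edge, entries beyond it
replaced by four times the threshold, double-centred and eigendecomposed;
positive-eigenvalue eigenvectors are rescaled to unit norm. The
computation delegates to `vegan::pcnm()` and the tests verify it against a
direct eigendecomposition written from the definition.

`fitDbrda()` is the package's own distance-based redundancy analysis:

1. principal-coordinates embedding of the response distances, keeping
   positive-eigenvalue axes only — genetic distance matrices are often
   slightly non-Euclidean and the small negative axes are discarded
   rather than corrected (a Lingoes/Cailliez-style correction was
   considered and rejected as it changes total inertia opaquely; the
   dropped inertia is visible by comparing embeddings);
2. residualisation of embedding and terms on the conditional design;
3. least-squares projection onto the explanatory terms.

The inertia decomposition (conditional + constrained + unconstrained =
total) is exact to machine precision and enforced by the class validity.
$R^2$ is the constrained fraction of post-conditioning inertia, adjusted
by the Ezekiel formula; marginal term significance uses permutation of
reduced-model residuals; effect sizes are $\eta^2 = SS_{term}/SS_{total}$;
collinearity is summarised by variance inflation factors of the
conditioned explanatory design. On Euclidean embeddings the fit reproduces
classical RDA (and `vegan::capscale` under conditioning) exactly, which
the tests assert — vegan here is the independent cross-check, not the
implementation. `forwardSelectDbrda()` adds candidate terms greedily by
adjusted $R^2$ and stops at the maximum, recording the inclusion order.

Two standing model layouts mirror the empirical workflow: a model with
the first two spatial eigenvectors of each matrix (geographic distance
included) as candidate terms, and a geography-partialled model whose
conditional matrix holds the geographic eigenvectors that are marginally
significant after Benjamini-Hochberg adjustment at 0.05
(`selectConditionalPcs()`); both the eigenvectors-per-matrix count and the
selection level are arguments.

# The simulator and the Type-I-error screen

Partial Mantel tests and constrained ordinations reject too often when
genetic structure carries IBD and landscape variables are themselves
spatially structured. The screen quantifies this per variable.

`runSimulation()` is a deliberately minimal, CDPOP-style forward model: a
fixed set of locations, one individual per location, discrete
non-overlapping generations (every adult dies, every location refills —
high recruitment, high mortality). The offspring refilling a location
draws its mother from all locations with probability $\propto e^{-d/b}$
and its father by the same kernel from the mother's location (no selfing);
each parent transmits one allele per locus at random. There is no
mutation, selection, sex-biased dispersal or age structure — the minimal
model sufficient for an IBD-only null. Initial genotypes are independent
Bernoulli(0.5) alleles, i.e. maximum diversity, so the locus count can be
matched to a real panel through Kimura-Crow effective alleles
(`effectiveAlleles()`, `lociForEffectiveAlleles()`: a real panel with 3694
effective alleles is matched by 1847 maximum-diversity loci). Edge effects
are handled implicitly: kernel weights are computed over the existing
location set only.

Study-scale defaults of `simulationConfig()` are 1500 locations (116 of
them focal sampling points jittered uniformly within 250 m so no two
individuals share coordinates), 1847 loci, 100 generations, and a kernel
scale of $b = 500$ m, whose median ($b\ln 2 \approx 347$ m) exceeds the
jitter radius while keeping most dispersal within 500 m. Locations are
placed by `placeLocations()` with density weights 1:3:5 across the three
habitat-index strata (0-2, 2-4, 4-6) of the kriged surface.

`runType1Suite()` computes the landscape matrices **once** from the real
(or fixture) geometry — only genotypes are simulated — then, per
simulation: samples the focal locations, computes Rousset's a, records the
IBD Mantel correlation against log distance, reruns every partial Mantel
(variable | distance), and refits the geography-conditioned dbRDA with the
empirical term structure. A variable whose count of significant
simulations strictly exceeds $\alpha \cdot n_{sims}$ (strictly more than 5
of 100 at the defaults) is flagged as untestable with the sampling design.
`verifyIbdMatch()` confirms that the simulations express IBD of the
intended strength before the counts are trusted.

# What the synthetic data do and do not emulate

`generateLandscape()` + `placeLocations()` + `runSimulation()` emulate the
features the statistics are sensitive to: a port-city geometry with
line networks and point terminals, clustered multi-site sampling (around
a dozen sites, 10-20 individuals each, separated by kilometres to tens of
kilometres), thousands of unlinked biallelic SNPs, within-site sibships
(via `generatePedigreeFixture()`, which also emits the exact pedigree
truth), weak IBD, and landscape variables that can be made spatially
confounded (all ports on one edge; barrier tiers cut along an axis) or
orthogonal (terminals on a symmetric internal grid) on demand. They do
not emulate: genotyping error and allelic dropout, linkage, demographic
history (bottlenecks, seasonal fluctuation), heterogeneous per-site
sampling effort, or real road topology. Green tests therefore demonstrate
the correctness and calibration of the statistical machinery under the
stated model, not robustness of inference to those unmodelled features of
real ddRADseq data.

# Numerical choices and problem sizes

* Permutation p-values are plus-one corrected everywhere; defaults are
  999 permutations for empirical fits and 99 inside simulation suites.
* Missing calls are `NA` at every layer; each estimator declares its
  policy (pairwise-complete loci for pair statistics, full-sample
  reference frequencies).
* Degenerate inputs (zero-call loci, constant matrices, rank-deficient
  designs, singular kriging systems, fixed opposite alleles) produce
  documented warnings/flags, not silent numbers.
* The test and acceptance workloads use scaled problem sizes chosen to
  exercise the same regimes at desk scale: calibration suites at 500
  replicates of 99-199 permutations; simulator checks at 200 locations,
  200 loci, 30 generations (50 runs); the Type-I screen at 10 suites of
  20 simulations over 250 locations with 100 focal points. For the
  screen's fixture the dispersal scale is 1500 m over a 20 km extent —
  scaling dispersal with the extent keeps the simulated IBD in the weak
  regime (Mantel r of order 0.1-0.3) that makes the confounded/orthogonal
  contrast meaningful; at full study scale the defaults above apply.

# Known limitations

* Rousset's a and Loiselle's k follow the cited estimators' defining
  identity/covariance sums with ratio-of-sums weighting; other programs
  differ in small-sample correction details, so third-party output may
  differ in the third decimal.
* The dbRDA drops negative PCoA axes; strongly non-Euclidean distance
  matrices lose the corresponding inertia (reported, not corrected).
* The simulator's mating system is a simplification (no explicit sexes,
  no multiple mating); it is intended as a null model for IBD only, not
  as a demographic model of mosquito populations.
* Barrier codes are ordinal; the tier-difference pairwise construction is
  one defensible choice among several, and is kept explicit so users can
  substitute their own matrix.
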