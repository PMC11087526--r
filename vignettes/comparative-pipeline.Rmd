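---
title: "Methods: comparing musical, linguistic and genetic diversity"
author: "songlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing musical, linguistic and genetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songlines)
```

# The question and the pipeline

Songs, like words and genes, are transmitted between generations, and a
long-standing question in cultural evolution is whether the global
structure of musical diversity recapitulates linguistic and genetic
history or moves independently of them. `songlines` implements the full
comparative pipeline for that question. The unit of musical observation
is a *song* coded on a battery of ordinal performance-style features;
songs nest in *societies*, which carry a language-family label, a
region label, coordinates, a position on a society phylogeny, and
(optionally) a population sample of biallelic genotypes. The pipeline
runs:

1. **Preparation** — resolve multi-coded cells, rescale features to
   0–1, filter societies by song count, optionally drop unreliable
   features, aggregate society profiles.
2. **Measurement** — a confirmatory factor model giving each song
   scores on five latent style dimensions.
3. **Variance decomposition** — AMOVA over song distances and pairwise
   Φ~ST~ fixation matrices between societies.
4. **Genetics** — Weir–Cockerham F~ST~ between the matched
   populations.
5. **Spatial structure** — distance-class autocorrelation of musical,
   genetic, and linguistic distances against geography.
6. **Treelikeness** — quartet delta scores of the musical distances.
7. **Association** — Mantel / partial Mantel and partial redundancy
   analysis between the distance matrices.

Every stage speaks the same interchange type: a labelled, symmetric,
zero-diagonal distance matrix (`DistMat`).

# Preparation

Ordinal codes are rescaled by *rank within the declared code set*,
`(rank − 1)/(K − 1)`, not by the raw code integer: coding schemes in
this tradition use non-consecutive code values on a 13-point scale, and
rank interpolation keeps the spacing of a feature's levels neutral.
Reversed features use the reversed rank so that high values always mean
"more of" the named trait. A cell holding several codes (a song showing
several characteristics of one feature) is resolved to a single code by
a seeded uniform choice; in real data this affects a few per cent of
cells, and the prep tests check that re-running with different seeds
moves factor scores only marginally (correlations above 0.95). The
scaling is idempotent: values already on the standardized grid pass
through unchanged, so a twice-standardized table equals a
once-standardized one.

Reliability filtering drops features whose inter-rater kappa falls
below a threshold (0.4 by default, a conventional floor for moderate
agreement), except features on an explicit keep-list retained for their
importance to model convergence. The shipped coding scheme and
indicator-to-latent map are editable YAML defaults, not canonical
tables; any study should substitute its own variable table.

# The latent measurement model

The five dimensions — Articulation, Tension, Ornamentation, Rhythm,
Dynamics — are modelled as correlated latent variables with each
indicator loading on exactly one of them, plus six residual covariances
for indicator pairs with shared method variance. Estimation is maximum
likelihood on the Pearson correlation matrix of the indicators,
minimising

$$F_{ML} = \log|\Sigma(\theta)| - \log|S| + \mathrm{tr}(S\,\Sigma(\theta)^{-1}) - p.$$

Identification fixes latent variances at 1 rather than marker
loadings, so the reported solution is completely standardized.
Treating 0–1 ordinal indicators as continuous is a deliberate
simplification (the default behaviour of mainstream SEM tooling);
a polychoric mode is out of scope, and with 13-level indicators the
attenuation this induces is about one per cent of a loading.

Numerical choices: latent correlations are parameterised by a
correlation Cholesky with unit-normalised rows, which keeps the matrix
positive definite with a free correlation structure; the row-norm
gauge freedom is pinned by a vanishing quadratic penalty so the
quasi-Newton optimiser (BFGS, relative tolerance 1e-8, up to 10 seeded
restarts) sees no flat ridge. Residual variances are log-parameterised.
Singleton latents (one indicator, used when reliability filtering
leaves a dimension with a single feature) are passthrough: loading
fixed at 1, residual variance at ~0, so the latent equals the
standardized indicator. Non-convergence flags the fit rather than
erroring; a non-positive-definite sample matrix errors.

Fit is judged by RMSEA `sqrt(max(χ² − df, 0)/(df (N−1)))` with a 90%
interval from inverting the noncentral χ² distribution, SRMR over
standardized residuals, and CFI against the independence baseline
(whose discrepancy on a correlation matrix is simply `−log|R|`).
Factor scores use the regression method,
$\hat\eta = \Phi\Lambda^\top\Sigma^{-1}(x - \bar x)$, which is
deterministic given the fit.

# AMOVA and fixation indices

Squared Euclidean distances between songs are decomposed with the
standard unequal-*n* AMOVA coefficients into within-society,
among-society(-within-group), and among-group components, for one- or
two-level hierarchies (groups are language families or regions). Sums
of squares partition exactly; the suite verifies every instance against
a brute-force double-loop implementation. Negative variance components
are reported raw — clamping would silently bias the Phi statistics —
and a Phi whose denominator is non-positive is NaN. Permutation tests
permute songs across societies (within groups for the nested level) and
whole societies across groups for the top level, 999 permutations by
default.

Pairwise Φ~ST~ runs the two-population decomposition for every society
pair, per latent dimension (1-D distances over factor scores) and for
the aggregate profile (all standardized features). Societies need at
least two songs to enter. The headline comparison with genetics is the
elementwise ratio Φ~ST~/F~ST~ over shared society pairs.

# Weir–Cockerham F~ST~

The 1984 estimator computes per-SNP variance components *a* (among
populations), *b* (among individuals within populations), and *c*
(within individuals) from allele frequencies, sample sizes, and
observed heterozygosity, and combines SNPs as a **ratio of averages**,
θ = Σa / Σ(a+b+c). The average-of-ratios variant is a known
implementation bug and a constructed two-SNP test pins the difference.
Missing dosages are excluded per SNP per population; a SNP is skipped
for a pair when either side has fewer than two called individuals or
when it is monomorphic across both. Populations below five individuals
warn (frequency estimates get noisy) but compute from two upward.
One subtlety the tests document: duplicating one sample into both
populations does *not* give θ = 0 — it forces the among-population
variance below its null expectation, so θ sits slightly negative; the
correct null check is two independent samples from one frequency
vector.

# Spatial autocorrelation

Trait distances are Gower-centered,
$C = -\tfrac12 J D^{(2)} J$, and for each geographic distance class
*h* (500 km bands to 20,000 km by default, the class of a pair being
`ceiling(d/band)` with zero-distance pairs in class 1) the coefficient

$$r_h = \frac{2\sum_{i<j\in h} c_{ij}}{\sum_{i<j\in h}(c_{ii}+c_{jj})}$$

compares within-class similarity to the overall level. The denominator
convention — diagonal terms of the two pair members, counted once per
pair involvement — is fixed by the brute-force oracle in the test
suite; published spreadsheet implementations differ in minor variants
of this denominator, and a strict-compatibility toggle is left as
future work. Significance permutes the society-to-location assignment;
confidence intervals bootstrap pairs within class. The summary
"autocorrelation persists to X km" is the largest distance up to which
every class has positive r with p below α (0.01 by default).

# Delta scores

For four taxa the three pairing sums of pairwise distances are ordered
m₁ ≥ m₂ ≥ m₃ and δ = (m₁ − m₂)/(m₁ − m₃); on an additive tree metric
the two largest sums tie, so δ = 0. When m₁ = m₃ (all pairings equal,
as on star trees or all-equal matrices) δ is 0 by the convention of
the delta-score literature. The score of a matrix is the mean over all
C(n,4) quartets, enumerated exhaustively up to 10⁶ quartets and
seeded-subsampled (10⁵ by default) beyond; taxa can also be subsampled
first, which is how regional tables of 50 societies are built.

One mathematical point shapes the regional interface: a 1-D score
distance |xᵢ − xⱼ| is a path metric and therefore *exactly additive* —
its delta is identically zero. Per-variable treelikeness is therefore
only informative on genuinely multivariate per-dimension distances,
and the pipeline scores the per-dimension Φ~ST~ matrices (the musical
distances used everywhere else), keeping the 1-D mode as the
documented default of `deltaByRegion()` for transparency.

# Associations

Distance matrices are embedded by principal coordinates
(eigendecomposition of the Gower-centered matrix); negative eigenvalues
are dropped from the variance total (no Cailliez/Lingoes correction,
matching the default of the standard tooling) and axes explaining more
than 10% of the positive variance are retained, with the leading axis
always kept. RDA regresses response axes on explanatory axes, after
residualising both on the conditioning axes for the partial case, and
reports the Ezekiel-adjusted
$R^2_{adj} = 1 - (1 - R^2)\frac{n-1}{n-m-1}$; a permutation-based
adjustment (`1 − (1−R²)/(1−mean R²_perm)`) is available as an option
since the two estimators differ under conditioning. Significance
permutes rows of the (residualised) explanatory axes. Mantel tests
correlate upper triangles with simultaneous row/column permutations;
the partial version correlates residuals and permutes the residualised
response. Two-sided p-values are the default throughout. A conditioning
matrix that explains the explanatory one exactly leaves no partial
association (r = 0 by construction), while zero residual variance in
the *response* is an error.

# The synthetic world

The generator produces worlds in which every stage has a recoverable
target. A Yule tree (depth rescaled to 1) carries: Brownian latent
trait means per dimension (rate σ²_v = 1 per unit depth by default);
Brownian diffusion of longitude/latitude (40 degrees per unit depth,
giving continental-scale spatial autocorrelation); Balding–Nichols
allele-frequency drift with a fixed per-branch F (0.05 by default,
yielding pairwise θ around 0.1–0.3, the magnitude of global human
population structure); and populations of 10 diploid individuals
(matching the typical panel sizes of desk-scale genetic databases).
Songs are society means plus within-society noise (σ_w = 0.5),
standardized per dimension and mapped to 24 indicators through a known
loading vector (uniform 0.55–0.85 unless supplied) with unit-variance
residuals, then binned to the 13-level ordinal scale; 3% of cells are
duplicated as multi-coded. A single global seed fans out to component
seeds via a documented linear rule, so worlds are exactly reproducible.

**Horizontal transmission is adoption, not averaging.** With
probability *h* each latent dimension of a society is replaced
wholesale by the value of a random one of its k = 5 nearest geographic
neighbours. The obvious alternative — blending each society with its
neighbourhood mean — turns out to do the opposite of what a borrowing
process should: convex averaging shrinks between-society variance,
compressing the distance matrix toward a star, which the delta
convention reads as *more* treelike. Copying transfers traits without
variance shrinkage and creates genuine quartet conflict, so delta
scores rise with h, as a borrowing process must. This is a deliberate
design choice made after the averaging model was shown (across
neighbourhood sizes, iteration counts, and tree-linked or independent
geography) to reduce delta at every mixing weight.

What the generator does *not* emulate: real coding schemes' uneven
code-set granularity and rater error; non-neutral (functional) musical
evolution; migration and admixture in the genetic model beyond
tree-shaped drift; language change of any kind (the tree itself stands
in for linguistic history); and any dependence of sampling density on
geography. Passing tests therefore show the statistics recover the
*generating* structure of a neutral, tree-plus-borrowing world — they
do not certify conclusions about real musical corpora.

# Problem sizes and test design

The suite checks every statistic against independent brute-force
implementations (explicit loops, exhaustive enumerations, `cmdscale`,
`vegan`) on upwards of a hundred random small instances, then exercises
ground-truth recovery at deliberately modest sizes chosen to keep a
full run around three minutes on one CPU: loading recovery on 2,000
songs (100 societies × 20), the drift sweep on 8 populations × 300
SNPs over five drift values × 10 seeds, the treelikeness ordering on
30-society worlds over 20 paired seeds, and partial-Mantel power/size
on 25-society worlds over 50 replicates each. The acceptance script
uses a 60-society world (600 songs, 500 SNPs) and finishes in about a
minute. Larger worlds change none of the logic, only the runtime.

# Known limitations

* ML on Pearson correlations of ordinal indicators; no robust standard
  errors or polychoric correlations.
* The latent correlation sign convention (majority-positive loadings
  per latent) is arbitrary, as in any factor model.
* Phi permutation p-values are one-sided (differentiation greater than
  chance), the field's convention, while Mantel/RDA p-values are
  two-sided.
* The spatial r denominator follows the oracle-pinned convention
  described above; other published variants exist.
* `DistMat` tolerates NaN entries (undefined fixation values) and
  downstream stages drop the affected pairs/quartets; heavy missingness
  will thin the effective sample.
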