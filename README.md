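# epiland

Tools for studying **global epistasis** — the striking empirical pattern
that a mutation's fitness effect declines linearly with the fitness of the
genetic background it arises on (diminishing returns for beneficial
mutations, increasing costs for deleterious ones) — as an emergent
consequence of widespread *microscopic* epistasis, with no saturating
trait or fitness peak assumed.

The package is for evolutionary geneticists and fitness-landscape
modellers who want to (i) compute exact locus-level epistasis statistics
of explicit genotype–fitness maps, (ii) simulate adaptation on such maps,
(iii) analyse mutant-by-background fitness assays with the estimators the
theory motivates, and (iv) explore the long-time consequences for
adaptability.

## The model in brief

Fitness of $\ell$ biallelic loci ($x_i = \pm 1$) is a sparse Fourier
(Walsh) expansion

$$y = \bar y + \sum_i f_i x_i + \sum_{i>j} f_{ij} x_i x_j + \ldots,
\qquad V = \sum_{S \neq \emptyset} f_S^2 .$$

The **variance fraction** of locus $i$,
$v_i = \sum_{S \ni i} f_S^2 / V$, obeys an exact identity: across all
genotypes, the regression of the flip effect $s_i$ on background fitness
$y$ has slope $-2 v_i$ and residual variance $4 v_i (1 - v_i) V$. When a
locus has many independent epistatic partners (the widespread-epistasis
limit) the residuals are Gaussian — one number per locus therefore
controls both the strength of global epistasis and the size of the
idiosyncratic fluctuations around it, which is the package's central
testable prediction for panel data.

On top of that core the package provides:

* **`cnLandscape()`** — the *connectedness* model: loci join a fraction
  $\mu_i$ of independent, all-orders-interacting pathways, giving
  $v_i \approx \mu_i/(1+\mu_i)$ and memoryless adaptation (the current
  fitness summarises the entire history);
* **`evolveGenerations()` / `evolveToFitness()` / `founderExperiment()`**
  — strong-selection weak-mutation adaptive walks (one proposal per
  generation, beneficial fixation probability $\min(1, 2s)$);
* **`fitPanel()`** and friends — slope, variance-fraction, AoIL,
  additivity and residual estimators for mutant-by-background panels,
  exact on full genotype subcubes;
* **`dfeDensityClosed()` / `sswmAnalytic()`** — the closed-form
  distribution of fitness effects at adaptedness $z$ (two-sided
  exponential, $\rho(\sigma|z)/\rho(-\sigma|z) = e^{-\sigma z}$) and
  origin-fixation dynamics on it, reproducing the $z \sim t^{1/5}$ and
  $n_s \sim t^{2/5}$ adaptation laws;
* **`synthPanel()` / `readPanel()` / `writePanel()`** — synthetic assay
  generation (directed non-segregating mutations, measurement noise,
  effect screening) and a plain TSV panel format;
* **`epilandCLI()`** — a small subcommand CLI
  (`inst/scripts/epiland.R`) over the same functions.

## Worked example

```r
library(epiland)

# a two-locus toy map: y = 1 + 0.5 x1 - 0.3 x2 + 0.2 x1 x2
toy <- fourierLandscape(2, baseline = 1,
                        terms = list(1, 2, c(1, 2)),
                        coef = c(0.5, -0.3, 0.2))
varianceFraction(toy, 1)          # 0.7631579
bruteForceRegression(toy, 1)$slope  # -1.526316  = -2 v_1, exactly

# a connectedness landscape in the widespread-epistasis regime
set.seed(1)
land <- cnLandscape(nLoci = 100, nPathways = 300, muBar = 0.05)
totalVariance(land)               # 1

# adaptive walk and a mutant-by-background panel
set.seed(2)
walk <- evolveGenerations(land, randomGenotypes(1, 100)[1, ], 50)
walk$nFixed                       # 4 mutations fixed in 50 generations

loci <- order(-varianceFractions(land))[1:10]
panel <- buildPanel(land, loci, randomGenotypes(200, 100))
head(fitStats(fitPanel(panel))[, c("mutation", "slope", "vTildeHat")], 3)
#   mutation      slope vTildeHat
# 1      L52 -0.5174701 0.2587350
# 2      L53 -0.4443852 0.2221926
# 3      L73 -0.4232544 0.2116272
```

The fitted slopes are negative for every strong-epistasis locus —
diminishing returns — and `-slope/2` estimates each locus's variance
fraction; `residualVarianceRelation()` then checks that the residual
variance scales with $\hat{\tilde v}(1-\hat{\tilde v})$, the signature
separating widespread epistasis from, e.g., a nonlinearity applied to an
additive trait.

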