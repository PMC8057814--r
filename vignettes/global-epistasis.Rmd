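---
title: "Global epistasis from sparse Fourier fitness landscapes: models and methods"
author: "epiland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global epistasis from sparse Fourier fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiland)
```

## The model

A quantitative trait (we say "fitness" throughout) of $\ell$ biallelic loci
with alleles coded $x_i = \pm 1$ admits the Fourier (Walsh) representation

$$y = \bar y + \sum_i f_i x_i + \sum_{i>j} f_{ij} x_i x_j + \ldots,$$

where $\bar y$ is the mean fitness over all $2^\ell$ genotypes, first-order
coefficients are additive effects, and higher orders encode idiosyncratic
(microscopic) epistasis of all orders. Because the basis functions
$\prod_{i\in S} x_i$ are orthonormal under the uniform distribution on
genotypes, the total genetic variance is $V = \sum_{S\neq\emptyset} f_S^2$
and the **variance fraction** (VF) of a locus,
$v_i = \sum_{S\ni i} f_S^2 / V$, measures its total contribution, all
orders of epistasis included.

The package's central exact identities, which hold for *every* coefficient
table and are enforced in the test suite by genotype enumeration:

* regressing the flip effect $s_i$ on background fitness $y$ over all
  genotypes gives slope $-2 v_i$ and residual variance $4 v_i (1-v_i) V$;
* on the $x_i = -1$ subcube (a directed mutation) the slope is
  $-2\tilde v_i$, with $\tilde v_i$ a ratio of coefficient sums that may be
  negative, and the implied additive term is $2 f_i (1 - \tilde v_i)$;
* a simultaneous double flip regresses with slope
  $-2(v_i + v_j - 2 e_{ij})$, where
  $e_{ij} = \sum_{S\supseteq\{i,j\}} f_S^2/V$.

When a locus has many independent nonzero epistatic terms whose partners
are not overwhelmingly additive — the *widespread epistasis* (WE) limit —
the residual around the linear trend is approximately Gaussian with
variance proportional to $v_i(1 - v_i)$. This is the mechanism by which
diminishing-returns and increasing-costs epistasis (mutations are
systematically less beneficial, and more deleterious, on fitter
backgrounds) emerge from microscopic idiosyncrasy alone. The **additivity
of interacting loci** (AoIL) decides the sign of the trend: below $1/2$
the trend is provably negative; above $1/2$ either sign can occur. The
additivity of the mutated locus itself, $f_i^2 / V_i$, does not.

## Containers and conventions

`FourierLandscape` stores the coefficient table sparsely (one sorted locus
subset per coefficient; the baseline kept separately) together with a
loci-by-terms incidence matrix, so the effect of one mutation costs only
the subsets containing the flipped locus and the effects of *all* $\ell$
mutations on one background cost a single sparse product. `MutationPanel`
holds a mutant-by-background fitness assay (backgrounds in rows, mutations
in columns, `NA` marking dropped pairs), `GlobalEpistasisFit` the
per-mutation regression summaries.

Conventions fixed once and used everywhere:

* alleles are $\pm 1$; the default mutation direction for directed
  statistics is $-1 \to +1$. Reversing the direction flips the sign of all
  odd-order coefficients first.
* second moments divide by $n$ (population normalization), so the exact
  subcube identities hold without small-sample corrections; sample
  normalization is available for real-data use.
* "exact" identities are asserted at $10^{-9}$ relative tolerance — the
  computations are sums of products of doubles.
* the degenerate AoIL case (a locus with no epistatic terms, a $0/0$
  ratio) returns 0 with a warning: its partners are vacuously additive and
  the numerator vanishes identically.

## Panel estimators

Given an assay of mutant and background fitnesses, per mutation:

* $\hat{\tilde v} = -\text{slope}/2$ from OLS of $s = y_i - y$ on $y$;
* $\hat v = (1 - \hat\rho)/2$, with $\hat\rho$ the Pearson correlation of
  the concatenations $(y_i \oplus y)$ and $(y \oplus y_i)$;
* $\widehat{\text{AoIL}} = |\mathrm{Cov}(s, y_i + y)| /
  (|\mathrm{Cov}(s, y_i+y)| + \mathrm{Var}(s))$;
* additivity $= \hat f^2 / (\hat f^2 + \mathrm{Var}(s)/4)$ with
  $\hat f = \bar s / 2$;
* residuals $(y_i + c_i y) - \overline{(y_i + c_i y)}$ with
  $c_i = 2\hat{\tilde v} - 1$, identical to the OLS residuals.

On panels containing a full genotype subcube each estimator equals its
coefficient-level counterpart exactly; this is the strongest oracle in the
test suite. Two estimator-level caveats worth knowing: the covariance AoIL
form is derived for directed panels, and on symmetric flip panels it does
not track the coefficient-level AoIL (the package therefore lets you
disable the AoIL filter in `residualVarianceRelation()`, and does so in
its own flip-panel checks); and the pooled residual prediction scales
standard normal draws by $\sqrt{\tilde v(1-\tilde v)}$ — the *standard
deviation* implied by a variance proportional to $\tilde v(1-\tilde v)$ —
before variance-matching the pooled distributions.

## The connectedness landscape generator

`cnLandscape()` builds landscapes from $M$ independent "pathways": locus
$i$ joins each pathway with its own probability $\mu_i$ (drawn from an
exponential with mean $\bar\mu$, resampled above 1 — a $\sim 10^{-22}$
event at $\bar\mu = 0.02$), all loci within a pathway interact at every
order, every subset coefficient is standard normal, subsets reached by
several pathways sum their contributions, and the table is rescaled to
unit total variance with zero baseline. For many loci this gives
$v_i \approx \mu_i/(1+\mu_i)$: influential loci are influential because
they touch many pathways, and an exponential sparsity distribution yields
an approximately exponential VF distribution. $\mu_i = 1$ for all loci is
the House-of-Cards limit ($v = 1/2$, post-mutation fitness uncorrelated
with pre-mutation fitness).

The reference configuration is $\ell = 400$, $M = 500$,
$\bar\mu = 0.02$, so $\bar\mu\ell = 8$ puts the landscape firmly in the WE
regime. Pathway sizes concentrate around $\bar\mu\ell$; interaction order
is capped at `maxOrder = 12` (configurable), with larger pathways
truncated to subsets of at most that size and a warning. The cap bounds
the worst-case subset enumeration of rare large pathways while leaving the
typical pathway untouched; how rare super-cap pathways were handled in
comparable simulation protocols is generally unstated, so truncation with
a warning is this package's own policy. Two finite-size facts matter when
interpreting tests: the realized VF distribution of one landscape is a
400-draw sample from its target (Kolmogorov distance $\sim 0.07$ from the
ideal exponential is *expected*), and with $M$ finite the relation
$e_{ij} \approx v_i v_j$ — the memorylessness condition under which the
current fitness is a sufficient statistic for the future — holds with
sampling scatter, not exactly.

## Adaptive walks and the distribution of fitness effects

SSWM walks propose one uniformly chosen locus flip per generation;
beneficial proposals fix with probability $\min(1, 2s)$ (the classic
origin-fixation $\pi \approx 2s$; only proportionality is fundamental, so
acceptance bands on fixation counts are wide), deleterious ones never fix,
and reversions are ordinary flips. Time is counted in proposals.

Conditioning on background fitness in the WE limit makes $(y, s_1,
\ldots, s_\ell)$ jointly normal, giving
$\mathrm{Mean}_y(s_i) = -2 v_i (y - \bar y)$ and
$\mathrm{Cov}_y(s_i, s_j) = 4V(e_{ij} - v_i v_j)$. With scaled units
$z = (y - \bar y)/\sqrt V$ and an exponential VF distribution of mean
$\bar v$, the distribution of fitness effects (DFE) integrates in closed
form to a two-sided exponential with rates
$(\sqrt{2\bar v^{-1} + z^2} \pm z)/2$ and prefactor
$[2\bar v\sqrt{2\bar v^{-1}+z^2}]^{-1}$. The printed form of that
prefactor is typographically ambiguous in common renderings; the package
fixes it by requiring $\int \rho\, d\sigma = 1$ and lets the direct
quadrature of the defining $v$-integral arbitrate — the two agree to
$10^{-6}$ and better on a $(\sigma, z)$ grid. Consequences carried by the
closed form: $\rho(\sigma|z)/\rho(-\sigma|z) = e^{-\sigma z}$ exactly, a
beneficial fraction of exactly $1/2$ at $z = 0$ decaying as
$(2\bar v z^2)^{-1}$, and a typical fixed-mutation VF of $1/(2z^2)$ —
late adaptation is carried by loci of moderate connectivity.

`sswmAnalytic()` iterates origin-fixation dynamics on this DFE directly
(compiled loop; draws use R's RNG, so runs are seed-reproducible). In the
well-adapted regime $z \gg \bar v^{-1/2}$ the mean trajectory follows
$z \sim t^{1/5}$ and the substitution count $n_s \sim t^{2/5}$; a
point-mass VF distribution (every locus equivalent) instead collapses to
log-slow creep past $z \sim \bar v^{-1/2}$ — the wide range of locus
connectivities is what keeps adaptation going.

## Synthetic panels

`synthPanel()` emulates the structure of a large insertion-mutation assay:
mutation loci are non-segregating (all backgrounds carry $-1$ there;
mutants set $+1$, a directed mutation), backgrounds are either uniform
random genotypes or linkage-free two-parent recombinants (each locus
inherited independently — real crosses have linkage, which this
deliberately omits, so the recombinant scheme is a labelled
simplification), i.i.d. Gaussian measurement noise of chosen standard
deviation is added to every reported fitness, and an optional screen
discards candidate mutations whose mean absolute noiseless effect falls
below a threshold, reproducing the upward VF bias of assays that select
mutations for nonzero effect. Adding noise of variance $\sigma_n^2$
inflates each per-mutation residual variance by $\approx 2\sigma_n^2$
(noise enters both $y$ and $y_i$), which is why residual-variance
comparisons on real data need a noise model.

## Problem sizes and test design

The suite checks exact identities by enumeration on $\geq 50$ random
sparse landscapes of up to 10 loci, and the stochastic claims at the
reference scales: one 400-locus connectedness landscape shared across
checks; 128 fifty-generation walks for fixation counts; 128 founders
evolved through fitness targets $1,\ldots,5$ for the 640-background panel
(30 loci); 64 founders $\times$ 12 replicates for declining adaptability;
64 genotypes evolved to $z = 2.5$ and $5$ with 200 measured loci for the
empirical DFE; $10^6$ proposals $\times$ 100 replicates (20 for the
point-mass control) for the scaling laws, fitting the final time decade.

The slope-versus-VF proportionality constant is estimated per 30-locus
panel by the inverse-variance-weighted through-origin fit
$\sum_i \text{slope}_i / \sum_i v_i$ (per-locus slope noise has standard
deviation $\propto \sqrt v$, so plain through-origin OLS is dominated by
the one or two largest-VF loci), and averaged over eight disjoint panels
measured on the same backgrounds: the panel-to-panel spread reflects
quenched per-locus deviations of a single landscape realization rather
than measurement noise, and a single panel's coefficient scatters several
times more widely than the panel average.

Distributional agreement tests are calibrated to what a finite landscape
can deliver. The empirical DFE is compared with the closed form at
Kolmogorov distance 0.15 (about twice the intrinsic 400-locus sampling
scale of the VF distribution), while the sharper WE-limit statement —
each locus Gaussian with its *realized* VF — is held below 0.05. The
pooled-residual Gaussianity comparison uses the 30 largest-VF loci on
uniform random backgrounds, where the WE limit is sharpest; for small-VF
loci the Gaussian approximation degrades and a significance test at
pooled-sample size would reject for reasons the theory itself predicts.

What passing these tests does and does not show: the synthetic generator
reproduces the *structure* of mutant-by-background assays (directed
non-segregating mutations, measurement noise, effect screening) but not
linkage among background loci, shared-clone error correlation, or
frequency-dependent fitness measurement — agreement here does not imply
the estimators are unbiased on data with those features.

## Known limitations

* Coefficient inference from data is out of scope: the landscape side is
  forward-only, and the panel side estimates the aggregate statistics the
  theory actually uses.
* Enumeration oracles cap at 16 loci by design.
* The SSWM acceptance rule is the only population-genetic ingredient: no
  clonal interference, drift beyond the acceptance probability, or finite
  population sizes.
* Pathway truncation above `maxOrder` slightly depletes the upper VF tail
  of generated landscapes relative to the ideal model.
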