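#' Distribution-of-variance-fractions specification
#'
#' Describes the distribution \eqn{P(v)} of variance fractions across loci,
#' from which the analytic distribution of fitness effects (DFE) is built.
#' Supported kinds: `"exponential"` with mean `vBar` (truncated and
#' renormalized on `(0, vMax]`), `"fixed"` (a point mass, the
#' regular-landscape limit), and `"tabulated"` (a density given on a grid,
#' renormalized to integrate to 1).
#'
#' @param kind one of `"exponential"`, `"fixed"`, `"tabulated"`.
#' @param vBar mean VF for `"exponential"`, or the point mass location for
#'   `"fixed"`.
#' @param v,density grid and density values for `"tabulated"` (density is
#'   linearly interpolated and renormalized).
#' @param vMax upper support limit for the exponential kind; `Inf` uses the
#'   untruncated exponential (useful for closed-form cross-checks, exact up
#'   to the exponentially small mass above 1 when `vBar` is small).
#' @return an object of class `dvfSpec`.
#' @export
dvfSpec <- function(kind = c("exponential", "fixed", "tabulated"),
                    vBar = 0.02, v = NULL, density = NULL, vMax = 1) {
  kind <- match.arg(kind)
  if (kind %in% c("exponential", "fixed")) {
    if (!is.finite(vBar) || vBar <= 0 || vBar >= 1)
      stop("vBar must lie in (0, 1)")
  }
  if (kind == "tabulated") {
    if (is.null(v) || is.null(density) || length(v) != length(density))
      stop("tabulated kind requires matching v and density vectors")
    if (any(density < 0) || any(v <= 0) || any(v > 1))
      stop("tabulated density must be nonnegative on (0, 1]")
    o <- order(v)
    v <- v[o]
    density <- density[o]
    z <- sum(diff(v) * (density[-1] + density[-length(density)]) / 2)
    if (z <= 0) stop("tabulated density integrates to zero")
    density <- density / z
  }
  structure(list(kind = kind, vBar = vBar, v = v, density = density,
                 vMax = vMax), class = "dvfSpec")
}

#' @export
print.dvfSpec <- function(x, ...) {
  cat("DVF spec:", x$kind,
      switch(x$kind,
             exponential = paste0("(vBar = ", x$vBar, ", vMax = ", x$vMax, ")"),
             fixed = paste0("(v = ", x$vBar, ")"),
             tabulated = paste0("(", length(x$v), " grid points)")), "\n")
  invisible(x)
}

# density P(v) of a dvfSpec (vectorized); exponential is truncated to
# (0, vMax] and renormalized
.dvfDensity <- function(dvf, v) {
  switch(dvf$kind,
    exponential = {
      z <- if (is.finite(dvf$vMax)) 1 - exp(-dvf$vMax / dvf$vBar) else 1
      ifelse(v > 0 & v <= dvf$vMax, exp(-v / dvf$vBar) / (dvf$vBar * z), 0)
    },
    tabulated = {
      out <- approx(dvf$v, dvf$density, xout = v, yleft = 0, yright = 0)$y
      out[is.na(out)] <- 0
      out
    },
    fixed = stop("point-mass DVF has no density; handled specially")
  )
}

.dvfSample <- function(dvf, n) {
  switch(dvf$kind,
    exponential = {
      v <- rexp(n, rate = 1 / dvf$vBar)
      while (any(bad <- v > dvf$vMax)) v[bad] <- rexp(sum(bad), 1 / dvf$vBar)
      v
    },
    fixed = rep(dvf$vBar, n),
    tabulated = {
      # inverse-CDF sampling on the tabulated grid
      cw <- cumsum(c(0, diff(dvf$v) *
                       (dvf$density[-1] + dvf$density[-length(dvf$v)]) / 2))
      cw <- cw / cw[length(cw)]
      u <- runif(n)
      approx(cw, dvf$v, xout = u, ties = "ordered")$y
    }
  )
}

#' Numeric distribution of fitness effects
#'
#' Evaluates the DFE of a genotype of fitness `y` by integrating over the
#' distribution of variance fractions:
#' \deqn{\rho(s \mid y) = \int_0^{v_{\max}} \frac{P(v)}{2\sqrt{vV}}\,
#'   \varphi\!\left(\frac{s + 2v(y - \bar y)}{2\sqrt{vV}}\right) dv,}
#' where \eqn{\varphi} is the standard normal pdf: each locus' effect is
#' normal with mean \eqn{-2v(y-\bar y)} and variance \eqn{4vV}. The
#' integrable \eqn{v \to 0} endpoint is handled by the substitution
#' \eqn{v = u^2}. For the `"fixed"` kind the integral collapses to a single
#' Gaussian.
#'
#' @param s fitness effect(s) at which to evaluate the density.
#' @param y background fitness.
#' @param dvf a [dvfSpec()].
#' @param V total genetic variance (default 1).
#' @param yBar baseline fitness (default 0).
#' @param relTol quadrature tolerance passed to [stats::integrate()].
#' @return density value(s); attribute `"abs.error"` carries the largest
#'   quadrature error estimate. Non-converged quadrature warns and returns
#'   the estimate.
#' @export
dfeDensity <- function(s, y = 0, dvf = dvfSpec(), V = 1, yBar = 0,
                       relTol = 1e-10) {
  stopifnot(V > 0)
  if (dvf$kind == "fixed") {
    v <- dvf$vBar
    sd <- 2 * sqrt(v * V)
    return(dnorm(s, mean = -2 * v * (y - yBar), sd = sd))
  }
  uMax <- sqrt(if (dvf$kind == "tabulated") max(dvf$v) else dvf$vMax)
  if (dvf$kind == "tabulated") {
    # the tabulated density is piecewise linear, which defeats adaptive
    # quadrature; composite Simpson in u = sqrt(v), aligned with the knots
    # so every panel sees a smooth integrand, is accurate and deterministic
    uk <- sqrt(dvf$v)
    m <- 10L   # subintervals per knot interval (even, for Simpson)
    u <- unlist(lapply(seq_len(length(uk) - 1L), function(k)
      seq(uk[k], uk[k + 1L], length.out = m + 1L)[-(m + 1L)]))
    u <- c(u, uk[length(uk)])
    h <- diff(u)
    # per-interval Simpson weights accumulated on the shared grid
    w <- numeric(length(u))
    simp <- c(1, rep(c(4, 2), length.out = m - 1L), 1)
    for (k in seq_len(length(uk) - 1L)) {
      idx <- (k - 1L) * m + seq_len(m + 1L)
      w[idx] <- w[idx] + simp * (uk[k + 1L] - uk[k]) / (3 * m)
    }
    # sqrt/square round trips can land a knot a rounding step outside the
    # table; clamp so the interpolant is evaluated on its support
    vq <- pmin(pmax(u^2, min(dvf$v)), max(dvf$v))
    P <- .dvfDensity(dvf, vq)
    out <- vapply(s, function(si) {
      sum(w * P * dnorm((si + 2 * vq * (y - yBar)) / (2 * u * sqrt(V))))
    }, numeric(1)) / sqrt(V)
    attr(out, "abs.error") <- NA_real_
    return(out)
  }
  worst <- 0
  out <- vapply(s, function(si) {
    fn <- function(u) {
      v <- u^2
      # dv = 2 u du cancels the 1/(2 sqrt(v)) prefactor
      .dvfDensity(dvf, v) * dnorm((si + 2 * v * (y - yBar)) / (2 * u * sqrt(V)))
    }
    q <- tryCatch(
      integrate(fn, 0, uMax, rel.tol = relTol, abs.tol = 1e-15,
                subdivisions = 400L),
      error = function(e) NULL)
    if (is.null(q)) {
      # far tails: the integral is at rounding scale; retry loosely and
      # only complain when the value is actually non-negligible
      q <- integrate(fn, 0, uMax, rel.tol = 1e-6, abs.tol = 1e-12,
                     subdivisions = 1000L, stop.on.error = FALSE)
      if (q$value > 1e-8)
        warning("quadrature did not converge cleanly (", q$message,
                "); returning the estimate")
      q$abs.error <- NA_real_
    }
    worst <<- max(worst, q$abs.error, na.rm = TRUE)
    q$value / sqrt(V)
  }, numeric(1))
  attr(out, "abs.error") <- worst
  out
}

.kappa <- function(z, vBar) sqrt(2 / vBar + z^2)

#' Closed-form distribution of fitness effects for an exponential DVF
#'
#' With an exponential distribution of variance fractions of mean
#' \eqn{\bar v} (and scaled units \eqn{V = 1}, \eqn{z = y - \bar y}), the
#' DFE is two-sided exponential:
#' \deqn{\rho(\sigma \mid z) = \frac{1}{2\bar v \kappa}
#'   e^{-\sigma z / 2 - |\sigma| \kappa / 2}, \qquad
#'   \kappa = \sqrt{2 \bar v^{-1} + z^2}.}
#' The prefactor is fixed by normalization \eqn{\int \rho\, d\sigma = 1}
#' (the numeric quadrature of [dfeDensity()] is the arbiter). Beneficial
#' and deleterious tails decay at rates \eqn{(\kappa + z)/2} and
#' \eqn{(\kappa - z)/2}, giving the detailed-balance-like identity
#' \eqn{\rho(\sigma|z)/\rho(-\sigma|z) = e^{-\sigma z}}.
#'
#' @param sigma scaled fitness effect(s).
#' @param z adaptedness (scaled background fitness).
#' @param vBar mean variance fraction, in (0, 1).
#' @return density value(s).
#' @export
dfeDensityClosed <- function(sigma, z, vBar) {
  k <- .kappa(z, vBar)
  exp(-sigma * z / 2 - abs(sigma) * k / 2) / (2 * vBar * k)
}

#' @rdname dfeDensityClosed
#' @return `dfeCDFClosed` returns the cumulative distribution
#'   \eqn{P(\Sigma \le \sigma \mid z)}.
#' @export
dfeCDFClosed <- function(sigma, z, vBar) {
  k <- .kappa(z, vBar)
  A <- 1 / (2 * vBar * k)
  lower <- 2 * A / (k - z) * exp(pmin(sigma, 0) * (k - z) / 2)
  upper <- 1 - 2 * A / (k + z) * exp(-pmax(sigma, 0) * (k + z) / 2)
  ifelse(sigma <= 0, lower, upper)
}

#' Beneficial fraction of the closed-form DFE
#'
#' \eqn{\int_0^\infty \rho(\sigma\mid z)\, d\sigma =
#' [\bar v \kappa (\kappa + z)]^{-1}}: exactly 1/2 at \eqn{z = 0} and
#' asymptotically \eqn{(2\bar v z^2)^{-1}} in the well-adapted regime, the
#' slow \eqn{z^{-2}} depletion of the beneficial-mutation supply.
#'
#' @inheritParams dfeDensityClosed
#' @export
beneficialFraction <- function(z, vBar) {
  k <- .kappa(z, vBar)
  1 / (vBar * k * (k + z))
}

#' Conditional moments of fitness effects given background fitness
#'
#' In the widespread-epistasis limit, fitness and fitness effects are
#' jointly normal over genotypes, so conditional on background fitness
#' \eqn{y} the effects at loci \eqn{i, j} have
#' \eqn{\mathrm{Mean}_y(s_i) = -2 v_i (y - \bar y)} and
#' \eqn{\mathrm{Cov}_y(s_i, s_j) = 4V(e_{ij} - v_i v_j)}; with
#' \eqn{e_{ii} = v_i} the conditional variance is \eqn{4V v_i(1-v_i)}.
#'
#' @param vi,vj variance fractions of the two loci.
#' @param eij epistatic VF between them (use `vi` for `i = j`).
#' @param V total genetic variance.
#' @param y background fitness.
#' @param yBar baseline fitness.
#' @return list with `meanI` (conditional mean of \eqn{s_i}) and `covIJ`.
#' @export
conditionalMoments <- function(vi, vj, eij, V = 1, y = 0, yBar = 0) {
  list(meanI = -2 * vi * (y - yBar), covIJ = 4 * V * (eij - vi * vj))
}

#' Conditioning of a second mutation's effect on the first
#'
#' For two successive mutations, the expected effect of the second given
#' the post-first fitness \eqn{y_1} and the first effect \eqn{s_1} is
#' \eqn{E[s_2] = -2v_2 (y_1 - \bar y) + \frac{v_1 v_2 - e_{12}}{v_1} s_1}.
#' When \eqn{e_{12} = v_1 v_2} the dependence on \eqn{s_1} vanishes:
#' adaptation is memoryless and the current fitness is a sufficient
#' statistic.
#'
#' @param v1,v2 variance fractions of the first and second locus.
#' @param e12 epistatic VF between them.
#' @return list with `coefY1` (\eqn{-2v_2}, the coefficient on
#'   \eqn{y_1 - \bar y}) and `coefS1` (\eqn{(v_1 v_2 - e_{12})/v_1}).
#' @export
secondMutationCoefficients <- function(v1, v2, e12) {
  if (any(v1 <= 0)) stop("v1 must be positive")
  list(coefY1 = -2 * v2, coefS1 = (v1 * v2 - e12) / v1)
}

#' Typical variance fraction of mutations fixing at adaptedness z
#'
#' Fixed beneficial mutations in the well-adapted regime have typical
#' effect \eqn{\sigma_{\rm fix} \sim z^{-1}} and hence typical VF
#' \eqn{v^*_{\rm fix} = 1/(2z^2)}: loci of moderate connectivity drive
#' late adaptation.
#'
#' @param z adaptedness, must be positive.
#' @export
vfixStar <- function(z) {
  if (any(z <= 0)) stop("z must be positive")
  1 / (2 * z^2)
}

#' Sample (variance fraction, fitness effect) pairs from the analytic DFE
#'
#' Draws \eqn{v \sim P(v)} and then
#' \eqn{\sigma \mid v \sim N(-2vz, 4v)} in scaled units (\eqn{V = 1}).
#'
#' @param n number of draws.
#' @param z adaptedness.
#' @param dvf a [dvfSpec()].
#' @return data.frame with columns `v` and `sigma`.
#' @export
sampleEffect <- function(n, z, dvf = dvfSpec()) {
  v <- .dvfSample(dvf, n)
  data.frame(v = v, sigma = rnorm(n, mean = -2 * v * z, sd = 2 * sqrt(v)))
}
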