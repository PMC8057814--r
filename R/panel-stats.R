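# population or sample second moments
.mom <- function(x, y = x, normalization = "population") {
  n <- length(x)
  den <- if (normalization == "population") n else n - 1L
  sum((x - mean(x)) * (y - mean(y))) / den
}

#' Global-epistasis regression for one mutation of a panel
#'
#' Ordinary least squares of the fitness effect \eqn{s = y_i - y} on the
#' background fitness \eqn{y}. The directed variance fraction is estimated
#' as \eqn{\hat{\tilde v} = -\mathrm{slope}/2}. Residuals are computed as
#' \eqn{(y_i + c_i y) - \overline{(y_i + c_i y)}} with
#' \eqn{c_i = 2\hat{\tilde v} - 1}, which is algebraically identical to the
#' OLS residuals of the \eqn{s}-on-\eqn{y} fit.
#'
#' @param panel a [MutationPanel-class].
#' @param mutation mutation id or column index.
#' @param normalization `"population"` (divide by n; preserves the exact
#'   subcube identities) or `"sample"` (divide by n-1).
#' @return list with `slope`, `intercept`, `vTildeHat`, `residuals` (named
#'   by background id), `residualVariance`, and `n`.
#' @export
fitMutation <- function(panel, mutation,
                        normalization = c("population", "sample")) {
  normalization <- match.arg(normalization)
  p <- .panelPairs(panel, mutation)
  if (length(p$y) < 2L) stop("need at least 2 backgrounds")
  s <- p$yi - p$y
  vy <- .mom(p$y, normalization = normalization)
  if (vy == 0) {
    warning("constant background fitness; slope undefined")
    return(list(slope = NA_real_, intercept = NA_real_, vTildeHat = NA_real_,
                residuals = setNames(rep(NA_real_, length(s)), p$id),
                residualVariance = NA_real_, n = length(s)))
  }
  slope <- .mom(p$y, s, normalization) / vy
  intercept <- mean(s) - slope * mean(p$y)
  vTilde <- -slope / 2
  ci <- 2 * vTilde - 1
  r <- (p$yi + ci * p$y) - mean(p$yi + ci * p$y)
  den <- if (normalization == "population") length(s) else length(s) - 1L
  list(slope = slope, intercept = intercept, vTildeHat = vTilde,
       residuals = setNames(r, p$id),
       residualVariance = sum(r^2) / den, n = length(s))
}

#' Variance-fraction estimate from concatenated correlation
#'
#' Estimates the (symmetric) variance fraction of a mutation as
#' \eqn{\hat v = (1 - \hat\rho)/2}, where \eqn{\hat\rho} is the Pearson
#' correlation between the concatenations \eqn{(y_i \oplus y)} and
#' \eqn{(y \oplus y_i)} of the mutant and background fitness vectors. On a
#' panel containing the full genotype subcube this equals the exact VF.
#'
#' @inheritParams fitMutation
#' @return the estimate \eqn{\hat v}.
#' @export
estimateVFConcat <- function(panel, mutation) {
  p <- .panelPairs(panel, mutation)
  if (length(p$y) < 2L) stop("need at least 2 backgrounds")
  a <- c(p$yi, p$y)
  b <- c(p$y, p$yi)
  if (var(a) == 0 || var(b) == 0)
    stop("zero variance in concatenated fitness vectors")
  (1 - cor(a, b)) / 2
}

#' Estimate the additivity of interacting loci from a panel
#'
#' Uses the covariance form
#' \eqn{\widehat{\mathrm{AoIL}} = |\mathrm{Cov}(s, y_i + y)| /
#' (|\mathrm{Cov}(s, y_i + y)| + \mathrm{Var}(s))}, which on a full directed
#' subcube equals the coefficient-level AoIL.
#'
#' @inheritParams fitMutation
#' @return estimate in \eqn{[0, 1]}; the degenerate all-zero case returns 0
#'   with a warning.
#' @export
estimateAoil <- function(panel, mutation,
                         normalization = c("population", "sample")) {
  normalization <- match.arg(normalization)
  p <- .panelPairs(panel, mutation)
  if (length(p$y) < 2L) stop("need at least 2 backgrounds")
  s <- p$yi - p$y
  # a (relatively) constant effect leaves the 0/0 ratio of the degenerate
  # case, with both moments at rounding scale
  if (max(s) - min(s) <= 1e-9 * max(abs(s), abs(p$y), 1e-300)) {
    warning("degenerate AoIL (constant effect); returning 0")
    return(0)
  }
  cv <- abs(.mom(s, p$yi + p$y, normalization))
  vs <- .mom(s, normalization = normalization)
  cv / (cv + vs)
}

#' Estimate the additivity of the mutated locus from a panel
#'
#' The additive effect is estimated as \eqn{\hat f = \overline{s}/2} and the
#' summed squared epistatic terms as \eqn{\mathrm{Var}(s)/4}, giving
#' \eqn{\hat f^2 / (\hat f^2 + \mathrm{Var}(s)/4)}.
#'
#' @inheritParams fitMutation
#' @return estimate in \eqn{[0, 1]}; `NaN` with a warning when both terms
#'   vanish.
#' @export
estimateAdditivity <- function(panel, mutation,
                               normalization = c("population", "sample")) {
  normalization <- match.arg(normalization)
  p <- .panelPairs(panel, mutation)
  if (length(p$y) < 2L) stop("need at least 2 backgrounds")
  s <- p$yi - p$y
  fhat2 <- (mean(s) / 2)^2
  epi <- .mom(s, normalization = normalization) / 4
  if (fhat2 + epi == 0) {
    warning("all-zero effect; additivity undefined")
    return(NaN)
  }
  fhat2 / (fhat2 + epi)
}

#' Fit every mutation of a panel
#'
#' Runs [fitMutation()], [estimateVFConcat()], [estimateAoil()] and
#' [estimateAdditivity()] for each mutation and collects the results.
#'
#' @inheritParams fitMutation
#' @return a [GlobalEpistasisFit-class].
#' @export
fitPanel <- function(panel, normalization = c("population", "sample")) {
  normalization <- match.arg(normalization)
  ids <- mutationIds(panel)
  rows <- vector("list", length(ids))
  res <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    ft <- fitMutation(panel, ids[k], normalization)
    rows[[k]] <- data.frame(
      mutation = ids[k],
      locus = panel@loci[k],
      direction = panel@direction[k],
      n = ft$n,
      slope = ft$slope,
      intercept = ft$intercept,
      vTildeHat = ft$vTildeHat,
      vHat = estimateVFConcat(panel, ids[k]),
      aoilHat = suppressWarnings(estimateAoil(panel, ids[k], normalization)),
      additivityHat = suppressWarnings(
        estimateAdditivity(panel, ids[k], normalization)),
      residualVariance = ft$residualVariance)
    res[[k]] <- ft$residuals
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  names(res) <- ids
  new("GlobalEpistasisFit", stats = stats, residuals = res,
      normalization = normalization)
}

#' @describeIn fitPanel per-mutation summary table.
#' @param fit a `GlobalEpistasisFit`.
#' @export
fitStats <- function(fit) fit@stats

#' @describeIn fitPanel named list of per-mutation residual vectors.
#' @export
fitResiduals <- function(fit) fit@residuals

setMethod("show", "GlobalEpistasisFit", function(object) {
  st <- object@stats
  cat("GlobalEpistasisFit for", nrow(st), "mutations (",
      object@normalization, "normalization )\n")
  cat("  vTildeHat: median", format(stats::median(st$vTildeHat), digits = 3),
      " range [", format(min(st$vTildeHat), digits = 3), ",",
      format(max(st$vTildeHat), digits = 3), "]\n")
  cat("  negative slopes:", sum(st$slope < 0), "/", nrow(st), "\n")
})

#' Residual variance versus the global-epistasis prediction
#'
#' Regresses the per-mutation residual variance on
#' \eqn{\hat{\tilde v}(1-\hat{\tilde v})}. In the widespread-epistasis limit
#' the residual variance is proportional to this quantity (for the
#' symmetric flip case, exactly \eqn{4 v(1-v) V}), so the relation should
#' be linear through the origin. Mutations with estimated AoIL at or above
#' `aoilThreshold` can be excluded, since only small-AoIL loci are
#' guaranteed to follow the negative-trend regime.
#'
#' @param fit a [GlobalEpistasisFit-class].
#' @param aoilThreshold retain mutations with `aoilHat` below this value.
#' @param applyFilter whether to apply the AoIL filter.
#' @return list with `slope`, `intercept`, `rSquared`, `n`.
#' @export
residualVarianceRelation <- function(fit, aoilThreshold = 0.5,
                                     applyFilter = TRUE) {
  st <- fit@stats
  keep <- if (applyFilter) st$aoilHat < aoilThreshold else rep(TRUE, nrow(st))
  keep <- keep & is.finite(st$vTildeHat) & is.finite(st$residualVariance)
  x <- st$vTildeHat[keep] * (1 - st$vTildeHat[keep])
  y <- st$residualVariance[keep]
  if (length(x) < 3L)
    stop("need at least 3 mutations for the relation fit")
  if (var(x) == 0)
    stop("degenerate relation fit: at least 3 distinct v(1-v) values needed")
  m <- lm(y ~ x)
  list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
       rSquared = summary(m)$r.squared, n = length(x))
}

#' Pooled residual-distribution prediction
#'
#' In the widespread-epistasis limit the regression residual of each
#' mutation is Gaussian with variance proportional to
#' \eqn{\hat{\tilde v}(1-\hat{\tilde v})}. The predicted pooled residual
#' sample therefore draws `nDraws` standard normal variables per mutation,
#' scales them by \eqn{\sqrt{\hat{\tilde v}(1-\hat{\tilde v})}}, pools
#' across mutations, and rescales the pool so its variance matches the
#' observed pooled residuals. A two-sample Kolmogorov-Smirnov comparison
#' between observed and predicted pools is attached.
#'
#' @param fit a [GlobalEpistasisFit-class].
#' @param nDraws draws per mutation (default 10000).
#' @return list with `predicted`, `observed`, and `ks` (the `ks.test`
#'   result, `NULL` when either pool is degenerate).
#' @export
pooledResidualPrediction <- function(fit, nDraws = 10000) {
  st <- fit@stats
  w <- sqrt(pmax(st$vTildeHat * (1 - st$vTildeHat), 0))
  predicted <- unlist(lapply(w, function(wi) wi * rnorm(nDraws)),
                      use.names = FALSE)
  observed <- unlist(fit@residuals, use.names = FALSE)
  observed <- observed[is.finite(observed)]
  if (length(predicted) && var(predicted) > 0 && length(observed) > 1 &&
      var(observed) > 0) {
    predicted <- predicted * sqrt(var(observed) / var(predicted))
    ks <- suppressWarnings(ks.test(observed, predicted))
  } else ks <- NULL
  list(predicted = predicted, observed = observed, ks = ks)
}
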