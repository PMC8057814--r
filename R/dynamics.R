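#' SSWM adaptation driven by the analytic DFE
#'
#' Simulates origin-fixation dynamics directly from the analytic
#' distribution of fitness effects, without an explicit landscape: at the
#' current adaptedness \eqn{z} each proposal draws a variance fraction
#' \eqn{v \sim P(v)} and an effect
#' \eqn{\sigma \mid v \sim N(-2vz, 4v)}; beneficial proposals fix with
#' probability \eqn{\min(1, 2\sigma)} and advance \eqn{z} by \eqn{\sigma}.
#' Time is counted in proposals. With an exponential DVF the mean
#' trajectory crosses over, beyond \eqn{z \sim \bar v^{-1/2}}, to the
#' power laws \eqn{z \sim t^{1/5}} and \eqn{n_s \sim t^{2/5}}; a point-mass
#' DVF instead plateaus sharply near \eqn{z \sim \bar v^{-1/2}}.
#'
#' @param dvf a [dvfSpec()].
#' @param nProposals proposals per replicate.
#' @param z0 initial adaptedness.
#' @param replicates number of independent walks.
#' @param fixationScale constant \eqn{C} in \eqn{\min(1, C\sigma)}.
#' @return object of class `analyticTrajectory`: a list with `fixations`
#'   (data.frame: `replicate`, `time`, `sigma`, `v`), `nProposals`, `z0`,
#'   and `replicates`.
#' @seealso [trajectoryGrid()], [powerlawExponent()]
#' @export
sswmAnalytic <- function(dvf, nProposals, z0 = 0, replicates = 1,
                         fixationScale = 2) {
  stopifnot(nProposals >= 1, replicates >= 1)
  kind <- match(dvf$kind, c("exponential", "fixed", "tabulated")) - 1L
  vGrid <- numeric()
  cdfGrid <- numeric()
  if (dvf$kind == "tabulated") {
    vGrid <- dvf$v
    cdfGrid <- cumsum(c(0, diff(vGrid) *
                          (dvf$density[-1] + dvf$density[-length(vGrid)]) / 2))
    cdfGrid <- cdfGrid / cdfGrid[length(cdfGrid)]
  }
  vMax <- if (is.null(dvf$vMax)) 1 else dvf$vMax
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    res <- .cppSswmAnalytic(z0, nProposals, kind, dvf$vBar, vMax,
                            vGrid, cdfGrid, fixationScale)
    out[[r]] <- data.frame(replicate = r, time = res$time,
                           sigma = res$sigma, v = res$v)
  }
  structure(list(fixations = do.call(rbind, out),
                 nProposals = nProposals, z0 = z0, replicates = replicates),
            class = "analyticTrajectory")
}

#' @export
print.analyticTrajectory <- function(x, ...) {
  nf <- nrow(x$fixations) / x$replicates
  cat("Analytic SSWM trajectories:", x$replicates, "replicate(s),",
      format(x$nProposals, scientific = TRUE), "proposals each;",
      format(nf, digits = 4), "fixations/replicate on average\n")
  invisible(x)
}

#' Evaluate analytic trajectories on a time grid
#'
#' Reconstructs adaptedness \eqn{z(t)} and the cumulative number of fixed
#' beneficial mutations \eqn{n_s(t)} at the requested times from the
#' recorded fixation events.
#'
#' @param trajectory an object from [sswmAnalytic()].
#' @param times proposal counts at which to evaluate (default: 30
#'   log-spaced points).
#' @return list with `times`, `z` (replicates x times matrix), and
#'   `nFixed` (same shape).
#' @export
trajectoryGrid <- function(trajectory,
                           times = round(10^seq(0, log10(trajectory$nProposals),
                                                length.out = 30))) {
  times <- sort(unique(pmin(times, trajectory$nProposals)))
  R <- trajectory$replicates
  z <- matrix(trajectory$z0, R, length(times))
  nf <- matrix(0, R, length(times))
  fx <- trajectory$fixations
  for (r in seq_len(R)) {
    d <- fx[fx$replicate == r, , drop = FALSE]
    if (!nrow(d)) next
    idx <- findInterval(times, d$time)
    cz <- cumsum(d$sigma)
    z[r, ] <- trajectory$z0 + c(0, cz)[idx + 1]
    nf[r, ] <- idx
  }
  list(times = times, z = z, nFixed = nf)
}

#' Power-law exponent of a mean trajectory
#'
#' Fits an ordinary least-squares line to \eqn{\log(\bar x)} versus
#' \eqn{\log t} over a time window, where \eqn{\bar x} is the mean over
#' replicates of the supplied curve.
#'
#' @param times vector of times.
#' @param values vector (one curve) or replicates-by-times matrix of
#'   values; the mean curve is fitted.
#' @param window `c(tMin, tMax)` fitting window (default: the last decade).
#' @return list with `exponent`, `stderr`, and `n` (points fitted).
#' @export
powerlawExponent <- function(times, values,
                             window = c(max(times) / 10, max(times))) {
  if (is.matrix(values)) values <- colMeans(values)
  stopifnot(length(values) == length(times))
  keep <- times >= window[1] & times <= window[2] & values > 0 & times > 0
  if (sum(keep) < 2L) stop("fewer than 2 usable points in the fitting window")
  m <- lm(log(values[keep]) ~ log(times[keep]))
  sm <- summary(m)$coefficients
  list(exponent = unname(coef(m)[2]),
       stderr = if (nrow(sm) > 1) sm[2, 2] else NA_real_,
       n = sum(keep))
}
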