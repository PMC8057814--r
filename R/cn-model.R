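#' Sample per-locus pathway sparsities
#'
#' In the connectedness model each locus joins every interaction pathway
#' independently with its own probability \eqn{\mu_i}. Sparsities are drawn
#' from an exponential distribution with mean `muBar`; because \eqn{\mu_i}
#' is a probability, draws above 1 are resampled (at \eqn{\bar\mu = 0.02}
#' this is a ~1e-22 event and numerically irrelevant).
#'
#' @param nLoci number of loci.
#' @param muBar mean sparsity, in (0, 1).
#' @return numeric vector of \eqn{\mu_i} values in \eqn{[0, 1]}.
#' @export
sampleMu <- function(nLoci, muBar) {
  if (!is.finite(muBar) || muBar <= 0 || muBar >= 1)
    stop("muBar must lie in (0, 1)")
  mu <- rexp(nLoci, rate = 1 / muBar)
  while (any(bad <- mu > 1)) mu[bad] <- rexp(sum(bad), rate = 1 / muBar)
  mu
}

#' Generate a connectedness-model fitness landscape
#'
#' Builds a sparse Fourier landscape from `nPathways` independent pathways.
#' Each locus joins each pathway with probability \eqn{\mu_i}; all loci in a
#' pathway interact at every order, i.e. every non-empty subset of the
#' pathway members (up to `maxOrder`) receives an independent standard
#' normal coefficient. Contributions from all pathways are summed per
#' subset, and with `normalize = TRUE` the coefficients are rescaled so that
#' the total genetic variance \eqn{\sum_S f_S^2} is 1; the baseline is 0.
#'
#' For large \eqn{\ell} the resulting variance fraction of locus \eqn{i} is
#' \eqn{v_i \approx \mu_i / (1 + \mu_i)}, so an exponential sparsity
#' distribution produces an approximately exponential distribution of
#' variance fractions with mean \eqn{\approx \bar\mu/(1+\bar\mu)}.
#'
#' @param nLoci number of loci \eqn{\ell} (reference scale: 400).
#' @param nPathways number of pathways \eqn{M} (reference scale: 500).
#' @param muBar mean sparsity for exponentially distributed \eqn{\mu_i}
#'   (reference scale: 0.02, so that \eqn{\bar\mu\ell = 8} gives widespread
#'   epistasis); ignored when `mu` is supplied.
#' @param mu optional explicit vector of per-locus sparsities in
#'   \eqn{[0, 1]}.
#' @param maxOrder cap on interaction order: pathways larger than this are
#'   truncated to subsets of at most `maxOrder` loci, with a warning.
#' @param normalize rescale coefficients to unit total variance.
#' @return a [FourierLandscape-class] with attribute-free slots plus the
#'   drawn sparsities retrievable via `attr(, "mu")`.
#' @examples
#' set.seed(1)
#' ls <- cnLandscape(20, nPathways = 50, muBar = 0.1)
#' totalVariance(ls)
#' @export
cnLandscape <- function(nLoci, nPathways, muBar = 0.02, mu = NULL,
                        maxOrder = 12L, normalize = TRUE) {
  nLoci <- as.integer(nLoci)
  nPathways <- as.integer(nPathways)
  if (nLoci < 1L || nPathways < 1L) stop("nLoci and nPathways must be >= 1")
  if (maxOrder < 1L) stop("maxOrder must be >= 1")
  if (is.null(mu)) {
    mu <- sampleMu(nLoci, muBar)
  } else {
    if (length(mu) != nLoci || any(mu < 0 | mu > 1))
      stop("explicit mu must have length nLoci with entries in [0, 1]")
  }
  termList <- vector("list", nPathways)
  coefList <- vector("list", nPathways)
  truncated <- 0L
  for (m in seq_len(nPathways)) {
    members <- which(runif(nLoci) < mu)
    n <- length(members)
    if (n == 0L) {
      termList[[m]] <- list()
      coefList[[m]] <- numeric()
      next
    }
    if (n > maxOrder) truncated <- truncated + 1L
    kMax <- min(n, maxOrder)
    subs <- vector("list", kMax)
    for (k in seq_len(kMax)) {
      cm <- combn(members, k)
      subs[[k]] <- lapply(seq_len(ncol(cm)), function(jj) cm[, jj])
    }
    subs <- do.call(c, subs)
    termList[[m]] <- subs
    coefList[[m]] <- rnorm(length(subs))
  }
  if (truncated > 0L)
    warning(truncated, " pathway(s) larger than maxOrder = ", maxOrder,
            "; interactions truncated to subsets of at most that size")
  terms <- do.call(c, termList)
  coefs <- unlist(coefList)
  if (length(terms) == 0L)
    stop("no pathway recruited any locus; increase muBar, nLoci or nPathways")
  # a subset reached through several pathways keeps one entry whose
  # coefficient is the sum of the pathway contributions
  keys <- vapply(terms, paste, "", collapse = ",")
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  f <- as.vector(rowsum(coefs, idx, reorder = TRUE))
  terms <- terms[first]
  if (normalize) f <- f / sqrt(sum(f^2))
  out <- fourierLandscape(nLoci, baseline = 0, terms = terms, coef = f)
  attr(out, "mu") <- mu
  out
}

#' Theoretical variance fraction of a connectedness-model locus
#'
#' For a locus with sparsity \eqn{\mu} the model predicts
#' \eqn{v = \mu/(1+\mu)} when the number of loci is large (`"large_l"`), and
#' \eqn{v = \mu/(\bar\mu \ell)} in the few-locus regime (`"small_l"`). The
#' maximal-epistasis (House-of-Cards) limit is \eqn{\mu = 1}, giving
#' \eqn{v = 1/2}.
#'
#' @param mu sparsity value(s) in \eqn{[0, 1]}.
#' @param muBar mean sparsity (required for `"small_l"`).
#' @param nLoci number of loci (required for `"small_l"`).
#' @param regime `"large_l"` (default) or `"small_l"`.
#' @return predicted variance fraction(s).
#' @export
theoreticalVF <- function(mu, muBar = NULL, nLoci = NULL,
                          regime = c("large_l", "small_l")) {
  regime <- match.arg(regime)
  if (any(mu < 0 | mu > 1)) stop("mu must lie in [0, 1]")
  if (regime == "large_l") return(mu / (1 + mu))
  if (is.null(muBar) || is.null(nLoci) || muBar * nLoci == 0)
    stop("small_l regime requires muBar and nLoci with muBar * nLoci > 0")
  mu / (muBar * nLoci)
}
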