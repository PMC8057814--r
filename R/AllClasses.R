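#' Sparse Fourier representation of a genotype-fitness map
#'
#' A `FourierLandscape` stores a genotype-fitness map over \eqn{\ell}
#' biallelic loci (alleles coded \eqn{\pm 1}) as a sparse collection of
#' Fourier coefficients: a baseline \eqn{\bar y} (the mean fitness over all
#' \eqn{2^\ell} genotypes) plus one coefficient \eqn{f_S} per non-empty locus
#' subset \eqn{S}. Fitness of a genotype is
#' \eqn{y = \bar y + \sum_S f_S \prod_{i \in S} x_i}.
#'
#' Internally the object also carries a loci-by-terms sparse incidence matrix
#' and a per-locus index of the terms containing each locus, so that single
#' mutation effects cost no more than the number of stored subsets containing
#' the flipped locus.
#'
#' @slot nLoci number of loci \eqn{\ell}.
#' @slot baseline mean fitness \eqn{\bar y} over all genotypes (trait units).
#' @slot terms list of strictly increasing 1-based integer vectors, one per
#'   stored subset.
#' @slot coef numeric vector of coefficients \eqn{f_S}, parallel to `terms`.
#' @slot incidence `nLoci x nTerms` sparse 0/1 incidence matrix.
#' @slot termsByLocus list mapping each locus to the indices of the terms
#'   that contain it.
#'
#' @seealso [fourierLandscape()], [evaluateFitness()], [varianceFraction()]
#' @export
setClass("FourierLandscape",
  representation(
    nLoci = "integer",
    baseline = "numeric",
    terms = "list",
    coef = "numeric",
    incidence = "CsparseMatrix",
    termsByLocus = "list"
  )
)

setValidity("FourierLandscape", function(object) {
  l <- object@nLoci
  if (length(l) != 1L || is.na(l) || l < 1L)
    return("nLoci must be a single positive integer")
  if (length(object@baseline) != 1L || !is.finite(object@baseline))
    return("baseline must be a single finite number")
  if (length(object@terms) != length(object@coef))
    return("terms and coef must have equal length")
  if (!all(is.finite(object@coef)))
    return("coefficients must be finite")
  for (s in object@terms) {
    if (length(s) == 0L) return("empty subset stored; keep the baseline separate")
    if (anyNA(s) || any(s < 1L) || any(s > l))
      return("subset indices out of [1, nLoci]")
    if (is.unsorted(s, strictly = TRUE))
      return("subset indices must be strictly increasing (sorted, duplicate-free)")
  }
  if (anyDuplicated(vapply(object@terms, paste, "", collapse = ",")))
    return("duplicate subsets; coefficients for a repeated subset must be summed")
  TRUE
})

#' Mutant-by-background fitness panel
#'
#' Holds the background fitnesses \eqn{y(g)} of a set of genotypes and the
#' mutant fitnesses \eqn{y_i(g)} obtained by applying each of a set of
#' mutations to each background, the structure of large mutant-by-background
#' fitness assays. Mutant fitness entries may be `NA`; estimators drop the
#' affected (background, mutation) pair only.
#'
#' @slot backgroundId character identifiers of the backgrounds.
#' @slot backgroundFitness numeric background fitnesses \eqn{y(g)}.
#' @slot mutantFitness numeric matrix, backgrounds in rows and mutations in
#'   columns (column names are the mutation identifiers).
#' @slot direction character vector, one entry per mutation: `"directed"`
#'   (a mutation always applied in the same direction, e.g. an insertion) or
#'   `"flip"` (symmetric allele flip relative to the background).
#' @slot loci integer vector of mutated loci (NA when unknown, e.g. panels
#'   read from a file).
#'
#' @seealso [mutationPanel()], [buildPanel()], [synthPanel()], [fitPanel()]
#' @export
setClass("MutationPanel",
  representation(
    backgroundId = "character",
    backgroundFitness = "numeric",
    mutantFitness = "matrix",
    direction = "character",
    loci = "integer"
  )
)

setValidity("MutationPanel", function(object) {
  n <- length(object@backgroundId)
  if (length(object@backgroundFitness) != n)
    return("backgroundFitness length must match backgroundId")
  if (anyDuplicated(object@backgroundId))
    return("duplicate background identifiers")
  if (!all(is.finite(object@backgroundFitness)))
    return("background fitnesses must be finite")
  if (nrow(object@mutantFitness) != n)
    return("mutantFitness must have one row per background")
  if (is.null(colnames(object@mutantFitness)) && ncol(object@mutantFitness) > 0L)
    return("mutantFitness columns must be named by mutation id")
  if (anyDuplicated(colnames(object@mutantFitness)))
    return("duplicate mutation identifiers")
  m <- ncol(object@mutantFitness)
  if (length(object@direction) != m)
    return("direction must have one entry per mutation")
  if (!all(object@direction %in% c("directed", "flip")))
    return("direction entries must be 'directed' or 'flip'")
  if (length(object@loci) != m)
    return("loci must have one entry per mutation (NA allowed)")
  TRUE
})

#' Per-mutation global-epistasis fits for a panel
#'
#' Result container of [fitPanel()]: one row of summary statistics per
#' mutation (regression slope and intercept of effect on background fitness,
#' the directed variance fraction \eqn{\hat{\tilde v} = -\mathrm{slope}/2},
#' the concatenation estimate \eqn{\hat v = (1-\hat\rho)/2}, estimated
#' additivity of interacting loci and additivity, and the residual variance)
#' plus the per-background residual vectors.
#'
#' @slot stats data.frame with columns `mutation`, `locus`, `direction`, `n`,
#'   `slope`, `intercept`, `vTildeHat`, `vHat`, `aoilHat`, `additivityHat`,
#'   `residualVariance`.
#' @slot residuals named list of per-mutation residual vectors (named by
#'   background id).
#' @slot normalization `"population"` or `"sample"` variance normalization.
#' @export
setClass("GlobalEpistasisFit",
  representation(
    stats = "data.frame",
    residuals = "list",
    normalization = "character"
  )
)

setValidity("GlobalEpistasisFit", function(object) {
  need <- c("mutation", "n", "slope", "intercept", "vTildeHat", "vHat",
            "aoilHat", "additivityHat", "residualVariance")
  if (!all(need %in% names(object@stats)))
    return(paste("stats must contain columns:", paste(need, collapse = ", ")))
  if (length(object@residuals) != nrow(object@stats))
    return("one residual vector per mutation required")
  if (!object@normalization %in% c("population", "sample"))
    return("normalization must be 'population' or 'sample'")
  TRUE
})
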