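#' Construct a sparse Fourier fitness landscape
#'
#' @param nLoci number of biallelic loci \eqn{\ell}.
#' @param baseline mean fitness \eqn{\bar y} over all genotypes.
#' @param terms list of integer vectors, each a non-empty set of 1-based
#'   locus indices. Unsorted input is sorted; duplicate subsets are an error
#'   (sum their coefficients first).
#' @param coef numeric coefficients \eqn{f_S}, parallel to `terms`.
#'
#' @return A [FourierLandscape-class] object.
#' @examples
#' # two-locus toy map: y = 1 + 0.5 x1 - 0.3 x2 + 0.2 x1 x2
#' ls <- fourierLandscape(2, 1, list(1, 2, c(1, 2)), c(0.5, -0.3, 0.2))
#' evaluateFitness(ls, c(1, 1))
#' @export
fourierLandscape <- function(nLoci, baseline = 0, terms = list(), coef = numeric()) {
  nLoci <- as.integer(nLoci)
  terms <- lapply(terms, function(s) as.integer(sort(s)))
  coef <- as.numeric(coef)
  for (s in terms) {
    if (length(s) == 0L || anyNA(s) || any(s < 1L) || any(s > nLoci))
      stop("subset indices out of [1, nLoci] (or empty subset)")
  }
  sizes <- lengths(terms)
  inc <- sparseMatrix(
    i = as.integer(unlist(terms)),
    j = rep(seq_along(terms), sizes),
    x = 1,
    dims = c(nLoci, length(terms))
  )
  tbl <- .termsByLocus(terms, nLoci)
  new("FourierLandscape", nLoci = nLoci, baseline = as.numeric(baseline),
      terms = terms, coef = coef, incidence = inc, termsByLocus = tbl)
}

.termsByLocus <- function(terms, nLoci) {
  sizes <- lengths(terms)
  idx <- rep(seq_along(terms), sizes)
  loc <- unlist(terms)
  out <- rep(list(integer()), nLoci)
  if (length(loc)) {
    byl <- split(idx, factor(loc, levels = seq_len(nLoci)))
    out <- lapply(byl, as.integer)
  }
  out
}

#' @describeIn fourierLandscape number of loci.
#' @param object,x a `FourierLandscape`.
#' @export
nLoci <- function(object) {
  stopifnot(is(object, "FourierLandscape"))
  object@nLoci
}

#' @describeIn fourierLandscape baseline (mean) fitness \eqn{\bar y}.
#' @export
baseline <- function(object) {
  stopifnot(is(object, "FourierLandscape"))
  object@baseline
}

#' @describeIn fourierLandscape list of stored locus subsets.
#' @export
landscapeTerms <- function(object) {
  stopifnot(is(object, "FourierLandscape"))
  object@terms
}

#' @describeIn fourierLandscape coefficients \eqn{f_S}, parallel to
#'   `landscapeTerms()`.
#' @export
landscapeCoefs <- function(object) {
  stopifnot(is(object, "FourierLandscape"))
  object@coef
}

#' Total genetic variance of a landscape
#'
#' The variance of fitness over the uniform distribution on all \eqn{2^\ell}
#' genotypes equals \eqn{V = \sum_{S \neq \emptyset} f_S^2}, because the
#' Fourier basis functions \eqn{\prod_{i\in S} x_i} are orthonormal under
#' that distribution.
#'
#' @param landscape a [FourierLandscape-class].
#' @return total genetic variance \eqn{V} (squared trait units).
#' @export
totalVariance <- function(landscape) {
  sum(landscape@coef^2)
}

setMethod("show", "FourierLandscape", function(object) {
  ord <- lengths(object@terms)
  cat("FourierLandscape with", object@nLoci, "loci,",
      length(object@coef), "coefficients\n")
  cat("  baseline:", format(object@baseline), "  total variance:",
      format(totalVariance(object)), "\n")
  if (length(ord)) {
    tab <- table(factor(ord, levels = seq_len(max(ord))))
    cat("  terms by order:", paste(sprintf("%d:%d", seq_along(tab), tab),
                                   collapse = " "), "\n")
  }
})

.checkGenotype <- function(landscape, g) {
  if (is.matrix(g)) {
    if (ncol(g) != landscape@nLoci)
      stop("genotype matrix must have nLoci columns")
    if (!all(g == 1 | g == -1))
      stop("alleles must be -1 or +1")
  } else {
    if (length(g) != landscape@nLoci)
      stop("genotype length must equal nLoci (", landscape@nLoci, ")")
    if (!all(g == 1 | g == -1))
      stop("alleles must be -1 or +1")
  }
  invisible(TRUE)
}

# signs of all stored terms for one genotype: prod_{i in S} x_i, via the
# parity of -1 alleles among the subset members
.termSigns <- function(landscape, g) {
  b <- as.numeric(g == -1)
  par <- as.vector(crossprod(landscape@incidence, b)) %% 2
  1 - 2 * par
}

#' Evaluate fitness of genotypes on a landscape
#'
#' Computes \eqn{y = \bar y + \sum_S f_S \prod_{i\in S} x_i}.
#'
#' @param landscape a [FourierLandscape-class].
#' @param g a genotype: numeric vector of \eqn{\pm 1} alleles of length
#'   `nLoci`, or a matrix with one genotype per row.
#' @return a fitness value, or a vector with one fitness per row of `g`.
#' @export
evaluateFitness <- function(landscape, g) {
  .checkGenotype(landscape, g)
  f <- landscape@coef
  if (!is.matrix(g)) {
    if (!length(f)) return(landscape@baseline)
    return(landscape@baseline + sum(f * .termSigns(landscape, g)))
  }
  n <- nrow(g)
  if (!length(f)) return(rep(landscape@baseline, n))
  out <- numeric(n)
  # chunked so the dense n x nTerms parity block stays small
  chunk <- max(1L, floor(2e7 / max(1L, length(f))))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    b <- (g[rows, , drop = FALSE] == -1) * 1
    par <- as.matrix(b %*% landscape@incidence) %% 2
    out[rows] <- landscape@baseline + as.vector((1 - 2 * par) %*% f)
  }
  out
}

#' Fitness effect of a single mutation
#'
#' The effect of flipping the allele at `locus` on background `g`, keeping
#' all other alleles constant:
#' \eqn{s_i(g) = y(g^{(i)}) - y(g) = -2 \sum_{S \ni i} f_S
#' \prod_{j \in S} x_j}. Only the stored subsets containing `locus` are
#' visited.
#'
#' @inheritParams evaluateFitness
#' @param locus 1-based locus index (vector allowed).
#' @return the fitness effect(s) `s` in trait units.
#' @export
mutationEffect <- function(landscape, g, locus) {
  .checkGenotype(landscape, g)
  locus <- as.integer(locus)
  if (any(locus < 1L | locus > landscape@nLoci)) stop("locus out of range")
  signs <- .termSigns(landscape, g)
  contrib <- landscape@coef * signs
  vapply(locus, function(j) {
    -2 * sum(contrib[landscape@termsByLocus[[j]]])
  }, numeric(1))
}

#' Fitness effects of all possible single mutations on one background
#'
#' @inheritParams evaluateFitness
#' @return numeric vector of length `nLoci`: the effect of flipping each
#'   locus on background `g`.
#' @export
allMutationEffects <- function(landscape, g) {
  .checkGenotype(landscape, g)
  contrib <- landscape@coef * .termSigns(landscape, g)
  -2 * as.vector(landscape@incidence %*% contrib)
}

#' Enumerate all genotypes of a small landscape
#'
#' @param nLoci number of loci (capped to keep \eqn{2^\ell} enumerable).
#' @param cap refuse enumeration beyond this many loci.
#' @return a `2^nLoci x nLoci` matrix of \eqn{\pm 1} alleles.
#' @export
enumerateGenotypes <- function(nLoci, cap = 16L) {
  if (nLoci > cap) stop("refusing to enumerate 2^", nLoci, " genotypes")
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), nLoci), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  m
}

#' Read and write landscapes as JSON
#'
#' The on-disk format is
#' `{"n_loci": int, "baseline": float, "terms": [[[i, j, ...], f], ...]}`
#' with 0-based locus indices. Coefficients are written with full double
#' precision, so a write/read round trip is bit exact.
#'
#' @param path file path.
#' @return `readLandscape` returns a [FourierLandscape-class];
#'   `writeLandscape` returns `path` invisibly.
#' @export
readLandscape <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  terms <- lapply(obj$terms, function(t) as.integer(unlist(t[[1]])) + 1L)
  coef <- vapply(obj$terms, function(t) as.numeric(t[[2]]), numeric(1))
  fourierLandscape(obj$n_loci, obj$baseline, terms, coef)
}

#' @rdname readLandscape
#' @param landscape a [FourierLandscape-class].
#' @export
writeLandscape <- function(landscape, path) {
  # 17 significant digits round-trip IEEE doubles exactly; jsonlite's
  # numeric output does not, so the (simple) document is assembled directly
  num <- function(x) sprintf("%.17g", x)
  entries <- mapply(function(s, f)
    sprintf("[[%s],%s]", paste(s - 1L, collapse = ","), num(f)),
    landscape@terms, landscape@coef)
  json <- sprintf('{"n_loci":%d,"baseline":%s,"terms":[%s]}',
                  landscape@nLoci, num(landscape@baseline),
                  paste(entries, collapse = ","))
  writeLines(json, path)
  invisible(path)
}
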