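#' Variance fractions of loci
#'
#' The variance fraction (VF) of locus \eqn{i} is
#' \eqn{v_i = V_i / V = \sum_{S \ni i} f_S^2 / \sum_{S\neq\emptyset} f_S^2},
#' the fraction of the total genetic variance attributable to all
#' coefficients involving the locus. Over all \eqn{2^\ell} genotypes the
#' regression of the flip effect \eqn{s_i} on background fitness \eqn{y} has
#' slope exactly \eqn{-2 v_i}, so the VF is the landscape-level magnitude of
#' global (diminishing-returns / increasing-costs) epistasis for that locus.
#'
#' @param landscape a [FourierLandscape-class].
#' @param locus 1-based locus index or vector of indices.
#' @return variance fraction(s) in \eqn{[0, 1]}.
#' @export
varianceFraction <- function(landscape, locus) {
  V <- totalVariance(landscape)
  if (V <= 0) stop("zero total genetic variance; variance fractions undefined")
  locus <- .checkLocus(landscape, locus)
  f2 <- landscape@coef^2
  vapply(locus, function(j) sum(f2[landscape@termsByLocus[[j]]]), numeric(1)) / V
}

#' @rdname varianceFraction
#' @return `varianceFractions` returns the VF of every locus.
#' @export
varianceFractions <- function(landscape) {
  V <- totalVariance(landscape)
  if (V <= 0) stop("zero total genetic variance; variance fractions undefined")
  as.vector(landscape@incidence %*% landscape@coef^2) / V
}

.checkLocus <- function(landscape, locus) {
  locus <- as.integer(locus)
  if (anyNA(locus) || any(locus < 1L | locus > landscape@nLoci))
    stop("locus out of range")
  locus
}

# named lookup environment: subset key -> coefficient
.coefLookup <- function(landscape) {
  keys <- vapply(landscape@terms, paste, "", collapse = ",")
  env <- new.env(hash = TRUE, size = max(29L, length(keys)))
  for (k in seq_along(keys)) assign(keys[k], landscape@coef[k], envir = env)
  env
}

.lookupCoef <- function(env, subset) {
  key <- paste(subset, collapse = ",")
  if (exists(key, envir = env, inherits = FALSE))
    get(key, envir = env, inherits = FALSE)
  else 0
}

# For each locus in `loci`, the three sums over non-empty subsets S not
# containing i that enter the directed statistics:
#   epi   = sum_S f_{S u i}^2          (epistatic terms of i)
#   cross = sum_S f_S f_{S u i}        (additive-by-epistatic cross terms)
#   dvar  = sum_S (f_S - f_{S u i})^2  (background variance on the x_i=-1 subcube)
# plus fi, the first-order coefficient of i. Coefficients may be sign-flipped
# at odd orders first (direction reversal).
.directedSums <- function(landscape, loci, flipOdd = FALSE) {
  coef <- landscape@coef
  if (flipOdd) {
    odd <- lengths(landscape@terms) %% 2L == 1L
    coef[odd] <- -coef[odd]
  }
  tmp <- landscape
  tmp@coef <- coef
  env <- .coefLookup(tmp)
  V <- sum(coef^2)
  out <- lapply(loci, function(i) {
    withI <- landscape@termsByLocus[[i]]
    fi <- 0
    epi <- 0
    cross <- 0
    for (t in withI) {
      S <- landscape@terms[[t]]
      fSi <- coef[t]
      if (length(S) == 1L) {
        fi <- fSi
        next
      }
      fS <- .lookupCoef(env, S[S != i])
      epi <- epi + fSi^2
      cross <- cross + fS * fSi
    }
    # background variance of the x_i = -1 subcube, expanded as
    # sum_{S not containing i} (f_S - f_{S u i})^2 = (V - V_i) - 2 cross + epi;
    # subsets with an absent companion enter through V - V_i
    Vi <- sum(coef[withI]^2)
    dvar <- (V - Vi) - 2 * cross + epi
    c(fi = fi, epi = epi, cross = cross, dvar = dvar)
  })
  do.call(rbind, out)
}

#' Directed variance fraction of a locus
#'
#' For a mutation applied in a fixed direction, the regression of its fitness
#' effect on background fitness over the relevant subcube of genotypes has
#' slope \eqn{-2\tilde v_i}, with
#' \deqn{\tilde v_i = \frac{\sum_{S \not\ni i, S\neq\emptyset}
#'   (f_{S\cup i}^2 - f_S f_{S\cup i})}{\sum_{S \not\ni i, S\neq\emptyset}
#'   (f_S - f_{S\cup i})^2}}
#' for the \eqn{-1 \to +1} direction. For the reverse direction the signs of
#' all odd-order coefficients are flipped first. Unlike the symmetric VF,
#' \eqn{\tilde v_i} may be negative.
#'
#' @inheritParams varianceFraction
#' @param direction `"up"` for \eqn{-1 \to +1} (the default convention) or
#'   `"down"` for \eqn{+1 \to -1}.
#' @return directed variance fraction(s); `NaN` with a warning when the
#'   background variance of the subcube is zero.
#' @export
directedVF <- function(landscape, locus, direction = c("up", "down")) {
  direction <- match.arg(direction)
  locus <- .checkLocus(landscape, locus)
  s <- .directedSums(landscape, locus, flipOdd = direction == "down")
  den <- s[, "dvar"]
  num <- s[, "epi"] - s[, "cross"]
  bad <- den == 0
  if (any(bad))
    warning("degenerate background variance on the mutation subcube; ",
            "directed VF undefined for ", sum(bad), " locus/loci")
  out <- num / den
  out[bad] <- NaN
  unname(out)
}

#' Epistatic variance fraction between two loci
#'
#' \eqn{e_{ij} = \sum_{S \supseteq \{i,j\}} f_S^2 / V} for \eqn{i \neq j},
#' the fraction of genetic variance in coefficients coupling both loci; by
#' definition \eqn{e_{ii} = v_i}.
#'
#' @inheritParams varianceFraction
#' @param i,j 1-based locus indices.
#' @export
pairEpistaticVF <- function(landscape, i, j) {
  i <- .checkLocus(landscape, i)
  j <- .checkLocus(landscape, j)
  if (i == j) return(unname(varianceFraction(landscape, i)))
  both <- intersect(landscape@termsByLocus[[i]], landscape@termsByLocus[[j]])
  sum(landscape@coef[both]^2) / totalVariance(landscape)
}

#' Variance fraction of a simultaneous double mutation
#'
#' The regression of the combined effect of flipping loci \eqn{i} and
#' \eqn{j} together on background fitness has slope \eqn{-2 v_{ij}} with
#' \eqn{v_{ij} = v_i + v_j - 2 e_{ij}}: flipping both loci changes the sign
#' of exactly those terms containing an odd number of the two.
#'
#' @inheritParams pairEpistaticVF
#' @export
doubleMutantVF <- function(landscape, i, j) {
  if (i == j) stop("double mutant requires two distinct loci")
  v <- varianceFraction(landscape, c(i, j))
  v[1] + v[2] - 2 * pairEpistaticVF(landscape, i, j)
}

#' Variance fraction of a joint multi-locus flip
#'
#' Treats the simultaneous flip of all loci in `loci` as a single
#' perturbation: terms whose subset overlaps `loci` in an odd number of
#' elements change sign, so the joint VF is the summed squared coefficient of
#' those terms over \eqn{V}.
#'
#' @inheritParams varianceFraction
#' @param loci integer vector of distinct loci.
#' @export
jointVF <- function(landscape, loci) {
  loci <- .checkLocus(landscape, loci)
  if (anyDuplicated(loci)) stop("loci must be distinct")
  b <- numeric(landscape@nLoci)
  b[loci] <- 1
  odd <- as.vector(crossprod(landscape@incidence, b)) %% 2 == 1
  sum(landscape@coef[odd]^2) / totalVariance(landscape)
}

#' @rdname jointVF
#' @param locus a single locus not in `loci`; returns the epistatic VF
#'   between the single flip at `locus` and the joint flip of `loci`
#'   (squared coefficients of terms containing `locus` and overlapping
#'   `loci` oddly, over \eqn{V}).
#' @export
crossEpistaticVF <- function(landscape, locus, loci) {
  locus <- .checkLocus(landscape, locus)
  loci <- .checkLocus(landscape, loci)
  if (locus %in% loci) stop("locus must not be part of the joint flip")
  b <- numeric(landscape@nLoci)
  b[loci] <- 1
  odd <- as.vector(crossprod(landscape@incidence, b)) %% 2 == 1
  withI <- landscape@termsByLocus[[locus]]
  sum(landscape@coef[withI[odd[withI]]]^2) / totalVariance(landscape)
}

#' Additivity of interacting loci (AoIL)
#'
#' Measures how additive the interaction partners of a locus are:
#' \deqn{\mathrm{AoIL}(i) = \frac{|c_i|}{e_i + |c_i|}, \quad
#'   c_i = \sum_{S \not\ni i, S \neq \emptyset} f_S f_{S\cup i}, \quad
#'   e_i = \sum_{S \not\ni i, S \neq \emptyset} f_{S\cup i}^2.}
#' When the AoIL is below 1/2 the directed effect-versus-fitness trend is
#' guaranteed to be negative; above 1/2 either sign can occur. A locus with
#' no epistatic terms gives the degenerate 0/0 case and returns 0 with a
#' warning (its partners are vacuously additive and the numerator vanishes).
#'
#' @inheritParams varianceFraction
#' @return AoIL value(s) in \eqn{[0, 1]}.
#' @export
aoil <- function(landscape, locus) {
  locus <- .checkLocus(landscape, locus)
  s <- .directedSums(landscape, locus)
  num <- abs(s[, "cross"])
  den <- s[, "epi"] + num
  out <- num / den
  bad <- den == 0
  if (any(bad)) {
    warning("locus with no epistatic terms: AoIL 0/0 case, returning 0")
    out[bad] <- 0
  }
  unname(out)
}

#' Additivity of a mutated locus
#'
#' \eqn{\mathrm{Additivity}(i) = f_i^2 / (f_i^2 + \sum_{S\not\ni i,
#' S\neq\emptyset} f_{S\cup i}^2) = f_i^2 / V_i}: the share of the locus'
#' own variance contribution that is additive.
#'
#' @inheritParams varianceFraction
#' @return additivity value(s) in \eqn{[0, 1]}; `NaN` with a warning when
#'   the locus has no nonzero coefficients at all.
#' @export
additivity <- function(landscape, locus) {
  locus <- .checkLocus(landscape, locus)
  f2 <- landscape@coef^2
  firstOrder <- lengths(landscape@terms) == 1L
  out <- vapply(locus, function(i) {
    ti <- landscape@termsByLocus[[i]]
    Vi <- sum(f2[ti])
    if (Vi == 0) return(NaN)
    fi2 <- sum(f2[ti[firstOrder[ti]]])
    fi2 / Vi
  }, numeric(1))
  if (anyNA(out))
    warning("locus with all-zero contribution: additivity undefined")
  out
}

#' Exact per-locus epistasis summary
#'
#' @inheritParams varianceFraction
#' @param loci loci to summarise (default: all).
#' @return data.frame with one row per locus: `locus`, `additive` (the
#'   first-order coefficient \eqn{f_i}), `vf`, `directedVF`, `aoil`,
#'   `additivity`.
#' @export
locusSummary <- function(landscape, loci = seq_len(nLoci(landscape))) {
  loci <- .checkLocus(landscape, loci)
  firstOrder <- lengths(landscape@terms) == 1L
  fi <- vapply(loci, function(i) {
    ti <- landscape@termsByLocus[[i]]
    t1 <- ti[firstOrder[ti]]
    if (length(t1)) landscape@coef[t1[1]] else 0
  }, numeric(1))
  data.frame(
    locus = loci,
    additive = fi,
    vf = varianceFraction(landscape, loci),
    directedVF = suppressWarnings(directedVF(landscape, loci)),
    aoil = suppressWarnings(aoil(landscape, loci)),
    additivity = suppressWarnings(additivity(landscape, loci))
  )
}

#' Brute-force effect-versus-fitness regression by genotype enumeration
#'
#' Enumerates genotypes of a small landscape and regresses the mutation
#' effect at `locus` on background fitness, with population (divide by n)
#' variance normalization. In `"symmetric"` mode all \eqn{2^\ell} genotypes
#' are used and the slope equals \eqn{-2 v_i} exactly, with residual
#' variance \eqn{4 v_i (1 - v_i) V}. In `"directed"` mode only the
#' \eqn{x_i = -1} subcube is used, the slope equals \eqn{-2\tilde v_i}, and
#' the implied additive term
#' \eqn{\bar s + 2\tilde v_i(\bar y - \bar y_{\rm landscape})} equals
#' \eqn{2 f_i (1 - \tilde v_i)}. Serves as the enumeration oracle for the
#' closed-form statistics.
#'
#' @inheritParams varianceFraction
#' @param mode `"symmetric"` or `"directed"`.
#' @param cap refuse enumeration beyond this many loci (default 16).
#' @return list with `slope`, `intercept`, `residualVariance`, `additiveTerm`
#'   (directed mode only), and `n` (number of genotypes used).
#' @export
bruteForceRegression <- function(landscape, locus,
                                 mode = c("symmetric", "directed"),
                                 cap = 16L) {
  mode <- match.arg(mode)
  locus <- .checkLocus(landscape, locus)
  stopifnot(length(locus) == 1L)
  if (landscape@nLoci > cap)
    stop("enumeration capped at ", cap, " loci")
  G <- enumerateGenotypes(landscape@nLoci, cap)
  if (mode == "directed") G <- G[G[, locus] == -1, , drop = FALSE]
  y <- evaluateFitness(landscape, G)
  s <- apply(G, 1L, function(g) mutationEffect(landscape, g, locus))
  n <- length(y)
  vy <- sum((y - mean(y))^2) / n
  if (vy == 0) stop("constant background fitness; regression undefined")
  cov <- sum((y - mean(y)) * (s - mean(s))) / n
  slope <- cov / vy
  intercept <- mean(s) - slope * mean(y)
  resid <- s - (intercept + slope * y)
  out <- list(slope = slope, intercept = intercept,
              residualVariance = sum(resid^2) / n, n = n)
  if (mode == "directed")
    out$additiveTerm <- mean(s) - slope * (mean(y) - landscape@baseline)
  out
}
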