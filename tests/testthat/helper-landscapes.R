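# two-locus toy map used throughout: y = 1 + 0.5 x1 - 0.3 x2 + 0.2 x1 x2
toyMap <- function() {
  fourierLandscape(2, baseline = 1, terms = list(1, 2, c(1, 2)),
                   coef = c(0.5, -0.3, 0.2))
}

# independent oracle: evaluate fitness by the plain definition, without the
# package's incidence-matrix machinery
naiveFitness <- function(nLociV, baselineV, terms, coefs, g) {
  baselineV + sum(vapply(seq_along(terms),
                         function(k) coefs[k] * prod(g[terms[[k]]]),
                         numeric(1)))
}

# random sparse landscape: all first-order terms plus extra higher-order
# subsets, standard-normal-ish coefficients
randomSparseLandscape <- function(nLoci, nExtra = 2 * nLoci, maxOrder = 4,
                                  baseline = 0) {
  terms <- as.list(seq_len(nLoci))
  if (nExtra > 0 && nLoci >= 2) {
    extra <- replicate(nExtra,
      sort(sample.int(nLoci, sample(2:min(maxOrder, nLoci), 1))),
      simplify = FALSE)
    terms <- c(terms, extra)
  }
  keys <- vapply(terms, paste, "", collapse = ",")
  terms <- terms[!duplicated(keys)]
  fourierLandscape(nLoci, baseline, terms, rnorm(length(terms), sd = 0.5))
}

# population OLS of s on y: slope, intercept, residual variance (divide by n)
popOLS <- function(y, s) {
  n <- length(y)
  vy <- sum((y - mean(y))^2) / n
  slope <- sum((y - mean(y)) * (s - mean(s))) / n / vy
  intercept <- mean(s) - slope * mean(y)
  r <- s - intercept - slope * y
  list(slope = slope, intercept = intercept, residualVariance = sum(r^2) / n)
}

# fitness effects of flipping `loci` simultaneously, by direct evaluation
jointFlipEffect <- function(landscape, g, loci) {
  g2 <- g
  g2[loci] <- -g2[loci]
  evaluateFitness(landscape, g2) - evaluateFitness(landscape, g)
}
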