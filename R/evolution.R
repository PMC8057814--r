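# Mutable walk state: current genotype, per-term signed contributions
# (coef * prod x), and current fitness. A proposal at locus j costs only the
# terms containing j; an accepted flip negates those contributions in place.
.walkState <- function(landscape, g) {
  .checkGenotype(landscape, g)
  st <- new.env(parent = emptyenv())
  st$g <- as.numeric(g)
  st$contrib <- landscape@coef * .termSigns(landscape, g)
  st$y <- landscape@baseline + sum(st$contrib)
  st
}

.effectAt <- function(landscape, st, j) {
  -2 * sum(st$contrib[landscape@termsByLocus[[j]]])
}

.applyFlip <- function(landscape, st, j, s) {
  tj <- landscape@termsByLocus[[j]]
  st$contrib[tj] <- -st$contrib[tj]
  st$g[j] <- -st$g[j]
  st$y <- st$y + s
  invisible(st)
}

#' One strong-selection weak-mutation generation
#'
#' A single uniformly random locus is proposed for mutation. Beneficial
#' proposals (\eqn{s > 0}) fix with probability
#' \eqn{\min(1, C s)}; deleterious or neutral proposals are always lost.
#' The default \eqn{C = 2} is the classic SSWM beneficial fixation
#' probability \eqn{\pi \approx 2s}.
#'
#' @param landscape a [FourierLandscape-class].
#' @param g background genotype (\eqn{\pm 1} vector).
#' @param fixationScale the constant \eqn{C} in the acceptance probability.
#' @return list with `genotype` (after the generation) and `record`, a
#'   one-row data.frame with columns `locus`, `effect`, `accepted`,
#'   `fitnessAfter`.
#' @export
sswmGeneration <- function(landscape, g, fixationScale = 2) {
  st <- .walkState(landscape, g)
  j <- sample.int(landscape@nLoci, 1L)
  s <- .effectAt(landscape, st, j)
  accepted <- s > 0 && runif(1) < min(1, fixationScale * s)
  if (accepted) .applyFlip(landscape, st, j, s)
  list(genotype = st$g,
       record = data.frame(locus = j, effect = s, accepted = accepted,
                           fitnessAfter = st$y))
}

.emptyRecords <- function(n) {
  data.frame(generation = integer(n), locus = integer(n),
             effect = numeric(n), accepted = logical(n),
             fitness = numeric(n))
}

#' Simulate an SSWM adaptive walk for a fixed number of generations
#'
#' One mutation is proposed per generation (the proposal count is the
#' clock). Every proposal is recorded, whether or not it fixes.
#'
#' @inheritParams sswmGeneration
#' @param nGenerations number of proposals to simulate.
#' @return list of class `adaptiveWalk` with elements `founder`, `records`
#'   (data.frame: `generation`, `locus`, `effect`, `accepted`, `fitness`
#'   after the proposal), `final` (genotype), `finalFitness`, and
#'   `nFixed`.
#' @export
evolveGenerations <- function(landscape, g, nGenerations, fixationScale = 2) {
  nGenerations <- as.integer(nGenerations)
  stopifnot(nGenerations >= 0L)
  st <- .walkState(landscape, g)
  rec <- .emptyRecords(nGenerations)
  l <- landscape@nLoci
  for (t in seq_len(nGenerations)) {
    j <- sample.int(l, 1L)
    s <- .effectAt(landscape, st, j)
    accepted <- s > 0 && runif(1) < min(1, fixationScale * s)
    if (accepted) .applyFlip(landscape, st, j, s)
    rec$generation[t] <- t
    rec$locus[t] <- j
    rec$effect[t] <- s
    rec$accepted[t] <- accepted
    rec$fitness[t] <- st$y
  }
  structure(list(founder = as.numeric(g), records = rec, final = st$g,
                 finalFitness = st$y, nFixed = sum(rec$accepted),
                 termination = "generations"),
            class = "adaptiveWalk")
}

#' @export
print.adaptiveWalk <- function(x, ...) {
  cat("SSWM adaptive walk:", nrow(x$records), "proposals,", x$nFixed,
      "fixed; final fitness", format(x$finalFitness),
      sprintf("(%s)\n", x$termination))
  invisible(x)
}

#' Evolve a genotype until it reaches a target fitness
#'
#' Repeats SSWM proposals until fitness reaches `targetFitness`, a local
#' optimum is detected (no locus offers a beneficial flip), or
#' `maxProposals` is exhausted. Proposals are recorded as in
#' [evolveGenerations()].
#'
#' @inheritParams evolveGenerations
#' @param targetFitness stop once fitness is at least this value; must
#'   exceed the founder fitness.
#' @param maxProposals proposal budget.
#' @return an `adaptiveWalk` whose `termination` is one of `"target"`,
#'   `"local_optimum"`, `"max_proposals"`.
#' @export
evolveToFitness <- function(landscape, g, targetFitness, maxProposals = 1e6,
                            fixationScale = 2) {
  st <- .walkState(landscape, g)
  if (st$y >= targetFitness)
    stop("founder fitness (", format(st$y), ") already at or above target")
  l <- landscape@nLoci
  recs <- list()
  n <- 0L
  termination <- "max_proposals"
  while (n < maxProposals) {
    n <- n + 1L
    j <- sample.int(l, 1L)
    s <- .effectAt(landscape, st, j)
    accepted <- s > 0 && runif(1) < min(1, fixationScale * s)
    if (accepted) .applyFlip(landscape, st, j, s)
    recs[[n]] <- c(j, s, accepted, st$y)
    if (st$y >= targetFitness) {
      termination <- "target"
      break
    }
    # cheap local-optimum check only occasionally: all effects <= 0
    if (n %% 1000L == 0L && all(allMutationEffects(landscape, st$g) <= 0)) {
      termination <- "local_optimum"
      break
    }
  }
  m <- do.call(rbind, recs)
  rec <- data.frame(generation = seq_len(nrow(m)), locus = as.integer(m[, 1]),
                    effect = m[, 2], accepted = m[, 3] > 0, fitness = m[, 4])
  if (termination == "max_proposals")
    warning("target fitness not reached within ", maxProposals,
            " proposals; returning partial trajectory")
  structure(list(founder = as.numeric(g), records = rec, final = st$g,
                 finalFitness = st$y, nFixed = sum(rec$accepted),
                 termination = termination),
            class = "adaptiveWalk")
}

#' Draw uniformly random genotypes
#'
#' @param n number of genotypes.
#' @param nLoci number of loci.
#' @return an `n x nLoci` matrix of \eqn{\pm 1} alleles.
#' @export
randomGenotypes <- function(n, nLoci) {
  matrix(sample(c(-1, 1), n * nLoci, replace = TRUE), nrow = n)
}

#' Founder-replicate adaptation experiment
#'
#' Evolves `nReplicates` independent SSWM walks from each of `nFounders`
#' uniformly random founder genotypes and summarises the fitness gain per
#' founder at the requested generation checkpoints (mean and standard error
#' over replicates). On landscapes with widespread epistasis the mean gain
#' declines with founder fitness (declining adaptability).
#'
#' @inheritParams evolveGenerations
#' @param nFounders number of founder genotypes.
#' @param nReplicates replicate walks per founder.
#' @param nGenerations total generations per walk.
#' @param checkpoints generations at which gains are reported (subset of
#'   `1:nGenerations`).
#' @return data.frame with columns `founder`, `founderFitness`,
#'   `generation`, `meanGain`, `seGain` (`NA` when `nReplicates == 1`).
#' @export
founderExperiment <- function(landscape, nFounders, nReplicates, nGenerations,
                              checkpoints = nGenerations, fixationScale = 2) {
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (nGenerations > 0 && any(checkpoints < 1L | checkpoints > nGenerations))
    stop("checkpoints must lie in 1..nGenerations")
  founders <- randomGenotypes(nFounders, landscape@nLoci)
  out <- vector("list", nFounders)
  for (i in seq_len(nFounders)) {
    y0 <- evaluateFitness(landscape, founders[i, ])
    gains <- matrix(0, nReplicates, length(checkpoints))
    for (r in seq_len(nReplicates)) {
      if (nGenerations == 0L) break
      w <- evolveGenerations(landscape, founders[i, ], nGenerations,
                             fixationScale)
      gains[r, ] <- w$records$fitness[checkpoints] - y0
    }
    se <- if (nReplicates > 1)
      apply(gains, 2, function(x) stats::sd(x) / sqrt(length(x)))
    else rep(NA_real_, length(checkpoints))
    out[[i]] <- data.frame(founder = i, founderFitness = y0,
                           generation = checkpoints,
                           meanGain = colMeans(gains), seGain = se)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Measure a mutant-by-background fitness panel on a landscape
#'
#' For each background genotype and each locus in `loci`, records the
#' background fitness \eqn{y(g)} and the mutant fitness
#' \eqn{y_i(g) = y(g^{(i)})} obtained by flipping that locus (symmetric
#' "flip" direction).
#'
#' @param landscape a [FourierLandscape-class].
#' @param loci distinct loci to mutate.
#' @param backgrounds matrix of background genotypes (one per row).
#' @return a [MutationPanel-class] with mutation ids `"L<locus>"`.
#' @export
buildPanel <- function(landscape, loci, backgrounds) {
  loci <- .checkLocus(landscape, loci)
  if (anyDuplicated(loci)) stop("loci must be distinct")
  if (!is.matrix(backgrounds)) backgrounds <- matrix(backgrounds, nrow = 1)
  .checkGenotype(landscape, backgrounds)
  n <- nrow(backgrounds)
  y <- evaluateFitness(landscape, backgrounds)
  mf <- matrix(NA_real_, n, length(loci))
  if (length(loci)) colnames(mf) <- paste0("L", loci)
  for (b in seq_len(n)) {
    s <- if (length(loci))
      mutationEffect(landscape, backgrounds[b, ], loci) else numeric()
    mf[b, ] <- y[b] + s
  }
  mutationPanel(backgroundFitness = y, mutantFitness = mf,
                backgroundId = sprintf("g%04d", seq_len(n)),
                direction = rep("flip", length(loci)), loci = loci)
}

#' Evolved backgrounds spanning a range of fitnesses
#'
#' Draws `nFounders` uniformly random genotypes (fitness near the landscape
#' mean) and evolves each of them under SSWM through the increasing fitness
#' targets in `targets`, recording the genotype the first time each target
#' is reached. With the default five targets this yields
#' `nFounders * length(targets)` backgrounds at roughly `length(targets)`
#' fitness levels, the standard design for measuring effect-versus-fitness
#' regressions across a wide fitness range.
#'
#' @inheritParams evolveGenerations
#' @param nFounders number of founder genotypes.
#' @param targets increasing fitness targets.
#' @param maxProposals proposal budget per founder and target.
#' @return list with `genotypes` (matrix, one background per row),
#'   `fitness`, `founder` (founder index per background), and `target`.
#' @export
evolvedBackgrounds <- function(landscape, nFounders = 128, targets = 1:5,
                               maxProposals = 1e6, fixationScale = 2) {
  targets <- sort(targets)
  founders <- randomGenotypes(nFounders, landscape@nLoci)
  G <- matrix(NA_real_, nFounders * length(targets), landscape@nLoci)
  fit <- numeric(nrow(G))
  fidx <- integer(nrow(G))
  tidx <- numeric(nrow(G))
  row <- 0L
  for (i in seq_len(nFounders)) {
    g <- founders[i, ]
    for (k in seq_along(targets)) {
      y <- evaluateFitness(landscape, g)
      if (y < targets[k]) {
        w <- evolveToFitness(landscape, g, targets[k], maxProposals,
                             fixationScale)
        g <- w$final
        y <- w$finalFitness
      }
      row <- row + 1L
      G[row, ] <- g
      fit[row] <- y
      fidx[row] <- i
      tidx[row] <- targets[k]
    }
  }
  list(genotypes = G, fitness = fit, founder = fidx, target = tidx)
}
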