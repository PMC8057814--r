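#' Read and write mutation panels as TSV
#'
#' The panel dialect is a UTF-8 tab-separated table with a header row and
#' columns `background_id`, `background_fitness`, then one column per
#' mutation id holding the mutant fitness on that background. Values use
#' `.` decimals and full double precision (17 significant digits), so a
#' write/read round trip is value exact. Empty cells are read as missing
#' measurements (the estimators drop the affected pair, with a warning at
#' read time). Duplicate background ids are an error.
#'
#' @param path file path.
#' @return `readPanel` returns a [MutationPanel-class]; `writePanel`
#'   returns `path` invisibly.
#' @export
readPanel <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!all(c("background_id", "background_fitness") %in% names(d)))
    stop("malformed panel header: need background_id and background_fitness")
  if (anyDuplicated(d$background_id))
    stop("duplicate background_id in panel file")
  mcols <- setdiff(names(d), c("background_id", "background_fitness"))
  num <- function(x, what) {
    x[x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    if (any(is.na(out) & !is.na(x)))
      stop("non-numeric cell in column ", what)
    out
  }
  y <- num(d$background_fitness, "background_fitness")
  if (anyNA(y)) stop("missing background fitness")
  mf <- vapply(mcols, function(cl) num(d[[cl]], cl), numeric(nrow(d)))
  mf <- matrix(mf, nrow = nrow(d), dimnames = list(NULL, mcols))
  if (anyNA(mf))
    warning(sum(is.na(mf)), " missing mutant-fitness cell(s); ",
            "the affected (background, mutation) pairs are dropped by estimators")
  mutationPanel(backgroundFitness = y, mutantFitness = mf,
                backgroundId = d$background_id, direction = "directed")
}

#' @rdname readPanel
#' @param panel a [MutationPanel-class].
#' @export
writePanel <- function(panel, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  d <- data.frame(background_id = panel@backgroundId,
                  background_fitness = fmt(panel@backgroundFitness),
                  check.names = FALSE)
  for (id in mutationIds(panel)) d[[id]] <- fmt(panel@mutantFitness[, id])
  .writeAtomic(path, function(tmp)
    utils::write.table(d, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

# write via a temporary file in the same directory, then rename
.writeAtomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path)
  invisible(path)
}

#' Generate a synthetic mutant-by-background panel
#'
#' Emulates the structure of large insertion-mutation fitness assays: a set
#' of background genotypes segregating at many loci, a set of mutations at
#' loci that do not segregate among the backgrounds (all backgrounds carry
#' the \eqn{-1} allele there; the mutation sets it to \eqn{+1}, a directed
#' mutation), true fitnesses computed from the landscape, and optional
#' i.i.d. Gaussian measurement noise added to every reported fitness.
#'
#' Background schemes: `"uniform"` draws alleles uniformly at random;
#' `"recombinant"` draws two random parent genotypes and lets every
#' background inherit each locus from either parent independently (a
#' linkage-free cartoon of a two-parent cross: loci where the parents agree
#' do not segregate).
#'
#' With `screenNonzero = TRUE`, candidate mutation loci whose mean absolute
#' noiseless effect across the backgrounds falls below `screenThreshold`
#' are discarded and redrawn, mimicking the selection of assayed mutations
#' for nonzero effect (which biases the recovered VF distribution upwards).
#'
#' @param landscape a [FourierLandscape-class].
#' @param nMutations number of mutations (default 91).
#' @param nBackgrounds number of backgrounds (default 145).
#' @param scheme background generation scheme, `"uniform"` or
#'   `"recombinant"`.
#' @param noiseSd standard deviation of Gaussian measurement noise, in
#'   fitness units.
#' @param screenNonzero screen mutation loci for nonzero effect.
#' @param screenThreshold mean |effect| threshold used by the screen.
#' @param loci optional explicit mutation loci (bypasses screening).
#' @param backgrounds optional explicit background matrix (bypasses the
#'   scheme; alleles at mutation loci are still forced to \eqn{-1}).
#' @return a [MutationPanel-class] with direction `"directed"`.
#' @export
synthPanel <- function(landscape, nMutations = 91, nBackgrounds = 145,
                       scheme = c("uniform", "recombinant"),
                       noiseSd = 0, screenNonzero = FALSE,
                       screenThreshold = 0.05, loci = NULL,
                       backgrounds = NULL) {
  scheme <- match.arg(scheme)
  l <- landscape@nLoci
  if (is.null(loci) && nMutations > l)
    stop("more mutations requested than loci")
  stopifnot(nBackgrounds >= 1, noiseSd >= 0)
  if (is.null(backgrounds)) {
    backgrounds <- switch(scheme,
      uniform = randomGenotypes(nBackgrounds, l),
      recombinant = {
        p1 <- randomGenotypes(1, l)[1, ]
        p2 <- randomGenotypes(1, l)[1, ]
        pick <- matrix(runif(nBackgrounds * l) < 0.5, nBackgrounds, l)
        out <- matrix(rep(p1, each = nBackgrounds), nBackgrounds, l)
        out[pick] <- rep(p2, each = nBackgrounds)[pick]
        out
      })
  } else {
    backgrounds <- as.matrix(backgrounds)
    .checkGenotype(landscape, backgrounds)
    nBackgrounds <- nrow(backgrounds)
  }
  if (is.null(loci)) {
    pool <- seq_len(l)
    if (screenNonzero) {
      # screen on the mean |flip effect| across the (unforced) backgrounds
      S <- vapply(seq_len(nBackgrounds),
                  function(b) allMutationEffects(landscape, backgrounds[b, ]),
                  numeric(l))
      pool <- which(rowMeans(abs(S)) >= screenThreshold)
    }
    if (length(pool) < nMutations)
      stop("screening left fewer than nMutations usable loci; ",
           "lower screenThreshold")
    loci <- sample(pool, nMutations)
  } else {
    loci <- .checkLocus(landscape, loci)
    if (anyDuplicated(loci)) stop("mutation loci must be distinct")
    nMutations <- length(loci)
  }
  # mutated loci do not segregate among the backgrounds: ancestral allele -1
  backgrounds[, loci] <- -1
  y <- evaluateFitness(landscape, backgrounds)
  mf <- matrix(NA_real_, nBackgrounds, nMutations,
               dimnames = list(NULL, paste0("L", loci)))
  for (b in seq_len(nBackgrounds))
    mf[b, ] <- y[b] + mutationEffect(landscape, backgrounds[b, ], loci)
  if (noiseSd > 0) {
    y <- y + rnorm(nBackgrounds, sd = noiseSd)
    mf <- mf + matrix(rnorm(length(mf), sd = noiseSd), nrow = nBackgrounds)
  }
  mutationPanel(backgroundFitness = y, mutantFitness = mf,
                direction = "directed", loci = loci)
}
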