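#' Construct a mutant-by-background fitness panel
#'
#' @param backgroundFitness numeric background fitnesses.
#' @param mutantFitness matrix of mutant fitnesses, backgrounds in rows,
#'   mutations in columns (column names are mutation ids; `NA` entries mark
#'   missing measurements and the affected pair is dropped by estimators).
#' @param backgroundId background identifiers (default `"g0001"`, ...).
#' @param direction per-mutation direction metadata, `"directed"` or
#'   `"flip"`; a single value is recycled.
#' @param loci optional per-mutation mutated locus indices.
#' @return a [MutationPanel-class].
#' @export
mutationPanel <- function(backgroundFitness, mutantFitness,
                          backgroundId = sprintf("g%04d", seq_along(backgroundFitness)),
                          direction = "directed",
                          loci = rep(NA_integer_, ncol(mutantFitness))) {
  mutantFitness <- as.matrix(mutantFitness)
  if (is.null(colnames(mutantFitness)) && ncol(mutantFitness) > 0L)
    colnames(mutantFitness) <- paste0("m", seq_len(ncol(mutantFitness)))
  if (length(direction) == 1L)
    direction <- rep(direction, ncol(mutantFitness))
  new("MutationPanel",
      backgroundId = as.character(backgroundId),
      backgroundFitness = as.numeric(backgroundFitness),
      mutantFitness = mutantFitness,
      direction = as.character(direction),
      loci = as.integer(loci))
}

#' @describeIn mutationPanel mutation identifiers.
#' @param panel a `MutationPanel`.
#' @export
mutationIds <- function(panel) colnames(panel@mutantFitness)

#' @describeIn mutationPanel background fitness vector (named by id).
#' @export
backgroundFitness <- function(panel)
  setNames(panel@backgroundFitness, panel@backgroundId)

#' @describeIn mutationPanel mutant fitness matrix.
#' @export
mutantFitness <- function(panel) panel@mutantFitness

#' @describeIn mutationPanel number of backgrounds.
#' @export
nBackgrounds <- function(panel) length(panel@backgroundFitness)

setMethod("show", "MutationPanel", function(object) {
  nm <- ncol(object@mutantFitness)
  cat("MutationPanel:", length(object@backgroundFitness), "backgrounds x",
      nm, "mutations\n")
  if (nm) cat("  direction:", paste(unique(object@direction), collapse = "/"),
              "  missing cells:", sum(is.na(object@mutantFitness)), "\n")
  cat("  background fitness range: [",
      format(min(object@backgroundFitness)), ", ",
      format(max(object@backgroundFitness)), "]\n", sep = "")
})

# resolve a mutation given by id or index; returns the column index
.panelColumn <- function(panel, mutation) {
  if (is.character(mutation)) {
    j <- match(mutation, mutationIds(panel))
    if (is.na(j)) stop("unknown mutation id: ", mutation)
  } else {
    j <- as.integer(mutation)
    if (j < 1L || j > ncol(panel@mutantFitness)) stop("mutation index out of range")
  }
  j
}

# complete (background, mutation) pairs for one mutation
.panelPairs <- function(panel, mutation) {
  j <- .panelColumn(panel, mutation)
  yi <- panel@mutantFitness[, j]
  keep <- !is.na(yi)
  list(y = panel@backgroundFitness[keep], yi = yi[keep],
       id = panel@backgroundId[keep], j = j)
}
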