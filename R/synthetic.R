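#' Configuration for the synthetic single-cell reference generator
#'
#' @param nTypes number of cell types K.
#' @param nGenes number of genes G.
#' @param cellsPerType cells simulated per type.
#' @param nMarkersPerType marker genes per type (disjoint blocks by default).
#' @param markerFold over-expression factor of a marker gene in its own
#'   type (> 1 for signal; 1 makes all types exchangeable).
#' @param baseMean baseline negative-binomial mean per gene.
#' @param nbDispersion negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2); shared across genes.
#' @param librarySizeCV coefficient of variation of the lognormal per-cell
#'   library-size multiplier.
#' @param overlapFrac fraction of each type's markers shared with the next
#'   type (cyclically); emulates overlapping signatures. 0 = disjoint.
#' @param seed integer RNG seed.
#' @return validated configuration list of class \code{SynthRefConfig}.
#' @export
synthRefConfig <- function(nTypes = 5L, nGenes = 300L, cellsPerType = 100L,
                           nMarkersPerType = 10L, markerFold = 20,
                           baseMean = 5, nbDispersion = 0.1,
                           librarySizeCV = 0.2, overlapFrac = 0,
                           seed = 1L) {
  checkCountScalar(nTypes, "nTypes", 2L)
  checkCountScalar(nGenes, "nGenes")
  checkCountScalar(cellsPerType, "cellsPerType")
  checkCountScalar(nMarkersPerType, "nMarkersPerType")
  checkPositiveScalar(markerFold, "markerFold")
  checkPositiveScalar(baseMean, "baseMean")
  checkPositiveScalar(nbDispersion, "nbDispersion")
  stopIfNot(is.numeric(librarySizeCV) && length(librarySizeCV) == 1L &&
              librarySizeCV >= 0, "'librarySizeCV' must be >= 0")
  stopIfNot(is.numeric(overlapFrac) && length(overlapFrac) == 1L &&
              overlapFrac >= 0 && overlapFrac < 1,
            "'overlapFrac' must lie in [0, 1)")
  stopIfNot(nTypes * nMarkersPerType <= nGenes,
            "nTypes * nMarkersPerType must not exceed nGenes")
  structure(list(nTypes = as.integer(nTypes), nGenes = as.integer(nGenes),
                 cellsPerType = as.integer(cellsPerType),
                 nMarkersPerType = as.integer(nMarkersPerType),
                 markerFold = markerFold, baseMean = baseMean,
                 nbDispersion = nbDispersion, librarySizeCV = librarySizeCV,
                 overlapFrac = overlapFrac, seed = as.integer(seed)),
            class = "SynthRefConfig")
}

# Marker gene indices per type: contiguous disjoint blocks at the start of
# the gene vector, optionally sharing a leading fraction with the previous
# type's block (cyclic) to emulate overlapping signatures.
markerSets <- function(config) {
  K <- config$nTypes; m <- config$nMarkersPerType
  blocks <- lapply(seq_len(K), function(k) ((k - 1L) * m + 1L):(k * m))
  if (config$overlapFrac > 0) {
    nShare <- floor(config$overlapFrac * m)
    if (nShare > 0) {
      for (k in seq_len(K)) {
        prev <- blocks[[if (k == 1L) K else k - 1L]]
        blocks[[k]][seq_len(nShare)] <- prev[seq_len(nShare)]
      }
    }
  }
  blocks
}

#' Simulate a synthetic single-cell reference
#'
#' Draws a cells x genes counts matrix from a negative-binomial model:
#' gene g in type k has mean \code{baseMean * markerFold} if g is a marker
#' of type k and \code{baseMean} otherwise, scaled by a per-cell lognormal
#' library-size multiplier. Overdispersion is shared
#' (\code{variance = mu + nbDispersion * mu^2}). A fixed seed gives
#' bit-identical output (Mersenne-Twister draws under a scoped seed).
#'
#' @param config a configuration from [synthRefConfig()].
#' @return A [RawCounts-class] object with gene ids \code{gene0001, ...}
#'   and cell types \code{type1, ..., typeK}.
#' @examples
#' rc <- simulateReference(synthRefConfig(nTypes = 3, nGenes = 60,
#'                                        cellsPerType = 20, seed = 7))
#' @export
simulateReference <- function(config) {
  stopIfNot(inherits(config, "SynthRefConfig"),
            "'config' must come from synthRefConfig()")
  K <- config$nTypes; G <- config$nGenes; n <- config$cellsPerType
  markers <- markerSets(config)
  geneIds <- sprintf("gene%04d", seq_len(G))
  types <- sprintf("type%d", seq_len(K))
  withSeed(config$seed, {
    counts <- matrix(0L, nrow = K * n, ncol = G)
    cellTypes <- rep(types, each = n)
    size <- 1 / config$nbDispersion
    cv <- config$librarySizeCV
    sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
    for (k in seq_len(K)) {
      muGene <- rep(config$baseMean, G)
      muGene[markers[[k]]] <- config$baseMean * config$markerFold
      libMult <- if (sdlog > 0)
        rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(1, n)
      mu <- outer(libMult, muGene)  # n x G
      rows <- ((k - 1L) * n + 1L):(k * n)
      counts[rows, ] <- matrix(rnbinom(n * G, size = size, mu = mu),
                               nrow = n, ncol = G)
    }
    RawCounts(counts, geneIds, cellTypes)
  })
}

#' Per-type mean expression profiles (signature matrix)
#'
#' Mean log-normalised profile of each cell type, one row per type in
#' \code{typeNames(atlas)} order. This is the signature matrix consumed by
#' the NNLS linear baseline.
#'
#' @param atlas a [ReferenceAtlas-class] object.
#' @return K x G numeric matrix with type names as row names and gene ids
#'   as column names.
#' @export
typeCentroids <- function(atlas) {
  stopIfNot(methods::is(atlas, "ReferenceAtlas"),
            "'atlas' must be a ReferenceAtlas")
  K <- nTypes(atlas)
  out <- matrix(NA_real_, nrow = K, ncol = ncol(atlas@lognorm),
                dimnames = list(atlas@typeNames, atlas@hvgIds))
  for (k in seq_len(K)) {
    idx <- which(atlas@cellTypes == atlas@typeNames[k])
    if (!length(idx))
      stop(sprintf("cell type '%s' has no cells in the atlas",
                   atlas@typeNames[k]), call. = FALSE)
    out[k, ] <- colMeans(atlas@lognorm[idx, , drop = FALSE])
  }
  out
}
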