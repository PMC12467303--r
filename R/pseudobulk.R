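#' Pseudo-bulk simulation configuration
#'
#' Defaults match the study conditions of the simulation protocol:
#' symmetric Dirichlet concentration 1.0 (uniform over the simplex),
#' 2000 cells per pseudo-bulk sample, 5000 training and 500 test samples.
#'
#' @param alpha symmetric Dirichlet concentration (> 0).
#' @param nCells cells mixed into each pseudo-bulk sample.
#' @param nTrain,nTest number of training / test samples.
#' @param seed integer RNG seed; one stream drives proportions and cell
#'   sampling so a single seed fixes the whole dataset.
#' @param latentTruth if TRUE, record the latent Dirichlet draw as ground
#'   truth instead of the realized multinomial fractions (sensitivity mode).
#' @return configuration list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(alpha = 1.0, nCells = 2000L, nTrain = 5000L,
                             nTest = 500L, seed = 1L, latentTruth = FALSE) {
  checkPositiveScalar(alpha, "alpha")
  checkCountScalar(nCells, "nCells")
  checkCountScalar(nTrain, "nTrain")
  checkCountScalar(nTest, "nTest")
  structure(list(alpha = alpha, nCells = as.integer(nCells),
                 nTrain = as.integer(nTrain), nTest = as.integer(nTest),
                 seed = as.integer(seed), latentTruth = isTRUE(latentTruth)),
            class = "SimulationConfig")
}

#' Draw a proportion vector from a symmetric Dirichlet
#'
#' One draw from Dirichlet(alpha, ..., alpha) over K components via
#' normalised gamma variates. alpha = 1 is uniform over the simplex.
#' Consumes the current RNG stream (seed at the caller).
#'
#' @param K number of components (>= 1).
#' @param alpha concentration parameter (> 0).
#' @return numeric vector length K, non-negative, summing to 1.
#' @export
sampleProportions <- function(K, alpha = 1.0) {
  checkCountScalar(K, "K", 1L)
  checkPositiveScalar(alpha, "alpha")
  if (K == 1L) return(1)
  g <- rgamma(K, shape = alpha, rate = 1)
  while (sum(g) == 0) g <- rgamma(K, shape = alpha, rate = 1)  # guard tiny alpha
  g / sum(g)
}

#' Compose one pseudo-bulk sample from a reference atlas
#'
#' Draws per-type cell counts as a single multinomial(nCells, p), samples
#' that many cells with replacement within each type, and averages their
#' log-normalised profiles. The recorded ground truth is the realized
#' fraction (multinomial counts / nCells), since those are the cells the
#' profile was actually built from.
#'
#' @param atlas a [ReferenceAtlas-class] object.
#' @param p proportion vector of length \code{nTypes(atlas)} in
#'   \code{typeNames(atlas)} order.
#' @param nCells total number of cells to mix.
#' @param latentTruth if TRUE, report \code{p} itself as ground truth.
#' @return list with \code{bulk} (numeric length G), \code{pTrue}
#'   (numeric length K) and \code{nCells}.
#' @export
composePseudobulk <- function(atlas, p, nCells = 2000L, latentTruth = FALSE) {
  stopIfNot(methods::is(atlas, "ReferenceAtlas"),
            "'atlas' must be a ReferenceAtlas")
  K <- nTypes(atlas)
  stopIfNot(length(p) == K, "'p' must have one entry per atlas cell type")
  stopIfNot(all(p >= 0) && abs(sum(p) - 1) <= 1e-9,
            "'p' must be a probability vector (sum 1)")
  checkCountScalar(nCells, "nCells")
  for (k in which(p > 0)) {
    if (!any(atlas@cellTypes == atlas@typeNames[k]))
      stop(sprintf("type '%s' has positive weight but no reference cells",
                   atlas@typeNames[k]), call. = FALSE)
  }
  cnt <- as.vector(rmultinom(1, size = nCells, prob = p))
  acc <- numeric(ncol(atlas@lognorm))
  for (k in seq_len(K)) {
    if (cnt[k] == 0L) next
    pool <- which(atlas@cellTypes == atlas@typeNames[k])
    pick <- pool[sample.int(length(pool), cnt[k], replace = TRUE)]
    acc <- acc + colSums(atlas@lognorm[pick, , drop = FALSE])
  }
  list(bulk = acc / nCells,
       pTrue = if (isTRUE(latentTruth)) as.numeric(p) else cnt / nCells,
       nCells = as.integer(nCells))
}

#' Generate a paired train/test pseudo-bulk dataset
#'
#' Draws \code{nTrain + nTest} independent samples from one seeded RNG
#' stream (proportion draw then cell sampling, per sample, in that order),
#' then splits them in generation order: the first \code{nTrain} form the
#' training set. Deterministic given the config seed.
#'
#' @param atlas a [ReferenceAtlas-class] object.
#' @param sim a configuration from [simulationConfig()].
#' @return list with [PseudoBulkDataset-class] elements \code{train} and
#'   \code{test}.
#' @export
generateDataset <- function(atlas, sim = simulationConfig()) {
  stopIfNot(inherits(sim, "SimulationConfig"),
            "'sim' must come from simulationConfig()")
  K <- nTypes(atlas); G <- ncol(atlas@lognorm)
  N <- sim$nTrain + sim$nTest
  withSeed(sim$seed, {
    bulk <- matrix(NA_real_, N, G)
    props <- matrix(NA_real_, N, K)
    for (i in seq_len(N)) {
      p <- sampleProportions(K, sim$alpha)
      s <- composePseudobulk(atlas, p, sim$nCells, sim$latentTruth)
      bulk[i, ] <- s$bulk
      props[i, ] <- s$pTrue
    }
    mk <- function(idx) methods::new("PseudoBulkDataset",
      bulk = bulk[idx, , drop = FALSE], props = props[idx, , drop = FALSE],
      typeNames = atlas@typeNames, hvgIds = atlas@hvgIds,
      config = unclass(sim))
    list(train = mk(seq_len(sim$nTrain)),
         test = mk(sim$nTrain + seq_len(sim$nTest)))
  })
}
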