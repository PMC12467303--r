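#' Reduced CPU-scale study configuration
#'
#' A desk-scale version of the full deconvolution study, sized to run in
#' minutes on one CPU core: the synthetic reference at its default,
#' well-separated setting (5 types, 300 genes, 20-fold markers), 1000
#' training and 100 test pseudo-bulk samples, a T = 200 diffusion
#' schedule, and 50 training epochs. The learning rate is raised to 1e-3
#' (from the full-scale 1e-4) because the optimisation budget is roughly
#' ten times fewer steps; the cosine floor scales with it. The HVG mean
#' window's upper bound is lifted because with only 300 genes the CP10K
#' per-gene means sit far above the genome-scale window the default
#' targets; the dispersion cutoff still applies.
#'
#' @param seed global pipeline seed.
#' @param outDir artifact directory.
#' @param models models to run (default: both denoisers).
#' @return a configuration list for [runPipeline()].
#' @export
reducedStudyConfig <- function(seed = 42L, outDir = tempfile("diffdeconv_reduced_"),
                               models = c("diffformer", "diffmlp")) {
  list(seed = as.integer(seed), outDir = outDir,
       preprocess = list(hvg = list(nTop = 300L, maxMean = Inf)),
       simulation = list(nTrain = 1000L, nTest = 100L),
       schedule = list(nSteps = 200L),
       training = list(lr = 1e-3, etaMin = 1e-5, epochs = 50L),
       models = models)
}
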