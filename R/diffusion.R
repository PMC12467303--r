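#' Build a linear noise schedule
#'
#' beta_t is linearly spaced from \code{betaStart} to \code{betaEnd}
#' inclusive over \code{nSteps} timesteps; alpha_t = 1 - beta_t and
#' alphaBar_t is the running product of alpha. Timesteps are 1-based.
#'
#' @param nSteps number of diffusion timesteps T.
#' @param betaStart,betaEnd first and last noise variances,
#'   0 < betaStart <= betaEnd < 1.
#' @return A [NoiseSchedule-class] object.
#' @examples
#' sch <- makeSchedule(1000)
#' sch@beta[c(1, 1000)]  # 1e-4, 0.02
#' @export
makeSchedule <- function(nSteps = 1000L, betaStart = 1e-4, betaEnd = 0.02) {
  checkCountScalar(nSteps, "nSteps")
  stopIfNot(is.numeric(betaStart) && is.numeric(betaEnd) &&
              betaStart > 0 && betaEnd < 1 && betaStart <= betaEnd,
            "need 0 < betaStart <= betaEnd < 1")
  beta <- if (nSteps == 1L) betaStart else
    seq(betaStart, betaEnd, length.out = nSteps)
  alpha <- 1 - beta
  methods::new("NoiseSchedule", nSteps = as.integer(nSteps), beta = beta,
               alpha = alpha, alphaBar = cumprod(alpha))
}

#' Closed-form forward diffusion
#'
#' Applies the marginal of the Gaussian forward process at timestep t:
#' \code{xt = sqrt(alphaBar_t) * x0 + sqrt(1 - alphaBar_t) * eps}.
#'
#' @param x0 matrix batch x K of clean proportion vectors (a vector is
#'   treated as one row).
#' @param t integer timestep(s) in \code{1..nSteps}; length 1 or batch.
#' @param eps standard-normal noise, same shape as \code{x0}.
#' @param schedule a [NoiseSchedule-class] object.
#' @return matrix of noised vectors, same shape as \code{x0}.
#' @export
forwardNoise <- function(x0, t, eps, schedule) {
  if (is.vector(x0)) x0 <- matrix(x0, nrow = 1)
  if (is.vector(eps)) eps <- matrix(eps, nrow = 1)
  stopIfNot(all(dim(x0) == dim(eps)), "x0 and eps must have the same shape")
  stopIfNot(all(t >= 1 & t <= schedule@nSteps & t == floor(t)),
            sprintf("t must be integer in [1, %d]", schedule@nSteps))
  t <- rep_len(as.integer(t), nrow(x0))
  ab <- schedule@alphaBar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Noise-prediction (denoising score matching) loss
#'
#' Mean squared error between the true injected noise and the denoiser's
#' prediction, averaged over the batch and the K components.
#'
#' @param denoiser a denoiser model (see [diffFormer()], [diffMLP()]) or a
#'   function \code{(xt, t, cond) -> eps} for analytic stubs.
#' @param xt,t,cond,eps the diffusion batch: noisy vectors, timesteps,
#'   conditioning profiles and true noise.
#' @param training logical; forwarded to [predictNoise()].
#' @return non-negative scalar loss.
#' @export
noisePredictionLoss <- function(denoiser, xt, t, cond, eps, training = FALSE) {
  stopIfNot(all(dim(xt) == dim(eps)), "xt and eps must have the same shape")
  pred <- callDenoiser(denoiser, xt, t, cond, training = training)
  stopIfNot(all(dim(pred) == dim(eps)), "denoiser output shape mismatch")
  mean((eps - pred)^2)
}

callDenoiser <- function(denoiser, xt, t, cond, training = FALSE) {
  if (is.function(denoiser)) denoiser(xt, t, cond)
  else predictNoise(denoiser, xt, t, cond, training = training)
}

#' Project a vector onto the probability simplex by clip + renormalise
#'
#' Negative components are clipped to zero and the result rescaled to sum
#' to one. Preserves exact zeros for absent cell types (which a softmax
#' could not). An all-zero vector after clipping falls back to uniform.
#'
#' @param x finite numeric vector.
#' @return numeric vector on the simplex.
#' @examples
#' projectToSimplex(c(-0.1, 0.6, 0.6))  # 0, 0.5, 0.5
#' @export
projectToSimplex <- function(x) {
  stopIfNot(all(is.finite(x)), "projectToSimplex: input must be finite")
  x <- pmax(x, 0)
  s <- sum(x)
  if (s <= 0) rep(1 / length(x), length(x)) else x / s
}

#' Ancestral DDPM sampling conditioned on a bulk profile
#'
#' Standard ancestral sampling of the reverse process: starting from
#' \code{x_T ~ N(0, I)}, iterate for t = T..1
#' \deqn{x_{t-1} = (x_t - \beta_t/\sqrt{1-\bar\alpha_t}\,\epsilon_\theta(x_t,t,c)) / \sqrt{\alpha_t} + \sigma_t z}
#' with \code{z ~ N(0, I)} for t > 1 and \code{z = 0} at t = 1. The
#' reverse-process standard deviation is \code{sigma_t = sqrt(beta_t)}
#' (\code{sigmaStyle = "beta"}) or the posterior variance
#' \code{beta_t * (1 - alphaBar_{t-1}) / (1 - alphaBar_t)}
#' (\code{"betaTilde"}). With \code{nDraws > 1} the raw draws are averaged
#' before the final simplex projection.
#'
#' @param denoiser a denoiser model or a function \code{(xt, t, cond) -> eps}.
#' @param cond conditioning bulk profile, numeric vector length G.
#' @param schedule a [NoiseSchedule-class] object.
#' @param seed integer seed for the sampling randomness (NULL = current
#'   RNG stream).
#' @param nDraws number of independent draws to average.
#' @param sigmaStyle reverse-process variance choice; see Details.
#' @return proportion vector of length K (simplex-valid).
#' @export
ddpmSample <- function(denoiser, cond, schedule, seed = NULL, nDraws = 1L,
                       sigmaStyle = c("beta", "betaTilde")) {
  sigmaStyle <- match.arg(sigmaStyle)
  checkCountScalar(nDraws, "nDraws")
  cond <- as.numeric(cond)
  withSeed(seed, {
    Tn <- schedule@nSteps
    Kdim <- denoiserK(denoiser, cond)
    condM <- matrix(cond, nrow = nDraws, ncol = length(cond), byrow = TRUE)
    x <- matrix(rnorm(nDraws * Kdim), nrow = nDraws)
    for (t in Tn:1) {
      epsHat <- callDenoiser(denoiser, x, rep(t, nDraws), condM)
      if (!all(is.finite(epsHat)) || !all(is.finite(x)))
        stop(sprintf("non-finite values in reverse process at timestep %d", t),
             call. = FALSE)
      b <- schedule@beta[t]; a <- schedule@alpha[t]; ab <- schedule@alphaBar[t]
      x <- (x - (b / sqrt(1 - ab)) * epsHat) / sqrt(a)
      if (t > 1L) {
        sigma <- if (sigmaStyle == "beta") sqrt(b) else
          sqrt(b * (1 - schedule@alphaBar[t - 1L]) / (1 - ab))
        x <- x + sigma * matrix(rnorm(nDraws * Kdim), nrow = nDraws)
      }
    }
    projectToSimplex(colMeans(x))
  })
}

# Work out the proportion dimension K for a denoiser; analytic function
# stubs are probed with a K inferred from a single evaluation.
denoiserK <- function(denoiser, cond) {
  if (is.function(denoiser)) {
    attrK <- attr(denoiser, "K")
    if (!is.null(attrK)) return(as.integer(attrK))
    stop("function denoisers must carry an integer attribute 'K'", call. = FALSE)
  }
  denoiser@config$K
}
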