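#' Accessors for DiffDeconv containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return The slot value; see each class for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("refCounts", function(x) standardGeneric("refCounts"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setGeneric("lognorm", function(x) standardGeneric("lognorm"))
#' @rdname accessors
#' @export
setGeneric("hvgIds", function(x) standardGeneric("hvgIds"))
#' @rdname accessors
#' @export
setGeneric("typeNames", function(x) standardGeneric("typeNames"))
#' @rdname accessors
#' @export
setGeneric("nTypes", function(x) standardGeneric("nTypes"))
#' @rdname accessors
#' @export
setGeneric("bulkMatrix", function(x) standardGeneric("bulkMatrix"))
#' @rdname accessors
#' @export
setGeneric("trueProps", function(x) standardGeneric("trueProps"))

#' @rdname accessors
#' @export
setMethod("refCounts", "RawCounts", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("geneIds", "RawCounts", function(x) x@geneIds)
#' @rdname accessors
#' @export
setMethod("cellTypes", "RawCounts", function(x) x@cellTypes)
#' @rdname accessors
#' @export
setMethod("lognorm", "ReferenceAtlas", function(x) x@lognorm)
#' @rdname accessors
#' @export
setMethod("hvgIds", "ReferenceAtlas", function(x) x@hvgIds)
#' @rdname accessors
#' @export
setMethod("cellTypes", "ReferenceAtlas", function(x) x@cellTypes)
#' @rdname accessors
#' @export
setMethod("typeNames", "ReferenceAtlas", function(x) x@typeNames)
#' @rdname accessors
#' @export
setMethod("nTypes", "ReferenceAtlas", function(x) length(x@typeNames))
#' @rdname accessors
#' @export
setMethod("bulkMatrix", "PseudoBulkDataset", function(x) x@bulk)
#' @rdname accessors
#' @export
setMethod("trueProps", "PseudoBulkDataset", function(x) x@props)
#' @rdname accessors
#' @export
setMethod("typeNames", "PseudoBulkDataset", function(x) x@typeNames)
#' @rdname accessors
#' @export
setMethod("hvgIds", "PseudoBulkDataset", function(x) x@hvgIds)

#' Predict the injected diffusion noise
#'
#' Generic implemented by the denoiser models. Given a batch of noisy
#' proportion vectors, their timesteps and the conditioning bulk profiles,
#' returns the predicted noise (same shape as \code{xt}).
#'
#' @param model a denoiser model object.
#' @param xt numeric matrix batch x K of noisy proportion vectors.
#' @param t integer vector (length batch, or 1 recycled) of timesteps in
#'   \code{1..nSteps}.
#' @param cond numeric matrix batch x G of conditioning bulk profiles.
#' @param training logical; if TRUE dropout is active (consumes RNG).
#' @return numeric matrix batch x K of predicted noise.
#' @export
setGeneric("predictNoise",
  function(model, xt, t, cond, training = FALSE) standardGeneric("predictNoise"))

#' Number of trainable parameters of a denoiser
#'
#' @param model a denoiser model object.
#' @return integer count of scalar trainable parameters.
#' @export
setGeneric("nParams", function(model) standardGeneric("nParams"))
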