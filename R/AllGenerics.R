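#' @include AllClasses.R
NULL

#' Maximum-intensity z-projection
#'
#' @param x an [ImageStack-class].
#' @param channel channel name or index to project.
#' @return numeric matrix (y by x) of per-pixel maxima over z.
#' @export
setGeneric("maxProject", function(x, channel) standardGeneric("maxProject"))

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("zStep", function(x) standardGeneric("zStep"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Accessors for CondensateKit classes
#'
#' `voxels()`, `pixelSize()`, `zStep()` and `channelNames()` extract the
#' corresponding slots of an [ImageStack-class]; `tHalf()`,
#' `mobileFraction()` and `recoveryRate()` extract fitted FRAP kinetics
#' from a [FrapFit-class].
#'
#' @param x an object.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tHalf", function(x) standardGeneric("tHalf"))

#' @rdname accessors
#' @export
setGeneric("mobileFraction", function(x) standardGeneric("mobileFraction"))

#' @rdname accessors
#' @export
setGeneric("recoveryRate", function(x) standardGeneric("recoveryRate"))

#' @rdname accessors
setMethod("voxels", "ImageStack", function(x) x@voxels)

#' @rdname accessors
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @rdname accessors
setMethod("zStep", "ImageStack", function(x) x@zStep)

#' @rdname accessors
setMethod("channelNames", "ImageStack", function(x) x@channelNames)

#' @rdname accessors
setMethod("tHalf", "FrapFit", function(x) x@tHalf)

#' @rdname accessors
setMethod("mobileFraction", "FrapFit", function(x) x@mobileFraction)

#' @rdname accessors
setMethod("recoveryRate", "FrapFit", function(x) x@rate)
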