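#' @import methods
NULL

#' Multi-channel confocal image stack
#'
#' Container for a multi-channel z-stack with physical pixel geometry.
#' Voxels are stored as a 4-dimensional array with axes channel, z, y, x
#' (intensities in arbitrary units, AU), together with the lateral pixel
#' size and the axial step, both in micrometres.
#'
#' @slot voxels numeric 4-d array, dimensions C x Z x Y x X, all values >= 0.
#' @slot pixelSize lateral pixel size in micrometres per pixel.
#' @slot zStep axial step between slices in micrometres.
#' @slot channelNames character vector of length C naming the channels.
#'
#' @seealso [imageStack()] for the user-facing constructor,
#'   [maxProject()] for z-projection.
#' @export
setClass("ImageStack",
    slots = c(
        voxels = "array",
        pixelSize = "numeric",
        zStep = "numeric",
        channelNames = "character"
    )
)

setValidity("ImageStack", function(object) {
    msg <- character()
    d <- dim(object@voxels)
    if (length(d) != 4L)
        msg <- c(msg, "'voxels' must have 4 axes (C, Z, Y, X)")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be a single positive number")
    if (length(object@zStep) != 1L || !is.finite(object@zStep) ||
        object@zStep <= 0)
        msg <- c(msg, "'zStep' must be a single positive number")
    if (length(d) == 4L && length(object@channelNames) != d[1L])
        msg <- c(msg, "'channelNames' length must equal the channel axis")
    if (anyNA(object@voxels) || any(object@voxels < 0))
        msg <- c(msg, "voxel intensities must be non-negative and non-NA")
    if (length(msg)) msg else TRUE
})

#' Construct an ImageStack
#'
#' @param voxels 4-d numeric array with axes channel, z, y, x.
#' @param pixelSize lateral pixel size (micrometres/pixel).
#' @param zStep axial step (micrometres).
#' @param channelNames channel names; defaults to `"ch1"`, `"ch2"`, ...
#' @return An [ImageStack-class] object.
#' @examples
#' v <- array(0, dim = c(2, 3, 8, 8))
#' imageStack(v, pixelSize = 0.067, zStep = 0.21,
#'            channelNames = c("dapi", "green"))
#' @export
imageStack <- function(voxels, pixelSize, zStep,
                       channelNames = paste0("ch", seq_len(dim(voxels)[1L]))) {
    new("ImageStack", voxels = voxels, pixelSize = pixelSize,
        zStep = zStep, channelNames = channelNames)
}

#' @describeIn ImageStack compact description of geometry and channels
#' @param object an `ImageStack`
#' @export
setMethod("show", "ImageStack", function(object) {
    d <- dim(object@voxels)
    cat("ImageStack:", d[1L], "channel(s) x", d[2L], "z x",
        d[3L], "y x", d[4L], "x\n")
    cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
    cat(sprintf("  pixel size: %g um/px, z-step: %g um\n",
                object@pixelSize, object@zStep))
})

#' FRAP recovery trace
#'
#' A bleached-region and reference-region intensity time series from a
#' fluorescence recovery after photobleaching (FRAP) experiment. The first
#' `nPreFrames` frames precede the (instantaneous) bleach event; frame
#' `nPreFrames + 1` is the first post-bleach frame.
#'
#' @slot times numeric, ascending acquisition times in seconds.
#' @slot bleached mean intensity of the bleached region per frame (AU).
#' @slot reference mean intensity of an unbleached reference region per
#'   frame (AU); must be strictly positive.
#' @slot nPreFrames integer >= 1, number of pre-bleach frames.
#' @seealso [recoveryTrace()], [normalizeTrace()], [fitRecovery()]
#' @export
setClass("RecoveryTrace",
    slots = c(
        times = "numeric",
        bleached = "numeric",
        reference = "numeric",
        nPreFrames = "integer"
    )
)

setValidity("RecoveryTrace", function(object) {
    msg <- character()
    n <- length(object@times)
    if (length(object@bleached) != n || length(object@reference) != n)
        msg <- c(msg, "'times', 'bleached' and 'reference' must have equal length")
    if (n > 1L && any(diff(object@times) <= 0))
        msg <- c(msg, "'times' must be strictly ascending")
    if (any(!is.finite(object@reference)) || any(object@reference <= 0))
        msg <- c(msg, "'reference' must be positive at every frame")
    if (length(object@nPreFrames) != 1L || object@nPreFrames < 1L)
        msg <- c(msg, "'nPreFrames' must be a single integer >= 1")
    if (object@nPreFrames >= n)
        msg <- c(msg, "'nPreFrames' must leave at least one post-bleach frame")
    if (length(msg)) msg else TRUE
})

#' Construct a RecoveryTrace
#'
#' @param times acquisition times in seconds (ascending).
#' @param bleached bleached-region mean intensities (AU).
#' @param reference reference-region mean intensities (AU, > 0).
#' @param nPreFrames number of pre-bleach frames (>= 1).
#' @return A [RecoveryTrace-class] object.
#' @export
recoveryTrace <- function(times, bleached, reference, nPreFrames) {
    new("RecoveryTrace", times = as.numeric(times),
        bleached = as.numeric(bleached), reference = as.numeric(reference),
        nPreFrames = as.integer(nPreFrames))
}

#' @describeIn RecoveryTrace brief summary
#' @param object a `RecoveryTrace`
#' @export
setMethod("show", "RecoveryTrace", function(object) {
    cat("RecoveryTrace:", length(object@times), "frames (",
        object@nPreFrames, "pre-bleach ),",
        sprintf("t = %g..%g s\n", min(object@times), max(object@times)))
})

#' Double-normalized FRAP trace
#'
#' The result of [normalizeTrace()]: the bleached/reference intensity
#' ratio rescaled so that the mean pre-bleach level is exactly 1.
#'
#' @slot times acquisition times in seconds.
#' @slot values normalized intensities (pre-bleach mean = 1).
#' @slot nPreFrames number of pre-bleach frames.
#' @export
setClass("NormalizedTrace",
    slots = c(times = "numeric", values = "numeric", nPreFrames = "integer")
)

setValidity("NormalizedTrace", function(object) {
    if (length(object@times) != length(object@values))
        return("'times' and 'values' must have equal length")
    TRUE
})

#' @describeIn NormalizedTrace brief summary
#' @param object a `NormalizedTrace`
#' @export
setMethod("show", "NormalizedTrace", function(object) {
    cat("NormalizedTrace:", length(object@times), "frames,",
        object@nPreFrames, "pre-bleach; pre mean =",
        format(mean(object@values[seq_len(object@nPreFrames)])), "\n")
})

#' Single-exponential FRAP fit
#'
#' Parameters of the recovery model
#' \deqn{F(t') = F_\infty - (F_\infty - F_0)\,e^{-k t'}}
#' fitted to a double-normalized trace, with the first post-bleach value
#' fixed as \eqn{F_0}. Half-time is \eqn{t_{1/2} = \ln 2 / k} and the
#' mobile fraction (percent of the reference signal) is
#' \eqn{100\,(F_\infty - F_0)/(F_{pre} - F_0)} with \eqn{F_{pre} = 1}.
#'
#' @slot tHalf recovery half-time in seconds.
#' @slot mobileFraction mobile fraction in percent (not clamped to
#'   \[0, 100\]; see `qualityFlag`).
#' @slot rate exponential recovery rate k (1/s).
#' @slot fPre normalized pre-bleach level (1 after double normalization).
#' @slot f0 first post-bleach normalized value (fixed, not fitted).
#' @slot fInf fitted plateau.
#' @slot rss residual sum of squares of the fit.
#' @slot qualityFlag character; `"ok"` or a note such as
#'   `"mobile_fraction_out_of_range"`.
#' @export
setClass("FrapFit",
    slots = c(
        tHalf = "numeric", mobileFraction = "numeric", rate = "numeric",
        fPre = "numeric", f0 = "numeric", fInf = "numeric",
        rss = "numeric", qualityFlag = "character"
    )
)

setValidity("FrapFit", function(object) {
    msg <- character()
    if (!is.finite(object@rate) || object@rate <= 0)
        msg <- c(msg, "'rate' must be positive")
    if (abs(object@tHalf - log(2) / object@rate) >
        1e-8 * max(1, object@tHalf))
        msg <- c(msg, "'tHalf' must equal ln(2)/rate")
    if (length(msg)) msg else TRUE
})

#' @describeIn FrapFit print fitted kinetics
#' @param object a `FrapFit`
#' @export
setMethod("show", "FrapFit", function(object) {
    cat(sprintf(
        "FrapFit: t1/2 = %.3f s, mobile fraction = %.2f%% (k = %.4f 1/s)\n",
        object@tHalf, object@mobileFraction, object@rate))
    if (!identical(object@qualityFlag, "ok"))
        cat("  flag:", object@qualityFlag, "\n")
})

#' Linear standard-curve fit
#'
#' Ordinary least-squares line of band intensity (AU) on concentration
#' (micromolar), used for densitometry-based concentration estimation.
#'
#' @slot slope AU per micromolar.
#' @slot intercept AU at zero concentration.
#' @slot rSquared coefficient of determination.
#' @slot residualSd residual standard deviation (AU).
#' @slot n number of standard points.
#' @slot meanConc mean of the standard concentrations (for prediction SE).
#' @slot sxx centred sum of squares of the standard concentrations.
#' @export
setClass("LineFit",
    slots = c(
        slope = "numeric", intercept = "numeric", rSquared = "numeric",
        residualSd = "numeric", n = "integer", meanConc = "numeric",
        sxx = "numeric"
    )
)

setValidity("LineFit", function(object) {
    msg <- character()
    if (!is.finite(object@slope))
        msg <- c(msg, "'slope' must be finite")
    if (is.finite(object@rSquared) &&
        (object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8))
        msg <- c(msg, "'rSquared' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn LineFit print the fitted calibration line
#' @param object a `LineFit`
#' @export
setMethod("show", "LineFit", function(object) {
    cat(sprintf(
        "LineFit: intensity = %.4g * conc + %.4g (R^2 = %.4f, n = %d)\n",
        object@slope, object@intercept, object@rSquared, object@n))
})
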