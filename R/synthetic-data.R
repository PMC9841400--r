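#' @include AllClasses.R utils.R
NULL

#' Specification for a synthetic nuclear-foci field
#'
#' Describes a two-channel confocal z-stack (nuclear stain + green foci
#' channel) containing `nNuclei` non-overlapping nuclei, each with a
#' requested number of diffraction-limited fluorescent puncta over a
#' diffuse nucleoplasmic background. Defaults follow the acquisition
#' geometry used for focus counting (0.067 um/pixel laterally, 0.21 um
#' z-step).
#'
#' @param fieldShape integer c(y, x) image size in pixels.
#' @param nZ number of z slices.
#' @param pixelSize lateral pixel size, um/pixel.
#' @param zStepUm axial step, um.
#' @param nNuclei number of nuclei to place.
#' @param nucleusRadius nucleus radius, um.
#' @param fociPerNucleus integer vector of length `nNuclei`: ground-truth
#'   focus count per nucleus.
#' @param focusSigma lateral Gaussian width of a focus, um. The axial
#'   width is fixed at twice the lateral width (confocal axial
#'   elongation).
#' @param focusAmplitude peak focus amplitude above the nucleoplasm (AU).
#' @param nucleoplasmLevel diffuse intensity inside nuclei (AU); also
#'   used as the nuclear-stain level.
#' @param backgroundLevel extranuclear background (AU).
#' @param readNoiseSd additive Gaussian read-noise SD (AU).
#' @param shotNoise logical; apply Poisson shot noise before read noise.
#' @param seed integer RNG seed.
#' @return a validated list of class `"FociFieldSpec"`.
#' @export
fociFieldSpec <- function(fieldShape = c(256L, 256L), nZ = 9L,
                          pixelSize = 0.067, zStepUm = 0.21,
                          nNuclei = 2L, nucleusRadius = 4,
                          fociPerNucleus = rep(5L, nNuclei),
                          focusSigma = 0.15, focusAmplitude = 200,
                          nucleoplasmLevel = 20, backgroundLevel = 5,
                          readNoiseSd = 2, shotNoise = TRUE, seed = 1L) {
    spec <- list(fieldShape = as.integer(fieldShape), nZ = as.integer(nZ),
                 pixelSize = pixelSize, zStepUm = zStepUm,
                 nNuclei = as.integer(nNuclei),
                 nucleusRadius = nucleusRadius,
                 fociPerNucleus = as.integer(fociPerNucleus),
                 focusSigma = focusSigma, focusAmplitude = focusAmplitude,
                 nucleoplasmLevel = nucleoplasmLevel,
                 backgroundLevel = backgroundLevel,
                 readNoiseSd = readNoiseSd, shotNoise = isTRUE(shotNoise),
                 seed = as.integer(seed))
    if (length(spec$fieldShape) != 2L || any(spec$fieldShape <= 0L))
        stop("'fieldShape' must be two positive integers (y, x)")
    if (spec$nZ < 1L) stop("'nZ' must be >= 1")
    stopifnotScalar(spec$pixelSize, "pixelSize", positive = TRUE)
    stopifnotScalar(spec$zStepUm, "zStepUm", positive = TRUE)
    stopifnotScalar(spec$nucleusRadius, "nucleusRadius", positive = TRUE)
    stopifnotScalar(spec$focusSigma, "focusSigma", positive = TRUE)
    if (length(spec$fociPerNucleus) != spec$nNuclei)
        stop("'fociPerNucleus' must have one entry per nucleus")
    if (any(spec$fociPerNucleus < 0L))
        stop("'fociPerNucleus' must be non-negative")
    class(spec) <- "FociFieldSpec"
    spec
}

# rejection-sample `n` points in a disc of radius rMax around (cy, cx)
# with minimum pairwise distance minSep; bounded retries.
placeInDisc <- function(n, cy, cx, rMax, minSep, maxTries = 1000L) {
    ys <- numeric(0); xs <- numeric(0)
    for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(maxTries)) {
            r <- rMax * sqrt(runif(1))
            th <- runif(1, 0, 2 * pi)
            y <- cy + r * sin(th); x <- cx + r * cos(th)
            if (!length(ys) || all((ys - y)^2 + (xs - x)^2 >= minSep^2)) {
                ys <- c(ys, y); xs <- c(xs, x); ok <- TRUE
                break
            }
        }
        if (!ok)
            stop("could not place ", n, " resolvable foci in the nucleus ",
                 "after ", maxTries, " retries; reduce the count or the ",
                 "minimum separation", call. = FALSE)
    }
    cbind(y = ys, x = xs)
}

#' Generate a synthetic nuclear-foci field with ground truth
#'
#' Renders a two-channel z-stack from a [fociFieldSpec()]: channel 1 is a
#' nuclear stain (uniform level inside each nucleus), channel 2 ("green")
#' carries, inside each nucleus, exactly the requested number of 3D
#' Gaussian puncta on top of a diffuse nucleoplasmic level. Poisson shot
#' noise (optional) and additive Gaussian read noise are applied last and
#' the result is clipped at zero. Focus centroids are placed with a
#' minimum pairwise separation of five lateral sigmas so the ground-truth
#' count corresponds to resolvable puncta. The same spec and seed always
#' produce bit-identical output.
#'
#' @param spec a [fociFieldSpec()].
#' @return list with elements `stack` ([ImageStack-class], channels
#'   `"nuclei"`, `"green"`) and `truth` (list: `fociPerNucleus`,
#'   `centroids` data.frame with 0-based y/x/z pixel coordinates and
#'   nucleus ids, `nucleusCenters`, `nucleusRadiusPx`, `nucleusLabels`
#'   label matrix).
#' @examples
#' f <- makeFociField(fociFieldSpec(fieldShape = c(96, 96), nNuclei = 1,
#'     nucleusRadius = 2.5, fociPerNucleus = 3, seed = 7))
#' f$truth$fociPerNucleus
#' @export
makeFociField <- function(spec) {
    stopifnot(inherits(spec, "FociFieldSpec"))
    withSeed(spec$seed, {
        ny <- spec$fieldShape[1L]; nx <- spec$fieldShape[2L]
        nz <- spec$nZ
        rPx <- spec$nucleusRadius / spec$pixelSize
        if (2 * rPx + 2 > min(ny, nx))
            stop("nucleus does not fit in the field", call. = FALSE)
        # nucleus centres: non-overlapping, away from the border
        cys <- numeric(0); cxs <- numeric(0)
        for (i in seq_len(spec$nNuclei)) {
            ok <- FALSE
            for (try in seq_len(1000L)) {
                cy <- runif(1, rPx + 2, ny - rPx - 1)
                cx <- runif(1, rPx + 2, nx - rPx - 1)
                if (!length(cys) ||
                    all((cys - cy)^2 + (cxs - cx)^2 >= (2 * rPx + 2)^2)) {
                    cys <- c(cys, cy); cxs <- c(cxs, cx); ok <- TRUE
                    break
                }
            }
            if (!ok)
                stop("could not place ", spec$nNuclei, " non-overlapping ",
                     "nuclei after 1000 retries; the field is too dense",
                     call. = FALSE)
        }
        yy <- matrix(seq_len(ny), ny, nx)
        xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
        nucLab <- matrix(0L, ny, nx)
        for (i in seq_len(spec$nNuclei)) {
            inside <- (yy - cys[i])^2 + (xx - cxs[i])^2 <= rPx^2
            nucLab[inside] <- i
        }
        nucMask <- nucLab > 0L

        sigPx <- spec$focusSigma / spec$pixelSize
        sigZ <- 2 * spec$focusSigma / spec$zStepUm
        zc <- (nz + 1) / 2
        zHalf <- max((nz - 1) / 4, 0)

        cent <- data.frame(nucleus = integer(0), y = numeric(0),
                           x = numeric(0), z = numeric(0))
        green <- array(0, dim = c(nz, ny, nx))
        for (i in seq_len(spec$nNuclei)) {
            k <- spec$fociPerNucleus[i]
            if (k == 0L) next
            pts <- placeInDisc(k, cys[i], cxs[i], 0.85 * rPx, 5 * sigPx)
            zs <- runif(k, zc - zHalf, zc + zHalf)
            cent <- rbind(cent, data.frame(nucleus = i, y = pts[, "y"],
                                           x = pts[, "x"], z = zs))
            # full-frame separable rendering: no truncation steps that a
            # local-contrast threshold would pick up in noiseless images
            for (j in seq_len(k)) {
                y0 <- pts[j, "y"]; x0 <- pts[j, "x"]; z0 <- zs[j]
                gy <- exp(-((seq_len(ny) - y0)^2) / (2 * sigPx^2))
                gx <- exp(-((seq_len(nx) - x0)^2) / (2 * sigPx^2))
                gz <- exp(-((seq_len(nz) - z0)^2) / (2 * sigZ^2))
                patch <- outer(gy, gx)
                for (z in seq_len(nz))
                    green[z, , ] <- green[z, , ] +
                        spec$focusAmplitude * gz[z] * patch
            }
        }
        # soft nucleus edges: blur the diffuse base so the rim is an
        # optical-style ramp rather than a hard step
        base2d <- spec$backgroundLevel +
            spec$nucleoplasmLevel * nucMask
        base2d <- as.matrix(EBImage::gblur(EBImage::Image(base2d),
                                           sigma = 2))
        # nucleoplasm contributes inside the nucleus footprint on all slices
        for (z in seq_len(nz)) green[z, , ] <- green[z, , ] + base2d
        nucChan <- array(rep(base2d, each = nz), dim = c(nz, ny, nx))

        vox <- array(0, dim = c(2L, nz, ny, nx))
        vox[1L, , , ] <- nucChan
        vox[2L, , , ] <- green
        if (spec$shotNoise)
            vox[] <- rpois(length(vox), lambda = vox)
        if (spec$readNoiseSd > 0)
            vox[] <- vox + rnorm(length(vox), 0, spec$readNoiseSd)
        vox[vox < 0] <- 0

        stack <- imageStack(vox, pixelSize = spec$pixelSize,
                            zStep = spec$zStepUm,
                            channelNames = c("nuclei", "green"))
        truth <- list(
            fociPerNucleus = spec$fociPerNucleus,
            centroids = data.frame(nucleus = cent$nucleus,
                                   y = cent$y - 1, x = cent$x - 1,
                                   z = cent$z - 1),
            nucleusCenters = data.frame(nucleus = seq_len(spec$nNuclei),
                                        y = cys - 1, x = cxs - 1),
            nucleusRadiusPx = rPx,
            nucleusLabels = nucLab)
        list(stack = stack, truth = truth)
    })
}

#' Specification for a synthetic FRAP trace
#'
#' Single-exponential recovery after an instantaneous bleach at frame
#' `nPreFrames`, with acquisition photobleaching applied to both the
#' bleached and the reference trace and multiplicative Gaussian noise on
#' each. Defaults follow a 30 s continuous-scanning window sampled every
#' 0.5 s.
#'
#' @param tHalf recovery half-time, seconds.
#' @param mobileFraction mobile fraction, percent (0-100).
#' @param preBleachLevel pre-bleach intensity (AU).
#' @param bleachDepth fraction of the pre-bleach signal removed by the
#'   bleach pulse (0-1).
#' @param nPreFrames number of pre-bleach frames.
#' @param duration total acquisition time, seconds.
#' @param frameInterval sampling interval, seconds.
#' @param acquisitionDecayRate mono-exponential acquisition-bleaching
#'   rate (1/s) applied to both traces.
#' @param noiseSd relative (multiplicative) Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return list of class `"FrapTraceSpec"`.
#' @export
frapTraceSpec <- function(tHalf = 3.8, mobileFraction = 51,
                          preBleachLevel = 1000, bleachDepth = 0.8,
                          nPreFrames = 5L, duration = 30,
                          frameInterval = 0.5,
                          acquisitionDecayRate = 0.01,
                          noiseSd = 0.02, seed = 1L) {
    stopifnotScalar(tHalf, "tHalf", positive = TRUE)
    stopifnotScalar(duration, "duration", positive = TRUE)
    stopifnotScalar(frameInterval, "frameInterval", positive = TRUE)
    if (mobileFraction < 0 || mobileFraction > 100)
        stop("'mobileFraction' must lie in [0, 100]")
    if (bleachDepth <= 0 || bleachDepth > 1)
        stop("'bleachDepth' must lie in (0, 1]")
    if (frameInterval >= duration)
        stop("'frameInterval' must be smaller than 'duration'")
    spec <- list(tHalf = tHalf, mobileFraction = mobileFraction,
                 preBleachLevel = preBleachLevel, bleachDepth = bleachDepth,
                 nPreFrames = as.integer(nPreFrames), duration = duration,
                 frameInterval = frameInterval,
                 acquisitionDecayRate = acquisitionDecayRate,
                 noiseSd = noiseSd, seed = as.integer(seed))
    class(spec) <- "FrapTraceSpec"
    spec
}

#' Generate a synthetic FRAP recovery trace with ground truth
#'
#' The bleached-region trace follows
#' \eqn{F(t') = F_\infty - (F_\infty - F_0) e^{-t'\ln 2 / t_{1/2}}}
#' from the first post-bleach frame (t' = 0), where
#' \eqn{F_0 = F_{pre}(1 - d)} for bleach depth d and \eqn{F_\infty}
#' encodes the mobile fraction. Both traces are attenuated by
#' \eqn{e^{-\beta t}} (acquisition photobleaching) and carry independent
#' multiplicative Gaussian noise; intensities are clipped at zero.
#'
#' @param spec a [frapTraceSpec()].
#' @return list with `trace` ([RecoveryTrace-class]) and `truth`
#'   (list: `tHalf`, `mobileFraction`, `f0`, `fInf` on the normalized
#'   scale).
#' @examples
#' tr <- makeFrapTrace(frapTraceSpec(tHalf = 3, mobileFraction = 80,
#'     noiseSd = 0, seed = 2))
#' fitRecovery(normalizeTrace(tr$trace))
#' @export
makeFrapTrace <- function(spec) {
    stopifnot(inherits(spec, "FrapTraceSpec"))
    withSeed(spec$seed, {
        times <- seq(0, spec$duration, by = spec$frameInterval)
        n <- length(times)
        if (spec$nPreFrames >= n - 1L)
            stop("not enough post-bleach frames", call. = FALSE)
        pre <- spec$preBleachLevel
        f0 <- pre * (1 - spec$bleachDepth)
        fInf <- f0 + (spec$mobileFraction / 100) * (pre - f0)
        bl <- numeric(n)
        bl[seq_len(spec$nPreFrames)] <- pre
        post <- (spec$nPreFrames + 1L):n
        tp <- times[post] - times[spec$nPreFrames + 1L]
        bl[post] <- fInf - (fInf - f0) * exp(-tp * log(2) / spec$tHalf)
        ref <- rep(pre, n)
        decay <- exp(-spec$acquisitionDecayRate * times)
        bl <- bl * decay
        ref <- ref * decay
        if (spec$noiseSd > 0) {
            bl <- bl * (1 + rnorm(n, 0, spec$noiseSd))
            ref <- ref * (1 + rnorm(n, 0, spec$noiseSd))
        }
        bl[bl < 0] <- 0
        ref[ref <= 0] <- .Machine$double.eps
        trace <- recoveryTrace(times, bl, ref, spec$nPreFrames)
        truth <- list(tHalf = spec$tHalf,
                      mobileFraction = spec$mobileFraction,
                      f0 = 1 - spec$bleachDepth,
                      fInf = (1 - spec$bleachDepth) +
                          spec$mobileFraction / 100 * spec$bleachDepth)
        list(trace = trace, truth = truth)
    })
}

#' Specification for a synthetic two-channel droplet field
#'
#' A 2D field of uniform-intensity discs in a green and a red channel; a
#' `colocFraction` share of the green discs is centred on red discs.
#' Defaults give 256 x 256 frames with disc intensities well above the
#' fixed analysis threshold ranges.
#'
#' @param framePx integer c(y, x) frame size in pixels.
#' @param pixelSize um/pixel.
#' @param nGreen,nRed number of discs per channel.
#' @param dropletRadius disc radius in um; a length-2 vector gives a
#'   uniform sampling range per disc.
#' @param colocFraction fraction (0-1) of green discs co-placed on red
#'   discs; requires `round(colocFraction * nGreen) <= nRed`.
#' @param intensityGreen,intensityRed disc intensities (AU).
#' @param background background level (AU).
#' @param noiseSd additive Gaussian noise SD (AU).
#' @param seed integer RNG seed.
#' @return list of class `"DropletFieldSpec"`.
#' @export
dropletFieldSpec <- function(framePx = c(256L, 256L), pixelSize = 0.2,
                             nGreen = 20L, nRed = 20L,
                             dropletRadius = 0.5, colocFraction = 0,
                             intensityGreen = 2000, intensityRed = 1500,
                             background = 50, noiseSd = 10, seed = 1L) {
    if (colocFraction < 0 || colocFraction > 1)
        stop("'colocFraction' must lie in [0, 1]")
    if (nGreen < 0L || nRed < 0L) stop("droplet counts must be >= 0")
    if (round(colocFraction * nGreen) > nRed)
        stop("not enough red discs to host the requested colocalized ",
             "green discs")
    spec <- list(framePx = as.integer(framePx), pixelSize = pixelSize,
                 nGreen = as.integer(nGreen), nRed = as.integer(nRed),
                 dropletRadius = dropletRadius,
                 colocFraction = colocFraction,
                 intensityGreen = intensityGreen,
                 intensityRed = intensityRed, background = background,
                 noiseSd = noiseSd, seed = as.integer(seed))
    class(spec) <- "DropletFieldSpec"
    spec
}

#' Generate a synthetic two-channel droplet image with ground truth
#'
#' @param spec a [dropletFieldSpec()].
#' @return list with `green` and `red` intensity matrices, `pixelSize`,
#'   and `truth` (centroids per channel, 0-based, and the realized
#'   colocalized-disc count and fraction).
#' @export
makeDropletImage <- function(spec) {
    stopifnot(inherits(spec, "DropletFieldSpec"))
    withSeed(spec$seed, {
        ny <- spec$framePx[1L]; nx <- spec$framePx[2L]
        rr <- spec$dropletRadius / spec$pixelSize
        sampleR <- function() if (length(rr) == 2L) runif(1, rr[1], rr[2]) else rr
        rMax <- max(rr)
        placeAway <- function(n, othersY, othersX, minD) {
            ys <- numeric(0); xs <- numeric(0)
            for (i in seq_len(n)) {
                ok <- FALSE
                for (try in seq_len(1000L)) {
                    y <- runif(1, rMax + 1, ny - rMax)
                    x <- runif(1, rMax + 1, nx - rMax)
                    oy <- c(othersY, ys); ox <- c(othersX, xs)
                    if (!length(oy) || all((oy - y)^2 + (ox - x)^2 >= minD^2)) {
                        ys <- c(ys, y); xs <- c(xs, x); ok <- TRUE
                        break
                    }
                }
                if (!ok) stop("droplet field too dense to place all discs",
                              call. = FALSE)
            }
            cbind(y = ys, x = xs)
        }
        minD <- 2 * rMax + 3
        red <- placeAway(spec$nRed, numeric(0), numeric(0), minD)
        nCo <- as.integer(round(spec$colocFraction * spec$nGreen))
        coIdx <- if (nCo > 0) sample.int(spec$nRed, nCo) else integer(0)
        gCo <- red[coIdx, , drop = FALSE]
        gFree <- placeAway(spec$nGreen - nCo, red[, "y"], red[, "x"], minD)
        green <- rbind(gCo, gFree)

        yy <- matrix(seq_len(ny), ny, nx)
        xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
        render <- function(cents, intensity) {
            img <- matrix(spec$background, ny, nx)
            for (i in seq_len(nrow(cents))) {
                ri <- sampleR()
                img[(yy - cents[i, "y"])^2 + (xx - cents[i, "x"])^2 <= ri^2] <-
                    spec$background + intensity
            }
            img
        }
        gImg <- render(green, spec$intensityGreen)
        rImg <- render(red, spec$intensityRed)
        if (spec$noiseSd > 0) {
            gImg <- gImg + rnorm(length(gImg), 0, spec$noiseSd)
            rImg <- rImg + rnorm(length(rImg), 0, spec$noiseSd)
        }
        gImg[gImg < 0] <- 0
        rImg[rImg < 0] <- 0
        truth <- list(
            greenCentroids = data.frame(y = green[, "y"] - 1,
                                        x = green[, "x"] - 1),
            redCentroids = data.frame(y = red[, "y"] - 1,
                                      x = red[, "x"] - 1),
            nColocalized = nCo,
            colocFraction = if (spec$nGreen > 0) nCo / spec$nGreen else 0)
        list(green = gImg, red = rImg, pixelSize = spec$pixelSize,
             truth = truth)
    })
}

#' Generate a synthetic turbidity (OD340) concentration series
#'
#' Optical density at 340 nm stays at `baselineOd` below the saturation
#' concentration and rises exponentially toward `plateauOd` above it,
#' with additive Gaussian noise per replicate.
#'
#' @param cGrid ascending protein concentrations (uM).
#' @param cSat true saturation concentration (uM), within the grid span.
#' @param plateauOd plateau OD340.
#' @param noiseSd additive noise SD on OD.
#' @param seed integer RNG seed.
#' @param baselineOd OD of the dilute phase (default 0.05).
#' @param nReplicates replicates per concentration (default 3).
#' @param riseScale exponential rise scale in uM; default a third of the
#'   span above `cSat`.
#' @return list with `series` (data.frame condition, od340, replicate)
#'   and `truth` (list with `cSat`, `baselineOd`, `plateauOd`).
#' @export
makeTurbiditySeries <- function(cGrid, cSat, plateauOd = 0.6,
                                noiseSd = 0.01, seed = 1L,
                                baselineOd = 0.05, nReplicates = 3L,
                                riseScale = NULL) {
    if (is.unsorted(cGrid, strictly = TRUE))
        stop("'cGrid' must be strictly ascending")
    if (cSat < min(cGrid) || cSat > max(cGrid))
        stop("'cSat' must lie within the span of 'cGrid'")
    if (is.null(riseScale))
        riseScale <- max((max(cGrid) - cSat) / 3, .Machine$double.eps)
    withSeed(seed, {
        mu <- ifelse(cGrid <= cSat, baselineOd,
                     baselineOd + (plateauOd - baselineOd) *
                         (1 - exp(-(cGrid - cSat) / riseScale)))
        df <- data.frame(
            condition = rep(cGrid, each = nReplicates),
            od340 = rep(mu, each = nReplicates) +
                rnorm(length(cGrid) * nReplicates, 0, noiseSd),
            replicate = rep(seq_len(nReplicates), times = length(cGrid)))
        df$od340[df$od340 < 0] <- 0
        list(series = df,
             truth = list(cSat = cSat, baselineOd = baselineOd,
                          plateauOd = plateauOd))
    })
}

#' Generate a synthetic densitometry standard curve with a query band
#'
#' Band intensities are linear in concentration with relative Gaussian
#' noise; a query band is generated at a held-out true concentration
#' (default: the midpoint of the standard range) and recorded in the
#' ground truth.
#'
#' @param slope AU per uM.
#' @param intercept AU.
#' @param concPoints standard concentrations (uM), at least two distinct.
#' @param noiseRel relative noise SD.
#' @param seed integer RNG seed.
#' @param queryConc true concentration of the query band (uM).
#' @return list with `data` (list: `standards` data.frame
#'   (concentration, intensity), `queryBands` numeric) and `truth`
#'   (list: `slope`, `intercept`, `queryConc`).
#' @export
makeStandardCurve <- function(slope, intercept, concPoints,
                              noiseRel = 0, seed = 1L,
                              queryConc = mean(range(concPoints))) {
    if (length(unique(concPoints)) < 2L)
        stop("at least two distinct standard concentrations are required")
    withSeed(seed, {
        mu <- slope * concPoints + intercept
        ints <- mu * (1 + rnorm(length(mu), 0, noiseRel))
        qMu <- slope * queryConc + intercept
        q <- qMu * (1 + rnorm(1, 0, noiseRel))
        ints[ints < 0] <- 0
        q <- max(q, 0)
        list(data = list(standards = data.frame(concentration = concPoints,
                                                intensity = ints),
                         queryBands = q),
             truth = list(slope = slope, intercept = intercept,
                          queryConc = queryConc))
    })
}
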