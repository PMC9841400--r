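#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Analysis configuration for foci quantification
#'
#' Parameters of the foci-counting pipeline. The adaptive threshold marks
#' a pixel as foreground when its intensity exceeds the local mean plus
#' `adaptiveOffsetK` local standard deviations inside an
#' `adaptiveWindow`-pixel box (reflective padding at borders). The
#' default window of 15 px spans about 1 um at 0.067 um/pixel, the scale
#' of a diffraction-limited punctum. The minimum focus area defaults to
#' zero so every detected object is kept, and a nucleus is classified
#' foci-positive when it contains at least `positivityCutoff` foci
#' (default 20, inclusive).
#'
#' @param fociChannel name of the foci (green) channel.
#' @param nucleusChannel name of the nuclear-stain channel.
#' @param adaptiveWindow odd integer window width, pixels (>= 3).
#' @param adaptiveOffsetK local-SD multiple added to the local mean.
#' @param minFocusAreaPx minimum focus size in pixels (0 keeps all).
#' @param positivityCutoff minimum focus count for a foci-positive
#'   nucleus (inclusive, >= 1).
#' @param nucleusThreshold scalar intensity threshold for the nuclear
#'   channel, or `"otsu"` for an automatic threshold.
#' @param excludeBorderNuclei drop nuclei touching the image border.
#' @return list of class `"AnalysisConfig"`.
#' @export
analysisConfig <- function(fociChannel = "green",
                           nucleusChannel = "nuclei",
                           adaptiveWindow = 15L, adaptiveOffsetK = 3,
                           minFocusAreaPx = 0L, positivityCutoff = 20L,
                           nucleusThreshold = "otsu",
                           excludeBorderNuclei = TRUE) {
    adaptiveWindow <- as.integer(adaptiveWindow)
    if (adaptiveWindow < 3L || adaptiveWindow %% 2L == 0L)
        stop("'adaptiveWindow' must be an odd integer >= 3")
    positivityCutoff <- as.integer(positivityCutoff)
    if (positivityCutoff < 1L) stop("'positivityCutoff' must be >= 1")
    cfg <- list(fociChannel = fociChannel, nucleusChannel = nucleusChannel,
                adaptiveWindow = adaptiveWindow,
                adaptiveOffsetK = adaptiveOffsetK,
                minFocusAreaPx = as.integer(minFocusAreaPx),
                positivityCutoff = positivityCutoff,
                nucleusThreshold = nucleusThreshold,
                excludeBorderNuclei = isTRUE(excludeBorderNuclei))
    class(cfg) <- "AnalysisConfig"
    cfg
}

#' @describeIn maxProject project one channel of an `ImageStack`
#' @export
setMethod("maxProject", "ImageStack", function(x, channel) {
    v <- x@voxels
    if (is.character(channel)) {
        idx <- match(channel, x@channelNames)
        if (is.na(idx))
            stop("unknown channel '", channel, "'; available: ",
                 paste(x@channelNames, collapse = ", "), call. = FALSE)
    } else {
        idx <- as.integer(channel)
        if (idx < 1L || idx > dim(v)[1L])
            stop("channel index out of range", call. = FALSE)
    }
    ch <- v[idx, , , , drop = FALSE]
    dim(ch) <- dim(v)[-1L]
    nz <- dim(ch)[1L]
    out <- ch[1L, , ]
    dim(out) <- dim(ch)[-1L]
    for (z in seq_len(nz)[-1L]) {
        sl <- ch[z, , ]
        dim(sl) <- dim(out)
        out <- pmax(out, sl)
    }
    out
})

#' Adaptive local-contrast threshold
#'
#' Marks a pixel as foreground when its intensity strictly exceeds the
#' mean plus `offsetK` standard deviations of the `window`-pixel square
#' neighbourhood around it. Borders are handled by reflective padding, so
#' the statistics are always computed over a full window.
#'
#' @param image numeric matrix (y by x).
#' @param window odd window width in pixels, >= 3 and at most the
#'   smaller image dimension.
#' @param offsetK number of local standard deviations above the local
#'   mean required for foreground.
#' @return logical matrix of the same size.
#' @examples
#' img <- matrix(0, 32, 32); img[16, 16] <- 100
#' sum(adaptiveThreshold(img, 15, 3))
#' @export
adaptiveThreshold <- function(image, window = 15L, offsetK = 3) {
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
        stop("'window' must be an odd integer >= 3")
    if (window > min(dim(image)))
        stop("'window' exceeds the image size")
    p <- (window - 1L) %/% 2L
    nr <- nrow(image); nc <- ncol(image)
    pad <- padReflect(image, p)
    # centring before the summed-area tables keeps the accumulated sums
    # small, limiting cancellation in the local variance
    m0 <- mean(pad)
    pad <- pad - m0
    n <- window^2
    s1 <- boxSum(pad, window, nr, nc)
    s2 <- boxSum(pad^2, window, nr, nc)
    mu <- s1 / n
    sd <- sqrt(pmax(s2 / n - mu^2, 0))
    # relative tolerance guards against floating-point rounding in the
    # integral images flagging numerically flat regions
    tol <- 1e-6 * diff(range(image))
    (image - m0 - mu) > offsetK * sd + tol
}

#' Label foci in a binary mask
#'
#' Extracts 8-connected components, drops those smaller than
#' `minAreaPx` pixels, and returns one record per focus with 0-based
#' centroid coordinates, area in square micrometres
#' (`pixels * pixelSize^2`) and mean intensity. Ids follow the raster
#' order of each component's first pixel, so labelling is deterministic.
#'
#' @param mask logical matrix from [adaptiveThreshold()].
#' @param pixelSize lateral pixel size (um/pixel).
#' @param minAreaPx minimum component size in pixels (default 0: keep
#'   everything, including single-pixel foci).
#' @param image optional intensity matrix for per-focus mean intensity.
#' @return data.frame with columns `id`, `centroid_y`, `centroid_x`
#'   (0-based), `area_px`, `area_um2`, `mean_intensity`, `nucleus_id`
#'   (NA until assigned).
#' @export
labelFoci <- function(mask, pixelSize, minAreaPx = 0L, image = NULL) {
    stopifnotScalar(pixelSize, "pixelSize", positive = TRUE)
    lab <- labelComponents(mask, connectivity = 8L)
    nlab <- max(lab)
    empty <- data.frame(id = integer(0), centroid_y = numeric(0),
                        centroid_x = numeric(0), area_px = integer(0),
                        area_um2 = numeric(0), mean_intensity = numeric(0),
                        nucleus_id = integer(0))
    if (nlab == 0L) return(empty)
    idx <- which(lab > 0L)
    lv <- lab[idx]
    nr <- nrow(mask)
    ys <- (idx - 1L) %% nr      # 0-based row
    xs <- (idx - 1L) %/% nr     # 0-based column
    areaPx <- tabulate(lv, nlab)
    cy <- tapply(ys, lv, mean)
    cx <- tapply(xs, lv, mean)
    mi <- if (is.null(image)) rep(NA_real_, nlab)
          else as.numeric(tapply(image[idx], lv, mean))
    keep <- areaPx >= minAreaPx & areaPx > 0L
    out <- data.frame(id = seq_len(nlab), centroid_y = as.numeric(cy),
                      centroid_x = as.numeric(cx), area_px = areaPx,
                      area_um2 = areaPx * pixelSize^2,
                      mean_intensity = mi,
                      nucleus_id = NA_integer_)[keep, , drop = FALSE]
    out$id <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Segment nuclei on a nuclear-stain projection
#'
#' Applies a global threshold (a fixed intensity, or Otsu's method when
#' `threshold = "otsu"`), labels 4-connected components, fills holes,
#' and (optionally) removes components touching the image border, whose
#' focus counts would be biased low by clipping. A threshold above the
#' image maximum yields an empty segmentation, not an error.
#'
#' @param image numeric matrix (nuclear-channel projection).
#' @param threshold scalar intensity (AU) or `"otsu"`.
#' @param excludeBorderNuclei drop border-touching components.
#' @param minAreaPx minimum nucleus area in pixels (default 9, guards
#'   against speckle).
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `nuclei` (data.frame: `nucleus_id`, `area_px`, `area_um2` is added
#'   by callers that know the pixel size).
#' @export
segmentNuclei <- function(image, threshold = "otsu",
                          excludeBorderNuclei = TRUE, minAreaPx = 9L) {
    if (identical(threshold, "otsu")) {
        rng <- range(image)
        threshold <- if (rng[1L] == rng[2L]) rng[2L] + 1
                     else EBImage::otsu(EBImage::Image(image), range = rng)
    }
    mask <- image > threshold
    lab <- labelComponents(mask, connectivity = 4L)
    if (max(lab) > 0L) {
        filled <- EBImage::fillHull(EBImage::Image(lab))
        lab <- matrix(as.integer(round(filled)), nrow(lab), ncol(lab))
    }
    if (excludeBorderNuclei && max(lab) > 0L) {
        border <- unique(c(lab[1L, ], lab[nrow(lab), ],
                           lab[, 1L], lab[, ncol(lab)]))
        border <- border[border > 0L]
        lab[lab %in% border] <- 0L
        lab <- relabelRaster(lab)
    }
    nlab <- max(lab)
    if (nlab > 0L) {
        areaPx <- tabulate(lab[lab > 0L], nlab)
        small <- which(areaPx < minAreaPx)
        if (length(small)) {
            lab[lab %in% small] <- 0L
            lab <- relabelRaster(lab)
            nlab <- max(lab)
            areaPx <- if (nlab > 0L) tabulate(lab[lab > 0L], nlab) else integer(0)
        }
    } else areaPx <- integer(0)
    list(labels = lab,
         nuclei = data.frame(nucleus_id = seq_len(nlab),
                             area_px = areaPx))
}

#' Assign foci to nuclei and count per nucleus
#'
#' A focus belongs to the nucleus whose mask contains its centroid
#' (rounded to the nearest pixel); foci falling outside every nucleus
#' stay unassigned and are excluded from nuclear counts. Each focus is
#' assigned at most once.
#'
#' @param foci data.frame from [labelFoci()].
#' @param segmentation list from [segmentNuclei()].
#' @param pixelSize lateral pixel size (um/pixel) for nuclear areas.
#' @return list with `foci` (input with `nucleus_id` filled in, NA when
#'   unassigned) and `nuclei` (data.frame: `nucleus_id`, `area_um2`,
#'   `foci_count`).
#' @export
countFociPerNucleus <- function(foci, segmentation, pixelSize = 1) {
    lab <- segmentation$labels
    nNuc <- max(lab, 0L)
    if (nrow(foci)) {
        ry <- pmin(pmax(as.integer(round(foci$centroid_y)) + 1L, 1L),
                   nrow(lab))
        rx <- pmin(pmax(as.integer(round(foci$centroid_x)) + 1L, 1L),
                   ncol(lab))
        ids <- lab[cbind(ry, rx)]
        foci$nucleus_id <- ifelse(ids > 0L, ids, NA_integer_)
    }
    counts <- integer(nNuc)
    if (nrow(foci)) {
        tab <- table(factor(foci$nucleus_id, levels = seq_len(nNuc)))
        counts <- as.integer(tab)
    }
    nuc <- data.frame(nucleus_id = seq_len(nNuc),
                      area_um2 = segmentation$nuclei$area_px * pixelSize^2,
                      foci_count = counts)
    list(foci = foci, nuclei = nuc)
}

#' Classify nuclei as foci-positive
#'
#' A nucleus is foci-positive when it contains at least `cutoff` foci
#' (inclusive: a count equal to the cutoff is positive).
#'
#' @param fociCount integer vector of per-nucleus counts, or the
#'   `nuclei` data.frame from [countFociPerNucleus()].
#' @param cutoff positivity cutoff (>= 1), default 20.
#' @return logical vector, or the data.frame with a `foci_positive`
#'   column added.
#' @examples
#' classifyPositive(c(0, 19, 20, 25))   # FALSE FALSE TRUE TRUE
#' @export
classifyPositive <- function(fociCount, cutoff = 20L) {
    cutoff <- as.integer(cutoff)
    if (cutoff < 1L) stop("'cutoff' must be >= 1")
    if (is.data.frame(fociCount)) {
        fociCount$foci_positive <- fociCount$foci_count >= cutoff
        return(fociCount)
    }
    fociCount >= cutoff
}

#' Summarize a field of classified nuclei
#'
#' @param nuclei data.frame with `foci_count` and `foci_positive`
#'   columns (from [classifyPositive()]); must be non-empty.
#' @return data.frame with `n_nuclei`, `n_positive`, `percent_positive`
#'   (0-100) and `mean_foci_per_nucleus`.
#' @export
summarizeField <- function(nuclei) {
    if (!nrow(nuclei))
        stop("cannot summarize an empty field: no nuclei were segmented")
    data.frame(
        n_nuclei = nrow(nuclei),
        n_positive = sum(nuclei$foci_positive),
        percent_positive = 100 * mean(nuclei$foci_positive),
        mean_foci_per_nucleus = mean(nuclei$foci_count))
}

#' Run the full foci-quantification pipeline on one stack
#'
#' Max-projects the foci channel, applies the adaptive threshold, labels
#' foci, segments nuclei on the nuclear-channel projection, assigns foci
#' to nuclei, classifies positivity and summarizes the field.
#'
#' @param stack an [ImageStack-class].
#' @param config an [analysisConfig()].
#' @return list with `foci`, `nuclei`, `summary` data.frames and the
#'   nucleus `labels` matrix.
#' @examples
#' f <- makeFociField(fociFieldSpec(fieldShape = c(128, 128), nNuclei = 1,
#'     nucleusRadius = 3, fociPerNucleus = 4, seed = 11))
#' res <- quantifyFoci(f$stack, analysisConfig())
#' res$nuclei
#' @export
quantifyFoci <- function(stack, config = analysisConfig()) {
    proj <- maxProject(stack, config$fociChannel)
    mask <- adaptiveThreshold(proj, config$adaptiveWindow,
                              config$adaptiveOffsetK)
    foci <- labelFoci(mask, pixelSize(stack), config$minFocusAreaPx,
                      image = proj)
    nucProj <- maxProject(stack, config$nucleusChannel)
    seg <- segmentNuclei(nucProj, config$nucleusThreshold,
                         config$excludeBorderNuclei)
    counted <- countFociPerNucleus(foci, seg, pixelSize(stack))
    nuclei <- classifyPositive(counted$nuclei, config$positivityCutoff)
    list(foci = counted$foci, nuclei = nuclei,
         summary = if (nrow(nuclei)) summarizeField(nuclei) else NULL,
         labels = seg$labels)
}
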