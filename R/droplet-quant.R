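#' @include utils.R
NULL

#' Fixed-range intensity thresholds
#'
#' The analysis thresholds used for in vitro droplet images on a 16-bit
#' intensity scale: 550-60000 for the green channel, 300-60000 for the
#' red channel and 100-60000 for gray levels. Both bounds are inclusive;
#' the upper bound excludes saturated pixels.
#'
#' @param lo lower bound (AU, inclusive, >= 0).
#' @param hi upper bound (AU, inclusive, > lo).
#' @return list of class `"ThresholdRange"`.
#' @examples
#' defaultThresholds()$green
#' @export
thresholdRange <- function(lo, hi) {
    if (lo < 0 || hi <= lo)
        stop("require 0 <= lo < hi")
    structure(list(lo = lo, hi = hi), class = "ThresholdRange")
}

#' @rdname thresholdRange
#' @export
defaultThresholds <- function() {
    list(green = thresholdRange(550, 60000),
         red = thresholdRange(300, 60000),
         gray = thresholdRange(100, 60000))
}

#' Threshold an image within a fixed intensity range
#'
#' @param image numeric matrix.
#' @param range a [thresholdRange()].
#' @return logical matrix: `lo <= intensity <= hi` (both inclusive).
#' @export
thresholdInRange <- function(image, range) {
    stopifnot(inherits(range, "ThresholdRange"))
    image >= range$lo & image <= range$hi
}

#' Measure droplets in a thresholded image
#'
#' Labels 8-connected components of the mask and reports object count,
#' per-object and total area in square micrometres, and the mean
#' intensity over the mask.
#'
#' @param mask logical matrix.
#' @param pixelSize um/pixel.
#' @param image optional intensity matrix for the mean intensity.
#' @return list with `n_objects`, `total_area_um2`, `object_areas_um2`,
#'   `mean_intensity`.
#' @export
measureDroplets <- function(mask, pixelSize, image = NULL) {
    stopifnotScalar(pixelSize, "pixelSize", positive = TRUE)
    if (!is.null(image) && !identical(dim(mask), dim(image)))
        stop("mask and image shapes differ")
    lab <- labelComponents(mask, connectivity = 8L)
    nlab <- max(lab)
    areas <- if (nlab > 0L) tabulate(lab[lab > 0L], nlab) * pixelSize^2
             else numeric(0)
    list(n_objects = nlab,
         total_area_um2 = sum(areas),
         object_areas_um2 = areas,
         mean_intensity = if (is.null(image) || !any(mask)) NA_real_
                          else mean(image[mask]))
}

#' Manders colocalization coefficients on thresholded channels
#'
#' Intensity-weighted Manders split coefficients restricted to
#' threshold-passing pixels:
#' \deqn{M_1 = \frac{\sum_{G \cap R} G_i}{\sum_{G} G_i}, \qquad
#'       M_2 = \frac{\sum_{G \cap R} R_i}{\sum_{R} R_i}}
#' where G and R are the sets of pixels passing the green and red
#' threshold ranges. If no pixel passes a channel's threshold the
#' corresponding coefficient is defined as 0 and flagged.
#'
#' @param imgGreen,imgRed numeric matrices of identical shape.
#' @param rangeGreen,rangeRed [thresholdRange()]s (defaults: the fixed
#'   550-60000 / 300-60000 ranges).
#' @param pixelSize um/pixel for the overlap area.
#' @return list with `m1`, `m2`, `overlap_area_um2`, `flag`
#'   (`"ok"` or `"empty_channel"`).
#' @export
mandersColoc <- function(imgGreen, imgRed,
                         rangeGreen = defaultThresholds()$green,
                         rangeRed = defaultThresholds()$red,
                         pixelSize = 1) {
    if (!identical(dim(imgGreen), dim(imgRed)))
        stop("channel images must have the same shape")
    mg <- thresholdInRange(imgGreen, rangeGreen)
    mr <- thresholdInRange(imgRed, rangeRed)
    both <- mg & mr
    flag <- "ok"
    if (!any(mg) || !any(mr)) {
        flag <- "empty_channel"
        warning("no pixels pass the threshold in at least one channel; ",
                "Manders coefficients set to 0")
    }
    m1 <- if (any(mg)) sum(imgGreen[both]) / sum(imgGreen[mg]) else 0
    m2 <- if (any(mr)) sum(imgRed[both]) / sum(imgRed[mr]) else 0
    list(m1 = m1, m2 = m2,
         overlap_area_um2 = sum(both) * pixelSize^2, flag = flag)
}

#' Dose-response summary and saturation-concentration estimate
#'
#' Summarizes a droplet statistic (count, area, ...) per concentration
#' and tests each concentration against the blank (concentration 0) with
#' a two-tailed unpaired Student's t-test. The saturation concentration
#' is estimated operationally as the lowest concentration with p < 0.05
#' and a mean above the blank mean; `NA` when no concentration
#' qualifies.
#'
#' @param data data.frame with columns `concentration_uM` and `value`
#'   (one row per replicate); must contain a blank at concentration 0
#'   and at least 2 replicates per concentration.
#' @param alpha significance level for the c_sat call (default 0.05).
#' @return list with `table` (per-concentration n, mean, sd, t, p, star)
#'   and `c_sat_uM`.
#' @export
doseResponse <- function(data, alpha = 0.05) {
    if (!all(c("concentration_uM", "value") %in% names(data)))
        stop("'data' needs columns concentration_uM and value")
    concs <- sort(unique(data$concentration_uM))
    if (!0 %in% concs)
        stop("a blank control (concentration 0) is required")
    if (length(concs) < 2L)
        stop("at least two concentrations (incl. blank) are required")
    blank <- data$value[data$concentration_uM == 0]
    rows <- lapply(concs, function(cc) {
        v <- data$value[data$concentration_uM == cc]
        if (length(v) < 2L)
            stop("at least 2 replicates per concentration are required")
        if (cc == 0) {
            data.frame(concentration_uM = cc, n = length(v),
                       mean = mean(v), sd = stats::sd(v),
                       t = NA_real_, p_vs_blank = NA_real_,
                       star = NA_character_)
        } else {
            tt <- tTestTwoTailed(v, blank)
            data.frame(concentration_uM = cc, n = length(v),
                       mean = mean(v), sd = stats::sd(v),
                       t = tt$t, p_vs_blank = tt$p,
                       star = starLabel(tt$p)$label)
        }
    })
    tab <- do.call(rbind, rows)
    sig <- tab$concentration_uM > 0 & !is.na(tab$p_vs_blank) &
        tab$p_vs_blank < alpha & tab$mean > mean(blank)
    cSat <- if (any(sig)) min(tab$concentration_uM[sig]) else NA_real_
    list(table = tab, c_sat_uM = cSat)
}

#' Summarize a turbidity series
#'
#' Per-condition mean and SD of OD340, pairwise two-tailed t-tests
#' against a control condition, and — when the conditions are numeric —
#' a breakpoint estimate: the condition at the lower end of the largest
#' consecutive increase in means (where the turbidity rise begins).
#'
#' @param points data.frame with columns `condition`, `od340` (and
#'   optionally `replicate`).
#' @param control control condition label (default: the first condition
#'   in sorted order).
#' @return list with `table` (condition, n, mean, sd, t, p, star) and
#'   `breakpoint` (condition value or NA).
#' @export
turbiditySummary <- function(points, control = NULL) {
    if (!all(c("condition", "od340") %in% names(points)))
        stop("'points' needs columns condition and od340")
    conds <- sort(unique(points$condition))
    if (length(conds) < 2L) stop("at least 2 conditions are required")
    if (is.null(control)) control <- conds[1L]
    if (!control %in% conds) stop("control condition not found")
    ctrl <- points$od340[points$condition == control]
    singleRep <- any(vapply(conds, function(cc)
        sum(points$condition == cc) < 2L, logical(1)))
    if (singleRep)
        warning("some conditions have a single replicate; ",
                "tests skipped, reporting means only")
    rows <- lapply(conds, function(cc) {
        v <- points$od340[points$condition == cc]
        if (identical(cc, control) || singleRep) {
            data.frame(condition = cc, n = length(v), mean = mean(v),
                       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                       t = NA_real_, p = NA_real_, star = NA_character_)
        } else {
            tt <- tTestTwoTailed(v, ctrl)
            data.frame(condition = cc, n = length(v), mean = mean(v),
                       sd = stats::sd(v), t = tt$t, p = tt$p,
                       star = starLabel(tt$p)$label)
        }
    })
    tab <- do.call(rbind, rows)
    bp <- NA
    if (is.numeric(conds) && length(conds) >= 2L) {
        inc <- diff(tab$mean)
        bp <- conds[which.max(inc)]
    }
    list(table = tab, breakpoint = bp)
}
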