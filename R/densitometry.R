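#' @include AllClasses.R
NULL

#' Fit a densitometry standard curve
#'
#' Ordinary least squares of band intensity on concentration across the
#' recombinant-protein standards.
#'
#' @param standards data.frame with columns `concentration` (uM) and
#'   `intensity` (AU); at least two distinct concentrations.
#' @return a [LineFit-class].
#' @examples
#' std <- data.frame(concentration = 1:5, intensity = 2 * (1:5) + 1)
#' fitStandardCurve(std)
#' @export
fitStandardCurve <- function(standards) {
    if (is.list(standards) && !is.data.frame(standards) &&
        !is.null(standards$standards))
        standards <- standards$standards
    if (!all(c("concentration", "intensity") %in% names(standards)))
        stop("'standards' needs columns concentration and intensity")
    x <- standards$concentration; y <- standards$intensity
    if (length(unique(x)) < 2L)
        stop("all standard concentrations are equal; cannot fit a line")
    fit <- stats::lm(y ~ x)
    n <- length(x)
    res <- stats::resid(fit)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
    rsd <- if (n > 2L) sqrt(sum(res^2) / (n - 2L)) else 0
    new("LineFit",
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        rSquared = min(max(r2, 0), 1), residualSd = rsd,
        n = as.integer(n), meanConc = mean(x),
        sxx = sum((x - mean(x))^2))
}

#' Estimate a concentration from a band intensity
#'
#' Inverse prediction on the standard curve: \eqn{\hat c = (I - b)/m}.
#' The standard deviation is first-order calibration error propagation,
#' \deqn{\mathrm{sd}(\hat c) = \frac{s}{|m|}
#'   \sqrt{1 + \frac{1}{n} + \frac{(\hat c - \bar c)^2}{S_{cc}}}}
#' with s the residual SD of the fit, n the number of standards, and
#' \eqn{S_{cc}} the centred sum of squares of the standard
#' concentrations. Estimates below zero or outside the standards' span
#' are returned as-is with a flag.
#'
#' @param fit a [LineFit-class] with non-zero slope.
#' @param intensity query band intensity (AU); vectorized.
#' @param concRange optional c(lo, hi) span of the standards for the
#'   extrapolation flag.
#' @return data.frame with `concentration_uM`, `sd_uM`, `flag`
#'   (`"ok"`, `"below_range"` or `"extrapolated"`).
#' @export
estimateConcentration <- function(fit, intensity, concRange = NULL) {
    stopifnot(is(fit, "LineFit"))
    if (fit@slope == 0) stop("slope is zero; concentration is undefined")
    cHat <- (intensity - fit@intercept) / fit@slope
    sdC <- (fit@residualSd / abs(fit@slope)) *
        sqrt(1 + 1 / fit@n + (cHat - fit@meanConc)^2 / fit@sxx)
    flag <- rep("ok", length(cHat))
    flag[cHat < 0] <- "below_range"
    if (!is.null(concRange))
        flag[cHat >= 0 & (cHat < concRange[1L] | cHat > concRange[2L])] <-
            "extrapolated"
    data.frame(concentration_uM = cHat, sd_uM = sdC, flag = flag)
}
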