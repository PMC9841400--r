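# Statistical reporting layer: one-way ANOVA, unpaired two-tailed
# Student's t-tests, significance stars, summary tables.

#' One-way ANOVA
#'
#' Classical between/within mean-square F test with (k - 1, N - k)
#' degrees of freedom, computed via [stats::aov()].
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   non-empty, total N > k).
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @examples
#' oneWayAnova(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
#' @export
oneWayAnova <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("at least 2 groups are required")
    k <- length(groups)
    n <- vapply(groups, length, integer(1))
    if (any(n < 1L)) stop("every group must contain observations")
    if (sum(n) <= k) stop("total n must exceed the number of groups")
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_len(k), times = n))
    withinSS <- sum(vapply(groups,
                           function(v) sum((v - mean(v))^2), numeric(1)))
    if (withinSS == 0)
        stop("zero within-group variance in all groups; F is undefined")
    tab <- stats::anova(stats::aov(y ~ g))
    list(F = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
         df_between = tab[["Df"]][1L], df_within = tab[["Df"]][2L])
}

#' Two-tailed unpaired Student's t-test
#'
#' Pooled-variance (Student) t-test by default, via [stats::t.test()]
#' with `var.equal = TRUE`; Welch's correction is available behind
#' `welch = TRUE`. Two degenerate cases are handled explicitly: zero
#' pooled variance with equal means gives t = 0, p = 1; zero pooled
#' variance with unequal means is an error (the statistic is infinite).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param welch use Welch's unequal-variance t-test.
#' @return list with `t`, `p`, `df`.
#' @examples
#' tTestTwoTailed(c(1, 2, 3), c(2, 3, 4))
#' @export
tTestTwoTailed <- function(a, b, welch = FALSE) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each sample needs at least 2 observations")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
        if (mean(a) == mean(b))
            return(list(t = 0, p = 1, df = length(a) + length(b) - 2L))
        stop("zero variance in both samples with unequal means; ",
             "the t statistic is undefined")
    }
    tt <- stats::t.test(a, b, var.equal = !welch,
                        alternative = "two.sided")
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter))
}

#' Significance-star annotation
#'
#' Maps a p-value to the star labels used in the figures:
#' ns for p >= 0.05, `*` for 0.01 <= p < 0.05, `**` for
#' 0.001 <= p < 0.01, `***` for 0.0001 <= p < 0.001 and `****` for
#' p < 0.0001.
#'
#' @param p p-value in \[0, 1\].
#' @return list with `p` and `label`.
#' @examples
#' starLabel(0.03)$label   # "*"
#' starLabel(0.05)$label   # "ns"
#' @export
starLabel <- function(p) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
        stop("'p' must be a single number in [0, 1]")
    label <- if (p >= 0.05) "ns"
             else if (p >= 0.01) "*"
             else if (p >= 0.001) "**"
             else if (p >= 1e-4) "***"
             else "****"
    list(p = p, label = label)
}

#' Write per-group summary tables with tests
#'
#' For each named table (a list of group vectors), writes a CSV with
#' per-group n, mean and SD; with two or more groups, every non-control
#' group is tested against the control with a two-tailed unpaired
#' Student's t-test and annotated with stars. Single-group tables get
#' descriptive statistics only. An empty table set writes nothing and
#' says so.
#'
#' @param tables named list; each element is a named list of numeric
#'   vectors (groups).
#' @param outDir output directory (created if needed).
#' @param control control group name per table (default: first group).
#' @param bonferroni apply Bonferroni correction across the tests within
#'   a table (off by default; no correction is applied in the standard
#'   reporting).
#' @return invisibly, the paths written.
#' @export
writeSummary <- function(tables, outDir, control = NULL,
                         bonferroni = FALSE) {
    if (!length(tables)) {
        message("no tables supplied; nothing written")
        return(invisible(character(0)))
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (nm in names(tables)) {
        groups <- tables[[nm]]
        ctrl <- if (is.null(control)) names(groups)[1L] else control
        nTests <- sum(names(groups) != ctrl)
        rows <- lapply(names(groups), function(g) {
            v <- groups[[g]]
            row <- data.frame(group = g, n = length(v), mean = mean(v),
                              sd = if (length(v) > 1L) stats::sd(v)
                                   else NA_real_,
                              t = NA_real_, p = NA_real_,
                              star = NA_character_)
            if (length(groups) >= 2L && g != ctrl &&
                length(v) >= 2L && length(groups[[ctrl]]) >= 2L) {
                tt <- tTestTwoTailed(v, groups[[ctrl]])
                p <- if (bonferroni) min(1, tt$p * nTests) else tt$p
                row$t <- tt$t; row$p <- p
                row$star <- starLabel(p)$label
            }
            row
        })
        tab <- do.call(rbind, rows)
        path <- file.path(outDir, paste0(nm, "_summary.csv"))
        utils::write.csv(tab, path, row.names = FALSE)
        paths <- c(paths, path)
    }
    invisible(paths)
}
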