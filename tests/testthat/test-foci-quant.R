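test_that("max projection matches a brute-force oracle and trivial cases", {
    v <- array(0, dim = c(1, 4, 6, 5))
    st <- imageStack(v, 0.1, 0.2, "green")
    expect_equal(maxProject(st, "green"), matrix(0, 6, 5))

    v[1, 3, 2, 4] <- 7
    st <- imageStack(v, 0.1, 0.2, "green")
    pr <- maxProject(st, "green")
    expect_equal(pr[2, 4], 7)
    expect_equal(sum(pr), 7)

    set.seed(31)
    v <- array(runif(2 * 5 * 8 * 9), dim = c(2, 5, 8, 9))
    st <- imageStack(v, 0.1, 0.2, c("a", "b"))
    ch <- v[2, , , ]
    expect_equal(maxProject(st, "b"), oracleMaxProject(ch))

    # projection of a single-slice stack returns the slice unchanged
    v1 <- array(runif(1 * 1 * 6 * 6), dim = c(1, 1, 6, 6))
    st1 <- imageStack(v1, 0.1, 0.2, "x")
    expect_equal(maxProject(st1, "x"), matrix(v1[1, 1, , ], 6, 6))

    expect_error(maxProject(st, "nope"), "unknown channel")
})

test_that("adaptive threshold matches direct windowed statistics", {
    # one Gaussian spot, amplitude 10x flat background
    img <- matrix(10, 48, 48)
    yy <- row(img); xx <- col(img)
    img <- img + 100 * exp(-((yy - 24)^2 + (xx - 20)^2) / (2 * 2^2))
    m <- adaptiveThreshold(img, window = 15, offsetK = 3)
    expect_true(any(m))
    # all foreground pixels within 3 sigma of the spot centre
    d <- sqrt((yy[m] - 24)^2 + (xx[m] - 20)^2)
    expect_lte(max(d), 6)
    expect_equal(m, oracleAdaptive(img, 15L, 3))
})

test_that("adaptive threshold: constant image yields an empty mask", {
    expect_false(any(adaptiveThreshold(matrix(5, 30, 30), 15, 3)))
    expect_error(adaptiveThreshold(matrix(0, 30, 30), 14, 3), "odd")
    expect_error(adaptiveThreshold(matrix(0, 10, 10), 15, 3), "exceeds")
})

test_that("adaptive threshold is shift-equivariant away from borders", {
    base <- matrix(10, 96, 96)
    spot <- function(cy, cx) {
        yy <- row(base); xx <- col(base)
        base + 100 * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * 2^2))
    }
    m1 <- adaptiveThreshold(spot(40, 40), 15, 3)
    m2 <- adaptiveThreshold(spot(45, 47), 15, 3)
    # interior crop: shifting the input shifts the mask by the same offset
    expect_equal(m2[21:76 + 5, 21:76 + 7], m1[21:76, 21:76])
    # detected centroids shift by exactly the offset
    f1 <- labelFoci(m1, 1)
    f2 <- labelFoci(m2, 1)
    expect_equal(f2$centroid_y, f1$centroid_y + 5, tolerance = 1e-9)
    expect_equal(f2$centroid_x, f1$centroid_x + 7, tolerance = 1e-9)
})

test_that("labelFoci counts, areas and connectivity are correct", {
    expect_equal(nrow(labelFoci(matrix(FALSE, 5, 5), 0.1)), 0)

    # min area 0 keeps a single-pixel focus
    m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE
    f <- labelFoci(m, 0.067, minAreaPx = 0)
    expect_equal(nrow(f), 1)
    expect_equal(f$area_um2, 0.067^2)
    # and a min-area filter removes it
    expect_equal(nrow(labelFoci(m, 0.067, minAreaPx = 2)), 0)

    # two disjoint 2x2 squares at 0.067 um/px
    m <- matrix(FALSE, 12, 12)
    m[2:3, 2:3] <- TRUE; m[8:9, 9:10] <- TRUE
    f <- labelFoci(m, 0.067)
    expect_equal(nrow(f), 2)
    expect_equal(f$area_um2, rep(4 * 0.067^2, 2))

    # 8-connectivity: diagonally touching pixels form one focus
    m <- matrix(FALSE, 6, 6); m[2, 2] <- TRUE; m[3, 3] <- TRUE
    expect_equal(nrow(labelFoci(m, 1)), 1)
})

test_that("nucleus segmentation applies threshold, border rule and IoU", {
    img <- matrix(0, 60, 60)
    yy <- row(img); xx <- col(img)
    img[(yy - 30)^2 + (xx - 30)^2 <= 100] <- 50
    seg <- segmentNuclei(img, threshold = 20)
    expect_equal(max(seg$labels), 1)

    # threshold above the maximum: empty result, not an error
    segHi <- segmentNuclei(img, threshold = 100)
    expect_equal(max(segHi$labels), 0)

    # a disc clipped by the border is removed
    img2 <- img
    img2[(yy - 2)^2 + (xx - 50)^2 <= 100] <- 50
    seg2 <- segmentNuclei(img2, threshold = 20)
    expect_equal(max(seg2$labels), 1)
    seg2k <- segmentNuclei(img2, threshold = 20,
                           excludeBorderNuclei = FALSE)
    expect_equal(max(seg2k$labels), 2)

    # synthetic field: segmented nuclei overlap ground truth (IoU >= 0.95)
    f <- makeFociField(cleanFieldSpec(c(2, 2), seed = 21,
                                      shape = c(200L, 200L)))
    np <- maxProject(f$stack, "nuclei")
    seg3 <- segmentNuclei(np, threshold = "otsu")
    expect_equal(max(seg3$labels), 2)
    for (i in 1:2) {
        tmask <- f$truth$nucleusLabels == i
        best <- 0
        for (j in seq_len(max(seg3$labels))) {
            smask <- seg3$labels == j
            iou <- sum(tmask & smask) / sum(tmask | smask)
            best <- max(best, iou)
        }
        expect_gte(best, 0.95)
    }
})

test_that("focus-to-nucleus assignment and count conservation hold", {
    lab <- matrix(0L, 20, 20)
    lab[5:10, 5:10] <- 1L; lab[14:18, 14:18] <- 2L
    seg <- list(labels = lab,
                nuclei = data.frame(nucleus_id = 1:2, area_px = c(36L, 25L)))
    foci <- data.frame(id = 1:3,
                       centroid_y = c(6, 15, 1), centroid_x = c(6, 15, 1),
                       area_px = 1L, area_um2 = 0.01,
                       mean_intensity = 1, nucleus_id = NA_integer_)
    out <- countFociPerNucleus(foci, seg, pixelSize = 0.1)
    expect_equal(out$nuclei$foci_count, c(1L, 1L))
    expect_true(is.na(out$foci$nucleus_id[3]))   # outside every nucleus
    # conservation: assigned + unassigned = total
    expect_equal(sum(out$nuclei$foci_count) + sum(is.na(out$foci$nucleus_id)),
                 nrow(foci))

    # no foci: all counts zero
    out0 <- countFociPerNucleus(foci[0, ], seg, pixelSize = 0.1)
    expect_equal(out0$nuclei$foci_count, c(0L, 0L))
})

test_that("positivity uses an inclusive cutoff and summary arithmetic", {
    expect_identical(classifyPositive(c(0, 19, 20, 25), 20),
                     c(FALSE, FALSE, TRUE, TRUE))
    expect_error(classifyPositive(5, 0), ">= 1")

    nuc <- data.frame(nucleus_id = 1:10, area_um2 = 1,
                      foci_count = c(rep(25, 3), rep(5, 7)))
    nuc <- classifyPositive(nuc, 20)
    s <- summarizeField(nuc)
    expect_equal(s$percent_positive, 30)
    expect_equal(s$n_positive, 3)
    expect_equal(s$mean_foci_per_nucleus, mean(nuc$foci_count))

    allPos <- classifyPositive(data.frame(nucleus_id = 1, area_um2 = 1,
                                          foci_count = 40), 20)
    expect_equal(summarizeField(allPos)$percent_positive, 100)
    nonePos <- classifyPositive(data.frame(nucleus_id = 1, area_um2 = 1,
                                           foci_count = 0), 20)
    expect_equal(summarizeField(nonePos)$percent_positive, 0)
    expect_error(summarizeField(nuc[0, ]), "empty")
})

test_that("raising the positivity cutoff never raises percent positive", {
    set.seed(8)
    counts <- data.frame(nucleus_id = 1:30, area_um2 = 1,
                         foci_count = rpois(30, 15))
    pcts <- vapply(c(1, 5, 10, 20, 30), function(k)
        summarizeField(classifyPositive(counts, k))$percent_positive,
        numeric(1))
    expect_true(all(diff(pcts) <= 0))
})

test_that("pipeline recovers exact per-nucleus counts on clean fields", {
    # high SNR, no noise: per-nucleus counts exact for >= 95% of nuclei
    nok <- 0L; ntot <- 0L
    for (s in 1:20) {
        f <- makeFociField(cleanFieldSpec(c(3, 10), seed = 100 + s,
                                          shape = c(224L, 224L),
                                          radius = 3))
        res <- quantifyFoci(f$stack)
        ntot <- ntot + 2L
        if (nrow(res$nuclei) == 2L)
            nok <- nok + sum(sort(res$nuclei$foci_count) == c(3L, 10L))
    }
    expect_gte(nok / ntot, 0.95)

    # one denser field with counts spanning the positivity cutoff
    f <- makeFociField(cleanFieldSpec(c(19, 20, 25), seed = 77,
                                      shape = c(360L, 360L), radius = 3.8))
    res <- quantifyFoci(f$stack)
    expect_equal(sort(res$nuclei$foci_count), c(19L, 20L, 25L))
    expect_equal(sort(res$nuclei$foci_positive), c(FALSE, TRUE, TRUE))
})
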