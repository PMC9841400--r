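test_that("range threshold is inclusive at both bounds", {
    img <- matrix(c(549, 550, 30000, 60000, 60001, 0), 2, 3)
    m <- thresholdInRange(img, thresholdRange(550, 60000))
    expect_identical(as.vector(m), c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
    expect_false(any(thresholdInRange(matrix(0, 4, 4),
                                      defaultThresholds()$green)))
    expect_error(thresholdRange(100, 100), "lo < hi")
})

test_that("droplet measurement counts objects and areas correctly", {
    e <- measureDroplets(matrix(FALSE, 8, 8), 0.1)
    expect_equal(e$n_objects, 0)
    expect_equal(e$total_area_um2, 0)

    # one rasterized disc of radius 5 px at 0.1 um/px: area near pi * 0.25
    img <- matrix(0, 40, 40)
    mask <- (row(img) - 20)^2 + (col(img) - 20)^2 <= 25
    st <- measureDroplets(mask, 0.1)
    expect_equal(st$n_objects, 1)
    expect_lt(abs(st$total_area_um2 - pi * 0.25) / (pi * 0.25), 0.10)
    # oracle: explicit pixel count of the same rasterization
    expect_equal(st$total_area_um2, sum(mask) * 0.01)

    # generated field: every disc is found
    d <- makeDropletImage(dropletFieldSpec(nGreen = 12, nRed = 5, seed = 4))
    m <- thresholdInRange(d$green, defaultThresholds()$green)
    expect_equal(measureDroplets(m, d$pixelSize)$n_objects, 12)
    expect_equal(length(measureDroplets(m, d$pixelSize)$object_areas_um2), 12)
})

test_that("Manders coefficients honour their limiting cases", {
    img <- matrix(0, 20, 20)
    img[5:8, 5:8] <- 1000
    # identical channels: M1 = M2 = 1
    cc <- mandersColoc(img, img)
    expect_equal(cc$m1, 1)
    expect_equal(cc$m2, 1)

    # disjoint discs: M1 = M2 = 0
    img2 <- matrix(0, 20, 20); img2[14:17, 14:17] <- 1000
    cc0 <- mandersColoc(img, img2)
    expect_equal(cc0$m1, 0)
    expect_equal(cc0$m2, 0)

    # two equal green discs, one co-centred with red: M1 = 0.5
    g <- matrix(0, 30, 30); g[4:7, 4:7] <- 1000; g[20:23, 20:23] <- 1000
    r <- matrix(0, 30, 30); r[4:7, 4:7] <- 800
    cc5 <- mandersColoc(g, r)
    expect_equal(cc5$m1, 0.5)
    expect_equal(cc5$m2, 1)
    expect_equal(cc5$overlap_area_um2, 16)  # pixelSize 1

    # empty channel: defined as zero with a warning flag
    expect_warning(ccE <- mandersColoc(matrix(0, 5, 5), matrix(0, 5, 5)),
                   "threshold")
    expect_equal(ccE$m1, 0)
    expect_identical(ccE$flag, "empty_channel")
})

test_that("Manders symmetry and scale invariance hold", {
    d <- makeDropletImage(dropletFieldSpec(nGreen = 10, nRed = 8,
                                           colocFraction = 0.5, seed = 9))
    thr <- defaultThresholds()
    a <- mandersColoc(d$green, d$red, thr$green, thr$red)
    b <- mandersColoc(d$red, d$green, thr$red, thr$green)
    expect_equal(a$m1, b$m2)
    expect_equal(a$m2, b$m1)

    # scaling one channel (and its threshold) leaves M1/M2 unchanged
    sc <- mandersColoc(3 * d$green, d$red,
                       thresholdRange(3 * thr$green$lo, 3 * thr$green$hi),
                       thr$red)
    expect_equal(sc$m1, a$m1, tolerance = 1e-12)
    expect_equal(sc$m2, a$m2, tolerance = 1e-12)
})

test_that("enlarging a threshold range never shrinks the mask", {
    d <- makeDropletImage(dropletFieldSpec(nGreen = 6, nRed = 6, seed = 2))
    narrow <- thresholdInRange(d$green, thresholdRange(550, 30000))
    wide <- thresholdInRange(d$green, thresholdRange(300, 60000))
    expect_true(all(wide[narrow]))
    expect_gte(sum(wide), sum(narrow))
})

test_that("dose response finds the step concentration and trivial cases", {
    # step up at 0.03 uM
    set.seed(5)
    concs <- c(0, 0.003, 0.01, 0.03, 0.1, 0.3)
    mkRow <- function(cc, mu) data.frame(concentration_uM = cc,
                                         value = rnorm(4, mu, 1))
    dat <- do.call(rbind, lapply(concs, function(cc)
        mkRow(cc, if (cc >= 0.03) 60 else 2)))
    dr <- doseResponse(dat)
    expect_equal(dr$c_sat_uM, 0.03)
    expect_true(all(dr$table$p_vs_blank[dr$table$concentration_uM >= 0.03] <
                    0.05))

    # all concentrations identical to blank: no c_sat
    flat <- do.call(rbind, lapply(concs, function(cc) mkRow(cc, 2)))
    expect_true(is.na(doseResponse(flat)$c_sat_uM))

    # monotone counts: means increase with concentration
    mono <- do.call(rbind, lapply(seq_along(concs), function(i)
        mkRow(concs[i], 5 * i)))
    tab <- doseResponse(mono)$table
    expect_true(all(diff(tab$mean) > 0))

    expect_error(doseResponse(dat[dat$concentration_uM > 0, ]), "blank")
})

test_that("turbidity summary reports per-condition stats and breakpoint", {
    ts <- makeTurbiditySeries(1:8, cSat = 3, plateauOd = 0.8,
                              noiseSd = 0.005, seed = 6)
    out <- turbiditySummary(ts$series)
    expect_lte(abs(out$breakpoint - 3), 1)   # within one grid step
    expect_equal(nrow(out$table), 8)
    # blank-level condition mean close to the configured baseline
    expect_equal(out$table$mean[1], 0.05, tolerance = 0.02)

    # constant OD: no significant pairs
    set.seed(3)
    flat <- data.frame(condition = rep(1:4, each = 3),
                       od340 = rnorm(12, 0.1, 0.01))
    tf <- turbiditySummary(flat)
    expect_true(all(tf$table$p[-1] > 0.05))

    # single replicate: means only, with a warning
    single <- data.frame(condition = 1:3, od340 = c(0.1, 0.2, 0.3))
    expect_warning(ts1 <- turbiditySummary(single), "single replicate")
    expect_true(all(is.na(ts1$table$p)))
})

test_that("generated colocalization fraction is recovered by Manders M1", {
    m1s <- vapply(1:50, function(s) {
        d <- makeDropletImage(dropletFieldSpec(nGreen = 40, nRed = 40,
            colocFraction = 0.5, seed = 500 + s))
        mandersColoc(d$green, d$red, pixelSize = d$pixelSize)$m1
    }, numeric(1))
    expect_lt(abs(mean(m1s) - 0.5), 0.05)

    # full overlap limit
    dFull <- makeDropletImage(dropletFieldSpec(nGreen = 10, nRed = 10,
        colocFraction = 1, noiseSd = 0, seed = 1))
    expect_equal(mandersColoc(dFull$green, dFull$red)$m1, 1)
})
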