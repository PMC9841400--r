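test_that("double normalization has the stated invariances", {
    t <- seq(0, 10, 0.5)
    # bleached identical to reference: normalized trace is exactly 1
    tr <- recoveryTrace(t, rep(300, length(t)), rep(300, length(t)), 4)
    expect_equal(normalizeTrace(tr)@values, rep(1, length(t)))

    # acquisition photobleaching cancels: beta > 0 equals beta = 0
    mk <- function(beta) makeFrapTrace(frapTraceSpec(tHalf = 3,
        mobileFraction = 60, acquisitionDecayRate = beta, noiseSd = 0,
        seed = 1))$trace
    n0 <- normalizeTrace(mk(0))@values
    nb <- normalizeTrace(mk(0.05))@values
    expect_equal(nb, n0, tolerance = 1e-9)

    # scaling the bleached channel is absorbed by the pre-bleach ratio
    tr2 <- recoveryTrace(t, 2 * tr@bleached, tr@reference, 4)
    expect_equal(normalizeTrace(tr2)@values, normalizeTrace(tr)@values)

    expect_error(recoveryTrace(t, rep(1, length(t)), rep(0, length(t)), 4),
                 "positive")
})

test_that("noiseless fits recover the generating parameters exactly", {
    tr <- makeFrapTrace(frapTraceSpec(tHalf = 3.8, mobileFraction = 51,
                                      noiseSd = 0))$trace
    fit <- fitRecovery(tr)
    expect_equal(tHalf(fit), 3.8, tolerance = 1e-6)
    expect_equal(mobileFraction(fit), 51, tolerance = 1e-6)
    expect_equal(tHalf(fit), log(2) / recoveryRate(fit))

    # full recovery: mobile fraction 100
    tr100 <- makeFrapTrace(frapTraceSpec(tHalf = 2, mobileFraction = 100,
                                         noiseSd = 0))$trace
    expect_equal(mobileFraction(fitRecovery(tr100)), 100, tolerance = 1e-6)
})

test_that("fit is invariant to a constant shift of the time axis", {
    tr <- makeFrapTrace(frapTraceSpec(tHalf = 4, mobileFraction = 70,
                                      noiseSd = 0.02, seed = 3))$trace
    f1 <- fitRecovery(tr)
    tr2 <- recoveryTrace(tr@times + 12.5, tr@bleached, tr@reference,
                         tr@nPreFrames)
    f2 <- fitRecovery(tr2)
    expect_equal(recoveryRate(f2), recoveryRate(f1), tolerance = 1e-9)
    expect_equal(mobileFraction(f2), mobileFraction(f1), tolerance = 1e-9)
})

test_that("fitted plateau increases strictly with generator mobile fraction", {
    plateaus <- vapply(c(20, 40, 60, 80, 100), function(m) {
        tr <- makeFrapTrace(frapTraceSpec(tHalf = 3, mobileFraction = m,
                                          noiseSd = 0))$trace
        fitRecovery(tr)@fInf
    }, numeric(1))
    expect_true(all(diff(plateaus) > 0))
})

test_that("parameter recovery from noisy traces is nearly unbiased", {
    fitAt <- function(sigma, n = 100) {
        fits <- lapply(seq_len(n), function(i) fitRecovery(makeFrapTrace(
            frapTraceSpec(tHalf = 3, mobileFraction = 80, noiseSd = sigma,
                          seed = 2000 + i))$trace))
        c(t = mean(vapply(fits, tHalf, numeric(1))),
          m = mean(vapply(fits, mobileFraction, numeric(1))))
    }
    lo <- fitAt(0.01)
    expect_lt(abs(lo["t"] - 3) / 3, 0.02)
    expect_lt(abs(lo["m"] - 80) / 80, 0.02)
    hi <- fitAt(0.03)
    expect_lt(abs(hi["t"] - 3) / 3, 0.05)
    expect_lt(abs(hi["m"] - 80) / 80, 0.05)
})

test_that("immobile condensates fit to a mobile fraction near zero", {
    mob <- vapply(1:40, function(i) mobileFraction(fitRecovery(
        makeFrapTrace(frapTraceSpec(tHalf = 3, mobileFraction = 0,
                                    noiseSd = 0.02,
                                    seed = 300 + i))$trace)), numeric(1))
    expect_lt(abs(mean(mob)), 3)
})

test_that("degenerate traces are rejected with informative errors", {
    t <- seq(0, 5, 0.5)
    up <- recoveryTrace(t, c(rep(100, 3), seq(120, 200, length.out = 8)),
                        rep(100, 11), 3)
    expect_error(fitRecovery(up), "no bleach")
    short <- makeFrapTrace(frapTraceSpec(duration = 3,
        nPreFrames = 3, noiseSd = 0))$trace
    expect_error(fitRecovery(short), "post-bleach frames")
})

test_that("population summary matches the t-interval formula", {
    mkFit <- function(th, mob) {
        tr <- makeFrapTrace(frapTraceSpec(tHalf = th, mobileFraction = mob,
                                          noiseSd = 0))$trace
        fitRecovery(tr)
    }
    fits <- lapply(1:5, function(i) mkFit(i, 50))
    s <- summarizePopulation(fits, "tHalf")
    v <- 1:5
    half <- qt(0.975, 4) * sd(v) / sqrt(5)
    expect_equal(s$mean, 3, tolerance = 1e-6)
    expect_equal(s$ci_lo, 3 - half, tolerance = 1e-5)
    expect_equal(s$ci_hi, 3 + half, tolerance = 1e-5)

    # identical fits: zero-width interval
    same <- lapply(1:3, function(i) mkFit(2.5, 60))
    s2 <- summarizePopulation(same, "mobileFraction")
    expect_equal(s2$ci_lo, s2$ci_hi, tolerance = 1e-6)
    expect_equal(s2$mean, 60, tolerance = 1e-5)

    expect_error(summarizePopulation(fits[1], "tHalf"), "at least 2")
})

test_that("population CI covers the truth at close to nominal rate", {
    # 21 foci per repetition, as in the cellular FRAP population
    covered <- vapply(1:60, function(r) {
        fits <- lapply(1:21, function(i) fitRecovery(makeFrapTrace(
            frapTraceSpec(tHalf = 3, mobileFraction = 80, noiseSd = 0.03,
                          seed = r * 100 + i))$trace))
        s <- summarizePopulation(fits, "tHalf")
        s$ci_lo <= 3 && 3 <= s$ci_hi
    }, logical(1))
    expect_gte(mean(covered), 0.80)
})
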