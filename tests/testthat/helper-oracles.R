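# Independent brute-force oracles used by the tests. These deliberately
# avoid the package's own code paths.

# per-pixel maximum over z by explicit triple loop
oracleMaxProject <- function(chArr) {
    d <- dim(chArr)   # z, y, x
    out <- matrix(-Inf, d[2L], d[3L])
    for (z in seq_len(d[1L]))
        for (y in seq_len(d[2L]))
            for (x in seq_len(d[3L]))
                out[y, x] <- max(out[y, x], chArr[z, y, x])
    out
}

# local mean/SD threshold with reflective padding, computed directly
# per pixel (no integral images)
oracleAdaptive <- function(img, w, k) {
    p <- (w - 1L) %/% 2L
    nr <- nrow(img); nc <- ncol(img)
    mirror <- function(i, n) {
        i <- ifelse(i < 1L, 2L - i, i)
        ifelse(i > n, 2L * n - i, i)
    }
    tol <- 1e-6 * diff(range(img))
    out <- matrix(FALSE, nr, nc)
    for (y in seq_len(nr)) for (x in seq_len(nc)) {
        ys <- mirror((y - p):(y + p), nr)
        xs <- mirror((x - p):(x + p), nc)
        v <- img[ys, xs]
        mu <- mean(v)
        s <- sqrt(mean((v - mu)^2))
        out[y, x] <- (img[y, x] - mu) > k * s + tol
    }
    out
}

# pooled-variance two-sample t statistic and two-sided p, by the
# textbook formula
oraclePooledT <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# one-way ANOVA F and p from explicit sums of squares
oracleAnovaF <- function(groups) {
    y <- unlist(groups)
    k <- length(groups); N <- length(y)
    gm <- mean(y)
    ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2,
                      numeric(1)))
    ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
    f <- (ssb / (k - 1)) / (ssw / (N - k))
    list(F = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# small high-SNR noise-free foci field used by end-to-end checks
cleanFieldSpec <- function(counts, seed, shape = c(256L, 256L),
                           radius = 2.5) {
    fociFieldSpec(fieldShape = shape, nZ = 7L, nNuclei = length(counts),
                  nucleusRadius = radius, fociPerNucleus = counts,
                  focusAmplitude = 200, nucleoplasmLevel = 20,
                  backgroundLevel = 5, readNoiseSd = 0, shotNoise = FALSE,
                  seed = seed)
}
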