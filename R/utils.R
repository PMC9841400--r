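# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never perturb the
# session RNG stream.
withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Derive a bounded sub-seed from a master seed and an index; keeps every
# derived seed inside 32-bit integer range.
deriveSeed <- function(seed, i) {
    as.integer((as.numeric(seed) * 10007 + i * 7919) %% .Machine$integer.max)
}

stopifnotScalar <- function(x, name, positive = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        stop("'", name, "' must be a single finite number", call. = FALSE)
    if (positive && x <= 0)
        stop("'", name, "' must be > 0", call. = FALSE)
    invisible(x)
}

# Reflective (mirror) padding of a matrix by `p` pixels on every side.
padReflect <- function(m, p) {
    nr <- nrow(m); nc <- ncol(m)
    if (p >= nr || p >= nc)
        stop("padding exceeds image size", call. = FALSE)
    ri <- c(rev(seq_len(p) + 1L), seq_len(nr), nr - seq_len(p))
    ci <- c(rev(seq_len(p) + 1L), seq_len(nc), nc - seq_len(p))
    m[ri, ci, drop = FALSE]
}

# Local box sums via a summed-area table; `m` already padded, `w` odd
# window width. Returns matrix of the original (unpadded) size.
boxSum <- function(mPad, w, nr, nc) {
    sat <- apply(apply(mPad, 2L, cumsum), 1L, cumsum)
    sat <- t(sat)
    sat <- rbind(0, cbind(0, sat))
    # for output pixel (i, j) (1-based in original frame) the window in the
    # padded frame spans rows i..i+w-1, cols j..j+w-1
    i2 <- seq_len(nr) + w; j2 <- seq_len(nc) + w
    i1 <- seq_len(nr); j1 <- seq_len(nc)
    sat[i2, j2, drop = FALSE] - sat[i1, j2, drop = FALSE] -
        sat[i2, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]
}

# Connected-component labelling. EBImage::bwlabel is 4-connected; for
# 8-connectivity diagonal-adjacent labels are merged with a union-find
# pass over the two diagonal shift directions.
labelComponents <- function(mask, connectivity = 8L) {
    stopifnot(connectivity %in% c(4L, 8L))
    lab <- EBImage::bwlabel(mask * 1)
    lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
    nlab <- max(lab)
    if (connectivity == 4L || nlab <= 1L)
        return(relabelRaster(lab))
    parent <- seq_len(nlab)
    findRoot <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
        cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
        cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))
    )
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    if (nrow(pairs)) {
        pairs <- unique(pairs)
        for (r in seq_len(nrow(pairs))) {
            a <- findRoot(pairs[r, 1L]); b <- findRoot(pairs[r, 2L])
            if (a != b) parent[max(a, b)] <- min(a, b)
        }
        roots <- vapply(seq_len(nlab), findRoot, integer(1))
        lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
    relabelRaster(lab)
}

# Renumber labels 1..n in raster order of each component's first
# (minimum linear-index, column-major by row) pixel so ids are
# deterministic.
relabelRaster <- function(lab) {
    if (max(lab) == 0L) return(lab)
    nr <- nrow(lab)
    idx <- which(lab > 0L)
    # raster order: by row, then column
    row <- (idx - 1L) %% nr + 1L
    col <- (idx - 1L) %/% nr + 1L
    ord <- order(row, col)
    firstSeen <- !duplicated(lab[idx][ord])
    old <- lab[idx][ord][firstSeen]
    map <- integer(max(lab))
    map[old] <- seq_along(old)
    lab[idx] <- map[lab[idx]]
    lab
}
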