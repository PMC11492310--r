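# Independent oracles and small fixture builders. All oracles are
# deliberately naive (pairwise distances, recursive flood fill,
# per-point crossing counts) so they share no code path with the
# implementations they check.

# brute-force physical dilation: voxel in result iff its center is within
# margin of some foreground center
bruteDilate <- function(voxels, spacing, margin_mm) {
    d <- dim(voxels)
    idx <- which(voxels, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(voxels)
    fg <- cbind(idx[, 1L] * spacing[1L], idx[, 2L] * spacing[2L],
                idx[, 3L] * spacing[3L])
    all_idx <- as.matrix(expand.grid(i = seq_len(d[1L]), j = seq_len(d[2L]),
                                     k = seq_len(d[3L])))
    pts <- cbind(all_idx[, 1L] * spacing[1L], all_idx[, 2L] * spacing[2L],
                 all_idx[, 3L] * spacing[3L])
    m2 <- margin_mm^2 + 1e-9
    d2 <- outer(pts[, 1L], fg[, 1L], `-`)^2 +
          outer(pts[, 2L], fg[, 2L], `-`)^2 +
          outer(pts[, 3L], fg[, 3L], `-`)^2
    array(rowSums(d2 <= m2) > 0L, d)
}

# iterative flood fill counting 26-connected components
floodFillComponents <- function(voxels) {
    d <- dim(voxels)
    seen <- array(FALSE, d)
    n <- 0L
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
    for (s in which(voxels & !seen)) {
        if (seen[s]) next
        n <- n + 1L
        queue <- s
        seen[s] <- TRUE
        while (length(queue)) {
            cur <- queue[length(queue)]
            queue <- queue[-length(queue)]
            ci <- arrayInd(cur, d)
            for (o in seq_len(nrow(offs))) {
                p <- ci + offs[o, ]
                if (any(p < 1L) || any(p > d)) next
                lin <- p[1L] + (p[2L] - 1L) * d[1L] +
                    (p[3L] - 1L) * d[1L] * d[2L]
                if (voxels[lin] && !seen[lin]) {
                    seen[lin] <- TRUE
                    queue <- c(queue, lin)
                }
            }
        }
    }
    n
}

# per-point even-odd crossing test, same half-open convention as the
# rasterizer but coded independently (scalar loop over edges)
pointInPolyOracle <- function(x, y, vx, vy) {
    n <- length(vx)
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
        if ((vy[i] > y) != (vy[j] > y)) {
            xint <- vx[i] + (y - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
            if (x < xint) inside <- !inside
        }
        j <- i
    }
    inside
}

# O(n^2) symmetric mean surface distance over explicit surface voxel sets
bruteMsd <- function(va, vb, spacing) {
    surf <- function(v) {
        d <- dim(v)
        out <- array(FALSE, d)
        for (i in seq_len(d[1L])) for (j in seq_len(d[2L]))
            for (k in seq_len(d[3L])) {
                if (!v[i, j, k]) next
                nb <- c(
                    if (i > 1L) v[i - 1L, j, k] else FALSE,
                    if (i < d[1L]) v[i + 1L, j, k] else FALSE,
                    if (j > 1L) v[i, j - 1L, k] else FALSE,
                    if (j < d[2L]) v[i, j + 1L, k] else FALSE,
                    if (k > 1L) v[i, j, k - 1L] else FALSE,
                    if (k < d[3L]) v[i, j, k + 1L] else FALSE)
                if (!all(nb)) out[i, j, k] <- TRUE
            }
        out
    }
    pts <- function(v) {
        w <- which(surf(v), arr.ind = TRUE)
        cbind(w[, 1L] * spacing[1L], w[, 2L] * spacing[2L],
              w[, 3L] * spacing[3L])
    }
    pa <- pts(va); pb <- pts(vb)
    dmin <- function(p, q) {
        vapply(seq_len(nrow(p)), function(r)
            sqrt(min((q[, 1L] - p[r, 1L])^2 + (q[, 2L] - p[r, 2L])^2 +
                     (q[, 3L] - p[r, 3L])^2)), numeric(1))
    }
    (mean(dmin(pa, pb)) + mean(dmin(pb, pa))) / 2
}

# seeded random blob mask: a few dilated seed points
randomBlobMask <- function(shape, density = 0.02) {
    v <- array(stats::runif(prod(shape)) < density, shape)
    v
}

unitGrid <- function(shape = c(10L, 10L, 10L), spacing = c(1, 1, 1),
                     origin = c(0, 0, 0)) {
    ImageGrid(as.integer(shape), spacing, origin)
}

voxMask <- function(grid, ..., name = "m") {
    v <- array(FALSE, gridShape(grid))
    idx <- list(...)
    for (p in idx) v[p[1L], p[2L], p[3L]] <- TRUE
    StructureMask(name, grid, v)
}

# shared heavyweight fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

defaultPhantom <- function() {
    if (is.null(.fixture_env$phantom))
        .fixture_env$phantom <- generatePhantom(phantomSpec(seed = 7))
    .fixture_env$phantom
}

defaultPipeline <- function() {
    if (is.null(.fixture_env$pipeline)) {
        ph <- defaultPhantom()
        .fixture_env$pipeline <- runPipeline(ph$structures, ph$tumor)
    }
    .fixture_env$pipeline
}

scenarioSuite <- function() {
    if (is.null(.fixture_env$suite))
        .fixture_env$suite <- generateScenarioSuite(seed = 1)
    .fixture_env$suite
}
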