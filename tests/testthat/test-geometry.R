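test_that("margin expansion equals brute-force dilation and derived counts", {
    # single center voxel derived counts at two spacings
    g <- unitGrid(c(9L, 9L, 9L))
    m <- voxMask(g, c(5, 5, 5))
    expect_identical(maskVoxels(expandMask(m, 0)), maskVoxels(m))
    expect_identical(sum(maskVoxels(expandMask(m, 3))), 123L)
    ga <- unitGrid(c(9L, 9L, 9L), spacing = c(2.5, 1, 1))
    ma <- voxMask(ga, c(5, 5, 5))
    expect_identical(sum(maskVoxels(expandMask(ma, 3))), 47L)
    expect_warning(out <- expandMask(StructureMask("e", g), 3), "empty")
    expect_true(isEmptyMask(out))
    # random masks at several anisotropic spacings, voxel-for-voxel
    set.seed(101)
    spacings <- list(c(1, 1, 1), c(2.5, 1, 1), c(2, 0.98, 0.98))
    for (r in 1:9) {
        sp <- spacings[[(r - 1L) %% 3L + 1L]]
        shape <- c(8L, 9L, 7L)
        v <- randomBlobMask(shape, density = 0.05)
        if (!any(v)) v[3, 3, 3] <- TRUE
        gg <- unitGrid(shape, spacing = sp)
        mm <- StructureMask("m", gg, v)
        margin <- c(1.5, 2.5, 3)[(r - 1L) %/% 3L + 1L]
        expect_identical(maskVoxels(expandMask(mm, margin)),
                         bruteDilate(v, sp, margin),
                         info = sprintf("rep %d", r))
    }
})

test_that("expansion is monotone in mask and margin, origin-invariant", {
    set.seed(7)
    shape <- c(8L, 8L, 8L)
    v <- randomBlobMask(shape, 0.08); v[4, 4, 4] <- TRUE
    g <- unitGrid(shape, spacing = c(2.5, 1, 1))
    a <- StructureMask("a", g, v)
    bvox <- v; bvox[2, 6, 3] <- TRUE
    b <- StructureMask("b", g, bvox)
    ea <- maskVoxels(expandMask(a, 2)); eb <- maskVoxels(expandMask(b, 2))
    expect_true(all(!ea | eb))                       # A subset B preserved
    e1 <- maskVoxels(expandMask(a, 1.2))
    expect_true(all(!e1 | ea))                       # smaller margin nested
    expect_true(all(!v | ea))                        # input always kept
    g2 <- unitGrid(shape, spacing = c(2.5, 1, 1), origin = c(40, -12, 7))
    a2 <- StructureMask("a", g2, v)
    expect_identical(maskVoxels(expandMask(a2, 2)), ea)
})

test_that("protected subtraction never removes the protected zone", {
    g <- unitGrid(c(12L, 12L, 12L))
    gtv <- voxMask(g, name = "gtv")
    vg <- array(FALSE, c(12, 12, 12)); vg[5:8, 5:8, 5:8] <- TRUE
    gtv <- StructureMask("gtv", g, vg)
    target <- expandMask(gtv, 3, name = "ctv")
    oarVox <- array(FALSE, c(12, 12, 12)); oarVox[, 10:12, ] <- TRUE
    oar <- StructureMask("brainstem", g, oarVox)
    out <- subtractProtected(target, list(oar), gtv, 0)
    expect_true(all(!(maskVoxels(out) & oarVox & !vg)))  # OAR cleared
    expect_true(all(!vg | maskVoxels(out)))              # GTV intact
    expect_true(all(!maskVoxels(out) | maskVoxels(target)))  # subset
    # disjoint subtrahend leaves the target untouched
    far <- voxMask(g, c(1, 1, 1), name = "far")
    expect_identical(maskVoxels(subtractProtected(target, list(far), gtv, 0)),
                     maskVoxels(target))
    # full protection with a margin covering the expansion
    out2 <- subtractProtected(target, list(oar), target, 0)
    expect_identical(maskVoxels(out2), maskVoxels(target))
    # floor margin keeps a shell: with min margin 1 the OAR voxels within
    # 1 mm of the GTV survive
    out3 <- subtractProtected(target, list(oar), gtv, 1)
    shell <- maskVoxels(expandMask(gtv, 1))
    expect_identical(maskVoxels(out3),
                     maskVoxels(target) & (!oarVox | shell))
})

test_that("centroid split partitions at the weighted slice", {
    g <- unitGrid(c(20L, 8L, 8L))
    # heavy mass on slices 15-16 plus one voxel 10 slices above (superior)
    v <- array(FALSE, c(20, 8, 8))
    v[15:16, 3:6, 3:6] <- TRUE
    v[5, 4, 4] <- TRUE
    m <- StructureMask("sphenoid_sinus", g, v)
    parts <- splitInferiorAtCentroid(m)
    counts <- sum(v[15:16, , ])
    cFrac <- (sum(15:16) / 2 * counts + 5) / (counts + 1)
    cIdx <- floor(cFrac + 0.5)
    expect_true(cIdx >= 15 - 1)                      # near the heavy end
    infSlices <- which(apply(maskVoxels(parts$inferior), 1L, any))
    expect_true(all(c(15L, 16L) %in% infSlices))
    # exact partition
    expect_identical(maskVoxels(parts$inferior) | maskVoxels(parts$superior), v)
    expect_false(any(maskVoxels(parts$inferior) & maskVoxels(parts$superior)))
    # single-slice mask: all inferior
    v1 <- array(FALSE, c(20, 8, 8)); v1[9, 2:4, 2:4] <- TRUE
    p1 <- splitInferiorAtCentroid(StructureMask("s", g, v1))
    expect_identical(maskVoxels(p1$inferior), v1)
    expect_true(isEmptyMask(p1$superior))
    expect_error(splitInferiorAtCentroid(StructureMask("e", g)), "empty")
})

test_that("bounding boxes and candidate grids follow voxel centers", {
    g <- unitGrid(c(4L, 10L, 10L), origin = c(0, 2, 5))
    m <- voxMask(g, c(2, 3, 4))
    bb <- boundingBox(m, 2L)
    expect_equal(unname(bb), c(8, 8, 4, 4))  # degenerate box at the center
    # 5 x 3 voxel rectangle: width 4 mm, height 2 mm center-to-center
    v <- array(FALSE, c(4, 10, 10)); v[2, 4:6, 3:7] <- TRUE
    bb2 <- boundingBox(StructureMask("m", g, v), 2L)
    expect_equal(bb2[["xmax"]] - bb2[["xmin"]], 4)
    expect_equal(bb2[["ymax"]] - bb2[["ymin"]], 2)
    # L-shape: box is the enclosing rectangle
    v[2, 4, 3:9] <- TRUE
    bb3 <- boundingBox(StructureMask("m", g, v), 2L)
    expect_equal(bb3[["xmax"]], 5 + 8)
    expect_error(boundingBox(StructureMask("m", g, v), 1L), "empty")
    # candidate grids
    pts <- gridPoints(c(xmin = 0, xmax = 1, ymin = 0, ymax = 1))
    expect_identical(nrow(pts), 49L)
    expect_equal(sort(unique(pts[, 1L])), seq(0, 1, by = 1 / 6))
    deg <- gridPoints(c(xmin = 2, xmax = 2, ymin = 3, ymax = 3))
    expect_true(all(deg[, 1L] == 2) && all(deg[, 2L] == 3))
    four <- gridPoints(c(xmin = 0, xmax = 6, ymin = 0, ymax = 6), 2L, 2L)
    expect_equal(unname(four), cbind(c(0, 6, 0, 6), c(0, 0, 6, 6)))
})

test_that("Chaikin smoothing cuts corners with the 1/4-3/4 rule", {
    sq <- SlicePolygon(1L, cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
    expect_identical(polygonVertices(chaikinSmooth(sq, 0)),
                     polygonVertices(sq))
    oct <- chaikinSmooth(sq, 1)
    expected <- cbind(c(0.25, 0.75, 1, 1, 0.75, 0.25, 0, 0),
                      c(0, 0, 0.25, 0.75, 1, 1, 0.75, 0.25))
    expect_equal(unname(polygonVertices(oct)), expected)
    # vertex count law and convex-hull containment
    set.seed(3)
    for (n in c(3L, 5L, 8L)) {
        ang <- sort(stats::runif(n, 0, 2 * pi))
        v <- cbind(cos(ang), sin(ang)) * stats::runif(n, 1, 2)
        p <- SlicePolygon(1L, v)
        for (k in 0:3) {
            out <- chaikinSmooth(p, k)
            expect_equal(nrow(polygonVertices(out)), n * 2^k)
        }
        sm <- polygonVertices(chaikinSmooth(p, 3))
        hull <- v[grDevices::chull(v), , drop = FALSE]
        inHull <- vapply(seq_len(nrow(sm)), function(i) {
            # point-in-convex-hull via sign of cross products
            h <- rbind(hull, hull[1L, ])
            cr <- (h[-1L, 1L] - h[-nrow(h), 1L]) * (sm[i, 2L] - h[-nrow(h), 2L]) -
                  (h[-1L, 2L] - h[-nrow(h), 2L]) * (sm[i, 1L] - h[-nrow(h), 1L])
            all(cr <= 1e-9) || all(cr >= -1e-9)
        }, logical(1))
        expect_true(all(inHull))
    }
    expect_error(chaikinSmooth(SlicePolygon(1L, cbind(0:1, 0:1))),
                 "vertices")
})

test_that("polygon rasterization matches the even-odd oracle", {
    g <- unitGrid(c(1L, 12L, 12L))
    # square aligned to voxel centers
    sq <- SlicePolygon(1L, cbind(c(3, 7, 7, 3), c(3, 3, 7, 7)))
    m <- polygonToMask(sq, g)
    oracle <- array(FALSE, c(1, 12, 12))
    for (j in 1:12) for (k in 1:12)
        oracle[1, j, k] <- pointInPolyOracle(k - 1, j - 1,
                                             c(3, 7, 7, 3), c(3, 3, 7, 7))
    expect_identical(maskVoxels(m), oracle)
    # translation by exactly one spacing unit preserves the count
    sq2 <- SlicePolygon(1L, cbind(c(4, 8, 8, 4), c(3, 3, 7, 7)))
    expect_identical(sum(maskVoxels(polygonToMask(sq2, g))),
                     sum(maskVoxels(m)))
    # random simple polygons against the oracle
    set.seed(21)
    for (r in 1:5) {
        ang <- sort(stats::runif(6, 0, 2 * pi))
        v <- cbind(5.5 + 4 * stats::runif(6, 0.4, 1) * cos(ang),
                   5.5 + 4 * stats::runif(6, 0.4, 1) * sin(ang))
        p <- SlicePolygon(1L, v)
        got <- maskVoxels(polygonToMask(p, g))
        want <- array(FALSE, c(1, 12, 12))
        for (j in 1:12) for (k in 1:12)
            want[1, j, k] <- pointInPolyOracle(k - 1, j - 1, v[, 1L], v[, 2L])
        expect_identical(got, want, info = sprintf("poly %d", r))
    }
    # sub-voxel triangle neither crashes nor goes negative
    tri <- SlicePolygon(1L, cbind(c(5, 5.3, 5.1), c(5, 5.1, 5.3)))
    expect_gte(sum(maskVoxels(polygonToMask(tri, g))), 0L)
    far <- SlicePolygon(1L, cbind(c(50, 60, 55), c(50, 50, 60)))
    expect_error(polygonToMask(far, g), "outside")
})

test_that("connected components agree with a flood-fill oracle", {
    g <- unitGrid(c(6L, 6L, 6L))
    # diagonal touch is one component under 26-connectivity
    m <- voxMask(g, c(2, 2, 2), c(3, 3, 3))
    expect_length(connectedComponents(m), 1L)
    # a one-voxel gap makes two
    m2 <- voxMask(g, c(2, 2, 2), c(2, 2, 4))
    expect_length(connectedComponents(m2), 2L)
    set.seed(5)
    for (r in 1:4) {
        v <- randomBlobMask(c(7L, 7L, 7L), 0.12)
        mm <- StructureMask("m", unitGrid(c(7L, 7L, 7L)), v)
        cc <- connectedComponents(mm)
        expect_identical(length(cc), floodFillComponents(v))
        if (length(cc)) {
            expect_identical(Reduce(`|`, lapply(cc, maskVoxels)), v)
            if (length(cc) > 1L)
                expect_false(any(maskVoxels(cc[[1L]]) & maskVoxels(cc[[2L]])))
        }
    }
})

test_that("equivalent sphere diameter follows the closed form", {
    g <- unitGrid(c(20L, 20L, 20L))
    # V = 1 cm^3 as a 10 x 10 x 10 block of 1 mm voxels
    v <- array(FALSE, c(20, 20, 20)); v[1:10, 1:10, 1:10] <- TRUE
    expect_equal(equivalentSphereDiameter(StructureMask("m", g, v)),
                 1.240701, tolerance = 1e-6)
    # V = (4/3) pi cm^3 gives exactly 2 cm
    vol_mm3 <- (4 / 3) * pi * 1000
    gg <- ImageGrid(c(10L, 10L, 10L), c(vol_mm3 / 100, 1, 1))
    v2 <- array(FALSE, c(10, 10, 10)); v2[1, 1:10, 1:10] <- TRUE
    expect_equal(equivalentSphereDiameter(StructureMask("m", gg, v2)), 2)
    expect_identical(equivalentSphereDiameter(StructureMask("e", g)), 0)
})

test_that("alpha-shape joining bridges near islands and leaves far ones", {
    g <- ImageGrid(c(1L, 60L, 60L), c(2.5, 1, 1))
    v <- array(FALSE, c(1, 60, 60))
    v[1, 20:29, 10:19] <- TRUE
    v[1, 20:29, 25:34] <- TRUE   # 5 mm gap
    m <- StructureMask("ctv3", g, v)
    joined <- alphashapeJoin(m, alpha = 0.2, max_gap_mm = 15)
    expect_length(connectedComponents(joined), 1L)
    expect_true(all(!v | maskVoxels(joined)))        # input preserved
    # single component: unchanged
    v1 <- array(FALSE, c(1, 60, 60)); v1[1, 10:40, 10:40] <- TRUE
    m1 <- StructureMask("c", g, v1)
    expect_identical(maskVoxels(alphashapeJoin(m1)), v1)
    # islands beyond the gap threshold stay unmerged and untouched
    v2 <- array(FALSE, c(1, 60, 60))
    v2[1, 20:29, 5:9] <- TRUE
    v2[1, 20:29, 50:54] <- TRUE  # 40 mm apart
    m2 <- StructureMask("c", g, v2)
    out2 <- alphashapeJoin(m2, alpha = 0.2, max_gap_mm = 15)
    expect_length(connectedComponents(out2), 2L)
    expect_identical(maskVoxels(out2), v2)
})

test_that("morphological refinement fills holes and prunes specks", {
    g <- unitGrid(c(20L, 20L, 20L))
    cube <- array(FALSE, c(20, 20, 20)); cube[5:16, 5:16, 5:16] <- TRUE
    m <- StructureMask("c", g, cube)
    # a large convex solid changes only in a thin boundary layer
    out <- morphRefine(m, open_mm = 1, close_mm = 2.5,
                       min_hole_voxels = 100L, min_island_voxels = 50L)
    changed <- maskVoxels(out) != cube
    expect_lt(sum(changed) / sum(cube), 0.1)
    shellZone <- maskVoxels(expandMask(m, 2)) &
        !maskVoxels(npCTV:::erodeMask(m, 2))
    expect_true(all(!changed | shellZone))
    # an interior hole voxel is filled
    hole <- cube; hole[10, 10, 10] <- FALSE
    mh <- morphRefine(StructureMask("c", g, hole), open_mm = 0, close_mm = 0,
                      min_hole_voxels = 10L, min_island_voxels = 0L)
    expect_identical(maskVoxels(mh), cube)
    # a distant speck is dropped unless it intersects the keep mask
    speck <- cube; speck[1, 1, 1:2] <- TRUE
    ms <- StructureMask("c", g, speck)
    dropped <- morphRefine(ms, open_mm = 0, close_mm = 0,
                           min_hole_voxels = 0L, min_island_voxels = 50L)
    expect_identical(maskVoxels(dropped), cube)
    keep <- voxMask(g, c(1, 1, 1), name = "gtv")
    kept <- morphRefine(ms, open_mm = 0, close_mm = 0,
                        min_hole_voxels = 0L, min_island_voxels = 50L,
                        keep = keep)
    expect_identical(maskVoxels(kept), speck)
})
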