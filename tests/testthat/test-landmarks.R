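test_that("sphenoid targeting follows the T-stage rule", {
    ph <- defaultPhantom()
    sph <- getStructure(ph$structures, "sphenoid_sinus")
    t1 <- sphenoidTarget(sph, 1L)
    t2 <- sphenoidTarget(sph, 2L)
    t3 <- sphenoidTarget(sph, 3L)
    t4 <- sphenoidTarget(sph, 4L)
    expect_identical(maskVoxels(t3), maskVoxels(sph))   # whole sinus
    expect_identical(maskVoxels(t4), maskVoxels(sph))
    expect_identical(maskVoxels(t1),
                     maskVoxels(splitInferiorAtCentroid(sph)$inferior))
    expect_lt(maskVolume(t2), maskVolume(t3))
    expect_true(all(!maskVoxels(t2) | maskVoxels(t3)))  # nesting
    expect_error(sphenoidTarget(StructureMask("s", maskGrid(sph)), 1L),
                 "empty")
})

test_that("GTVp localization resolves side and touched structures", {
    g <- ImageGrid(c(4L, 20L, 20L), c(2.5, 1, 1))
    mk <- function(cols) {
        v <- array(FALSE, c(4, 20, 20)); v[2:3, 8:12, cols] <- TRUE
        StructureMask("gtvp", g, v)
    }
    clv <- array(FALSE, c(4, 20, 20)); clv[2, 10, 4:6] <- TRUE
    set <- StructureSet(list(clivus = StructureMask("clivus", g, clv)), g)
    # midline x = 9.5; low x = patient right in LPS
    expect_identical(localizeGtvp(mk(2:6), set)$confined_side, "right")
    expect_identical(localizeGtvp(mk(14:18), set)$confined_side, "left")
    expect_identical(localizeGtvp(mk(1:20), set)$confined_side, "bilateral")
    loc <- localizeGtvp(mk(4:6), set)
    expect_true(loc$invades_clivus)
    expect_true("clivus" %in% loc$touches)
    expect_false(localizeGtvp(mk(14:18), set)$invades_clivus)
})

test_that("axial grouping matches the published structure groups", {
    ph <- defaultPhantom()
    ga <- assignAxialGroups(ph$structures)
    groups <- vapply(ga, `[[`, integer(1), "group")
    expect_true(all(1:8 %in% groups))  # default phantom exercises each
    bySlice <- split(vapply(ga, `[[`, integer(1), "slice"), groups)
    # hand-checkable slices: build minimal sets and verify the match
    g <- ImageGrid(c(1L, 30L, 30L), c(2.5, 1, 1))
    blk <- function(nm, cols) {
        v <- array(FALSE, c(1, 30, 30)); v[1, 10:20, cols] <- TRUE
        StructureMask(nm, g, v)
    }
    s1 <- StructureSet(list(blk("LN_RP_L", 18:20), blk("LN_RP_R", 10:12),
                            blk("pterygoid_fossa_L", 24:26),
                            blk("pterygoid_fossa_R", 4:6)), g)
    expect_identical(assignAxialGroups(s1)[[1L]]$group, 1L)
    s4 <- StructureSet(list(blk("clivus", 13:17),
                            blk("pterygoid_fossa_L", 24:26),
                            blk("pterygoid_fossa_R", 4:6),
                            blk("nasopharynx", 13:17)), g)
    expect_identical(assignAxialGroups(s4)[[1L]]$group, 4L)
    s8 <- StructureSet(list(blk("sphenoid_sinus", 12:18)), g)
    expect_identical(assignAxialGroups(s8)[[1L]]$group, 8L)
    # maxillary + sphenoid resolves to the more specific group 7
    s7 <- StructureSet(list(blk("sphenoid_sinus", 12:18),
                            blk("maxillary_sinus_L", 22:26),
                            blk("maxillary_sinus_R", 4:8)), g)
    expect_identical(assignAxialGroups(s7)[[1L]]$group, 7L)
    # insertion order is irrelevant
    s7b <- StructureSet(rev(s7@masks), g)
    expect_identical(assignAxialGroups(s7b)[[1L]]$group, 7L)
    # a slice matching no group stays unassigned
    s0 <- StructureSet(list(blk("clivus", 13:17)), g)
    expect_length(assignAxialGroups(s0), 0L)
})

test_that("landmark selection follows the per-structure anchor rules", {
    g <- ImageGrid(c(1L, 40L, 40L), c(2.5, 1, 1))
    blk <- function(nm, cols, rows) {
        v <- array(FALSE, c(1, 40, 40)); v[1, rows, cols] <- TRUE
        StructureMask(nm, g, v)
    }
    # group 4: clivus 13 x 7 box, pterygoids, nasopharynx
    set <- StructureSet(list(
        blk("clivus", 14:26, 25:31),
        blk("pterygoid_fossa_L", 30:36, 15:23),
        blk("pterygoid_fossa_R", 4:10, 15:23),
        blk("nasopharynx", 14:26, 15:22)), g)
    asg <- assignAxialGroups(set)
    expect_identical(asg[[1L]]$group, 4L)
    locNo <- list(confined_side = "right", invades_clivus = FALSE,
                  touches = character())
    pts <- selectLandmarks(asg[[1L]], set, locNo)
    # clivus, not invaded: the two anterior-third corners. Box x 13-25,
    # y 24-30; the 7x7 y candidates step by 1; fy=1/3 snaps to y 26.
    expect_true(all(c(paste(13, 26), paste(25, 26)) %in%
                    paste(pts[, 1L], pts[, 2L])))
    # pterygoid fossae (uninvolved left side): anterior mid-line point
    expect_true(paste(32, 14) %in% paste(pts[, 1L], pts[, 2L]))
    # involved right side shifts to the lateral (low-x) edge
    expect_true(paste(3, 14) %in% paste(pts[, 1L], pts[, 2L]))
    # invaded clivus moves the posterior boundary to the full box
    locInv <- modifyList(locNo, list(invades_clivus = TRUE,
                                     touches = "clivus"))
    ptsInv <- selectLandmarks(asg[[1L]], set, locInv)
    expect_true(all(c(paste(13, 30), paste(25, 30)) %in%
                    paste(ptsInv[, 1L], ptsInv[, 2L])))
    # every landmark lies inside its group's structure boxes
    boxes <- lapply(asg[[1L]]$present, function(nm)
        boundingBox(getStructure(set, nm), 1L))
    inAny <- vapply(seq_len(nrow(pts)), function(i)
        any(vapply(boxes, function(b)
            pts[i, 1L] >= b[["xmin"]] - 1e-9 &&
            pts[i, 1L] <= b[["xmax"]] + 1e-9 &&
            pts[i, 2L] >= b[["ymin"]] - 1e-9 &&
            pts[i, 2L] <= b[["ymax"]] + 1e-9, logical(1))),
        logical(1))
    expect_true(all(inAny))
    # maxillary sinus landmarks sit on the posterior-quarter boundary at
    # both lateral edges (group 7 with sphenoid)
    set7 <- StructureSet(list(
        blk("maxillary_sinus_L", 28:36, 8:26),
        blk("maxillary_sinus_R", 4:12, 8:26),
        blk("sphenoid_sinus", 16:24, 12:20)), g)
    asg7 <- assignAxialGroups(set7)
    pts7 <- selectLandmarks(asg7[[1L]], set7, locNo)
    # box y 7-25 spans 18 mm; fy = 0.75 -> y 20.5, snapped to candidate 19
    expect_true(all(c(paste(27, 19), paste(35, 19)) %in%
                    paste(pts7[, 1L], pts7[, 2L])))
})

test_that("polygon construction orders landmarks angularly", {
    sqr <- cbind(c(4, 0, 4, 0), c(0, 4, 4, 0))   # shuffled square corners
    p <- buildSlicePolygon(sqr, 3L)
    expect_s4_class(p, "SlicePolygon")
    expect_identical(p@sliceIndex, 3L)
    expect_equal(polygonArea(p), 16)
    tri <- buildSlicePolygon(cbind(c(0, 2, 1), c(0, 0, 2)))
    expect_equal(polygonArea(tri), 2)
    # star-shaped ring: area equals the shoelace value of the ring sorted
    # by angle about the centroid (computed independently here)
    set.seed(9)
    ang <- sort(stats::runif(8, 0, 2 * pi))
    rad <- stats::runif(8, 1, 3)
    pts <- cbind(rad * cos(ang), rad * sin(ang))
    ctr <- colMeans(pts)
    ring <- pts[order(atan2(pts[, 2L] - ctr[2L], pts[, 1L] - ctr[1L])), ]
    shoelace <- abs(sum(ring[, 1L] * ring[c(2:8, 1L), 2L] -
                        ring[c(2:8, 1L), 1L] * ring[, 2L])) / 2
    ps <- buildSlicePolygon(pts[sample(8), ])
    expect_equal(polygonArea(ps), shoelace)
    expect_warning(expect_null(buildSlicePolygon(cbind(c(0, 1), c(0, 0)))),
                   "fewer than 3")
    expect_warning(expect_null(
        buildSlicePolygon(cbind(c(0, 1, 2), c(0, 1, 2)))), "collinear")
})

test_that("CTV3p unites expansion, polygons, sphenoid target and NP", {
    ph <- defaultPhantom()
    gtvp <- gtvpMask(ph$tumor)
    loc <- localizeGtvp(gtvp, ph$structures)
    ctv1p <- buildCtv1p(gtvp, list())
    out <- buildCtv3p(ctv1p, ph$structures, loc, 2L)
    ctv3p <- out$mask
    expect_true(all(!maskVoxels(ctv1p) | maskVoxels(ctv3p)))
    expect_true(all(!maskVoxels(expandMask(ctv1p, 5)) | maskVoxels(ctv3p)))
    np <- getStructure(ph$structures, "nasopharynx")
    expect_true(all(!maskVoxels(np) | maskVoxels(ctv3p)))
    sphInf <- sphenoidTarget(getStructure(ph$structures, "sphenoid_sinus"), 2L)
    expect_true(all(!maskVoxels(sphInf) | maskVoxels(ctv3p)))
    expect_gt(length(out$landmark_log), 0L)
    # monotone in T stage on the same phantom
    ctv3pT3 <- buildCtv3p(ctv1p, ph$structures, loc, 3L)$mask
    expect_true(all(!maskVoxels(ctv3p) | maskVoxels(ctv3pT3)))
    # with no landmark structures: expansion + sphenoid + NP only
    mini <- StructureSet(list(
        nasopharynx = np,
        sphenoid_sinus = getStructure(ph$structures, "sphenoid_sinus")),
        ph$structures@grid)
    out2 <- buildCtv3p(ctv1p, mini, loc, 3L)$mask
    manual <- maskVoxels(expandMask(ctv1p, 5)) | maskVoxels(np) |
        maskVoxels(getStructure(ph$structures, "sphenoid_sinus"))
    expect_identical(maskVoxels(out2), manual)
    # clivus invasion enlarges CTV3p
    phInv <- generatePhantom(phantomSpec(seed = 7,
        gtvp = list(invades_clivus = TRUE)))
    gtvpI <- gtvpMask(phInv$tumor)
    locI <- localizeGtvp(gtvpI, phInv$structures)
    expect_true(locI$invades_clivus)
    c1pI <- buildCtv1p(gtvpI, list())
    cInv <- buildCtv3p(c1pI, phInv$structures, locI, 2L)$mask
    clv <- getStructure(phInv$structures, "clivus")
    cNoInv <- buildCtv3p(c1pI, phInv$structures,
                         modifyList(locI, list(invades_clivus = FALSE)),
                         2L)$mask
    expect_gt(sum(maskVoxels(cInv) & maskVoxels(clv)),
              sum(maskVoxels(cNoInv) & maskVoxels(clv)))
})
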