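## Seeded geometric head-and-neck phantom.
##
## Every registry structure is laid out as an ellipsoid/box/tube at fixed
## relative positions (mirror-symmetric lateral pairs), scaled to the
## requested grid. Positions are authored for a 128 x 128 x 80 grid at
## (2.5, 1, 1) mm — the pipeline's working resolution — and rescaled for
## other grids. Jitter perturbs each structure's in-plane position only,
## so the superior-inferior band layout (which drives the axial grouping)
## is stable; the generator is deterministic for a fixed seed.

## layout table: per structure a primitive in reference coordinates.
## x/y in mm on the 127 x 127 mm in-plane reference extent, slice bands
## as 1-based indices on the 80-slice reference stack. Lateral pairs are
## authored on the left and mirrored about the midline.
.phantomLayout <- function() {
    box <- function(x0, x1, y0, y1, s0, s1)
        list(kind = "box", x = c(x0, x1), y = c(y0, y1), s = c(s0, s1))
    ell <- function(cx, cy, cs, rx, ry, rs)
        list(kind = "ellipsoid", c = c(cx, cy, cs), r = c(rx, ry, rs))
    left <- list(
        brain = ell(63.5, 60, 11, 45, 40, 10),
        brainstem = box(55, 72, 68, 84, 21, 32),
        orbit_L = ell(95.5, 30, 20, 9, 9, 3.2),
        optic_nerve_L = box(73.5, 89.5, 40, 48, 19, 20),
        optic_chiasm = box(55, 72, 52, 58, 18, 19),
        sphenoid_sinus = box(52, 75, 42, 58, 19, 26),
        skull_base = box(30, 98, 35, 85, 22, 24),
        maxillary_sinus_L = box(70, 95, 22, 48, 23, 34),
        clivus = box(52, 75, 62, 74, 25, 36),
        nasal_cavity = box(53, 74, 14, 38, 25, 34),
        nasopharynx = box(50, 77, 48, 62, 27, 39),
        pterygoid_fossa_L = box(78, 90, 44, 60, 27, 41),
        LN_RP_L = box(70, 78, 62, 70, 37, 43),
        mastoid_L = box(100, 110, 70, 82, 37, 38),
        parotid_L = box(95, 110, 55, 75, 41, 49),
        mandible = box(40, 88, 18, 28, 41, 49),
        spinal_cord = box(60, 67, 78, 85, 31, 80),
        c1_vertebral_body = box(52, 75, 72, 88, 37, 40),
        c2_vertebral_body = box(52, 75, 72, 88, 41, 44),
        vertebral_column = box(50, 77, 70, 92, 37, 80),
        hyoid = box(48, 80, 30, 38, 49, 51),
        larynx = box(52, 75, 30, 44, 51, 61),
        cricoid = box(52, 75, 32, 42, 59, 61),
        LN_Ib_L = box(70, 92, 25, 45, 43, 51),
        LN_II_L = box(78, 95, 50, 70, 39, 51),
        LN_III_L = box(78, 95, 50, 70, 52, 63),
        LN_IV_L = box(78, 95, 50, 70, 64, 75),
        LN_Va_L = box(97, 112, 62, 80, 43, 59),
        LN_Vb_L = box(97, 112, 62, 80, 60, 71)
    )
    # mirror the lateral pairs about the reference midline x = 63.5
    out <- left
    for (nm in names(left)) {
        if (!grepl("_L$", nm)) next
        p <- left[[nm]]
        if (p$kind == "box") p$x <- sort(127 - p$x)
        else p$c[1L] <- 127 - p$c[1L]
        out[[sub("_L$", "_R", nm)]] <- p
    }
    out
}

.refExtent <- c(s = 80, y = 127, x = 127)  # slices, y mm, x mm

## rasterizers on an ImageGrid; x/y in mm, slice band in (possibly
## fractional) slice indices
.rasterBox <- function(grid, x, y, s) {
    vox <- array(FALSE, dim3(grid))
    si <- which(seq_len(grid@shape[1L]) >= s[1L] - 1e-9 &
                seq_len(grid@shape[1L]) <= s[2L] + 1e-9)
    yi <- which(yCoords(grid) >= y[1L] - 1e-9 & yCoords(grid) <= y[2L] + 1e-9)
    xi <- which(xCoords(grid) >= x[1L] - 1e-9 & xCoords(grid) <= x[2L] + 1e-9)
    if (length(si) && length(yi) && length(xi)) vox[si, yi, xi] <- TRUE
    vox
}

.rasterEllipsoid <- function(grid, c3, r3) {
    # c3/r3 in (x mm, y mm, slice index units); r3 slice radius in slices
    xs <- xCoords(grid); ys <- yCoords(grid); ss <- seq_len(grid@shape[1L])
    si <- which(abs(ss - c3[3L]) <= r3[3L])
    yi <- which(abs(ys - c3[2L]) <= r3[2L])
    xi <- which(abs(xs - c3[1L]) <= r3[1L])
    vox <- array(FALSE, dim3(grid))
    if (length(si) && length(yi) && length(xi)) {
        fx <- ((xs[xi] - c3[1L]) / r3[1L])^2
        fy <- ((ys[yi] - c3[2L]) / r3[2L])^2
        fs <- ((ss[si] - c3[3L]) / r3[3L])^2
        vox[si, yi, xi] <- outer(fs, outer(fy, fx, `+`), `+`) <= 1 + 1e-12
    }
    vox
}

.rasterSphere <- function(grid, cx, cy, cslice, radius_mm) {
    xs <- xCoords(grid); ys <- yCoords(grid)
    zc <- (seq_len(grid@shape[1L]) - cslice) * grid@spacing[1L]
    si <- which(abs(zc) <= radius_mm)
    yi <- which(abs(ys - cy) <= radius_mm)
    xi <- which(abs(xs - cx) <= radius_mm)
    vox <- array(FALSE, dim3(grid))
    if (length(si) && length(yi) && length(xi)) {
        fx <- (xs[xi] - cx)^2; fy <- (ys[yi] - cy)^2; fz <- zc[si]^2
        vox[si, yi, xi] <-
            outer(fz, outer(fy, fx, `+`), `+`) <= radius_mm^2 + 1e-9
    }
    vox
}

#' Specify a synthetic head-and-neck phantom
#'
#' @param gridShape integer(3), (slices, rows, cols); default 80 slices
#'   of 128 x 128.
#' @param spacing mm spacing (slice, row, col); default (2.5, 1, 1),
#'   the working resolution of the pipeline.
#' @param seed integer RNG seed driving the jitter.
#' @param tStage,nStage TNM stages of the emulated case.
#' @param gtvp list: \code{side} ("left", "right" or "bilateral"),
#'   \code{invades_clivus} flag, \code{diameter_mm}, and an optional
#'   \code{center_offset_mm} numeric(3) (x, y, slice-axis mm) nudging the
#'   placement.
#' @param gtvn list of placements, each a list with \code{level}
#'   (e.g. "II"), \code{side} ("L"/"R") and \code{diameter_mm}.
#' @param jitter_mm maximum per-structure in-plane jitter (default 1 mm).
#' @return A \code{PhantomSpec} (classed list).
#' @export
phantomSpec <- function(gridShape = c(80L, 128L, 128L),
                        spacing = c(2.5, 1, 1),
                        seed = 0L,
                        tStage = 2L,
                        nStage = NULL,
                        gtvp = list(side = "left", invades_clivus = FALSE,
                                    diameter_mm = 30),
                        gtvn = list(list(level = "II", side = "L",
                                         diameter_mm = 15)),
                        jitter_mm = 1) {
    gtvp <- utils::modifyList(
        list(side = "left", invades_clivus = FALSE, diameter_mm = 30,
             center_offset_mm = c(0, 0, 0)), gtvp)
    stopifnot(gtvp$diameter_mm > 0, jitter_mm >= 0)
    for (g in gtvn) {
        stopifnot(g$diameter_mm > 0, g$side %in% c("L", "R"))
        lev <- paste0("LN_", g$level, "_", g$side)
        if (!lev %in% canonicalStructureNames())
            stop("unknown nodal level placement '", lev, "'", call. = FALSE)
    }
    if (is.null(nStage)) nStage <- if (length(gtvn)) 1L else 0L
    structure(list(gridShape = as.integer(gridShape),
                   spacing = as.numeric(spacing), seed = as.integer(seed),
                   tStage = as.integer(tStage), nStage = as.integer(nStage),
                   gtvp = gtvp, gtvn = gtvn, jitter_mm = jitter_mm),
              class = "PhantomSpec")
}

#' @rdname phantomSpec
#' @param x a \code{PhantomSpec}.
#' @param ... ignored.
#' @export
print.PhantomSpec <- function(x, ...) {
    cat(sprintf(
        "PhantomSpec: %d x %d x %d grid, seed %d, T%d N%d, GTVp %s%s, %d GTVn\n",
        x$gridShape[1L], x$gridShape[2L], x$gridShape[3L], x$seed,
        x$tStage, x$nStage, x$gtvp$side,
        if (isTRUE(x$gtvp$invades_clivus)) " (clivus-invading)" else "",
        length(x$gtvn)))
    invisible(x)
}

## run fn under a local RNG state
.withSeed <- function(seed, fn) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", globalenv())
        on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    fn()
}

#' Generate a synthetic head-and-neck phantom
#'
#' Builds the full canonical structure set as geometric solids at
#' anatomically plausible relative positions on the requested grid, plus
#' the GTVp sphere (side-shifted, optionally clivus-invading) and GTVn
#' spheres centered in their nodal level masks. Deterministic for a
#' fixed seed. The default layout guarantees that each of the eight
#' axial structure groups matches on at least one slice.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{structures} (a \linkS4class{StructureSet})
#'   and \code{tumor} (a \linkS4class{TumorContext}).
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7))
#' length(ph$structures)
#' @export
generatePhantom <- function(spec) {
    stopifnot(inherits(spec, "PhantomSpec"))
    grid <- ImageGrid(spec$gridShape, spec$spacing)
    # scale reference coordinates to this grid
    scS <- (grid@shape[1L] - 1L) / (.refExtent[["s"]] - 1L)
    scY <- (yCoords(grid)[grid@shape[2L]] - yCoords(grid)[1L]) /
        .refExtent[["y"]]
    scX <- (xCoords(grid)[grid@shape[3L]] - xCoords(grid)[1L]) /
        .refExtent[["x"]]
    layout <- .phantomLayout()
    masks <- .withSeed(spec$seed, function() {
        out <- vector("list", length(layout))
        names(out) <- names(layout)
        for (nm in names(layout)) {
            jit <- if (spec$jitter_mm > 0)
                stats::runif(2L, -spec$jitter_mm, spec$jitter_mm)
            else c(0, 0)
            p <- layout[[nm]]
            vox <- if (p$kind == "box")
                .rasterBox(grid,
                           x = p$x * scX + jit[1L], y = p$y * scY + jit[2L],
                           s = 1 + (p$s - 1) * scS)
            else
                .rasterEllipsoid(grid,
                    c3 = c(p$c[1L] * scX + jit[1L], p$c[2L] * scY + jit[2L],
                           1 + (p$c[3L] - 1) * scS),
                    r3 = c(p$r[1L] * scX, p$r[2L] * scY, p$r[3L] * scS))
            if (!any(vox))
                stop("phantom structure '", nm,
                     "' fell outside the grid", call. = FALSE)
            out[[nm]] <- StructureMask(nm, grid, vox)
        }
        out
    })
    structures <- StructureSet(masks, grid)

    # GTVp: sphere in/near the nasopharynx, shifted by side, optionally
    # reaching the clivus
    mid <- gridMidlineX(grid)
    r <- spec$gtvp$diameter_mm / 2
    dx <- switch(spec$gtvp$side,
                 left = 12 * scX, right = -12 * scX, bilateral = 0,
                 stop("gtvp side must be left, right or bilateral"))
    cy <- (if (isTRUE(spec$gtvp$invades_clivus)) 52 else 44) * scY
    off <- spec$gtvp$center_offset_mm
    gtvpVox <- .rasterSphere(grid, mid + dx + off[1L], cy + off[2L],
                             1 + (31 - 1) * scS + off[3L] / grid@spacing[1L],
                             r)
    if (!any(gtvpVox)) stop("GTVp placement exceeds the grid", call. = FALSE)
    gtvp <- StructureMask("gtvp", grid, gtvpVox)

    gtvn <- .placeGtvn(structures, spec$gtvn)

    list(structures = structures,
         tumor = TumorContext(gtvp, gtvn, spec$tStage, spec$nStage))
}

## GTVn spheres centered at the (realized, jittered) nodal level masks
.placeGtvn <- function(structures, placements) {
    grid <- structures@grid
    out <- vector("list", length(placements))
    for (i in seq_along(placements)) {
        g <- placements[[i]]
        lev <- getStructure(structures, paste0("LN_", g$level, "_", g$side))
        w <- which(lev@voxels, arr.ind = TRUE)
        cs <- mean(w[, 1L])
        cyn <- mean(yCoords(grid)[w[, 2L]])
        cxn <- mean(xCoords(grid)[w[, 3L]])
        vox <- .rasterSphere(grid, cxn, cyn, cs, g$diameter_mm / 2)
        if (!any(vox))
            stop("GTVn placement exceeds the grid", call. = FALSE)
        m <- StructureMask(paste0("gtvn_", i), grid, vox)
        attr(m, "level") <- paste0("LN_", g$level, "_", g$side)
        out[[i]] <- m
    }
    out
}

#' Scenario coverage suite
#'
#' A fixed panel of phantom cases covering all nine nodal coverage
#' scenarios and all CTV2 condition combinations, each with its
#' analytically expected labels. All cases share one structure set;
#' only the nodal disease varies.
#'
#' @param seed phantom seed (default 1).
#' @return list of cases, each with \code{structures}, \code{tumor},
#'   \code{expected_scenario} (1..9) and \code{expected_ctv2}
#'   (integer subset of \{1, 2\}).
#' @export
generateScenarioSuite <- function(seed = 1L) {
    nodes <- function(...) {
        lapply(list(...), function(p)
            list(level = p[[1L]], side = p[[2L]],
                 diameter_mm = if (length(p) > 2L) p[[3L]] else 15))
    }
    defs <- list(
        list(gtvn = list(), scenario = 1L, ctv2 = integer()),
        list(gtvn = nodes(list("II", "L"), list("II", "R")),
             scenario = 2L, ctv2 = integer()),
        list(gtvn = nodes(list("II", "L")), scenario = 3L, ctv2 = integer()),
        list(gtvn = nodes(list("II", "R")), scenario = 4L, ctv2 = integer()),
        list(gtvn = nodes(list("IV", "L"), list("IV", "R")),
             scenario = 5L, ctv2 = 2L),
        list(gtvn = nodes(list("II", "R"), list("IV", "L")),
             scenario = 6L, ctv2 = 2L),
        list(gtvn = nodes(list("II", "L"), list("IV", "R")),
             scenario = 7L, ctv2 = 2L),
        list(gtvn = nodes(list("IV", "L")), scenario = 8L, ctv2 = 2L),
        list(gtvn = nodes(list("IV", "R")), scenario = 9L, ctv2 = 2L),
        list(gtvn = nodes(list("Ib", "L", 12)), scenario = 3L, ctv2 = 1L),
        list(gtvn = nodes(list("Ib", "R", 12), list("IV", "R")),
             scenario = 9L, ctv2 = c(1L, 2L)),
        list(gtvn = nodes(list("Ib", "L", 24)), scenario = 3L,
             ctv2 = integer())
    )
    base <- generatePhantom(phantomSpec(seed = seed, gtvn = list()))
    lapply(defs, function(d) {
        gtvn <- .placeGtvn(base$structures, d$gtvn)
        list(structures = base$structures,
             tumor = TumorContext(base$tumor@gtvp, gtvn, tStage = 2L,
                                  nStage = if (length(d$gtvn)) 2L else 0L),
             expected_scenario = d$scenario,
             expected_ctv2 = d$ctv2)
    })
}
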