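## Spacing-aware 3-D binary-mask geometry.
##
## All margins and distances are physical millimetres: the anisotropic
## voxel spacing enters every operation through an exact Euclidean
## distance transform (separable lower-envelope method, compiled), so a
## 3 mm margin means the same thing on 1 mm and 2.5 mm axes.

## squared EDT to the nearest TRUE voxel center; +Inf everywhere if none
distanceSqToForeground <- function(voxels, spacing) {
    d <- cpp_edt_sq(as.logical(voxels), dim(voxels), as.numeric(spacing))
    array(d, dim(voxels))
}

## relative slack for comparing squared distances against a squared margin:
## both sides are short sums of products of spacings, so a tiny relative
## epsilon keeps exact lattice ties (e.g. 3.0^2 <= 9) inclusive.
.distTolSq <- function(margin_mm) margin_mm^2 * 1e-9 + 1e-9

#' Expand a mask by a physical margin
#'
#' Isotropic physical margin expansion: the result contains every voxel
#' whose center lies within Euclidean distance \code{margin_mm} (in mm) of
#' some input foreground voxel center. The input is always a subset of
#' the output; an empty input yields an empty output with a warning.
#'
#' @param mask a \linkS4class{StructureMask}.
#' @param margin_mm non-negative margin in mm.
#' @param name name of the result.
#' @return A \linkS4class{StructureMask}.
#' @examples
#' g <- ImageGrid(c(9L, 9L, 9L), c(1, 1, 1))
#' v <- array(FALSE, c(9, 9, 9)); v[5, 5, 5] <- TRUE
#' sum(maskVoxels(expandMask(StructureMask("gtvp", g, v), 2)))
#' @export
expandMask <- function(mask, margin_mm, name = mask@name) {
    stopifnot(margin_mm >= 0)
    if (isEmptyMask(mask)) {
        warning("expanding an empty mask returns an empty mask",
                call. = FALSE)
        return(withVoxels(mask, mask@voxels, name))
    }
    if (margin_mm == 0) return(withVoxels(mask, mask@voxels, name))
    d2 <- distanceSqToForeground(mask@voxels, mask@grid@spacing)
    withVoxels(mask, d2 <= margin_mm^2 + .distTolSq(margin_mm), name)
}

## erosion as the morphological dual of expansion, so that the two share
## one boundary convention exactly
erodeMask <- function(mask, margin_mm, name = mask@name) {
    stopifnot(margin_mm >= 0)
    if (margin_mm == 0 || isEmptyMask(mask))
        return(withVoxels(mask, mask@voxels, name))
    bg <- withVoxels(mask, !mask@voxels)
    if (isEmptyMask(bg)) return(withVoxels(mask, mask@voxels, name))
    dil <- expandMask(bg, margin_mm)
    withVoxels(mask, !dil@voxels, name)
}

#' Subtract structures from a target while protecting a core
#'
#' Removes the union of \code{subtrahends} from \code{target}, except
#' that voxels within \code{min_margin_mm} of the \code{protect} mask
#' (including the mask itself) are never removed. This realizes the
#' protocol's "margin reduced to as low as X mm near critical organs at
#' risk" rule: the gross tumor plus its floor margin always survives the
#' subtraction.
#'
#' @param target \linkS4class{StructureMask} to be trimmed.
#' @param subtrahends list of \linkS4class{StructureMask} to remove.
#' @param protect \linkS4class{StructureMask} whose
#'   \code{min_margin_mm}-expansion is kept.
#' @param min_margin_mm non-negative floor margin in mm.
#' @return A \linkS4class{StructureMask}, always a subset of
#'   \code{target}.
#' @export
subtractProtected <- function(target, subtrahends, protect,
                              min_margin_mm = 0) {
    if (is(subtrahends, "StructureMask")) subtrahends <- list(subtrahends)
    for (s in subtrahends) stopIfGridMismatch(target@grid, s@grid)
    stopIfGridMismatch(target@grid, protect@grid)
    if (!length(subtrahends)) return(target)
    sub <- maskUnionAll(subtrahends, grid = target@grid)
    zone <- if (isEmptyMask(protect)) protect
            else expandMask(protect, min_margin_mm)
    keep <- !sub@voxels | zone@voxels
    withVoxels(target, target@voxels & keep)
}

#' Split a mask at its centroid's axial plane
#'
#' Computes the foreground centroid's (fractional) slice coordinate and
#' partitions the mask at that axial plane. The slice containing the
#' centroid goes to the inferior part (inclusive tie rule, the
#' conservative-coverage choice for inferior-section targeting).
#'
#' @param mask non-empty \linkS4class{StructureMask}.
#' @return list with elements \code{inferior} and \code{superior}
#'   (StructureMasks); their union is the input, their intersection empty.
#' @export
splitInferiorAtCentroid <- function(mask) {
    if (isEmptyMask(mask)) stop("cannot split an empty mask", call. = FALSE)
    perSlice <- apply(mask@voxels, 1L, sum)
    idx <- seq_along(perSlice)
    cFrac <- sum(idx * perSlice) / sum(perSlice)
    cIdx <- floor(cFrac + 0.5)  # slice whose center is nearest
    inferiorIdx <- if (mask@grid@sliceInferior) idx >= cIdx else idx <= cIdx
    inf <- mask@voxels; inf[!inferiorIdx, , ] <- FALSE
    sup <- mask@voxels; sup[inferiorIdx, , ] <- FALSE
    list(
        inferior = withVoxels(mask, inf, paste0(mask@name, "_inferior")),
        superior = withVoxels(mask, sup, paste0(mask@name, "_superior"))
    )
}

#' Tight bounding box of a mask's slice, in mm
#'
#' Axis-aligned box over the foreground voxel centers of one axial slice.
#'
#' @param mask a \linkS4class{StructureMask}.
#' @param sliceIndex axial slice (1-based).
#' @return Named numeric: \code{xmin, xmax, ymin, ymax} (mm, voxel-center
#'   coordinates). Errors on an empty slice.
#' @export
boundingBox <- function(mask, sliceIndex) {
    sl <- mask@voxels[sliceIndex, , , drop = TRUE]
    if (!any(sl)) stop("slice ", sliceIndex, " of '", mask@name,
                       "' is empty", call. = FALSE)
    w <- which(sl, arr.ind = TRUE)  # (row, col)
    ys <- yCoords(mask@grid)[w[, 1L]]
    xs <- xCoords(mask@grid)[w[, 2L]]
    c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

#' Evenly spaced candidate grid inside a bounding box
#'
#' \code{nx * ny} points, inclusive of the box edges, row-major (y-major)
#' order. The default 7 x 7 grid supplies the landmark candidates.
#'
#' @param box named numeric with \code{xmin, xmax, ymin, ymax}.
#' @param nx,ny points per axis (>= 2, or a degenerate box).
#' @return numeric matrix, (nx*ny) x 2, columns (x, y).
#' @export
gridPoints <- function(box, nx = 7L, ny = 7L) {
    xs <- if (box[["xmax"]] > box[["xmin"]])
        seq(box[["xmin"]], box[["xmax"]], length.out = nx)
    else rep(box[["xmin"]], nx)
    ys <- if (box[["ymax"]] > box[["ymin"]])
        seq(box[["ymin"]], box[["ymax"]], length.out = ny)
    else rep(box[["ymin"]], ny)
    cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
}

#' Construct a SlicePolygon
#'
#' @param sliceIndex axial slice index.
#' @param vertices n x 2 numeric matrix of (x, y) mm vertices, implicitly
#'   closed.
#' @return A \linkS4class{SlicePolygon}.
#' @export
SlicePolygon <- function(sliceIndex, vertices) {
    new("SlicePolygon", sliceIndex = as.integer(sliceIndex),
        vertices = as.matrix(vertices))
}

#' @rdname SlicePolygon
#' @param poly a \linkS4class{SlicePolygon}.
#' @export
polygonVertices <- function(poly) poly@vertices

#' @rdname SlicePolygon
#' @details \code{polygonArea} is the shoelace area (always >= 0).
#' @export
polygonArea <- function(poly) {
    v <- poly@vertices
    n <- nrow(v)
    j <- c(2:n, 1L)
    abs(sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])) / 2
}

## proper-crossing test between closed-polygon edges; shared endpoints of
## adjacent edges are not intersections
isSimplePolygon <- function(poly) {
    v <- poly@vertices
    n <- nrow(v)
    if (n < 3L) return(FALSE)
    a <- v
    b <- v[c(2:n, 1L), , drop = FALSE]
    seg_int <- function(p1, p2, p3, p4) {
        d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
        d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
        d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
        d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
        (d1 * d2 < 0) && (d3 * d4 < 0)
    }
    for (i in seq_len(n - 2L)) {
        jmax <- if (i == 1L) n - 1L else n
        for (j in (i + 2L):jmax) {
            if (j > n) next
            if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
        }
    }
    TRUE
}

#' Chaikin corner-cutting smoothing of a closed polygon
#'
#' Each edge (P_i, P_{i+1}) of the closed loop is replaced by the two
#' points Q = 3/4 P_i + 1/4 P_{i+1} and R = 1/4 P_i + 3/4 P_{i+1}, so the
#' vertex count doubles per iteration and the smoothed curve stays inside
#' the convex hull of the input.
#'
#' @param poly a \linkS4class{SlicePolygon} with >= 3 vertices.
#' @param iterations number of corner-cutting passes (>= 0; 0 = identity).
#' @return A \linkS4class{SlicePolygon}.
#' @export
chaikinSmooth <- function(poly, iterations = 3L) {
    stopifnot(iterations >= 0)
    v <- poly@vertices
    if (nrow(v) < 3L) stop("polygon needs >= 3 vertices", call. = FALSE)
    for (it in seq_len(iterations)) {
        nxt <- v[c(2:nrow(v), 1L), , drop = FALSE]
        q <- 0.75 * v + 0.25 * nxt
        r <- 0.25 * v + 0.75 * nxt
        v <- matrix(rbind(t(q), t(r)), ncol = 2L, byrow = TRUE)
    }
    SlicePolygon(poly@sliceIndex, v)
}

## even-odd point-in-polygon on many points at once; half-open crossing
## convention ((yi > y) != (yj > y), strict x < intersection) so voxel
## centers exactly on a shared edge of two polygons land in exactly one
pointsInPolygon <- function(px, py, vx, vy) {
    n <- length(vx)
    inside <- rep(FALSE, length(px))
    j <- n
    for (i in seq_len(n)) {
        yi <- vy[i]; yj <- vy[j]
        if (yi != yj) {
            crossed <- (yi > py) != (yj > py)
            if (any(crossed)) {
                xint <- vx[i] + (py[crossed] - yi) * (vx[j] - vx[i]) / (yj - yi)
                hit <- px[crossed] < xint
                w <- which(crossed)[hit]
                inside[w] <- !inside[w]
            }
        }
        j <- i
    }
    inside
}

#' Rasterize a slice polygon onto a grid
#'
#' Marks the voxel centers of the polygon's slice that fall inside the
#' polygon under the even-odd rule with a fixed half-open boundary
#' convention, making rasterization deterministic and
#' translation-invariant on aligned grids.
#'
#' @param poly a \linkS4class{SlicePolygon}.
#' @param grid an \linkS4class{ImageGrid}; the polygon must lie within the
#'   grid's in-plane extent.
#' @param name name of the resulting mask.
#' @return A single-slice \linkS4class{StructureMask}.
#' @export
polygonToMask <- function(poly, grid, name = "polygon") {
    v <- poly@vertices
    xs <- xCoords(grid); ys <- yCoords(grid)
    hx <- grid@spacing[3L] / 2; hy <- grid@spacing[2L] / 2
    if (min(v[, 1L]) < xs[1L] - hx || max(v[, 1L]) > xs[length(xs)] + hx ||
        min(v[, 2L]) < ys[1L] - hy || max(v[, 2L]) > ys[length(ys)] + hy)
        stop("polygon extends outside the grid", call. = FALSE)
    if (poly@sliceIndex < 1L || poly@sliceIndex > grid@shape[1L])
        stop("polygon slice outside the grid", call. = FALSE)
    # restrict the test to the polygon's bounding box of voxel centers
    ci <- which(xs >= min(v[, 1L]) - hx & xs <= max(v[, 1L]) + hx)
    ri <- which(ys >= min(v[, 2L]) - hy & ys <= max(v[, 2L]) + hy)
    vox <- array(FALSE, dim3(grid))
    if (length(ci) && length(ri)) {
        px <- rep(xs[ci], each = length(ri))
        py <- rep(ys[ri], times = length(ci))
        inside <- pointsInPolygon(px, py, v[, 1L], v[, 2L])
        sl <- matrix(inside, nrow = length(ri), ncol = length(ci))
        plane <- matrix(FALSE, grid@shape[2L], grid@shape[3L])
        plane[ri, ci] <- sl
        vox[poly@sliceIndex, , ] <- plane
    }
    StructureMask(name, grid, vox)
}

#' Connected components of a mask
#'
#' 26-connected labelling in 3-D (or 6-connected on request). The union
#' of the returned components is the input; components are pairwise
#' disjoint and ordered by first voxel encountered in array order.
#'
#' @param mask a \linkS4class{StructureMask}.
#' @param connectivity 26 (default) or 6.
#' @return list of \linkS4class{StructureMask}, one per component
#'   (empty list for an empty mask).
#' @export
connectedComponents <- function(mask, connectivity = 26L) {
    stopifnot(connectivity %in% c(6L, 26L))
    lab <- cpp_label_components(as.logical(mask@voxels), dim(mask@voxels),
                                as.integer(connectivity))
    ncomp <- attr(lab, "ncomp")
    if (ncomp == 0L) return(list())
    lab <- array(lab, dim(mask@voxels))
    lapply(seq_len(ncomp), function(k)
        withVoxels(mask, lab == k, paste0(mask@name, "_cc", k)))
}

## labelled array + count, used internally where lists are wasteful
labelComponents <- function(voxels, connectivity = 26L) {
    lab <- cpp_label_components(as.logical(voxels), dim(voxels),
                                as.integer(connectivity))
    list(labels = array(lab, dim(voxels)), n = attr(lab, "ncomp"))
}

#' Equivalent-sphere diameter of a mask, in cm
#'
#' Diameter of the sphere whose volume equals the mask's foreground
#' volume: \eqn{d = 2 (3V / 4\pi)^{1/3}}. Used for the protocol's
#' "nodal GTV of at most 2 cm" size criterion. Returns 0 for an empty
#' mask.
#'
#' @param mask a \linkS4class{StructureMask}.
#' @return numeric(1), cm.
#' @export
equivalentSphereDiameter <- function(mask) {
    v_cm3 <- maskVolume(mask) / 1000
    if (v_cm3 == 0) return(0)
    2 * (3 * v_cm3 / (4 * pi))^(1 / 3)
}

#' Join nearby islands of a mask with per-slice alpha shapes
#'
#' On each axial slice holding more than one connected component, if the
#' minimum center-to-center gap between two components does not exceed
#' \code{max_gap_mm}, the slice is replaced by the rasterized alpha shape
#' of its foreground. The alpha shape is computed through its
#' disk-complement characterization (a point belongs to the alpha shape
#' iff no empty open disk of radius 1/alpha covers it), which on a raster
#' is a morphological closing with that disk; the effective disk radius is
#' \code{max(1/alpha, gap/2 + voxel diagonal)} so that a gap within the
#' threshold is actually bridged. The input is always a subset of the
#' output, and components farther apart than \code{max_gap_mm} from every
#' other component are retained unmerged.
#'
#' @param mask a \linkS4class{StructureMask}.
#' @param alpha alpha-shape curvature parameter, 1/mm (default 0.2, i.e.
#'   a 5 mm disk).
#' @param max_gap_mm largest inter-component gap that triggers joining
#'   (default 15 mm).
#' @return A \linkS4class{StructureMask}.
#' @export
alphashapeJoin <- function(mask, alpha = 0.2, max_gap_mm = 15) {
    stopifnot(alpha > 0, max_gap_mm >= 0)
    sp2 <- mask@grid@spacing[2:3]
    voxDiag <- sqrt(sum(sp2^2))
    out <- mask@voxels
    for (s in seq_len(mask@grid@shape[1L])) {
        sl <- mask@voxels[s, , , drop = TRUE]
        if (!any(sl)) next
        slArr <- array(sl, c(dim(sl), 1L))
        cc <- labelComponents(slArr)  # 26-conn in a single slice = 8-conn
        if (cc$n < 2L) next
        # pairwise minimum gaps via per-component distance transforms
        gaps <- c()
        for (k in seq_len(cc$n - 1L)) {
            dk <- cpp_edt_sq(as.vector(cc$labels == k), dim(slArr),
                             c(sp2, 1))
            for (m in (k + 1L):cc$n) {
                g <- sqrt(min(dk[as.vector(cc$labels == m)]))
                gaps <- c(gaps, g)
            }
        }
        joinable <- gaps[gaps <= max_gap_mm]
        if (!length(joinable)) next
        r <- max(1 / alpha, max(joinable) / 2 + voxDiag)
        closed <- .closeSlice(slArr, sp2, r)
        out[s, , ] <- sl | closed[, , 1L]
    }
    withVoxels(mask, out)
}

## binary closing of a single-slice array with an in-plane disk
.closeSlice <- function(slArr, sp2, r_mm) {
    spacing <- c(sp2, 1)
    tolD <- r_mm^2 * 1e-9 + 1e-9
    d2 <- array(cpp_edt_sq(as.vector(slArr), dim(slArr), spacing), dim(slArr))
    dil <- d2 <= r_mm^2 + tolD
    d2b <- array(cpp_edt_sq(as.vector(!dil), dim(slArr), spacing), dim(slArr))
    dil & !(d2b <= r_mm^2 + tolD)
}

#' Morphological refinement of a mask
#'
#' Post-processing used on the final target volumes: binary opening with
#' a physical radius, then binary closing, then filling of interior
#' cavities below a voxel-count threshold, then removal of connected
#' components below a voxel-count threshold unless they intersect the
#' \code{keep} mask (typically the gross tumor volumes).
#'
#' @param mask a \linkS4class{StructureMask}.
#' @param open_mm,close_mm opening/closing radii in mm (0 disables).
#' @param min_hole_voxels fill background cavities smaller than this.
#' @param min_island_voxels drop components smaller than this.
#' @param keep optional \linkS4class{StructureMask}; small components
#'   intersecting it survive.
#' @return A \linkS4class{StructureMask}.
#' @export
morphRefine <- function(mask, open_mm = 1, close_mm = 2.5,
                        min_hole_voxels = 100L, min_island_voxels = 50L,
                        keep = NULL) {
    stopifnot(open_mm >= 0, close_mm >= 0)
    m <- mask
    if (open_mm > 0 && !isEmptyMask(m))
        m <- expandMask(erodeMask(m, open_mm), open_mm, name = mask@name)
    if (close_mm > 0 && !isEmptyMask(m))
        m <- erodeMask(expandMask(m, close_mm), close_mm, name = mask@name)
    # fill small interior cavities: 6-connected background components that
    # do not touch the array border
    if (min_hole_voxels > 0 && !isEmptyMask(m)) {
        bg <- labelComponents(!m@voxels, connectivity = 6L)
        if (bg$n > 0L) {
            border <- unique(c(
                bg$labels[c(1L, dim(bg$labels)[1L]), , ],
                bg$labels[, c(1L, dim(bg$labels)[2L]), ],
                bg$labels[, , c(1L, dim(bg$labels)[3L])]))
            sizes <- tabulate(bg$labels[bg$labels > 0L], nbins = bg$n)
            fill <- setdiff(which(sizes < min_hole_voxels), border)
            if (length(fill)) {
                vox <- m@voxels
                vox[bg$labels %in% fill] <- TRUE
                m <- withVoxels(m, vox)
            }
        }
    }
    if (min_island_voxels > 0 && !isEmptyMask(m)) {
        cc <- labelComponents(m@voxels)
        if (cc$n > 1L || (cc$n == 1L && sum(m@voxels) < min_island_voxels)) {
            sizes <- tabulate(cc$labels[cc$labels > 0L], nbins = cc$n)
            drop <- which(sizes < min_island_voxels)
            if (!is.null(keep) && length(drop)) {
                touches <- vapply(drop, function(k)
                    any(keep@voxels[cc$labels == k]), logical(1))
                drop <- drop[!touches]
            }
            if (length(drop)) {
                vox <- m@voxels
                vox[cc$labels %in% drop] <- FALSE
                m <- withVoxels(m, vox)
            }
        }
    }
    m
}
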