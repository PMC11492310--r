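#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib npCTV, .registration = TRUE
NULL

#' ImageGrid: the shared voxel lattice of a case
#'
#' Describes the 3-D voxel lattice that all masks of a case live on:
#' array shape (slices, rows, cols), physical spacing in mm
#' (slice thickness, row pitch, column pitch), the physical coordinate of
#' the first voxel center, and the superior-inferior convention of the
#' slice axis.
#'
#' Array axes map to physical axes as: column -> x (increasing toward the
#' patient's left, LPS), row -> y (increasing posteriorly), slice -> the
#' superior-inferior axis. When \code{sliceInferior} is \code{TRUE} (the
#' default) the slice index increases inferiorly, i.e. slice 1 is the most
#' superior slice.
#'
#' @slot shape integer(3), (slices, rows, cols); all positive.
#' @slot spacing numeric(3), mm per step along (slice, row, col); all > 0.
#' @slot origin numeric(3), physical mm coordinate of voxel (1,1,1) center,
#'   in (slice-axis, y, x) order.
#' @slot sliceInferior logical(1), slice index increases inferiorly.
#' @aliases ImageGrid
#' @exportClass ImageGrid
setClass("ImageGrid",
    slots = c(
        shape = "integer",
        spacing = "numeric",
        origin = "numeric",
        sliceInferior = "logical"
    ),
    prototype = prototype(
        shape = c(1L, 1L, 1L),
        spacing = c(1, 1, 1),
        origin = c(0, 0, 0),
        sliceInferior = TRUE
    )
)

setValidity("ImageGrid", function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(is.na(object@shape)) ||
        any(object@shape < 1L))
        msg <- c(msg, "'shape' must be three positive integers")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "all 'spacing' components must be > 0")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "'origin' must be three finite numbers")
    if (length(object@sliceInferior) != 1L || is.na(object@sliceInferior))
        msg <- c(msg, "'sliceInferior' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' StructureMask: one named binary mask on a grid
#'
#' A single anatomical structure (or tumor volume, or constructed target
#' volume) as a binary 3-D array on an \linkS4class{ImageGrid}. The array
#' is indexed (slice, row, col).
#'
#' @slot name character(1), canonical structure identifier (see
#'   \code{\link{canonicalStructureNames}}) or a custom name.
#' @slot grid the \linkS4class{ImageGrid} the voxels live on.
#' @slot voxels logical 3-D array whose dim equals the grid shape.
#' @aliases StructureMask
#' @exportClass StructureMask
setClass("StructureMask",
    slots = c(name = "character", grid = "ImageGrid", voxels = "array")
)

setValidity("StructureMask", function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name) ||
        !nzchar(object@name))
        msg <- c(msg, "'name' must be a non-empty string")
    if (!is.logical(object@voxels))
        msg <- c(msg, "'voxels' must be a logical array")
    if (!identical(dim(object@voxels), dim3(object@grid)))
        msg <- c(msg, "voxels shape must equal the grid shape")
    if (anyNA(object@voxels))
        msg <- c(msg, "'voxels' must not contain NA")
    if (length(msg)) msg else TRUE
})

#' StructureSet: registry of masks sharing one grid
#'
#' Named collection of \linkS4class{StructureMask} objects that all share
#' one \linkS4class{ImageGrid}. Access members with \code{[[} or
#' \code{\link{getStructure}}; list names with
#' \code{\link{structureNames}}.
#'
#' @slot grid the shared \linkS4class{ImageGrid}.
#' @slot masks named list of \linkS4class{StructureMask}.
#' @aliases StructureSet
#' @exportClass StructureSet
setClass("StructureSet",
    slots = c(grid = "ImageGrid", masks = "list")
)

setValidity("StructureSet", function(object) {
    msg <- character()
    if (length(object@masks)) {
        if (is.null(names(object@masks)) || anyDuplicated(names(object@masks)))
            msg <- c(msg, "'masks' must be uniquely named")
        ok <- vapply(object@masks, function(m)
            is(m, "StructureMask") && sameGrid(m@grid, object@grid),
            logical(1))
        if (!all(ok))
            msg <- c(msg, "all members must be StructureMasks on the shared grid")
    }
    if (length(msg)) msg else TRUE
})

#' TumorContext: gross tumor volumes and stage
#'
#' The tumor-specific inputs of a case: the primary gross tumor volume
#' (GTVp), zero or more nodal gross tumor volume (GTVn) components, and
#' the TNM T and N stages that drive sphenoid/clivus coverage and the
#' nodal scenario logic.
#'
#' @slot gtvp \linkS4class{StructureMask}, non-empty primary GTV.
#' @slot gtvn list of non-empty \linkS4class{StructureMask} components;
#'   an element may carry a \code{level} attribute naming its nodal level.
#' @slot tStage integer in 1..4.
#' @slot nStage integer in 0..3.
#' @aliases TumorContext
#' @exportClass TumorContext
setClass("TumorContext",
    slots = c(
        gtvp = "StructureMask",
        gtvn = "list",
        tStage = "integer",
        nStage = "integer"
    )
)

setValidity("TumorContext", function(object) {
    msg <- character()
    if (!(length(object@tStage) == 1L && object@tStage %in% 1:4))
        msg <- c(msg, "tStage must be one of 1,2,3,4")
    if (!(length(object@nStage) == 1L && object@nStage %in% 0:3))
        msg <- c(msg, "nStage must be one of 0,1,2,3")
    if (sum(object@gtvp@voxels) == 0L)
        msg <- c(msg, "GTVp must be non-empty")
    if (length(object@gtvn)) {
        ok <- vapply(object@gtvn, function(m)
            is(m, "StructureMask") && sum(m@voxels) > 0L, logical(1))
        if (!all(ok))
            msg <- c(msg, "every GTVn component must be a non-empty StructureMask")
    }
    if (length(msg)) msg else TRUE
})

#' SlicePolygon: a closed landmark loop on one axial slice
#'
#' An implicitly closed planar polygon in physical (x, y) mm on a single
#' axial slice: the last vertex connects back to the first, which is not
#' repeated.
#'
#' @slot sliceIndex integer(1), the axial slice the loop lives on.
#' @slot vertices numeric matrix, n x 2, columns (x, y) mm; n >= 3.
#' @aliases SlicePolygon
#' @exportClass SlicePolygon
setClass("SlicePolygon",
    slots = c(sliceIndex = "integer", vertices = "matrix")
)

setValidity("SlicePolygon", function(object) {
    msg <- character()
    v <- object@vertices
    if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 3L || anyNA(v))
        msg <- c(msg, "vertices must be a numeric n x 2 matrix, n >= 3")
    else if (all(v[1L, ] == v[nrow(v), ]))
        msg <- c(msg, "first vertex must not be duplicated as the last")
    if (length(object@sliceIndex) != 1L || is.na(object@sliceIndex))
        msg <- c(msg, "sliceIndex must be a single integer")
    if (length(msg)) msg else TRUE
})

#' CTVSet: the constructed target volumes of a case
#'
#' Output container of \code{\link{runPipeline}}: the per-tier target
#' volumes (ctv1p, ctv1n, ctv1, ctv2, ctv3p, ctv3n, ctv3, ctv4) plus the
#' composite envelopes ctv_expansion (= ctv1 with ctv2) and ctv_overall
#' (outer envelope of all tiers), and an ordered provenance log of every
#' operation and parameter applied.
#'
#' @slot volumes named list of \linkS4class{StructureMask}, possibly
#'   empty masks for tiers a case does not use.
#' @slot provenance list of step records (name, parameters), in execution
#'   order; serialize with \code{\link{writeProvenance}}.
#' @aliases CTVSet
#' @exportClass CTVSet
setClass("CTVSet",
    slots = c(volumes = "list", provenance = "list")
)

.ctv_volume_names <- c("ctv1p", "ctv1n", "ctv1", "ctv2", "ctv3p", "ctv3n",
                       "ctv3", "ctv4", "ctv_expansion", "ctv_overall")

setValidity("CTVSet", function(object) {
    msg <- character()
    nm <- names(object@volumes)
    if (!all(nm %in% .ctv_volume_names))
        msg <- c(msg, paste0("unknown CTV volume name(s): ",
                             paste(setdiff(nm, .ctv_volume_names),
                                   collapse = ", ")))
    if (length(object@volumes) &&
        !all(vapply(object@volumes, is, logical(1), "StructureMask")))
        msg <- c(msg, "all volumes must be StructureMasks")
    if (length(msg)) msg else TRUE
})
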