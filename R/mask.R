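#' Construct a StructureMask
#'
#' @param name structure name; canonical names are listed by
#'   \code{\link{canonicalStructureNames}}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param voxels logical (or coercible) array with dim equal to the grid
#'   shape; missing means an all-background mask.
#' @return A \linkS4class{StructureMask}.
#' @examples
#' g <- ImageGrid(c(10L, 10L, 10L), c(1, 1, 1))
#' m <- StructureMask("nasopharynx", g)
#' maskVolume(m)
#' @export
StructureMask <- function(name, grid, voxels = NULL) {
    if (is.null(voxels))
        voxels <- array(FALSE, dim3(grid))
    if (!is.logical(voxels)) {
        storage.mode(voxels) <- "logical"
    }
    new("StructureMask", name = as.character(name), grid = grid,
        voxels = voxels)
}

#' @rdname StructureMask
#' @param mask a \linkS4class{StructureMask}.
#' @export
maskName <- function(mask) mask@name

#' @rdname StructureMask
#' @export
maskGrid <- function(mask) mask@grid

#' @rdname StructureMask
#' @export
maskVoxels <- function(mask) mask@voxels

#' @rdname StructureMask
#' @export
maskVoxelCount <- function(mask) sum(mask@voxels)

#' @rdname StructureMask
#' @details \code{maskVolume} returns the foreground volume in mm^3.
#' @export
maskVolume <- function(mask) sum(mask@voxels) * voxelVolume(mask@grid)

#' @rdname StructureMask
#' @export
isEmptyMask <- function(mask) !any(mask@voxels)

## derive a mask sharing grid from new voxels
withVoxels <- function(mask, voxels, name = mask@name) {
    new("StructureMask", name = name, grid = mask@grid, voxels = voxels)
}

#' Voxelwise boolean combinations of masks
#'
#' Union, intersection and difference of masks on a shared grid.
#' @param a,b \linkS4class{StructureMask} objects on one grid.
#' @param name name of the derived mask.
#' @return A \linkS4class{StructureMask}.
#' @export
maskUnion <- function(a, b, name = a@name) {
    stopIfGridMismatch(a@grid, b@grid)
    withVoxels(a, a@voxels | b@voxels, name)
}

#' @rdname maskUnion
#' @export
maskIntersect <- function(a, b, name = a@name) {
    stopIfGridMismatch(a@grid, b@grid)
    withVoxels(a, a@voxels & b@voxels, name)
}

#' @rdname maskUnion
#' @export
maskDiff <- function(a, b, name = a@name) {
    stopIfGridMismatch(a@grid, b@grid)
    withVoxels(a, a@voxels & !b@voxels, name)
}

#' @rdname maskUnion
#' @param masks list of \linkS4class{StructureMask} on one grid (may be
#'   empty, in which case \code{grid} must be given).
#' @param grid grid for the empty-list case.
#' @export
maskUnionAll <- function(masks, name = "union", grid = NULL) {
    if (!length(masks)) {
        if (is.null(grid)) stop("empty mask list needs an explicit grid")
        return(StructureMask(name, grid))
    }
    out <- masks[[1L]]@voxels
    if (length(masks) > 1L)
        for (m in masks[-1L]) {
            stopIfGridMismatch(masks[[1L]]@grid, m@grid)
            out <- out | m@voxels
        }
    withVoxels(masks[[1L]], out, name)
}

#' @describeIn StructureMask show method
#' @param object a \linkS4class{StructureMask}.
#' @export
setMethod("show", "StructureMask", function(object) {
    cat(sprintf("StructureMask '%s': %d foreground voxels (%.2f cm^3)\n",
        object@name, sum(object@voxels),
        sum(object@voxels) * voxelVolume(object@grid) / 1000))
    show(object@grid)
})

#' Construct a StructureSet
#'
#' @param masks named list of \linkS4class{StructureMask}; names default
#'   to each mask's own name.
#' @param grid shared grid; defaults to the first mask's grid.
#' @return A \linkS4class{StructureSet}.
#' @export
StructureSet <- function(masks = list(), grid = NULL) {
    if (is.null(grid)) {
        if (!length(masks)) stop("an empty StructureSet needs a grid")
        grid <- masks[[1L]]@grid
    }
    if (is.null(names(masks)) && length(masks))
        names(masks) <- vapply(masks, maskName, character(1))
    new("StructureSet", grid = grid, masks = masks)
}

#' @rdname StructureSet
#' @param x,set a \linkS4class{StructureSet}.
#' @export
structureNames <- function(set) names(set@masks)

#' @rdname StructureSet
#' @param name structure name to fetch.
#' @export
getStructure <- function(set, name) {
    if (!name %in% names(set@masks))
        stop("structure '", name, "' is not in the set", call. = FALSE)
    set@masks[[name]]
}

#' @rdname StructureSet
#' @export
hasStructure <- function(set, name) name %in% names(set@masks)

#' @rdname StructureSet
#' @param mask mask to add (replaces an existing member of the same name).
#' @export
addStructure <- function(set, mask) {
    stopIfGridMismatch(set@grid, mask@grid)
    set@masks[[mask@name]] <- mask
    validObject(set)
    set
}

#' @rdname StructureSet
#' @param required character vector of names that must be present.
#' @details \code{checkRequiredStructures} errors (rather than silently
#'   skipping) when a declared-required structure is absent.
#' @export
checkRequiredStructures <- function(set, required) {
    missing <- setdiff(required, names(set@masks))
    if (length(missing))
        stop("required structure(s) missing from set: ",
             paste(missing, collapse = ", "), call. = FALSE)
    invisible(TRUE)
}

#' @rdname StructureSet
#' @param i structure name.
#' @export
setMethod("[[", "StructureSet", function(x, i) getStructure(x, i))

#' @describeIn StructureSet number of member masks
#' @export
setMethod("length", "StructureSet", function(x) length(x@masks))

#' @describeIn StructureSet show method
#' @param object a \linkS4class{StructureSet}.
#' @export
setMethod("show", "StructureSet", function(object) {
    cat(sprintf("StructureSet with %d structure(s)\n", length(object@masks)))
    show(object@grid)
    if (length(object@masks)) {
        nm <- names(object@masks)
        if (length(nm) > 12L) nm <- c(nm[1:12], "...")
        cat("  members:", paste(nm, collapse = ", "), "\n")
    }
})

#' Construct a TumorContext
#'
#' @param gtvp non-empty \linkS4class{StructureMask} of the primary GTV.
#' @param gtvn list of non-empty GTVn component masks (empty list for N0).
#' @param tStage integer T stage, 1..4.
#' @param nStage integer N stage, 0..3.
#' @return A \linkS4class{TumorContext}.
#' @export
TumorContext <- function(gtvp, gtvn = list(), tStage, nStage) {
    new("TumorContext", gtvp = gtvp, gtvn = gtvn,
        tStage = as.integer(tStage), nStage = as.integer(nStage))
}

#' @rdname TumorContext
#' @param tumor a \linkS4class{TumorContext}.
#' @export
gtvpMask <- function(tumor) tumor@gtvp

#' @rdname TumorContext
#' @export
gtvnComponents <- function(tumor) tumor@gtvn

#' @rdname TumorContext
#' @export
tStage <- function(tumor) tumor@tStage

#' @rdname TumorContext
#' @export
nStage <- function(tumor) tumor@nStage

#' @describeIn TumorContext show method
#' @param object a \linkS4class{TumorContext}.
#' @export
setMethod("show", "TumorContext", function(object) {
    cat(sprintf("TumorContext: T%d N%d, GTVp %.2f cm^3, %d GTVn component(s)\n",
        object@tStage, object@nStage, maskVolume(object@gtvp) / 1000,
        length(object@gtvn)))
})
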