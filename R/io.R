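## NIfTI mask input/output and grid resampling.
##
## One binary mask per .nii/.nii.gz file, filename stem = structure name.
## On disk the array is ordered x (col), y (row), z (slice); voxel
## spacing travels in pixdim and the origin in the sform translation
## (identity rotation). These are the package's LPS working coordinates
## written directly, so write/read round-trips are lossless.

#' Write a mask as NIfTI
#'
#' @param mask a \linkS4class{StructureMask}.
#' @param path output path ending in .nii or .nii.gz.
#' @return Invisibly, \code{path}.
#' @seealso \code{\link{readMask}}, \code{\link{readStructureSet}}
#' @export
writeMask <- function(mask, path) {
    g <- mask@grid
    arr <- aperm(array(as.integer(mask@voxels), dim(mask@voxels)),
                 c(3L, 2L, 1L))  # (x, y, z)
    sx <- g@spacing[3L]; sy <- g@spacing[2L]; sz <- g@spacing[1L]
    hdr <- RNifti::niftiHeader(list(
        dim = c(3L, dim(arr), 1L, 1L, 1L, 1L),
        pixdim = c(1, sx, sy, sz, 0, 0, 0, 0),
        srow_x = c(sx, 0, 0, g@origin[3L]),
        srow_y = c(0, sy, 0, g@origin[2L]),
        srow_z = c(0, 0, sz, g@origin[1L]),
        sform_code = 2L,
        intent_name = if (g@sliceInferior) "SLICE_INF" else "SLICE_SUP",
        descrip = substr(mask@name, 1L, 79L)
    ))
    img <- RNifti::asNifti(arr, reference = hdr)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a mask from NIfTI
#'
#' @param path path to a .nii/.nii.gz binary mask.
#' @param name structure name; defaults to the canonicalized file stem,
#'   falling back to the name stored in the header by
#'   \code{\link{writeMask}}.
#' @param custom allow names outside the canonical registry.
#' @return A \linkS4class{StructureMask}; voxels are \code{> 0.5} of the
#'   stored values.
#' @export
readMask <- function(path, name = NULL, custom = FALSE) {
    if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
    img <- RNifti::readNifti(path)
    hdr <- RNifti::niftiHeader(img)
    if (is.null(name)) {
        stem <- sub("\\.nii(\\.gz)?$", "", basename(path))
        name <- tryCatch(canonicalizeStructureName(stem, custom = custom),
                         error = function(e) {
                             if (nzchar(hdr$descrip)) hdr$descrip else stop(e)
                         })
    }
    arr <- aperm(array(as.numeric(img), dim(img)[1:3]), c(3L, 2L, 1L)) > 0.5
    spacing <- c(hdr$pixdim[4L], hdr$pixdim[3L], hdr$pixdim[2L])
    origin <- if (hdr$sform_code > 0L)
        c(hdr$srow_z[4L], hdr$srow_y[4L], hdr$srow_x[4L])
    else c(0, 0, 0)
    grid <- ImageGrid(dim(arr), spacing, origin,
                      sliceInferior = !identical(hdr$intent_name, "SLICE_SUP"))
    StructureMask(name, grid, arr)
}

#' Nearest-neighbour resampling of a binary mask to a target grid
#'
#' Each target voxel center is mapped to its nearest source voxel center
#' in physical coordinates; centers falling outside the source extent
#' become background. Resampling an already-matching grid is the
#' identity.
#'
#' @param mask a \linkS4class{StructureMask}.
#' @param target target \linkS4class{ImageGrid}; must overlap the source
#'   extent.
#' @return A \linkS4class{StructureMask} on \code{target}.
#' @export
resampleToGrid <- function(mask, target) {
    src <- mask@grid
    if (sameGrid(src, target)) return(mask)
    # nearest source index along one axis for every target center
    nn <- function(tc, s0, ds, n) {
        i <- as.integer(floor((tc - s0) / ds + 0.5)) + 1L
        i[i < 1L | i > n] <- NA_integer_
        i
    }
    iz <- nn(sliceAxisCoords(target), src@origin[1L], src@spacing[1L],
             src@shape[1L])
    iy <- nn(yCoords(target), src@origin[2L], src@spacing[2L], src@shape[2L])
    ix <- nn(xCoords(target), src@origin[3L], src@spacing[3L], src@shape[3L])
    if (all(is.na(iz)) || all(is.na(iy)) || all(is.na(ix)))
        stop("source and target grids have disjoint physical extents",
             call. = FALSE)
    out <- array(FALSE, dim3(target))
    okz <- !is.na(iz); oky <- !is.na(iy); okx <- !is.na(ix)
    out[okz, oky, okx] <-
        mask@voxels[iz[okz], iy[oky], ix[okx], drop = FALSE]
    StructureMask(mask@name, target, out)
}

#' Read a structure set from NIfTI files
#'
#' Reads a collection of per-structure NIfTI masks into a
#' \linkS4class{StructureSet}. File stems are mapped to canonical names
#' through the registry with case-insensitive aliasing. Under the
#' \code{"strict"} grid policy all masks must share one grid; under
#' \code{"resample"} every mask is nearest-neighbour resampled to
#' \code{referenceGrid} (default: the first mask's grid).
#'
#' @param paths character vector of .nii/.nii.gz paths, or a single
#'   directory containing them.
#' @param gridPolicy "strict" or "resample".
#' @param referenceGrid \linkS4class{ImageGrid} for the resample policy.
#' @param custom allow non-registry structure names.
#' @return A \linkS4class{StructureSet}.
#' @export
readStructureSet <- function(paths, gridPolicy = c("strict", "resample"),
                             referenceGrid = NULL, custom = FALSE) {
    gridPolicy <- match.arg(gridPolicy)
    if (length(paths) == 1L && dir.exists(paths))
        paths <- list.files(paths, pattern = "\\.nii(\\.gz)?$",
                            full.names = TRUE)
    if (!length(paths)) stop("no NIfTI files to read", call. = FALSE)
    masks <- lapply(paths, readMask, custom = custom)
    if (gridPolicy == "strict") {
        for (m in masks[-1L])
            if (!sameGrid(masks[[1L]]@grid, m@grid))
                stop("grid mismatch under the 'strict' policy ('",
                     m@name, "')", call. = FALSE)
        grid <- masks[[1L]]@grid
    } else {
        grid <- referenceGrid %||% masks[[1L]]@grid
        masks <- lapply(masks, resampleToGrid, target = grid)
    }
    names(masks) <- vapply(masks, maskName, character(1))
    StructureSet(masks, grid)
}

#' Write every volume of a CTVSet as NIfTI
#'
#' @param ctvs a \linkS4class{CTVSet}.
#' @param dir output directory (created if needed).
#' @param gzip write .nii.gz (default) or plain .nii.
#' @return Invisibly, the written paths.
#' @export
writeCTVSet <- function(ctvs, dir, gzip = TRUE) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ext <- if (gzip) ".nii.gz" else ".nii"
    paths <- vapply(names(ctvs@volumes), function(nm) {
        p <- file.path(dir, paste0(nm, ext))
        writeMask(ctvs@volumes[[nm]], p)
        p
    }, character(1))
    invisible(paths)
}

#' Serialize a CTVSet provenance log as JSON
#'
#' @param ctvs a \linkS4class{CTVSet}.
#' @param path output .json path.
#' @return Invisibly, \code{path}.
#' @export
writeProvenance <- function(ctvs, path) {
    jsonlite::write_json(ctvs@provenance, path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
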