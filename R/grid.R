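#' Construct an ImageGrid
#'
#' @param shape integer(3), (slices, rows, cols).
#' @param spacing numeric(3), mm per step along (slice, row, col).
#'   Default \code{c(2.5, 1, 1)}: 2.5 mm slices with 1 mm in-plane pitch.
#' @param origin numeric(3), physical mm coordinate of the first voxel
#'   center, (slice-axis, y, x).
#' @param sliceInferior slice index increases inferiorly (default TRUE).
#' @return An \linkS4class{ImageGrid}.
#' @examples
#' g <- ImageGrid(c(80L, 128L, 128L))
#' gridSpacing(g)
#' @export
ImageGrid <- function(shape, spacing = c(2.5, 1, 1), origin = c(0, 0, 0),
                      sliceInferior = TRUE) {
    new("ImageGrid", shape = as.integer(shape), spacing = as.numeric(spacing),
        origin = as.numeric(origin), sliceInferior = isTRUE(sliceInferior))
}

## dim of the voxel array implied by a grid
dim3 <- function(grid) grid@shape

#' @rdname ImageGrid
#' @param x,grid an \linkS4class{ImageGrid}.
#' @export
gridShape <- function(grid) grid@shape

#' @rdname ImageGrid
#' @export
gridSpacing <- function(grid) grid@spacing

#' @rdname ImageGrid
#' @export
gridOrigin <- function(grid) grid@origin

#' @rdname ImageGrid
#' @export
voxelVolume <- function(grid) prod(grid@spacing)

## physical center coordinates along each array axis
sliceAxisCoords <- function(grid)
    grid@origin[1L] + (seq_len(grid@shape[1L]) - 1L) * grid@spacing[1L]
yCoords <- function(grid)
    grid@origin[2L] + (seq_len(grid@shape[2L]) - 1L) * grid@spacing[2L]
xCoords <- function(grid)
    grid@origin[3L] + (seq_len(grid@shape[3L]) - 1L) * grid@spacing[3L]

#' Sagittal midline x coordinate of a grid
#'
#' Physical x (mm) of the grid's in-plane center, used to split a volume
#' into patient-left and patient-right halves.
#' @param grid an \linkS4class{ImageGrid}.
#' @return numeric(1), mm.
#' @export
gridMidlineX <- function(grid) {
    xs <- xCoords(grid)
    (xs[1L] + xs[length(xs)]) / 2
}

sameGrid <- function(a, b, tol = 1e-6) {
    identical(a@shape, b@shape) &&
        all(abs(a@spacing - b@spacing) <= tol) &&
        all(abs(a@origin - b@origin) <= tol) &&
        identical(a@sliceInferior, b@sliceInferior)
}

stopIfGridMismatch <- function(a, b, what = "masks") {
    if (!sameGrid(a, b))
        stop("grid mismatch: ", what, " must share one ImageGrid",
             call. = FALSE)
    invisible(TRUE)
}

#' @describeIn ImageGrid show method
#' @param object an \linkS4class{ImageGrid}.
#' @export
setMethod("show", "ImageGrid", function(object) {
    cat(sprintf(
        "ImageGrid: %d x %d x %d (slices x rows x cols)\n",
        object@shape[1L], object@shape[2L], object@shape[3L]))
    cat(sprintf("  spacing (mm): %.4g x %.4g x %.4g | origin (mm): %.4g, %.4g, %.4g\n",
        object@spacing[1L], object@spacing[2L], object@spacing[3L],
        object@origin[1L], object@origin[2L], object@origin[3L]))
    cat(sprintf("  slice index increases %s\n",
        if (object@sliceInferior) "inferiorly" else "superiorly"))
})
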