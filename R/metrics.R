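## Contour-comparison metrics: Dice similarity coefficient and mean
## surface distance.

#' Dice similarity coefficient
#'
#' \eqn{DSC = 2|A \cap B| / (|A| + |B|)} on masks sharing one grid. Two
#' empty masks are defined to agree perfectly (DSC 1).
#'
#' @param a,b \linkS4class{StructureMask} objects on a shared grid.
#' @return numeric(1) in [0, 1].
#' @export
dsc <- function(a, b) {
    stopIfGridMismatch(a@grid, b@grid)
    na <- sum(a@voxels); nb <- sum(b@voxels)
    if (na + nb == 0L) return(1.0)
    2 * sum(a@voxels & b@voxels) / (na + nb)
}

## surface voxels: foreground with a face-adjacent (6-neighbour)
## background voxel; the volume border counts as background
surfaceVoxels <- function(voxels) {
    d <- dim(voxels)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- voxels
    i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
    interior <- pad[i - 1, j, k] & pad[i + 1, j, k] &
                pad[i, j - 1, k] & pad[i, j + 1, k] &
                pad[i, j, k - 1] & pad[i, j, k + 1]
    voxels & !interior
}

#' Mean surface distance
#'
#' Symmetric mean surface distance in mm: the average of the two
#' directed mean nearest-surface distances between the masks' surface
#' voxels (foreground voxels with a face-adjacent background neighbor),
#' measured between voxel centers in physical coordinates. Errors on an
#' empty mask.
#'
#' @param a,b non-empty \linkS4class{StructureMask} objects on a shared
#'   grid.
#' @return numeric(1), mm (0 for identical masks).
#' @export
msd <- function(a, b) {
    stopIfGridMismatch(a@grid, b@grid)
    if (isEmptyMask(a) || isEmptyMask(b))
        stop("mean surface distance is undefined for empty masks",
             call. = FALSE)
    sa <- surfaceVoxels(a@voxels)
    sb <- surfaceVoxels(b@voxels)
    sp <- a@grid@spacing
    da <- sqrt(distanceSqToForeground(sb, sp)[sa])  # A-surface -> B-surface
    db <- sqrt(distanceSqToForeground(sa, sp)[sb])
    (mean(da) + mean(db)) / 2
}

#' Compare two structure sets
#'
#' Evaluates every structure name present in both sets with DSC and MSD
#' plus the two volumes; masks empty on either side get an NA MSD.
#'
#' @param test,reference \linkS4class{StructureSet}s on one grid.
#' @return data.frame with columns structure, dsc, msd_mm,
#'   volume_test_mm3, volume_reference_mm3.
#' @export
evaluateContours <- function(test, reference) {
    common <- intersect(structureNames(test), structureNames(reference))
    rows <- lapply(common, function(nm) {
        a <- getStructure(test, nm)
        b <- getStructure(reference, nm)
        data.frame(
            structure = nm,
            dsc = dsc(a, b),
            msd_mm = if (isEmptyMask(a) || isEmptyMask(b)) NA_real_
                     else msd(a, b),
            volume_test_mm3 = maskVolume(a),
            volume_reference_mm3 = maskVolume(b)
        )
    })
    do.call(rbind, rows)
}
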