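## Landmark engine for the intermediate-dose primary target (CTV3p):
## sphenoid-stage targeting, primary-tumor localization, axial structure
## grouping, per-slice landmark selection, polygon formation and the
## CTV3p union.

## axial structure groups, inferior (1) to superior (8); a slice matches a
## group only when every listed structure has foreground on that slice
.axialGroups <- list(
    `1` = c("LN_RP_L", "LN_RP_R", "pterygoid_fossa_L", "pterygoid_fossa_R"),
    `2` = c("mastoid_L", "mastoid_R", "LN_RP_L", "LN_RP_R",
            "pterygoid_fossa_L", "pterygoid_fossa_R", "nasopharynx"),
    `3` = c("LN_RP_L", "LN_RP_R", "pterygoid_fossa_L", "pterygoid_fossa_R",
            "nasopharynx"),
    `4` = c("clivus", "pterygoid_fossa_L", "pterygoid_fossa_R",
            "nasopharynx"),
    `5` = c("clivus", "pterygoid_fossa_L", "pterygoid_fossa_R",
            "nasopharynx", "maxillary_sinus_L", "maxillary_sinus_R"),
    `6` = c("clivus", "maxillary_sinus_L", "maxillary_sinus_R",
            "sphenoid_sinus"),
    `7` = c("maxillary_sinus_L", "maxillary_sinus_R", "sphenoid_sinus"),
    `8` = c("sphenoid_sinus")
)

#' Axial group definitions
#'
#' The structure lists that define the eight axial groups used to pick
#' landmark rules per slice, from the most inferior group (1,
#' retropharyngeal nodes and pterygoid fossae) to the most superior
#' (8, sphenoid sinus alone).
#' @return Named list of character vectors.
#' @export
axialGroupDefinitions <- function() .axialGroups

#' Stage-dependent sphenoid sinus target
#'
#' For T stage 1-2 only the inferior half of the sphenoid sinus (split at
#' the centroid's axial plane) is targeted; for T stage 3-4 the whole
#' sinus is.
#'
#' @param sphenoid non-empty \linkS4class{StructureMask}.
#' @param t_stage integer 1..4.
#' @return A \linkS4class{StructureMask}.
#' @export
sphenoidTarget <- function(sphenoid, t_stage) {
    stopifnot(t_stage %in% 1:4)
    if (isEmptyMask(sphenoid))
        stop("sphenoid sinus mask is empty", call. = FALSE)
    if (t_stage <= 2L) splitInferiorAtCentroid(sphenoid)$inferior
    else sphenoid
}

#' Localize the primary GTV
#'
#' Determines on which side of the sagittal midline the GTVp lies
#' (bilateral when at least \code{bilateral_fraction} of its voxels sit on
#' each side; in LPS coordinates x increases toward the patient's left,
#' so x below the midline is the right side) and which reference
#' structures it touches (one or more overlapping voxels). Clivus
#' invasion is equivalent to clivus membership of \code{touches}.
#'
#' @param gtvp non-empty \linkS4class{StructureMask}.
#' @param structures a \linkS4class{StructureSet}; absent reference
#'   structures are skipped.
#' @param midline_x sagittal midline (mm); default the grid center.
#' @param bilateral_fraction voxel fraction per side that makes the GTVp
#'   bilateral (default 0.05).
#' @return list with \code{confined_side} ("left", "right" or
#'   "bilateral"), \code{invades_clivus} flag and \code{touches}
#'   (character vector).
#' @export
localizeGtvp <- function(gtvp, structures, midline_x = NULL,
                         bilateral_fraction = 0.05) {
    if (isEmptyMask(gtvp)) stop("GTVp is empty", call. = FALSE)
    if (is.null(midline_x)) midline_x <- gridMidlineX(gtvp@grid)
    counts <- apply(gtvp@voxels, 3L, sum)  # per-column voxel counts
    xs <- xCoords(gtvp@grid)
    leftFrac <- sum(counts[xs > midline_x]) / sum(counts)
    side <- if (leftFrac >= bilateral_fraction &&
                1 - leftFrac >= bilateral_fraction) "bilateral"
            else if (leftFrac >= 0.5) "left" else "right"
    refs <- c("clivus", "skull_base", "pterygoid_fossa_L",
              "pterygoid_fossa_R", "sphenoid_sinus", "nasal_cavity",
              "maxillary_sinus_L", "maxillary_sinus_R")
    touches <- refs[vapply(refs, function(nm)
        hasStructure(structures, nm) &&
            any(gtvp@voxels & getStructure(structures, nm)@voxels),
        logical(1))]
    list(confined_side = side,
         invades_clivus = "clivus" %in% touches,
         touches = touches)
}

#' Assign axial groups to slices
#'
#' For every axial slice, finds the groups whose full structure list has
#' foreground on that slice and assigns the most specific one (largest
#' structure list; ties broken toward the higher, more superior group
#' number). Slices matching no group stay unassigned. The assignment
#' depends only on slice-wise structure presence.
#'
#' @param structures a \linkS4class{StructureSet}.
#' @return list of assignments, each with \code{slice}, \code{group}
#'   (integer 1..8) and \code{present} (the group-relevant structure
#'   names with foreground on the slice).
#' @export
assignAxialGroups <- function(structures) {
    relevant <- unique(unlist(.axialGroups))
    nm <- intersect(structureNames(structures), relevant)
    if (!length(nm)) return(list())
    nSlices <- structures@grid@shape[1L]
    presence <- vapply(nm, function(n)
        apply(getStructure(structures, n)@voxels, 1L, any),
        logical(nSlices))
    if (nSlices == 1L) presence <- matrix(presence, nrow = 1L,
                                          dimnames = list(NULL, nm))
    sizes <- lengths(.axialGroups)
    out <- list()
    for (s in seq_len(nSlices)) {
        present <- nm[presence[s, ]]
        ok <- vapply(.axialGroups, function(req) all(req %in% present),
                     logical(1))
        if (!any(ok)) next
        cand <- which(ok)
        best <- cand[order(sizes[cand], cand, decreasing = TRUE)][1L]
        out[[length(out) + 1L]] <-
            list(slice = s, group = as.integer(best), present = present)
    }
    out
}

#' Load the landmark rule table
#'
#' @param path YAML rule file; default the table shipped with the
#'   package.
#' @return list of rules (structure, groups, anchors, condition,
#'   lateral_shift_if_involved).
#' @export
loadLandmarkRules <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "landmark_rules.yaml",
                            package = "npCTV", mustWork = TRUE)
    yaml::read_yaml(path)$rules
}

## snap a point to the nearest 7x7 candidate; ties toward lower index
.snapToGrid <- function(pt, candidates) {
    d2 <- (candidates[, 1L] - pt[1L])^2 + (candidates[, 2L] - pt[2L])^2
    candidates[which.min(round(d2, 9L)), ]
}

#' Select landmarks on one assigned slice
#'
#' For every structure of the slice's group with a matching rule, emits
#' the rule's anchors evaluated on the structure's slice bounding box and
#' snapped to the 7 x 7 candidate grid. The clivus rule switches between
#' its anterior-third line and its posterior corners with clivus
#' invasion; pterygoid anchors shift laterally on the hemineck involved
#' by the GTVp. Structures with no rule are skipped with a warning.
#'
#' @param assignment one element of \code{\link{assignAxialGroups}}'s
#'   result.
#' @param structures a \linkS4class{StructureSet}.
#' @param loc GTVp localization from \code{\link{localizeGtvp}}.
#' @param rules rule table from \code{\link{loadLandmarkRules}}.
#' @return numeric matrix of landmark (x, y) mm positions (possibly
#'   0-row).
#' @export
selectLandmarks <- function(assignment, structures, loc,
                            rules = loadLandmarkRules()) {
    req <- .axialGroups[[assignment$group]]
    pts <- matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("x", "y")))
    for (st in req) {
        if (!hasStructure(structures, st)) next
        matches <- Filter(function(r)
            r$structure == st && assignment$group %in% r$groups &&
                .ruleConditionHolds(r$condition %||% "none", loc),
            rules)
        if (!length(matches)) {
            warning("no landmark rule for structure '", st, "' in group ",
                    assignment$group, "; structure skipped", call. = FALSE)
            next
        }
        box <- boundingBox(getStructure(structures, st), assignment$slice)
        cand <- gridPoints(box)
        for (r in matches) {
            for (a in r$anchors) {
                fx <- a$fx
                if (isTRUE(r$lateral_shift_if_involved))
                    fx <- .lateralShift(fx, st, loc$confined_side)
                p <- c(box[["xmin"]] + fx * (box[["xmax"]] - box[["xmin"]]),
                       box[["ymin"]] + a$fy * (box[["ymax"]] - box[["ymin"]]))
                pts <- rbind(pts, .snapToGrid(p, cand))
            }
        }
    }
    unique(round(pts, 6L))
}

.ruleConditionHolds <- function(condition, loc) {
    switch(condition,
        none = TRUE,
        clivus_invaded = isTRUE(loc$invades_clivus),
        clivus_not_invaded = !isTRUE(loc$invades_clivus),
        stop("unknown landmark rule condition '", condition, "'")
    )
}

## lateral box edge in fx terms: patient left = fx 1, right = fx 0
.lateralShift <- function(fx, structure, confined_side) {
    side <- structureSide(structure)
    involved <- (side == "L" && confined_side %in% c("left", "bilateral")) ||
                (side == "R" && confined_side %in% c("right", "bilateral"))
    if (!involved) return(fx)
    if (side == "L") 1 else 0
}

#' Build a simple polygon from landmark points
#'
#' Orders the landmarks counter-clockwise by angle about their centroid
#' (ties broken by radius, then input order) and returns the resulting
#' loop. Fewer than three distinct points, collinear points, or a
#' self-intersecting loop yield \code{NULL} with a warning: the slice
#' then contributes no polygon.
#'
#' @param landmarks n x 2 matrix of (x, y) mm points.
#' @param sliceIndex the axial slice the loop lives on.
#' @return A \linkS4class{SlicePolygon}, or \code{NULL}.
#' @export
buildSlicePolygon <- function(landmarks, sliceIndex = 1L) {
    landmarks <- unique(as.matrix(landmarks))
    if (nrow(landmarks) < 3L) {
        warning("fewer than 3 distinct landmarks; slice skipped",
                call. = FALSE)
        return(NULL)
    }
    ctr <- colMeans(landmarks)
    dx <- landmarks[, 1L] - ctr[1L]
    dy <- landmarks[, 2L] - ctr[2L]
    ang <- atan2(dy, dx)
    r <- sqrt(dx^2 + dy^2)
    ord <- order(ang, r, seq_len(nrow(landmarks)))
    v <- landmarks[ord, , drop = FALSE]
    poly <- SlicePolygon(sliceIndex, v)
    if (polygonArea(poly) < 1e-9) {
        warning("landmarks are collinear; slice skipped", call. = FALSE)
        return(NULL)
    }
    if (!isSimplePolygon(poly)) {
        warning("landmark polygon self-intersects; slice skipped",
                call. = FALSE)
        return(NULL)
    }
    poly
}

#' Build the intermediate-dose primary target CTV3p
#'
#' CTV3p is the union of (a) the 5 mm expansion of CTV1p, (b) the
#' rasterized, Chaikin-smoothed landmark polygons of every
#' group-assigned axial slice, (c) the stage-dependent sphenoid target
#' and (d) the whole nasopharynx.
#'
#' @param ctv1p the high-dose primary target
#'   (\code{\link{buildCtv1p}}).
#' @param structures a \linkS4class{StructureSet}.
#' @param loc GTVp localization (\code{\link{localizeGtvp}}).
#' @param t_stage integer 1..4.
#' @param config pipeline configuration (\code{\link{ctvConfig}}).
#' @return list: \code{mask} (the CTV3p \linkS4class{StructureMask}) and
#'   \code{landmark_log} (per-slice group and landmark count, for
#'   provenance).
#' @export
buildCtv3p <- function(ctv1p, structures, loc, t_stage,
                       config = ctvConfig()) {
    rules <- config$landmark_rules %||% loadLandmarkRules(config$landmark_rules_path)
    out <- expandMask(ctv1p, config$ctv3p_expansion_mm, name = "ctv3p")
    log <- list()
    for (a in assignAxialGroups(structures)) {
        pts <- selectLandmarks(a, structures, loc, rules)
        if (nrow(pts) < 3L) next
        poly <- buildSlicePolygon(pts, a$slice)
        if (is.null(poly)) next
        poly <- chaikinSmooth(poly, config$chaikin_iterations)
        out <- maskUnion(out, polygonToMask(poly, structures@grid),
                         name = "ctv3p")
        log[[length(log) + 1L]] <-
            list(slice = a$slice, group = a$group, landmarks = nrow(pts))
    }
    if (hasStructure(structures, "sphenoid_sinus"))
        out <- maskUnion(out,
            sphenoidTarget(getStructure(structures, "sphenoid_sinus"),
                           t_stage), name = "ctv3p")
    if (hasStructure(structures, "nasopharynx"))
        out <- maskUnion(out, getStructure(structures, "nasopharynx"),
                         name = "ctv3p")
    list(mask = out, landmark_log = log)
}
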