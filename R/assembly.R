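## Pipeline assembly: CTV1p, the CTV3 merge, island joining,
## normal-structure subtraction, morphological refinement, and the
## composite CTV-Expansion / CTV-Overall envelopes.

#' Build the high-dose primary target CTV1p
#'
#' 3 mm volumetric expansion of the GTVp, with the margin reduced (to as
#' low as \code{min_margin_mm}) where it would enter a critical organ at
#' risk: a protected subtraction keeps the GTVp and its floor margin
#' intact while trimming the expansion out of the listed structures.
#'
#' @param gtvp non-empty \linkS4class{StructureMask}.
#' @param critical_oars list of \linkS4class{StructureMask} (possibly
#'   empty).
#' @param margin_mm expansion margin (default 3 mm).
#' @param min_margin_mm protected floor margin (default 0 mm).
#' @return A \linkS4class{StructureMask} named "ctv1p"; always contains
#'   the GTVp.
#' @export
buildCtv1p <- function(gtvp, critical_oars, margin_mm = 3,
                       min_margin_mm = 0) {
    if (isEmptyMask(gtvp)) stop("GTVp is empty", call. = FALSE)
    exp <- expandMask(gtvp, margin_mm, name = "ctv1p")
    subtractProtected(exp, critical_oars, gtvp, min_margin_mm)
}

## subtract a precomputed normal-structure union from one CTV,
## protecting a core
.subtractNormals <- function(ctv, sub_union, protect, min_margin_mm) {
    if (is.null(sub_union)) return(ctv)
    subtractProtected(ctv, list(sub_union), protect, min_margin_mm)
}

#' Subtract normal structures from the target volumes
#'
#' Removes the configured normal-structure list (brain, spinal cord,
#' optic apparatus, orbits, vertebral column and bodies, hyoid, cricoid,
#' mandible) from each CTV, protecting the corresponding gross tumor
#' volume plus its floor margin: 0 mm for the high-dose tier and CTV2,
#' 1 mm for the intermediate and low tiers. Absent structures are
#' skipped with a warning.
#'
#' @param volumes named list of CTV \linkS4class{StructureMask}s.
#' @param structures a \linkS4class{StructureSet}.
#' @param gtvp,gtvn_union gross tumor masks used as protected cores.
#' @param config pipeline configuration.
#' @return The trimmed named list of masks.
#' @export
subtractNormalStructures <- function(volumes, structures, gtvp, gtvn_union,
                                     config = ctvConfig()) {
    present <- intersect(config$subtract_structures,
                         structureNames(structures))
    absent <- setdiff(config$subtract_structures, present)
    if (length(absent))
        warning("subtraction skipped for absent structure(s): ",
                paste(absent, collapse = ", "), call. = FALSE)
    if (!length(present)) return(volumes)
    subUnion <- maskUnionAll(lapply(present, getStructure, set = structures),
                             name = "normal_structures",
                             grid = structures@grid)
    gtvAll <- maskUnion(gtvp, gtvn_union, name = "gtv_all")
    protectFor <- function(nm) switch(nm,
        ctv1p = gtvp, ctv3p = gtvp,
        ctv1n = gtvn_union, ctv2 = gtvn_union, ctv3n = gtvn_union,
        ctv4 = gtvn_union,
        gtvAll)
    floorFor <- function(nm)
        if (nm %in% c("ctv1p", "ctv1n", "ctv1", "ctv2"))
            config$min_margin_ctv1_mm else config$min_margin_ctv3_mm
    # protected zones depend only on (protect mask, floor margin): cache
    zones <- new.env(parent = emptyenv())
    zoneFor <- function(protect, floor_mm) {
        key <- paste0(protect@name, "@", floor_mm)
        if (is.null(zones[[key]]))
            zones[[key]] <- if (isEmptyMask(protect)) protect
                            else expandMask(protect, floor_mm)
        zones[[key]]
    }
    for (nm in names(volumes)) {
        v <- volumes[[nm]]
        if (isEmptyMask(v)) next
        zone <- zoneFor(protectFor(nm), floorFor(nm))
        keep <- !subUnion@voxels | zone@voxels
        volumes[[nm]] <- withVoxels(v, v@voxels & keep)
    }
    volumes
}

#' Run the full CTV construction pipeline
#'
#' Executes the complete rule-based construction in order: GTVp
#' localization and CTV1p; the landmark-driven CTV3p; nodal assessment,
#' scenario classification and CTV3n/CTV4/CTV2/CTV1n; the CTV3 merge;
#' alpha-shape island joining on CTV3; normal-structure subtraction with
#' gross-tumor protection; morphological refinement (with the
#' subtraction re-applied afterwards, since closing may push a contour
#' back into a removed structure); and finally the composite
#' CTV-Expansion (ctv1 with ctv2) and CTV-Overall (outer envelope of all
#' tiers). Every step is recorded in the provenance log with its
#' parameters; the construction path contains no randomness.
#'
#' @param structures a \linkS4class{StructureSet} (resampled to the GTVp
#'   grid if needed).
#' @param tumor a \linkS4class{TumorContext}.
#' @param config pipeline configuration from \code{\link{ctvConfig}}.
#' @return A \linkS4class{CTVSet}.
#' @examples
#' \donttest{
#' ph <- generatePhantom(phantomSpec(seed = 1))
#' ctvs <- runPipeline(ph$structures, ph$tumor)
#' ctvs
#' }
#' @export
runPipeline <- function(structures, tumor, config = ctvConfig()) {
    checkRequiredStructures(structures, config$required_structures)
    grid <- structures@grid
    prov <- list()
    note <- function(step, ...) {
        prov[[length(prov) + 1L]] <<- c(list(step = step), list(...))
    }

    gtvp <- resampleToGrid(tumor@gtvp, grid)
    gtvn <- lapply(tumor@gtvn, resampleToGrid, target = grid)
    gtvnUnion <- maskUnionAll(gtvn, name = "gtvn_union", grid = grid)
    criticalOars <- lapply(
        intersect(config$critical_oars, structureNames(structures)),
        getStructure, set = structures)

    loc <- localizeGtvp(gtvp, structures,
                        bilateral_fraction = config$bilateral_fraction)
    note("localize_gtvp", side = loc$confined_side,
         invades_clivus = loc$invades_clivus, touches = loc$touches)

    ctv1p <- buildCtv1p(gtvp, criticalOars,
                        margin_mm = config$ctv1p_margin_mm,
                        min_margin_mm = config$min_margin_ctv1_mm)
    note("build_ctv1p", margin_mm = config$ctv1p_margin_mm,
         min_margin_mm = config$min_margin_ctv1_mm)

    c3p <- buildCtv3p(ctv1p, structures, loc, tumor@tStage, config)
    ctv3p <- c3p$mask
    note("build_ctv3p", expansion_mm = config$ctv3p_expansion_mm,
         chaikin_iterations = config$chaikin_iterations,
         t_stage = tumor@tStage, slices = c3p$landmark_log)

    assessment <- assessNodes(gtvn, structures,
                              bilateral_fraction = config$bilateral_fraction,
                              small_node_cm = config$small_node_cm)
    cls <- classifyScenario(assessment)
    note("classify_scenario", scenario = cls$scenario,
         ctv2_scenarios = cls$ctv2_scenarios)

    nodal <- buildCtv3nCtv4(cls$scenario, structures)
    # intermediate-dose nodal margin: the elective levels plus GTVn + 5 mm
    if (!isEmptyMask(gtvnUnion))
        nodal$ctv3n <- maskUnion(nodal$ctv3n,
            expandMask(gtvnUnion, config$ctv3n_margin_mm), name = "ctv3n")
    ctv2 <- buildCtv2(assessment, gtvn, grid,
                      margin_mm = config$ctv2_margin_mm)
    ctv1n <- buildCtv1n(assessment, gtvn, criticalOars, grid,
                        margin_mm = config$ctv1n_margin_mm,
                        min_margin_mm = config$min_margin_ctv1_mm)
    note("build_nodal_volumes", scenario = cls$scenario,
         ctv2_margin_mm = config$ctv2_margin_mm,
         ctv1n_margin_mm = config$ctv1n_margin_mm)

    ctv1 <- maskUnion(ctv1p, ctv1n, name = "ctv1")
    ctv3 <- maskUnion(ctv3p, nodal$ctv3n, name = "ctv3")
    note("merge_ctv3", parts = c("ctv3p", "ctv3n"))

    if (config$join_islands) {
        ctv3 <- alphashapeJoin(ctv3, alpha = config$alpha_per_mm,
                               max_gap_mm = config$max_gap_mm)
        note("alphashape_join", alpha_per_mm = config$alpha_per_mm,
             max_gap_mm = config$max_gap_mm)
    }

    volumes <- list(ctv1p = ctv1p, ctv1n = ctv1n, ctv1 = ctv1, ctv2 = ctv2,
                    ctv3p = ctv3p, ctv3n = nodal$ctv3n, ctv3 = ctv3,
                    ctv4 = nodal$ctv4)
    volumes <- subtractNormalStructures(volumes, structures, gtvp,
                                        gtvnUnion, config)
    note("subtract_normal_structures",
         structures = config$subtract_structures,
         min_margin_ctv1_mm = config$min_margin_ctv1_mm,
         min_margin_ctv3_mm = config$min_margin_ctv3_mm)

    if (config$refine) {
        keep <- maskUnion(gtvp, gtvnUnion, name = "gtv_all")
        volumes <- lapply(volumes, function(v) {
            if (isEmptyMask(v)) return(v)
            morphRefine(v, open_mm = config$open_mm,
                        close_mm = config$close_mm,
                        min_hole_voxels = config$min_hole_voxels,
                        min_island_voxels = config$min_island_voxels,
                        keep = keep)
        })
        # closing can cross back into a subtracted structure; re-apply
        volumes <- subtractNormalStructures(volumes, structures, gtvp,
                                            gtvnUnion, config)
        note("morph_refine", open_mm = config$open_mm,
             close_mm = config$close_mm,
             min_hole_voxels = config$min_hole_voxels,
             min_island_voxels = config$min_island_voxels,
             resubtracted = TRUE)
    }

    volumes$ctv_expansion <- maskUnion(volumes$ctv1, volumes$ctv2,
                                       name = "ctv_expansion")
    volumes$ctv_overall <- Reduce(maskUnion,
        volumes[c("ctv1", "ctv2", "ctv3", "ctv4")])
    volumes$ctv_overall@name <- "ctv_overall"
    note("composites", ctv_expansion = c("ctv1", "ctv2"),
         ctv_overall = c("ctv1", "ctv2", "ctv3", "ctv4"))

    new("CTVSet", volumes = volumes, provenance = prov)
}

#' @rdname runPipeline
#' @param ctvs a \linkS4class{CTVSet}.
#' @param name one of the volume names (e.g. "ctv1", "ctv_overall").
#' @export
ctvVolume <- function(ctvs, name) {
    if (!name %in% names(ctvs@volumes))
        stop("no volume '", name, "' in this CTVSet", call. = FALSE)
    ctvs@volumes[[name]]
}

#' @rdname runPipeline
#' @export
ctvVolumeNames <- function(ctvs) names(ctvs@volumes)

#' @rdname runPipeline
#' @export
ctvProvenance <- function(ctvs) ctvs@provenance

#' @describeIn runPipeline show method
#' @param object a \linkS4class{CTVSet}.
#' @export
setMethod("show", "CTVSet", function(object) {
    cat(sprintf("CTVSet with %d volume(s), %d provenance step(s)\n",
        length(object@volumes), length(object@provenance)))
    for (nm in names(object@volumes)) {
        m <- object@volumes[[nm]]
        cat(sprintf("  %-13s %8d voxels  %8.2f cm^3\n", nm,
            sum(m@voxels), maskVolume(m) / 1000))
    }
})
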