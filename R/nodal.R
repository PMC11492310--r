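## Nodal target logic: GTVn localization and laterality, the 2 cm
## equivalent-diameter size criterion, the nine CTV3n/CTV4 neck-coverage
## scenarios, CTV2 routing and CTV1n.

#' Assess the nodal gross tumor volume components
#'
#' Per GTVn component: laterality by the sagittal-midline rule
#' (bilateral when at least \code{bilateral_fraction} of voxels lie on
#' each side), containing nodal levels (one or more overlapping voxels
#' with a level mask), equivalent-sphere diameter and the small-node flag
#' (diameter of at most 2 cm). Hemineck presence and low-neck
#' (level IV / Vb) involvement flags aggregate over components. An empty
#' component list is the N0 case: all flags false.
#'
#' @param gtvn_components list of non-empty \linkS4class{StructureMask}.
#' @param structures a \linkS4class{StructureSet} holding the nodal level
#'   masks.
#' @param midline_x sagittal midline (mm); default the grid center.
#' @param bilateral_fraction per-side voxel fraction that makes a
#'   component bilateral.
#' @param small_node_cm size criterion (default 2 cm).
#' @return list with \code{components} (per-component side, levels,
#'   diameter_cm, small_node), and aggregate flags \code{present_L},
#'   \code{present_R}, \code{low_neck_L}, \code{low_neck_R}.
#' @export
assessNodes <- function(gtvn_components, structures, midline_x = NULL,
                        bilateral_fraction = 0.05, small_node_cm = 2.0) {
    if (is.null(midline_x) && length(gtvn_components))
        midline_x <- gridMidlineX(gtvn_components[[1L]]@grid)
    levelNames <- intersect(nodalLevelNames(), structureNames(structures))
    comps <- lapply(gtvn_components, function(comp) {
        if (isEmptyMask(comp))
            stop("GTVn components must be non-empty", call. = FALSE)
        counts <- apply(comp@voxels, 3L, sum)
        xs <- xCoords(comp@grid)
        leftFrac <- sum(counts[xs > midline_x]) / sum(counts)
        side <- if (leftFrac >= bilateral_fraction &&
                    1 - leftFrac >= bilateral_fraction) "bilateral"
                else if (leftFrac >= 0.5) "left" else "right"
        levels <- levelNames[vapply(levelNames, function(nm)
            any(comp@voxels & getStructure(structures, nm)@voxels),
            logical(1))]
        d <- equivalentSphereDiameter(comp)
        list(name = comp@name, side = side, levels = levels,
             diameter_cm = d, small_node = d <= small_node_cm)
    })
    onSide <- function(side) vapply(comps, function(cp)
        cp$side %in% c(side, "bilateral"), logical(1))
    lowOn <- function(side) vapply(comps, function(cp)
        any(cp$levels %in% paste0(c("LN_IV_", "LN_Vb_"), side)), logical(1))
    list(components = comps,
         present_L = any(onSide("left")),
         present_R = any(onSide("right")),
         low_neck_L = any(lowOn("L")),
         low_neck_R = any(lowOn("R")))
}

#' Classify the nodal coverage scenario
#'
#' Total and exhaustive mapping of the hemineck presence and low-neck
#' involvement flags onto the nine CTV3n/CTV4 scenarios, plus the set of
#' CTV2 conditions that apply (1: a small, sub-2-cm node in level Ib;
#' 2: a node in level IV or Vb). Low-neck flags are clamped to their
#' hemineck presence flag so the function is total on all flag
#' combinations.
#'
#' @param assessment result of \code{\link{assessNodes}}.
#' @return list with \code{scenario} (integer 1..9) and
#'   \code{ctv2_scenarios} (integer subset of \{1, 2\}).
#' @export
classifyScenario <- function(assessment) {
    a <- assessment
    L <- isTRUE(a$present_L); R <- isTRUE(a$present_R)
    lowL <- isTRUE(a$low_neck_L) && L
    lowR <- isTRUE(a$low_neck_R) && R
    scenario <-
        if (!L && !R) 1L
        else if (!lowL && !lowR) { if (L && R) 2L else if (L) 3L else 4L }
        else if (L && R) { if (lowL && lowR) 5L else if (lowL) 6L else 7L }
        else if (L) 8L else 9L
    ctv2 <- integer()
    smallIb <- any(vapply(a$components, function(cp)
        cp$diameter_cm < 2.0 && any(grepl("^LN_Ib_", cp$levels)),
        logical(1)))
    lowAny <- any(vapply(a$components, function(cp)
        any(grepl("^LN_IV_|^LN_Vb_", cp$levels)), logical(1)))
    if (smallIb) ctv2 <- c(ctv2, 1L)
    if (lowAny) ctv2 <- c(ctv2, 2L)
    list(scenario = scenario, ctv2_scenarios = ctv2)
}

#' Nodal-level membership per scenario
#'
#' The scenario-to-level membership matrix (which nodal level mask joins
#' CTV3n, which joins CTV4, per scenario), shipped as a data file for
#' auditability.
#'
#' @return data.frame, one row per scenario, one column per level mask
#'   with values "ctv3n", "ctv4" or "none".
#' @export
nodalScenarioTable <- function() {
    path <- system.file("extdata", "nodal_scenarios.csv",
                        package = "npCTV", mustWork = TRUE)
    utils::read.csv(path, check.names = FALSE)
}

#' Build CTV3n and CTV4 for a scenario
#'
#' Unions the nodal level masks assigned to each volume by the scenario
#' membership table. Levels II, III and Va enter CTV3n bilaterally in
#' every scenario; level Ib and the low-neck levels IV/Vb follow the
#' scenario.
#'
#' @param scenario integer 1..9 (from \code{\link{classifyScenario}}).
#' @param structures a \linkS4class{StructureSet} holding the required
#'   level masks (an absent required level is an error).
#' @return list with masks \code{ctv3n} and \code{ctv4} (CTV4 may be
#'   empty, e.g. scenario 5).
#' @export
buildCtv3nCtv4 <- function(scenario, structures) {
    stopifnot(scenario %in% 1:9)
    tab <- nodalScenarioTable()
    row <- tab[tab$scenario == scenario, , drop = FALSE]
    levelCols <- setdiff(names(tab), "scenario")
    pick <- function(vol) levelCols[as.character(row[1L, levelCols]) == vol]
    take <- function(names, out) {
        checkRequiredStructures(structures, names)
        maskUnionAll(lapply(names, getStructure, set = structures),
                     name = out, grid = structures@grid)
    }
    n3 <- pick("ctv3n"); n4 <- pick("ctv4")
    list(
        ctv3n = take(n3, "ctv3n"),
        ctv4 = if (length(n4)) take(n4, "ctv4")
               else StructureMask("ctv4", structures@grid)
    )
}

#' Build CTV2
#'
#' CTV2 unites the 3 mm expansions of (condition 1) every GTVn component
#' overlapping level Ib with equivalent diameter strictly below 2 cm and
#' (condition 2) every component overlapping level IV or Vb. With
#' neither condition the result is an empty mask.
#'
#' @param assessment result of \code{\link{assessNodes}}.
#' @param gtvn_components the assessed component masks, same order.
#' @param grid grid for the empty result.
#' @param margin_mm expansion margin (default 3 mm).
#' @return A \linkS4class{StructureMask} named "ctv2".
#' @export
buildCtv2 <- function(assessment, gtvn_components, grid,
                      margin_mm = 3) {
    picks <- list()
    for (i in seq_along(assessment$components)) {
        cp <- assessment$components[[i]]
        route1 <- cp$diameter_cm < 2.0 && any(grepl("^LN_Ib_", cp$levels))
        route2 <- any(grepl("^LN_IV_|^LN_Vb_", cp$levels))
        if (route1 || route2)
            picks[[length(picks) + 1L]] <-
                expandMask(gtvn_components[[i]], margin_mm)
    }
    maskUnionAll(picks, name = "ctv2", grid = grid)
}

#' Build CTV1n
#'
#' The high-dose nodal target: each GTVn component expanded by 3 mm with
#' the margin reduced (to as low as 0 mm) where it would enter a critical
#' organ at risk — realized as a protected subtraction with the component
#' itself as the protected core. Components already routed to CTV2 by
#' the small-Ib condition are excluded, so a node is never assigned to
#' both high-dose and intermediate-dose nodal volumes.
#'
#' @param assessment result of \code{\link{assessNodes}}.
#' @param gtvn_components the assessed component masks, same order.
#' @param critical_oars list of \linkS4class{StructureMask} to avoid.
#' @param grid grid for the empty result.
#' @param margin_mm expansion margin (default 3 mm).
#' @param min_margin_mm protected floor margin (default 0 mm).
#' @return A \linkS4class{StructureMask} named "ctv1n".
#' @export
buildCtv1n <- function(assessment, gtvn_components, critical_oars, grid,
                       margin_mm = 3, min_margin_mm = 0) {
    picks <- list()
    for (i in seq_along(assessment$components)) {
        cp <- assessment$components[[i]]
        routedToCtv2 <- cp$diameter_cm < 2.0 &&
            any(grepl("^LN_Ib_", cp$levels))
        if (routedToCtv2) next
        comp <- gtvn_components[[i]]
        exp <- expandMask(comp, margin_mm)
        picks[[length(picks) + 1L]] <-
            subtractProtected(exp, critical_oars, comp, min_margin_mm)
    }
    maskUnionAll(picks, name = "ctv1n", grid = grid)
}
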