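#' Pipeline configuration
#'
#' All tunable parameters of the CTV construction pipeline with their
#' protocol defaults. Margins are physical mm. Override any element via
#' arguments, or load a YAML file with \code{loadCtvConfig}.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A named list of parameters:
#' \describe{
#'   \item{ctv1p_margin_mm, ctv1n_margin_mm, ctv2_margin_mm}{3 mm gross
#'     tumor expansions of the high-dose and CTV2 volumes.}
#'   \item{ctv3p_expansion_mm}{5 mm expansion of CTV1p feeding CTV3p
#'     (3 + 5 = the protocol's 8 mm total primary margin).}
#'   \item{ctv3n_margin_mm}{5 mm gross-node margin united into CTV3n at
#'     assembly, the intermediate-dose nodal margin.}
#'   \item{min_margin_ctv1_mm, min_margin_ctv3_mm}{protected floor
#'     margins near critical organs at risk: 0 mm for the high-dose
#'     volumes (and CTV2), 1 mm for the intermediate/low tiers.}
#'   \item{chaikin_iterations}{corner-cutting passes on landmark
#'     polygons (default 3).}
#'   \item{alpha_per_mm, max_gap_mm}{island-joining alpha shape
#'     parameters (defaults 0.2 /mm and 15 mm).}
#'   \item{refine, open_mm, close_mm, min_hole_voxels,
#'     min_island_voxels}{morphological refinement switch and
#'     parameters.}
#'   \item{join_islands}{apply alpha-shape island joining to CTV3.}
#'   \item{bilateral_fraction}{per-side voxel fraction that makes a GTV
#'     bilateral (default 0.05).}
#'   \item{small_node_cm}{nodal size criterion (default 2 cm).}
#'   \item{critical_oars}{structures whose proximity caps the high-dose
#'     margins.}
#'   \item{subtract_structures}{normal structures removed from the final
#'     CTVs.}
#'   \item{required_structures}{structures whose absence aborts
#'     \code{\link{runPipeline}}.}
#'   \item{landmark_rules_path, landmark_rules}{override the shipped
#'     landmark rule table (path, or pre-parsed list).}
#'   \item{include_ib_t12n0, cavernous_sinus_coverage,
#'     skull_base_foramina_coverage, posterior_ethmoid_coverage}{config
#'     hooks for protocol rows without an algorithmic definition; all
#'     ship disabled.}
#' }
#' @export
ctvConfig <- function(...) {
    cfg <- list(
        ctv1p_margin_mm = 3,
        ctv1n_margin_mm = 3,
        ctv2_margin_mm = 3,
        ctv3p_expansion_mm = 5,
        ctv3n_margin_mm = 5,
        min_margin_ctv1_mm = 0,
        min_margin_ctv3_mm = 1,
        chaikin_iterations = 3L,
        alpha_per_mm = 0.2,
        max_gap_mm = 15,
        refine = TRUE,
        open_mm = 1,
        close_mm = 2.5,
        min_hole_voxels = 100L,
        min_island_voxels = 50L,
        join_islands = TRUE,
        bilateral_fraction = 0.05,
        small_node_cm = 2.0,
        critical_oars = c("brainstem", "spinal_cord", "optic_chiasm",
                          "optic_nerve_L", "optic_nerve_R"),
        subtract_structures = c("brain", "spinal_cord", "optic_nerve_L",
                                "optic_nerve_R", "optic_chiasm", "orbit_L",
                                "orbit_R", "vertebral_column",
                                "c1_vertebral_body", "c2_vertebral_body",
                                "hyoid", "cricoid", "mandible"),
        required_structures = c("nasopharynx", "sphenoid_sinus",
                                nodalLevelNames(levels = c("Ib", "II", "III",
                                                           "IV", "Va", "Vb"))),
        landmark_rules_path = NULL,
        landmark_rules = NULL,
        include_ib_t12n0 = FALSE,
        cavernous_sinus_coverage = FALSE,
        skull_base_foramina_coverage = FALSE,
        posterior_ethmoid_coverage = FALSE
    )
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    cfg[names(dots)] <- dots
    cfg
}

#' @rdname ctvConfig
#' @param path YAML file whose top-level keys override the defaults.
#' @export
loadCtvConfig <- function(path) {
    overrides <- yaml::read_yaml(path)
    do.call(ctvConfig, overrides)
}
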