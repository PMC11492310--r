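## Canonical structure-name registry.
##
## Shipped as inst/extdata/structure_registry.yaml so downstream rules and
## user data files agree on one vocabulary. Aliasing is case-insensitive;
## laterality may be written as a prefix or suffix ("Lt_Orbit",
## "orbit_left", "ORBIT_L" all resolve to "orbit_L").

.registry_env <- new.env(parent = emptyenv())

loadRegistry <- function() {
    if (!is.null(.registry_env$reg)) return(.registry_env$reg)
    path <- system.file("extdata", "structure_registry.yaml",
                        package = "npCTV", mustWork = TRUE)
    raw <- yaml::read_yaml(path)
    canonical <- vapply(raw$structures, `[[`, character(1), "name")
    # alias -> canonical map, all keys normalized
    amap <- new.env(parent = emptyenv())
    put <- function(key, val) assign(.normName(key), val, envir = amap)
    for (s in raw$structures) {
        put(s$name, s$name)
        base <- sub("_[LR]$", "", s$name)
        for (al in s$aliases %||% character()) {
            if (grepl("_[LR]$", s$name)) {
                # alias applies to both sides of the pair
                for (side in c("L", "R"))
                    if (paste0(base, "_", side) %in% canonical)
                        put(paste0(al, "_", side), paste0(base, "_", side))
            } else put(al, s$name)
        }
    }
    # base names of lateral pairs ("orbit" alone is ambiguous; keep the
    # base -> "<base>_%s" template for lateral-word resolution
    lateral <- lapply(raw$lateral_aliases, unlist)
    reg <- list(canonical = canonical, amap = amap, lateral = lateral)
    .registry_env$reg <- reg
    reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.normName <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))

#' Canonical structure names
#'
#' The canonical vocabulary of structure names used by the CTV rules:
#' anatomical structures, organs at risk, and nodal levels (suffix
#' \code{_L}/\code{_R} for laterality, \code{LN_<level>} for lymph node
#' levels).
#'
#' @return Character vector of canonical names.
#' @examples
#' head(canonicalStructureNames())
#' canonicalizeStructureName("Lt Orbit")
#' @export
canonicalStructureNames <- function() loadRegistry()$canonical

#' @rdname canonicalStructureNames
#' @param x character vector of structure names as found in file names or
#'   external data.
#' @param custom allow names outside the registry (returned normalized,
#'   with a warning) instead of erroring.
#' @export
canonicalizeStructureName <- function(x, custom = FALSE) {
    reg <- loadRegistry()
    vapply(x, function(one) {
        key <- .normName(one)
        hit <- mget(key, envir = reg$amap, ifnotfound = list(NULL))[[1L]]
        if (!is.null(hit)) return(hit)
        # try moving a lateral word from prefix/suffix onto the base name
        toks <- strsplit(key, "_", fixed = TRUE)[[1L]]
        for (side in c("L", "R")) {
            words <- reg$lateral[[side]]
            if (length(toks) >= 2L && toks[1L] %in% words) {
                cand <- paste0(paste(toks[-1L], collapse = "_"), "_", side)
                hit <- mget(.normName(cand), envir = reg$amap,
                            ifnotfound = list(NULL))[[1L]]
                if (!is.null(hit)) return(hit)
            }
            if (length(toks) >= 2L && toks[length(toks)] %in% words) {
                cand <- paste0(paste(toks[-length(toks)], collapse = "_"),
                               "_", side)
                hit <- mget(.normName(cand), envir = reg$amap,
                            ifnotfound = list(NULL))[[1L]]
                if (!is.null(hit)) return(hit)
            }
        }
        if (custom) {
            warning("structure name '", one,
                    "' is not in the canonical registry; kept as custom name",
                    call. = FALSE)
            return(key)
        }
        stop("unknown structure name '", one,
             "' (use custom = TRUE to keep it)", call. = FALSE)
    }, character(1), USE.NAMES = FALSE)
}

#' @rdname canonicalStructureNames
#' @details \code{nodalLevelNames} returns the canonical lymph node level
#'   mask names, optionally restricted to one side.
#' @param side "L", "R" or "both".
#' @param levels which levels (default all of Ib, II, III, IV, Va, Vb, RP).
#' @export
nodalLevelNames <- function(side = c("both", "L", "R"),
                            levels = c("Ib", "II", "III", "IV", "Va", "Vb",
                                       "RP")) {
    side <- match.arg(side)
    sides <- if (side == "both") c("L", "R") else side
    as.vector(t(outer(paste0("LN_", levels), sides, paste, sep = "_")))
}

#' @rdname canonicalStructureNames
#' @export
structureSide <- function(x) {
    ifelse(grepl("_L$", x), "L", ifelse(grepl("_R$", x), "R", "none"))
}
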