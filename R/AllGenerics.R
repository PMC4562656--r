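## Generics for accessors and polymorphic operations.

#' @rdname accessors
#' @param object an OCTrepeat S4 object
#' @export
setGeneric("protocolName", function(object) standardGeneric("protocolName"))

#' @rdname accessors
#' @export
setGeneric("scanDevice", function(object) standardGeneric("scanDevice"))

#' @rdname accessors
#' @export
setGeneric("layerIds", function(object) standardGeneric("layerIds"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("maskProvenance",
           function(object) standardGeneric("maskProvenance"))

#' @rdname accessors
#' @export
setGeneric("thicknessValues",
           function(object) standardGeneric("thicknessValues"))

#' Extract one B-scan profile from a map or volume
#'
#' Selects a single B-scan either by index or as the B-scan nearest to a
#' physical offset (mm) from the fovea along the B-scan stacking axis.
#' When an offset falls exactly midway between two B-scans the lower index
#' wins; out-of-range indices and offsets outside the scan extent are
#' errors, not wraparounds.
#'
#' @param x a \code{\link{ThicknessMap-class}} or
#'   \code{\link{LayerMaps-class}} object
#' @param index 1-based B-scan index
#' @param offsetMm offset in mm from the fovea along the stacking axis
#'   (used when \code{index} is missing)
#' @param ... further arguments (e.g. \code{layer} for LayerMaps)
#' @return list with \code{index}, \code{values} and \code{alongMm}, the
#'   coordinate of each A-scan along the B-scan.
#' @export
setGeneric("extractBScan",
           function(x, index = NULL, offsetMm = NULL, ...)
             standardGeneric("extractBScan"))

#' Evaluate a thickness estimate on segmented data
#'
#' Computes the unweighted mean of a layer's thickness map over the
#' estimate's region mask intersected with its B-scan selection, excluding
#' missing cells.
#'
#' @param defn an \code{\link{EstimateDefinition-class}}
#' @param x a \code{\link{SegmentedVolume-class}} or
#'   \code{\link{LayerMaps-class}}
#' @param layer layer id, one of \code{defn@layers}
#' @param ... further arguments (e.g. \code{foveaMm},
#'   \code{missingFlagThreshold})
#' @return list with \code{value} (micrometres), \code{nCellsUsed},
#'   \code{nCellsMask} and \code{flagged} (TRUE when the missing fraction
#'   inside the mask exceeds the threshold).
#' @export
setGeneric("applyEstimate",
           function(defn, x, layer, ...) standardGeneric("applyEstimate"))
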