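#' @import methods
NULL

## Canonical layer and boundary vocabulary -------------------------------

#' Retinal layer identifiers
#'
#' The seven macular layers handled by the package, in conventional
#' inner-to-outer report order: macular retinal nerve fiber layer (RNFL),
#' ganglion cell layer (GCL), inner plexiform layer (IPL), the combined
#' ganglion cell + inner plexiform layer (GCIP), inner nuclear layer (INL),
#' outer plexiform layer (OPL) and outer nuclear layer (ONL).
#'
#' @return Character vector of layer ids.
#' @export
#' @examples
#' retinalLayers()
retinalLayers <- function() {
  c("RNFL", "GCL", "IPL", "GCIP", "INL", "OPL", "ONL")
}

#' Segmentation boundary surfaces, ordered inner to outer
#'
#' Boundary names delimiting the macular layers, from the inner limiting
#' membrane (ILM) down to the outer ONL boundary. A layer's thickness is the
#' axial distance between two consecutive boundaries; the composite GCIP
#' spans RNFL/GCL to IPL/INL.
#'
#' @return Character vector of boundary names.
#' @export
boundaryNames <- function() {
  c("ILM", "RNFL_GCL", "GCL_IPL", "IPL_INL", "INL_OPL", "OPL_ONL",
    "ONL_outer")
}

## (inner, outer) boundary pair per layer; GCIP spans two layers
.layerBounds <- list(
  RNFL = c("ILM", "RNFL_GCL"),
  GCL  = c("RNFL_GCL", "GCL_IPL"),
  IPL  = c("GCL_IPL", "IPL_INL"),
  GCIP = c("RNFL_GCL", "IPL_INL"),
  INL  = c("IPL_INL", "INL_OPL"),
  OPL  = c("INL_OPL", "OPL_ONL"),
  ONL  = c("OPL_ONL", "ONL_outer")
)

## ScanProtocol -----------------------------------------------------------

#' ScanProtocol: geometry of one OCT volume acquisition
#'
#' Describes a macular volume scan as the concatenation of scan direction,
#' the number of B-scans and the number of A-scans per B-scan (the name
#' pattern \code{direction-nB-nA}, e.g. \code{"V-25-1024"}), plus the
#' physical extent of the scanned area, the axial sampling and the device.
#'
#' @slot name character, \code{direction-nB-nA} pattern; round-trips through
#'   \code{\link{parseProtocolName}} / \code{\link{formatProtocolName}}.
#' @slot direction \code{"horizontal"} or \code{"vertical"} B-scan
#'   orientation.
#' @slot nBScans,nAScans integer counts (\code{nBScans >= 1},
#'   \code{nAScans >= 2}).
#' @slot widthMm,heightMm scan-area extent in mm (x respectively y).
#' @slot axialScaleUmPerPx axial sampling in micrometres per pixel.
#' @slot artFrames Spectralis automatic-real-time averaging frames
#'   (\code{NA} where not applicable).
#' @slot device \code{"spectralis"} or \code{"cirrus"}.
#'
#' @seealso \code{\link{ScanProtocol}} constructor,
#'   \code{\link{builtinProtocols}}
#' @export
setClass("ScanProtocol",
  representation(
    name = "character",
    direction = "character",
    nBScans = "integer",
    nAScans = "integer",
    widthMm = "numeric",
    heightMm = "numeric",
    axialScaleUmPerPx = "numeric",
    artFrames = "integer",
    device = "character"
  ),
  prototype(artFrames = NA_integer_, axialScaleUmPerPx = 3.87)
)

setValidity("ScanProtocol", function(object) {
  msg <- character()
  if (!object@direction %in% c("horizontal", "vertical"))
    msg <- c(msg, "direction must be 'horizontal' or 'vertical'")
  if (is.na(object@nBScans) || object@nBScans < 1L)
    msg <- c(msg, "nBScans must be >= 1")
  if (is.na(object@nAScans) || object@nAScans < 2L)
    msg <- c(msg, "nAScans must be >= 2")
  if (!isTRUE(object@widthMm > 0) || !isTRUE(object@heightMm > 0))
    msg <- c(msg, "scan-area extents must be > 0")
  if (!isTRUE(object@axialScaleUmPerPx > 0))
    msg <- c(msg, "axialScaleUmPerPx must be > 0")
  if (!object@device %in% c("spectralis", "cirrus"))
    msg <- c(msg, "device must be 'spectralis' or 'cirrus'")
  expect <- paste0(toupper(substr(object@direction, 1L, 1L)), "-",
                   object@nBScans, "-", object@nAScans)
  if (length(msg) == 0L && !identical(object@name, expect))
    msg <- c(msg, sprintf("name '%s' does not match geometry (expected '%s')",
                          object@name, expect))
  if (length(msg)) msg else TRUE
})

## SegmentedVolume ---------------------------------------------------------

#' SegmentedVolume: exported boundary surfaces for one eye and session
#'
#' Per-boundary axial positions (pixels from the image top, increasing with
#' depth) on the protocol's B-scan-by-A-scan grid. Boundaries may be a
#' subset of \code{\link{boundaryNames}} (Cirrus exports carry only ILM,
#' RNFL/GCL and IPL/INL); missing positions are \code{NA}. Boundary order
#' inner-to-outer is enforced wherever all values are present.
#'
#' @slot protocol a \code{\link{ScanProtocol-class}} object.
#' @slot boundaries named list of numeric matrices (nBScans x nAScans),
#'   names from \code{\link{boundaryNames}}.
#' @slot meta list of acquisition tags (subjectId, eye, group, session).
#' @export
setClass("SegmentedVolume",
  representation(
    protocol = "ScanProtocol",
    boundaries = "list",
    meta = "list"
  ),
  prototype(meta = list())
)

setValidity("SegmentedVolume", function(object) {
  p <- object@protocol
  nms <- names(object@boundaries)
  if (is.null(nms) || !all(nms %in% boundaryNames()))
    return("boundaries must be named with known boundary names")
  if (anyDuplicated(nms))
    return("duplicate boundary surface")
  for (nm in nms) {
    b <- object@boundaries[[nm]]
    if (!is.matrix(b) || !identical(dim(b), c(p@nBScans, p@nAScans)))
      return(sprintf("boundary '%s' must be a %d x %d matrix",
                     nm, p@nBScans, p@nAScans))
  }
  ## inner-to-outer ordering at every A-scan where both neighbours exist
  ord <- intersect(boundaryNames(), nms)
  for (i in seq_len(length(ord) - 1L)) {
    a <- object@boundaries[[ord[i]]]
    b <- object@boundaries[[ord[i + 1L]]]
    bad <- which(!is.na(a) & !is.na(b) & b < a, arr.ind = TRUE)
    if (nrow(bad)) {
      return(sprintf(
        "inverted boundaries %s/%s at B-scan %d, A-scan %d",
        ord[i], ord[i + 1L], bad[1L, 1L], bad[1L, 2L]))
    }
  }
  TRUE
})

## ThicknessMap ------------------------------------------------------------

#' ThicknessMap: per-layer thickness on a fovea-centred physical grid
#'
#' Thickness values in micrometres for one retinal layer, on the protocol's
#' B-scan grid, together with x/y coordinates in millimetres whose origin is
#' the fovea centre (x horizontal, y vertical).
#'
#' @slot layer one of \code{\link{retinalLayers}}.
#' @slot values numeric matrix, micrometres, \code{NA} where segmentation is
#'   missing; all non-missing values are \code{>= 0}.
#' @slot x,y coordinate matrices in mm, same dimension as \code{values}.
#' @export
setClass("ThicknessMap",
  representation(
    layer = "character",
    values = "matrix",
    x = "matrix",
    y = "matrix"
  )
)

setValidity("ThicknessMap", function(object) {
  if (!object@layer %in% retinalLayers())
    return(sprintf("unknown layer '%s'", object@layer))
  d <- dim(object@values)
  if (!identical(dim(object@x), d) || !identical(dim(object@y), d))
    return("coordinate grids must match the value grid")
  v <- object@values
  if (any(v[!is.na(v)] < 0))
    return("thickness values must be >= 0")
  TRUE
})

## RegionMask --------------------------------------------------------------

#' RegionMask: boolean region of interest on a thickness-map grid
#'
#' A logical inclusion grid aligned with a \code{\link{ThicknessMap-class}}
#' grid, carrying its provenance (the rule and parameters that produced it)
#' so that identical grids and parameters always reproduce the identical
#' mask.
#'
#' @slot mask logical matrix.
#' @slot provenance list with element \code{type} (one of \code{"circle"},
#'   \code{"elliptical_annulus"}, \code{"full_area"}, \code{"bscan_line"},
#'   \code{"point_set"}) plus the rule's parameters.
#' @export
setClass("RegionMask",
  representation(mask = "matrix", provenance = "list")
)

setValidity("RegionMask", function(object) {
  if (!is.logical(object@mask))
    return("mask must be a logical matrix")
  if (is.null(object@provenance$type))
    return("provenance must name its type")
  TRUE
})

## LayerMaps ---------------------------------------------------------------

#' LayerMaps: all layer thickness grids for one eye, session and protocol
#'
#' Container used by the simulator and the estimate engine: thickness values
#' (micrometres) for each available layer on one protocol grid, plus the
#' fovea position and acquisition tags. Thickness maps for individual layers
#' are obtained with \code{\link{getLayerMap}}.
#'
#' @slot protocol a \code{\link{ScanProtocol-class}}.
#' @slot maps named list of numeric matrices, one per layer id.
#' @slot foveaMm numeric length-2, fovea offset from the scan-area centre
#'   (mm).
#' @slot meta list of acquisition tags (subjectId, eye, group, session).
#' @export
setClass("LayerMaps",
  representation(
    protocol = "ScanProtocol",
    maps = "list",
    foveaMm = "numeric",
    meta = "list"
  ),
  prototype(foveaMm = c(0, 0), meta = list())
)

setValidity("LayerMaps", function(object) {
  p <- object@protocol
  nms <- names(object@maps)
  if (is.null(nms) || !all(nms %in% retinalLayers()))
    return("maps must be named with known layer ids")
  for (nm in nms) {
    m <- object@maps[[nm]]
    if (!is.matrix(m) || !identical(dim(m), c(p@nBScans, p@nAScans)))
      return(sprintf("map '%s' must be a %d x %d matrix",
                     nm, p@nBScans, p@nAScans))
    if (any(m[!is.na(m)] < 0))
      return(sprintf("map '%s' has negative thickness", nm))
  }
  if (length(object@foveaMm) != 2L)
    return("foveaMm must have length 2")
  TRUE
})

## EstimateDefinition ------------------------------------------------------

#' EstimateDefinition: a declarative recipe for one thickness estimate
#'
#' A thickness estimate is a rule mapping a segmented volume to a single
#' mean layer thickness: the scan protocol it expects, a B-scan selector,
#' a spatial region mask and the set of layers it applies to. The twelve
#' published estimates A-L ship in \code{\link{builtinEstimates}}.
#'
#' @slot id single letter "A".."L" (unique within a registry).
#' @slot device \code{"spectralis"} or \code{"cirrus"}.
#' @slot protocol the \code{\link{ScanProtocol-class}} the estimate reads.
#' @slot bscanSelector list with \code{type} in \code{"all"},
#'   \code{"subset"} (\code{indices}), \code{"single"} (\code{offsetMm}),
#'   \code{"point_set"} (\code{offsetMm}, \code{pointsMm}).
#' @slot maskSpec list with \code{type} in \code{"circle"}
#'   (\code{diameterMm}), \code{"elliptical_annulus"} (four radii),
#'   \code{"full_area"}.
#' @slot layers character, the layers the estimate may be evaluated on.
#' @export
setClass("EstimateDefinition",
  representation(
    id = "character",
    device = "character",
    protocol = "ScanProtocol",
    bscanSelector = "list",
    maskSpec = "list",
    layers = "character"
  )
)

setValidity("EstimateDefinition", function(object) {
  if (!grepl("^[A-L]$", object@id))
    return("id must be a single letter A..L")
  if (!object@device %in% c("spectralis", "cirrus"))
    return("device must be 'spectralis' or 'cirrus'")
  if (!object@bscanSelector$type %in%
        c("all", "subset", "single", "point_set"))
    return("unknown bscanSelector type")
  if (!object@maskSpec$type %in%
        c("circle", "elliptical_annulus", "full_area"))
    return("unknown maskSpec type")
  if (!all(object@layers %in% retinalLayers()))
    return("unknown layer in layers")
  TRUE
})

## CohortConfig ------------------------------------------------------------

#' CohortConfig: parameters of the synthetic repeated-measurement cohort
#'
#' Defines the study design (healthy-control cohorts with three sessions,
#' a patient cohort with two sessions, both eyes of every subject included)
#' and the noise model with known variance components. All standard
#' deviations are in micrometres unless noted. See the methods vignette for
#' how each default was chosen.
#'
#' @slot nHcSubjects healthy controls per device cohort (default 15).
#' @slot nMsSubjects patients measured on both devices (default 13).
#' @slot sessionsHc,sessionsMs sessions per eye (defaults 3 and 2).
#' @slot eyesPerSubject eyes included per subject (default 2).
#' @slot protocols list of \code{\link{ScanProtocol-class}} to simulate.
#' @slot sigmaBetween named numeric, between-eye SD per base layer.
#' @slot sigmaOffset session-level global offset SD per layer.
#' @slot sigmaField SD of the spatially correlated session field.
#' @slot fieldCorrLengthMm correlation length of that field, mm.
#' @slot jitterSdMm SD of the scan-window translation between sessions, mm.
#' @slot hflAmplitude amplitude A (micrometres) of the beam-angle OPL/ONL
#'   boundary-shift artifact; 0 disables it.
#' @slot hflThetaRange beam-offset \code{theta} is drawn uniformly on
#'   \code{[-hflThetaRange, hflThetaRange]} per session.
#' @slot msInnerScale multiplicative thinning of GCL/IPL (and hence GCIP)
#'   templates in the patient group.
#' @slot seed integer; fixes the complete cohort.
#' @export
setClass("CohortConfig",
  representation(
    nHcSubjects = "integer",
    nMsSubjects = "integer",
    sessionsHc = "integer",
    sessionsMs = "integer",
    eyesPerSubject = "integer",
    protocols = "list",
    sigmaBetween = "numeric",
    sigmaOffset = "numeric",
    sigmaField = "numeric",
    fieldCorrLengthMm = "numeric",
    jitterSdMm = "numeric",
    hflAmplitude = "numeric",
    hflThetaRange = "numeric",
    msInnerScale = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@sessionsHc < 2L || object@sessionsMs < 2L)
    msg <- c(msg, "at least 2 sessions per cohort are required")
  sds <- c(object@sigmaBetween, object@sigmaOffset, object@sigmaField,
           object@jitterSdMm, object@hflAmplitude)
  if (any(sds < 0)) msg <- c(msg, "all SDs and amplitudes must be >= 0")
  if (object@fieldCorrLengthMm <= 0)
    msg <- c(msg, "fieldCorrLengthMm must be > 0")
  if (!all(names(object@sigmaBetween) %in% retinalLayers()))
    msg <- c(msg, "sigmaBetween must be named by layer")
  if (length(msg)) msg else TRUE
})

## Statistic result containers --------------------------------------------

#' VarianceComponents: one-way ANOVA mean squares for repeated measures
#'
#' Between-unit and within-unit mean squares from a one-way ANOVA with the
#' eye as the unit of measurement, plus the effective number of sessions
#' per unit (the group size k for balanced designs; the unbalanced-design
#' k0 otherwise).
#'
#' @slot nUnits number of eyes retained.
#' @slot groupSizes integer, sessions per retained eye.
#' @slot MSB,MSW between- and within-unit mean squares.
#' @slot kEff effective sessions per unit.
#' @export
setClass("VarianceComponents",
  representation(
    nUnits = "integer",
    groupSizes = "integer",
    MSB = "numeric",
    MSW = "numeric",
    kEff = "numeric"
  )
)

setValidity("VarianceComponents", function(object) {
  if (object@MSB < 0 || object@MSW < 0)
    return("mean squares must be >= 0")
  if (!(object@kEff > 1) || object@kEff > max(object@groupSizes))
    return("kEff must lie in (1, max group size]")
  TRUE
})

#' ICCResult: single-measures intraclass correlation with 95 percent CI
#'
#' @slot icc point estimate (negative estimates are reported, not
#'   truncated).
#' @slot ciLow,ciHigh exact F-based confidence bounds.
#' @slot classification \code{"excellent"} (ICC above 0.9),
#'   \code{"moderate"} (between 0.8 and 0.9) or \code{"insufficient"}
#'   (below 0.8).
#' @export
setClass("ICCResult",
  representation(
    icc = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    classification = "character"
  )
)

setValidity("ICCResult", function(object) {
  if (!(object@ciLow <= object@icc + 1e-12 &&
        object@icc <= object@ciHigh + 1e-12))
    return("confidence bounds must bracket the point estimate")
  if (!identical(object@classification, classifyICC(object@icc)))
    return("classification inconsistent with thresholds")
  TRUE
})

#' CRResult: coefficient of repeatability
#'
#' The coefficient of repeatability CR = 2.77 x within-subject SD is the
#' 95 percent bound on the absolute difference between two repeated
#' measurements of the same eye.
#'
#' @slot cr coefficient of repeatability, micrometres.
#' @slot sw within-subject standard deviation, micrometres.
#' @export
setClass("CRResult",
  representation(cr = "numeric", sw = "numeric")
)

setValidity("CRResult", function(object) {
  if (object@sw < 0) return("sw must be >= 0")
  if (abs(object@cr - 2.77 * object@sw) > 1e-12)
    return("cr must equal 2.77 * sw")
  TRUE
})

#' BlandAltmanResult: pairwise difference-versus-mean analysis
#'
#' For each eye every unordered session pair contributes one point (mean of
#' the pair, difference of the pair); the bias and the 1.96 SD limits of
#' agreement summarise the point cloud.
#'
#' @slot points data.frame with columns \code{unit}, \code{mean},
#'   \code{diff}.
#' @slot bias mean difference.
#' @slot sdDiff SD of the differences.
#' @slot loaLow,loaHigh limits of agreement, bias -/+ 1.96 sdDiff.
#' @export
setClass("BlandAltmanResult",
  representation(
    points = "data.frame",
    bias = "numeric",
    sdDiff = "numeric",
    loaLow = "numeric",
    loaHigh = "numeric"
  )
)

setValidity("BlandAltmanResult", function(object) {
  if (abs((object@loaHigh - object@loaLow) - 2 * 1.96 * object@sdDiff) >
      1e-9)
    return("limits of agreement must span 2 x 1.96 x sdDiff")
  TRUE
})

## show methods ------------------------------------------------------------

setMethod("show", "ScanProtocol", function(object) {
  cat(sprintf("ScanProtocol %s (%s): %d B-scans x %d A-scans, %.1f x %.1f mm, %.2f um/px%s\n",
              object@name, object@device, object@nBScans, object@nAScans,
              object@widthMm, object@heightMm, object@axialScaleUmPerPx,
              if (is.na(object@artFrames)) ""
              else sprintf(", ART %d", object@artFrames)))
})

setMethod("show", "SegmentedVolume", function(object) {
  cat(sprintf("SegmentedVolume on %s with %d boundary surfaces (%s)\n",
              object@protocol@name, length(object@boundaries),
              paste(names(object@boundaries), collapse = ", ")))
})

setMethod("show", "ThicknessMap", function(object) {
  v <- object@values
  cat(sprintf("ThicknessMap %s: %d x %d grid, %.1f-%.1f um (%d missing)\n",
              object@layer, nrow(v), ncol(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask (%s): %d of %d cells included\n",
              object@provenance$type, sum(object@mask),
              length(object@mask)))
})

setMethod("show", "LayerMaps", function(object) {
  cat(sprintf("LayerMaps on %s: layers %s\n", object@protocol@name,
              paste(names(object@maps), collapse = ", ")))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(object@meta),
                         sep = "=", collapse = " "), "\n")
})

setMethod("show", "EstimateDefinition", function(object) {
  cat(sprintf("Estimate %s (%s, %s): B-scans '%s', mask '%s', layers %s\n",
              object@id, object@device, object@protocol@name,
              object@bscanSelector$type, object@maskSpec$type,
              paste(object@layers, collapse = "/")))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("One-way ANOVA: %d units, MSB = %.4g, MSW = %.4g, k_eff = %.4g\n",
              object@nUnits, object@MSB, object@MSW, object@kEff))
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC(1,1) = %.4f [%.4f, %.4f] (%s)\n", object@icc,
              object@ciLow, object@ciHigh, object@classification))
})

setMethod("show", "CRResult", function(object) {
  cat(sprintf("CR = %.4f um (within-subject SD %.4f um)\n",
              object@cr, object@sw))
})

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf("Bland-Altman: %d pairs, bias %.4f, LoA [%.4f, %.4f]\n",
              nrow(object@points), object@bias, object@loaLow,
              object@loaHigh))
})
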