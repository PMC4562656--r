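#' Construct a scan protocol
#'
#' @param direction \code{"horizontal"} or \code{"vertical"} B-scan
#'   orientation. Horizontal B-scans run along x and are stacked along y;
#'   vertical B-scans run along y and are stacked along x.
#' @param nBScans,nAScans number of B-scans and A-scans per B-scan.
#' @param widthMm,heightMm physical extent of the scanned area (x, y), mm.
#' @param axialScaleUmPerPx axial sampling, micrometres per pixel
#'   (default 3.87, the Spectralis value).
#' @param artFrames Spectralis real-time averaging frames, or \code{NA}.
#' @param device \code{"spectralis"} or \code{"cirrus"}.
#' @param name protocol name; derived from the geometry when omitted.
#'
#' @return a \code{\link{ScanProtocol-class}} object
#' @export
#' @examples
#' ScanProtocol("vertical", 25, 1024, 6, 6, artFrames = 49)
ScanProtocol <- function(direction, nBScans, nAScans, widthMm, heightMm,
                         axialScaleUmPerPx = 3.87, artFrames = NA,
                         device = "spectralis", name = NULL) {
  if (is.null(name))
    name <- paste0(toupper(substr(direction, 1L, 1L)), "-",
                   as.integer(nBScans), "-", as.integer(nAScans))
  new("ScanProtocol", name = name, direction = direction,
      nBScans = as.integer(nBScans), nAScans = as.integer(nAScans),
      widthMm = as.numeric(widthMm), heightMm = as.numeric(heightMm),
      axialScaleUmPerPx = as.numeric(axialScaleUmPerPx),
      artFrames = as.integer(artFrames), device = device)
}

#' Parse and format protocol names
#'
#' Protocol names concatenate the scan direction, the number of B-scans and
#' the number of A-scans per B-scan, e.g. \code{"V-25-1024"} for a vertical
#' volume of 25 B-scans with 1024 A-scans each. \code{parseProtocolName}
#' inverts \code{formatProtocolName}; a protocol name always round-trips.
#'
#' @param name protocol name string
#' @return \code{parseProtocolName}: list with \code{direction},
#'   \code{nBScans}, \code{nAScans}. \code{formatProtocolName}: the name
#'   string.
#' @export
#' @examples
#' parseProtocolName("V-25-1024")
parseProtocolName <- function(name) {
  m <- regmatches(name, regexec("^([HV])-([0-9]+)-([0-9]+)$", name))[[1L]]
  if (length(m) != 4L)
    stop("malformed protocol name '", name,
         "' (expected direction-nB-nA, e.g. 'V-25-1024')")
  list(direction = if (m[2L] == "H") "horizontal" else "vertical",
       nBScans = as.integer(m[3L]), nAScans = as.integer(m[4L]))
}

#' @rdname parseProtocolName
#' @param protocol a \code{\link{ScanProtocol-class}} object
#' @export
formatProtocolName <- function(protocol) {
  paste0(toupper(substr(protocol@direction, 1L, 1L)), "-",
         protocol@nBScans, "-", protocol@nAScans)
}

#' Built-in scan protocol registry
#'
#' The five Spectralis macular volume designs and the two standard Cirrus
#' macular cubes used by the estimate registry. Only the vertical
#' 25 x 1024 design is fixed by name; the remaining Spectralis settings and
#' the exact Cirrus presets (512 x 128 and 200 x 200 A- x B-scans over
#' 6 x 6 mm) are configurable defaults of this registry, not device facts.
#'
#' @param maxAScans,maxBScans optional caps on the sampling density; when
#'   given, each protocol is thinned to at most this many A-/B-scans (the
#'   physical extent is unchanged and the name tracks the new counts).
#'   Used to keep simulation studies cheap; \code{NULL} keeps native
#'   resolution.
#' @return named list of \code{\link{ScanProtocol-class}} objects with
#'   semantic keys (\code{spectralis_a} .. \code{spectralis_e},
#'   \code{cirrus_512x128}, \code{cirrus_200x200}).
#' @export
#' @examples
#' names(builtinProtocols())
#' builtinProtocols(maxAScans = 96)$spectralis_a
builtinProtocols <- function(maxAScans = NULL, maxBScans = NULL) {
  ps <- list(
    spectralis_a = ScanProtocol("vertical", 25, 1024, 6, 6,
                                artFrames = 49),
    spectralis_b = ScanProtocol("horizontal", 61, 768, 6, 6,
                                artFrames = 12),
    spectralis_c = ScanProtocol("horizontal", 25, 512, 6, 6,
                                artFrames = 49),
    spectralis_d = ScanProtocol("horizontal", 19, 512, 6, 6,
                                artFrames = 16),
    spectralis_e = ScanProtocol("horizontal", 25, 1536, 9, 6,
                                artFrames = 9),
    cirrus_512x128 = ScanProtocol("horizontal", 128, 512, 6, 6,
                                  axialScaleUmPerPx = 1.96,
                                  device = "cirrus"),
    cirrus_200x200 = ScanProtocol("horizontal", 200, 200, 6, 6,
                                  axialScaleUmPerPx = 1.96,
                                  device = "cirrus")
  )
  if (is.null(maxAScans) && is.null(maxBScans)) return(ps)
  lapply(ps, function(p) {
    nA <- if (is.null(maxAScans)) p@nAScans else min(p@nAScans,
                                                     as.integer(maxAScans))
    nB <- if (is.null(maxBScans)) p@nBScans else min(p@nBScans,
                                                     as.integer(maxBScans))
    ScanProtocol(p@direction, nB, nA, p@widthMm, p@heightMm,
                 p@axialScaleUmPerPx, p@artFrames, p@device)
  })
}

#' @rdname accessors
#' @export
setMethod("protocolName", "ScanProtocol", function(object) object@name)

#' @rdname accessors
#' @export
setMethod("scanDevice", "ScanProtocol", function(object) object@device)

#' @rdname accessors
#' @export
setMethod("scanDevice", "EstimateDefinition",
          function(object) object@device)

#' @rdname accessors
#' @export
setMethod("protocolName", "EstimateDefinition",
          function(object) object@protocol@name)

#' @rdname accessors
#' @export
setMethod("layerIds", "LayerMaps", function(object) names(object@maps))

#' @rdname accessors
#' @export
setMethod("layerIds", "EstimateDefinition", function(object) object@layers)

#' @rdname accessors
#' @export
setMethod("maskMatrix", "RegionMask", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("maskProvenance", "RegionMask",
          function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("thicknessValues", "ThicknessMap", function(object) object@values)
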