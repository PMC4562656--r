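#' Physical coordinates of every A-scan in a protocol grid
#'
#' Computes the (x, y) position in millimetres of every A-scan, with the
#' origin at the fovea centre. B-scans are the rows of the returned
#' matrices: horizontal B-scans run along x and are stacked along y,
#' vertical B-scans run along y and are stacked along x. Grid spacing is
#' uniform, extent/(n - 1) per axis, so a 25-B-scan protocol over 6 mm has
#' a B-scan spacing of 0.25 mm; a single-B-scan protocol sits at the scan
#' centre.
#'
#' @param protocol a \code{\link{ScanProtocol-class}} object
#' @param foveaMm fovea-centre offset from the scan-area centre, mm
#'   (default \code{c(0, 0)}); must lie inside the scan area.
#' @return list with matrices \code{x} and \code{y} (nBScans x nAScans,
#'   mm relative to the fovea), \code{stackMm} (per-B-scan coordinate along
#'   the stacking axis) and \code{alongAxis} (\code{"x"} or \code{"y"}, the
#'   axis a B-scan runs along).
#' @export
#' @examples
#' p <- ScanProtocol("vertical", 25, 64, 6, 6)
#' g <- gridCoordinates(p)
#' diff(g$stackMm)[1]  # 6/24 = 0.25 mm B-scan spacing
gridCoordinates <- function(protocol, foveaMm = c(0, 0)) {
  stopifnot(is(protocol, "ScanProtocol"), length(foveaMm) == 2L)
  w <- protocol@widthMm; h <- protocol@heightMm
  if (abs(foveaMm[1L]) > w / 2 || abs(foveaMm[2L]) > h / 2)
    stop("fovea centre (", foveaMm[1L], ", ", foveaMm[2L],
         ") lies outside the ", w, " x ", h, " mm scan area")
  axisSeq <- function(extent, n) {
    if (n == 1L) 0 else seq(-extent / 2, extent / 2, length.out = n)
  }
  nB <- protocol@nBScans; nA <- protocol@nAScans
  if (protocol@direction == "horizontal") {
    stack <- axisSeq(h, nB) - foveaMm[2L]      # row position along y
    along <- axisSeq(w, nA) - foveaMm[1L]      # within-B-scan x
    x <- matrix(along, nB, nA, byrow = TRUE)
    y <- matrix(stack, nB, nA)
    alongAxis <- "x"
  } else {
    stack <- axisSeq(w, nB) - foveaMm[1L]      # column position along x
    along <- axisSeq(h, nA) - foveaMm[2L]      # within-B-scan y
    x <- matrix(stack, nB, nA)
    y <- matrix(along, nB, nA, byrow = TRUE)
    alongAxis <- "y"
  }
  list(x = x, y = y, stackMm = stack, alongAxis = alongAxis)
}

#' Construct a segmented volume from boundary surfaces
#'
#' @param protocol a \code{\link{ScanProtocol-class}}
#' @param boundaries named list of nBScans x nAScans matrices of axial
#'   positions (pixels from the image top, increasing with depth); names
#'   from \code{\link{boundaryNames}}. Missing positions are \code{NA}.
#' @param meta optional list of acquisition tags
#' @return a \code{\link{SegmentedVolume-class}} object
#' @export
SegmentedVolume <- function(protocol, boundaries, meta = list()) {
  new("SegmentedVolume", protocol = protocol, boundaries = boundaries,
      meta = meta)
}

#' Layer thickness map from segmentation surfaces
#'
#' Thickness at every A-scan is the axial distance between the layer's
#' outer and inner boundary, converted to micrometres with the protocol's
#' axial scale; it is missing wherever either boundary is missing. The
#' composite GCIP spans the RNFL/GCL boundary to the IPL/INL boundary, so
#' its map equals the elementwise sum of the GCL and IPL maps wherever
#' those exist.
#'
#' @param volume a \code{\link{SegmentedVolume-class}}
#' @param layer one of \code{\link{retinalLayers}}
#' @param foveaMm fovea offset from the scan centre, mm
#' @return a \code{\link{ThicknessMap-class}} in micrometres
#' @export
#' @examples
#' p <- ScanProtocol("vertical", 3, 4, 6, 6)
#' b <- list(ILM = matrix(10, 3, 4), RNFL_GCL = matrix(20, 3, 4))
#' v <- SegmentedVolume(p, b)
#' thicknessValues(thicknessFromSurfaces(v, "RNFL"))[1, 1]  # 10 * 3.87
thicknessFromSurfaces <- function(volume, layer, foveaMm = c(0, 0)) {
  stopifnot(is(volume, "SegmentedVolume"))
  if (!layer %in% retinalLayers())
    stop("unknown layer id '", layer, "'")
  bounds <- .layerBounds[[layer]]
  bn <- names(volume@boundaries)
  ## GCIP is the exact elementwise sum of GCL and IPL whenever the
  ## GCL/IPL boundary is available (identical floating-point result as
  ## summing the two layer maps); the direct outer-minus-inner difference
  ## is used only for exports without the intermediate boundary
  if (layer == "GCIP" && "GCL_IPL" %in% bn &&
      all(bounds %in% bn)) {
    gcl <- thicknessFromSurfaces(volume, "GCL", foveaMm)
    ipl <- thicknessFromSurfaces(volume, "IPL", foveaMm)
    gcl@layer <- "GCIP"
    gcl@values <- gcl@values + ipl@values
    return(gcl)
  }
  if (!all(bounds %in% bn)) {
    stop("volume lacks boundary surface(s) ",
         paste(setdiff(bounds, bn), collapse = ", "),
         " needed for layer ", layer)
  }
  inner <- volume@boundaries[[bounds[1L]]]
  outer <- volume@boundaries[[bounds[2L]]]
  d <- outer - inner
  bad <- which(!is.na(d) & d < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("inverted boundaries for layer %s at B-scan %d, A-scan %d",
                 layer, bad[1L, 1L], bad[1L, 2L]))
  g <- gridCoordinates(volume@protocol, foveaMm)
  new("ThicknessMap", layer = layer,
      values = d * volume@protocol@axialScaleUmPerPx, x = g$x, y = g$y)
}

#' All available layer maps of a segmented volume
#'
#' Converts every layer whose delimiting boundaries are present (plus the
#' composite GCIP when GCL and IPL are available) into a
#' \code{\link{LayerMaps-class}} container.
#'
#' @inheritParams thicknessFromSurfaces
#' @return a \code{\link{LayerMaps-class}}
#' @export
asLayerMaps <- function(volume, foveaMm = c(0, 0)) {
  bn <- names(volume@boundaries)
  have <- vapply(retinalLayers(),
                 function(l) all(.layerBounds[[l]] %in% bn), logical(1L))
  maps <- lapply(retinalLayers()[have], function(l)
    thicknessFromSurfaces(volume, l, foveaMm)@values)
  names(maps) <- retinalLayers()[have]
  new("LayerMaps", protocol = volume@protocol, maps = maps,
      foveaMm = as.numeric(foveaMm), meta = volume@meta)
}

#' Thickness map for one layer of a LayerMaps container
#'
#' GCIP is derived as GCL + IPL when not stored explicitly.
#'
#' @param x a \code{\link{LayerMaps-class}}
#' @param layer layer id
#' @return a \code{\link{ThicknessMap-class}}
#' @export
getLayerMap <- function(x, layer) {
  stopifnot(is(x, "LayerMaps"))
  if (!layer %in% retinalLayers())
    stop("unknown layer id '", layer, "'")
  if (!is.null(x@maps[[layer]])) {
    v <- x@maps[[layer]]
  } else if (layer == "GCIP" &&
             all(c("GCL", "IPL") %in% names(x@maps))) {
    v <- x@maps[["GCL"]] + x@maps[["IPL"]]
  } else {
    stop("layer ", layer, " is not available in this volume")
  }
  g <- gridCoordinates(x@protocol, x@foveaMm)
  new("ThicknessMap", layer = layer, values = v, x = g$x, y = g$y)
}

## shared B-scan selection logic ------------------------------------------

.resolveBScan <- function(stackMm, index, offsetMm) {
  nB <- length(stackMm)
  if (!is.null(index)) {
    index <- as.integer(index)
    if (length(index) != 1L || is.na(index) || index < 1L || index > nB)
      stop("B-scan index ", index, " out of range 1..", nB)
    return(index)
  }
  if (is.null(offsetMm))
    stop("either 'index' or 'offsetMm' must be given")
  step <- if (nB > 1L) abs(stackMm[2L] - stackMm[1L]) else
    max(abs(stackMm), 1)
  if (offsetMm < min(stackMm) - step / 2 ||
      offsetMm > max(stackMm) + step / 2)
    stop("offset ", offsetMm, " mm lies outside the scanned extent")
  d <- abs(stackMm - offsetMm)
  cand <- which(d <= min(d) + 1e-9)
  cand[1L]  # midway ties break toward the lower index
}

#' @rdname extractBScan
#' @export
setMethod("extractBScan", "ThicknessMap",
  function(x, index = NULL, offsetMm = NULL, ...) {
    ## infer the stacking axis: rows with constant y are horizontal B-scans
    horiz <- nrow(x@y) == 1L || all(x@y[, 1L] == x@y[, ncol(x@y)])
    stackMm <- if (horiz) x@y[, 1L] else x@x[, 1L]
    i <- .resolveBScan(stackMm, index, offsetMm)
    list(index = i, values = x@values[i, ],
         alongMm = if (horiz) x@x[i, ] else x@y[i, ])
  })

#' @rdname extractBScan
#' @param layer layer id (LayerMaps method)
#' @export
setMethod("extractBScan", "LayerMaps",
  function(x, index = NULL, offsetMm = NULL, layer, ...) {
    extractBScan(getLayerMap(x, layer), index = index, offsetMm = offsetMm)
  })

#' Stack layer maps into a segmented volume
#'
#' Rebuilds boundary surfaces by accumulating base-layer thicknesses below
#' a flat inner limiting membrane. Inverse of
#' \code{\link{asLayerMaps}} up to the arbitrary ILM position; useful for
#' writing simulator output in the surface-export schema.
#'
#' @param x a \code{\link{LayerMaps-class}} holding all six base layers
#' @param ilmPx axial position of the ILM in pixels (default 40)
#' @return a \code{\link{SegmentedVolume-class}}
#' @export
layerMapsToVolume <- function(x, ilmPx = 40) {
  stopifnot(is(x, "LayerMaps"))
  base <- c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL")
  missing <- setdiff(base, names(x@maps))
  if (length(missing))
    stop("cannot rebuild surfaces without base layer(s): ",
         paste(missing, collapse = ", "))
  p <- x@protocol
  pos <- matrix(as.numeric(ilmPx), p@nBScans, p@nAScans)
  boundaries <- list(ILM = pos)
  outerNames <- vapply(base, function(l) .layerBounds[[l]][2L],
                       character(1L))
  for (i in seq_along(base)) {
    pos <- pos + x@maps[[base[i]]] / p@axialScaleUmPerPx
    boundaries[[outerNames[i]]] <- pos
  }
  SegmentedVolume(p, boundaries, meta = x@meta)
}
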