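## Population-mean macular thickness profiles for the simulator.
##
## Smooth, radially structured analytic maps: the inner layers (GCL, IPL,
## INL) show a foveal depression with a perifoveal ridge, the RNFL thickens
## towards the periphery, and the ONL peaks at the fovea. Values are plain
## plausible magnitudes in micrometres, bounded to [0, 120]; they only have
## to be smooth and layer-typical, not anatomically exact.

.templateParams <- list(
  #       base  amp   r0    sd
  RNFL = c(5,   25,   NA,   NA),     # periphery ramp, handled separately
  GCL  = c(10,  40,   1.2,  0.55),
  IPL  = c(15,  25,   1.1,  0.65),
  INL  = c(12,  25,   1.3,  0.70),
  OPL  = c(20,  15,   1.0,  0.80),
  ONL  = c(35,  45,   0.0,  0.90)    # foveal peak
)

#' Population-mean thickness of a layer at arbitrary positions
#'
#' Evaluates the analytic population template of a layer at (x, y)
#' positions in mm relative to the fovea. The patient group gets thinned
#' inner layers (GCL and IPL, hence GCIP, scaled by \code{msInnerScale};
#' the RNFL by half that thinning) to emulate disease-related atrophy.
#'
#' @param layer layer id (GCIP is the sum of the GCL and IPL templates)
#' @param x,y numeric positions (mm from the fovea); any common shape
#' @param group \code{"HC"} or \code{"MS"}
#' @param msInnerScale multiplicative inner-layer thinning for MS
#'   (default 0.85)
#' @return numeric array of thicknesses, micrometres, same shape as x
#' @export
layerTemplateValues <- function(layer, x, y, group = "HC",
                                msInnerScale = 0.85) {
  if (!layer %in% retinalLayers())
    stop("unknown layer id '", layer, "'")
  if (layer == "GCIP")
    return(layerTemplateValues("GCL", x, y, group, msInnerScale) +
           layerTemplateValues("IPL", x, y, group, msInnerScale))
  r <- sqrt(x^2 + y^2)
  p <- .templateParams[[layer]]
  v <- if (layer == "RNFL") {
    p[1L] + p[2L] * pmin(r / 3, 1)^1.5
  } else if (layer == "ONL") {
    p[1L] + p[2L] * exp(-r^2 / (2 * p[4L]^2))
  } else {
    p[1L] + p[2L] * exp(-(r - p[3L])^2 / (2 * p[4L]^2))
  }
  if (identical(group, "MS")) {
    scale <- switch(layer, GCL = , IPL = msInnerScale,
                    RNFL = 1 - (1 - msInnerScale) / 2, 1)
    v <- v * scale
  }
  pmin(pmax(v, 0), 120)
}

#' Population-mean thickness map of a layer on a protocol grid
#'
#' @param layer layer id
#' @param coords coordinate grids from \code{\link{gridCoordinates}}
#' @inheritParams layerTemplateValues
#' @return numeric matrix (micrometres) on the grid
#' @export
#' @examples
#' g <- gridCoordinates(ScanProtocol("vertical", 25, 64, 6, 6))
#' range(layerTemplate("GCL", g))
layerTemplate <- function(layer, coords, group = "HC",
                          msInnerScale = 0.85) {
  layerTemplateValues(layer, coords$x, coords$y, group, msInnerScale)
}
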