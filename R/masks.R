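## Region-of-interest masks on protocol grids.
##
## Membership is evaluated at A-scan cell centres with closed outer
## boundaries and an open inner annulus boundary; for a fixed grid and
## parameters the result is bit-for-bit deterministic.

.maskNew <- function(mask, provenance) {
  if (!any(mask))
    warning("region mask '", provenance$type,
            "' selects no grid cells on this grid")
  new("RegionMask", mask = mask, provenance = provenance)
}

#' Fovea-centred circular disc mask
#'
#' A cell is included iff its centre satisfies
#' \code{x^2 + y^2 <= (diameter/2)^2} (closed boundary). The 6-mm-diameter
#' macular disc used by the large-area estimates is
#' \code{circularMask(g, 6)}.
#'
#' @param coords coordinate grids from \code{\link{gridCoordinates}}
#' @param diameterMm disc diameter in mm (> 0)
#' @return a \code{\link{RegionMask-class}}
#' @export
#' @examples
#' g <- gridCoordinates(ScanProtocol("horizontal", 61, 61, 6, 6))
#' sum(maskMatrix(circularMask(g, 6))) / (61 * 61)  # ~ pi/4
circularMask <- function(coords, diameterMm) {
  stopifnot(diameterMm > 0)
  r2 <- (diameterMm / 2)^2
  .maskNew(coords$x^2 + coords$y^2 <= r2,
           list(type = "circle", diameterMm = diameterMm))
}

#' Fovea-centred elliptical annulus mask
#'
#' The annular region between two axis-aligned ellipses used for the
#' Cirrus ganglion-cell analyses, conventionally with outer radii of
#' 2.4 mm (horizontal) and 2.0 mm (vertical) and inner radii of 0.6 and
#' 0.5 mm. A cell is included iff it lies inside or on the outer ellipse
#' and strictly outside the inner ellipse, testing
#' \code{(x/rh)^2 + (y/rv)^2} against 1.
#'
#' @param coords coordinate grids from \code{\link{gridCoordinates}}
#' @param outerHMm,outerVMm outer horizontal/vertical radii, mm
#' @param innerHMm,innerVMm inner radii, mm; each must be positive and
#'   strictly smaller than the corresponding outer radius
#' @return a \code{\link{RegionMask-class}}
#' @export
ellipticalAnnulusMask <- function(coords, outerHMm = 2.4, outerVMm = 2.0,
                                  innerHMm = 0.6, innerVMm = 0.5) {
  if (!(innerHMm > 0 && innerVMm > 0 &&
        innerHMm < outerHMm && innerVMm < outerVMm))
    stop("annulus radii must satisfy 0 < inner < outer componentwise")
  outer <- (coords$x / outerHMm)^2 + (coords$y / outerVMm)^2 <= 1
  inner <- (coords$x / innerHMm)^2 + (coords$y / innerVMm)^2 <= 1
  .maskNew(outer & !inner,
           list(type = "elliptical_annulus", outerHMm = outerHMm,
                outerVMm = outerVMm, innerHMm = innerHMm,
                innerVMm = innerVMm))
}

#' Mask covering the whole scanned area
#'
#' @param coords coordinate grids from \code{\link{gridCoordinates}}
#' @return a \code{\link{RegionMask-class}} including every cell
#' @export
fullAreaMask <- function(coords) {
  .maskNew(matrix(TRUE, nrow(coords$x), ncol(coords$x)),
           list(type = "full_area"))
}

#' Mask selecting the nearest grid cell to each listed point
#'
#' Used for the sparse point-set estimate: each (x, y) point in mm is
#' mapped to the single closest A-scan cell centre.
#'
#' @param coords coordinate grids from \code{\link{gridCoordinates}}
#' @param pointsMm two-column matrix of (x, y) positions in mm
#' @return a \code{\link{RegionMask-class}}
#' @export
pointSetMask <- function(coords, pointsMm) {
  pointsMm <- matrix(as.numeric(pointsMm), ncol = 2L)
  mask <- matrix(FALSE, nrow(coords$x), ncol(coords$x))
  for (i in seq_len(nrow(pointsMm))) {
    d2 <- (coords$x - pointsMm[i, 1L])^2 + (coords$y - pointsMm[i, 2L])^2
    mask[which.min(d2)] <- TRUE
  }
  .maskNew(mask, list(type = "point_set", pointsMm = pointsMm))
}

#' Mask selecting the rows of one or more B-scans
#'
#' @param coords coordinate grids from \code{\link{gridCoordinates}}
#' @param indices B-scan row indices to include
#' @return a \code{\link{RegionMask-class}}
#' @export
bscanLineMask <- function(coords, indices) {
  nB <- nrow(coords$x)
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > nB))
    stop("B-scan index out of range 1..", nB)
  mask <- matrix(FALSE, nB, ncol(coords$x))
  mask[indices, ] <- TRUE
  .maskNew(mask, list(type = "bscan_line", indices = indices))
}

## Build a mask from a declarative spec (EstimateDefinition@maskSpec)
.maskFromSpec <- function(spec, coords) {
  switch(spec$type,
    circle = circularMask(coords, spec$diameterMm),
    elliptical_annulus = ellipticalAnnulusMask(
      coords, spec$outerHMm, spec$outerVMm, spec$innerHMm, spec$innerVMm),
    full_area = fullAreaMask(coords),
    stop("unknown mask spec type '", spec$type, "'"))
}
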