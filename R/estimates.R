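#' Registry of the twelve published thickness estimates A-L
#'
#' Encodes the twelve ways mean layer thickness has been computed in the
#' literature as declarative \code{\link{EstimateDefinition-class}}
#' recipes:
#' \itemize{
#'   \item A, B, C - mean over the 6-mm-diameter disc around the fovea on
#'     three different Spectralis volume settings;
#'   \item D, E - full-area means on two further volume settings;
#'   \item F - mean over a reduced B-scan subset (every 4th B-scan);
#'   \item G, H - single respectively paired fovea-centred B-scan means
#'     over the full scan width;
#'   \item I - the central 6 mm of a single fovea-centred B-scan from a
#'     9-mm-wide scan;
#'   \item J - mean of a sparse point set (default 3 points) on a single
#'     fovea-centred B-scan;
#'   \item K, L - Cirrus elliptical-annulus means (outer radii 2.4/2.0 mm,
#'     inner radii 0.6/0.5 mm) on the 512 x 128 and 200 x 200 macular
#'     cubes, restricted to RNFL and GCIP.
#' }
#' Only the geometry above that the sources state explicitly (the 6-mm
#' disc for A-C, single-B-scan basis for G-J, the annulus radii and its
#' RNFL/GCIP restriction for K-L) is fixed; per-estimate scan settings and
#' B-scan subsets are documented, overridable defaults.
#'
#' @param protocols protocol set as returned by
#'   \code{\link{builtinProtocols}}; pass a thinned set to evaluate the
#'   same estimates on cheaper grids.
#' @param jPointsAlongMm offsets (mm from the fovea, along the B-scan) of
#'   the sparse points of estimate J.
#' @param annulusRadiiMm numeric length-4: outer horizontal, outer
#'   vertical, inner horizontal, inner vertical radii for K/L.
#' @return named list of \code{\link{EstimateDefinition-class}} objects
#'   (names "A".."L"; all 12 with the full protocol set, fewer when
#'   \code{protocols} omits some keys), with a \code{version} attribute.
#' @export
#' @examples
#' reg <- builtinEstimates()
#' length(reg)
#' reg$K
builtinEstimates <- function(protocols = builtinProtocols(),
                             jPointsAlongMm = c(0, 1, 2),
                             annulusRadiiMm = c(2.4, 2.0, 0.6, 0.5)) {
  allLayers <- retinalLayers()
  cirrusLayers <- c("RNFL", "GCIP")
  disc6 <- list(type = "circle", diameterMm = 6)
  annulus <- list(type = "elliptical_annulus",
                  outerHMm = annulusRadiiMm[1L],
                  outerVMm = annulusRadiiMm[2L],
                  innerHMm = annulusRadiiMm[3L],
                  innerVMm = annulusRadiiMm[4L])
  full <- list(type = "full_area")
  ## estimates whose protocol is absent from the set are omitted, so a
  ## registry can be built for a cohort that simulates fewer protocols
  def <- function(id, key, selector, mask, layers = allLayers) {
    p <- protocols[[key]]
    if (is.null(p)) return(NULL)
    new("EstimateDefinition", id = id, device = p@device, protocol = p,
        bscanSelector = selector, maskSpec = mask, layers = layers)
  }
  reg <- list(
    A = def("A", "spectralis_a", list(type = "all"), disc6),
    B = def("B", "spectralis_b", list(type = "all"), disc6),
    C = def("C", "spectralis_c", list(type = "all"), disc6),
    D = def("D", "spectralis_d", list(type = "all"), full),
    E = def("E", "spectralis_e", list(type = "all"), full),
    F = def("F", "spectralis_b", list(type = "subset", stride = 4L),
            full),
    G = def("G", "spectralis_a", list(type = "single", offsetMm = 0),
            full),
    H = def("H", "spectralis_b", list(type = "subset", central = 2L),
            full),
    I = def("I", "spectralis_e", list(type = "single", offsetMm = 0),
            disc6),
    J = def("J", "spectralis_a",
            list(type = "point_set", offsetMm = 0,
                 alongMm = jPointsAlongMm), full),
    K = def("K", "cirrus_512x128", list(type = "all"), annulus,
            cirrusLayers),
    L = def("L", "cirrus_200x200", list(type = "all"), annulus,
            cirrusLayers)
  )
  reg <- Filter(Negate(is.null), reg)
  attr(reg, "version") <- "1"
  reg
}

## Protocols are interchangeable when the full acquisition geometry
## agrees; the name alone is ambiguous (different extents can share
## direction and counts).
.sameProtocol <- function(p1, p2) {
  identical(p1@name, p2@name) && identical(p1@device, p2@device) &&
    isTRUE(all.equal(c(p1@widthMm, p1@heightMm),
                     c(p2@widthMm, p2@heightMm)))
}

## Resolve a B-scan selector into the set of selected row indices
.selectorRows <- function(selector, stackMm) {
  nB <- length(stackMm)
  switch(selector$type,
    all = seq_len(nB),
    subset = {
      if (!is.null(selector$indices)) {
        idx <- as.integer(selector$indices)
        if (any(idx < 1L | idx > nB))
          stop("B-scan subset index out of range 1..", nB)
        idx
      } else if (!is.null(selector$stride)) {
        seq(1L, nB, by = as.integer(selector$stride))
      } else if (!is.null(selector$central)) {
        k <- as.integer(selector$central)
        mid <- .resolveBScan(stackMm, NULL, 0)
        idx <- sort(order(abs(stackMm - stackMm[mid]))[seq_len(min(k, nB))])
        idx
      } else stop("subset selector needs 'indices', 'stride' or 'central'")
    },
    single = .resolveBScan(stackMm, selector$index, selector$offsetMm),
    point_set = .resolveBScan(stackMm, selector$index, selector$offsetMm),
    stop("unknown B-scan selector type '", selector$type, "'"))
}

## Logical selection matrix for a selector on a given coordinate grid
.selectorMask <- function(selector, coords) {
  rows <- .selectorRows(selector, coords$stackMm)
  sel <- matrix(FALSE, nrow(coords$x), ncol(coords$x))
  if (selector$type == "point_set") {
    along <- if (coords$alongAxis == "x") coords$x[rows, ] else
      coords$y[rows, ]
    for (t in selector$alongMm) {
      j <- which.min(abs(along - t))
      sel[rows, j] <- TRUE
    }
  } else {
    sel[rows, ] <- TRUE
  }
  sel
}

#' @rdname applyEstimate
#' @param foveaMm fovea offset used for SegmentedVolume input (LayerMaps
#'   carry their own)
#' @param missingFlagThreshold flag the record when more than this
#'   fraction of in-mask cells is missing (default 0.2)
#' @export
setMethod("applyEstimate", signature(x = "LayerMaps"),
  function(defn, x, layer, missingFlagThreshold = 0.2, ...) {
    if (!layer %in% defn@layers)
      stop("layer ", layer, " is not supported by estimate ", defn@id,
           " on device ", defn@device)
    if (!.sameProtocol(x@protocol, defn@protocol))
      stop("estimate ", defn@id, " expects protocol ",
           defn@protocol@name, " (", defn@protocol@device, "), got ",
           x@protocol@name, " (", x@protocol@device, ")")
    coords <- gridCoordinates(x@protocol, x@foveaMm)
    region <- suppressWarnings(.maskFromSpec(defn@maskSpec, coords))
    sel <- maskMatrix(region) & .selectorMask(defn@bscanSelector, coords)
    nMask <- sum(sel)
    if (nMask == 0L)
      stop("estimate ", defn@id, ": empty effective mask on grid ",
           x@protocol@name)
    v <- getLayerMap(x, layer)@values[sel]
    used <- sum(!is.na(v))
    if (used == 0L)
      stop("estimate ", defn@id, ": all in-mask cells are missing")
    list(value = mean(v, na.rm = TRUE), nCellsUsed = used,
         nCellsMask = nMask,
         flagged = (nMask - used) / nMask > missingFlagThreshold)
  })

#' @rdname applyEstimate
#' @export
setMethod("applyEstimate", signature(x = "SegmentedVolume"),
  function(defn, x, layer, foveaMm = c(0, 0),
           missingFlagThreshold = 0.2, ...) {
    applyEstimate(defn, asLayerMaps(x, foveaMm), layer,
                  missingFlagThreshold = missingFlagThreshold)
  })

#' Evaluate an estimate registry over a cohort of volumes
#'
#' Applies every estimate whose protocol matches each volume, for every
#' layer the estimate supports and the volume provides, and returns the
#' long-format repeated-measures table that the reliability statistics
#' consume. Output ordering is deterministic (subject, eye, session,
#' estimate, layer) regardless of input order; a duplicated
#' (eye, session, estimate, layer) combination is an error.
#'
#' @param registry estimate registry from \code{\link{builtinEstimates}}
#' @param cohort list of \code{\link{LayerMaps-class}} (or
#'   \code{\link{SegmentedVolume-class}}) objects, each tagged in
#'   \code{meta} with \code{subjectId}, \code{eye} ("OD"/"OS"),
#'   \code{group} ("HC"/"MS") and \code{session}
#' @param missingFlagThreshold see \code{\link{applyEstimate}}
#' @return data.frame with columns \code{subject_id}, \code{eye},
#'   \code{group}, \code{session}, \code{device}, \code{estimate},
#'   \code{layer}, \code{thickness_um}, \code{n_cells}
#' @export
applyAll <- function(registry, cohort, missingFlagThreshold = 0.2) {
  rows <- vector("list", length(cohort) * length(registry))
  n <- 0L
  for (vol in cohort) {
    if (is(vol, "SegmentedVolume")) vol <- asLayerMaps(vol)
    meta <- vol@meta
    need <- c("subjectId", "eye", "group", "session")
    if (!all(need %in% names(meta)))
      stop("cohort volume lacks meta tag(s): ",
           paste(setdiff(need, names(meta)), collapse = ", "))
    avail <- layerIds(vol)
    if (all(c("GCL", "IPL") %in% avail)) avail <- union(avail, "GCIP")
    for (defn in registry) {
      if (!.sameProtocol(defn@protocol, vol@protocol)) next
      for (layer in intersect(defn@layers, avail)) {
        r <- applyEstimate(defn, vol, layer,
                           missingFlagThreshold = missingFlagThreshold)
        n <- n + 1L
        rows[[n]] <- data.frame(
          subject_id = as.character(meta$subjectId),
          eye = as.character(meta$eye),
          group = as.character(meta$group),
          session = as.integer(meta$session),
          device = defn@device, estimate = defn@id, layer = layer,
          thickness_um = r$value, n_cells = r$nCellsUsed,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n == 0L) stop("no estimate applies to any volume in the cohort")
  tab <- do.call(rbind, rows[seq_len(n)])
  key <- with(tab, paste(subject_id, eye, session, estimate, layer,
                         sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (eye, session, estimate, layer) record: ",
         gsub("\r", "/", key[duplicated(key)][1L]))
  ord <- with(tab, order(subject_id, eye, session, estimate,
                         match(layer, retinalLayers())))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
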