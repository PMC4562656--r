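#' Configuration of a synthetic repeated-measurement cohort
#'
#' Builds a \code{\link{CohortConfig-class}} with defaults mirroring the
#' repeatability study design: two healthy-control cohorts of 15 subjects
#' with three sessions each (one cohort per device) and 13 patients with
#' two sessions on both devices, both eyes included. The noise model has
#' four session-level components, each with a known variance contribution:
#' a global per-scan offset, a spatially correlated segmentation-error
#' field, a translation jitter of the scan window, and the beam-angle
#' OPL/ONL boundary-shift artifact. Defaults for the noise magnitudes are
#' the package's calibrated study conditions (see the methods vignette).
#'
#' @param nHcSubjects,nMsSubjects,sessionsHc,sessionsMs,eyesPerSubject
#'   study design; defaults 15, 13, 3, 2, 2.
#' @param protocols protocol set to simulate; defaults to
#'   \code{builtinProtocols(maxAScans = 96)}, the native designs thinned
#'   to at most 96 A-scans per B-scan to keep simulation studies cheap.
#' @param sigmaBetween named between-eye SD per base layer, micrometres.
#' @param sigmaOffset per-scan global offset SD, micrometres.
#' @param sigmaField SD of the correlated field at each A-scan.
#' @param fieldCorrLengthMm correlation length of the field, mm.
#' @param jitterSdMm SD of the scan-window translation per session, mm.
#' @param hflAmplitude amplitude of the HFL boundary-shift artifact,
#'   micrometres (0 disables).
#' @param hflThetaRange per-session beam offset theta is uniform on
#'   \code{[-hflThetaRange, hflThetaRange]}.
#' @param msInnerScale inner-layer thinning factor for the MS group.
#' @param seed integer seed fixing the complete cohort.
#' @return a \code{\link{CohortConfig-class}}
#' @export
#' @examples
#' cfg <- CohortConfig(nHcSubjects = 2, nMsSubjects = 1, seed = 7)
CohortConfig <- function(nHcSubjects = 15, nMsSubjects = 13,
                         sessionsHc = 3, sessionsMs = 2,
                         eyesPerSubject = 2,
                         protocols = builtinProtocols(maxAScans = 96),
                         sigmaBetween = c(RNFL = 4, GCL = 4.5, IPL = 3.5,
                                          INL = 3.5, OPL = 2.2, ONL = 6),
                         sigmaOffset = 0.3, sigmaField = 7,
                         fieldCorrLengthMm = 0.10, jitterSdMm = 0.1,
                         hflAmplitude = 60, hflThetaRange = 0.5,
                         msInnerScale = 0.85, seed = 1) {
  new("CohortConfig",
      nHcSubjects = as.integer(nHcSubjects),
      nMsSubjects = as.integer(nMsSubjects),
      sessionsHc = as.integer(sessionsHc),
      sessionsMs = as.integer(sessionsMs),
      eyesPerSubject = as.integer(eyesPerSubject),
      protocols = protocols, sigmaBetween = sigmaBetween,
      sigmaOffset = as.numeric(sigmaOffset),
      sigmaField = as.numeric(sigmaField),
      fieldCorrLengthMm = as.numeric(fieldCorrLengthMm),
      jitterSdMm = as.numeric(jitterSdMm),
      hflAmplitude = as.numeric(hflAmplitude),
      hflThetaRange = as.numeric(hflThetaRange),
      msInnerScale = as.numeric(msInnerScale), seed = as.integer(seed))
}

## Gaussian-kernel weight matrix for positions pos (mm); rows are output
## cells. Used for separable smoothing of white noise.
.smoothKernel <- function(pos, corrLengthMm) {
  d <- outer(pos, pos, "-")
  exp(-d^2 / (2 * corrLengthMm^2))
}

#' Spatially correlated zero-mean noise field on a protocol grid
#'
#' Gaussian-kernel-smoothed white noise with the kernel width set by the
#' correlation length, rescaled so that every grid cell has exactly the
#' requested marginal SD (the variance, not the spectrum, is the
#' simulator's contract). Deterministic given the RNG state.
#'
#' @param coords coordinate grids from \code{\link{gridCoordinates}}
#' @param sigma marginal SD of the field, micrometres
#' @param corrLengthMm correlation length, mm
#' @param kernels optional precomputed kernel pair (internal caching)
#' @return numeric matrix, same dimension as the grid
#' @export
correlatedField <- function(coords, sigma, corrLengthMm,
                            kernels = NULL) {
  nB <- nrow(coords$x); nA <- ncol(coords$x)
  if (sigma == 0) return(matrix(0, nB, nA))
  if (is.null(kernels)) {
    rowPos <- coords$stackMm
    alongRow <- if (coords$alongAxis == "x") coords$x[1L, ] else
      coords$y[1L, ]
    kernels <- list(R = .smoothKernel(rowPos, corrLengthMm),
                    C = .smoothKernel(alongRow, corrLengthMm))
  }
  w <- matrix(stats::rnorm(nB * nA), nB, nA)
  s <- kernels$R %*% w %*% kernels$C
  ## exact per-cell variance of the separable convolution of white noise
  norm <- sqrt(outer(rowSums(kernels$R^2), rowSums(kernels$C^2)))
  sigma * s / norm
}

#' Beam-angle-dependent OPL/ONL boundary-shift artifact
#'
#' The Henle fiber layer's reflectivity depends on where the OCT beam
#' enters the pupil, which shifts the apparent OPL/ONL boundary: one side
#' of the fovea gains apparent OPL thickness at the ONL's expense while
#' the opposite side loses it. The shift applied here is
#' \deqn{\delta(x, y) = A \theta \, s(x, y), \quad
#'   s = \tanh(t / 0.8) e^{-r^2 / (2 \cdot 1.8^2)},}
#' with \eqn{t} the coordinate along the beam-offset direction, so that
#' \eqn{s} is smooth, bounded by 1 in magnitude and antisymmetric across
#' the fovea along that direction. The OPL gains \eqn{\delta}, the ONL
#' loses it, both floored at 0.5 micrometres; wherever the floor is not
#' hit the OPL + ONL sum is conserved exactly.
#'
#' @param opl,onl \code{\link{ThicknessMap-class}} objects on identical
#'   grids
#' @param theta per-session beam offset (dimensionless, typically in
#'   [-0.5, 0.5]); 0 leaves the maps untouched
#' @param amplitude artifact amplitude A, micrometres (>= 0)
#' @param directionRad beam-offset direction in radians (0 = along x)
#' @return list with elements \code{opl} and \code{onl} (shifted
#'   \code{ThicknessMap}s) and \code{delta} (the applied shift matrix)
#' @export
hflArtifact <- function(opl, onl, theta, amplitude = 60,
                        directionRad = 0) {
  stopifnot(is(opl, "ThicknessMap"), is(onl, "ThicknessMap"),
            amplitude >= 0)
  if (!identical(dim(opl@values), dim(onl@values)) ||
      !isTRUE(all.equal(opl@x, onl@x)) ||
      !isTRUE(all.equal(opl@y, onl@y)))
    stop("OPL and ONL maps are not on aligned grids")
  delta <- amplitude * theta *
    .hflShape(opl@x, opl@y, directionRad)
  new1 <- opl; new2 <- onl
  new1@values <- pmax(opl@values + delta, 0.5)
  new2@values <- pmax(onl@values - delta, 0.5)
  list(opl = new1, onl = new2, delta = delta)
}

.hflShape <- function(x, y, directionRad = 0) {
  t <- x * cos(directionRad) + y * sin(directionRad)
  r2 <- x^2 + y^2
  tanh(t / 0.8) * exp(-r2 / (2 * 1.8^2))
}

## design table: one row per eye in the cohort
.cohortEyes <- function(config) {
  eyes <- c("OD", "OS")[seq_len(config@eyesPerSubject)]
  mk <- function(prefix, n, group, device, sessions) {
    if (n == 0L) return(NULL)
    expand.grid(subjectId = sprintf("%s%02d", prefix, seq_len(n)),
                eye = eyes, stringsAsFactors = FALSE)[
      , c("subjectId", "eye")] |>
      transform(group = group, device = device, sessions = sessions)
  }
  rbind(mk("HCS", config@nHcSubjects, "HC", "spectralis",
           config@sessionsHc),
        mk("HCC", config@nHcSubjects, "HC", "cirrus", config@sessionsHc),
        mk("MS", config@nMsSubjects, "MS", "both", config@sessionsMs))
}

#' Simulate a synthetic repeated-measurement OCT cohort
#'
#' Generates per-eye true thickness maps (analytic layer templates plus a
#' per-eye, per-layer offset with SD \code{sigmaBetween}) and observes
#' them repeatedly under the session noise model: each scan sees the truth
#' through a translated sampling window (jitter), plus a global offset,
#' plus a spatially correlated field, and - for the OPL/ONL pair - the
#' beam-angle HFL artifact with a fresh beam offset per session. Cirrus
#' volumes carry RNFL and GCIP maps only (the GCIP assembled from the
#' same GCL and IPL truths), Spectralis volumes all six base layers. The
#' seed in the config fixes the complete output bit for bit.
#'
#' @param config a \code{\link{CohortConfig-class}}
#' @return list with \code{cohort} (list of \code{\link{LayerMaps-class}},
#'   one per eye x session x protocol) and \code{truth}, a list holding
#'   the design table (\code{eyes}), the per-eye layer offsets
#'   (\code{eyeOffsets}), the between-eye SD per layer (\code{sigmaB},
#'   GCIP included), the within-eye SD per layer implied by offset-only
#'   noise (\code{sigmaWOffset}) and the offset-only true ICC per layer
#'   (\code{trueICCOffsetOnly}); within-eye variances under the full noise
#'   model are obtained by Monte Carlo via
#'   \code{\link{estimateWithinVariance}}.
#' @export
#' @examples
#' cfg <- CohortConfig(nHcSubjects = 1, nMsSubjects = 0,
#'                     protocols = builtinProtocols(maxAScans = 24,
#'                                                  maxBScans = 13),
#'                     seed = 1)
#' sim <- simulateCohort(cfg)
#' length(sim$cohort)
simulateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)
  base <- c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL")
  eyes <- .cohortEyes(config)
  nEyes <- nrow(eyes)
  eyeOffsets <- matrix(stats::rnorm(nEyes * length(base)), nEyes,
                       dimnames = list(NULL, base))
  eyeOffsets <- sweep(eyeOffsets, 2L, config@sigmaBetween[base], "*")

  ## per-protocol caches: coordinates and smoothing kernels
  coordsList <- lapply(config@protocols, gridCoordinates)
  kernelList <- lapply(coordsList, function(g) {
    alongRow <- if (g$alongAxis == "x") g$x[1L, ] else g$y[1L, ]
    list(R = .smoothKernel(g$stackMm, config@fieldCorrLengthMm),
         C = .smoothKernel(alongRow, config@fieldCorrLengthMm))
  })
  protoDevice <- vapply(config@protocols, function(p) p@device,
                        character(1L))

  cohort <- vector("list",
                   nEyes * max(config@sessionsHc, config@sessionsMs) *
                     length(config@protocols))
  nVol <- 0L
  for (e in seq_len(nEyes)) {
    row <- eyes[e, ]
    devs <- if (row$device == "both") c("spectralis", "cirrus") else
      row$device
    for (s in seq_len(row$sessions)) {
      for (dev in devs) {
        jitter <- stats::rnorm(2L, 0, config@jitterSdMm)
        theta <- stats::runif(1L, -config@hflThetaRange,
                              config@hflThetaRange)
        phi <- stats::runif(1L, 0, 2 * pi)
        for (k in which(protoDevice == dev)) {
          g <- coordsList[[k]]
          maps <- list()
          for (layer in base) {
            truth <- layerTemplateValues(
              layer, g$x + jitter[1L], g$y + jitter[2L], row$group,
              config@msInnerScale) + eyeOffsets[e, layer]
            noise <- stats::rnorm(1L, 0, config@sigmaOffset) +
              correlatedField(g, config@sigmaField,
                              config@fieldCorrLengthMm,
                              kernels = kernelList[[k]])
            maps[[layer]] <- truth + noise
          }
          if (config@hflAmplitude > 0 && theta != 0) {
            delta <- config@hflAmplitude * theta *
              .hflShape(g$x, g$y, phi)
            opl <- maps$OPL + delta
            onl <- maps$ONL - delta
            maps$OPL <- pmax(opl, 0.5)
            maps$ONL <- pmax(onl, 0.5)
          }
          maps <- lapply(maps, function(m) pmax(m, 0))
          if (dev == "cirrus")
            maps <- list(RNFL = maps$RNFL, GCIP = maps$GCL + maps$IPL)
          nVol <- nVol + 1L
          cohort[[nVol]] <- new(
            "LayerMaps", protocol = config@protocols[[k]], maps = maps,
            foveaMm = c(0, 0),
            meta = list(subjectId = row$subjectId, eye = row$eye,
                        group = row$group, session = s))
        }
      }
    }
  }
  sigmaB <- config@sigmaBetween[base]
  sigmaB <- c(sigmaB, GCIP = sqrt(sum(sigmaB[c("GCL", "IPL")]^2)))
  sigmaW <- rep(config@sigmaOffset, length(base))
  names(sigmaW) <- base
  sigmaW <- c(sigmaW, GCIP = config@sigmaOffset * sqrt(2))
  truth <- list(
    eyes = eyes, eyeOffsets = eyeOffsets, sigmaB = sigmaB,
    sigmaWOffset = sigmaW,
    trueICCOffsetOnly = sigmaB^2 / (sigmaB^2 + sigmaW^2),
    config = config)
  list(cohort = cohort[seq_len(nVol)], truth = truth)
}

#' Monte-Carlo within-eye variance of one estimate under the noise model
#'
#' Repeatedly re-observes a single fixed eye under the session noise model
#' of a config and returns the empirical variance of the estimate values.
#' Complements the closed-form offset-only variance stored in the ground
#' truth, for noise components (correlated field, jitter, HFL artifact)
#' whose contribution to a regional mean has no simple closed form.
#'
#' @param config a \code{\link{CohortConfig-class}}
#' @param defn an \code{\link{EstimateDefinition-class}} built on one of
#'   the config's protocols
#' @param layer layer id
#' @param nsim number of simulated sessions (default 200)
#' @param group template group for the probe eye
#' @return list with \code{varWithin} and the simulated \code{values}
#' @export
estimateWithinVariance <- function(config, defn, layer, nsim = 200,
                                   group = "HC") {
  probe <- CohortConfig(
    nHcSubjects = 1L, nMsSubjects = 0L, sessionsHc = as.integer(nsim),
    eyesPerSubject = 1L, protocols = list(only = defn@protocol),
    sigmaBetween = config@sigmaBetween, sigmaOffset = config@sigmaOffset,
    sigmaField = config@sigmaField,
    fieldCorrLengthMm = config@fieldCorrLengthMm,
    jitterSdMm = config@jitterSdMm, hflAmplitude = config@hflAmplitude,
    hflThetaRange = config@hflThetaRange,
    msInnerScale = config@msInnerScale, seed = config@seed)
  sim <- simulateCohort(probe)
  vals <- vapply(sim$cohort, function(vol)
    applyEstimate(defn, vol, layer)$value, numeric(1L))
  list(varWithin = stats::var(vals), values = vals)
}

#' Record-level generator for variance-component studies
#'
#' Draws repeated measurements directly from the two-variance-component
#' model that the map-level simulator reduces to when only between-eye
#' variation and global session offsets are active: each eye has a true
#' value \code{mean + N(0, sigmaBetween)} and every session observes it
#' plus \code{N(0, sigmaWithin)}. The implied true ICC is
#' \code{sigmaBetween^2 / (sigmaBetween^2 + sigmaWithin^2)}. Used for
#' calibration studies (parameter recovery, CI coverage) where simulating
#' full thickness maps adds nothing.
#'
#' @param nEyes number of eyes
#' @param sessions sessions per eye (scalar or per-eye vector)
#' @param sigmaBetween,sigmaWithin variance components, micrometres
#' @param mean population mean (default 0)
#' @return data.frame with columns \code{unit}, \code{session},
#'   \code{value} and attribute \code{trueICC}
#' @export
#' @examples
#' set.seed(1)
#' d <- simulateRecords(60, 3, 4, 1.5)
#' attr(d, "trueICC")  # 16 / 18.25
simulateRecords <- function(nEyes, sessions, sigmaBetween, sigmaWithin,
                            mean = 0) {
  sessions <- rep_len(as.integer(sessions), nEyes)
  truth <- mean + stats::rnorm(nEyes, 0, sigmaBetween)
  unit <- rep(seq_len(nEyes), sessions)
  out <- data.frame(
    unit = unit,
    session = unlist(lapply(sessions, seq_len)),
    value = truth[unit] + stats::rnorm(sum(sessions), 0, sigmaWithin))
  attr(out, "trueICC") <- sigmaBetween^2 /
    (sigmaBetween^2 + sigmaWithin^2)
  out
}
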