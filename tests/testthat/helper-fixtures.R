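# Shared fixtures: everything is generated in code, nothing on disk.

# cheap thinned protocol set for estimate-engine tests; B-scan counts are
# kept so that no two protocols collapse onto the same geometry
tinyProtocols <- function() builtinProtocols(maxAScans = 24)

# LayerMaps with constant thickness on every layer a device provides
constantLayerMaps <- function(protocol, value = 50,
                              meta = list(subjectId = "S1", eye = "OD",
                                          group = "HC", session = 1L)) {
  layers <- if (protocol@device == "cirrus") c("RNFL", "GCIP") else
    c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL")
  maps <- lapply(layers, function(l)
    matrix(value, protocol@nBScans, protocol@nAScans))
  names(maps) <- layers
  new("LayerMaps", protocol = protocol, maps = maps, foveaMm = c(0, 0),
      meta = meta)
}

# a full monotone boundary stack with given per-layer pixel increments
volumeFromIncrements <- function(protocol, increments, ilmPx = 40) {
  stopifnot(length(dim(increments)) == 3L, dim(increments)[3L] == 6L)
  pos <- matrix(ilmPx, protocol@nBScans, protocol@nAScans)
  boundaries <- list(ILM = pos)
  outer <- c("RNFL_GCL", "GCL_IPL", "IPL_INL", "INL_OPL", "OPL_ONL",
             "ONL_outer")
  for (i in 1:6) {
    pos <- pos + increments[, , i]
    boundaries[[outer[i]]] <- pos
  }
  SegmentedVolume(protocol, boundaries)
}

# independent ANOVA/ICC oracle via lm(): a different code path entirely
oracleICC <- function(values, unit, alpha = 0.05) {
  fit <- stats::lm(values ~ factor(unit))
  an <- suppressWarnings(stats::anova(fit))  # perfect-fit warning on MSW ~ 0
  MSB <- an$`Mean Sq`[1L]
  MSW <- an$`Mean Sq`[2L]
  ni <- as.numeric(table(unit))
  a <- length(ni)
  N <- sum(ni)
  k <- if (length(unique(ni)) == 1L) ni[1L] else
    (N - sum(ni^2) / N) / (a - 1)
  icc <- (MSB - MSW) / (MSB + (k - 1) * MSW)
  F <- MSB / MSW
  lo <- (F / stats::qf(1 - alpha / 2, a - 1, N - a) - 1) /
    (F / stats::qf(1 - alpha / 2, a - 1, N - a) + k - 1)
  hi <- (F * stats::qf(1 - alpha / 2, N - a, a - 1) - 1) /
    (F * stats::qf(1 - alpha / 2, N - a, a - 1) + k - 1)
  list(icc = icc, lo = lo, hi = hi, MSB = MSB, MSW = MSW, k = k)
}

# random small repeated-measures dataset (n <= 5 units, k <= 3 sessions,
# integer values) that is guaranteed non-degenerate
randomSmallDataset <- function() {
  repeat {
    a <- sample(2:5, 1L)
    ni <- sample(2:3, a, replace = TRUE)
    unit <- rep(seq_len(a), ni)
    values <- sample(0:4, sum(ni), replace = TRUE)
    if (stats::var(values) > 0) return(list(values = values, unit = unit))
  }
}

# cell-centred square grid: n x n cell centres covering [-half, half]^2
cellCentredGrid <- function(half, step) {
  centres <- seq(-half + step / 2, half - step / 2, by = step)
  list(x = matrix(centres, length(centres), length(centres),
                  byrow = TRUE),
       y = matrix(centres, length(centres), length(centres)),
       stackMm = centres, alongAxis = "x")
}
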