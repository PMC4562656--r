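test_that("protocol names encode direction and counts and round-trip", {
  p <- ScanProtocol("vertical", 25, 1024, 6, 6, artFrames = 49)
  expect_identical(protocolName(p), "V-25-1024")
  expect_identical(formatProtocolName(p), p@name)
  parsed <- parseProtocolName("V-25-1024")
  expect_identical(parsed$direction, "vertical")
  expect_identical(parsed$nBScans, 25L)
  expect_identical(parsed$nAScans, 1024L)
  q <- do.call(ScanProtocol,
               c(parsed, list(widthMm = 6, heightMm = 6)))
  expect_identical(formatProtocolName(q), "V-25-1024")
  expect_error(parseProtocolName("25-1024"), "malformed")
})

test_that("protocol invariants reject bad geometry", {
  expect_error(ScanProtocol("horizontal", 0, 512, 6, 6), "nBScans")
  expect_error(ScanProtocol("horizontal", 25, 1, 6, 6), "nAScans")
  expect_error(ScanProtocol("horizontal", 25, 512, -6, 6), "extent")
  expect_error(ScanProtocol("diagonal", 25, 512, 6, 6), "direction")
})

test_that("grid spacing is uniform and fovea-centred", {
  g <- gridCoordinates(ScanProtocol("vertical", 25, 64, 6, 6))
  expect_equal(unique(round(diff(g$stackMm), 12)), 6 / 24)
  # vertical volume: B-scans stacked along x, running along y
  expect_equal(g$alongAxis, "y")
  expect_equal(range(g$x), c(-3, 3))
  expect_equal(range(g$y), c(-3, 3))
  # corner A-scans sit at the scan-area corners
  expect_equal(c(g$x[1, 1], g$y[1, 1]), c(-3, -3))
  expect_equal(c(g$x[25, 64], g$y[25, 64]), c(3, 3))
  # off-centre fovea shifts the origin
  g2 <- gridCoordinates(ScanProtocol("vertical", 25, 64, 6, 6),
                        foveaMm = c(1, -0.5))
  expect_equal(g2$x, g$x - 1)
  expect_equal(g2$y, g$y + 0.5)
  expect_error(gridCoordinates(ScanProtocol("vertical", 25, 64, 6, 6),
                               foveaMm = c(4, 0)), "outside")
})

test_that("horizontal and vertical grids with equal counts are transposes", {
  gh <- gridCoordinates(ScanProtocol("horizontal", 31, 31, 6, 6))
  gv <- gridCoordinates(ScanProtocol("vertical", 31, 31, 6, 6))
  expect_equal(gv$x, t(gh$x))
  expect_equal(gv$y, t(gh$y))
})

test_that("grid index -> mm -> nearest index round-trips for all cells", {
  for (p in list(ScanProtocol("horizontal", 13, 24, 6, 6),
                 ScanProtocol("vertical", 12, 25, 9, 6))) {
    g <- gridCoordinates(p)
    # nearest-cell lookup by exhaustive distance minimisation
    for (b in seq_len(p@nBScans)) for (a in seq_len(p@nAScans)) {
      d2 <- (g$x - g$x[b, a])^2 + (g$y - g$y[b, a])^2
      idx <- arrayInd(which.min(d2), dim(d2))
      expect_identical(c(idx), c(b, a))
    }
  }
})

test_that("thickness is boundary distance times the axial scale", {
  p <- ScanProtocol("vertical", 3, 4, 6, 6)  # scale 3.87 um/px
  v <- SegmentedVolume(p, list(ILM = matrix(10, 3, 4),
                               RNFL_GCL = matrix(20, 3, 4)))
  tm <- thicknessFromSurfaces(v, "RNFL")
  expect_equal(thicknessValues(tm), matrix(38.7, 3, 4))
  expect_error(thicknessFromSurfaces(v, "XXX"), "unknown layer")
  expect_error(thicknessFromSurfaces(v, "ONL"), "lacks boundary")
})

test_that("GCIP equals GCL plus IPL exactly and layers add up", {
  p <- ScanProtocol("horizontal", 5, 8, 6, 6)
  set.seed(71)
  inc <- array(stats::runif(5 * 8 * 6, 0.5, 20), dim = c(5, 8, 6))
  vol <- volumeFromIncrements(p, inc)
  gcl <- thicknessValues(thicknessFromSurfaces(vol, "GCL"))
  ipl <- thicknessValues(thicknessFromSurfaces(vol, "IPL"))
  gcip <- thicknessValues(thicknessFromSurfaces(vol, "GCIP"))
  expect_identical(gcip, gcl + ipl)
  # every layer nonnegative; layers sum to the ILM-to-outer total
  layers <- c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL")
  maps <- lapply(layers, function(l)
    thicknessValues(thicknessFromSurfaces(vol, l)))
  for (m in maps) expect_true(all(m >= 0))
  total <- (vol@boundaries$ONL_outer - vol@boundaries$ILM) *
    p@axialScaleUmPerPx
  expect_equal(Reduce(`+`, maps), total, tolerance = 1e-12)
  # brute-force per-A-scan subtraction oracle on one layer
  oracle <- matrix(0, 5, 8)
  for (b in 1:5) for (a in 1:8)
    oracle[b, a] <- (vol@boundaries$INL_OPL[b, a] -
                       vol@boundaries$IPL_INL[b, a]) * 3.87
  expect_equal(thicknessValues(thicknessFromSurfaces(vol, "INL")),
               oracle, tolerance = 1e-12)
})

test_that("missing boundary positions propagate as missing thickness", {
  p <- ScanProtocol("horizontal", 3, 4, 6, 6)
  ilm <- matrix(10, 3, 4); ilm[2, 3] <- NA
  out <- matrix(30, 3, 4); out[1, 1] <- NA
  v <- SegmentedVolume(p, list(ILM = ilm, RNFL_GCL = out))
  tv <- thicknessValues(thicknessFromSurfaces(v, "RNFL"))
  expect_true(is.na(tv[2, 3]) && is.na(tv[1, 1]))
  expect_equal(sum(is.na(tv)), 2L)
})

test_that("inverted boundaries are rejected naming the offending A-scan", {
  p <- ScanProtocol("horizontal", 3, 4, 6, 6)
  b <- list(ILM = matrix(10, 3, 4), RNFL_GCL = matrix(20, 3, 4))
  b$RNFL_GCL[2, 3] <- 5
  expect_error(SegmentedVolume(p, b), "B-scan 2, A-scan 3")
})

test_that("B-scan extraction honours index bounds and tie-breaks", {
  p <- ScanProtocol("vertical", 25, 16, 6, 6)
  v <- constantLayerMaps(p)
  tm <- getLayerMap(v, "RNFL")
  # odd count, fovea centred: nearest-to-0 is the middle B-scan
  expect_identical(extractBScan(tm, offsetMm = 0)$index, 13L)
  # even count: midway offsets resolve to the lower of the two indices
  pe <- ScanProtocol("vertical", 24, 16, 6, 6)
  tme <- getLayerMap(constantLayerMaps(pe), "RNFL")
  expect_identical(extractBScan(tme, offsetMm = 0)$index, 12L)
  expect_error(extractBScan(tm, index = -1), "out of range")
  expect_error(extractBScan(tm, index = 26), "out of range")
  expect_error(extractBScan(tm, offsetMm = 5), "outside")
  # profile carries mm coordinates along the B-scan
  prof <- extractBScan(tm, index = 13)
  expect_length(prof$values, 16L)
  expect_equal(range(prof$alongMm), c(-3, 3))
})

test_that("layer maps and segmentation surfaces are mutually consistent", {
  p <- ScanProtocol("horizontal", 5, 8, 6, 6)
  set.seed(5)
  inc <- array(stats::runif(5 * 8 * 6, 1, 15), dim = c(5, 8, 6))
  vol <- volumeFromIncrements(p, inc)
  lm <- asLayerMaps(vol)
  back <- layerMapsToVolume(lm, ilmPx = 40)
  for (nm in boundaryNames())
    expect_equal(back@boundaries[[nm]], vol@boundaries[[nm]],
                 tolerance = 1e-9)
})
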