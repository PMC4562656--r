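test_that("the registry holds the twelve published estimates", {
  reg <- builtinEstimates()
  expect_length(reg, 12L)
  expect_identical(names(reg), LETTERS[1:12])
  expect_identical(vapply(reg, function(d) d@id, character(1)),
                   stats::setNames(LETTERS[1:12], LETTERS[1:12]))
  # K and L: Cirrus elliptical annulus with the conventional radii,
  # restricted to RNFL and GCIP
  for (id in c("K", "L")) {
    d <- reg[[id]]
    expect_identical(scanDevice(d), "cirrus")
    expect_identical(d@maskSpec$type, "elliptical_annulus")
    expect_equal(unlist(d@maskSpec[c("outerHMm", "outerVMm", "innerHMm",
                                     "innerVMm")]),
                 c(outerHMm = 2.4, outerVMm = 2.0, innerHMm = 0.6,
                   innerVMm = 0.5))
    expect_identical(layerIds(d), c("RNFL", "GCIP"))
  }
  # A-C share the 6-mm disc and differ only in protocol
  specs <- lapply(reg[c("A", "B", "C")], function(d) d@maskSpec)
  expect_identical(specs$A, list(type = "circle", diameterMm = 6))
  expect_identical(specs$A, specs$B)
  expect_identical(specs$A, specs$C)
  protos <- vapply(reg[c("A", "B", "C")], protocolName, character(1))
  expect_identical(anyDuplicated(protos), 0L)
  # G-J are single-B-scan based
  for (id in c("G", "I", "J"))
    expect_true(reg[[id]]@bscanSelector$type %in%
                  c("single", "point_set"))
})

test_that("every estimate returns the constant on a constant map", {
  reg <- builtinEstimates(protocols = tinyProtocols())
  for (d in reg) {
    v <- constantLayerMaps(d@protocol, value = 50)
    for (layer in layerIds(d)) {
      r <- applyEstimate(d, v, layer)
      # on Spectralis maps GCIP is derived as GCL + IPL
      expected <- if (layer == "GCIP" && d@device == "spectralis")
        100 else 50
      expect_identical(r$value, expected)
      expect_gte(r$nCellsUsed, 1L)
      expect_false(r$flagged)
    }
  }
})

test_that("estimate values match brute-force enumeration over the mask", {
  # 10 um inside 1 mm of the fovea, 20 um elsewhere; 6-mm disc mean
  reg <- builtinEstimates()  # native-resolution grid for the A estimate
  d <- reg$A
  g <- gridCoordinates(d@protocol)
  v <- constantLayerMaps(d@protocol, value = 20)
  v@maps$RNFL[g$x^2 + g$y^2 <= 1] <- 10
  r <- applyEstimate(d, v, "RNFL")
  # continuum limit: 20 - 10 * (1/3)^2
  expect_lt(abs(r$value - (20 - 10 / 9)), 0.05)
  inMask <- maskMatrix(circularMask(g, 6))
  brute <- mean(v@maps$RNFL[inMask])
  expect_equal(r$value, brute, tolerance = 1e-12)
  expect_identical(r$nCellsUsed, sum(inMask))
})

test_that("GCIP estimates equal the sum of GCL and IPL estimates", {
  reg <- builtinEstimates(protocols = tinyProtocols())
  set.seed(9)
  for (id in c("A", "F", "G", "J")) {
    d <- reg[[id]]
    v <- constantLayerMaps(d@protocol)
    v@maps <- lapply(v@maps, function(m)
      m + matrix(stats::runif(length(m), 0, 30), nrow(m)))
    expect_equal(applyEstimate(d, v, "GCIP")$value,
                 applyEstimate(d, v, "GCL")$value +
                   applyEstimate(d, v, "IPL")$value,
                 tolerance = 1e-9)
  }
})

test_that("missing cells are excluded and heavy missingness is flagged", {
  reg <- builtinEstimates(protocols = tinyProtocols())
  d <- reg$A
  v <- constantLayerMaps(d@protocol, value = 50)
  g <- gridCoordinates(d@protocol)
  inMask <- which(maskMatrix(circularMask(g, 6)))
  v@maps$RNFL[inMask[1:3]] <- NA
  r <- applyEstimate(d, v, "RNFL")
  expect_identical(r$value, 50)
  expect_identical(r$nCellsUsed, length(inMask) - 3L)
  expect_false(r$flagged)
  v@maps$RNFL[inMask[seq_len(ceiling(0.3 * length(inMask)))]] <- NA
  expect_true(applyEstimate(d, v, "RNFL")$flagged)
})

test_that("device and protocol mismatches are rejected", {
  reg <- builtinEstimates(protocols = tinyProtocols())
  vK <- constantLayerMaps(reg$K@protocol)
  expect_error(applyEstimate(reg$K, vK, "GCL"), "not supported")
  expect_error(applyEstimate(reg$A, vK, "RNFL"), "expects protocol")
})

test_that("applyAll produces one ordered record per eye-session-layer", {
  reg <- builtinEstimates(protocols = tinyProtocols())["A"]
  cohort <- list()
  for (eye in c("OD", "OS")) for (s in 1:3)
    cohort[[paste(eye, s)]] <- constantLayerMaps(
      builtinEstimates(protocols = tinyProtocols())$A@protocol,
      value = 40 + s,
      meta = list(subjectId = "S1", eye = eye, group = "HC",
                  session = s))
  tab <- applyAll(reg, cohort)
  expect_identical(nrow(tab), 2L * 3L * 7L)   # eyes x sessions x layers
  expect_identical(unique(tab$estimate), "A")
  # shuffled input yields the identical table
  set.seed(2)
  tab2 <- applyAll(reg, sample(cohort))
  expect_identical(tab, tab2)
  # duplicated session is an error
  dup <- c(cohort, cohort[1])
  expect_error(applyAll(reg, dup), "duplicate")
})

test_that("cirrus-only eyes contribute no Spectralis estimates", {
  reg <- builtinEstimates(protocols = tinyProtocols())
  vol <- constantLayerMaps(reg$K@protocol,
                           meta = list(subjectId = "C1", eye = "OD",
                                       group = "HC", session = 1L))
  vol2 <- vol; vol2@meta$session <- 2L
  tab <- applyAll(reg, list(vol, vol2))
  expect_identical(sort(unique(tab$estimate)), "K")
  expect_identical(sort(unique(tab$layer)), c("GCIP", "RNFL"))
})

test_that("estimates are permutation-invariant and shift-equivariant", {
  reg <- builtinEstimates(protocols = tinyProtocols())
  d <- reg$A
  g <- gridCoordinates(d@protocol)
  sel <- maskMatrix(circularMask(g, 6))
  set.seed(33)
  v <- constantLayerMaps(d@protocol)
  v@maps$RNFL[] <- stats::runif(length(sel), 10, 60)
  base <- applyEstimate(d, v, "RNFL")$value
  # permuting values inside the mask leaves the mean unchanged
  vp <- v
  vp@maps$RNFL[sel] <- sample(v@maps$RNFL[sel])
  expect_equal(applyEstimate(d, vp, "RNFL")$value, base,
               tolerance = 1e-12)
  # adding a constant adds exactly that constant
  vc <- v
  vc@maps$RNFL <- v@maps$RNFL + 7.25
  expect_equal(applyEstimate(d, vc, "RNFL")$value, base + 7.25,
               tolerance = 1e-12)
})

test_that("larger masks average away more i.i.d. noise", {
  p <- tinyProtocols()$spectralis_a
  g <- gridCoordinates(p)
  small <- maskMatrix(circularMask(g, 2))
  large <- maskMatrix(circularMask(g, 6))
  expect_true(all(large[small]))  # nested
  set.seed(808)
  reps <- 1000L
  meansS <- meansL <- numeric(reps)
  for (i in seq_len(reps)) {
    noise <- matrix(stats::rnorm(length(small), 50, 5), nrow(small))
    meansS[i] <- mean(noise[small])
    meansL[i] <- mean(noise[large])
  }
  expect_lt(stats::var(meansL), stats::var(meansS))
})
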