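smallConfig <- function(seed = 7, ...) {
  CohortConfig(nHcSubjects = 2, nMsSubjects = 1,
               protocols = tinyProtocols()["spectralis_a"], seed = seed,
               ...)
}

test_that("layer templates are smooth, bounded and anatomically shaped", {
  g <- gridCoordinates(ScanProtocol("horizontal", 61, 61, 6, 6))
  r <- sqrt(g$x^2 + g$y^2)
  for (layer in retinalLayers()) {
    tmpl <- layerTemplate(layer, g)
    expect_true(all(tmpl >= 0 & tmpl <= 120))
  }
  # the GCL peaks in a perifoveal ring
  gcl <- layerTemplate("GCL", g)
  peak <- r[which.max(gcl)]
  expect_gt(peak, 0.5)
  expect_lt(peak, 2.5)
  # the ONL peaks at the fovea
  onl <- layerTemplate("ONL", g)
  expect_equal(r[which.max(onl)], min(r))
  # GCIP is exactly GCL + IPL
  expect_identical(layerTemplate("GCIP", g),
                   layerTemplate("GCL", g) + layerTemplate("IPL", g))
  # MS thinning affects GCL but not ONL
  expect_true(all(layerTemplate("GCL", g, group = "MS") < gcl))
  expect_identical(layerTemplate("ONL", g, group = "MS"), onl)
  expect_error(layerTemplate("XXX", g), "unknown layer")
})

test_that("the same config and seed reproduce the cohort bit for bit", {
  cfg <- smallConfig()
  s1 <- simulateCohort(cfg)
  s2 <- simulateCohort(cfg)
  expect_length(s1$cohort, (2 * 2 * 3 + 1 * 2 * 2) * 1)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth$eyeOffsets, s2$truth$eyeOffsets)
  # a different seed changes the data
  s3 <- simulateCohort(smallConfig(seed = 8))
  expect_false(identical(s1$cohort, s3$cohort))
})

test_that("correlated fields have unit-accurate marginal variance", {
  g <- gridCoordinates(tinyProtocols()$spectralis_b)
  set.seed(21)
  cells <- replicate(400, correlatedField(g, 5, 0.3)[c(1, 40, 150)])
  sds <- apply(cells, 1, stats::sd)
  expect_true(all(abs(sds - 5) / 5 < 0.15))
  expect_identical(correlatedField(g, 0, 0.3),
                   matrix(0, nrow(g$x), ncol(g$x)))
})

test_that("noise-free cohorts repeat exactly and reach ICC 1, CR 0", {
  cfg <- smallConfig(sigmaOffset = 0, sigmaField = 0, jitterSdMm = 0,
                     hflAmplitude = 0)
  sim <- simulateCohort(cfg)
  tags <- vapply(sim$cohort, function(v)
    paste(v@meta$subjectId, v@meta$eye), character(1))
  for (tag in unique(tags)) {
    reps <- sim$cohort[tags == tag]
    for (v in reps[-1]) expect_identical(v@maps, reps[[1]]@maps)
  }
  tab <- applyAll(builtinEstimates(protocols = tinyProtocols())["A"],
                  sim$cohort)
  rt <- repeatabilityTable(tab)
  expect_true(all(rt$icc == 1))
  expect_true(all(rt$cr == 0))
})

test_that("ANOVA recovers the generator's variance components", {
  # offset-only noise: the estimate collapses to truth + session offset
  cfg <- CohortConfig(nHcSubjects = 100, nMsSubjects = 0,
                      protocols = tinyProtocols()["spectralis_a"],
                      sigmaBetween = c(RNFL = 4, GCL = 4, IPL = 4,
                                       INL = 4, OPL = 4, ONL = 4),
                      sigmaOffset = 1.5, sigmaField = 0, jitterSdMm = 0,
                      hflAmplitude = 0, seed = 31)
  sim <- simulateCohort(cfg)
  tab <- applyAll(builtinEstimates(protocols = tinyProtocols())["A"],
                  sim$cohort)
  cell <- tab[tab$layer == "RNFL", ]
  vc <- onewayAnova(cell$thickness_um,
                    paste(cell$subject_id, cell$eye))
  sigmaWHat <- sqrt(vc@MSW)
  sigmaBHat <- sqrt(max((vc@MSB - vc@MSW) / vc@kEff, 0))
  expect_lt(abs(sigmaWHat - 1.5) / 1.5, 0.10)
  expect_lt(abs(sigmaBHat - 4) / 4, 0.10)
  expect_equal(sim$truth$trueICCOffsetOnly[["RNFL"]], 16 / 18.25,
               tolerance = 1e-12)
})

test_that("the HFL artifact shifts OPL against ONL, conserving their sum", {
  p <- ScanProtocol("vertical", 25, 64, 6, 6)
  v <- constantLayerMaps(p, value = 30)
  opl <- getLayerMap(v, "OPL")
  onl <- getLayerMap(v, "ONL")
  # zero beam offset: identity
  r0 <- hflArtifact(opl, onl, theta = 0)
  expect_identical(thicknessValues(r0$opl), thicknessValues(opl))
  # conservation wherever the floor is not hit
  r <- hflArtifact(opl, onl, theta = 0.4, amplitude = 60)
  sums <- thicknessValues(r$opl) + thicknessValues(r$onl)
  noFloor <- thicknessValues(r$opl) > 0.5 & thicknessValues(r$onl) > 0.5
  expect_true(any(noFloor))
  expect_equal(sums[noFloor], (thicknessValues(opl) +
                                 thicknessValues(onl))[noFloor],
               tolerance = 1e-9)
  # antisymmetry along the beam-offset direction
  expect_equal(r$delta, -r$delta[, rev(seq_len(64))][rev(seq_len(25)), ],
               tolerance = 1e-9)
  # opposite beam offsets differ by tens of micrometres; the maximum is
  # attained on some single B-scan and bounded by 2 A theta
  rNeg <- hflArtifact(opl, onl, theta = -0.4, amplitude = 60)
  dOPL <- abs(thicknessValues(r$opl) - thicknessValues(rNeg$opl))
  expect_gt(max(dOPL), 20)
  expect_lt(max(dOPL), 2 * 60 * 0.4)
  # misaligned grids are rejected
  onlBad <- getLayerMap(constantLayerMaps(
    ScanProtocol("vertical", 25, 32, 6, 6), 30), "ONL")
  expect_error(hflArtifact(opl, onlBad, 0.2), "aligned")
})

test_that("the artifact degrades OPL ICC but not the OPL+ONL composite", {
  # noise and amplitude chosen so the 0.5 um floor is never hit and the
  # OPL + ONL sum is conserved exactly
  cfgOff <- CohortConfig(nHcSubjects = 8, nMsSubjects = 0,
                         protocols = tinyProtocols()["spectralis_a"],
                         sigmaField = 2, hflAmplitude = 0, seed = 55)
  cfgOn <- CohortConfig(nHcSubjects = 8, nMsSubjects = 0,
                        protocols = tinyProtocols()["spectralis_a"],
                        sigmaField = 2, hflAmplitude = 40, seed = 55)
  # the artifact is antisymmetric across the fovea, so it cancels in
  # fovea-centred area means; its ICC damage shows on the sparse-point
  # estimate J, which samples one side of the fovea
  reg <- builtinEstimates(protocols = tinyProtocols())["J"]
  iccOf <- function(tab, layer) {
    cell <- tab[tab$layer == layer, ]
    iccOneway(onewayAnova(cell$thickness_um,
                          paste(cell$subject_id, cell$eye)))@icc
  }
  tabOff <- applyAll(reg, simulateCohort(cfgOff)$cohort)
  tabOn <- applyAll(reg, simulateCohort(cfgOn)$cohort)
  # same seed: everything but the OPL/ONL pair is untouched
  expect_identical(tabOff[tabOff$layer == "INL", ],
                   tabOn[tabOn$layer == "INL", ])
  expect_lt(iccOf(tabOn, "OPL"), iccOf(tabOff, "OPL"))
  # the composite OPL+ONL record is conserved by construction
  sumOn <- tabOn[tabOn$layer == "OPL", "thickness_um"] +
    tabOn[tabOn$layer == "ONL", "thickness_um"]
  sumOff <- tabOff[tabOff$layer == "OPL", "thickness_um"] +
    tabOff[tabOff$layer == "ONL", "thickness_um"]
  expect_equal(sumOn, sumOff, tolerance = 1e-9)
})

test_that("all simulated thickness values are nonnegative", {
  cfg <- smallConfig(sigmaField = 20)  # deliberately violent noise
  sim <- simulateCohort(cfg)
  for (v in sim$cohort)
    for (m in v@maps) expect_true(all(m >= 0))
})

test_that("Monte-Carlo within-variance tracks the offset-only closed form", {
  cfg <- smallConfig(sigmaField = 0, jitterSdMm = 0, hflAmplitude = 0,
                     sigmaOffset = 2)
  d <- builtinEstimates(protocols = tinyProtocols())$A
  mc <- estimateWithinVariance(cfg, d, "RNFL", nsim = 300)
  expect_lt(abs(sqrt(mc$varWithin) - 2) / 2, 0.15)
})
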