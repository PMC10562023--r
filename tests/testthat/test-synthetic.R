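# synthetic cohort generator: invariants, determinism, error-response

test_that("generated plans satisfy the arc-plan contract", {
  for (seed in c(1, 2)) {
    p <- generatePlan(planGenParams(nControlPoints = 60, seed = seed))
    expect_true(validObject(p, test = FALSE))
    gap <- apertureGap(p)
    expect_true(all(gap >= 0))
    expect_true(all(diff(metersetWeights(p)) >= 0))
    # designated always-closed pairs never open
    expect_true(all(gap[vmatqa:::.alwaysClosedSet(5L), ] == 0))
    # leaf-motion smoothness: no leaf jumps more than the configured travel
    expect_lte(max(abs(t(diff(t(bankA(p)))))), 3 + 1e-9)
    expect_lte(max(abs(t(diff(t(bankB(p)))))), 3 + 1e-9)
  }
  expect_identical(generatePlan(planGenParams(seed = 5)),
                   generatePlan(planGenParams(seed = 5)))
  expect_false(identical(generatePlan(planGenParams(seed = 5)),
                         generatePlan(planGenParams(seed = 6))))
  expect_error(planGenParams(meanGap = -2), "infeasible")
})

test_that("zero aperture jitter yields a static aperture", {
  p <- generatePlan(planGenParams(nControlPoints = 30, gapJitterSd = 0,
                                  seed = 4))
  gap <- apertureGap(p)
  expect_true(all(abs(gap - gap[, 1]) < 1e-9))
})

test_that("all-closed plan deposits no dose; zero error reproduces the planned dose", {
  d0 <- simulateDose(closedPlan(ncp = 5L), grid = doseGridSpec(20, 20, 10))
  expect_true(all(doseArray(d0) == 0))

  p <- generatePlan(planGenParams(nControlPoints = 30, seed = 3))
  planned <- simulateDose(p, grid = doseGridSpec(24, 24, 12))
  again <- simulateDose(p, error = errorModel(), grid = doseGridSpec(24, 24, 12))
  expect_identical(doseArray(planned), doseArray(again))
  kz <- 6
  v <- gprVector(doseArray(planned)[, , kz], doseArray(again)[, , kz],
                 spacing = 2)
  expect_equal(unname(v), rep(100, 9))
})

test_that("mean GPR decreases as leaf noise grows", {
  levels <- c(0, 0.5, 1, 2)
  gs <- doseGridSpec(28, 28, 12)
  m <- sapply(1:8, function(seed) {
    p <- generatePlan(planGenParams(nControlPoints = 30, seed = seed,
                                    meanGap = 16))
    ref <- doseArray(simulateDose(p, grid = gs))[, , 6]
    sapply(levels, function(s) {
      if (s == 0) return(100)
      e <- errorModel(leafNoiseSd = s, seed = 900 + seed)
      gpr(gammaMap(ref, doseArray(simulateDose(p, e, gs))[, , 6], 2, 2,
                   spacing = 2))
    })
  })
  expect_true(all(diff(rowMeans(m)) <= 0))
  expect_lt(rowMeans(m)[4], rowMeans(m)[1])
})

test_that("datasets have the advertised structure and reproduce byte-identically", {
  ds <- smallStudy(nPlans = 8, seed = 3)
  expect_s4_class(ds, "QaDataset")
  expect_equal(dim(qaLabels(ds)), c(8L, 9L))
  expect_equal(dim(mapValues(ds@mlpms[[1]])), c(110L, 52L))
  expect_equal(dim(ds@planes[[1]]@sagittal), c(52L, 52L))
  expect_true(all(apply(qaLabels(ds), 1, function(g)
    vmatqa:::.checkGprLabel(setNames(g, colnames(qaLabels(ds)))))))

  ds2 <- smallStudy(nPlans = 8, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".rds")
  f2 <- withr::local_tempfile(fileext = ".rds")
  writeQaDataset(ds, f1); writeQaDataset(ds2, f2)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
  back <- readQaDataset(f1)
  expect_equal(qaLabels(back), qaLabels(ds))
  expect_error(generateDataset(nPlans = 4), "at least 8")
})

test_that("an error-free cohort labels every plan 100% and is flagged as constant", {
  expect_warning(
    ds <- generateDataset(
      nPlans = 8,
      planParams = planGenParams(nControlPoints = 30),
      errorSampler = function(n) data.frame(
        systematicOffset = rep(0, n), leafNoiseSd = rep(0, n),
        outputScale = rep(1, n), blurSd = rep(0, n)),
      grid = doseGridSpec(24, 24, 12),
      targetShapes = list(sagittal = c(52L, 52L), coronal = c(52L, 52L),
                          axial = c(52L, 52L)),
      mlpmShape = c(110L, 52L), seed = 2),
    "constant labels")
  expect_true(all(qaLabels(ds) == 100))
  expect_length(ds@flags, 1L)
})

test_that("stronger applied leaf perturbations go with lower 2%/2mm GPR across a cohort", {
  ds <- generateDataset(
    nPlans = 56,
    planParams = planGenParams(nControlPoints = 40),
    grid = doseGridSpec(32, 32, 16),
    targetShapes = list(sagittal = c(52L, 52L), coronal = c(52L, 52L),
                        axial = c(52L, 52L)),
    mlpmShape = c(110L, 52L), seed = 9)
  rho <- cor(qaMeta(ds)$meanAbsPerturbation, qaLabels(ds)[, "2%/2mm"],
             method = "spearman")
  expect_lt(rho, 0)
})
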