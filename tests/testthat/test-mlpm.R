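# leaf-position matrix and MLC leaf-position map construction

test_that("all-closed plan gives a matrix equal to the junction everywhere and a zero map", {
  jun <- seq(-10, 10, length.out = 60)
  p <- closedPlan(ncp = 2L, jun = jun)
  m <- buildLeafMatrix(p)
  expect_equal(dim(mapValues(m)), c(120L, 2L))
  expect_equal(mapValues(m), rbind(matrix(jun, 60, 2), matrix(jun, 60, 2)),
               ignore_attr = TRUE)
  expect_equal(closedReference(m), jun)
  map <- buildMlpm(m, excluded = integer(), fixedShape = c(120L, 4L))
  expect_true(all(mapValues(map) == 0))
})

test_that("hand-worked toy: symmetric opening maps to half-gap displacements on both bank rows", {
  m <- buildLeafMatrix(toyPlan(jun30 = 2))
  # every pair except 30 is always closed
  expect_equal(findAlwaysClosedPairs(list(m)), setdiff(1:60, 30L))
  map <- buildMlpm(m, excluded = setdiff(1:60, 30L), fixedShape = c(2L, 3L))
  expect_equal(mapValues(map), rbind(c(0, 2.5, 5), c(0, 2.5, 5)),
               ignore_attr = TRUE)
  # zero-padding on the control-point axis fabricates no motion
  wide <- buildMlpm(m, excluded = setdiff(1:60, 30L), fixedShape = c(2L, 6L))
  expect_equal(mapValues(wide)[, 1:3], mapValues(map), ignore_attr = TRUE)
  expect_true(all(mapValues(wide)[, 4:6] == 0))
})

test_that("always-closed detection honours 'all cases' across the dataset", {
  pinned <- c(1:5, 56:60)
  mk <- function(seed, openPairs) {
    p <- closedPlan(ncp = 4L)
    set.seed(seed)
    for (q in openPairs) {
      g <- runif(4, 1, 10)
      p@bankA[q, ] <- -g / 2
      p@bankB[q, ] <- g / 2
    }
    buildLeafMatrix(p)
  }
  ms <- list(mk(1, setdiff(6:55, 9L)), mk(2, setdiff(6:55, 9L)))
  # pair 9 closed in these two plans plus the 10 pinned pairs
  expect_equal(findAlwaysClosedPairs(ms), sort(c(pinned, 9L)))
  # brute-force check over all pairs x control points
  brute <- which(vapply(1:60, function(q) {
    all(vapply(ms, function(m) {
      v <- mapValues(m)
      all(v[60 + q, ] - v[q, ] <= 0.5)
    }, logical(1)))
  }, logical(1)))
  expect_equal(findAlwaysClosedPairs(ms), brute)
  # one plan opening pair 9 once rescues it
  m3 <- mk(3, 9L)
  expect_equal(findAlwaysClosedPairs(c(ms, list(m3))), pinned)
  # every pair opening somewhere -> empty set
  allOpen <- mk(4, 1:60)
  expect_length(findAlwaysClosedPairs(list(allOpen)), 0L)
  expect_error(findAlwaysClosedPairs(list()), "at least one")
})

test_that("default synthetic plans give the standard 110 x 178 map", {
  p <- generatePlan(planGenParams(seed = 21))
  m <- buildLeafMatrix(p)
  map <- buildMlpm(m, excluded = vmatqa:::.alwaysClosedSet(5L))
  expect_equal(dim(mapValues(map)), c(110L, 178L))
  expect_equal(nControlPoints(map), 178L)
  expect_true(all(mapValues(map) >= 0))
})

test_that("wrong exclusion set for the configured shape is a configuration error", {
  m <- buildLeafMatrix(closedPlan())
  expect_error(buildMlpm(m, excluded = 1:4, fixedShape = c(110L, 178L)),
               "configuration error")
  expect_error(buildMlpm(m, excluded = c(0L, 61L), fixedShape = c(116L, 178L)),
               "1..60")
  p <- generatePlan(planGenParams(nControlPoints = 200L, seed = 1))
  expect_error(buildMlpm(buildLeafMatrix(p), excluded = integer(),
                         fixedShape = c(120L, 178L)), "more than")
})

test_that("column permutation of control points permutes the map columns identically", {
  p <- generatePlan(planGenParams(nControlPoints = 20L, seed = 5))
  m <- buildLeafMatrix(p)
  perm <- sample(20)
  m2 <- m
  slot(m2, "values") <- mapValues(m)[, perm]
  a <- buildMlpm(m, excluded = vmatqa:::.alwaysClosedSet(5L),
                 fixedShape = c(110L, 20L))
  b <- buildMlpm(m2, excluded = vmatqa:::.alwaysClosedSet(5L),
                 fixedShape = c(110L, 20L))
  expect_equal(mapValues(b), mapValues(a)[, perm], ignore_attr = TRUE)
})

test_that("monotone opening: uniformly wider apertures never shrink the map total", {
  base <- closedPlan(ncp = 5L)
  set.seed(8)
  g <- matrix(runif(60 * 5, 0, 12), 60, 5)
  wide <- narrow <- base
  narrow@bankA <- base@bankA - g / 2; narrow@bankB <- base@bankB + g / 2
  wide@bankA <- base@bankA - g / 2 - 1; wide@bankB <- base@bankB + g / 2 + 1
  mapN <- buildMlpm(buildLeafMatrix(narrow), fixedShape = c(120L, 5L))
  mapW <- buildMlpm(buildLeafMatrix(wide), fixedShape = c(120L, 5L))
  expect_gte(sum(mapValues(mapW)), sum(mapValues(mapN)))
})

test_that("closed leaves stay exactly zero in the map", {
  p <- generatePlan(planGenParams(nControlPoints = 15L, seed = 9))
  m <- buildLeafMatrix(p)
  map <- buildMlpm(m, excluded = integer(), fixedShape = c(120L, 30L))
  closedRows <- vmatqa:::.alwaysClosedSet(5L)
  expect_true(all(mapValues(map)[c(closedRows, 60 + closedRows), ] == 0))
})
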