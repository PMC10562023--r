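# in-code fixtures shared across test files

# plan with every pair closed at a given junction contour
closedPlan <- function(ncp = 2L, jun = rep(0, 60)) {
  m <- matrix(jun, 60, ncp)
  ArcPlan(planId = "closed", gantryAngle = seq(181, 179, length.out = ncp) %% 360,
          metersetWeight = seq(0, 1, length.out = ncp),
          bankA = m, bankB = m)
}

# the hand-worked toy: all pairs closed except pair 30, which opens
# symmetrically about its junction (gap 0 -> 5 -> 10 mm)
toyPlan <- function(jun30 = 2) {
  p <- closedPlan(ncp = 3L)
  half <- c(0, 2.5, 5)
  p@bankA[30, ] <- jun30 - half
  p@bankB[30, ] <- jun30 + half
  p
}

# small random dose pair with localized discrepancies
randomDosePair <- function(n = 12L, seed = 1, bumps = 3L, spacing = 1) {
  set.seed(seed)
  x <- seq_len(n)
  ref <- outer(exp(-(x - n / 2)^2 / (n / 1.5)^2),
               exp(-(x - n / 2)^2 / (n / 1.5)^2)) + 0.05
  ref <- ref / max(ref)
  ev <- ref * (1 + matrix(rnorm(n * n, 0, 0.01), n, n))
  for (k in seq_len(bumps)) {
    i <- sample(n, 1); j <- sample(n, 1)
    ev[i, j] <- ev[i, j] * runif(1, 0.9, 1.1)
  }
  list(ref = ref, ev = ev, spacing = spacing)
}

# reduced-scale study settings used by training-level tests: smallest input
# images the three-stage branches accept, coarse dose grid, short arcs
smallStudy <- function(nPlans = 8L, seed = 1L, nCp = 40L) {
  generateDataset(
    nPlans = nPlans,
    planParams = planGenParams(nControlPoints = nCp),
    grid = doseGridSpec(32, 32, 16),
    targetShapes = list(sagittal = c(52L, 52L), coronal = c(52L, 52L),
                        axial = c(52L, 52L)),
    mlpmShape = c(110L, 52L), seed = seed)
}

smallShapes <- function()
  list(sagittal = c(52L, 52L), coronal = c(52L, 52L), axial = c(52L, 52L),
       mlpm = c(110L, 52L))
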