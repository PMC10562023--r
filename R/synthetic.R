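# Synthetic study cohort: single-arc plans with smooth random leaf
# trajectories, a toy arc-accumulation dose engine, a parameterized
# delivery-error model, and gamma-derived GPR labels. This module exists so
# the whole prediction pipeline (maps -> planes -> network -> evaluation) can
# be exercised and validated end to end without clinical data; it emulates
# the statistical structure QA data shows (labels mostly high with a long
# lower tail, complexity-dependent sensitivity to delivery error), not
# radiation transport.

#' Plan generator parameters
#'
#' @param nControlPoints control points along the arc (default 178, a full
#'   arc).
#' @param nAlwaysClosedPairs leaf pairs pinned closed for the whole dataset
#'   (default 5, giving a 110-row leaf-position map); split between the top
#'   and bottom of the banks.
#' @param meanGap target mean aperture gap, mm (aperture complexity: smaller
#'   is more modulated).
#' @param gapJitterSd per-control-point jitter SD of the aperture walk, mm;
#'   0 gives a static aperture.
#' @param maxTravelPerCp leaf-motion smoothness: maximum leaf travel between
#'   adjacent control points, mm.
#' @param seed plan seed.
#' @return list of class `PlanGenParams`.
#' @export
planGenParams <- function(nControlPoints = 178L, nAlwaysClosedPairs = 5L,
                          meanGap = 20, gapJitterSd = 4, maxTravelPerCp = 3,
                          seed = 1L) {
  if (meanGap <= 0) stop("infeasible parameters: meanGap must be positive")
  if (maxTravelPerCp <= 0)
    stop("infeasible parameters: maxTravelPerCp must be positive")
  if (gapJitterSd < 0) stop("infeasible parameters: negative jitter SD")
  structure(list(nControlPoints = as.integer(nControlPoints),
                 nAlwaysClosedPairs = as.integer(nAlwaysClosedPairs),
                 meanGap = meanGap, gapJitterSd = gapJitterSd,
                 maxTravelPerCp = maxTravelPerCp, seed = as.integer(seed)),
            class = "PlanGenParams")
}

.alwaysClosedSet <- function(n) {
  nTop <- ceiling(n / 2)
  c(seq_len(nTop), .N_LEAF_PAIRS - (n - nTop) + seq_len(n - nTop))
}

#' Generate a synthetic single-arc plan
#'
#' Leaf trajectories are bounded random walks: each open pair follows an
#' elliptically tapered target gap (so central pairs open widest, as for a
#' central target) with seeded jitter on both the gap and the aperture
#' centre, clipped so no leaf moves more than `maxTravelPerCp` between
#' control points and no gap goes negative. Designated always-closed pairs
#' never open. Deterministic given the seed.
#'
#' @param params a [planGenParams()].
#' @return an [ArcPlan-class].
#' @export
generatePlan <- function(params = planGenParams()) {
  ncp <- params$nControlPoints
  set.seed(params$seed)
  closed <- .alwaysClosedSet(params$nAlwaysClosedPairs)
  # smooth junction contour across pairs (closed-state coordinate)
  jun <- as.numeric(stats::filter(rnorm(.N_LEAF_PAIRS, 0, 3),
                                  rep(1 / 5, 5), circular = TRUE))
  p_idx <- seq_len(.N_LEAF_PAIRS)
  taper <- sqrt(pmax(0, 1 - ((p_idx - (.N_LEAF_PAIRS + 1) / 2) /
                               (0.47 * .N_LEAF_PAIRS))^2))
  target <- pmax(params$meanGap * taper, 5)
  target[closed] <- 0

  gap <- matrix(0, .N_LEAF_PAIRS, ncp)
  ctr <- matrix(0, .N_LEAF_PAIRS, ncp)
  open <- setdiff(p_idx, closed)
  mt <- params$maxTravelPerCp
  js <- params$gapJitterSd
  gap[open, 1] <- pmax(target[open] + rnorm(length(open), 0, js), 0)
  ctr[open, 1] <- rnorm(length(open), 0, 2)
  if (ncp > 1) for (j in 2:ncp) {
    dg <- pmin(pmax(rnorm(length(open), 0, js / 3) +
                      0.1 * (target[open] - gap[open, j - 1]), -mt), mt)
    dc <- pmin(pmax(rnorm(length(open), 0, js / 4), -mt / 2), mt / 2)
    gap[open, j] <- pmax(gap[open, j - 1] + dg, 0)
    ctr[open, j] <- ctr[open, j - 1] + dc
  }
  bankA <- jun + ctr - gap / 2
  bankB <- jun + ctr + gap / 2
  mu_inc <- runif(ncp - 1, 0.5, 1.5)
  ArcPlan(planId = sprintf("synth-%08d", params$seed),
          gantryAngle = (181 + (seq_len(ncp) - 1) * (358 / (ncp - 1))) %% 360,
          metersetWeight = c(0, cumsum(mu_inc)) / sum(mu_inc),
          bankA = bankA, bankB = bankB, isocenter = c(0, 0, 0),
          prescriptionDose = 74)
}

#' Delivery-error model
#'
#' Parameterizes how the "delivered" dose differs from the planned one:
#' a systematic leaf offset applied symmetrically to both banks (positive
#' values open every aperture by the offset on each side, the classic
#' dosimetric-leaf-gap-type error, negative values close it), per-leaf
#' position noise held fixed over the arc (a calibration-type error, so it
#' does not average out over control points), a global output (dose
#' scaling) factor, and extra spatial blurring. The all-zero model
#' reproduces the planned dose exactly.
#'
#' @param systematicOffset systematic leaf offset, mm; bank A shifts by
#'   `-offset` and bank B by `+offset`, widening (or narrowing) the gap by
#'   twice the offset.
#' @param leafNoiseSd SD of the per-leaf position noise, mm (drawn once per
#'   leaf and bank, applied at every control point).
#' @param outputScale multiplicative dose scaling (1 = none).
#' @param blurSd extra Gaussian blur of the delivered dose, mm.
#' @param seed noise seed.
#' @return list of class `ErrorModel`.
#' @export
errorModel <- function(systematicOffset = 0, leafNoiseSd = 0,
                       outputScale = 1, blurSd = 0, seed = 1L) {
  if (leafNoiseSd < 0 || blurSd < 0 || outputScale <= 0)
    stop("invalid error-model parameters")
  structure(list(systematicOffset = systematicOffset,
                 leafNoiseSd = leafNoiseSd, outputScale = outputScale,
                 blurSd = blurSd, seed = as.integer(seed)),
            class = "ErrorModel")
}

.isZeroError <- function(e) {
  is.null(e) || (e$systematicOffset == 0 && e$leafNoiseSd == 0 &&
                 e$outputScale == 1 && e$blurSd == 0)
}

#' Apply a delivery-error model to a plan's leaf positions
#'
#' The systematic offset acts like a dynamic leaf lag: its local magnitude
#' scales with how fast the leaf is travelling at that control point (a
#' stationary leaf sees half the nominal offset, a leaf at the 3 mm/CP
#' travel limit twice), so heavily modulated plans accumulate more delivery
#' error -- the behaviour real MLC delivery shows. Per-leaf noise is added
#' on top, then tip crossings are repaired by snapping the offending pair to
#' its midpoint. Returns the perturbed plan and the mean absolute leaf
#' perturbation actually applied (mm).
#'
#' @param plan an [ArcPlan-class].
#' @param error an [errorModel()].
#' @return list with `plan` (perturbed [ArcPlan-class]) and
#'   `meanAbsPerturbation` (mm).
#' @export
applyDeliveryError <- function(plan, error) {
  if (.isZeroError(error))
    return(list(plan = plan, meanAbsPerturbation = 0))
  a <- bankA(plan); b <- bankB(plan)
  set.seed(error$seed)
  speedFactor <- function(m) {
    v <- abs(cbind(m[, 2] - m[, 1], t(diff(t(m))))) # mm moved entering each CP
    0.5 + 1.5 * pmin(v / 3, 1)
  }
  noise <- function() if (error$leafNoiseSd > 0)
    rnorm(.N_LEAF_PAIRS, 0, error$leafNoiseSd) else 0
  da <- -error$systematicOffset * speedFactor(a) + noise()
  db <- error$systematicOffset * speedFactor(b) + noise()
  a2 <- a + da; b2 <- b + db
  crossed <- b2 < a2
  if (any(crossed)) {
    mid <- (a2 + b2) / 2
    a2[crossed] <- mid[crossed]; b2[crossed] <- mid[crossed]
  }
  pert <- mean(abs(c(a2 - a, b2 - b)))
  out <- plan
  out@bankA <- a2; out@bankB <- b2
  list(plan = out, meanAbsPerturbation = pert)
}

# separable Gaussian blur of a 3D array; sigma in mm, zero-padded edges
.gaussBlur3d <- function(arr, sigma, spacing) {
  for (ax in 1:3) {
    s <- sigma / spacing[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- rbind(matrix(0, r, prod(d[-1])),
               matrix(a, d[1], prod(d[-1])),
               matrix(0, r, prod(d[-1])))
    f <- stats::filter(m, k, sides = 2)
    f <- f[(r + 1):(r + d[1]), , drop = FALSE]
    a <- array(f, d)
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Grid specification for the toy dose engine
#'
#' @param nx,ny,nz voxel counts; @param spacing isotropic spacing, mm.
#' @export
doseGridSpec <- function(nx = 56L, ny = 56L, nz = 20L, spacing = 1.5) {
  list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
       spacing = spacing)
}

#' Toy forward dose model for a synthetic arc
#'
#' Accumulates binary aperture fluence over the arc: at each control-point
#' interval, voxels whose beam-axis coordinate `x cos(theta) + y sin(theta)`
#' lies inside the leaf-pair aperture covering their z position receive the
#' interval's meterset weight; the accumulated field is then blurred with a
#' Gaussian kernel (sigma 1.5 mm) to mimic scatter/penumbra. Leaf pairs map to
#' z bands of 2.5 mm. With an [errorModel()], leaf positions are perturbed
#' and the output scaled/blurred first; the zero error model reproduces the
#' planned dose exactly.
#'
#' @param plan an [ArcPlan-class].
#' @param error optional [errorModel()].
#' @param grid a [doseGridSpec()].
#' @param kernelSd base penumbra blur, mm.
#' @return a [DoseGrid-class] centred on the plan isocenter.
#' @export
simulateDose <- function(plan, error = NULL, grid = doseGridSpec(),
                         kernelSd = 1.5) {
  scale <- 1
  if (!.isZeroError(error)) {
    pe <- applyDeliveryError(plan, error)
    plan <- pe$plan
    scale <- error$outputScale
  }
  sp <- grid$spacing
  xs <- (seq_len(grid$nx) - (grid$nx + 1) / 2) * sp + plan@isocenter[1]
  ys <- (seq_len(grid$ny) - (grid$ny + 1) / 2) * sp + plan@isocenter[2]
  zs <- (seq_len(grid$nz) - (grid$nz + 1) / 2) * sp + plan@isocenter[3]
  pair_of_z <- round((zs - plan@isocenter[3]) / 2.5 + (.N_LEAF_PAIRS + 1) / 2)
  dose <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  a <- bankA(plan); b <- bankB(plan)
  w <- metersetWeights(plan)
  th <- gantryAngles(plan) * pi / 180
  ncp <- nControlPoints(plan)
  upairs <- unique(pair_of_z[pair_of_z >= 1 & pair_of_z <= .N_LEAF_PAIRS])
  for (j in 2:ncp) {
    dw <- w[j] - w[j - 1]
    if (dw <= 0) next
    tmid <- (th[j] + th[j - 1]) / 2
    tv <- outer(xs, ys, function(x, y) x * cos(tmid) + y * sin(tmid))
    am <- (a[, j] + a[, j - 1]) / 2
    bm <- (b[, j] + b[, j - 1]) / 2
    for (p in upairs) {
      if (bm[p] - am[p] <= 0) next
      mask <- tv >= am[p] & tv <= bm[p]
      if (!any(mask)) next
      sl <- which(pair_of_z == p)
      dose[, , sl] <- dose[, , sl] + rep(dw * mask, times = length(sl))
    }
  }
  sigma <- sqrt(kernelSd^2 + if (!.isZeroError(error)) error$blurSd^2 else 0)
  dose <- .gaussBlur3d(dose, sigma, rep(sp, 3))
  dose[dose < 0] <- 0
  DoseGrid(dose * scale,
           origin = c(xs[1], ys[1], zs[1]), spacing = rep(sp, 3))
}
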