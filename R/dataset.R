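# Labeled synthetic dataset: per plan an MLC leaf-position map, the
# fixed-size dose planes of the planned distribution, and the nine-criterion
# GPR label obtained by gamma-comparing the planned against the
# error-perturbed "delivered" dose on the central axial detector plane.

#' Labeled QA dataset
#'
#' Container produced by [generateDataset()] (or assembled from clinical
#' ingestion): per-plan network inputs, nine-criterion GPR labels, the
#' per-plan generation/error metadata, and the dataset-wide normalization
#' constants used to map inputs to `[0, 1]`.
#'
#' @slot mlpms list of [MLPMap-class], one per plan.
#' @slot planes list of [DosePlaneSet-class], one per plan.
#' @slot labels `n x 9` matrix of GPRs (%), columns named by criterion.
#' @slot meta per-plan data.frame (ids, complexity, error magnitudes, mean
#'   applied leaf perturbation).
#' @slot norm list of normalization constants (`mlpm`, `dose`, `surface`).
#' @slot excludedPairs always-closed leaf pairs removed from the maps.
#' @slot flags character vector of degeneracy warnings.
#' @export
setClass("QaDataset",
  representation(mlpms = "list", planes = "list", labels = "matrix",
                 meta = "data.frame", norm = "list",
                 excludedPairs = "integer", flags = "character"))

setValidity("QaDataset", function(object) {
  n <- nrow(object@labels)
  if (length(object@mlpms) != n || length(object@planes) != n ||
      nrow(object@meta) != n)
    return("per-plan components disagree in length")
  if (ncol(object@labels) != 9L)
    return("labels must have nine criterion columns")
  TRUE
})

setMethod("show", "QaDataset", function(object) {
  n <- nrow(object@labels)
  cat(sprintf("QaDataset: %d plans, MLPM %s, labels %d x 9\n", n,
              if (n) paste(dim(mapValues(object@mlpms[[1]])), collapse = " x ")
              else "-", n))
  if (n) {
    rng <- range(object@labels)
    cat(sprintf("  GPR range %.1f..%.1f %%; excluded pairs: %s\n", rng[1],
                rng[2], paste(object@excludedPairs, collapse = ", ")))
  }
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})

#' @param x a `QaDataset`.
#' @rdname QaDataset-class
#' @export
qaLabels <- function(x) x@labels
#' @rdname QaDataset-class
#' @export
qaMeta <- function(x) x@meta

#' Sampler for per-plan delivery-error magnitudes
#'
#' Draws each plan's [errorModel()] parameters from a mixture: mostly small
#' errors with an occasional large one, so the GPR distribution acquires the
#' long lower tail patient QA data shows.
#'
#' @param probLarge probability of a large-error plan.
#' @param smallNoise mean/SD of the folded-normal leaf-noise SD for ordinary
#'   plans, mm.
#' @param largeNoise range of the leaf-noise SD for large-error plans, mm.
#' @param offset mean/SD of the folded-normal magnitude of the systematic
#'   (aperture-opening, velocity-scaled) leaf offset, mm; the sign is random
#'   per plan.
#' @param scaleSd SD of the output scaling factor around 1.
#' @param blurSdMax upper bound of the extra delivered-dose blur, mm.
#' @return a function `f(n)` returning an `n`-row data.frame of error
#'   parameters.
#' @export
errorDistribution <- function(probLarge = 0.12, smallNoise = c(0.6, 0.15),
                              largeNoise = c(0.9, 1.2), offset = c(0.3, 0.08),
                              scaleSd = 0.006, blurSdMax = 0.5) {
  function(n) {
    large <- runif(n) < probLarge
    noise <- abs(rnorm(n, smallNoise[1], smallNoise[2]))
    noise[large] <- runif(sum(large), largeNoise[1], largeNoise[2])
    data.frame(systematicOffset = sample(c(-1, 1), n, TRUE) *
                 abs(rnorm(n, offset[1], offset[2])),
               leafNoiseSd = noise,
               outputScale = pmax(1 + rnorm(n, 0, scaleSd), 0.5),
               blurSd = runif(n, 0, blurSdMax))
  }
}

#' Generate a labeled synthetic dataset
#'
#' For each plan: draw a complexity level (target mean aperture gap), build
#' the plan, simulate the planned dose and an error-perturbed delivered
#' dose, gamma-compare them on the central axial detector plane (global,
#' 10% threshold) to obtain the nine-criterion GPR label, and build the MLPM
#' (always-closed pairs determined across the whole generated cohort) and
#' the fixed-size dose planes of the planned grid.
#'
#' @param nPlans number of plans (at least 8).
#' @param planParams template [planGenParams()]; per-plan seeds and mean
#'   gaps override its `seed`/`meanGap`.
#' @param errorSampler a sampler as returned by [errorDistribution()].
#' @param complexityRange range of per-plan target mean gaps, mm.
#' @param grid a [doseGridSpec()] for the toy dose engine.
#' @param targetShapes plane shapes as in [extractIsocenterPlanes()]; may
#'   contain an extra `surface = c(rows, cols)` to also sample the
#'   cylindrical surface map.
#' @param mlpmShape fixed MLPM shape `c(rows, cols)`.
#' @param surfaceRadius cylinder radius (mm) for the surface map; default
#'   fits inside the toy grid.
#' @param smallFieldDeficit `c(amplitude, scale mm)`: the delivered output
#'   of a plan is additionally reduced by
#'   `amplitude * exp(-meanApertureGap / scale)`, emulating the small-field
#'   output deficit (source occlusion, interleaf effects) that delivery
#'   shows but the planning calculation underestimates for heavily
#'   modulated apertures. Deterministic given the plan; set the amplitude
#'   to 0 to disable.
#' @param seed master seed; everything is deterministic given it.
#' @return a [QaDataset-class].
#' @export
generateDataset <- function(nPlans = 96L, planParams = planGenParams(),
                            errorSampler = errorDistribution(),
                            complexityRange = c(10, 34),
                            grid = doseGridSpec(),
                            targetShapes = list(sagittal = c(68L, 146L),
                                                coronal = c(64L, 200L),
                                                axial = c(143L, 242L)),
                            mlpmShape = c(110L, 178L),
                            surfaceRadius = NULL,
                            smallFieldDeficit = c(0.05, 15), seed = 1L) {
  if (nPlans < 8L) stop("need at least 8 plans")
  set.seed(seed)
  planSeeds <- sample.int(2^31 - 2, nPlans)
  errSeeds <- sample.int(2^31 - 2, nPlans)
  meanGaps <- runif(nPlans, complexityRange[1], complexityRange[2])
  errs <- errorSampler(nPlans)

  plans <- vector("list", nPlans)
  labels <- matrix(NA_real_, nPlans, 9L)
  planes <- vector("list", nPlans)
  pert <- numeric(nPlans)
  wantSurface <- !is.null(targetShapes$surface)
  if (is.null(surfaceRadius))
    surfaceRadius <- 0.4 * min(grid$nx, grid$ny) * grid$spacing
  for (i in seq_len(nPlans)) {
    pp <- planParams
    pp$seed <- planSeeds[i]; pp$meanGap <- meanGaps[i]
    plan <- generatePlan(pp)
    plans[[i]] <- plan
    # the small-field output deficit is itself a delivery error: a plan with
    # an all-zero sampled error keeps the exact planned dose (zero-error
    # identity), so the deficit only applies when delivery error exists
    zeroErr <- errs$systematicOffset[i] == 0 && errs$leafNoiseSd[i] == 0 &&
      errs$outputScale[i] == 1 && errs$blurSd[i] == 0
    gap <- apertureGap(plan)
    mg <- mean(gap[gap > 0])
    deficit <- if (zeroErr) 0 else
      smallFieldDeficit[1] * exp(-mg / smallFieldDeficit[2])
    err <- errorModel(systematicOffset = errs$systematicOffset[i],
                      leafNoiseSd = errs$leafNoiseSd[i],
                      outputScale = errs$outputScale[i] * (1 - deficit),
                      blurSd = errs$blurSd[i], seed = errSeeds[i])
    errs$outputScale[i] <- errs$outputScale[i] * (1 - deficit)
    planned <- simulateDose(plan, error = NULL, grid = grid)
    delivered <- simulateDose(plan, error = err, grid = grid)
    pert[i] <- applyDeliveryError(plan, err)$meanAbsPerturbation
    kz <- (grid$nz + 1L) %/% 2L
    labels[i, ] <- gprVector(doseArray(planned)[, , kz],
                             doseArray(delivered)[, , kz],
                             spacing = grid$spacing)
    surf <- if (wantSurface)
      extractSurfaceDose(planned, isocenter(plan), radius = surfaceRadius,
                         nAngles = targetShapes$surface[2],
                         nAxial = targetShapes$surface[1],
                         axialSpacing = 1)
    planes[[i]] <- extractIsocenterPlanes(
      planned, isocenter(plan),
      targetShapes = targetShapes[c("sagittal", "coronal", "axial")],
      surface = surf)
  }
  colnames(labels) <- gammaCriteria()$label

  matrices <- lapply(plans, buildLeafMatrix)
  excluded <- findAlwaysClosedPairs(matrices)
  mlpms <- lapply(matrices, buildMlpm, excluded = excluded,
                  fixedShape = mlpmShape)

  flags <- character()
  if (all(apply(labels, 2L, sd) == 0)) {
    flags <- "constant labels: correlation metrics undefined downstream"
    warning(flags)
  }
  meta <- data.frame(planId = vapply(plans, planId, character(1)),
                     planSeed = planSeeds, meanGap = meanGaps,
                     errs, meanAbsPerturbation = pert)
  norm <- list(
    mlpm = max(1e-9, max(vapply(mlpms, function(m) max(mapValues(m)),
                                numeric(1)))),
    dose = max(1e-9, max(vapply(planes, function(p)
      max(p@sagittal, p@coronal, p@axial), numeric(1)))),
    surface = if (wantSurface)
      max(1e-9, max(vapply(planes, function(p) max(p@surface), numeric(1))))
    else NA_real_)
  new("QaDataset", mlpms = mlpms, planes = planes, labels = labels,
      meta = meta, norm = norm, excludedPairs = as.integer(excluded),
      flags = flags)
}

#' Assemble normalized network inputs from a dataset
#'
#' Divides every image by its dataset-wide maximum so network inputs lie in
#' `[0, 1]`, and returns them with the labels in the layout [trainModel()]
#' expects.
#'
#' @param ds a [QaDataset-class].
#' @param variant network variant (decides which branches are included).
#' @param which optional plan indices or ids (default: all).
#' @return list with `inputs` (list of named lists of matrices) and `labels`
#'   (`n x 9`, %).
#' @export
assembleInputs <- function(ds, variant = c("model1", "model2", "model3"),
                           which = NULL) {
  variant <- match.arg(variant)
  branches <- .VARIANT_BRANCHES[[variant]]
  idx <- seq_len(nrow(ds@labels))
  if (!is.null(which)) {
    idx <- if (is.character(which)) match(which, ds@meta$planId) else which
    if (anyNA(idx)) stop("unknown plan id(s)")
  }
  inputs <- lapply(idx, function(i) {
    s <- list()
    for (nm in branches) {
      s[[nm]] <- switch(nm,
        mlpm = mapValues(ds@mlpms[[i]]) / ds@norm$mlpm,
        surface = ds@planes[[i]]@surface / ds@norm$surface,
        slot(ds@planes[[i]], nm) / ds@norm$dose)
    }
    s
  })
  list(inputs = inputs, labels = ds@labels[idx, , drop = FALSE])
}

#' Write / read the dataset archive
#'
#' The archive is a single-file serialized container with one record per
#' plan (`mlpm`, `planes`, `labels`) plus provenance (generation metadata,
#' excluded pairs, normalization constants). Byte-identical for identical
#' datasets, so a regenerated archive with the same seed reproduces exactly.
#'
#' @param ds a [QaDataset-class].
#' @param path archive path (conventionally `.qads.rds`).
#' @return `path` / the [QaDataset-class].
#' @export
writeQaDataset <- function(ds, path) {
  saveRDS(ds, path, version = 3L, compress = "gzip")
  invisible(path)
}

#' @rdname writeQaDataset
#' @export
readQaDataset <- function(path) {
  ds <- readRDS(path)
  if (!is(ds, "QaDataset")) stop("archive does not contain a QaDataset")
  validObject(ds)
  ds
}

#' Train and test one cross-validation fold
#'
#' Builds a fresh network for the variant (input shapes taken from the
#' dataset), trains it on the fold's training/validation split, and predicts
#' the held-out test plans.
#'
#' @param ds a [QaDataset-class].
#' @param variant network variant.
#' @param foldPlan a [makeFolds()] plan over `qaMeta(ds)$planId`.
#' @param fold fold index.
#' @param cfg a [trainConfig()].
#' @return list with `measured` / `predicted` test matrices (`n x 9`, %),
#'   the trained `net`, and the fold id sets.
#' @export
runFold <- function(ds, variant, foldPlan, fold = 1L, cfg = trainConfig()) {
  f <- foldPlan$folds[[fold]]
  shapes <- list(
    sagittal = dim(ds@planes[[1]]@sagittal),
    coronal = dim(ds@planes[[1]]@coronal),
    axial = dim(ds@planes[[1]]@axial),
    mlpm = dim(mapValues(ds@mlpms[[1]])))
  if (!is.null(ds@planes[[1]]@surface))
    shapes$surface <- dim(ds@planes[[1]]@surface)
  net <- buildNetwork(variant, inputShapes = shapes, seed = cfg$seed)
  trained <- trainModel(net, assembleInputs(ds, variant, f$train),
                        assembleInputs(ds, variant, f$val), cfg)
  test <- assembleInputs(ds, variant, f$test)
  pred <- predictGpr(trained, test$inputs)
  list(measured = test$labels, predicted = pred, net = trained,
       ids = f)
}

#' Full cross-validated evaluation
#'
#' Runs [runFold()] for every fold of the plan and aggregates with
#' [evaluateGpr()].
#'
#' @inheritParams runFold
#' @return an `EvalReport`.
#' @export
crossValidate <- function(ds, variant, foldPlan, cfg = trainConfig()) {
  folds <- lapply(seq_len(foldPlan$k), function(f) {
    r <- runFold(ds, variant, foldPlan, f, cfg)
    list(measured = r$measured, predicted = r$predicted)
  })
  evaluateGpr(folds)
}
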