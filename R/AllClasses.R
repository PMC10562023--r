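#' @useDynLib vmatqa, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif sd cor quantile setNames
NULL

.N_LEAF_PAIRS <- 60L

# a leaf pair counts as closed when its tip gap is <= this (dosimetric
# leaf-gap scale); also the slack allowed on the aperture >= 0 invariant
.CLOSED_TOL_MM <- 0.5

#' Single-arc VMAT plan
#'
#' An `ArcPlan` holds the machine state of one volumetric-modulated arc:
#' the ordered control-point sequence (gantry angle and cumulative meterset
#' weight per control point) and the two opposing 60-leaf MLC banks.
#' Leaf-tip coordinates are signed millimetres along the leaf-travel axis
#' (IEC 61217), stored exactly as found in the RT-Plan; the aperture of a
#' leaf pair is `bankB - bankA` and is non-negative up to the closure
#' tolerance.
#'
#' @slot planId opaque plan identifier.
#' @slot gantryAngle gantry angle in degrees, one value per control point.
#' @slot metersetWeight cumulative meterset fraction in `[0, 1]`,
#'   non-decreasing over control points.
#' @slot bankA,bankB `60 x nControlPoints` matrices of leaf-tip coordinates
#'   (mm); row `i` is leaf `i` of the bank.
#' @slot isocenter isocenter position (mm, patient coordinates).
#' @slot prescriptionDose prescription dose in Gy (may be `NA`).
#'
#' @export
setClass("ArcPlan",
  representation(planId = "character", gantryAngle = "numeric",
                 metersetWeight = "numeric", bankA = "matrix",
                 bankB = "matrix", isocenter = "numeric",
                 prescriptionDose = "numeric"))

setValidity("ArcPlan", function(object) {
  ncp <- length(object@gantryAngle)
  msg <- character()
  if (ncp < 2L)
    msg <- c(msg, "an arc needs at least 2 control points")
  if (nrow(object@bankA) != .N_LEAF_PAIRS || nrow(object@bankB) != .N_LEAF_PAIRS)
    msg <- c(msg, "leaf banks must have exactly 60 leaves each")
  if (ncol(object@bankA) != ncp || ncol(object@bankB) != ncp ||
      length(object@metersetWeight) != ncp)
    msg <- c(msg, "control-point fields disagree in length")
  w <- object@metersetWeight
  if (length(w) && (any(diff(w) < -1e-9) || min(w) < -1e-9 || max(w) > 1 + 1e-9))
    msg <- c(msg, "cumulative meterset weight must be non-decreasing in [0, 1]")
  if (length(object@isocenter) != 3L)
    msg <- c(msg, "isocenter must be a 3-vector (mm)")
  gap <- object@bankB - object@bankA
  if (length(gap) && min(gap) < -.CLOSED_TOL_MM)
    msg <- c(msg, sprintf(
      "negative aperture gap beyond the %.1f mm closure tolerance", .CLOSED_TOL_MM))
  if (length(msg)) msg else TRUE
})

#' @param planId,gantryAngle,metersetWeight,bankA,bankB,isocenter,prescriptionDose
#'   see the corresponding slots.
#' @rdname ArcPlan-class
#' @export
ArcPlan <- function(planId, gantryAngle, metersetWeight, bankA, bankB,
                    isocenter = c(0, 0, 0), prescriptionDose = NA_real_) {
  new("ArcPlan", planId = as.character(planId),
      gantryAngle = as.numeric(gantryAngle),
      metersetWeight = as.numeric(metersetWeight),
      bankA = bankA, bankB = bankB, isocenter = as.numeric(isocenter),
      prescriptionDose = as.numeric(prescriptionDose))
}

#' 3D dose grid
#'
#' Dose in Gy on a regular grid. The value array is indexed `[x, y, z]`
#' (x = left-right, y = anterior-posterior, z = superior-inferior);
#' `origin` is the position (mm) of the centre of voxel `[1, 1, 1]`.
#'
#' @slot values 3D array of dose values (Gy), all non-negative.
#' @slot origin position (mm) of the first voxel centre.
#' @slot spacing voxel spacing (mm) per axis, all positive.
#' @export
setClass("DoseGrid",
  representation(values = "array", origin = "numeric", spacing = "numeric"))

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@origin) != 3L || length(object@spacing) != 3L)
    msg <- c(msg, "origin and spacing must be 3-vectors")
  if (any(object@spacing <= 0))
    msg <- c(msg, "spacing must be positive on every axis")
  if (length(object@values) && min(object@values) < 0)
    msg <- c(msg, "dose values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param values,origin,spacing see the corresponding slots.
#' @rdname DoseGrid-class
#' @export
DoseGrid <- function(values, origin = c(0, 0, 0), spacing = c(2, 2, 2)) {
  new("DoseGrid", values = values, origin = as.numeric(origin),
      spacing = as.numeric(spacing))
}

#' Fixed-size dose planes through the isocenter
#'
#' The three anatomical planes of a dose grid through the isocenter
#' (sagittal: rows = y, cols = z; coronal: rows = x, cols = z; axial:
#' rows = y, cols = x), center-cropped or zero-padded so the isocenter
#' falls on the centre pixel, plus an optional unrolled cylindrical-surface
#' dose map (rows = axial position, cols = azimuth).
#'
#' @slot sagittal,coronal,axial dose-plane matrices (Gy).
#' @slot surface optional surface dose map, or `NULL`.
#' @slot spacing in-plane pixel spacing (mm).
#' @export
setClass("DosePlaneSet",
  representation(sagittal = "matrix", coronal = "matrix", axial = "matrix",
                 surface = "ANY", spacing = "numeric"))

setValidity("DosePlaneSet", function(object) {
  planes <- list(object@sagittal, object@coronal, object@axial)
  if (!is.null(object@surface)) planes <- c(planes, list(object@surface))
  if (any(vapply(planes, function(p) min(p) < 0, logical(1))))
    return("dose planes must be non-negative")
  TRUE
})

DosePlaneSet <- function(sagittal, coronal, axial, surface = NULL,
                         spacing = 2) {
  new("DosePlaneSet", sagittal = sagittal, coronal = coronal, axial = axial,
      surface = surface, spacing = as.numeric(spacing))
}

#' Stacked leaf-position matrix
#'
#' The raw 120-row leaf-coordinate matrix of a plan: rows 1-60 are bank A
#' leaves 1-60, rows 61-120 bank B leaves 1-60, one column per control point.
#' `closedReference` records, per leaf pair, the coordinate of the closed
#' state (the pair's junction), the zero point of the leaf-position map.
#'
#' @slot values `120 x nControlPoints` matrix (mm).
#' @slot closedReference length-60 vector of closed-state coordinates (mm).
#' @slot planId source plan identifier.
#' @export
setClass("LeafPositionMatrix",
  representation(values = "matrix", closedReference = "numeric",
                 planId = "character"))

setValidity("LeafPositionMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != 2L * .N_LEAF_PAIRS)
    msg <- c(msg, "leaf-position matrix must have exactly 120 rows")
  if (length(object@closedReference) != .N_LEAF_PAIRS)
    msg <- c(msg, "closedReference must have one entry per leaf pair")
  if (length(msg)) msg else TRUE
})

#' MLC leaf-position map
#'
#' The network-input image derived from a plan: each cell is the absolute
#' displacement (mm) of a leaf from its closed-state coordinate, rows are the
#' retained leaves (bank A block then bank B block, always-closed pairs
#' removed), columns are control points right-padded with zeros to a fixed
#' width. Closed leaves map to exactly 0.
#'
#' @slot values non-negative displacement map (mm).
#' @slot excludedPairs indices of the leaf pairs removed from the map.
#' @slot nControlPoints number of real (unpadded) control-point columns.
#' @slot planId source plan identifier.
#' @export
setClass("MLPMap",
  representation(values = "matrix", excludedPairs = "integer",
                 nControlPoints = "integer", planId = "character"))

setValidity("MLPMap", function(object) {
  if (length(object@values) && min(object@values) < 0)
    return("MLPM values are displacement magnitudes and must be >= 0")
  TRUE
})

# ---- accessors ----------------------------------------------------------

#' @export
setGeneric("planId", function(x) standardGeneric("planId"))
#' @export
setGeneric("nControlPoints", function(x) standardGeneric("nControlPoints"))
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @describeIn ArcPlan-class plan identifier.
#' @export
setMethod("planId", "ArcPlan", function(x) x@planId)
#' @describeIn ArcPlan-class number of control points.
#' @export
setMethod("nControlPoints", "ArcPlan", function(x) length(x@gantryAngle))
setMethod("nControlPoints", "LeafPositionMatrix", function(x) ncol(x@values))
setMethod("nControlPoints", "MLPMap", function(x) x@nControlPoints)
setMethod("planId", "LeafPositionMatrix", function(x) x@planId)
setMethod("planId", "MLPMap", function(x) x@planId)
setMethod("mapValues", "LeafPositionMatrix", function(x) x@values)
setMethod("mapValues", "MLPMap", function(x) x@values)

#' @param x an `ArcPlan`.
#' @rdname ArcPlan-class
#' @export
bankA <- function(x) x@bankA
#' @rdname ArcPlan-class
#' @export
bankB <- function(x) x@bankB
#' Signed aperture gap (mm) per leaf pair and control point
#' @param x an `ArcPlan`.
#' @export
apertureGap <- function(x) x@bankB - x@bankA
#' @rdname ArcPlan-class
#' @export
gantryAngles <- function(x) x@gantryAngle
#' @rdname ArcPlan-class
#' @export
metersetWeights <- function(x) x@metersetWeight
#' @rdname ArcPlan-class
#' @export
isocenter <- function(x) x@isocenter

#' @param x a `DoseGrid`.
#' @rdname DoseGrid-class
#' @export
doseArray <- function(x) x@values
#' @rdname DoseGrid-class
#' @export
gridOrigin <- function(x) x@origin
#' @rdname DoseGrid-class
#' @export
gridSpacing <- function(x) x@spacing

#' @param x an `MLPMap`.
#' @rdname MLPMap-class
#' @export
excludedPairs <- function(x) x@excludedPairs
#' @param x a `LeafPositionMatrix`.
#' @rdname LeafPositionMatrix-class
#' @export
closedReference <- function(x) x@closedReference

# ---- show methods -------------------------------------------------------

setMethod("show", "ArcPlan", function(object) {
  cat(sprintf("ArcPlan '%s': %d control points, 60 leaf pairs/bank\n",
              object@planId, nControlPoints(object)))
  cat(sprintf("  gantry %.1f..%.1f deg, meterset %.3f..%.3f\n",
              object@gantryAngle[1], object@gantryAngle[length(object@gantryAngle)],
              min(object@metersetWeight), max(object@metersetWeight)))
  g <- apertureGap(object)
  cat(sprintf("  aperture gap: mean %.1f mm, max %.1f mm; isocenter (%g, %g, %g) mm\n",
              mean(g), max(g), object@isocenter[1], object@isocenter[2],
              object@isocenter[3]))
})

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DoseGrid %d x %d x %d voxels @ (%g, %g, %g) mm, max %.3f Gy\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], max(object@values)))
})

setMethod("show", "DosePlaneSet", function(object) {
  cat("DosePlaneSet:\n")
  for (nm in c("sagittal", "coronal", "axial")) {
    p <- slot(object, nm)
    cat(sprintf("  %-8s %d x %d, max %.3f Gy\n", nm, nrow(p), ncol(p), max(p)))
  }
  if (!is.null(object@surface))
    cat(sprintf("  %-8s %d x %d, max %.3f Gy\n", "surface",
                nrow(object@surface), ncol(object@surface), max(object@surface)))
})

setMethod("show", "MLPMap", function(object) {
  cat(sprintf("MLPMap '%s': %d x %d (rows x control-point columns)\n",
              object@planId, nrow(object@values), ncol(object@values)))
  cat(sprintf("  %d real control points, excluded pairs: %s\n",
              object@nControlPoints,
              if (length(object@excludedPairs))
                paste(object@excludedPairs, collapse = ", ") else "none"))
  cat(sprintf("  displacement range %.2f..%.2f mm\n",
              min(object@values), max(object@values)))
})
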