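# RT-Plan / RT-Dose input: reading plans and dose grids, writing synthetic
# fixtures, and turning a dose grid into the fixed-size plane images the
# prediction network consumes.

#' Read a single-arc VMAT RT-Plan
#'
#' Parses a DICOM RT-Plan (Explicit VR Little Endian) with one arc beam and a
#' 120-leaf MLC into an [ArcPlan-class]. Control points are ordered by
#' cumulative meterset weight; leaf coordinates are kept in mm exactly as
#' stored. MLC positions absent at a control point are carried forward from
#' the previous one (standard RT-Plan semantics).
#'
#' @param path path to the RT-Plan file.
#' @return an [ArcPlan-class].
#' @export
readRtplan <- function(path) {
  ds <- .dcm_read(path)
  modality <- .dcm_string(ds[[.dcm_key(0x0008, 0x0060)]])
  if (!identical(modality, "RTPLAN"))
    stop("not an RT-Plan file (Modality = ", modality, ")")
  beams <- ds[[.dcm_key(0x300A, 0x00B0)]]
  if (is.null(beams) || length(beams$items) < 1L)
    stop("RT-Plan has no BeamSequence")
  if (length(beams$items) > 1L)
    stop("unsupported plan: expected a single arc beam, found ",
         length(beams$items))
  beam <- beams$items[[1]]
  cps <- beam[[.dcm_key(0x300A, 0x0111)]]
  if (is.null(cps) || length(cps$items) < 2L)
    stop("beam has no usable ControlPointSequence")
  ncp <- length(cps$items)

  gantry <- numeric(ncp); mu <- numeric(ncp)
  bankA <- matrix(NA_real_, .N_LEAF_PAIRS, ncp)
  bankB <- matrix(NA_real_, .N_LEAF_PAIRS, ncp)
  iso <- c(0, 0, 0)
  lastGantry <- NA_real_; lastA <- NULL; lastB <- NULL
  for (j in seq_len(ncp)) {
    cp <- cps$items[[j]]
    g <- .dcm_numeric(cp[[.dcm_key(0x300A, 0x011E)]])
    if (!is.null(g)) lastGantry <- g
    gantry[j] <- lastGantry
    w <- .dcm_numeric(cp[[.dcm_key(0x300A, 0x0134)]])
    if (is.null(w)) stop("control point ", j, " lacks CumulativeMetersetWeight")
    mu[j] <- w
    if (j == 1L) {
      ip <- .dcm_numeric(cp[[.dcm_key(0x300A, 0x012C)]])
      if (!is.null(ip)) iso <- ip
    }
    bld <- cp[[.dcm_key(0x300A, 0x011A)]]
    if (!is.null(bld)) {
      for (it in bld$items) {
        type <- .dcm_string(it[[.dcm_key(0x300A, 0x00B8)]])
        if (identical(type, "MLCX") || identical(type, "MLCY")) {
          pos <- .dcm_numeric(it[[.dcm_key(0x300A, 0x011C)]])
          if (length(pos) != 2L * .N_LEAF_PAIRS)
            stop("expected 120 MLC leaf positions, found ", length(pos))
          lastA <- pos[seq_len(.N_LEAF_PAIRS)]
          lastB <- pos[.N_LEAF_PAIRS + seq_len(.N_LEAF_PAIRS)]
        }
      }
    }
    if (is.null(lastA))
      stop("RT-Plan format error: no MLC leaf-position sequence at the first ",
           "control point")
    bankA[, j] <- lastA; bankB[, j] <- lastB
  }
  # normalize cumulative meterset to [0, 1] of final weight (plans store it
  # relative to FinalCumulativeMetersetWeight)
  final <- .dcm_numeric(beam[[.dcm_key(0x300A, 0x010E)]])
  if (!is.null(final) && final > 0) mu <- mu / final

  rx <- NA_real_
  dr <- ds[[.dcm_key(0x300A, 0x0010)]]
  if (!is.null(dr) && length(dr$items))
    rx <- .dcm_numeric(dr$items[[1]][[.dcm_key(0x300A, 0x0026)]]) %||% NA_real_

  label <- .dcm_string(ds[[.dcm_key(0x300A, 0x0002)]]) %||% "plan"
  ArcPlan(planId = label, gantryAngle = gantry, metersetWeight = mu,
          bankA = bankA, bankB = bankB, isocenter = iso,
          prescriptionDose = rx)
}

#' Write an ArcPlan as a DICOM RT-Plan fixture
#'
#' Emits a minimal Explicit-VR-Little-Endian RT-Plan with one beam, the full
#' control-point sequence and 120 MLC positions per control point. Intended
#' for fixtures and for exporting synthetic plans; readable by any DICOM
#' toolkit.
#'
#' @param plan an [ArcPlan-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRtplan <- function(plan, path) {
  ncp <- nControlPoints(plan)
  cp_items <- vector("list", ncp)
  for (j in seq_len(ncp)) {
    mlc <- .dcm_item(c(
      .dcm_elem(0x300A, 0x00B8, "CS", .dcm_text("MLCX")),
      .dcm_elem(0x300A, 0x011C, "DS",
                .dcm_ds(c(plan@bankA[, j], plan@bankB[, j])))))
    body <- c(
      .dcm_elem(0x300A, 0x0112, "IS", .dcm_is(j - 1L)),
      .dcm_sq(0x300A, 0x011A, list(mlc)),
      .dcm_elem(0x300A, 0x011E, "DS", .dcm_ds(plan@gantryAngle[j])))
    if (j == 1L)
      body <- c(body, .dcm_elem(0x300A, 0x012C, "DS", .dcm_ds(plan@isocenter)))
    body <- c(body,
      .dcm_elem(0x300A, 0x0134, "DS", .dcm_ds(plan@metersetWeight[j])))
    cp_items[[j]] <- .dcm_item(body)
  }
  beam <- .dcm_item(c(
    .dcm_elem(0x300A, 0x00C0, "IS", .dcm_is(1L)),
    .dcm_elem(0x300A, 0x010E, "DS", .dcm_ds(1)),
    .dcm_elem(0x300A, 0x0110, "IS", .dcm_is(ncp)),
    .dcm_sq(0x300A, 0x0111, cp_items)))
  dataset <- c(
    .dcm_elem(0x0008, 0x0016, "UI", .dcm_text(.SOP_RTPLAN, "nul")),
    .dcm_elem(0x0008, 0x0018, "UI", .dcm_text(.dcm_uid("1001"), "nul")),
    .dcm_elem(0x0008, 0x0060, "CS", .dcm_text("RTPLAN")),
    .dcm_elem(0x300A, 0x0002, "SH", .dcm_text(plan@planId)))
  if (!is.na(plan@prescriptionDose))
    dataset <- c(dataset, .dcm_sq(0x300A, 0x0010, list(.dcm_item(
      .dcm_elem(0x300A, 0x0026, "DS", .dcm_ds(plan@prescriptionDose))))))
  dataset <- c(dataset, .dcm_sq(0x300A, 0x00B0, list(beam)))
  writeBin(.dcm_file(.SOP_RTPLAN, .dcm_uid("1001"), dataset), path)
  invisible(path)
}

#' Read a DICOM RT-Dose grid
#'
#' Returns dose in Gy (DoseGridScaling applied) with origin and spacing in
#' mm. The value array is indexed `[x, y, z]`: DICOM frames become z slices,
#' rows y, columns x.
#'
#' @param path path to the RT-Dose file.
#' @return a [DoseGrid-class].
#' @export
readRtdose <- function(path) {
  ds <- .dcm_read(path)
  modality <- .dcm_string(ds[[.dcm_key(0x0008, 0x0060)]])
  if (!identical(modality, "RTDOSE"))
    stop("not an RT-Dose file (Modality = ", modality, ")")
  scaling <- .dcm_numeric(ds[[.dcm_key(0x3004, 0x000E)]])
  if (is.null(scaling))
    stop("RT-Dose format error: missing DoseGridScaling")
  ny <- .dcm_u16vec(ds[[.dcm_key(0x0028, 0x0010)]])
  nx <- .dcm_u16vec(ds[[.dcm_key(0x0028, 0x0011)]])
  nz <- .dcm_int(ds[[.dcm_key(0x0028, 0x0008)]]) %||% 1L
  bits <- .dcm_u16vec(ds[[.dcm_key(0x0028, 0x0100)]]) %||% 32L
  if (bits != 32L) stop("only 32-bit RT-Dose pixel data is supported")
  spacing_rc <- .dcm_numeric(ds[[.dcm_key(0x0028, 0x0030)]])
  origin <- .dcm_numeric(ds[[.dcm_key(0x0020, 0x0032)]]) %||% c(0, 0, 0)
  gfov <- .dcm_numeric(ds[[.dcm_key(0x3004, 0x000C)]])
  sz <- if (!is.null(gfov) && length(gfov) >= 2L) gfov[2] - gfov[1] else spacing_rc[1]
  pix_raw <- ds[[.dcm_key(0x7FE0, 0x0010)]]$value
  n <- as.numeric(nx) * ny * nz
  pix <- readBin(pix_raw, "integer", n = n, size = 4L, endian = "little")
  values <- array(as.numeric(pix) * scaling, dim = c(nx, ny, nz))
  DoseGrid(values, origin = origin,
           spacing = c(spacing_rc[2], spacing_rc[1], sz))
}

#' Write a DoseGrid as a DICOM RT-Dose fixture
#'
#' Dose is stored as 32-bit unsigned integers with a DoseGridScaling factor
#' (default: full-range scaling of the grid maximum), as real RT-Dose objects
#' do; values exactly on the scaling lattice round-trip bit-identically.
#'
#' @param grid a [DoseGrid-class].
#' @param path output path.
#' @param scaling dose-grid scaling (Gy per integer unit); default scales the
#'   maximum dose to the integer range.
#' @return `path`, invisibly.
#' @export
writeRtdose <- function(grid, path, scaling = NULL) {
  d <- dim(grid@values)
  if (is.null(scaling)) {
    mx <- max(grid@values)
    scaling <- if (mx > 0) mx / (2^31 - 1) else 1e-6
  }
  pix <- as.integer(round(as.vector(grid@values) / scaling))
  sp <- grid@spacing
  dataset <- c(
    .dcm_elem(0x0008, 0x0016, "UI", .dcm_text(.SOP_RTDOSE, "nul")),
    .dcm_elem(0x0008, 0x0018, "UI", .dcm_text(.dcm_uid("1002"), "nul")),
    .dcm_elem(0x0008, 0x0060, "CS", .dcm_text("RTDOSE")),
    .dcm_elem(0x0020, 0x0032, "DS", .dcm_ds(grid@origin)),
    .dcm_elem(0x0020, 0x0037, "DS", .dcm_ds(c(1, 0, 0, 0, 1, 0))),
    .dcm_elem(0x0028, 0x0002, "US", .raw_u16(1L)),
    .dcm_elem(0x0028, 0x0004, "CS", .dcm_text("MONOCHROME2")),
    .dcm_elem(0x0028, 0x0008, "IS", .dcm_is(d[3])),
    .dcm_elem(0x0028, 0x0010, "US", .raw_u16(d[2])),
    .dcm_elem(0x0028, 0x0011, "US", .raw_u16(d[1])),
    .dcm_elem(0x0028, 0x0030, "DS", .dcm_ds(c(sp[2], sp[1]))),
    .dcm_elem(0x0028, 0x0100, "US", .raw_u16(32L)),
    .dcm_elem(0x0028, 0x0101, "US", .raw_u16(32L)),
    .dcm_elem(0x0028, 0x0102, "US", .raw_u16(31L)),
    .dcm_elem(0x0028, 0x0103, "US", .raw_u16(0L)),
    .dcm_elem(0x3004, 0x0002, "CS", .dcm_text("GY")),
    .dcm_elem(0x3004, 0x0004, "CS", .dcm_text("PHYSICAL")),
    .dcm_elem(0x3004, 0x000A, "CS", .dcm_text("PLAN")),
    .dcm_elem(0x3004, 0x000C, "DS", .dcm_ds((seq_len(d[3]) - 1) * sp[3])),
    .dcm_elem(0x3004, 0x000E, "DS", .dcm_ds(scaling)),
    .dcm_elem(0x7FE0, 0x0010, "OW",
              writeBin(pix, raw(), size = 4L, endian = "little")))
  writeBin(.dcm_file(.SOP_RTDOSE, .dcm_uid("1002"), dataset), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- plane extraction ---------------------------------------------------

# center-crop / zero-pad a matrix so `center` (row, col) lands on the centre
# pixel floor(shape/2)+1 of the target shape
.cropPad2D <- function(mat, center, target) {
  out <- matrix(0, target[1], target[2])
  ctr <- floor(target / 2) + 1L
  off <- center - ctr                      # src index = out index + off
  r_out <- seq_len(target[1]); c_out <- seq_len(target[2])
  r_src <- r_out + off[1]; c_src <- c_out + off[2]
  rk <- r_src >= 1L & r_src <= nrow(mat)
  ck <- c_src >= 1L & c_src <= ncol(mat)
  out[r_out[rk], c_out[ck]] <- mat[r_src[rk], c_src[ck]]
  out
}

.isoVoxel <- function(grid, isocenter) {
  idx <- round((isocenter - grid@origin) / grid@spacing) + 1L
  d <- dim(grid@values)
  if (any(idx < 1L) || any(idx > d))
    stop("isocenter lies outside the dose grid")
  as.integer(idx)
}

#' Extract fixed-size dose planes through the isocenter
#'
#' Slices the dose grid through the isocenter voxel on the three anatomical
#' planes and center-crops / zero-pads each slice (at native spacing, never
#' resampled, so dose-gradient magnitudes are preserved) to the requested
#' shape with the isocenter on the centre pixel. Default shapes are the
#' network's standard input sizes.
#'
#' @param grid a [DoseGrid-class].
#' @param isocenter isocenter (mm); must lie inside the grid.
#' @param targetShapes named list of `c(rows, cols)` for `sagittal`
#'   (rows = y, cols = z), `coronal` (rows = x, cols = z) and `axial`
#'   (rows = y, cols = x).
#' @param surface optional surface dose map to attach (see
#'   [extractSurfaceDose()]).
#' @return a [DosePlaneSet-class].
#' @export
extractIsocenterPlanes <- function(grid, isocenter = c(0, 0, 0),
                                   targetShapes = list(
                                     sagittal = c(68L, 146L),
                                     coronal = c(64L, 200L),
                                     axial = c(143L, 242L)),
                                   surface = NULL) {
  iv <- .isoVoxel(grid, isocenter)
  v <- grid@values
  sag <- .cropPad2D(v[iv[1], , ], iv[c(2, 3)], targetShapes$sagittal)
  cor_ <- .cropPad2D(v[, iv[2], ], iv[c(1, 3)], targetShapes$coronal)
  ax <- .cropPad2D(t(v[, , iv[3]]), iv[c(2, 1)], targetShapes$axial)
  DosePlaneSet(sagittal = sag, coronal = cor_, axial = ax, surface = surface,
               spacing = grid@spacing[1])
}

# vectorized trilinear interpolation; points outside the grid give 0
.trilinear <- function(grid, pts) {
  d <- dim(grid@values)
  g <- sweep(sweep(pts, 2L, grid@origin, "-"), 2L, grid@spacing, "/")
  inside <- g[, 1] >= 0 & g[, 1] <= d[1] - 1 &
            g[, 2] >= 0 & g[, 2] <= d[2] - 1 &
            g[, 3] >= 0 & g[, 3] <= d[3] - 1
  out <- numeric(nrow(pts))
  if (!any(inside)) return(out)
  g <- g[inside, , drop = FALSE]
  i0 <- pmin(floor(g), rep(pmax(d - 2, 0), each = nrow(g)))
  f <- g - i0
  i0 <- i0 + 1L # 1-based corner
  v <- grid@values
  ix <- i0[, 1]; iy <- i0[, 2]; iz <- i0[, 3]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  at <- function(dx, dy, dz)
    v[cbind(pmin(ix + dx, d[1]), pmin(iy + dy, d[2]), pmin(iz + dz, d[3]))]
  val <- at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
         at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
         at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
         at(1, 1, 0) * fx * fy * (1 - fz) +
         at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
         at(1, 0, 1) * fx * (1 - fy) * fz +
         at(0, 1, 1) * (1 - fx) * fy * fz +
         at(1, 1, 1) * fx * fy * fz
  out[inside] <- val
  out
}

#' Sample dose on an unrolled cylinder around the superior-inferior axis
#'
#' Emulates a cylindrical-detector-style dose image: dose is sampled by
#' trilinear interpolation on a cylinder of given radius about the z axis
#' through the isocenter and unrolled to a 2D map (rows = axial position at
#' `axialSpacing`, columns = azimuth). Samples outside the grid are 0.
#'
#' @param grid a [DoseGrid-class].
#' @param isocenter cylinder axis passes through this point (mm).
#' @param radius cylinder radius in mm (default 105, diode-array-like).
#' @param nAngles number of azimuth bins (columns).
#' @param nAxial number of axial bins (rows).
#' @param axialSpacing axial bin size in mm.
#' @return a `nAxial x nAngles` matrix.
#' @export
extractSurfaceDose <- function(grid, isocenter = c(0, 0, 0), radius = 105,
                               nAngles = 680L, nAxial = 220L,
                               axialSpacing = 1) {
  if (radius <= 0) stop("cylinder radius must be positive")
  theta <- 2 * pi * (seq_len(nAngles) - 1L) / nAngles
  zs <- isocenter[3] + (seq_len(nAxial) - (nAxial + 1) / 2) * axialSpacing
  pts <- cbind(isocenter[1] + radius * cos(rep(theta, each = nAxial)),
               isocenter[2] + radius * sin(rep(theta, each = nAxial)),
               rep(zs, times = nAngles))
  matrix(.trilinear(grid, pts), nAxial, nAngles)
}
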