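# RT-Plan / RT-Dose reading and plane extraction

test_that("RT-Plan round trip preserves every plan field", {
  p <- generatePlan(planGenParams(nControlPoints = 178L, seed = 11))
  path <- withr::local_tempfile(fileext = ".dcm")
  writeRtplan(p, path)
  p2 <- readRtplan(path)
  expect_equal(nControlPoints(p2), 178L)
  expect_equal(planId(p2), planId(p))
  expect_equal(bankA(p2), bankA(p), tolerance = 1e-8)
  expect_equal(bankB(p2), bankB(p), tolerance = 1e-8)
  expect_equal(gantryAngles(p2), gantryAngles(p), tolerance = 1e-8)
  expect_equal(metersetWeights(p2), metersetWeights(p), tolerance = 1e-8)
  expect_equal(isocenter(p2), isocenter(p))
  expect_equal(p2@prescriptionDose, p@prescriptionDose)
})

test_that("closed-plan fixture reads back with all apertures exactly zero", {
  p <- closedPlan(ncp = 2L, jun = seq(-5, 5, length.out = 60))
  path <- withr::local_tempfile(fileext = ".dcm")
  writeRtplan(p, path)
  p2 <- readRtplan(path)
  expect_true(all(apertureGap(p2) == 0))
})

test_that("malformed plans are rejected", {
  # non-monotone meterset violates the ArcPlan invariant on read
  p <- closedPlan(ncp = 3L)
  path <- withr::local_tempfile(fileext = ".dcm")
  slot(p, "metersetWeight", check = FALSE) <- c(0, 0.8, 0.5)
  writeRtplan(p, path)
  expect_error(readRtplan(path), "non-decreasing")

  # two beams are unsupported (single-arc tool)
  cp_item <- function(j) vmatqa:::.dcm_item(c(
    vmatqa:::.dcm_elem(0x300A, 0x0112, "IS", vmatqa:::.dcm_is(j)),
    vmatqa:::.dcm_sq(0x300A, 0x011A, list(vmatqa:::.dcm_item(c(
      vmatqa:::.dcm_elem(0x300A, 0x00B8, "CS", vmatqa:::.dcm_text("MLCX")),
      vmatqa:::.dcm_elem(0x300A, 0x011C, "DS",
                         vmatqa:::.dcm_ds(c(rep(-5, 60), rep(5, 60)))))))),
    vmatqa:::.dcm_elem(0x300A, 0x011E, "DS", vmatqa:::.dcm_ds(180)),
    vmatqa:::.dcm_elem(0x300A, 0x0134, "DS", vmatqa:::.dcm_ds(j))))
  beam_item <- vmatqa:::.dcm_item(vmatqa:::.dcm_sq(
    0x300A, 0x0111, list(cp_item(0), cp_item(1))))
  twoBeam <- vmatqa:::.dcm_file(vmatqa:::.SOP_RTPLAN, "2.25.3", c(
    vmatqa:::.dcm_elem(0x0008, 0x0060, "CS", vmatqa:::.dcm_text("RTPLAN")),
    vmatqa:::.dcm_sq(0x300A, 0x00B0, list(beam_item, beam_item))))
  writeBin(twoBeam, path)
  expect_error(readRtplan(path), "single arc")

  # a plan whose control points carry no MLC sequence is a format error
  noMlc <- vmatqa:::.dcm_file(
    vmatqa:::.SOP_RTPLAN, "2.25.1", c(
      vmatqa:::.dcm_elem(0x0008, 0x0060, "CS", vmatqa:::.dcm_text("RTPLAN")),
      vmatqa:::.dcm_sq(0x300A, 0x00B0, list(vmatqa:::.dcm_item(c(
        vmatqa:::.dcm_elem(0x300A, 0x0110, "IS", vmatqa:::.dcm_is(2L)),
        vmatqa:::.dcm_sq(0x300A, 0x0111, lapply(0:1, function(j)
          vmatqa:::.dcm_item(c(
            vmatqa:::.dcm_elem(0x300A, 0x0112, "IS", vmatqa:::.dcm_is(j)),
            vmatqa:::.dcm_elem(0x300A, 0x011E, "DS", vmatqa:::.dcm_ds(180)),
            vmatqa:::.dcm_elem(0x300A, 0x0134, "DS", vmatqa:::.dcm_ds(j))))))))))))
  writeBin(noMlc, path)
  expect_error(readRtplan(path), "MLC")
})

test_that("RT-Dose round trip: scaling applied, geometry kept, values exact on the quantization lattice", {
  # integer multiples of the scaling survive the uint round trip bit-exactly
  set.seed(4)
  vals <- array(sample.int(5000, 6 * 5 * 4, replace = TRUE) * 1e-3,
                c(6, 5, 4))
  g <- DoseGrid(vals, origin = c(-6, -5, -4), spacing = c(2, 2, 2))
  path <- withr::local_tempfile(fileext = ".dcm")
  writeRtdose(g, path, scaling = 1e-3)
  g2 <- readRtdose(path)
  expect_identical(doseArray(g2), doseArray(g))
  expect_identical(gridOrigin(g2), gridOrigin(g))
  expect_identical(gridSpacing(g2), gridSpacing(g))

  ones <- DoseGrid(array(1, c(3, 3, 3)), spacing = c(2, 2, 2))
  writeRtdose(ones, path, scaling = 0.01)
  expect_true(all(doseArray(readRtdose(path)) == 0.01 * round(1 / 0.01)))
  expect_equal(gridSpacing(readRtdose(path)), c(2, 2, 2))
})

test_that("RT-Dose without grid scaling is a format error", {
  bad <- vmatqa:::.dcm_file(
    vmatqa:::.SOP_RTDOSE, "2.25.2", c(
      vmatqa:::.dcm_elem(0x0008, 0x0060, "CS", vmatqa:::.dcm_text("RTDOSE")),
      vmatqa:::.dcm_elem(0x0028, 0x0010, "US", vmatqa:::.raw_u16(2L)),
      vmatqa:::.dcm_elem(0x0028, 0x0011, "US", vmatqa:::.raw_u16(2L))))
  path <- withr::local_tempfile(fileext = ".dcm")
  writeBin(bad, path)
  expect_error(readRtdose(path), "DoseGridScaling")
})

test_that("package-written DICOM agrees with pydicom and vice versa", {
  plan <- generatePlan(planGenParams(nControlPoints = 12L, seed = 3))
  path <- withr::local_tempfile(fileext = ".dcm")
  out <- withr::local_tempfile(fileext = ".txt")
  writeRtplan(plan, path)
  script <- sprintf(paste0(
    "import pydicom\n",
    "ds = pydicom.dcmread('%s')\n",
    "cps = ds.BeamSequence[0].ControlPointSequence\n",
    "s = sum(float(v) for cp in cps\n",
    "        for b in cp.get('BeamLimitingDevicePositionSequence', [])\n",
    "        for v in b.LeafJawPositions)\n",
    "print(len(ds.BeamSequence), len(cps), round(s, 4))\n"), path)
  pys <- withr::local_tempfile(fileext = ".py")
  writeLines(script, pys)
  res <- system2("python", pys, stdout = TRUE)
  parts <- strsplit(res, " ")[[1]]
  expect_equal(as.integer(parts[1]), 1L)
  expect_equal(as.integer(parts[2]), 12L)
  expect_equal(as.numeric(parts[3]),
               round(sum(bankA(plan)) + sum(bankB(plan)), 4),
               tolerance = 1e-3)

  # reverse: a pydicom-authored plan is readable by the package
  pyw <- withr::local_tempfile(fileext = ".py")
  target <- withr::local_tempfile(fileext = ".dcm")
  writeLines(sprintf(paste0(
    "import pydicom, pydicom.uid\n",
    "from pydicom.dataset import Dataset, FileDataset, FileMetaDataset\n",
    "meta = FileMetaDataset()\n",
    "meta.MediaStorageSOPClassUID = pydicom.uid.UID('1.2.840.10008.5.1.4.1.1.481.5')\n",
    "meta.MediaStorageSOPInstanceUID = pydicom.uid.generate_uid()\n",
    "meta.TransferSyntaxUID = pydicom.uid.ExplicitVRLittleEndian\n",
    "f = FileDataset('x', {}, file_meta=meta, preamble=b'\\0'*128)\n",
    "f.Modality = 'RTPLAN'; f.RTPlanLabel = 'pyplan'\n",
    "beam = Dataset(); beam.BeamNumber = 1\n",
    "beam.FinalCumulativeMetersetWeight = 1.0\n",
    "cps = []\n",
    "for j in range(4):\n",
    "    cp = Dataset(); cp.ControlPointIndex = j\n",
    "    cp.GantryAngle = 181.0 + j\n",
    "    cp.CumulativeMetersetWeight = j/3.0\n",
    "    b = Dataset(); b.RTBeamLimitingDeviceType = 'MLCX'\n",
    "    b.LeafJawPositions = [-10.0 - j]*60 + [10.0 + j]*60\n",
    "    cp.BeamLimitingDevicePositionSequence = [b]\n",
    "    if j == 0: cp.IsocenterPosition = [1.0, 2.0, 3.0]\n",
    "    cps.append(cp)\n",
    "beam.NumberOfControlPoints = 4\n",
    "beam.ControlPointSequence = cps\n",
    "f.BeamSequence = [beam]\n",
    "f.save_as('%s', enforce_file_format=True)\n"), target), pyw)
  system2("python", pyw)
  p <- readRtplan(target)
  expect_equal(nControlPoints(p), 4L)
  expect_equal(unname(apertureGap(p)[1, ]), c(20, 22, 24, 26))
  expect_equal(isocenter(p), c(1, 2, 3))
})

test_that("isocenter planes: constant field, delta localization, zero-padding", {
  shapes <- list(sagittal = c(9L, 11L), coronal = c(7L, 13L),
                 axial = c(15L, 9L))
  g <- DoseGrid(array(2.5, c(12, 12, 12)), origin = c(-11, -11, -11),
                spacing = c(2, 2, 2))
  ps <- extractIsocenterPlanes(g, c(0, 0, 0), targetShapes = shapes)
  # constant where the grid covers the plane, zero in the padding
  expect_equal(dim(ps@sagittal), c(9L, 11L))
  expect_equal(dim(ps@coronal), c(7L, 13L))
  expect_equal(dim(ps@axial), c(15L, 9L))
  expect_true(all(ps@sagittal %in% c(0, 2.5)))

  # delta at the isocenter voxel appears at the centre pixel of every plane
  v <- array(0, c(12, 12, 12))
  v[6, 6, 6] <- 7 # voxel at -11 + 5*2 = -1 mm on each axis
  gd <- DoseGrid(v, origin = c(-11, -11, -11), spacing = c(2, 2, 2))
  psd <- extractIsocenterPlanes(gd, c(-1, -1, -1), targetShapes = shapes)
  for (nm in c("sagittal", "coronal", "axial")) {
    pl <- slot(psd, nm)
    ctr <- floor(dim(pl) / 2) + 1L
    expect_equal(which(pl == max(pl), arr.ind = TRUE)[1, ],
                 c(row = ctr[1], col = ctr[2]))
    expect_equal(max(pl), 7)
  }

  # grid smaller than the target: original values preserved around the centre
  small <- DoseGrid(array(1:27, c(3, 3, 3)) * 1.0, origin = c(-2, -2, -2),
                    spacing = c(2, 2, 2))
  pss <- extractIsocenterPlanes(small, c(0, 0, 0),
                                targetShapes = list(sagittal = c(9L, 9L),
                                                    coronal = c(9L, 9L),
                                                    axial = c(9L, 9L)))
  ctr <- c(5L, 5L)
  expect_equal(pss@sagittal[ctr[1] + (-1:1), ctr[2] + (-1:1)],
               doseArray(small)[2, , ])
  expect_equal(sum(pss@sagittal != 0) , 9L)
  expect_error(extractIsocenterPlanes(small, c(50, 0, 0)), "outside")
})

test_that("surface dose map: constant field, azimuth symmetry, out-of-grid zeros", {
  g <- DoseGrid(array(3, c(21, 21, 21)), origin = c(-20, -20, -20),
                spacing = c(2, 2, 2))
  s <- extractSurfaceDose(g, c(0, 0, 0), radius = 10, nAngles = 60L,
                          nAxial = 55L, axialSpacing = 0.5)
  expect_equal(dim(s), c(55L, 60L))
  expect_true(all(abs(s - 3) < 1e-9))

  # dose varying only along the cylinder axis is azimuth-invariant
  v <- array(rep(seq(0, 2, length.out = 21), each = 21 * 21), c(21, 21, 21))
  gz <- DoseGrid(v, origin = c(-20, -20, -20), spacing = c(2, 2, 2))
  sz <- extractSurfaceDose(gz, c(0, 0, 0), radius = 12, nAngles = 40L,
                           nAxial = 31L, axialSpacing = 1)
  expect_true(all(abs(sz - sz[, 1]) < 1e-9))
  expect_true(all(diff(rowMeans(sz)) > 0))

  # a cylinder wider than the grid samples zeros outside
  sbig <- extractSurfaceDose(g, c(0, 0, 0), radius = 60, nAngles = 16L,
                             nAxial = 11L)
  expect_true(all(sbig == 0))
  expect_error(extractSurfaceDose(g, c(0, 0, 0), radius = -1), "positive")
})
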