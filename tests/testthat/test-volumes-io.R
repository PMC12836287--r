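test_that("grid geometry validates its invariants", {
  expect_error(grid_geometry(c(0, 0, 0), c(1, 0, 1), c(4, 4, 4)), "spacing")
  expect_error(grid_geometry(c(0, 0, 0), c(1, 1, 1), c(4, 0, 4)), "shape")
  expect_error(grid_geometry(c(0, 0, 0), c(1, 1, 1), c(4, 4, 4),
                             matrix(1, 3, 3)), "orthonormal")
  g <- grid_geometry(c(-10, 0, 5), c(2, 3, 5), c(4, 5, 6))
  expect_equal(voxel_volume_cc(g), 2 * 3 * 5 / 1000)
})

test_that("mask volume equals voxel count times voxel volume", {
  set.seed(7)
  g <- grid_geometry(c(0, 0, 0), c(1.7, 2.3, 4.1), c(9, 8, 7))
  v <- array(runif(prod(g$shape)) < 0.3, g$shape)
  m <- binary_mask(v, g, "m")
  expect_identical(mask_volume_cc(m), sum(v) * prod(g$spacing) / 1000)
})

test_that("dose volumes reject negative and non-finite values", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3))
  expect_error(image_volume(array(-1, c(3, 3, 3)), g, "DOSE"), ">= 0")
  expect_error(image_volume(array(NA_real_, c(3, 3, 3)), g, "CT"), "finite")
})

test_that("resampling to an identical geometry is the identity", {
  rc <- random_grid_case(11)
  out <- resample(rc$dose, rc$geometry)
  expect_identical(out$values, rc$dose$values)
  mout <- resample(rc$mask, rc$geometry)
  expect_identical(mout$values, rc$mask$values)
})

test_that("a constant volume stays constant under resampling", {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(10, 10, 10))
  vol <- image_volume(array(3.5, g$shape), g, "DOSE")
  tgt <- grid_geometry(c(3, 3, 3), c(1.5, 2.5, 3.5), c(5, 4, 3))
  out <- resample(vol, tgt)
  expect_true(all(abs(out$values - 3.5) < 1e-12))
})

test_that("downsampling a linear ramp matches the analytic ramp", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(21, 9, 9))
  xs <- (seq_len(21) - 1)
  vals <- array(rep(xs, times = 81), g$shape)
  vol <- image_volume(vals, g, "CT")
  tgt <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(10, 4, 4))
  out <- resample(vol, tgt)
  expected <- array(rep((seq_len(10) - 1) * 2, times = 16), tgt$shape)
  expect_lt(max(abs(out$values - expected)), 1e-6)
})

test_that("degenerate resampling targets are rejected", {
  rc <- random_grid_case(3)
  expect_error(resample(rc$dose, grid_geometry(c(0, 0, 0), c(0, 1, 1), c(3, 3, 3))),
               "spacing")
})

test_that("mask resampling never escapes the dilated support", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(12, 12, 12))
    v <- array(FALSE, g$shape)
    v[4:8, 5:9, 3:6] <- TRUE
    m <- binary_mask(v, g, "m")
    tgt <- grid_geometry(runif(3, -1, 1), c(1.3, 1.7, 2.4), c(15, 14, 11))
    out <- resample(m, tgt)
    if (!any(out$values)) next
    # every true target voxel center must be within one source voxel of the
    # original support
    d <- distance_to_mask(m)
    ctrs <- voxel_centers(tgt)[as.vector(out$values), , drop = FALSE]
    dd <- dosemimic:::cpp_sample_volume(as.numeric(d), g$shape, g$origin,
                                        g$spacing, ctrs, TRUE, Inf)
    expect_true(all(dd <= sqrt(sum(g$spacing^2))))
  }
})

test_that("MetaImage volumes round-trip exactly", {
  rc <- random_grid_case(21)
  tmp <- tempfile(fileext = ".mha")
  write_mha(rc$dose, tmp)
  back <- read_mha(tmp)
  expect_equal(back$values, rc$dose$values, tolerance = 0)
  expect_equal(back$geometry$origin, rc$dose$geometry$origin)
  expect_identical(back$modality, "DOSE")

  write_mha(rc$mask, tmp)
  mb <- read_mha(tmp)
  expect_identical(mb$values, rc$mask$values)
  expect_identical(mb$name, rc$mask$name)

  f <- deformation_field(array(rnorm(prod(rc$geometry$shape) * 3),
                               c(rc$geometry$shape, 3L)), rc$geometry)
  write_mha(f, tmp)
  fb <- read_mha(tmp)
  expect_equal(fb$vectors, f$vectors, tolerance = 0)
  unlink(tmp)
})

test_that("research-format case directories round-trip", {
  tp <- fx_case_with_dose("helical")
  dir <- tempfile("casedir")
  write_case_dir(tp, dir)
  back <- read_case_dir(dir)
  expect_identical(back$id, tp$id)
  expect_equal(back$prescription_gy, tp$prescription_gy)
  expect_equal(back$dose$values, tp$dose$values, tolerance = 0)
  expect_identical(back$structures$masks$Body$values,
                   tp$structures$masks$Body$values)
  unlink(dir, recursive = TRUE)
})

test_that("DICOM-RT cases round-trip (dose to scaling quantization, masks by DSC)", {
  tp <- fx_case_with_dose("helical")
  dir <- tempfile("dicom")
  paths <- write_dicom_case(tp, dir)
  back <- read_dicom_case(dir, paths$rtdose, paths$rtstruct,
                          prescription_gy = tp$prescription_gy)
  expect_equal(back$ct$geometry$shape, tp$ct$geometry$shape)
  expect_lt(max(abs(back$ct$geometry$origin - tp$ct$geometry$origin)), 1e-6)
  expect_lt(max(abs(back$dose$values - tp$dose$values)), 1e-3)
  expect_lt(max(abs(back$ct$values - tp$ct$values)), 0.51)
  for (nm in c("Body", "PTV_Breast", "Heart", "Lung_Ipsi", "Lung_Contra")) {
    expect_gte(dice(back$structures$masks[[nm]], tp$structures$masks[[nm]]),
               0.95)
  }
  unlink(dir, recursive = TRUE)
})

test_that("an all-zero dose round-trips as all zeros", {
  tp <- fx_template()
  zc <- patient_case("zero", tp$ct,
                     image_volume(array(0, tp$ct$geometry$shape),
                                  tp$ct$geometry, "DOSE"),
                     structure_set(tp$structures$masks["Body"]))
  dir <- tempfile("dicom0")
  paths <- write_dicom_case(zc, dir)
  back <- read_dicom_case(dir, paths$rtdose, paths$rtstruct)
  expect_true(all(back$dose$values == 0))
  unlink(dir, recursive = TRUE)
})

test_that("an empty structure set writes a valid zero-ROI RTSTRUCT", {
  tp <- fx_template()
  ec <- patient_case("empty", tp$ct, structures = structure_set())
  dir <- tempfile("dicomE")
  paths <- write_dicom_case(ec, dir)
  ss <- read_rtstruct(paths$rtstruct, tp$ct$geometry)
  expect_length(ss$masks, 0)
  unlink(dir, recursive = TRUE)
})

test_that("RTDOSE DoseGridScaling is honoured on read", {
  # hand-built single-frame RTDOSE: stored value 5000, scaling 0.01 -> 50 Gy
  tp_g <- grid_geometry(c(0, 0, 0), c(3, 3, 5), c(4, 4, 1))
  ct <- image_volume(array(0, tp_g$shape), tp_g, "CT")
  dir <- tempfile("dicomS")
  write_dicom_case(patient_case("s", ct), dir)
  stored <- rep(5000L, 16)
  pix <- writeBin(stored, raw(), size = 4L, endian = "little")
  ds <- c(
    dosemimic:::dcm_el(0x0008, 0x0016, "UI", dosemimic:::UID_RTDOSE),
    dosemimic:::dcm_el(0x0008, 0x0018, "UI", "2.25.999"),
    dosemimic:::dcm_el(0x0008, 0x0060, "CS", "RTDOSE"),
    dosemimic:::dcm_el(0x0020, 0x0032, "DS", c("0", "0", "0")),
    dosemimic:::dcm_el(0x0028, 0x0008, "IS", "1"),
    dosemimic:::dcm_el(0x0028, 0x0010, "US", 4L),
    dosemimic:::dcm_el(0x0028, 0x0011, "US", 4L),
    dosemimic:::dcm_el(0x0028, 0x0030, "DS", c("3", "3")),
    dosemimic:::dcm_el(0x0028, 0x0100, "US", 32L),
    dosemimic:::dcm_el(0x3004, 0x000C, "DS", "0"),
    dosemimic:::dcm_el(0x3004, 0x000E, "DS", "0.01"),
    dosemimic:::dcm_el(0x7FE0, 0x0010, "OW", pix))
  rd <- file.path(dir, "dose_manual.dcm")
  dosemimic:::dcm_write_file(rd, dosemimic:::UID_RTDOSE, "2.25.999", ds)
  back <- read_dicom_case(dir, rtdose = rd)
  expect_equal(max(back$dose$values), 50, tolerance = 1e-9)
})

test_that("a 30 mm square contour rasterizes to about 4.5 cc on a 5 mm slice", {
  g <- grid_geometry(c(0, 0, 0), c(3, 3, 5), c(40, 40, 3))
  sq <- rbind(c(20, 20, 5), c(50, 20, 5), c(50, 50, 5), c(20, 50, 5))
  vals <- dosemimic:::rasterize_contours(list(sq), g)
  vol_cc <- sum(vals) * prod(g$spacing) / 1000
  expect_lt(abs(vol_cc - 4.5) / 4.5, 0.10)
})

test_that("frame-of-reference mismatch is a hard error", {
  tp_g <- grid_geometry(c(0, 0, 0), c(3, 3, 5), c(4, 4, 2))
  ct <- image_volume(array(0, tp_g$shape), tp_g, "CT")
  d1 <- tempfile("forA"); d2 <- tempfile("forB")
  m <- binary_mask(array(TRUE, tp_g$shape), tp_g, "Body")
  case <- patient_case("a", ct,
                       image_volume(array(1, tp_g$shape), tp_g, "DOSE"),
                       structure_set(list(Body = m)))
  p1 <- write_dicom_case(case, d1)
  p2 <- write_dicom_case(case, d2) # fresh frame of reference
  expect_error(read_dicom_case(d1, rtdose = p2$rtdose), "frame of reference")
  expect_error(read_dicom_case(d1, rtstruct = p2$rtstruct), "frame of reference")
  unlink(c(d1, d2), recursive = TRUE)
})
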