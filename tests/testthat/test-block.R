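test_that("isodose extraction is inclusive and monotone in the threshold", {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(10, 10, 10))
  u5 <- image_volume(array(5, g$shape), g, "DOSE")
  expect_true(all(extract_isodose(u5, 2)$values))
  expect_false(any(extract_isodose(u5, 5.01)$values))
  expect_true(all(extract_isodose(u5, 5)$values)) # inclusive >=

  set.seed(12)
  d <- image_volume(array(runif(1000, 0, 10), g$shape), g, "DOSE")
  lo <- extract_isodose(d, 3); hi <- extract_isodose(d, 6)
  expect_true(all(lo$values[hi$values]))
})

test_that("the helical low-dose envelope exceeds the tangential one", {
  hel <- fx_case_with_dose("helical")
  tan <- fx_case_with_dose("tangential")
  expect_gt(mask_volume_cc(extract_isodose(hel$dose, 2)),
            mask_volume_cc(extract_isodose(tan$dose, 2)))
})

test_that("block subtraction identities hold", {
  tp <- fx_template()
  body <- tp$structures$masks$Body
  empty_iso <- binary_mask(array(FALSE, body$geometry$shape), body$geometry, "iso")
  blk <- make_complete_block(body, empty_iso)
  expect_gte(dice(blk, body), 0.99)

  full_iso <- binary_mask(array(TRUE, body$geometry$shape), body$geometry, "iso")
  expect_false(any(make_complete_block(body, full_iso)$values))

  expect_error(make_complete_block(empty_iso, full_iso), "empty")
})

test_that("cylinder-minus-sphere block volume matches voxel arithmetic", {
  g <- grid_geometry(c(-60, -60, -40), c(2, 2, 2), c(61, 61, 41))
  ctr <- voxel_centers(g)
  cyl <- binary_mask(array(ctr[, 1]^2 + ctr[, 2]^2 <= 50^2, g$shape), g, "body")
  sph <- binary_mask(array(rowSums(ctr^2) <= 30^2, g$shape), g, "iso")
  # pre-smoothing: exact voxel count
  raw <- make_complete_block(cyl, sph, block_params(closing_radius_mm = 0,
                                                    opening_radius_mm = 0))
  expect_identical(sum(raw$values), sum(cyl$values & !sph$values))
  # with smoothing: within 5% of the Boolean volume
  sm <- make_complete_block(cyl, sph)
  expect_lt(abs(sum(sm$values) - sum(cyl$values & !sph$values)) /
              sum(cyl$values & !sph$values), 0.05)
})

test_that("the block avoids the isodose and stays inside the body", {
  hel <- fx_case_with_dose("helical")
  body <- hel$structures$masks$Body
  iso <- extract_isodose(hel$dose, 2)
  blk <- make_complete_block(body, iso)
  expect_false(any(blk$values & iso$values))
  expect_true(all(body$values[blk$values]))
  # smoothing changes the volume by < 10%
  raw_n <- sum(body$values & !iso$values)
  expect_lt(abs(sum(blk$values) - raw_n) / raw_n, 0.10)
})

test_that("raising the threshold never shrinks the pre-smoothing block", {
  hel <- fx_case_with_dose("helical")
  body <- hel$structures$masks$Body
  p0 <- block_params(closing_radius_mm = 0, opening_radius_mm = 0)
  b2 <- make_complete_block(body, extract_isodose(hel$dose, 2), p0)
  b4 <- make_complete_block(body, extract_isodose(hel$dose, 4), p0)
  expect_true(all(b4$values[b2$values]))
})

test_that("block constraint checks use strict inequalities", {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(10, 10, 2))
  blk <- binary_mask(array(TRUE, g$shape), g, "CompleteBlock")
  u <- function(x) image_volume(array(x, g$shape), g, "DOSE")
  r1 <- check_block_dose(blk, u(0.5))
  expect_true(r1$dmax_pass); expect_true(r1$v1_pass)
  expect_equal(r1$v1_pct, 0)
  r2 <- check_block_dose(blk, u(3))
  expect_false(r2$dmax_pass)
  # exactly half the block at 1.5 Gy: V1 = 50 fails the strict "< 50"
  half <- array(0, g$shape); half[1:5, , ] <- 1.5
  r3 <- check_block_dose(blk, image_volume(half, g, "DOSE"))
  expect_equal(r3$v1_pct, 50)
  expect_false(r3$v1_pass)
  # empty block: not applicable
  e <- binary_mask(array(FALSE, g$shape), g, "CompleteBlock")
  expect_false(check_block_dose(e, u(1))$applicable)
})

test_that("check_block_dose agrees with a voxel-counting oracle on random doses", {
  for (seed in 1:10) {
    rc <- random_grid_case(seed + 400)
    rep <- check_block_dose(rc$mask, rc$dose)
    dv <- rc$dose$values[rc$mask$values]
    expect_equal(rep$dmax_gy, max(dv))
    expect_equal(rep$v1_pct, 100 * sum(dv >= 1) / length(dv))
    expect_identical(rep$dmax_pass, max(dv) < 2)
    expect_identical(rep$v1_pass, 100 * mean(dv >= 1) < 50)
  }
})

test_that("an exported block round-trips through RTSTRUCT with high overlap", {
  hel <- fx_case_with_dose("helical")
  blk <- make_complete_block(hel$structures$masks$Body,
                             extract_isodose(hel$dose, 2))
  path <- tempfile(fileext = ".dcm")
  export_block(blk, hel, path)
  ss <- read_rtstruct(path, hel$ct$geometry)
  expect_true("CompleteBlock" %in% names(ss$masks))
  expect_gte(dice(ss$masks$CompleteBlock, blk), 0.95)
  unlink(path)
})

test_that("a name collision gets a suffixed ROI name", {
  hel <- fx_case_with_dose("helical")
  g <- hel$ct$geometry
  blk <- binary_mask(hel$structures$masks$Heart$values, g, "CompleteBlock")
  case2 <- hel
  case2$structures <- structure_set(c(
    hel$structures$masks,
    list(CompleteBlock = binary_mask(hel$structures$masks$Body$values, g,
                                     "CompleteBlock"))))
  path <- tempfile(fileext = ".dcm")
  expect_message(export_block(blk, case2, path), "collision")
  ss <- read_rtstruct(path, g)
  expect_true("CompleteBlock_1" %in% names(ss$masks))
  unlink(path)
})
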