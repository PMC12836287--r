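test_that("template anatomy has plausible structure volumes", {
  tp <- fx_template()
  st <- tp$structures$masks
  ptv <- mask_volume_cc(st$PTV_Breast)
  expect_gte(ptv, 300)
  expect_lte(ptv, 900)
  expect_gt(mask_volume_cc(st$PTV_SCF), 40)
  expect_lt(mask_volume_cc(st$PTV_SCF), 150)
  expect_gt(mask_volume_cc(st$Lung_Contra), 400)
  expect_gt(mask_volume_cc(st$Heart), 200)
})

test_that("all organs are contained in the body and key masks are disjoint", {
  tp <- fx_template()
  st <- tp$structures$masks
  body <- st$Body$values
  for (nm in setdiff(names(st), "Body"))
    expect_true(all(body[st[[nm]]$values]), info = nm)
  expect_false(any(st$Heart$values & st$Lung_Contra$values))
  expect_false(any(st$Heart$values & st$Lung_Ipsi$values))
  expect_false(any(st$PTV_Breast$values & st$Heart$values))
})

test_that("a too-small grid is rejected", {
  g <- grid_geometry(c(-50, -50, -50), c(3, 3, 5), c(30, 30, 10))
  expect_error(make_template_phantom(g), "too small")
})

test_that("deformation sampling is seed-deterministic and amplitude-scaled", {
  g <- default_phantom_grid()
  expect_identical(sample_deformation(g, 5, 0)$vectors,
                   array(0, c(g$shape, 3L)))
  f1 <- sample_deformation(g, 9, 5)
  f2 <- sample_deformation(g, 9, 5)
  expect_identical(f1$vectors, f2$vectors)
  f3 <- sample_deformation(g, 10, 5)
  expect_false(identical(f1$vectors, f3$vectors))

  body <- fx_template()$structures$masks$Body$values
  mag <- sqrt(f1$vectors[, , , 1]^2 + f1$vectors[, , , 2]^2 +
                f1$vectors[, , , 3]^2)
  m <- mean(mag[body])
  expect_gte(m, 2)
  expect_lte(m, 10)
  expect_lte(max(mag), 10 + 1e-9) # clamp at 2 x amplitude
})

test_that("both dose styles deliver exactly the prescription inside the targets", {
  for (style in c("tangential", "helical")) {
    cs <- fx_case_with_dose(style)
    ptv <- cs$structures$masks$PTV_Breast$values
    expect_lt(max(abs(cs$dose$values[ptv] - cs$prescription_gy)), 1e-6,
              label = style)
  }
})

test_that("the dose styles reproduce the low-dose-bath contrast", {
  hel <- fx_case_with_dose("helical")
  tan <- fx_case_with_dose("tangential")
  cl <- hel$structures$masks$Lung_Contra$values
  expect_gt(mean(hel$dose$values[cl]), 2)
  expect_lt(mean(tan$dose$values[cl]), 1)
})

test_that("the helical bath follows the exponential distance law", {
  cs <- fx_case_with_dose("helical")
  spec <- phantom_spec(dose_style = "helical")
  st <- cs$structures$masks
  ptv <- st$PTV_Breast$values | st$PTV_SCF$values
  body <- st$Body$values
  g <- cs$ct$geometry
  # brute-force distance for a handful of voxels, independent of the EDT
  ptv_pts <- voxel_centers(g)[as.vector(ptv), , drop = FALSE]
  cand <- which(body & !ptv)
  set.seed(1)
  ctrs <- voxel_centers(g)
  for (i in sample(cand, 5)) {
    d <- min(sqrt(colSums((t(ptv_pts) - ctrs[i, ])^2)))
    expect_equal(cs$dose$values[i],
                 min(spec$bath_dose_gy * exp(-d / spec$bath_lambda_mm),
                     1.1 * spec$prescription_gy),
                 tolerance = 1e-6)
  }
  # in particular, a voxel at distance ~lambda carries ~bath/e
  dmap <- distance_to_mask(binary_mask(ptv, g, "ptv"))
  j <- cand[which.min(abs(dmap[cand] - spec$bath_lambda_mm))]
  expect_equal(cs$dose$values[j],
               spec$bath_dose_gy * exp(-dmap[j] / spec$bath_lambda_mm),
               tolerance = 1e-6)
})

test_that("doses are bounded by 1.1 x prescription and nonnegative", {
  for (style in c("tangential", "helical")) {
    cs <- fx_case_with_dose(style)
    expect_gte(min(cs$dose$values), 0)
    expect_lte(max(cs$dose$values), 1.1 * cs$prescription_gy + 1e-9)
  }
})

test_that("cohort generation is deterministic and volume-stable", {
  spec <- phantom_spec(dose_style = "tangential", seed = 11L)
  co1 <- make_phantom_cohort(4, spec)
  co2 <- make_phantom_cohort(4, spec)
  expect_identical(co1$cases[[3]]$dose$values, co2$cases[[3]]$dose$values)
  expect_identical(co1$cases[[2]]$structures$masks$Body$values,
                   co2$cases[[2]]$structures$masks$Body$values)
  tpl_vol <- mask_volume_cc(co1$template$structures$masks$PTV_Breast)
  for (cs in co1$cases) {
    v <- mask_volume_cc(cs$structures$masks$PTV_Breast)
    expect_lt(abs(v - tpl_vol) / tpl_vol, 0.40)
  }
})

test_that("zero-amplitude cohorts reproduce the template", {
  spec <- phantom_spec(dose_style = "helical", deform_amplitude_mm = 0)
  co <- make_phantom_cohort(2, spec)
  expect_identical(co$cases[[1]]$ct$values, co$template$ct$values)
  expect_identical(co$cases[[2]]$structures$masks$Body$values,
                   co$template$structures$masks$Body$values)
  expect_error(make_phantom_cohort(1, spec), "at least 2")
})

test_that("the helical 2-Gy envelope exceeds the tangential one on every case", {
  for (style in c("helical", "tangential")) {
    assign(paste0("v_", style),
           vapply(make_phantom_cohort(3, phantom_spec(dose_style = style,
                                                      seed = 5L))$cases,
                  function(cs) mask_volume_cc(extract_isodose(cs$dose, 2)),
                  numeric(1)))
  }
  expect_true(all(v_helical > v_tangential))
})

test_that("a case without targets cannot receive a synthetic dose", {
  tp <- fx_template()
  bare <- patient_case("bare", tp$ct,
                       structures = structure_set(tp$structures$masks["Body"]))
  expect_error(synth_dose(bare, phantom_spec()), "PTV")
})
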