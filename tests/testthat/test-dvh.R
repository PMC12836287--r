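test_that("cumulative DVHs are exact voxel-counting curves", {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(10, 10, 1))
  m <- binary_mask(array(TRUE, g$shape), g, "roi")
  u10 <- image_volume(array(10, g$shape), g, "DOSE")
  cv <- cumulative_dvh(u10, m)
  expect_equal(cv$rel_volume_pct[cv$edges_gy <= 10], rep(100, sum(cv$edges_gy <= 10)))
  expect_equal(cv$rel_volume_pct[cv$edges_gy > 10], rep(0, sum(cv$edges_gy > 10)))
  expect_equal(cv$rel_volume_pct[1], 100)
  expect_true(all(diff(cv$rel_volume_pct) <= 0))

  half <- array(0, g$shape); half[1:5, , ] <- 10
  ch <- cumulative_dvh(image_volume(half, g, "DOSE"), m)
  mid <- ch$edges_gy > 0.02 & ch$edges_gy <= 10
  expect_equal(unique(ch$rel_volume_pct[mid]), 50)

  expect_error(cumulative_dvh(u10, binary_mask(array(FALSE, g$shape), g, "e")),
               "empty")
})

test_that("V(x) read off the DVH equals the brute-force count", {
  for (seed in 1:5) {
    rc <- random_grid_case(seed + 100)
    cv <- cumulative_dvh(rc$dose, rc$mask)
    for (x in c(0, 1, 7.3, 25, 59)) {
      idx <- findInterval(x, cv$edges_gy)
      # the curve at the bin edge just below x bounds V(x) by construction;
      # compare exactly at an edge
      edge <- cv$edges_gy[idx]
      expect_equal(cv$rel_volume_pct[idx],
                   oracle_v_at_dose(rc$dose, rc$mask, edge),
                   tolerance = 1e-9)
      expect_equal(v_at_dose(rc$dose, rc$mask, x),
                   oracle_v_at_dose(rc$dose, rc$mask, x))
    }
  }
})

test_that("Dx% and Vx follow their enumeration examples", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(10, 10, 1))
  m <- binary_mask(array(TRUE, g$shape), g, "roi")
  d <- image_volume(array(1:100, g$shape), g, "DOSE")
  expect_equal(v_at_dose(d, m, 25), 76)
  u5 <- image_volume(array(5, g$shape), g, "DOSE")
  expect_equal(v_at_dose(u5, m, 5), 100)
  expect_equal(d_at_volume(u5, m, 50), 5)
  expect_error(d_at_volume(u5, m, 0), "x_pct")
  expect_error(d_at_volume(u5, m, 101), "x_pct")

  # two-valued target: D2 = 52, D98 = 48, D50 = 52 -> HI = 4/52
  tv <- array(c(rep(48, 50), rep(52, 50)), g$shape)
  td <- image_volume(tv, g, "DOSE")
  expect_equal(d_at_volume(td, m, 2), 52)
  expect_equal(d_at_volume(td, m, 98), 48)
  expect_equal(d_at_volume(td, m, 50), 52)
  expect_equal(homogeneity_index(td, m), 4 / 52)
  expect_equal(homogeneity_index(u5, m), 0)
})

test_that("widening the dose spread increases the homogeneity index", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(10, 10, 1))
  m <- binary_mask(array(TRUE, g$shape), g, "roi")
  his <- vapply(c(1, 2, 4), function(s) {
    v <- array(50 + s * rep(seq(-1, 1, length.out = 100)), g$shape)
    homogeneity_index(image_volume(v, g, "DOSE"), m)
  }, numeric(1))
  expect_true(all(diff(his) > 0))
})

test_that("integral dose matches its oracle and is additive", {
  g <- grid_geometry(c(0, 0, 0), c(10, 10, 10), c(10, 10, 10))
  m <- binary_mask(array(TRUE, g$shape), g, "roi") # exactly 1 L
  u2 <- image_volume(array(2, g$shape), g, "DOSE")
  expect_equal(integral_dose(u2, m), 2, tolerance = 1e-12)
  z <- image_volume(array(0, g$shape), g, "DOSE")
  expect_equal(integral_dose(z, m), 0)
  expect_warning(
    e <- integral_dose(u2, binary_mask(array(FALSE, g$shape), g, "e")), "empty")
  expect_equal(e, 0)

  for (seed in 1:5) {
    rc <- random_grid_case(seed + 200)
    expect_equal(integral_dose(rc$dose, rc$mask),
                 oracle_integral_dose(rc$dose, rc$mask),
                 tolerance = 1e-9)
    # additivity over a disjoint partition
    a <- rc$mask$values & array(rep(c(TRUE, FALSE), length.out =
                                      prod(rc$geometry$shape)), rc$geometry$shape)
    b <- rc$mask$values & !a
    if (any(a) && any(b)) {
      ia <- integral_dose(rc$dose, binary_mask(a, rc$geometry, "a"))
      ib <- integral_dose(rc$dose, binary_mask(b, rc$geometry, "b"))
      expect_equal(ia + ib, integral_dose(rc$dose, rc$mask), tolerance = 1e-9)
    }
  }
})

test_that("conformity index follows the Paddick formula", {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(20, 20, 5))
  tvals <- array(FALSE, g$shape); tvals[5:14, 5:14, 2:4] <- TRUE
  target <- binary_mask(tvals, g, "ptv")
  # dose exactly on the target -> CI 1
  dv <- array(0, g$shape); dv[tvals] <- 50
  expect_equal(conformity_index(image_volume(dv, g, "DOSE"), target, 50), 1)
  # PIV = 2 x TV, fully covering -> 0.5
  pv <- tvals
  pv[which(!tvals)[seq_len(sum(tvals))]] <- TRUE
  dv2 <- array(0, g$shape); dv2[pv] <- 50
  expect_equal(conformity_index(image_volume(dv2, g, "DOSE"), target, 50), 0.5)
  # disjoint PIV -> 0
  dv3 <- array(0, g$shape); dv3[15:19, 15:19, 1] <- 50
  expect_equal(conformity_index(image_volume(dv3, g, "DOSE"), target, 50), 0)
  # no PIV at all -> 0 with a warning
  expect_warning(ci0 <- conformity_index(image_volume(array(0, g$shape), g,
                                                      "DOSE"), target, 50),
                 "empty")
  expect_equal(ci0, 0)
  # coverage variant
  expect_equal(conformity_index(image_volume(dv, g, "DOSE"), target, 50,
                                method = "coverage"), 1)
})

test_that("dice follows its definition and symmetry", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(10, 10, 2))
  av <- array(FALSE, g$shape); av[1:100] <- TRUE
  bv <- array(FALSE, g$shape); bv[61:120] <- TRUE
  a <- binary_mask(av, g, "a"); b <- binary_mask(bv, g, "b")
  expect_equal(dice(a, b), 2 * 40 / 160) # |A|=100, |B|=60, |A n B|=40 -> 0.5
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 1)
  e <- binary_mask(array(FALSE, g$shape), g, "e")
  expect_equal(dice(e, e), 1)
  expect_equal(dice(a, e), 0)
  g2 <- grid_geometry(c(1, 0, 0), c(1, 1, 1), c(10, 10, 2))
  expect_error(dice(a, binary_mask(bv, g2, "b")), "mismatch")
})

test_that("clinical goals use strict inequalities and flag missing structures", {
  hel <- fx_case_with_dose("helical")
  goals <- evaluate_clinical_goals(hel)
  expect_true(is.na(goals$pass[goals$structure == "LeftVentricle"]))
  heart_row <- goals[goals$structure == "Heart", ]
  expect_identical(heart_row$pass, heart_row$value < 5)

  # boundary: V95% exactly 95 fails the strict "> 95"
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(10, 10, 1))
  pv <- array(TRUE, g$shape)
  dv <- array(50, g$shape); dv[1:5, 1, 1] <- 10
  cs <- patient_case("b", image_volume(array(0, g$shape), g, "CT"),
                     image_volume(dv, g, "DOSE"),
                     structure_set(list(PTV_Breast = binary_mask(pv, g, "PTV_Breast"))),
                     prescription_gy = 50)
  gl <- evaluate_clinical_goals(cs)
  row <- gl[gl$structure == "PTV_Breast", ]
  expect_equal(row$value, 95)
  expect_false(row$pass)

  none <- patient_case("n", image_volume(array(0, g$shape), g, "CT"))
  gl2 <- evaluate_clinical_goals(none)
  expect_true(all(is.na(gl2$pass)))
})

test_that("plan metrics agree with their oracles on the phantom", {
  hel <- fx_case_with_dose("helical")
  pm <- plan_metrics(hel)
  heart <- hel$structures$masks$Heart
  row <- pm[pm$structure == "Heart", ]
  expect_equal(row$mean_gy, oracle_mean(hel$dose, heart), tolerance = 1e-12)
  expect_equal(row$v5_pct, oracle_v_at_dose(hel$dose, heart, 5))
  expect_equal(row$integral_dose_gyl, oracle_integral_dose(hel$dose, heart),
               tolerance = 1e-9)
  expect_false(any(is.na(pm$ci[grepl("^PTV", pm$structure)])))
})
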