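# Dose-volume histogram machinery and plan-quality metrics: Vx / Vx% / Dx%,
# mean/max/min dose, Paddick conformity index, ICRU-83 homogeneity index,
# integral dose (Gy.L), Dice overlap, and the clinical dose-volume goal
# checker. All metrics are exact voxel-counting quantities.

#' Cumulative dose-volume histogram
#'
#' Exact voxel-counting cumulative DVH: for each bin edge d, the percentage
#' of the structure volume receiving at least d Gy. Starts at 100% at 0 Gy,
#' is non-increasing, and reaches 0% above the maximum dose.
#'
#' @param dose an `image_volume` (DOSE).
#' @param mask a nonempty `binary_mask` on the same geometry.
#' @param bin_gy bin width, Gy.
#' @return an object of class `dvh_curve`: `structure`, `edges_gy`,
#'   `rel_volume_pct`, `volume_cc`.
#' @export
cumulative_dvh <- function(dose, mask, bin_gy = 0.01) {
  stopifnot(geom_equal(dose$geometry, mask$geometry), bin_gy > 0)
  dv <- dose$values[mask$values]
  if (!length(dv)) stop("mask is empty")
  edges <- seq(0, max(dv) + bin_gy, by = bin_gy)
  # count(dose >= edge) via the sorted sample
  s <- sort(dv)
  n <- length(s)
  below <- findInterval(edges - 1e-12, s) # values strictly below edge
  rel <- 100 * (n - below) / n
  structure(list(structure = mask$name, edges_gy = edges,
                 rel_volume_pct = rel,
                 volume_cc = mask_volume_cc(mask)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve '%s'> %.2f cc, Dmax bin %.2f Gy\n", x$structure,
              x$volume_cc, max(x$edges_gy)))
  invisible(x)
}

#' Volume receiving at least a dose (Vx)
#'
#' @param dose an `image_volume`.
#' @param mask a nonempty `binary_mask`.
#' @param x_gy dose threshold, Gy (inclusive `>=`).
#' @return percent of the structure volume.
#' @export
v_at_dose <- function(dose, mask, x_gy) {
  stopifnot(geom_equal(dose$geometry, mask$geometry))
  dv <- dose$values[mask$values]
  if (!length(dv)) stop("mask is empty")
  100 * mean(dv >= x_gy)
}

#' Volume receiving at least a percentage of prescription (Vx%)
#' @inheritParams v_at_dose
#' @param x_pct percentage of `prescription_gy`.
#' @param prescription_gy prescription, Gy.
#' @return percent of the structure volume.
#' @export
v_at_pct <- function(dose, mask, x_pct, prescription_gy)
  v_at_dose(dose, mask, x_pct / 100 * prescription_gy)

#' Dose to the hottest x% of a structure (Dx%)
#'
#' The largest dose d such that at least x% of the structure receives >= d,
#' linearly interpolated between the sorted voxel doses.
#'
#' @inheritParams v_at_dose
#' @param x_pct volume percentage in (0, 100].
#' @return dose, Gy.
#' @export
d_at_volume <- function(dose, mask, x_pct) {
  if (x_pct <= 0 || x_pct > 100) stop("x_pct must be in (0, 100]")
  stopifnot(geom_equal(dose$geometry, mask$geometry))
  dv <- dose$values[mask$values]
  if (!length(dv)) stop("mask is empty")
  s <- sort(dv, decreasing = TRUE)
  r <- x_pct / 100 * length(s)
  if (r <= 1) return(s[1])
  lo <- floor(r); hi <- ceiling(r)
  if (lo == hi) return(s[r])
  s[lo] + (r - lo) * (s[hi] - s[lo])
}

#' Mean, maximum and minimum structure dose
#' @inheritParams v_at_dose
#' @return named numeric vector `mean`, `max`, `min` (Gy).
#' @export
dose_stats <- function(dose, mask) {
  stopifnot(geom_equal(dose$geometry, mask$geometry))
  dv <- dose$values[mask$values]
  if (!length(dv)) stop("mask is empty")
  c(mean = mean(dv), max = max(dv), min = min(dv))
}

#' Integral dose (Gy x Liter)
#'
#' Mean structure dose times structure volume in liters, at unit tissue
#' density; algebraically the voxel-wise dose sum times the voxel volume.
#'
#' @inheritParams v_at_dose
#' @return integral dose, Gy.L; 0 with a warning for an empty mask.
#' @export
integral_dose <- function(dose, mask) {
  stopifnot(geom_equal(dose$geometry, mask$geometry))
  dv <- dose$values[mask$values]
  if (!length(dv)) {
    warning("empty mask: integral dose 0")
    return(0)
  }
  mean(dv) * mask_volume_cc(mask) / 1000
}

#' Conformity index of target coverage
#'
#' Default is the Paddick index `CI = TV_PIV^2 / (TV x PIV)` where PIV is
#' the volume receiving at least `iso_fraction` of the prescription and
#' TV_PIV its overlap with the target; `method = "coverage"` gives the
#' simple ratio `TV_PIV / TV`.
#'
#' @param dose an `image_volume`.
#' @param target a nonempty `binary_mask`.
#' @param prescription_gy prescription, Gy.
#' @param iso_fraction prescription fraction defining the PIV.
#' @param method `"paddick"` or `"coverage"`.
#' @return CI in [0, 1]; 0 with a warning when the PIV is empty.
#' @export
conformity_index <- function(dose, target, prescription_gy,
                             iso_fraction = 0.95,
                             method = c("paddick", "coverage")) {
  method <- match.arg(method)
  stopifnot(geom_equal(dose$geometry, target$geometry), prescription_gy > 0)
  tv <- sum(target$values)
  if (tv == 0) stop("target mask is empty")
  piv_mask <- dose$values >= iso_fraction * prescription_gy
  piv <- sum(piv_mask)
  if (piv == 0) {
    warning("prescription isodose volume is empty; CI = 0")
    return(0)
  }
  tvpiv <- sum(piv_mask & target$values)
  if (method == "paddick") tvpiv^2 / (tv * piv) else tvpiv / tv
}

#' Homogeneity index of target dose
#'
#' ICRU-83 style: `HI = (D2% - D98%) / D50%` (0 for a perfectly uniform
#' dose; larger is less homogeneous).
#'
#' @inheritParams v_at_dose
#' @param target a nonempty `binary_mask`.
#' @return HI (dimensionless).
#' @export
homogeneity_index <- function(dose, target) {
  d50 <- d_at_volume(dose, target, 50)
  if (d50 == 0) stop("D50% is zero; homogeneity index undefined")
  (d_at_volume(dose, target, 2) - d_at_volume(dose, target, 98)) / d50
}

#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b `binary_mask`s on one geometry.
#' @return DSC in [0, 1].
#' @export
dice <- function(a, b) {
  if (!geom_equal(a$geometry, b$geometry)) stop("geometry mismatch")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) return(1)
  2 * sum(a$values & b$values) / (na + nb)
}

#' Evaluate the clinical dose-volume goals
#'
#' Checks the institutional breast-planning goals: PTV V95% > 95%, spinal
#' cord Dmax < 45 Gy, heart mean < 5 Gy, ipsilateral lung V5/V10/V20/V30 <
#' 50/40/30/20%, esophagus Dmax < 40 Gy, left-ventricle mean < 5.5 Gy.
#' Strict inequalities throughout; structures missing from the case are
#' marked unevaluated.
#'
#' @param case a `patient_case` with a dose.
#' @param dose optional dose overriding `case$dose`.
#' @return data.frame with `structure`, `parameter`, `goal`, `value`,
#'   `pass` (NA when unevaluated).
#' @export
evaluate_clinical_goals <- function(case, dose = case$dose) {
  st <- case$structures$masks
  rx <- case$prescription_gy
  rows <- list(
    list("PTV_Breast", "V95% (%)", ">95",
         function(m) v_at_pct(dose, m, 95, rx), `>`, 95),
    list("PTV_SCF", "V95% (%)", ">95",
         function(m) v_at_pct(dose, m, 95, rx), `>`, 95),
    list("SpinalCord", "Dmax (Gy)", "<45",
         function(m) dose_stats(dose, m)[["max"]], `<`, 45),
    list("Heart", "Mean dose (Gy)", "<5",
         function(m) dose_stats(dose, m)[["mean"]], `<`, 5),
    list("Lung_Ipsi", "V5 (%)", "<50", function(m) v_at_dose(dose, m, 5), `<`, 50),
    list("Lung_Ipsi", "V10 (%)", "<40", function(m) v_at_dose(dose, m, 10), `<`, 40),
    list("Lung_Ipsi", "V20 (%)", "<30", function(m) v_at_dose(dose, m, 20), `<`, 30),
    list("Lung_Ipsi", "V30 (%)", "<20", function(m) v_at_dose(dose, m, 30), `<`, 20),
    list("Esophagus", "Dmax (Gy)", "<40",
         function(m) dose_stats(dose, m)[["max"]], `<`, 40),
    list("LeftVentricle", "Mean dose (Gy)", "<5.5",
         function(m) dose_stats(dose, m)[["mean"]], `<`, 5.5))
  out <- do.call(rbind, lapply(rows, function(r) {
    m <- st[[r[[1]]]]
    if (is.null(m) || !any(m$values) || is.null(dose)) {
      data.frame(structure = r[[1]], parameter = r[[2]], goal = r[[3]],
                 value = NA_real_, pass = NA)
    } else {
      v <- r[[4]](m)
      data.frame(structure = r[[1]], parameter = r[[2]], goal = r[[3]],
                 value = v, pass = r[[5]](v, r[[6]]))
    }
  }))
  rownames(out) <- NULL
  out
}

#' Per-structure plan metrics table
#'
#' Tidy per-structure summary: mean/max/min dose, V2/V5/V10/V20/V30, V95%,
#' D2%/D50%/D98%, integral dose, and for the targets CI and HI.
#'
#' @param case a `patient_case` with dose and structures.
#' @param dose optional dose overriding `case$dose`.
#' @return data.frame, one row per structure.
#' @export
plan_metrics <- function(case, dose = case$dose) {
  st <- case$structures$masks
  rx <- case$prescription_gy
  rows <- lapply(st, function(m) {
    if (!any(m$values)) return(NULL)
    s <- dose_stats(dose, m)
    is_target <- grepl("^PTV", m$name)
    data.frame(
      structure = m$name, volume_cc = mask_volume_cc(m),
      mean_gy = s[["mean"]], max_gy = s[["max"]], min_gy = s[["min"]],
      v2_pct = v_at_dose(dose, m, 2), v5_pct = v_at_dose(dose, m, 5),
      v10_pct = v_at_dose(dose, m, 10), v20_pct = v_at_dose(dose, m, 20),
      v30_pct = v_at_dose(dose, m, 30),
      v95pct_pct = v_at_pct(dose, m, 95, rx),
      d2pct_gy = d_at_volume(dose, m, 2),
      d50pct_gy = d_at_volume(dose, m, 50),
      d98pct_gy = d_at_volume(dose, m, 98),
      integral_dose_gyl = integral_dose(dose, m),
      ci = if (is_target) conformity_index(dose, m, rx) else NA_real_,
      hi = if (is_target) homogeneity_index(dose, m) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
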