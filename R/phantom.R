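# Seeded deformable thorax-phantom cohort with analytic dose styles:
# "tangential" (tight oblique corridors, minimal contralateral dose) and
# "helical" (prescription-conformal target dose plus an extended low-dose
# bath). Each cohort member is a smooth B-spline deformation of a common
# template, emulating inter-patient anatomical variation in a left-breast
# radiotherapy population.

#' Phantom cohort specification
#'
#' @param grid `grid_geometry`; default 96 x 96 x 48 voxels at 3 x 3 x 5 mm
#'   (dose-grid resolution and CT slice thickness typical of this treatment
#'   site).
#' @param seed integer; the cohort is a pure function of the
#'   `phantom_spec` object, seed included.
#' @param deform_amplitude_mm scale of inter-patient deformation (mm);
#'   per-voxel displacement is clamped at twice this value.
#' @param dose_style `"tangential"` or `"helical"`.
#' @param prescription_gy prescribed dose, 50 or 50.4 Gy.
#' @param bath_dose_gy helical low-dose-bath level at the target surface (Gy).
#' @param bath_lambda_mm exponential decay length of the bath (mm).
#' @param tangential_falloff_mm lateral decay of the tangential corridors (mm).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = default_phantom_grid(), seed = 42L,
                         deform_amplitude_mm = 5,
                         dose_style = c("tangential", "helical"),
                         prescription_gy = 50,
                         bath_dose_gy = 6, bath_lambda_mm = 40,
                         tangential_falloff_mm = 12) {
  dose_style <- match.arg(dose_style)
  stopifnot(deform_amplitude_mm >= 0, bath_dose_gy > 0, bath_lambda_mm > 0,
            tangential_falloff_mm > 0, prescription_gy > 0)
  structure(list(grid = grid, seed = as.integer(seed),
                 deform_amplitude_mm = deform_amplitude_mm,
                 dose_style = dose_style,
                 prescription_gy = prescription_gy,
                 bath_dose_gy = bath_dose_gy,
                 bath_lambda_mm = bath_lambda_mm,
                 tangential_falloff_mm = tangential_falloff_mm),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_phantom_grid <- function() {
  shape <- c(96L, 96L, 48L); spacing <- c(3, 3, 5)
  extent <- (shape - 1) * spacing
  grid_geometry(-extent / 2, spacing, shape)
}

# ellipsoid membership over precomputed center-coordinate arrays
.ellipsoid <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
}

#' Template thorax phantom (anatomy only, no dose)
#'
#' Builds the common anatomical template: elliptic-cylinder body, two
#' ellipsoidal lungs (-700 HU), a left-shifted spherical heart, a left-sided
#' breast + chest-wall target (PTV_Breast), a superior supraclavicular
#' target (PTV_SCF), a contralateral breast, esophagus and spinal cord.
#' The ipsilateral side is the patient's left (+x in LPS).
#'
#' @param grid a `grid_geometry`; must be large enough to contain the organs
#'   (about 24 cm x 20 cm x 20 cm).
#' @return a `patient_case` with CT and structures, no dose.
#' @export
make_template_phantom <- function(grid = default_phantom_grid()) {
  g <- grid
  extent <- (g$shape - 1) * g$spacing
  if (any(extent < c(240, 180, 200)))
    stop("grid too small to contain the thorax template")
  xs <- g$origin[1] + (seq_len(g$shape[1]) - 1) * g$spacing[1]
  ys <- g$origin[2] + (seq_len(g$shape[2]) - 1) * g$spacing[2]
  zs <- g$origin[3] + (seq_len(g$shape[3]) - 1) * g$spacing[3]
  X <- array(rep(xs, times = g$shape[2] * g$shape[3]), g$shape)
  Y <- array(rep(rep(ys, each = g$shape[1]), times = g$shape[3]), g$shape)
  Z <- array(rep(zs, each = g$shape[1] * g$shape[2]), g$shape)

  chest <- (X / 105)^2 + (Y / 80)^2 <= 1
  # breast mounds protrude from the anterior chest; the external body is
  # chest plus mounds
  breast_l <- .ellipsoid(X, Y, Z, c(58, -72, 5), c(50, 42, 60))
  breast_r <- .ellipsoid(X, Y, Z, c(-58, -72, 5), c(45, 37, 54))
  body <- chest | breast_l | breast_r
  lung_l <- .ellipsoid(X, Y, Z, c(55, 2, 5), c(36, 52, 82)) & chest
  lung_r <- .ellipsoid(X, Y, Z, c(-42, -16, 5), c(38, 46, 84)) & chest
  heart <- .ellipsoid(X, Y, Z, c(14, -12, -40), c(48, 48, 48)) & chest &
    !lung_l & !lung_r
  # target: whole left breast mound plus the superficial chest wall
  # (medial border crossing the sternum, as for chest-wall + IMN coverage)
  inner <- (X / 88)^2 + (Y / 62)^2 <= 1
  shell <- chest & !inner & (Y < 12) & (X > -40) & (Z > -65) & (Z < 60)
  ptv_breast <- ((breast_l & !inner) | shell) & body & !lung_l & !lung_r & !heart
  ptv_scf <- .ellipsoid(X, Y, Z, c(38, -30, 92), c(30, 25, 28)) & chest &
    !lung_l & !ptv_breast
  breast_c <- breast_r & !inner & body & !lung_r & !ptv_breast
  esoph <- ((X - 2)^2 + (Y - 20)^2 <= 8^2) & (Z > -80) & (Z < 95) & chest &
    !lung_l & !lung_r
  cord <- (X^2 + (Y - 58)^2 <= 6^2) & chest

  ct <- array(-1000, g$shape)
  ct[body] <- 0
  ct[lung_l | lung_r] <- -700
  ct[cord] <- 300 # vertebral surrogate: gives the registration a spine anchor
  # partial-volume emulation: real CT edges are spread over 1-2 voxels
  ct <- smooth_volume(image_volume(ct, g, "CT"), 0.6)$values
  masks <- list(
    Body = binary_mask(body, g, "Body"),
    PTV_Breast = binary_mask(ptv_breast, g, "PTV_Breast"),
    PTV_SCF = binary_mask(ptv_scf, g, "PTV_SCF"),
    Heart = binary_mask(heart, g, "Heart"),
    Lung_Ipsi = binary_mask(lung_l, g, "Lung_Ipsi"),
    Lung_Contra = binary_mask(lung_r, g, "Lung_Contra"),
    Breast_Contra = binary_mask(breast_c, g, "Breast_Contra"),
    Esophagus = binary_mask(esoph, g, "Esophagus"),
    SpinalCord = binary_mask(cord, g, "SpinalCord"))
  patient_case("template", image_volume(ct, g, "CT"),
               structures = structure_set(masks))
}

#' Sample a smooth random deformation field
#'
#' Random cubic B-spline coefficients on a 50 mm control grid, evaluated on
#' the image grid and clamped so that no displacement exceeds twice the
#' amplitude. Deterministic in `seed`.
#'
#' @param grid `grid_geometry` of the fixed frame.
#' @param seed integer seed.
#' @param amplitude_mm deformation scale (mm); 0 gives the zero field.
#' @param control_spacing_mm control-point spacing (mm).
#' @return a `deformation_field`.
#' @export
sample_deformation <- function(grid, seed, amplitude_mm,
                               control_spacing_mm = 50) {
  g <- grid
  if (amplitude_mm == 0) return(zero_field(g))
  cs <- rep(control_spacing_mm, 3)
  corigin <- g$origin - 2 * cs
  extent <- (g$shape - 1) * g$spacing
  cshape <- as.integer(ceiling(extent / cs) + 5)
  coef <- withr_seed(seed, {
    array(rnorm(prod(cshape) * 3, sd = 2 * amplitude_mm), c(cshape, 3L))
  })
  vec <- cpp_bspline_field(as.numeric(coef), cshape, corigin, cs,
                           g$shape, g$origin, g$spacing)
  mag <- sqrt(vec[, , , 1]^2 + vec[, , , 2]^2 + vec[, , , 3]^2)
  cap <- 2 * amplitude_mm
  scl <- ifelse(mag > cap, cap / pmax(mag, 1e-12), 1)
  for (d in 1:3) vec[, , , d] <- vec[, , , d] * scl
  deformation_field(vec, g)
}

# evaluate expr with a local, restored RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize an analytic dose distribution for a phantom case
#'
#' Tangential style: full prescription inside the targets and along two
#' oblique corridor slabs through the breast (emulating opposed tangential
#' arcs), decaying exponentially outside the slabs and beyond the target's
#' cranio-caudal extent; essentially no contralateral dose. Helical style:
#' prescription-conformal target dose plus a low-dose bath
#' `bath_dose_gy * exp(-d/bath_lambda_mm)` everywhere in the body, `d` the
#' Euclidean distance to the target. Both styles are zero outside the body
#' and clipped to 1.1 x prescription.
#'
#' @param case a `patient_case` with Body, PTV_Breast and PTV_SCF masks.
#' @param spec a `phantom_spec`.
#' @return an `image_volume` with modality DOSE on the case geometry.
#' @export
synth_dose <- function(case, spec) {
  g <- case$ct$geometry
  st <- case$structures$masks
  if (is.null(st$PTV_Breast) || is.null(st$PTV_SCF))
    stop("case must carry PTV_Breast and PTV_SCF masks")
  body <- st$Body$values
  ptv <- st$PTV_Breast$values | st$PTV_SCF$values
  rx <- spec$prescription_gy
  if (spec$dose_style == "helical") {
    d <- distance_to_mask(binary_mask(ptv, g, "ptv"))
    dose <- spec$bath_dose_gy * exp(-d / spec$bath_lambda_mm)
    dose[ptv] <- rx
    dose[!body] <- 0
  } else {
    xs <- g$origin[1] + (seq_len(g$shape[1]) - 1) * g$spacing[1]
    ys <- g$origin[2] + (seq_len(g$shape[2]) - 1) * g$spacing[2]
    zs <- g$origin[3] + (seq_len(g$shape[3]) - 1) * g$spacing[3]
    X <- array(rep(xs, times = g$shape[2] * g$shape[3]), g$shape)
    Y <- array(rep(rep(ys, each = g$shape[1]), times = g$shape[3]), g$shape)
    Z <- array(rep(zs, each = g$shape[1] * g$shape[2]), g$shape)
    pb <- st$PTV_Breast$values
    idx <- which(pb)
    ctr <- c(mean(X[idx]), mean(Y[idx]))
    zr <- range(Z[idx])
    half_w <- 30
    corridor <- function(theta) {
      n <- c(-sin(theta), cos(theta)) # slab normal (axial plane)
      dn <- abs(n[1] * (X - ctr[1]) + n[2] * (Y - ctr[2]))
      pmax(dn - half_w, 0)
    }
    base_theta <- atan2(39, 105) # tangent direction of the left chest wall
    d1 <- corridor(base_theta - 8 * pi / 180)
    d2 <- corridor(base_theta + 8 * pi / 180)
    dmin <- pmin(d1, d2)
    dz <- pmax(pmax(zr[1] - 10 - Z, Z - zr[2] - 10), 0)
    dose <- rx * exp(-(dmin + dz) / spec$tangential_falloff_mm)
    # tangent beams skim the chest wall: the deep chest core sees no
    # primary fluence
    deep <- (X / 85)^2 + ((Y - 5) / 58)^2 <= 1
    dose[deep] <- 0
    # medial field border: tangent fields do not cross to the
    # contralateral side
    dose <- dose * exp(-pmax(-25 - X, 0) / spec$tangential_falloff_mm)
    dose[ptv] <- rx
    dose[!body] <- 0
  }
  dose <- pmin(dose, 1.1 * rx)
  dim(dose) <- g$shape
  image_volume(dose, g, "DOSE")
}

#' Generate a deformable phantom cohort
#'
#' Each case is the template warped by a random smooth deformation (CT by
#' linear, masks by nearest-neighbour pull-back), with its dose synthesized
#' in the deformed geometry. Case 1 is the designated reference. The cohort
#' is bit-reproducible from its `phantom_spec` (seed included).
#'
#' @param n number of cases, >= 2.
#' @param spec a `phantom_spec`.
#' @return an object of class `phantom_cohort`: list with `template`,
#'   `cases` (list of `patient_case`), and `true_fields`.
#' @export
make_phantom_cohort <- function(n, spec = phantom_spec()) {
  if (n < 2) stop("a cohort needs at least 2 cases")
  template <- make_template_phantom(spec$grid)
  cases <- vector("list", n)
  fields <- vector("list", n)
  for (i in seq_len(n)) {
    f <- sample_deformation(spec$grid, spec$seed + i, spec$deform_amplitude_mm)
    ct <- apply_field(f, template$ct, mode = "linear", fill = -1000)
    masks <- lapply(template$structures$masks, function(m)
      apply_field(f, m, mode = "nearest"))
    cs <- patient_case(sprintf("case%02d", i), ct,
                       structures = structure_set(masks),
                       prescription_gy = spec$prescription_gy)
    cs$dose <- synth_dose(cs, spec)
    cases[[i]] <- cs
    fields[[i]] <- f
  }
  structure(list(template = template, cases = cases, true_fields = fields,
                 spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases, style %s, seed %d\n",
              length(x$cases), x$spec$dose_style, x$spec$seed))
  invisible(x)
}
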