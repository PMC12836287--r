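#' @useDynLib dosemimic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile
#' @importFrom utils head tail write.csv
NULL

#' Grid geometry of a volumetric image
#'
#' Describes the sampling lattice shared by CT volumes, dose grids, binary
#' masks and deformation fields: the physical position (mm, DICOM LPS) of the
#' center of voxel (1,1,1), per-axis voxel spacing, voxel counts, and
#' direction cosines. Only axis-aligned (identity orientation) grids are
#' supported by the registration and DICOM layers.
#'
#' @param origin numeric length-3, mm position of the first voxel center.
#' @param spacing numeric length-3, mm, all > 0.
#' @param shape integer length-3 voxel counts, all >= 1.
#' @param orientation 3x3 orthonormal direction-cosine matrix.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(origin, spacing, shape, orientation = diag(3)) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(shape) == 3L)
  if (any(spacing <= 0)) stop("grid spacing must be > 0 on all axes")
  if (any(shape < 1L)) stop("grid shape must be >= 1 on all axes")
  orientation <- as.matrix(orientation)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation must be orthonormal")
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 orientation = orientation),
            class = "grid_geometry")
}

#' @export
format.grid_geometry <- function(x, ...) {
  sprintf("grid %dx%dx%d @ %.3gx%.3gx%.3g mm, origin (%.4g, %.4g, %.4g)",
          x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3],
          x$origin[1], x$origin[2], x$origin[3])
}

#' @export
print.grid_geometry <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

geom_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

#' Voxel volume in cubic centimeters
#' @param geometry a `grid_geometry`.
#' @return scalar, cc per voxel.
#' @export
voxel_volume_cc <- function(geometry) prod(geometry$spacing) / 1000

#' Physical coordinates of every voxel center
#'
#' @param geometry a `grid_geometry`.
#' @return an n-voxel x 3 matrix (column-major voxel order), mm.
#' @export
voxel_centers <- function(geometry) {
  g <- geometry
  xs <- g$origin[1] + (seq_len(g$shape[1]) - 1) * g$spacing[1]
  ys <- g$origin[2] + (seq_len(g$shape[2]) - 1) * g$spacing[2]
  zs <- g$origin[3] + (seq_len(g$shape[3]) - 1) * g$spacing[3]
  cbind(rep(xs, times = g$shape[2] * g$shape[3]),
        rep(rep(ys, each = g$shape[1]), times = g$shape[3]),
        rep(zs, each = g$shape[1] * g$shape[2]))
}

#' Scalar image volume (CT or dose)
#'
#' @param values numeric 3D array matching `geometry$shape`. HU for CT,
#'   Gy for dose.
#' @param geometry a `grid_geometry`.
#' @param modality `"CT"` or `"DOSE"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, geometry, modality = c("CT", "DOSE")) {
  modality <- match.arg(modality)
  values <- as.array(values)
  stopifnot(inherits(geometry, "grid_geometry"))
  if (!identical(dim(values), NULL) && !all(dim(values) == geometry$shape))
    stop("values dimensions do not match geometry shape")
  if (is.null(dim(values))) dim(values) <- geometry$shape
  if (anyNA(values) || any(!is.finite(values)))
    stop("image values must be finite")
  if (modality == "DOSE" && any(values < 0))
    stop("dose values must be >= 0")
  storage.mode(values) <- "double"
  structure(list(values = values, geometry = geometry, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s, range [%.4g, %.4g]\n", x$modality,
              format(x$geometry), min(x$values), max(x$values)))
  invisible(x)
}

#' Binary structure mask
#'
#' @param values logical 3D array matching `geometry$shape`.
#' @param geometry a `grid_geometry`.
#' @param name structure label, e.g. `"Heart"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, geometry, name = "mask") {
  values <- as.array(values)
  stopifnot(inherits(geometry, "grid_geometry"))
  if (is.null(dim(values))) dim(values) <- geometry$shape
  if (!all(dim(values) == geometry$shape))
    stop("mask dimensions do not match geometry shape")
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask must not contain NA")
  structure(list(values = values, geometry = geometry, name = name),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask '%s'> %s, %.2f cc\n", x$name, format(x$geometry),
              mask_volume_cc(x)))
  invisible(x)
}

#' Mask volume in cubic centimeters
#' @param mask a `binary_mask`.
#' @return voxel count times voxel volume, cc.
#' @export
mask_volume_cc <- function(mask) sum(mask$values) * voxel_volume_cc(mask$geometry)

#' Named collection of masks on one geometry
#'
#' @param masks named list of `binary_mask` objects sharing one geometry.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks = list()) {
  if (length(masks)) {
    nms <- vapply(masks, function(m) m$name, character(1))
    if (is.null(names(masks))) names(masks) <- nms
    if (anyDuplicated(names(masks))) stop("structure names must be unique")
    g <- masks[[1]]$geometry
    ok <- vapply(masks, function(m) geom_equal(m$geometry, g), logical(1))
    if (!all(ok)) stop("all masks must share one geometry")
  }
  structure(list(masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures: %s\n", length(x$masks),
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Per-voxel displacement field
#'
#' Displacements (mm) defined on a fixed-frame grid; the zero field is the
#' identity mapping. Applying the field pulls values back:
#' `out(x) = in(x + u(x))`.
#'
#' @param vectors numeric 4D array `c(shape, 3)`.
#' @param geometry a `grid_geometry` (the fixed frame).
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(vectors, geometry) {
  vectors <- as.array(vectors)
  stopifnot(inherits(geometry, "grid_geometry"))
  if (!all(dim(vectors) == c(geometry$shape, 3L)))
    stop("vectors must have dim c(shape, 3)")
  if (any(!is.finite(vectors))) stop("displacements must be finite")
  storage.mode(vectors) <- "double"
  structure(list(vectors = vectors, geometry = geometry),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<deformation_field> %s, |u| mean %.3g max %.3g mm\n",
              format(x$geometry), mean(mag), max(mag)))
  invisible(x)
}

zero_field <- function(geometry)
  deformation_field(array(0, c(geometry$shape, 3L)), geometry)

#' Patient case: CT, planned dose, structures, prescription
#'
#' @param id case label.
#' @param ct `image_volume` with modality CT.
#' @param dose `image_volume` with modality DOSE, on the CT geometry (it is
#'   resampled there if not).
#' @param structures a `structure_set` on the CT geometry.
#' @param prescription_gy prescribed dose, Gy (50 or 50.4 in this cohort).
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(id, ct, dose = NULL, structures = structure_set(),
                         prescription_gy = 50) {
  stopifnot(inherits(ct, "image_volume"), ct$modality == "CT",
            prescription_gy > 0)
  if (!is.null(dose)) {
    stopifnot(inherits(dose, "image_volume"), dose$modality == "DOSE")
    if (!geom_equal(dose$geometry, ct$geometry))
      dose <- resample(dose, ct$geometry, mode = "linear")
  }
  if (length(structures$masks) &&
      !geom_equal(structures$masks[[1]]$geometry, ct$geometry))
    stop("structures must be on (or resampled to) the CT geometry")
  structure(list(id = as.character(id), ct = ct, dose = dose,
                 structures = structures,
                 prescription_gy = as.numeric(prescription_gy)),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case '%s'> %s; dose: %s; %d structures; Rx %.1f Gy\n",
              x$id, format(x$ct$geometry),
              if (is.null(x$dose)) "none" else "present",
              length(x$structures$masks), x$prescription_gy))
  invisible(x)
}

sample_points <- function(volume, pts, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  g <- volume$geometry
  vals <- if (inherits(volume, "binary_mask")) volume$values + 0 else volume$values
  cpp_sample_volume(as.numeric(vals), g$shape, g$origin, g$spacing,
                    pts, mode == "nearest", fill)
}

#' Resample a volume or mask onto a target geometry
#'
#' Linear interpolation for scalar volumes, nearest-neighbour for masks;
#' voxels outside the source support are filled with 0 / `FALSE`.
#'
#' @param x an `image_volume` or `binary_mask`.
#' @param target target `grid_geometry`.
#' @param mode `"linear"` or `"nearest"`; masks always use nearest.
#' @return object of the same class as `x` on `target`.
#' @export
resample <- function(x, target, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "grid_geometry"))
  if (inherits(x, "binary_mask")) mode <- "nearest"
  if (geom_equal(x$geometry, target)) {
    out <- x; out$geometry <- target
    return(out)
  }
  pts <- voxel_centers(target)
  vals <- sample_points(x, pts, mode)
  if (inherits(x, "binary_mask")) {
    binary_mask(array(vals > 0.5, target$shape), target, x$name)
  } else {
    vals <- array(vals, target$shape)
    if (x$modality == "DOSE") vals[vals < 0] <- 0
    image_volume(vals, target, x$modality)
  }
}

#' Euclidean distance map to a mask
#'
#' Distance (mm) from each voxel center to the nearest voxel of the mask,
#' honouring anisotropic spacing. Empty mask gives `Inf` everywhere.
#'
#' @param mask a `binary_mask`.
#' @return numeric 3D array of distances, mm.
#' @export
distance_to_mask <- function(mask) {
  g <- mask$geometry
  cpp_edt(as.logical(mask$values), g$shape, g$spacing)
}
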