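# Two-stage intensity-based registration: a multiresolution affine stage
# (translation, rotation, scaling, shear) followed by a cubic B-spline
# free-form deformation on a uniform 50 mm control grid, both minimizing
# mean-squared intensity error with analytic gradients. The final transform
# is exported as a single displacement field on the fixed grid (pull-back
# convention: warped(x) = moving(x + u(x))).

#' Registration configuration
#'
#' Staged configuration for the affine and B-spline stages. Iterations apply
#' per resolution level. The gradient optimizer uses a seeded randomized
#' initialization of the affine translation.
#'
#' @param affine_iterations,bspline_iterations gradient iterations per level.
#' @param affine_levels,bspline_levels number of resolution levels.
#' @param downsampling per-axis downsampling factors at the coarsest level;
#'   finer levels interpolate geometrically down to full resolution.
#' @param control_spacing_mm isotropic B-spline control-point spacing (mm);
#'   must exceed the largest voxel spacing.
#' @param metric similarity metric; `"mse"` (same-modality CT).
#' @param seed integer seed for the randomized initialization.
#' @param init_sd_mm standard deviation (mm) of the random initial
#'   translation perturbation.
#' @return an object of class `registration_config`.
#' @export
registration_config <- function(affine_iterations = 20L, affine_levels = 3L,
                                bspline_iterations = 30L, bspline_levels = 3L,
                                downsampling = c(4, 4, 2),
                                control_spacing_mm = 50,
                                metric = "mse", seed = 0L,
                                init_sd_mm = 0.5) {
  stopifnot(affine_iterations >= 1, bspline_iterations >= 1,
            affine_levels >= 1, bspline_levels >= 1,
            length(downsampling) == 3, all(downsampling >= 1))
  if (!identical(metric, "mse"))
    stop("only the mean-squared-error metric is implemented")
  structure(list(affine_iterations = as.integer(affine_iterations),
                 affine_levels = as.integer(affine_levels),
                 bspline_iterations = as.integer(bspline_iterations),
                 bspline_levels = as.integer(bspline_levels),
                 downsampling = as.numeric(downsampling),
                 control_spacing_mm = control_spacing_mm,
                 metric = metric, seed = as.integer(seed),
                 init_sd_mm = init_sd_mm),
            class = "registration_config")
}

# per-level downsampling factors: geometric schedule from `downsampling`
# (coarsest) to 1 (finest)
level_factors <- function(downsampling, levels) {
  if (levels == 1) return(list(c(1, 1, 1)))
  lapply(seq_len(levels), function(l) {
    e <- (levels - l) / (levels - 1)
    pmax(round(downsampling^e), 1)
  })
}

downsample_geometry <- function(g, f) {
  shape <- pmax(as.integer(ceiling(g$shape / f)), 1L)
  grid_geometry(g$origin, g$spacing * f, shape, g$orientation)
}

# sample `moving` through the centered affine A(x - ctr) + ctr + t at the
# voxel centers of `target_geom`
affine_resample <- function(moving, target_geom, A, t, ctr, fill = 0) {
  pts <- voxel_centers(target_geom)
  pts <- sweep(pts, 2, ctr) %*% t(A)
  pts <- sweep(pts, 2, ctr + t, "+")
  vals <- sample_points(moving, pts, "linear", fill = NA_real_)
  outside <- is.na(vals)
  vals[outside] <- fill
  out <- image_volume(array(vals, target_geom$shape), target_geom,
                      moving$modality)
  attr(out, "outside") <- array(outside, target_geom$shape)
  out
}

# separable 3D Gaussian smoothing (sigma in voxels); standard pyramid
# prefilter so both images at a level carry comparable blur
smooth_volume <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  v <- vol$values
  dims <- dim(v)
  Gx <- gauss_mat(dims[1], sigma_vox)
  Gy <- gauss_mat(dims[2], sigma_vox)
  Gz <- gauss_mat(dims[3], sigma_vox)
  v <- array(Gx %*% matrix(v, dims[1], dims[2] * dims[3]), dims)
  v <- aperm(array(Gy %*% matrix(aperm(v, c(2, 1, 3)), dims[2], dims[1] * dims[3]),
                   dims[c(2, 1, 3)]), c(2, 1, 3))
  v <- array(t(Gz %*% t(matrix(v, dims[1] * dims[2], dims[3]))), dims)
  image_volume(v, vol$geometry, vol$modality)
}

control_grid_for <- function(g, cspacing) {
  cs <- rep(cspacing, 3)
  corigin <- g$origin - 2 * cs
  extent <- (g$shape - 1) * g$spacing
  cshape <- as.integer(ceiling(extent / cs) + 5)
  list(origin = corigin, spacing = cs, shape = cshape)
}

#' Register a moving image to a fixed image (affine then B-spline)
#'
#' The affine stage seeds the B-spline stage; the result is one displacement
#' field on the fixed grid encoding the total transform
#' (affine composed with the B-spline refinement). Deterministic for a given
#' `config$seed`.
#'
#' @param fixed,moving CT `image_volume`s with overlapping physical extent.
#' @param config a `registration_config`.
#' @param verbose print per-level metric values.
#' @return an object of class `registration_result`: `field`
#'   (a `deformation_field` on the fixed grid), `warped_moving`, `affine`
#'   (list A, t, center), `metric_trace`.
#' @export
register <- function(fixed, moving, config = registration_config(),
                     verbose = FALSE) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  fg <- fixed$geometry; mg <- moving$geometry
  flo <- fg$origin; fhi <- fg$origin + (fg$shape - 1) * fg$spacing
  mlo <- mg$origin; mhi <- mg$origin + (mg$shape - 1) * mg$spacing
  if (any(pmin(fhi, mhi) - pmax(flo, mlo) <= 0))
    stop("fixed and moving volumes do not overlap")
  if (config$control_spacing_mm <= max(fg$spacing))
    stop("control spacing must exceed the voxel spacing")
  ctr <- fg$origin + (fg$shape - 1) * fg$spacing / 2
  trace <- numeric(0)

  withr_seed(config$seed, {
    # ---- affine stage ----
    A <- diag(3); tt <- rnorm(3, sd = config$init_sd_mm)
    char_len <- max((fg$shape - 1) * fg$spacing) / 2 # mm lever arm of linear part
    facs <- level_factors(config$downsampling, config$affine_levels)
    for (f in facs) {
      gl <- downsample_geometry(fg, f)
      fx <- resample(fixed, gl, "linear")
      lr <- max(gl$spacing)
      par <- c(as.vector(t(A)), tt)
      ev <- cpp_affine_mse_grad(fx$values, gl$shape, gl$origin, gl$spacing,
                                moving$values, mg$shape, mg$origin, mg$spacing,
                                par, ctr)
      mse <- ev$mse
      if (!is.finite(mse)) stop("non-finite registration metric")
      for (it in seq_len(config$affine_iterations)) {
        gvec <- ev$grad
        # diagonal preconditioning: linear-part curvature scales with the
        # squared lever arm, so divide its gradient by char_len^2
        d <- gvec * c(rep(1 / char_len^2, 9), rep(1, 3))
        eff <- sqrt(sum((d[1:9] * char_len)^2) + sum(d[10:12]^2))
        if (eff < 1e-12) break
        cand <- par - (lr / eff) * d
        ev2 <- cpp_affine_mse_grad(fx$values, gl$shape, gl$origin, gl$spacing,
                                   moving$values, mg$shape, mg$origin, mg$spacing,
                                   cand, ctr)
        if (is.finite(ev2$mse) && ev2$mse < mse) {
          par <- cand; mse <- ev2$mse; ev <- ev2; lr <- lr * 1.2
        } else {
          lr <- lr / 2
        }
        trace <- c(trace, mse)
      }
      A <- matrix(par[1:9], 3, 3, byrow = TRUE); tt <- par[10:12]
      if (verbose) message(sprintf("affine level (%s): mse %.4g",
                                   paste(f, collapse = "x"), mse))
    }

    # ---- B-spline stage on the affinely resampled moving image ----
    cg <- control_grid_for(fg, config$control_spacing_mm)
    coef <- array(0, c(cg$shape, 3L))
    facs <- level_factors(config$downsampling, config$bspline_levels)
    for (f in facs) {
      gl <- downsample_geometry(fg, f)
      sig <- max(f) / 2
      fx <- resample(smooth_volume(fixed, sig), gl, "linear")
      mv <- affine_resample(smooth_volume(moving, sig), gl, A, tt, ctr,
                            fill = min(moving$values))
      # conservative step growth: start at sub-voxel steps so flat-region
      # coefficients are not dragged by edge noise
      lr <- 0.5
      vld <- !attr(mv, "outside")
      ev <- cpp_bspline_mse_grad(fx$values, mv$values, gl$shape, gl$origin,
                                 gl$spacing, as.numeric(coef), cg$shape,
                                 cg$origin, cg$spacing, vld)
      mse <- ev$mse
      if (!is.finite(mse)) stop("non-finite registration metric")
      for (it in seq_len(config$bspline_iterations)) {
        gr <- ev$grad
        gmax <- max(sqrt(gr[, , , 1]^2 + gr[, , , 2]^2 + gr[, , , 3]^2))
        if (gmax < 1e-12) break
        cand <- coef - (lr / gmax) * gr
        ev2 <- cpp_bspline_mse_grad(fx$values, mv$values, gl$shape, gl$origin,
                                    gl$spacing, as.numeric(cand), cg$shape,
                                    cg$origin, cg$spacing, vld)
        if (is.finite(ev2$mse) && ev2$mse < mse * (1 - 1e-6)) {
          coef <- cand; mse <- ev2$mse; ev <- ev2; lr <- min(lr * 1.3, 6)
        } else {
          lr <- lr / 2
        }
        trace <- c(trace, mse)
      }
      if (verbose) message(sprintf("bspline level (%s): mse %.4g",
                                   paste(f, collapse = "x"), mse))
    }
  })

  # total displacement on the full-resolution fixed grid:
  # x -> A(x + u_b(x) - ctr) + ctr + t, i.e. u = A(x + u_b - ctr) + ctr + t - x
  ub <- cpp_bspline_field(as.numeric(coef), cg$shape, cg$origin, cg$spacing,
                          fg$shape, fg$origin, fg$spacing)
  pts <- voxel_centers(fg)
  nv <- nrow(pts)
  ubm <- matrix(ub, nv, 3)
  warped_pts <- sweep(pts + ubm, 2, ctr) %*% t(A)
  warped_pts <- sweep(warped_pts, 2, ctr + tt, "+")
  u <- warped_pts - pts
  field <- deformation_field(array(u, c(fg$shape, 3L)), fg)
  wvals <- sample_points(moving, warped_pts, "linear", fill = min(moving$values))
  warped <- image_volume(array(wvals, fg$shape), fg, moving$modality)
  structure(list(field = field, warped_moving = warped,
                 affine = list(A = A, t = tt, center = ctr),
                 metric_trace = trace, config = config),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s; final mse %.4g (%d evals)\n",
              format(x$field$geometry),
              if (length(x$metric_trace)) tail(x$metric_trace, 1) else NA,
              length(x$metric_trace)))
  invisible(x)
}

#' Apply a displacement field to a volume or mask (pull-back)
#'
#' `out(x) = in(x + u(x))` at the voxel centers of the field's (fixed)
#' geometry: linear interpolation for CT/dose, nearest for masks;
#' out-of-support voxels get `fill` (0 / `FALSE` by default).
#'
#' @param field a `deformation_field`.
#' @param x an `image_volume` or `binary_mask`.
#' @param mode `"linear"` or `"nearest"`; masks always use nearest.
#' @param fill fill value outside the support of `x`.
#' @return same class as `x`, on the field geometry.
#' @export
apply_field <- function(field, x, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  if (inherits(x, "binary_mask")) mode <- "nearest"
  g <- field$geometry
  pts <- voxel_centers(g) + matrix(field$vectors, prod(g$shape), 3)
  vals <- sample_points(x, pts, mode, fill = fill)
  if (inherits(x, "binary_mask")) {
    binary_mask(array(vals > 0.5, g$shape), g, x$name)
  } else {
    v <- array(vals, g$shape)
    if (x$modality == "DOSE") v[v < 0] <- 0
    image_volume(v, g, x$modality)
  }
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `v(x) = -u(x + v(x))` so that the composed mapping is the identity
#' up to `tol_mm`. Convergence is guaranteed for displacement fields that
#' are small relative to their smoothness (as produced by the phantom
#' generator's clamp and by the registration of such cohorts).
#'
#' @param field a `deformation_field`.
#' @param max_iter maximum fixed-point iterations.
#' @param tol_mm stop when the mean residual `|u(x+v(x)) + v(x)|` drops
#'   below this value.
#' @return a `deformation_field`; attribute `residual_mm` carries the final
#'   mean residual. Non-convergence warns but still returns the result.
#' @export
invert_field <- function(field, max_iter = 20L, tol_mm = 0.1) {
  g <- field$geometry
  nv <- prod(g$shape)
  u <- matrix(field$vectors, nv, 3)
  ctrs <- voxel_centers(g)
  v <- matrix(0, nv, 3)
  ucomp <- lapply(1:3, function(d)
    image_volume(array(u[, d], g$shape), g, "CT"))
  res <- Inf
  for (it in seq_len(max_iter)) {
    pts <- ctrs + v
    uv <- vapply(1:3, function(d)
      sample_points(ucomp[[d]], pts, "linear", fill = NA_real_), numeric(nv))
    ok <- !is.na(uv[, 1])
    if (!any(ok)) break
    res <- mean(sqrt(rowSums((uv[ok, , drop = FALSE] +
                                v[ok, , drop = FALSE])^2)))
    if (res < tol_mm) break
    # points mapping outside the support keep their current estimate
    v[ok, ] <- -uv[ok, , drop = FALSE]
  }
  if (res >= tol_mm)
    warning(sprintf("field inversion stopped at mean residual %.3f mm", res))
  out <- deformation_field(array(v, c(g$shape, 3L)), g)
  attr(out, "residual_mm") <- res
  out
}
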