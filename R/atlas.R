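# Atlas construction in a common reference frame and patient-specific dose
# prediction: every atlas CT/dose pair is deformably warped into the
# reference frame; a new patient is registered to the same reference, ranked
# against each member by slice-wise structural similarity (SSIM) of the CTs,
# and the predicted dose is the similarity-weighted sum of all member doses
# pulled back into the patient's geometry through the inverse field.

#' Build a dose-prediction atlas
#'
#' Registers every non-reference case (moving) to the reference case (fixed)
#' and stores its CT and dose warped into the reference frame. The reference
#' itself is a member with the identity warp. A member whose registration
#' fails is skipped with a warning.
#'
#' @param cases list of `patient_case`s with CT and dose.
#' @param reference_id id of the reference case (must be among `cases`).
#' @param config a `registration_config`.
#' @param reg_cache optional environment memoizing registrations across
#'   calls, keyed `"<moving_id>-><fixed_id>"` (used by [leave_one_out()]).
#' @return an object of class `dose_atlas`.
#' @export
build_atlas <- function(cases, reference_id, config = registration_config(),
                        reg_cache = NULL) {
  if (length(cases) < 2) stop("an atlas needs at least 2 cases")
  ids <- vapply(cases, function(cs) cs$id, character(1))
  ref_i <- match(reference_id, ids)
  if (is.na(ref_i)) stop("reference_id not among the cases")
  reference <- cases[[ref_i]]
  members <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    if (i == ref_i) {
      members[[cs$id]] <- list(id = cs$id, warped_ct = reference$ct,
                               warped_dose = reference$dose)
      next
    }
    reg <- tryCatch(
      cached_register(reference$ct, cs$ct, config, reg_cache, cs$id,
                      reference$id),
      error = function(e) {
        warning("registration of '", cs$id, "' failed (", conditionMessage(e),
                "); member skipped")
        NULL
      })
    if (is.null(reg)) next
    members[[cs$id]] <- list(
      id = cs$id,
      warped_ct = reg$warped_moving,
      warped_dose = apply_field(reg$field, cs$dose, mode = "linear"))
  }
  if (!length(members)) stop("no atlas member could be registered")
  structure(list(reference = reference, members = members, config = config),
            class = "dose_atlas")
}

cached_register <- function(fixed, moving, config, reg_cache,
                            moving_id, fixed_id) {
  if (is.null(reg_cache)) return(register(fixed, moving, config))
  key <- paste0(moving_id, "->", fixed_id)
  if (!is.null(reg_cache[[key]])) return(reg_cache[[key]])
  reg <- register(fixed, moving, config)
  reg_cache[[key]] <- reg
  reg
}

#' @export
print.dose_atlas <- function(x, ...) {
  cat(sprintf("<dose_atlas> reference '%s', %d members\n",
              x$reference$id, length(x$members)))
  invisible(x)
}

# normalized 1D Gaussian convolution matrix (reflect-free: rows renormalized
# at the borders)
gauss_mat <- function(n, sigma_vox, radius = ceiling(3 * sigma_vox)) {
  idx <- seq_len(n)
  G <- outer(idx, idx, function(i, j) {
    d <- i - j
    ifelse(abs(d) <= radius, exp(-d^2 / (2 * sigma_vox^2)), 0)
  })
  G / rowSums(G)
}

#' Slice-wise structural similarity between two volumes
#'
#' Mean local SSIM per axial slice (Gaussian window, constants
#' `c1 = (K1*L)^2`, `c2 = (K2*L)^2`), averaged over the slices that
#' intersect `body` (all slices if `body` is `NULL`). The dynamic range `L`
#' defaults to a fixed 2000 HU CT window (-1000 to +1000) so that air-only
#' regions cannot inflate the similarity.
#'
#' @param a,b `image_volume`s on one geometry.
#' @param body optional `binary_mask` restricting the slice set.
#' @param L dynamic range; if 0, returns 1 when the volumes are identical
#'   and 0 otherwise.
#' @param K1,K2 SSIM stabilization constants.
#' @param sigma_vox Gaussian window standard deviation, voxels.
#' @return scalar similarity in [-1, 1].
#' @export
slicewise_ssim <- function(a, b, body = NULL, L = 2000, K1 = 0.01, K2 = 0.03,
                           sigma_vox = 1.5) {
  stopifnot(geom_equal(a$geometry, b$geometry))
  if (L == 0) return(if (identical(a$values, b$values)) 1 else 0)
  g <- a$geometry
  slices <- seq_len(g$shape[3])
  if (!is.null(body)) {
    keep <- vapply(slices, function(k) any(body$values[, , k]), logical(1))
    if (any(keep)) slices <- slices[keep]
  }
  c1 <- (K1 * L)^2; c2 <- (K2 * L)^2
  Gx <- gauss_mat(g$shape[1], sigma_vox)
  Gy <- gauss_mat(g$shape[2], sigma_vox)
  sm <- function(S) Gx %*% S %*% t(Gy)
  vals <- vapply(slices, function(k) {
    A <- a$values[, , k]; B <- b$values[, , k]
    mu_a <- sm(A); mu_b <- sm(B)
    va <- sm(A * A) - mu_a^2
    vb <- sm(B * B) - mu_b^2
    cab <- sm(A * B) - mu_a * mu_b
    mean(((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
           ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
  }, numeric(1))
  mean(vals)
}

#' Atlas member weights from similarities
#'
#' `w_i = s_i^p / sum_j s_j^p` after clamping each similarity to at least
#' `eps`; `p` sharpens the weighting (`p -> Inf` selects the single most
#' similar member). All-nonpositive similarities give uniform weights with a
#' warning.
#'
#' @param similarities numeric vector of raw similarities.
#' @param p sharpening exponent (>= 0).
#' @param eps clamping floor.
#' @return an object of class `similarity_weights`: data.frame with
#'   `raw_similarity` and `weight` (summing to 1).
#' @export
compute_weights <- function(similarities, p = 1, eps = 1e-6) {
  stopifnot(length(similarities) >= 1, p >= 0)
  s <- as.numeric(similarities)
  if (all(s <= 0)) {
    warning("all similarities nonpositive; falling back to uniform weights")
    w <- rep(1 / length(s), length(s))
  } else {
    sc <- pmax(s, eps)
    if (is.infinite(p)) {
      w <- as.numeric(sc == max(sc))
      w <- w / sum(w)
    } else {
      lw <- p * log(sc)
      w <- exp(lw - max(lw))
      w <- w / sum(w)
    }
  }
  structure(data.frame(raw_similarity = s, weight = w),
            class = c("similarity_weights", "data.frame"))
}

#' Predict a patient's 3D dose from an atlas
#'
#' Registers the test patient (moving) to the atlas reference (fixed),
#' computes the slice-wise SSIM between the warped test CT and each member's
#' warped CT in the reference frame, turns similarities into weights, pulls
#' every member dose into the test geometry through the inverse field, and
#' sums them with the weights.
#'
#' @param atlas a `dose_atlas`.
#' @param test a `patient_case` with CT (and ideally a Body mask).
#' @param p sharpening exponent for [compute_weights()].
#' @param weights optional: force these weights (length = member count)
#'   instead of SSIM-derived ones.
#' @param reg_cache optional registration memo (see [build_atlas()]).
#' @return an object of class `prediction_result`: `predicted_dose` (on the
#'   test geometry), `weights`, `field` (test-to-reference),
#'   `inverse_field`, `member_ids`.
#' @export
predict_dose <- function(atlas, test, p = 1, weights = NULL,
                         reg_cache = NULL) {
  if (!length(atlas$members)) stop("empty atlas")
  reference <- atlas$reference
  reg <- cached_register(reference$ct, test$ct, atlas$config, reg_cache,
                         test$id, reference$id)
  finv <- invert_field(reg$field)
  tg <- test$ct$geometry
  if (!geom_equal(finv$geometry, tg)) {
    # express the inverse field on the test grid (component-wise resampling)
    comps <- lapply(1:3, function(d)
      resample(image_volume(finv$vectors[, , , d], finv$geometry, "CT"), tg,
               "linear"))
    finv <- deformation_field(
      array(c(comps[[1]]$values, comps[[2]]$values, comps[[3]]$values),
            c(tg$shape, 3L)), tg)
  }
  body_ref <- reference$structures$masks$Body
  sims <- vapply(atlas$members, function(m)
    slicewise_ssim(reg$warped_moving, m$warped_ct, body = body_ref),
    numeric(1))
  w <- if (is.null(weights)) compute_weights(sims, p = p)
       else {
         stopifnot(length(weights) == length(atlas$members),
                   abs(sum(weights) - 1) < 1e-6)
         structure(data.frame(raw_similarity = sims, weight = weights),
                   class = c("similarity_weights", "data.frame"))
       }
  pred <- array(0, tg$shape)
  for (i in seq_along(atlas$members)) {
    if (w$weight[i] == 0) next
    d_test <- apply_field(finv, atlas$members[[i]]$warped_dose, mode = "linear")
    pred <- pred + w$weight[i] * d_test$values
  }
  pred[pred < 0] <- 0
  structure(list(predicted_dose = image_volume(pred, tg, "DOSE"),
                 weights = w, field = reg$field, inverse_field = finv,
                 member_ids = names(atlas$members)),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s; top member %s (w = %.3f)\n",
              format(x$predicted_dose$geometry),
              x$member_ids[which.max(x$weights$weight)],
              max(x$weights$weight)))
  invisible(x)
}
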