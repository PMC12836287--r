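# Personalized "complete block" avoidance structure: the external body minus
# the predicted 2-Gy isodose volume, morphologically smoothed for geometric
# continuity. A complete block forbids any beamlet whose path crosses it, so
# it must stay strictly clear of the predicted low-dose envelope.

#' Block-generation parameters
#'
#' @param threshold_gy isodose level defining the low-dose envelope (Gy).
#' @param closing_radius_mm radius of the morphological closing (mm).
#' @param opening_radius_mm radius of the morphological opening (mm).
#' @param enforce_disjoint re-subtract the isodose volume after smoothing so
#'   the block can never overlap it.
#' @return an object of class `block_params`.
#' @export
block_params <- function(threshold_gy = 2.0, closing_radius_mm = 5,
                         opening_radius_mm = 2, enforce_disjoint = TRUE) {
  stopifnot(threshold_gy > 0, closing_radius_mm >= 0, opening_radius_mm >= 0)
  structure(list(threshold_gy = threshold_gy,
                 closing_radius_mm = closing_radius_mm,
                 opening_radius_mm = opening_radius_mm,
                 enforce_disjoint = isTRUE(enforce_disjoint)),
            class = "block_params")
}

#' Isodose volume at a threshold
#'
#' Voxels receiving at least `threshold_gy` (inclusive, matching the
#' V_x convention "volume receiving >= x Gy").
#'
#' @param dose an `image_volume` (DOSE).
#' @param threshold_gy threshold, Gy.
#' @return a `binary_mask` named `"isodose_<threshold>"`.
#' @export
extract_isodose <- function(dose, threshold_gy = 2.0) {
  binary_mask(dose$values >= threshold_gy, dose$geometry,
              sprintf("isodose_%g", threshold_gy))
}

# ball morphology via the Euclidean distance transform (anisotropic-aware)
ball_dilate <- function(mask, radius_mm) {
  if (radius_mm <= 0 || !any(mask$values)) return(mask)
  d <- distance_to_mask(mask)
  binary_mask(d <= radius_mm, mask$geometry, mask$name)
}

ball_erode <- function(mask, radius_mm) {
  if (radius_mm <= 0 || all(mask$values)) return(mask)
  inv <- binary_mask(!mask$values, mask$geometry, mask$name)
  d <- distance_to_mask(inv)
  binary_mask(mask$values & d > radius_mm, mask$geometry, mask$name)
}

ball_closing <- function(mask, radius_mm)
  ball_erode(ball_dilate(mask, radius_mm), radius_mm)

ball_opening <- function(mask, radius_mm)
  ball_dilate(ball_erode(mask, radius_mm), radius_mm)

#' Build the complete-block structure
#'
#' Boolean subtraction (body minus isodose volume), then morphological
#' closing and opening with spherical elements to ensure geometric
#' continuity; with `enforce_disjoint` the isodose volume is re-subtracted
#' after smoothing. The block is always a subset of the body.
#'
#' @param body,isodose `binary_mask`s on one geometry.
#' @param params a `block_params`.
#' @return a `binary_mask` named `"CompleteBlock"`.
#' @export
make_complete_block <- function(body, isodose, params = block_params()) {
  stopifnot(geom_equal(body$geometry, isodose$geometry))
  if (!any(body$values)) stop("body mask is empty")
  blk <- binary_mask(body$values & !isodose$values, body$geometry,
                     "CompleteBlock")
  blk <- ball_closing(blk, params$closing_radius_mm)
  blk <- ball_opening(blk, params$opening_radius_mm)
  v <- blk$values & body$values
  if (params$enforce_disjoint) v <- v & !isodose$values
  binary_mask(v, body$geometry, "CompleteBlock")
}

#' Check the block against its planning constraints
#'
#' The complete block must receive a maximum dose below 2 Gy and have less
#' than half its volume above 1 Gy (strict inequalities, as these are
#' planning constraints of the form "< x").
#'
#' @param block a `binary_mask`.
#' @param dose an `image_volume` on the same geometry.
#' @param dmax_limit_gy,v1_limit_pct constraint values.
#' @return list with `dmax_gy`, `v1_pct`, per-constraint pass flags, and
#'   `applicable` (`FALSE` for an empty block).
#' @export
check_block_dose <- function(block, dose, dmax_limit_gy = 2.0,
                             v1_limit_pct = 50) {
  stopifnot(geom_equal(block$geometry, dose$geometry))
  if (!any(block$values))
    return(list(applicable = FALSE, dmax_gy = NA_real_, v1_pct = NA_real_,
                dmax_pass = NA, v1_pass = NA))
  dv <- dose$values[block$values]
  dmax <- max(dv)
  v1 <- 100 * mean(dv >= 1)
  list(applicable = TRUE, dmax_gy = dmax, v1_pct = v1,
       dmax_pass = dmax < dmax_limit_gy, v1_pass = v1 < v1_limit_pct)
}

#' Export a block into a case's RTSTRUCT
#'
#' Contourizes the block slice by slice and writes an RTSTRUCT containing
#' the case's structures plus the block. A name collision gets a numeric
#' suffix (logged); an empty block yields a valid ROI with zero contours and
#' a warning.
#'
#' @param block a `binary_mask` on the case geometry.
#' @param case the `patient_case` the block belongs to.
#' @param path output RTSTRUCT path.
#' @param name ROI name for the block.
#' @return `path`, invisibly.
#' @export
export_block <- function(block, case, path, name = "CompleteBlock") {
  stopifnot(geom_equal(block$geometry, case$ct$geometry))
  existing <- names(case$structures$masks)
  nm <- name
  while (nm %in% existing) {
    nm <- paste0(nm, "_1")
    message("ROI name collision; exporting block as '", nm, "'")
  }
  blk <- binary_mask(block$values, block$geometry, nm)
  ss <- structure_set(c(case$structures$masks, stats::setNames(list(blk), nm)))
  write_rtstruct(ss, case$ct$geometry, for_uid = new_uid(), path,
                 pid = case$id)
  invisible(path)
}
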