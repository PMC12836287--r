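# Minimal DICOM-RT codec: explicit-VR little-endian CT image series, RTDOSE
# (DoseGridScaling honoured) and RTSTRUCT (closed planar contours). Covers
# the subset of DICOM the dose-mimicking workflow exchanges with treatment
# planning systems; axis-aligned (identity orientation) geometry only.

UID_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

new_uid <- function() {
  # 2.25-rooted UID from timestamp + counter + random digits
  n <- get0(".dcm_uid_counter", envir = .dosemimic_env, ifnotfound = 0L) + 1L
  assign(".dcm_uid_counter", n, envir = .dosemimic_env)
  sprintf("2.25.%s%05d%04d", format(as.numeric(Sys.time()) * 1000, scientific = FALSE,
                                    trim = TRUE, digits = 13),
          n %% 100000L, sample.int(9999L, 1L))
}

.dosemimic_env <- new.env(parent = emptyenv())

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536; hi <- (x - lo) / 65536
  c(u16(lo), u16(hi))
}

dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                    "PN", "SH", "ST", "TM", "UI", "UC", "UR", "UT")
dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_encode_value <- function(vr, value) {
  if (vr %in% dcm_string_vrs) {
    s <- paste(as.character(value), collapse = "\\")
    v <- charToRaw(s)
    if (length(v) %% 2L == 1L)
      v <- c(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    v
  } else if (vr == "US") {
    u16(value)
  } else if (vr == "UL") {
    do.call(c, lapply(value, u32))
  } else if (vr %in% c("OW", "OB")) {
    as.raw(value)
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8L, endian = "little")
  } else stop("unsupported VR for encoding: ", vr)
}

dcm_el <- function(group, element, vr, value) {
  v <- dcm_encode_value(vr, value)
  hdr <- c(u16(group), u16(element), charToRaw(vr))
  if (vr %in% dcm_long_vrs) {
    c(hdr, as.raw(c(0L, 0L)), u32(length(v)), v)
  } else {
    if (length(v) > 65534L) stop("value too long for short-form VR ", vr)
    c(hdr, u16(length(v)), v)
  }
}

# sequence with undefined length; items with undefined length + delimiters
dcm_item <- function(elements_raw)
  c(u16(0xFFFE), u16(0xE000), u32(0xFFFFFFFF), elements_raw,
    u16(0xFFFE), u16(0xE00D), u32(0L))

dcm_sq <- function(group, element, items_raw) {
  body <- if (length(items_raw)) do.call(c, items_raw) else raw(0)
  c(u16(group), u16(element), charToRaw("SQ"), as.raw(c(0L, 0L)),
    u32(0xFFFFFFFF), body, u16(0xFFFE), u16(0xE0DD), u32(0L))
}

dcm_write_file <- function(path, sop_class, sop_instance, dataset_raw) {
  meta <- c(
    dcm_el(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_el(0x0002, 0x0002, "UI", sop_class),
    dcm_el(0x0002, 0x0003, "UI", sop_instance),
    dcm_el(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_el(0x0002, 0x0012, "UI", "2.25.0.1"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_el(0x0002, 0x0000, "UL", length(meta)), con)
  writeBin(meta, con)
  writeBin(dataset_raw, con)
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

rd_u16 <- function(r, pos) readBin(r[pos:(pos + 1L)], "integer", size = 2L,
                                   signed = FALSE, endian = "little")
rd_u32 <- function(r, pos) {
  b <- as.numeric(r[pos:(pos + 3L)])
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

# Parse explicit-VR little-endian elements in r[pos..end] into a named list
# keyed "GGGGEEEE" (upper hex). SQ values become lists of such lists.
dcm_parse <- function(r, pos, end) {
  out <- list()
  while (pos <= end) {
    group <- rd_u16(r, pos); element <- rd_u16(r, pos + 2L)
    if (group == 0xFFFE) { # item/sequence delimiters at this level: stop
      return(list(elements = out, pos = pos))
    }
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% dcm_long_vrs) {
      len <- rd_u32(r, pos + 8L); vstart <- pos + 12L
    } else {
      len <- rd_u16(r, pos + 6L); vstart <- pos + 8L
    }
    key <- sprintf("%04X%04X", group, element)
    if (vr == "SQ") {
      items <- list()
      if (len == 4294967295) { # undefined length
        p <- vstart
        repeat {
          g2 <- rd_u16(r, p); e2 <- rd_u16(r, p + 2L)
          if (g2 == 0xFFFE && e2 == 0xE0DD) { p <- p + 8L; break }
          if (!(g2 == 0xFFFE && e2 == 0xE000)) stop("malformed sequence")
          ilen <- rd_u32(r, p + 4L)
          p <- p + 8L
          if (ilen == 4294967295) {
            res <- dcm_parse(r, p, end)
            items[[length(items) + 1L]] <- res$elements
            p <- res$pos
            # expect item delimiter
            if (!(rd_u16(r, p) == 0xFFFE && rd_u16(r, p + 2L) == 0xE00D))
              stop("missing item delimiter")
            p <- p + 8L
          } else {
            res <- dcm_parse(r, p, p + ilen - 1L)
            items[[length(items) + 1L]] <- res$elements
            p <- p + ilen
          }
        }
        pos <- p
      } else {
        p <- vstart
        while (p < vstart + len) {
          if (!(rd_u16(r, p) == 0xFFFE && rd_u16(r, p + 2L) == 0xE000))
            stop("malformed sequence item")
          ilen <- rd_u32(r, p + 4L)
          p <- p + 8L
          res <- dcm_parse(r, p, p + ilen - 1L)
          items[[length(items) + 1L]] <- res$elements
          p <- p + ilen
        }
        pos <- vstart + len
      }
      out[[key]] <- structure(items, vr = "SQ")
    } else {
      val <- if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0)
      out[[key]] <- structure(val, vr = vr)
      pos <- vstart + len
    }
  }
  list(elements = out, pos = pos)
}

dcm_read_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 200L || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  # skip file meta (group 0002, always explicit LE)
  stopifnot(rd_u16(r, 133L) == 0x0002, rd_u16(r, 135L) == 0x0000)
  meta_len <- rd_u32(r, 141L)
  dcm_parse(r, 145L + meta_len, length(r))$elements
}

dcm_str <- function(ds, key) {
  v <- ds[[key]]
  if (is.null(v)) return(NULL)
  v <- as.raw(v)
  trimws(rawToChar(v[v != as.raw(0L)]))
}
dcm_num <- function(ds, key) {
  s <- dcm_str(ds, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}
dcm_u16val <- function(ds, key) {
  v <- ds[[key]]
  if (is.null(v)) return(NULL)
  readBin(as.raw(v), "integer", n = length(v) / 2L, size = 2L,
          signed = FALSE, endian = "little")
}

# ---- contour rasterization --------------------------------------------------

# Even-odd point-in-polygon membership of grid points (voxel centers) for one
# planar polygon given in mm.
points_in_polygon <- function(px, py, X, Y) {
  n <- length(px)
  inside <- rep(FALSE, length(X))
  j <- n
  for (i in seq_len(n)) {
    x1 <- px[j]; y1 <- py[j]; x2 <- px[i]; y2 <- py[i]
    if (y1 != y2) {
      cross <- ((y1 > Y) != (y2 > Y)) &
        (X < (x2 - x1) * (Y - y1) / (y2 - y1) + x1)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

# Rasterize a list of closed planar (axial) contours, each an n x 3 matrix of
# mm coordinates, onto a grid geometry. Even-odd rule: overlapping contours
# on one slice toggle (holes supported).
rasterize_contours <- function(contours, geometry) {
  g <- geometry
  vals <- array(FALSE, g$shape)
  xs <- g$origin[1] + (seq_len(g$shape[1]) - 1) * g$spacing[1]
  ys <- g$origin[2] + (seq_len(g$shape[2]) - 1) * g$spacing[2]
  XY <- cbind(rep(xs, times = g$shape[2]), rep(ys, each = g$shape[1]))
  for (ct in contours) {
    z <- ct[1, 3]
    k <- round((z - g$origin[3]) / g$spacing[3]) + 1
    if (k < 1 || k > g$shape[3]) next
    sel <- which(XY[, 1] >= min(ct[, 1]) - g$spacing[1] &
                 XY[, 1] <= max(ct[, 1]) + g$spacing[1] &
                 XY[, 2] >= min(ct[, 2]) - g$spacing[2] &
                 XY[, 2] <= max(ct[, 2]) + g$spacing[2])
    if (!length(sel)) next
    inside <- points_in_polygon(ct[, 1], ct[, 2], XY[sel, 1], XY[sel, 2])
    slice <- vals[, , k]
    slice[sel] <- xor(slice[sel], inside)
    vals[, , k] <- slice
  }
  vals
}

# Extract closed planar contours (list of n x 3 mm matrices) from a mask,
# slice by slice, via marching-squares iso-lines at 0.5 on a zero-padded
# slice (so boundary-touching regions close).
mask_to_contours <- function(mask) {
  g <- mask$geometry
  xs <- c(g$origin[1] - g$spacing[1],
          g$origin[1] + (seq_len(g$shape[1]) - 1) * g$spacing[1],
          g$origin[1] + g$shape[1] * g$spacing[1])
  ys <- c(g$origin[2] - g$spacing[2],
          g$origin[2] + (seq_len(g$shape[2]) - 1) * g$spacing[2],
          g$origin[2] + g$shape[2] * g$spacing[2])
  out <- list()
  for (k in seq_len(g$shape[3])) {
    sl <- mask$values[, , k]
    if (!any(sl)) next
    pad <- matrix(0, g$shape[1] + 2L, g$shape[2] + 2L)
    pad[2:(g$shape[1] + 1L), 2:(g$shape[2] + 1L)] <- sl + 0
    z <- g$origin[3] + (k - 1) * g$spacing[3]
    cls <- grDevices::contourLines(xs, ys, pad, levels = 0.5)
    for (cl in cls)
      out[[length(out) + 1L]] <- cbind(cl$x, cl$y, z)
  }
  out
}

# ---- case-level writers -----------------------------------------------------

#' Write a patient case as DICOM-RT (CT series + RTDOSE + RTSTRUCT)
#'
#' Explicit-VR little-endian files: one CT image per axial slice
#' (`ct_###.dcm`), a multiframe `rtdose.dcm` with `DoseGridScaling`, and an
#' `rtstruct.dcm` with one closed-planar ROI per structure. All three share
#' one frame of reference.
#'
#' @param case a `patient_case` on an axis-aligned geometry.
#' @param out_dir output directory, created if needed.
#' @return named list of written paths (`ct`, `rtdose`, `rtstruct`),
#'   invisibly.
#' @export
write_dicom_case <- function(case, out_dir) {
  g <- case$ct$geometry
  if (max(abs(g$orientation - diag(3))) > 1e-9)
    stop("write_dicom_case supports axis-aligned (identity orientation) geometry only")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for_uid <- new_uid(); study_uid <- new_uid()
  ct_series <- new_uid()
  pid <- case$id

  common <- function(modality, sop_class, sop_inst, series_uid) c(
    dcm_el(0x0008, 0x0016, "UI", sop_class),
    dcm_el(0x0008, 0x0018, "UI", sop_inst),
    dcm_el(0x0008, 0x0060, "CS", modality),
    dcm_el(0x0010, 0x0010, "PN", pid),
    dcm_el(0x0010, 0x0020, "LO", pid),
    dcm_el(0x0020, 0x000D, "UI", study_uid),
    dcm_el(0x0020, 0x000E, "UI", series_uid),
    dcm_el(0x0020, 0x0052, "UI", for_uid))

  # CT slices: stored value = HU + 1024, slope 1, intercept -1024
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  ct_paths <- character(nz)
  for (k in seq_len(nz)) {
    inst <- new_uid()
    z <- g$origin[3] + (k - 1) * g$spacing[3]
    stored <- round(case$ct$values[, , k]) + 1024
    stored[stored < 0] <- 0; stored[stored > 65535] <- 65535
    pix <- writeBin(as.integer(stored), raw(), size = 2L, endian = "little")
    ds <- c(
      common("CT", UID_CT, inst, ct_series),
      dcm_el(0x0018, 0x0050, "DS", format(g$spacing[3])),
      dcm_el(0x0020, 0x0013, "IS", as.character(k)),
      dcm_el(0x0020, 0x0032, "DS", c(format(g$origin[1]), format(g$origin[2]), format(z))),
      dcm_el(0x0020, 0x0037, "DS", c("1", "0", "0", "0", "1", "0")),
      dcm_el(0x0028, 0x0002, "US", 1L),
      dcm_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_el(0x0028, 0x0010, "US", ny),
      dcm_el(0x0028, 0x0011, "US", nx),
      dcm_el(0x0028, 0x0030, "DS", c(format(g$spacing[2]), format(g$spacing[1]))),
      dcm_el(0x0028, 0x0100, "US", 16L),
      dcm_el(0x0028, 0x0101, "US", 16L),
      dcm_el(0x0028, 0x0102, "US", 15L),
      dcm_el(0x0028, 0x0103, "US", 0L),
      dcm_el(0x0028, 0x1052, "DS", "-1024"),
      dcm_el(0x0028, 0x1053, "DS", "1"),
      dcm_el(0x7FE0, 0x0010, "OW", pix))
    ct_paths[k] <- file.path(out_dir, sprintf("ct_%03d.dcm", k))
    dcm_write_file(ct_paths[k], UID_CT, inst, ds)
  }

  # RTDOSE: multiframe 32-bit, scaling chosen from the dose maximum
  rtdose_path <- NULL
  if (!is.null(case$dose)) {
    dvals <- case$dose$values
    dmax <- max(dvals)
    scaling <- if (dmax > 0) dmax / 2e9 else 1e-5
    stored <- round(dvals / scaling)
    pix <- writeBin(as.integer(stored), raw(), size = 4L, endian = "little")
    inst <- new_uid()
    offsets <- (seq_len(nz) - 1) * g$spacing[3]
    ds <- c(
      common("RTDOSE", UID_RTDOSE, inst, new_uid()),
      dcm_el(0x0020, 0x0032, "DS", vapply(g$origin, format, character(1))),
      dcm_el(0x0020, 0x0037, "DS", c("1", "0", "0", "0", "1", "0")),
      dcm_el(0x0028, 0x0002, "US", 1L),
      dcm_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_el(0x0028, 0x0008, "IS", as.character(nz)),
      dcm_el(0x0028, 0x0010, "US", ny),
      dcm_el(0x0028, 0x0011, "US", nx),
      dcm_el(0x0028, 0x0030, "DS", c(format(g$spacing[2]), format(g$spacing[1]))),
      dcm_el(0x0028, 0x0100, "US", 32L),
      dcm_el(0x0028, 0x0101, "US", 32L),
      dcm_el(0x0028, 0x0102, "US", 31L),
      dcm_el(0x0028, 0x0103, "US", 0L),
      dcm_el(0x3004, 0x0002, "CS", "GY"),
      dcm_el(0x3004, 0x0004, "CS", "PHYSICAL"),
      dcm_el(0x3004, 0x000A, "CS", "PLAN"),
      dcm_el(0x3004, 0x000C, "DS", vapply(offsets, format, character(1))),
      dcm_el(0x3004, 0x000E, "DS", format(scaling, digits = 15)),
      dcm_el(0x7FE0, 0x0010, "OW", pix))
    rtdose_path <- file.path(out_dir, "rtdose.dcm")
    dcm_write_file(rtdose_path, UID_RTDOSE, inst, ds)
  }

  rtstruct_path <- file.path(out_dir, "rtstruct.dcm")
  write_rtstruct(case$structures, g, for_uid, rtstruct_path, pid = pid,
                 study_uid = study_uid)

  invisible(list(ct = ct_paths, rtdose = rtdose_path, rtstruct = rtstruct_path))
}

write_rtstruct <- function(structures, geometry, for_uid, path,
                           pid = "anon", study_uid = new_uid()) {
  inst <- new_uid()
  roi_items <- list(); cont_items <- list()
  nms <- names(structures$masks)
  for (i in seq_along(structures$masks)) {
    m <- structures$masks[[i]]
    roi_items[[i]] <- dcm_item(c(
      dcm_el(0x3006, 0x0022, "IS", as.character(i)),
      dcm_el(0x3006, 0x0024, "UI", for_uid),
      dcm_el(0x3006, 0x0026, "LO", m$name)))
    contours <- mask_to_contours(m)
    citems <- lapply(contours, function(ct) {
      pts <- as.vector(t(ct))
      dcm_item(c(
        dcm_el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_el(0x3006, 0x0046, "IS", as.character(nrow(ct))),
        dcm_el(0x3006, 0x0050, "DS",
               vapply(pts, function(p) sprintf("%.4f", p), character(1)))))
    })
    if (!length(contours))
      warning("structure '", m$name, "' has no contours (empty mask)")
    cont_items[[i]] <- dcm_item(c(
      dcm_el(0x3006, 0x002A, "IS", c("255", "0", "0")),
      if (length(citems)) dcm_sq(0x3006, 0x0040, citems) else raw(0),
      dcm_el(0x3006, 0x0084, "IS", as.character(i))))
  }
  ds <- c(
    dcm_el(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    dcm_el(0x0008, 0x0018, "UI", inst),
    dcm_el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_el(0x0010, 0x0010, "PN", pid),
    dcm_el(0x0010, 0x0020, "LO", pid),
    dcm_el(0x0020, 0x000D, "UI", study_uid),
    dcm_el(0x0020, 0x000E, "UI", new_uid()),
    dcm_el(0x3006, 0x0002, "SH", "StructureSet"),
    dcm_sq(0x3006, 0x0010, list(dcm_item(
      dcm_el(0x0020, 0x0052, "UI", for_uid)))),
    if (length(roi_items)) dcm_sq(0x3006, 0x0020, roi_items) else
      dcm_sq(0x3006, 0x0020, list()),
    if (length(cont_items)) dcm_sq(0x3006, 0x0039, cont_items) else
      dcm_sq(0x3006, 0x0039, list()))
  dcm_write_file(path, UID_RTSTRUCT, inst, ds)
}

#' Read an RTSTRUCT file onto a known geometry
#'
#' Rasterizes every ROI's closed planar contours onto `geometry` (even-odd
#' rule at voxel centers). No frame-of-reference check is performed: use
#' this to re-import structures (e.g. an exported complete block) whose
#' geometry is known out-of-band; [read_dicom_case()] performs the check.
#'
#' @param path RTSTRUCT file path.
#' @param geometry target `grid_geometry`.
#' @return a `structure_set`.
#' @export
read_rtstruct <- function(path, geometry) {
  ds <- dcm_read_file(path)
  masks <- list()
  rois <- ds[["30060020"]]
  roinames <- list()
  for (it in rois)
    roinames[[dcm_str(it, "30060022")]] <- dcm_str(it, "30060026")
  for (it in ds[["30060039"]]) {
    num <- dcm_str(it, "30060084")
    nm <- roinames[[num]]
    if (is.null(nm)) nm <- paste0("ROI_", num)
    cseq <- it[["30060040"]]
    contours <- list()
    if (!is.null(cseq)) {
      for (cit in cseq) {
        pts <- dcm_num(cit, "30060050")
        contours[[length(contours) + 1L]] <- matrix(pts, ncol = 3, byrow = TRUE)
      }
    }
    masks[[nm]] <- if (length(contours)) {
      binary_mask(rasterize_contours(contours, geometry), geometry, nm)
    } else {
      binary_mask(array(FALSE, geometry$shape), geometry, nm)
    }
  }
  structure_set(masks)
}

# ---- case-level reader ------------------------------------------------------

#' Read a patient case from DICOM-RT files
#'
#' Reads a CT image series, an RTDOSE object (scaled to Gy via
#' `DoseGridScaling` and resampled onto the CT grid) and an RTSTRUCT whose
#' planar contours are rasterized to masks on the CT geometry (even-odd
#' rule, voxel centers). All inputs must reference a common frame of
#' reference; a mismatch is a hard error. ROIs without contours become
#' empty masks with a warning.
#'
#' @param ct_dir directory containing the CT series (`*.dcm`).
#' @param rtdose path to the RTDOSE file, or `NULL`.
#' @param rtstruct path to the RTSTRUCT file, or `NULL`.
#' @param id case id; defaults to the PatientID in the CT series.
#' @param prescription_gy prescription, Gy.
#' @return a `patient_case`.
#' @export
read_dicom_case <- function(ct_dir, rtdose = NULL, rtstruct = NULL,
                            id = NULL, prescription_gy = 50) {
  files <- list.files(ct_dir, pattern = "\\.dcm$", full.names = TRUE)
  slices <- lapply(files, dcm_read_file)
  is_ct <- vapply(slices, function(ds) identical(dcm_str(ds, "00080060"), "CT"),
                  logical(1))
  slices <- slices[is_ct]
  if (!length(slices)) stop("no CT slices found in ", ct_dir)
  zpos <- vapply(slices, function(ds) dcm_num(ds, "00200032")[3], numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  s1 <- slices[[1]]
  for_uid <- dcm_str(s1, "00200052")
  ipp <- dcm_num(s1, "00200032")
  ps <- dcm_num(s1, "00280030") # row (y), col (x)
  ny <- dcm_u16val(s1, "00280010"); nx <- dcm_u16val(s1, "00280011")
  nz <- length(slices)
  dz <- if (nz > 1) zpos[2] - zpos[1] else dcm_num(s1, "00180050")
  g <- grid_geometry(c(ipp[1], ipp[2], zpos[1]), c(ps[2], ps[1], dz),
                     c(nx, ny, nz))
  vals <- array(0, g$shape)
  for (k in seq_len(nz)) {
    ds <- slices[[k]]
    slope <- dcm_num(ds, "00281053"); icpt <- dcm_num(ds, "00281052")
    if (is.null(slope)) slope <- 1; if (is.null(icpt)) icpt <- 0
    pix <- readBin(as.raw(ds[["7FE00010"]]), "integer", n = nx * ny,
                   size = 2L, signed = FALSE, endian = "little")
    vals[, , k] <- array(pix, c(nx, ny)) * slope + icpt
  }
  ct <- image_volume(vals, g, "CT")

  dose <- NULL
  if (!is.null(rtdose)) {
    ds <- dcm_read_file(rtdose)
    dfor <- dcm_str(ds, "00200052")
    if (!is.null(dfor) && !identical(dfor, for_uid))
      stop("RTDOSE frame of reference does not match the CT series")
    dipp <- dcm_num(ds, "00200032")
    dps <- dcm_num(ds, "00280030")
    dny <- dcm_u16val(ds, "00280010"); dnx <- dcm_u16val(ds, "00280011")
    nframes <- as.integer(dcm_str(ds, "00280008"))
    offs <- dcm_num(ds, "3004000C")
    scaling <- dcm_num(ds, "3004000E")
    bits <- dcm_u16val(ds, "00280100")
    raw_pix <- as.raw(ds[["7FE00010"]])
    n <- dnx * dny * nframes
    stored <- if (bits == 32L) {
      v <- readBin(raw_pix, "integer", n = n, size = 4L, endian = "little")
      ifelse(v < 0, v + 4294967296, v)
    } else {
      readBin(raw_pix, "integer", n = n, size = 2L, signed = FALSE,
              endian = "little")
    }
    dzd <- if (length(offs) > 1) offs[2] - offs[1] else g$spacing[3]
    dg <- grid_geometry(c(dipp[1], dipp[2], dipp[3] + offs[1]),
                        c(dps[2], dps[1], dzd), c(dnx, dny, nframes))
    dvol <- image_volume(array(stored * scaling, dg$shape), dg, "DOSE")
    dose <- resample(dvol, g, mode = "linear")
  }

  masks <- list()
  if (!is.null(rtstruct)) {
    ds <- dcm_read_file(rtstruct)
    sfor <- NULL
    frseq <- ds[["30060010"]]
    if (!is.null(frseq) && length(frseq)) sfor <- dcm_str(frseq[[1]], "00200052")
    if (!is.null(sfor) && !identical(sfor, for_uid))
      stop("RTSTRUCT frame of reference does not match the CT series")
    rois <- ds[["30060020"]]
    roinames <- list()
    for (it in rois)
      roinames[[dcm_str(it, "30060022")]] <- dcm_str(it, "30060026")
    for (it in ds[["30060039"]]) {
      num <- dcm_str(it, "30060084")
      nm <- roinames[[num]]
      if (is.null(nm)) nm <- paste0("ROI_", num)
      cseq <- it[["30060040"]]
      contours <- list()
      if (!is.null(cseq)) {
        for (cit in cseq) {
          pts <- dcm_num(cit, "30060050")
          contours[[length(contours) + 1L]] <- matrix(pts, ncol = 3, byrow = TRUE)
        }
      }
      if (!length(contours)) {
        warning("ROI '", nm, "' has no contours; empty mask")
        masks[[nm]] <- binary_mask(array(FALSE, g$shape), g, nm)
      } else {
        masks[[nm]] <- binary_mask(rasterize_contours(contours, g), g, nm)
      }
    }
  }
  if (is.null(id)) id <- dcm_str(s1, "00100020")
  if (is.null(id) || !nzchar(id)) id <- "case"
  patient_case(id, ct, dose, structure_set(masks), prescription_gy)
}
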