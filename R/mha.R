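# MetaImage (.mha, local data) reader/writer: the package's research volume
# format. One file per volume; masks stored as MET_UCHAR 0/1, scalar volumes
# and deformation fields (ElementNumberOfChannels = 3) as MET_FLOAT or
# MET_DOUBLE. Little-endian, uncompressed.

#' Write a volume, mask or deformation field as MetaImage (.mha)
#'
#' @param x an `image_volume`, `binary_mask` or `deformation_field`.
#' @param path output file path (conventionally `.mha`).
#' @return `path`, invisibly.
#' @export
write_mha <- function(x, path) {
  g <- x$geometry
  if (inherits(x, "deformation_field")) {
    nch <- 3L; et <- "MET_DOUBLE"
    dat <- aperm(x$vectors, c(4, 1, 2, 3)) # channel-fastest on disk
  } else if (inherits(x, "binary_mask")) {
    nch <- 1L; et <- "MET_UCHAR"
    dat <- x$values + 0L
  } else {
    nch <- 1L; et <- "MET_DOUBLE"
    dat <- x$values
  }
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s",
            paste(formatC(as.vector(t(g$orientation)), format = "g", digits = 15),
                  collapse = " ")),
    sprintf("Offset = %s",
            paste(formatC(g$origin, format = "g", digits = 15), collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(formatC(g$spacing, format = "g", digits = 15), collapse = " ")),
    sprintf("DimSize = %d %d %d", g$shape[1], g$shape[2], g$shape[3]),
    if (nch > 1L) sprintf("ElementNumberOfChannels = %d", nch),
    if (inherits(x, "image_volume")) sprintf("Modality = %s", x$modality),
    if (inherits(x, "binary_mask")) sprintf("StructureName = %s", x$name),
    sprintf("ElementType = %s", et),
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (et == "MET_UCHAR") {
    writeBin(as.integer(dat), con, size = 1L)
  } else {
    writeBin(as.numeric(dat), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage (.mha) volume written by [write_mha()]
#'
#' @param path file path.
#' @return an `image_volume`, `binary_mask` or `deformation_field`,
#'   according to the stored element type and channel count.
#' @export
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL element data is supported")
  shape <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  orient <- diag(3)
  if (!is.null(hdr[["TransformMatrix"]]))
    orient <- t(matrix(as.numeric(strsplit(hdr[["TransformMatrix"]], "\\s+")[[1]]), 3, 3))
  g <- grid_geometry(origin, spacing, shape, orient)
  nch <- if (is.null(hdr[["ElementNumberOfChannels"]])) 1L
         else as.integer(hdr[["ElementNumberOfChannels"]])
  et <- hdr[["ElementType"]]
  n <- prod(shape) * nch
  dat <- switch(et,
    MET_UCHAR = readBin(con, "integer", n = n, size = 1L, signed = FALSE),
    MET_FLOAT = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n = n, size = 8L, endian = "little"),
    MET_SHORT = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                        endian = "little"),
    stop("unsupported ElementType: ", et))
  if (nch == 3L) {
    vec <- aperm(array(dat, c(3L, shape)), c(2, 3, 4, 1))
    return(deformation_field(vec, g))
  }
  if (identical(et, "MET_UCHAR")) {
    nm <- if (is.null(hdr[["StructureName"]])) "mask" else hdr[["StructureName"]]
    return(binary_mask(array(dat > 0, shape), g, nm))
  }
  modality <- if (is.null(hdr[["Modality"]])) "CT" else hdr[["Modality"]]
  image_volume(array(dat, shape), g, modality)
}

#' Write a patient case as a research-format directory
#'
#' Emits `ct.mha`, `dose.mha` (if present), one `struct_<name>.mha` per
#' structure, and a `case.json` manifest with id and prescription.
#'
#' @param case a `patient_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case_dir <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mha(case$ct, file.path(dir, "ct.mha"))
  if (!is.null(case$dose)) write_mha(case$dose, file.path(dir, "dose.mha"))
  for (m in case$structures$masks)
    write_mha(m, file.path(dir, sprintf("struct_%s.mha", gsub("[^A-Za-z0-9_-]", "_", m$name))))
  jsonlite::write_json(
    list(id = case$id, prescription_gy = case$prescription_gy,
         structures = I(names(case$structures$masks))),
    file.path(dir, "case.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a research-format case directory written by [write_case_dir()]
#'
#' @param dir case directory.
#' @return a `patient_case`.
#' @export
read_case_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "case.json"), simplifyVector = TRUE)
  ct <- read_mha(file.path(dir, "ct.mha"))
  dose_path <- file.path(dir, "dose.mha")
  dose <- if (file.exists(dose_path)) read_mha(dose_path) else NULL
  sfiles <- list.files(dir, pattern = "^struct_.*\\.mha$", full.names = TRUE)
  masks <- lapply(sfiles, read_mha)
  if (length(masks)) names(masks) <- vapply(masks, function(m) m$name, character(1))
  patient_case(meta$id, ct, dose, structure_set(masks), meta$prescription_gy)
}
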