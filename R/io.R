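#' Read and write volumes (MetaImage and NIfTI)
#'
#' `write_volume()` writes a [volume_image()] or [binary_mask()] to disk;
#' `read_volume()` reads it back, preserving values, per-axis voxel pitch
#' and origin.  The format follows the file extension: `.mhd` writes a
#' MetaImage header plus a little-endian `.raw` payload (`MET_DOUBLE` for
#' volumes, `MET_UCHAR` 0/1 for masks); `.nii`/`.nii.gz` use NIfTI-1.
#'
#' @param vol a [volume_image()] or [binary_mask()].
#' @param path output path ending in `.mhd`, `.nii` or `.nii.gz`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a [volume_image()] (or [binary_mask()] for 0/1 `MET_UCHAR`
#'   data).
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "binary_mask")
  stopifnot(is_mask || inherits(vol, "volume_image"))
  ext <- file_ext2(path)
  d <- dim(vol$values)
  pitch <- rep(vol$voxel_pitch, length(d))
  if (ext == "mhd") {
    rawpath <- sub("\\.mhd$", ".raw", path)
    hdr <- c(
      "ObjectType = Image",
      sprintf("NDims = %d", length(d)),
      "BinaryData = True",
      "BinaryDataByteOrderMSB = False",
      "CompressedData = False",
      sprintf("DimSize = %s", paste(d, collapse = " ")),
      sprintf("ElementSpacing = %s", paste(format(pitch, scientific = FALSE), collapse = " ")),
      sprintf("Offset = %s", paste(format(vol$origin, scientific = FALSE), collapse = " ")),
      sprintf("ElementType = %s", if (is_mask) "MET_UCHAR" else "MET_DOUBLE"),
      sprintf("ElementDataFile = %s", basename(rawpath)))
    writeLines(hdr, path)
    con <- file(rawpath, "wb")
    on.exit(close(con), add = TRUE)
    if (is_mask)
      writeBin(as.integer(vol$values), con, size = 1L, endian = "little")
    else
      writeBin(as.numeric(vol$values), con, size = 8L, endian = "little")
  } else if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(array(as.numeric(vol$values), d))
    RNifti::pixdim(img) <- pitch
    RNifti::writeNifti(img, path)
    # origin stored in a json sidecar: RNifti's qform round-trip is not
    # needed for the package's own pipelines
    jsonlite::write_json(list(origin = vol$origin, mask = is_mask),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else stop("unknown volume format: ", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_volume
#' @param path file path to read.
#' @export
read_volume <- function(path) {
  ext <- file_ext2(path)
  if (ext == "mhd") {
    lines <- readLines(path)
    kv <- strsplit(lines, "\\s*=\\s*")
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, `[`, "", 2)
    need <- function(k) {
      i <- match(k, keys)
      if (is.na(i)) stop("MetaImage header missing ", k, call. = FALSE)
      vals[i]
    }
    d <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
    sp <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
    off <- as.numeric(strsplit(need("Offset"), "\\s+")[[1]])
    et <- need("ElementType")
    rawpath <- file.path(dirname(path), need("ElementDataFile"))
    n <- prod(d)
    con <- file(rawpath, "rb")
    on.exit(close(con), add = TRUE)
    if (et == "MET_UCHAR") {
      v <- readBin(con, "integer", n = n, size = 1L, signed = FALSE, endian = "little")
      return(binary_mask(array(v != 0, d), voxel_pitch = sp[1], origin = off))
    } else if (et %in% c("MET_DOUBLE", "MET_FLOAT")) {
      v <- readBin(con, "double", n = n, size = if (et == "MET_FLOAT") 4L else 8L,
                   endian = "little")
      vol <- volume_image(array(v, d), voxel_pitch = sp[1], origin = off)
      if (length(unique(sp)) > 1) attr(vol, "anisotropic_pitch") <- sp
      return(vol)
    }
    stop("unsupported MetaImage element type ", et, call. = FALSE)
  } else if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    side <- paste0(path, ".json")
    origin <- NULL; is_mask <- FALSE
    if (file.exists(side)) {
      meta <- jsonlite::read_json(side, simplifyVector = TRUE)
      origin <- meta$origin; is_mask <- isTRUE(meta$mask)
    }
    arr <- array(as.numeric(img), dim(img))
    if (is_mask)
      return(binary_mask(arr != 0, voxel_pitch = pd[1], origin = origin))
    vol <- volume_image(arr, voxel_pitch = pd[1], origin = origin)
    if (length(unique(pd)) > 1) attr(vol, "anisotropic_pitch") <- pd
    return(vol)
  }
  stop("unknown volume format: ", ext, call. = FALSE)
}

file_ext2 <- function(path) {
  if (grepl("\\.nii\\.gz$", path)) return("nii.gz")
  tolower(sub(".*\\.", "", path))
}

#' Read and write sinograms (flat binary + JSON sidecar)
#'
#' Projection data are stored as a little-endian double `.raw` payload next
#' to a JSON sidecar holding the array shape, view angles and full scan
#' geometry, so a dataset can be reloaded without ambiguity.
#'
#' @param proj a [projection_data()].
#' @param path output path ending in `.json` (the payload uses the same
#'   stem with `.raw`).
#' @return `write_projections()` returns `path` invisibly;
#'   `read_projections()` returns a [projection_data()].
#' @export
write_projections <- function(proj, path) {
  stopifnot(inherits(proj, "projection_data"), grepl("\\.json$", path))
  rawpath <- sub("\\.json$", ".raw", path)
  g <- proj$geometry
  meta <- list(shape = dim(proj$values),
               geometry = list(mode = g$mode, sad = g$sad, sdd = g$sdd,
                               det_pitch = g$det_pitch,
                               det_count = g$det_count,
                               det_rows = g$det_rows,
                               angles = g$angles),
               photon_budget = proj$photon_budget,
               neg_tol = proj$neg_tol,
               data_file = basename(rawpath))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(rawpath, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(proj$values), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- meta$geometry
  geom <- scan_geometry(mode = g$mode, sad = g$sad, sdd = g$sdd,
                        det_pitch = g$det_pitch, det_count = g$det_count,
                        det_rows = g$det_rows, angles = g$angles)
  rawpath <- file.path(dirname(path), meta$data_file)
  con <- file(rawpath, "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, "double", n = prod(meta$shape), size = 8L, endian = "little")
  pb <- meta$photon_budget
  if (is.null(pb)) pb <- NULL
  projection_data(array(v, meta$shape), geom, photon_budget = pb,
                  neg_tol = if (is.null(meta$neg_tol)) 0 else meta$neg_tol)
}
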