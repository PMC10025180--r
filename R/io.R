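# interface_io: volume and table I/O. NIfTI via RNifti, multi-page TIFF via
# the tiff package (voxel size carried in a JSON sidecar), and a minimal
# MetaImage (.mha) reader/writer for uncompressed, locally stored data.
# All volumes are required to be isotropic; axis order is (x, y, z = scan
# axis) and is preserved through every round trip.

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.mha$", lower)) return("mha")
  if (grepl("\\.tiff?$", lower)) return("tiff")
  stop("unknown format: ", path)
}

#' Read / write a 3D volume
#'
#' Supported formats (by extension): NIfTI (`.nii`, `.nii.gz`), MetaImage
#' (`.mha`, uncompressed with local data), and multi-page TIFF (`.tif`,
#' with the voxel size in a JSON sidecar `<path>.json`). The voxel size is
#' preserved exactly through a write-read round trip; anisotropic volumes are
#' rejected since the pipeline assumes isotropic grids.
#'
#' @param path file path; the extension selects the format.
#' @return [read_volume()]: a [volume_image()].
#' @export
read_volume <- function(path) {
  fmt <- volume_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(fmt,
    nifti = {
      im <- RNifti::readNifti(path)
      pd <- attr(im, "pixdim")
      if (is.null(pd)) pd <- RNifti::pixdim(im)
      pd <- pd[seq_len(min(3, length(pd)))]
      if (max(pd) - min(pd) > 1e-6 * max(pd)) stop("anisotropic voxels")
      # NIfTI stores pixdim as float32; snap to its 7 significant decimal
      # digits so voxel sizes written by this package round-trip exactly
      arr <- as.array(im)
      attributes(arr) <- list(dim = dim(arr))
      volume_image(arr, grid_spec(dim(arr), voxel_size = signif(pd[1], 7)))
    },
    mha = read_mha(path),
    tiff = {
      sidecar <- paste0(path, ".json")
      if (!file.exists(sidecar))
        stop("voxel-size sidecar missing: ", sidecar,
             " (expected JSON with field voxel_size_mm)")
      meta <- jsonlite::read_json(sidecar)
      if (is.null(meta$voxel_size_mm)) stop("sidecar lacks voxel_size_mm")
      pages <- tiff::readTIFF(path, all = TRUE)
      arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                              length(pages)))
      for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
      volume_image(arr, grid_spec(dim(arr), voxel_size = meta$voxel_size_mm))
    })
}

#' @param image a [volume_image()], or a 3D array combined with `voxel_size`.
#' @param voxel_size voxel size in mm when `image` is a bare array.
#' @rdname read_volume
#' @export
write_volume <- function(image, path, voxel_size = NULL) {
  if (!inherits(image, "volume_image")) {
    if (is.null(voxel_size)) stop("voxel_size required for bare arrays")
    image <- volume_image(image * 1.0, grid_spec(dim(image), voxel_size))
  }
  h <- image$grid$voxel_size
  switch(volume_format(path),
    nifti = {
      im <- RNifti::asNifti(image$values)
      RNifti::pixdim(im) <- rep(h, 3)
      RNifti::writeNifti(im, path)
    },
    mha = write_mha(image$values, path, h),
    tiff = {
      v <- image$values
      if (min(v) < 0 || max(v) > 1)
        stop("TIFF output supports grayscale in [0, 1] only")
      pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k])
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
      jsonlite::write_json(list(voxel_size_mm = h), paste0(path, ".json"),
                           auto_unbox = TRUE, digits = NA)
    })
  invisible(path)
}

# ---- minimal MetaImage (.mha) support: 3D, binary, local, little-endian ----

MHA_TYPES <- list(MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
                  MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
                  MET_INT = list(what = "integer", size = 4, signed = TRUE),
                  MET_FLOAT = list(what = "numeric", size = 4),
                  MET_DOUBLE = list(what = "numeric", size = 8))

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) stop("malformed MetaImage header")
    kv <- regmatches(line, regexec("^([A-Za-z]+) *= *(.*)$", line))[[1]]
    if (length(kv) != 3) stop("malformed MetaImage header line: ", line)
    header[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(header$ElementDataFile, "LOCAL"))
    stop("only MetaImage files with local data are supported")
  if (!is.null(header$CompressedData) &&
      tolower(header$CompressedData) == "true")
    stop("compressed MetaImage data is not supported")
  if (!identical(header$NDims, "3")) stop("only 3D MetaImage volumes supported")
  if (!is.null(header$BinaryDataByteOrderMSB) &&
      tolower(header$BinaryDataByteOrderMSB) == "true")
    stop("big-endian MetaImage data is not supported")
  dims <- as.integer(strsplit(trimws(header$DimSize), " +")[[1]])
  spacing <- as.numeric(strsplit(trimws(header$ElementSpacing), " +")[[1]])
  if (max(spacing) - min(spacing) > 1e-9 * max(spacing))
    stop("anisotropic voxels")
  type <- MHA_TYPES[[header$ElementType]]
  if (is.null(type)) stop("unsupported ElementType: ", header$ElementType)
  n <- prod(dims)
  raw <- readBin(con, what = type$what, n = n, size = type$size,
                 signed = if (type$what == "integer" && type$size <= 2)
                   isTRUE(type$signed) else TRUE,
                 endian = "little")
  if (length(raw) != n) stop("truncated MetaImage data")
  volume_image(array(as.numeric(raw), dim = dims),
               grid_spec(dims, voxel_size = spacing[1]))
}

write_mha <- function(values, path, voxel_size) {
  int_like <- all(values == round(values)) && max(abs(values)) <= .Machine$integer.max
  type <- if (int_like) "MET_INT" else "MET_DOUBLE"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("DimSize = %d %d %d", dim(values)[1], dim(values)[2], dim(values)[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g", voxel_size, voxel_size, voxel_size),
           sprintf("ElementType = %s", type),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  if (int_like) writeBin(as.integer(values), con, size = 4, endian = "little")
  else writeBin(as.numeric(values), con, size = 8, endian = "little")
  invisible(path)
}

#' Write / read a label volume (0 background, 1 distal, 2 proximal)
#'
#' @param bones a [bone_pair_mask()].
#' @param path output path (`.nii`, `.nii.gz` or `.mha`).
#' @rdname read_volume
#' @export
write_labels <- function(bones, path) {
  stopifnot(inherits(bones, "bone_pair_mask"))
  write_volume(volume_image(as_label_volume(bones) * 1.0, bones$grid), path)
}

#' @param grid optional [grid_spec()] cross-check when reading labels.
#' @rdname read_volume
#' @export
read_labels <- function(path, grid = NULL) {
  vol <- read_volume(path)
  if (!is.null(grid) && !isTRUE(all.equal(grid, vol$grid)))
    stop("label grid mismatch")
  from_label_volume(array(as.integer(round(vol$values)), dim = vol$grid$shape),
                    vol$grid)
}

#' Write ground-truth gap statistics as a JSON sidecar
#'
#' @param truth the `truth` element of a [make_phantom()] result.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  keep <- truth[setdiff(names(truth), "gap_field")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write / read a cohort table as CSV
#'
#' Column schema: `id`, `group`, `sex`, `joint`, demographic columns, the six
#' morphometry parameters (`jsv` mm^3, `jsw`, `jsw_sd`, `jsw_min`, `jsw_max`
#' mm, `jsw_as` unitless) and the `ankylotic` flag.
#'
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
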