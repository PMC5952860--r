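#' Read a 3D volume or mask from disk
#'
#' Supported formats: MetaImage (`.mha`, uncompressed with embedded raw
#' data), NIfTI (`.nii`, `.nii.gz`) and multi-page TIFF stacks (`.tif`,
#' `.tiff`, voxel size from a JSON sidecar `<file>.json` containing
#' `{"voxel_size_mm": x}` or from the `voxel_size_mm` argument).  Voxel
#' values are returned untouched; no rescaling is applied.  Files with
#' missing or anisotropic spacing are rejected because all diameter
#' thresholds in the detection algorithm are defined on an isotropic grid.
#'
#' @param path file path.
#' @param format one of `"mha"`, `"nifti"`, `"tiff_stack"`; guessed from
#'   the extension when `NULL`.
#' @param voxel_size_mm spacing override, required for TIFF stacks without
#'   a sidecar.
#' @return An [image_volume] object.
#' @seealso [write_volume()], [write_mask()]
#' @export
read_volume <- function(path, format = NULL, voxel_size_mm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% guess_format(path)
  out <- switch(format,
    mha = read_mha(path),
    nifti = read_nifti_vol(path),
    tiff_stack = read_tiff_stack(path, voxel_size_mm),
    stop("unsupported format: ", format))
  sp <- out$spacing
  if (is.null(sp) || any(!is.finite(sp)))
    stop("voxel size unknown for ", path,
         " (supply spacing metadata or `voxel_size_mm`)")
  if (max(sp) - min(sp) > 1e-6 * max(sp))
    stop(sprintf("anisotropic spacing (%s) not supported",
                 paste(signif(sp, 6), collapse = " x ")))
  image_volume(out$data, sp[1])
}

#' Read a mask from disk
#'
#' [read_volume()] followed by a strict 0/1 check.
#'
#' @inheritParams read_volume
#' @param role mask role tag (see [binary_mask()]).
#' @return A [binary_mask] object.
#' @export
read_mask <- function(path, role = "bone", format = NULL,
                      voxel_size_mm = NULL) {
  v <- read_volume(path, format, voxel_size_mm)
  if (!all(v$data %in% c(0, 1)))
    stop("file does not contain a 0/1 mask: ", path)
  binary_mask(v$data != 0, v$voxel_size_mm, role)
}

#' Write a volume or mask to disk
#'
#' Masks are written as unsigned 8-bit 0/1, volumes in their native double
#' precision (MetaImage), 32-bit float (NIfTI) or 32-bit float TIFF.  TIFF
#' stacks get a JSON sidecar `<file>.json` carrying the voxel size.
#'
#' @param vol an [image_volume].
#' @param path destination path.
#' @param format as in [read_volume()]; guessed from the extension when
#'   `NULL`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot(is_volume(vol) || is_mask(vol))
  format <- format %||% guess_format(path)
  arr <- if (is_mask(vol)) array(as.numeric(vol$data), dim(vol$data)) else vol$data
  sp <- rep(vol$voxel_size_mm, 3)
  switch(format,
    mha = write_mha(arr, sp, path, uint8 = is_mask(vol)),
    nifti = write_nifti_vol(arr, sp, path, uint8 = is_mask(vol)),
    tiff_stack = write_tiff_stack(arr, sp, path, uint8 = is_mask(vol)),
    stop("unsupported format: ", format))
  invisible(path)
}

#' @rdname write_volume
#' @param mask a [binary_mask].
#' @export
write_mask <- function(mask, path, format = NULL) {
  stopifnot(is_mask(mask))
  write_volume(mask, path, format)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.mha$", lower)) return("mha")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.tiff?$", lower)) return("tiff_stack")
  stop("cannot guess format from extension of ", path)
}

# ---- MetaImage (.mha), local uncompressed raw ------------------------------

mha_types <- c(MET_UCHAR = "integer", MET_SHORT = "integer",
               MET_USHORT = "integer", MET_INT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
mha_sizes <- c(MET_UCHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header in ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only ElementDataFile = LOCAL .mha files are supported")
  if (!is.null(hdr[["CompressedData"]]) &&
      toupper(hdr[["CompressedData"]]) == "TRUE")
    stop("compressed MetaImage not supported")
  ndims <- as.integer(hdr[["NDims"]] %||% "3")
  if (ndims != 3L) stop("expected NDims = 3, got ", ndims)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing_str <- hdr[["ElementSpacing"]] %||% hdr[["ElementSize"]]
  spacing <- if (is.null(spacing_str)) NULL else
    as.numeric(strsplit(spacing_str, "\\s+")[[1]])
  type <- hdr[["ElementType"]]
  if (is.null(type) || !type %in% names(mha_types))
    stop("unsupported ElementType: ", type %||% "<missing>")
  msb <- toupper(hdr[["BinaryDataByteOrderMSB"]] %||%
                 hdr[["ElementByteOrderMSB"]] %||% "FALSE") == "TRUE"
  n <- prod(dims)
  raw_what <- mha_types[[type]]
  size <- mha_sizes[[type]]
  vals <- readBin(con, what = raw_what, n = n, size = size,
                  signed = !(type %in% c("MET_UCHAR", "MET_USHORT")),
                  endian = if (msb) "big" else "little")
  if (length(vals) != n) stop("truncated MetaImage data in ", path)
  list(data = array(as.numeric(vals), dims), spacing = spacing)
}

write_mha <- function(arr, spacing, path, uint8 = FALSE) {
  dims <- dim(arr)
  type <- if (uint8) "MET_UCHAR" else "MET_DOUBLE"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g",
            spacing[1], spacing[2], spacing[3]),
    sprintf("ElementType = %s", type),
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (uint8) {
    writeBin(as.integer(arr), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  }
  invisible(path)
}

# ---- NIfTI -----------------------------------------------------------------

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  list(data = array(as.numeric(img), dim(img)[1:3]), spacing = sp)
}

write_nifti_vol <- function(arr, spacing, path, uint8 = FALSE) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path,
                     datatype = if (uint8) "uint8" else "double")
  invisible(path)
}

# ---- multi-page TIFF + JSON sidecar ----------------------------------------

tiff_sidecar <- function(path) paste0(path, ".json")

read_tiff_stack <- function(path, voxel_size_mm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d12 <- dim(pages[[1]])
  arr <- array(0, c(d12[2], d12[1], nz))  # TIFF rows are y; store as x,y,z
  for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
  sp <- voxel_size_mm
  if (is.null(sp) && file.exists(tiff_sidecar(path))) {
    meta <- jsonlite::read_json(tiff_sidecar(path))
    sp <- meta$voxel_size_mm
  }
  if (is.null(sp)) stop("voxel size unknown for TIFF stack ", path,
                        " (no sidecar, no `voxel_size_mm`)")
  # 8-bit pages come back scaled to [0,1]; restore integer gray levels
  list(data = array(round(arr * 255), dim(arr)),
       spacing = rep(as.numeric(sp), 3))
}

write_tiff_stack <- function(arr, spacing, path, uint8 = FALSE) {
  dims <- dim(arr)
  if (!uint8) {
    rng <- range(arr)
    if (any(arr < 0) || any(arr > 255) || any(arr != round(arr)))
      stop("TIFF stack export supports integer gray levels 0..255; ",
           sprintf("data range is [%g, %g]; use mha or nifti", rng[1], rng[2]))
  }
  pages <- lapply(seq_len(dims[3]), function(k) t(arr[, , k]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(voxel_size_mm = spacing[1]), tiff_sidecar(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
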