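#' Read a 3D volume from multi-page TIFF or NIfTI-1
#'
#' Multi-page grayscale TIFF (8/16-bit integer or float32) and NIfTI-1
#' (`.nii`, `.nii.gz`) are supported. For NIfTI input, a positive voxel
#' spacing recorded in the header takes precedence over the `spacing`
#' argument (a header spacing of exactly (1,1,1) is treated as absent when an
#' explicit `spacing` is supplied, since 1 is the NIfTI default).
#'
#' @param path path to the volume file.
#' @param spacing voxel size in micrometres (length 3). Defaults to
#'   (1,1,1) with a warning, in which case physical outputs are in voxel
#'   units.
#' @return an [image_volume()] (numeric `vol3d`).
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path))
    lob_stop(sprintf("cannot read volume: '%s' does not exist", path), "lobuseg_io_error")
  if (is.null(spacing)) {
    warning("no spacing supplied; assuming (1, 1, 1) µm (voxel units)")
    spacing <- c(1, 1, 1)
    explicit <- FALSE
  } else explicit <- TRUE
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e) lob_stop(
                        sprintf("failed to read TIFF '%s': %s", path, conditionMessage(e)),
                        "lobuseg_io_error"))
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2 && length(dim(pages[[1]])) == 2)
      lob_stop("TIFF contains a single 2D page; a 3D volume is required",
               "lobuseg_dim_error")
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) {
        if (dim(p)[3] != 1)
          lob_stop("multi-channel TIFF is not supported; grayscale required",
                   "lobuseg_io_error")
        p <- p[, , 1]
      }
      # readTIFF returns row-major matrices (rows = y); transpose so the
      # first array axis is x, matching the package's (x, y, z) convention.
      t(p)
    })
    data <- array(unlist(pages, use.names = FALSE),
                  dim = c(dim(pages[[1]]), length(pages)))
    return(image_volume(data, spacing = spacing))
  }
  if (ext == "nii") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) lob_stop(
                      sprintf("failed to read NIfTI '%s': %s", path, conditionMessage(e)),
                      "lobuseg_io_error"))
    data <- as.array(img)
    if (length(dim(data)) == 2)
      lob_stop("NIfTI contains a 2D image; a 3D volume is required", "lobuseg_dim_error")
    hdr_sp <- RNifti::pixdim(img)[seq_len(3)]
    if (all(is.finite(hdr_sp)) && all(hdr_sp > 0) &&
        !(explicit && all(hdr_sp == 1))) {
      spacing <- hdr_sp
    }
    return(image_volume(data, spacing = spacing))
  }
  lob_stop(sprintf("unrecognised volume format '%s' (use .tif/.tiff/.nii/.nii.gz)", ext),
           "lobuseg_io_error")
}

#' Write a 3D volume to multi-page TIFF or NIfTI-1
#'
#' Integer-valued data (labels, masks, 8/16-bit intensities up to 65535) can
#' be written to TIFF losslessly. Floating-point data must be written as
#' NIfTI-1, which stores float32 together with the voxel spacing; spacing is
#' not representable in the plain TIFF baseline tags used here, so prefer
#' NIfTI when geometry must round-trip.
#'
#' @param vol a `vol3d` (or plain 3D array).
#' @param path output path ending in `.tif`, `.tiff` or `.nii`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    lob_stop(sprintf("parent directory of '%s' does not exist", path), "lobuseg_io_error")
  data <- as_array3d(vol)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.logical(data)) data <- array(as.integer(data), dim(data))
    if (any(data != round(data)))
      lob_stop("TIFF output supports integer-valued data only; use .nii for float volumes",
               "lobuseg_io_error")
    if (min(data) < 0 || max(data) > 65535)
      lob_stop("TIFF output requires values in [0, 65535]", "lobuseg_io_error")
    bits <- if (max(data) <= 255) 8L else 16L
    scale <- 2^bits - 1
    pages <- lapply(seq_len(dim(data)[3]), function(k) t(data[, , k]) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
    return(invisible(path))
  }
  if (ext == "nii") {
    arr <- data
    attributes(arr) <- list(dim = dim(data))
    dtype <- if (is.integer(arr) ||
                 (is.double(arr) && all(arr == round(arr)) &&
                  max(abs(arr)) < 2^31)) "int32" else "float"
    if (dtype == "int32") storage.mode(arr) <- "integer"
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vol_spacing(vol)
    RNifti::writeNifti(img, path, datatype = dtype)
    return(invisible(path))
  }
  lob_stop(sprintf("unrecognised output format '%s' (use .tif/.tiff/.nii)", ext),
           "lobuseg_io_error")
}

#' Block-mean downscaling
#'
#' Reduces the volume by integer factors per axis, replacing each
#' `fx * fy * fz` block with its mean; trailing partial blocks are dropped.
#' Block averaging (rather than subsampling) preserves the intensity
#' statistics of thin septa at reduced resolution. Output spacing is the
#' input spacing multiplied by the factors; the origin moves to the centre
#' of the first block.
#'
#' @param vol a `vol3d` or 3D array.
#' @param factor positive integer length-3 reduction factor, default
#'   `c(4, 4, 1)` reflecting the coarser native z sampling of confocal
#'   stacks.
#' @return downscaled [image_volume()].
#' @export
downscale <- function(vol, factor = c(4, 4, 1)) {
  data <- as_array3d(vol)
  factor <- as.numeric(factor)
  if (length(factor) != 3 || any(factor < 1) || any(factor != round(factor)))
    lob_stop("factor must be 3 positive integers", "lobuseg_param_error")
  factor <- as.integer(factor)
  d <- dim(data)
  out_d <- d %/% factor
  if (any(out_d < 1))
    lob_stop("each dimension must be at least its downscale factor", "lobuseg_dim_error")
  a <- data[seq_len(out_d[1] * factor[1]),
            seq_len(out_d[2] * factor[2]),
            seq_len(out_d[3] * factor[3]), drop = FALSE]
  storage.mode(a) <- "double"
  dim(a) <- c(factor[1], out_d[1], factor[2], out_d[2], factor[3], out_d[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(prod(factor), prod(out_d))
  out <- colMeans(a)
  dim(out) <- out_d
  sp <- vol_spacing(vol)
  o <- vol_origin(vol)
  image_volume(out, spacing = sp * factor, origin = o + (factor - 1) / 2 * sp)
}
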