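#' 3D image volumes with physical voxel geometry
#'
#' A `vol3d` is a plain 3D array carrying `spacing` (voxel size in
#' micrometres, per axis) and `origin` (physical coordinate of the centre of
#' voxel `(1,1,1)`, in micrometres) as attributes. Intensity volumes are
#' numeric, label volumes integer (0 = background, k > 0 = subunit k), and
#' masks logical. All package operations preserve these attributes.
#'
#' The physical centre of voxel `(i, j, k)` (1-based array index) is
#' `origin + ((i,j,k) - 1) * spacing`.
#'
#' @param data a 3D array (numeric, integer or logical).
#' @param spacing numeric length-3, voxel size in micrometres; all > 0.
#' @param origin numeric length-3, physical coordinate (micrometres) of the
#'   first voxel centre.
#' @return `image_volume()` returns a numeric `vol3d`; `label_volume()` an
#'   integer `vol3d` whose negative-free values label subunits.
#' @examples
#' v <- image_volume(array(rnorm(24), c(4, 3, 2)), spacing = c(1, 1, 2))
#' vol_spacing(v)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) lob_stop("volume intensities must be finite", "lobuseg_param_error")
  new_vol3d(data, spacing, origin)
}

#' @rdname image_volume
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  if (any(data < 0, na.rm = TRUE)) lob_stop("labels must be >= 0", "lobuseg_param_error")
  storage.mode(data) <- "integer"
  new_vol3d(data, spacing, origin)
}

new_vol3d <- function(data, spacing, origin) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    lob_stop("spacing must be 3 positive finite values", "lobuseg_param_error")
  if (length(origin) != 3 || any(!is.finite(origin)))
    lob_stop("origin must be 3 finite values", "lobuseg_param_error")
  structure(data, spacing = spacing, origin = origin, class = "vol3d")
}

as_array3d <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) == 2) {
    lob_stop("input is not a 3D volume", "lobuseg_dim_error")
  }
  if (length(dim(data)) != 3)
    lob_stop("input must have exactly 3 dimensions", "lobuseg_dim_error")
  data
}

#' @rdname image_volume
#' @param x a `vol3d` or plain array.
#' @export
vol_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) {
    warning("volume has no spacing; assuming (1, 1, 1) µm (voxel units)")
    sp <- c(1, 1, 1)
  }
  sp
}

#' @rdname image_volume
#' @export
vol_origin <- function(x) {
  o <- attr(x, "origin")
  if (is.null(o)) o <- c(0, 0, 0)
  o
}

# Re-wrap raw array data with the geometry of a template volume.
with_geometry <- function(data, template) {
  structure(data,
            spacing = vol_spacing(template), origin = vol_origin(template),
            class = "vol3d")
}

# Strip to a plain logical array (masks stay plain logicals internally).
as_mask <- function(x) {
  m <- x
  attributes(m) <- list(dim = dim(x))
  storage.mode(m) <- "logical"
  m
}

#' @export
Ops.vol3d <- function(e1, e2) {
  tmpl <- if (inherits(e1, "vol3d")) e1 else e2
  strip <- function(x) {
    if (inherits(x, "vol3d")) attributes(x) <- list(dim = dim(x))
    x
  }
  r <- if (missing(e2)) get(.Generic)(strip(e1)) else get(.Generic)(strip(e1), strip(e2))
  if (is.array(r) && identical(dim(r), dim(tmpl))) {
    structure(r, spacing = attr(tmpl, "spacing"), origin = attr(tmpl, "origin"),
              class = "vol3d")
  } else r
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf("<vol3d> %d x %d x %d %s, spacing (%s) µm\n",
              d[1], d[2], d[3], storage.mode(x),
              paste(format(sp, trim = TRUE), collapse = ", ")))
  if (storage.mode(x) == "integer") {
    labs <- sort(unique(x[x > 0L]))
    cat(sprintf("  %d positive labels, %d labelled voxels\n",
                length(labs), sum(x > 0L)))
  } else {
    cat(sprintf("  intensity range [%g, %g]\n", min(x), max(x)))
  }
  invisible(x)
}

# Physical coordinates (micrometres) of voxel centres along each axis.
axis_coords <- function(vol) {
  d <- dim(vol)
  sp <- vol_spacing(vol)
  o <- vol_origin(vol)
  list(x = o[1] + (seq_len(d[1]) - 1) * sp[1],
       y = o[2] + (seq_len(d[2]) - 1) * sp[2],
       z = o[3] + (seq_len(d[3]) - 1) * sp[3])
}

check_same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    lob_stop(paste(what, "must have identical dimensions"), "lobuseg_dim_error")
  invisible(TRUE)
}
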