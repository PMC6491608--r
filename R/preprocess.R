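#' Preprocessing parameters
#'
#' Parameters for contrast-enhancement filtering, binarization and
#' morphological cleanup, plus the heuristic that separates the Segmentable
#' Lobule Area (SLA) from the unstructured periphery.
#'
#' @param box_radius integer length-3, per-axis half-extent (voxels) of the
#'   analysis boxes used by the Kuwahara-ratio filter and the local-SD
#'   contrast map. Default `c(2, 2, 1)`: smaller along z, matching the
#'   coarser axial sampling of confocal stacks.
#' @param variance_epsilon additive variance regulariser (intensity
#'   squared) preventing division by zero in perfectly flat boxes.
#' @param binarize_threshold threshold for the raw intensity volume;
#'   a number or `"otsu"`.
#' @param filtered_threshold threshold for the Kuwahara-filtered volume
#'   (which is not in input intensity units); a number or `"otsu"`.
#' @param closing_radius radius (voxels) of the ball structuring element for
#'   morphological closing of the binarized volume.
#' @param min_island_voxels foreground components (26-connectivity) smaller
#'   than this are removed.
#' @param kuwahara_mode `"classic"` (default: each voxel takes the mean of
#'   its minimum-variance octant box, which preserves boundary sharpness
#'   when septa are only a few voxels wide) or `"ratio"` (average of the
#'   per-box mean/variance ratios; preferable when structures span many
#'   voxels relative to the box).
#' @param sla_contrast_threshold threshold on the local-SD septum-contrast
#'   map; a number or `"otsu"`.
#' @param sla_closing_radius closing radius (voxels) used when consolidating
#'   the contrast map into the SLA candidate region.
#' @param sla_min_island minimum size (voxels) of contrast-map components
#'   kept during SLA detection.
#' @return a named list of class `preprocess_params`.
#' @export
preprocess_params <- function(box_radius = c(2, 2, 1),
                              variance_epsilon = 1,
                              binarize_threshold = "otsu",
                              filtered_threshold = "otsu",
                              closing_radius = 0,
                              min_island_voxels = 64,
                              kuwahara_mode = c("classic", "ratio"),
                              sla_contrast_threshold = "otsu",
                              sla_closing_radius = 4,
                              sla_min_island = 500) {
  box_radius <- as.integer(rep_len(box_radius, 3))
  if (any(box_radius < 1))
    lob_stop("box_radius must be >= 1 per axis", "lobuseg_param_error")
  if (!is.numeric(variance_epsilon) || variance_epsilon <= 0)
    lob_stop("variance_epsilon must be > 0", "lobuseg_param_error")
  if (min_island_voxels < 0)
    lob_stop("min_island_voxels must be >= 0", "lobuseg_param_error")
  structure(list(box_radius = box_radius,
                 variance_epsilon = variance_epsilon,
                 binarize_threshold = binarize_threshold,
                 filtered_threshold = filtered_threshold,
                 closing_radius = closing_radius,
                 min_island_voxels = as.integer(min_island_voxels),
                 kuwahara_mode = match.arg(kuwahara_mode),
                 sla_contrast_threshold = sla_contrast_threshold,
                 sla_closing_radius = sla_closing_radius,
                 sla_min_island = as.integer(sla_min_island)),
            class = "preprocess_params")
}

# ---- integral-image machinery -------------------------------------------

# Cumulative sums along all three axes (robust to singleton dimensions).
cumsum_axis <- function(a, axis) {
  d <- dim(a)
  if (d[axis] == 1) return(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = d[axis])
  m <- apply(m, 2, cumsum)
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

cumsum3 <- function(a) cumsum_axis(cumsum_axis(cumsum_axis(a, 1), 2), 3)

pad_integral <- function(s) {
  d <- dim(s)
  p <- array(0, d + 1L)
  p[seq_len(d[1]) + 1L, seq_len(d[2]) + 1L, seq_len(d[3]) + 1L] <- s
  p
}

# Per-voxel sums over the box [i + lo, i + hi] (per axis), clipped to the
# volume. Returns the (nx,ny,nz) array of box sums given a padded integral
# image; `counts3` gives the matching in-bounds voxel counts.
box_sums <- function(p, d, lo, hi) {
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  lx <- pmax(ix + lo[1], 1L); hx <- pmin(ix + hi[1], d[1]) + 1L
  ly <- pmax(iy + lo[2], 1L); hy <- pmin(iy + hi[2], d[2]) + 1L
  lz <- pmax(iz + lo[3], 1L); hz <- pmin(iz + hi[3], d[3]) + 1L
  p[hx, hy, hz] - p[lx, hy, hz] - p[hx, ly, hz] - p[hx, hy, lz] +
    p[lx, ly, hz] + p[lx, hy, lz] + p[hx, ly, lz] - p[lx, ly, lz]
}

counts3 <- function(d, lo, hi) {
  cx <- pmin(seq_len(d[1]) + hi[1], d[1]) - pmax(seq_len(d[1]) + lo[1], 1L) + 1
  cy <- pmin(seq_len(d[2]) + hi[2], d[2]) - pmax(seq_len(d[2]) + lo[2], 1L) + 1
  cz <- pmin(seq_len(d[3]) + hi[3], d[3]) - pmax(seq_len(d[3]) + lo[3], 1L) + 1
  cx %o% cy %o% cz
}

#' Kuwahara-ratio contrast-enhancement filter
#'
#' Edge-preserving contrast filter: around every voxel, eight octant boxes
#' of per-axis half-extent `box_radius` (the 3D analogue of the four 2D
#' Kuwahara quadrants, each box corner-anchored at the voxel) are evaluated;
#' per box the mean \eqn{m_b} and population variance \eqn{v_b} are
#' computed, and the output is the average over boxes of
#' \eqn{m_b / (v_b + \epsilon)}. Homogeneous (dense, bright) regions map to
#' high values, noisy or edge-straddling neighbourhoods to low values, so
#' septa between lobules become dark valleys while lobule interiors are
#' flattened. Boxes clipped at the volume border use in-bounds voxels only.
#'
#' In `"classic"` mode the filter instead returns the mean of the
#' minimum-variance box (conventional Kuwahara smoothing, output in input
#' intensity units).
#'
#' @param vol an [image_volume()].
#' @param params a [preprocess_params()].
#' @return filtered `vol3d` (dimensionless in `"ratio"` mode).
#' @export
kuwahara_ratio_filter <- function(vol, params = preprocess_params()) {
  a <- as_array3d(vol)
  d <- dim(a)
  r <- params$box_radius
  if (any(d < r + 1L & d > 1L))   # singleton axes degenerate the box cleanly
    lob_stop("volume is smaller than one filter box along some axis",
             "lobuseg_dim_error")
  storage.mode(a) <- "double"
  p1 <- pad_integral(cumsum3(a))
  p2 <- pad_integral(cumsum3(a * a))
  eps <- params$variance_epsilon
  acc <- array(0, d)
  if (params$kuwahara_mode == "classic") {
    best_v <- array(Inf, d)
  }
  for (sx in c(-1L, 1L)) for (sy in c(-1L, 1L)) for (sz in c(-1L, 1L)) {
    lo <- c(if (sx < 0) -r[1] else 0L, if (sy < 0) -r[2] else 0L, if (sz < 0) -r[3] else 0L)
    hi <- c(if (sx < 0) 0L else r[1], if (sy < 0) 0L else r[2], if (sz < 0) 0L else r[3])
    cnt <- counts3(d, lo, hi)
    m <- box_sums(p1, d, lo, hi) / cnt
    v <- pmax(box_sums(p2, d, lo, hi) / cnt - m * m, 0)
    if (params$kuwahara_mode == "ratio") {
      acc <- acc + m / (v + eps)
    } else {
      take <- v < best_v
      acc[take] <- m[take]
      best_v <- pmin(best_v, v)
    }
  }
  if (params$kuwahara_mode == "ratio") acc <- acc / 8
  with_geometry(acc, vol)
}

# Local standard deviation over the centred box of per-axis radius r:
# the septum-contrast map used for SLA separation.
local_sd_map <- function(vol, box_radius) {
  a <- as_array3d(vol)
  d <- dim(a)
  r <- as.integer(rep_len(box_radius, 3))
  storage.mode(a) <- "double"
  p1 <- pad_integral(cumsum3(a))
  p2 <- pad_integral(cumsum3(a * a))
  cnt <- counts3(d, -r, r)
  m <- box_sums(p1, d, -r, r) / cnt
  v <- pmax(box_sums(p2, d, -r, r) / cnt - m * m, 0)
  with_geometry(sqrt(v), vol)
}

# ---- thresholding --------------------------------------------------------

#' Otsu threshold from a 256-bin histogram
#'
#' Maximises the between-class variance over a 256-bin histogram spanning
#' the data range. The returned value is the upper edge of the optimal
#' split bin, to be used as `value > threshold`.
#'
#' @param x numeric data (volume or vector).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    lob_stop("intensity histogram is degenerate (constant data); cannot apply Otsu",
             "lobuseg_degenerate_histogram")
  nb <- 256L
  edges <- seq(rng[1], rng[2], length.out = nb + 1L)
  bin <- findInterval(x, edges, all.inside = TRUE)
  p <- tabulate(bin, nbins = nb) / length(x)
  centers <- (edges[-1] + edges[-(nb + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nb]
  t_idx <- seq_len(nb - 1L)
  denom <- omega[t_idx] * (1 - omega[t_idx])
  sigma_b <- (mu_t * omega[t_idx] - mu[t_idx])^2 / denom
  sigma_b[denom <= 0] <- -Inf
  edges[which.max(sigma_b) + 1L]
}

#' Binarize a volume
#'
#' Foreground is `value > threshold`; `"otsu"` computes the threshold with
#' [otsu_threshold()].
#'
#' @param vol an [image_volume()].
#' @param threshold a number or `"otsu"`.
#' @return logical `vol3d` mask.
#' @export
binarize <- function(vol, threshold = "otsu") {
  a <- as_array3d(vol)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(a) else {
    if (!is.numeric(threshold) || length(threshold) != 1)
      lob_stop("threshold must be a single number or \"otsu\"", "lobuseg_param_error")
    threshold
  }
  m <- a > thr
  out <- with_geometry(m, vol)
  attr(out, "threshold") <- thr
  out
}

# ---- morphology ----------------------------------------------------------

# Euclidean-ball dilation/erosion via the package's distance transform.
# `scale` rescales the per-axis voxel step, allowing per-axis radii
# (radius 1 at scale 1/r erodes r voxels along that axis).
mask_dilate <- function(mask, radius, scale = c(1, 1, 1)) {
  m <- as_mask(mask)
  d2 <- cpp_edt_sq(!m, dim(m), as.numeric(scale))
  array(m | (d2 <= radius^2 + 1e-9), dim(m))
}

mask_erode <- function(mask, radius, scale = c(1, 1, 1)) {
  m <- as_mask(mask)
  d2 <- cpp_edt_sq(m, dim(m), as.numeric(scale))
  array(m & (d2 > radius^2 + 1e-9), dim(m))
}

mask_close <- function(mask, radius, scale = c(1, 1, 1)) {
  if (radius <= 0) return(as_mask(mask))
  mask_erode(mask_dilate(mask, radius, scale), radius, scale)
}

# Fill background cavities not connected to the volume border
# (6-connectivity on the background).
fill_holes <- function(mask) {
  m <- as_mask(mask)
  d <- dim(m)
  lab <- array(cpp_label_components(!m, d, 6L), d)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0]
  holes <- !m & !(lab %in% border)
  array(m | holes, d)
}

#' Morphological cleanup of a binary mask
#'
#' Closing with a Euclidean ball of `closing_radius` voxels (voxel units,
#' anisotropy ignored) fills small gaps and pits; foreground components
#' (26-connectivity) smaller than `min_island_voxels` are then removed.
#' Idempotent for fixed parameters.
#'
#' @param mask logical `vol3d` (or plain 3D logical array).
#' @param closing_radius ball radius in voxels (0 = no closing).
#' @param min_island_voxels minimum surviving component size (0 = keep all).
#' @return cleaned logical `vol3d`.
#' @export
cleanup <- function(mask, closing_radius = 2, min_island_voxels = 64) {
  m <- mask_close(mask, closing_radius)
  if (min_island_voxels > 0 && any(m)) {
    lab <- cpp_label_components(m, dim(m), 26L)
    sizes <- tabulate(lab)
    drop <- which(sizes < min_island_voxels)
    if (length(drop)) m[array(lab, dim(m)) %in% drop] <- FALSE
  }
  out <- if (inherits(mask, "vol3d")) with_geometry(m, mask) else m
  out
}

# ---- SLA separation ------------------------------------------------------

#' Separate the Segmentable Lobule Area from the periphery
#'
#' Preliminary partition of the tissue into the core region in which
#' lobule-like subunits can be delineated (the Segmentable Lobule Area,
#' SLA) and the unstructured bright periphery. The heuristic: a per-voxel
#' local standard deviation over the `box_radius` neighbourhood is
#' thresholded (septa and their surroundings score high, homogeneous
#' periphery low), restricted to the eroded tissue foreground to suppress
#' the tissue/background boundary shell, and cleaned; the largest connected
#' component with its cavities filled is taken as the core, trimmed by the
#' outward reach of the SD estimator (one `box_radius` per axis), and the
#' optional exclusion mask (e.g. a manually delineated lymph node) is
#' subtracted. The periphery is the remaining tissue foreground.
#'
#' @param vol an [image_volume()].
#' @param params a [preprocess_params()].
#' @param exclusion optional logical mask of the same shape (e.g. lymph
#'   node) removed from both compartments.
#' @return list with disjoint logical masks `sla` and `periphery`.
#' @export
separate_sla <- function(vol, params = preprocess_params(), exclusion = NULL) {
  a <- as_array3d(vol)
  if (!is.null(exclusion)) {
    check_same_shape(a, exclusion, "volume and exclusion mask")
    exclusion <- as_mask(exclusion)
  }
  as_empty_sla <- function(expr) {
    tryCatch(expr, lobuseg_degenerate_histogram = function(e)
      lob_stop("no septum contrast found: SLA is empty", "lobuseg_empty_sla"))
  }
  fg <- as_empty_sla(as_mask(binarize(vol, params$binarize_threshold)))
  # solid tissue extent: the binarization may classify dark septa as
  # background, so cavities are filled before the boundary-shell erosion
  tissue <- fill_holes(fg)
  sdmap <- local_sd_map(vol, params$box_radius)
  thr <- if (identical(params$sla_contrast_threshold, "otsu"))
    as_empty_sla(otsu_threshold(sdmap)) else params$sla_contrast_threshold
  contrast <- as_mask(sdmap > thr)
  interior <- mask_erode(tissue, 1, scale = 1 / (params$box_radius + 1))
  m <- contrast & interior
  if (!any(m))
    lob_stop("no voxel passes the septum-contrast threshold: SLA is empty",
             "lobuseg_empty_sla")
  m <- cleanup(m, params$sla_closing_radius, params$sla_min_island)
  if (!any(m))
    lob_stop("contrast map vanished during cleanup: SLA is empty", "lobuseg_empty_sla")
  lab <- array(cpp_label_components(m, dim(m), 26L), dim(m))
  largest <- which.max(tabulate(lab))
  filled <- fill_holes(lab == largest)
  trimmed <- mask_erode(filled, 1, scale = 1 / params$box_radius)
  sla <- trimmed & tissue
  if (!is.null(exclusion)) sla <- sla & !exclusion
  if (!any(sla))
    lob_stop("SLA is empty after masking", "lobuseg_empty_sla")
  periphery <- fg & !sla
  if (!is.null(exclusion)) periphery <- periphery & !exclusion
  list(sla = with_geometry(sla, vol), periphery = with_geometry(periphery, vol))
}
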