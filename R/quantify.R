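#' Per-subunit morphometrics
#'
#' One record per distinct positive label: voxel count, physical volume
#' (voxel count times the voxel volume, reported in cubic millimetres) and
#' barycenter (unweighted mean of member-voxel physical centres, in
#' micrometres).
#'
#' @param labels integer `vol3d`.
#' @return `data.frame` with columns `label`, `voxel_count`, `volume_mm3`,
#'   `bx`, `by`, `bz`.
#' @export
subunit_volumes <- function(labels) {
  a <- as_array3d(labels)
  if (!any(a > 0))
    lob_stop("label volume contains no positive labels", "lobuseg_param_error")
  sp <- vol_spacing(labels)
  co <- axis_coords(labels)
  d <- dim(a)
  pos <- which(a > 0)
  lab <- a[pos]
  i <- ((pos - 1L) %% d[1]) + 1L
  j <- (((pos - 1L) %/% d[1]) %% d[2]) + 1L
  k <- ((pos - 1L) %/% (d[1] * d[2])) + 1L
  cnt <- rowsum(rep.int(1L, length(lab)), lab)
  sx <- rowsum(co$x[i], lab)
  sy <- rowsum(co$y[j], lab)
  sz <- rowsum(co$z[k], lab)
  out <- data.frame(label = as.integer(rownames(cnt)),
                    voxel_count = as.integer(cnt[, 1]),
                    volume_mm3 = cnt[, 1] * prod(sp) * 1e-9,
                    bx = sx[, 1] / cnt[, 1],
                    by = sy[, 1] / cnt[, 1],
                    bz = sz[, 1] / cnt[, 1])
  out[order(out$label), , drop = FALSE]
}

#' Contact surfaces between all label pairs
#'
#' Every unordered pair of distinct positive labels sharing at least one
#' 6-neighbour voxel face, with the face count, the physical interface
#' area (summing per-orientation face areas from the anisotropic spacing,
#' in square millimetres) and the normalized weight
#' `face_count / mean(total surface face counts of the two labels)` — the
#' edge weight of the subunit connectivity graph.
#'
#' @param labels integer `vol3d`.
#' @return `data.frame` with columns `label_i`, `label_j` (`label_i <
#'   label_j`), `face_count`, `area_mm2`, `weight`; zero rows if no two
#'   labels touch.
#' @export
contact_surfaces <- function(labels) {
  a <- as_array3d(labels)
  sp <- vol_spacing(labels)
  face_area <- prod(sp) / sp * 1e-6     # mm^2 of a face normal to each axis
  ft <- face_table(a)
  empty <- data.frame(label_i = integer(), label_j = integer(),
                      face_count = integer(), area_mm2 = numeric(),
                      weight = numeric())
  labs <- sort(unique(a[a > 0]))
  if (!nrow(ft) || !length(labs)) return(empty)
  sm <- surface_matrices(ft, labs)
  S <- rowSums(sm$M) + sm$B
  pos <- ft[ft$lo > 0, , drop = FALSE]
  if (!nrow(pos)) return(empty)
  key <- paste(pos$lo, pos$hi)
  cnt <- rowsum(pos$n, key)
  area <- rowsum(pos$n * face_area[pos$axis], key)
  pair <- do.call(rbind, strsplit(rownames(cnt), " "))
  li <- as.integer(pair[, 1]); lj <- as.integer(pair[, 2])
  ii <- match(li, labs); jj <- match(lj, labs)
  out <- data.frame(label_i = li, label_j = lj,
                    face_count = as.integer(cnt[, 1]),
                    area_mm2 = area[, 1],
                    weight = cnt[, 1] / ((S[ii] + S[jj]) / 2))
  out <- out[order(out$label_i, out$label_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SLA to fat-pad volume ratio
#'
#' Percentage of the whole fat-pad volume occupied by the Segmentable
#' Lobule Area: `100 * sla_volume / total_volume`.
#'
#' @param sla_volume SLA volume (mm^3).
#' @param total_volume whole fat-pad volume (mm^3), > 0.
#' @return percentage.
#' @export
sla_ratio <- function(sla_volume, total_volume) {
  if (total_volume <= 0)
    lob_stop("total_volume must be > 0", "lobuseg_param_error")
  if (sla_volume > total_volume)
    lob_stop("sla_volume exceeds total_volume", "lobuseg_consistency_error")
  100 * sla_volume / total_volume
}

#' Subunit volumes normalized to the fat-pad volume
#'
#' @param records `data.frame` from [subunit_volumes()].
#' @param fat_pad_volume whole fat-pad volume (mm^3), > 0.
#' @return numeric vector of dimensionless normalized volumes.
#' @export
normalized_volumes <- function(records, fat_pad_volume) {
  if (fat_pad_volume <= 0)
    lob_stop("fat_pad_volume must be > 0", "lobuseg_param_error")
  records$volume_mm3 / fat_pad_volume
}

#' Mean and standard error
#'
#' Summary in the conventional "mean ± SEM" form; the SEM uses the sample
#' (n - 1) standard deviation and is `NA` for a single value.
#'
#' @param values numeric vector, length >= 1.
#' @return `data.frame` with columns `n`, `mean`, `sem`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (!length(values))
    lob_stop("cannot summarize an empty vector", "lobuseg_param_error")
  n <- length(values)
  data.frame(n = n, mean = mean(values),
             sem = if (n >= 2) sd(values) / sqrt(n) else NA_real_)
}

#' Mean grayscale density over a region of interest
#'
#' Average intensity over the ROI voxels; with a vessel-label channel this
#' serves as a proxy for local vascular density.
#'
#' @param vol an [image_volume()].
#' @param roi logical mask of the same shape, non-empty.
#' @return mean intensity.
#' @export
density_proxy_mean <- function(vol, roi) {
  check_same_shape(vol, roi, "volume and ROI")
  roi <- as_mask(roi)
  if (!any(roi)) lob_stop("ROI is empty", "lobuseg_param_error")
  mean(as_array3d(vol)[roi])
}

#' Fraction of labelled voxels in a region of interest
#'
#' `(labelled AND roi) / roi`, in `[0, 1]`; used e.g. for the ratio of
#' antibody- or lectin-labelled pixels to the ROI size on binarized
#' images.
#'
#' @param binary logical mask of labelled voxels.
#' @param roi logical mask of the same shape, non-empty.
#' @return fraction in `[0, 1]`.
#' @export
labelled_fraction <- function(binary, roi) {
  check_same_shape(binary, roi, "binary mask and ROI")
  roi <- as_mask(roi)
  if (!any(roi)) lob_stop("ROI is empty", "lobuseg_param_error")
  sum(as_mask(binary) & roi) / sum(roi)
}

#' Axis-aligned box ROI in physical coordinates
#'
#' Convenience constructor for a box ROI given physical bounds in
#' micrometres (inclusive of voxel centres falling inside).
#'
#' @param vol template `vol3d` supplying shape and geometry.
#' @param xlim,ylim,zlim numeric length-2 physical bounds (µm).
#' @return logical `vol3d` mask.
#' @export
roi_box <- function(vol, xlim, ylim, zlim) {
  co <- axis_coords(vol)
  m <- outer(outer(co$x >= xlim[1] & co$x <= xlim[2],
                   co$y >= ylim[1] & co$y <= ylim[2], "&"),
             co$z >= zlim[1] & co$z <= zlim[2], "&")
  with_geometry(m, vol)
}

#' Segmentation robustness sweep
#'
#' Runs [segment_lobules()] once per grid row, reporting the subunit count,
#' the volume distribution, and the adjusted Rand index of each run's
#' labelling against the first run. Grid columns may override any
#' [segmentation_params()] field or the numeric [preprocess_params()]
#' fields by name.
#'
#' @param vol an [image_volume()].
#' @param grid `data.frame`; each row is one parameter combination.
#' @param pre,seg baseline parameter sets to override.
#' @param ... passed on to [segment_lobules()].
#' @return `data.frame` with one row per grid point: the grid columns plus
#'   `n_subunits`, `total_volume_mm3`, `mean_volume_mm3`, `min_volume_mm3`,
#'   `max_volume_mm3` and `ari_vs_first` (`NA` for the first row).
#' @export
parameter_sweep <- function(vol, grid, pre = preprocess_params(),
                            seg = segmentation_params(), ...) {
  if (!nrow(grid)) lob_stop("parameter grid is empty", "lobuseg_param_error")
  first_labels <- NULL
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    p <- pre
    s <- seg
    for (nm in names(grid)) {
      if (nm %in% names(s)) s[[nm]] <- grid[[nm]][r]
      else if (nm %in% names(p)) p[[nm]] <- grid[[nm]][r]
      else lob_stop(sprintf("unknown sweep parameter '%s'", nm), "lobuseg_param_error")
    }
    labs <- segment_lobules(vol, p, s, ...)
    rec <- subunit_volumes(labs)
    ari <- if (is.null(first_labels)) NA_real_ else
      mclust::adjustedRandIndex(as.vector(first_labels), as.vector(labs))
    if (is.null(first_labels)) first_labels <<- labs
    cbind(grid[r, , drop = FALSE],
          data.frame(n_subunits = nrow(rec),
                     total_volume_mm3 = sum(rec$volume_mm3),
                     mean_volume_mm3 = mean(rec$volume_mm3),
                     min_volume_mm3 = min(rec$volume_mm3),
                     max_volume_mm3 = max(rec$volume_mm3),
                     ari_vs_first = ari))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
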