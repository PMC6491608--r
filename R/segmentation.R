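#' Segmentation parameters
#'
#' @param distance_threshold seed threshold on the Euclidean distance map,
#'   in micrometres (physical units, so the value is robust to
#'   downscaling). Voxels deeper than this inside the binarized tissue
#'   become watershed seeds.
#' @param seed_connectivity connectivity for seed connected components:
#'   6, 18 or 26 (default 26).
#' @param merge_threshold contact-ratio threshold in (0, 1]: pre-segmented
#'   subunits whose shared interface, relative to their mean total surface,
#'   reaches this value are merged.
#' @param min_seed_voxels seed components smaller than this are discarded.
#' @return a named list of class `segmentation_params`.
#' @export
segmentation_params <- function(distance_threshold = 3.2,
                                seed_connectivity = 26,
                                merge_threshold = 0.1,
                                min_seed_voxels = 20) {
  if (!is.numeric(distance_threshold) || distance_threshold <= 0)
    lob_stop("distance_threshold must be > 0", "lobuseg_param_error")
  if (!seed_connectivity %in% c(6, 18, 26))
    lob_stop("seed_connectivity must be 6, 18 or 26", "lobuseg_param_error")
  if (merge_threshold <= 0 || merge_threshold > 1)
    lob_stop("merge_threshold must be in (0, 1]", "lobuseg_param_error")
  structure(list(distance_threshold = distance_threshold,
                 seed_connectivity = as.integer(seed_connectivity),
                 merge_threshold = merge_threshold,
                 min_seed_voxels = as.integer(min_seed_voxels)),
            class = "segmentation_params")
}

#' Euclidean distance map
#'
#' Per-voxel Euclidean distance (micrometres, using the anisotropic voxel
#' spacing) from each foreground voxel to the nearest background voxel
#' centre; background voxels map to 0. Computed exactly with a separable
#' lower-envelope transform. If the mask has no background at all,
#' foreground distances are `Inf`.
#'
#' @param mask logical `vol3d`.
#' @return numeric `vol3d` of distances.
#' @export
distance_map <- function(mask) {
  m <- as_mask(mask)
  sp <- vol_spacing(mask)
  d2 <- cpp_edt_sq(m, dim(m), sp)
  with_geometry(array(sqrt(d2), dim(m)), mask)
}

# 1D convolution along one axis with a 3-tap kernel, border replicated.
conv3_axis <- function(a, axis, w) {
  n <- dim(a)[axis]
  prev <- c(1L, seq_len(n - 1L))
  nxt <- c(seq_len(n - 1L) + 1L, n)
  slice <- function(idx) switch(axis,
                                a[idx, , , drop = FALSE],
                                a[, idx, , drop = FALSE],
                                a[, , idx, drop = FALSE])
  w[1] * slice(prev) + w[2] * a + w[3] * slice(nxt)
}

#' 3D Sobel gradient magnitude
#'
#' Euclidean norm of the three axis-wise 3D Sobel responses (derivative
#' kernel `(-1, 0, 1)` along the gradient axis, smoothing `(1, 2, 1)` along
#' the two others), with borders handled by edge replication.
#'
#' @param vol numeric `vol3d` (a binarized volume may be passed; it is
#'   coerced to numeric).
#' @return numeric `vol3d` of gradient magnitudes.
#' @export
gradient_magnitude <- function(vol) {
  a <- as_array3d(vol)
  if (any(dim(a) < 3))
    lob_stop("every dimension must be >= 3 for the Sobel gradient", "lobuseg_dim_error")
  storage.mode(a) <- "double"
  deriv <- c(-1, 0, 1)
  smooth <- c(1, 2, 1)
  g2 <- array(0, dim(a))
  for (ax in 1:3) {
    g <- a
    for (other in 1:3) {
      g <- conv3_axis(g, other, if (other == ax) deriv else smooth)
    }
    g2 <- g2 + g * g
  }
  with_geometry(sqrt(g2), vol)
}

#' Extract watershed seeds from a distance map
#'
#' Thresholds the distance map at `distance_threshold` (micrometres),
#' labels the connected components at `seed_connectivity`, discards
#' components smaller than `min_seed_voxels`, and numbers the survivors
#' 1..n in scan order of each component's first voxel.
#'
#' @param dist distance map from [distance_map()].
#' @param params a [segmentation_params()].
#' @return integer `vol3d` of seed labels.
#' @export
extract_seeds <- function(dist, params = segmentation_params()) {
  m <- as_mask(as_array3d(dist) > params$distance_threshold)
  if (!any(m))
    lob_stop("no voxel exceeds the distance threshold: no seeds", "lobuseg_no_seed")
  lab <- cpp_label_components(m, dim(m), params$seed_connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= params$min_seed_voxels)
  if (!length(keep))
    lob_stop("all seed components are below min_seed_voxels: no seeds",
             "lobuseg_no_seed")
  lut <- integer(length(sizes) + 1L)          # labels are in first-voxel scan
  lut[keep + 1L] <- seq_along(keep)           # order already; renumber 1..n
  with_geometry(array(lut[lab + 1L], dim(m)), dist)
}

#' Seeded priority-flood watershed
#'
#' Floods the relief restricted to `mask` from the given seeds: voxels are
#' assigned in ascending relief order (ties broken by ascending linear
#' voxel index, then by queue insertion order), each receiving the label of
#' the seed whose flood reaches it first. 6-connectivity. Masked voxels
#' unreachable from any seed keep label 0.
#'
#' @param relief numeric `vol3d` (typically a gradient magnitude).
#' @param seeds integer `vol3d` of seed labels; must lie inside `mask`.
#' @param mask logical `vol3d` flooding domain.
#' @return integer `vol3d` of watershed labels.
#' @export
watershed_flood <- function(relief, seeds, mask) {
  check_same_shape(relief, seeds, "relief and seeds")
  check_same_shape(relief, mask, "relief and mask")
  m <- as_mask(mask)
  s <- as_array3d(seeds)
  if (any(s > 0 & !m))
    lob_stop("seed voxels must lie inside the mask", "lobuseg_consistency_error")
  lab <- cpp_watershed(as.numeric(as_array3d(relief)), as.integer(s), m, dim(m))
  with_geometry(array(lab, dim(m)), relief)
}

#' Restrict labels to a foreground mask
#'
#' Pointwise product of a label volume with a binary foreground indicator:
#' labels survive where the foreground is true, all other voxels become 0.
#'
#' @param labels integer `vol3d`.
#' @param foreground logical `vol3d` of the same shape.
#' @return integer `vol3d`.
#' @export
apply_foreground <- function(labels, foreground) {
  check_same_shape(labels, foreground, "labels and foreground")
  out <- as_array3d(labels) * as.integer(as_mask(foreground))
  storage.mode(out) <- "integer"
  if (inherits(labels, "vol3d")) with_geometry(out, labels) else out
}

# ---- contact surfaces ----------------------------------------------------

# Enumerate all 6-neighbour voxel face pairs with differing labels.
# Returns a data.frame with columns lo, hi (lo < hi, 0 = background),
# axis (1..3) and n (face count). Faces on the volume border (voxel vs
# outside) are not counted.
face_table <- function(labels) {
  a <- as_array3d(labels)
  d <- dim(a)
  parts <- list()
  for (ax in 1:3) {
    if (d[ax] < 2) next
    n <- d[ax]
    u <- switch(ax, a[-n, , , drop = FALSE], a[, -n, , drop = FALSE], a[, , -n, drop = FALSE])
    v <- switch(ax, a[-1, , , drop = FALSE], a[, -1, , drop = FALSE], a[, , -1, drop = FALSE])
    sel <- u != v
    if (!any(sel)) next
    parts[[length(parts) + 1L]] <-
      data.frame(lo = pmin(u[sel], v[sel]), hi = pmax(u[sel], v[sel]), axis = ax)
  }
  if (!length(parts))
    return(data.frame(lo = integer(), hi = integer(), axis = integer(), n = integer()))
  ft <- do.call(rbind, parts)
  agg <- stats::aggregate(list(n = rep.int(1L, nrow(ft))),
                          by = ft[c("lo", "hi", "axis")], FUN = sum)
  agg[order(agg$lo, agg$hi, agg$axis), , drop = FALSE]
}

# Pairwise face-count matrix between positive labels plus each label's
# face count against background, from a face_table.
surface_matrices <- function(ft, labs) {
  L <- length(labs)
  idx <- integer(max(labs, 1L))
  idx[labs] <- seq_len(L)
  M <- matrix(0, L, L)
  B <- numeric(L)
  pos <- ft[ft$lo > 0, , drop = FALSE]
  if (nrow(pos)) {
    for (r in seq_len(nrow(pos))) {
      i <- idx[pos$lo[r]]; j <- idx[pos$hi[r]]
      M[i, j] <- M[i, j] + pos$n[r]
      M[j, i] <- M[i, j]
    }
  }
  bg <- ft[ft$lo == 0, , drop = FALSE]
  if (nrow(bg)) {
    for (r in seq_len(nrow(bg))) B[idx[bg$hi[r]]] <- B[idx[bg$hi[r]]] + bg$n[r]
  }
  list(M = M, B = B)
}

#' Contact ratio between two labels
#'
#' `S_ij / ((S_i + S_j) / 2)` where `S_ij` counts 6-neighbour voxel face
#' pairs with labels `{i, j}` and `S_k` counts all faces between label `k`
#' and any different label or background (the total surface of `k`).
#' Always in `[0, 1]`.
#'
#' @param labels integer `vol3d`.
#' @param i,j two distinct labels present in `labels`.
#' @return dimensionless contact ratio.
#' @export
contact_ratio <- function(labels, i, j) {
  if (i == j) lob_stop("labels i and j must differ", "lobuseg_param_error")
  a <- as_array3d(labels)
  present <- unique(a[a > 0])
  if (!(i %in% present) || !(j %in% present))
    lob_stop("label absent from the volume", "lobuseg_missing_label")
  ft <- face_table(a)
  sm <- surface_matrices(ft, sort(present))
  labs <- sort(present)
  ii <- match(i, labs); jj <- match(j, labs)
  S <- rowSums(sm$M) + sm$B
  if (S[ii] + S[jj] == 0) return(0)
  sm$M[ii, jj] / ((S[ii] + S[jj]) / 2)
}

#' Merge pre-segmented subunits by contact ratio
#'
#' Greedy region-adjacency-graph merging correcting over-segmentation from
#' holes in the gradient borders: while any pair of labels has a contact
#' ratio at or above `merge_threshold`, the pair with the highest ratio is
#' merged (ties resolved towards the lexicographically smallest label
#' pair), the higher label being relabelled into the lower, and the
#' affected ratios are updated. Voxel membership in the foreground is
#' unchanged; labels need not be consecutive afterwards.
#'
#' @param labels integer `vol3d`.
#' @param merge_threshold dimensionless threshold in (0, 1].
#' @return merged integer `vol3d`.
#' @export
merge_subunits <- function(labels, merge_threshold = 0.05) {
  if (merge_threshold <= 0 || merge_threshold > 1)
    lob_stop("merge_threshold must be in (0, 1]", "lobuseg_param_error")
  a <- as_array3d(labels)
  labs <- sort(unique(a[a > 0]))
  if (length(labs) < 2) return(labels)
  sm <- surface_matrices(face_table(a), labs)
  M <- sm$M
  B <- sm$B
  parent <- seq_len(max(labs))            # final relabelling map
  alive <- labs
  repeat {
    if (length(alive) < 2 || !any(M > 0)) break
    S <- rowSums(M) + B
    R <- 2 * M / outer(S, S, "+")
    R[M == 0] <- 0
    diag(R) <- 0
    best <- max(R)
    if (best < merge_threshold) break
    cand <- which(R == best, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(alive[cand[, 1]], alive[cand[, 2]]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    parent[alive[j]] <- alive[i]
    M[i, ] <- M[i, ] + M[j, ]
    M[, i] <- M[, i] + M[j, ]
    M[i, i] <- 0
    B[i] <- B[i] + B[j]
    M <- M[-j, -j, drop = FALSE]
    B <- B[-j]
    alive <- alive[-j]
  }
  # resolve chains a -> b -> c
  for (l in seq_along(parent)) {
    p <- parent[l]
    while (parent[p] != p) p <- parent[p]
    parent[l] <- p
  }
  lut <- c(0L, as.integer(parent))
  out <- array(lut[a + 1L], dim(a))
  storage.mode(out) <- "integer"
  if (inherits(labels, "vol3d")) with_geometry(out, labels) else out
}

#' Full lobule segmentation pipeline
#'
#' Composition of the whole workflow: optional preliminary SLA separation,
#' Kuwahara-ratio filtering, binarization of the filtered volume plus
#' morphological cleanup (the segmentation support), Euclidean distance
#' map, seed extraction, Sobel gradient of the binarized support as the
#' watershed relief, priority-flood watershed, pointwise masking with the
#' *unfiltered* binarized volume, and contact-ratio graph merging.
#' Deterministic for fixed input and parameters.
#'
#' @param vol an [image_volume()].
#' @param pre a [preprocess_params()].
#' @param seg a [segmentation_params()].
#' @param sla optional precomputed SLA mask; if `NULL` and
#'   `restrict_sla = TRUE` it is computed with [separate_sla()].
#' @param exclusion optional exclusion mask (e.g. lymph node).
#' @param restrict_sla if `TRUE` (default) processing is confined to the
#'   Segmentable Lobule Area.
#' @param relief_source source of the watershed relief: `"support"`
#'   (default; Sobel gradient of the cleaned binarized support, whose
#'   ridges straddle the septum walls), `"binarized"` (gradient of the
#'   unfiltered binarized volume) or `"filtered"` (gradient of the
#'   Kuwahara-filtered volume itself).
#' @param flood_domain domain flooded by the watershed: `"support"`
#'   (default; the cleaned filtered support) or `"sla"` (the whole
#'   Segmentable Lobule Area, so that dark septum voxels are also
#'   attributed to a subunit before the foreground masking trims them).
#' @param debug_dir optional directory into which every intermediate stage
#'   is written as NIfTI.
#' @return integer `vol3d` of merged subunit labels.
#' @export
segment_lobules <- function(vol, pre = preprocess_params(),
                            seg = segmentation_params(),
                            sla = NULL, exclusion = NULL, restrict_sla = TRUE,
                            relief_source = c("support", "binarized", "filtered"),
                            flood_domain = c("support", "sla"),
                            debug_dir = NULL) {
  relief_source <- match.arg(relief_source)
  flood_domain <- match.arg(flood_domain)
  if (!is.null(exclusion)) check_same_shape(vol, exclusion, "volume and exclusion")
  if (restrict_sla && is.null(sla))
    sla <- separate_sla(vol, pre, exclusion)$sla
  if (!is.null(sla)) check_same_shape(vol, sla, "volume and SLA mask")

  filt <- kuwahara_ratio_filter(vol, pre)
  # when processing is confined to the SLA, automatic thresholds are
  # computed from the SLA histogram (lobule vs septum), not from the whole
  # volume whose histogram is dominated by periphery and background
  b2_thr <- pre$binarize_threshold
  sup_thr <- pre$filtered_threshold
  if (!is.null(sla)) {
    slam <- as_mask(sla)
    if (!is.null(exclusion)) slam <- slam & !as_mask(exclusion)
    if (identical(b2_thr, "otsu")) b2_thr <- otsu_threshold(as_array3d(vol)[slam])
    if (identical(sup_thr, "otsu")) sup_thr <- otsu_threshold(as_array3d(filt)[slam])
  }
  b2 <- as_mask(binarize(vol, b2_thr))
  support <- as_mask(binarize(filt, sup_thr))
  if (!is.null(sla)) {
    b2 <- b2 & as_mask(sla)
    support <- support & as_mask(sla)
  }
  if (!is.null(exclusion)) {
    b2 <- b2 & !as_mask(exclusion)
    support <- support & !as_mask(exclusion)
  }
  support <- cleanup(support, pre$closing_radius, pre$min_island_voxels)
  if (!is.null(sla)) support <- support & as_mask(sla)   # closing must not escape the SLA
  if (!is.null(exclusion)) support <- support & !as_mask(exclusion)
  support <- with_geometry(support, vol)

  dist <- distance_map(support)
  seeds <- extract_seeds(dist, seg)
  relief <- switch(relief_source,
    binarized = gradient_magnitude(with_geometry(array(as.double(b2), dim(b2)), vol)),
    support = gradient_magnitude(with_geometry(array(as.double(support), dim(support)), vol)),
    filtered = gradient_magnitude(filt))
  domain <- if (flood_domain == "sla" && !is.null(sla)) {
    dm <- as_mask(sla)
    if (!is.null(exclusion)) dm <- dm & !as_mask(exclusion)
    dm
  } else {
    as_mask(support)
  }
  ws <- watershed_flood(relief, seeds, with_geometry(domain, vol))
  pre_seg <- apply_foreground(ws, with_geometry(b2, vol))
  out <- merge_subunits(pre_seg, seg$merge_threshold)

  if (!is.null(debug_dir)) {
    dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
    dump <- function(x, name) write_volume(with_geometry(
      array(as.numeric(x), dim(x)), vol), file.path(debug_dir, paste0(name, ".nii")))
    dump(filt, "b1_filtered")
    dump(b2, "b2_binarized")
    dump(support, "c_support")
    dump(dist, "d1_distance")
    dump(relief, "d2_gradient")
    dump(seeds, "f_seeds")
    dump(ws, "g_watershed")
    dump(pre_seg, "h_preseg")
    dump(out, "i_merged")
  }
  out
}
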