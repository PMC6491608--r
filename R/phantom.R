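#' Synthetic cleared-fat-pad phantom specification
#'
#' Parameterization of the forward model used to benchmark the whole
#' workflow: a box-shaped fat pad containing an interior core of
#' inter-digitated poly-lobular subunits (bright interiors separated by
#' darker mesenchymal septa, enclosed by a thin mesenchymal capsule), an
#' unstructured bright periphery, an optional ovoid occluder (lymph node)
#' at the core's edge, and additive Gaussian noise.
#'
#' Subunits are generated as 1..k overlapping random ellipsoids elongated
#' preferentially in the x-y plane; each core voxel covered by at least one
#' ellipsoid belongs to the subunit whose nearest lobe (in normalized
#' ellipsoidal distance) covers it, which produces inter-digitated
#' poly-lobular shapes. Septa are realized by eroding every subunit by half
#' the septum width (anisotropic Euclidean distance); per adjacent pair a
#' small "window" may re-open the septum so that subunits share true
#' contact surfaces, as real mesenchymal septa are incomplete.
#'
#' @param shape volume dimensions in voxels, default `c(128, 128, 32)`.
#' @param spacing voxel size in micrometres, default `c(1, 1, 2)` (coarser
#'   z, as in confocal stacks).
#' @param n_subunits number of subunits, default 18 (mid-range of the
#'   15-21 observed per fat pad).
#' @param lobes_per_subunit integer range `c(min, max)` of ellipsoidal
#'   lobes per subunit.
#' @param ellipsoid_radii list with per-axis micrometre ranges `x`, `y`,
#'   `z`; defaults elongate lobes 1.5-3x in-plane relative to z.
#' @param septum_width full septum thickness in micrometres.
#' @param core_fraction fraction of the x extent spanned by the core slab,
#'   default 0.2 (the core then occupies 15-25 percent of the tissue
#'   volume, matching the observed SLA/fat-pad ratio of about 20 percent).
#' @param intensities named vector with `lobule`, `septum`, `periphery`,
#'   `background` and `node` means; must satisfy
#'   `lobule > septum >= background`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param include_node_occluder place the ovoid lymph-node occluder at the
#'   core's edge.
#' @param node_radii occluder semi-axes in micrometres.
#' @param window_prob probability that an adjacent subunit pair keeps an
#'   open septum window (a true contact surface).
#' @param window_radius radius (µm) of each septum window.
#' @param min_center_sep minimum 3D separation (µm) between subunit
#'   centres during placement.
#' @param rng_seed integer seed; generation is fully deterministic given
#'   the spec.
#' @return a named list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 32),
                         spacing = c(1, 1, 2),
                         n_subunits = 18,
                         lobes_per_subunit = c(1, 3),
                         ellipsoid_radii = list(x = c(18, 42), y = c(18, 42), z = c(10, 16)),
                         septum_width = 4,
                         core_fraction = 0.2,
                         intensities = c(lobule = 200, septum = 60,
                                         periphery = 180, background = 10,
                                         node = 120),
                         noise_sd = 10,
                         include_node_occluder = TRUE,
                         node_radii = c(8, 12, 7),
                         window_prob = 0.7,
                         window_radius = 3,
                         min_center_sep = 9,
                         rng_seed = 42) {
  if (n_subunits < 1) lob_stop("n_subunits must be >= 1", "lobuseg_param_error")
  if (noise_sd < 0) lob_stop("noise_sd must be >= 0", "lobuseg_param_error")
  need <- c("lobule", "septum", "periphery", "background", "node")
  if (!all(need %in% names(intensities)))
    lob_stop("intensities must name lobule, septum, periphery, background, node",
             "lobuseg_param_error")
  if (!(intensities["lobule"] > intensities["septum"] &&
        intensities["septum"] >= intensities["background"]))
    lob_stop("intensities must satisfy lobule > septum >= background",
             "lobuseg_param_error")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_subunits = as.integer(n_subunits),
                 lobes_per_subunit = as.integer(lobes_per_subunit),
                 ellipsoid_radii = ellipsoid_radii,
                 septum_width = septum_width,
                 core_fraction = core_fraction,
                 intensities = intensities,
                 noise_sd = noise_sd,
                 include_node_occluder = include_node_occluder,
                 node_radii = node_radii,
                 window_prob = window_prob,
                 window_radius = window_radius,
                 min_center_sep = min_center_sep,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Geometry of the phantom compartments, in 1-based voxel index ranges.
phantom_geometry <- function(spec) {
  d <- spec$shape
  m <- c(4L, 4L, 1L)                   # background margin around the tissue
  if (any(d <= 2L * m + 4L))
    lob_stop("phantom shape too small for the tissue margins", "lobuseg_dim_error")
  tissue <- list(x = c(m[1] + 1L, d[1] - m[1]),
                 y = c(m[2] + 1L, d[2] - m[2]),
                 z = c(m[3] + 1L, d[3] - m[3]))
  cw <- max(4L, round(spec$core_fraction * d[1]))
  cx0 <- floor(0.15 * d[1]) + 1L
  core <- list(x = c(cx0, min(cx0 + cw - 1L, tissue$x[2] - 4L)),
               y = c(tissue$y[1] + 4L, tissue$y[2] - 4L),
               z = c(tissue$z[1] + 3L, tissue$z[2] - 3L))
  if (core$x[1] <= tissue$x[1] || core$y[2] <= core$y[1] || core$z[2] <= core$z[1])
    lob_stop("phantom shape too small to host a core region", "lobuseg_dim_error")
  list(tissue = tissue, core = core)
}

range_mask <- function(d, r) {
  m <- array(FALSE, d)
  m[r$x[1]:r$x[2], r$y[1]:r$y[2], r$z[1]:r$z[2]] <- TRUE
  m
}

#' Generate a synthetic fat-pad phantom with ground truth
#'
#' Deterministic forward model given the spec (see [phantom_spec()]).
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an [image_volume()]) and `truth`, itself a
#'   list: `labels` (ground-truth subunit labels, 0 on septa), `core_mask`
#'   (the SLA-like core, occluder excluded), `node_mask`, `tissue_mask`,
#'   `records` ([subunit_volumes()] of the truth) and `edges`
#'   ([contact_surfaces()] of the truth).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$rng_seed)
  d <- spec$shape
  sp <- spec$spacing
  geo <- phantom_geometry(spec)
  tissue <- range_mask(d, geo$tissue)
  core_box <- range_mask(d, geo$core)
  n <- prod(d)

  # physical voxel-centre coordinates
  cx <- (seq_len(d[1]) - 1) * sp[1]
  cy <- (seq_len(d[2]) - 1) * sp[2]
  cz <- (seq_len(d[3]) - 1) * sp[3]
  core_idx <- which(core_box)
  i <- ((core_idx - 1L) %% d[1]) + 1L
  j <- (((core_idx - 1L) %/% d[1]) %% d[2]) + 1L
  k <- ((core_idx - 1L) %/% (d[1] * d[2])) + 1L
  X <- cx[i]; Y <- cy[j]; Z <- cz[k]

  core_lo <- c(cx[geo$core$x[1]], cy[geo$core$y[1]], cz[geo$core$z[1]])
  core_hi <- c(cx[geo$core$x[2]], cy[geo$core$y[2]], cz[geo$core$z[2]])

  # --- subunit centres with minimum separation --------------------------
  centers <- matrix(NA_real_, spec$n_subunits, 3)
  attempts <- 0L
  for (s in seq_len(spec$n_subunits)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 1000L * spec$n_subunits)
        lob_stop("could not place all subunits with the requested separation",
                 "lobuseg_placement_error")
      p <- c(runif(1, core_lo[1], core_hi[1]),
             runif(1, core_lo[2], core_hi[2]),
             runif(1, core_lo[3], core_hi[3]))
      if (s == 1 || all(sqrt(colSums((t(centers[seq_len(s - 1), , drop = FALSE]) - p)^2)) >=
                        spec$min_center_sep)) {
        centers[s, ] <- p
        break
      }
    }
  }

  # --- lobes and ownership ----------------------------------------------
  rr <- spec$ellipsoid_radii
  best_d <- rep(Inf, length(core_idx))
  best_s <- integer(length(core_idx))
  for (s in seq_len(spec$n_subunits)) {
    k_lobes <- if (spec$lobes_per_subunit[1] == spec$lobes_per_subunit[2])
      spec$lobes_per_subunit[1] else
        sample(spec$lobes_per_subunit[1]:spec$lobes_per_subunit[2], 1)
    for (l in seq_len(k_lobes)) {
      ctr <- if (l == 1) centers[s, ] else
        centers[s, ] + c(rnorm(2, 0, 6), rnorm(1, 0, 3))
      rad <- c(runif(1, rr$x[1], rr$x[2]),
               runif(1, rr$y[1], rr$y[2]),
               runif(1, rr$z[1], rr$z[2]))
      nd <- sqrt(((X - ctr[1]) / rad[1])^2 + ((Y - ctr[2]) / rad[2])^2 +
                   ((Z - ctr[3]) / rad[3])^2)
      take <- nd < best_d & nd <= 1
      best_d[take] <- nd[take]
      best_s[take] <- s
    }
  }
  owner <- array(0L, d)
  owner[core_idx] <- best_s

  # --- ovoid occluder at the core's edge --------------------------------
  node <- array(FALSE, d)
  if (spec$include_node_occluder) {
    nctr <- c(core_hi[1], (core_lo[2] + core_hi[2]) / 2, (core_lo[3] + core_hi[3]) / 2)
    nr <- spec$node_radii
    ex <- outer(outer(((cx - nctr[1]) / nr[1])^2, ((cy - nctr[2]) / nr[2])^2, "+"),
                ((cz - nctr[3]) / nr[3])^2, "+")
    node <- ex <= 1 & tissue
    owner[node] <- 0L
  }

  # --- septa: erode each subunit by half the septum width ---------------
  labels <- owner
  half_w <- spec$septum_width / 2
  for (s in seq_len(spec$n_subunits)) {
    ms <- owner == s
    if (!any(ms)) next
    d2 <- cpp_edt_sq(as.vector(ms), d, sp)
    band <- ms & array(d2 <= half_w^2 + 1e-9, d)
    labels[band] <- 0L
  }

  # --- re-open septum windows so adjacent subunits keep true contacts ---
  bf <- boundary_faces(owner)
  bf <- bf[bf$lo > 0, , drop = FALSE]
  if (nrow(bf)) {
    pair_key <- paste(bf$lo, bf$hi)
    lab_phys <- function(idx) {
      ii <- ((idx - 1L) %% d[1]) + 1L
      jj <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
      kk <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
      cbind(cx[ii], cy[jj], cz[kk])
    }
    for (key in unique(pair_key)) {
      if (runif(1) >= spec$window_prob) next
      rows <- which(pair_key == key)
      pick <- rows[sample.int(length(rows), 1)]
      st <- c(bf$lo[pick], bf$hi[pick])
      ctr <- colMeans(lab_phys(c(bf$idx_a[pick], bf$idx_b[pick])))
      cand <- core_idx[owner[core_idx] %in% st & labels[core_idx] == 0L]
      if (!length(cand)) next
      pc <- lab_phys(cand)
      near <- sqrt((pc[, 1] - ctr[1])^2 + (pc[, 2] - ctr[2])^2 +
                     (pc[, 3] - ctr[3])^2) <= spec$window_radius
      labels[cand[near]] <- owner[cand[near]]
    }
  }

  placed <- sort(unique(labels[labels > 0L]))
  if (length(placed) != spec$n_subunits)
    lob_stop("some subunits vanished during septum carving; enlarge radii or shrink septa",
             "lobuseg_placement_error")

  # --- intensities -------------------------------------------------------
  ints <- spec$intensities
  img <- array(ints[["background"]], d)
  img[tissue] <- ints[["periphery"]]
  img[core_box] <- ints[["septum"]]
  img[labels > 0L] <- ints[["lobule"]]
  img[node] <- ints[["node"]]
  if (spec$noise_sd > 0) img <- img + array(rnorm(n, 0, spec$noise_sd), d)

  labels_vol <- label_volume(labels, spacing = sp)
  core_mask <- core_box & !node
  truth <- list(labels = labels_vol,
                core_mask = with_geometry(core_mask, labels_vol),
                node_mask = with_geometry(node, labels_vol),
                tissue_mask = with_geometry(tissue, labels_vol),
                records = subunit_volumes(labels_vol),
                edges = contact_surfaces(labels_vol))
  list(volume = image_volume(img, spacing = sp), truth = truth)
}

# All 6-neighbour face pairs with differing values: linear indices of the
# two voxels and the (lo, hi) value pair.
boundary_faces <- function(a) {
  d <- dim(a)
  L <- array(seq_along(a), d)
  parts <- list()
  for (ax in 1:3) {
    if (d[ax] < 2) next
    n <- d[ax]
    u <- switch(ax, a[-n, , , drop = FALSE], a[, -n, , drop = FALSE], a[, , -n, drop = FALSE])
    v <- switch(ax, a[-1, , , drop = FALSE], a[, -1, , drop = FALSE], a[, , -1, drop = FALSE])
    Lu <- switch(ax, L[-n, , , drop = FALSE], L[, -n, , drop = FALSE], L[, , -n, drop = FALSE])
    Lv <- switch(ax, L[-1, , , drop = FALSE], L[, -1, , drop = FALSE], L[, , -1, drop = FALSE])
    sel <- u != v
    if (!any(sel)) next
    parts[[length(parts) + 1L]] <-
      data.frame(idx_a = Lu[sel], idx_b = Lv[sel],
                 lo = pmin(u[sel], v[sel]), hi = pmax(u[sel], v[sel]))
  }
  if (!length(parts))
    return(data.frame(idx_a = integer(), idx_b = integer(),
                      lo = integer(), hi = integer()))
  do.call(rbind, parts)
}
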