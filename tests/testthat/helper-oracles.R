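# Strip a vol3d down to a plain array (dim attribute only).
bare <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# Independent brute-force oracles. Deliberately naive (exhaustive search,
# explicit loops) so that they share no code path with the implementation.

# nearest-background Euclidean distance by exhaustive search
o_distance_map <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  out <- array(0, d)
  bg <- which(!mask, arr.ind = TRUE)
  for (v in which(mask)) {
    idx <- arrayInd(v, d)
    if (nrow(bg) == 0) { out[v] <- Inf; next }
    dx <- (bg[, 1] - idx[1]) * spacing[1]
    dy <- (bg[, 2] - idx[2]) * spacing[2]
    dz <- (bg[, 3] - idx[3]) * spacing[3]
    out[v] <- sqrt(min(dx^2 + dy^2 + dz^2))
  }
  out
}

# 6-neighbour linear indices, in the fixed order x-1, x+1, y-1, y+1, z-1, z+1
o_neighbours <- function(v, d) {
  i <- (v - 1) %% d[1] + 1
  j <- ((v - 1) %/% d[1]) %% d[2] + 1
  k <- (v - 1) %/% (d[1] * d[2]) + 1
  res <- integer(0)
  if (i > 1) res <- c(res, v - 1)
  if (i < d[1]) res <- c(res, v + 1)
  if (j > 1) res <- c(res, v - d[1])
  if (j < d[2]) res <- c(res, v + d[1])
  if (k > 1) res <- c(res, v - d[1] * d[2])
  if (k < d[3]) res <- c(res, v + d[1] * d[2])
  res
}

# exhaustive priority flood: ascending (relief, linear index, insertion order)
o_priority_flood <- function(relief, seeds, mask) {
  d <- dim(relief)
  lab <- array(0L, d)
  lab[seeds > 0] <- seeds[seeds > 0]
  qr <- numeric(0); qi <- integer(0); qc <- integer(0); ql <- integer(0)
  cnt <- 0L
  push <- function(v, l) {
    cnt <<- cnt + 1L
    qr <<- c(qr, relief[v]); qi <<- c(qi, v); qc <<- c(qc, cnt); ql <<- c(ql, l)
  }
  for (v in which(lab > 0)) {
    for (w in o_neighbours(v, d)) if (mask[w] && lab[w] == 0L) push(w, lab[v])
  }
  while (length(qi)) {
    o <- order(qr, qi, qc)[1]
    v <- qi[o]; l <- ql[o]
    qr <- qr[-o]; qi <- qi[-o]; qc <- qc[-o]; ql <- ql[-o]
    if (lab[v] != 0L) next
    lab[v] <- l
    for (w in o_neighbours(v, d)) if (mask[w] && lab[w] == 0L) push(w, l)
  }
  lab
}

# exhaustive face scan over all 6-neighbour pairs: per-pair face counts
# (including background pairs, lo < hi)
o_face_scan <- function(a) {
  d <- dim(a)
  res <- list()
  add <- function(p, q) {
    key <- paste(min(p, q), max(p, q))
    res[[key]] <<- (if (is.null(res[[key]])) 0L else res[[key]]) + 1L
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (i < d[1] && a[i, j, k] != a[i + 1, j, k]) add(a[i, j, k], a[i + 1, j, k])
    if (j < d[2] && a[i, j, k] != a[i, j + 1, k]) add(a[i, j, k], a[i, j + 1, k])
    if (k < d[3] && a[i, j, k] != a[i, j, k + 1]) add(a[i, j, k], a[i, j, k + 1])
  }
  res
}

# total surface (faces against anything different) of one label
o_surface <- function(faces, lab) {
  s <- 0L
  for (key in names(faces)) {
    pq <- as.integer(strsplit(key, " ")[[1]])
    if (lab %in% pq) s <- s + faces[[key]]
  }
  s
}

o_contact_ratio <- function(a, i, j) {
  faces <- o_face_scan(a)
  key <- paste(min(i, j), max(i, j))
  sij <- if (is.null(faces[[key]])) 0L else faces[[key]]
  si <- o_surface(faces, i)
  sj <- o_surface(faces, j)
  if (si + sj == 0) return(0)
  sij / ((si + sj) / 2)
}

# recompute-everything greedy merging oracle
o_merge <- function(a, thr) {
  repeat {
    labs <- sort(unique(a[a > 0]))
    if (length(labs) < 2) break
    best <- NULL; bestr <- -1
    for (ii in seq_along(labs)) for (jj in seq_along(labs)) {
      if (jj <= ii) next
      r <- o_contact_ratio(a, labs[ii], labs[jj])
      if (r > bestr) { bestr <- r; best <- c(labs[ii], labs[jj]) }
    }
    if (bestr < thr) break
    a[a == best[2]] <- best[1]
  }
  a
}

# per-voxel Kuwahara-ratio value by direct octant enumeration
o_kuwahara_ratio <- function(a, r, eps) {
  d <- dim(a)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
      xs <- max(1, i + min(sx * r[1], 0)):min(d[1], i + max(sx * r[1], 0))
      ys <- max(1, j + min(sy * r[2], 0)):min(d[2], j + max(sy * r[2], 0))
      zs <- max(1, k + min(sz * r[3], 0)):min(d[3], k + max(sz * r[3], 0))
      vals <- as.vector(a[xs, ys, zs])
      m <- mean(vals)
      v <- mean((vals - m)^2)         # population variance
      acc <- acc + m / (v + eps)
    }
    out[i, j, k] <- acc / 8
  }
  out
}

# direct 3x3x3 Sobel response at one voxel, border replicated
o_sobel_at <- function(a, i, j, k) {
  d <- dim(a)
  cl <- function(x, n) min(max(x, 1), n)
  deriv <- c(-1, 0, 1); smooth <- c(1, 2, 1)
  g <- c(0, 0, 0)
  for (ax in 1:3) for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    w <- switch(ax,
                deriv[di + 2] * smooth[dj + 2] * smooth[dk + 2],
                smooth[di + 2] * deriv[dj + 2] * smooth[dk + 2],
                smooth[di + 2] * smooth[dj + 2] * deriv[dk + 2])
    g[ax] <- g[ax] + w * a[cl(i + di, d[1]), cl(j + dj, d[2]), cl(k + dk, d[3])]
  }
  sqrt(sum(g^2))
}

# random label field with n_labs compact-ish blobs for merge/face tests
o_random_labels <- function(d, n_labs) {
  a <- array(0L, d)
  ctr <- cbind(runif(n_labs, 1, d[1]), runif(n_labs, 1, d[2]), runif(n_labs, 1, d[3]))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dist2 <- (ctr[, 1] - i)^2 + (ctr[, 2] - j)^2 + (ctr[, 3] - k)^2
    if (min(dist2) < (max(d) / 1.6)^2) a[i, j, k] <- which.min(dist2)
  }
  a
}

# small, quick phantom used throughout the unit tests
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(phantom_spec(
        shape = c(64, 64, 24), n_subunits = 6, rng_seed = 7,
        node_radii = c(5, 8, 5), min_center_sep = 8))
    }
    cache
  }
})

small_pre <- function(...) preprocess_params(sla_min_island = 200, ...)
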