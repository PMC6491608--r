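test_that("subunit volumes and barycenters follow the voxel geometry", {
  a <- array(0L, c(10, 10, 10)); a[1:10, 1:10, 1:10] <- 1L
  rec <- subunit_volumes(label_volume(a, spacing = c(10, 10, 10)))
  expect_equal(rec$voxel_count, 1000L)
  expect_equal(rec$volume_mm3, 1e-3)   # 1000 voxels x 1000 µm³

  b <- array(0L, c(6, 6, 6)); b[3, 4, 5] <- 1L
  r1 <- subunit_volumes(label_volume(b))
  expect_equal(c(r1$bx, r1$by, r1$bz), c(2, 3, 4))  # 0-based centre, origin 0

  cc <- array(0L, c(5, 5, 5)); cc[1:3, 1:3, 1:3] <- 2L
  r2 <- subunit_volumes(label_volume(cc))
  expect_equal(c(r2$bx, r2$by, r2$bz), c(1, 1, 1))
  expect_equal(r2$label, 2L)

  expect_error(subunit_volumes(label_volume(array(0L, c(3, 3, 3)))),
               class = "lobuseg_param_error")
})

test_that("contact surfaces match the exhaustive face scan", {
  a <- array(0L, c(4, 3, 3)); a[2, 2, 2] <- 1L; a[3, 2, 2] <- 2L
  ed <- contact_surfaces(label_volume(a, spacing = c(1, 2, 3)))
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$face_count, 1L)
  expect_equal(ed$area_mm2, 2 * 3 * 1e-6)  # face normal to x: dy*dz
  expect_equal(ed$weight, 1 / 6)

  b <- array(0L, c(6, 3, 3)); b[2, 2, 2] <- 1L; b[5, 2, 2] <- 2L
  expect_equal(nrow(contact_surfaces(label_volume(b))), 0L)

  set.seed(81)
  for (t in 1:12) {
    r <- o_random_labels(c(5, 5, 5), 3)
    ed <- contact_surfaces(label_volume(r))
    faces <- o_face_scan(r)
    pos_keys <- Filter(function(k) {
      pq <- as.integer(strsplit(k, " ")[[1]]); all(pq > 0)
    }, names(faces))
    expect_equal(nrow(ed), length(pos_keys))
    for (k in pos_keys) {
      pq <- as.integer(strsplit(k, " ")[[1]])
      row <- ed[ed$label_i == pq[1] & ed$label_j == pq[2], ]
      expect_equal(row$face_count, faces[[k]])
      expect_equal(row$weight, o_contact_ratio(r, pq[1], pq[2]))
    }
  }
})

test_that("SLA ratio reproduces the published per-pad percentages", {
  expect_equal(round(sla_ratio(7.58, 38.58), 1), 19.6)
  expect_equal(round(sla_ratio(34.57, 145.54), 1), 23.8)
  expect_equal(round(sla_ratio(16.34, 95.89), 1), 17.0)
  expect_equal(sla_ratio(5, 5), 100)
  expect_error(sla_ratio(1, 0), class = "lobuseg_param_error")
  expect_error(sla_ratio(2, 1), class = "lobuseg_consistency_error")
})

test_that("normalized volumes are a simple rescaling", {
  rec <- data.frame(label = 1:3, volume_mm3 = c(1, 2, 3))
  expect_equal(normalized_volumes(rec, 6), c(1, 2, 3) / 6)
  expect_equal(normalized_volumes(data.frame(volume_mm3 = 4), 4), 1)
  expect_length(normalized_volumes(data.frame(volume_mm3 = numeric()), 4), 0)
  expect_error(normalized_volumes(rec, 0), class = "lobuseg_param_error")
})

test_that("summaries reproduce the published means and SEM conventions", {
  s1 <- summarize_values(c(38.58, 95.89, 145.54))
  expect_equal(round(s1$mean, 1), 93.3)
  s2 <- summarize_values(c(7.58, 16.34, 34.57))
  expect_equal(round(s2$mean, 1), 19.5)
  s3 <- summarize_values(c(19.6, 17, 23.8))
  expect_equal(round(s3$mean, 1), 20.1)
  expect_equal(round(s3$sem, 1), 2.0)

  expect_equal(summarize_values(c(5, 5, 5))$sem, 0)
  expect_true(is.na(summarize_values(42)$sem))
  # permutation invariance
  set.seed(91); x <- rnorm(9)
  expect_equal(summarize_values(x), summarize_values(rev(x)))
  expect_error(summarize_values(numeric()), class = "lobuseg_param_error")
})

test_that("density proxy and labelled fraction aggregate over the ROI", {
  vol <- image_volume(array(40, c(4, 4, 4)))
  roi <- vol > 0
  expect_equal(density_proxy_mean(vol, roi), 40)

  v2 <- image_volume(array(0, c(4, 4, 4)))
  v2[1, 1, 1] <- 10; v2[2, 1, 1] <- 30
  roi2 <- array(FALSE, c(4, 4, 4)); roi2[1:2, 1, 1] <- TRUE
  expect_equal(density_proxy_mean(v2, roi2), 20)
  set.seed(14)
  v3 <- image_volume(array(rnorm(64), c(4, 4, 4)))
  expect_equal(density_proxy_mean(v3, v3 > -Inf), mean(bare(v3)))
  expect_error(density_proxy_mean(vol, vol > 99), class = "lobuseg_param_error")

  half <- array(FALSE, c(4, 4, 4)); half[1:2, , ] <- TRUE
  full <- array(TRUE, c(4, 4, 4))
  expect_equal(labelled_fraction(half, full), 0.5)
  expect_equal(labelled_fraction(array(FALSE, c(4, 4, 4)), full), 0)
  expect_equal(labelled_fraction(half, half), 1)

  rb <- roi_box(image_volume(array(0, c(10, 10, 10)), spacing = c(2, 2, 2)),
                c(0, 4), c(0, 4), c(0, 4))
  expect_equal(sum(rb), 27)  # voxel centres at 0,2,4 per axis
})

test_that("parameter sweep reports counts, volumes and reproducibility", {
  ph <- small_phantom()
  tr <- ph$truth
  sla <- separate_sla(ph$volume, small_pre(), tr$node_mask)$sla
  one <- parameter_sweep(ph$volume, data.frame(merge_threshold = 0.1),
                         pre = small_pre(), sla = sla, exclusion = tr$node_mask)
  expect_equal(nrow(one), 1L)
  expect_true(is.na(one$ari_vs_first))
  expect_gt(one$n_subunits, 0)

  dup <- parameter_sweep(ph$volume,
                         data.frame(merge_threshold = c(0.1, 0.1)),
                         pre = small_pre(), sla = sla, exclusion = tr$node_mask)
  expect_equal(dup$ari_vs_first[2], 1.0)
  expect_equal(dup$n_subunits[1], dup$n_subunits[2])

  expect_error(parameter_sweep(ph$volume, data.frame(nonsense = 1)),
               class = "lobuseg_param_error")
})
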