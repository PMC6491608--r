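test_that("Kuwahara-ratio filter matches the direct octant enumeration", {
  # hand-checkable 1D profile: the centre voxel sees two distinct boxes
  # {0,0,10} is never one of them at radius 1 -> both boxes are {0,10}:
  # mean 5, population variance 25, ratio 5/26 each
  v <- image_volume(array(c(0, 0, 10, 0, 0), c(5, 1, 1)))
  p <- preprocess_params(box_radius = c(1, 1, 1), variance_epsilon = 1,
                         kuwahara_mode = "ratio")
  f <- kuwahara_ratio_filter(v, p)
  expect_equal(f[3, 1, 1], 5 / 26)
  expect_equal(bare(f) + 0, o_kuwahara_ratio(bare(v) + 0, c(1, 1, 1), 1))

  set.seed(21)
  a <- array(rexp(6 * 5 * 4), c(6, 5, 4))
  for (r in list(c(1, 1, 1), c(2, 1, 1))) {
    f2 <- kuwahara_ratio_filter(image_volume(a),
                                preprocess_params(box_radius = r,
                                                  variance_epsilon = 0.5,
                                                  kuwahara_mode = "ratio"))
    expect_equal(bare(f2) + 0, o_kuwahara_ratio(a, r, 0.5))
  }
})

test_that("Kuwahara filter handles flat fields and stays non-negative", {
  p <- preprocess_params(box_radius = c(1, 1, 1), variance_epsilon = 2,
                         kuwahara_mode = "ratio")
  expect_true(all(kuwahara_ratio_filter(image_volume(array(7, c(4, 4, 4))), p) == 3.5))
  expect_true(all(kuwahara_ratio_filter(image_volume(array(0, c(4, 4, 4))), p) == 0))
  set.seed(4)
  a <- array(rexp(5^3), c(5, 5, 5))
  expect_true(all(kuwahara_ratio_filter(image_volume(a), p) >= 0))
  expect_error(kuwahara_ratio_filter(image_volume(array(1, c(2, 2, 2))),
                                     preprocess_params(box_radius = c(3, 3, 3))),
               class = "lobuseg_dim_error")
})

test_that("Kuwahara response is translation invariant away from borders", {
  set.seed(5)
  blk <- array(rexp(3 * 3 * 3), c(3, 3, 3))
  emb <- function(off) {
    a <- array(0, c(12, 12, 12))
    a[off + 1:3, off + 1:3, off + 1:3] <- blk
    a
  }
  p <- preprocess_params(box_radius = c(1, 1, 1), variance_epsilon = 1,
                         kuwahara_mode = "ratio")
  f4 <- kuwahara_ratio_filter(image_volume(emb(4)), p)
  f6 <- kuwahara_ratio_filter(image_volume(emb(6)), p)
  expect_equal(f4[3 + 1:5, 3 + 1:5, 3 + 1:5] + 0, f6[5 + 1:5, 5 + 1:5, 5 + 1:5] + 0)
})

test_that("classic Kuwahara mode returns the minimum-variance box mean", {
  # step volume: voxels adjacent to the step keep their side's plateau value
  a <- array(10, c(6, 4, 4)); a[4:6, , ] <- 50
  f <- kuwahara_ratio_filter(image_volume(a),
                             preprocess_params(box_radius = c(1, 1, 1),
                                               kuwahara_mode = "classic"))
  expect_equal(f[3, 2, 2], 10)
  expect_equal(f[4, 2, 2], 50)
})

test_that("binarize thresholds correctly, including Otsu on bimodal data", {
  a <- array(c(0, 10), c(4, 5, 2))
  m <- binarize(image_volume(a), 5)
  expect_equal(bare(m), a > 5, ignore_attr = TRUE)
  expect_false(any(binarize(image_volume(a), 10)))   # threshold >= max -> empty

  set.seed(9)
  x <- array(c(rnorm(1000, 20, 3), rnorm(1000, 200, 10)), c(20, 10, 10))
  thr <- otsu_threshold(x)   # strictly between the two modes
  expect_gt(thr, 20)
  expect_lt(thr, 200)
  mm <- binarize(image_volume(x), "otsu")
  expect_equal(sum(mm), sum(x > thr))
  expect_error(otsu_threshold(array(3, c(2, 2, 2))),
               class = "lobuseg_degenerate_histogram")
})

test_that("cleanup fills pits, removes islands, and is idempotent", {
  m <- array(FALSE, c(9, 9, 9))
  m[3:7, 3:7, 3:7] <- TRUE
  m[5, 5, 5] <- FALSE                      # interior pit
  m[1, 1, 1] <- TRUE; m[1, 1, 2] <- TRUE   # 2-voxel island
  vol <- image_volume(array(as.numeric(m), dim(m))) > 0.5
  out <- cleanup(vol, closing_radius = 1, min_island_voxels = 3)
  expect_true(out[5, 5, 5])
  expect_false(out[1, 1, 1])
  expect_equal(bare(cleanup(out, 1, 3)), bare(out))
  # empty mask passes through
  empty <- image_volume(array(0, c(4, 4, 4))) > 0.5
  expect_false(any(cleanup(empty, 2, 5)))
})

test_that("SLA separation recovers the phantom core and excludes periphery", {
  ph <- small_phantom()
  tr <- ph$truth
  excl <- tr$node_mask
  comp <- separate_sla(ph$volume, small_pre(), excl)
  core <- bare(tr$core_mask)
  peri <- bare(tr$tissue_mask) & !core & !bare(excl)
  expect_gte(sum(bare(comp$sla) & core) / sum(core), 0.9)
  expect_lte(sum(bare(comp$sla) & peri) / sum(peri), 0.1)
  # compartments are disjoint and exclusion-free
  expect_false(any(bare(comp$sla) & bare(comp$periphery)))
  expect_false(any(bare(comp$sla) & bare(excl)))
  expect_false(any(bare(comp$periphery) & bare(excl)))
})

test_that("SLA separation fails informatively on degenerate inputs", {
  flat <- image_volume(array(100, c(16, 16, 8)))
  expect_error(separate_sla(flat, preprocess_params()), class = "lobuseg_empty_sla")
  ph <- small_phantom()
  all_excluded <- bare(ph$truth$tissue_mask) | TRUE
  expect_error(separate_sla(ph$volume, small_pre(), all_excluded),
               class = "lobuseg_empty_sla")
})
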