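# ROI selection: thumbnail arithmetic, superpixel partition, intensity
# ranking against an exhaustive oracle, crop mapping, pen-mark behavior.

test_that("thumbnails preserve aspect and intensity", {
  big <- array(runif(4000 * 2000 * 3, 0, 255), c(2000, 4000, 3))
  th <- make_thumbnail(big, roi_config(thumbnail_max_dim = 1000))
  expect_equal(dim(th$thumbnail)[1:2], c(500, 1000))
  expect_equal(th$scale_factor, 4.0)

  small <- array(17, c(500, 500, 3))
  th2 <- make_thumbnail(small, roi_config(thumbnail_max_dim = 1000))
  expect_identical(th2$thumbnail, small)
  expect_equal(th2$scale_factor, 1)

  mw <- generate_mock_wsi(1, seed = 2)
  th3 <- make_thumbnail(mw$image, desk_roi_config())
  expect_lte(abs(mean(rgb_to_gray(th3$thumbnail)) -
                   mean(rgb_to_gray(mw$image))), 2)
  expect_error(make_thumbnail("no/such/file.png"), "cannot read")
})

test_that("oversegmentation partitions the image into contiguous labels", {
  mw <- generate_mock_wsi(2, seed = 3)
  cfg <- desk_roi_config()
  th <- make_thumbnail(mw$image, cfg)
  lab <- oversegment(th$thumbnail, cfg)
  expect_identical(dim(lab), dim(th$thumbnail)[1:2])
  expect_false(anyNA(lab))                       # partition: every pixel labeled
  k <- max(lab)
  expect_gte(k, 0.5 * cfg$n_superpixels)
  expect_lte(k, 2.0 * cfg$n_superpixels)
  # every label is one connected component
  for (l in sample(seq_len(k), 10)) {
    bw <- EBImage::bwlabel(matrix(as.integer(lab == l), nrow(lab), ncol(lab)))
    expect_equal(max(bw), 1)
  }

  # constant image degenerates gracefully (spatial grid, warning)
  flat <- array(128, c(40, 40, 3))
  expect_warning(labf <- oversegment(flat, roi_config(n_superpixels = 9)),
                 "constant")
  expect_false(anyNA(labf))
})

test_that("two-half image yields superpixels with strongly separated means", {
  img <- array(0, c(40, 80, 3))
  img[, 41:80, ] <- 255
  lab <- oversegment(img, roi_config(n_superpixels = 8))
  cand <- rank_and_select(lab, img, roi_config(n_superpixels = 8,
                                               percentile = 1,
                                               background_threshold = 300))
  expect_gt(max(cand$mean_intensity) - min(cand$mean_intensity), 100)
})

test_that("rank_and_select matches an exhaustive sort-and-threshold oracle", {
  cfg <- roi_config(percentile = 0.10, background_threshold = 240)
  set.seed(99)
  for (trial in 1:25) {
    h <- sample(12:24, 1); w <- sample(12:24, 1)
    k <- sample(4:9, 1)
    lab <- matrix(sample(seq_len(k), h * w, replace = TRUE), h, w)
    img <- array(runif(h * w * 3, 0, 230), c(h, w, 3))
    got <- rank_and_select(lab, img, cfg)

    gray <- rgb_to_gray(img)
    means <- vapply(seq_len(k), function(l) mean(gray[lab == l]), numeric(1))
    areas <- vapply(seq_len(k), function(l) sum(lab == l), numeric(1))
    qv <- quantile(means, 0.10, type = 7, names = FALSE)
    keep <- which(means <= qv)
    keep <- keep[order(means[keep], -areas[keep], keep)]
    expect_identical(got$superpixel_id, as.integer(keep))
    expect_equal(got$mean_intensity, means[keep])
    expect_gte(nrow(got), 1)
  }
})

test_that("selection is invariant to label renumbering", {
  set.seed(7)
  lab <- matrix(sample(1:6, 400, replace = TRUE), 20, 20)
  img <- array(runif(1200, 0, 200), c(20, 20, 3))
  cfg <- roi_config(percentile = 0.25)
  a <- rank_and_select(lab, img, cfg)
  perm <- sample(6)                   # renumber labels
  lab2 <- matrix(perm[lab], 20, 20)
  b <- rank_and_select(lab2, img, cfg)
  expect_equal(a$mean_intensity, b$mean_intensity)
  expect_equal(a$centroid_row, b$centroid_row)
  expect_equal(a$centroid_col, b$centroid_col)
})

test_that("ties at the quantile are all kept", {
  lab <- matrix(rep(1:4, each = 25), 10, 10)
  img <- array(100, c(10, 10, 3))     # all superpixels share one mean
  got <- rank_and_select(lab, img, roi_config(percentile = 0.10))
  expect_equal(nrow(got), 4)
  # equal means: sorted by larger area first is moot, ids ascending
  expect_equal(got$superpixel_id, 1:4)
})

test_that("crop windows are centered, clamped and content-exact", {
  cfg <- roi_config(roi_size = 100)
  wsi <- array(runif(300 * 300 * 3, 0, 255), c(300, 300, 3))
  cand <- data.frame(centroid_wsi_row = 150, centroid_wsi_col = 150)
  crop <- crop_roi(wsi, cand, cfg)
  expect_identical(crop, wsi[101:200, 101:200, , drop = FALSE])

  # near-corner centroid: window shifted, not padded
  cand2 <- data.frame(centroid_wsi_row = 10, centroid_wsi_col = 10)
  crop2 <- crop_roi(wsi, cand2, cfg)
  expect_identical(crop2, wsi[1:100, 1:100, , drop = FALSE])

  expect_error(crop_roi(array(0, c(50, 50, 3)), cand, cfg), "smaller")
})

test_that("mock WSI ROI lands in tissue; pen marks hijack it; exclusion recovers it", {
  cfg <- desk_roi_config()
  hits <- 0L
  for (s in 1:10) {
    mw <- generate_mock_wsi(2, seed = s)
    sel <- select_rois(mw$image, cfg)
    top <- sel$candidates[1, ]
    hits <- hits + in_any_box(top$centroid_wsi_row, top$centroid_wsi_col,
                              mw$regions)
  }
  expect_gte(hits, 9L)

  mp <- generate_mock_wsi(2, with_pen_mark = TRUE, seed = 123)
  th <- make_thumbnail(mp$image, cfg)
  lab <- oversegment(th$thumbnail, cfg)
  cand <- rank_and_select(lab, th$thumbnail, cfg,
                          scale_factor = th$scale_factor)
  top <- cand[1, ]
  r <- round(top$centroid_wsi_row); c <- round(top$centroid_wsi_col)
  expect_equal(mp$pen_mask[r, c], 1L)   # the documented failure mode

  # user-supplied exclusion mask (downscaled to thumbnail coordinates)
  # restores tissue selection
  eb <- EBImage::resize(EBImage::Image(t(mp$pen_mask)),
                        w = ncol(th$thumbnail), h = nrow(th$thumbnail))
  ex_th <- t(matrix(as.integer(EBImage::imageData(eb) > 0.1),
                    ncol(th$thumbnail), nrow(th$thumbnail)))
  cand2 <- rank_and_select(lab, th$thumbnail, cfg,
                           scale_factor = th$scale_factor,
                           exclude_mask = ex_th)
  top2 <- cand2[1, ]
  expect_true(in_any_box(top2$centroid_wsi_row, top2$centroid_wsi_col,
                         mp$regions))
})
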