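# small rendered ROI shared by the classifier tests in this file
.seg_fixture <- local({
  lay <- layout_spec("random", image_size = c(150, 150),
                     n_cells = c(A = 8, B = 8))
  cells <- place_cells(lay, seed = 21)
  r <- render_roi(cells, tiny_signatures(), noise_spec(seed = 21))
  stack <- build_stack(r$image, tiny_panel(), "segmentation")
  feats <- compute_pixel_features(stack)
  scrib <- scribbles_from_truth(cells, n_per_class = 600, seed = 21)
  list(cells = cells, roi = r, feats = feats, scrib = scrib)
})

test_that("pixel features follow the channels x kinds x scales contract", {
  arr <- array(3, dim = c(20, 20, 2))
  img <- multiplex_image(arr, c("c1", "c2"))
  ft <- compute_pixel_features(img)
  expect_equal(ncol(ft$features), 2 * 5 * 3)
  # derivatives of a constant vanish; smoothing preserves the constant
  expect_true(all(abs(ft$features[, grep("gradmag|_log", ft$names)]) < 1e-10))
  expect_true(all(abs(ft$features[, grep("gauss", ft$names)] - 3) < 1e-10))
})

test_that("gradient magnitude peaks on the rim of a bright disk", {
  H <- 41
  img <- matrix(0, H, H)
  for (r in 1:H) for (c in 1:H)
    if ((r - 21)^2 + (c - 21)^2 <= 100) img[r, c] <- 1
  ft <- compute_pixel_features(multiplex_image(array(img, c(H, H, 1)), "d"),
                               scales = 1)
  mag <- matrix(ft$features[, "d_s1_gradmag"], H, H)
  peak <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  d_peak <- sqrt(sum((peak - 21)^2))
  expect_lt(abs(d_peak - 10), 2)
})

test_that("the classifier separates a separable toy and is deterministic", {
  # three horizontal bands with distinct intensity, scribbles well inside
  H <- 36; W <- 40
  img <- matrix(0, H, W)
  img[13:24, ] <- 0.5
  img[25:36, ] <- 1
  ft <- compute_pixel_features(multiplex_image(array(img, c(H, W, 1)), "x"))
  rows <- list(nuclei = 3:8, cytoplasm = 16:21, background = 29:34)
  scrib <- do.call(rbind, lapply(names(rows), function(cl) {
    idx <- as.vector(outer(rows[[cl]], (seq_len(W) - 1) * H, "+"))
    data.frame(index = idx, class = cl)
  }))
  clf <- train_pixel_classifier(ft, scrib, seed = 3)
  expect_gte(clf$oob_accuracy, 0.99)

  pm1 <- predict_probability_maps(clf, ft)
  clf2 <- train_pixel_classifier(ft, scrib, seed = 3)
  pm2 <- predict_probability_maps(clf2, ft)
  expect_identical(unclass(pm1), unclass(pm2))

  bad <- scrib[scrib$class != "cytoplasm", ]
  expect_error(train_pixel_classifier(ft, bad, seed = 1), "cytoplasm")
})

test_that("probability maps are calibrated on a rendered ROI", {
  fx <- .seg_fixture
  clf <- train_pixel_classifier(fx$feats, fx$scrib, seed = 2)
  pm <- predict_probability_maps(clf, fx$feats)
  sums <- pm[, , 1] + pm[, , 2] + pm[, , 3]
  expect_true(all(abs(sums - 1) < 1e-6))
  # posterior at each ground-truth nucleus center and at a far corner
  for (i in seq_len(nrow(fx$cells))) {
    rr <- round(fx$cells$y[i]); cc <- round(fx$cells$x[i])
    expect_gt(pm[rr, cc, "nuclei"], 0.5)
  }
  # a pixel far from every footprint should be confidently background
  covered <- fx$roi$mask > 0
  far <- which(!covered & EBImage::distmap(!covered) > 6)[1]
  expect_gt(pm[, , "background"][far], 0.5)
})

test_that("feature-layout mismatches are rejected", {
  fx <- .seg_fixture
  clf <- train_pixel_classifier(fx$feats, fx$scrib, seed = 2)
  arr <- array(1, dim = c(10, 10, 1))
  other <- compute_pixel_features(multiplex_image(arr, "z"))
  expect_error(predict_probability_maps(clf, other), "layout")
})

test_that("segmentation splits, expands and renumbers correctly", {
  # two well-separated nuclei
  pm <- make_probmaps(40, 40, centers = cbind(x = c(10, 30), y = c(10, 30)))
  mask <- segment_cells(pm)
  expect_equal(max(mask), 2)
  expect_true(mask[10, 10] > 0 && mask[30, 30] > 0)
  expect_false(mask[10, 10] == mask[30, 30])
  expect_setequal(unique(mask[mask > 0]), 1:2)
  # deterministic
  expect_identical(segment_cells(pm), mask)

  # all background
  bg <- array(0, c(20, 20, 3),
              dimnames = list(NULL, NULL, c("nuclei", "cytoplasm", "background")))
  bg[, , "background"] <- 1
  expect_warning(m0 <- segment_cells(structure(bg, class = "ProbabilityMaps")),
                 "empty")
  expect_equal(max(m0), 0)

  # dumbbell: two overlapping disks -> split by the distance transform
  pm2 <- make_probmaps(40, 40, centers = cbind(x = c(15, 25), y = c(20, 20)),
                       r_nuc = 5)
  m2 <- segment_cells(pm2)
  expect_equal(max(m2), 2)
  expect_false(m2[20, 15] == m2[20, 25])
})

test_that("small objects are removed before expansion", {
  pm <- make_probmaps(30, 30, centers = cbind(x = 15, y = 15), r_nuc = 4)
  pm[5, 5, "nuclei"] <- 1; pm[5, 5, "background"] <- 0  # 1-px speck
  mask <- segment_cells(pm, min_nucleus_area = 10)
  expect_equal(max(mask), 1)
  expect_equal(mask[5, 5], 0L)
})
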