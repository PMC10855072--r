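test_that("placement honors the hard-core constraint and empty case", {
  lay <- layout_spec("random", image_size = c(300, 300), n_cells = c(A = 0))
  expect_equal(nrow(place_cells(lay, seed = 1)), 0)

  lay <- layout_spec("random", image_size = c(500, 500),
                     n_cells = c(A = 100, B = 100), min_center_distance = 12)
  cells <- place_cells(lay, seed = 7)
  expect_equal(nrow(cells), 200)
  d <- as.matrix(dist(cells[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 12)
  # centroids inside bounds
  expect_true(all(cells$x > 0 & cells$x < 500 & cells$y > 0 & cells$y < 500))
})

test_that("paired attraction places every B near an A anchor", {
  lay <- layout_spec("paired_attraction", image_size = c(500, 500),
                     n_cells = c(A = 50, B = 50), min_center_distance = 8,
                     attraction = list(a = "A", b = "B", max_distance = 10))
  cells <- place_cells(lay, seed = 11)
  a <- cells[cells$type == "A", c("x", "y")]
  b <- cells[cells$type == "B", c("x", "y")]
  for (i in seq_len(nrow(b))) {
    dmin <- min(sqrt((a$x - b$x[i])^2 + (a$y - b$y[i])^2))
    expect_lte(dmin, 10)
  }
})

test_that("infeasible layouts fail loudly", {
  expect_error(layout_spec("random", n_cells = c(A = 10),
                           min_center_distance = 4),
               "min_center_distance")
  expect_error(layout_spec("paired_attraction", n_cells = c(A = 1, B = 1),
                           attraction = list(a = "A", b = "B",
                                             max_distance = 5)),
               "max_distance")
  lay <- layout_spec("random", image_size = c(60, 60),
                     n_cells = c(A = 500), min_center_distance = 12)
  expect_error(place_cells(lay, seed = 1, max_attempts = 50), "density")
})

test_that("core/margin mode confines types to their compartments", {
  lay <- layout_spec("core_margin", image_size = c(400, 400),
                     n_cells = c(tumor = 60, stromal = 60),
                     margin_band_width = 100, core_types = "tumor")
  cells <- place_cells(lay, seed = 3)
  d_border <- pmin(cells$x, 400 - cells$x, cells$y, 400 - cells$y)
  expect_true(all(d_border[cells$type == "tumor"] > 100))
  expect_true(all(d_border[cells$type == "stromal"] <= 100))
})

test_that("rendering is deterministic and conserves labels", {
  lay <- layout_spec("random", image_size = c(120, 120),
                     n_cells = c(A = 10, B = 10))
  cells <- place_cells(lay, seed = 5)
  r1 <- render_roi(cells, tiny_signatures(), noise_spec(seed = 5))
  r2 <- render_roi(cells, tiny_signatures(), noise_spec(seed = 5))
  expect_identical(r1$image$data, r2$image$data)
  expect_identical(r1$mask, r2$mask)
  expect_setequal(unique(r1$mask[r1$mask > 0]), cells$mask_label)
})

test_that("noise-free limit renders exact intensities", {
  lay <- layout_spec("random", image_size = c(60, 60), n_cells = c(A = 1))
  cells <- place_cells(lay, seed = 2)
  ns <- noise_spec(background_mean = 5, poisson = FALSE, hot_pixel_rate = 0)
  r <- render_roi(cells, tiny_signatures(dispersion = 1e-9), ns)
  m1 <- get_channel(r$image, "M1")
  expect_true(all(m1[r$mask > 0] == 100))
  expect_true(all(m1[r$mask == 0] == 5))
})

test_that("unknown cell types are rejected", {
  lay <- layout_spec("random", image_size = c(60, 60), n_cells = c(Z = 1))
  cells <- place_cells(lay, seed = 2)
  expect_error(render_roi(cells, tiny_signatures(), noise_spec()), "unknown")
})

test_that("hot pixels appear at the binomial rate and are isolated", {
  lay <- layout_spec("random", image_size = c(500, 500), n_cells = c(A = 0))
  cells <- place_cells(lay, seed = 1)
  ns <- noise_spec(background_mean = 1, poisson = FALSE,
                   hot_pixel_rate = 0.001, hot_pixel_amplitude = 2000,
                   seed = 9)
  r <- render_roi(cells, tiny_signatures(), ns, image_size = c(500, 500))
  hot <- which(get_channel(r$image, "M1") == 2000, arr.ind = TRUE)
  expect_lt(abs(nrow(hot) - 250), 4 * sqrt(250))
  if (nrow(hot) > 1) {
    d <- as.matrix(dist(hot, method = "maximum"))
    diag(d) <- Inf
    expect_gt(min(d), 1)  # no two hot pixels 8-adjacent
  }
})

test_that("the default panel renders 28 marker channels plus DNA", {
  lay <- layout_spec("random", image_size = c(80, 80), n_cells = c(tumor = 3))
  cells <- place_cells(lay, seed = 4)
  r <- render_roi(cells, default_signatures(), noise_spec(seed = 4))
  expect_length(r$image$channels, 29)
  expect_equal(r$image$channels[29], "DNA")
  expect_identical(r$image$channels[1:28], imc_panel()$target)
})

test_that("fixtures round-trip bit-identically through disk", {
  lay <- layout_spec("random", image_size = c(500, 500),
                     n_cells = c(A = 150, B = 150))
  cells <- place_cells(lay, seed = 8)
  r <- render_roi(cells, tiny_signatures(), noise_spec(seed = 8))
  dir <- withr::local_tempdir()
  write_fixture(r$image, r$mask, cells, tiny_panel(), dir)
  back <- read_fixture(dir)
  expect_equal(back$image$data, r$image$data)
  expect_identical(dim(back$mask), dim(r$mask))
  expect_true(all(back$mask == r$mask))
  expect_equal(length(unique(back$mask[back$mask > 0])), 300)
  expect_equal(back$cells$x, cells$x)
  expect_identical(back$panel$target, tiny_panel()$target)
})

test_that("synthetic cell matrices follow the signature means", {
  sig <- default_signatures()
  sm <- synth_cell_matrix(c(tumor = 2000, stromal = 2000), sig, seed = 3)
  expect_equal(nrow(sm$intensity), 4000)
  # lognormal with median mu: geometric mean of draws approaches mu
  gm <- exp(mean(log(sm$intensity[sm$type == "tumor", "ZO-1"])))
  expect_lt(abs(gm - 100) / 100, 0.05)
  gm_bg <- exp(mean(log(sm$intensity[sm$type == "tumor", "CD3"])))
  expect_lt(abs(gm_bg - 1), 0.05)
})
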