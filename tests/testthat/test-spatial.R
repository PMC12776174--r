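test_that("accelerated LA counts equal brute force on a random slide", {
  set.seed(14)
  n <- 1000
  rec <- make_records(runif(n, 0, 20000), runif(n, 0, 16000),
                      cell_type = sample(cell_types(), n, TRUE),
                      structure_type = sample(structure_types(), n, TRUE))
  grid <- local_autocorrelation(rec, "fibrin", nx = 30, ny = 25,
                                radius_um = 200, min_cells = 5)
  or <- oracle_la(rec, rec$structure_type == "fibrin", grid$gx, grid$gy,
                  grid$radius_px)
  expect_identical(grid$counts, or$counts)
  vals_or <- ifelse(or$counts >= 5, or$hits / pmax(or$counts, 1), NA_real_)
  expect_equal(grid$values, vals_or, tolerance = 1e-12)
})

test_that("LA is 1 for an all-target slide and 0 when the target is absent", {
  rec <- make_records(runif(500, 0, 5000), runif(500, 0, 5000),
                      cell_type = "leukocyte")
  g1 <- local_autocorrelation(rec, "leukocyte", nx = 10, ny = 10)
  expect_true(all(g1$values[!g1$mask] == 1))
  g0 <- local_autocorrelation(rec, "hofbauer_cell", nx = 10, ny = 10)
  expect_true(all(g0$values[!g0$mask] == 0))
  expect_error(local_autocorrelation(rec, "astrocyte"), "unknown target")
})

test_that("raising min_cells only grows the mask", {
  set.seed(15)
  rec <- make_records(runif(800, 0, 30000), runif(800, 0, 30000))
  g5 <- local_autocorrelation(rec, "terminal_villi", nx = 20, ny = 20,
                              min_cells = 5)
  g10 <- local_autocorrelation(rec, "terminal_villi", nx = 20, ny = 20,
                               min_cells = 10)
  expect_true(all(g10$mask[g5$mask]))
  shared <- !g10$mask
  expect_identical(g5$values[shared], g10$values[shared])
})

test_that("LA is invariant to record order and non-target relabelling", {
  set.seed(16)
  n <- 400
  rec <- make_records(runif(n, 0, 10000), runif(n, 0, 10000),
                      cell_type = sample(c("leukocyte", "fibroblast",
                                           "hofbauer_cell"), n, TRUE))
  g <- local_autocorrelation(rec, "leukocyte", nx = 12, ny = 12)
  gp <- local_autocorrelation(rec[sample(n), ], "leukocyte", nx = 12,
                              ny = 12)
  expect_identical(g$values, gp$values)

  rec2 <- rec
  swap <- rec2$cell_type == "fibroblast"
  rec2$cell_type[swap] <- "vascular_myocyte"
  g2 <- local_autocorrelation(rec2, "leukocyte", nx = 12, ny = 12)
  expect_identical(g$values, g2$values)
})

test_that("Gaussian smoothing is mask-aware and preserves constants", {
  set.seed(17)
  rec <- make_records(runif(2000, 0, 10000), runif(2000, 0, 10000),
                      cell_type = sample(c("leukocyte", "fibroblast"), 2000,
                                         TRUE))
  g <- local_autocorrelation(rec, "leukocyte", nx = 25, ny = 25)
  expect_identical(smooth_gaussian(g, 0), g)

  # constant field stays constant, mask unchanged
  gc <- g
  gc$values[!gc$mask] <- 0.37
  sm <- smooth_gaussian(gc, 1.5)
  expect_equal(sm$values[!sm$mask], rep(0.37, sum(!sm$mask)),
               tolerance = 1e-12)
  expect_identical(sm$mask, gc$mask)
  expect_true(all(is.na(sm$values[sm$mask])))

  # values remain in [0,1]
  sm2 <- smooth_gaussian(g, 2)
  expect_true(all(sm2$values[!sm2$mask] >= 0 & sm2$values[!sm2$mask] <= 1))
  expect_error(smooth_gaussian(g, -1), ">= 0")
})

test_that("a single hot point decays monotonically under smoothing", {
  g <- structure(list(
    values = matrix(0, 21, 21), counts = matrix(100L, 21, 21),
    mask = matrix(FALSE, 21, 21), gx = 1:21, gy = 1:21, nx = 21, ny = 21,
    radius_um = 200, radius_px = 1803.4, target = "fibrin", min_cells = 5
  ), class = "la_grid")
  g$values[11, 11] <- 1
  sm <- smooth_gaussian(g, 1.5)
  h <- ceiling(3 * 1.5)  # kernel support half-width
  centre_row <- sm$values[11, ]
  expect_true(all(diff(centre_row[(11 - h):11]) > 0))
  expect_true(all(diff(centre_row[11:(11 + h)]) < 0))
  expect_true(all(centre_row[c(1:(10 - h), (12 + h):21)] == 0))
  # direct kernel evaluation at the centre
  offs <- -h:h
  kern <- outer(dnorm(offs, sd = 1.5), dnorm(offs, sd = 1.5))
  expect_equal(sm$values[11, 11], kern[h + 1, h + 1] / sum(kern),
               tolerance = 1e-12)
})

test_that("heatmap export writes an exact matrix and a transparent mask", {
  set.seed(18)
  rec <- make_records(runif(1500, 0, 10000), runif(1500, 0, 10000),
                      structure_type = sample(c("fibrin", "terminal_villi"),
                                              1500, TRUE))
  g <- local_autocorrelation(rec, "fibrin", nx = 15, ny = 15)
  png_path <- withr::local_tempfile(fileext = ".png")
  paths <- export_heatmap(g, png_path)
  back <- read_heatmap_matrix(paths["csv"])
  expect_identical(back, g$values)

  img <- png::readPNG(png_path)
  expect_equal(dim(img)[1:2], c(15, 15))
  expect_equal(img[, , 4][g$mask], rep(0, sum(g$mask)))
  expect_true(all(img[, , 4][!g$mask] == 1))

  # fully masked grid: all-NA matrix, fully transparent image
  gm <- g
  gm$mask[] <- TRUE
  gm$values[] <- NA_real_
  paths2 <- export_heatmap(gm, png_path)
  expect_true(all(is.na(read_heatmap_matrix(paths2["csv"]))))
  expect_true(all(png::readPNG(png_path)[, , 4] == 0))
})
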