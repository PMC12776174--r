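test_that("identical seeds reproduce slides and cohorts exactly", {
  tmpl <- tiny_template()
  a <- generate_slide(tmpl, seed = 5)
  b <- generate_slide(tmpl, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$cells,
                         generate_slide(tmpl, seed = 6)$cells))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- lesion_spec("infarction", 0.2)
  generate_cohort(2, 1, list(list(spec = spec, n = 1)), tmpl, seed = 9,
                  out_dir = d1)
  generate_cohort(2, 1, list(list(spec = spec, n = 1)), tmpl, seed = 9,
                  out_dir = d2)
  for (f in c("cells.csv", "slides.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("nucleus counts follow the Poisson point process intensity", {
  tmpl <- slide_template(width_px = 10000, height_px = 8000,
                         nuclei_per_mm2 = 5000)
  expected <- 5000 * 10000 * 8000 * (0.1109 / 1000)^2
  expect_gt(expected, 1000)
  for (seed in 1:5) {
    n <- nrow(generate_slide(tmpl, seed = seed)$cells)
    expect_lt(abs(n - expected), 4 * sqrt(expected))
  }
})

test_that("a zero-coverage neutral lesion is bitwise identical to no lesion", {
  tmpl <- tiny_template()
  neutral <- lesion_spec("infarction", coverage_fraction = 0,
                         focal_cell = c(), focal_structure = c(),
                         field_cell = c(), field_structure = c())
  a <- generate_slide(tmpl, lesion = NULL, seed = 3)
  b <- generate_slide(tmpl, lesion = neutral, seed = 3)
  expect_identical(a$cells, b$cells)
  expect_identical(b$meta$category, "no_apparent_lesion")
  expect_identical(a$meta$category, "control")
})

test_that("neutral focal effects leave inside and outside mixtures equal", {
  # all fold-changes 1: inside-lesion resampling draws from the same
  # marginal, so per-class proportions differ only by sampling error
  tmpl <- slide_template(width_px = 20000, height_px = 18000,
                         axis_gradient = c())
  neutral <- lesion_spec("infarction", coverage_fraction = 0.3,
                         focal_cell = c(), focal_structure = c(),
                         field_cell = c(), field_structure = c())
  res <- generate_slide(tmpl, neutral, seed = 17)
  geom <- res$lesion_geometry
  cells <- exclude_plate_cells(res$cells)
  d2 <- rep(Inf, nrow(cells))
  for (i in seq_len(nrow(geom$centers))) {
    d2 <- pmin(d2, (cells$x - geom$centers[i, 1])^2 +
                 (cells$y - geom$centers[i, 2])^2)
  }
  inside <- d2 <= geom$radius^2
  expect_gt(sum(inside), 1000)
  p_in <- table(factor(cells$cell_type[inside], cell_types())) / sum(inside)
  p_out <- table(factor(cells$cell_type[!inside], cell_types())) /
    sum(!inside)
  pool <- table(factor(cells$cell_type, cell_types())) / nrow(cells)
  se <- sqrt(pool * (1 - pool) * (1 / sum(inside) + 1 / sum(!inside)))
  expect_true(all(abs(p_in - p_out) < 3 * se))
})

test_that("slide marginals converge to the template mixture", {
  # >= 50k nuclei: total-variation distance to the analytic marginal < 0.02
  tmpl <- slide_template(width_px = 30000, height_px = 27500)
  res <- generate_slide(tmpl, seed = 21)
  paren <- exclude_plate_cells(res$cells)
  expect_gt(nrow(paren), 50000 * 0.8)
  w <- tmpl$structure_weights
  emp_s <- table(factor(paren$structure_type, names(w))) / nrow(paren)
  expect_lt(0.5 * sum(abs(emp_s - w)), 0.02)
  marginal <- colSums(w * tmpl$cell_mixture[names(w), ])
  emp_c <- table(factor(paren$cell_type, names(marginal))) / nrow(paren)
  expect_lt(0.5 * sum(abs(emp_c - marginal)), 0.02)
})

test_that("realised lesion coverage tracks the requested fraction", {
  tmpl <- tiny_template()
  for (cov in c(0.05, 0.25, 0.6)) {
    spec <- lesion_spec("infarction", cov)
    res <- generate_slide(tmpl, spec, seed = 31)
    expect_lt(abs(res$lesion_geometry$realized_coverage - cov) / cov, 0.1)
    # nuclei inside the disc union approximate the area fraction
    paren <- exclude_plate_cells(res$cells)
    geom <- res$lesion_geometry
    d2 <- rep(Inf, nrow(paren))
    for (i in seq_len(nrow(geom$centers))) {
      d2 <- pmin(d2, (paren$x - geom$centers[i, 1])^2 +
                   (paren$y - geom$centers[i, 2])^2)
    }
    frac <- mean(d2 <= geom$radius^2)
    expect_lt(abs(frac - cov) / cov, 0.15)
  }
})

test_that("cohort pairing links no-apparent-lesion slides to lesion patients", {
  tmpl <- tiny_template()
  out <- generate_cohort(2, 0, list(), tmpl, seed = 1)
  expect_equal(sum(out$meta$category == "control"), 2)
  expect_equal(length(unique(out$meta$patient_id)), 2)

  spec <- lesion_spec("infarction", 0.2)
  out <- generate_cohort(0, 1, list(list(spec = spec, n = 1)), tmpl,
                         seed = 1)
  expect_equal(nrow(out$meta), 2)
  expect_equal(length(unique(out$meta$patient_id)), 1)
  expect_setequal(out$meta$category, c("lesion_present",
                                       "no_apparent_lesion"))

  expect_error(generate_cohort(0, 2, list(list(spec = spec, n = 1)), tmpl,
                               seed = 1),
               "pairing")
})

test_that("generator output passes the data-model validators", {
  tmpl <- tiny_template()
  out <- generate_cohort(1, 1,
                         list(list(spec = lesion_spec("perivillous_fibrin",
                                                      0.15), n = 1)),
                         tmpl, seed = 4)
  expect_silent(validate_cells(out$cells))
  expect_silent(validate_slide_meta(out$meta))
  expect_true(all(out$cells$confidence >= 0 & out$cells$confidence <= 1))
})
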