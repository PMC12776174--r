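test_that("dedup retains the higher-confidence record within the radius", {
  rec <- make_records(c(0, 3), c(0, 0), confidence = c(0.9, 0.8))
  out <- dedup_points(rec, 4)
  expect_equal(nrow(out), 1)
  expect_equal(out$confidence, 0.9)

  rec <- make_records(c(0, 5), c(0, 0), confidence = c(0.9, 0.8))
  expect_equal(nrow(dedup_points(rec, 4)), 2)
})

test_that("greedy suppression follows priority order in chains", {
  # equal confidence: ties break by (y, x); x=0 suppresses x=3, x=6 survives
  rec <- make_records(c(0, 3, 6), c(0, 0, 0))
  out <- dedup_points(rec, 4)
  expect_equal(out$x, c(0, 6))
})

test_that("dedup equals the brute-force greedy oracle and is idempotent", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 120
    rec <- make_records(runif(n, 0, 60), runif(n, 0, 60),
                        confidence = runif(n))
    out <- dedup_points(rec, 4)
    expect_identical(which(rownames(rec) %in% rownames(out)),
                     oracle_dedup(rec, 4))
    expect_identical(dedup_points(out, 4), out)
  }
  expect_equal(nrow(dedup_points(make_records(numeric(0), numeric(0)), 4)), 0)
})

test_that("isolated knots become syncytiotrophoblasts, clusters persist", {
  rec <- make_records(c(0, 1000, 1010, 1020, 1030, 1040), rep(0, 6),
                      cell_type = "syncytial_knot")
  out <- postprocess_syncytial_knots(rec, isolation_radius_px = 200)
  expect_identical(out$cell_type[1], "syncytiotrophoblast")
  expect_true(all(out$cell_type[2:6] == "syncytial_knot"))

  # two knots just over the radius apart: both isolated, both relabelled
  rec <- make_records(c(0, 201), c(0, 0), cell_type = "syncytial_knot")
  out <- postprocess_syncytial_knots(rec, isolation_radius_px = 200)
  expect_true(all(out$cell_type == "syncytiotrophoblast"))

  # non-knot records are never touched
  rec <- make_records(c(0, 1), c(0, 0),
                      cell_type = c("leukocyte", "syncytial_knot"))
  out <- postprocess_syncytial_knots(rec, 200)
  expect_identical(out$cell_type, c("leukocyte", "syncytiotrophoblast"))
})

test_that("knot clustering matches the union-find oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 80
    x <- runif(n, 0, 2000)
    y <- runif(n, 0, 2000)
    comp_cpp <- placomp:::cpp_radius_components(x, y, 200)
    comp_or <- oracle_components(x, y, 200)
    # same partition up to relabelling
    expect_equal(length(unique(comp_cpp)), length(unique(comp_or)))
    key_cpp <- split(seq_len(n), comp_cpp)
    key_or <- split(seq_len(n), comp_or)
    expect_setequal(unname(vapply(key_cpp, paste, "", collapse = ",")),
                    unname(vapply(key_or, paste, "", collapse = ",")))
  }
})

test_that("plate exclusion removes exactly the plate-labelled records", {
  rec <- make_records(1:10, 1:10,
                      structure_type = c(rep("chorionic_plate", 2),
                                         rep("basal_plate_septum", 2),
                                         rep("terminal_villi", 6)))
  out <- exclude_plate_cells(rec)
  expect_equal(nrow(out), 6)
  expect_identical(exclude_plate_cells(out), out)
  expect_equal(nrow(exclude_plate_cells(
    make_records(1:3, 1:3, structure_type = "chorionic_plate"))), 0)
})

test_that("tissue area counts occupied patches with half-open boxes", {
  cal <- calibration()
  one_patch <- 1600 * 1200 * (0.1109 / 1000)^2
  a <- estimate_tissue_area(make_records(5, 5), cal = cal)
  expect_equal(a$area_mm2, one_patch, tolerance = 1e-12)

  a3 <- estimate_tissue_area(make_records(c(5, 100, 1599.9), c(5, 6, 7)),
                             cal = cal)
  expect_equal(a3$area_mm2, a$area_mm2)

  ab <- estimate_tissue_area(make_records(c(0, 1600), c(0, 0)), cal = cal)
  expect_equal(ab$occupied_patches, 2L)

  a0 <- estimate_tissue_area(make_records(numeric(0), numeric(0)), cal = cal)
  expect_equal(a0$area_mm2, 0)
})

test_that("compositions are closed proportions over the vocabulary", {
  rec <- make_records(1:10, 1:10, cell_type = "leukocyte")
  p <- compute_composition(rec, "cell")
  expect_equal(unname(p["leukocyte"]), 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  rec <- make_records(1:4, 1:4,
                      cell_type = c(rep("syncytiotrophoblast", 3),
                                    "leukocyte"))
  p <- compute_composition(rec, "cell")
  expect_equal(unname(p["syncytiotrophoblast"]), 0.75)
  expect_equal(unname(p["leukocyte"]), 0.25)
  expect_equal(attr(p, "n_total"), 4)

  expect_error(compute_composition(make_records(numeric(0), numeric(0))),
               "zero records")
})

test_that("densities conserve counts and respond monotonically to patching", {
  cal <- calibration()
  rec <- make_records(runif(100, 0, 1599), runif(100, 0, 1199),
                      cell_type = "fibroblast")
  area <- estimate_tissue_area(rec, cal = cal)
  d <- compute_densities(rec, area, "cell")
  expect_equal(unname(d["fibroblast"]), 100 / area$area_mm2)
  expect_equal(d * area$area_mm2,
               table(factor(rec$cell_type, cell_types())) * 1.0,
               tolerance = 1e-9, ignore_attr = TRUE)

  # larger patches can only grow area, so never increase any density
  set.seed(3)
  rec <- make_records(runif(400, 0, 20000), runif(400, 0, 15000))
  a1 <- estimate_tissue_area(rec, 1600, 1200, cal)
  a2 <- estimate_tissue_area(rec, 3200, 2400, cal)
  expect_true(all(compute_densities(rec, a2, "cell") <=
                    compute_densities(rec, a1, "cell") + 1e-12))

  expect_error(compute_densities(rec, structure(list(area_mm2 = 0),
                                                class = "tissue_area")),
               "zero")
})

test_that("region segmentation recovers the plate-to-plate axis", {
  res <- generate_slide(tiny_template(), seed = 13)
  part <- segment_regions(res$cells)
  expect_identical(part$axis_source, "plate_centroids")
  angle <- acos(abs(part$axis[2])) * 180 / pi  # deviation from vertical
  expect_lt(angle, 5)
  # equal-count split
  counts <- table(part$region)
  expect_lt(diff(range(counts)), 0.05 * max(counts))
})

test_that("region splitting is equal-count and order-invariant", {
  rec <- make_records(rep(0, 9), 10 * (1:9))
  part <- segment_regions(rec, 3)
  expect_identical(part$axis_source, "bounding_box")
  expect_equal(unname(table(part$region)), rep(3L, 3), ignore_attr = TRUE)

  set.seed(5)
  rec <- make_records(runif(60, 0, 100), runif(60, 0, 300))
  part <- segment_regions(rec, 3)
  perm <- sample(nrow(rec))
  part_p <- segment_regions(rec[perm, ], 3)
  expect_identical(part_p$region, part$region[perm])

  expect_error(segment_regions(make_records(1, 1), 3), "fewer")
})

test_that("count-weighted region compositions reproduce the slide composition", {
  res <- generate_slide(tiny_template(), seed = 19)
  q <- quantify_slides(res$cells, res$meta)
  s <- q$slides[[1]]
  w <- vapply(s$regions, `[[`, numeric(1), "n")
  for (vocab in c("cell", "structure")) {
    mat <- vapply(s$regions, function(r) {
      placomp:::comp_values(r[[vocab]])
    }, numeric(if (vocab == "cell") 11 else 9))
    pooled <- as.numeric(mat %*% w) / sum(w)
    field <- if (vocab == "cell") s$cell_comp else s$structure_comp
    expect_equal(pooled, unname(placomp:::comp_values(field)),
                 tolerance = 1e-9)
  }
})

test_that("quantification is deterministic and reports QC exclusions", {
  out <- generate_cohort(2, 0, list(), tiny_template(), seed = 2)
  q1 <- quantify_slides(out$cells, out$meta)
  q2 <- quantify_slides(out$cells, out$meta)
  expect_identical(q1$slides, q2$slides)

  q3 <- quantify_slides(out$cells, out$meta,
                        exclude_slides = out$meta$slide_id[1])
  expect_equal(length(q3$slides), 1)
  expect_identical(q3$qc$reason, "manual_exclusion")
})
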