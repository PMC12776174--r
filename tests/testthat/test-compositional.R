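test_that("clr matches hand-computed log-ratios and sums to zero", {
  k <- 5
  u <- composition(setNames(rep(1 / k, k), paste0("c", 1:k)), "custom")
  expect_equal(unname(clr(u)), rep(0, k), tolerance = 1e-15)

  p <- composition(c(a = 0.8, b = 0.2), "custom")
  z <- clr(p)
  expect_equal(unname(z), c(log(2), -log(2)), tolerance = 1e-12)

  set.seed(4)
  for (i in 1:20) {
    p <- random_composition(k = 7)
    expect_lt(abs(sum(clr(p))), 1e-12)
  }
})

test_that("zero components are replaced or rejected explicitly", {
  p <- composition(c(a = 3, b = 0, c = 1), "custom", n_total = 4)
  expect_error(clr(p, zero_strategy = "none"), "zero component.*b")

  # multiplicative replacement: delta = 0.5/n, nonzeros shrunk, re-closed
  z <- clr(p)
  delta <- 0.5 / 4
  manual <- c(0.75 * (1 - delta), delta, 0.25 * (1 - delta))
  manual <- manual / sum(manual)
  expect_equal(unname(z), unname(log(manual) - mean(log(manual))),
               tolerance = 1e-12)

  # pseudocount adds delta everywhere
  z2 <- clr(p, "pseudocount", delta = 0.01)
  manual2 <- (c(0.75, 0, 0.25) + 0.01)
  manual2 <- manual2 / sum(manual2)
  expect_equal(unname(z2), unname(log(manual2) - mean(log(manual2))),
               tolerance = 1e-12)

  # no count and no delta: cannot pick a replacement
  q <- composition(c(a = 1, b = 0), "custom")
  expect_error(clr(q), "delta")
})

test_that("the Aitchison distance agrees with the closed-form example", {
  p <- composition(c(a = 0.8, b = 0.2), "custom")
  q <- composition(c(a = 0.5, b = 0.5), "custom")
  expect_equal(aitchison_distance(p, p), 0)
  # sqrt(2 * ln(2)^2) = ln(2) * sqrt(2), frozen from exact arithmetic
  expect_equal(aitchison_distance(p, q), 0.980258143468547,
               tolerance = 1e-12)
  r <- composition(c(x = 0.5, y = 0.5), "custom")
  expect_error(aitchison_distance(p, r), "vocabular")
})

test_that("the Aitchison distance satisfies the metric axioms", {
  set.seed(8)
  for (i in 1:1000) {
    p <- random_composition(4)
    q <- random_composition(4)
    r <- random_composition(4)
    dpq <- aitchison_distance(p, q)
    dqp <- aitchison_distance(q, p)
    expect_gte(dpq, 0)
    expect_lt(abs(dpq - dqp), 1e-9)
    expect_lte(dpq, aitchison_distance(p, r) + aitchison_distance(r, q) +
                 1e-9)
  }
  p <- random_composition(4)
  expect_lt(aitchison_distance(p, p), 1e-9)
})

test_that("distances are scale-invariant and permutation-equivariant", {
  counts <- c(a = 30, b = 14, c = 56, d = 11)
  p1 <- composition(counts, "custom", n_total = sum(counts))
  p7 <- composition(7 * counts, "custom", n_total = 7 * sum(counts))
  q <- composition(c(a = 10, b = 20, c = 30, d = 40), "custom",
                   n_total = 100)
  expect_equal(aitchison_distance(p1, q), aitchison_distance(p7, q),
               tolerance = 1e-12)

  perm <- c("c", "a", "d", "b")
  pp <- composition(placomp:::comp_values(p1)[perm], "custom",
                    n_total = sum(counts))
  qp <- composition(placomp:::comp_values(q)[perm], "custom", n_total = 100)
  expect_equal(aitchison_distance(pp, qp), aitchison_distance(p1, q),
               tolerance = 1e-12)
})

test_that("reference construction averages control compositions", {
  p <- composition(c(a = 0.6, b = 0.4), "custom", n_total = 10)
  q <- composition(c(a = 0.4, b = 0.6), "custom", n_total = 10)
  for (m in c("arithmetic", "clr_mean")) {
    same <- build_reference(list(p, p), method = m)
    expect_equal(unname(placomp:::comp_values(same$mean_composition)),
                 c(0.6, 0.4), tolerance = 1e-12)
    ref <- build_reference(list(p, q), method = m)
    expect_equal(unname(placomp:::comp_values(ref$mean_composition)),
                 c(0.5, 0.5), tolerance = 1e-12)
  }
  expect_error(build_reference(list(p)), "at least 2")
})

test_that("bootstrap null handles degenerate region sets", {
  p <- composition(c(a = 0.3, b = 0.7), "custom", n_total = 100)
  null <- bootstrap_null(list(p, p, p), c("s1", "s2", "s3"), n_boot = 500,
                         seed = 1)
  expect_equal(null$threshold, 0)

  q <- composition(c(a = 0.6, b = 0.4), "custom", n_total = 100)
  null2 <- bootstrap_null(list(p, q), c("s1", "s2"), n_boot = 500, seed = 1)
  expect_equal(null2$threshold, aitchison_distance(p, q),
               tolerance = 1e-12)

  expect_error(bootstrap_null(list(p, q), c("s1", "s1"), seed = 1),
               "2 slides")
})

test_that("bootstrap draws converge to the exhaustive pair distribution", {
  set.seed(12)
  comps <- lapply(1:12, function(i) random_composition(6, n_total = 500))
  ids <- rep(paste0("s", 1:4), each = 3)
  null <- bootstrap_null(comps, ids, n_boot = 10000, seed = 33)
  # oracle: exact enumeration of all 66 unordered pairs
  exact <- c()
  for (i in 1:11) for (j in (i + 1):12) {
    exact <- c(exact, aitchison_distance(comps[[i]], comps[[j]]))
  }
  expect_equal(sort(unique(null$pair_distances)), sort(unique(exact)),
               tolerance = 1e-12)
  grid <- sort(exact)
  gap <- max(abs(vapply(grid, function(g) mean(null$distances <= g),
                        numeric(1)) -
                   vapply(grid, function(g) mean(exact <= g), numeric(1))))
  expect_lt(gap, 0.03)

  # same seed, bitwise identical threshold; cross-slide pairing drops
  # same-slide pairs
  null_b <- bootstrap_null(comps, ids, n_boot = 10000, seed = 33)
  expect_identical(null_b$threshold, null$threshold)
  null_x <- bootstrap_null(comps, ids, n_boot = 100, seed = 1,
                           pairing = "cross_slide_only")
  expect_equal(length(null_x$pair_distances), 66 - 4 * 3)
})

test_that("slide scoring flags only distances beyond the threshold", {
  set.seed(9)
  comps <- lapply(1:6, function(i) random_composition(5, n_total = 300))
  ids <- rep(c("s1", "s2"), each = 3)
  null <- bootstrap_null(comps, ids, n_boot = 1000, seed = 2)
  ref <- build_reference(comps[1:4])

  scored <- score_slides(list(ref_slide = ref$mean_composition), ref, null)
  expect_equal(scored$distance, 0)
  expect_false(scored$significant)

  # degenerate null (threshold 0) flags every positive distance
  p <- comps[[1]]
  null0 <- bootstrap_null(list(p, p), c("a", "b"), n_boot = 100, seed = 1)
  scored0 <- score_slides(list(x = comps[[2]]), ref, null0)
  expect_true(scored0$significant)
})

test_that("leave-one-out stability enumerates removal of each slide", {
  out <- loo_significance(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sort(out$values), c(100 / 3, 100 / 3, 200 / 3, 200 / 3),
               tolerance = 1e-12)
  expect_equal(out$mean_percent, 50)
  expect_equal(out$range, c(100 / 3, 200 / 3), tolerance = 1e-12)

  expect_equal(loo_significance(c(TRUE, TRUE, TRUE))$values, rep(100, 3))
  expect_equal(loo_significance(c(FALSE, FALSE))$values, rep(0, 2))
  expect_error(loo_significance(TRUE), "at least 2")
})
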