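# Shared fixtures: a small slide template for fast tests, hand-built record
# tables, and a Dirichlet sampler for random compositions.

tiny_template <- function(...) {
  slide_template(width_px = 8000, height_px = 7000, nuclei_per_mm2 = 5000,
                 n_structure_seeds = 60, ...)
}

# records at explicit positions; labels recycled
make_records <- function(x, y, cell_type = "syncytiotrophoblast",
                         structure_type = "terminal_villi",
                         confidence = 1.0, slide_id = "s1") {
  validate_cells(data.frame(
    slide_id = rep_len(slide_id, length(x)), x = x, y = y,
    cell_type = rep_len(cell_type, length(x)),
    structure_type = rep_len(structure_type, length(x)),
    confidence = rep_len(confidence, length(x)),
    stringsAsFactors = FALSE
  ))
}

rdirichlet1 <- function(k, alpha = 1) {
  g <- rgamma(k, shape = alpha)
  g / sum(g)
}

random_composition <- function(k = 5, alpha = 2, n_total = 1000) {
  p <- rdirichlet1(k, alpha)
  names(p) <- paste0("c", seq_len(k))
  composition(p, "custom", n_total = n_total)
}

# distances of a list of slides (generated on the fly) to a reference/null
score_generated <- function(slides, ref, null, vocabulary = "cell") {
  vapply(slides, function(s) {
    q <- quantify_slides(s$cells, s$meta)
    comps <- slide_compositions(q, vocabulary)
    score_slides(comps, ref, null)$distance
  }, numeric(1))
}

# brute-force greedy radius suppression (oracle for dedup_points)
oracle_dedup <- function(records, radius) {
  ord <- order(-records$confidence, records$y, records$x)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 ||
        all((records$x[kept] - records$x[i])^2 +
              (records$y[kept] - records$y[i])^2 > radius^2)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

# brute-force ECDF scan (oracle for the KS statistic)
oracle_ks_stat <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g), numeric(1)) -
            vapply(grid, function(g) mean(y <= g), numeric(1))))
}

# pairwise enumeration (oracle for the Mann-Whitney U statistic)
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided MWU p by enumerating all assignments (tie-free data)
oracle_u_pvalue <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  combs <- combn(length(pooled), n)
  u_all <- apply(combs, 2, function(idx) {
    oracle_u_stat(pooled[idx], pooled[-idx])
  })
  u_obs <- oracle_u_stat(x, y)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# row-blocked brute-force radius scan (oracle for the LA grid)
oracle_la <- function(records, target_mask, gx, gy, radius_px) {
  counts <- matrix(0L, length(gy), length(gx))
  hits <- matrix(0L, length(gy), length(gx))
  dx2 <- outer(gx, records$x, "-")^2  # nx x n
  r2 <- radius_px^2
  for (iy in seq_along(gy)) {
    d2 <- dx2 + matrix((gy[iy] - records$y)^2, length(gx),
                       length(records$y), byrow = TRUE)
    inside <- d2 <= r2
    counts[iy, ] <- as.integer(rowSums(inside))
    hits[iy, ] <- as.integer(inside %*% target_mask)
  }
  list(counts = counts, hits = hits)
}

# brute-force connected components of the radius graph (oracle for knots)
oracle_components <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && (x[i] - x[j])^2 + (y[i] - y[j])^2 <= radius^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
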