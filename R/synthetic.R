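# Synthetic per-nucleus tables with the statistical structure the analysis
# assumes: Poisson nuclei placement, horizontal plate bands, a clustered
# structure field built from a seed-point partition with quota-balanced
# structure assignment, structure-conditional cell mixtures, focal lesion
# discs and organ-wide field effects.

#' Synthetic slide template
#'
#' Parameters of the healthy slide model. Nuclei are placed by a homogeneous
#' Poisson point process; the top and bottom bands are labelled chorionic
#' plate and basal plate; the parenchyma is partitioned into structure
#' patches (Voronoi cells of random seed points, assigned to structure
#' classes so that realised nuclei counts match the abundance weights); each
#' nucleus draws its cell type from the mixture of its structure. Optional
#' per-structure linear gradients along the plate-to-plate (vertical) axis
#' model normal spatial heterogeneity. Defaults are synthetic study
#' conditions: no composition table exists for real slides, so the mixtures
#' are qualitative (syncytiotrophoblast-dominant cells, terminal-villi
#' dominant structures, near-zero avascular villi).
#'
#' @param width_px,height_px canvas size in pixels.
#' @param nuclei_per_mm2 expected nuclei density (cells/mm^2).
#' @param plate_band_fraction fraction of slide height for each plate band.
#' @param n_structure_seeds number of structure seed points in the
#'   parenchyma; more seeds give finer structure texture.
#' @param structure_weights named nonnegative weights over the seven
#'   parenchymal structures (closed internally).
#' @param cell_mixture 9 x 11 matrix of structure-conditional cell-type
#'   probabilities (rows = structures, strictly positive, each summing to 1).
#' @param axis_gradient named vector in `[-1, 1]`: linear tilt of a
#'   structure's abundance along the chorionic (top) to basal (bottom) axis;
#'   positive values increase towards the basal plate.
#' @param confidence_shape two Beta shape parameters for detection
#'   confidences.
#' @param um_per_px pixel calibration.
#' @return A `slide_template` object.
#' @export
slide_template <- function(width_px = 30000, height_px = 25000,
                           nuclei_per_mm2 = 5000,
                           plate_band_fraction = 0.08,
                           n_structure_seeds = 400,
                           structure_weights = default_structure_weights(),
                           cell_mixture = default_cell_mixture(),
                           axis_gradient = c(stem_villi = -0.3,
                                             terminal_villi = 0.15),
                           confidence_shape = c(8, 2),
                           um_per_px = 0.1109) {
  stopifnot(width_px > 0, height_px > 0, nuclei_per_mm2 > 0,
            plate_band_fraction >= 0, plate_band_fraction < 0.5,
            n_structure_seeds >= length(PARENCHYMA_STRUCTURES))
  structure_weights <- structure_weights[PARENCHYMA_STRUCTURES]
  if (anyNA(structure_weights) || any(structure_weights < 0) ||
      sum(structure_weights) <= 0) {
    stop("structure_weights must cover all parenchymal structures, be ",
         "nonnegative, with at least one positive", call. = FALSE)
  }
  if (!identical(rownames(cell_mixture), STRUCTURE_TYPES) ||
      !identical(colnames(cell_mixture), CELL_TYPES)) {
    stop("cell_mixture must be a 9 x 11 matrix with structure rows and cell ",
         "columns in vocabulary order", call. = FALSE)
  }
  if (any(cell_mixture <= 0)) {
    stop("cell_mixture rows must be strictly positive", call. = FALSE)
  }
  row_sums <- rowSums(cell_mixture)
  if (any(abs(row_sums - 1) > 1e-6)) {
    stop("cell_mixture rows must sum to 1", call. = FALSE)
  }
  cell_mixture <- cell_mixture / row_sums
  grad <- setNames(rep(0, length(PARENCHYMA_STRUCTURES)),
                   PARENCHYMA_STRUCTURES)
  if (length(axis_gradient) > 0) {
    bad <- setdiff(names(axis_gradient), PARENCHYMA_STRUCTURES)
    if (length(bad) > 0) {
      stop("axis_gradient names outside parenchymal structures: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    stopifnot(all(abs(axis_gradient) <= 1))
    grad[names(axis_gradient)] <- axis_gradient
  }
  structure(list(
    width_px = width_px, height_px = height_px,
    nuclei_per_mm2 = nuclei_per_mm2,
    plate_band_fraction = plate_band_fraction,
    n_structure_seeds = as.integer(n_structure_seeds),
    structure_weights = structure_weights / sum(structure_weights),
    cell_mixture = cell_mixture,
    axis_gradient = grad,
    confidence_shape = confidence_shape,
    um_per_px = um_per_px
  ), class = "slide_template")
}

#' Default parenchymal structure abundance weights
#'
#' Terminal-villi-dominant healthy structure mix with near-zero avascular
#' villi; synthetic values (no quantitative healthy composition table exists
#' to validate against).
#'
#' @return Named numeric weights over the seven parenchymal structures.
#' @export
default_structure_weights <- function() {
  c(stem_villi = 0.15, anchoring_villi = 0.07,
    mature_intermediate_villi = 0.20, terminal_villi = 0.45,
    villous_sprouts = 0.05, fibrin = 0.06, avascular_villi = 0.02)
}

#' Default structure-conditional cell-type mixtures
#'
#' Strictly positive 9 x 11 matrix (structures x cell types); rows sum to 1.
#' Synthetic, qualitatively matched to a healthy term placenta:
#' syncytiotrophoblasts dominate villous structures, plates carry
#' fibroblasts/decidual cells, fibrin regions are enriched for leukocytes.
#'
#' @return The mixture matrix.
#' @export
default_cell_mixture <- function() {
  m <- rbind(
    stem_villi                = c(.18, .04, .02, .02, .28, .06, .10, .14, .10, .01, .05),
    anchoring_villi           = c(.20, .06, .02, .08, .22, .05, .08, .10, .10, .02, .07),
    mature_intermediate_villi = c(.32, .06, .04, .01, .16, .09, .14, .06, .08, .01, .03),
    terminal_villi            = c(.44, .07, .06, .005, .08, .10, .15, .03, .04, .005, .02),
    villous_sprouts           = c(.30, .16, .03, .01, .14, .08, .08, .04, .12, .01, .03),
    chorionic_plate           = c(.08, .03, .01, .04, .42, .03, .08, .10, .12, .02, .07),
    basal_plate_septum        = c(.04, .02, .01, .16, .12, .02, .05, .05, .06, .36, .11),
    fibrin                    = c(.22, .04, .06, .10, .12, .05, .06, .04, .08, .03, .20),
    avascular_villi           = c(.28, .05, .05, .02, .22, .06, .04, .06, .14, .02, .06)
  )
  colnames(m) <- CELL_TYPES
  m[STRUCTURE_TYPES, ]
}

#' Focal lesion specification
#'
#' A lesion is a union of discs covering a target fraction of the parenchyma.
#' `focal_*` fold-changes multiply the cell mixtures and structure weights
#' inside the lesion region only; `field_*` fold-changes apply everywhere on
#' the slide (organ-wide shifts, used alone for "no apparent lesion"
#' slides). All mixtures are re-closed after scaling. Default magnitudes are
#' synthetic parameters for parameter-recovery experiments, oriented by the
#' qualitative lesion biology (fibrin and leukocyte enrichment, Hofbauer
#' depletion, extravillous trophoblast increase).
#'
#' @param lesion_type one of [lesion_types()].
#' @param coverage_fraction target fraction of parenchyma area in `[0, 1]`;
#'   0 means no focal region (field effects only).
#' @param focal_cell,focal_structure,field_cell,field_structure named
#'   positive fold-changes over the respective vocabularies (missing names
#'   mean 1).
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(lesion_type = "infarction", coverage_fraction = 0.25,
                        focal_cell = c(leukocyte = 3,
                                       hofbauer_cell = 0.4,
                                       extravillous_trophoblast = 2.5),
                        focal_structure = c(fibrin = 8,
                                            avascular_villi = 2,
                                            terminal_villi = 0.6),
                        field_cell = c(leukocyte = 1.6,
                                       hofbauer_cell = 0.6,
                                       extravillous_trophoblast = 1.8),
                        field_structure = c(fibrin = 2)) {
  lesion_type <- match_vocabulary(lesion_type, LESION_TYPES, "lesion_type")
  stopifnot(length(coverage_fraction) == 1, coverage_fraction >= 0,
            coverage_fraction <= 1)
  check_folds <- function(folds, vocab, what) {
    if (length(folds) == 0) return(folds)
    bad <- setdiff(names(folds), vocab)
    if (length(bad) > 0) {
      stop(what, " names outside vocabulary: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(folds <= 0)) stop(what, " fold-changes must be > 0", call. = FALSE)
    folds
  }
  structure(list(
    lesion_type = lesion_type,
    coverage_fraction = coverage_fraction,
    focal_cell = check_folds(focal_cell, CELL_TYPES, "focal_cell"),
    focal_structure = check_folds(focal_structure, PARENCHYMA_STRUCTURES,
                                  "focal_structure"),
    field_cell = check_folds(field_cell, CELL_TYPES, "field_cell"),
    field_structure = check_folds(field_structure, PARENCHYMA_STRUCTURES,
                                  "field_structure")
  ), class = "lesion_spec")
}

# fold-change helpers ---------------------------------------------------

apply_folds <- function(weights, folds) {
  if (length(folds) > 0) {
    weights[names(folds)] <- weights[names(folds)] * folds
  }
  weights
}

scale_folds <- function(folds, exponent) {
  if (length(folds) == 0) return(folds)
  folds^exponent
}

largest_remainder <- function(total, w) {
  if (total == 0) return(integer(length(w)))
  target <- total * w / sum(w)
  base <- floor(target)
  need <- as.integer(round(total - sum(base)))
  if (need > 0) {
    idx <- order(target - base, decreasing = TRUE)[seq_len(need)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Assign structure seeds to structure classes so realised nuclei counts per
# class track the quotas, preferring seeds whose axis position matches the
# class gradient. E is a pre-drawn exponential matrix (seeds x structures):
# weighted sampling without replacement by exponential race.
assign_seed_structures <- function(cluster_sizes, quotas, pref, E) {
  n_seeds <- length(cluster_sizes)
  ns <- length(quotas)
  assigned <- rep(NA_integer_, n_seeds)
  for (s in order(quotas, decreasing = TRUE)) {
    if (quotas[s] <= 0) next
    avail <- which(is.na(assigned))
    if (length(avail) == 0) break
    avail <- avail[order(E[avail, s] / pref[avail, s])]
    cum <- 0
    for (j in avail) {
      if (cum >= quotas[s]) break
      assigned[j] <- s
      cum <- cum + cluster_sizes[j]
    }
  }
  realized <- vapply(seq_len(ns), function(s) {
    sum(cluster_sizes[assigned == s], na.rm = TRUE)
  }, numeric(1))
  deficit <- quotas - realized
  deficit[quotas == 0] <- -Inf
  if (all(!is.finite(deficit))) deficit <- quotas - realized
  for (j in which(is.na(assigned))) {
    s <- which.max(deficit)
    assigned[j] <- s
    deficit[s] <- deficit[s] - cluster_sizes[j]
  }
  assigned
}

# Calibrate the disc-union radius so the realised covered fraction of the
# parenchyma matches the target, by bisection against an occupancy grid.
calibrate_disc_radius <- function(cx, cy, target, x_range, y_range,
                                  n_grid = 256) {
  gx <- seq(x_range[1], x_range[2], length.out = n_grid)
  gy <- seq(y_range[1], y_range[2], length.out = n_grid)
  gxm <- rep(gx, times = n_grid)
  gym <- rep(gy, each = n_grid)
  d2min <- rep(Inf, n_grid * n_grid)
  for (i in seq_along(cx)) {
    d2 <- (gxm - cx[i])^2 + (gym - cy[i])^2
    d2min <- pmin(d2min, d2)
  }
  dmin <- sqrt(d2min)
  coverage_at <- function(r) mean(dmin <= r)
  lo <- 0
  hi <- sqrt(diff(x_range)^2 + diff(y_range)^2)
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    if (coverage_at(mid) < target) lo <- mid else hi <- mid
  }
  r <- (lo + hi) / 2
  list(radius = r, realized = coverage_at(r))
}

draw_categorical <- function(u, prob) {
  findInterval(u, cumsum(prob / sum(prob))) + 1L
}

#' Generate one synthetic slide
#'
#' Produces a per-nucleus table and its metadata row from a
#' [slide_template()], optionally with a [lesion_spec()]. All randomness
#' flows from `seed`: identical arguments and seed give identical output.
#' The slide category is inferred: no lesion gives `control`, a lesion with
#' positive coverage gives `lesion_present`, and a lesion with zero coverage
#' (field effects only) gives `no_apparent_lesion`.
#'
#' @param template a [slide_template()].
#' @param lesion a [lesion_spec()] or `NULL`.
#' @param seed integer seed (mandatory).
#' @param slide_id,patient_id,site identifiers for the metadata row.
#' @return list with `cells` (cell-record data.frame), `meta` (one-row slide
#'   metadata), and `lesion_geometry` (`centers`, `radius`,
#'   `realized_coverage`, or `NULL`).
#' @export
generate_slide <- function(template, lesion = NULL, seed,
                           slide_id = "slide_1",
                           patient_id = paste0("pat_", slide_id),
                           site = "site_a") {
  stopifnot(inherits(template, "slide_template"))
  if (!is.null(lesion)) stopifnot(inherits(lesion, "lesion_spec"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)

  W <- template$width_px
  H <- template$height_px
  cal <- calibration(template$um_per_px)
  band <- template$plate_band_fraction * H
  y_par <- c(band, H - band)

  field_cell <- if (is.null(lesion)) numeric(0) else lesion$field_cell
  field_structure <- if (is.null(lesion)) numeric(0) else
    lesion$field_structure
  w_par <- apply_folds(template$structure_weights, field_structure)
  w_par <- w_par / sum(w_par)

  # -- fixed RNG draw order; consumption independent of lesion effects ----
  n <- rpois(1, template$nuclei_per_mm2 * px_area_mm2(W, H, cal))
  x <- runif(n, 0, W)
  y <- runif(n, 0, H)
  n_seeds <- template$n_structure_seeds
  sx <- runif(n_seeds, 0, W)
  sy <- runif(n_seeds, y_par[1], y_par[2])
  E <- matrix(rexp(n_seeds * length(PARENCHYMA_STRUCTURES)),
              nrow = n_seeds)
  k_discs <- if (!is.null(lesion) && lesion$coverage_fraction > 0) {
    max(1L, ceiling(lesion$coverage_fraction / 0.2))
  } else 0L
  disc_cx <- runif(k_discs, 0, W)
  disc_cy <- runif(k_discs, y_par[1], y_par[2])
  u_struct <- runif(n)
  u_cell <- runif(n)
  confidence <- rbeta(n, template$confidence_shape[1],
                      template$confidence_shape[2])

  # -- plate bands and clustered structure field --------------------------
  in_chorionic <- y < y_par[1]
  in_basal <- y >= y_par[2]
  paren <- !(in_chorionic | in_basal)
  idx_par <- which(paren)
  n_par <- length(idx_par)

  nearest <- integer(n_par)
  if (n_par > 0) {
    best <- rep(Inf, n_par)
    for (j in seq_len(n_seeds)) {
      d2 <- (x[idx_par] - sx[j])^2 + (y[idx_par] - sy[j])^2
      upd <- d2 < best
      best[upd] <- d2[upd]
      nearest[upd] <- j
    }
  }
  cluster_sizes <- tabulate(nearest, nbins = n_seeds)
  quotas <- largest_remainder(n_par, w_par)
  t_seed <- (sy - y_par[1]) / max(y_par[2] - y_par[1], 1)
  pref <- vapply(seq_along(PARENCHYMA_STRUCTURES), function(s) {
    pmax(1 + template$axis_gradient[s] * (2 * t_seed - 1), 0.05)
  }, numeric(n_seeds))
  if (is.null(dim(pref))) pref <- matrix(pref, nrow = n_seeds)
  seed_struct <- assign_seed_structures(cluster_sizes, quotas, pref, E)

  structure_idx <- integer(n)  # index into STRUCTURE_TYPES
  structure_idx[in_chorionic] <- match("chorionic_plate", STRUCTURE_TYPES)
  structure_idx[in_basal] <- match("basal_plate_septum", STRUCTURE_TYPES)
  structure_idx[idx_par] <- match(PARENCHYMA_STRUCTURES[seed_struct[nearest]],
                                  STRUCTURE_TYPES)

  # -- focal lesion region ------------------------------------------------
  inside <- rep(FALSE, n)
  lesion_geometry <- NULL
  if (k_discs > 0) {
    calib <- calibrate_disc_radius(disc_cx, disc_cy,
                                   lesion$coverage_fraction,
                                   c(0, W), y_par)
    d2min <- rep(Inf, n_par)
    for (i in seq_len(k_discs)) {
      d2 <- (x[idx_par] - disc_cx[i])^2 + (y[idx_par] - disc_cy[i])^2
      d2min <- pmin(d2min, d2)
    }
    inside[idx_par] <- d2min <= calib$radius^2
    lesion_geometry <- list(centers = cbind(x = disc_cx, y = disc_cy),
                            radius = calib$radius,
                            realized_coverage = calib$realized)
    w_focal <- apply_folds(w_par, lesion$focal_structure)
    res_idx <- which(inside)
    if (length(res_idx) > 0) {
      new_s <- draw_categorical(u_struct[res_idx], w_focal)
      structure_idx[res_idx] <- match(PARENCHYMA_STRUCTURES[new_s],
                                      STRUCTURE_TYPES)
    }
  }

  # -- structure-conditional cell types ----------------------------------
  cell_idx <- integer(n)
  for (s in unique(structure_idx)) {
    for (side in c(FALSE, TRUE)) {
      sel <- which(structure_idx == s & inside == side)
      if (length(sel) == 0) next
      p <- template$cell_mixture[s, ]
      p <- apply_folds(p, field_cell)
      if (side) p <- apply_folds(p, lesion$focal_cell)
      cell_idx[sel] <- draw_categorical(u_cell[sel], p)
    }
  }

  cells <- data.frame(
    slide_id = slide_id, x = x, y = y,
    cell_type = CELL_TYPES[cell_idx],
    structure_type = STRUCTURE_TYPES[structure_idx],
    confidence = confidence,
    stringsAsFactors = FALSE
  )

  category <- if (is.null(lesion)) "control" else if
    (lesion$coverage_fraction > 0) "lesion_present" else "no_apparent_lesion"
  meta <- data.frame(
    slide_id = slide_id, patient_id = patient_id, site = site,
    category = category,
    lesions = if (category == "lesion_present") lesion$lesion_type else "",
    coverage_percent = if (category == "lesion_present")
      100 * lesion$coverage_fraction else NA_real_,
    width_px = W, height_px = H,
    stringsAsFactors = FALSE
  )
  list(cells = cells, meta = meta, lesion_geometry = lesion_geometry)
}

#' Generate a synthetic cohort
#'
#' Builds a cohort of control, "no apparent lesion", and lesion-present
#' slides. Each no-apparent-lesion slide shares a patient with one lesion
#' slide, and both inherit that patient's field effects (the base
#' fold-changes of the lesion spec raised to a patient-specific log-normal
#' exponent), which enables the paired intra-placenta analysis. All
#' randomness flows from `seed`; identical calls are byte-identical.
#'
#' @param n_control,n_no_apparent slide counts; `n_no_apparent` must not
#'   exceed the total number of lesion slides (pairing would be impossible).
#' @param lesion_specs list of `list(spec = lesion_spec(), n = count)`.
#' @param template a [slide_template()].
#' @param seed integer seed.
#' @param out_dir if non-`NULL`, writes `cells.csv`, `slides.csv`, and a
#'   `provenance.json` recording all parameters and the seed.
#' @param field_jitter_sd standard deviation of the patient-level log-normal
#'   exponent applied to field fold-changes (0 = identical field effects for
#'   every patient).
#' @return list with `cells`, `meta`, and (invisibly written) file paths.
#' @export
generate_cohort <- function(n_control, n_no_apparent, lesion_specs = list(),
                            template = slide_template(), seed,
                            out_dir = NULL, field_jitter_sd = 0.25) {
  stopifnot(n_control >= 0, n_no_apparent >= 0)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  flat_specs <- list()
  for (entry in lesion_specs) {
    stopifnot(inherits(entry$spec, "lesion_spec"), entry$n >= 0)
    flat_specs <- c(flat_specs, rep(list(entry$spec), entry$n))
  }
  n_lesion <- length(flat_specs)
  if (n_no_apparent > n_lesion) {
    stop("n_no_apparent exceeds the number of lesion slides; pairing ",
         "requires one lesion slide per no-apparent-lesion slide",
         call. = FALSE)
  }
  set.seed(seed)
  n_total <- n_control + n_no_apparent + n_lesion
  slide_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  patient_exponent <- exp(rnorm(max(n_lesion, 1), 0, field_jitter_sd))

  all_cells <- vector("list", n_total)
  all_meta <- vector("list", n_total)
  geoms <- list()
  slide_no <- 0L

  add_slide <- function(res) {
    force(res)
    slide_no <<- slide_no + 1L
    all_cells[[slide_no]] <<- res$cells
    all_meta[[slide_no]] <<- res$meta
    if (!is.null(res$lesion_geometry)) {
      geoms[[res$meta$slide_id]] <<- res$lesion_geometry
    }
  }

  for (i in seq_len(n_control)) {
    add_slide(generate_slide(
      template, lesion = NULL, seed = slide_seeds[slide_no + 1L],
      slide_id = sprintf("ctrl_%03d", i),
      patient_id = sprintf("C%03d", i),
      site = if (i %% 2 == 0) "site_b" else "site_a"
    ))
  }
  for (i in seq_len(n_lesion)) {
    spec <- flat_specs[[i]]
    spec$field_cell <- scale_folds(spec$field_cell, patient_exponent[i])
    spec$field_structure <- scale_folds(spec$field_structure,
                                        patient_exponent[i])
    add_slide(generate_slide(
      template, lesion = spec, seed = slide_seeds[slide_no + 1L],
      slide_id = sprintf("les_%03d", i),
      patient_id = sprintf("P%03d", i),
      site = if (i %% 2 == 0) "site_b" else "site_a"
    ))
  }
  for (i in seq_len(n_no_apparent)) {
    spec <- flat_specs[[i]]
    spec$coverage_fraction <- 0
    spec$field_cell <- scale_folds(spec$field_cell, patient_exponent[i])
    spec$field_structure <- scale_folds(spec$field_structure,
                                        patient_exponent[i])
    add_slide(generate_slide(
      template, lesion = spec, seed = slide_seeds[slide_no + 1L],
      slide_id = sprintf("nal_%03d", i),
      patient_id = sprintf("P%03d", i),
      site = if (i %% 2 == 0) "site_b" else "site_a"
    ))
  }

  cells <- do.call(rbind, all_cells)
  meta <- do.call(rbind, all_meta)
  rownames(cells) <- rownames(meta) <- NULL
  out <- list(cells = cells, meta = meta, lesion_geometry = geoms)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cell_records(cells, file.path(out_dir, "cells.csv"))
    write_slide_meta(meta, file.path(out_dir, "slides.csv"))
    provenance <- list(
      seed = seed, n_control = n_control, n_no_apparent = n_no_apparent,
      field_jitter_sd = field_jitter_sd,
      lesion_specs = lapply(lesion_specs, function(e) {
        c(unclass(e$spec), list(n = e$n))
      }),
      template = unclass(template)
    )
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- file.path(out_dir, c("cells.csv", "slides.csv",
                                      "provenance.json"))
  }
  invisible(out)
}
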