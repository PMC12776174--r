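# Pre-analysis processing of per-nucleus tables. Fixed pipeline order:
# dedup -> knot post-processing -> area estimation (all records) ->
# plate exclusion -> compositions / densities / regions.

#' Deduplicate nucleus predictions within a radius
#'
#' Greedy non-maximum suppression of duplicate detections: records are
#' visited in descending confidence (ties broken by `(y, x)` lexicographic
#' order) and a record is retained iff no already-retained record lies within
#' `radius_px` Euclidean distance. Output preserves the input order of the
#' survivors. Idempotent.
#'
#' @param records validated cell-record data.frame (one slide's worth;
#'   deduplication is within-slide, so multi-slide input is processed per
#'   slide).
#' @param radius_px suppression radius in pixels (default 4).
#' @return The surviving records, input order preserved.
#' @export
dedup_points <- function(records, radius_px = 4) {
  stopifnot(radius_px > 0)
  if (nrow(records) == 0) return(records)
  if (length(unique(records$slide_id)) > 1) {
    keep <- unlist(lapply(split(seq_len(nrow(records)), records$slide_id),
                          function(idx) {
                            idx[dedup_keep_one(records[idx, , drop = FALSE],
                                               radius_px)]
                          }), use.names = FALSE)
    return(records[sort(keep), , drop = FALSE])
  }
  records[dedup_keep_one(records, radius_px), , drop = FALSE]
}

dedup_keep_one <- function(records, radius_px) {
  ord <- order(-records$confidence, records$y, records$x)
  which(cpp_dedup_keep(records$x, records$y, as.integer(ord - 1L), radius_px))
}

#' Post-process isolated syncytial knot predictions
#'
#' Syncytial knots are nuclear aggregates, so a lone knot prediction is more
#' plausibly a syncytiotrophoblast nucleus. Builds the graph on
#' `syncytial_knot` records with edges at distance `<= isolation_radius_px`;
#' connected components smaller than `min_cluster` are relabelled
#' `syncytiotrophoblast`, larger components keep their label. No other
#' records are touched.
#'
#' @param records validated cell-record data.frame.
#' @param isolation_radius_px clustering radius in pixels (default 200,
#'   roughly one cell-crop width at 0.1109 um/px).
#' @param min_cluster minimum component size to remain a knot (default 2).
#' @return Records with knot labels revised.
#' @export
postprocess_syncytial_knots <- function(records, isolation_radius_px = 200,
                                        min_cluster = 2) {
  stopifnot(isolation_radius_px > 0)
  idx <- which(records$cell_type == "syncytial_knot")
  if (length(idx) == 0) return(records)
  for (slide_idx in split(idx, records$slide_id[idx])) {
    comp <- cpp_radius_components(records$x[slide_idx], records$y[slide_idx],
                                  isolation_radius_px)
    sizes <- tabulate(comp)
    lone <- slide_idx[sizes[comp] < min_cluster]
    records$cell_type[lone] <- "syncytiotrophoblast"
  }
  records
}

#' Exclude chorionic- and basal-plate cells
#'
#' Removes records whose structure label is `chorionic_plate` or
#' `basal_plate_septum`, restricting the analysis population to the
#' parenchyma (controls for sampling variation at the slide margins).
#'
#' @param records validated cell-record data.frame.
#' @return Parenchymal records, order preserved.
#' @export
exclude_plate_cells <- function(records) {
  records[!(records$structure_type %in% PLATE_STRUCTURES), , drop = FALSE]
}

#' Estimate tissue area from occupied patches
#'
#' Divides the slide into non-overlapping patches anchored at the origin; a
#' patch is occupied iff at least one record falls inside its half-open box
#' `[i*w, (i+1)*w) x [j*h, (j+1)*h)`. The tissue area is the summed physical
#' area of occupied patches, which excludes background regions free of
#' nuclei.
#'
#' @param records validated cell-record data.frame (one slide; all records,
#'   before plate exclusion — nuclei of any class mark tissue).
#' @param patch_w_px,patch_h_px patch dimensions in pixels (default
#'   1600 x 1200, the inference tiling).
#' @param cal a [calibration()].
#' @return A `tissue_area` object: `area_mm2`, `occupied_patches`,
#'   `patch_w_px`, `patch_h_px`.
#' @export
estimate_tissue_area <- function(records, patch_w_px = 1600,
                                 patch_h_px = 1200, cal = calibration()) {
  stopifnot(patch_w_px > 0, patch_h_px > 0)
  if (nrow(records) == 0) {
    occ <- 0L
  } else {
    occ <- nrow(unique(cbind(floor(records$x / patch_w_px),
                             floor(records$y / patch_h_px))))
  }
  structure(list(
    area_mm2 = occ * px_area_mm2(patch_w_px, patch_h_px, cal),
    occupied_patches = occ,
    patch_w_px = patch_w_px, patch_h_px = patch_h_px
  ), class = "tissue_area")
}

#' @export
print.tissue_area <- function(x, ...) {
  cat(sprintf("tissue area: %.4g mm2 (%d patches of %gx%g px)\n",
              x$area_mm2, x$occupied_patches, x$patch_w_px, x$patch_h_px))
  invisible(x)
}

#' Cell or structure densities
#'
#' Counts per square millimetre of estimated tissue area, over the chosen
#' vocabulary.
#'
#' @param records validated cell-record data.frame.
#' @param area a [estimate_tissue_area()] result with positive area.
#' @param vocabulary `"cell"` or `"structure"`.
#' @return Named numeric vector of densities (cells/mm^2).
#' @export
compute_densities <- function(records, area,
                              vocabulary = c("cell", "structure")) {
  vocabulary <- match.arg(vocabulary)
  stopifnot(inherits(area, "tissue_area"))
  if (area$area_mm2 <= 0) stop("tissue area is zero", call. = FALSE)
  labels <- vocabulary_labels(vocabulary)
  col <- if (vocabulary == "cell") "cell_type" else "structure_type"
  counts <- table(factor(records[[col]], levels = labels))
  d <- as.numeric(counts) / area$area_mm2
  names(d) <- labels
  d
}

#' Segment a slide into regions along the plate-to-plate axis
#'
#' The axis is the unit vector from the centroid of `chorionic_plate`
#' records to the centroid of `basal_plate_septum` records; when either
#' plate class has fewer than 10 records the longer bounding-box axis of all
#' records is used instead. Parenchymal records are projected onto the axis
#' and split into `n_regions` equal-count groups by linear-interpolation
#' quantile cuts, ties at a cut going to the lower region.
#'
#' @param records validated cell-record data.frame for one slide, including
#'   any plate-labelled cells (they anchor the axis but receive no region).
#' @param n_regions number of regions (default 3).
#' @param min_plate_records minimum records per plate class for the
#'   centroid-based axis (default 10).
#' @return A `region_partition`: `region` (integer in `1..n_regions`, `NA`
#'   for plate records, parallel to the input rows), `axis` (unit vector),
#'   `boundaries` (cut positions along the axis), `axis_source`.
#' @export
segment_regions <- function(records, n_regions = 3, min_plate_records = 10) {
  stopifnot(n_regions >= 1)
  paren <- !(records$structure_type %in% PLATE_STRUCTURES)
  if (sum(paren) < n_regions) {
    stop("fewer parenchymal records than regions", call. = FALSE)
  }
  cp <- records$structure_type == "chorionic_plate"
  bp <- records$structure_type == "basal_plate_septum"
  if (sum(cp) >= min_plate_records && sum(bp) >= min_plate_records) {
    v <- c(mean(records$x[bp]) - mean(records$x[cp]),
           mean(records$y[bp]) - mean(records$y[cp]))
    if (sqrt(sum(v^2)) == 0) v <- c(0, 1)
    axis_source <- "plate_centroids"
  } else {
    w <- diff(range(records$x))
    h <- diff(range(records$y))
    v <- if (h >= w) c(0, 1) else c(1, 0)
    axis_source <- "bounding_box"
  }
  axis <- v / sqrt(sum(v^2))
  t_all <- records$x * axis[1] + records$y * axis[2]
  tp <- t_all[paren]
  cuts <- if (n_regions > 1) {
    unname(quantile(tp, seq_len(n_regions - 1) / n_regions, type = 7))
  } else numeric(0)
  region <- rep(NA_integer_, nrow(records))
  region[paren] <- 1L + rowSums(outer(tp, cuts, ">"))
  structure(list(region = region, axis = axis, boundaries = cuts,
                 axis_source = axis_source, n_regions = n_regions),
            class = "region_partition")
}

#' Quantify a cohort of slides
#'
#' Runs the fixed pre-analysis pipeline per slide — deduplication, syncytial
#' knot post-processing, tissue-area estimation on all records, plate
#' exclusion, then compositions, densities, and region compositions on the
#' parenchymal records — and collects per-slide results plus a QC table of
#' slides excluded and why.
#'
#' @param cells validated cell-record data.frame (whole cohort).
#' @param meta validated slide metadata.
#' @param cal a [calibration()].
#' @param dedup_radius_px,knot_radius_px,knot_min_cluster,patch_w_px,patch_h_px,n_regions
#'   stage parameters; see the stage functions.
#' @param exclude_slides slide ids to drop before processing (manual QC, e.g.
#'   scanning artefacts).
#' @param min_records minimum parenchymal records for a slide to pass QC
#'   (default 50).
#' @return A `slide_quant` object: `slides` (named list of per-slide results
#'   with compositions, densities, areas, region compositions), `qc`
#'   (data.frame of excluded slides with reasons), `params`.
#' @export
quantify_slides <- function(cells, meta, cal = calibration(),
                            dedup_radius_px = 4, knot_radius_px = 200,
                            knot_min_cluster = 2, patch_w_px = 1600,
                            patch_h_px = 1200, n_regions = 3,
                            exclude_slides = character(),
                            min_records = 50) {
  meta <- validate_slide_meta(meta)
  qc <- data.frame(slide_id = character(0), reason = character(0),
                   stringsAsFactors = FALSE)
  if (length(exclude_slides) > 0) {
    qc <- rbind(qc, data.frame(slide_id = exclude_slides,
                               reason = "manual_exclusion"))
  }
  keep_ids <- setdiff(meta$slide_id, exclude_slides)
  per_slide <- list()
  for (sid in keep_ids) {
    rec <- cells[cells$slide_id == sid, , drop = FALSE]
    if (nrow(rec) == 0) {
      qc <- rbind(qc, data.frame(slide_id = sid, reason = "no_records"))
      next
    }
    rec <- dedup_points(rec, dedup_radius_px)
    rec <- postprocess_syncytial_knots(rec, knot_radius_px, knot_min_cluster)
    area <- estimate_tissue_area(rec, patch_w_px, patch_h_px, cal)
    paren <- exclude_plate_cells(rec)
    if (nrow(paren) < min_records) {
      qc <- rbind(qc, data.frame(slide_id = sid,
                                 reason = "too_few_parenchymal_records"))
      next
    }
    part <- segment_regions(rec, n_regions)
    paren_region <- part$region[!(rec$structure_type %in% PLATE_STRUCTURES)]
    regions <- lapply(seq_len(n_regions), function(r) {
      sub <- paren[paren_region == r, , drop = FALSE]
      list(n = nrow(sub),
           cell = compute_composition(sub, "cell"),
           structure = compute_composition(sub, "structure"))
    })
    per_slide[[sid]] <- list(
      slide_id = sid,
      n_records = nrow(rec),
      n_parenchymal = nrow(paren),
      area = area,
      cell_comp = compute_composition(paren, "cell"),
      structure_comp = compute_composition(paren, "structure"),
      cell_density = compute_densities(paren, area, "cell"),
      structure_density = compute_densities(paren, area, "structure"),
      regions = regions,
      axis = part$axis,
      axis_source = part$axis_source
    )
  }
  structure(list(
    slides = per_slide,
    meta = meta[meta$slide_id %in% names(per_slide), , drop = FALSE],
    qc = qc,
    params = list(dedup_radius_px = dedup_radius_px,
                  knot_radius_px = knot_radius_px,
                  knot_min_cluster = knot_min_cluster,
                  patch_w_px = patch_w_px, patch_h_px = patch_h_px,
                  n_regions = n_regions, um_per_px = cal$um_per_px,
                  min_records = min_records)
  ), class = "slide_quant")
}

#' @export
print.slide_quant <- function(x, ...) {
  cat(sprintf("slide_quant: %d slides quantified, %d excluded by QC\n",
              length(x$slides), nrow(x$qc)))
  invisible(x)
}

#' Extract compositions from a quantified cohort
#'
#' Accessors for [quantify_slides()] results: `slide_compositions` returns
#' the named list of slide-level compositions for one vocabulary;
#' `region_compositions` returns the region-level compositions (with their
#' slide ids) for a subset of slides, the inputs to [bootstrap_null()].
#'
#' @param quant a [quantify_slides()] result.
#' @param vocabulary `"cell"` or `"structure"`.
#' @return `slide_compositions`: named list of [composition()]s.
#' @export
slide_compositions <- function(quant, vocabulary = c("cell", "structure")) {
  vocabulary <- match.arg(vocabulary)
  field <- if (vocabulary == "cell") "cell_comp" else "structure_comp"
  lapply(quant$slides, `[[`, field)
}

#' @rdname slide_compositions
#' @param slide_ids slide ids whose regions to collect (e.g. the controls).
#' @return `region_compositions`: list with `comps` (compositions) and
#'   `slide_ids` (parallel character vector).
#' @export
region_compositions <- function(quant, slide_ids,
                                vocabulary = c("cell", "structure")) {
  vocabulary <- match.arg(vocabulary)
  comps <- list()
  ids <- character(0)
  for (sid in slide_ids) {
    s <- quant$slides[[sid]]
    if (is.null(s)) next
    for (r in s$regions) {
      comps[[length(comps) + 1L]] <- r[[vocabulary]]
      ids <- c(ids, sid)
    }
  }
  list(comps = comps, slide_ids = ids)
}

# Per-slide density table (long format).
density_table <- function(quant, vocabulary = c("cell", "structure")) {
  vocabulary <- match.arg(vocabulary)
  field <- if (vocabulary == "cell") "cell_density" else "structure_density"
  do.call(rbind, lapply(quant$slides, function(s) {
    data.frame(slide_id = s$slide_id, label = names(s[[field]]),
               density = unname(s[[field]]), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}
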