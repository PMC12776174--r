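# End-to-end orchestration: quantify -> reference/null -> score -> stats ->
# LA maps -> machine- and human-readable report.

#' Default pipeline configuration
#'
#' Nested key-value configuration for [run_pipeline()]; every entry can be
#' overridden by a partial list or a YAML file with the same structure. The
#' resolved configuration is written alongside the report so every run is
#' self-describing.
#'
#' @param cells,slides input file paths.
#' @param seed master seed for every stochastic stage.
#' @return Nested list of parameters.
#' @export
default_config <- function(cells = "cells.csv", slides = "slides.csv",
                           seed = 1L) {
  list(
    paths = list(cells = cells, slides = slides),
    seed = as.integer(seed),
    calibration = list(um_per_px = 0.1109),
    dedup = list(radius_px = 4),
    knots = list(isolation_radius_px = 200, min_cluster = 2),
    area = list(patch_w_px = 1600, patch_h_px = 1200),
    regions = list(n_regions = 3),
    qc = list(exclude_slides = character(0), min_records = 50),
    zero = list(strategy = "multiplicative", delta = NULL),
    reference = list(method = "arithmetic"),
    bootstrap = list(n_boot = 10000, percentile = 95,
                     pairing = "any_distinct"),
    la = list(nx = 150, ny = 150, radius_um = 200, min_cells = 5,
              targets = "fibrin", max_slides = 2, sigma_cells = 1.5),
    stats = list(correlation_method = "spearman",
                 density_labels = c("leukocyte", "hofbauer_cell",
                                    "extravillous_trophoblast", "fibrin"))
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  merge_config(default_config(), config)
}

#' Run the full analysis pipeline
#'
#' Executes quantification, healthy-reference and bootstrap-null
#' construction, per-slide deviation scoring, group statistics (KS on
#' distance distributions, Mann-Whitney on densities with Bonferroni
#' families per label, coverage and intra-placenta correlations,
#' leave-one-out stability), and local-autocorrelation maps, then writes a
#' machine-readable `report.json`, a human-readable `report.md`, CSV tables,
#' and heatmap figures. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config a configuration list (see [default_config()]), a partial
#'   override of it, or the path to a YAML file.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and returns the report only.
#' @param verbose log resolved configuration and stage progress.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, verbose = FALSE) {
  cfg <- resolve_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  say("configuration:\n%s", yaml::as.yaml(cfg))

  cal <- calibration(cfg$calibration$um_per_px)
  cells <- read_cell_records(cfg$paths$cells)
  meta <- read_slide_meta(cfg$paths$slides)

  say("quantifying %d slides", nrow(meta))
  quant <- quantify_slides(
    cells, meta, cal,
    dedup_radius_px = cfg$dedup$radius_px,
    knot_radius_px = cfg$knots$isolation_radius_px,
    knot_min_cluster = cfg$knots$min_cluster,
    patch_w_px = cfg$area$patch_w_px, patch_h_px = cfg$area$patch_h_px,
    n_regions = cfg$regions$n_regions,
    exclude_slides = cfg$qc$exclude_slides,
    min_records = cfg$qc$min_records
  )
  meta <- quant$meta
  control_ids <- meta$slide_id[meta$category == "control"]
  if (length(control_ids) < 2) {
    stop("stage reference: need >= 2 quantified control slides, have ",
         length(control_ids), call. = FALSE)
  }

  say("building reference and bootstrap nulls (%d control slides)",
      length(control_ids))
  zero <- cfg$zero$strategy
  delta <- cfg$zero$delta
  dev <- deviation_analysis(
    quant, control_ids,
    reference_method = cfg$reference$method,
    n_boot = cfg$bootstrap$n_boot, percentile = cfg$bootstrap$percentile,
    pairing = cfg$bootstrap$pairing, seed = cfg$seed,
    zero_strategy = zero, delta = delta
  )
  deviation <- dev$deviation

  say("group statistics")
  stats_out <- group_statistics(deviation, quant, meta,
                                method = cfg$stats$correlation_method,
                                density_labels = cfg$stats$density_labels)

  la_out <- list()
  if (!is.null(out_dir) && cfg$la$max_slides > 0) {
    lesion_ids <- meta$slide_id[meta$category == "lesion_present"]
    pick <- head(sort(lesion_ids), cfg$la$max_slides)
    for (sid in pick) {
      rec <- cells[cells$slide_id == sid, , drop = FALSE]
      for (target in cfg$la$targets) {
        grid <- local_autocorrelation(rec, target, cal, nx = cfg$la$nx,
                                      ny = cfg$la$ny,
                                      radius_um = cfg$la$radius_um,
                                      min_cells = cfg$la$min_cells)
        la_out[[paste(sid, target, sep = "_")]] <- list(
          slide_id = sid, target = target,
          masked_fraction = mean(grid$mask),
          mean_la = mean(grid$values, na.rm = TRUE),
          grid = grid
        )
      }
    }
  }

  report <- list(
    config = cfg,
    qc = quant$qc,
    n_slides = length(quant$slides),
    thresholds = list(
      cell = dev$null_cell$threshold,
      structure = dev$null_structure$threshold,
      percentile = cfg$bootstrap$percentile,
      n_boot = cfg$bootstrap$n_boot,
      pairing = cfg$bootstrap$pairing,
      seed = cfg$seed,
      zero_strategy = zero,
      reference_method = cfg$reference$method
    ),
    deviation = deviation,
    group_rates = stats_out$group_rates,
    ks_tests = stats_out$ks_tests,
    density_tests = stats_out$density_tests,
    correlations = stats_out$correlations,
    la_summaries = lapply(la_out, function(e) e[c("slide_id", "target",
                                                  "masked_fraction",
                                                  "mean_la")])
  )

  if (!is.null(out_dir)) {
    say("writing report to %s", out_dir)
    write_report(report, dev, la_out, out_dir, cfg)
  }
  invisible(report)
}

# Reference, nulls, and deviation table for both vocabularies.
deviation_analysis <- function(quant, control_ids,
                               reference_method = "arithmetic",
                               n_boot = 10000, percentile = 95,
                               pairing = "any_distinct", seed = 1,
                               zero_strategy = "multiplicative",
                               delta = NULL) {
  out <- list()
  for (vocab in c("cell", "structure")) {
    slide_comps <- slide_compositions(quant, vocab)
    ctrl_comps <- slide_comps[intersect(control_ids, names(slide_comps))]
    reference <- build_reference(ctrl_comps, method = reference_method)
    reg <- region_compositions(quant, control_ids, vocab)
    null <- bootstrap_null(reg$comps, reg$slide_ids, n_boot = n_boot,
                           percentile = percentile,
                           seed = seed + if (vocab == "cell") 1L else 2L,
                           pairing = pairing, zero_strategy = zero_strategy,
                           delta = delta)
    scores <- score_slides(slide_comps, reference, null,
                           zero_strategy = zero_strategy, delta = delta)
    out[[paste0("reference_", vocab)]] <- reference
    out[[paste0("null_", vocab)]] <- null
    out[[paste0("scores_", vocab)]] <- scores
  }
  deviation <- data.frame(
    slide_id = out$scores_cell$slide_id,
    d_cell = out$scores_cell$distance,
    sig_cell = out$scores_cell$significant,
    d_structure = out$scores_structure$distance,
    sig_structure = out$scores_structure$significant,
    stringsAsFactors = FALSE
  )
  c(out, list(deviation = deviation))
}

# KS tests, density MWU tests with Bonferroni families per label,
# correlations, and per-group significance rates with LOO stability.
group_statistics <- function(deviation, quant, meta, method = "spearman",
                             density_labels = character(0)) {
  merged <- merge(deviation, meta, by = "slide_id")
  lesion_sets <- parse_lesions(merged$lesions)
  groups <- list(control = which(merged$category == "control"),
                 no_apparent_lesion =
                   which(merged$category == "no_apparent_lesion"))
  for (lt in LESION_TYPES) {
    idx <- which(vapply(lesion_sets, function(l) lt %in% l, logical(1)) &
                   merged$category == "lesion_present")
    if (length(idx) > 0) groups[[lt]] <- idx
  }

  group_rates <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    row <- data.frame(
      group = g, n = length(idx),
      pct_sig_cell = 100 * mean(merged$sig_cell[idx]),
      pct_sig_structure = 100 * mean(merged$sig_structure[idx]),
      pct_sig_both = 100 * mean(merged$sig_cell[idx] &
                                  merged$sig_structure[idx]),
      loo_cell_lo = NA_real_, loo_cell_hi = NA_real_,
      loo_structure_lo = NA_real_, loo_structure_hi = NA_real_,
      stringsAsFactors = FALSE
    )
    if (length(idx) >= 2) {
      lc <- loo_significance(merged$sig_cell[idx])
      ls <- loo_significance(merged$sig_structure[idx])
      row$loo_cell_lo <- lc$range[1]
      row$loo_cell_hi <- lc$range[2]
      row$loo_structure_lo <- ls$range[1]
      row$loo_structure_hi <- ls$range[2]
    }
    row
  }))

  ctrl <- groups$control
  ks_tests <- list()
  for (g in setdiff(names(groups), "control")) {
    idx <- groups[[g]]
    if (length(idx) == 0 || length(ctrl) == 0) next
    for (col in c("d_cell", "d_structure")) {
      ks_tests[[paste(g, col, sep = "_")]] <-
        ks_two_sample(merged[[col]][idx], merged[[col]][ctrl],
                      group_a = g, group_b = "control", metric = col)
    }
  }

  density_tests <- list()
  dens_cell <- density_table(quant, "cell")
  dens_struct <- density_table(quant, "structure")
  for (label in density_labels) {
    tab <- if (label %in% CELL_TYPES) dens_cell else dens_struct
    sub <- merge(tab[tab$label == label, , drop = FALSE],
                 merged[, c("slide_id", "category", "lesions")],
                 by = "slide_id")
    fam <- list()
    for (g in setdiff(names(groups), "control")) {
      ids_g <- merged$slide_id[groups[[g]]]
      ids_c <- merged$slide_id[ctrl]
      xg <- sub$density[sub$slide_id %in% ids_g]
      xc <- sub$density[sub$slide_id %in% ids_c]
      if (length(xg) == 0 || length(xc) == 0) next
      fam[[g]] <- mann_whitney(xg, xc, group_a = g, group_b = "control",
                               metric = paste0("density(", label, ")"))
    }
    # Bonferroni family: all comparisons for one label
    if (length(fam) > 0) {
      adj <- bonferroni(vapply(fam, `[[`, numeric(1), "p_value"),
                        m = length(fam))
      for (i in seq_along(fam)) fam[[i]]$p_adjusted <- unname(adj[i])
      fam_m <- length(fam)
      for (i in seq_along(fam)) fam[[i]]$family_size <- fam_m
    }
    density_tests[[label]] <- fam
  }

  correlations <- list()
  for (lt in intersect(LESION_TYPES, names(groups))) {
    for (col in c("d_cell", "d_structure")) {
      correlations[[paste("coverage", lt, col, sep = "_")]] <-
        coverage_correlation(deviation, meta, lt, distance_col = col,
                             method = method)
    }
  }
  for (col in c("d_cell", "d_structure")) {
    correlations[[paste("intra_placenta", col, sep = "_")]] <-
      intra_placenta_correlation(deviation, meta, distance_col = col,
                                 method = method)
  }

  list(group_rates = group_rates, ks_tests = ks_tests,
       density_tests = density_tests, correlations = correlations)
}

write_report <- function(report, dev, la_out, out_dir, cfg) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "figures"), recursive = TRUE,
             showWarnings = FALSE)

  # machine-readable report: strip the heavy grid objects
  json_report <- report
  json_report$ks_tests <- lapply(report$ks_tests, unclass)
  json_report$density_tests <- lapply(report$density_tests,
                                      function(fam) lapply(fam, unclass))
  json_report$correlations <- lapply(report$correlations, unclass)
  jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  writeLines(yaml::as.yaml(cfg), file.path(out_dir, "config_used.yaml"))

  write.csv(report$deviation, file.path(out_dir, "tables", "deviation.csv"),
            row.names = FALSE)
  write.csv(report$group_rates,
            file.path(out_dir, "tables", "group_rates.csv"),
            row.names = FALSE)
  write.csv(data.frame(d = dev$null_cell$distances),
            file.path(out_dir, "tables", "null_cell.csv"), row.names = FALSE)
  write.csv(data.frame(d = dev$null_structure$distances),
            file.path(out_dir, "tables", "null_structure.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$thresholds,
                       file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  for (nm in names(la_out)) {
    entry <- la_out[[nm]]
    smoothed <- smooth_gaussian(entry$grid, cfg$la$sigma_cells)
    export_heatmap(smoothed,
                   file.path(out_dir, "figures", paste0("la_", nm, ".png")),
                   file.path(out_dir, "figures",
                             paste0("la_", nm, "_smoothed.csv")))
    # quantitative matrix: unsmoothed
    export_heatmap(entry$grid,
                   file.path(out_dir, "figures",
                             paste0("la_", nm, "_raw.png")),
                   file.path(out_dir, "figures", paste0("la_", nm, ".csv")))
  }

  md <- c(
    "# Compositional deviation report", "",
    sprintf("Slides quantified: %d; excluded by QC: %d", report$n_slides,
            nrow(report$qc)),
    sprintf("Significance thresholds (%gth pct of %d bootstrap draws, seed %d):",
            report$thresholds$percentile, report$thresholds$n_boot,
            report$thresholds$seed),
    sprintf("  cell d_A = %.4f, structure d_A = %.4f",
            report$thresholds$cell, report$thresholds$structure), "",
    "## Group significance rates", "",
    paste(capture.output(print(report$group_rates, row.names = FALSE)),
          collapse = "\n"), "",
    "## KS tests vs control", ""
  )
  for (nm in names(report$ks_tests)) {
    t <- report$ks_tests[[nm]]
    md <- c(md, sprintf("- %s [%s]: D=%.3f, p=%.3g (n=%d vs %d)",
                        t$group_a, t$metric, t$statistic, t$p_value, t$n_a,
                        t$n_b))
  }
  md <- c(md, "", "## Correlations", "")
  for (nm in names(report$correlations)) {
    r <- report$correlations[[nm]]
    md <- c(md, if (isTRUE(r$computable)) {
      sprintf("- %s: r=%.3f, p=%.3g (n=%d)", nm, r$r, r$p_value, r$n)
    } else {
      sprintf("- %s: not computable (%s)", nm, r$reason)
    })
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
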