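# Local autocorrelation mapping: LA(i) = (1/n_i) * sum_{j in N_i} delta_j,
# where N_i is the set of cells within a fixed physical radius of grid point
# i and delta_j indicates membership of the target class.

#' Local autocorrelation grid of a target class
#'
#' Lays an `nx` x `ny` grid over the records' bounding box and, at each grid
#' square centre, computes the fraction of cells within `radius_um` that
#' belong to the target class. Grid squares with fewer than `min_cells`
#' neighbours are masked (excluded from analysis, transparent in renderings).
#' The neighbourhood search is exact (equal to brute force within floating
#' tolerance).
#'
#' @param records validated cell-record data.frame (one slide).
#' @param target a label from the cell or structure vocabulary; matched
#'   against the corresponding column.
#' @param cal a [calibration()] to convert the radius to pixels.
#' @param nx,ny grid dimensions (default 150 x 150).
#' @param radius_um neighbourhood radius in micrometres (default 200).
#' @param min_cells minimum neighbourhood size for an unmasked value
#'   (default 5).
#' @return An `la_grid` object: `values` (`ny` x `nx` matrix in `[0, 1]`,
#'   `NA` where masked), `counts`, `mask`, grid geometry (`gx`, `gy` centre
#'   coordinates in px), `radius_um`, `target`, `min_cells`.
#' @export
local_autocorrelation <- function(records, target, cal = calibration(),
                                  nx = 150, ny = 150, radius_um = 200,
                                  min_cells = 5) {
  stopifnot(nrow(records) > 0, nx >= 1, ny >= 1, radius_um > 0,
            min_cells >= 0)
  target <- canonical_label(target)
  if (target %in% CELL_TYPES) {
    is_target <- records$cell_type == target
  } else if (target %in% STRUCTURE_TYPES) {
    is_target <- records$structure_type == target
  } else {
    stop("unknown target label: ", target, call. = FALSE)
  }
  radius_px <- radius_um / cal$um_per_px
  xr <- range(records$x)
  yr <- range(records$y)
  cw <- (xr[2] - xr[1]) / nx
  ch <- (yr[2] - yr[1]) / ny
  gx <- xr[1] + (seq_len(nx) - 0.5) * cw
  gy <- yr[1] + (seq_len(ny) - 0.5) * ch
  res <- cpp_la_counts(records$x, records$y, as.integer(is_target),
                       gx, gy, radius_px)
  counts <- res$counts
  values <- ifelse(counts > 0, res$hits / pmax(counts, 1L), NA_real_)
  mask <- counts < min_cells
  values[mask] <- NA_real_
  structure(list(values = values, counts = counts, mask = mask,
                 gx = gx, gy = gy, nx = nx, ny = ny,
                 radius_um = radius_um, radius_px = radius_px,
                 target = target, min_cells = min_cells),
            class = "la_grid")
}

#' @export
print.la_grid <- function(x, ...) {
  cat(sprintf(
    "la_grid: %dx%d, target '%s', radius %g um, %d/%d squares masked (<%d cells)\n",
    x$nx, x$ny, x$target, x$radius_um, sum(x$mask), length(x$mask),
    x$min_cells))
  invisible(x)
}

#' Mask-aware Gaussian smoothing of an LA grid
#'
#' Normalised Gaussian convolution in grid-cell units: masked squares
#' contribute zero weight and remain masked, so no value bleeds across the
#' mask, and unmasked values stay within the convex hull of their
#' neighbours (hence in `[0, 1]`). `sigma_cells = 0` returns the grid
#' unchanged. Intended for visualisation; quantitative outputs should use
#' the unsmoothed grid.
#'
#' @param grid an [local_autocorrelation()] result.
#' @param sigma_cells Gaussian standard deviation in grid cells.
#' @return An `la_grid` with smoothed `values`.
#' @export
smooth_gaussian <- function(grid, sigma_cells = 1.5) {
  stopifnot(inherits(grid, "la_grid"))
  if (sigma_cells < 0) stop("sigma_cells must be >= 0", call. = FALSE)
  if (sigma_cells == 0) return(grid)
  h <- max(1L, ceiling(3 * sigma_cells))
  offsets <- -h:h
  kernel <- outer(dnorm(offsets, sd = sigma_cells),
                  dnorm(offsets, sd = sigma_cells))
  v <- grid$values
  w <- !grid$mask
  v[is.na(v)] <- 0
  acc <- matrix(0, nrow(v), ncol(v))
  wacc <- matrix(0, nrow(v), ncol(v))
  nr <- nrow(v)
  nc <- ncol(v)
  for (di in seq_along(offsets)) {
    for (dj in seq_along(offsets)) {
      oi <- offsets[di]
      oj <- offsets[dj]
      ri <- max(1, 1 - oi):min(nr, nr - oi)
      rj <- max(1, 1 - oj):min(nc, nc - oj)
      k <- kernel[di, dj]
      acc[ri, rj] <- acc[ri, rj] + k * v[ri + oi, rj + oj]
      wacc[ri, rj] <- wacc[ri, rj] + k * w[ri + oi, rj + oj]
    }
  }
  out <- grid
  sm <- acc / wacc
  sm[grid$mask | wacc == 0] <- NA_real_
  out$values <- sm
  out
}

#' Export an LA grid as a heatmap image and a matrix file
#'
#' Writes a PNG raster with a diverging colormap (low values blue, high
#' values red) in which masked squares are fully transparent, plus a
#' plain-text CSV matrix (`NA` for masked squares) that round-trips the grid
#' values exactly.
#'
#' @param grid an [la_grid()] (optionally smoothed).
#' @param png_path output PNG path.
#' @param csv_path output CSV path (default: `png_path` with extension
#'   swapped).
#' @param colormap character vector of colours for the diverging ramp.
#' @param with_outline if `TRUE`, unmasked squares bordering the mask are
#'   darkened to outline the tissue.
#' @return Invisibly, the two paths.
#' @export
export_heatmap <- function(grid, png_path,
                           csv_path = sub("\\.png$", ".csv", png_path),
                           colormap = c("#2166AC", "#F7F7F7", "#B2182B"),
                           with_outline = FALSE) {
  stopifnot(inherits(grid, "la_grid"))
  v <- grid$values
  # exact round-trip: full precision text matrix
  txt <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))
  txt[is.na(v)] <- "NA"
  ok <- tryCatch({
    writeLines(apply(txt, 1, paste, collapse = ","), csv_path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write ", csv_path, ": ", conditionMessage(ok), call. = FALSE)
  }

  ramp <- colorRampPalette(colormap)(256)
  idx <- pmin(255L, pmax(0L, as.integer(round(v * 255)))) + 1L
  rgb_vals <- col2rgb(ramp) / 255
  nr <- nrow(v)
  nc <- ncol(v)
  img <- array(0, dim = c(nr, nc, 4))
  fill <- !is.na(v)
  for (ch in 1:3) {
    plane <- matrix(0, nr, nc)
    plane[fill] <- rgb_vals[ch, idx[fill]]
    img[, , ch] <- plane
  }
  alpha <- matrix(0, nr, nc)
  alpha[fill] <- 1
  if (with_outline && any(fill) && any(!fill)) {
    edge <- fill & !(shift_mat(fill, 1, 0) & shift_mat(fill, -1, 0) &
                       shift_mat(fill, 0, 1) & shift_mat(fill, 0, -1))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[edge] <- plane[edge] * 0.4
      img[, , ch] <- plane
    }
  }
  img[, , 4] <- alpha
  ok <- tryCatch({
    png::writePNG(img, png_path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write ", png_path, ": ", conditionMessage(ok), call. = FALSE)
  }
  invisible(c(png = png_path, csv = csv_path))
}

# logical shift with FALSE padding
shift_mat <- function(m, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  ri <- max(1, 1 + di):min(nrow(m), nrow(m) + di)
  rj <- max(1, 1 + dj):min(ncol(m), ncol(m) + dj)
  out[ri, rj] <- m[ri - di, rj - dj]
  out
}

#' Read back a heatmap matrix file
#'
#' @param csv_path path written by [export_heatmap()].
#' @return Numeric matrix with `NA` for masked squares.
#' @export
read_heatmap_matrix <- function(csv_path) {
  rows <- strsplit(readLines(csv_path), ",", fixed = TRUE)
  t(vapply(rows, function(r) as.numeric(ifelse(r == "NA", NA, r)),
           numeric(length(rows[[1]]))))
}
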