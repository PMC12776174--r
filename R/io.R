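# Tabular interchange formats.
#
# cells table:  slide_id,x,y,cell_type,structure_type,confidence
# slides table: slide_id,patient_id,site,category,lesions,coverage_percent,
#               width_px,height_px
# Delimiter by extension (.tsv/.tab/.txt -> tab, otherwise comma), UTF-8,
# header row mandatory. Lesions are semicolon-joined tokens in one column.

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.table(path, header = TRUE, sep = delim_for(path),
             stringsAsFactors = FALSE, check.names = FALSE,
             quote = "\"", comment.char = "", na.strings = c("NA", ""),
             fileEncoding = "UTF-8")
}

write_delim_auto <- function(df, path) {
  # full-precision numeric text so read(write(x)) is exact
  for (i in seq_along(df)) {
    if (is.double(df[[i]])) {
      s <- sprintf("%.17g", df[[i]])
      s[is.na(df[[i]])] <- NA
      df[[i]] <- s
    }
  }
  ok <- tryCatch({
    write.table(df, path, sep = delim_for(path), row.names = FALSE,
                col.names = TRUE, quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Validate a table of per-nucleus cell records
#'
#' Checks the schema of a cell-record table (one row per detected nucleus),
#' canonicalises the two classification labels against the fixed
#' vocabularies, enforces nonnegative coordinates and confidence in `[0, 1]`,
#' and fills a missing confidence column with 1.0.
#'
#' @param df data.frame with columns `slide_id`, `x`, `y`, `cell_type`,
#'   `structure_type` and optionally `confidence`.
#' @return The validated data.frame, row order preserved.
#' @export
validate_cells <- function(df) {
  require_columns(df, c("slide_id", "x", "y", "cell_type", "structure_type"),
                  "cell records")
  df$slide_id <- as.character(df$slide_id)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  if (anyNA(df$x) || anyNA(df$y)) {
    stop("non-numeric or missing coordinate at row(s) ",
         paste(head(which(is.na(df$x) | is.na(df$y)), 5L), collapse = ", "),
         call. = FALSE)
  }
  neg <- which(df$x < 0 | df$y < 0)
  if (length(neg) > 0) {
    stop("negative coordinate at row(s) ", paste(head(neg, 5L), collapse = ", "),
         call. = FALSE)
  }
  df$cell_type <- match_vocabulary(df$cell_type, CELL_TYPES, "cell_type")
  df$structure_type <- match_vocabulary(df$structure_type, STRUCTURE_TYPES,
                                        "structure_type")
  if (is.null(df$confidence)) {
    df$confidence <- rep(1.0, nrow(df))
  } else {
    df$confidence <- as.numeric(df$confidence)
    df$confidence[is.na(df$confidence)] <- 1.0
    bad <- which(df$confidence < 0 | df$confidence > 1)
    if (length(bad) > 0) {
      stop("confidence outside [0,1] at row(s) ",
           paste(head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df[, c("slide_id", "x", "y", "cell_type", "structure_type", "confidence")]
}

#' Read and write per-nucleus cell records
#'
#' Delimiter-separated text with a header row; comma or tab is chosen by file
#' extension. Unknown labels and negative coordinates are rejected with the
#' offending row numbers; row order is preserved, so
#' `read_cell_records(write_cell_records(r, path))` is the identity.
#'
#' @param path file path (`.csv` comma, `.tsv`/`.tab`/`.txt` tab).
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(x = "pos_x")`.
#' @return `read_cell_records`: validated data.frame of cell records.
#' @export
read_cell_records <- function(path, schema = NULL) {
  df <- read_delim_auto(path)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(df)) {
        names(df)[names(df) == schema[[canon]]] <- canon
      }
    }
  }
  validate_cells(df)
}

#' @rdname read_cell_records
#' @param records data.frame of cell records (validated on write).
#' @export
write_cell_records <- function(records, path) {
  records <- validate_cells(records)
  write_delim_auto(records, path)
}

#' Validate a slide metadata table
#'
#' Enforces the category/lesion consistency rules: `control` slides must list
#' no lesions and `lesion_present` slides must list at least one; lesion
#' tokens are semicolon-joined in one column and validated against the four
#' lesion labels; `coverage_percent`, when present, must lie in `[0, 100]`.
#'
#' @param df data.frame with columns `slide_id`, `patient_id`, `site`,
#'   `category`, `lesions`, and optionally `coverage_percent`, `width_px`,
#'   `height_px`.
#' @return The validated data.frame.
#' @export
validate_slide_meta <- function(df) {
  require_columns(df, c("slide_id", "patient_id", "site", "category", "lesions"),
                  "slide metadata")
  df$slide_id <- as.character(df$slide_id)
  df$patient_id <- as.character(df$patient_id)
  df$site <- as.character(df$site)
  df$category <- match_vocabulary(df$category, SLIDE_CATEGORIES, "category")
  df$lesions <- as.character(df$lesions)
  df$lesions[is.na(df$lesions)] <- ""
  lesion_sets <- parse_lesions(df$lesions)
  df$lesions <- vapply(lesion_sets, paste, character(1), collapse = ";")
  n_lesions <- lengths(lesion_sets)
  bad_ctrl <- which(df$category == "control" & n_lesions > 0)
  if (length(bad_ctrl) > 0) {
    stop("control slide with nonempty lesions at row(s) ",
         paste(head(bad_ctrl, 5L), collapse = ", "), call. = FALSE)
  }
  bad_les <- which(df$category == "lesion_present" & n_lesions == 0)
  if (length(bad_les) > 0) {
    stop("lesion_present slide with empty lesions at row(s) ",
         paste(head(bad_les, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(df$coverage_percent)) {
    df$coverage_percent <- as.numeric(df$coverage_percent)
    bad_cov <- which(!is.na(df$coverage_percent) &
                       (df$coverage_percent < 0 | df$coverage_percent > 100))
    if (length(bad_cov) > 0) {
      stop("coverage_percent outside [0,100] at row(s) ",
           paste(head(bad_cov, 5L), collapse = ", "), call. = FALSE)
    }
  } else {
    df$coverage_percent <- rep(NA_real_, nrow(df))
  }
  for (col in c("width_px", "height_px")) {
    df[[col]] <- if (is.null(df[[col]])) rep(NA_real_, nrow(df)) else
      as.numeric(df[[col]])
  }
  dup <- df$slide_id[duplicated(df$slide_id)]
  if (length(dup) > 0) {
    stop("duplicated slide_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  df[, c("slide_id", "patient_id", "site", "category", "lesions",
         "coverage_percent", "width_px", "height_px")]
}

parse_lesions <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(tokens) {
    tokens <- tokens[nzchar(trimws(tokens))]
    if (length(tokens) == 0) return(character(0))
    unique(match_vocabulary(tokens, LESION_TYPES, "lesion"))
  })
}

#' Read and write slide metadata
#'
#' @inheritParams read_cell_records
#' @return `read_slide_meta`: validated data.frame of slide metadata.
#' @export
read_slide_meta <- function(path) {
  validate_slide_meta(read_delim_auto(path))
}

#' @rdname read_slide_meta
#' @param meta data.frame of slide metadata (validated on write).
#' @export
write_slide_meta <- function(meta, path) {
  meta <- validate_slide_meta(meta)
  write_delim_auto(meta, path)
}
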