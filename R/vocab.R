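# Controlled vocabularies for the two classification heads.
# Sizes (11 cells, 9 structures) are fixed contracts; tests guard against drift.

CELL_TYPES <- c(
  "syncytiotrophoblast", "cytotrophoblast", "syncytial_knot",
  "extravillous_trophoblast", "fibroblast", "hofbauer_cell",
  "vascular_endothelial_cell", "vascular_myocyte",
  "undifferentiated_mesenchymal_cell", "maternal_decidual_cell", "leukocyte"
)

STRUCTURE_TYPES <- c(
  "stem_villi", "anchoring_villi", "mature_intermediate_villi",
  "terminal_villi", "villous_sprouts", "chorionic_plate",
  "basal_plate_septum", "fibrin", "avascular_villi"
)

PLATE_STRUCTURES <- c("chorionic_plate", "basal_plate_septum")
PARENCHYMA_STRUCTURES <- setdiff(STRUCTURE_TYPES, PLATE_STRUCTURES)

LESION_TYPES <- c(
  "infarction", "perivillous_fibrin", "intervillous_thrombosis",
  "avascular_villi"
)

SLIDE_CATEGORIES <- c("control", "no_apparent_lesion", "lesion_present")

#' Controlled vocabularies
#'
#' The fixed classification vocabularies used throughout the package: 11 cell
#' types and 9 tissue structures, plus the four focal lesion labels and the
#' three slide categories.
#'
#' @return A character vector of canonical labels.
#' @examples
#' cell_types()
#' structure_types()
#' @export
cell_types <- function() CELL_TYPES

#' @rdname cell_types
#' @export
structure_types <- function() STRUCTURE_TYPES

#' @rdname cell_types
#' @export
lesion_types <- function() LESION_TYPES

#' @rdname cell_types
#' @export
slide_categories <- function() SLIDE_CATEGORIES

#' Canonicalise labels
#'
#' Trims whitespace, lowercases, and converts internal spaces/hyphens to
#' underscores so cosmetic variants ("Leukocyte ", "hofbauer-cell") map onto
#' the canonical vocabulary without silent aliasing.
#'
#' @param x character vector of labels.
#' @return character vector of canonical labels (not validated).
#' @export
canonical_label <- function(x) {
  x <- trimws(as.character(x))
  x <- tolower(x)
  x <- gsub("[ -]+", "_", x)
  x
}

# Canonicalise then validate against a vocabulary; errors cite the offending
# row numbers and labels.
match_vocabulary <- function(x, vocabulary, what = "label") {
  x <- canonical_label(x)
  bad <- which(!(x %in% vocabulary))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s at row(s) %s: %s (allowed: %s)", what,
      paste(head(bad, 5L), collapse = ", "),
      paste(unique(x[head(bad, 5L)]), collapse = ", "),
      paste(vocabulary, collapse = ", ")
    ), call. = FALSE)
  }
  x
}

vocabulary_labels <- function(vocabulary = c("cell", "structure")) {
  vocabulary <- match.arg(vocabulary)
  if (vocabulary == "cell") CELL_TYPES else STRUCTURE_TYPES
}
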