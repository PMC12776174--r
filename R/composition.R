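#' Compositions over a fixed vocabulary
#'
#' A composition is a closed vector of named proportions over exactly one full
#' vocabulary (cell or structure) in fixed order. The total count it was
#' derived from, when known, is kept as an attribute and drives the default
#' zero-replacement value in [clr()].
#'
#' @param values nonnegative numeric vector; closed (divided by its sum) on
#'   construction.
#' @param vocabulary `"cell"`, `"structure"`, or `"custom"` (labels taken from
#'   `names(values)`).
#' @param n_total optional integer: total count behind the proportions.
#' @return An object of class `composition`: named proportions summing to 1.
#' @examples
#' composition(c(a = 3, b = 1), vocabulary = "custom")
#' @export
composition <- function(values, vocabulary = c("cell", "structure", "custom"),
                        n_total = NULL) {
  vocabulary <- match.arg(vocabulary)
  if (vocabulary == "custom") {
    if (is.null(names(values)) || anyDuplicated(names(values))) {
      stop("custom composition needs unique names", call. = FALSE)
    }
    labels <- names(values)
  } else {
    labels <- vocabulary_labels(vocabulary)
    if (is.null(names(values))) {
      if (length(values) != length(labels)) {
        stop("unnamed values must match vocabulary length", call. = FALSE)
      }
      names(values) <- labels
    } else {
      missing <- setdiff(labels, names(values))
      if (length(missing) > 0) {
        stop("missing component(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      values <- values[labels]
    }
  }
  values <- as.numeric(values)
  names(values) <- labels
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("composition values must be finite and nonnegative", call. = FALSE)
  }
  total <- sum(values)
  if (total <= 0) stop("composition has zero total", call. = FALSE)
  structure(values / total,
            class = "composition",
            vocabulary = vocabulary,
            n_total = if (is.null(n_total)) NA_real_ else as.numeric(n_total))
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("composition (%s, n=%s)\n", attr(x, "vocabulary"),
              format(attr(x, "n_total"))))
  print(round(unclass(x), 4))
  invisible(x)
}

comp_values <- function(p) {
  v <- unclass(p)
  attributes(v) <- list(names = names(v))
  v
}

check_same_vocabulary <- function(p, q) {
  if (!identical(names(p), names(q))) {
    stop("compositions are over different vocabularies or orders",
         call. = FALSE)
  }
}

#' Composition of a set of records
#'
#' Proportion of records carrying each label of the chosen vocabulary. Zero
#' counts are allowed here; replacement of zeros is deferred to [clr()].
#'
#' @param records validated cell-record data.frame (see [validate_cells()]).
#' @param vocabulary `"cell"` or `"structure"`.
#' @return A [composition()] with `n_total = nrow(records)`.
#' @export
compute_composition <- function(records, vocabulary = c("cell", "structure")) {
  vocabulary <- match.arg(vocabulary)
  if (nrow(records) == 0) {
    stop("cannot compute a composition from zero records", call. = FALSE)
  }
  labels <- vocabulary_labels(vocabulary)
  col <- if (vocabulary == "cell") "cell_type" else "structure_type"
  counts <- table(factor(records[[col]], levels = labels))
  composition(as.numeric(counts) / nrow(records), vocabulary,
              n_total = nrow(records))
}
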