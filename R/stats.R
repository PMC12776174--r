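# Group-level statistics: two-sample KS on distance distributions,
# Mann-Whitney U on densities, Spearman rank correlations, Bonferroni
# correction, and the two correlation analyses (lesion coverage vs distance,
# intra-placenta paired averages).

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test on two samples of Aitchison distances (or any
#' continuous metric): the statistic is the maximum absolute difference of
#' the two empirical CDFs.
#'
#' @param x,y nonempty numeric samples.
#' @param group_a,group_b optional labels carried into the result.
#' @param metric optional metric label.
#' @return list of class `group_comparison` with fields `test`, `statistic`,
#'   `p_value`, `n_a`, `n_b`, `group_a`, `group_b`, `metric`.
#' @export
ks_two_sample <- function(x, y, group_a = "a", group_b = "b",
                          metric = "distance") {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  res <- suppressWarnings(ks.test(x, y, alternative = "two.sided"))
  structure(list(test = "ks_two_sample",
                 statistic = unname(res$statistic),
                 p_value = unname(res$p.value),
                 n_a = length(x), n_b = length(y),
                 group_a = group_a, group_b = group_b, metric = metric),
            class = "group_comparison")
}

#' Two-sample Mann-Whitney U test
#'
#' U statistic for `x` against `y` (number of pairs with `x > y`, ties
#' counting one half). The p-value is exact by enumeration when
#' `n_a * n_b <= 400` and the data are tie-free, and uses the tie-corrected
#' normal approximation otherwise.
#'
#' @inheritParams ks_two_sample
#' @param alternative passed to [stats::wilcox.test()].
#' @return A `group_comparison` (statistic is U).
#' @export
mann_whitney <- function(x, y, alternative = "two.sided", group_a = "a",
                         group_b = "b", metric = "density") {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) * length(y) <= 400) && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = !exact)
  )
  structure(list(test = "mann_whitney",
                 statistic = unname(res$statistic),
                 p_value = unname(res$p.value),
                 n_a = length(x), n_b = length(y),
                 group_a = group_a, group_b = group_b, metric = metric),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s [%s]: %s (n=%d) vs %s (n=%d): stat=%.4g, p=%.3g%s\n",
              x$test, x$metric, x$group_a, x$n_a, x$group_b, x$n_b,
              x$statistic, x$p_value,
              if (!is.null(x$p_adjusted)) sprintf(" (adj %.3g)", x$p_adjusted)
              else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with a two-sided t-approximation
#' p-value. Constant input leaves the coefficient undefined (`NA`), which is
#' reported as such rather than as zero.
#'
#' @param x,y paired numeric samples, `n >= 3`.
#' @return list of class `correlation_result`: `method`, `r`, `p_value`,
#'   `n`, `computable`.
#' @export
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    return(structure(list(method = "spearman", r = NA_real_,
                          p_value = NA_real_, n = n, computable = FALSE,
                          reason = "fewer than 3 complete pairs"),
                     class = "correlation_result"))
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(structure(list(method = "spearman", r = NA_real_,
                          p_value = NA_real_, n = n, computable = FALSE,
                          reason = "constant input"),
                     class = "correlation_result"))
  }
  r <- cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(method = "spearman", r = r, p_value = p, n = n,
                 computable = TRUE),
            class = "correlation_result")
}

#' Pearson correlation (companion to [spearman_cor()])
#'
#' @inheritParams spearman_cor
#' @return A `correlation_result`.
#' @export
pearson_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(structure(list(method = "pearson", r = NA_real_,
                          p_value = NA_real_, n = n, computable = FALSE,
                          reason = if (n < 3) "fewer than 3 complete pairs"
                          else "constant input"),
                     class = "correlation_result"))
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(method = "pearson", r = r, p_value = p, n = n,
                 computable = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (isTRUE(x$computable)) {
    cat(sprintf("%s correlation: r=%.3f, p=%.3g, n=%d\n", x$method, x$r,
                x$p_value, x$n))
  } else {
    cat(sprintf("%s correlation: not computable (%s), n=%d\n", x$method,
                x$reason, x$n))
  }
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size `m` and caps at 1. The family
#' size may exceed the number of supplied tests (when some family members
#' are reported elsewhere) but never be smaller.
#'
#' @param p_values numeric vector of raw p-values.
#' @param m family size (default: number of tests).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    stop("family size m must be >= number of tests", call. = FALSE)
  }
  pmin(1, p_values * m)
}

#' Correlation of lesion coverage with compositional deviation
#'
#' For slides carrying the given lesion type and a coverage estimate,
#' correlates the coverage percentage with the slide's Aitchison distance.
#' Fewer than 3 eligible slides or constant coverage yield a first-class
#' "not computable" result rather than an error (some lesion types never
#' cover enough of a slide for binned estimates).
#'
#' @param deviation data.frame with `slide_id` and the distance column.
#' @param meta validated slide metadata.
#' @param lesion_type one of [lesion_types()].
#' @param distance_col column of `deviation` to use (e.g. `"d_cell"`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `correlation_result` with `n_excluded` (slides of the type
#'   lacking coverage).
#' @export
coverage_correlation <- function(deviation, meta, lesion_type,
                                 distance_col = "d_cell",
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  lesion_type <- match_vocabulary(lesion_type, LESION_TYPES, "lesion_type")
  has_lesion <- vapply(parse_lesions(meta$lesions), function(l) {
    lesion_type %in% l
  }, logical(1))
  eligible <- meta[has_lesion & meta$category == "lesion_present", ,
                   drop = FALSE]
  merged <- merge(eligible[, c("slide_id", "coverage_percent")], deviation,
                  by = "slide_id")
  n_excluded <- sum(is.na(merged$coverage_percent))
  merged <- merged[!is.na(merged$coverage_percent), , drop = FALSE]
  fn <- if (method == "spearman") spearman_cor else pearson_cor
  res <- fn(merged$coverage_percent, merged[[distance_col]])
  res$kind <- "coverage_vs_distance"
  res$lesion_type <- lesion_type
  res$distance_col <- distance_col
  res$n_excluded <- n_excluded
  res
}

#' Intra-placenta correlation of paired average deviations
#'
#' For each patient contributing both a "no apparent lesion" slide and a
#' lesion-present slide, averages the Aitchison distance within each
#' category and correlates the two averages across patients (one point per
#' patient). Fewer than 3 eligible patients yields a "not computable"
#' result.
#'
#' @inheritParams coverage_correlation
#' @return A `correlation_result` with `n_patients`.
#' @export
intra_placenta_correlation <- function(deviation, meta,
                                       distance_col = "d_cell",
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  merged <- merge(meta[, c("slide_id", "patient_id", "category")], deviation,
                  by = "slide_id")
  nal <- merged[merged$category == "no_apparent_lesion", , drop = FALSE]
  les <- merged[merged$category == "lesion_present", , drop = FALSE]
  patients <- intersect(unique(nal$patient_id), unique(les$patient_id))
  if (length(patients) < 3) {
    return(structure(list(method = method, r = NA_real_, p_value = NA_real_,
                          n = length(patients), computable = FALSE,
                          reason = "fewer than 3 patients with both slide types",
                          kind = "intra_placenta_paired",
                          n_patients = length(patients)),
                     class = "correlation_result"))
  }
  avg <- function(df, pid) mean(df[[distance_col]][df$patient_id == pid])
  x <- vapply(patients, avg, numeric(1), df = nal)
  y <- vapply(patients, avg, numeric(1), df = les)
  fn <- if (method == "spearman") spearman_cor else pearson_cor
  res <- fn(x, y)
  res$method <- method
  res$kind <- "intra_placenta_paired"
  res$distance_col <- distance_col
  res$n_patients <- length(patients)
  res
}
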