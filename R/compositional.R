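# Compositional deviation machinery: CLR transform, Aitchison distance,
# healthy reference, bootstrap null with percentile threshold, per-slide
# deviation flags, leave-one-out stability.

# Replace zeros so the log-ratio is defined.
#  - multiplicative: zeros -> delta, nonzero parts shrunk by (1 - z*delta),
#    then re-closed; delta defaults to 0.5/n_total when the composition
#    carries its count.
#  - pseudocount: add delta to every part, re-close.
replace_zeros <- function(p, zero_strategy = c("multiplicative", "pseudocount",
                                               "none"),
                          delta = NULL) {
  zero_strategy <- match.arg(zero_strategy)
  v <- comp_values(p)
  if (all(v > 0) && zero_strategy != "pseudocount") return(v)
  if (zero_strategy == "none") {
    stop("zero component(s) with no zero strategy: ",
         paste(names(v)[v == 0], collapse = ", "), call. = FALSE)
  }
  if (is.null(delta)) {
    n <- attr(p, "n_total")
    if (is.null(n) || is.na(n)) {
      stop("composition carries no total count; supply delta explicitly",
           call. = FALSE)
    }
    delta <- 0.5 / n
  }
  stopifnot(delta > 0, delta < 1 / length(v))
  if (zero_strategy == "multiplicative") {
    z <- sum(v == 0)
    out <- ifelse(v == 0, delta, v * (1 - z * delta))
  } else {
    out <- v + delta
  }
  out / sum(out)
}

#' Centred log-ratio transform
#'
#' Maps a composition p to `clr(p)_i = ln(p_i / g(p))` where `g(p)` is the
#' geometric mean of the k parts. Components equal to zero are handled first
#' by the chosen strategy (multiplicative replacement by default, with
#' `delta = 0.5 / n_total` when the composition carries its count). The
#' output always sums to zero.
#'
#' @param p a [composition()].
#' @param zero_strategy `"multiplicative"`, `"pseudocount"`, or `"none"`
#'   (error on zeros).
#' @param delta replacement value; default `0.5 / n_total`.
#' @return Named numeric vector of log-ratio coordinates (sums to 0).
#' @examples
#' clr(composition(c(a = 0.8, b = 0.2), "custom")) # c(log(2)/... )
#' @export
clr <- function(p, zero_strategy = c("multiplicative", "pseudocount", "none"),
                delta = NULL) {
  stopifnot(inherits(p, "composition"))
  v <- replace_zeros(p, zero_strategy, delta)
  lg <- log(v)
  lg - mean(lg)
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the CLR-transformed vectors,
#' `d_A(p, q) = sqrt(sum_i (clr(p)_i - clr(q)_i)^2)`. Symmetric, zero iff the
#' compositions agree (after zero handling), and satisfies the triangle
#' inequality.
#'
#' @inheritParams clr
#' @param q a second [composition()] over the same vocabulary and order.
#' @return Nonnegative scalar distance (log-ratio units).
#' @export
aitchison_distance <- function(p, q,
                               zero_strategy = c("multiplicative",
                                                 "pseudocount", "none"),
                               delta = NULL) {
  stopifnot(inherits(p, "composition"), inherits(q, "composition"))
  check_same_vocabulary(p, q)
  zp <- clr(p, zero_strategy, delta)
  zq <- clr(q, zero_strategy, delta)
  sqrt(sum((zp - zq)^2))
}

# CLR-transform a list of compositions into an n x k matrix.
clr_matrix <- function(comps, zero_strategy = "multiplicative", delta = NULL) {
  stopifnot(length(comps) >= 1)
  labels <- names(comps[[1]])
  for (p in comps) {
    if (!identical(names(p), labels)) {
      stop("compositions are over different vocabularies or orders",
           call. = FALSE)
    }
  }
  t(vapply(comps, clr, numeric(length(labels)),
           zero_strategy = zero_strategy, delta = delta))
}

#' Healthy reference composition
#'
#' Builds the mean healthy reference from control-slide compositions. The
#' default is the component-wise arithmetic mean followed by closure;
#' `"clr_mean"` instead averages in CLR space and back-transforms, i.e. the
#' compositional geometric mean.
#'
#' @param control_comps list of [composition()]s from control slides (>= 2).
#' @param method `"arithmetic"` (default) or `"clr_mean"`.
#' @param ... passed to [clr()] for the `"clr_mean"` method.
#' @return A `healthy_reference` object with fields `mean_composition`,
#'   `method`, `n_slides`.
#' @export
build_reference <- function(control_comps, method = c("arithmetic", "clr_mean"),
                            ...) {
  method <- match.arg(method)
  if (length(control_comps) < 2) {
    stop("need at least 2 control compositions", call. = FALSE)
  }
  labels <- names(control_comps[[1]])
  vocab <- attr(control_comps[[1]], "vocabulary")
  mean_n <- mean(vapply(control_comps, function(p) attr(p, "n_total"),
                        numeric(1)))
  if (method == "arithmetic") {
    m <- rowMeans(vapply(control_comps, comp_values, numeric(length(labels))))
  } else {
    z <- colMeans(clr_matrix(control_comps, ...))
    m <- exp(z)
  }
  names(m) <- labels
  ref <- composition(m, if (vocab == "custom") "custom" else vocab,
                     n_total = mean_n)
  structure(list(mean_composition = ref, method = method,
                 n_slides = length(control_comps)),
            class = "healthy_reference")
}

#' @export
print.healthy_reference <- function(x, ...) {
  cat(sprintf("healthy reference (%s mean of %d control slides, %s vocabulary)\n",
              x$method, x$n_slides, attr(x$mean_composition, "vocabulary")))
  print(round(comp_values(x$mean_composition), 4))
  invisible(x)
}

#' Bootstrap null of healthy compositional variation
#'
#' Resamples pairs of healthy regions (with replacement over iterations,
#' uniformly over eligible unordered pairs of distinct regions) and records
#' the Aitchison distance of each draw. The significance threshold is the
#' stated percentile of the sampled distances, computed with the
#' linear-interpolation quantile definition (R type 7). Under the default
#' `"any_distinct"` pairing, same-slide region pairs are allowed — intra-slide
#' heterogeneity is part of the healthy null; `"cross_slide_only"` restricts
#' to pairs from different slides.
#'
#' @param region_comps list of [composition()]s, one per healthy region.
#' @param slide_ids character vector parallel to `region_comps`.
#' @param n_boot number of bootstrap draws (default 10000).
#' @param percentile threshold percentile of the null distances (default 95).
#' @param seed integer seed; mandatory, the threshold is a function of it.
#' @param pairing `"any_distinct"` or `"cross_slide_only"`.
#' @param zero_strategy,delta zero handling passed to [clr()].
#' @return A `bootstrap_null` object with fields `distances`, `threshold`,
#'   `n_boot`, `percentile`, `seed`, `pairing`, `n_regions`.
#' @export
bootstrap_null <- function(region_comps, slide_ids, n_boot = 10000,
                           percentile = 95, seed,
                           pairing = c("any_distinct", "cross_slide_only"),
                           zero_strategy = "multiplicative", delta = NULL) {
  pairing <- match.arg(pairing)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n <- length(region_comps)
  stopifnot(length(slide_ids) == n)
  if (n < 2 || length(unique(slide_ids)) < 2) {
    stop("need regions from at least 2 slides", call. = FALSE)
  }
  z <- clr_matrix(region_comps, zero_strategy, delta)
  pairs <- t(utils::combn(n, 2L))
  if (pairing == "cross_slide_only") {
    pairs <- pairs[slide_ids[pairs[, 1]] != slide_ids[pairs[, 2]], ,
                   drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no eligible region pairs", call. = FALSE)
  pair_d <- sqrt(rowSums((z[pairs[, 1], , drop = FALSE] -
                            z[pairs[, 2], , drop = FALSE])^2))
  set.seed(seed)
  draws <- pair_d[sample.int(nrow(pairs), n_boot, replace = TRUE)]
  structure(list(
    distances = draws,
    pair_distances = pair_d,
    threshold = unname(quantile(draws, percentile / 100, type = 7)),
    n_boot = n_boot, percentile = percentile, seed = seed,
    pairing = pairing, n_regions = n
  ), class = "bootstrap_null")
}

#' @export
print.bootstrap_null <- function(x, ...) {
  cat(sprintf(
    "bootstrap null: %d draws over %d regions (%s), %gth percentile threshold = %.4g (seed %d)\n",
    x$n_boot, x$n_regions, x$pairing, x$percentile, x$threshold, x$seed))
  invisible(x)
}

#' Score slides against the healthy reference
#'
#' Computes each slide's Aitchison distance to the reference mean composition
#' and flags slides whose distance exceeds the bootstrap threshold. Control
#' slides are scored too, as a sanity output.
#'
#' @param slide_comps named list of [composition()]s (names are slide ids).
#' @param reference a [build_reference()] result.
#' @param null a [bootstrap_null()] on the matching vocabulary.
#' @param zero_strategy,delta zero handling passed to [clr()].
#' @return data.frame with columns `slide_id`, `distance`, `significant`,
#'   `threshold`.
#' @export
score_slides <- function(slide_comps, reference, null,
                         zero_strategy = "multiplicative", delta = NULL) {
  stopifnot(inherits(reference, "healthy_reference"),
            inherits(null, "bootstrap_null"))
  ref <- reference$mean_composition
  d <- vapply(slide_comps, function(p) {
    aitchison_distance(p, ref, zero_strategy, delta)
  }, numeric(1))
  data.frame(slide_id = names(slide_comps),
             distance = unname(d),
             significant = unname(d > null$threshold),
             threshold = null$threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Leave-one-out stability of a percent-significant summary
#'
#' Removes each slide of a group once and recomputes the percentage of
#' significant slides among the rest, quantifying the stability of the
#' group-level rate; the min-max of the leave-out values is the error-bar
#' range.
#'
#' @param significant logical vector of per-slide significance flags (one
#'   group).
#' @return list with `mean_percent` (mean of the leave-out values),
#'   `values` (percent per left-out slide), `range` (min, max).
#' @export
loo_significance <- function(significant) {
  significant <- as.logical(significant)
  n <- length(significant)
  if (n < 2) stop("group must contain at least 2 slides", call. = FALSE)
  total <- sum(significant)
  values <- 100 * (total - as.numeric(significant)) / (n - 1)
  list(mean_percent = mean(values), values = values, range = range(values))
}
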