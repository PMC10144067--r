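#' Delineate low/high crop-growth cluster regions
#'
#' Aggregates per-plant LISA classes to plot level: a plot joins the
#' low-growth region when at least `min_fraction` of its non-outlier
#' plants are significant L-L, and the high-growth region analogously for
#' H-H. With `min_fraction <= 0.5` a plot could qualify for both; ties go
#' to the larger fraction and an exact tie raises a consistency error.
#'
#' @param lisa plant table from [run_lisa()] (needs `plot_id`, `class`).
#' @param layout the `field_layout` the plants came from.
#' @param min_fraction minimum fraction of a plot's plants carrying the
#'   class (default 0.5).
#' @return List with elements `low` and `high`, each a `cluster_region`:
#'   `kind`, `plot_ids`, `fraction_per_plot` (named vector) and
#'   `rectangles` (the member plots' bounding boxes).
#' @export
delineate_regions <- function(lisa, layout, min_fraction = 0.5) {
  if (is.null(lisa) || !nrow(lisa))
    stop("invalid input: empty LISA table", call. = FALSE)
  if (min_fraction <= 0 || min_fraction > 1)
    stop("`min_fraction` must be in (0, 1]", call. = FALSE)
  plots <- layout$plots
  frac <- function(cls) {
    v <- vapply(split(lisa$class == cls, lisa$plot_id), mean, numeric(1))
    out <- stats::setNames(numeric(nrow(plots)), plots$plot_id)
    out[names(v)] <- v
    out
  }
  f_ll <- frac("LL")
  f_hh <- frac("HH")
  in_low <- f_ll >= min_fraction
  in_high <- f_hh >= min_fraction
  both <- in_low & in_high
  if (any(both)) {
    if (any(f_ll[both] == f_hh[both]))
      stop("consistency error: plot(s) qualify equally for both regions: ",
           paste(names(which(both))[f_ll[both] == f_hh[both]], collapse = ", "),
           call. = FALSE)
    in_low[both] <- f_ll[both] > f_hh[both]
    in_high[both] <- f_hh[both] > f_ll[both]
  }
  region <- function(kind, members, fr) {
    ids <- as.integer(names(which(members)))
    structure(list(
      kind = kind, plot_ids = ids,
      fraction_per_plot = fr[as.character(ids)],
      rectangles = plots[plots$plot_id %in% ids,
                         c("plot_id", "xmin", "ymin", "xmax", "ymax")]
    ), class = "cluster_region")
  }
  list(low = region("low_growth", in_low, f_ll),
       high = region("high_growth", in_high, f_hh))
}

#' @export
print.cluster_region <- function(x, ...) {
  cat(sprintf("<cluster_region> %s: %d plot(s)\n", x$kind, length(x$plot_ids)))
  invisible(x)
}

#' Jaccard similarity of two cluster regions
#'
#' Compares the plot-id sets of the same kind of region delineated at two
#' acquisition dates; 1 means identical membership, 0 disjoint.
#'
#' @param region_t1,region_t2 `cluster_region` objects on the same layout.
#' @return `|intersection| / |union|`, or `NA` (with a warning) when both
#'   sets are empty.
#' @export
compare_dates <- function(region_t1, region_t2) {
  a <- region_t1$plot_ids
  b <- region_t2$plot_ids
  u <- union(a, b)
  if (!length(u)) {
    warning("both regions are empty; Jaccard undefined", call. = FALSE)
    return(NA_real_)
  }
  length(intersect(a, b)) / length(u)
}

#' Assign management zones A/B/C
#'
#' Partitions the plots into zone A (low-growth region), zone B
#' (high-growth region) and zone C (everything else, including bare
#' plots) — the blocking used to neutralize field heterogeneity when
#' randomizing germplasms within spatially similar conditions.
#'
#' @param low,high `cluster_region` objects from [delineate_regions()].
#' @param layout the `field_layout`.
#' @return data.frame with `plot_id` and `zone` (factor A/B/C) covering
#'   every plot exactly once.
#' @export
assign_zones <- function(low, high, layout) {
  if (length(intersect(low$plot_ids, high$plot_ids)))
    stop("consistency error: low and high regions overlap", call. = FALSE)
  zone <- rep("C", nrow(layout$plots))
  zone[layout$plots$plot_id %in% low$plot_ids] <- "A"
  zone[layout$plots$plot_id %in% high$plot_ids] <- "B"
  data.frame(plot_id = layout$plots$plot_id,
             zone = factor(zone, levels = c("A", "B", "C")))
}
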