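#' Canopy height model from DSM and DTM
#'
#' Per-cell difference between the crop surface model and the bare-ground
#' terrain model, `height = DSM - DTM`. Cells where either input is nodata
#' are nodata. (Field reports sometimes phrase the differencing the other
#' way around; canopy height is always surface minus terrain, which is
#' what is computed here.)
#'
#' @param dsm crop surface `field_raster`.
#' @param dtm bare-ground `field_raster`, aligned with `dsm`.
#' @param clamp_negative set negative heights (terrain noise artifacts)
#'   to zero.
#' @return A `field_raster` of canopy heights (m).
#' @export
compute_height_map <- function(dsm, dtm, clamp_negative = FALSE) {
  check_aligned(dsm, dtm, "DSM and DTM")
  h <- dsm$values - dtm$values
  if (clamp_negative) h <- pmax(h, 0)
  field_raster(h, dsm$cell_size, origin = dsm$origin, nodata = dsm$nodata)
}

#' Extract per-plant heights as buffer maxima
#'
#' For each plant, the estimated height is the maximum height-map value
#' over cells whose centers lie within `buffer_diameter / 2` of the plant
#' point (a circular buffer around the sowing position, robust to small
#' georeferencing offsets between map and plant coordinates). Plants whose
#' buffer holds only nodata cells are dropped with a warning.
#'
#' @param height_map canopy height `field_raster`.
#' @param plants data.frame with at least `plant_id`, `x`, `y` columns.
#' @param buffer_diameter buffer diameter in meters (default 0.40 m).
#' @return `plants` with a `height_est` column, restricted to plants with
#'   at least one valid cell in the buffer.
#' @export
extract_buffer_max <- function(height_map, plants, buffer_diameter = 0.40) {
  stopifnot(inherits(height_map, "field_raster"))
  buffer_diameter <- check_positive_number(buffer_diameter, "buffer_diameter")
  cs <- height_map$cell_size
  if (buffer_diameter < cs)
    stop("invalid parameter: buffer smaller than one raster cell", call. = FALSE)
  radius <- buffer_diameter / 2
  d <- dim(height_map$values)
  cc <- raster_cell_centers(height_map)
  rc <- raster_rowcol(height_map, plants$x, plants$y)
  nr <- ceiling(radius / cs) + 1L
  est <- rep(NA_real_, nrow(plants))
  for (i in seq_len(nrow(plants))) {
    if (is.na(rc$row[i])) next
    r0 <- max(1L, rc$row[i] - nr); r1 <- min(d[1], rc$row[i] + nr)
    c0 <- max(1L, rc$col[i] - nr); c1 <- min(d[2], rc$col[i] + nr)
    dy2 <- (cc$y[r0:r1] - plants$y[i])^2
    dx2 <- (cc$x[c0:c1] - plants$x[i])^2
    inside <- outer(dy2, dx2, `+`) <= radius^2
    vals <- height_map$values[r0:r1, c0:c1, drop = FALSE][inside]
    vals <- vals[is.finite(vals)]
    if (length(vals)) est[i] <- max(vals)
  }
  if (anyNA(est)) {
    warning(sprintf("%d plant(s) had no valid height cells in their buffer and were dropped",
                    sum(is.na(est))), call. = FALSE)
  }
  plants$height_est <- est
  out <- plants[!is.na(est), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize extracted heights
#'
#' Adds the z-score `z = (h - mean(h)) / sd_pop(h)` using the population
#' (divide-by-N) standard deviation over all extracted plants of the
#' acquisition date jointly. With this convention the second moment
#' `m = sum(z^2) / N` equals 1, so the local Moran statistic reduces to
#' `I_i = z_i * sum_j W_ij z_j`.
#'
#' @param plants data.frame with a `height_est` column.
#' @return `plants` with a `z` column.
#' @export
normalize_heights <- function(plants) {
  h <- plants$height_est
  if (is.null(h) || sum(!is.na(h)) < 2)
    stop("need at least 2 extracted heights to normalize", call. = FALSE)
  mu <- mean(h)
  s <- sqrt(mean((h - mu)^2))  # population sd
  if (s < 1e-12)
    stop("degenerate variance: all extracted heights are equal", call. = FALSE)
  plants$z <- (h - mu) / s
  plants
}

#' Flag low-z outliers
#'
#' Marks plants whose z-score falls below `cutoff` (default -1.646, the
#' lower ~5% of the standard-normal cumulative probability) as outliers —
#' typically failed or heavily damaged individuals whose heights would
#' distort the spatial analysis. Downstream stages receive only
#' non-outlier plants; z-scores are not re-standardized after removal.
#'
#' @param plants data.frame with a `z` column.
#' @param cutoff z threshold; `outlier <- z < cutoff`.
#' @return `plants` with a logical `outlier` column.
#' @export
filter_outliers <- function(plants, cutoff = -1.646) {
  if (is.null(plants$z)) stop("`z` column missing; run normalize_heights()",
                              call. = FALSE)
  plants$outlier <- plants$z < cutoff
  plants
}

#' Validate estimated against actual plot heights
#'
#' Ordinary least-squares fit of actual on estimated plot-maximum heights;
#' the regression coefficient (slope) and R-squared summarize how well the
#' map-derived heights track ground truth.
#'
#' @param estimated_plot_max numeric, per-plot maxima of estimated height (m).
#' @param actual_plot_max numeric, per-plot maxima of actual height (m).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
validate_heights <- function(estimated_plot_max, actual_plot_max) {
  if (length(estimated_plot_max) != length(actual_plot_max))
    stop("invalid input: estimated and actual vectors differ in length",
         call. = FALSE)
  ok <- is.finite(estimated_plot_max) & is.finite(actual_plot_max)
  if (sum(ok) < 3) stop("need at least 3 plots to validate", call. = FALSE)
  fit <- stats::lm(actual_plot_max[ok] ~ estimated_plot_max[ok])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = sum(ok))
}
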