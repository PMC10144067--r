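#' @useDynLib fieldlisa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Default accession labels for a 24-entry kenaf trial. "EF-2" is the entry
# that fails to germinate under the default growth model, leaving its plots
# as bare ground.
default_germplasms <- function(n = 24L) {
  labels <- c("EF-1", "EF-2", "EF-3", "ET-2", "WIR119", "WIR214", "WIR275",
              "WIR276", "WIR333", "Cubano", "Everglades 41", "Everglades 71",
              "PI365441", "PI468075", "PI468077", "Local", "Kenaf", "G-1",
              "G-2", "G-3", "G-4", "G-5", "G-6", "G-7")
  if (n <= length(labels)) labels[seq_len(n)]
  else c(labels, sprintf("X-%d", seq_len(n - length(labels))))
}

#' Generate a randomized breeding-field layout
#'
#' Lays `n_germplasms * n_reps` rectangular plots on a `grid_cols`-wide
#' grid and sows `plants_per_plot` points in a single row per plot (ridge
#' planting), `plant_spacing` apart. Germplasms are assigned to plots by a
#' uniform random permutation under `seed`, so each germplasm receives
#' exactly `n_reps` plots scattered over the field.
#'
#' The default design is a 24-germplasm, 3-replicate trial (72 plots) with
#' 15 sowing points per plot at 25 cm spacing and 50 cm between plots.
#'
#' @param n_germplasms number of entries in the trial.
#' @param n_reps replicate plots per germplasm.
#' @param plants_per_plot sowing points per plot.
#' @param plant_spacing within-row spacing between sowing points (m).
#' @param plot_spacing gap between adjacent plot rectangles (m).
#' @param grid_cols plots per grid row.
#' @param seed integer seed for the germplasm-to-plot permutation.
#' @param germplasms optional character vector of entry labels
#'   (length `n_germplasms`); defaults to a built-in accession list.
#' @param margin margin between the sowing row and the plot edge (m).
#' @return A `field_layout`: list with `plots` (data.frame: `plot_id`,
#'   `germplasm`, `replicate`, `xmin`, `ymin`, `xmax`, `ymax`), `plants`
#'   (data.frame: `plant_id`, `plot_id`, `germplasm`, `replicate`, `x`,
#'   `y`), and `extent` (xmin, xmax, ymin, ymax). Coordinates are planar
#'   meters, x eastward, y northward; plot row 1 is the northernmost.
#' @export
generate_layout <- function(n_germplasms = 24, n_reps = 3,
                            plants_per_plot = 15, plant_spacing = 0.25,
                            plot_spacing = 0.50, grid_cols = 8,
                            seed = 1L, germplasms = NULL, margin = 0.25) {
  n_germplasms <- check_positive_count(n_germplasms, "n_germplasms")
  n_reps <- check_positive_count(n_reps, "n_reps")
  plants_per_plot <- check_positive_count(plants_per_plot, "plants_per_plot")
  grid_cols <- check_positive_count(grid_cols, "grid_cols")
  plant_spacing <- check_positive_number(plant_spacing, "plant_spacing")
  plot_spacing <- check_positive_number(plot_spacing, "plot_spacing")
  margin <- check_positive_number(margin, "margin")

  if (is.null(germplasms)) germplasms <- default_germplasms(n_germplasms)
  if (length(germplasms) != n_germplasms || anyDuplicated(germplasms))
    stop("`germplasms` must hold n_germplasms distinct labels", call. = FALSE)

  n_plots <- n_germplasms * n_reps
  n_grid_rows <- ceiling(n_plots / grid_cols)
  pw <- (plants_per_plot - 1) * plant_spacing + 2 * margin
  ph <- 2 * margin
  pad <- 0.5
  width <- 2 * pad + grid_cols * pw + (grid_cols - 1) * plot_spacing
  height <- 2 * pad + n_grid_rows * ph + (n_grid_rows - 1) * plot_spacing

  plot_id <- seq_len(n_plots)
  gr <- (plot_id - 1L) %/% grid_cols + 1L  # grid row, 1 = north
  gc <- (plot_id - 1L) %% grid_cols + 1L
  xmin <- pad + (gc - 1) * (pw + plot_spacing)
  ymax <- height - pad - (gr - 1) * (ph + plot_spacing)
  plots <- data.frame(
    plot_id = plot_id, germplasm = NA_character_, replicate = NA_integer_,
    xmin = xmin, ymin = ymax - ph, xmax = xmin + pw, ymax = ymax,
    stringsAsFactors = FALSE
  )

  assignment <- with_local_seed(seed, {
    sample(rep(germplasms, each = n_reps))
  })
  plots$germplasm <- assignment
  plots$replicate <- stats::ave(seq_len(n_plots), assignment,
                                FUN = seq_along)

  offs <- margin + (seq_len(plants_per_plot) - 1) * plant_spacing
  plants <- data.frame(
    plant_id = seq_len(n_plots * plants_per_plot),
    plot_id = rep(plot_id, each = plants_per_plot),
    germplasm = rep(plots$germplasm, each = plants_per_plot),
    replicate = rep(plots$replicate, each = plants_per_plot),
    x = rep(plots$xmin, each = plants_per_plot) + rep(offs, n_plots),
    y = rep((plots$ymin + plots$ymax) / 2, each = plants_per_plot),
    stringsAsFactors = FALSE
  )

  structure(
    list(plots = plots, plants = plants,
         extent = c(xmin = 0, xmax = width, ymin = 0, ymax = height)),
    class = "field_layout"
  )
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf("<field_layout> %d plots (%d germplasms x %d reps), %d plants\n",
              nrow(x$plots), length(unique(x$plots$germplasm)),
              max(x$plots$replicate), nrow(x$plants)))
  cat(sprintf("  extent: %.1f m x %.1f m\n",
              x$extent["xmax"] - x$extent["xmin"],
              x$extent["ymax"] - x$extent["ymin"]))
  invisible(x)
}

#' Generate a sloped terrain raster (DTM)
#'
#' Builds a bare-ground elevation model whose plane component descends by
#' `slope_drop` meters toward `slope_azimuth` (degrees clockwise from
#' north; the default 315 drops toward the northwest, so the southeast
#' corner is the highest point), plus smoothed seeded noise of standard
#' deviation `roughness_sd`. With `roughness_sd = 0` the raster is an
#' exact plane and `max - min == slope_drop`.
#'
#' @param extent named numeric (xmin, xmax, ymin, ymax) in meters, e.g.
#'   `layout$extent`.
#' @param slope_azimuth downhill direction, degrees clockwise from north.
#' @param slope_drop total elevation drop across the extent (m, >= 0).
#' @param roughness_sd standard deviation of the smoothed noise (m, >= 0).
#' @param cell_size raster resolution (m/pixel).
#' @param seed integer seed for the roughness field.
#' @param base_elevation elevation of the lowest plane corner (m).
#' @param roughness_scale correlation length of the noise (m); noise is
#'   drawn on a coarse grid at this spacing and bilinearly interpolated.
#' @return A `field_raster` DTM.
#' @export
generate_terrain <- function(extent, slope_azimuth = 315, slope_drop = 2,
                             roughness_sd = 0.05, cell_size = 0.05,
                             seed = 1L, base_elevation = 100,
                             roughness_scale = 2) {
  cell_size <- check_positive_number(cell_size, "cell_size")
  slope_drop <- check_positive_number(slope_drop, "slope_drop", allow_zero = TRUE)
  roughness_sd <- check_positive_number(roughness_sd, "roughness_sd", allow_zero = TRUE)
  ext <- extent[c("xmin", "xmax", "ymin", "ymax")]
  if (anyNA(ext)) stop("`extent` must name xmin, xmax, ymin, ymax", call. = FALSE)

  ncols <- max(1L, ceiling((ext["xmax"] - ext["xmin"]) / cell_size))
  nrows <- max(1L, ceiling((ext["ymax"] - ext["ymin"]) / cell_size))
  origin <- c(ext[["xmin"]], ext[["ymin"]] + nrows * cell_size)

  cx <- origin[1] + (seq_len(ncols) - 0.5) * cell_size
  cy <- origin[2] - (seq_len(nrows) - 0.5) * cell_size
  az <- slope_azimuth * pi / 180
  u <- c(sin(az), cos(az))  # downhill unit vector
  p <- outer(cy * u[2], cx * u[1], `+`)  # nrows x ncols projection
  pr <- range(p)
  elev <- if (pr[2] > pr[1]) {
    base_elevation + slope_drop * (1 - (p - pr[1]) / (pr[2] - pr[1]))
  } else matrix(base_elevation, nrows, ncols)

  if (roughness_sd > 0) {
    noise <- with_local_seed(seed, {
      nx <- max(2L, ceiling((ext["xmax"] - ext["xmin"]) / roughness_scale) + 1L)
      ny <- max(2L, ceiling((ext["ymax"] - ext["ymin"]) / roughness_scale) + 1L)
      coarse <- matrix(stats::rnorm(nx * ny), ny, nx)
      gx <- seq(ext[["xmin"]], ext[["xmax"]], length.out = nx)
      gy <- seq(ext[["ymax"]], ext[["ymin"]], length.out = ny)
      bilinear_grid(coarse, gx, gy, cx, cy)
    })
    s <- stats::sd(as.vector(noise))
    if (s > 0) elev <- elev + noise * (roughness_sd / s)
  }

  field_raster(elev, cell_size, origin = origin)
}

# Bilinear interpolation of a coarse grid (rows follow gy, cols follow gx,
# gy descending) onto target cell centers cx (ascending) x cy (descending).
bilinear_grid <- function(coarse, gx, gy, cx, cy) {
  ix <- findInterval(cx, gx, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(gx) - 1L)
  tx <- (cx - gx[ix]) / (gx[ix + 1L] - gx[ix])
  # gy descends; use reversed axis for interval lookup
  ry <- rev(gy)
  iy0 <- findInterval(cy, ry, rightmost.closed = TRUE)
  iy0 <- pmin(pmax(iy0, 1L), length(gy) - 1L)
  ty_rev <- (cy - ry[iy0]) / (ry[iy0 + 1L] - ry[iy0])
  iy <- length(gy) - iy0  # row index in coarse of the lower-y bound + 1
  out <- matrix(0, length(cy), length(cx))
  for (r in seq_along(cy)) {
    r1 <- iy[r]; r0 <- r1 + 1L  # r0 lower y (larger row index), r1 upper
    w <- ty_rev[r]
    rowv <- coarse[r0, ix] * (1 - tx) + coarse[r0, ix + 1L] * tx
    rowv2 <- coarse[r1, ix] * (1 - tx) + coarse[r1, ix + 1L] * tx
    out[r, ] <- rowv * (1 - w) + rowv2 * w
  }
  out
}

#' Elevation-linked growth suppression
#'
#' Returns a monotone non-decreasing function of elevation used as the
#' environmental multiplier on germplasm mean heights: a logistic ramp
#' rising from `floor` at low elevations to 1 at high elevations,
#' transitioning between the `low_q` and `high_q` elevation quantiles of
#' the terrain. This emulates growth suppression by excess soil moisture
#' that collects in the low-altitude (downslope) part of a poorly drained
#' field.
#'
#' @param dtm the terrain `field_raster` whose elevation distribution
#'   anchors the ramp.
#' @param floor suppression multiplier at the bottom of the field (0, 1].
#' @param low_q,high_q elevation quantiles bracketing the transition.
#' @return A function elevation (m) -> multiplier in (0, 1].
#' @export
env_effect_logistic <- function(dtm, floor = 0.6, low_q = 0.10, high_q = 0.40) {
  stopifnot(inherits(dtm, "field_raster"), floor > 0, floor <= 1,
            low_q < high_q)
  q <- stats::quantile(dtm$values, c(low_q, high_q), na.rm = TRUE, names = FALSE)
  if (q[2] - q[1] < 1e-9) return(function(elev) rep(1, length(elev)))
  mid <- mean(q)
  k <- 8 / (q[2] - q[1])
  function(elev) floor + (1 - floor) * stats::plogis(k * (elev - mid))
}

#' Growth model for a germplasm trial
#'
#' @param germplasm_means named numeric vector, mean plant height (m) per
#'   germplasm; all strictly positive.
#' @param env_effect function elevation -> multiplier in (0, 1], or `NULL`
#'   for no environmental effect (multiplier 1 everywhere).
#' @param noise_sd per-plant height noise standard deviation (m, >= 0).
#' @param bare_germplasms labels of entries that fail to germinate; their
#'   plots stay bare and produce no plants.
#' @return A `growth_model` object.
#' @export
growth_model <- function(germplasm_means, env_effect = NULL, noise_sd = 0.08,
                         bare_germplasms = character()) {
  if (is.null(names(germplasm_means)) || any(germplasm_means <= 0))
    stop("`germplasm_means` must be a named vector of positive heights",
         call. = FALSE)
  noise_sd <- check_positive_number(noise_sd, "noise_sd", allow_zero = TRUE)
  if (!is.null(env_effect) && !is.function(env_effect))
    stop("`env_effect` must be a function or NULL", call. = FALSE)
  structure(list(germplasm_means = germplasm_means, env_effect = env_effect,
                 noise_sd = noise_sd,
                 bare_germplasms = as.character(bare_germplasms)),
            class = "growth_model")
}

#' Default growth model for a layout
#'
#' Draws a relative vigor per germplasm once under `seed` and scales it
#' by a stage-typical kenaf height (early season ~1.2 m, late season
#' ~2.5 m), so the same seed gives the same genotype ranking at both
#' acquisition dates. Attaches the logistic elevation suppression of
#' [env_effect_logistic()] when a DTM is supplied, and marks "EF-2"
#' (when present) as the non-germinating entry.
#'
#' @param layout a `field_layout`.
#' @param dtm optional terrain raster; when given, the elevation-linked
#'   suppression is enabled.
#' @param stage `"early"` (~50 days after sowing) or `"late"` (~99 days).
#' @param seed integer seed for the germplasm means.
#' @param noise_sd per-plant noise (m); default 0.08 early, 0.15 late.
#' @param suppression_floor multiplier at the lowest elevations; 1 turns
#'   the environmental effect off.
#' @param vigor_sd genotype spread: sd of the relative vigor around 1;
#'   0 makes all germplasms identical (the exchangeable null).
#' @return A `growth_model`.
#' @export
default_growth_model <- function(layout, dtm = NULL,
                                 stage = c("early", "late"), seed = 1L,
                                 noise_sd = NULL, suppression_floor = 0.6,
                                 vigor_sd = 0.125) {
  stage <- match.arg(stage)
  g <- unique(layout$plots$germplasm)
  base <- if (stage == "early") 1.2 else 2.5
  if (is.null(noise_sd)) noise_sd <- if (stage == "early") 0.08 else 0.15
  means <- with_local_seed(seed, {
    vigor <- pmax(stats::rnorm(length(g), 1, vigor_sd), 0.2)
    base * vigor
  })
  names(means) <- g
  env <- if (!is.null(dtm) && suppression_floor < 1)
    env_effect_logistic(dtm, floor = suppression_floor)
  growth_model(means, env_effect = env, noise_sd = noise_sd,
               bare_germplasms = intersect("EF-2", g))
}

#' Simulate true plant heights
#'
#' Height of each plant is its germplasm mean times the environmental
#' multiplier at the plant's terrain elevation, plus Gaussian noise,
#' truncated below at zero. Plants of non-germinating (bare) germplasms
#' are omitted.
#'
#' @param layout a `field_layout`.
#' @param dtm terrain `field_raster` covering every plant point.
#' @param model a `growth_model`.
#' @param seed integer seed for the per-plant noise.
#' @return The plant table (data.frame) restricted to germinated plants,
#'   with a `true_height` column (m).
#' @export
generate_true_heights <- function(layout, dtm, model, seed = 1L) {
  stopifnot(inherits(layout, "field_layout"), inherits(model, "growth_model"))
  plants <- layout$plants
  missing_means <- setdiff(unique(plants$germplasm),
                           c(names(model$germplasm_means), model$bare_germplasms))
  if (length(missing_means))
    stop("growth model lacks means for germplasm(s): ",
         paste(missing_means, collapse = ", "), call. = FALSE)
  plants <- plants[!(plants$germplasm %in% model$bare_germplasms), , drop = FALSE]
  elev <- raster_value_at(dtm, plants$x, plants$y)
  if (anyNA(elev)) {
    bad <- plants$plant_id[which(is.na(elev))[1]]
    stop(sprintf("plant %s lies outside the DTM extent", bad), call. = FALSE)
  }
  mult <- if (is.null(model$env_effect)) rep(1, nrow(plants))
          else model$env_effect(elev)
  mu <- unname(model$germplasm_means[plants$germplasm]) * mult
  h <- with_local_seed(seed, mu + stats::rnorm(nrow(plants), 0, model$noise_sd))
  plants$true_height <- pmax(h, 0)
  rownames(plants) <- NULL
  plants
}

#' Render a crop surface model (DSM) over a terrain
#'
#' Stands in for the photogrammetric surface: the DSM equals the DTM
#' everywhere except within `canopy_radius` of each plant, where a
#' cosine-tapered crown is added whose apex cell (the cell containing the
#' plant point) carries the plant's full height. Overlapping crowns take
#' the pointwise maximum. Seeded Gaussian render noise is added and the
#' result clamped at `DTM - 3 * render_noise_sd`.
#'
#' @param layout a `field_layout` (used for its extent conventions).
#' @param true_heights plant table from [generate_true_heights()].
#' @param dtm terrain `field_raster`.
#' @param canopy_radius crown radius (m); must be at least half a cell.
#' @param render_noise_sd surface reconstruction noise (m, >= 0).
#' @param seed integer seed for the render noise.
#' @return A `field_raster` DSM aligned with `dtm`.
#' @export
render_dsm <- function(layout, true_heights, dtm, canopy_radius = 0.12,
                       render_noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(dtm, "field_raster"))
  cs <- dtm$cell_size
  if (canopy_radius < cs / 2)
    stop("invalid parameter: `canopy_radius` must be at least cell_size/2",
         call. = FALSE)
  render_noise_sd <- check_positive_number(render_noise_sd, "render_noise_sd",
                                           allow_zero = TRUE)
  d <- dim(dtm$values)
  crown <- matrix(0, d[1], d[2])
  if (nrow(true_heights)) {
    cc <- raster_cell_centers(dtm)
    nr <- ceiling(canopy_radius / cs) + 1L
    rc <- raster_rowcol(dtm, true_heights$x, true_heights$y)
    if (anyNA(rc$row)) {
      bad <- true_heights$plant_id[which(is.na(rc$row))[1]]
      stop(sprintf("plant %s lies outside the DTM extent", bad), call. = FALSE)
    }
    for (i in seq_len(nrow(true_heights))) {
      h <- true_heights$true_height[i]
      if (h <= 0) next
      r0 <- max(1L, rc$row[i] - nr); r1 <- min(d[1], rc$row[i] + nr)
      c0 <- max(1L, rc$col[i] - nr); c1 <- min(d[2], rc$col[i] + nr)
      dy <- cc$y[r0:r1] - true_heights$y[i]
      dx <- cc$x[c0:c1] - true_heights$x[i]
      rr <- sqrt(outer(dy^2, dx^2, `+`))
      prof <- ifelse(rr <= canopy_radius,
                     0.5 * (1 + cos(pi * rr / canopy_radius)), 0)
      block <- crown[r0:r1, c0:c1, drop = FALSE]
      crown[r0:r1, c0:c1] <- pmax(block, h * prof)
      crown[rc$row[i], rc$col[i]] <- max(crown[rc$row[i], rc$col[i]], h)
    }
  }
  vals <- dtm$values + crown
  if (render_noise_sd > 0) {
    noise <- with_local_seed(seed,
      matrix(stats::rnorm(d[1] * d[2], 0, render_noise_sd), d[1], d[2]))
    vals <- pmax(vals + noise, dtm$values - 3 * render_noise_sd)
  }
  field_raster(vals, cs, origin = dtm$origin, nodata = dtm$nodata)
}
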