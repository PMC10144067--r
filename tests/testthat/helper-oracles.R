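# Independent oracles used against the package implementation. These stay
# deliberately naive (double loops, full enumeration) so they share no code
# path with the functions they check.

# dense weight matrix from a spatial_weights object
weights_matrix <- function(w) {
  W <- matrix(0, w$n, w$n)
  for (i in seq_len(w$n)) W[i, w$neighbors[[i]]] <- w$weights[[i]]
  W
}

# global Moran's I by explicit double sum
global_moran_brute <- function(z, W) {
  n <- length(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# buffer max by brute force over every raster cell
buffer_max_brute <- function(r, px, py, radius) {
  cc <- fieldlisa:::raster_cell_centers(r)
  best <- -Inf
  for (row in seq_along(cc$y)) for (col in seq_along(cc$x)) {
    if ((cc$x[col] - px)^2 + (cc$y[row] - py)^2 <= radius^2) {
      v <- r$values[row, col]
      if (is.finite(v) && v > best) best <- v
    }
  }
  if (is.finite(best)) best else NA_real_
}

# exact conditional pseudo-p analog for point i under binary weights:
# enumerate every k-subset of the other values as the neighbor set and
# return the one-sided extreme fraction relative to the enumeration mean.
exact_cond_fraction <- function(z, w, i) {
  k <- length(w$neighbors[[i]])
  m <- sum(z^2) / length(z)
  obs <- z[i] / m * sum(z[w$neighbors[[i]]])
  others <- z[-i]
  sets <- utils::combn(length(others), k)
  istar <- apply(sets, 2, function(s) z[i] / m * sum(others[s]))
  if (obs >= mean(istar)) mean(istar >= obs) else mean(istar <= obs)
}

# small noise-free synthetic field used by several suites
tiny_field <- function(seed = 11, n_germplasms = 4, n_reps = 2,
                       plants_per_plot = 5, roughness_sd = 0,
                       noise_sd = 0, render_noise_sd = 0) {
  layout <- generate_layout(n_germplasms, n_reps, plants_per_plot,
                            grid_cols = 4, seed = seed)
  dtm <- generate_terrain(layout$extent, slope_drop = 1,
                          roughness_sd = roughness_sd, cell_size = 0.05,
                          seed = seed)
  means <- stats::setNames(seq(1, 2, length.out = n_germplasms),
                           unique(layout$plots$germplasm))
  model <- growth_model(means, env_effect = NULL, noise_sd = noise_sd)
  truth <- generate_true_heights(layout, dtm, model, seed = seed)
  dsm <- render_dsm(layout, truth, dtm, canopy_radius = 0.12,
                    render_noise_sd = render_noise_sd, seed = seed)
  list(layout = layout, dtm = dtm, dsm = dsm, model = model, truth = truth)
}

# plot ids in the northwest half of a layout (projection onto the
# NW-pointing diagonal above its median)
nw_half_plots <- function(layout) {
  p <- layout$plots
  proj <- -(p$xmin + p$xmax) / 2 + (p$ymin + p$ymax) / 2
  p$plot_id[proj > stats::median(proj)]
}
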