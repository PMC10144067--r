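test_that("default trial design is conserved: plots, replicates, plants", {
  layout <- generate_layout(24, 3, 15, 0.25, 0.50, 8, seed = 1)
  expect_equal(nrow(layout$plots), 72)
  expect_equal(nrow(layout$plants), 1080)
  counts <- table(layout$plots$germplasm)
  expect_true(all(counts == 3))
  expect_true(all(table(layout$plants$plot_id) == 15))
  # plant points inside their plot rectangle, consecutive spacing 0.25
  p <- merge(layout$plants, layout$plots[, c("plot_id", "xmin", "xmax", "ymin", "ymax")])
  expect_true(all(p$x >= p$xmin & p$x <= p$xmax & p$y >= p$ymin & p$y <= p$ymax))
  one <- layout$plants[layout$plants$plot_id == 1, ]
  expect_equal(diff(sort(one$x)), rep(0.25, 14))
})

test_that("layout generation is deterministic in the seed and validates counts", {
  a <- generate_layout(6, 2, 4, grid_cols = 3, seed = 42)
  b <- generate_layout(6, 2, 4, grid_cols = 3, seed = 42)
  c <- generate_layout(6, 2, 4, grid_cols = 3, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$plots$germplasm, c$plots$germplasm))
  expect_error(generate_layout(0, 3, 15), "positive")
  expect_error(generate_layout(24, 3, 15, grid_cols = 0), "positive")
  minimal <- generate_layout(1, 1, 1, grid_cols = 1, seed = 0)
  expect_equal(nrow(minimal$plots), 1)
  expect_equal(nrow(minimal$plants), 1)
})

test_that("plot rectangles are pairwise disjoint", {
  layout <- generate_layout(8, 3, 5, grid_cols = 5, seed = 3)
  p <- layout$plots
  for (i in seq_len(nrow(p) - 1)) {
    j <- (i + 1):nrow(p)
    overlap <- p$xmin[i] < p$xmax[j] & p$xmax[i] > p$xmin[j] &
               p$ymin[i] < p$ymax[j] & p$ymax[i] > p$ymin[j]
    expect_false(any(overlap))
  }
})

test_that("noise-free terrain is an exact plane, highest in the southeast", {
  ext <- c(xmin = 0, xmax = 10, ymin = 0, ymax = 8)
  dtm <- generate_terrain(ext, slope_azimuth = 315, slope_drop = 2,
                          roughness_sd = 0, cell_size = 0.1, seed = 1)
  expect_equal(max(dtm$values) - min(dtm$values), 2.0)
  d <- dim(dtm$values)
  expect_equal(which(dtm$values == max(dtm$values), arr.ind = TRUE)[1, ],
               c(row = d[1], col = d[2]))  # SE corner cell
  expect_equal(which(dtm$values == min(dtm$values), arr.ind = TRUE)[1, ],
               c(row = 1L, col = 1L))      # NW corner cell
})

test_that("terrain roughness is seeded, reproducible and has the target sd", {
  ext <- c(xmin = 0, xmax = 20, ymin = 0, ymax = 20)
  a <- generate_terrain(ext, roughness_sd = 0.1, cell_size = 0.1, seed = 9)
  b <- generate_terrain(ext, roughness_sd = 0.1, cell_size = 0.1, seed = 9)
  c <- generate_terrain(ext, roughness_sd = 0.1, cell_size = 0.1, seed = 10)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  plane <- generate_terrain(ext, roughness_sd = 0, cell_size = 0.1, seed = 9)
  expect_equal(sd(as.vector(a$values - plane$values)), 0.1, tolerance = 1e-6)
  expect_error(generate_terrain(ext, cell_size = -1), "cell_size")
})

test_that("noise-free heights equal germplasm means; suppression multiplies exactly", {
  f <- tiny_field()
  means <- f$model$germplasm_means
  expect_equal(f$truth$true_height, unname(means[f$truth$germplasm]))
  # forced two-level environmental effect
  med <- stats::median(f$dtm$values)
  model2 <- growth_model(means, env_effect = function(e) ifelse(e < med, 0.7, 1),
                         noise_sd = 0)
  truth2 <- generate_true_heights(f$layout, f$dtm, model2, seed = 1)
  elev <- raster_value_at(f$dtm, truth2$x, truth2$y)
  expect_equal(truth2$true_height,
               unname(means[truth2$germplasm]) * ifelse(elev < med, 0.7, 1))
})

test_that("bare germplasms are omitted and out-of-extent plants are named", {
  layout <- generate_layout(4, 2, 3, grid_cols = 4, seed = 5,
                            germplasms = c("EF-1", "EF-2", "EF-3", "ET-2"))
  dtm <- generate_terrain(layout$extent, roughness_sd = 0, cell_size = 0.05)
  means <- stats::setNames(rep(1.5, 4), c("EF-1", "EF-2", "EF-3", "ET-2"))
  model <- growth_model(means, noise_sd = 0, bare_germplasms = "EF-2")
  truth <- generate_true_heights(layout, dtm, model, seed = 1)
  expect_false("EF-2" %in% truth$germplasm)
  expect_equal(nrow(truth), (4 * 2 - 2) * 3)
  small <- generate_terrain(c(xmin = 0, xmax = 1, ymin = 0, ymax = 1),
                            roughness_sd = 0, cell_size = 0.05)
  expect_error(generate_true_heights(layout, small, model, seed = 1),
               "outside the DTM extent")
})

test_that("rendered DSM carries the exact true height at each apex cell", {
  f <- tiny_field()
  chm <- compute_height_map(f$dsm, f$dtm)
  apex <- raster_value_at(chm, f$truth$x, f$truth$y)
  expect_equal(apex, f$truth$true_height)
  expect_equal(max(chm$values), max(f$truth$true_height))
})

test_that("DSM without plants equals the DTM bit-exactly", {
  layout <- generate_layout(2, 1, 2, grid_cols = 2, seed = 1)
  dtm <- generate_terrain(layout$extent, roughness_sd = 0.02, cell_size = 0.05,
                          seed = 2)
  empty <- layout$plants[0, ]
  empty$true_height <- numeric(0)
  dsm <- render_dsm(layout, empty, dtm, render_noise_sd = 0, seed = 1)
  expect_identical(dsm$values, dtm$values)
  expect_error(render_dsm(layout, empty, dtm, canopy_radius = 0.01),
               "canopy_radius")
})

test_that("growth model validates its fields", {
  expect_error(growth_model(c(a = -1)), "positive")
  expect_error(growth_model(c(1, 2)), "named")
  expect_error(growth_model(c(a = 1), noise_sd = -0.1), "noise_sd")
})
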