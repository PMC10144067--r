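#' Distance-band spatial weights
#'
#' Connects every pair of points within `threshold` meters (Euclidean).
#' Binary style assigns weight 1 to each neighbor ("1 for a neighbor and
#' 0 for a non-neighbor"); inverse-distance style assigns `1 / d_ij`.
#' Points with no neighbor inside the band are flagged isolated and
#' excluded from inference (they are reported, never silently dropped).
#'
#' The default threshold of 1.75 m is the largest distance between plants
#' of adjacent plots in the default field design, guaranteeing every
#' plant at least one neighbor from another plot.
#'
#' @param x,y point coordinates in meters (equal length, >= 2 points).
#' @param threshold neighbor distance band (m, > 0).
#' @param style `"binary"` or `"inverse_distance"`.
#' @return A `spatial_weights` object: lists `neighbors` and `weights`
#'   (per point), `threshold`, `style`, `n`, `S0` (total weight sum) and
#'   the logical `isolated` flag.
#' @export
build_weights <- function(x, y, threshold = 1.75,
                          style = c("binary", "inverse_distance")) {
  style <- match.arg(style)
  threshold <- check_positive_number(threshold, "threshold")
  n <- length(x)
  if (n < 2 || length(y) != n)
    stop("need >= 2 points with equal-length x and y", call. = FALSE)
  d <- as.matrix(stats::dist(cbind(x, y)))
  neighbors <- vector("list", n)
  weights <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- unname(which(d[i, ] <= threshold & seq_len(n) != i))
    neighbors[[i]] <- as.integer(nb)
    weights[[i]] <- if (style == "binary") rep(1, length(nb))
                    else unname(1 / d[i, nb])
  }
  isolated <- lengths(neighbors) == 0L
  if (all(isolated))
    stop("no neighbors: every point is isolated at this threshold",
         call. = FALSE)
  if (any(isolated))
    warning(sprintf("%d isolated point(s) at threshold %.3g m; excluded from inference",
                    sum(isolated), threshold), call. = FALSE)
  structure(list(neighbors = neighbors, weights = weights,
                 threshold = threshold, style = style, n = n,
                 S0 = sum(unlist(weights)), isolated = isolated),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %d points, %s style, threshold %.3g m\n",
              x$n, x$style, x$threshold))
  cat(sprintf("  S0 = %.4g, avg neighbors %.2f, %d isolated\n",
              x$S0, mean(lengths(x$neighbors)), sum(x$isolated)))
  invisible(x)
}

# second moment m = sum(z^2) / N of the standardized variable
moment2 <- function(z) sum(z^2) / length(z)

#' Local Moran's I
#'
#' Computes, for each point, the local Moran statistic
#' `I_i = (z_i / m) * sum_j W_ij z_j` with `m = sum(z^2) / N`, the spatial
#' lag `sum_j W_ij z_j`, and the Moran-scatterplot quadrant from the signs
#' of (z_i, lag_i): (+,+) H-H, (-,-) L-L, (-,+) L-H, (+,-) H-L. Zero
#' values tie-break to the "high" side. Isolated points get `NA`
#' statistics.
#'
#' @param z standardized values (mean approximately 0), one per point.
#' @param w a `spatial_weights` built on the same points.
#' @return data.frame with columns `I`, `lag`, `quadrant`.
#' @export
local_moran <- function(z, w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (length(z) != w$n)
    stop("invalid input: z length does not match the weights", call. = FALSE)
  m <- moment2(z)
  if (m <= 0) stop("z has zero variance", call. = FALSE)
  lag <- vapply(seq_along(z), function(i) {
    nb <- w$neighbors[[i]]
    if (!length(nb)) return(NA_real_)
    sum(w$weights[[i]] * z[nb])
  }, numeric(1))
  I <- z / m * lag
  quadrant <- ifelse(z >= 0,
                     ifelse(lag >= 0, "HH", "HL"),
                     ifelse(lag >= 0, "LH", "LL"))
  quadrant[is.na(lag)] <- NA_character_
  data.frame(I = I, lag = lag, quadrant = quadrant,
             stringsAsFactors = FALSE)
}

#' Conditional-permutation pseudo p-values for local Moran's I
#'
#' For each point the observed value is held fixed while its neighbors'
#' values are re-drawn `n_permutations` times without replacement from
#' the remaining observations. With `R` the count of permuted statistics
#' at least as extreme as the observed one on the observed side of the
#' permutation mean, the folded one-sided pseudo p-value is
#' `(R + 1) / (n_permutations + 1)`; the default `"two.sided"` doubles it
#' (capped at 1), so that under spatial randomness the fraction of points
#' with `p <= alpha` matches `alpha` (the folded variant, offered for
#' compatibility with common LISA software, flags about twice the nominal
#' level because the tail is chosen after seeing the statistic). Identical
#' seeds give identical p-values.
#'
#' @param z standardized values.
#' @param w a `spatial_weights` on the same points.
#' @param n_permutations number of conditional permutations (default 999).
#' @param seed integer seed.
#' @param sided `"two.sided"` (calibrated, default) or `"folded"`
#'   (one-sided toward the observed side; minimum attainable p is
#'   `1/(M+1)`).
#' @return Numeric vector of pseudo p-values; `NA` for isolated points.
#' @export
permutation_pvalues <- function(z, w, n_permutations = 999, seed = 1L,
                                sided = c("two.sided", "folded")) {
  stopifnot(inherits(w, "spatial_weights"))
  sided <- match.arg(sided)
  if (length(z) != w$n)
    stop("invalid input: z length does not match the weights", call. = FALSE)
  n_permutations <- check_positive_count(n_permutations, "n_permutations")
  m <- moment2(z)
  with_local_seed(seed,
    cond_perm_pvalues_cpp(as.numeric(z), w$neighbors, w$weights,
                          n_permutations, m, sided == "two.sided"))
}

#' Classify LISA results at a significance level
#'
#' @param lisa data.frame from [local_moran()].
#' @param pseudo_p pseudo p-values from [permutation_pvalues()].
#' @param alpha significance level (default 0.01); a point is significant
#'   when `pseudo_p <= alpha`.
#' @return `lisa` with `pseudo_p`, `significant` and `class` columns;
#'   `class` is the quadrant label for significant points and `"NS"`
#'   otherwise (isolated points are always `"NS"`).
#' @export
classify_lisa <- function(lisa, pseudo_p, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1 + 1e-12)
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  if (length(pseudo_p) != nrow(lisa))
    stop("invalid input: pseudo_p length mismatch", call. = FALSE)
  lisa$pseudo_p <- pseudo_p
  lisa$significant <- !is.na(pseudo_p) & pseudo_p <= alpha
  lisa$class <- ifelse(lisa$significant, lisa$quadrant, "NS")
  lisa$class[is.na(lisa$class)] <- "NS"
  lisa
}

#' Run the full LISA analysis on a plant table
#'
#' Convenience wrapper: builds distance-band weights on the non-outlier
#' plants, computes local Moran's I, conditional-permutation pseudo
#' p-values and significance classes.
#'
#' @param plants data.frame with `x`, `y`, `z` columns (and optionally an
#'   `outlier` flag; flagged rows are excluded beforehand).
#' @param threshold neighbor distance band (m).
#' @param style weight style, `"binary"` or `"inverse_distance"`.
#' @param n_permutations conditional permutations per point.
#' @param alpha pseudo p-value significance level.
#' @param seed integer seed for the permutations.
#' @param sided sidedness of the permutation test, see
#'   [permutation_pvalues()].
#' @return `plants` (non-outlier rows) augmented with `I`, `lag`,
#'   `quadrant`, `pseudo_p`, `significant`, `class`.
#' @export
run_lisa <- function(plants, threshold = 1.75, style = "binary",
                     n_permutations = 999, alpha = 0.01, seed = 1L,
                     sided = "two.sided") {
  if (!is.null(plants$outlier)) plants <- plants[!plants$outlier, , drop = FALSE]
  if (!nrow(plants)) stop("invalid input: no plants to analyze", call. = FALSE)
  w <- build_weights(plants$x, plants$y, threshold = threshold, style = style)
  res <- local_moran(plants$z, w)
  p <- permutation_pvalues(plants$z, w, n_permutations = n_permutations,
                           seed = seed, sided = sided)
  res <- classify_lisa(res, p, alpha = alpha)
  out <- cbind(plants, res)
  rownames(out) <- NULL
  out
}

#' Moran scatterplot coordinates
#'
#' Returns the (z, spatial lag, quadrant) coordinates behind the Moran
#' scatterplot. With `row_standardize = TRUE` each point's weights are
#' rescaled to sum to one, making the lag the average neighbor value; the
#' OLS slope of lag on z then equals global Moran's I under those
#' weights.
#'
#' @param z standardized values.
#' @param w a `spatial_weights`.
#' @param row_standardize rescale each weight row to sum to 1.
#' @return data.frame with `z`, `lag`, `quadrant`.
#' @export
moran_scatterplot_data <- function(z, w, row_standardize = TRUE) {
  stopifnot(inherits(w, "spatial_weights"))
  lag <- vapply(seq_along(z), function(i) {
    nb <- w$neighbors[[i]]
    if (!length(nb)) return(NA_real_)
    wi <- w$weights[[i]]
    if (row_standardize) wi <- wi / sum(wi)
    sum(wi * z[nb])
  }, numeric(1))
  quadrant <- ifelse(z >= 0,
                     ifelse(lag >= 0, "HH", "HL"),
                     ifelse(lag >= 0, "LH", "LL"))
  quadrant[is.na(lag)] <- NA_character_
  data.frame(z = z, lag = lag, quadrant = quadrant, stringsAsFactors = FALSE)
}
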