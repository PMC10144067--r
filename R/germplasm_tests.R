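#' Kruskal-Wallis test across replicate plots
#'
#' Rank-based one-way comparison of the plant heights of a germplasm's
#' replicate plots (tie-corrected H, chi-square approximation with
#' `groups - 1` degrees of freedom). A small p-value means the replicates
#' differ more than random sowing of the same entry would allow —
#' evidence of a location (environmental) effect rather than a genotype
#' effect.
#'
#' @param groups list of numeric vectors, one per replicate plot.
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 || any(lengths(groups) < 1))
    stop("invalid input: need >= 2 non-empty groups", call. = FALSE)
  all_v <- unlist(groups)
  if (length(unique(all_v)) < 2)
    stop("degenerate input: all values identical", call. = FALSE)
  invisible(TRUE)
}

#' Dunn's post hoc test with Benjamini-Hochberg correction
#'
#' Pairwise follow-up to [kruskal_wallis()]: for each pair of groups the
#' z statistic on pooled, tie-corrected ranks
#' `z = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_a + 1/n_b))`
#' with `T = sum(t^3 - t)` over tie groups, two-sided normal p-values,
#' and Benjamini-Hochberg step-up adjustment over the comparison family.
#'
#' @param groups list of numeric vectors (named or numbered).
#' @return data.frame with `group_a`, `group_b`, `z`, `p_raw`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups) {
  check_groups(groups)
  g <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_len(g))
  v <- unlist(groups, use.names = FALSE)
  N <- length(v)
  r <- rank(v)
  idx <- rep(seq_len(g), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n <- lengths(groups)
  ties <- table(v)
  T <- sum(ties^3 - ties)
  var_term <- N * (N + 1) / 12 - T / (12 * (N - 1))
  pairs <- utils::combn(g, 2)
  z <- apply(pairs, 2, function(ab) {
    a <- ab[1]; b <- ab[2]
    (rbar[a] - rbar[b]) / sqrt(var_term * (1 / n[a] + 1 / n[b]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group_a = labels[pairs[1, ]], group_b = labels[pairs[2, ]],
             z = as.numeric(z), p_raw = p_raw,
             p_adjusted = stats::p.adjust(p_raw, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum comparison with average ranks for ties: exact
#' enumeration when the smaller sample has at most 8 values and there are
#' no ties, normal approximation (no continuity correction) otherwise.
#' The `alternative` refers to sample `a` relative to `b`.
#'
#' @param a,b numeric samples (each >= 1 value).
#' @param alternative `"two.sided"`, `"less"` (a shifted below b) or
#'   `"greater"`.
#' @return List with `W` (rank-sum statistic of `a`, Mann-Whitney form)
#'   and `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b))
    stop("invalid input: empty sample", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = FALSE)
  )
  list(W = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Significance star coding
#'
#' `"**"` for p < 0.01, `"*"` for 0.01 <= p < 0.1, `""` otherwise — the
#' coding used in replicate-similarity tables.
#'
#' @param p_value numeric vector of p-values in (0, 1].
#' @return Character vector of star codes.
#' @export
star_code <- function(p_value) {
  ifelse(p_value < 0.01, "**", ifelse(p_value < 0.1, "*", ""))
}

#' Replicate-similarity table for every germplasm
#'
#' Runs the Kruskal-Wallis test across the replicate plots of each
#' germplasm (and Dunn's post hoc with BH correction per germplasm
#' family) on per-plant heights, producing one row per entry with the
#' star-coded p-value. Entries with fewer than 2 replicate plots carrying
#' plants are skipped.
#'
#' @param plants data.frame with `germplasm`, `plot_id` and a value
#'   column.
#' @param value name of the value column (default `"height_est"`).
#' @return data.frame with `germplasm`, `n_plots`, `H`, `df`, `p_value`,
#'   `stars`; the per-germplasm Dunn tables are attached as the
#'   `"pairwise"` attribute (a named list).
#' @export
germplasm_similarity <- function(plants, value = "height_est") {
  if (!value %in% names(plants))
    stop(sprintf("invalid input: column `%s` not found", value), call. = FALSE)
  rows <- list()
  pairwise <- list()
  for (g in sort(unique(plants$germplasm))) {
    sub <- plants[plants$germplasm == g, , drop = FALSE]
    groups <- split(sub[[value]], sub$plot_id)
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2 || length(unique(unlist(groups))) < 2) next
    kw <- kruskal_wallis(groups)
    rows[[g]] <- data.frame(germplasm = g, n_plots = length(groups),
                            H = kw$H, df = kw$df, p_value = kw$p_value,
                            stars = star_code(kw$p_value),
                            stringsAsFactors = FALSE)
    pairwise[[g]] <- dunn_posthoc(groups)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pairwise") <- pairwise
  out
}
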