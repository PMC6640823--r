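#' Aggregate repeated measurements into one per-animal value
#'
#' Each region of interest is measured at 3 positions x 3 repeats (up to 9
#' measurements); the per-measurement parameter values are analyzed
#' independently and then averaged to a single animal-level value, which is
#' the unit of analysis for group comparisons (avoids pseudo-replication).
#'
#' @param values numeric vector of 1-9 per-measurement values.
#' @return their arithmetic mean.
#' @export
aggregate_animal <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L)
    stop("no measurement values to aggregate", call. = FALSE)
  mean(values)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic
#' \deqn{t = \frac{\bar x - \bar y}{\sqrt{s_x^2/n_x + s_y^2/n_y}}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' Degenerate inputs are handled explicitly: both variances zero with equal
#' means gives `t = 0, p = 1`; with different means `t = +/-Inf, p = 0`.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  welch_t_summary(mean(x), stats::sd(x), length(x),
                  mean(y), stats::sd(y), length(y))
}

#' Welch's t-test from summary statistics
#'
#' Same computation as [welch_t()] but from printed `mean +/- SD (n)`
#' summaries, as needed when re-analyzing published tables.
#'
#' @param mean_x,sd_x,n_x first group's mean, SD and size.
#' @param mean_y,sd_y,n_y second group's mean, SD and size.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  if (n_x < 2L || n_y < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  vx <- sd_x^2 / n_x
  vy <- sd_y^2 / n_y
  se2 <- vx + vy
  if (se2 <= 0) {
    if (mean_x == mean_y) return(list(t = 0, df = n_x + n_y - 2, p = 1))
    return(list(t = sign(mean_x - mean_y) * Inf, df = n_x + n_y - 2, p = 0))
  }
  t <- (mean_x - mean_y) / sqrt(se2)
  df <- se2^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the m p-values ascending and sets
#' \deqn{p^{adj}_{(i)} = 1 - (1 - p_{(i)})^{m - i + 1},}
#' enforces monotone non-decrease down the sorted list, caps at 1, and
#' returns the adjusted values in the original order. Never smaller than the
#' input p-values and permutation-equivariant.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
holm_sidak_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Cohen's d effect size
#'
#' Standardized mean difference using the pooled standard deviation
#' \deqn{s_p = \sqrt{\frac{(n_x - 1)s_x^2 + (n_y - 1)s_y^2}{n_x + n_y - 2}}.}
#'
#' @param x,y numeric samples (each n >= 2), or summary statistics via the
#'   `_summary` variant.
#' @return Cohen's d (signed, x minus y).
#' @export
cohen_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  cohen_d_summary(mean(x), stats::sd(x), length(x),
                  mean(y), stats::sd(y), length(y))
}

#' @rdname cohen_d
#' @inheritParams welch_t_summary
#' @export
cohen_d_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / (n_x + n_y - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero", call. = FALSE)
  (mean_x - mean_y) / sqrt(sp2)
}

#' Significance stars for an adjusted p-value
#'
#' `* p < 0.05; ** p < 0.01; *** p < 0.001; **** p < 0.0001`; `ns` otherwise.
#'
#' @param p adjusted p-value(s).
#' @return character vector of star codes.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Group comparisons across weeks and regions
#'
#' Runs Welch's t-test and Cohen's d for the two study groups at every
#' (parameter, region, week) cell of an animal-level table, then applies the
#' Holm-Sidak step-down adjustment within each comparison family. The
#' default family is the four time-point comparisons of one parameter within
#' one region (m = 4). Cells missing a group (or with n < 2 in either) are
#' skipped with a warning.
#'
#' @param animals data.frame with columns `animal_id`, `group`, `week`,
#'   `roi`, `parameter`, `value` (one row per animal x region x parameter).
#' @param group_levels length-2 character; differences are computed as
#'   first minus second (default `c("AMC", "MI")`).
#' @param family how p-values are grouped for adjustment: `"roi_parameter"`
#'   (default, across weeks), `"parameter"` (across weeks and regions), or
#'   `"none"`.
#' @param alpha significance level for the star notation (applied to
#'   adjusted p-values).
#' @return data.frame of comparison results: group means/SDs/sizes, `t_stat`,
#'   `df_welch`, `p_raw`, `p_adj`, `cohen_d`, `stars`.
#' @export
compare_groups <- function(animals, group_levels = c("AMC", "MI"),
                           family = c("roi_parameter", "parameter", "none"),
                           alpha = 0.05) {
  family <- match.arg(family)
  need <- c("animal_id", "group", "week", "roi", "parameter", "value")
  if (!all(need %in% names(animals)))
    stop("`animals` must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  cells <- unique(animals[, c("parameter", "roi", "week")])
  cells <- cells[order(cells$parameter, cells$roi, cells$week), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- animals[animals$parameter == cell$parameter &
                     animals$roi == cell$roi & animals$week == cell$week, ]
    x <- sub$value[sub$group == group_levels[1L]]
    y <- sub$value[sub$group == group_levels[2L]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) {
      warning(sprintf(
        "skipping %s / %s / week %s: need both groups with n >= 2",
        cell$parameter, cell$roi, cell$week), call. = FALSE)
      next
    }
    wt <- welch_t(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = cell$parameter, roi = cell$roi, week = cell$week,
      n_x = length(x), n_y = length(y),
      mean_x = mean(x), sd_x = stats::sd(x),
      mean_y = mean(y), sd_y = stats::sd(y),
      t_stat = wt$t, df_welch = wt$df, p_raw = wt$p,
      cohen_d = cohen_d(x, y), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame())
  res <- do.call(rbind, rows)
  fam_key <- switch(family,
                    roi_parameter = paste(res$parameter, res$roi),
                    parameter = res$parameter,
                    none = seq_len(nrow(res)))
  res$p_adj <- stats::ave(res$p_raw, fam_key,
                          FUN = holm_sidak_adjust)
  res$stars <- p_stars(res$p_adj)
  names(res)[names(res) %in% c("n_x", "mean_x", "sd_x")] <-
    paste0(c("n_", "mean_", "sd_"), tolower(group_levels[1L]))
  names(res)[names(res) %in% c("n_y", "mean_y", "sd_y")] <-
    paste0(c("n_", "mean_", "sd_"), tolower(group_levels[2L]))
  res
}
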