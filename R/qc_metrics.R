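# Per-sample alignment quality metrics and read-size-stratified analysis.
#
# R_m  = mapped / total cleaned primary reads (endogenous-content proxy)
# R_m0 = multi-mapped / mapped (repetitive-placement proxy; NA if no
#        mapped reads)
# A_L  = mean read length (fragmentation proxy)

# primary (and optionally non-duplicate) records form every denominator
metric_scope <- function(records, count_duplicates = TRUE) {
  keep <- records$is_primary
  if (!count_duplicates) keep <- keep & !records$is_duplicate
  records[keep, , drop = FALSE]
}

is_multi_mapped <- function(records, multi_def = c("mapq0", "xt_r")) {
  multi_def <- match.arg(multi_def)
  if (multi_def == "mapq0") records$is_mapped & records$mapq == 0L
  else records$is_mapped & !is.na(records$xt) & records$xt == "R"
}

#' Per-sample alignment quality metrics
#'
#' Computes the three per-sample metrics: mapping rate `r_m` (mapped /
#' total, the endogenous-content proxy), multi-mapping ratio `r_m0`
#' (multi-mapped / mapped; `NA` when nothing maps) and mean read length
#' `a_l`. Counts run over primary records; duplicates are counted by
#' default (set `count_duplicates = FALSE` to drop them).
#'
#' @param records a `shaftqc_alignments` data.frame.
#' @param sample_id label copied into the result.
#' @param multi_def what counts as multi-mapped: `"mapq0"` (mapped with
#'   MAPQ 0, the BWA convention for repetitive placements) or `"xt_r"`
#'   (XT:A:R tag present).
#' @param count_duplicates logical; if `FALSE`, duplicate-flagged records
#'   are excluded from all counts.
#' @param a_l_scope `"all"` (every cleaned read, the default) or
#'   `"mapped"`: which reads enter the mean length.
#' @return a one-row data.frame of class `sample_metrics` with columns
#'   `sample_id`, `n_total`, `n_mapped`, `n_multi`, `r_m`, `r_m0`, `a_l`.
#' @export
compute_sample_metrics <- function(records, sample_id = "sample",
                                   multi_def = c("mapq0", "xt_r"),
                                   count_duplicates = TRUE,
                                   a_l_scope = c("all", "mapped")) {
  a_l_scope <- match.arg(a_l_scope)
  sc <- metric_scope(records, count_duplicates)
  if (!nrow(sc)) stop("empty sample: no primary records", call. = FALSE)
  n_total <- nrow(sc)
  n_mapped <- sum(sc$is_mapped)
  n_multi <- sum(is_multi_mapped(sc, multi_def))
  len <- if (a_l_scope == "all") sc$length else sc$length[sc$is_mapped]
  out <- data.frame(
    sample_id = sample_id,
    n_total = n_total,
    n_mapped = n_mapped,
    n_multi = n_multi,
    r_m = n_mapped / n_total,
    r_m0 = if (n_mapped > 0L) n_multi / n_mapped else NA_real_,
    a_l = if (length(len)) mean(len) else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_metrics", "data.frame")
  out
}

#' Read-size-stratified mapping metrics
#'
#' Partitions records into read-length bins `[k*step, (k+1)*step)` anchored
#' at multiples of `step`, and computes per-bin mapping metrics. Each bin
#' is represented by its midpoint `lower + step/2`. Bins holding fewer than
#' `min_reads` records are still emitted but flagged
#' `included_in_fit = FALSE` so they do not lever the trend regression.
#'
#' @inheritParams compute_sample_metrics
#' @param step bin width in bp (default 10).
#' @param min_reads minimum records for a bin to enter the trend fit
#'   (default 100).
#' @return data.frame with columns `lower`, `upper`, `midpoint`, `n_total`,
#'   `n_mapped`, `n_multi`, `r_m`, `r_m0`, `included_in_fit`.
#' @export
bin_by_read_size <- function(records, step = 10L, min_reads = 100L,
                             multi_def = c("mapq0", "xt_r"),
                             count_duplicates = TRUE) {
  stopifnot(step >= 1L)
  sc <- metric_scope(records, count_duplicates)
  if (!nrow(sc)) stop("empty sample: no primary records", call. = FALSE)
  multi <- is_multi_mapped(sc, multi_def)
  k <- sc$length %/% step
  kk <- seq(min(k), max(k))
  idx <- factor(k, levels = kk)
  n_total <- as.integer(table(idx))
  n_mapped <- as.integer(tapply(sc$is_mapped, idx, sum, default = 0L))
  n_multi <- as.integer(tapply(multi, idx, sum, default = 0L))
  out <- data.frame(
    lower = kk * step,
    upper = (kk + 1L) * step,
    midpoint = kk * step + step / 2,
    n_total = n_total,
    n_mapped = n_mapped,
    n_multi = n_multi,
    r_m = ifelse(n_total > 0L, n_mapped / n_total, NA_real_),
    r_m0 = ifelse(n_mapped > 0L, n_multi / n_mapped, NA_real_),
    included_in_fit = n_total >= min_reads
  )
  class(out) <- c("size_bins", "data.frame")
  out
}

#' Ordinary least squares trend of a mapping metric on read size
#'
#' Fits `response ~ midpoint` by OLS over the included bin points (pooled
#' across samples when `bins` stacks several samples' bins), reporting the
#' slope, intercept, coefficient of determination and the two-sided t-test
#' p-value on the slope.
#'
#' @param bins output of [bin_by_read_size()], possibly row-bound across
#'   samples; only rows with `included_in_fit` and a defined response are
#'   used.
#' @param response `"r_m"` or `"r_m0"`.
#' @return a list of class `trend_fit` with elements `response`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `slope_se`, `n_points`.
#' @export
fit_size_trend <- function(bins, response = c("r_m", "r_m0")) {
  response <- match.arg(response)
  use <- bins$included_in_fit & !is.na(bins[[response]])
  x <- bins$midpoint[use]
  y <- bins[[response]][use]
  if (length(x) < 3L)
    stop("trend fit needs at least 3 included points", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("trend fit needs at least 2 distinct midpoints", call. = FALSE)
  if (var(y) == 0) {
    # constant response: no trend by definition (summary.lm is unreliable
    # when TSS is exactly zero)
    return(structure(list(
      response = response, slope = 0, intercept = y[1], r_squared = 0,
      p_value = 1, slope_se = NA_real_, n_points = length(x)
    ), class = "trend_fit"))
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  slope_row <- sm$coefficients["x", ]
  structure(list(
    response = response,
    slope = unname(coef(fit)[["x"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    r_squared = sm$r.squared,
    p_value = unname(slope_row["Pr(>|t|)"]),
    slope_se = unname(slope_row["Std. Error"]),
    n_points = length(x)
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Size trend of %s: slope = %.4g (SE %.3g), intercept = %.4g, R^2 = %.3f, p = %.4g, n = %d\n",
    x$response, x$slope, x$slope_se, x$intercept, x$r_squared, x$p_value,
    x$n_points))
  invisible(x)
}
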