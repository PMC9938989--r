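# Baseline-anchored beta-distance time series, winter interpolation, STL
# decomposition, detrending, and Friedman seasonality inference -- the core
# temporal analysis. For each (site, sample-type) stream, every monthly
# community is compared (UniFrac) to a fixed early-spring "baseline"
# community of the same stream; the resulting monthly distance series is
# interpolated across unsampled winters, STL-decomposed, detrended (trend
# removed, seasonal + remainder retained) and tested for a calendar-month
# effect across (site, year) blocks with Friedman's two-way ranks test.

#' Build baseline-anchored distance series
#'
#' For each (site_id, sample_type) stream present in the metadata, orders
#' the samples by month and records the distance of each to the stream's
#' baseline sample. The baseline defaults to the earliest available
#' `baseline_month` (March); if that month was never sampled, behaviour is
#' governed by `on_missing`: `"fallback"` uses the earliest sample in any
#' spring month (3--5) with a warning, `"error"` fails.
#'
#' @param dm distance matrix covering all samples of the groups
#' @param metadata sample metadata
#' @param baseline_month calendar month anchoring the baseline (default 3)
#' @param baseline_year optional fixed baseline year (default: earliest year
#'   in which `baseline_month` was sampled, per stream)
#' @param on_missing `"fallback"` or `"error"` when the baseline month is absent
#' @return named list of `baseline_series` data.frames (year, month,
#'   distance, interpolated) with attributes `site_id`, `sample_type`,
#'   `baseline_sample_id`, `baseline_date`
#' @export
build_baseline_series <- function(dm, metadata, baseline_month = 3L,
                                  baseline_year = NULL,
                                  on_missing = c("fallback", "error")) {
  on_missing <- match.arg(on_missing)
  m <- as_distance_matrix(dm)
  md <- metadata[metadata$sample_id %in% rownames(m), , drop = FALSE]
  if (nrow(md) == 0) stop("no metadata samples present in distance matrix", call. = FALSE)
  groups <- split(md, list(md$site_id, md$sample_type), drop = TRUE)
  out <- list()
  for (g in groups) {
    g <- g[order(ym_index(g$year, g$month)), , drop = FALSE]
    cand <- g[g$month == baseline_month &
              (is.null(baseline_year) | g$year == (baseline_year %||% 0L)), ,
              drop = FALSE]
    if (nrow(cand) == 0 && is.null(baseline_year))
      cand <- g[g$month == baseline_month, , drop = FALSE]
    if (nrow(cand) == 0) {
      if (on_missing == "error")
        stop(sprintf("no baseline sample (month %d) for %s/%s", baseline_month,
                     g$site_id[1], g$sample_type[1]), call. = FALSE)
      cand <- g[g$month %in% 3:5, , drop = FALSE]
      if (nrow(cand) == 0)
        stop(sprintf("no spring sample available as baseline for %s/%s",
                     g$site_id[1], g$sample_type[1]), call. = FALSE)
      warning(sprintf("baseline month %d absent for %s/%s; using %d-%02d",
                      baseline_month, g$site_id[1], g$sample_type[1],
                      cand$year[1], cand$month[1]), call. = FALSE)
    }
    base <- cand[1, ]
    agg <- stats::aggregate(
      distance ~ year + month,
      data = data.frame(year = g$year, month = g$month,
                        distance = m[g$sample_id, base$sample_id]),
      FUN = mean)
    agg <- agg[order(ym_index(agg$year, agg$month)), ]
    ser <- data.frame(year = agg$year, month = agg$month,
                      distance = agg$distance, interpolated = FALSE)
    rownames(ser) <- NULL
    attr(ser, "site_id") <- base$site_id
    attr(ser, "sample_type") <- base$sample_type
    attr(ser, "baseline_sample_id") <- base$sample_id
    attr(ser, "baseline_date") <- c(base$year, base$month)
    class(ser) <- c("baseline_series", "data.frame")
    out[[paste(base$site_id, base$sample_type, sep = ".")]] <- ser
  }
  out
}

#' Fill unsampled months by linear interpolation
#'
#' Every month between the first and last observation is given a value;
#' missing interior months are filled by piecewise-linear (linear spline)
#' interpolation between their nearest observed neighbours and flagged
#' `interpolated = TRUE`. Observed values are untouched; nothing is
#' extrapolated beyond the observed range.
#'
#' @param series a `baseline_series` (or data.frame with year, month,
#'   distance)
#' @return the completed series with interpolation flags
#' @export
interpolate_winter <- function(series) {
  if (nrow(series) < 2) stop("need >= 2 observed points to interpolate", call. = FALSE)
  idx <- ym_index(series$year, series$month)
  if (anyDuplicated(idx)) stop("duplicate months in series", call. = FALSE)
  full <- seq(min(idx), max(idx))
  fit <- stats::approx(idx, series$distance, xout = full, method = "linear")
  ym <- ym_from_index(full)
  out <- data.frame(year = ym$year, month = ym$month, distance = fit$y,
                    interpolated = !(full %in% idx))
  obs <- match(idx, full)
  out$distance[obs] <- series$distance  # exact, no float drift on observed points
  for (a in c("site_id", "sample_type", "baseline_sample_id", "baseline_date"))
    attr(out, a) <- attr(series, a)
  class(out) <- class(series)
  out
}

#' STL decomposition of a monthly series
#'
#' Additive seasonal-trend decomposition by loess via [stats::stl()]:
#' input = trend + seasonal + remainder (identity exact). The seasonal
#' smoother span defaults to 7 cycles with one robustness iteration.
#'
#' @param x numeric series (complete, no gaps -- run [interpolate_winter()]
#'   first) or a `baseline_series`
#' @param period months per cycle (default 12); series must cover at least
#'   two full periods
#' @param s_window span (in cycles) of the seasonal loess smoother
#' @param robust_iterations outer robustness iterations (0 = none)
#' @return list of class `stl_components`: `trend`, `seasonal`, `remainder`,
#'   `period`
#' @export
stl_decompose <- function(x, period = 12L, s_window = 7L,
                          robust_iterations = 1L) {
  if (inherits(x, "baseline_series") || is.data.frame(x)) x <- x$distance
  x <- as.numeric(x)
  if (anyNA(x))
    stop("series contains missing values; run interpolate_winter() first",
         call. = FALSE)
  if (length(x) < 2 * period)
    stop("series must cover at least two full periods", call. = FALSE)
  fit <- stats::stl(stats::ts(x, frequency = period), s.window = s_window,
                    robust = robust_iterations > 0,
                    inner = if (robust_iterations > 0) 1L else 2L,
                    outer = max(0L, as.integer(robust_iterations)))
  comp <- fit$time.series
  structure(list(trend = as.numeric(comp[, "trend"]),
                 seasonal = as.numeric(comp[, "seasonal"]),
                 remainder = as.numeric(comp[, "remainder"]),
                 period = as.integer(period)),
            class = "stl_components")
}

#' Remove the STL trend from a series
#'
#' Returns series - trend; the seasonal and remainder components are
#' retained, so the calendar-month signal survives for rank testing while
#' year-on-year drift is removed.
#'
#' @param x numeric series (or `baseline_series`)
#' @param components matching [stl_decompose()] output
#' @return detrended numeric series
#' @export
detrend <- function(x, components) {
  if (inherits(x, "baseline_series") || is.data.frame(x)) x <- x$distance
  x <- as.numeric(x)
  if (length(x) != length(components$trend))
    stop("series and components have different lengths", call. = FALSE)
  x - components$trend
}

#' Carve a detrended monthly series into complete 12-month blocks
#'
#' Blocks are consecutive `period`-month windows anchored at the series
#' start (for a March-anchored baseline series: March through the following
#' February), so one stream observed over Y years yields Y - 1 complete
#' blocks. Within each block the values are reordered to calendar-month
#' columns 1..12.
#'
#' @param detrended numeric detrended series
#' @param start_index linear month index ([ym_index()]) of the first value
#' @param period months per block (default 12)
#' @return blocks x period matrix (columns = calendar months); zero rows if
#'   the series is shorter than one period
#' @export
seasonality_blocks <- function(detrended, start_index, period = 12L) {
  n_blocks <- length(detrended) %/% period
  out <- matrix(NA_real_, n_blocks, period,
                dimnames = list(NULL, month.abb[seq_len(period)]))
  for (b in seq_len(n_blocks)) {
    pos <- (b - 1L) * period + seq_len(period)
    mon <- (start_index + pos - 1L) %% period + 1L
    out[b, mon] <- detrended[pos]
  }
  out
}

#' Friedman test for a calendar-month effect
#'
#' Two-way analysis of variance by ranks: treatments are the `period`
#' calendar months, blocks are (site, year) detrended series. Tie-corrected
#' chi-square statistic with the chi-square reference distribution; the
#' fully tied degenerate case (no variation within any block) returns
#' statistic 0, p = 1.
#'
#' @param blocks numeric matrix, blocks x months (no missing values), or a
#'   list of per-stream block matrices to be stacked
#' @return [test_result()] with `df` field
#' @export
friedman_seasonality <- function(blocks) {
  if (is.list(blocks) && !is.data.frame(blocks)) blocks <- do.call(rbind, blocks)
  blocks <- as.matrix(blocks)
  if (anyNA(blocks))
    stop("blocks contain missing months; interpolate before testing", call. = FALSE)
  if (nrow(blocks) < 2) stop("need >= 2 complete blocks", call. = FALSE)
  r <- t(apply(blocks, 1, rank))
  if (all(apply(r, 1, stats::var) == 0))
    return(test_result(0, 1, "Friedman rank sum test (degenerate: all months tied)",
                       df = ncol(blocks) - 1, n_blocks = nrow(blocks)))
  ft <- stats::friedman.test(blocks)
  test_result(unname(ft$statistic), ft$p.value, "Friedman rank sum test",
              df = unname(ft$parameter), n_blocks = nrow(blocks))
}

#' End-to-end seasonality inference for a study
#'
#' For every sample type: builds baseline-anchored UniFrac series per site,
#' interpolates winters, STL-decomposes and detrends each stream, stacks
#' complete (site, year) blocks, and runs the Friedman month-effect test.
#' P-values are BH-adjusted across sample types.
#'
#' @param table feature table
#' @param tree phylogenetic tree
#' @param metadata sample metadata
#' @param metric UniFrac variant for the distances
#' @param baseline_month baseline anchor month (default March)
#' @param period months per cycle
#' @param s_window,robust_iterations STL parameters (see [stl_decompose()])
#' @param min_blocks minimum stacked blocks required per sample type
#' @return data.frame: sample_type, statistic, df, n_blocks, p_value,
#'   p_adjusted
#' @export
seasonality_analysis <- function(table, tree, metadata,
                                 metric = c("unweighted", "weighted"),
                                 baseline_month = 3L, period = 12L,
                                 s_window = 7L, robust_iterations = 1L,
                                 min_blocks = 2L) {
  metric <- match.arg(metric)
  table <- as_feature_table(table)
  bt <- branch_table(tree)
  md <- metadata[metadata$sample_id %in% rownames(table), , drop = FALSE]
  res <- list()
  for (ty in intersect(SAMPLE_TYPES, unique(md$sample_type))) {
    md_t <- md[md$sample_type == ty, , drop = FALSE]
    blocks <- list()
    for (site in unique(md_t$site_id)) {
      ids <- md_t$sample_id[md_t$site_id == site]
      if (length(ids) < 2 * period) next
      dm <- unifrac_matrix(table[ids, , drop = FALSE], tree, metric, bt = bt)
      ser <- build_baseline_series(dm, md_t[md_t$site_id == site, ],
                                   baseline_month = baseline_month)[[1]]
      ser <- interpolate_winter(ser)
      if (nrow(ser) < 2 * period) next
      det <- detrend(ser, stl_decompose(ser, period, s_window, robust_iterations))
      blk <- seasonality_blocks(det, ym_index(ser$year[1], ser$month[1]), period)
      if (nrow(blk) > 0) blocks[[site]] <- blk
    }
    stacked <- do.call(rbind, blocks)
    if (is.null(stacked) || nrow(stacked) < min_blocks) {
      warning("sample type ", ty, ": fewer than ", min_blocks,
              " complete blocks; skipped", call. = FALSE)
      next
    }
    tr <- friedman_seasonality(stacked)
    res[[ty]] <- data.frame(sample_type = ty, statistic = tr$statistic,
                            df = tr$df, n_blocks = nrow(stacked),
                            p_value = tr$p_value)
  }
  out <- do.call(rbind, res)
  if (!is.null(out)) {
    out$p_adjusted <- bh_adjust(out$p_value)
    rownames(out) <- NULL
  }
  out
}
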