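test_that("baseline series anchor at March with zero self-distance", {
  # three identical samples: all distances to baseline are 0
  tab <- matrix(5L, 3, 4, dimnames = list(paste0("S", 1:3), paste0("ASV_", 1:4)))
  md <- tiny_metadata()
  tree <- generate_tree(4, seed = 1)
  tree$tip.label <- paste0("ASV_", 1:4)
  dm <- unifrac_matrix(tab, tree)
  ser <- build_baseline_series(dm, as_sample_metadata(md))[[1]]
  expect_true(all(ser$distance == 0))
  expect_equal(attr(ser, "baseline_date"), c(2015L, 3L))
  expect_equal(ser$distance[ser$month == 3], 0)  # baseline's own point
})

test_that("baseline falls back to the earliest spring month with a warning", {
  md <- tiny_metadata()
  md$month <- c(4L, 6L, 8L)
  m <- matrix(0.2, 3, 3, dimnames = list(md$sample_id, md$sample_id))
  diag(m) <- 0
  expect_warning(ser <- build_baseline_series(m, as_sample_metadata(md))[[1]],
                 "using 2015-04")
  expect_equal(attr(ser, "baseline_date"), c(2015L, 4L))
  expect_error(build_baseline_series(m, as_sample_metadata(md),
                                     on_missing = "error"),
               "no baseline sample")
})

test_that("winter interpolation is piecewise linear, interior only, flags set", {
  ser <- data.frame(year = c(2014L, 2015L), month = c(11L, 3L),
                    distance = c(0.4, 0.8), interpolated = FALSE)
  class(ser) <- c("baseline_series", "data.frame")
  out <- interpolate_winter(ser)
  expect_equal(out$distance, c(0.4, 0.5, 0.6, 0.7, 0.8))
  expect_equal(out$interpolated, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$month, c(11L, 12L, 1L, 2L, 3L))

  # gap-free series is returned unchanged
  full <- data.frame(year = 2015L, month = 3:7,
                     distance = runif(5), interpolated = FALSE)
  class(full) <- c("baseline_series", "data.frame")
  expect_equal(interpolate_winter(full)$distance, full$distance)
  expect_error(interpolate_winter(full[1, ]), ">= 2")
})

test_that("interpolated values never leave the bracketing observed range", {
  set.seed(21)
  for (i in 1:200) {
    n_obs <- sample(4:10, 1)
    idx <- sort(sample(1:24, n_obs))
    ser <- data.frame(year = 2014L + idx %/% 12, month = idx %% 12 + 1,
                      distance = runif(n_obs), interpolated = FALSE)
    ser <- ser[!duplicated(ym_index(ser$year, ser$month)), ]
    if (nrow(ser) < 2) next
    out <- interpolate_winter(ser)
    obs_idx <- ym_index(ser$year, ser$month)
    for (j in which(out$interpolated)) {
      t <- ym_index(out$year[j], out$month[j])
      lo <- max(obs_idx[obs_idx < t]); hi <- min(obs_idx[obs_idx > t])
      bracket <- ser$distance[obs_idx %in% c(lo, hi)]
      expect_gte(out$distance[j], min(bracket) - 1e-12)
      expect_lte(out$distance[j], max(bracket) + 1e-12)
    }
  }
})

test_that("STL reconstruction identity holds and known signals are recovered", {
  # constant series
  comp <- stl_decompose(rep(3, 36))
  expect_lt(max(abs(comp$trend - 3)), 1e-6)
  expect_lt(max(abs(comp$seasonal)), 1e-6)
  expect_lt(max(abs(comp$remainder)), 1e-6)

  # pure sinusoid: remainder tiny, trend flat
  x <- 3 * sin(2 * pi * (1:48) / 12)
  comp <- stl_decompose(x)
  expect_lt(max(abs(comp$trend + comp$seasonal + comp$remainder - x)), 1e-9)
  expect_lt(sqrt(mean(comp$remainder^2)), 0.03)  # < 1% of amplitude
  expect_lt(diff(range(comp$trend)), 0.2)

  # sinusoid + ramp: trend recovers the slope on interior months
  slope <- 0.05
  y <- 2 * sin(2 * pi * (1:60) / 12) + slope * (1:60)
  comp <- stl_decompose(y)
  interior <- 13:48
  fit <- coef(lm(comp$trend[interior] ~ interior))[2]
  expect_lt(abs(fit - slope) / slope, 0.1)

  expect_error(stl_decompose(1:20), "two full periods")
  expect_error(stl_decompose(c(1:30, NA, 1:5)), "missing")
})

test_that("detrending removes the trend and preserves the identity", {
  x <- 2 * sin(2 * pi * (1:96) / 12) + 0.1 * (1:96)
  comp <- stl_decompose(x)
  det <- detrend(x, comp)
  expect_equal(det + comp$trend, x, tolerance = 1e-12)
  # regression slope of the detrended series on time is ~0
  sl <- coef(lm(det ~ seq_along(det)))[2]
  expect_lt(abs(sl), 0.05 * 0.1)
  # a series equal to its own trend detrends to zero
  expect_equal(detrend(comp$trend, comp), rep(0, 96))
  expect_error(detrend(1:10, comp), "lengths")
})

test_that("Friedman seasonality statistic matches the closed form under perfect concordance", {
  n <- 5; k <- 12
  blocks <- t(replicate(n, seq_len(k))) + matrix(rnorm(n * k, 0, 1e-6), n, k)
  res <- friedman_seasonality(blocks)
  Rj <- n * seq_len(k)
  closed <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  expect_equal(res$statistic, closed, tolerance = 1e-9)

  # fully tied blocks: statistic 0, p = 1
  tied <- friedman_seasonality(matrix(7, 4, 12))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)

  expect_error(friedman_seasonality(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("block construction maps consecutive windows onto calendar months", {
  det <- 1:24
  # series starting in March 2014
  blk <- seasonality_blocks(det, ym_index(2014, 3))
  expect_equal(dim(blk), c(2L, 12L))
  # first block: values 1..10 are Mar..Dec, 11..12 are Jan..Feb
  expect_equal(unname(blk[1, ]), c(11, 12, 1:10))
  expect_equal(unname(blk[2, ]), c(23, 24, 13:22))
})

test_that("end-to-end pipeline flags the seasonal sample types on a synthetic study", {
  cfg <- synthetic_config(n_taxa = 40, n_sites = 4, n_years = 4,
                          reads_per_sample = 500, seasonal_amplitude = 3,
                          noise_sd = 0.2, seed = 17)
  cm <- generate_counts(cfg)
  tree <- generate_tree(cfg$n_taxa, cfg$seed)
  res <- seasonality_analysis(cm$table, tree, cm$metadata)
  res <- res[match(c("water", "effluent", "sewage", "sediment"), res$sample_type), ]
  expect_lt(res$p_value[1], 0.01)
  expect_lt(res$p_value[2], 0.01)
  # seasonal statistics dominate the amplitude-0 types
  expect_gt(min(res$statistic[1:2]), max(res$statistic[3:4]))
  expect_true(all(res$p_adjusted >= res$p_value))
})
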