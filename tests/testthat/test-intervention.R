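test_that("BH adjustment: step-up evaluation, identity and cap", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # order-preserving with input ranks
  p <- c(0.3, 0.001, 0.04, 0.9)
  expect_equal(order(bh_adjust(p)), order(p))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\(0, 1\\]")
})

test_that("threshold exceedance fraction is exact", {
  expect_equal(fraction_above_threshold(c(100, 500, 400, 12000)), 0.5)
  expect_equal(fraction_above_threshold(c(1, 2), threshold = 0), 1)
})

test_that("coliform median bootstrap: effect size, degenerate case, and separation", {
  const <- series_df(2013:2019, 3:11, 700)
  names(const)[3] <- "cfu_per_100ml"
  res <- median_bootstrap_prepost(const, n_boot = 999, seed = 1)
  expect_equal(res$effect_size, 0)
  expect_equal(res$p_value, 1)

  # effect size is the plain difference of sample medians, no resampling
  ser <- series_df(2013:2019, 3:11, 0)
  names(ser)[3] <- "cfu_per_100ml"
  set.seed(2)
  pre <- ym_index(ser$year, ser$month) < ym_index(2016, 1)
  ser$cfu_per_100ml[pre] <- rlnorm(sum(pre), log(8000), 0.5)
  ser$cfu_per_100ml[!pre] <- rlnorm(sum(!pre), log(400), 0.5)
  res2 <- median_bootstrap_prepost(ser, n_boot = 1999, seed = 3)
  expect_equal(res2$effect_size,
               median(ser$cfu_per_100ml[pre]) - median(ser$cfu_per_100ml[!pre]))

  # post = pre / 20 exactly: p near the attainable floor
  n <- 30
  sep <- data.frame(year = c(rep(2013:2015, each = 10), rep(2016:2018, each = 10)),
                    month = rep(1:10, 6), cfu_per_100ml = 0)
  set.seed(4)
  v <- rlnorm(n, log(9000), 0.6)
  sep$cfu_per_100ml <- c(v, v / 20)
  res3 <- median_bootstrap_prepost(sep, n_boot = 9999, seed = 5)
  expect_gte(res3$p_value, 1 / 10000)
  expect_lt(res3$p_value, 0.005)

  expect_error(median_bootstrap_prepost(const[1:28, ]), ">= 3 timepoints")
})

test_that("up/down median bootstrap: identical series, separation, and unmatched drops", {
  up <- series_df(2013:2019, 3:11, 0)
  set.seed(6)
  up$value <- rnorm(nrow(up), 10, 2)
  down <- up
  res <- updown_median_bootstrap(up, down, n_boot = 999, seed = 1)
  expect_equal(res$effect_size, 0)
  expect_equal(res$p_value, 1)

  # strong spread-out post-period downstream shift: p at the floor before BH
  # (a *constant* shift does not saturate: the flipped-median null scales
  # with the shift itself -- see the methods vignette)
  down2 <- up
  post <- ym_index(up$year, up$month) >= ym_index(2016, 1)
  down2$value <- up$value + ifelse(post, runif(nrow(up), 0.5, 20),
                                   rnorm(nrow(up), 0, 0.5))
  res2 <- updown_median_bootstrap(up, down2, n_boot = 999, seed = 2)
  expect_equal(res2$p_value, 1 / 1000)

  # unmatched timepoints are dropped with a warning
  expect_warning(res3 <- updown_median_bootstrap(up[-1, ], down2, n_boot = 99,
                                                 seed = 3),
                 "unmatched")
  expect_equal(res3$n_pre + res3$n_post, nrow(up) - 1)

  # pooled-null variant runs and respects the floor
  res4 <- updown_median_bootstrap(up, down2, n_boot = 999, seed = 4,
                                  null = "pooled")
  expect_gte(res4$p_value, 1 / 1000)
})

test_that("shared seasonality without an up/down differential is not rejected above alpha", {
  rate <- updown_type1(n_sims = 300, n_boot = 499, seed = 31)
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.1)
})

test_that("study-level coliform analysis reproduces the downstream-decay pattern", {
  cfg <- synthetic_config(seed = 41)
  md <- study_metadata(cfg)
  ms <- generate_measurements(cfg, md)
  res <- coliform_analysis(ms$coliform, md, n_boot = 4999, seed = 11)
  expect_true(all(res$p_adjusted >= res$p_value))
  by_role <- split(res$p_adjusted < 0.05, res$spatial_role)
  expect_true(all(by_role$effluent))
  expect_true(all(by_role$immediate_downstream))
  expect_false(any(by_role$further_downstream))
  # effluent effect is the largest; pre-period exceedance of the 400 standard
  eff <- res[res$spatial_role == "effluent", ]
  expect_true(all(eff$abs_effect_size > max(res$abs_effect_size[
    res$spatial_role == "further_downstream"])))
  expect_true(all(eff$frac_above_400_pre == 1))
})

test_that("physchem analysis yields a per-region, BH-adjusted table with no intervention signal", {
  cfg <- synthetic_config(seed = 43)
  md <- study_metadata(cfg)
  ms <- generate_measurements(cfg, md)
  res <- physchem_analysis(ms$physchem, md, n_boot = 499, seed = 13)
  expect_equal(sort(unique(res$region)), c("Calumet", "OBrien"))
  expect_equal(nrow(res), 22)  # 11 variables x 2 regions
  # BH is applied within region
  for (reg in c("Calumet", "OBrien")) {
    sub <- res[res$region == reg, ]
    expect_equal(sub$p_adjusted, bh_adjust(sub$p_value))
  }
  expect_false(any(res$p_adjusted < 0.05))
})
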