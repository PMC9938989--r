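test_that("generate_tree builds deterministic rooted binary trees", {
  t2 <- generate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(t2$Nnode, 1)
  expect_true(all(t2$edge.length > 0))
  expect_error(generate_tree(1), ">= 2")

  a <- write_newick(generate_tree(64, seed = 7))
  b <- write_newick(generate_tree(64, seed = 7))
  expect_identical(a, b)

  # branch-length sum survives a round trip through the Newick parser
  tr <- generate_tree(64, seed = 7)
  rt <- parse_newick(write_newick(tr))
  expect_equal(sum(rt$edge.length), sum(tr$edge.length), tolerance = 1e-9)
})

test_that("generated counts conserve the read depth and the whole study is deterministic", {
  cfg <- small_config()
  st1 <- generate_study(cfg)
  expect_true(all(rowSums(st1$table) == cfg$reads_per_sample))
  expect_true(all(st1$metadata$sample_id == rownames(st1$table)))

  st2 <- generate_study(cfg)
  expect_identical(st1$table, st2$table)
  expect_identical(write_newick(st1$tree), write_newick(st2$tree))
  expect_identical(st1$coliform, st2$coliform)
  expect_identical(st1$physchem, st2$physchem)
})

test_that("no-signal limit: amplitude 0, noise 0 gives month-invariant expected composition", {
  cfg <- synthetic_config(n_taxa = 15, n_sites = 2, n_years = 1,
                          months_sampled = c(4, 9), reads_per_sample = 50000,
                          seasonal_amplitude = 0, noise_sd = 0, seed = 5)
  cm <- generate_counts(cfg)
  md <- cm$metadata
  id_a <- md$sample_id[md$sample_type == "sewage" & md$month == 4]
  id_b <- md$sample_id[md$sample_type == "sewage" & md$month == 9]
  pa <- cm$table[id_a[1], ] / sum(cm$table[id_a[1], ])
  pb <- cm$table[id_b[1], ] / sum(cm$table[id_b[1], ])
  # identical generating composition; only multinomial noise differs
  expect_lt(max(abs(pa - pb)), 0.015)
})

test_that("seasonal taxa peak in the month implied by their stored phase", {
  cfg <- synthetic_config(n_taxa = 30, n_sites = 2, n_years = 4,
                          reads_per_sample = 2000, seasonal_amplitude = 3,
                          noise_sd = 0.1, seed = 11)
  cm <- generate_counts(cfg)
  md <- cm$metadata
  phases <- cm$truth$phases
  # taxon with phase nearest 0: sinusoid sin(2 pi m/12) peaks at month 3
  tx <- names(phases)[which.min(abs(((phases + pi) %% (2 * pi)) - pi))]
  water <- md$sample_id[md$sample_type == "water"]
  prop <- cm$table[water, tx] / rowSums(cm$table[water, ])
  mono <- tapply(prop, md$month[match(water, md$sample_id)], mean)
  peak_month <- as.integer(names(which.max(mono)))
  expected_peak <- ((round(12 * (pi / 2 - phases[tx]) / (2 * pi)) - 1) %% 12) + 1
  dist12 <- min(abs(peak_month - expected_peak), 12 - abs(peak_month - expected_peak))
  expect_lte(dist12, 1)
})

test_that("coliform intervention scales the effluent median by the configured factor", {
  # Monte-Carlo over 100 replicate studies: the pre/post ratio of sample
  # medians concentrates at exp(intervention_log_reduction) = 20
  lr <- vapply(1:100, function(i) {
    cfg <- synthetic_config(n_sites = 4, seed = 1000 + i,
                            intervention_log_reduction = log(20))
    ms <- generate_measurements(cfg)
    ser <- ms$coliform[ms$coliform$site_id == "OBrien_WRP", ]
    post <- ym_index(ser$year, ser$month) >= ym_index(2016, 1)
    log(median(ser$cfu_per_100ml[!post]) / median(ser$cfu_per_100ml[post]))
  }, numeric(1))
  expect_lt(abs(mean(lr) - log(20)), 0.1)
})

test_that("null intervention leaves pre/post coliform medians exchangeable", {
  lr <- vapply(1:50, function(i) {
    cfg <- synthetic_config(n_sites = 4, seed = 2000 + i,
                            intervention_log_reduction = 0)
    ms <- generate_measurements(cfg)
    ser <- ms$coliform[ms$coliform$site_id == "Calumet_WRP", ]
    post <- ym_index(ser$year, ser$month) >= ym_index(2016, 1)
    log(median(ser$cfu_per_100ml[!post]) / median(ser$cfu_per_100ml[post]))
  }, numeric(1))
  expect_lt(abs(mean(lr)), 0.08)
})

test_that("noise-free physicochemistry reproduces its sinusoid exactly", {
  cfg <- synthetic_config(n_sites = 4, noise_sd = 0, seed = 3)
  ms <- generate_measurements(cfg)
  pc <- ms$physchem[ms$physchem$variable == "temperature" &
                    ms$physchem$site_id == "Calumet_S01", ]
  # same calendar month in different years: identical value (no noise term)
  for (m in unique(pc$month))
    expect_equal(var(pc$value[pc$month == m]), 0)
  # month-to-month differences follow the sinusoid shape exactly
  one_year <- pc[pc$year == 2014, ]
  season <- 10 * sin(2 * pi * one_year$month / 12 + (pi / 2 - 2 * pi * 7 / 12))
  expect_equal(one_year$value - mean(one_year$value),
               season - mean(season), tolerance = 1e-9)
})

test_that("truth record carries the per-stream generating parameters", {
  cfg <- small_config()
  st <- generate_study(cfg)
  tr <- st$truth$per_stream
  expect_true(all(tr$seasonal_amplitude[tr$sample_type %in% c("water", "effluent")] ==
                    cfg$seasonal_amplitude))
  expect_true(all(tr$seasonal_amplitude[tr$sample_type %in% c("sewage", "sediment")] == 0))
  eff <- tr[tr$sample_type == "effluent", ]
  expect_true(all(eff$intervention_effect == cfg$intervention_log_reduction))
  wat <- tr[tr$sample_type == "water" & tr$spatial_role == "upstream", ]
  expect_true(all(wat$intervention_effect == 0))
  expect_equal(length(st$truth$coliform_taxa),
               ceiling(cfg$coliform_taxon_fraction * cfg$n_taxa))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(months_sampled = integer(0)), "non-empty")
  expect_error(synthetic_config(months_sampled = 13), "non-empty|1..12")
  expect_error(synthetic_config(reads_per_sample = 0), ">= 1")
  expect_error(synthetic_config(seasonal_period = 1), ">= 2")
})
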