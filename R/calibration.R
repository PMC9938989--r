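# Simulation studies over the synthetic generator: type-I calibration of
# the four inferential procedures, power/recovery of the seasonality
# pipeline, and recovery of the downstream-decaying coliform intervention
# pattern. Shared by the test suite, the acceptance script and the
# analysis drivers; the problem sizes are the package's calibration
# defaults (see the methods vignette).

#' Type-I error of the Friedman seasonality test
#'
#' Null blocks are month-exchangeable (iid values within each block):
#' rejection at `alpha` should track `alpha`. This calibrates the
#' inferential test itself; end-to-end behaviour of the interpolation +
#' STL pipeline is measured by [seasonality_power()] with amplitude 0.
#'
#' @param n_sims simulation count
#' @param n_blocks,period block design (defaults 8 x 12)
#' @param alpha nominal level
#' @param seed RNG seed
#' @return rejection rate
#' @export
friedman_type1 <- function(n_sims = 1000L, n_blocks = 8L, period = 12L,
                           alpha = 0.05, seed = 0L) {
  rej <- with_seed(seed, vapply(seq_len(n_sims), function(i) {
    blocks <- matrix(stats::rnorm(n_blocks * period), n_blocks, period)
    friedman_seasonality(blocks)$p_value < alpha
  }, logical(1)))
  mean(rej)
}

#' Type-I error of the pre/post permutation test
#'
#' Null series: iid distances with no pre/post shift, at the study's
#' timepoint counts (27 pre, 36 post by default).
#'
#' @param n_sims simulation count
#' @param n_pre,n_post timepoints per side
#' @param n_perm permutations per test
#' @param alpha nominal level
#' @param seed RNG seed
#' @return rejection rate
#' @export
spatial_type1 <- function(n_sims = 1000L, n_pre = 27L, n_post = 36L,
                          n_perm = 999L, alpha = 0.05, seed = 0L) {
  months <- rep(3:11, length.out = n_pre + n_post)
  years <- c(rep(2013:2015, each = 9)[seq_len(n_pre)],
             rep(2016:2019, each = 9)[seq_len(n_post)])
  rej <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    ser <- data.frame(year = years, month = months,
                      distance = with_seed(seed + 7 * i,
                                           stats::runif(n_pre + n_post)))
    tr <- prepost_permutation_test(ser, c(2016L, 1L), n_perm, seed + 7 * i + 1)
    rej[i] <- tr$p_value < alpha
  }
  mean(rej)
}

#' Type-I error of the coliform median bootstrap
#'
#' Null studies come from the generator with the intervention effect set to
#' zero; each simulation tests one effluent site's coliform series.
#'
#' @param n_sims simulation count
#' @param n_boot bootstrap resamples per test
#' @param alpha nominal level
#' @param seed RNG seed
#' @param config base configuration (effect is forced to zero)
#' @return rejection rate
#' @export
coliform_type1 <- function(n_sims = 1000L, n_boot = 999L, alpha = 0.05,
                           seed = 0L, config = NULL) {
  cfg0 <- config %||% synthetic_config()
  rej <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    cfg <- cfg0
    cfg$intervention_log_reduction <- 0
    cfg$seed <- as.integer(seed + i)
    ms <- generate_measurements(cfg)
    ser <- ms$coliform[ms$coliform$site_id == "Calumet_WRP", ]
    tr <- median_bootstrap_prepost(ser, cfg$intervention_date, n_boot,
                                   seed + i)
    rej[i] <- tr$p_value < alpha
  }
  mean(rej)
}

#' Type-I error of the up/down physicochemical median bootstrap
#'
#' Simulates the test's null directly: upstream and downstream series share
#' a strong seasonal sinusoid (amplitude `amplitude`, the temporal
#' confound the pairing must absorb) plus independent measurement noise,
#' with zero persistent up/down differential and no intervention term.
#' A persistent differential makes the within-timepoint sign-flip null
#' conservative, never anticonservative (see the methods vignette).
#'
#' @inheritParams coliform_type1
#' @param n_pre,n_post matched timepoints per period
#' @param amplitude shared seasonal amplitude
#' @param noise_sd independent per-site measurement noise SD
#' @return rejection rate
#' @export
updown_type1 <- function(n_sims = 1000L, n_boot = 999L, alpha = 0.05,
                         seed = 0L, n_pre = 27L, n_post = 36L,
                         amplitude = 10, noise_sd = 2) {
  n <- n_pre + n_post
  months <- rep(3:11, length.out = n)
  years <- c(rep(2013:2015, each = 9)[seq_len(n_pre)],
             rep(2016:2019, each = 9)[seq_len(n_post)])
  season <- amplitude * sin(2 * pi * months / 12)
  rej <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    vals <- with_seed(seed + 13 * i,
                      season + matrix(stats::rnorm(2 * n, 0, noise_sd), n))
    up <- data.frame(year = years, month = months, value = vals[, 1])
    down <- data.frame(year = years, month = months, value = vals[, 2])
    tr <- updown_median_bootstrap(up, down, c(2016L, 1L), n_boot,
                                  seed + 13 * i + 1)
    rej[i] <- tr$p_value < alpha
  }
  mean(rej)
}

#' Seasonality power / specificity over replicate synthetic studies
#'
#' Runs the full pipeline (counts -> UniFrac baseline series -> winter
#' interpolation -> STL detrend -> Friedman per sample type) on `n_runs`
#' replicate studies and reports, per sample type, the fraction of runs
#' with raw p < `alpha`. With the default study configuration water and
#' effluent carry the seasonal signal (amplitude 3, noise 0.2) while sewage
#' and sediment have amplitude 0.
#'
#' @param n_runs replicate studies
#' @param config study configuration (default: a reduced design with 4
#'   river sites, 4 years, 40 taxa, 500 reads -- at least 6 stacked blocks
#'   per tested type)
#' @param alpha nominal level
#' @param seed RNG seed
#' @param metric UniFrac variant
#' @return data.frame: sample_type, rejection_rate, mean_statistic, n_runs
#' @export
seasonality_power <- function(n_runs = 200L, config = NULL, alpha = 0.05,
                              seed = 0L, metric = "unweighted") {
  cfg0 <- config %||% synthetic_config(n_taxa = 40L, n_sites = 4L,
                                       n_years = 4L, reads_per_sample = 500L)
  hits <- list(); stat <- list()
  for (i in seq_len(n_runs)) {
    cfg <- cfg0
    cfg$seed <- as.integer(seed + i)
    cm <- generate_counts(cfg)
    tree <- generate_tree(cfg$n_taxa, cfg$seed)
    res <- seasonality_analysis(cm$table, tree, cm$metadata, metric = metric)
    if (is.null(res)) next
    for (j in seq_len(nrow(res))) {
      ty <- res$sample_type[j]
      hits[[ty]] <- c(hits[[ty]], res$p_value[j] < alpha)
      stat[[ty]] <- c(stat[[ty]], res$statistic[j])
    }
  }
  data.frame(sample_type = names(hits),
             rejection_rate = vapply(hits, mean, numeric(1)),
             mean_statistic = vapply(stat, mean, numeric(1)),
             n_runs = n_runs, row.names = NULL)
}

#' Recovery of the downstream-decaying coliform intervention pattern
#'
#' Over `n_runs` replicate studies with the default ~20-fold effluent
#' reduction and exponential downstream mixing, counts the fraction of runs
#' in which the BH-adjusted coliform bootstrap is significant at every
#' effluent and immediately-downstream site and non-significant at every
#' further-downstream site.
#'
#' @param n_runs replicate studies
#' @param config study configuration (default [synthetic_config()])
#' @param alpha BH-adjusted significance level
#' @param n_boot bootstrap resamples
#' @param seed RNG seed
#' @return list: `pattern_rate`, plus per-role significance rates
#' @export
intervention_recovery <- function(n_runs = 20L, config = NULL, alpha = 0.05,
                                  n_boot = 10000L, seed = 0L) {
  cfg0 <- config %||% synthetic_config()
  pat <- logical(n_runs)
  role_sig <- list(effluent = NULL, immediate_downstream = NULL,
                   further_downstream = NULL)
  for (i in seq_len(n_runs)) {
    cfg <- cfg0
    cfg$seed <- as.integer(seed + i)
    md <- study_metadata(cfg)
    ms <- generate_measurements(cfg, md)
    res <- coliform_analysis(ms$coliform, md, intervention_date =
                             cfg$intervention_date, n_boot = n_boot,
                             seed = seed + 1000L * i)
    sig <- res$p_adjusted < alpha
    by_role <- split(sig, res$spatial_role)
    for (r in names(role_sig))
      role_sig[[r]] <- c(role_sig[[r]], mean(by_role[[r]]))
    pat[i] <- all(by_role$effluent) && all(by_role$immediate_downstream) &&
      !any(by_role$further_downstream)
  }
  list(pattern_rate = mean(pat),
       effluent_sig_rate = mean(role_sig$effluent),
       immediate_sig_rate = mean(role_sig$immediate_downstream),
       further_sig_rate = mean(role_sig$further_downstream),
       n_runs = n_runs)
}
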