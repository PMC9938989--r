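# Shared configuration for the analysis scripts. Each numbered script
# regenerates the synthetic study deterministically from this config (the
# generator takes seconds), so no large intermediates are stored.

library(riverseason)

analysis_config <- function() {
  synthetic_config(n_taxa = 60L, n_sites = 6L, n_years = 7L,
                   reads_per_sample = 1000L, seed = 20L)
}

analysis_study <- function() generate_study(analysis_config())

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}

write_result <- function(df, name) {
  path <- file.path(results_dir(), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  -> ", path)
}
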