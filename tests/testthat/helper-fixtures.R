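# Small fixtures built in code.

tiny_table <- function() {
  m <- matrix(c(5L, 0L, 2L,
                0L, 3L, 1L,
                4L, 4L, 0L), 3, 3, byrow = TRUE,
              dimnames = list(paste0("S", 1:3), paste0("ASV_", 1:3)))
  m
}

tiny_metadata <- function(n = 3) {
  data.frame(sample_id = paste0("S", seq_len(n)),
             site_id = "Calumet_S01", sample_type = "water",
             region = "Calumet", spatial_role = "upstream",
             year = 2015L, month = seq_len(n) + 2L,
             stringsAsFactors = FALSE)
}

# monthly series data.frame over given (year, month) grid
series_df <- function(years, months, values) {
  grid <- expand.grid(month = months, year = years)
  data.frame(year = grid$year, month = grid$month, value = values)
}

small_config <- function(...) {
  synthetic_config(n_taxa = 20L, n_sites = 4L, n_years = 3L,
                   reads_per_sample = 200L, seed = 7L, ...)
}
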