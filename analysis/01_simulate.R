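#!/usr/bin/env Rscript
# Generate the synthetic study: 6 river sites + 2 treatment plants across
# two regions, monthly samples March--November 2013-2019, seasonal
# community oscillation in water/effluent, a ~20x coliform reduction in
# effluent from 2016-01, and physicochemistry with shared seasonality but
# no intervention term.

source("analysis/00_config.R")

study <- analysis_study()

message(sprintf("study: %d samples x %d ASVs, %d sites, %d--%d",
                nrow(study$table), ncol(study$table),
                length(unique(study$metadata$site_id)),
                min(study$metadata$year), max(study$metadata$year)))
message(sprintf("coliform series: %d site-months; physicochemistry: %d values",
                nrow(study$coliform), nrow(study$physchem)))
print(table(study$metadata$sample_type, study$metadata$period))

write_result(site_layout(analysis_config()), "site_layout.tsv")
write_result(study$truth$per_stream, "study_truth.tsv")
write_result(data.frame(coliform_taxon = study$truth$coliform_taxa),
             "coliform_taxa.tsv")
message("done: the study regenerates deterministically from analysis/00_config.R")
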