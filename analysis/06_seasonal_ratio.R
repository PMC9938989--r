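#!/usr/bin/env Rscript
# Seasonal ASV log-ratio index: rank ASVs by mean CLR difference between
# March and August water/effluent samples, take the top/bottom 10, and
# track ln(sum March-associated / sum August-associated) with a
# pseudocount of one across the whole series. The monthly mean should
# trace a smooth annual cycle peaking near March and troughing near
# August.

source("analysis/00_config.R")

study <- analysis_study()
md <- study$metadata[study$metadata$sample_type %in% c("water", "effluent"), ]
tab <- study$table[md$sample_id, ]

sets <- rank_month_associated_asvs(tab, md, month_a = 3, month_b = 8, k = 10)
write_result(data.frame(set = rep(c("march", "august"), each = 10),
                        asv = c(sets$march_asvs, sets$august_asvs),
                        score = round(sets$scores[c(sets$march_asvs,
                                                    sets$august_asvs)], 4)),
             "seasonal_asv_sets.tsv")

ratio <- seasonal_log_ratio(tab, sets)
mm <- monthly_ratio_summary(ratio, md)
print(round(mm, 3))
write_result(round(mm, 5), "seasonal_ratio_monthly.tsv")
message(sprintf("monthly mean ln-ratio peaks in month %d, troughs in month %d",
                mm$month[which.max(mm$mean_ln_ratio)],
                mm$month[which.min(mm$mean_ln_ratio)]))
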