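#!/usr/bin/env Rscript
# Alpha and beta diversity by sample type: Shannon indices with
# Kruskal-Wallis + pairwise Wilcoxon (BH), unweighted UniFrac PCoA,
# PERMANOVA across sample types, and beta dispersion (mean distance to the
# sample-type centroid in ordination space).

source("analysis/00_config.R")

study <- analysis_study()
tab <- rarefy_table(study$table, depth = 800, seed = 2)
md <- study$metadata[match(rownames(tab), study$metadata$sample_id), ]

alpha <- apply(tab, 1, shannon)
cmp <- compare_alpha_groups(alpha, md$sample_type)
message("Shannon by sample type:")
print(round(tapply(alpha, md$sample_type, median), 3))
message(sprintf("Kruskal-Wallis H = %.2f, p = %.3g",
                cmp$omnibus$statistic, cmp$omnibus$p_value))
write_result(cmp$pairwise, "alpha_pairwise_tests.tsv")

# ordination analyses on a per-type subsample to keep the embedding readable
set.seed(3)
keep <- unlist(lapply(split(rownames(tab), md$sample_type),
                      function(ids) sample(ids, min(80, length(ids)))))
dm <- unifrac_matrix(tab[keep, ], study$tree, "unweighted")
groups <- md$sample_type[match(keep, md$sample_id)]

pc <- pcoa(dm)
message(sprintf("PCoA axis 1/2 explain %.1f%% / %.1f%%",
                100 * pc$proportion_explained[1], 100 * pc$proportion_explained[2]))
perma <- permanova(dm, groups, n_perm = 999, seed = 4)
message(sprintf("PERMANOVA across sample types: pseudo-F = %.2f, p = %.3g",
                perma$statistic, perma$p_value))

disp <- beta_dispersion(dm, groups)
message("beta dispersion (mean distance to type centroid):")
print(round(disp, 4))
write_result(data.frame(sample_type = names(disp), dispersion = disp),
             "beta_dispersion.tsv")
write_result(data.frame(sample_id = keep, group = groups,
                        round(pc$coordinates[, 1:2], 5)),
             "pcoa_coordinates.tsv")
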