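#!/usr/bin/env Rscript

# Stage 5: regress exon sequence features (splice-site strengths, PhyloP
# conservation, exon/intron lengths) on regulator multiplicity using the
# per-bin means.

suppressPackageStartupMessages(library(splicedep))

paths <- list.files("results/synthetic/HeLa", pattern = "\\.tsv$",
                    full.names = TRUE)
regulons <- lapply(paths, function(p)
  apply_filter(deduplicate(read_knockdown_table(p, "canonical",
                                                cell_line = "HeLa")),
               hela_policy()))
names(regulons) <- vapply(regulons, `[[`, "", "rbp_name")
profile <- build_multiplicity(regulons)
features <- read_feature_table("results/synthetic/features.tsv")

trend <- feature_trend(profile, features,
                       genome_reference = c(ss5_score = 8.8))
write.table(trend$trends, "results/tables/feature_trends.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(trend$bin_means, "results/tables/feature_bin_means.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

for (f in c("ss5_score", "phylop")) {
  row <- trend$trends[trend$trends$feature == f, ]
  cat(sprintf("%s vs multiplicity: slope %.3f (r^2 %.2f, p %.3g)\n",
              f, row$slope, row$r_squared, row$p_value))
}
cat(sprintf("exons without feature annotation: %d (excluded)\n",
            trend$n_missing_features))
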