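#!/usr/bin/env Rscript

# Stage 4: direction of regulation (enhancer vs silencer activity) over
# total / independent / interdependent exon populations, regulator
# multiplicity spectrum, per-bin direction consistency, and wildtype
# inclusion distributions of the independent vs interdependent exons.

suppressPackageStartupMessages(library(splicedep))

paths <- list.files("results/synthetic/HeLa", pattern = "\\.tsv$",
                    full.names = TRUE)
regulons <- lapply(paths, function(p)
  apply_filter(deduplicate(read_knockdown_table(p, "canonical",
                                                cell_line = "HeLa")),
               hela_policy()))
names(regulons) <- vapply(regulons, `[[`, "", "rbp_name")

profile <- build_multiplicity(regulons)
dirs <- direction_table(regulons, profile)
write.table(dirs, "results/tables/direction_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

mult_hist <- data.frame(count = as.integer(names(profile$bins)),
                        n_exons = lengths(profile$bins))
write.table(mult_hist, "results/tables/multiplicity_histogram.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

consistency <- direction_consistency(profile)
write.table(consistency, "results/tables/direction_consistency.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

incl <- inclusion_distributions(profile)
write.table(incl$histogram, "results/tables/inclusion_distributions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

tot <- dirs[dirs$population == "total" & dirs$n_exons > 0, ]
cat(sprintf("pooled enhancer activity (dPSI < 0): %.1f%% of affected exons\n",
            sum(tot$pct_decrease * tot$n_exons) / sum(tot$n_exons)))
cat(sprintf("multiplicity: %.1f%% of %d exons touched by a single RBP; max %d RBPs per exon\n",
            100 * mean(profile$per_exon$count == 1), nrow(profile$per_exon),
            max(profile$per_exon$count)))
top <- consistency[nrow(consistency), ]
cat(sprintf("mixed-direction regulation rises from 0%% (bin 1) to %.0f%% (bin %d)\n",
            top$pct_both, top$count))
cat(sprintf("intermediate wildtype inclusion (PSI 0.35-0.65): %.1f%% of independent vs %.1f%% of interdependent exons\n",
            100 * incl$intermediate_fraction[["independent"]],
            100 * incl$intermediate_fraction[["interdependent"]]))
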