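#!/usr/bin/env Rscript

# Stage 2: read the simulated knockdown tables back from disk, apply the
# |dPSI| > 15% significance filter, and tabulate per-RBP affected-exon
# counts (the regulon-size spectrum).

suppressPackageStartupMessages(library(splicedep))

in_dir <- "results/synthetic/HeLa"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

paths <- list.files(in_dir, pattern = "\\.tsv$", full.names = TRUE)
stopifnot(length(paths) >= 2)
regulons <- lapply(paths, function(p)
  apply_filter(deduplicate(read_knockdown_table(p, "canonical",
                                                cell_line = "HeLa")),
               hela_policy()))
names(regulons) <- vapply(regulons, `[[`, "", "rbp_name")

counts <- affected_counts(regulons)
write.table(counts, "results/tables/affected_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("filtered %d knockdown tables (HeLa policy: |dPSI| > 15%%)\n",
            length(regulons)))
cat(sprintf("affected exons per RBP: min %d, median %.0f, max %d\n",
            min(counts$n_affected), median(counts$n_affected),
            max(counts$n_affected)))
cat(sprintf("broadest regulator: %s (%d exons); narrowest: %s (%d exons)\n",
            counts$rbp_name[which.max(counts$n_affected)],
            max(counts$n_affected),
            counts$rbp_name[which.min(counts$n_affected)],
            min(counts$n_affected)))
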