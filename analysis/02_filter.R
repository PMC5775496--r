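#!/usr/bin/env Rscript
# Stage 2: locus quality control.
#
# MAF >= 5%, missingness <= 5%, forest-proximity imputation of the sparse
# remaining gaps, then greedy redundancy pruning (keep descending global FST,
# drop anything with r^2 > 0.2 against a kept locus or FST < 0.05). The
# surviving "top loci" are the candidate pool for every selection method.

library(finepanel)

seed <- as.integer(Sys.getenv("FINEPANEL_SEED", "1"))
m <- read_dosage_tsv("results/genotypes.tsv")

cfg <- filter_config(seed = seed)
out <- apply_filters(m, cfg)

cat(sprintf("input loci: %d\n", n_loci(m)))
tab <- table(out$report$reason)
for (r in names(tab)) cat(sprintf("  removed (%s): %d\n", r, tab[[r]]))
cat(sprintf("retained after pruning: %d loci\n", n_loci(out$matrix)))

write_dosage_tsv(out$matrix, "results/genotypes_filtered.tsv")
write.table(out$report, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(out$stats, "results/locus_stats_imputed.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/genotypes_filtered.tsv, filter_report.tsv, locus_stats_imputed.tsv\n")
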