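#!/usr/bin/env Rscript
# Stage 5: compare the selection methods.
#
# Three summaries: (i) the nested polynomial F-test for a selection-method
# effect on the accuracy-vs-size curve; (ii) the smallest panel reaching 90%
# overall holdout accuracy per method; (iii) pairwise mismatch differences
# between the GRRF and FST panels of matched (smallest) size against the
# pairwise FST of each population pair.

library(finepanel)

m <- read_dosage_tsv("results/genotypes_filtered.tsv")
tab <- rbind(read.delim("results/eval_table.tsv", stringsAsFactors = FALSE),
             read.delim("results/eval_table_small.tsv",
                        stringsAsFactors = FALSE))
manifest <- read.delim("results/panel_manifest.tsv", stringsAsFactors = FALSE)
sp_lines <- read.delim("results/split.tsv", header = FALSE,
                       stringsAsFactors = FALSE)
split <- structure(list(training = sp_lines$V2[sp_lines$V1 == "training"],
                        holdout = sp_lines$V2[sp_lines$V1 == "holdout"],
                        fraction = 1 / 3, seed = NA_integer_),
                   class = "split_spec")

eff <- method_effect_test(tab)
cat(sprintf("method effect: F(%d,%d) = %.2f, p = %.4f\n",
            eff$df1, eff$df2, eff$F, eff$p))
writeLines(sprintf("F\t%f\ndf1\t%d\ndf2\t%d\np\t%f",
                   eff$F, eff$df1, eff$df2, eff$p),
           "results/method_effect.tsv")

m90 <- min_panel_for_threshold(tab, 90)
print(m90)
write.table(m90, "results/min_panel_90.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

smallest <- function(mm) {
  sub <- manifest[manifest$method == mm, ]
  best <- sub[which.min(sub$size), ]
  snp_panel(best$method, best$parameter, read_whitelist(best$file))
}
res_fst <- self_assign(m, smallest("FST"), split)
res_grrf <- self_assign(m, smallest("GRRF"), split)
pw <- pairwise_fst(m)
md <- mismatch_delta(res_grrf, res_fst, pw)  # positive: FST panel mismatches more
write.table(md, "results/mismatch_delta.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mismatch delta (FST - GRRF) over %d population pairs: mean %.4f\n",
            nrow(md), mean(md$delta)))
cat("wrote results/method_effect.tsv, min_panel_90.tsv, mismatch_delta.tsv\n")
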