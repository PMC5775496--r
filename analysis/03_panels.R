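#!/usr/bin/env Rscript
# Stage 3: build SNP panels by all four selection methods.
#
# A stratified third of each population is set aside as the training set;
# every panel is derived from those individuals only. GRRF is swept over five
# gamma values; the resulting panel sizes define the matched sizes used for
# the FST-rank and RF-consensus panels (the comparison the whole study turns
# on), and RRF is swept over five lambda values for its own size ladder.

library(finepanel)

seed <- as.integer(Sys.getenv("FINEPANEL_SEED", "1"))
m <- read_dosage_tsv("results/genotypes_filtered.tsv")

split <- training_split(m, fraction = 1 / 3, seed = seed)
train <- subset_individuals(m, split$training)
cat(sprintf("training %d / holdout %d individuals\n",
            length(split$training), length(split$holdout)))

fc <- forest_config(ntree = 2000, seed = seed * 100)

gammas <- c(0.25, 0.15, 0.1, 0.05, 0.01)
lambdas <- c(0.75, 0.85, 0.9, 0.95, 0.99)

grrf <- sweep_panels(train, fc, "GRRF", gammas)
sizes <- vapply(grrf, `[[`, numeric(1), "size")
cat("GRRF sizes over gamma:", paste(sizes, collapse = " "), "\n")

fst <- sweep_panels(train, fc, "FST", sizes)
rf <- sweep_panels(train, fc, "RF", sizes)
rrf <- sweep_panels(train, fc, "RRF", lambdas)
cat("RRF sizes over lambda:", paste(vapply(rrf, `[[`, numeric(1), "size"),
                                    collapse = " "), "\n")

panels <- c(fst, rf, rrf, grrf)
dir.create("results/panels", showWarnings = FALSE)
manifest <- do.call(rbind, lapply(seq_along(panels), function(i) {
  p <- panels[[i]]
  file <- sprintf("results/panels/%s_%02d.txt", tolower(p$method), i)
  write_whitelist(p, file)
  data.frame(method = p$method, parameter = p$parameter, size = p$size,
             file = file, stringsAsFactors = FALSE)
}))
write.table(manifest, "results/panel_manifest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(c(paste0("training\t", split$training),
             paste0("holdout\t", split$holdout)),
           "results/split.tsv")
print(manifest[, c("method", "parameter", "size")])
cat("wrote results/panels/, panel_manifest.tsv, split.tsv\n")
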