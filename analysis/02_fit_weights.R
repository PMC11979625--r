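#!/usr/bin/env Rscript
# Stage 2: train cis-SNP protein weight models (top1, blup/ridge, lasso,
# elastic net) for every simulated gene and write the weight files.

source("analysis/_common.R")

study <- build_study()
genes <- study$pqtl$genes

models <- lapply(seq_len(nrow(genes)), function(g) {
  fit_weights(study$pqtl$genotypes[, genes$snp_ids[[g]], drop = FALSE],
              study$pqtl$abundance[, g], ld = study$ld,
              gene = genes$gene[g], seed = study$sc$seed + 10L + g)
})

wdir <- res_dir("weights")
write_weights(models, genes, wdir)

idx <- read.delim(file.path(wdir, "index.tsv"))
cat("Fitted weight models for", nrow(idx), "genes ->", wdir, "\n")
cat("Chosen models:\n")
print(table(idx$best_model))
cat("Median cv R2 of the chosen model:",
    round(median(apply(idx[, c("top1", "blup", "lasso", "enet")], 1, max)),
          3), "\n")
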