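#!/usr/bin/env Rscript
# Stage 3: proteome-wide association. Combines each gene's cis weights
# with the GWAS z-scores of both traits (z_pwas = w'z / sqrt(w'Rw)) and
# flags proteome-wide significant genes per trait; the genes significant
# for both traits are the PWAS overlap set.

source("analysis/_common.R")

study <- build_study()
genes <- study$pqtl$genes

# read the summary statistics back through the TSV interface
gwas1 <- read_gwas("results/data/gwas_trait1.tsv")
gwas2 <- read_gwas("results/data/gwas_trait2.tsv")

models <- lapply(seq_len(nrow(genes)), function(g) {
  fit_weights(study$pqtl$genotypes[, genes$snp_ids[[g]], drop = FALSE],
              study$pqtl$abundance[, g], ld = study$ld,
              gene = genes$gene[g], seed = study$sc$seed + 10L + g)
})

score <- function(gwas) {
  res <- do.call(rbind, lapply(models, pwas_association, gwas = gwas,
                               ld = study$ld))
  flag_significant(res, method = "bh_fdr", alpha = 0.05)
}
pwas1 <- score(gwas1)
pwas2 <- score(gwas2)

out <- res_dir("pwas")
write.table(pwas1, file.path(out, "pwas_trait1.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pwas2, file.path(out, "pwas_trait2.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

overlap <- intersect(pwas1$gene[pwas1$significant],
                     pwas2$gene[pwas2$significant])
cat("PWAS-significant genes: trait 1 =", sum(pwas1$significant),
    ", trait 2 =", sum(pwas2$significant), "\n")
cat("Overlap (significant for both):",
    if (length(overlap)) paste(overlap, collapse = ", ") else "(none)", "\n")
cat("Planted gene", study$plant_gene, "in overlap:",
    study$plant_gene %in% overlap, "\n")
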