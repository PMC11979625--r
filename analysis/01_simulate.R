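#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study and write its input files.
#
# Emulates the statistical structure of a two-trait shared-risk study: an
# LD reference panel, a cis-pQTL weight-training cohort, paired GWAS
# summary statistics for two traits with one planted pleiotropic gene, and
# a case/control expression matrix with that gene downregulated in cases.

source("analysis/_common.R")

study <- build_study()
data_dir <- res_dir("data")

write_gwas(study$biv$gwas1, file.path(data_dir, "gwas_trait1.tsv"))
write_gwas(study$biv$gwas2, file.path(data_dir, "gwas_trait2.tsv"))
write_expression(study$expr, file.path(data_dir, "expression.tsv"))

panel <- study$ld$panel
names(panel) <- c("SNP", "CHR", "BP", "A1", "A2", "MAF", "BLOCK")
write.table(panel, file.path(data_dir, "panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# gene annotation as BED (0-based half-open)
genes <- study$pqtl$genes
bed <- data.frame(chrom = paste0("chr", genes$chrom),
                  start = genes$start - 1, end = genes$end,
                  name = genes$gene)
write.table(bed, file.path(data_dir, "genes.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

# planted truth, the scoring key for everything downstream
write.table(study$biv$truth[study$biv$truth$class != "null", ],
            file.path(data_dir, "gwas_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(study$pqtl$truth, file.path(data_dir, "pqtl_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated study written to", data_dir, "\n")
cat("  variants:", nrow(panel), " genes:", nrow(genes), "\n")
cat("  planted three-way gene:", study$plant_gene, "( causal SNP",
    study$biv$truth$id[study$biv$truth$class == "shared"][1], ")\n")
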