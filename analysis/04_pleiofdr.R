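#!/usr/bin/env Rscript
# Stage 4: pleiotropy-informed conditional FDR. Builds conditional Q-Q
# curves, the two reciprocal condFDR lookups (with LD random-pruning
# weights), the per-variant conjFDR, and clumps significant variants into
# shared loci with lead SNPs, mapped genes and direction concordance.

source("analysis/_common.R")

study <- build_study()
gwas1 <- study$biv$gwas1
gwas2 <- study$biv$gwas2

qq <- conditional_qq(gwas1, gwas2)
weights <- random_prune(study$ld, r2_max = 0.1, n_iter = 100L,
                        seed = study$sc$seed + 40L)
lk12 <- build_condfdr_lookup(gwas1, gwas2, weights)
lk21 <- build_condfdr_lookup(gwas2, gwas1, weights)
cond12 <- assign_condfdr(gwas1, gwas2, lk12)
cond21 <- assign_condfdr(gwas2, gwas1, lk21)
cj <- conjfdr(cond12, cond21)

per_variant <- data.frame(SNP = names(cj), CHR = gwas1$chrom,
                          BP = gwas1$pos, p1 = gwas1$p, p2 = gwas2$p,
                          condfdr_1_2 = cond12, condfdr_2_1 = cond21,
                          conjfdr = cj)
loci <- define_loci(data.frame(id = names(cj), conjfdr = cj, p1 = gwas1$p),
                    study$ld, threshold = 0.01, r2_clump = 0.1)
annotation <- read_annotation("results/data/genes.bed")
loci <- map_genes(loci, annotation)
if (nrow(loci)) loci <- concordance_check(loci, gwas1, gwas2)

out <- res_dir("pleiofdr")
write.table(per_variant, file.path(out, "condfdr_per_variant.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(qq, file.path(out, "conditional_qq.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
loci_out <- loci
loci_out$members <- vapply(loci_out$members, paste, character(1),
                           collapse = ",")
loci_out$mapped_genes <- NULL
write.table(loci_out, file.path(out, "shared_loci.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

fig <- res_dir("figures")
ggplot2::ggsave(file.path(fig, "conditional_qq.pdf"),
                plot_conditional_qq(qq), width = 5, height = 4)
ggplot2::ggsave(file.path(fig, "manhattan_conjfdr.pdf"),
                plot_manhattan(data.frame(id = names(cj), conjfdr = cj),
                               study$ld, loci),
                width = 8, height = 3.5)

cat("Variants at conjFDR < 0.01:", sum(cj < 0.01), "at", nrow(loci),
    "loci\n")
if (nrow(loci)) {
  cat("Lead SNPs:", paste(loci$lead_snp, collapse = ", "), "\n")
  cat("Mapped genes:",
      paste(unique(unlist(loci$mapped_genes)), collapse = ", "), "\n")
  cat("Direction-concordant leads:", sum(loci$concordant), "/",
      nrow(loci), "\n")
}
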