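# Shared study definition for the analysis scripts. Everything downstream
# is a pure function of this scenario and the seeds below, so any script
# can regenerate the simulated study deterministically.

library(pleiopwas)

STUDY_SEED <- 2026L

# Study-scale synthetic scenario: 20000 variants in 200 AR(1) LD blocks,
# 50 cis-regulated proteins trained on 400 reference samples.
study_scenario <- function() scenario_config(seed = STUDY_SEED)

# One gene is planted as the three-way signal the pipeline is built to
# find: its causal cis variant is a shared causal variant for both traits
# (expected lead z = 8) and its transcript is downregulated by 2 SD in
# cases.
PLANT <- list(gene_index = 7L, lead_z = 8, expr_shift = -2)

DE_GROUPS <- c(control = 10L, case = 10L)

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# Rebuild the simulated study inputs (panel, training data, GWAS pair,
# expression) exactly as 01_simulate.R wrote them.
build_study <- function() {
  sc <- study_scenario()
  ld <- simulate_ld_panel(sc)
  pqtl <- simulate_pqtl_training(ld, sc)
  plant_gene <- pqtl$genes$gene[PLANT$gene_index]
  causal <- pqtl$truth$snp[pqtl$truth$gene == plant_gene]
  planted_gwas <- data.frame(id = causal,
                             beta1 = PLANT$lead_z / sqrt(sc$n_gwas1),
                             beta2 = PLANT$lead_z / sqrt(sc$n_gwas2))
  biv <- simulate_bivariate_gwas(ld, sc, planted = planted_gwas)
  expr <- simulate_expression(
    sc$n_genes, DE_GROUPS,
    planted = data.frame(gene = plant_gene, group = "case",
                         shift = PLANT$expr_shift),
    seed = sc$seed + 3L)
  list(sc = sc, ld = ld, pqtl = pqtl, biv = biv, expr = expr,
       plant_gene = plant_gene)
}
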