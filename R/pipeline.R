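#' End-to-end pipeline configuration
#'
#' Collects every stage's tunables with the package defaults. Unknown
#' arguments fail immediately (strict parsing), so a misspelled key can
#' never silently fall back to a default.
#'
#' @param scenario A [scenario_config()] describing the synthetic study.
#' @param stages Character subset of `c("simulate", "fit_weights", "pwas",
#'   "pleiofdr", "de")`, executed in this order.
#' @param plant Optional list planting a three-way gene: fields
#'   `gene_index` (which simulated gene), `lead_z` (target per-trait lead
#'   z-score at its causal cis SNP) and `expr_shift` (expression shift in
#'   cases, in baseline SDs). This mirrors a gene that is cis-regulator,
#'   shared causal variant, and differentially expressed at once.
#' @param pwas_mt_method,pwas_alpha Multiple-testing rule and level for the
#'   PWAS stage.
#' @param min_overlap Minimum model-SNP overlap fraction for scoring a gene.
#' @param conjfdr_threshold conjFDR significance threshold (default 0.01).
#' @param r2_prune,prune_iters Random-pruning parameters for the condFDR
#'   lookup.
#' @param r2_clump Locus-clumping r-squared.
#' @param qq_strata Conditional Q-Q strata.
#' @param de_groups Named sizes of the expression groups (first = control,
#'   second = case for the two-group test).
#' @param de_alpha DE call threshold.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            stages = c("simulate", "fit_weights", "pwas",
                                       "pleiofdr", "de"),
                            plant = NULL,
                            pwas_mt_method = "bh_fdr",
                            pwas_alpha = 0.05,
                            min_overlap = 0.5,
                            conjfdr_threshold = 0.01,
                            r2_prune = 0.1,
                            prune_iters = 100L,
                            r2_clump = 0.1,
                            qq_strata = c(1, 0.1, 0.01, 0.001),
                            de_groups = c(control = 10L, case = 10L),
                            de_alpha = 0.05) {
  stopifnot(inherits(scenario, "scenario_config"))
  bad <- setdiff(stages, c("simulate", "fit_weights", "pwas", "pleiofdr", "de"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(plant)) {
    extra <- setdiff(names(plant), c("gene_index", "lead_z", "expr_shift"))
    if (length(extra)) stop("unknown plant fields: ",
                            paste(extra, collapse = ", "), call. = FALSE)
  }
  structure(list(
    scenario = scenario, stages = stages, plant = plant,
    pwas_mt_method = pwas_mt_method, pwas_alpha = pwas_alpha,
    min_overlap = min_overlap,
    conjfdr_threshold = conjfdr_threshold,
    r2_prune = r2_prune, prune_iters = check_count(prune_iters, "prune_iters"),
    r2_clump = r2_clump, qq_strata = qq_strata,
    de_groups = de_groups, de_alpha = de_alpha
  ), class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Chains simulate -> fit_weights -> pwas (both traits) -> pleiofdr -> de on
#' a synthetic scenario and returns a combined report: per-stage outputs,
#' the overlap of PWAS-significant genes between the two traits, conjFDR
#' loci with mapped genes, DE-called genes, and the fully resolved
#' configuration. Identical configuration implies identical report. When
#' `out_dir` is given, the stage tables and the resolved configuration are
#' written there as TSV/JSON.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$scenario
  report <- list(config = config, stages_run = character(0))
  run <- function(stage) stage %in% config$stages

  if (!run("simulate") && any(run(c("fit_weights", "pwas", "pleiofdr", "de")))) {
    stop("downstream stages require the simulate stage in this synthetic ",
         "pipeline", call. = FALSE)
  }
  if (run("pwas") && !run("fit_weights")) {
    stop("the pwas stage requires fit_weights", call. = FALSE)
  }
  if (!length(config$stages)) return(structure(report, class = "pipeline_report"))

  ld <- simulate_ld_panel(sc)
  pqtl <- simulate_pqtl_training(ld, sc)
  genes <- pqtl$genes

  planted_gwas <- NULL
  planted_expr <- NULL
  plant_gene <- NA_character_
  if (!is.null(config$plant)) {
    gi <- check_count(config$plant$gene_index, "plant$gene_index")
    plant_gene <- genes$gene[gi]
    causal <- pqtl$truth$snp[pqtl$truth$gene == plant_gene]
    if (!length(causal)) {
      stop("planted gene has no causal cis SNP; use a scenario with ",
           "n_causal_cis > 0", call. = FALSE)
    }
    beta <- config$plant$lead_z / sqrt(sc$n_gwas1)
    beta2 <- config$plant$lead_z / sqrt(sc$n_gwas2)
    planted_gwas <- data.frame(id = causal, beta1 = beta, beta2 = beta2)
    planted_expr <- data.frame(gene = plant_gene,
                               group = names(config$de_groups)[2],
                               shift = config$plant$expr_shift)
  }

  biv <- simulate_bivariate_gwas(ld, sc, planted = planted_gwas)
  expr <- simulate_expression(sc$n_genes, config$de_groups,
                              planted = planted_expr, seed = sc$seed + 3L)
  report$ld <- ld
  report$genes <- genes
  report$gwas_truth <- biv$truth
  report$stages_run <- "simulate"

  if (run("fit_weights")) {
    models <- lapply(seq_len(nrow(genes)), function(g) {
      fit_weights(pqtl$genotypes[, genes$snp_ids[[g]], drop = FALSE],
                  pqtl$abundance[, g], ld = ld, gene = genes$gene[g],
                  seed = sc$seed + 10L + g)
    })
    report$models <- models
    report$stages_run <- c(report$stages_run, "fit_weights")
  }

  if (run("pwas")) {
    score <- function(gwas) {
      res <- do.call(rbind, lapply(report$models, pwas_association,
                                   gwas = gwas, ld = ld,
                                   min_overlap = config$min_overlap))
      flag_significant(res, method = config$pwas_mt_method,
                       alpha = config$pwas_alpha)
    }
    report$pwas1 <- score(biv$gwas1)
    report$pwas2 <- score(biv$gwas2)
    report$pwas_overlap <- intersect(
      report$pwas1$gene[report$pwas1$significant],
      report$pwas2$gene[report$pwas2$significant]
    )
    report$stages_run <- c(report$stages_run, "pwas")
  }

  if (run("pleiofdr")) {
    weights <- random_prune(ld, r2_max = config$r2_prune,
                            n_iter = config$prune_iters, seed = sc$seed + 40L)
    lk12 <- build_condfdr_lookup(biv$gwas1, biv$gwas2, weights)
    lk21 <- build_condfdr_lookup(biv$gwas2, biv$gwas1, weights)
    cond12 <- assign_condfdr(biv$gwas1, biv$gwas2, lk12)
    cond21 <- assign_condfdr(biv$gwas2, biv$gwas1, lk21)
    cj <- conjfdr(cond12, cond21)
    per_variant <- data.frame(id = names(cj), p1 = biv$gwas1$p,
                              p2 = biv$gwas2$p, cond12 = cond12,
                              cond21 = cond21, conjfdr = cj,
                              stringsAsFactors = FALSE)
    loci <- define_loci(per_variant, ld,
                        threshold = config$conjfdr_threshold,
                        r2_clump = config$r2_clump)
    loci <- map_genes(loci, genes)
    if (nrow(loci)) loci <- concordance_check(loci, biv$gwas1, biv$gwas2)
    report$qq <- conditional_qq(biv$gwas1, biv$gwas2, config$qq_strata)
    report$per_variant <- per_variant
    report$loci <- loci
    report$stages_run <- c(report$stages_run, "pleiofdr")
  }

  if (run("de")) {
    grp <- names(config$de_groups)
    de <- do.call(rbind, lapply(rownames(expr$values), function(g) {
      two_group_test(expr, g, grp[1:2], alpha = config$de_alpha,
                     seed = sc$seed + 50L)
    }))
    de$p_adjusted <- bh_adjust(de$p)
    report$de <- de
    report$de_called <- de$gene[de$called]
    report$stages_run <- c(report$stages_run, "de")
  }

  if (!is.na(plant_gene)) {
    report$plant_gene <- plant_gene
    locus_genes <- if (!is.null(report$loci) && nrow(report$loci)) {
      unique(unlist(report$loci$mapped_genes))
    } else character(0)
    case_col <- paste0("mean_", names(config$de_groups)[2])
    ctrl_col <- paste0("mean_", names(config$de_groups)[1])
    de_row <- if (!is.null(report$de)) {
      report$de[report$de$gene == plant_gene, , drop = FALSE]
    } else NULL
    report$triple_hit <- list(
      pwas_overlap = plant_gene %in% (report$pwas_overlap %||% character(0)),
      conjfdr_locus = plant_gene %in% locus_genes,
      de_called = !is.null(de_row) && nrow(de_row) == 1 && de_row$called &&
        de_row[[case_col]] < de_row[[ctrl_col]]
    )
    report$triple_hit$all <- all(unlist(report$triple_hit))
  }

  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  structure(report, class = "pipeline_report")
}

#' @noRd
write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cfg <- report$config
  resolved <- c(unclass(cfg$scenario),
                cfg[setdiff(names(cfg), "scenario")])
  resolved$plant <- if (is.null(resolved$plant)) NULL else as.list(resolved$plant)
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(report$pwas1)) wt(report$pwas1, "pwas_trait1.tsv")
  if (!is.null(report$pwas2)) wt(report$pwas2, "pwas_trait2.tsv")
  if (!is.null(report$per_variant)) wt(report$per_variant, "condfdr_per_variant.tsv")
  if (!is.null(report$loci)) {
    loci <- report$loci
    loci$members <- vapply(loci$members, paste, character(1), collapse = ",")
    loci$mapped_genes <- NULL
    wt(loci, "shared_loci.tsv")
  }
  if (!is.null(report$qq)) wt(report$qq, "conditional_qq.tsv")
  if (!is.null(report$de)) wt(report$de, "de_results.tsv")
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report - stages:", paste(x$stages_run, collapse = " -> "), "\n")
  if (!is.null(x$pwas_overlap)) {
    cat("  PWAS-significant overlap:",
        if (length(x$pwas_overlap)) paste(x$pwas_overlap, collapse = ", ")
        else "(none)", "\n")
  }
  if (!is.null(x$loci)) {
    cat("  conjFDR loci:", nrow(x$loci), "\n")
  }
  if (!is.null(x$de_called)) {
    cat("  DE-called genes:", length(x$de_called), "\n")
  }
  if (!is.null(x$triple_hit)) {
    cat("  planted gene", x$plant_gene, "triple hit:",
        x$triple_hit$all, "\n")
  }
  invisible(x)
}
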