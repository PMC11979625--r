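#' Simulation scenario configuration
#'
#' Bundles and validates every parameter of the synthetic-data generators:
#' the LD panel layout, the cis-genetic architecture of protein abundance,
#' the bivariate GWAS mixture, and the sample sizes. All generators are pure
#' functions of a `scenario_config` plus their `seed`, so any dataset can be
#' reproduced exactly.
#'
#' @param n_variants Total number of variants in the panel.
#' @param n_blocks Number of independent LD blocks; variants are split as
#'   evenly as possible across blocks and correlation is exactly zero across
#'   blocks.
#' @param block_rho Within-block AR(1) correlation parameter in \[0, 1);
#'   variants i and j of one block have correlation `block_rho^|i-j|`.
#' @param maf_range Length-2 numeric, lower and upper bound of the uniform
#'   minor-allele-frequency draw, each in (0, 0.5].
#' @param n_genes Number of genes with a cis-regulated protein product.
#' @param cis_window_bp Width in bases of the cis window around each gene.
#' @param h2_cis Cis heritability of protein abundance in \[0, 1\]: the
#'   expected fraction of abundance variance explained by the causal cis
#'   genotypes.
#' @param n_causal_cis Number of causal cis variants per gene.
#' @param n_ref Sample size of the weight-training (pQTL reference) cohort.
#' @param pi_shared,pi1,pi2 Fractions of panel variants causal for both
#'   traits, trait 1 only, and trait 2 only; the remainder is null. Must sum
#'   to at most 1.
#' @param sigma_beta Standard deviation of per-causal-variant standardized
#'   effect sizes.
#' @param n_gwas1,n_gwas2 GWAS sample sizes for the two traits.
#' @param seed Integer seed recorded with the scenario.
#' @return An object of class `scenario_config` (a validated named list).
#' @export
scenario_config <- function(n_variants = 20000L,
                            n_blocks = 200L,
                            block_rho = 0.8,
                            maf_range = c(0.05, 0.5),
                            n_genes = 50L,
                            cis_window_bp = 100000L,
                            h2_cis = 0.2,
                            n_causal_cis = 1L,
                            n_ref = 400L,
                            pi_shared = 0.0,
                            pi1 = 0.0,
                            pi2 = 0.0,
                            sigma_beta = 0.05,
                            n_gwas1 = 50000L,
                            n_gwas2 = 50000L,
                            seed = 1L) {
  cfg <- list(
    n_variants = check_count(n_variants, "n_variants"),
    n_blocks = check_count(n_blocks, "n_blocks"),
    block_rho = check_prob(block_rho, "block_rho", 0, 1, hi_open = TRUE),
    maf_range = maf_range,
    n_genes = check_count(n_genes, "n_genes"),
    cis_window_bp = check_count(cis_window_bp, "cis_window_bp"),
    h2_cis = check_prob(h2_cis, "h2_cis"),
    n_causal_cis = check_count(n_causal_cis, "n_causal_cis", min = 0L),
    n_ref = check_count(n_ref, "n_ref", min = 2L),
    pi_shared = check_prob(pi_shared, "pi_shared"),
    pi1 = check_prob(pi1, "pi1"),
    pi2 = check_prob(pi2, "pi2"),
    sigma_beta = check_prob(sigma_beta, "sigma_beta", 0, Inf),
    n_gwas1 = check_count(n_gwas1, "n_gwas1"),
    n_gwas2 = check_count(n_gwas2, "n_gwas2"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$maf_range) != 2L || !is.numeric(cfg$maf_range) ||
      any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("'maf_range' must be two frequencies in (0, 0.5] with low <= high",
         call. = FALSE)
  }
  if (cfg$pi_shared + cfg$pi1 + cfg$pi2 > 1) {
    stop("'pi_shared' + 'pi1' + 'pi2' must not exceed 1", call. = FALSE)
  }
  if (cfg$n_variants < cfg$n_blocks) {
    stop("'n_variants' must be at least 'n_blocks'", call. = FALSE)
  }
  if (cfg$h2_cis == 0 && cfg$n_causal_cis > 0) {
    stop(paste0("'h2_cis' = 0 contradicts 'n_causal_cis' > 0; ",
                "set n_causal_cis = 0 for a null architecture"), call. = FALSE)
  }
  if (cfg$h2_cis > 0 && cfg$n_causal_cis == 0) {
    stop("'n_causal_cis' = 0 contradicts 'h2_cis' > 0", call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$n_variants, "variants in", x$n_blocks,
      "AR(1) blocks (rho =", x$block_rho, ")\n")
  cat("  genes:", x$n_genes, " h2_cis:", x$h2_cis,
      " causal cis/gene:", x$n_causal_cis, " n_ref:", x$n_ref, "\n")
  cat("  mixture (shared/t1/t2):", x$pi_shared, x$pi1, x$pi2,
      " sigma_beta:", x$sigma_beta, "\n")
  cat("  GWAS N:", x$n_gwas1, "/", x$n_gwas2, " seed:", x$seed, "\n")
  invisible(x)
}
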