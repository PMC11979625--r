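#' Gene annotation for a simulated panel
#'
#' Assigns each gene to an LD block (round-robin) and gives it a cis interval
#' centred on the block, at most `cis_window_bp` wide, clipped to the block's
#' variant positions. The gene's cis variants are the panel variants inside
#' that interval. Intervals are 1-based inclusive, matching the panel.
#'
#' @param ld An `ld_reference`.
#' @param config A [scenario_config()].
#' @return Data frame with columns gene, chrom, start, end, block_id, and a
#'   list column `snp_ids` of cis variant ids.
#' @export
gene_annotation <- function(ld, config) {
  stopifnot(inherits(ld, "ld_reference"), inherits(config, "scenario_config"))
  ng <- config$n_genes
  nb <- length(ld$blocks)
  genes <- vector("list", ng)
  for (g in seq_len(ng)) {
    b <- ((g - 1L) %% nb) + 1L
    rows <- block_rows(ld, b)
    pos <- ld$panel$pos[rows]
    centre <- pos[ceiling(length(pos) / 2)]
    lo <- max(min(pos), centre - config$cis_window_bp %/% 2L)
    hi <- min(max(pos), centre + config$cis_window_bp %/% 2L)
    keep <- rows[pos >= lo & pos <= hi]
    genes[[g]] <- list(
      gene = sprintf("GENE%03d", g),
      chrom = ld$panel$chrom[rows[1]],
      start = lo, end = hi, block_id = b,
      snp_ids = ld$panel$id[keep]
    )
  }
  out <- data.frame(
    gene = vapply(genes, `[[`, character(1), "gene"),
    chrom = vapply(genes, `[[`, integer(1), "chrom"),
    start = vapply(genes, `[[`, numeric(1), "start"),
    end = vapply(genes, `[[`, numeric(1), "end"),
    block_id = vapply(genes, `[[`, integer(1), "block_id"),
    stringsAsFactors = FALSE
  )
  out$snp_ids <- lapply(genes, `[[`, "snp_ids")
  out
}

#' Simulate a pQTL weight-training dataset
#'
#' Draws `n_ref` individuals' genotypes from the panel and, per gene, a
#' protein abundance with a sparse cis-genetic component: `n_causal_cis`
#' variants of the gene's cis window receive nonzero effects, and Gaussian
#' noise is scaled so the genetic fraction of abundance variance equals
#' `h2_cis` (computed on the realized genetic component, so the sample-level
#' variance partition matches the target in expectation). With `h2_cis = 0`
#' the abundance is pure noise.
#'
#' @param ld An `ld_reference`.
#' @param config A [scenario_config()].
#' @param seed Integer seed; defaults to `config$seed + 1`.
#' @return List with `genotypes` (n_ref x n_variants dosage matrix),
#'   `abundance` (n_ref x n_genes matrix, columns named by gene), `genes`
#'   (the [gene_annotation()] table) and `truth` (data frame gene, snp, beta
#'   of all planted cis effects).
#' @export
simulate_pqtl_training <- function(ld, config, seed = config$seed + 1L) {
  stopifnot(inherits(ld, "ld_reference"), inherits(config, "scenario_config"))
  genes <- gene_annotation(ld, config)
  n_cis <- vapply(genes$snp_ids, length, integer(1))
  if (any(n_cis < config$n_causal_cis)) {
    stop(sprintf("gene %s has %d cis variants < n_causal_cis = %d",
                 genes$gene[which.min(n_cis)], min(n_cis),
                 config$n_causal_cis), call. = FALSE)
  }
  G <- simulate_genotypes(ld, config$n_ref, seed)
  set.seed(seed + 500000L)

  ng <- config$n_genes
  abundance <- matrix(NA_real_, config$n_ref, ng,
                      dimnames = list(NULL, genes$gene))
  truth <- vector("list", ng)
  for (g in seq_len(ng)) {
    snps <- genes$snp_ids[[g]]
    if (config$h2_cis == 0 || config$n_causal_cis == 0L) {
      abundance[, g] <- stats::rnorm(config$n_ref)
      truth[[g]] <- data.frame(gene = character(0), snp = character(0),
                               beta = numeric(0))
      next
    }
    causal <- sample(snps, config$n_causal_cis)
    beta <- stats::rnorm(config$n_causal_cis)
    gcomp <- as.vector(G[, causal, drop = FALSE] %*% beta)
    vg <- stats::var(gcomp)
    if (vg <= 0) { # degenerate draw (monomorphic causal set): noise only
      abundance[, g] <- stats::rnorm(config$n_ref)
    } else {
      sd_e <- sqrt(vg * (1 - config$h2_cis) / config$h2_cis)
      abundance[, g] <- gcomp + stats::rnorm(config$n_ref, sd = sd_e)
    }
    truth[[g]] <- data.frame(gene = genes$gene[g], snp = causal, beta = beta,
                             stringsAsFactors = FALSE)
  }
  list(
    genotypes = G,
    abundance = abundance,
    genes = genes,
    truth = do.call(rbind, truth)
  )
}
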