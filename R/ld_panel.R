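#' Simulate an LD reference panel with block-diagonal AR(1) correlation
#'
#' Builds a variant panel of `n_variants` SNPs split across `n_blocks`
#' independent LD blocks. Within a block the correlation between variants at
#' in-block offsets i and j is exactly `block_rho^|i-j|`; across blocks it is
#' zero by construction. Blocks are laid out round-robin over 22 chromosomes
#' with strictly increasing positions per chromosome, and each variant gets a
#' uniform MAF draw from `maf_range` and a random pair of effect/other
#' alleles.
#'
#' The AR(1) choice gives every LD-dependent computation (pruning, clumping,
#' the PWAS denominator) a closed-form oracle.
#'
#' @param config A [scenario_config()].
#' @return An object of class `ld_reference`: a list with `panel` (data frame
#'   with columns id, chrom, pos, effect_allele, other_allele, maf, block_id)
#'   and `blocks` (list of within-block correlation matrices).
#' @export
simulate_ld_panel <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)

  m <- config$n_variants
  nb <- config$n_blocks
  sizes <- rep(m %/% nb, nb)
  extra <- m %% nb
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block_id <- rep(seq_len(nb), times = sizes)

  chrom <- ((seq_len(nb) - 1L) %% 22L) + 1L
  # positions: per chromosome, variants 1.5 kb apart, 1 Mb gap between blocks
  pos <- integer(m)
  chrom_cursor <- integer(22)
  offset <- 0L
  for (b in seq_len(nb)) {
    ch <- chrom[b]
    start <- chrom_cursor[ch] + 1000000L
    idx <- offset + seq_len(sizes[b])
    pos[idx] <- start + (seq_len(sizes[b]) - 1L) * 1500L
    chrom_cursor[ch] <- pos[idx[length(idx)]]
    offset <- offset + sizes[b]
  }

  # allele pairs avoid strand-ambiguous combinations (A/T, C/G) so that
  # simulated summary statistics are fully usable after allele alignment
  alleles <- c("A", "C", "G", "T")
  complement <- c(A = "T", C = "G", G = "C", T = "A")
  a1 <- sample(alleles, m, replace = TRUE)
  a2 <- vapply(a1, function(a) {
    sample(setdiff(alleles, c(a, complement[[a]])), 1L)
  }, character(1))
  # MAFs sorted within a block: adjacent variants then have similar
  # frequencies, which keeps the haplotype Markov construction in
  # simulate_genotypes feasible at the target adjacent correlation
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  maf <- unlist(lapply(split(maf, block_id), sort), use.names = FALSE)

  panel <- data.frame(
    id = sprintf("rs%06d", seq_len(m)),
    chrom = chrom[block_id],
    pos = pos,
    effect_allele = a1,
    other_allele = a2,
    maf = maf,
    block_id = block_id,
    stringsAsFactors = FALSE
  )

  blocks <- lapply(sizes, function(s) ar1_matrix(s, config$block_rho))

  structure(
    list(panel = panel, blocks = blocks, block_rho = config$block_rho),
    class = "ld_reference"
  )
}

#' AR(1) correlation matrix
#' @param n Dimension.
#' @param rho Correlation parameter in \[0, 1).
#' @return n x n matrix with entries `rho^|i-j|`.
#' @export
ar1_matrix <- function(n, rho) {
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

#' @export
print.ld_reference <- function(x, ...) {
  cat("LD reference:", nrow(x$panel), "variants,", length(x$blocks),
      "blocks, AR(1) rho =", x$block_rho, "\n")
  invisible(x)
}

#' Row indices of a block's variants in the panel
#' @noRd
block_rows <- function(ld, b) which(ld$panel$block_id == b)

#' LD submatrix for an arbitrary set of panel variant ids
#'
#' Returns the correlation matrix of the given variants, assembled from the
#' per-block matrices; pairs in different blocks get correlation 0.
#'
#' @param ld An `ld_reference`.
#' @param ids Character vector of variant ids (order preserved).
#' @return Correlation matrix with dimnames `ids`.
#' @export
ld_submatrix <- function(ld, ids) {
  ridx <- match(ids, ld$panel$id)
  if (anyNA(ridx)) {
    stop("unknown variant ids: ", paste(ids[is.na(ridx)], collapse = ", "),
         call. = FALSE)
  }
  k <- length(ids)
  R <- diag(1, k)
  bid <- ld$panel$block_id[ridx]
  for (b in unique(bid)) {
    sel <- which(bid == b)
    if (length(sel) < 2L) next
    within <- match(ridx[sel], block_rows(ld, b))
    R[sel, sel] <- ld$blocks[[b]][within, within]
  }
  dimnames(R) <- list(ids, ids)
  R
}

#' Simulate genotype dosages consistent with the panel
#'
#' Draws `n` individuals' dosages (0/1/2) as the sum of two independent
#' haplotypes. Within a block each haplotype is a binary Markov chain along
#' the variants: allele i+1 is Bernoulli with marginal equal to the panel
#' MAF and correlation `block_rho` with allele i. Because the conditional
#' expectation of a binary variable is linear, correlations multiply along
#' the chain, so the dosage correlation between variants at lag d is
#' `block_rho^d` — the panel's AR(1) target — exactly in expectation
#' (adjacent correlations are truncated to the feasible range when
#' neighbouring MAFs differ too much for the target, which the sorted
#' within-block MAFs make rare). Marginals are binomial(2, maf).
#'
#' @param ld An `ld_reference`.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return n x n_variants integer matrix, columns named by variant id.
#' @export
simulate_genotypes <- function(ld, n, seed) {
  n <- check_count(n, "n")
  set.seed(check_count(seed, "seed", min = 0L))
  m <- nrow(ld$panel)
  G <- matrix(0L, n, m, dimnames = list(NULL, ld$panel$id))
  rho <- ld$block_rho
  for (b in seq_along(ld$blocks)) {
    idx <- block_rows(ld, b)
    maf <- ld$panel$maf[idx]
    k <- length(idx)
    block <- matrix(0L, n, k)
    for (hap in 1:2) {
      H <- matrix(0L, n, k)
      H[, 1] <- stats::rbinom(n, 1L, maf[1])
      for (j in seq_len(k - 1L)) {
        p <- maf[j]
        q <- maf[j + 1L]
        # conditional Bernoulli giving marginal q and correlation rho with
        # the previous site, truncated to a valid probability pair
        s <- sqrt(q * (1 - q) / (p * (1 - p)))
        r <- min(rho, sqrt(min(p * (1 - q) / (q * (1 - p)),
                               q * (1 - p) / (p * (1 - q)))))
        b1 <- r * s
        a1 <- q - b1 * p
        pr <- pmin(pmax(a1 + b1 * H[, j], 0), 1)
        H[, j + 1L] <- stats::rbinom(n, 1L, pr)
      }
      block <- block + H
    }
    G[, idx] <- block
  }
  G
}
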