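#' Conditional Q-Q enrichment curves
#'
#' For each conditional stratum `s` (a trait-2 p-value threshold), builds the
#' Q-Q curve of trait-1 p-values restricted to variants with trait-2 p <= s.
#' The expected quantile of rank i among n is `-log10(i / (n + 1))`. A
#' leftward shift of stricter strata relative to the all-SNP curve indicates
#' cross-trait enrichment of polygenic effects.
#'
#' @param gwas1,gwas2 [gwas_summary()] tables over the same variants
#'   (trait 1 is the primary trait, trait 2 the conditioning trait).
#' @param strata Thresholds in (0, 1], sorted descending, first element 1.
#' @return Data frame with columns stratum, expected, observed, n_snps,
#'   low_count (TRUE when a stratum holds fewer than 100 variants).
#' @export
conditional_qq <- function(gwas1, gwas2, strata = c(1, 0.1, 0.01, 0.001)) {
  common <- match_gwas_pair(gwas1, gwas2)
  if (any(strata <= 0) || any(strata > 1)) {
    stop("strata must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(rev(strata), strictly = TRUE) || strata[1] != 1) {
    stop("strata must be sorted descending and start at 1", call. = FALSE)
  }
  out <- lapply(strata, function(s) {
    sel <- common$p2 <= s
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(stratum = s, expected = numeric(0),
                        observed = numeric(0), n_snps = 0L,
                        low_count = TRUE))
    }
    obs <- sort(-log10(common$p1[sel]), decreasing = TRUE)
    expd <- -log10(seq_len(n) / (n + 1))
    data.frame(stratum = s, expected = expd, observed = obs,
               n_snps = n, low_count = n < 100L)
  })
  do.call(rbind, out)
}

#' @noRd
match_gwas_pair <- function(gwas1, gwas2) {
  stopifnot(inherits(gwas1, "gwas_summary"), inherits(gwas2, "gwas_summary"))
  idx <- match(gwas1$id, gwas2$id)
  if (anyNA(idx) || nrow(gwas1) != nrow(gwas2)) {
    stop("the two GWAS tables must cover the same variants", call. = FALSE)
  }
  list(id = gwas1$id, p1 = gwas1$p, p2 = gwas2$p[idx],
       z1 = gwas1$z, z2 = gwas2$z[idx])
}

#' Random-pruning inclusion weights
#'
#' Repeatedly draws a random maximal subset of variants with all pairwise
#' LD r-squared at most `r2_max` (greedy in a random order, independently per
#' LD block) and returns each variant's inclusion fraction across
#' iterations. These weights downweight variants in strong LD when building
#' the empirical condFDR lookup, so redundant variants do not dominate the
#' counts.
#'
#' @param ld An `ld_reference`.
#' @param r2_max Maximum pairwise r-squared within the kept set (0, 1].
#' @param n_iter Number of pruning iterations (>= 1).
#' @param seed Integer seed.
#' @return Named numeric vector of inclusion weights in \[0, 1\] over the
#'   panel's variant ids.
#' @export
random_prune <- function(ld, r2_max = 0.1, n_iter = 100L, seed = 1L) {
  stopifnot(inherits(ld, "ld_reference"))
  check_prob(r2_max, "r2_max", 0, 1, lo_open = TRUE)
  n_iter <- check_count(n_iter, "n_iter")
  set.seed(check_count(seed, "seed", min = 0L))

  m <- nrow(ld$panel)
  inc <- numeric(m)
  for (b in seq_along(ld$blocks)) {
    rows <- block_rows(ld, b)
    r2 <- ld$blocks[[b]]^2
    k <- length(rows)
    # adjacency: in-block neighbours in too-strong LD
    nb <- lapply(seq_len(k), function(v) {
      w <- which(r2[v, ] > r2_max)
      w[w != v]
    })
    cnt <- numeric(k)
    for (it in seq_len(n_iter)) {
      kept <- logical(k)
      for (v in sample.int(k)) {
        if (!any(kept[nb[[v]]])) kept[v] <- TRUE
      }
      cnt <- cnt + kept
    }
    inc[rows] <- cnt / n_iter
  }
  stats::setNames(inc, ld$panel$id)
}

# Lookup grid: 101 nodes uniform in -log10 p over [0, 10] plus one overflow
# node at the p-value floor.
fdr_grid_nodes <- function() c(seq(0, 10, length.out = 101L), -log10(P_FLOOR))

# Snap -log10 p values lying within floating error of a grid node onto it,
# so p-values that are exact powers of ten bin and interpolate node-exactly.
snap_to_nodes <- function(t, nodes) {
  i <- findInterval(t, nodes, all.inside = TRUE)
  near_lo <- abs(t - nodes[i]) < 1e-9
  near_hi <- abs(t - nodes[i + 1]) < 1e-9
  t[near_lo] <- nodes[i][near_lo]
  t[near_hi] <- nodes[i + 1][near_hi]
  t
}

#' Build a condFDR lookup table
#'
#' Empirical-Bayes conditional FDR on a 2-D grid over
#' `(-log10 p1, -log10 p2)`. At each grid node with thresholds (p1, p2):
#' `condFDR(p1 | p2) = p1 * W(p2) / W(p1, p2)`, where `W(p2)` is the
#' (pruning-)weighted count of variants with trait-2 p <= p2 and `W(p1, p2)`
#' the weighted count passing both thresholds; values are capped at 1, empty
#' cells take the cap, and each conditioning column is then made
#' nonincreasing in `-log10 p1` by a cumulative minimum (the raw counting
#' estimator is nonmonotone under sparsity).
#'
#' @param gwas1,gwas2 [gwas_summary()] tables over the same variants.
#' @param weights Optional named inclusion weights from [random_prune()];
#'   defaults to unit weights (no pruning correction).
#' @return An object of class `fdr_lookup` with the node grid and the
#'   condFDR matrix (rows index the p1 axis, columns the p2 axis).
#' @export
build_condfdr_lookup <- function(gwas1, gwas2, weights = NULL) {
  common <- match_gwas_pair(gwas1, gwas2)
  m <- length(common$id)
  if (m == 0L) stop("empty GWAS input", call. = FALSE)
  if (is.null(weights)) {
    w <- rep(1, m)
  } else {
    w <- weights[common$id]
    if (anyNA(w)) stop("weights missing for some variants", call. = FALSE)
  }

  nodes <- fdr_grid_nodes()
  K <- length(nodes)
  t1 <- snap_to_nodes(pmin(-log10(common$p1), -log10(P_FLOOR)), nodes)
  t2 <- snap_to_nodes(pmin(-log10(common$p2), -log10(P_FLOOR)), nodes)

  # 2-D weighted histogram, then reverse cumulative sums: C[k1, k2] =
  # weighted count with t1 >= nodes[k1] and t2 >= nodes[k2]
  i1 <- findInterval(t1, nodes)
  i2 <- findInterval(t2, nodes)
  H <- matrix(0, K, K)
  for (v in seq_len(m)) H[i1[v], i2[v]] <- H[i1[v], i2[v]] + w[v]
  C <- apply(apply(H, 2, function(col) rev(cumsum(rev(col)))), 1,
             function(row) rev(cumsum(rev(row))))
  C <- t(C) # rows: p1 axis, cols: p2 axis

  W2 <- C[1, ] # all variants pass p1 <= 1
  p1_thr <- 10^(-nodes)
  grid <- matrix(1, K, K)
  pos <- C > 0
  grid[pos] <- pmin(1, (p1_thr[row(C)] * rep(W2, each = K) / C)[pos])
  grid <- apply(grid, 2, cummin)

  structure(list(nodes = nodes, grid = grid, weights = w,
                 ids = common$id),
            class = "fdr_lookup")
}

#' @export
print.fdr_lookup <- function(x, ...) {
  cat("condFDR lookup:", length(x$nodes), "x", length(x$nodes),
      "nodes over -log10 p in [0,", max(x$nodes), "],",
      length(x$ids), "variants\n")
  invisible(x)
}

#' @noRd
interp_lookup <- function(lookup, t1, t2) {
  nodes <- lookup$nodes
  K <- length(nodes)
  t1 <- snap_to_nodes(pmin(pmax(t1, 0), nodes[K]), nodes)
  t2 <- snap_to_nodes(pmin(pmax(t2, 0), nodes[K]), nodes)
  i1 <- pmin(findInterval(t1, nodes), K - 1L)
  i2 <- pmin(findInterval(t2, nodes), K - 1L)
  f1 <- (t1 - nodes[i1]) / (nodes[i1 + 1] - nodes[i1])
  f2 <- (t2 - nodes[i2]) / (nodes[i2 + 1] - nodes[i2])
  g <- lookup$grid
  g00 <- g[cbind(i1, i2)]
  g10 <- g[cbind(i1 + 1L, i2)]
  g01 <- g[cbind(i1, i2 + 1L)]
  g11 <- g[cbind(i1 + 1L, i2 + 1L)]
  out <- (1 - f1) * (1 - f2) * g00 + f1 * (1 - f2) * g10 +
    (1 - f1) * f2 * g01 + f1 * f2 * g11
  pmin(pmax(out, 0), 1) # guard against ulp-level overshoot of the cap
}

#' Per-variant condFDR assignment
#'
#' Maps each variant's `(p1, p2)` pair to the lookup grid by bilinear
#' interpolation in `(-log10 p1, -log10 p2)`; queries that fall exactly on a
#' grid node return the cell value exactly.
#'
#' @param gwas1,gwas2 [gwas_summary()] tables (same variant universe as the
#'   lookup).
#' @param lookup An `fdr_lookup` from [build_condfdr_lookup()].
#' @return Named numeric vector: condFDR of trait 1 given trait 2 per
#'   variant.
#' @export
assign_condfdr <- function(gwas1, gwas2, lookup) {
  stopifnot(inherits(lookup, "fdr_lookup"))
  common <- match_gwas_pair(gwas1, gwas2)
  check_pvalues(common$p1, "p1")
  check_pvalues(common$p2, "p2")
  t1 <- pmin(-log10(common$p1), -log10(P_FLOOR))
  t2 <- pmin(-log10(common$p2), -log10(P_FLOOR))
  stats::setNames(interp_lookup(lookup, t1, t2), common$id)
}

#' Conjunctional FDR
#'
#' The conjFDR of a variant is the maximum of its two reciprocal condFDR
#' values (trait 1 given trait 2, and trait 2 given trait 1) — a conservative
#' bound on the posterior probability of being null for either trait.
#'
#' @param cond12,cond21 Named per-variant condFDR vectors over the same
#'   variant set.
#' @return Named numeric vector of conjFDR values.
#' @export
conjfdr <- function(cond12, cond21) {
  if (is.null(names(cond12)) || is.null(names(cond21)) ||
      !setequal(names(cond12), names(cond21))) {
    stop("the two condFDR vectors must cover the same variants",
         call. = FALSE)
  }
  cond21 <- cond21[names(cond12)]
  pmax(cond12, cond21)
}

#' Define shared loci by LD clumping of conjFDR-significant variants
#'
#' Variants passing the conjFDR threshold are sorted by conjFDR ascending
#' (ties by smaller trait-1 p, then id); each unassigned variant seeds a new
#' locus and absorbs every unassigned passing variant with r-squared at
#' least `r2_clump` to it. The seed is the locus lead SNP: the member with
#' minimal conjFDR.
#'
#' @param conj Data frame with columns id, conjfdr and optionally p1 (used
#'   for tie-breaks).
#' @param ld An `ld_reference`.
#' @param threshold conjFDR significance threshold (default 0.01).
#' @param r2_clump Clumping r-squared in (0, 1), default 0.1.
#' @return Data frame of loci (locus, lead_snp, chrom, pos, conjfdr,
#'   n_members, and a list column `members`); zero rows when nothing passes.
#' @export
define_loci <- function(conj, ld, threshold = 0.01, r2_clump = 0.1) {
  stopifnot(is.data.frame(conj), all(c("id", "conjfdr") %in% names(conj)))
  check_prob(r2_clump, "r2_clump", 0, 1, lo_open = TRUE, hi_open = TRUE)
  pass <- conj[conj$conjfdr < threshold, , drop = FALSE]
  empty <- data.frame(locus = integer(0), lead_snp = character(0),
                      chrom = integer(0), pos = numeric(0),
                      conjfdr = numeric(0), n_members = integer(0))
  empty$members <- list()
  if (nrow(pass) == 0L) return(empty)

  p1 <- if ("p1" %in% names(pass)) pass$p1 else rep(0, nrow(pass))
  ord <- order(pass$conjfdr, p1, pass$id)
  pass <- pass[ord, , drop = FALSE]

  r2 <- ld_submatrix(ld, pass$id)^2
  n <- nrow(pass)
  assigned <- logical(n)
  loci <- list()
  for (v in seq_len(n)) {
    if (assigned[v]) next
    memb <- which(!assigned & r2[v, ] >= r2_clump)
    memb <- union(v, memb)
    assigned[memb] <- TRUE
    ridx <- match(pass$id[v], ld$panel$id)
    loci[[length(loci) + 1L]] <- list(
      lead_snp = pass$id[v],
      chrom = ld$panel$chrom[ridx],
      pos = ld$panel$pos[ridx],
      conjfdr = pass$conjfdr[v],
      members = pass$id[memb]
    )
  }
  out <- data.frame(
    locus = seq_along(loci),
    lead_snp = vapply(loci, `[[`, character(1), "lead_snp"),
    chrom = vapply(loci, function(l) as.integer(l$chrom), integer(1)),
    pos = vapply(loci, function(l) as.numeric(l$pos), numeric(1)),
    conjfdr = vapply(loci, `[[`, numeric(1), "conjfdr"),
    n_members = vapply(loci, function(l) length(l$members), integer(1)),
    stringsAsFactors = FALSE
  )
  out$members <- lapply(loci, `[[`, "members")
  out
}

#' Map locus lead SNPs to genes
#'
#' A gene is assigned to a locus when its interval (plus an optional flank)
#' contains the lead SNP position on the same chromosome. Overlapping genes
#' all map; a lead outside every interval is reported as intergenic.
#'
#' @param loci Data frame from [define_loci()].
#' @param annotation Data frame with columns gene, chrom, start, end
#'   (1-based inclusive, as from [read_annotation()]).
#' @param flank Bases added on each side of every gene interval (default 0).
#' @return `loci` with list column `mapped_genes` and a display column
#'   `genes` ("intergenic" when empty).
#' @export
map_genes <- function(loci, annotation, flank = 0) {
  stopifnot(is.data.frame(annotation),
            all(c("gene", "chrom", "start", "end") %in% names(annotation)))
  if (nrow(annotation) > 0 && any(annotation$start > annotation$end)) {
    stop("malformed annotation: start > end", call. = FALSE)
  }
  mg <- lapply(seq_len(nrow(loci)), function(i) {
    hit <- annotation$chrom == loci$chrom[i] &
      annotation$start - flank <= loci$pos[i] &
      annotation$end + flank >= loci$pos[i]
    annotation$gene[hit]
  })
  loci$mapped_genes <- mg
  loci$genes <- vapply(mg, function(g) {
    if (length(g) == 0L) "intergenic" else paste(g, collapse = ", ")
  }, character(1))
  loci
}

#' Effect-direction concordance of locus lead SNPs
#'
#' Flags each locus lead as concordant when its z-scores for the two traits
#' share a sign. A zero z counts as sign 0 and is flagged discordant with a
#' warning.
#'
#' @param loci Data frame from [define_loci()].
#' @param gwas1,gwas2 [gwas_summary()] tables containing the lead SNPs.
#' @return `loci` with columns z1, z2 and `concordant` added.
#' @export
concordance_check <- function(loci, gwas1, gwas2) {
  i1 <- match(loci$lead_snp, gwas1$id)
  i2 <- match(loci$lead_snp, gwas2$id)
  if (anyNA(i1) || anyNA(i2)) {
    stop("lead SNPs missing from a GWAS table", call. = FALSE)
  }
  loci$z1 <- gwas1$z[i1]
  loci$z2 <- gwas2$z[i2]
  if (any(loci$z1 == 0 | loci$z2 == 0)) {
    warning("zero z-score at a lead SNP; flagged discordant", call. = FALSE)
  }
  loci$concordant <- sign(loci$z1) == sign(loci$z2) & loci$z1 != 0 &
    loci$z2 != 0
  loci
}
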