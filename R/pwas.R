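#' Train cis-SNP weight models for a protein
#'
#' Fits four weight models for predicting a protein's abundance from its cis
#' genotypes: `top1` (the single best marginal SNP, weight = its marginal
#' regression slope), `blup` (ridge regression, penalty by cross-validation),
#' `lasso`, and `enet` (elastic net, mixing 0.5). Each model gets a k-fold
#' cross-validated R-squared (1 - SSE/SST on held-out predictions), and
#' `best_model` is the cv-R2 argmax among models whose weight vector is not
#' identically zero (an all-zero lasso path falls back to the next-best model
#' with a warning). Constant genotype columns are dropped with a record;
#' constant abundance yields a flagged degenerate model, never an error.
#'
#' @param genotypes n x p dosage matrix of the gene's cis variants, columns
#'   named by variant id.
#' @param abundance Numeric vector of length n.
#' @param ld Optional `ld_reference` used to attach the reference alleles of
#'   the cis variants (needed later for allele alignment).
#' @param gene Gene label.
#' @param k_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `protein_weight_model`.
#' @export
fit_weights <- function(genotypes, abundance, ld = NULL, gene = "gene",
                        k_folds = 5L, seed = 1L) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) == length(abundance))
  k_folds <- check_count(k_folds, "k_folds", min = 2L)
  if (is.null(colnames(genotypes))) {
    stop("genotype columns must be named by variant id", call. = FALSE)
  }
  set.seed(check_count(seed, "seed", min = 0L))

  sds <- apply(genotypes, 2, stats::sd)
  dropped <- colnames(genotypes)[sds == 0 | !is.finite(sds)]
  X <- genotypes[, sds > 0, drop = FALSE]

  alleles <- NULL
  if (!is.null(ld)) {
    ridx <- match(colnames(X), ld$panel$id)
    alleles <- data.frame(
      id = colnames(X),
      effect_allele = ld$panel$effect_allele[ridx],
      other_allele = ld$panel$other_allele[ridx],
      stringsAsFactors = FALSE
    )
  }

  base <- list(gene = gene, snp_ids = colnames(X), alleles = alleles,
               dropped = dropped, k_folds = k_folds, seed = seed)
  if (ncol(X) == 0L || stats::sd(abundance) == 0) {
    return(structure(c(base, list(
      weights = matrix(0, ncol(X), 4,
                       dimnames = list(colnames(X), WEIGHT_MODELS)),
      cv_r2 = stats::setNames(rep(NA_real_, 4), WEIGHT_MODELS),
      best_model = NA_character_, degenerate = TRUE
    )), class = "protein_weight_model"))
  }

  y <- as.numeric(abundance)
  n <- length(y)
  p <- ncol(X)
  foldid <- sample(rep(seq_len(k_folds), length.out = n))

  W <- matrix(0, p, 4, dimnames = list(colnames(X), WEIGHT_MODELS))
  cv_pred <- matrix(NA_real_, n, 4, dimnames = list(NULL, WEIGHT_MODELS))

  # top1: best marginal SNP by |correlation|; weight = its OLS slope
  top1_fit <- function(Xtr, ytr) {
    cors <- suppressWarnings(abs(stats::cor(Xtr, ytr)))
    cors[is.na(cors)] <- 0
    j <- which.max(cors)
    slope <- stats::cov(Xtr[, j], ytr) / stats::var(Xtr[, j])
    list(j = j, slope = slope, intercept = mean(ytr) - slope * mean(Xtr[, j]))
  }
  full_top1 <- top1_fit(X, y)
  W[full_top1$j, "top1"] <- full_top1$slope
  for (k in seq_len(k_folds)) {
    tr <- foldid != k
    f <- top1_fit(X[tr, , drop = FALSE], y[tr])
    cv_pred[!tr, "top1"] <- f$intercept + f$slope * X[!tr, f$j]
  }

  # penalized models; a single cis SNP degenerates to its OLS slope
  pen <- c(blup = 0, lasso = 1, enet = 0.5)
  if (p >= 2L) {
    for (mname in names(pen)) {
      cvfit <- glmnet::cv.glmnet(X, y, alpha = pen[[mname]], foldid = foldid,
                                 keep = TRUE, standardize = TRUE)
      s <- which(cvfit$lambda == cvfit$lambda.min)[1]
      W[, mname] <- as.numeric(stats::coef(cvfit$glmnet.fit,
                                           s = cvfit$lambda.min))[-1]
      cv_pred[, mname] <- cvfit$fit.preval[, s]
    }
  } else {
    for (mname in names(pen)) {
      W[, mname] <- full_top1$slope
      cv_pred[, mname] <- cv_pred[, "top1"]
    }
  }

  sst <- sum((y - mean(y))^2)
  cv_r2 <- apply(cv_pred, 2, function(pr) 1 - sum((y - pr)^2) / sst)

  nonzero <- colSums(W != 0) > 0
  if (!nonzero[["lasso"]]) {
    warning(sprintf("gene %s: lasso solution is all-zero; excluded from model selection",
                    gene), call. = FALSE)
  }
  eligible <- cv_r2
  eligible[!nonzero] <- -Inf
  best <- names(which.max(eligible))

  structure(c(base, list(weights = W, cv_r2 = cv_r2, best_model = best,
                         degenerate = FALSE)),
            class = "protein_weight_model")
}

WEIGHT_MODELS <- c("top1", "blup", "lasso", "enet")

#' @export
print.protein_weight_model <- function(x, ...) {
  cat("Weight model for", x$gene, "-", length(x$snp_ids), "cis SNPs\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate (constant input)\n")
  } else {
    cat("  cv R2:", paste(sprintf("%s=%.3f", names(x$cv_r2), x$cv_r2),
                          collapse = " "), "\n")
    cat("  best model:", x$best_model, "\n")
  }
  invisible(x)
}

#' PWAS association statistic for one gene
#'
#' Combines a gene's cis-SNP weights with GWAS z-scores into the weighted
#' association z-score `z_pwas = (w' z) / sqrt(w' R w)`, where R is the cis
#' LD submatrix; the quadratic-form denominator makes the linear combination
#' a proper z-score under the null. GWAS alleles are aligned to the weight
#' reference first: swapped effect/other alleles flip the z sign,
#' strand-ambiguous SNPs (A/T, C/G) are dropped by default, and weights of
#' SNPs missing from the GWAS are set to zero with the denominator
#' recomputed on the present subset. Genes with too little SNP overlap or a
#' numerically zero denominator are skipped with an explicit reason.
#'
#' @param model A `protein_weight_model`.
#' @param gwas A [gwas_summary()].
#' @param ld An `ld_reference`.
#' @param model_type Which weight vector to use; default the fitted
#'   `best_model`.
#' @param min_overlap Minimum fraction of model SNPs that must be present in
#'   the GWAS (default 0.5).
#' @param drop_ambiguous Drop strand-ambiguous SNPs (default TRUE).
#' @return A one-row data frame (gene, z_pwas, p, model_used, n_snps_used,
#'   skipped, skip_reason).
#' @export
pwas_association <- function(model, gwas, ld, model_type = model$best_model,
                             min_overlap = 0.5, drop_ambiguous = TRUE) {
  stopifnot(inherits(model, "protein_weight_model"),
            inherits(gwas, "gwas_summary"))
  skip <- function(reason) data.frame(
    gene = model$gene, z_pwas = NA_real_, p = NA_real_,
    model_used = model_type %||% NA_character_, n_snps_used = 0L,
    skipped = TRUE, skip_reason = reason, stringsAsFactors = FALSE
  )
  if (isTRUE(model$degenerate)) return(skip("degenerate model"))
  if (!model_type %in% colnames(model$weights)) {
    stop("unknown model type '", model_type, "'", call. = FALSE)
  }
  w_all <- model$weights[, model_type]
  snps <- model$snp_ids

  gidx <- match(snps, gwas$id)
  present <- !is.na(gidx)
  if (mean(present) < min_overlap) return(skip("insufficient SNP overlap"))

  z <- gwas$z[gidx[present]]
  w <- w_all[present]
  keep_ids <- snps[present]

  if (!is.null(model$alleles)) {
    ref <- model$alleles[match(keep_ids, model$alleles$id), ]
    ga1 <- toupper(gwas$effect_allele[gidx[present]])
    ga2 <- toupper(gwas$other_allele[gidx[present]])
    ra1 <- toupper(ref$effect_allele)
    ra2 <- toupper(ref$other_allele)
    ambiguous <- paste0(ra1, ra2) %in% c("AT", "TA", "CG", "GC")
    same <- ga1 == ra1 & ga2 == ra2
    swapped <- ga1 == ra2 & ga2 == ra1
    if (drop_ambiguous && any(ambiguous)) {
      same[ambiguous] <- FALSE
      swapped[ambiguous] <- FALSE
    }
    z[swapped] <- -z[swapped]
    usable <- same | swapped
    z <- z[usable]
    w <- w[usable]
    keep_ids <- keep_ids[usable]
    if (length(keep_ids) / length(snps) < min_overlap) {
      return(skip("insufficient SNP overlap after allele alignment"))
    }
  }

  nz <- w != 0
  if (!any(nz)) return(skip("degenerate weight"))
  w <- w[nz]
  z <- z[nz]
  keep_ids <- keep_ids[nz]

  R <- ld_submatrix(ld, keep_ids)
  denom <- as.numeric(t(w) %*% R %*% w)
  if (denom <= 1e-12) return(skip("degenerate weight"))

  z_pwas <- sum(w * z) / sqrt(denom)
  data.frame(gene = model$gene, z_pwas = z_pwas, p = z_to_p(z_pwas),
             model_used = model_type, n_snps_used = length(keep_ids),
             skipped = FALSE, skip_reason = NA_character_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag proteome-wide significant PWAS results
#'
#' Applies Bonferroni or Benjamini-Hochberg multiple-testing control over the
#' tested genes. `m` may exceed the number of rows (e.g. the full proteome
#' size when only a subset was testable).
#'
#' @param results Data frame of [pwas_association()] rows.
#' @param method "bh_fdr" (default) or "bonferroni".
#' @param alpha Significance level in (0, 1).
#' @param m Number of tests; defaults to the number of non-skipped genes.
#' @return `results` with columns `p_adjusted` and `significant` added.
#' @export
flag_significant <- function(results, method = c("bh_fdr", "bonferroni"),
                             alpha = 0.05, m = NULL) {
  method <- match.arg(method)
  check_prob(alpha, "alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  tested <- !is.na(results$p)
  if (is.null(m)) m <- sum(tested)
  if (m < sum(tested)) stop("'m' must be >= number of tested genes",
                            call. = FALSE)
  adj <- rep(NA_real_, nrow(results))
  adj[tested] <- switch(method,
    bonferroni = pmin(1, results$p[tested] * m),
    bh_fdr = stats::p.adjust(results$p[tested], method = "BH", n = m)
  )
  results$p_adjusted <- adj
  results$significant <- !is.na(adj) & adj <= alpha
  results
}
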