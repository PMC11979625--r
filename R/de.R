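#' Kolmogorov-Smirnov normality check with bootstrap calibration
#'
#' Tests a sample against a normal distribution with the sample's own mean
#' and standard deviation. Because the parameters are estimated, the naive
#' KS reference distribution is anti-conservative; the p-value is therefore
#' calibrated Lilliefors-style by a seeded parametric bootstrap: the KS
#' statistic is recomputed on `n_boot` normal samples of the same size, each
#' with re-estimated parameters, and the p-value is the smoothed exceedance
#' fraction.
#'
#' @param values Numeric sample, length >= 3.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @return List with `statistic`, `p` and `degenerate` (TRUE for a constant
#'   sample, which gets p = 0).
#' @export
ks_normality <- function(values, n_boot = 1000L, seed = 1L) {
  if (length(values) < 3L || any(!is.finite(values))) {
    stop("need >= 3 finite values", call. = FALSE)
  }
  n_boot <- check_count(n_boot, "n_boot")
  if (stats::sd(values) == 0) {
    return(list(statistic = NA_real_, p = 0, degenerate = TRUE))
  }
  ks_stat <- function(x) {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))$statistic
  }
  d_obs <- ks_stat(values)
  set.seed(check_count(seed, "seed", min = 0L))
  n <- length(values)
  d_boot <- vapply(seq_len(n_boot),
                   function(i) ks_stat(stats::rnorm(n)), numeric(1))
  list(statistic = unname(d_obs),
       p = (1 + sum(d_boot >= d_obs)) / (n_boot + 1),
       degenerate = FALSE)
}

#' @noRd
get_gene_values <- function(expr, gene) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!gene %in% rownames(expr$values)) {
    stop("gene '", gene, "' not in expression matrix", call. = FALSE)
  }
  expr$values[gene, ]
}

#' Two-group differential-expression test (Welch t)
#'
#' Welch's unequal-variance t-test of one gene's expression between two
#' groups, with group means reported so the direction of a shift (e.g.
#' disease downregulation) is checkable. A KS normality pre-check
#' ([ks_normality()]) is run on the pooled residuals.
#'
#' @param expr An `expression_matrix`.
#' @param gene Gene label.
#' @param groups Character vector of exactly two group labels
#'   (reference first, e.g. `c("control", "case")`).
#' @param alpha Call threshold (default 0.05).
#' @param seed Seed for the normality bootstrap.
#' @param check_normality Run the KS pre-check (default TRUE); large screens
#'   may disable it and get `normality_p = NA`.
#' @return One-row data frame: gene, test, statistic, p, per-group means,
#'   normality_p, called.
#' @export
two_group_test <- function(expr, gene, groups, alpha = 0.05, seed = 1L,
                           check_normality = TRUE) {
  if (length(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  vals <- get_gene_values(expr, gene)
  g <- expr$group
  missing_grp <- setdiff(groups, g)
  if (length(missing_grp)) {
    stop("unknown groups: ", paste(missing_grp, collapse = ", "),
         call. = FALSE)
  }
  x <- vals[g == groups[1]]
  y <- vals[g == groups[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  if (stats::sd(c(x, y)) == 0) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(y, x, var.equal = FALSE)
  }
  norm_p <- NA_real_
  if (check_normality) {
    resid <- c(x - mean(x), y - mean(y))
    norm_p <- if (stats::sd(resid) == 0) 0 else ks_normality(resid, seed = seed)$p
  }
  out <- data.frame(
    gene = gene, test = "welch_t",
    statistic = unname(tt$statistic), p = unname(tt$p.value),
    mean_1 = mean(x), mean_2 = mean(y),
    normality_p = norm_p,
    called = tt$p.value < alpha,
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "mean_1"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", groups[2])
  out
}

#' One-way ANOVA differential-expression test
#'
#' Classic one-way ANOVA F-test of one gene's expression across three or
#' more groups, with per-group means reported and a KS normality pre-check
#' on the residuals. Two groups are rejected with a pointer to
#' [two_group_test()].
#'
#' @inheritParams two_group_test
#' @param groups Character vector of >= 3 group labels.
#' @return One-row data frame: gene, test, statistic (F), p, per-group
#'   means, normality_p, called.
#' @export
anova_test <- function(expr, gene, groups, alpha = 0.05, seed = 1L,
                       check_normality = TRUE) {
  if (length(groups) < 3L) {
    stop("one-way ANOVA here requires >= 3 groups; use two_group_test() ",
         "for two groups", call. = FALSE)
  }
  vals <- get_gene_values(expr, gene)
  g <- expr$group
  missing_grp <- setdiff(groups, g)
  if (length(missing_grp)) {
    stop("unknown groups: ", paste(missing_grp, collapse = ", "),
         call. = FALSE)
  }
  sel <- g %in% groups
  counts <- table(factor(g[sel], levels = groups))
  if (any(counts < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  fit <- stats::oneway.test(v ~ grp,
                            data = data.frame(v = vals[sel],
                                              grp = factor(g[sel],
                                                           levels = groups)),
                            var.equal = TRUE)
  means <- tapply(vals[sel], factor(g[sel], levels = groups), mean)
  norm_p <- NA_real_
  if (check_normality) {
    resid <- vals[sel] - means[as.character(g[sel])]
    norm_p <- if (stats::sd(resid) == 0) 0 else ks_normality(resid, seed = seed)$p
  }
  out <- data.frame(gene = gene, test = "anova",
                    statistic = unname(fit$statistic),
                    p = unname(fit$p.value),
                    normality_p = norm_p,
                    called = fit$p.value < alpha,
                    stringsAsFactors = FALSE)
  for (grp in groups) out[[paste0("mean_", grp)]] <- unname(means[grp])
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment over a vector of raw p-values (monotone, capped at
#' 1). Provided for multi-gene screens; single-gene validation calls use raw
#' p-values.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  check_pvalues(pvals, "pvals")
  stats::p.adjust(pvals, method = "BH")
}
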