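make_model <- function(snp_ids, w, gene = "G1", alleles = NULL,
                       model = "lasso") {
  W <- matrix(0, length(snp_ids), 4,
              dimnames = list(snp_ids, c("top1", "blup", "lasso", "enet")))
  W[, model] <- w
  structure(list(gene = gene, snp_ids = snp_ids, alleles = alleles,
                 dropped = character(0),
                 weights = W,
                 cv_r2 = c(top1 = 0.1, blup = 0.1, lasso = 0.5, enet = 0.1),
                 best_model = model, degenerate = FALSE),
            class = "protein_weight_model")
}

test_that("z-to-p conversion reproduces known two-sided tails", {
  expect_equal(z_to_p(-6.02), 1.75e-09, tolerance = 0.005)
  expect_equal(z_to_p(3.26), 1.11e-03, tolerance = 0.005)
  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(z_to_p(-1e3), 1e-300) # floored, never exactly zero
  expect_error(z_to_p(Inf), "finite")
})

test_that("single-SNP weight passes the GWAS z through unchanged", {
  ld <- small_panel(block_rho = 0)
  ids <- ld$panel$id[1:3]
  gwas <- gwas_summary(ids, z = c(2.5, -1, 0.3), n = 1e4,
                       effect_allele = ld$panel$effect_allele[1:3],
                       other_allele = ld$panel$other_allele[1:3])
  m <- make_model(ids, c(1, 0, 0)) # no allele table: identity alignment
  res <- pwas_association(m, gwas, ld)
  expect_equal(res$z_pwas, 2.5, tolerance = 1e-12)
})

test_that("z_pwas matches the hand-computed quadratic form", {
  ld <- small_panel(block_rho = 0.5)
  ids <- ld$panel$id[1:2] # adjacent: off-diagonal correlation 0.5
  gwas <- gwas_summary(ids, z = c(2, 2), n = 1e4,
                       effect_allele = ld$panel$effect_allele[1:2],
                       other_allele = ld$panel$other_allele[1:2])
  m <- make_model(ids, c(0.5, 0.5))
  res <- pwas_association(m, gwas, ld)
  expect_equal(res$z_pwas, 2 / sqrt(0.75), tolerance = 1e-6)
  expect_equal(res$z_pwas, 2.3094, tolerance = 1e-4)
})

test_that("z_pwas is invariant to positive rescaling of the weights", {
  ld <- small_panel(block_rho = 0.8)
  ids <- ld$panel$id[1:5]
  gwas <- gwas_summary(ids, z = c(1.2, -0.4, 2.2, 0.1, -1.9), n = 1e4,
                       effect_allele = ld$panel$effect_allele[1:5],
                       other_allele = ld$panel$other_allele[1:5])
  w <- c(0.3, -0.2, 0.5, 0, 0.1)
  r1 <- pwas_association(make_model(ids, w), gwas, ld)
  r2 <- pwas_association(make_model(ids, 17.3 * w), gwas, ld)
  expect_equal(r1$z_pwas, r2$z_pwas, tolerance = 1e-12)
})

test_that("z_pwas agrees with explicit matrix arithmetic on random genes", {
  ld <- small_panel(block_rho = 0.8, seed = 41)
  set.seed(42)
  for (rep in 1:20) {
    b <- sample(length(ld$blocks), 1)
    rows <- which(ld$panel$block_id == b)
    ids <- ld$panel$id[sort(sample(rows, 12))]
    z <- stats::rnorm(12)
    gwas <- gwas_summary(ids, z, 1e4,
                         effect_allele = ld$panel$effect_allele[match(ids, ld$panel$id)],
                         other_allele = ld$panel$other_allele[match(ids, ld$panel$id)])
    w <- stats::rnorm(12) * rbinom(12, 1, 0.6)
    if (all(w == 0)) w[1] <- 1
    R <- ld_submatrix(ld, ids)
    z_oracle <- sum(w * z) / sqrt(as.numeric(t(w) %*% R %*% w))
    res <- pwas_association(make_model(ids, w), gwas, ld)
    expect_equal(res$z_pwas, z_oracle, tolerance = 1e-10)
    expect_equal(res$p, z_to_p(z_oracle), tolerance = 1e-12)
  }
})

test_that("allele flips in the GWAS leave z_pwas unchanged", {
  ld <- small_panel(seed = 43)
  # pick non-strand-ambiguous SNPs so flipped records stay resolvable
  ok <- !(paste0(ld$panel$effect_allele, ld$panel$other_allele) %in%
            c("AT", "TA", "CG", "GC"))
  rows <- which(ok & ld$panel$block_id == 1)[1:4]
  ids <- ld$panel$id[rows]
  z <- c(1.5, -2.1, 0.7, 3.0)
  a1 <- ld$panel$effect_allele[rows]
  a2 <- ld$panel$other_allele[rows]
  gwas <- gwas_summary(ids, z, 1e4, a1, a2)
  flipped <- gwas_summary(ids, z * c(-1, 1, 1, 1), 1e4,
                          c(a2[1], a1[2:4]), c(a1[1], a2[2:4]))
  m <- make_model(ids, c(0.4, -0.3, 0.2, 0.6),
                  alleles = data.frame(id = ids, effect_allele = a1,
                                       other_allele = a2))
  expect_equal(pwas_association(m, gwas, ld)$z_pwas,
               pwas_association(m, flipped, ld)$z_pwas, tolerance = 1e-12)
})

test_that("strand-ambiguous SNPs are dropped from the weighted sum", {
  ld <- small_panel()
  ids <- ld$panel$id[1:4]
  amb <- data.frame(id = ids,
                    effect_allele = c("A", "C", "A", "G"),
                    other_allele = c("T", "G", "C", "T"))
  gwas <- gwas_summary(ids, z = c(5, 5, 1, 1), n = 1e4,
                       effect_allele = amb$effect_allele,
                       other_allele = amb$other_allele)
  m <- make_model(ids, c(0.5, 0.5, 0.5, 0.5), alleles = amb)
  res <- pwas_association(m, gwas, ld)
  # rs 1 and 2 are A/T and C/G: excluded even though alleles match
  expect_identical(res$n_snps_used, 2L)
  R <- ld_submatrix(ld, ids[3:4])
  w <- c(0.5, 0.5)
  expect_equal(res$z_pwas, sum(w * c(1, 1)) /
                 sqrt(as.numeric(t(w) %*% R %*% w)), tolerance = 1e-12)
  kept <- pwas_association(m, gwas, ld, drop_ambiguous = FALSE)
  expect_identical(kept$n_snps_used, 4L)
})

test_that("degenerate weights and poor overlap are skipped with reasons", {
  ld <- small_panel()
  ids <- ld$panel$id[1:4]
  gwas <- gwas_summary(ids, z = rep(1, 4), n = 1e4,
                       effect_allele = ld$panel$effect_allele[1:4],
                       other_allele = ld$panel$other_allele[1:4])
  res <- pwas_association(make_model(ids, rep(0, 4)), gwas, ld)
  expect_true(res$skipped)
  expect_match(res$skip_reason, "degenerate")
  # only 1 of 4 model SNPs present in the GWAS -> below min_overlap
  gwas1 <- gwas_summary(ids[1], z = 1, n = 1e4,
                        effect_allele = ld$panel$effect_allele[1],
                        other_allele = ld$panel$other_allele[1])
  res2 <- pwas_association(make_model(ids, rep(0.5, 4)), gwas1, ld)
  expect_true(res2$skipped)
  expect_match(res2$skip_reason, "overlap")
})

test_that("top1 keeps exactly one weight, at the strongest marginal SNP", {
  sc <- small_scenario(h2_cis = 0.5, n_causal_cis = 1, n_ref = 500, seed = 44)
  ld <- simulate_ld_panel(sc)
  pq <- simulate_pqtl_training(ld, sc)
  X <- pq$genotypes[, pq$genes$snp_ids[[1]]]
  m <- fit_weights(X, pq$abundance[, 1], ld = ld, gene = "GENE001", seed = 1)
  w_top1 <- m$weights[, "top1"]
  expect_identical(sum(w_top1 != 0), 1L)
  cors <- abs(stats::cor(X, pq$abundance[, 1]))
  expect_identical(names(which(w_top1 != 0)), rownames(cors)[which.max(cors)])
  expect_identical(m$best_model, names(which.max(m$cv_r2)))
})

test_that("constant inputs yield flagged degenerate models, not errors", {
  X <- matrix(1, 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- fit_weights(X, stats::rnorm(50), gene = "G")
  expect_true(m$degenerate)
  X2 <- matrix(rbinom(150, 2, 0.3), 50, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  m2 <- fit_weights(X2, rep(1, 50), gene = "G")
  expect_true(m2$degenerate)
  res <- pwas_association(m2,
                          gwas_summary(c("a", "b", "c"), c(1, 1, 1), 100,
                                       "A", "G"),
                          small_panel())
  expect_true(res$skipped)
})

test_that("significance flags follow the chosen multiple-testing rule", {
  one <- data.frame(gene = "g", p = 0.04)
  expect_true(flag_significant(one, "bonferroni", 0.05)$significant)
  expect_true(flag_significant(one, "bh_fdr", 0.05)$significant)
  four <- data.frame(gene = letters[1:4], p = c(0.01, 0.02, 0.03, 0.04))
  bh <- flag_significant(four, "bh_fdr", 0.05)
  expect_equal(bh$p_adjusted, rep(0.04, 4))
  expect_true(all(bh$significant))
  # proteome-scale Bonferroni threshold: alpha / m
  # proteome of 1475 genes: the Bonferroni cutoff is 0.05/1475 ~ 3.39e-5
  expect_true(flag_significant(data.frame(gene = "g", p = 3.35e-5),
                               "bonferroni", 0.05, m = 1475)$significant)
  expect_false(flag_significant(data.frame(gene = "g", p = 3.43e-5),
                                "bonferroni", 0.05, m = 1475)$significant)
  expect_error(flag_significant(four, "bh_fdr", alpha = 1.2), "alpha")
  expect_error(flag_significant(four, "bh_fdr", 0.05, m = 2), "m")
})
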