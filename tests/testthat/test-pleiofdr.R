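test_that("conditional Q-Q strata are nested and curves well-formed", {
  sc <- small_scenario(pi_shared = 0.02, sigma_beta = 0.05, seed = 51)
  ld <- simulate_ld_panel(sc)
  biv <- simulate_bivariate_gwas(ld, sc)
  qq <- conditional_qq(biv$gwas1, biv$gwas2, c(1, 0.1, 0.01, 0.001))
  counts <- tapply(qq$n_snps, qq$stratum, unique)
  expect_true(all(diff(counts[order(-as.numeric(names(counts)))]) <= 0))
  for (s in unique(qq$stratum)) {
    cur <- qq[qq$stratum == s, ]
    ord <- order(cur$expected)
    expect_true(all(cur$observed[ord] >= 0))
    expect_true(!is.unsorted(cur$observed[ord]))
  }
  expect_error(conditional_qq(biv$gwas1, biv$gwas2, c(0.5, 0.1)), "start at 1")
  expect_error(conditional_qq(biv$gwas1, biv$gwas2, c(1, 0)), "strata")
})

test_that("null independent traits give diagonal Q-Q curves", {
  # deviation checked over the bulk of each curve (rank >= 100), where the
  # order-statistic noise is small; extreme ranks fluctuate by construction
  sc <- scenario_config(block_rho = 0, seed = 52)
  ld <- simulate_ld_panel(sc)
  worst <- 0
  for (s in 1:20) {
    biv <- simulate_bivariate_gwas(ld, sc, seed = 1000 + s)
    qq <- conditional_qq(biv$gwas1, biv$gwas2, c(1, 0.1, 0.01))
    for (st in unique(qq$stratum)) {
      cur <- qq[qq$stratum == st, ]
      cur <- cur[order(cur$expected, decreasing = TRUE), ]
      bulk <- seq_len(nrow(cur)) >= 100
      if (any(bulk)) {
        worst <- max(worst, max(abs(cur$observed[bulk] - cur$expected[bulk])))
      }
    }
  }
  expect_lt(worst, 0.3)
})

test_that("planted overlap produces ordered enrichment across strata", {
  sc <- scenario_config(pi_shared = 0.01, sigma_beta = 0.02, seed = 53)
  ld <- simulate_ld_panel(sc)
  biv <- simulate_bivariate_gwas(ld, sc)
  qq <- conditional_qq(biv$gwas1, biv$gwas2, c(1, 0.1, 0.01, 0.001))
  shift <- function(s) {
    cur <- qq[qq$stratum == s, ]
    mean(cur$observed - cur$expected)
  }
  expect_gt(shift(0.001), shift(1))
})

test_that("random pruning has the no-pruning and symmetric-choice limits", {
  ld <- small_panel()
  w_all <- random_prune(ld, r2_max = 1, n_iter = 5, seed = 1)
  expect_true(all(w_all == 1))
  # one block of 4 variants all in mutual r^2 > 0.5: one survivor/iteration
  sc4 <- scenario_config(n_variants = 4, n_blocks = 1, block_rho = 0.95,
                         n_genes = 1, seed = 2)
  ld4 <- simulate_ld_panel(sc4)
  expect_true(all(ld4$blocks[[1]]^2 > 0.5))
  w4 <- random_prune(ld4, r2_max = 0.5, n_iter = 100, seed = 3)
  expect_equal(sum(w4), 1, tolerance = 1e-12) # exactly one kept each time
  expect_true(all(abs(w4 - 0.25) < 0.1))
  expect_identical(random_prune(ld, 0.1, 10, seed = 9),
                   random_prune(ld, 0.1, 10, seed = 9))
})

test_that("condFDR lookup matches the brute-force counting oracle", {
  set.seed(61)
  for (rep in 1:3) {
    n <- c(200, 500, 120)[rep]
    p1 <- c(stats::runif(n - 20), 10^-stats::runif(20, 2, 9))
    p2 <- c(stats::runif(n - 30), 10^-stats::runif(30, 1, 8))
    p2 <- sample(p2)
    w <- if (rep == 2) stats::runif(n, 0.2, 1) else rep(1, n)
    g1 <- gwas_from_p(p1)
    g2 <- gwas_from_p(p2)
    lk <- build_condfdr_lookup(g1, g2, stats::setNames(w, g1$id))
    expect_equal(lk$grid, oracle_condfdr_grid(p1, p2, w), tolerance = 1e-12)
  }
})

test_that("conditioning on everything reduces to the empirical FDR", {
  # hand-counted 10-variant table, unit weights, p2 threshold = 1
  p1 <- c(0.5, 0.05, 0.005, 5e-4, 5e-5, 1, 1, 1, 1, 1)
  p2 <- rep(1, 10)
  lk <- build_condfdr_lookup(gwas_from_p(p1), gwas_from_p(p2))
  node_of <- function(t) which(abs(lk$nodes - t) < 1e-12)
  col1 <- 1 # p2 threshold 1
  expect_equal(lk$grid[node_of(0), col1], 1)           # 1 * 10/10
  expect_equal(lk$grid[node_of(1), col1], 0.1 * 10 / 4)  # 4 pass p1 <= 0.1
  expect_equal(lk$grid[node_of(2), col1], 0.01 * 10 / 3)
  expect_equal(lk$grid[node_of(3), col1], 0.001 * 10 / 2)
  expect_equal(lk$grid[node_of(4), col1], 1e-4 * 10 / 1)
})

test_that("a single variant gets condFDR = p1 when conditioned on all", {
  lk <- build_condfdr_lookup(gwas_from_p(0.001), gwas_from_p(1))
  cfdr <- assign_condfdr(gwas_from_p(0.001), gwas_from_p(1), lk)
  expect_equal(unname(cfdr), 0.001, tolerance = 1e-12)
})

test_that("per-variant assignment is node-exact and monotone", {
  set.seed(62)
  k_nodes <- c(1, 11, 31, 51, 101) # -log10 p of 0, 1, 3, 5, 10
  p_nodes <- 10^-(seq(0, 10, length.out = 101)[k_nodes])
  n <- 300
  p1 <- c(p_nodes, stats::runif(n - 5))
  p2 <- c(stats::runif(n - 5), p_nodes)
  g1 <- gwas_from_p(p1)
  g2 <- gwas_from_p(p2)
  lk <- build_condfdr_lookup(g1, g2)
  got <- assign_condfdr(g1, g2, lk)
  oracle <- oracle_condfdr_grid(p1, p2)
  # variants whose (p1, p2) sit exactly on grid nodes match cells exactly
  for (i in seq_along(k_nodes)) {
    t2 <- -log10(p2[i])
    i2 <- which(abs(lk$nodes - t2) < 1e-9)
    if (length(i2) == 1) {
      expect_equal(unname(got[i]), oracle[k_nodes[i], i2], tolerance = 1e-12)
    }
  }
  expect_true(all(got >= 0 & got <= 1))
  # fixed p2: condFDR nonincreasing as p1 decreases, probed post-interpolation
  probe_p1 <- 10^-seq(0, 9.9, length.out = 100)
  probe <- assign_condfdr(gwas_from_p(probe_p1),
                          gwas_from_p(rep(0.05, 100)), lk)
  expect_true(all(diff(unname(probe)) <= 1e-12))
})

test_that("pruning weights of one leave the lookup unchanged", {
  set.seed(63)
  p1 <- stats::runif(150)
  p2 <- stats::runif(150)
  g1 <- gwas_from_p(p1)
  g2 <- gwas_from_p(p2)
  lk_w <- build_condfdr_lookup(g1, g2,
                               stats::setNames(rep(1, 150), g1$id))
  lk_u <- build_condfdr_lookup(g1, g2)
  expect_identical(lk_w$grid, lk_u$grid)
})

test_that("conjFDR is the max of the two conditional directions", {
  a <- c(rs1 = 0.002, rs2 = 0.5)
  b <- c(rs2 = 0.3, rs1 = 0.005)
  cj <- conjfdr(a, b)
  expect_equal(unname(cj["rs1"]), 0.005)
  expect_equal(unname(cj["rs2"]), 0.5)
  expect_equal(conjfdr(a, a[names(a)]), a)
  expect_error(conjfdr(a, c(rs3 = 0.1, rs1 = 0.2)), "same variants")
  set.seed(64)
  x <- stats::setNames(stats::runif(500), paste0("v", 1:500))
  y <- stats::setNames(stats::runif(500), paste0("v", 1:500))
  cj2 <- conjfdr(x, y)
  expect_true(all(cj2 >= x & cj2 >= y[names(x)]))
})

test_that("clumping reconstructs planted uncorrelated clusters", {
  # 34 passing SNPs in 5 mutually uncorrelated LD clusters -> 5 loci
  sc <- scenario_config(n_variants = 500, n_blocks = 5, block_rho = 0.9,
                        n_genes = 1, seed = 71)
  ld <- simulate_ld_panel(sc)
  sizes <- c(7, 7, 7, 7, 6)
  ids <- unlist(lapply(1:5, function(b) {
    rows <- which(ld$panel$block_id == b)
    ld$panel$id[rows[40 + seq_len(sizes[b])]] # contiguous run, r2 >= 0.28
  }))
  set.seed(72)
  conj <- data.frame(id = ids, conjfdr = stats::runif(34, 1e-6, 0.009),
                     p1 = stats::runif(34, 1e-8, 1e-4))
  loci <- define_loci(conj, ld, threshold = 0.01, r2_clump = 0.1)
  expect_identical(nrow(loci), 5L)
  expect_identical(sum(loci$n_members), 34L)
  members <- unlist(loci$members)
  expect_false(anyDuplicated(members) > 0)
  # lead is a member and attains the member-minimal conjFDR
  for (i in seq_len(nrow(loci))) {
    memb <- loci$members[[i]]
    expect_true(loci$lead_snp[i] %in% memb)
    expect_equal(loci$conjfdr[i],
                 min(conj$conjfdr[conj$id %in% memb]))
  }
})

test_that("singletons, empty sets and tie-breaks behave as specified", {
  ld <- small_panel()
  one <- define_loci(data.frame(id = ld$panel$id[5], conjfdr = 0.001), ld)
  expect_identical(nrow(one), 1L)
  expect_identical(one$lead_snp, ld$panel$id[5])
  none <- define_loci(data.frame(id = ld$panel$id[5], conjfdr = 0.5), ld)
  expect_identical(nrow(none), 0L)
  # equal conjFDR: the seed is the variant with the smaller trait-1 p
  ids <- ld$panel$id[1:2]
  tie <- data.frame(id = ids, conjfdr = c(0.005, 0.005), p1 = c(1e-4, 1e-6))
  loci <- define_loci(tie, ld, r2_clump = 0.1)
  expect_identical(loci$lead_snp[1], ids[2])
})

test_that("the strongest printed locus lead has the minimal conjFDR", {
  # the five per-locus conjFDR values of the published shared-locus table
  printed <- c(rs6599389 = 5.74e-3, rs1051613 = 1.94e-3,
               rs2230288 = 8.51e-4, rs1372519 = 4.17e-6,
               rs11150577 = 6.27e-3)
  sc <- scenario_config(n_variants = 100, n_blocks = 5, n_genes = 1,
                        seed = 73)
  ld <- simulate_ld_panel(sc)
  ld$panel$id[c(1, 21, 41, 61, 81)] <- names(printed)
  conj <- data.frame(id = names(printed), conjfdr = unname(printed))
  loci <- define_loci(conj, ld, threshold = 0.01, r2_clump = 0.1)
  expect_identical(nrow(loci), 5L)
  strongest <- loci[which.min(loci$conjfdr), ]
  expect_identical(strongest$lead_snp, "rs1372519")
  expect_equal(strongest$conjfdr, 4.17e-6)
})

test_that("gene mapping handles containment, overlap and boundaries", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr4\t951178\t951180\tTMEM175",
               "chr4\t950000\t952000\tDGKQ",
               "chr2\t100\t200\tOTHER"), bed)
  ann <- read_annotation(bed)
  loci <- data.frame(locus = 1:3, lead_snp = c("a", "b", "c"),
                     chrom = c(4L, 4L, 2L), pos = c(951179, 949999, 201),
                     conjfdr = c(1e-4, 1e-4, 1e-4), n_members = 1L)
  mapped <- map_genes(loci, ann)
  expect_setequal(mapped$mapped_genes[[1]], c("TMEM175", "DGKQ"))
  expect_identical(mapped$genes[2], "intergenic")  # 1 bp left of DGKQ
  expect_identical(mapped$genes[3], "intergenic")  # 1 bp right of OTHER
  withflank <- map_genes(loci, ann, flank = 1)
  expect_identical(withflank$genes[3], "OTHER")
  expect_error(map_genes(loci, data.frame(gene = "g", chrom = 1,
                                          start = 10, end = 5)),
               "malformed")
})

test_that("lead-SNP direction concordance follows z-score signs", {
  g1 <- gwas_summary(c("rs6599389", "rs1372519", "rsX", "rs0"),
                     z = c(4.07, -5.52, 2, 1), n = 1e5,
                     effect_allele = "A", other_allele = "G")
  g2 <- gwas_summary(c("rs6599389", "rs1372519", "rsX", "rs0"),
                     z = c(3.88, -5.48, -2, 0), n = 1e5,
                     effect_allele = "A", other_allele = "G")
  loci <- data.frame(locus = 1:4,
                     lead_snp = c("rs6599389", "rs1372519", "rsX", "rs0"))
  expect_warning(out <- concordance_check(loci, g1, g2), "zero z")
  expect_identical(out$concordant, c(TRUE, TRUE, FALSE, FALSE))
})
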