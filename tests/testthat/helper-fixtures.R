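# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is stored on disk.

small_scenario <- function(seed = 1L, ...) {
  scenario_config(n_variants = 2000L, n_blocks = 20L, n_genes = 5L,
                  seed = seed, ...)
}

small_panel <- function(seed = 1L, ...) {
  simulate_ld_panel(small_scenario(seed = seed, ...))
}

# A gwas_summary built directly from chosen p-values (z solved back from p,
# signs alternating) -- used for condFDR toy tables.
gwas_from_p <- function(p, ids = sprintf("rs%06d", seq_along(p)), n = 1e4) {
  z <- stats::qnorm(p / 2) * rep_len(c(-1, 1), length(p))
  gwas_summary(ids, z, n, effect_allele = "A", other_allele = "G", p = NULL)
}

# Independent brute-force condFDR oracle: per grid node, loop over variants
# counting in -log10 space, then enforce monotonicity with an explicit
# column-wise running minimum. Shares no code with build_condfdr_lookup.
oracle_condfdr_grid <- function(p1, p2, w = rep(1, length(p1))) {
  nodes <- c(seq(0, 10, length.out = 101L), 300)
  K <- length(nodes)
  # a p that is an exact power of ten counts as passing its node threshold
  snap <- function(t) {
    for (v in seq_along(t)) {
      d <- abs(nodes - t[v])
      if (min(d) < 1e-9) t[v] <- nodes[which.min(d)]
    }
    t
  }
  t1 <- snap(pmin(-log10(p1), 300))
  t2 <- snap(pmin(-log10(p2), 300))
  raw <- matrix(1, K, K)
  for (k1 in seq_len(K)) {
    for (k2 in seq_len(K)) {
      w12 <- 0
      w2 <- 0
      for (v in seq_along(p1)) {
        if (t2[v] >= nodes[k2]) {
          w2 <- w2 + w[v]
          if (t1[v] >= nodes[k1]) w12 <- w12 + w[v]
        }
      }
      if (w12 > 0) raw[k1, k2] <- min(1, 10^(-nodes[k1]) * w2 / w12)
    }
  }
  for (k2 in seq_len(K)) {
    running <- raw[1, k2]
    for (k1 in seq_len(K)) {
      running <- min(running, raw[k1, k2])
      raw[k1, k2] <- running
    }
  }
  raw
}

# Expression matrix wrapped from a raw matrix, for direct-value DE tests.
expr_from_matrix <- function(values, group) {
  structure(list(values = values, group = group, planted = NULL),
            class = "expression_matrix")
}
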