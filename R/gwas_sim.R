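#' Construct a GWAS summary-statistics table
#'
#' Validates the core invariant of a summary table: the p-value of every
#' variant is the two-sided normal tail of its z-score (to 1e-10 relative
#' tolerance), ids are unique, and p lies in (0, 1]. If `p` is omitted it is
#' derived from `z`.
#'
#' @param id Character variant ids.
#' @param z Numeric z-scores.
#' @param n Sample size (scalar or per variant).
#' @param effect_allele,other_allele Allele labels per variant.
#' @param chrom,pos Optional coordinates.
#' @param p Optional p-values; checked against `z` when supplied.
#' @param p_tol Relative tolerance for the z/p consistency check; loaders
#'   of rounded external tables may relax it (see [read_gwas()]).
#' @return A data frame of class `gwas_summary`.
#' @export
gwas_summary <- function(id, z, n, effect_allele, other_allele,
                         chrom = NA, pos = NA, p = NULL, p_tol = 1e-10) {
  if (anyDuplicated(id)) {
    stop("duplicate variant ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(z))) stop("non-finite z-scores", call. = FALSE)
  p_from_z <- z_to_p(z)
  if (is.null(p)) {
    p <- p_from_z
  } else {
    check_pvalues(p)
    rel <- abs(p - p_from_z) / pmax(p_from_z, P_FLOOR)
    bad <- rel > p_tol & p_from_z > P_FLOOR
    if (any(bad)) {
      stop("p-values inconsistent with z-scores beyond ", p_tol,
           " relative tolerance at ", sum(bad), " variants", call. = FALSE)
    }
  }
  out <- data.frame(
    id = as.character(id), chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    z = as.numeric(z), p = as.numeric(p),
    n = as.numeric(n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Simulate paired GWAS summary statistics with controlled overlap
#'
#' Assigns each panel variant to one of four causal classes — shared,
#' trait-1-only, trait-2-only, null — with probabilities `(pi_shared, pi1,
#' pi2, remainder)` from the scenario. Causal variants receive standardized
#' effects drawn N(0, `sigma_beta`^2); shared variants use one draw for both
#' traits, so planted pleiotropic signals are direction-concordant in
#' expectation. Per LD block, each trait's z-vector is
#' `sqrt(N) * R %*% beta + eps` with `eps ~ MVN(0, R)`: effects are LD-smeared
#' and the noise is LD-correlated within blocks, independent across traits.
#' Under the all-null scenario every z is exactly standard normal marginally.
#'
#' `planted` overrides the mixture at chosen variants, for planting known
#' high-effect pleiotropic clusters: a data frame with columns `id`, `beta1`,
#' `beta2` (standardized effects; the expected lead z is `sqrt(N) * beta`).
#'
#' @param ld An `ld_reference`.
#' @param config A [scenario_config()].
#' @param seed Integer seed; defaults to `config$seed + 2`.
#' @param planted Optional data frame (id, beta1, beta2) of forced effects.
#' @return List with `gwas1`, `gwas2` (each a [gwas_summary()]) and `truth`
#'   (data frame id, class, beta1, beta2).
#' @export
simulate_bivariate_gwas <- function(ld, config, seed = config$seed + 2L,
                                    planted = NULL) {
  stopifnot(inherits(ld, "ld_reference"), inherits(config, "scenario_config"))
  set.seed(check_count(seed, "seed", min = 0L))
  m <- nrow(ld$panel)

  probs <- c(config$pi_shared, config$pi1, config$pi2,
             1 - config$pi_shared - config$pi1 - config$pi2)
  cls <- sample(c("shared", "trait1", "trait2", "null"), m,
                replace = TRUE, prob = probs)
  beta1 <- beta2 <- numeric(m)
  sh <- cls == "shared"
  beta_sh <- stats::rnorm(sum(sh), sd = config$sigma_beta)
  beta1[sh] <- beta_sh
  beta2[sh] <- beta_sh
  beta1[cls == "trait1"] <- stats::rnorm(sum(cls == "trait1"),
                                         sd = config$sigma_beta)
  beta2[cls == "trait2"] <- stats::rnorm(sum(cls == "trait2"),
                                         sd = config$sigma_beta)

  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("id", "beta1", "beta2") %in% names(planted)))
    idx <- match(planted$id, ld$panel$id)
    if (anyNA(idx)) {
      stop("planted ids not in panel: ",
           paste(planted$id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    beta1[idx] <- planted$beta1
    beta2[idx] <- planted$beta2
    cls[idx] <- ifelse(planted$beta1 != 0 & planted$beta2 != 0, "shared",
                       ifelse(planted$beta1 != 0, "trait1",
                              ifelse(planted$beta2 != 0, "trait2", "null")))
  }

  z1 <- z2 <- numeric(m)
  for (b in seq_along(ld$blocks)) {
    idx <- block_rows(ld, b)
    R <- ld$blocks[[b]]
    U <- chol(R)
    k <- length(idx)
    z1[idx] <- sqrt(config$n_gwas1) * as.vector(R %*% beta1[idx]) +
      as.vector(crossprod(U, stats::rnorm(k)))
    z2[idx] <- sqrt(config$n_gwas2) * as.vector(R %*% beta2[idx]) +
      as.vector(crossprod(U, stats::rnorm(k)))
  }

  pan <- ld$panel
  list(
    gwas1 = gwas_summary(pan$id, z1, config$n_gwas1, pan$effect_allele,
                         pan$other_allele, pan$chrom, pan$pos),
    gwas2 = gwas_summary(pan$id, z2, config$n_gwas2, pan$effect_allele,
                         pan$other_allele, pan$chrom, pan$pos),
    truth = data.frame(id = pan$id, class = cls, beta1 = beta1,
                       beta2 = beta2, stringsAsFactors = FALSE)
  )
}
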