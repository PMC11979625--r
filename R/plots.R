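#' Conditional Q-Q plot
#'
#' One curve per conditional stratum; leftward deflection of stricter
#' strata from the identity line indicates cross-trait enrichment.
#'
#' @param qq Data frame from [conditional_qq()].
#' @param max_points Per-stratum thinning cap for plotting (default 2000).
#' @return A ggplot object.
#' @export
plot_conditional_qq <- function(qq, max_points = 2000L) {
  qq$stratum <- factor(qq$stratum, levels = sort(unique(qq$stratum),
                                                 decreasing = TRUE))
  thin <- do.call(rbind, lapply(split(qq, qq$stratum), function(d) {
    if (nrow(d) > max_points) d[seq(1, nrow(d), length.out = max_points), ]
    else d
  }))
  ggplot2::ggplot(thin, ggplot2::aes(x = .data$expected, y = .data$observed,
                                     colour = .data$stratum)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  colour = "p2 stratum") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of conjFDR values
#'
#' Plots -log10 conjFDR by genomic position, with the significance
#' threshold as a dotted line and locus lead SNPs circled.
#'
#' @param per_variant Data frame with columns id, conjfdr (as produced by
#'   the pleiofdr stage of [run_pipeline()]).
#' @param ld The `ld_reference` giving variant coordinates.
#' @param loci Optional loci table from [define_loci()] for lead highlights.
#' @param threshold conjFDR threshold line (default 0.01).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(per_variant, ld, loci = NULL, threshold = 0.01) {
  idx <- match(per_variant$id, ld$panel$id)
  d <- data.frame(
    chrom = ld$panel$chrom[idx],
    pos = ld$panel$pos[idx],
    y = -log10(pmax(per_variant$conjfdr, P_FLOOR))
  )
  # cumulative genome coordinate for the x axis
  offsets <- c(0, cumsum(tapply(d$pos, d$chrom, max)))
  d$x <- d$pos + offsets[as.integer(factor(d$chrom))]
  d$chrom_f <- factor(d$chrom %% 2)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$chrom_f)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 3) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "Genomic position", y = expression(-log[10](conjFDR))) +
    ggplot2::theme_minimal()
  if (!is.null(loci) && nrow(loci)) {
    lead_idx <- match(loci$lead_snp, per_variant$id)
    leads <- d[lead_idx, , drop = FALSE]
    g <- g + ggplot2::geom_point(data = leads, shape = 21, size = 2.5,
                                 colour = "black", fill = NA, stroke = 0.8)
  }
  g
}
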