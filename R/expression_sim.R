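#' Simulate a case/control expression matrix with planted shifts
#'
#' Generates a genes x samples matrix of log-scale normal noise (mean 0,
#' unit variance) and shifts selected genes in selected groups by a stated
#' effect, in units of the baseline standard deviation. This emulates
#' normalized postmortem expression profiles with planted group differences,
#' e.g. a disease-downregulated gene.
#'
#' @param n_genes Number of genes.
#' @param groups Named integer vector of group sizes, e.g.
#'   `c(control = 10, case = 10)`; at least 2 samples per group.
#' @param planted Optional data frame with columns `gene`, `group`, `shift`;
#'   all genes/groups must exist.
#' @param seed Integer seed.
#' @return An object of class `expression_matrix`: list with `values`
#'   (genes x samples matrix), `group` (label per sample) and `planted`.
#' @export
simulate_expression <- function(n_genes, groups, planted = NULL, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  if (is.null(names(groups)) || any(names(groups) == "") ||
      anyDuplicated(names(groups))) {
    stop("'groups' must be a uniquely named vector of sizes", call. = FALSE)
  }
  if (any(groups < 2)) stop("each group needs at least 2 samples", call. = FALSE)
  set.seed(check_count(seed, "seed", min = 0L))

  group <- rep(names(groups), times = groups)
  ns <- length(group)
  gene_ids <- sprintf("GENE%03d", seq_len(n_genes))
  values <- matrix(stats::rnorm(n_genes * ns), n_genes, ns,
                   dimnames = list(gene_ids,
                                   paste0(group, "_", seq_len(ns))))
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("gene", "group", "shift") %in% names(planted)))
    bad_gene <- setdiff(planted$gene, gene_ids)
    if (length(bad_gene)) {
      stop("planted genes not in matrix: ",
           paste(bad_gene, collapse = ", "), call. = FALSE)
    }
    bad_grp <- setdiff(planted$group, names(groups))
    if (length(bad_grp)) {
      stop("planted groups unknown: ", paste(bad_grp, collapse = ", "),
           call. = FALSE)
    }
    for (i in seq_len(nrow(planted))) {
      cols <- group == planted$group[i]
      values[planted$gene[i], cols] <-
        values[planted$gene[i], cols] + planted$shift[i]
    }
  }
  structure(list(values = values, group = group, planted = planted),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples; groups:",
      paste(sprintf("%s(%d)", names(table(x$group)), table(x$group)),
            collapse = ", "), "\n")
  invisible(x)
}
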