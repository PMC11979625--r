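#' Read a GWAS summary-statistics TSV
#'
#' Expects tab-delimited columns SNP, CHR, BP, A1, A2 plus either Z or the
#' pair (BETA, SE); P and N are optional. Z is derived as BETA/SE when
#' absent. P is recomputed from Z when absent or when it disagrees with the
#' two-sided normal tail beyond 1e-6 relative tolerance (the number of
#' corrections is reported via a message). Duplicate SNP ids and p-values
#' outside (0, 1] are load errors naming the offenders.
#'
#' @param path Path to the TSV.
#' @return A [gwas_summary()].
#' @export
read_gwas <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"Z" %in% names(tab) && !all(c("BETA", "SE") %in% names(tab))) {
    stop("need either column Z or columns BETA and SE", call. = FALSE)
  }
  dup <- unique(tab$SNP[duplicated(tab$SNP)])
  if (length(dup)) {
    stop("duplicated SNP ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  num_col <- function(name) {
    v <- suppressWarnings(as.numeric(tab[[name]]))
    bad <- which(is.na(v) & !is.na(tab[[name]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at line(s) %s", name,
                   paste(utils::head(bad + 1L, 5), collapse = ", ")),
           call. = FALSE)
    }
    v
  }
  z <- if ("Z" %in% names(tab)) {
    num_col("Z")
  } else {
    beta <- num_col("BETA")
    se <- num_col("SE")
    if (any(se <= 0)) {
      stop("SE must be positive at line(s) ",
           paste(utils::head(which(se <= 0) + 1L, 5), collapse = ", "),
           call. = FALSE)
    }
    beta / se
  }
  p_expect <- z_to_p(z)
  if ("P" %in% names(tab)) {
    p <- num_col("P")
    bad <- which(is.na(p) | p <= 0 | p > 1)
    if (length(bad)) {
      stop("P outside (0, 1] at line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
    }
    off <- abs(p - p_expect) / pmax(p_expect, P_FLOOR) > 1e-6
    if (any(off)) {
      message(sum(off), " p-value(s) inconsistent with z; recomputed")
      p[off] <- p_expect[off]
    }
  } else {
    p <- p_expect
  }
  n <- if ("N" %in% names(tab)) num_col("N") else NA_real_
  # rounded-on-disk values are accepted to the loader tolerance
  gwas_summary(tab$SNP, z, n, tab$A1, tab$A2, chrom = tab$CHR,
               pos = tab$BP, p = p, p_tol = 1e-6)
}

#' Write a GWAS summary table as TSV
#'
#' Columns SNP, CHR, BP, A1, A2, Z, P, N; numeric values at 10 significant
#' digits, missing values as NA.
#'
#' @param gwas A [gwas_summary()].
#' @param path Output path.
#' @export
write_gwas <- function(gwas, path) {
  stopifnot(inherits(gwas, "gwas_summary"))
  out <- data.frame(
    SNP = gwas$id, CHR = gwas$chrom, BP = gwas$pos,
    A1 = gwas$effect_allele, A2 = gwas$other_allele,
    Z = signif(gwas$z, 10), P = signif(gwas$p, 10), N = gwas$n,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED gene annotation
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention (`start + 1`, `end`). Overlapping genes are
#' permitted; a leading "chr" prefix is stripped.
#'
#' @param path Path to a 4-column BED file (chrom, start, end, name).
#' @return Data frame with columns gene, chrom, start, end.
#' @export
read_annotation <- function(path) {
  empty <- data.frame(gene = character(0), chrom = integer(0),
                      start = numeric(0), end = numeric(0))
  if (length(readLines(path, n = 1L)) == 0L) return(empty)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "gene"))
  if (nrow(tab) == 0L) return(empty)
  if (!is.numeric(tab$start) || !is.numeric(tab$end)) {
    stop("non-numeric BED coordinates", call. = FALSE)
  }
  if (any(tab$start < 0)) {
    stop("negative BED coordinate at line(s) ",
         paste(utils::head(which(tab$start < 0), 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(tab$start >= tab$end)
  if (length(bad)) {
    stop("BED start >= end at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  chrom <- sub("^chr", "", tab$chrom)
  chrom_int <- suppressWarnings(as.integer(chrom))
  data.frame(
    gene = tab$gene,
    chrom = ifelse(is.na(chrom_int), NA_integer_, chrom_int),
    start = as.numeric(tab$start) + 1,
    end = as.numeric(tab$end),
    stringsAsFactors = FALSE
  )
}

#' Write an expression matrix as TSV
#'
#' First column `gene`, one column per sample; the second line (row label
#' `__group__`) carries the per-sample group labels.
#'
#' @param expr An `expression_matrix`.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(expr$values)), collapse = "\t"), con)
  writeLines(paste(c("__group__", expr$group), collapse = "\t"), con)
  for (i in seq_len(nrow(expr$values))) {
    writeLines(paste(c(rownames(expr$values)[i],
                       signif(expr$values[i, ], 10)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an expression matrix TSV written by [write_expression()]
#' @param path Input path.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed expression file", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  grp_line <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (grp_line[1] != "__group__") {
    stop("expected a __group__ label line", call. = FALSE)
  }
  samples <- header[-1]
  group <- grp_line[-1]
  rows <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  genes <- vapply(rows, `[[`, character(1), 1L)
  values <- t(vapply(rows, function(r) as.numeric(r[-1]),
                     numeric(length(samples))))
  if (any(!is.finite(values))) stop("missing expression values", call. = FALSE)
  dimnames(values) <- list(genes, samples)
  structure(list(values = values, group = group, planted = NULL),
            class = "expression_matrix")
}

#' Write per-gene weight files and an index
#'
#' One TSV per gene (SNP, A1, A2, one weight column per model, chosen
#' model) plus `index.tsv` (gene, chrom, start, end, cv_r2 per model,
#' best_model).
#'
#' @param models List of `protein_weight_model`s.
#' @param genes Gene annotation table (as from [gene_annotation()]).
#' @param dir Output directory (created if needed).
#' @export
write_weights <- function(models, genes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- lapply(models, function(m) {
    gi <- genes[genes$gene == m$gene, , drop = FALSE]
    per_gene <- data.frame(
      SNP = m$snp_ids,
      A1 = if (is.null(m$alleles)) NA else m$alleles$effect_allele,
      A2 = if (is.null(m$alleles)) NA else m$alleles$other_allele,
      stringsAsFactors = FALSE
    )
    for (mod in colnames(m$weights)) per_gene[[mod]] <- signif(m$weights[, mod], 10)
    per_gene$chosen <- m$best_model
    utils::write.table(per_gene, file.path(dir, paste0(m$gene, ".weights.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    data.frame(gene = m$gene, chrom = gi$chrom[1], start = gi$start[1],
               end = gi$end[1],
               t(signif(m$cv_r2, 6)),
               best_model = m$best_model, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, idx), file.path(dir, "index.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
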