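#' Per-gene per-sample promoter mean methylation
#'
#' Maps the matrix's CpG sites into the strand-aware promoter windows of
#' the annotated genes ([promoter_windows()]; overlap resolved with
#' GenomicRanges) and averages each sample's non-missing methylation
#' fractions over the CpGs inside each window. Genes with no matrix CpG
#' in their window are excluded; a (gene, sample) pair with window CpGs
#' but none observed is missing, not an error.
#'
#' @param meth samples x sites methylation matrix with `"chrom:pos"` keys.
#' @param records gene records (see [parse_gtf()]).
#' @param upstream,downstream window in bp around the TSS (defaults 1500
#'   and 500).
#' @return list with `values` (genes x samples matrix of mean promoter
#'   methylation) and `n_cpg` (named count of matrix CpGs per gene
#'   window).
#' @export
promoter_methylation <- function(meth, records, upstream = 1500L,
                                 downstream = 500L) {
  wins <- promoter_windows(records, upstream, downstream)
  sites <- parse_site_keys(colnames(meth))
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  win_gr <- GenomicRanges::GRanges(wins$chrom,
                                   IRanges::IRanges(wins$start, wins$end))
  hits <- GenomicRanges::findOverlaps(win_gr, site_gr)
  by_gene <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  if (!length(by_gene))
    return(list(values = matrix(NA_real_, 0, nrow(meth),
                                dimnames = list(NULL, rownames(meth))),
                n_cpg = stats::setNames(integer(0), character(0))))
  gene_idx <- as.integer(names(by_gene))
  values <- t(vapply(by_gene, function(cols)
    rowMeans(meth[, cols, drop = FALSE], na.rm = TRUE),
    numeric(nrow(meth))))
  values[is.nan(values)] <- NA_real_
  rownames(values) <- wins$gene_id[gene_idx]
  colnames(values) <- rownames(meth)
  list(values = values,
       n_cpg = stats::setNames(lengths(by_gene), wins$gene_id[gene_idx]))
}

#' Bonferroni correction
#'
#' `min(1, p * n)`; monotone in both arguments.
#'
#' @param p uncorrected p-value(s) in `[0,1]`.
#' @param n_tests number of tests (>= 1).
#' @return corrected p-value(s).
#' @export
bonferroni <- function(p, n_tests) {
  stopifnot(n_tests >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, p * n_tests)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR-adjusted values via [stats::p.adjust()].
#'
#' @param p vector of p-values in `[0,1]`.
#' @return adjusted values, capped at 1.
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential test of one gene's promoter methylation
#'
#' Two-sided Welch's t-test on the per-sample promoter means; the
#' direction is the sign of `mean(second group) - mean(first group)`
#' (with groups in the order of `levels`), reported as
#' `"hyper"`/`"hypo"` in the second group.
#'
#' @param values per-sample promoter methylation for one gene.
#' @param groups group labels aligned with `values`.
#' @param levels the two group labels in (reference, effect) order;
#'   defaults to their order of appearance.
#' @return list with `p`, `direction`, `means` (named), `n` per group;
#'   `NULL` if either group has fewer than 2 non-missing values.
#' @export
test_gene <- function(values, groups, levels = unique(as.character(groups))) {
  stopifnot(length(levels) == 2L)
  a <- values[groups == levels[1L] & !is.na(values)]
  b <- values[groups == levels[2L] & !is.na(values)]
  if (length(a) < 2L || length(b) < 2L) return(NULL)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    p <- stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  delta <- mean(b) - mean(a)
  list(p = p,
       direction = if (delta > 0) "hyper" else if (delta < 0) "hypo"
                   else "equal",
       means = stats::setNames(c(mean(a), mean(b)), levels),
       n = stats::setNames(c(length(a), length(b)), levels))
}

#' Per-organ promoter differential-methylation table
#'
#' Runs [test_gene()] for every gene of a promoter methylation matrix and
#' Bonferroni-corrects with G = the number of genes actually tested
#' (genes with >= 2 non-missing values per group). Genes that cannot be
#' tested are skipped and counted in the `n_skipped` attribute.
#'
#' @param prom result of [promoter_methylation()] (or a genes x samples
#'   matrix).
#' @param groups group labels aligned with the matrix columns.
#' @param levels two group labels in (reference, effect) order.
#' @param organ optional organ label recorded in the result.
#' @return data.frame with `gene_id`, `organ`, `n_cpg`, per-group means,
#'   `direction`, `p`, `p_bonf`, `n_genes_tested`, sorted by `p`.
#' @export
test_promoters <- function(prom, groups,
                           levels = unique(as.character(groups)),
                           organ = NA_character_) {
  values <- if (is.list(prom) && !is.data.frame(prom)) prom$values else prom
  n_cpg <- if (is.list(prom) && !is.data.frame(prom)) prom$n_cpg
           else stats::setNames(rep(NA_integer_, nrow(values)),
                                rownames(values))
  res <- lapply(rownames(values), function(g)
    test_gene(values[g, ], groups, levels))
  tested <- !vapply(res, is.null, logical(1))
  G <- sum(tested)
  if (G == 0L) stop("no testable genes")
  rows <- do.call(rbind, lapply(which(tested), function(i) {
    r <- res[[i]]
    data.frame(gene_id = rownames(values)[i], organ = organ,
               n_cpg = unname(n_cpg[rownames(values)[i]]),
               mean_ref = unname(r$means[1L]), mean_eff = unname(r$means[2L]),
               direction = r$direction, p = r$p, stringsAsFactors = FALSE)
  }))
  names(rows)[names(rows) == "mean_ref"] <- paste0("mean_", levels[1L])
  names(rows)[names(rows) == "mean_eff"] <- paste0("mean_", levels[2L])
  rows$p_bonf <- bonferroni(rows$p, G)
  rows$n_genes_tested <- G
  rows <- rows[order(rows$p, rows$gene_id, method = "radix"), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "n_skipped") <- sum(!tested)
  rows
}

#' Best-hit genes of a differential table
#'
#' The `k` genes with the smallest uncorrected p-values; ties break by
#' lexicographic gene id. If fewer than `k` genes were tested, all are
#' returned with a message.
#'
#' @param results a [test_promoters()] table.
#' @param k number of hits (default 6).
#' @return the top rows, in rank order.
#' @export
best_hits <- function(results, k = 6L) {
  stopifnot(nrow(results) >= 1L)
  if (k > nrow(results)) {
    message("best_hits: only ", nrow(results), " tested genes; returning all")
    k <- nrow(results)
  }
  ord <- order(results$p, results$gene_id, method = "radix")
  results[ord[seq_len(k)], , drop = FALSE]
}

#' Genes significant across all organs
#'
#' Returns the genes of the shared universe with uncorrected `p < alpha`
#' (strict) in every organ's table, with per-organ directions and a flag
#' for direction consistency (consistency is reported, not required).
#'
#' @param results_list named list of per-organ [test_promoters()] tables
#'   (>= 2 organs).
#' @param alpha significance level (default 0.05, strict inequality).
#' @return data.frame with `gene_id`, one `direction_<organ>` column per
#'   organ, `max_p`, and `consistent`.
#' @export
common_significant_genes <- function(results_list, alpha = 0.05) {
  stopifnot(length(results_list) >= 2L)
  universe <- Reduce(intersect, lapply(results_list, `[[`, "gene_id"))
  if (!length(universe)) stop("empty shared gene universe")
  keep <- universe
  for (res in results_list) {
    sig <- res$gene_id[res$p < alpha]
    keep <- intersect(keep, sig)
  }
  keep <- sort(keep)
  dirs <- vapply(results_list, function(res)
    res$direction[match(keep, res$gene_id)], character(length(keep)))
  if (length(keep) == 1L) dirs <- matrix(dirs, nrow = 1L,
                                         dimnames = list(NULL,
                                                         names(results_list)))
  maxp <- vapply(seq_along(keep), function(i)
    max(vapply(results_list, function(res)
      res$p[match(keep[i], res$gene_id)], numeric(1))), numeric(1))
  out <- data.frame(gene_id = keep, stringsAsFactors = FALSE)
  for (org in names(results_list))
    out[[paste0("direction_", org)]] <- dirs[, org]
  out$max_p <- maxp
  out$consistent <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
  out
}
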