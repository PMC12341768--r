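#' Binary Shannon entropy of a methylation fraction
#'
#' `-m * log2(m) - (1 - m) * log2(1 - m)` in bits, with the convention
#' `0 * log2(0) = 0`, so the entropy is 0 at fully (un)methylated sites
#' and maximal (1 bit) at `m = 0.5`. Vectorized; `NA` passes through.
#'
#' @param m methylation fraction(s) in `[0,1]`.
#' @return entropy in bits, in `[0,1]`.
#' @export
site_entropy <- function(m) {
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("methylation fraction outside [0,1]")
  term <- function(p) ifelse(p > 0, -p * log2(p), 0)
  term(m) + term(1 - m)
}

#' Per-sample global mean methylation (GMM)
#'
#' Mean of each sample's observed (non-missing) methylation fractions.
#'
#' @param meth samples x sites methylation matrix.
#' @return named numeric vector, one fraction per sample.
#' @export
sample_gmm <- function(meth) {
  n_obs <- rowSums(!is.na(meth))
  if (any(n_obs == 0L))
    stop("sample(s) with no observed sites: ",
         paste(rownames(meth)[n_obs == 0L], collapse = ", "))
  rowMeans(meth, na.rm = TRUE)
}

#' Per-sample mean methylation entropy (MME)
#'
#' Mean of [site_entropy()] over each sample's observed sites, in bits.
#'
#' @param meth samples x sites methylation matrix.
#' @return named numeric vector in `[0,1]`, one value per sample.
#' @export
sample_mme <- function(meth) {
  n_obs <- rowSums(!is.na(meth))
  if (any(n_obs == 0L))
    stop("sample(s) with no observed sites: ",
         paste(rownames(meth)[n_obs == 0L], collapse = ", "))
  rowMeans(site_entropy(meth), na.rm = TRUE)
}

#' Per-sample global methylation statistics table
#'
#' @param meth samples x sites methylation matrix.
#' @param sample_table optional sample sheet joined on `sample_id`.
#' @return data.frame with `sample_id`, `gmm`, `mme`, `n_sites_used`,
#'   plus any sample-sheet columns.
#' @export
global_stats_table <- function(meth, sample_table = NULL) {
  out <- data.frame(sample_id = rownames(meth),
                    gmm = unname(sample_gmm(meth)),
                    mme = unname(sample_mme(meth)),
                    n_sites_used = unname(rowSums(!is.na(meth))),
                    stringsAsFactors = FALSE)
  if (!is.null(sample_table))
    out <- merge(sample_table, out, by = "sample_id", sort = FALSE)
  out
}

#' Pearson correlation of a per-sample statistic with age
#'
#' @param stat numeric statistic per sample.
#' @param ages ages in months.
#' @return list with `r`, two-sided `p`, and `n`.
#' @export
age_correlation <- function(stat, ages) {
  stopifnot(length(stat) == length(ages), length(stat) >= 3L)
  if (stats::sd(stat) == 0 || stats::sd(ages) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(stat, ages, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(stat))
}

#' Significance stars
#'
#' `ns` for p > 0.05; `*` for 0.01 < p <= 0.05; `**` for
#' 0.001 < p <= 0.01; `***` for p <= 0.001; `****` for p <= 1e-4.
#'
#' @param p p-value(s) in `[0,1]`.
#' @return character vector of labels.
#' @export
stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(is.na(p), NA_character_,
  ifelse(p <= 1e-4, "****",
  ifelse(p <= 0.001, "***",
  ifelse(p <= 0.01, "**",
  ifelse(p <= 0.05, "*", "ns")))))
}

#' Two-group comparison of a per-sample statistic
#'
#' Two-sided Welch's t-test (unequal variances) between the two groups,
#' with the direction taken from the group means and stars per the
#' package's significance notation. Exactly identical groups (zero
#' pooled variance) are reported as statistic 0, p = 1.
#'
#' @param stat numeric statistic per sample.
#' @param groups two-level group labels aligned with `stat`.
#' @param metric name recorded in the result.
#' @return list of class `"group_comparison"`: `metric`, `statistic`,
#'   `p`, `mean_per_group` (named), `direction` (label of the higher
#'   group, or `"equal"`), `stars`.
#' @export
group_compare <- function(stat, groups, metric = "stat") {
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2L)
  a <- stat[groups == lv[1L]]
  b <- stat[groups == lv[2L]]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  means <- stats::setNames(c(mean(a), mean(b)), lv)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: no within-group variance
    if (mean(a) == mean(b)) { statistic <- 0; p <- 1 }
    else { statistic <- sign(mean(a) - mean(b)) * Inf; p <- 0 }
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    statistic <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(metric = metric, statistic = statistic, p = p,
                 mean_per_group = means,
                 direction = if (means[1L] == means[2L]) "equal"
                             else names(which.max(means)),
                 stars = stars(p)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$metric, ": ", paste(names(x$mean_per_group),
                            round(x$mean_per_group, 4), collapse = " vs "),
      "; Welch t = ", round(x$statistic, 3), ", p = ",
      format(x$p, digits = 3), " (", x$stars, ")\n", sep = "")
  invisible(x)
}
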