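#' Read a Bismark coverage file
#'
#' Bismark `.cov` files are tab-separated with six columns: chromosome,
#' start, end (both 1-based, equal for a single cytosine), methylation
#' percentage, count methylated, count unmethylated. The returned
#' methylation fraction is recomputed from the counts
#' (`n_meth / (n_meth + n_unmeth)`), which equals the percentage column up
#' to its printed rounding; coverage is the count sum.
#'
#' @param path path to a (possibly empty) coverage file.
#' @return data.frame with columns `chrom`, `pos`, `fraction`, `coverage`,
#'   `n_meth`, `n_unmeth`. Zero-coverage rows get `fraction = NA`.
#' @export
read_bismark_cov <- function(path) {
  lines <- readLines(path)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      fraction = numeric(0), coverage = integer(0),
                      n_meth = integer(0), n_unmeth = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop("malformed coverage line ", which(nf != 6L)[1L], " in ", path,
         ": expected 6 tab-separated fields")
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  pct <- suppressWarnings(as.numeric(m[, 4L]))
  n_meth <- suppressWarnings(as.integer(m[, 5L]))
  n_unmeth <- suppressWarnings(as.integer(m[, 6L]))
  bad <- is.na(pos) | is.na(pct) | is.na(n_meth) | is.na(n_unmeth)
  if (any(bad))
    stop("malformed coverage line ", which(bad)[1L], " in ", path,
         ": non-numeric field")
  if (any(n_meth < 0L | n_unmeth < 0L))
    stop("negative read count at line ",
         which(n_meth < 0L | n_unmeth < 0L)[1L], " in ", path)
  cov <- n_meth + n_unmeth
  frac <- ifelse(cov > 0L, n_meth / cov, NA_real_)
  data.frame(chrom = m[, 1L], pos = pos, fraction = frac,
             coverage = cov, n_meth = n_meth, n_unmeth = n_unmeth,
             stringsAsFactors = FALSE)
}

#' Write a Bismark coverage file
#'
#' Inverse of [read_bismark_cov()] on its own output: the percentage column
#' is written at full precision so the fraction round-trips exactly.
#'
#' @param tab data.frame with columns `chrom`, `pos`, `n_meth`, `n_unmeth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(tab, path) {
  stopifnot(all(c("chrom", "pos", "n_meth", "n_unmeth") %in% names(tab)))
  cov <- tab$n_meth + tab$n_unmeth
  pct <- ifelse(cov > 0, 100 * tab$n_meth / cov, 0)
  out <- data.frame(tab$chrom, tab$pos, tab$pos,
                    format(pct, digits = 15, trim = TRUE, scientific = FALSE),
                    tab$n_meth, tab$n_unmeth)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CGmap methylation file
#'
#' CGmap files are tab-separated with eight columns: chromosome, nucleotide,
#' position (1-based), context (`CG`/`CHG`/`CHH`), dinucleotide context,
#' methylation level in `[0,1]`, methylated count, total count. Only
#' CpG-context rows are retained; rows with an unknown context code are
#' skipped and their number reported via a message.
#'
#' @param path path to a CGmap file.
#' @return data.frame with columns `chrom`, `pos`, `fraction`, `coverage`.
#' @export
read_cgmap <- function(path) {
  lines <- readLines(path)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      fraction = numeric(0), coverage = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8L))
    stop("malformed CGmap line ", which(nf != 8L)[1L], " in ", path,
         ": expected 8 tab-separated fields")
  m <- matrix(unlist(fields), ncol = 8L, byrow = TRUE)
  known <- c("CG", "CHG", "CHH")
  unknown <- !(m[, 4L] %in% known)
  if (any(unknown))
    message("read_cgmap: skipped ", sum(unknown),
            " row(s) with unknown context code")
  keep <- m[, 4L] == "CG"
  m <- m[keep & !unknown, , drop = FALSE]
  if (!nrow(m)) return(empty)
  pos <- suppressWarnings(as.integer(m[, 3L]))
  frac <- suppressWarnings(as.numeric(m[, 6L]))
  cov <- suppressWarnings(as.integer(m[, 8L]))
  bad <- is.na(pos) | is.na(frac) | is.na(cov)
  if (any(bad)) stop("malformed CGmap row in ", path)
  data.frame(chrom = m[, 1L], pos = pos, fraction = frac, coverage = cov,
             stringsAsFactors = FALSE)
}

#' Assemble per-sample site tables into methylation and coverage matrices
#'
#' Takes one table per sample (as returned by [read_bismark_cov()] or
#' [read_cgmap()]) and builds aligned samples x sites matrices over the
#' union of site keys. Pairs absent from a sample's table are `NA` in the
#' methylation matrix and `0` in the coverage matrix. Site columns are in
#' deterministic sorted key order; sample rows follow `sample_table`.
#'
#' @param tables named list of per-sample data.frames with columns `chrom`,
#'   `pos`, `fraction`, `coverage`.
#' @param sample_table data.frame with at least a `sample_id` column whose
#'   ids match `names(tables)`.
#' @return list with elements `meth` (numeric matrix, fractions in
#'   `[0,1]` or `NA`) and `cov` (integer matrix of read counts).
#' @export
assemble_matrix <- function(tables, sample_table) {
  stopifnot(is.list(tables), "sample_id" %in% names(sample_table))
  ids <- as.character(sample_table$sample_id)
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  if (!all(ids %in% names(tables)))
    stop("sample sheet ids missing from tables: ",
         paste(setdiff(ids, names(tables)), collapse = ", "))
  keys_per <- lapply(tables[ids], function(t) make_site_keys(t$chrom, t$pos))
  for (i in seq_along(keys_per))
    if (anyDuplicated(keys_per[[i]]))
      stop("duplicate site within sample ", ids[i])
  all_keys <- sort_site_keys(unique(unlist(keys_per, use.names = FALSE)))
  meth <- matrix(NA_real_, length(ids), length(all_keys),
                 dimnames = list(ids, all_keys))
  cov <- matrix(0L, length(ids), length(all_keys),
                dimnames = list(ids, all_keys))
  for (i in seq_along(ids)) {
    idx <- match(keys_per[[i]], all_keys)
    meth[i, idx] <- tables[[ids[i]]]$fraction
    cov[i, idx] <- as.integer(tables[[ids[i]]]$coverage)
  }
  list(meth = meth, cov = cov)
}

#' Mask methylation values below a coverage depth
#'
#' Entries whose read coverage is below `min_depth` are set to missing
#' (`NA`); all other entries are returned bit-identical. The default depth
#' of 5 reads implements the "at least five reads" masking rule, with
#' coverage of exactly 5 retained.
#'
#' @param meth samples x sites methylation matrix.
#' @param cov aligned coverage matrix.
#' @param min_depth minimum read count to keep a value (default 5).
#' @return methylation matrix with low-coverage entries set to `NA`.
#' @export
mask_low_coverage <- function(meth, cov, min_depth = 5L) {
  check_aligned(meth, cov)
  stopifnot(min_depth >= 1)
  meth[is.na(cov) | cov < min_depth] <- NA_real_
  meth
}

#' Retain sites with sufficient coverage across samples
#'
#' Keeps exactly the sites covered by at least `min_depth` reads in at
#' least `min_sample_fraction` of the samples (both bounds inclusive),
#' the site-selection rule applied to the RRBS matrices before any
#' downstream analysis. Site order is preserved; the operation is
#' idempotent.
#'
#' @inheritParams mask_low_coverage
#' @param min_sample_fraction minimum fraction of samples meeting the
#'   depth (default 0.9).
#' @return the methylation matrix restricted to retained sites.
#' @export
filter_by_coverage <- function(meth, cov, min_depth = 5L,
                               min_sample_fraction = 0.9) {
  check_aligned(meth, cov)
  stopifnot(min_depth >= 1, min_sample_fraction > 0, min_sample_fraction <= 1)
  if (nrow(meth) == 0L) stop("no samples in matrix")
  ok <- colMeans(!is.na(cov) & cov >= min_depth)
  meth[, ok >= min_sample_fraction, drop = FALSE]
}

#' Intersect site keys across matrices
#'
#' @param ... two or more methylation matrices (site keys as column names)
#'   or character vectors of site keys.
#' @return sorted character vector of the common site keys.
#' @export
intersect_common_sites <- function(...) {
  args <- list(...)
  if (length(args) < 2L) stop("need at least two matrices")
  keysets <- lapply(args, function(x) if (is.matrix(x)) colnames(x) else x)
  sort_site_keys(Reduce(intersect, keysets))
}

check_aligned <- function(meth, cov) {
  if (!identical(dim(meth), dim(cov)) ||
      !identical(dimnames(meth), dimnames(cov)))
    stop("methylation and coverage matrices are not aligned")
  invisible(TRUE)
}

#' Write / read a methylation matrix as TSV
#'
#' Serialization with a header row of `"chrom:pos"` site keys and a first
#' `sample_id` column; missing values are empty cells.
#'
#' @param meth samples x sites matrix.
#' @param path file path.
#' @return `write_meth_matrix()`: the path, invisibly;
#'   `read_meth_matrix()`: the matrix.
#' @export
write_meth_matrix <- function(meth, path) {
  df <- data.frame(sample_id = rownames(meth), meth, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_meth_matrix
#' @export
read_meth_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  m
}
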