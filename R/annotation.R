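#' Parse gene records from a GTF annotation
#'
#' Imports a standard GTF (1-based, closed intervals) via rtracklayer
#' and keeps `gene` features. The transcription
#' start site honours strand: feature start on `+`, feature end on `-`.
#'
#' @param path GTF file path.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, ordered by chromosome then start.
#' @export
parse_gtf <- function(path) {
  empty_ok <- !any(nzchar(sub("#.*", "", readLines(path))))
  if (empty_ok)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), tss = integer(0),
                      stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "gtf")
  type <- S4Vectors::mcols(gr)$type
  if (length(gr) && !is.null(type)) gr <- gr[type == "gene"]
  if (!length(gr))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), tss = integer(0),
                      stringsAsFactors = FALSE))
  gene_id <- S4Vectors::mcols(gr)$gene_id
  if (is.null(gene_id) || anyNA(gene_id)) stop("gene feature without gene_id")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) stop("gene with unknown strand")
  rec <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    strand = strand,
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  rec$tss <- ifelse(rec$strand == "+", rec$start, rec$end)
  rec[order(rec$chrom, rec$start, method = "radix"), , drop = FALSE]
}

#' Write gene records as a toy GTF fixture
#'
#' Emits one `gene` line per record in standard GTF (tab-separated,
#' 1-based closed intervals, `gene_id` attribute), such that
#' `parse_gtf(make_toy_gtf(x, f))` round-trips `x`.
#'
#' @param records data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+` or `-`), `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
make_toy_gtf <- function(records, path) {
  needed <- c("gene_id", "chrom", "strand", "start", "end")
  stopifnot(all(needed %in% names(records)))
  if (nrow(records) && any(!records$strand %in% c("+", "-")))
    stop("invalid strand: must be '+' or '-'")
  if (nrow(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$start, end = records$end),
    strand = records$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "ratclocks"
  S4Vectors::mcols(gr)$gene_id <- records$gene_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Deterministic toy gene grid
#'
#' Builds `n_genes` evenly spaced gene records on one chromosome with
#' alternating strand, for fixtures and simulations.
#'
#' @param n_genes number of genes.
#' @param chrom chromosome name.
#' @param spacing distance between successive gene starts (bp).
#' @param gene_length span of each gene (bp).
#' @param offset position of the first gene start (must leave room for a
#'   promoter window upstream).
#' @return gene record data.frame as in [parse_gtf()].
#' @export
make_gene_records <- function(n_genes, chrom = "chr1", spacing = 10000L,
                              gene_length = 2000L, offset = 5000L) {
  stopifnot(n_genes >= 1, spacing > gene_length)
  start <- offset + spacing * (seq_len(n_genes) - 1L)
  end <- start + gene_length - 1L
  strand <- rep_len(c("+", "-"), n_genes)
  rec <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = chrom, strand = strand, start = start, end = end,
    stringsAsFactors = FALSE)
  rec$tss <- ifelse(rec$strand == "+", rec$start, rec$end)
  rec
}

#' Strand-aware promoter windows
#'
#' The promoter of a gene is the closed interval `[-upstream, +downstream]`
#' bp around its TSS following the direction of transcription: on `+`,
#' `[tss - upstream, tss + downstream]`; on `-`,
#' `[tss - downstream, tss + upstream]`. Bounds are inclusive (a window is
#' `upstream + downstream + 1` bp long) and clipped at position 1.
#'
#' @param records gene record data.frame with `gene_id`, `chrom`, `strand`
#'   and either `tss` or `start`/`end`.
#' @param upstream bp upstream of the TSS (default 1500).
#' @param downstream bp downstream of the TSS (default 500).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_windows <- function(records, upstream = 1500L, downstream = 500L) {
  stopifnot(upstream >= 0, downstream >= 0)
  if (is.null(records$tss))
    records$tss <- ifelse(records$strand == "+", records$start, records$end)
  plus <- records$strand == "+"
  start <- ifelse(plus, records$tss - upstream, records$tss - downstream)
  end <- ifelse(plus, records$tss + downstream, records$tss + upstream)
  data.frame(gene_id = records$gene_id, chrom = records$chrom,
             start = pmax(1L, as.integer(start)), end = as.integer(end),
             stringsAsFactors = FALSE)
}
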