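#' CpG site keys
#'
#' CpG sites are keyed by `"chrom:pos"` strings with 1-based positions.
#' Strands are never merged: a key identifies a cytosine exactly as reported
#' by the source file. Keys order by chromosome (C-locale lexicographic) and
#' then by numeric position.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @return `make_site_keys()`: character vector of keys.
#' @export
make_site_keys <- function(chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep_len(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  if (length(pos) && (any(!is.finite(pos)) || any(pos < 1)))
    stop("positions must be finite and >= 1")
  paste0(chrom, ":", as.integer(pos))
}

#' @rdname make_site_keys
#' @param keys character vector of `"chrom:pos"` keys.
#' @return `parse_site_keys()`: data.frame with columns `chrom`, `pos`.
#' @export
parse_site_keys <- function(keys) {
  chrom <- sub(":[0-9]+$", "", keys)
  pos <- as.integer(sub("^.*:", "", keys))
  if (length(keys) && anyNA(pos)) stop("malformed site key(s)")
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' @rdname make_site_keys
#' @return `sort_site_keys()`: keys sorted by chromosome then position.
#' @export
sort_site_keys <- function(keys) {
  if (!length(keys)) return(character(0))
  p <- parse_site_keys(keys)
  keys[order(p$chrom, p$pos, method = "radix")]
}
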