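# Shared fixture builders; everything is generated in code at test time.

# Random per-sample site table in the shape returned by read_bismark_cov().
random_site_table <- function(n, chrom = "chr1", seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(n * 20L, n))
  n_meth <- rpois(n, 6)
  n_unmeth <- rpois(n, 6)
  cov <- n_meth + n_unmeth
  data.frame(chrom = chrom, pos = pos,
             fraction = ifelse(cov > 0, n_meth / cov, NA_real_),
             coverage = cov, n_meth = n_meth, n_unmeth = n_unmeth,
             stringsAsFactors = FALSE)
}

# Aligned random methylation/coverage matrices with controllable holes.
random_meth_cov <- function(n = 10, p = 10, seed = 1, missing_rate = 0.2) {
  set.seed(seed)
  keys <- ratclocks::make_site_keys("chr1", sort(sample.int(p * 50L, p)))
  ids <- sprintf("s%02d", seq_len(n))
  cov <- matrix(rpois(n * p, 10), n, p, dimnames = list(ids, keys))
  meth <- matrix(round(runif(n * p), 3), n, p, dimnames = list(ids, keys))
  meth[matrix(runif(n * p) < missing_rate, n, p)] <- NA
  list(meth = meth, cov = cov)
}

# Hand-built clock model for arithmetic oracles.
toy_clock <- function(keys, weights, intercept = 10) {
  structure(list(site_keys = keys,
                 weights = stats::setNames(weights, keys),
                 intercept = intercept,
                 site_means = stats::setNames(rep(0.5, length(keys)), keys),
                 reference_regression = list(slope = 1, intercept = 0)),
            class = "clock_model")
}

# Two-sided permutation test on a group-mean difference (independent
# oracle for Welch-test significance checks).
permutation_p <- function(a, b, n_perm = 2000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  hits <- replicate(n_perm, {
    idx <- sample(length(pool), length(a))
    abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
  })
  (sum(hits) + 1) / (n_perm + 1)
}
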