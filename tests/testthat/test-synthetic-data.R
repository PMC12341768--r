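test_that("generators are seed-deterministic", {
  cfg <- simulation_config(n_samples = 20, n_sites = 100, seed = 1)
  a <- simulate_training_cohort(cfg)
  b <- simulate_training_cohort(cfg)
  expect_identical(a$meth, b$meth)
  expect_identical(a$cov, b$cov)
  expect_identical(a$truth, b$truth)

  des <- multiorgan_design(n_per_group = 2)
  rec <- make_gene_records(5)
  m1 <- simulate_multiorgan_cohort(simulation_config(n_sites = 80, seed = 2),
                                   des, rec)
  m2 <- simulate_multiorgan_cohort(simulation_config(n_sites = 80, seed = 2),
                                   des, rec)
  expect_identical(m1$meth, m2$meth)
  expect_false(identical(
    m1$meth,
    simulate_multiorgan_cohort(simulation_config(n_sites = 80, seed = 3),
                               des, rec)$meth))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_samples = 1), "n_samples")
  expect_error(simulation_config(frac_age_associated = 1.2), "frac_age")
  expect_error(simulation_config(age_range = c(5, 5)), "age_range")
  expect_error(simulation_config(coverage_mean = 0), "coverage_mean")
  expect_error(simulation_config(noise_sd = NaN), "non-finite")
})

test_that("observed fractions equal methylated over total reads exactly", {
  coh <- simulate_training_cohort(simulation_config(n_samples = 10,
                                                    n_sites = 200, seed = 4))
  covered <- coh$cov > 0
  expect_identical(coh$meth[covered],
                   (coh$n_meth / coh$cov)[covered])
  expect_true(all(is.na(coh$meth[!covered])))
  expect_true(all(coh$n_meth <= coh$cov))
})

test_that("without age-associated sites, site-age correlations are null", {
  cfg <- simulation_config(n_samples = 60, n_sites = 1000,
                           frac_age_associated = 0, seed = 42)
  coh <- simulate_training_cohort(cfg)
  ages <- coh$samples$age_months
  p <- apply(coh$meth, 2, function(m) {
    ok <- !is.na(m)
    if (sum(ok) < 10 || stats::sd(m[ok]) == 0) return(NA_real_)
    stats::cor.test(m[ok], ages[ok])$p.value
  })
  frac_sig <- mean(p < 0.05, na.rm = TRUE)
  n <- sum(!is.na(p))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n)
  expect_gt(frac_sig, ci[1])
  expect_lt(frac_sig, ci[2])
})

test_that("age-associated sites track their closed-form expectation", {
  cfg <- simulation_config(n_samples = 40, n_sites = 300, noise_sd = 0,
                           low_coverage_rate = 0, coverage_mean = 2000,
                           coverage_dispersion = 1e6, seed = 5)
  coh <- simulate_training_cohort(cfg)
  ages <- coh$samples$age_months
  expected <- sapply(coh$truth$age_site_ids, function(k)
    pmin(pmax(coh$truth$baseline[k] + coh$truth$slopes[k] * ages, 0), 1))
  observed <- coh$meth[, coh$truth$age_site_ids]
  # binomial sd at coverage 2000 is ~0.011; averaged deviation is far less
  expect_lt(mean(abs(observed - expected), na.rm = TRUE), 0.02)
  fit <- stats::lm(as.vector(observed) ~ as.vector(expected))
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.02)
})

test_that("multi-organ cohort has the designed size and injected effects", {
  rec <- make_gene_records(10)
  des <- multiorgan_design(n_per_group = 8)
  coh <- simulate_multiorgan_cohort(simulation_config(n_sites = 100, seed = 6),
                                    des, rec)
  expect_equal(nrow(coh$meth), 64L)  # 8 per group x 2 groups x 4 organs
  expect_equal(length(unique(coh$samples$individual)), 16L)

  # injected effect appears as the group-mean difference at promoter CpGs
  deterministic <- simulation_config(n_sites = 100, noise_sd = 0,
                                     low_coverage_rate = 0,
                                     coverage_mean = 5000,
                                     coverage_dispersion = 1e6, seed = 7)
  des2 <- multiorgan_design(n_per_group = 8,
                            affected_genes = data.frame(
                              organ = "soleus", gene_id = "gene0002",
                              effect = -0.15))
  coh2 <- simulate_multiorgan_cohort(deterministic, des2, rec)
  cols <- names(which(coh2$truth$site_gene == "gene0002"))
  idx <- coh2$samples$organ == "soleus"
  diff <- mean(coh2$meth[idx & coh2$samples$group == "HCR", cols]) -
    mean(coh2$meth[idx & coh2$samples$group == "LCR", cols])
  expect_equal(diff, -0.15, tolerance = 0.02)
  expect_equal(coh2$truth$affected_gene_table$direction, "hypo")

  # monotone construction: larger injected effect, larger mean difference
  des3 <- multiorgan_design(n_per_group = 8,
                            affected_genes = data.frame(
                              organ = "soleus", gene_id = "gene0002",
                              effect = -0.3))
  coh3 <- simulate_multiorgan_cohort(deterministic, des3, rec)
  diff3 <- mean(coh3$meth[idx & coh3$samples$group == "HCR", cols]) -
    mean(coh3$meth[idx & coh3$samples$group == "LCR", cols])
  expect_gt(abs(diff3), abs(diff))

  expect_error(
    simulate_multiorgan_cohort(deterministic,
      multiorgan_design(affected_genes = data.frame(
        organ = "soleus", gene_id = "nope", effect = 0.1)), rec),
    "absent from annotation")
})

test_that("a training-cohort template shares background sites and slopes", {
  tr <- simulate_training_cohort(simulation_config(n_samples = 10,
                                                   n_sites = 150, seed = 8))
  rec <- make_gene_records(4)
  app <- simulate_multiorgan_cohort(simulation_config(n_sites = 150, seed = 9),
                                    multiorgan_design(n_per_group = 2),
                                    rec, template = tr)
  expect_true(all(colnames(tr$meth) %in% colnames(app$meth)))
  expect_identical(app$truth$slopes[names(tr$truth$slopes)],
                   tr$truth$slopes)
})

test_that("entropy drift raises MME and lowers GMM with age", {
  cfg <- simulation_config(n_samples = 120, n_sites = 400,
                           frac_age_associated = 0, entropy_drift = 0.3,
                           seed = 10)
  coh <- simulate_training_cohort(cfg)
  ages <- coh$samples$age_months
  gmm <- sample_gmm(coh$meth)
  mme <- sample_mme(coh$meth)
  expect_lt(stats::cor(gmm, ages), 0)
  expect_gt(stats::cor(mme, ages), 0)
})

test_that("toy GTF writer and parser are mutual inverses", {
  rec1 <- make_gene_records(1)
  f <- withr::local_tempfile(fileext = ".gtf")
  make_toy_gtf(rec1, f)
  gene_lines <- grep("\tgene\t", readLines(f), value = TRUE)
  expect_length(gene_lines, 1L)

  set.seed(11)
  rec <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    chrom = sample(c("chr1", "chr2"), 10, replace = TRUE),
                    strand = sample(c("+", "-"), 10, replace = TRUE),
                    start = sample.int(1e5, 10), stringsAsFactors = FALSE)
  rec$end <- rec$start + sample.int(5000, 10)
  make_toy_gtf(rec, f)
  back <- parse_gtf(f)
  ord <- order(rec$chrom, rec$start)
  expect_equal(back$gene_id, rec$gene_id[ord])
  expect_equal(back$start, rec$start[ord])
  expect_equal(back$end, rec$end[ord])
  expect_equal(back$strand, rec$strand[ord])

  expect_error(make_toy_gtf(transform(rec1, strand = "*"), f), "strand")
  empty <- rec[0, ]
  make_toy_gtf(empty, f)
  expect_equal(nrow(parse_gtf(f)), 0L)
})

test_that("cohort export writes parseable coverage files", {
  coh <- simulate_training_cohort(simulation_config(n_samples = 3,
                                                    n_sites = 50, seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  id <- coh$samples$sample_id[1]
  back <- read_bismark_cov(file.path(dir, paste0(id, ".cov")))
  covered <- which(coh$cov[id, ] > 0)
  expect_equal(nrow(back), length(covered))
  expect_equal(back$fraction, unname(coh$meth[id, covered]))
  expect_equal(back$coverage, unname(coh$cov[id, covered]))
})
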