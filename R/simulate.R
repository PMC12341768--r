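#' Simulation configuration for synthetic methylation cohorts
#'
#' Defines the generative model for an age-structured RRBS-like cohort:
#' per-site baseline methylation drawn from a Beta distribution, a minority
#' of age-associated sites with linear drift in months, optional
#' entropy drift (age-proportional shrinkage of methylation toward 0.5),
#' per-observation Gaussian biological noise, and negative-binomial read
#' coverage with binomial sampling of methylated reads. Observed fractions
#' are always `methylated_reads / coverage` exactly.
#'
#' Defaults emulate a lifespan-wide blood training cohort: 134 samples
#' aged 1-27 months, 5,000 CpG sites of which 4% (200) drift with age at
#' slopes on the order of 0.01 fraction/month, baseline methylation
#' Beta(5, 2) (a globally hypermethylated methylome), biological noise
#' sd 0.05, mean coverage 30x with 5% of entries censorable below 5 reads.
#'
#' @param n_samples number of samples (>= 2).
#' @param age_range min and max age in months.
#' @param n_sites number of CpG sites.
#' @param frac_age_associated fraction of sites with a nonzero age slope.
#' @param slope_scale sd of per-site age slopes (fraction per month).
#' @param baseline_shape two shape parameters of the Beta baseline.
#' @param noise_sd per-observation biological noise sd (fraction units).
#' @param coverage_mean expected reads per site.
#' @param coverage_dispersion negative-binomial size (overdispersion).
#' @param low_coverage_rate fraction of entries with coverage forced below
#'   the 5-read masking threshold.
#' @param entropy_drift strength in `[0,1)` of age-proportional shrinkage
#'   of `|m - 0.5|`; 0 disables the drift.
#' @param seed integer RNG seed.
#' @return validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_samples = 134L, age_range = c(1, 27),
                              n_sites = 5000L, frac_age_associated = 0.04,
                              slope_scale = 0.01, baseline_shape = c(5, 2),
                              noise_sd = 0.05, coverage_mean = 30,
                              coverage_dispersion = 5,
                              low_coverage_rate = 0.05, entropy_drift = 0,
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), age_range = as.numeric(age_range),
              n_sites = as.integer(n_sites),
              frac_age_associated = frac_age_associated,
              slope_scale = slope_scale, baseline_shape = baseline_shape,
              noise_sd = noise_sd, coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              low_coverage_rate = low_coverage_rate,
              entropy_drift = entropy_drift, seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(!is.finite(num))) stop("non-finite simulation config value")
  if (cfg$n_samples < 2L) stop("n_samples must be >= 2")
  if (cfg$n_sites < 1L) stop("n_sites must be >= 1")
  if (cfg$frac_age_associated < 0 || cfg$frac_age_associated > 1)
    stop("frac_age_associated must be in [0,1]")
  if (length(cfg$age_range) != 2L || cfg$age_range[1] >= cfg$age_range[2])
    stop("age_range must be (min, max) with min < max")
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be > 0")
  if (cfg$low_coverage_rate < 0 || cfg$low_coverage_rate > 1)
    stop("low_coverage_rate must be in [0,1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$entropy_drift < 0 || cfg$entropy_drift >= 1)
    stop("entropy_drift must be in [0,1)")
  if (any(cfg$baseline_shape <= 0)) stop("baseline_shape must be positive")
  structure(cfg, class = "simulation_config")
}

# Observation layer shared by both generators: entropy drift, biological
# noise, clamping to [0,1], NB coverage with a censorable low tail,
# binomial read sampling. `true_m` is samples x sites expected methylation.
simulate_observations <- function(true_m, ages, config) {
  n <- nrow(true_m); p <- ncol(true_m)
  if (config$entropy_drift > 0) {
    fac <- pmax(0, 1 - config$entropy_drift * ages / max(config$age_range))
    true_m <- 0.5 + (true_m - 0.5) * fac
  }
  if (config$noise_sd > 0)
    true_m <- true_m + matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
  true_m <- pmin(pmax(true_m, 0), 1)
  cov <- matrix(stats::rnbinom(n * p, mu = config$coverage_mean,
                               size = config$coverage_dispersion), n, p)
  if (config$low_coverage_rate > 0) {
    low <- stats::runif(n * p) < config$low_coverage_rate
    cov[low] <- sample(0:4, sum(low), replace = TRUE)
  }
  n_meth <- matrix(stats::rbinom(n * p, as.vector(cov), as.vector(true_m)),
                   n, p)
  meth <- ifelse(cov > 0, n_meth / cov, NA_real_)
  dimnames(meth) <- dimnames(cov) <- dimnames(n_meth) <- dimnames(true_m)
  list(meth = meth, cov = cov, n_meth = n_meth)
}

#' Simulate a blood-like training cohort
#'
#' Generates a single-tissue cohort under [simulation_config()]: ages
#' uniform over `age_range`, expected methylation
#' `clamp(baseline + slope * age, 0, 1)` for age-associated sites, and
#' read-sampled observed fractions. Identical seeds give identical output.
#'
#' @param config a [simulation_config()].
#' @return list of class `"simulated_cohort"` with elements `meth`, `cov`,
#'   `n_meth` (aligned samples x sites matrices), `samples` (sample sheet
#'   with `sample_id`, `age_months`, `group`, `organ`) and `truth`
#'   (`age_site_ids`, named `slopes`, `baseline`, `reference_ages`).
#' @export
simulate_training_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples; p <- config$n_sites
  ids <- sprintf("blood%03d", seq_len(n))
  ages <- stats::runif(n, config$age_range[1], config$age_range[2])
  pos <- sort(sample.int(p * 200L, p))
  keys <- make_site_keys("chr1", pos)
  baseline <- stats::rbeta(p, config$baseline_shape[1], config$baseline_shape[2])
  k <- round(config$frac_age_associated * p)
  assoc <- if (k > 0) sort(sample.int(p, k)) else integer(0)
  slopes <- numeric(p)
  if (k > 0) {
    s <- stats::rnorm(k, 0, config$slope_scale)
    s[s == 0] <- config$slope_scale  # slopes are nonzero exactly on assoc
    slopes[assoc] <- s
  }
  true_m <- matrix(baseline, n, p, byrow = TRUE) + outer(ages, slopes)
  dimnames(true_m) <- list(ids, keys)
  obs <- simulate_observations(true_m, ages, config)
  samples <- data.frame(sample_id = ids, age_months = ages,
                        group = "other", organ = "blood",
                        stringsAsFactors = FALSE)
  truth <- list(age_site_ids = keys[assoc],
                slopes = stats::setNames(slopes[assoc], keys[assoc]),
                baseline = stats::setNames(baseline, keys),
                reference_ages = stats::setNames(ages, ids))
  structure(c(obs, list(samples = samples, truth = truth, config = config)),
            class = "simulated_cohort")
}

#' Multi-organ two-group study design
#'
#' Describes the application cohort: four organs by two selection-line
#' groups (LCR, low-capacity runner; HCR, high-capacity runner) with
#' `n_per_group` individuals per group, each contributing one sample per
#' organ. Promoter effects are injected for (organ, gene) pairs: for HCR
#' samples of that organ, all CpGs inside the gene's promoter window are
#' shifted by `effect` (negative = hypomethylated in HCR). Genes listed in
#' `common_affected_genes` are affected in every organ with
#' `common_effect`. Per-organ additive offsets emulate organ differences
#' in global methylation (`organ_gmm_offsets`, fraction units) and in age
#' acceleration (`organ_accel_offsets`, months added to the effective age
#' driving the age-associated sites).
#'
#' @param organs four unique organ labels.
#' @param groups two group labels; the second is the effect-carrying group.
#' @param n_per_group individuals per group.
#' @param organ_gmm_offsets named numeric per organ (default all 0).
#' @param organ_accel_offsets named numeric per organ (default all 0).
#' @param affected_genes data.frame with columns `organ`, `gene_id`,
#'   `effect` (signed, in (-1, 1)).
#' @param common_affected_genes gene ids affected in all organs.
#' @param common_effect signed effect for the common genes.
#' @param cpgs_per_promoter simulated CpGs per promoter window.
#' @return list of class `"multiorgan_design"`.
#' @export
multiorgan_design <- function(organs = c("hippocampus", "heart", "soleus",
                                         "large_intestine"),
                              groups = c("LCR", "HCR"), n_per_group = 8L,
                              organ_gmm_offsets = NULL,
                              organ_accel_offsets = NULL,
                              affected_genes = NULL,
                              common_affected_genes = character(0),
                              common_effect = -0.15,
                              cpgs_per_promoter = 10L) {
  if (anyDuplicated(organs)) stop("organ labels must be unique")
  if (length(groups) != 2L) stop("exactly two groups required")
  if (is.null(organ_gmm_offsets))
    organ_gmm_offsets <- stats::setNames(numeric(length(organs)), organs)
  if (is.null(organ_accel_offsets))
    organ_accel_offsets <- stats::setNames(numeric(length(organs)), organs)
  stopifnot(all(organs %in% names(organ_gmm_offsets)),
            all(organs %in% names(organ_accel_offsets)))
  if (is.null(affected_genes))
    affected_genes <- data.frame(organ = character(0), gene_id = character(0),
                                 effect = numeric(0), stringsAsFactors = FALSE)
  if (length(common_affected_genes)) {
    extra <- expand.grid(organ = organs, gene_id = common_affected_genes,
                         stringsAsFactors = FALSE)
    extra$effect <- common_effect
    affected_genes <- rbind(affected_genes, extra)
  }
  if (nrow(affected_genes)) {
    if (any(abs(affected_genes$effect) >= 1) || any(affected_genes$effect == 0))
      stop("effects must be nonzero and in (-1, 1)")
    if (any(!affected_genes$organ %in% organs))
      stop("affected_genes refers to unknown organ")
  }
  structure(list(organs = organs, groups = groups,
                 n_per_group = as.integer(n_per_group),
                 organ_gmm_offsets = organ_gmm_offsets,
                 organ_accel_offsets = organ_accel_offsets,
                 affected_genes = affected_genes,
                 common_affected_genes = common_affected_genes,
                 cpgs_per_promoter = as.integer(cpgs_per_promoter)),
            class = "multiorgan_design")
}

#' Simulate a multi-organ two-group cohort with known promoter effects
#'
#' Places `cpgs_per_promoter` CpGs inside the promoter window of every
#' annotated gene (plus background CpGs on a separate contig up to
#' `config$n_sites`), then generates one sample per (individual, organ)
#' under the observation model of [simulate_training_cohort()], with the
#' design's organ offsets and group promoter effects added to the expected
#' methylation. Ages are uniform over `config$age_range` per individual
#' and shared across that individual's organs.
#'
#' @param config a [simulation_config()]; `n_samples` is ignored (the
#'   design fixes `2 * n_per_group * length(organs)` samples).
#' @param design a [multiorgan_design()].
#' @param records gene records (see [make_gene_records()] / [parse_gtf()]).
#' @param upstream,downstream promoter window in bp around the TSS.
#' @param template optional `"simulated_cohort"` (typically the training
#'   cohort): its site coordinates, baselines and age slopes are reused
#'   as the background sites of this cohort, emulating that training and
#'   application data come from the same genome and share age-drifting
#'   CpGs — which is what makes blood-trained clocks applicable.
#' @return `"simulated_cohort"` as in [simulate_training_cohort()]; the
#'   sample sheet gains `individual`, and `truth` gains
#'   `affected_gene_table` (organ, gene_id, effect, direction) and
#'   `site_gene` (promoter gene id per site, `NA` for background).
#' @export
simulate_multiorgan_cohort <- function(config, design, records,
                                       upstream = 1500L, downstream = 500L,
                                       template = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(design, "multiorgan_design"))
  if (nrow(design$affected_genes) &&
      any(!design$affected_genes$gene_id %in% records$gene_id))
    stop("affected gene id absent from annotation: ",
         paste(setdiff(design$affected_genes$gene_id, records$gene_id),
               collapse = ", "))
  set.seed(config$seed)
  wins <- promoter_windows(records, upstream, downstream)
  prom_pos <- lapply(seq_len(nrow(wins)), function(i)
    sort(sample(seq.int(wins$start[i], wins$end[i]), design$cpgs_per_promoter)))
  sites <- data.frame(
    key = make_site_keys(rep(wins$chrom, each = design$cpgs_per_promoter),
                         unlist(prom_pos, use.names = FALSE)),
    gene = rep(wins$gene_id, each = design$cpgs_per_promoter),
    stringsAsFactors = FALSE)
  sites$baseline <- stats::rbeta(nrow(sites), config$baseline_shape[1],
                                 config$baseline_shape[2])
  sites$slope <- 0
  if (is.null(template)) {
    n_bg <- max(0L, config$n_sites - nrow(sites))
    if (n_bg > 0L) {
      bg <- data.frame(
        key = make_site_keys("chrU", sort(sample.int(n_bg * 200L, n_bg))),
        gene = NA_character_,
        baseline = stats::rbeta(n_bg, config$baseline_shape[1],
                                config$baseline_shape[2]),
        slope = 0, stringsAsFactors = FALSE)
      sites <- rbind(sites, bg)
    }
    k <- round(config$frac_age_associated * nrow(sites))
    if (k > 0) {
      assoc <- sample.int(nrow(sites), k)
      s <- stats::rnorm(k, 0, config$slope_scale)
      s[s == 0] <- config$slope_scale
      sites$slope[assoc] <- s
    }
  } else {
    stopifnot(inherits(template, "simulated_cohort"))
    tmpl_slopes <- stats::setNames(numeric(ncol(template$meth)),
                                   colnames(template$meth))
    tmpl_slopes[names(template$truth$slopes)] <- template$truth$slopes
    bg <- data.frame(key = colnames(template$meth), gene = NA_character_,
                     baseline = unname(template$truth$baseline),
                     slope = unname(tmpl_slopes), stringsAsFactors = FALSE)
    sites <- rbind(sites, bg[!bg$key %in% sites$key, , drop = FALSE])
  }
  sites <- sites[!duplicated(sites$key), , drop = FALSE]
  sites <- sites[order(match(sites$key, sort_site_keys(sites$key))), ,
                 drop = FALSE]
  keys <- sites$key
  site_gene <- sites$gene
  baseline <- sites$baseline
  slopes <- sites$slope
  p <- length(keys)

  n_ind <- 2L * design$n_per_group
  ind_ids <- sprintf("ind%02d", seq_len(n_ind))
  ind_group <- rep(design$groups, each = design$n_per_group)
  ind_age <- stats::runif(n_ind, config$age_range[1], config$age_range[2])
  samples <- expand.grid(individual = ind_ids, organ = design$organs,
                         stringsAsFactors = FALSE)
  samples$group <- ind_group[match(samples$individual, ind_ids)]
  samples$age_months <- ind_age[match(samples$individual, ind_ids)]
  samples$sample_id <- paste(samples$individual, samples$organ, sep = "_")
  samples <- samples[, c("sample_id", "individual", "age_months", "group",
                         "organ")]
  assoc <- which(slopes != 0)

  n <- nrow(samples)
  age_eff <- samples$age_months +
    design$organ_accel_offsets[samples$organ]
  true_m <- matrix(baseline, n, p, byrow = TRUE) + outer(age_eff, slopes) +
    matrix(design$organ_gmm_offsets[samples$organ], n, p)
  aff <- design$affected_genes
  effect_group <- design$groups[2]
  if (nrow(aff)) {
    for (i in seq_len(nrow(aff))) {
      cols <- which(!is.na(site_gene) & site_gene == aff$gene_id[i])
      rows <- which(samples$organ == aff$organ[i] &
                    samples$group == effect_group)
      true_m[rows, cols] <- true_m[rows, cols] + aff$effect[i]
    }
  }
  dimnames(true_m) <- list(samples$sample_id, keys)
  obs <- simulate_observations(true_m, samples$age_months, config)
  truth <- list(age_site_ids = keys[assoc],
                slopes = stats::setNames(slopes[assoc], keys[assoc]),
                baseline = stats::setNames(baseline, keys),
                reference_ages = stats::setNames(samples$age_months,
                                                 samples$sample_id),
                affected_gene_table =
                  if (nrow(aff)) data.frame(aff,
                    direction = ifelse(aff$effect > 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE) else aff,
                site_gene = stats::setNames(site_gene, keys))
  structure(c(obs, list(samples = samples, truth = truth, config = config)),
            class = "simulated_cohort")
}

#' Simulate paired rDNA-style methylation feature tables
#'
#' Generates high-coverage percent-scale feature tables over a shared set
#' of CpG positions on a single rDNA-like reference for a training cohort
#' and an application cohort, emulating the multi-copy rDNA repeat whose
#' deep coverage makes its CpGs nearly always observed. Age-associated
#' positions drift with positive slopes only (the rDNA CpGs correlate
#' positively with age when they correlate at all); a small fraction of
#' cells is missing at random.
#'
#' @param train_ages,app_ages ages in months for the two cohorts.
#' @param n_sites CpG positions on the reference.
#' @param frac_age_associated fraction of positions drifting with age.
#' @param slope_scale mean per-month drift (percent-scale slope is
#'   `100 * slope_scale`).
#' @param noise_sd observation noise in fraction units.
#' @param missing_rate fraction of missing cells.
#' @param reference reference sequence name.
#' @param seed integer seed.
#' @return list with `train` and `app` (samples x positions matrices of
#'   methylation percentages, `NA` missing) and `truth` (positions and
#'   slopes).
#' @export
simulate_rdna_tables <- function(train_ages, app_ages, n_sites = 200L,
                                 frac_age_associated = 0.15,
                                 slope_scale = 0.01, noise_sd = 0.05,
                                 missing_rate = 0.05,
                                 reference = "rDNA", seed = 1L) {
  set.seed(seed)
  pos <- sort(sample.int(n_sites * 40L, n_sites))
  keys <- make_site_keys(reference, pos)
  baseline <- stats::rbeta(n_sites, 2, 2)
  k <- round(frac_age_associated * n_sites)
  assoc <- if (k > 0) sort(sample.int(n_sites, k)) else integer(0)
  slopes <- numeric(n_sites)
  if (k > 0) slopes[assoc] <- abs(stats::rnorm(k, slope_scale,
                                               slope_scale / 2)) + 1e-4
  gen <- function(ages, prefix) {
    n <- length(ages)
    m <- matrix(baseline, n, n_sites, byrow = TRUE) + outer(ages, slopes) +
      matrix(stats::rnorm(n * n_sites, 0, noise_sd), n, n_sites)
    m <- 100 * pmin(pmax(m, 0), 1)
    m[matrix(stats::runif(n * n_sites) < missing_rate, n, n_sites)] <- NA
    dimnames(m) <- list(sprintf("%s%03d", prefix, seq_len(n)), keys)
    m
  }
  list(train = gen(train_ages, "rdtrain"), app = gen(app_ages, "rdapp"),
       truth = list(positions = keys[assoc],
                    slopes = stats::setNames(slopes[assoc], keys[assoc])))
}

#' Write a simulated cohort as Bismark coverage files and TSV sheets
#'
#' One `<sample_id>.cov` per sample (only covered sites are written, as in
#' real Bismark output), a `sample_sheet.tsv`, and a `truth_age_sites.tsv`.
#'
#' @param cohort a `"simulated_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- parse_site_keys(colnames(cohort$meth))
  for (id in rownames(cohort$meth)) {
    covered <- which(cohort$cov[id, ] > 0)
    tab <- data.frame(chrom = sites$chrom[covered], pos = sites$pos[covered],
                      n_meth = cohort$n_meth[id, covered],
                      n_unmeth = cohort$cov[id, covered] -
                        cohort$n_meth[id, covered])
    write_bismark_cov(tab, file.path(dir, paste0(id, ".cov")))
  }
  utils::write.table(cohort$samples, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(site = cohort$truth$age_site_ids,
                      slope = unname(cohort$truth$slopes))
  utils::write.table(truth, file.path(dir, "truth_age_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated methylation cohort: ", nrow(x$meth), " samples x ",
      ncol(x$meth), " CpG sites\n", sep = "")
  cat("  age range (months): ",
      paste(round(range(x$samples$age_months), 1), collapse = "-"),
      "; age-associated sites: ", length(x$truth$age_site_ids), "\n", sep = "")
  invisible(x)
}
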