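#' Paired cross-organ comparisons of a per-sample metric
#'
#' For every pair of organs, a two-sided paired t-test on the
#' within-individual differences (first organ minus second). Pairs whose
#' differences have zero variance are flagged degenerate and get no
#' p-value rather than an arbitrary one.
#'
#' @param tbl individuals x organs numeric matrix (rownames =
#'   individuals) or data.frame.
#' @param metric name recorded in the result.
#' @return data.frame with one row per organ pair: `metric`, `organ_a`,
#'   `organ_b`, `n_pairs`, `mean_difference` (a minus b), `statistic`,
#'   `p`, `stars`, `p_bh` (Benjamini-Hochberg across the pairs),
#'   `degenerate`.
#' @export
paired_organ_compare <- function(tbl, metric = "metric") {
  tbl <- as.matrix(tbl)
  organs <- colnames(tbl)
  stopifnot(length(organs) >= 2L)
  pairs <- utils::combn(organs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    ok <- !is.na(tbl[, a]) & !is.na(tbl[, b])
    if (sum(ok) < 2L) stop("fewer than 2 complete pairs for ", a, "/", b)
    d <- tbl[ok, a] - tbl[ok, b]
    degenerate <- stats::sd(d) == 0
    if (degenerate) {
      statistic <- NA_real_; p <- NA_real_
    } else {
      tt <- stats::t.test(d)
      statistic <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(metric = metric, organ_a = a, organ_b = b,
               n_pairs = sum(ok), mean_difference = mean(d),
               statistic = statistic, p = p, stars = stars(p),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- benjamini_hochberg(out$p)
  out
}

#' Cross-organ correlations of age acceleration
#'
#' Pearson correlation (two-sided p) of per-individual age accelerations
#' between every pair of organs; a significant correlation would indicate
#' that accelerated aging is a body-wide rather than organ-local process.
#'
#' @param tbl individuals x organs acceleration matrix.
#' @return data.frame with `organ_a`, `organ_b`, `n`, `r`, `p`, `stars`.
#' @export
acceleration_cross_correlation <- function(tbl) {
  tbl <- as.matrix(tbl)
  organs <- colnames(tbl)
  pairs <- utils::combn(organs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    ok <- !is.na(tbl[, a]) & !is.na(tbl[, b])
    if (sum(ok) < 3L) stop("fewer than 3 complete pairs for ", a, "/", b)
    if (stats::sd(tbl[ok, a]) == 0 || stats::sd(tbl[ok, b]) == 0)
      stop("constant acceleration column: ", a, " or ", b)
    ct <- stats::cor.test(tbl[ok, a], tbl[ok, b], method = "pearson")
    data.frame(organ_a = a, organ_b = b, n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value,
               stars = stars(ct$p.value), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' Bundles the simulation, filtering, clock and testing settings of a
#' full run. The pipeline is simulation-driven: a blood-like training
#' cohort and a multi-organ application cohort are generated with known
#' ground truth (real matrices can be substituted by calling the stage
#' functions directly).
#'
#' @param training_config [simulation_config()] for the training cohort.
#' @param application_config [simulation_config()] for the multi-organ
#'   cohort (its seed is offset internally so the two cohorts are
#'   independent).
#' @param design a [multiorgan_design()].
#' @param records gene records; default [make_gene_records()] grid sized
#'   to `n_genes`.
#' @param n_genes genes in the default annotation.
#' @param clock a [clock_config()].
#' @param min_depth,min_sample_fraction coverage rules.
#' @param upstream,downstream promoter window.
#' @param alpha significance level for common-gene detection.
#' @param run_intersection,run_rdna include the intersection and rDNA
#'   clocks (both TRUE by default).
#' @param n_rdna_sites sites of the simulated rDNA-like high-coverage
#'   feature table.
#' @param out_dir optional directory for TSV outputs.
#' @param seed master seed echoed into the report.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(training_config = simulation_config(),
                            application_config =
                              simulation_config(age_range = c(23, 24),
                                                seed = 2L),
                            design = multiorgan_design(),
                            records = NULL, n_genes = 50L,
                            clock = clock_config(),
                            min_depth = 5L, min_sample_fraction = 0.9,
                            upstream = 1500L, downstream = 500L,
                            alpha = 0.05, run_intersection = TRUE,
                            run_rdna = TRUE, n_rdna_sites = 200L,
                            out_dir = NULL, seed = 1L) {
  if (is.null(records)) records <- make_gene_records(n_genes)
  structure(list(training_config = training_config,
                 application_config = application_config, design = design,
                 records = records, clock = clock, min_depth = min_depth,
                 min_sample_fraction = min_sample_fraction,
                 upstream = upstream, downstream = downstream, alpha = alpha,
                 run_intersection = run_intersection, run_rdna = run_rdna,
                 n_rdna_sites = n_rdna_sites, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full multi-organ epigenetic-aging pipeline
#'
#' Simulate (training and multi-organ cohorts) -> mask low coverage ->
#' filter sites by coverage -> train the all-site and common-site
#' elastic-net clocks -> predict ages and residual age acceleration for
#' every clock (including the per-sample intersection clock and the
#' rDNA-style high-coverage clock) -> global mean methylation and
#' methylation entropy with LCR/HCR group comparisons per organ ->
#' per-organ promoter differential methylation, best hits, and
#' cross-organ common genes -> paired multi-organ comparisons and
#' cross-organ acceleration correlations. Reruns with the same
#' configuration are identical.
#'
#' @param config a [pipeline_config()].
#' @return a report list; see the elements written by the function. TSVs
#'   are additionally written when `config$out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = config, seed = config$seed)

  training <- stage("simulate_training",
                    simulate_training_cohort(config$training_config))
  cohort <- stage("simulate_multiorgan",
                  simulate_multiorgan_cohort(config$application_config,
                                             config$design, config$records,
                                             config$upstream,
                                             config$downstream,
                                             template = training))
  report$truth <- cohort$truth

  train_masked <- stage("mask", mask_low_coverage(training$meth,
                                                  training$cov,
                                                  config$min_depth))
  train_filtered <- stage("filter",
                          filter_by_coverage(train_masked, training$cov,
                                             config$min_depth,
                                             config$min_sample_fraction))
  app_masked <- stage("mask", mask_low_coverage(cohort$meth, cohort$cov,
                                                config$min_depth))
  app_filtered <- stage("filter",
                        filter_by_coverage(app_masked, cohort$cov,
                                           config$min_depth,
                                           config$min_sample_fraction))

  train_ages <- training$samples$age_months
  app <- cohort$samples
  clock1 <- stage("train_clock1",
                  train_elastic_net_clock(train_filtered, train_ages,
                                          config$clock))
  predictions <- list()
  predictions$clock1 <- predict_ages(app_masked, clock1)
  accel <- list()
  accel$clock1 <- age_acceleration(predictions$clock1, app$age_months,
                                   clock1$reference_regression)

  common <- intersect_common_sites(train_filtered, app_filtered)
  report$n_common_sites <- length(common)
  if (length(common) >= 2L) {
    clock2 <- stage("train_clock2",
                    train_elastic_net_clock(
                      train_filtered[, common, drop = FALSE], train_ages,
                      config$clock))
    predictions$clock2 <- predict_ages(app_masked, clock2)
    accel$clock2 <- age_acceleration(predictions$clock2, app$age_months,
                                     clock2$reference_regression)
    report$clock2 <- clock2
  }
  report$clock1 <- clock1

  if (config$run_intersection) {
    ip <- stage("intersection",
                intersection_predict_cohort(train_filtered, train_ages,
                                            app_masked,
                                            seed = config$clock$seed))
    predictions$intersection <- stats::setNames(ip$mean_pred, ip$sample_id)
    ref <- clock1$reference_regression
    accel$intersection <- age_acceleration(predictions$intersection,
                                           app$age_months, ref)
    report$intersection <- ip
  }

  if (config$run_rdna) {
    rdna <- stage("rdna_simulate",
                  simulate_rdna_tables(train_ages, app$age_months,
                                       n_sites = config$n_rdna_sites,
                                       seed = config$seed))
    rd <- stage("rdna", rdna_clock(rdna$train, train_ages, rdna$app,
                                   seed = config$clock$seed))
    predictions$rdna <- stats::setNames(rd$app_predictions, app$sample_id)
    accel$rdna <- age_acceleration(predictions$rdna, app$age_months,
                                   rd$reference_regression)
    report$rdna_grid <- rd$grid
    report$rdna_best <- rd$best
  }
  report$predictions <- predictions
  report$acceleration <- accel

  gs <- stage("global_stats", global_stats_table(app_masked, app))
  report$global_stats <- gs
  report$group_comparisons <- do.call(rbind, lapply(
    unique(app$organ), function(org) {
      sub <- gs[gs$organ == org, ]
      do.call(rbind, lapply(c("gmm", "mme"), function(metric) {
        gc <- group_compare(sub[[metric]], sub$group,
                            paste(org, metric, sep = "_"))
        data.frame(organ = org, metric = metric, statistic = gc$statistic,
                   p = gc$p, direction = gc$direction, stars = gc$stars,
                   stringsAsFactors = FALSE)
      }))
    }))

  prom_results <- list()
  for (org in config$design$organs) {
    idx <- app$organ == org
    prom <- promoter_methylation(app_filtered[idx, , drop = FALSE],
                                 config$records, config$upstream,
                                 config$downstream)
    prom_results[[org]] <- test_promoters(prom, app$group[idx],
                                          levels = config$design$groups,
                                          organ = org)
  }
  report$promoter_results <- prom_results
  report$best_hits <- lapply(prom_results, best_hits)
  report$common_genes <- common_significant_genes(prom_results,
                                                  config$alpha)

  ind <- unique(app$individual)
  metric_tables <- list()
  for (nm in names(predictions)) {
    tb <- matrix(NA_real_, length(ind), length(config$design$organs),
                 dimnames = list(ind, config$design$organs))
    ta <- tb
    for (i in seq_len(nrow(app))) {
      tb[app$individual[i], app$organ[i]] <- predictions[[nm]][i]
      ta[app$individual[i], app$organ[i]] <- accel[[nm]]$acceleration[i]
    }
    metric_tables[[paste0("age_", nm)]] <- tb
    metric_tables[[paste0("accel_", nm)]] <- ta
  }
  for (metric in c("gmm", "mme")) {
    tb <- matrix(NA_real_, length(ind), length(config$design$organs),
                 dimnames = list(ind, config$design$organs))
    for (i in seq_len(nrow(gs)))
      tb[gs$individual[i], gs$organ[i]] <- gs[[metric]][i]
    metric_tables[[metric]] <- tb
  }
  report$paired_comparisons <- do.call(rbind, lapply(
    names(metric_tables), function(nm)
      paired_organ_compare(metric_tables[[nm]], nm)))
  report$cross_organ_correlations <- lapply(
    names(predictions), function(nm)
      acceleration_cross_correlation(metric_tables[[paste0("accel_", nm)]]))
  names(report$cross_organ_correlations) <- names(predictions)

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Refit route for the rDNA-style clock: grid-select the best
# (imputation, model family) combination, refit it, and carry a test-set
# reference regression for age acceleration.
rdna_clock <- function(train_table, train_ages, app_table, seed = 1L) {
  grid <- run_model_grid(train_table, train_ages, seed = seed)
  best <- select_best(grid)
  split <- split_train_test(rownames(train_table), 0.8, seed)
  spec <- imputation_spec(best$imputation)
  tr_raw <- train_table[split$train, , drop = FALSE]
  keep <- colSums(!is.na(tr_raw)) > 0
  tr_raw <- tr_raw[, keep, drop = FALSE]
  tr_x <- impute_methylation(tr_raw, spec)
  te_x <- impute_test_rows(tr_raw, tr_x,
                           train_table[split$test, keep, drop = FALSE], spec)
  ages <- stats::setNames(train_ages, rownames(train_table))
  pred_test <- fit_predict_family(best$model, tr_x, ages[split$train],
                                  te_x, seed)
  ref <- stats::coef(stats::lm(pred_test ~ ages[split$test]))
  # application profiles: mean of all methylation percentages for missing
  app <- app_table[, intersect(colnames(app_table), colnames(tr_x)),
                   drop = FALSE]
  missing_cols <- setdiff(colnames(tr_x), colnames(app))
  if (length(missing_cols)) {
    pad <- matrix(NA_real_, nrow(app), length(missing_cols),
                  dimnames = list(rownames(app), missing_cols))
    app <- cbind(app, pad)[, colnames(tr_x), drop = FALSE]
  }
  app_x <- impute_test_rows(tr_raw, tr_x, app, spec)
  app_pred <- fit_predict_family(best$model, tr_x, ages[split$train],
                                 app_x, seed)
  list(grid = grid, best = best,
       test_evaluation = evaluate_clock(pred_test, ages[split$test]),
       reference_regression = list(intercept = unname(ref[1L]),
                                   slope = unname(ref[2L])),
       app_predictions = app_pred)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name)
    utils::write.table(x, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  pred <- data.frame(sample_id = names(report$predictions[[1L]]))
  for (nm in names(report$predictions)) {
    pred[[paste0("predicted_", nm)]] <- unname(report$predictions[[nm]])
    pred[[paste0("accel_", nm)]] <- report$acceleration[[nm]]$acceleration
  }
  w(pred, "predictions")
  w(report$global_stats, "global_stats")
  w(report$group_comparisons, "group_comparisons")
  for (org in names(report$promoter_results))
    w(report$promoter_results[[org]], paste0("promoters_", org))
  w(report$common_genes, "common_genes")
  w(report$paired_comparisons, "paired_comparisons")
  w(do.call(rbind, report$cross_organ_correlations),
    "cross_organ_correlations")
  writeLines(paste0("seed\t", report$seed), file.path(dir, "run_info.tsv"))
  invisible(dir)
}
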