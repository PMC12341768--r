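#' Per-sample intersection-clock prediction
#'
#' For one test sample: (1) the common sites are the training matrix's
#' sites intersected with the sites covered (non-missing) in the test
#' profile; (2) training data and profile are restricted to them; (3) the
#' training samples are partitioned into `n_folds` seed-deterministic
#' folds; (4) one elastic-net model is fitted per fold on the other
#' folds (penalty chosen by nested cross-validation inside that fold's
#' training portion); (5) each model predicts the test profile; (6) the
#' arithmetic mean of the fold predictions (MeanPred) is the sample's
#' predicted age.
#'
#' @param train_meth training samples x sites methylation matrix.
#' @param train_ages training ages in months.
#' @param test_profile named numeric vector of methylation fractions
#'   (`NA` = not covered).
#' @param n_folds number of folds (default 5).
#' @param mixing elastic-net mixing parameter.
#' @param cv_folds folds of the nested penalty-selection CV.
#' @param lambda_rule penalty rule as in [clock_config()].
#' @param seed seed fixing the fold partition (shared across samples of a
#'   cohort) and the nested CV.
#' @param sample_id label for the result.
#' @param folds optional precomputed fold assignment.
#' @return object of class `"intersection_prediction"`: `sample_id`,
#'   `n_common_sites`, `fold_predictions` (length `n_folds`), and
#'   `mean_pred` = their arithmetic mean.
#' @export
intersection_predict <- function(train_meth, train_ages, test_profile,
                                 n_folds = 5L, mixing = 0.5, cv_folds = 10L,
                                 lambda_rule = "lambda.min", seed = 1L,
                                 sample_id = "sample", folds = NULL) {
  stopifnot(nrow(train_meth) == length(train_ages))
  if (nrow(train_meth) < n_folds)
    stop("need at least ", n_folds, " training samples")
  covered <- names(test_profile)[!is.na(test_profile)]
  usable <- colnames(train_meth)[colSums(!is.na(train_meth)) > 0]
  common <- sort_site_keys(intersect(usable, covered))
  if (!length(common)) stop("zero common sites for sample ", sample_id)
  if (is.null(folds)) folds <- make_folds(nrow(train_meth), n_folds, seed)
  models <- fit_fold_models(train_meth, train_ages, common, folds,
                            mixing, cv_folds, lambda_rule, seed)
  preds <- vapply(models, predict_fold_model, numeric(1), test_profile)
  structure(list(sample_id = sample_id, n_common_sites = length(common),
                 fold_predictions = preds, mean_pred = mean(preds)),
            class = "intersection_prediction")
}

fit_fold_models <- function(train_meth, train_ages, common, folds,
                            mixing, cv_folds, lambda_rule, seed) {
  lapply(sort(unique(folds)), function(f) {
    x <- fill_column_means(train_meth[folds != f, common, drop = FALSE])
    fit <- fit_elastic_net(x, train_ages[folds != f], mixing,
                           min(cv_folds, nrow(x)), lambda_rule,
                           standardize = TRUE, seed = seed + f)
    fit[c("intercept", "weights", "site_keys")]
  })
}

predict_fold_model <- function(model, profile) {
  if (!length(model$site_keys)) return(model$intercept)
  model$intercept + sum(model$weights * profile[model$site_keys])
}

#' @export
print.intersection_prediction <- function(x, ...) {
  cat("Intersection-clock prediction for ", x$sample_id, ": ",
      round(x$mean_pred, 2), " months (MeanPred of ",
      length(x$fold_predictions), " fold models over ", x$n_common_sites,
      " common sites)\n", sep = "")
  invisible(x)
}

#' Intersection-clock predictions for a cohort
#'
#' Applies [intersection_predict()] to every sample of a cohort matrix
#' with a fold partition fixed once (same seed for every sample), so a
#' 64-sample cohort entails `5 x 64` fold models. Samples sharing an
#' identical common-site set reuse the same fitted fold models via a
#' cache; cached and uncached runs give identical predictions.
#'
#' @param train_meth,train_ages training data as in
#'   [intersection_predict()].
#' @param cohort_meth application samples x sites matrix (`NA` = not
#'   covered).
#' @inheritParams intersection_predict
#' @param cache reuse fold models across samples with identical
#'   common-site sets (default TRUE).
#' @return data.frame with one row per cohort sample: `sample_id`,
#'   `n_common_sites`, `fold1..foldK`, `mean_pred`. Attributes
#'   `models_fitted` (`n_folds * n_samples`) and `unique_fits` (distinct
#'   models actually trained) record the work done. Samples with zero
#'   common sites are reported with `NA` predictions and listed in the
#'   `failed_samples` attribute rather than dropped.
#' @export
intersection_predict_cohort <- function(train_meth, train_ages, cohort_meth,
                                        n_folds = 5L, mixing = 0.5,
                                        cv_folds = 10L,
                                        lambda_rule = "lambda.min",
                                        seed = 1L, cache = TRUE) {
  stopifnot(nrow(train_meth) == length(train_ages))
  folds <- make_folds(nrow(train_meth), n_folds, seed)
  usable <- colnames(train_meth)[colSums(!is.na(train_meth)) > 0]
  cache_keys <- character(0)
  cache_models <- list()
  ids <- rownames(cohort_meth)
  failed <- character(0)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    profile <- cohort_meth[i, ]
    common <- sort_site_keys(intersect(usable, names(profile)[!is.na(profile)]))
    if (!length(common)) {
      failed <- c(failed, ids[i])
      rows[[i]] <- c(n_common_sites = 0, rep(NA_real_, n_folds),
                     mean_pred = NA_real_)
      next
    }
    key <- paste(common, collapse = "\r")
    hit <- if (cache) match(key, cache_keys) else NA_integer_
    if (!is.na(hit)) {
      models <- cache_models[[hit]]
    } else {
      models <- fit_fold_models(train_meth, train_ages, common, folds,
                                mixing, cv_folds, lambda_rule, seed)
      if (cache) {
        cache_keys <- c(cache_keys, key)
        cache_models[[length(cache_keys)]] <- models
      }
    }
    preds <- vapply(models, predict_fold_model, numeric(1), profile)
    rows[[i]] <- c(n_common_sites = length(common), preds,
                   mean_pred = mean(preds))
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("n_common_sites", paste0("fold", seq_len(n_folds)),
                  "mean_pred")
  out <- cbind(sample_id = ids, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (length(failed))
    warning("samples with zero common sites: ", paste(failed, collapse = ", "))
  attr(out, "models_fitted") <- n_folds * (length(ids) - length(failed))
  attr(out, "unique_fits") <- n_folds * length(cache_keys)
  attr(out, "failed_samples") <- failed
  out
}
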