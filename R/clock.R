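#' Clock training configuration
#'
#' Settings for elastic-net epigenetic clock training: the elastic-net
#' mixing parameter (0 = ridge, 1 = lasso; 0.5 by default), the penalty
#' selection rule applied to the internal cross-validation path
#' (`"lambda.min"`, `"lambda.1se"`, or a fixed numeric penalty), the
#' number of CV folds for penalty selection, the train fraction of the
#' holdout split, and whether features are standardized internally during
#' fitting (coefficients are always returned on the original
#' months-per-fraction scale).
#'
#' @param mixing elastic-net mixing parameter in `[0,1]`.
#' @param lambda_rule `"lambda.min"`, `"lambda.1se"`, or a numeric lambda.
#' @param cv_folds folds for internal penalty-selection CV.
#' @param train_fraction fraction of samples used for training.
#' @param standardize standardize features during fitting.
#' @param seed integer seed controlling the split and CV fold assignment.
#' @return list of class `"clock_config"`.
#' @export
clock_config <- function(mixing = 0.5, lambda_rule = "lambda.min",
                         cv_folds = 10L, train_fraction = 0.8,
                         standardize = TRUE, seed = 1L) {
  stopifnot(mixing >= 0, mixing <= 1,
            train_fraction > 0, train_fraction < 1, cv_folds >= 3)
  structure(list(mixing = mixing, lambda_rule = lambda_rule,
                 cv_folds = as.integer(cv_folds),
                 train_fraction = train_fraction,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "clock_config")
}

#' Split sample ids into train and test sets
#'
#' The test set size is `round((1 - train_fraction) * n)` (so 134 samples
#' at 0.8 split into 107 train / 27 test) and membership is a
#' seed-deterministic random draw. Train and test are disjoint and
#' exhaustive.
#'
#' @param sample_ids character vector of ids (n >= 2).
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_train_test <- function(sample_ids, train_fraction = 0.8, seed = 1L) {
  n <- length(sample_ids)
  if (n < 2L) stop("need at least two samples to split")
  n_test <- round((1 - train_fraction) * n)
  if (n_test < 1L || n_test >= n)
    stop("split leaves an empty train or test set")
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  list(train = sample_ids[-test_idx], test = sample_ids[test_idx])
}

# Deterministic partition into k near-equal folds.
make_folds <- function(n, k, seed = 1L) {
  stopifnot(n >= k, k >= 2)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

# Fill missing entries of a matrix with per-column means over observed
# entries; columns with no observed value are dropped.
fill_column_means <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  keep <- is.finite(mu)
  x <- x[, keep, drop = FALSE]
  mu <- mu[keep]
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2L]]
  x
}

# cv.glmnet wrapper tolerating a single-feature matrix (glmnet needs two
# columns; a zero pseudo-column is added and excluded from the model).
fit_elastic_net <- function(x, y, mixing, cv_folds, lambda_rule, standardize,
                            seed) {
  padded <- FALSE
  if (ncol(x) == 1L) {
    x <- cbind(x, `..pad..` = 0)
    padded <- TRUE
  }
  set.seed(seed)
  if (is.numeric(lambda_rule)) {
    # fixed penalty: fit a short descending path ending at the target
    s <- lambda_rule
    fit0 <- glmnet::glmnet(x, y, alpha = mixing, standardize = standardize,
                           lambda = c(s * 1000, s * 10, s))
    beta <- as.matrix(stats::coef(fit0, s = s))
  } else {
    cvfit <- glmnet::cv.glmnet(x, y, alpha = mixing,
                               nfolds = min(cv_folds, length(y)),
                               standardize = standardize)
    s <- cvfit[[lambda_rule]]
    beta <- as.matrix(stats::coef(cvfit, s = s))
  }
  w <- beta[-1L, 1L]
  if (padded) w <- w[names(w) != "..pad.."]
  nz <- which(w != 0)
  list(intercept = beta[1L, 1L], weights = w[nz],
       site_keys = names(w)[nz], lambda = s)
}

#' Train an elastic-net epigenetic clock
#'
#' Fits `age ~ methylation` with an elastic-net penalty at the configured
#' mixing parameter. Missing values are first filled with per-site mean
#' methylation over the whole matrix; the samples are then split into
#' train/test by [split_train_test()], the penalty strength is chosen by
#' internal cross-validation on the training set, and the
#' predicted-versus-chronological reference regression used for age
#' acceleration is fitted on the held-out test set.
#'
#' @param meth samples x sites methylation matrix (fractions, `NA` allowed).
#' @param ages chronological ages in months, one per sample.
#' @param config a [clock_config()].
#' @return object of class `"clock_model"`: `site_keys` and `weights`
#'   (nonzero-weight sites only, months per methylation fraction),
#'   `intercept` (months), `site_means` (per-site means used for
#'   imputation), `reference_regression` (`slope`, `intercept` of the
#'   test-set predicted~chronological fit), `evaluation`
#'   (a [evaluate_clock()] result on the test set), `train_ids`,
#'   `test_ids`, `lambda`, and `config`.
#' @export
train_elastic_net_clock <- function(meth, ages, config = clock_config()) {
  stopifnot(inherits(config, "clock_config"), nrow(meth) == length(ages))
  if (stats::sd(ages) == 0) stop("ages are constant; cannot train a clock")
  x <- fill_column_means(meth)
  split <- split_train_test(rownames(x), config$train_fraction, config$seed)
  if (length(split$train) < config$cv_folds)
    stop("fewer training samples than cv_folds")
  ages <- stats::setNames(ages, rownames(x))
  fit <- fit_elastic_net(x[split$train, , drop = FALSE], ages[split$train],
                         config$mixing, config$cv_folds, config$lambda_rule,
                         config$standardize, config$seed)
  site_means <- colMeans(meth[, fit$site_keys, drop = FALSE], na.rm = TRUE)
  if (length(fit$site_keys)) {
    pred_test <- as.vector(fit$intercept +
      x[split$test, fit$site_keys, drop = FALSE] %*% fit$weights)
  } else {
    pred_test <- rep(fit$intercept, length(split$test))
  }
  names(pred_test) <- split$test
  ref <- stats::coef(stats::lm(pred_test ~ ages[split$test]))
  model <- structure(list(
    site_keys = fit$site_keys,
    weights = stats::setNames(fit$weights, fit$site_keys),
    intercept = fit$intercept,
    site_means = site_means,
    reference_regression = list(intercept = unname(ref[1L]),
                                slope = unname(ref[2L])),
    train_ids = split$train, test_ids = split$test,
    lambda = fit$lambda, config = config), class = "clock_model")
  model$evaluation <- evaluate_clock(pred_test, ages[split$test])
  model
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Elastic-net epigenetic clock: ", length(x$site_keys),
      " CpG sites, intercept ", round(x$intercept, 2), " months\n", sep = "")
  if (!is.null(x$evaluation))
    cat("  held-out test (n=", x$evaluation$n, "): MAE ",
        round(x$evaluation$mae, 2), " months, r ",
        round(x$evaluation$pearson_r, 3), "\n", sep = "")
  invisible(x)
}

#' Impute a cohort's clock-site profiles
#'
#' Completes a cohort matrix over a clock's CpG sites with the two-stage
#' rule used when applying blood-trained clocks to sparse RRBS data:
#' a missing value is filled with the cohort mean of that clock site over
#' the samples where it is covered; a clock site covered in no sample (or
#' absent from the matrix) is filled, per sample, with the mean of that
#' sample's covered clock-site values. Present values are never altered.
#'
#' @param meth samples x sites matrix, or a single named profile vector.
#' @param model a `"clock_model"`.
#' @return complete samples x `model$site_keys` matrix.
#' @export
impute_clock_sites <- function(meth, model) {
  if (is.null(dim(meth))) meth <- matrix(meth, 1L,
    dimnames = list("sample", names(meth)))
  out <- matrix(NA_real_, nrow(meth), length(model$site_keys),
                dimnames = list(rownames(meth), model$site_keys))
  present <- intersect(model$site_keys, colnames(meth))
  out[, present] <- meth[, present, drop = FALSE]
  covered_any <- colSums(!is.na(out)) > 0
  if (!any(covered_any)) stop("no covered clock sites at all")
  mu <- colMeans(out[, covered_any, drop = FALSE], na.rm = TRUE)
  idx <- which(is.na(out[, covered_any, drop = FALSE]), arr.ind = TRUE)
  if (nrow(idx)) {
    sub <- out[, covered_any, drop = FALSE]
    sub[idx] <- mu[idx[, 2L]]
    out[, covered_any] <- sub
  }
  if (any(!covered_any)) {
    row_mu <- rowMeans(meth[, present, drop = FALSE], na.rm = TRUE)
    bad <- !is.finite(row_mu)
    if (any(bad))
      stop("sample(s) with no covered clock sites: ",
           paste(rownames(meth)[bad], collapse = ", "))
    out[, !covered_any] <- row_mu
  }
  out
}

#' Predict epigenetic ages with a clock
#'
#' The prediction is affine in the methylation profile:
#' `intercept + sum(weight * m)` over the clock's sites, after
#' [impute_clock_sites()] completion (unless `impute = FALSE`, in which
#' case the matrix must already be complete over the clock sites).
#'
#' @param meth samples x sites matrix or single named profile.
#' @param model a `"clock_model"`.
#' @param impute complete profiles first (default TRUE).
#' @return named numeric vector of predicted ages in months.
#' @export
predict_ages <- function(meth, model, impute = TRUE) {
  x <- if (impute) impute_clock_sites(meth, model)
       else meth[, model$site_keys, drop = FALSE]
  if (anyNA(x)) stop("profiles contain missing clock sites")
  if (length(model$site_keys) == 0L)
    return(stats::setNames(rep(model$intercept, nrow(x)), rownames(x)))
  stats::setNames(
    as.vector(model$intercept +
                x[, model$site_keys, drop = FALSE] %*% model$weights),
    rownames(x))
}

#' Evaluate clock predictions against chronological age
#'
#' @param predicted predicted ages (months).
#' @param chronological chronological ages (months), same length >= 2.
#' @return list of class `"clock_evaluation"`: `mae` (mean absolute
#'   error), `medae` (median absolute error), `pearson_r`, two-sided
#'   `p_value`, `n`, and the `predictions`.
#' @export
evaluate_clock <- function(predicted, chronological) {
  stopifnot(length(predicted) == length(chronological),
            length(predicted) >= 2L)
  if (stats::sd(predicted) == 0 || stats::sd(chronological) == 0)
    stop("constant vector: Pearson correlation undefined")
  err <- abs(predicted - chronological)
  ct <- stats::cor.test(predicted, chronological, method = "pearson")
  structure(list(mae = mean(err), medae = stats::median(err),
                 pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(predicted), predictions = predicted),
            class = "clock_evaluation")
}

#' @export
print.clock_evaluation <- function(x, ...) {
  cat("Clock evaluation (n=", x$n, "): MAE ", round(x$mae, 3),
      " months, MedAE ", round(x$medae, 3), " months, r ",
      round(x$pearson_r, 3), " (p = ", format(x$p_value, digits = 3),
      ")\n", sep = "")
  invisible(x)
}

#' Residual-based epigenetic age acceleration
#'
#' Age acceleration is the predicted age minus the value of the reference
#' regression line (predicted versus chronological, fitted on the clock's
#' held-out test set) at the sample's chronological age. Over the set the
#' regression was fitted on, accelerations sum to zero by the
#' least-squares property.
#'
#' @param predicted predicted ages (months), optionally named.
#' @param chronological chronological ages (months).
#' @param reference a list with `slope` and `intercept`, e.g.
#'   `model$reference_regression`.
#' @return data.frame with `sample_id`, `predicted`, `expected`,
#'   `acceleration` (months; `predicted - expected` exactly).
#' @export
age_acceleration <- function(predicted, chronological, reference) {
  if (is.null(reference) || is.null(reference$slope))
    stop("missing reference regression")
  expected <- reference$slope * chronological + reference$intercept
  data.frame(
    sample_id = if (!is.null(names(predicted))) names(predicted)
                else seq_along(predicted),
    predicted = unname(predicted), expected = expected,
    acceleration = unname(predicted) - expected,
    stringsAsFactors = FALSE)
}
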