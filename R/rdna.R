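#' Build an rDNA methylation feature table from coverage files
#'
#' Merges per-sample Bismark coverage calls restricted to a single rDNA
#' reference sequence into a samples x positions table of methylation
#' percentages (0-100), with absent cells missing. The multi-copy nature
#' of rDNA gives these CpGs high coverage, which is what makes an
#' rDNA-restricted clock applicable to sparse external RRBS data.
#'
#' @param tables named list of per-sample data.frames as returned by
#'   [read_bismark_cov()], or a character vector of file paths (names used
#'   as sample ids, else file base names).
#' @param reference name of the rDNA reference sequence the rows must lie
#'   on (e.g. `"NR_046239.1"`).
#' @return numeric matrix samples x positions (column names are
#'   `"<reference>:<pos>"` keys), percent scale, `NA` = missing.
#' @export
build_rdna_table <- function(tables, reference) {
  if (is.character(tables)) {
    paths <- tables
    ids <- if (!is.null(names(paths))) names(paths)
           else sub("\\.cov$", "", basename(paths))
    tables <- stats::setNames(lapply(paths, read_bismark_cov), ids)
  }
  tables <- lapply(tables, function(t) t[t$chrom == reference, , drop = FALSE])
  if (!any(vapply(tables, nrow, integer(1)) > 0))
    stop("no rows on reference ", reference)
  positions <- sort(unique(unlist(lapply(tables, `[[`, "pos"))))
  out <- matrix(NA_real_, length(tables), length(positions),
                dimnames = list(names(tables),
                                make_site_keys(reference, positions)))
  for (id in names(tables)) {
    t <- tables[[id]]
    out[id, match(t$pos, positions)] <- 100 * t$fraction
  }
  out
}

#' Restrict two feature tables to their common positions
#'
#' @param a,b feature tables (samples x positions) with shared column-key
#'   conventions.
#' @return list with `a` and `b` restricted to the intersection of
#'   positions, same column order in both.
#' @export
restrict_to_common_features <- function(a, b) {
  stopifnot(ncol(a) > 0, ncol(b) > 0)
  common <- sort_site_keys(intersect(colnames(a), colnames(b)))
  if (!length(common)) stop("no common features between tables")
  list(a = a[, common, drop = FALSE], b = b[, common, drop = FALSE])
}

#' Imputation specification
#'
#' @param method one of `"mean"`, `"knn"`, `"soft_impute"`, `"pca"`.
#' @param k neighbours for KNN (>= 1).
#' @param rank number of components for SoftImpute/PCA; default
#'   `min(10, n_samples - 1)` resolved at imputation time.
#' @param lambda singular-value soft threshold for SoftImpute (>= 0).
#' @param tol relative convergence tolerance for the iterative methods.
#' @param max_iter iteration cap.
#' @return list of class `"imputation_spec"`.
#' @export
imputation_spec <- function(method = c("mean", "knn", "soft_impute", "pca"),
                            k = 5L, rank = NULL, lambda = 0, tol = 1e-4,
                            max_iter = 200L) {
  method <- match.arg(method)
  stopifnot(k >= 1, is.null(rank) || rank >= 1, tol > 0, lambda >= 0)
  structure(list(method = method, k = as.integer(k), rank = rank,
                 lambda = lambda, tol = tol, max_iter = as.integer(max_iter)),
            class = "imputation_spec")
}

#' Impute missing values in a feature table
#'
#' All four methods leave observed entries bit-identical and clip imputed
#' values to `bounds`. `mean` fills per-column means; `knn` fills each
#' missing cell with the mean of the `k` nearest samples (Euclidean
#' distance over mutually observed features, scaled by feature count) that
#' observe the cell, falling back to the column mean when no neighbour is
#' eligible; `soft_impute` runs iterative SVD with soft-thresholded
#' singular values until the relative change drops below `tol`; `pca`
#' runs iterative column-centred low-rank reconstruction.
#'
#' @param x samples x features numeric matrix with `NA` missing.
#' @param spec an [imputation_spec()].
#' @param bounds clipping interval for imputed values (default percent
#'   scale `c(0, 100)`).
#' @return completed matrix. For the iterative methods the per-iteration
#'   objective (observed squared-error plus nuclear-norm penalty) is
#'   attached as attribute `"objective"`.
#' @export
impute_methylation <- function(x, spec = imputation_spec("mean"),
                               bounds = c(0, 100)) {
  stopifnot(inherits(spec, "imputation_spec"))
  if (all(is.na(x))) stop("matrix is all-missing")
  if (!anyNA(x)) return(x)
  out <- switch(spec$method,
    mean = impute_mean(x),
    knn = impute_knn(x, spec$k),
    soft_impute = impute_svd(x, spec, center = FALSE),
    pca = impute_svd(x, spec, center = TRUE))
  miss <- is.na(x)
  out[miss] <- pmin(pmax(out[miss], bounds[1]), bounds[2])
  out[!miss] <- x[!miss]
  out
}

impute_mean <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  if (any(!is.finite(mu)))
    stop("column(s) with no observed value; mean imputation undefined")
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2L]]
  x
}

impute_knn <- function(x, k) {
  n <- nrow(x)
  obs <- !is.na(x)
  mu <- colMeans(x, na.rm = TRUE)
  # pairwise distances over mutually observed features, scaled by count
  d <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    both <- obs[i, ] & obs[j, ]
    if (any(both))
      d[i, j] <- d[j, i] <- sqrt(mean((x[i, both] - x[j, both])^2))
  }
  fallbacks <- 0L
  for (i in seq_len(n)) {
    for (cc in which(!obs[i, ])) {
      cand <- which(obs[, cc] & is.finite(d[i, ]))
      cand <- setdiff(cand, i)
      if (length(cand)) {
        nb <- cand[order(d[i, cand])][seq_len(min(k, length(cand)))]
        x[i, cc] <- mean(x[nb, cc])
      } else {
        x[i, cc] <- mu[cc]
        fallbacks <- fallbacks + 1L
      }
    }
  }
  if (fallbacks > 0L)
    message("impute_knn: ", fallbacks,
            " cell(s) fell back to the column mean (no eligible neighbour)")
  x
}

impute_svd <- function(x, spec, center) {
  obs <- !is.na(x)
  rank <- if (is.null(spec$rank)) min(10L, nrow(x) - 1L) else spec$rank
  rank <- max(1L, min(rank, nrow(x), ncol(x)))
  mu <- colMeans(x, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  z <- x
  idx <- which(!obs, arr.ind = TRUE)
  if (nrow(idx)) z[idx] <- mu[idx[, 2L]]
  objective <- numeric(0)
  for (it in seq_len(spec$max_iter)) {
    cmu <- if (center) colMeans(z) else numeric(ncol(z))
    s <- svd(sweep(z, 2L, cmu))
    d <- pmax(s$d - spec$lambda, 0)
    r <- min(rank, sum(d > 0))
    recon <- if (r > 0)
      s$u[, seq_len(r), drop = FALSE] %*%
        (d[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
    else matrix(0, nrow(z), ncol(z))
    recon <- sweep(recon, 2L, cmu, `+`)
    objective <- c(objective,
                   0.5 * sum((x[obs] - recon[obs])^2) +
                     spec$lambda * sum(d[seq_len(r)]))
    znew <- x
    znew[!obs] <- recon[!obs]
    delta <- sqrt(sum((znew - z)^2)) / max(sqrt(sum(z^2)), 1e-12)
    z <- znew
    if (delta < spec$tol) break
  }
  attr(z, "objective") <- objective
  z
}

# Impute test rows using training-side statistics only (no leakage):
# mean -> train column means; knn -> neighbours among training rows;
# soft_impute/pca -> least-squares projection of the observed part onto
# the rank-r right-singular basis of the completed training table.
impute_test_rows <- function(train_raw, train_complete, test_raw, spec,
                             bounds = c(0, 100)) {
  mu <- colMeans(train_raw, na.rm = TRUE)
  mu[!is.finite(mu)] <- mean(train_raw, na.rm = TRUE)
  out <- test_raw
  if (spec$method == "mean") {
    idx <- which(is.na(out), arr.ind = TRUE)
    if (nrow(idx)) out[idx] <- mu[idx[, 2L]]
  } else if (spec$method == "knn") {
    obs_tr <- !is.na(train_raw)
    for (i in seq_len(nrow(out))) {
      oi <- !is.na(test_raw[i, ])
      d <- rep(Inf, nrow(train_raw))
      for (j in seq_len(nrow(train_raw))) {
        both <- oi & obs_tr[j, ]
        if (any(both))
          d[j] <- sqrt(mean((test_raw[i, both] - train_raw[j, both])^2))
      }
      for (cc in which(!oi)) {
        cand <- which(obs_tr[, cc] & is.finite(d))
        if (length(cand)) {
          nb <- cand[order(d[cand])][seq_len(min(spec$k, length(cand)))]
          out[i, cc] <- mean(train_raw[nb, cc])
        } else out[i, cc] <- mu[cc]
      }
    }
  } else {
    rank <- if (is.null(spec$rank)) min(10L, nrow(train_raw) - 1L) else spec$rank
    rank <- max(1L, min(rank, nrow(train_complete) - 1L, ncol(train_complete)))
    center <- spec$method == "pca"
    cmu <- if (center) colMeans(train_complete) else numeric(ncol(train_complete))
    s <- svd(sweep(train_complete, 2L, cmu))
    v <- s$v[, seq_len(rank), drop = FALSE]
    for (i in seq_len(nrow(out))) {
      oi <- which(!is.na(test_raw[i, ]))
      mi <- which(is.na(test_raw[i, ]))
      if (!length(mi)) next
      if (length(oi) >= rank) {
        cf <- stats::lm.fit(v[oi, , drop = FALSE],
                            test_raw[i, oi] - cmu[oi])$coefficients
        cf[is.na(cf)] <- 0
        out[i, mi] <- cmu[mi] + as.vector(v[mi, , drop = FALSE] %*% cf)
      } else out[i, mi] <- mu[mi]
    }
  }
  miss <- is.na(test_raw)
  out[miss] <- pmin(pmax(out[miss], bounds[1]), bounds[2])
  out
}

#' Evaluate an imputation-by-model grid of age predictors
#'
#' Splits the samples 80/20 ([split_train_test()]), and for every
#' combination of imputation technique and model family: fits the
#' imputation on training rows only, completes the test rows from
#' training statistics, trains the model, and scores MAE and Pearson r on
#' the held-out test set. Model families: elastic net (mixing 0.5,
#' CV-selected penalty), gradient boosting (100 rounds, depth 3,
#' learning rate 0.1), and random forest (100 trees, unlimited depth).
#'
#' @param table samples x features table (percent scale, `NA` missing).
#' @param ages ages in months, one per row of `table`.
#' @param train_fraction,seed split parameters.
#' @param imputations subset of the four imputation method names.
#' @param models subset of
#'   `c("elastic_net", "gradient_boosting", "random_forest")`.
#' @param specs optional named list of [imputation_spec()] overrides.
#' @return data.frame of class `"model_grid_result"` with columns
#'   `imputation`, `model`, `mae`, `pearson_r`; one row per combination,
#'   in fixed method order.
#' @export
run_model_grid <- function(table, ages, train_fraction = 0.8, seed = 1L,
                           imputations = c("mean", "knn", "soft_impute",
                                           "pca"),
                           models = c("elastic_net", "gradient_boosting",
                                      "random_forest"),
                           specs = NULL) {
  stopifnot(nrow(table) >= 10L, nrow(table) == length(ages))
  if (stats::sd(ages) == 0) stop("ages are constant")
  if (is.null(rownames(table)))
    rownames(table) <- sprintf("s%03d", seq_len(nrow(table)))
  ages <- stats::setNames(ages, rownames(table))
  split <- split_train_test(rownames(table), train_fraction, seed)
  train_raw <- table[split$train, , drop = FALSE]
  test_raw <- table[split$test, , drop = FALSE]
  keep <- colSums(!is.na(train_raw)) > 0
  train_raw <- train_raw[, keep, drop = FALSE]
  test_raw <- test_raw[, keep, drop = FALSE]
  rows <- list()
  for (imp in imputations) {
    spec <- if (!is.null(specs[[imp]])) specs[[imp]] else imputation_spec(imp)
    train_x <- impute_methylation(train_raw, spec)
    test_x <- impute_test_rows(train_raw, train_x, test_raw, spec)
    for (mod in models) {
      pred <- fit_predict_family(mod, train_x, ages[split$train], test_x,
                                 seed)
      rows[[length(rows) + 1L]] <- data.frame(
        imputation = imp, model = mod,
        mae = mean(abs(pred - ages[split$test])),
        pearson_r = stats::cor(pred, ages[split$test]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("model_grid_result", class(out))
  out
}

fit_predict_family <- function(family, train_x, train_y, test_x, seed) {
  set.seed(seed)
  if (family == "elastic_net") {
    fit <- fit_elastic_net(train_x, train_y, mixing = 0.5,
                           cv_folds = min(10L, nrow(train_x)),
                           lambda_rule = "lambda.min", standardize = TRUE,
                           seed = seed)
    if (!length(fit$site_keys)) return(rep(fit$intercept, nrow(test_x)))
    as.vector(fit$intercept +
                test_x[, fit$site_keys, drop = FALSE] %*% fit$weights)
  } else if (family == "gradient_boosting") {
    bst <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = 3,
                    eta = 0.1, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(train_x, label = train_y), nrounds = 100)
    stats::predict(bst, xgboost::xgb.DMatrix(test_x))
  } else if (family == "random_forest") {
    rf <- randomForest::randomForest(x = train_x, y = train_y, ntree = 100)
    unname(stats::predict(rf, test_x))
  } else stop("unknown model family: ", family)
}

#' Select the best grid row
#'
#' Minimum MAE wins; ties break toward higher Pearson r, then the fixed
#' grid order.
#'
#' @param grid a `"model_grid_result"`.
#' @return the winning one-row data.frame.
#' @export
select_best <- function(grid) {
  if (!nrow(grid)) stop("empty grid")
  ord <- order(grid$mae, -grid$pearson_r)
  grid[ord[1L], , drop = FALSE]
}
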