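test_that("train/test split sizes follow the rounding rule and the seed", {
  ids <- sprintf("s%03d", 1:134)
  sp <- split_train_test(ids, 0.8, seed = 1)
  expect_length(sp$train, 107L)
  expect_length(sp$test, 27L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0L)

  expect_identical(split_train_test(ids[1:10], seed = 3),
                   split_train_test(ids[1:10], seed = 3))
  sp5 <- split_train_test(ids[1:5], 0.8, seed = 2)
  expect_length(sp5$train, 4L)
  expect_length(sp5$test, 1L)
  expect_error(split_train_test("only_one"), "at least two")
})

test_that("predictions are the affine form of the stored weights", {
  keys <- c("chr1:10", "chr1:20", "chr1:30")
  model <- toy_clock(keys, c(2, -1, 0.5), intercept = 10)
  prof <- stats::setNames(c(0.2, 0.4, 0.6), keys)
  expect_equal(unname(predict_ages(prof, model)),
               10 + sum(c(2, -1, 0.5) * c(0.2, 0.4, 0.6)))
  # all-zero profile -> intercept; zero weights -> intercept
  expect_equal(unname(predict_ages(stats::setNames(rep(0, 3), keys), model)),
               10)
  zero <- toy_clock(keys, rep(0, 3))
  m <- matrix(runif(9), 3, dimnames = list(NULL, keys))
  expect_equal(unname(predict_ages(m, zero)), rep(10, 3))

  # site-order permutation and non-clock columns do not change predictions
  set.seed(1)
  m2 <- matrix(runif(12), 3, dimnames = list(letters[1:3],
                                             c(keys, "chr9:99")))
  expect_equal(predict_ages(m2, model),
               predict_ages(m2[, rev(colnames(m2))], model))
  expect_equal(predict_ages(m2, model),
               predict_ages(m2[, keys], model))
})

test_that("two-stage clock-site imputation matches the brute-force oracle", {
  keys <- paste0("chr1:", 1:5)
  model <- toy_clock(keys, rep(1, 5))
  set.seed(2)
  m <- matrix(runif(20), 4, 5, dimnames = list(letters[1:4], keys))
  complete <- impute_clock_sites(m, model)
  expect_identical(complete, m)  # identity when fully covered

  m[1, 2] <- NA; m[3, 2] <- NA; m[2, 4] <- NA
  m[, 5] <- NA  # covered in no sample -> per-sample fallback
  got <- impute_clock_sites(m, model)
  # oracle: stage 1 cohort site means, stage 2 row means of covered sites
  oracle <- m
  for (j in 1:4) {
    if (all(is.na(m[, j]))) next
    oracle[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
  }
  for (i in 1:4) oracle[i, 5] <- mean(m[i, 1:4], na.rm = TRUE)
  expect_equal(got, oracle)
  # present values are untouched bit for bit
  expect_identical(got[!is.na(m)], m[!is.na(m)])

  all_missing <- matrix(NA_real_, 2, 5,
                        dimnames = list(c("a", "b"), keys))
  expect_error(impute_clock_sites(all_missing, model), "no covered")
})

test_that("clock evaluation matches textbook formulas", {
  x <- c(10, 12, 14, 20)
  ev <- evaluate_clock(x, x)
  expect_equal(ev$mae, 0)
  expect_equal(ev$pearson_r, 1)
  ev2 <- evaluate_clock(x + 2, x)
  expect_equal(ev2$mae, 2)
  expect_equal(ev2$medae, 2)
  expect_equal(ev2$pearson_r, 1)

  set.seed(3)
  pred <- runif(30, 0, 30); chron <- runif(30, 0, 30)
  ev3 <- evaluate_clock(pred, chron)
  expect_equal(ev3$mae, mean(abs(pred - chron)))
  expect_equal(ev3$medae, median(abs(pred - chron)))
  r_oracle <- sum((pred - mean(pred)) * (chron - mean(chron))) /
    sqrt(sum((pred - mean(pred))^2) * sum((chron - mean(chron))^2))
  expect_equal(ev3$pearson_r, r_oracle)
  expect_error(evaluate_clock(rep(1, 5), 1:5), "constant")
})

test_that("a noiseless age-linear site is recovered almost exactly", {
  set.seed(4)
  ages <- runif(60, 1, 27)
  m <- matrix(0.2 + 0.01 * ages, 60, 1,
              dimnames = list(sprintf("s%02d", 1:60), "chr1:100"))
  ck <- train_elastic_net_clock(m, ages,
                                clock_config(lambda_rule = 1e-4, seed = 1))
  expect_lte(ck$evaluation$mae, 0.1)
  expect_error(train_elastic_net_clock(m, rep(5, 60)), "constant")
})

test_that("training is deterministic and ignores zero-signal padding", {
  set.seed(5)
  coh <- simulate_training_cohort(simulation_config(n_samples = 60,
                                                    n_sites = 300, seed = 6))
  meth <- mask_low_coverage(coh$meth, coh$cov)
  ages <- coh$samples$age_months
  ck1 <- train_elastic_net_clock(meth, ages, clock_config(seed = 2))
  ck2 <- train_elastic_net_clock(meth, ages, clock_config(seed = 2))
  expect_identical(ck1$weights, ck2$weights)
  expect_identical(ck1$evaluation$predictions, ck2$evaluation$predictions)
})

test_that("age acceleration is the residual from the reference line", {
  ref <- list(slope = 0.9, intercept = 2)
  acc <- age_acceleration(0.9 * 10 + 2, 10, ref)
  expect_equal(acc$acceleration, 0)
  expect_error(age_acceleration(5, 5, NULL), "reference")

  # over the fitting set, residual accelerations sum to zero
  set.seed(7)
  chron <- runif(25, 5, 25)
  pred <- 0.8 * chron + 3 + rnorm(25, 0, 2)
  fit <- stats::coef(stats::lm(pred ~ chron))
  ref2 <- list(intercept = unname(fit[1]), slope = unname(fit[2]))
  acc2 <- age_acceleration(pred, chron, ref2)
  expect_equal(sum(acc2$acceleration), 0, tolerance = 1e-9)

  # uniform +3-month prediction offset appears as +3 mean acceleration
  acc3 <- age_acceleration(pred + 3, chron, ref2)
  expect_equal(mean(acc3$acceleration), 3, tolerance = 1e-9)

  # invariance to a constant age shift when the reference is refitted
  shift <- 7
  fit_s <- stats::coef(stats::lm(pred ~ I(chron + shift)))
  acc_s <- age_acceleration(pred, chron + shift,
                            list(intercept = unname(fit_s[1]),
                                 slope = unname(fit_s[2])))
  expect_equal(acc_s$acceleration, acc2$acceleration, tolerance = 1e-9)
})

test_that("held-out MAE sits at the feature-noise floor for a single site", {
  # one informative site: observation noise sd / slope months of
  # irreducible error; MAE floor = sqrt(2/pi) * sd
  slope <- 0.01; noise <- 0.03
  floor_months <- sqrt(2 / pi) * noise / slope
  mae_at <- function(n, seed) {
    set.seed(seed)
    ages <- runif(n, 0, 30)
    m <- matrix(0.3 + slope * ages + rnorm(n, 0, noise), n, 1,
                dimnames = list(sprintf("s%04d", 1:n), "chr1:1"))
    train_elastic_net_clock(m, ages, clock_config(seed = 1))$evaluation$mae
  }
  mae_big <- mae_at(600, 8)
  expect_gt(mae_big, 0.75 * floor_months)
  expect_lt(mae_big, 1.25 * floor_months)
  expect_gt(mae_at(60, 9), 0.6 * floor_months)
})
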