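test_that("rDNA feature tables union positions across samples", {
  t1 <- data.frame(chrom = "NR_046239.1", pos = c(10L, 20L),
                   fraction = c(0.5, 0.75), coverage = c(10L, 8L))
  t2 <- data.frame(chrom = "NR_046239.1", pos = c(20L, 30L),
                   fraction = c(0.25, 1), coverage = c(4L, 6L))
  tab <- build_rdna_table(list(a = t1, b = t2), "NR_046239.1")
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(colnames(tab),
               c("NR_046239.1:10", "NR_046239.1:20", "NR_046239.1:30"))
  expect_equal(unname(tab["a", ]), c(50, 75, NA))
  expect_equal(unname(tab["b", ]), c(NA, 25, 100))

  single <- build_rdna_table(list(a = t1), "NR_046239.1")
  expect_equal(unname(single["a", ]), c(50, 75))
  expect_error(build_rdna_table(list(a = t1), "NR_000000.0"), "no rows")

  # written cov files and per-cell brute-force lookup
  dir <- withr::local_tempdir()
  tabs <- lapply(1:3, function(i) {
    t <- random_site_table(12, chrom = "NR_046239.1", seed = 30 + i)
    write_bismark_cov(t, file.path(dir, paste0("s", i, ".cov")))
    t
  })
  built <- build_rdna_table(
    stats::setNames(file.path(dir, paste0("s", 1:3, ".cov")),
                    paste0("s", 1:3)), "NR_046239.1")
  for (i in 1:3) for (j in seq_len(nrow(tabs[[i]]))) {
    key <- paste0("NR_046239.1:", tabs[[i]]$pos[j])
    expect_equal(built[paste0("s", i), key], 100 * tabs[[i]]$fraction[j])
  }
})

test_that("common-feature restriction equals the set-intersection oracle", {
  set.seed(31)
  keys <- paste0("rDNA:", sort(sample.int(500, 40)))
  a <- matrix(runif(80), 2, 40, dimnames = list(c("a1", "a2"), keys))
  b <- matrix(runif(60), 2, 30,
              dimnames = list(c("b1", "b2"), sample(keys, 30)))
  res <- restrict_to_common_features(a, b)
  expect_setequal(colnames(res$a), intersect(colnames(a), colnames(b)))
  expect_identical(colnames(res$a), colnames(res$b))

  id <- restrict_to_common_features(a, a)
  expect_equal(dim(id$a), dim(a))
  disjoint <- b
  colnames(disjoint) <- paste0("other:", 1:30)
  expect_error(restrict_to_common_features(a, disjoint), "no common")
})

test_that("all imputers are identity on observed entries and full tables", {
  set.seed(32)
  x <- matrix(runif(15 * 12, 0, 100), 15, 12)
  holes <- matrix(runif(180) < 0.2, 15, 12)
  xm <- x; xm[holes] <- NA
  for (method in c("mean", "knn", "soft_impute", "pca")) {
    done <- impute_methylation(xm, imputation_spec(method))
    expect_identical(done[!holes], x[!holes])
    expect_false(anyNA(done))
    expect_true(all(done >= 0 & done <= 100))
    expect_identical(impute_methylation(x, imputation_spec(method)), x)
  }
})

test_that("mean imputation fills column means", {
  x <- matrix(c(10, NA, 20, 1, 2, 3), 3, 2)
  got <- impute_methylation(x, imputation_spec("mean"))
  expect_equal(got[2, 1], 15)
})

test_that("1-NN imputation recovers a duplicated row's holes exactly", {
  set.seed(33)
  base <- matrix(runif(5 * 8, 0, 100), 5, 8)
  x <- rbind(base, base[3, ])  # exact duplicate of row 3
  x[6, c(2, 5)] <- NA
  got <- impute_methylation(x, imputation_spec("knn", k = 1))
  expect_equal(got[6, c(2, 5)], base[3, c(2, 5)])
})

test_that("SoftImpute recovers a noiseless rank-1 matrix through holes", {
  set.seed(34)
  u <- runif(20, 0.2, 1); v <- runif(15, 20, 80)
  x <- u %o% v  # rank 1, values within [0,100]
  holes <- matrix(runif(300) < 0.1, 20, 15)
  xm <- x; xm[holes] <- NA
  got <- impute_methylation(xm, imputation_spec("soft_impute", rank = 1,
                                                tol = 1e-10,
                                                max_iter = 1000))
  expect_lt(max(abs(got - x)), 1e-6)

  # objective (observed squared error + nuclear penalty) never increases
  obj <- attr(impute_svd(xm, imputation_spec("soft_impute", rank = 2,
                                             lambda = 1, tol = 1e-8,
                                             max_iter = 100),
                         center = FALSE), "objective")
  expect_true(all(diff(obj) <= 1e-8))
})

test_that("PCA imputation reconstructs low-rank structure", {
  set.seed(35)
  scores <- matrix(rnorm(30 * 2), 30, 2)
  load <- matrix(rnorm(2 * 10), 2, 10)
  x <- 50 + scores %*% load * 5
  x <- pmin(pmax(x, 0), 100)
  holes <- matrix(runif(300) < 0.1, 30, 10)
  xm <- x; xm[holes] <- NA
  got <- impute_methylation(xm, imputation_spec("pca", rank = 2,
                                                tol = 1e-9, max_iter = 500))
  expect_lt(mean(abs(got[holes] - x[holes])), 1)
})

test_that("the model grid is complete, deterministic and leakage-free", {
  set.seed(36)
  ages <- runif(60, 1, 27)
  rd <- simulate_rdna_tables(ages, runif(5, 23, 24), n_sites = 80,
                             frac_age_associated = 0.3, seed = 37)
  grid <- run_model_grid(rd$train, ages, seed = 38)
  expect_equal(nrow(grid), 12L)
  expect_equal(nrow(unique(grid[, c("imputation", "model")])), 12L)
  grid2 <- run_model_grid(rd$train, ages, seed = 38)
  expect_equal(grid, grid2)
  expect_gte(select_best(grid)$pearson_r, 0.6)

  # test rows are imputed independently of each other (no cross-test
  # information): one-at-a-time equals all-at-once
  spec <- imputation_spec("knn", k = 3)
  split <- split_train_test(rownames(rd$train), 0.8, 38)
  tr <- rd$train[split$train, ]
  te <- rd$train[split$test, ]
  trc <- impute_methylation(tr, spec)
  all_at_once <- impute_test_rows(tr, trc, te, spec)
  for (i in seq_len(nrow(te))) {
    one <- impute_test_rows(tr, trc, te[i, , drop = FALSE], spec)
    expect_equal(one[1, ], all_at_once[i, ])
  }
})

test_that("grid selection minimizes MAE with the documented tie rules", {
  g <- data.frame(imputation = c("mean", "knn"),
                  model = c("elastic_net", "elastic_net"),
                  mae = c(4, 5), pearson_r = c(0.8, 0.9))
  expect_equal(select_best(g)$imputation, "mean")
  g$mae <- c(4, 4)
  expect_equal(select_best(g)$imputation, "knn")  # higher r wins the tie
  g$pearson_r <- c(0.9, 0.9)
  expect_equal(select_best(g)$imputation, "mean")  # fixed order
  expect_equal(select_best(g[1, ])$imputation, "mean")
  expect_error(select_best(g[0, ]), "empty")
})

test_that("simulated rDNA age drift is positive among informative sites", {
  set.seed(39)
  ages <- runif(80, 1, 27)
  rd <- simulate_rdna_tables(ages, runif(5, 23, 24), n_sites = 100,
                             frac_age_associated = 0.2, seed = 40)
  rs <- vapply(rd$truth$positions, function(k)
    stats::cor(rd$train[, k], ages, use = "complete.obs"), numeric(1))
  expect_true(all(rs > 0))
})
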