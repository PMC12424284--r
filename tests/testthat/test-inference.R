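# Varimax PCA, paired tests with BH FDR, PLSC, efficiency scoring.

test_that("block-structured data rotate onto separate components", {
  set.seed(41)
  n <- 400
  base <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))   # exactly orthogonal pair
  X <- cbind(base[, c(1, 1, 1)], base[, c(2, 2, 2)],
             matrix(rnorm(n * 10), n, 10))
  colnames(X) <- paste0("v", 1:16)
  res <- pca_varimax(X, n_components = 2)
  expect_gte(sum(res$eigenvalues > 1), 2)
  expect_gt(res$eigenvalues[1], 2.5)   # each block carries ~3 units
  L <- abs(res$loadings)
  blocks <- list(1:3, 4:6)
  own <- sapply(1:2, function(j) max(sapply(blocks, function(b) min(L[b, j]))))
  expect_true(all(own > 0.9))
  cross <- sapply(1:2, function(j)
    min(sapply(blocks, function(b) max(L[b, j]))))
  expect_true(all(cross < 0.1))
})

test_that("communalities are invariant under varimax rotation", {
  ft <- make_feature_table(n = 40, seed = 42)
  for (fn in feature_names())
    ft[[fn]] <- ft[[fn]] * exp(0.2 * rnorm(40))
  res <- pca_varimax(ft)
  expect_lt(max(abs(res$communalities -
                      rowSums(res$unrotated_loadings^2))), 1e-8)
  expect_lte(sum(res$explained_pct), 100 + 1e-9)
  # sign convention: dominant loading of each component positive
  for (j in seq_len(res$n_retained))
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
})

test_that("PCA rejects degenerate inputs", {
  X <- matrix(rnorm(100), 20, 5)
  X[, 2] <- 1
  expect_error(pca_varimax(X), "constant")
  expect_error(pca_varimax(matrix(rnorm(12), 3, 4)), "more rows")
})

test_that("identical rest and task tables give a null result", {
  ft <- make_feature_table(n = 8, seed = 43)
  task <- feature_table(transform(as.data.frame(ft), condition = "task"))
  res <- paired_compare(ft, task)
  expect_true(all(res$t == 0))
  expect_true(all(res$p_raw == 1))
  expect_true(all(res$cohens_d == 0))
})

test_that("paired statistics match hand arithmetic and d = t/sqrt(n)", {
  rest <- make_feature_table(n = 3, seed = 44)
  df <- as.data.frame(rest)
  for (fn in feature_names()) df[[fn]] <- df[[fn]] - c(1, 2, 3)
  df$condition <- "task"
  res <- paired_compare(rest, feature_table(df))
  expect_equal(res$t, rep(2 * sqrt(3), 16))
  expect_equal(res$cohens_d, rep(2, 16))

  # general internal consistency on random tables
  rest2 <- make_feature_table(n = 12, seed = 45)
  df2 <- as.data.frame(make_feature_table(n = 12, seed = 46))
  df2$condition <- "task"
  res2 <- paired_compare(rest2, feature_table(df2))
  expect_lt(max(abs(res2$cohens_d - res2$t / sqrt(res2$n))), 1e-9)
  expect_true(all(res2$p_adjusted >= res2$p_raw))
  expect_true(all(sign(res2$cohens_d) == sign(res2$t)))
})

test_that("subject mismatches and zero-variance differences error", {
  rest <- make_feature_table(n = 5, seed = 47)
  df <- as.data.frame(make_feature_table(n = 5, seed = 48))
  df$condition <- "task"; df$subject[1] <- "zz"
  expect_error(paired_compare(rest, feature_table(df)), "different subjects")
  df2 <- as.data.frame(rest)
  df2$condition <- "task"
  for (fn in feature_names()) df2[[fn]] <- df2[[fn]] + 1
  expect_error(paired_compare(rest, feature_table(df2)), "zero-variance")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(49)
  for (i in 1:50) {
    p <- runif(sample(3:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("rank-1 coupling gives a single latent with all covariance", {
  set.seed(50)
  u <- rnorm(30)
  X <- outer(u, rnorm(6)) ; Y <- outer(u, rnorm(2))
  fit <- plsc_fit(X, Y)
  expect_equal(fit$covexp[1], 1, tolerance = 1e-10)
  expect_equal(sum(fit$covexp), 1, tolerance = 1e-12)
  # q = 1 forces one LV with covexp 1
  fit1 <- plsc_fit(matrix(rnorm(60), 20, 3), matrix(rnorm(20), 20, 1))
  expect_length(fit1$covexp, 1)
  expect_equal(fit1$covexp, 1)
})

test_that("PLSC structure: unit-norm saliences, ordered singular values,
           column-order invariance", {
  set.seed(51)
  X <- matrix(rnorm(200 * 6), 200, 6); Y <- matrix(rnorm(200 * 3), 200, 3)
  colnames(X) <- paste0("x", 1:6)
  fit <- plsc_fit(X, Y)
  expect_true(all(diff(fit$singular_values) <= 1e-12))
  expect_equal(colSums(fit$x_saliences^2), rep(1, 3), ignore_attr = TRUE)
  expect_equal(colSums(fit$y_saliences^2), rep(1, 3), ignore_attr = TRUE)
  perm <- c(3, 1, 2, 6, 5, 4)
  fit2 <- plsc_fit(X[, perm], Y)
  expect_equal(fit2$singular_values, fit$singular_values)
  expect_equal(abs(fit2$x_saliences[colnames(X), ]), abs(fit$x_saliences),
               tolerance = 1e-8)
  expect_error(plsc_fit(cbind(X, 0), Y), "constant")
})

test_that("PLSC agrees with a direct eigendecomposition oracle", {
  set.seed(52)
  X <- matrix(rnorm(6 * 4), 6, 4); Y <- matrix(rnorm(6 * 3), 6, 3)
  fit <- plsc_fit(X, Y)
  R <- crossprod(scale(X), scale(Y)) / (nrow(X) - 1)
  ev <- eigen(crossprod(R), symmetric = TRUE)   # R'R eigenvalues = s^2
  expect_equal(fit$singular_values^2, ev$values[1:3], tolerance = 1e-10)
})

test_that("permutation p-values follow the add-one formula and identity
           permutation reproduces the fit", {
  set.seed(53)
  u <- rnorm(40)
  X <- outer(u, rnorm(5)) + matrix(rnorm(200, sd = 0.05), 40, 5)
  Y <- outer(u, rnorm(3)) + matrix(rnorm(120, sd = 0.05), 40, 3)
  fit <- plsc_fit(X, Y)
  expect_equal(breathdyn:::cross_singvals(fit$Xz, fit$Yz, 3),
               fit$singular_values)
  fit <- plsc_permutation(fit, n_perm = 1000, seed = 54)
  expect_equal(fit$perm_p[1], 1 / 1001)   # observed beats every permutation
  expect_error(plsc_permutation(fit, n_perm = 0), ">= 1")
  expect_warning(plsc_permutation(fit, n_perm = 50, seed = 1), "coarse")
})

test_that("coupled-block strengths are recovered through the SVD", {
  set.seed(55)
  A <- qr.Q(qr(matrix(rnorm(32), 16, 2)))
  B <- qr.Q(qr(matrix(rnorm(6), 3, 2)))
  g <- gen_coupled_blocks(3000, 16, 3, A, B, strengths = c(0.5, 0.25),
                          noise_sd = 1, seed = 56)
  fit <- plsc_fit(g$X, g$Y)
  # singular-value ratio tracks the 2:1 planted strengths; the band is
  # derived from the estimator's noise floor and z-scoring attenuation
  expect_gt(fit$singular_values[1] / fit$singular_values[2], 1.4)
  expect_lt(fit$singular_values[1] / fit$singular_values[2], 2.6)
  expect_gt(fit$covexp[1], fit$covexp[2])
  expect_error(gen_coupled_blocks(100, 16, 3, A, B * 2, c(1, 1)),
               "orthogonal")
})

test_that("bootstrap reliability flags strong saliences, not noise", {
  set.seed(57)
  n <- 200
  z <- rnorm(n)
  X <- cbind(0.9 * z, matrix(rnorm(n * 5), n, 5)) +
    matrix(rnorm(n * 6, sd = 0.3), n, 6)
  colnames(X) <- paste0("x", 1:6)
  Y <- cbind(0.9 * z + rnorm(n, sd = 0.3), rnorm(n))
  fit <- plsc_fit(X, Y)
  fit <- plsc_bootstrap(fit, n_boot = 300, seed = 58)
  expect_true(fit$x_reliable["x1", 1])
  expect_lt(mean(fit$x_reliable[paste0("x", 3:6), 1]), 0.5)
  expect_true(all(fit$x_ci_lo <= fit$x_ci_hi))
  expect_error(plsc_bootstrap(fit, n_boot = 0), ">= 1")
})

test_that("efficiency is accuracy over mean correct-trial RT", {
  trials <- data.frame(subject = "a", load = 1, speed = "slow",
                       correct = c(rep(1, 9), 0),
                       rt = c(rep(0.5, 9), 5))
  eff <- wm_efficiency(trials)
  expect_equal(eff$accuracy, 0.9)
  expect_equal(eff$mean_rt, 0.5)
  expect_equal(eff$efficiency, 1.8)
  # all-correct at constant rt r: efficiency = 1/r
  trials2 <- data.frame(subject = "a", load = 2, speed = "fast",
                        correct = 1, rt = rep(0.4, 20))
  expect_equal(wm_efficiency(trials2)$efficiency, 2.5)
  # zero accuracy gives zero efficiency
  trials3 <- data.frame(subject = "a", load = 3, speed = "fast",
                        correct = 0, rt = rep(0.4, 20))
  expect_equal(wm_efficiency(trials3)$efficiency, 0)
  # rt_trials = "all" pools incorrect trials into the RT
  eff_all <- wm_efficiency(trials, rt_trials = "all")
  expect_equal(eff_all$mean_rt, 0.95)
})

test_that("the efficiency block is one row per subject, one column per load", {
  trials <- expand.grid(subject = c("a", "b"), load = 1:3, i = 1:10)
  trials$speed <- "slow"; trials$correct <- 1
  trials$rt <- 0.5 + 0.1 * trials$load
  M <- efficiency_block(wm_efficiency(trials))
  expect_equal(dim(M), c(2, 3))
  expect_equal(M["a", "eff_2back"], 1 / 0.7)
})
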