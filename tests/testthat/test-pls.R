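test_that("a single informative predictor is fit by one component", {
  withr::local_seed(41)
  X <- cbind(x1 = rnorm(30), x2 = 0, x3 = 0)
  y <- 3 * X[, 1]
  fit <- fit_pls(X, y, ncomp = 1, scale = FALSE)
  r2 <- 1 - sum((y - predict(fit, X))^2) / sum((y - mean(y))^2)
  expect_gte(r2, 0.999)
})

test_that("full-rank PLS equals ordinary least squares", {
  withr::local_seed(42)
  for (i in 1:10) {
    X <- matrix(rnorm(100), 20, 5)
    y <- rnorm(20)
    fit <- fit_pls(X, y, ncomp = 5)
    ols <- drop(cbind(1, X) %*% solve(crossprod(cbind(1, X)),
                                      crossprod(cbind(1, X), y)))
    expect_equal(predict(fit, X), ols, tolerance = 1e-6)
  }
})

test_that("PLS scores are mutually orthogonal", {
  withr::local_seed(43)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  fit <- fit_pls(X, y, ncomp = 6)
  g <- crossprod(fit$T)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # residual X norm is non-increasing in the number of components
  cs <- psychoscreen:::center_scale(X, TRUE)
  Xd <- cs$X
  norms <- numeric(fit$n_components)
  for (a in seq_len(fit$n_components)) {
    Xd <- Xd - tcrossprod(fit$T[, a], fit$P[, a])
    norms[a] <- sum(Xd^2)
  }
  expect_true(all(diff(c(sum(cs$X^2), norms)) < 1e-10))
})

test_that("fit is invariant to sample order", {
  withr::local_seed(44)
  X <- matrix(rnorm(120), 24, 5)
  y <- rnorm(24)
  fit <- fit_pls(X, y, ncomp = 3)
  perm <- sample(24)
  fit_p <- fit_pls(X[perm, ], y[perm], ncomp = 3)
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-10)
  expect_equal(fit_p$T, fit$T[perm, ], tolerance = 1e-8)
})

test_that("predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  withr::local_seed(45)
  X <- matrix(rnorm(150), 30, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- drop(X %*% c(1, -2, 0.5, 0, 0)) + rnorm(30)
  fit <- fit_pls(X, y, ncomp = 3, scale = TRUE)
  ref <- mixOmics::pls(X, y, ncomp = 3, scale = TRUE, mode = "regression")
  pred_ref <- predict(ref, X)$predict[, 1, 3]
  expect_equal(unname(predict(fit, X)), unname(pred_ref),
               tolerance = 1e-8)
  expect_equal(unname(vip(fit)), unname(mixOmics::vip(ref)[, 3]),
               tolerance = 1e-8)
})

test_that("VIP satisfies its normalization identity", {
  withr::local_seed(46)
  # p = 1: VIP is exactly 1
  X1 <- matrix(rnorm(20), 20, 1)
  f1 <- fit_pls(X1, rnorm(20) + X1[, 1], ncomp = 1)
  expect_equal(unname(vip(f1)), 1)
  # mean of VIP^2 equals 1 on arbitrary models
  for (i in 1:5) {
    n <- sample(15:40, 1); p <- sample(3:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    A <- sample(seq_len(min(n - 2, p)), 1)
    v <- vip(fit_pls(X, y, ncomp = A))
    expect_equal(sum(v^2), p, tolerance = 1e-8)
  }
})

test_that("VIP ranks a planted driver above noise predictors", {
  withr::local_seed(47)
  hits <- replicate(50, {
    X <- matrix(rnorm(200 * 10), 200, 10)
    y <- X[, 1] + rnorm(200, sd = 0.5)
    v <- vip(fit_pls(X, y, ncomp = 2))
    which.max(v) == 1 && v[1] > 1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("VIP is invariant to positive scaling of the response", {
  withr::local_seed(48)
  X <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  expect_equal(vip(fit_pls(X, 13.7 * y, ncomp = 2)),
               vip(fit_pls(X, y, ncomp = 2)), tolerance = 1e-10)
})

test_that("LOO cross-validation equals the explicit refit loop", {
  withr::local_seed(49)
  for (i in 1:5) {
    X <- matrix(rnorm(60), 15, 4)
    y <- rnorm(15)
    ev <- loo_cv(X, y, ncomp = 2)
    expect_equal(ev$loo_predictions, naive_loo_predictions(X, y, 2),
                 tolerance = 1e-10)
    expect_equal(ev$q2, 1 - ev$press / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    expect_equal(ev$rmsecv, sqrt(ev$press / 15), tolerance = 1e-12)
  }
})

test_that("noiseless linear data is perfectly predicted, permuted data is not", {
  withr::local_seed(50)
  X <- matrix(rnorm(90), 30, 3)
  y <- drop(X %*% c(1, 2, -1))
  expect_gte(loo_cv(X, y, ncomp = 3)$q2, 0.999)

  q2s <- replicate(50, {
    Xp <- matrix(rnorm(60), 15, 4)
    loo_cv(Xp, rnorm(15), ncomp = 2)$q2
  })
  expect_lte(mean(q2s), 0)
})

test_that("cross-validated fit never beats the training fit", {
  withr::local_seed(51)
  for (i in 1:5) {
    X <- matrix(rnorm(80), 20, 4)
    y <- drop(X %*% rnorm(4)) + rnorm(20)
    A <- sample(1:3, 1)
    fit <- fit_pls(X, y, ncomp = A)
    r2 <- 1 - sum((y - predict(fit, X))^2) / sum((y - mean(y))^2)
    expect_lte(loo_cv(X, y, ncomp = A)$q2, r2 + 1e-8)
  }
})

test_that("component selection recovers the latent dimension", {
  withr::local_seed(52)
  # one latent factor: a single component suffices
  sel1 <- replicate(15, {
    t1 <- rnorm(60)
    X <- outer(t1, runif(6, 0.5, 2)) + matrix(rnorm(360, sd = 0.02), 60, 6)
    y <- t1 + rnorm(60, sd = 0.02)
    as.integer(select_components(X, y, max_A = 5))
  })
  expect_true(all(sel1 == 1L))

  # two latent components, the first insufficient by construction: the
  # response weights the minor block more than the covariance-dominant one
  hits <- replicate(25, {
    t1 <- rnorm(100); t2 <- rnorm(100)
    X <- cbind(outer(t1, runif(6, 0.5, 2)), outer(t2, runif(2, 0.5, 2))) +
      matrix(rnorm(800, sd = 0.05), 100, 8)
    y <- t1 + 2 * t2 + rnorm(100, sd = 0.05)
    as.integer(select_components(X, y, max_A = 5)) == 2L
  })
  expect_gte(mean(hits), 0.8)
  # the Q2 path itself is exposed for inspection
  a <- select_components(matrix(rnorm(80), 20, 4), rnorm(20), max_A = 3)
  expect_length(attr(a, "q2"), 3)
})

test_that("zero-variance columns error under scaling at fit time", {
  X <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_error(fit_pls(X, rnorm(20), ncomp = 1, scale = TRUE), "b")
  expect_error(fit_pls(X, rnorm(20), ncomp = 5), "exceeds")
})

test_that("Spearman correlation handles monotone data and ties", {
  x <- rnorm(10)
  expect_equal(spearman_cor(x, exp(x))$estimate, 1)
  expect_equal(spearman_cor(x, -x)$estimate, -1)
  expect_equal(spearman_cor(x, exp(x))$p.value, 0)
  expect_error(spearman_cor(x, rep(1, 10)), "constant")
  expect_error(spearman_cor(1:3, 3:1), "at least 4")
  # midranks: agreement with base R on tied data
  xt <- c(1, 2, 2, 3, 4, 4, 5, 6)
  yt <- c(2, 1, 3, 3, 5, 4, 7, 6)
  expect_equal(spearman_cor(xt, yt)$estimate,
               unname(cor(xt, yt, method = "spearman")), tolerance = 1e-12)
})

test_that("exact permutation p matches base R's exact Spearman test", {
  withr::local_seed(53)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    mine <- spearman_cor(x, y, "exact_perm")
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(mine$estimate, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(spearman_cor(rnorm(9), rnorm(9), "exact_perm"), "n <= 8")
})

test_that("per-factor evaluation table has the Table-1 shape", {
  co <- tiny_cohort(seed = 54, n_taxa = 30)
  norm <- normalize_abundance(co$abundance)
  cfg <- run_config(max_components = 3)
  tab <- pls_evaluation_table(norm, co$panel[1:4], cfg)
  expect_equal(tab$factor, setdiff(names(co$panel)[1:4], "sample_id"))
  expect_true(all(tab$q2 <= 1))
  expect_true(all(tab$spearman_p >= 0 & tab$spearman_p <= 1))
  expect_true(all(tab$rmsecv > 0))
})
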