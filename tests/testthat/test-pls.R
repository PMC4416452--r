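test_that("PLS1 recovers univariate and full-rank least squares", {
  # p = 1, exact linear relation: coefficient equals the OLS slope
  set.seed(2)
  x <- matrix(rnorm(25), 25, 1, dimnames = list(NULL, "x"))
  y <- 1.7 * x[, 1] + 0.3
  m <- pls1(x, y, 1)
  expect_equal(unname(coef(m)["x"]), 1.7, tolerance = 1e-10)
  expect_lt(max(abs(residuals(m))), 1e-10)

  # full column rank, A = p: PLS == OLS (oracle: normal equations)
  dat <- toy_xy(n = 20, p = 8, seed = 5)
  m8 <- pls1(dat$X, dat$y, 8)
  b_ols <- solve(crossprod(cbind(1, dat$X)), crossprod(cbind(1, dat$X), dat$y))
  expect_lt(max(abs(fitted(m8) - drop(cbind(1, dat$X) %*% b_ols))), 1e-8)
})

test_that("NIPALS model satisfies its structural invariants", {
  dat <- toy_xy(n = 30, p = 10, seed = 9)
  m <- pls1(dat$X, dat$y, 4)

  # unit-norm weights
  expect_equal(unname(colSums(m$weights^2)), rep(1, 4), tolerance = 1e-12)
  # orthogonal score columns
  G <- crossprod(m$scores)
  offdiag <- abs(G[upper.tri(G)]) / max(diag(G))
  expect_lt(max(offdiag), 1e-8)
  # prediction via (W, P, q) path equals prediction via b
  yhat_scores <- m$y_mean + m$y_sd * drop(m$scores %*% m$y_loadings)
  expect_lt(max(abs(yhat_scores - fitted(m))), 1e-10)
  expect_lt(max(abs(predict(m, dat$X) - fitted(m))), 1e-10)
  # explained Y sums of squares are nonnegative, bounded by the total
  expect_true(all(m$ss_y_per_factor >= 0))
  expect_lte(sum(m$ss_y_per_factor), m$ss_y_total + 1e-10)

  # centering identity: predicting at the column means gives the y mean
  expect_equal(unname(predict(m, matrix(m$x_mean, 1,
                                        dimnames = list(NULL, m$variables)))),
               m$y_mean, tolerance = 1e-10)

  # scale equivariance: rescaling a column is absorbed by autoscaling
  X2 <- dat$X
  X2[, 3] <- X2[, 3] * 10
  m2 <- pls1(X2, dat$y, 4)
  expect_equal(fitted(m2), fitted(m), tolerance = 1e-8)

  # zero-variance columns are dropped with a warning, coefficient zero
  X3 <- cbind(dat$X, const = 1)
  expect_warning(m3 <- pls1(X3, dat$y, 4), "zero-variance")
  expect_equal(unname(coef(m3)["const"]), 0)
})

test_that("explained variance is cumulative and saturates on exact data", {
  set.seed(4)
  t1 <- rnorm(30)
  X <- outer(t1, c(1, -0.5, 2)) # rank-1 X
  colnames(X) <- paste0("v", 1:3)
  y <- 2 * t1
  m <- pls1(X, y, 1)
  ev <- explained_variance(m)
  expect_equal(ev$y_variance_pct[1], 100, tolerance = 1e-8)

  dat <- toy_xy(n = 30, p = 6, seed = 13, noise_sd = 1)
  ev2 <- explained_variance(pls1(dat$X, dat$y, 4))
  expect_true(all(diff(ev2$y_cumulative_pct) >= -1e-10))
  expect_lte(max(ev2$y_cumulative_pct), 100 + 1e-8)
  expect_lte(max(ev2$x_cumulative_pct), 100 + 1e-8)
})

test_that("VIP has unit mean square and reduces algebraically for one factor", {
  dat <- toy_xy(n = 30, p = 12, seed = 21)
  for (A in c(1, 3, 5)) {
    v <- vip(pls1(dat$X, dat$y, A))
    expect_lt(abs(mean(v^2) - 1), 1e-10)
  }
  # 1-factor closed form: VIP_j = sqrt(p) |w_j| / ||w||
  m1 <- pls1(dat$X, dat$y, 1)
  w <- m1$weights[, 1]
  expect_equal(unname(vip(m1)), sqrt(12) * abs(w) / sqrt(sum(w^2)),
               tolerance = 1e-12)
  # equal |w_j| implies all VIP = 1
  Xeq <- matrix(rnorm(40), 40, 1) %*% t(rep(1, 4)) +
    matrix(rnorm(160, sd = 1e-6), 40, 4)
  colnames(Xeq) <- paste0("v", 1:4)
  yeq <- rowMeans(Xeq)
  veq <- vip(pls1(Xeq, yeq, 1))
  expect_equal(unname(veq), rep(1, 4), tolerance = 1e-3)
  # VIP follows column permutations
  perm <- c(3, 1, 2, 4:12)
  vp <- vip(pls1(dat$X[, perm], dat$y, 3))
  expect_equal(unname(vp), unname(vip(pls1(dat$X, dat$y, 3))[perm]),
               tolerance = 1e-10)
})

test_that("fitted values agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(31)
  for (i in 1:3) {
    X <- matrix(rnorm(30 * 12), 30, 12)
    colnames(X) <- paste0("v", 1:12)
    y <- rnorm(30)
    m <- pls1(X, y, 3)
    mo <- mixOmics::pls(X, matrix(y, ncol = 1), ncomp = 3,
                        mode = "regression", scale = TRUE)
    expect_lt(max(abs(fitted(m) - predict(mo, X)$predict[, , 3])), 1e-8)
  }
})

test_that("JSON serialization reloads the model exactly", {
  dat <- toy_xy(n = 25, p = 6, seed = 17)
  m <- pls1(dat$X, dat$y, 3)
  path <- withr::local_tempfile(fileext = ".json")
  pls1_save(m, path)
  m2 <- pls1_load(path)
  expect_equal(m2$coef_raw, m$coef_raw, tolerance = 1e-14)
  expect_equal(m2$intercept, m$intercept, tolerance = 1e-14)
  expect_equal(m2$weights, m$weights, tolerance = 1e-14)
  Xnew <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, colnames(dat$X)))
  expect_equal(predict(m2, Xnew), predict(m, Xnew), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with clear errors", {
  dat <- toy_xy(n = 15, p = 4, seed = 3)
  expect_error(pls1(dat$X, dat$y, 0), "ncomp")
  expect_error(pls1(dat$X, dat$y, 20), "ncomp")
  expect_error(pls1(dat$X, rep(1, 15), 2), "zero variance")
  m <- pls1(dat$X, dat$y, 2)
  expect_error(predict(m, dat$X[, 1:3]), "lacks|columns")
})
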