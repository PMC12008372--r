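test_that("observation sets validate their contract", {
  expect_error(observation_set(matrix(1, 2, 2), 1), "nrow")
  expect_error(observation_set(matrix(c(1, NA), 1), 1), "finite")
  expect_error(observation_set(matrix(1, 1, 1), -1, mode = "titer_proxy"),
               "non-negative")
  obs <- observation_set(matrix(1:6, 3), c(1, 2, 3))
  expect_s3_class(obs, "observation_set")
})

test_that("mixture prediction obeys the law of total variance", {
  # two members, mu = (0, 2), sigma = (0, 0), equal weight: E = 1, Var = 1
  mix <- function(mu, s2, w) {
    E <- sum(w * mu)
    list(E = E, V = sum(w * (s2 + mu^2)) - E^2)
  }
  m <- mix(c(0, 2), c(0, 0), c(0.5, 0.5))
  expect_equal(m$E, 1)
  expect_equal(m$V, 1)
  m1 <- mix(3, 0.25, 1)
  expect_equal(m1$E, 3)
  expect_equal(m1$V, 0.25)

  # the ensemble's own mixture agrees with direct enumeration for <= 4 members
  set.seed(21)
  X <- matrix(runif(40), 20, 2)
  y <- 1 + X[, 1] - 2 * X[, 2] + rnorm(20, 0, 0.05)
  obs <- observation_set(X, y, mode = "yield_proxy")
  fit <- fit_ensemble(obs, lower = c(0, 0), upper = c(1, 1), seed = 1)
  Xq <- matrix(runif(10), 5, 2)
  p <- predict(fit, Xq)
  # direct enumeration in standardized units
  U <- medialearn:::scale_query(fit$scaler, Xq)
  mu <- sapply(fit$members, function(m) medialearn:::predict_member(m, U)$mean)
  s2 <- sapply(seq_along(fit$members), function(i) {
    v <- medialearn:::predict_member(fit$members[[i]], U)$var
    if (is.null(v)) rep(fit$oof_var[[i]], nrow(U)) else v
  })
  E <- as.vector(mu %*% fit$weights)
  V <- pmax(as.vector((s2 + mu^2) %*% fit$weights) - E^2, 0)
  expect_equal(p$mean, fit$y_mu + fit$y_sd * E, tolerance = 1e-12)
  expect_equal(p$var, fit$y_sd^2 * V, tolerance = 1e-12)
})

test_that("GP member matches the closed-form posterior and interpolates", {
  # independent naive GP posterior on 3 points
  X <- matrix(c(0.1, 0.5, 0.9), 3, 1)
  y <- c(0.2, -0.1, 0.4)
  g <- medialearn:::gp_fit(X, y)
  K <- exp(-as.matrix(dist(X))^2 / (2 * g$ell^2)) + diag(g$nugget, 3)
  xq <- matrix(c(0.3, 0.7), 2, 1)
  ks <- exp(-outer(xq[, 1], X[, 1], "-")^2 / (2 * g$ell^2))
  mu_ref <- as.vector(ks %*% solve(K, y))
  var_ref <- 1 + g$nugget - diag(ks %*% solve(K, t(ks)))
  p <- predict(g, xq)
  expect_equal(p$mean, mu_ref, tolerance = 1e-8)
  expect_equal(p$var, pmax(var_ref, 0), tolerance = 1e-8)

  # noiseless smooth data: training-point variance collapses far below the
  # unit prior variance, and grows again away from the data
  Xs <- matrix(seq(0, 1, length.out = 9), 9, 1)
  ys <- sin(2 * pi * Xs[, 1])
  gs <- medialearn:::gp_fit(Xs, ys)
  pt <- predict(gs, Xs)
  expect_lt(max(pt$var), 1e-3)
  pfar <- predict(gs, matrix(3, 1, 1))
  expect_gt(pfar$var, 0.5)
})

test_that("ensemble recovers a noiseless line within tolerance of the OLS oracle", {
  X <- matrix(seq(0, 1, length.out = 8), 8, 1)
  y <- 2 * X[, 1] + 1
  obs <- observation_set(X, y)
  grid <- matrix(seq(0.05, 0.95, length.out = 19), ncol = 1)
  ols <- coef(lm(y ~ X))  # oracle: closed-form least squares
  truth <- ols[1] + ols[2] * grid[, 1]

  # smooth members interpolate the line to 1e-2
  fit_sm <- fit_ensemble(obs, lower = 0, upper = 1, seed = 1,
                         members = c("gp", "ridge"))
  expect_lt(max(abs(predict(fit_sm, grid)$mean - truth)), 1e-2)

  # full roster includes piecewise-constant trees; still close after
  # CV-RMSE down-weighting
  fit_all <- fit_ensemble(obs, lower = 0, upper = 1, seed = 1)
  expect_lt(max(abs(predict(fit_all, grid)$mean - truth)), 0.15)
  expect_gt(sum(fit_all$weights[fit_all$members_kind %in% c("gp", "ridge")]),
            0.5)
})

test_that("softmax weighting is symmetric under equal CV-RMSE", {
  rmse <- c(0.4, 0.4)
  tau <- median(rmse)
  w <- exp(-rmse / tau); w <- w / sum(w)
  expect_equal(w, c(0.5, 0.5))
})

test_that("predictive variance is non-negative over random queries", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    X <- matrix(runif(n * 3), n, 3)
    y <- rnorm(n)
    obs <- observation_set(X, y, mode = "yield_proxy")
    fit <- fit_ensemble(obs, lower = rep(0, 3), upper = rep(1, 3),
                        seed = rep)
    Xq <- matrix(runif(600), 200, 3)
    expect_true(all(predict(fit, Xq)$var >= 0))
  }
})

test_that("degenerate constant response falls back with a warning", {
  obs <- observation_set(matrix(runif(10), 5, 2), rep(2, 5))
  expect_warning(fit <- fit_ensemble(obs, lower = c(0, 0), upper = c(1, 1)),
                 "degenerate")
  p <- predict(fit, matrix(0.5, 1, 2))
  expect_equal(p$mean, 2)
  expect_equal(p$var, 0)
})

test_that("fits and predictions are bit-stable under a fixed seed", {
  set.seed(77)
  X <- matrix(runif(60), 20, 3)
  y <- X %*% c(1, -1, 2) + rnorm(20, 0, 0.1)
  obs <- observation_set(X, as.vector(y), mode = "yield_proxy")
  f1 <- fit_ensemble(obs, lower = rep(0, 3), upper = rep(1, 3), seed = 5)
  f2 <- fit_ensemble(obs, lower = rep(0, 3), upper = rep(1, 3), seed = 5)
  Xq <- matrix(runif(30), 10, 3)
  expect_identical(predict(f1, Xq), predict(f2, Xq))
  expect_identical(f1$weights, f2$weights)
})

test_that("extrapolation outside the box is flagged", {
  obs <- observation_set(matrix(runif(20), 10, 2), runif(10))
  fit <- fit_ensemble(obs, lower = c(0, 0), upper = c(1, 1), seed = 1)
  p <- predict(fit, rbind(c(0.5, 0.5), c(1.5, 0.5)))
  expect_equal(p$extrapolated, c(FALSE, TRUE))
})

test_that("pooled R2 follows its definition", {
  y <- c(1, 2, 3, 4)
  expect_equal(medialearn:::r_squared(y, y), 1)
  expect_equal(medialearn:::r_squared(y, rep(mean(y), 4)), 0)
  expect_lt(medialearn:::r_squared(y, rev(y)), 0)
})

test_that("cross-validated R2 rises with sample size on a smooth target", {
  quad <- function(X) 4 * (X[, 1] - 0.5)^2 + X[, 2]
  r2s <- sapply(c(8, 16, 32), function(n) {
    set.seed(n)
    X <- matrix(runif(2 * n), n, 2)
    obs <- observation_set(X, quad(X), mode = "yield_proxy")
    cross_validated_r2(obs, lower = c(0, 0), upper = c(1, 1), seed = 2)
  })
  expect_true(all(diff(r2s) > 0) || r2s[3] > r2s[1])
  expect_gt(r2s[3], 0.5)
})

test_that("label-permuted responses carry no predictive power", {
  set.seed(4)
  hits <- 0
  for (s in 1:20) {
    X <- matrix(runif(120), 60, 2)
    y <- sample(X[, 1])  # response values detached from inputs
    obs <- observation_set(X, y, mode = "yield_proxy")
    r2 <- cross_validated_r2(obs, lower = c(0, 0), upper = c(1, 1),
                             seed = s, members = c("gp", "ridge"))
    if (r2 <= 0.1) hits <- hits + 1
  }
  expect_gte(hits, 18)  # 95%-style bound at small trial count
})

test_that("replicate groups never straddle folds", {
  groups <- rep(letters[1:6], each = 3)
  fl <- medialearn:::grouped_folds(groups, k = 3, seed = 1)
  split_tab <- table(groups, fl$fold)
  expect_true(all(rowSums(split_tab > 0) == 1))
})
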