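# orthogonal standardized design: columns mean 0, sample sd 1, mutually
# orthogonal, so the lasso solution has the soft-thresholding closed form
orthogonal_design <- function(n, p, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n))))[, 2:(p + 1), drop = FALSE]
  apply(Q, 2, function(col) (col - mean(col)) / sd(col))
}

test_that("nodewise lasso matches the soft-thresholding closed form on an orthogonal design", {
  n <- 200
  X <- orthogonal_design(n, 2, seed = 8)
  set.seed(9)
  y <- as.numeric(0.5 * X[, 1] - 0.2 * X[, 2] + rnorm(n))
  d <- mixed_data(cbind(y = y, a = X[, 1], b = X[, 2]),
                  rep("continuous", 3))
  ys <- (y - mean(y)) / sd(y)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  m <- mean(X[, 1]^2)  # = (n-1)/n for sd-standardized columns
  for (lam in c(0.02, 0.1, 0.3)) {
    r <- as.numeric(crossprod(X, ys)) / n
    expect_equal(as.numeric(nodewise_fit(d, "y", lam)), soft(r, lam) / m,
                 tolerance = 1e-6)
  }
})

test_that("nodewise lasso at lambda 0 equals ordinary least squares", {
  set.seed(21)
  n <- 400
  X <- matrix(rnorm(n * 4), n)
  y <- as.numeric(X %*% c(0.5, -0.3, 0, 0.2) + rnorm(n))
  d <- mixed_data(cbind(y = y, a = X[, 1], b = X[, 2], c = X[, 3],
                        e = X[, 4]), rep("continuous", 5))
  Xs <- apply(X, 2, function(col) (col - mean(col)) / sd(col))
  ys <- (y - mean(y)) / sd(y)
  ols <- unname(coef(lm(ys ~ Xs))[-1])
  expect_equal(as.numeric(nodewise_fit(d, "y", 0)), ols, tolerance = 1e-5)
})

test_that("a lambda at or above the gradient bound shrinks every coefficient to zero", {
  set.seed(33)
  n <- 300
  vals <- cbind(y = rnorm(n), a = rnorm(n), b = rbinom(n, 1, 0.4))
  d <- mixed_data(vals, c("continuous", "continuous", "binary"))
  for (nd in c("y", "b")) {
    lmax <- max(lambda_grid(d, nd))
    expect_true(all(nodewise_fit(d, nd, lmax + 1e-12) == 0))
    expect_true(all(nodewise_fit(d, nd, 10) == 0))
  }
  expect_error(nodewise_fit(d, "y", -0.1), "non-negative")
  expect_error(nodewise_fit(d, "zz", 0.1), "unknown node")
})

test_that("both penalized solvers agree with an independent lasso implementation", {
  library(glmnet)
  set.seed(14)
  n <- 500
  X <- matrix(rnorm(n * 5), n)
  Xb <- cbind(X[, 1:4], rbinom(n, 1, 0.5))
  y <- as.numeric(Xb %*% c(0.4, -0.3, 0, 0.2, 0.5) + rnorm(n))
  yb <- rbinom(n, 1, plogis(0.8 * Xb[, 1] - 0.6 * Xb[, 5]))
  vals <- cbind(y = y, z = yb, a = Xb[, 1], b = Xb[, 2], c = Xb[, 3],
                e = Xb[, 4], f = Xb[, 5])
  d <- mixed_data(vals, c("continuous", "binary", rep("continuous", 4),
                          "binary"))
  std <- function(M, cont) {
    for (j in cont) M[, j] <- (M[, j] - mean(M[, j])) / sd(M[, j])
    M
  }
  for (lam in c(0.01, 0.05)) {
    Xp <- std(vals[, -1], 2:5)
    ref <- glmnet(Xp, (y - mean(y)) / sd(y), lambda = lam,
                  standardize = FALSE, thresh = 1e-12)
    expect_equal(as.numeric(nodewise_fit(d, "y", lam)),
                 as.numeric(coef(ref))[-1], tolerance = 1e-6)
    Xp2 <- std(vals[, -2], c(3, 4, 5, 6) - 1)
    ref2 <- glmnet(Xp2, yb, family = "binomial", lambda = lam,
                   standardize = FALSE, thresh = 1e-12)
    # logistic solutions can differ at a knife-edge coefficient whose
    # penalized objective is flat; compare coefficients loosely and the
    # achieved objective tightly
    mine <- nodewise_fit(d, "z", lam)
    gref <- as.numeric(coef(ref2))
    expect_lt(max(abs(as.numeric(mine) - gref[-1])), 2e-3)
    obj <- function(b0, b) {
      eta <- b0 + Xp2 %*% b
      -mean(yb * eta - log(1 + exp(eta))) + lam * sum(abs(b))
    }
    expect_lt(abs(obj(attr(mine, "intercept"), as.numeric(mine)) -
                    obj(gref[1], gref[-1])), 1e-6)
  }
})

test_that("EBIC selection matches an exhaustive per-lambda evaluation", {
  library(glmnet)
  set.seed(55)
  n <- 400
  X <- matrix(rnorm(n * 3), n)
  y <- as.numeric(0.4 * X[, 1] + rnorm(n))
  d <- mixed_data(cbind(y = y, a = X[, 1], b = X[, 2], c = X[, 3]),
                  rep("continuous", 4))
  grid <- lambda_grid(d, "y", nlambda = 20)
  # oracle: refit every grid value independently, recompute the criterion
  Xs <- apply(X, 2, function(col) (col - mean(col)) / sd(col))
  ys <- (y - mean(y)) / sd(y)
  for (gamma in c(0, 0.25)) {
    crit <- sapply(grid, function(lam) {
      b <- as.numeric(coef(glmnet(Xs, ys, lambda = lam, standardize = FALSE,
                                  thresh = 1e-12)))
      rss <- sum((ys - b[1] - Xs %*% b[-1])^2)
      df <- sum(b[-1] != 0)
      n * log(2 * pi * rss / n) + n + df * log(n) + 2 * gamma * df * log(3)
    })
    best <- grid[which(crit <= min(crit) + 1e-9)]
    expect_equal(as.numeric(select_lambda(d, "y", gamma = gamma,
                                          lambda_grid = grid)),
                 min(best), tolerance = 1e-10)
  }
  expect_error(select_lambda(d, "y", lambda_grid = numeric(0)), "empty")
})

test_that("EBIC picks the empty model on pure noise and keeps a strong predictor", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    n <- 500
    vals <- matrix(rnorm(n * 5), n,
                   dimnames = list(NULL, c("y", "a", "b", "c", "e")))
    d <- mixed_data(vals, rep("continuous", 5))
    lam <- select_lambda(d, "y")
    expect_true(all(nodewise_fit(d, "y", as.numeric(lam)) == 0))

    vals2 <- vals
    vals2[, "y"] <- 0.5 * vals[, "a"] + rnorm(n)
    d2 <- mixed_data(vals2, rep("continuous", 5))
    lam2 <- select_lambda(d2, "y")
    expect_gt(abs(nodewise_fit(d2, "y", as.numeric(lam2))[["a"]]), 0)
  }
})

test_that("edge aggregation follows the AND/OR conventions", {
  fits <- list(
    j = c(k = 0.2, l = 0),
    k = c(j = 0.3, l = 0.1),
    l = c(j = 0, k = 0)
  )
  net_and <- aggregate_edges(fits, rule = "AND")
  expect_equal(net_and$weights["j", "k"], 0.25)  # mean(|0.2|, |0.3|)
  expect_equal(net_and$signs["j", "k"], 1)
  expect_equal(net_and$weights["k", "l"], 0)     # one-sided -> dropped
  net_or <- aggregate_edges(fits, rule = "OR")
  expect_equal(net_or$weights["k", "l"], 0.05)   # mean(|0.1|, 0)

  conflicted <- list(j = c(k = 0.2), k = c(j = -0.3))
  net_c <- aggregate_edges(conflicted, rule = "AND")
  expect_equal(net_c$weights["j", "k"], 0.25)
  expect_true(is.na(net_c$signs["j", "k"]))

  empty <- aggregate_edges(list(j = c(k = 0, l = 0), k = c(j = 0, l = 0),
                                l = c(j = 0, k = 0)))
  expect_equal(network_summary(empty)$edge_count, 0)
  expect_error(aggregate_edges(list(j = c(k = 0.1), k = numeric(0))),
               "lacks coefficient")
})

test_that("the AND-rule edge set is contained in the OR-rule edge set", {
  d <- sample_mgm(recovery_graph(), 800, burn_in = 300, thin = 2, seed = 17)
  net_and <- estimate_network(d, rule = "AND")
  net_or <- estimate_network(d, rule = "OR")
  expect_true(all(net_or$weights[net_and$weights > 0] > 0))
})

test_that("the standardized-scale network is invariant to rescaling a continuous column", {
  d <- sample_mgm(four_node_graph(0.3, 0.2), 600, burn_in = 300, thin = 2,
                  seed = 23)
  net1 <- estimate_network(d)
  vals2 <- d$values
  vals2[, "x1"] <- vals2[, "x1"] * 1000
  net2 <- estimate_network(mixed_data(vals2, d$types))
  expect_lt(max(abs(net1$weights - net2$weights)), 1e-8)
})

test_that("predictability behaves as variance explained / normalized accuracy", {
  set.seed(31)
  n <- 10000
  a <- rnorm(n)
  twin <- a
  noisy <- a + rnorm(n)  # signal and noise of equal variance -> R^2 = 0.5
  d <- mixed_data(cbind(a = a, twin = twin, noisy = noisy),
                  rep("continuous", 3))
  pr <- predictability(d, list(a = character(0), twin = "a", noisy = "a"))
  expect_equal(pr[["a"]], 0)
  expect_equal(pr[["twin"]], 1, tolerance = 1e-10)
  expect_equal(pr[["noisy"]], 0.5, tolerance = 0.02)

  yb <- as.numeric(a + rnorm(n, sd = 0.3) > 0)
  db <- mixed_data(cbind(z = yb, a = a), c("binary", "continuous"))
  prb <- predictability(db, list(z = "a", a = "z"))
  expect_gt(prb[["z"]], 0.5)
  expect_lte(prb[["z"]], 1)

  # degenerate constant node: flagged, predictability undefined
  dz <- mixed_data(cbind(z = rep(0, 30), w = rnorm(30)),
                   c("binary", "continuous"))
  expect_warning(pz <- predictability(dz, list(z = "w", w = character(0))),
                 "degenerate")
  expect_true(is.na(pz[["z"]]))
})

test_that("estimated networks are symmetric with zero diagonal", {
  d <- sample_mgm(recovery_graph(), 700, burn_in = 300, thin = 2, seed = 41)
  net <- estimate_network(d)
  expect_equal(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
  expect_true(all(net$weights >= 0))
  expect_true(all(net$predictability >= 0 & net$predictability <= 1))
})
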