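# brute-force evaluation of the sandwich covariance: bread and meat assembled
# cluster by cluster with dense matrix arithmetic, gaussian identity family
oracle_sandwich_gaussian <- function(y, x, beta, Rwork) {
  p <- 2L
  bread <- matrix(0, p, p); meat <- matrix(0, p, p)
  for (k in seq_len(nrow(y))) {
    obs <- which(!is.na(y[k, ]))
    X <- cbind(1, x[k, obs])
    V <- Rwork[obs, obs, drop = FALSE]  # phi cancels in the sandwich
    Vi <- solve(V)
    r <- y[k, obs] - X %*% beta
    bread <- bread + t(X) %*% Vi %*% X
    meat <- meat + t(X) %*% Vi %*% r %*% t(r) %*% Vi %*% X
  }
  solve(bread) %*% meat %*% solve(bread)
}

test_that("independence GEE collapses to OLS and logistic MLE", {
  st <- default_structure()
  d <- small_gaussian_data(K = 80)
  pins <- zero_pins(st)
  fit <- fit_gee(d$y, d$x, st, family = "gaussian", pinned = pins)
  ols <- lm(as.vector(d$y) ~ as.vector(d$x))
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$phi,
               sum(residuals(ols)^2) / (length(d$y) - 2), tolerance = 1e-8)

  set.seed(100)
  yb <- matrix(rbinom(80 * 4, 1, plogis(-0.2 + 0.7 * d$x)), 80, 4)
  fitb <- fit_gee(yb, d$x, st, family = "binomial", pinned = pins)
  mle <- glm(as.vector(yb) ~ as.vector(d$x), family = binomial)
  expect_equal(unname(fitb$beta), unname(coef(mle)), tolerance = 1e-8)
  expect_equal(fitb$phi, 1)
})

test_that("sandwich equals HC0 for clusters of size one", {
  st <- default_structure()
  set.seed(101)
  K <- 120
  y <- matrix(NA_real_, K, 4)
  x <- matrix(0, K, 4)
  x[, 1] <- rbinom(K, 1, 0.5)
  y[, 1] <- rnorm(K, 1 + 0.4 * x[, 1], 0.7 + 0.6 * x[, 1])  # heteroskedastic
  # size-1 clusters leave every correlation class without pairs (warned)
  fit <- suppressWarnings(fit_gee(y, x, st, family = "gaussian"))
  X <- cbind(1, x[, 1]); r <- y[, 1] - X %*% fit$beta
  hc0 <- solve(crossprod(X)) %*% crossprod(X * as.numeric(r)) %*%
    solve(crossprod(X))
  expect_equal(unname(fit$vbeta), unname(hc0), tolerance = 1e-8)
})

test_that("dispersion estimator follows its formula", {
  expect_equal(estimate_phi(c(1, 1, 1, 1), p = 2), 2)
  expect_equal(estimate_phi(rep(0, 10), p = 2), 0)
  expect_error(estimate_phi(c(1, 1), p = 2), "exceed")
  # NA cells are dropped but total_obs can be supplied explicitly
  expect_equal(estimate_phi(c(1, NA, 1), total_obs = 2, p = 1), 2)
})

test_that("correlation moment estimator equals explicit pair enumeration", {
  st <- default_structure()
  set.seed(102)
  e <- matrix(rnorm(12), 3, 4)
  e[2, 4] <- NA  # one missing cell
  phi <- 1.3; p <- 2
  rho <- suppressWarnings(estimate_rho(e, st, phi = phi, p = p))
  # oracle: loop every cluster, every unordered cell pair, classify by label
  num <- c("D,i" = 0, "I,D" = 0, "I,i" = 0)
  cnt <- num
  for (k in 1:3) for (a in 1:3) for (b in (a + 1):4) {
    if (is.na(e[k, a]) || is.na(e[k, b])) next
    cl <- st$labels[a, b]
    num[cl] <- num[cl] + e[k, a] * e[k, b]
    cnt[cl] <- cnt[cl] + 1
  }
  expected <- num / ((cnt - p) * phi)
  expect_equal(rho[names(expected)], expected, tolerance = 1e-12)
})

test_that("correlation estimates are clipped and pinned classes held fixed", {
  st <- default_structure()
  e <- matrix(rep(c(2, 2, -2, -2), 8), 8, 4, byrow = TRUE)
  rho <- estimate_rho(e, st, phi = 0.1, p = 1)
  expect_true(all(abs(rho) <= 0.99))
  rho2 <- estimate_rho(e, st, phi = 1, p = 1, pinned = c("I,i" = 0.25))
  expect_equal(unname(rho2["I,i"]), 0.25)
})

test_that("sandwich matches brute-force evaluation on a structured fit", {
  st <- default_structure()
  set.seed(103)
  K <- 50
  x <- matrix(rep(sample(0:1, K, TRUE), 4), K, 4)
  y <- matrix(rnorm(K * 4, 0.5 + 0.3 * x), K, 4)
  y[1:10, 4] <- NA  # unequal cluster sizes
  fit <- fit_gee(y, x, st, family = "gaussian")
  Rwork <- realize_correlation(st, fit$rho)
  oracle <- oracle_sandwich_gaussian(y, x, fit$beta, Rwork)
  expect_equal(unname(fit$vbeta), unname(oracle), tolerance = 1e-8)
  expect_true(all(eigen(fit$vbeta, symmetric = TRUE,
                        only.values = TRUE)$values >= -1e-12))
})

test_that("the estimating equation is solved at the reported coefficients", {
  # fixed-point property: the weighted score at beta-hat is numerically zero
  st <- default_structure()
  set.seed(104)
  K <- 60
  x <- matrix(rbinom(K * 4, 1, 0.5), K, 4)
  y <- matrix(rbinom(K * 4, 1, plogis(0.2 + 0.5 * x)), K, 4)
  fit <- fit_gee(y, x, st, family = "binomial")
  expect_true(fit$converged)
  Rwork <- realize_correlation(st, fit$rho)
  U <- c(0, 0)
  for (k in seq_len(K)) {
    X <- cbind(1, x[k, ])
    mu <- plogis(X %*% fit$beta)
    A <- diag(as.numeric(mu * (1 - mu)))
    V <- sqrt(A) %*% Rwork %*% sqrt(A)
    D <- A %*% X
    U <- U + as.numeric(t(D) %*% solve(V, y[k, ] - mu))
  }
  expect_lt(max(abs(U)), 1e-4 * K)
})

test_that("Wald tests collapse correctly", {
  st <- default_structure()
  d <- small_gaussian_data(K = 70)
  fit <- fit_gee(d$y, d$x, st, family = "gaussian")
  # C beta = c exactly -> W = 0, p = 1
  w0 <- wald_test(fit, diag(2), c = unname(fit$beta))
  expect_equal(w0$statistic, 0, tolerance = 1e-12)
  expect_equal(w0$p_value, 1)
  # scalar 1-df collapse
  w1 <- wald_test(fit, c(0, 1), c = 0.2)
  expect_equal(w1$statistic,
               (fit$beta[[2]] - 0.2)^2 / fit$vbeta[2, 2], tolerance = 1e-12)
  expect_equal(w1$df, 1L)
  expect_error(wald_test(fit, matrix(c(1, 0, 2, 0), 2, 2, byrow = TRUE)),
               "rank")
})

test_that("rank-deficient designs and bad inputs are rejected", {
  st <- default_structure()
  d <- small_gaussian_data(K = 40)
  expect_error(fit_gee(d$y, list(a = d$x, b = d$x), st, family = "gaussian"),
               "rank")
  expect_error(fit_gee(d$y[, 1:3], d$x[, 1:3], st, family = "gaussian"),
               "dimension")
  xna <- d$x; xna[1, 1] <- NA
  expect_error(fit_gee(d$y, xna, st, family = "gaussian"), "NA")
})
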