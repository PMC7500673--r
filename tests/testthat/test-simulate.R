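test_that("latent correlation solver matches the arcsine closed form", {
  expect_identical(solve_latent_correlation(0.3, 0.7, 0), 0)
  # at p = 0.5 the binary correlation is (2/pi) asin(r)
  for (rho in c(-0.4, 0.1, 0.3, 0.5))
    expect_equal(solve_latent_correlation(0.5, 0.5, rho),
                 sin(pi * rho / 2), tolerance = 1e-6)
  # infeasible target beyond the Frechet bound errors with the bound named
  expect_error(solve_latent_correlation(0.2, 0.8, 0.5), "attainable range")
})

test_that("correlated Bernoulli draws match their target moments", {
  set.seed(300)
  st <- default_structure()
  corr <- realize_correlation(st, c("D,i" = 0.5, "I,D" = 0.5))
  n <- 1e5
  yb <- simulate_correlated_bernoulli(rep(0.5, 4), corr, n)
  expect_equal(unname(colMeans(yb)), rep(0.5, 4), tolerance = 0.01)
  emp <- cor(yb)
  expect_equal(emp[1, 2], 0.5, tolerance = 0.01)
  expect_equal(emp[1, 3], 0.5, tolerance = 0.01)
  expect_equal(emp[1, 4], 0, tolerance = 0.01)
  # independent case
  y0 <- simulate_correlated_bernoulli(c(0.3, 0.6), diag(2), 1e5)
  expect_lt(abs(cor(y0)[1, 2]), 0.01)
  expect_equal(unname(colMeans(y0)), c(0.3, 0.6), tolerance = 0.01)
  # heterogeneous means by row pattern
  pm <- matrix(rep(c(0.4, 0.6), each = 2), 4, 4)
  yh <- simulate_correlated_bernoulli(pm[rep(1:4, length.out = 2e4), ],
                                      corr)
  expect_equal(mean(yh[seq(1, 2e4, 4), 1]), 0.4, tolerance = 0.02)
})

test_that("truncated normal draws match their target moments", {
  set.seed(301)
  z <- simulate_truncated_mvn(rep(3, 4), diag(4), 1e5)
  expect_true(all(z > 0))
  expect_equal(attr(z, "acceptance"), pnorm(3)^4, tolerance = 0.005)
  expect_equal(unname(colMeans(z)), rep(3, 4), tolerance = 0.02)
  st <- default_structure()
  sig <- realize_correlation(st, c("D,i" = -0.3, "I,D" = -0.3))
  z2 <- simulate_truncated_mvn(rep(3, 4), sig, 1e5)
  expect_equal(cor(z2)[1, 2], -0.3, tolerance = 0.01)
  expect_equal(cor(z2)[1, 3], -0.3, tolerance = 0.01)
  # hopeless truncation is refused
  expect_error(simulate_truncated_mvn(rep(-3, 4), diag(4), 1000),
               "acceptance rate")
})

test_that("zero-inflated draws combine the parts independently", {
  set.seed(302)
  sc <- mtlc_scenario(K = 2e4, beta0 = 0, betap = 0)
  d <- simulate_zero_inflated(sc)
  expect_equal(mean(d$y == 0), 0.5, tolerance = 0.01)
  # prevalence indicator and latent abundance are independent
  for (j in 1:4)
    expect_lt(abs(cor(d$y0[, j], d$z[, j])), 0.02)
  # observed positive values equal 10^-z at prevalent cells
  pos <- d$y > 0
  expect_equal(d$y[pos], 10^(-d$z[pos]), tolerance = 1e-12)
  # cluster-constant predictor
  expect_true(all(d$x[, 1] == d$x[, 2]))
  expect_setequal(unique(as.vector(d$x)), c(-1, 1))
})

test_that("the per-cell predictor law remains available", {
  set.seed(303)
  sc <- mtlc_scenario(K = 500, x_law = "cell_bernoulli")
  d <- simulate_zero_inflated(sc)
  expect_setequal(sort(unique(as.vector(d$x))), c(0, 1))
  expect_gt(var(as.numeric(d$x[, 1] != d$x[, 2])), 0)
})

test_that("the study harness aggregates models and is reproducible", {
  sc <- mtlc_scenario(K = 150, beta0 = 0.3, betap = 0.2)
  models <- c("GEE0", "GEEplus", "MTLC", "2P_ind", "1P_GEE", "1P_ind")
  rep1 <- run_simulation_study(sc, models = models, reps = 4, seed = 77)
  rep2 <- run_simulation_study(sc, models = models, reps = 4, seed = 77)
  expect_identical(rep1$models, rep2$models)
  expect_equal(rep1$reps_used, 4L)
  for (m in models) {
    e <- rep1$models[[m]]
    expect_true(e$rejection_rate >= 0 && e$rejection_rate <= 1)
  }
  expect_named(rep1$models$MTLC$rho0, default_structure()$classes)
  expect_true(all(is.finite(rep1$models$MTLC$pearson0)))
  # misspecified structures pin the dropped classes at zero
  rep3 <- run_simulation_study(sc, models = c("MTLC_otu_ind",
                                              "MTLC_time_ind"),
                               reps = 2, seed = 5)
  expect_equal(unname(rep3$models$MTLC_otu_ind$rho0[c("I,D", "I,i")]),
               c(0, 0))
  expect_equal(unname(rep3$models$MTLC_time_ind$rho0[c("D,i", "I,i")]),
               c(0, 0))
})

test_that("the mixed-model comparator runs when lme4 is present", {
  skip_if_not_installed("lme4")
  sc <- mtlc_scenario(K = 120)
  rep1 <- run_simulation_study(sc, models = "1P_RE", reps = 2, seed = 3)
  expect_true(is.finite(rep1$models$`1P_RE`$beta$mean))
  expect_true(rep1$models$`1P_RE`$rejection_rate >= 0)
})
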