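# cache for solved latent correlations (keyed on pa, pb, target)
.latent_cache <- new.env(parent = emptyenv())

# P(Z1 <= a, Z2 <= b) for standard bivariate normal with correlation r,
# by one-dimensional quadrature over the conditional distribution
bvn_cdf <- function(a, b, r) {
  if (abs(r) < 1e-14) return(stats::pnorm(a) * stats::pnorm(b))
  if (r >= 1 - 1e-12) return(stats::pnorm(min(a, b)))
  if (r <= -1 + 1e-12) return(max(0, stats::pnorm(a) + stats::pnorm(b) - 1))
  s <- sqrt(1 - r^2)
  stats::integrate(function(t) stats::dnorm(t) * stats::pnorm((b - r * t) / s),
                   lower = -Inf, upper = a, abs.tol = 1e-12)$value
}

#' Latent Gaussian correlation for a target binary correlation
#'
#' Finds the correlation `r` of a standard bivariate normal such that
#' thresholding its coordinates at the quantiles of `pa` and `pb` yields
#' binary variables with product-moment correlation `target_rho`
#' (Gaussian-copula dichotomization). Solved by monotone bisection on the
#' bivariate normal rectangle probability to 1e-8; results are cached.
#'
#' @param pa,pb marginal success probabilities in (0, 1).
#' @param target_rho desired product-moment correlation of the two binaries;
#'   must lie strictly inside the Frechet-attainable range for `(pa, pb)`.
#' @return The latent correlation `r` in (-1, 1).
#' @export
solve_latent_correlation <- function(pa, pb, target_rho) {
  stopifnot(pa > 0, pa < 1, pb > 0, pb < 1, is.finite(target_rho))
  if (target_rho == 0) return(0)
  key <- sprintf("%.12g|%.12g|%.12g", pa, pb, target_rho)
  hit <- .latent_cache[[key]]
  if (!is.null(hit)) return(hit)
  za <- stats::qnorm(pa); zb <- stats::qnorm(pb)
  sdprod <- sqrt(pa * (1 - pa) * pb * (1 - pb))
  corr_of <- function(r) (bvn_cdf(za, zb, r) - pa * pb) / sdprod
  up <- corr_of(1)   # comonotone bound: P11 = min(pa, pb)
  lo_b <- corr_of(-1)  # antimonotone bound: P11 = max(0, pa + pb - 1)
  if (target_rho >= up || target_rho <= lo_b)
    stop(sprintf(
      "target correlation %.4f outside the attainable range (%.4f, %.4f) for margins (%.3f, %.3f)",
      target_rho, lo_b, up, pa, pb))
  lo <- -1; hi <- 1
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    val <- corr_of(mid)
    if (abs(val - target_rho) < 1e-8 * sdprod || (hi - lo) < 1e-12) break
    if (val < target_rho) lo <- mid else hi <- mid
  }
  r <- (lo + hi) / 2
  .latent_cache[[key]] <- r
  r
}

#' Simulate correlated Bernoulli vectors
#'
#' Draws binary vectors with given per-cell means and a given target
#' product-moment correlation matrix. The default (`method = "auto"`) uses
#' Gaussian-copula thresholding with pairwise latent correlations solved by
#' [solve_latent_correlation()]; when the required latent matrix is not
#' positive definite — which happens for jointly attainable targets near the
#' boundary of the feasible correlation region, where no Gaussian copula
#' exists — and `J` is small, it switches to an exact sampler that solves a
#' linear program for a joint probability mass function with the requested
#' first and second moments and samples from it directly.
#'
#' @param prob per-cell success probabilities: length-J vector or n x J
#'   matrix (rows with identical probabilities are grouped, so a small number
#'   of distinct rows — e.g. induced by a binary predictor — is fast).
#' @param corr J x J target correlation matrix of the binary variables.
#' @param n number of vectors (required when `prob` is a vector).
#' @param method `"auto"`, `"copula"` (always threshold, repairing an
#'   indefinite latent matrix with a warning) or `"exact"` (always solve the
#'   joint pmf; requires `J <= 12`).
#' @return n x J matrix of 0/1 values.
#' @export
simulate_correlated_bernoulli <- function(prob, corr, n = NULL,
                                          method = c("auto", "copula",
                                                     "exact")) {
  method <- match.arg(method)
  if (is.null(dim(prob))) {
    stopifnot(!is.null(n))
    prob <- matrix(prob, n, length(prob), byrow = TRUE)
  }
  n <- nrow(prob); J <- ncol(prob)
  stopifnot(all(prob > 0 & prob < 1), all(dim(corr) == c(J, J)))
  out <- matrix(0L, n, J)
  key <- apply(prob, 1L, paste, collapse = "|")
  for (rows in split(seq_len(n), key)) {
    p <- prob[rows[1L], ]
    m <- length(rows)
    lat <- diag(J)
    for (a in seq_len(J - 1L)) for (b in (a + 1L):J) {
      if (corr[a, b] != 0)
        lat[a, b] <- lat[b, a] <-
          solve_latent_correlation(p[a], p[b], corr[a, b])
    }
    lat_pd <- min(eigen(lat, symmetric = TRUE,
                        only.values = TRUE)$values) >= 1e-6
    use_exact <- method == "exact" ||
      (method == "auto" && !lat_pd && J <= 12L)
    if (use_exact) {
      q <- bernoulli_joint_pmf(p, corr)
      states <- attr(q, "states")
      out[rows, ] <- states[sample.int(length(q), m, replace = TRUE,
                                       prob = q), , drop = FALSE]
    } else {
      if (!lat_pd) {
        warning("latent correlation matrix indefinite; repaired (targets ",
                "only approximately attained)")
        lat <- pd_repair(lat)
      }
      z <- matrix(stats::rnorm(m * J), m, J) %*% chol(lat)
      thr <- stats::qnorm(p)
      out[rows, ] <- 1L * (z < matrix(thr, m, J, byrow = TRUE))
    }
  }
  out
}

# cache for solved joint pmfs
.pmf_cache <- new.env(parent = emptyenv())

# exact joint pmf of a multivariate Bernoulli with given means and
# product-moment correlations: a feasibility problem over the 2^J atom
# probabilities (equality-constrained on total mass and first and second
# moments), solved by alternating projections between the affine moment
# subspace and the nonnegative orthant; infeasible targets are detected by a
# non-vanishing residual
bernoulli_joint_pmf <- function(p, corr) {
  J <- length(p)
  if (J > 12L) stop("exact Bernoulli sampler limited to J <= 12")
  key <- paste(signif(c(p, corr[upper.tri(corr)]), 10), collapse = "|")
  hit <- .pmf_cache[[key]]
  if (!is.null(hit)) return(hit)
  states <- as.matrix(expand.grid(rep(list(0:1), J)))
  dimnames(states) <- NULL
  n_atom <- nrow(states)
  sd <- sqrt(p * (1 - p))
  cons <- list(rep(1, n_atom))  # total mass
  rhs <- 1
  for (a in seq_len(J)) {
    cons[[length(cons) + 1L]] <- states[, a]
    rhs <- c(rhs, p[a])
  }
  for (a in seq_len(J - 1L)) for (b in (a + 1L):J) {
    cons[[length(cons) + 1L]] <- states[, a] * states[, b]
    rhs <- c(rhs, corr[a, b] * sd[a] * sd[b] + p[a] * p[b])
  }
  A <- do.call(rbind, cons)
  # projection onto {q : Aq = rhs} uses the pseudo-inverse once
  AtAAt <- t(A) %*% solve(A %*% t(A))
  project_affine <- function(q) q - AtAAt %*% (A %*% q - rhs)
  q <- rep(1 / n_atom, n_atom)  # start at the uniform distribution
  for (it in seq_len(20000L)) {
    q_aff <- project_affine(q)
    q_new <- pmax(q_aff, 0)
    if (max(abs(q_new - q)) < 1e-12) { q <- q_new; break }
    q <- q_new
  }
  if (max(abs(A %*% q - rhs)) > 1e-7)
    stop("target correlations are not attainable by any joint Bernoulli ",
         "distribution with these margins (moment residual ",
         format(max(abs(A %*% q - rhs)), digits = 3), ")")
  q <- as.numeric(project_affine(q))
  q <- pmax(q, 0)
  q <- q / sum(q)
  attr(q, "states") <- states
  .pmf_cache[[key]] <- q
  q
}

#' Simulate a truncated multivariate normal (all coordinates positive)
#'
#' Vector-rejection sampling: whole vectors with any non-positive coordinate
#' are redrawn. When the per-vector truncation probability is small the
#' sample moments match the untruncated normal.
#'
#' @param mean length-J vector or n x J matrix of means.
#' @param sigma J x J positive-definite covariance matrix.
#' @param n number of vectors (required when `mean` is a vector).
#' @param max_tries error out if the acceptance rate makes the draw
#'   infeasible (acceptance below 1 percent).
#' @return n x J matrix of positive values, with attribute
#'   `acceptance` = accepted draws / proposed draws.
#' @export
simulate_truncated_mvn <- function(mean, sigma, n = NULL, max_tries = 1000L) {
  if (is.null(dim(mean))) {
    stopifnot(!is.null(n))
    mean <- matrix(mean, n, length(mean), byrow = TRUE)
  }
  n <- nrow(mean); J <- ncol(mean)
  stopifnot(all(dim(sigma) == c(J, J)))
  L <- chol(sigma)
  out <- matrix(NA_real_, n, J)
  pending <- seq_len(n)
  proposed <- 0L
  for (tries in seq_len(max_tries)) {
    m <- length(pending)
    z <- mean[pending, , drop = FALSE] +
      matrix(stats::rnorm(m * J), m, J) %*% L
    proposed <- proposed + m
    ok <- rowSums(z <= 0) == 0L
    out[pending[ok], ] <- z[ok, , drop = FALSE]
    pending <- pending[!ok]
    if (!length(pending)) break
    if (tries >= 10L && (n - length(pending)) / proposed < 0.01)
      stop("truncated-normal acceptance rate below 1%; increase the ",
           "intercept so the mass at non-positive values is negligible")
  }
  if (length(pending)) stop("truncated-normal sampling did not finish")
  attr(out, "acceptance") <- n / proposed
  out
}

#' Define a simulation scenario
#'
#' Encodes the generating model of the operating-characteristic study:
#' correlated Bernoulli prevalence with logit-linear means, truncated
#' multivariate normal -log10 abundances with identity-linear means, both on
#' one index-structured correlation matrix, combined multiplicatively into
#' zero-inflated outcomes. Defaults are the study's stated conditions: two
#' OTUs sharing one taxonomic class, two exchangeable time points, K = 1000
#' clusters, a per-cell Bernoulli(0.5) binary predictor, prevalence intercept
#' 0, positive-part intercept 3 and unit SD (so truncation at 0 is
#' negligible), and correlations `rho(D,i) = rho(I,D) = 0.3, rho(I,i) = 0`
#' in both parts.
#'
#' @param K number of clusters.
#' @param beta0,betap predictor effects on the prevalence part and the
#'   positive (-log10 abundance) part.
#' @param alpha0,alphap intercepts of the two parts.
#' @param sigma positive-part SD.
#' @param rho0,rhop named per-class generating correlations of the Bernoulli
#'   and normal parts.
#' @param x_law law of the binary predictor: `"cluster_pm1"` (default) draws
#'   one -1/+1 value per cluster, shared by all its cells; `"cell_bernoulli"`
#'   draws an independent 0/1 value per cell. The cluster-level law is the
#'   one whose closed-form operating characteristics agree with the reported
#'   comparator behaviour (naive two-part/one-part type I error inflated to
#'   ~0.12 by the design effect 1'R1/J = 1.6, structured-GEE power driven by
#'   1'R^{-1}1); a per-cell predictor makes the naive variances accidentally
#'   valid and shows no inflation at all.
#' @param gamma,omega structures defining the correlation pattern; defaults
#'   to 2 OTUs (single class `I`) and 2 exchangeable time points.
#' @return List of class `mtlc_scenario` (includes the built
#'   `integrative_structure` and realized generating matrices).
#' @export
mtlc_scenario <- function(K = 1000, beta0 = 0, betap = 0,
                          alpha0 = 0, alphap = 3, sigma = 1,
                          rho0 = c("D,i" = 0.3, "I,D" = 0.3, "I,i" = 0),
                          rhop = rho0,
                          x_law = c("cluster_pm1", "cell_bernoulli"),
                          gamma = NULL, omega = NULL) {
  x_law <- match.arg(x_law)
  if (is.null(gamma))
    gamma <- structure_matrix(matrix(c("D", "I", "I", "D"), 2, 2),
                              kind = "taxonomic")
  if (is.null(omega)) omega <- time_structure(2)
  structure_ <- build_integrative_structure(gamma, omega)
  stopifnot(all(abs(rho0) < 1), all(abs(rhop) < 1), sigma > 0, K >= 2)
  list2 <- list(K = as.integer(K), beta0 = beta0, betap = betap,
                alpha0 = alpha0, alphap = alphap, sigma = sigma,
                rho0 = rho0, rhop = rhop, x_law = x_law,
                gamma = gamma, omega = omega, structure = structure_,
                R0 = realize_correlation(structure_, rho0),
                Rp = realize_correlation(structure_, rhop))
  class(list2) <- "mtlc_scenario"
  list2
}

#' Draw one zero-inflated dataset from a scenario
#'
#' The binary predictor X is drawn according to the scenario's `x_law`
#' (cluster-constant -1/+1 by default); the prevalence grid and the positive
#' grid are drawn independently (so the positive part observed at prevalent
#' cells has the same law as the full normal part); the observed relative
#' abundance is `10^-z` where prevalent, 0 otherwise.
#'
#' @param scenario an `mtlc_scenario`.
#' @return List with `y` (K x J relative abundances), `y0` (prevalence grid),
#'   `z` (full -log10 abundance grid), `x` (predictor grid) and `scenario`.
#' @export
simulate_zero_inflated <- function(scenario) {
  stopifnot(inherits(scenario, "mtlc_scenario"))
  K <- scenario$K; J <- scenario$structure$dim
  x <- if (identical(scenario$x_law, "cell_bernoulli"))
    matrix(stats::rbinom(K * J, 1L, 0.5), K, J)
  else
    matrix(rep(sample(c(-1, 1), K, replace = TRUE), J), K, J)
  p0 <- stats::plogis(scenario$alpha0 + scenario$beta0 * x)
  y0 <- simulate_correlated_bernoulli(p0, scenario$R0)
  z <- simulate_truncated_mvn(scenario$alphap + scenario$betap * x,
                              scenario$sigma^2 * scenario$Rp)
  y <- ifelse(y0 == 1L, 10^(-z), 0)
  list(y = y, y0 = y0, z = z, x = x, scenario = scenario)
}

# pins that make a structure treat OTUs (or time points) as independent:
# every class whose taxonomic (repeat) index is not D is fixed at zero
misspecified_pins <- function(structure, drop = c("otu", "time")) {
  drop <- match.arg(drop)
  parts <- strsplit(structure$classes, ",", fixed = TRUE)
  hit <- vapply(parts, function(pp)
    if (drop == "otu") pp[1L] != "D" else pp[2L] != "D", logical(1))
  stats::setNames(rep(0, sum(hit)), structure$classes[hit])
}

# naive (model-based variance) pooled fits for the independence comparators
naive_glm_test <- function(yv, xv, family) {
  X <- cbind(1, xv)
  if (family == "binomial") {
    fit <- stats::glm.fit(X, yv, family = stats::binomial())
    disp <- 1
  } else {
    fit <- stats::glm.fit(X, yv, family = stats::gaussian())
    disp <- sum(fit$residuals^2 * fit$weights) / fit$df.residual
  }
  # model-based covariance (X' W X)^{-1} * dispersion: clustering ignored
  vc <- solve(crossprod(X * sqrt(fit$weights))) * disp
  beta <- fit$coefficients[2L]
  z2 <- beta^2 / vc[2L, 2L]
  list(beta = beta, p_value = stats::pchisq(z2, 1, lower.tail = FALSE))
}

#' Run a Monte-Carlo operating-characteristic study
#'
#' Replicates: draw a dataset from `scenario`, fit the requested models,
#' record coefficient estimates, test decisions at level `alpha` and (for the
#' structured fits) estimated correlation coefficients; aggregate across
#' replications. Models: `GEE0` / `GEEplus` (single-part GEEs with the full
#' structure), `MTLC` (two-part, Cauchy-combined), `MTLC_otu_ind` /
#' `MTLC_time_ind` (two-part with the working structure misspecified as
#' OTU- or time-independent), `2P_ind` (logistic + linear fits ignoring all
#' correlation, naive variances), `1P_GEE` (one Gaussian GEE on -log10
#' abundances with zeros replaced by `zero_replacement`), `1P_ind` (one naive
#' linear model on the same outcome) and `1P_RE` (random-intercept linear
#' mixed model via lme4, if installed).
#'
#' @param scenario an `mtlc_scenario`.
#' @param models character vector of model names (see Details).
#' @param reps number of Monte-Carlo replications.
#' @param seed integer seed; per-replication child seeds are derived from it.
#' @param alpha test level for the rejection rates.
#' @param zero_replacement value standing in for `-log10 0` in the one-part
#'   models.
#' @param keep_records keep the per-replication records in the report (field
#'   `records`), e.g. for per-rep dispersion of the correlation estimates.
#' @return Object of class `mtlc_sim_report`: per model, mean estimates with
#'   2.5/97.5 percentiles, rejection rate, mean estimated correlations,
#'   Pearson-correlation benchmarks per class, failed-replication count.
#' @export
run_simulation_study <- function(scenario,
                                 models = "MTLC",
                                 reps = 1000L, seed = NULL, alpha = 0.05,
                                 zero_replacement = 6,
                                 keep_records = FALSE) {
  all_models <- c("GEE0", "GEEplus", "MTLC", "MTLC_otu_ind", "MTLC_time_ind",
                  "2P_ind", "1P_GEE", "1P_ind", "1P_RE")
  stopifnot(all(models %in% all_models), reps >= 1)
  if ("1P_RE" %in% models && !requireNamespace("lme4", quietly = TRUE))
    stop("model 1P_RE requires the lme4 package")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(2147483646L, reps)
  recs <- vector("list", reps)
  n_fail <- 0L
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    rec <- tryCatch(
      simulate_one_rep(scenario, models, alpha, zero_replacement),
      error = function(e) NULL)
    if (is.null(rec)) n_fail <- n_fail + 1L else recs[[r]] <- rec
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  report <- aggregate_sim_records(recs, models)
  if (keep_records) report$records <- recs
  report$reps <- reps
  report$reps_used <- length(recs)
  report$n_fail <- n_fail
  report$seed <- seed
  report$alpha <- alpha
  report$zero_replacement <- zero_replacement
  report$scenario <- scenario[c("K", "beta0", "betap", "alpha0", "alphap",
                                "sigma", "rho0", "rhop")]
  class(report) <- "mtlc_sim_report"
  report
}

simulate_one_rep <- function(scenario, models, alpha, zero_replacement) {
  d <- simulate_zero_inflated(scenario)
  st <- scenario$structure
  rec <- list()
  two_part <- intersect(models, c("GEE0", "GEEplus", "MTLC"))
  if (length(two_part)) {
    fit <- fit_mtlc(d$y, d$x, gamma = scenario$gamma, omega = scenario$omega,
                    transform = "neglog10")
    if ("GEE0" %in% models)
      rec$GEE0 <- list(beta0 = unname(fit$fit0$beta[2L]),
                       rho0 = fit$fit0$rho,
                       reject = fit$wald0$p_value < alpha)
    if ("GEEplus" %in% models)
      rec$GEEplus <- list(betap = unname(fit$fitp$beta[2L]),
                          rhop = fit$fitp$rho,
                          reject = fit$waldp$p_value < alpha)
    if ("MTLC" %in% models)
      rec$MTLC <- list(beta0 = unname(fit$fit0$beta[2L]),
                       betap = unname(fit$fitp$beta[2L]),
                       rho0 = fit$fit0$rho, rhop = fit$fitp$rho,
                       reject = fit$combined$p_value < alpha,
                       pearson0 = class_pearson(d$y0, st),
                       pearsonp = class_pearson(ifelse(d$y0 == 1, d$z, NA), st))
  }
  for (nm in intersect(models, c("MTLC_otu_ind", "MTLC_time_ind"))) {
    pins <- misspecified_pins(st, if (nm == "MTLC_otu_ind") "otu" else "time")
    fitm <- fit_mtlc(d$y, d$x, gamma = scenario$gamma, omega = scenario$omega,
                     transform = "neglog10", pinned0 = pins, pinnedp = pins)
    rec[[nm]] <- list(beta0 = unname(fitm$fit0$beta[2L]),
                      betap = unname(fitm$fitp$beta[2L]),
                      rho0 = fitm$fit0$rho, rhop = fitm$fitp$rho,
                      reject = fitm$combined$p_value < alpha)
  }
  if ("2P_ind" %in% models) {
    y0v <- as.vector(d$y0); xv <- as.vector(d$x)
    pos <- y0v == 1
    t0 <- naive_glm_test(y0v, xv, "binomial")
    tp <- naive_glm_test(as.vector(d$z)[pos], xv[pos], "gaussian")
    comb <- suppressWarnings(cauchy_combine(t0$p_value, tp$p_value))
    rec$`2P_ind` <- list(beta0 = t0$beta, betap = tp$beta,
                         reject = comb$p_value < alpha)
  }
  if (any(c("1P_GEE", "1P_ind", "1P_RE") %in% models)) {
    y1 <- ifelse(d$y0 == 1, d$z, zero_replacement)
    if ("1P_GEE" %in% models) {
      fit1 <- fit_gee(y1, d$x, st, family = "gaussian")
      w <- wald_test(fit1, c(0, 1))
      rec$`1P_GEE` <- list(beta = unname(fit1$beta[2L]), rho = fit1$rho,
                           reject = w$p_value < alpha)
    }
    if ("1P_ind" %in% models) {
      t1 <- naive_glm_test(as.vector(y1), as.vector(d$x), "gaussian")
      rec$`1P_ind` <- list(beta = t1$beta, reject = t1$p_value < alpha)
    }
    if ("1P_RE" %in% models) {
      J <- st$dim; K <- scenario$K
      df <- data.frame(y = as.vector(y1), x = as.vector(d$x),
                       cluster = rep(seq_len(K), J),
                       otu = rep(rep(seq_len(st$n_otu), each = st$L),
                                 each = K),
                       time = rep(rep(seq_len(st$L), st$n_otu), each = K))
      mfit <- suppressWarnings(suppressMessages(
        lme4::lmer(y ~ x + (1 | cluster:time) + (1 | cluster:otu), data = df,
                   REML = TRUE)))
      cf <- lme4::fixef(mfit)[2L]
      se <- sqrt(stats::vcov(mfit)[2L, 2L])
      pv <- stats::pchisq((cf / se)^2, 1, lower.tail = FALSE)
      rec$`1P_RE` <- list(beta = unname(cf), reject = pv < alpha)
    }
  }
  rec
}

# mean raw Pearson correlation of outcome columns, per structure class
class_pearson <- function(ymat, structure) {
  cls <- structure$classes
  out <- stats::setNames(rep(NA_real_, length(cls)), cls)
  for (cl in cls) {
    pr <- which(structure$labels == cl & upper.tri(structure$labels),
                arr.ind = TRUE)
    if (!nrow(pr)) next
    vals <- vapply(seq_len(nrow(pr)), function(i)
      suppressWarnings(stats::cor(ymat[, pr[i, 1L]], ymat[, pr[i, 2L]],
                                  use = "pairwise.complete.obs")),
      numeric(1))
    out[cl] <- mean(vals, na.rm = TRUE)
  }
  out
}

aggregate_sim_records <- function(recs, models) {
  agg_scalar <- function(field, model) {
    v <- vapply(recs, function(r)
      if (!is.null(r[[model]][[field]])) r[[model]][[field]] else NA_real_,
      numeric(1))
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    list(mean = mean(v), q025 = unname(stats::quantile(v, 0.025)),
         q975 = unname(stats::quantile(v, 0.975)))
  }
  agg_named <- function(field, model) {
    ms <- lapply(recs, function(r) r[[model]][[field]])
    ms <- ms[!vapply(ms, is.null, logical(1))]
    if (!length(ms)) return(NULL)
    nm <- names(ms[[1L]])
    sapply(nm, function(k) mean(vapply(ms, `[[`, numeric(1), k)))
  }
  out <- list(models = list())
  for (m in models) {
    entry <- list()
    for (f in c("beta", "beta0", "betap")) {
      a <- agg_scalar(f, m)
      if (!is.null(a)) entry[[f]] <- a
    }
    rej <- vapply(recs, function(r)
      if (!is.null(r[[m]])) as.numeric(r[[m]]$reject) else NA_real_,
      numeric(1))
    entry$rejection_rate <- mean(rej, na.rm = TRUE)
    for (f in c("rho0", "rhop", "rho", "pearson0", "pearsonp")) {
      a <- agg_named(f, m)
      if (!is.null(a)) entry[[f]] <- a
    }
    out$models[[m]] <- entry
  }
  out
}

#' @export
print.mtlc_sim_report <- function(x, ...) {
  cat(sprintf("Simulation study: K = %d, beta0 = %g, betap = %g, %d/%d reps used\n",
              x$scenario$K, x$scenario$beta0, x$scenario$betap,
              x$reps_used, x$reps))
  for (m in names(x$models)) {
    e <- x$models[[m]]
    cat(sprintf("  %-14s rejection @ %.2f: %.3f", m, x$alpha,
                e$rejection_rate))
    for (f in c("beta", "beta0", "betap"))
      if (!is.null(e[[f]]))
        cat(sprintf("  %s = %.3f", f, e[[f]]$mean))
    cat("\n")
    for (f in c("rho0", "rhop", "rho"))
      if (!is.null(e[[f]]))
        cat(sprintf("    mean %s: %s\n", f,
                    paste(sprintf("%s=%.3f", names(e[[f]]), e[[f]]),
                          collapse = ", ")))
  }
  invisible(x)
}
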