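#' Control parameters for the GEE solver
#'
#' @param tol convergence tolerance on the maximum absolute change in the
#'   coefficients between iterations.
#' @param max_iter maximum number of iterations of the alternating
#'   (beta) / (phi, rho) scheme.
#' @return A list of control values.
#' @export
gee_control <- function(tol = 1e-6, max_iter = 100L) {
  stopifnot(tol > 0, max_iter >= 1)
  list(tol = tol, max_iter = as.integer(max_iter))
}

#' Fit a GEE with a patterned taxonomic-longitudinal working correlation
#'
#' Solves the generalized estimating equations for one outcome family over the
#' indexed working-correlation structure built by
#' [build_integrative_structure()]. Estimation alternates between a Fisher
#' scoring step for the regression coefficients (with cluster working
#' covariance `V_k = A_k^{1/2} R_k(rho) A_k^{1/2}`, `R_k` the per-cluster
#' subset of the realized structure) and moment updates of the dispersion
#' `phi` and the per-class correlation coefficients `rho` from Pearson
#' residuals. Missing cells are dropped listwise per cell via
#' [subset_structure()], so clusters may have unequal sizes.
#'
#' @param y K x J outcome matrix, one row per independent cluster, one column
#'   per OTU x repeat cell (OTU-major ordering); `NA` marks a missing cell.
#' @param x covariates: a single K x J matrix or a named list of K x J
#'   matrices, one per covariate. An intercept is prepended unless
#'   `intercept = FALSE`.
#' @param structure an `integrative_structure` of dimension J.
#' @param family `"gaussian"` (identity link, dispersion estimated) or
#'   `"binomial"` (logit link, dispersion fixed at 1).
#' @param pinned named numeric vector of class coefficients held fixed rather
#'   than estimated, e.g. `c("I,i" = 0)`.
#' @param intercept prepend an intercept column (default `TRUE`).
#' @param control see [gee_control()].
#' @return An object of class `gee_fit`: `beta` (named coefficients), `vbeta`
#'   (robust sandwich covariance), `phi`, `rho` (estimated coefficients per
#'   class, pinned ones included at their fixed values), `n_iter`,
#'   `converged`, `residuals` (Pearson, K x J with `NA` pattern preserved),
#'   `fitted`, and bookkeeping fields (`family`, `structure`, `n_clusters`,
#'   `n_obs`, `repaired`, `empty_classes`).
#' @seealso [wald_test()], [fit_mtlc()]
#' @export
fit_gee <- function(y, x, structure, family = c("gaussian", "binomial"),
                    pinned = NULL, intercept = TRUE,
                    control = gee_control()) {
  family <- match.arg(family)
  stopifnot(inherits(structure, "integrative_structure"))
  dat <- gee_prepare(y, x, structure, intercept)
  fit <- gee_solve(dat, family, pinned, control)
  fit
}

# --- data preparation -------------------------------------------------------

gee_prepare <- function(y, x, structure, intercept) {
  y <- as.matrix(y)
  K <- nrow(y); J <- ncol(y)
  if (J != structure$dim)
    stop("outcome grid has ", J, " cells but the structure has dimension ",
         structure$dim)
  if (is.matrix(x)) x <- list(x = x)
  if (!is.list(x)) stop("x must be a K x J matrix or a list of them")
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- paste0("x", seq_along(x))
  for (a in seq_along(x)) {
    x[[a]] <- as.matrix(x[[a]])
    if (!all(dim(x[[a]]) == c(K, J)))
      stop("covariate '", names(x)[a], "' is not K x J")
  }
  if (intercept)
    x <- c(list("(Intercept)" = matrix(1, K, J)), x)
  p <- length(x)
  obs <- !is.na(y)
  keep <- rowSums(obs) > 0L
  if (!all(keep)) {
    y <- y[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
    x <- lapply(x, function(m) m[keep, , drop = FALSE])
    K <- nrow(y)
  }
  if (K < 2L) stop("need at least two clusters with observations")
  for (a in seq_along(x))
    if (any(is.na(x[[a]][obs])))
      stop("covariate '", names(x)[a], "' has NA at an observed cell")
  # group clusters by identical missingness pattern
  key <- apply(obs, 1L, function(m) paste(as.integer(m), collapse = ""))
  groups <- lapply(split(seq_len(K), key), function(rows) {
    idx <- which(obs[rows[1L], ])
    sub <- subset_structure(structure, idx)
    lab <- sub$labels
    pairs <- lapply(sub$classes, function(cl) {
      w <- which(lab == cl & upper.tri(lab), arr.ind = TRUE)
      w
    })
    names(pairs) <- sub$classes
    list(rows = rows, idx = idx, sub = sub, pairs = pairs,
         y = y[rows, idx, drop = FALSE],
         x = lapply(x, function(m) m[rows, idx, drop = FALSE]))
  })
  list(K = K, J = J, p = p, coef_names = names(x), obs = obs,
       n_obs = sum(obs), structure = structure, groups = groups)
}

gee_family <- function(family) {
  switch(family,
    gaussian = list(linkinv = identity, variance = function(mu) rep(1, length(mu)),
                    mu_eta = function(mu) rep(1, length(mu)),
                    estimate_phi = TRUE),
    binomial = list(linkinv = stats::plogis,
                    variance = function(mu) mu * (1 - mu),
                    mu_eta = function(mu) mu * (1 - mu),
                    estimate_phi = FALSE))
}

# residual state (mu, Pearson residuals, scaled design) at a given beta
gee_state <- function(dat, fam, beta) {
  lapply(dat$groups, function(g) {
    eta <- matrix(0, nrow(g$y), ncol(g$y))
    for (a in seq_along(g$x)) eta <- eta + g$x[[a]] * beta[a]
    mu <- fam$linkinv(eta)
    v <- fam$variance(mu); dim(v) <- dim(mu)
    sdv <- sqrt(pmax(v, 1e-12))
    e <- (g$y - mu) / sdv
    # for logit, d mu / d eta equals the variance function, so the scaled
    # design A^{1/2} X used in both score and bread is sqrt(v) * x for both
    # families
    xt <- lapply(g$x, function(m) m * sdv)
    list(mu = mu, e = e, xt = xt)
  })
}

gee_phi <- function(dat, fam, states) {
  if (!fam$estimate_phi) return(1)
  ss <- sum(vapply(states, function(s) sum(s$e^2), numeric(1)))
  denom <- dat$n_obs - dat$p
  if (denom <= 0) stop("fewer observations than parameters")
  ss / denom
}

gee_rho <- function(dat, states, phi, pinned = NULL) {
  classes <- dat$structure$classes
  num <- stats::setNames(rep(0, length(classes)), classes)
  npairs <- num
  for (gi in seq_along(dat$groups)) {
    g <- dat$groups[[gi]]; e <- states[[gi]]$e
    for (cl in names(g$pairs)) {
      pr <- g$pairs[[cl]]
      if (!nrow(pr)) next
      num[cl] <- num[cl] + sum(e[, pr[, 1L], drop = FALSE] *
                               e[, pr[, 2L], drop = FALSE])
      npairs[cl] <- npairs[cl] + nrow(g$y) * nrow(pr)
    }
  }
  free <- setdiff(classes, names(pinned))
  rho <- stats::setNames(rep(0, length(classes)), classes)
  empty <- character()
  for (cl in free) {
    if (npairs[cl] == 0) { empty <- c(empty, cl); next }
    denom <- (npairs[cl] - dat$p) * phi
    if (denom <= 0) { empty <- c(empty, cl); next }
    rho[cl] <- max(-0.99, min(0.99, num[cl] / denom))
  }
  if (!is.null(pinned)) rho[names(pinned)] <- pinned
  attr(rho, "empty") <- empty
  rho
}

# per-group inverse working correlation matrices at given rho
gee_weights <- function(dat, rho) {
  repaired <- FALSE
  W <- lapply(dat$groups, function(g) {
    if (g$sub$dim == 1L) return(matrix(1, 1, 1))
    r <- realize_correlation(g$sub, rho)
    if (isTRUE(attr(r, "repaired"))) repaired <<- TRUE
    solve(r)
  })
  attr(W, "repaired") <- repaired
  W
}

# accumulate score U, bread B and (optionally) meat M over groups
gee_accumulate <- function(dat, states, W, meat = FALSE) {
  p <- dat$p
  U <- numeric(p); B <- matrix(0, p, p)
  M <- if (meat) matrix(0, p, p) else NULL
  for (gi in seq_along(dat$groups)) {
    s <- states[[gi]]; Wm <- W[[gi]]
    WE <- s$e %*% Wm
    for (a in seq_len(p)) {
      U[a] <- U[a] + sum(s$xt[[a]] * WE)
      for (b in a:p) {
        Cab <- crossprod(s$xt[[a]], s$xt[[b]])
        B[a, b] <- B[a, b] + sum(Wm * Cab)
      }
    }
    if (meat) {
      S <- vapply(s$xt, function(m) rowSums(m * WE), numeric(nrow(WE)))
      if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
      M <- M + crossprod(S)
    }
  }
  B[lower.tri(B)] <- t(B)[lower.tri(B)]
  list(U = U, B = B, M = M)
}

gee_init_beta <- function(dat, family) {
  # independence-model fit on the pooled rows
  yv <- unlist(lapply(dat$groups, function(g) as.vector(g$y)))
  X <- do.call(cbind, lapply(seq_len(dat$p), function(a)
    unlist(lapply(dat$groups, function(g) as.vector(g$x[[a]])))))
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  fit <- stats::glm.fit(X, yv, family = fam)
  if (qr(X)$rank < dat$p) stop("design matrix is rank deficient")
  stats::setNames(fit$coefficients, dat$coef_names)
}

gee_solve <- function(dat, family, pinned, control) {
  fam <- gee_family(family)
  beta <- gee_init_beta(dat, family)
  rho <- stats::setNames(rep(0, length(dat$structure$classes)),
                         dat$structure$classes)
  if (!is.null(pinned)) {
    bad <- setdiff(names(pinned), dat$structure$classes)
    if (length(bad)) stop("pinned classes not in structure: ",
                          paste(bad, collapse = ", "))
    rho[names(pinned)] <- pinned
  }
  phi <- 1
  converged <- FALSE
  repaired <- FALSE
  it <- 0L
  for (it in seq_len(control$max_iter)) {
    states <- gee_state(dat, fam, beta)
    phi <- gee_phi(dat, fam, states)
    rho <- gee_rho(dat, states, phi, pinned)
    W <- gee_weights(dat, rho)
    if (isTRUE(attr(W, "repaired"))) repaired <- TRUE
    acc <- gee_accumulate(dat, states, W)
    delta <- solve(acc$B, acc$U)
    beta <- beta + delta
    if (max(abs(delta)) <= control$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GEE did not converge in ", control$max_iter, " iterations")
  # final state at beta-hat: refresh phi/rho and compute the sandwich
  states <- gee_state(dat, fam, beta)
  phi <- gee_phi(dat, fam, states)
  rho <- gee_rho(dat, states, phi, pinned)
  empty <- attr(rho, "empty")
  if (length(empty))
    warning("correlation classes with no observed pairs set to 0: ",
            paste(empty, collapse = ", "))
  W <- gee_weights(dat, rho)
  acc <- gee_accumulate(dat, states, W, meat = TRUE)
  binv <- solve(acc$B)
  vbeta <- binv %*% acc$M %*% binv
  vbeta <- (vbeta + t(vbeta)) / 2
  dimnames(vbeta) <- list(dat$coef_names, dat$coef_names)
  res <- matrix(NA_real_, dat$K, dat$J)
  mu <- matrix(NA_real_, dat$K, dat$J)
  for (gi in seq_along(dat$groups)) {
    g <- dat$groups[[gi]]
    res[g$rows, g$idx] <- states[[gi]]$e
    mu[g$rows, g$idx] <- states[[gi]]$mu
  }
  structure(list(beta = beta, vbeta = vbeta, phi = phi,
                 rho = stats::setNames(as.numeric(rho), names(rho)),
                 n_iter = it, converged = converged,
                 residuals = res, fitted = mu,
                 family = family, structure = dat$structure,
                 n_clusters = dat$K, n_obs = dat$n_obs, p = dat$p,
                 repaired = repaired,
                 empty_classes = empty),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE fit (%s), %d clusters, %d observations, %s in %d iterations\n",
              x$family, x$n_clusters, x$n_obs,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  se <- sqrt(diag(x$vbeta))
  tab <- cbind(Estimate = x$beta, `Robust SE` = se, z = x$beta / se)
  print(round(tab, 4))
  cat("phi:", format(x$phi, digits = 4), "\n")
  if (length(x$rho)) {
    cat("rho:\n"); print(round(x$rho, 4))
  }
  invisible(x)
}

#' Dispersion moment estimator
#'
#' `phi = sum(e^2) / (total_obs - p)`, the Pearson-residual moment estimator
#' of the dispersion with a degrees-of-freedom correction.
#'
#' @param residuals Pearson residuals (any shape; `NA` entries are dropped).
#' @param total_obs total number of observations `sum(J_k)`; defaults to the
#'   number of non-missing residuals.
#' @param p number of regression parameters.
#' @return Estimated dispersion (scalar, `>= 0`).
#' @export
estimate_phi <- function(residuals, total_obs = sum(!is.na(residuals)), p) {
  e <- residuals[!is.na(residuals)]
  if (total_obs <= p) stop("total observations must exceed p")
  sum(e^2) / (total_obs - p)
}

#' Correlation-coefficient moment estimator
#'
#' For each free correlation class `c`,
#' `rho_c = sum over clusters and class-c pairs of e_kj * e_kj' /
#' ((N_c - p) * phi)` with `N_c` the total number of class-`c` pairs; pinned
#' classes keep their fixed value, estimates are clipped to (-0.99, 0.99), and
#' classes with no observed pairs are set to 0 with a warning.
#'
#' @param residuals K x J matrix of Pearson residuals (`NA` = missing cell).
#' @param structure the `integrative_structure` the residual grid follows.
#' @param phi dispersion estimate.
#' @param p number of regression parameters.
#' @param pinned named numeric vector of classes held fixed.
#' @return Named numeric vector of coefficients, one per structure class.
#' @export
estimate_rho <- function(residuals, structure, phi, p, pinned = NULL) {
  stopifnot(inherits(structure, "integrative_structure"),
            ncol(residuals) == structure$dim)
  obs <- !is.na(residuals)
  key <- apply(obs, 1L, function(m) paste(as.integer(m), collapse = ""))
  dat <- list(p = p, structure = structure,
              groups = lapply(split(seq_len(nrow(residuals)), key),
                              function(rows) {
    idx <- which(obs[rows[1L], ])
    sub <- subset_structure(structure, idx)
    pairs <- lapply(sub$classes, function(cl)
      which(sub$labels == cl & upper.tri(sub$labels), arr.ind = TRUE))
    names(pairs) <- sub$classes
    list(y = residuals[rows, idx, drop = FALSE], pairs = pairs)
  }))
  states <- lapply(dat$groups, function(g) list(e = g$y))
  rho <- gee_rho(dat, states, phi, pinned)
  empty <- attr(rho, "empty")
  if (length(empty))
    warning("correlation classes with no observed pairs set to 0: ",
            paste(empty, collapse = ", "))
  stats::setNames(as.numeric(rho), names(rho))
}

#' Wald test of linear hypotheses on GEE coefficients
#'
#' Tests `H0: C beta = c` with `W = (C b - c)' (C V C')^{-1} (C b - c)`,
#' referred to a chi-square distribution with `q = nrow(C)` degrees of
#' freedom, using the robust sandwich covariance.
#'
#' @param fit a `gee_fit`.
#' @param C q x p contrast matrix (a vector is treated as one row); must have
#'   full row rank.
#' @param c right-hand side, length q (default 0).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
wald_test <- function(fit, C, c = NULL) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!is.matrix(C)) C <- matrix(C, nrow = 1L)
  q <- nrow(C)
  if (is.null(c)) c <- rep(0, q)
  stopifnot(ncol(C) == length(fit$beta), length(c) == q)
  if (qr(C)$rank < q) stop("contrast matrix is rank deficient")
  d <- as.numeric(C %*% fit$beta - c)
  V <- C %*% fit$vbeta %*% t(C)
  W <- as.numeric(crossprod(d, solve(V, d)))
  list(statistic = W, df = q,
       p_value = stats::pchisq(W, df = q, lower.tail = FALSE))
}
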