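#' Split zero-inflated abundances into prevalence and positive parts
#'
#' Converts an OTU abundance grid into the two outcome grids of the two-part
#' model: a binary prevalence grid (`1` where the OTU was observed at positive
#' abundance) and a positive-part grid holding the log-transformed abundance
#' where it is positive and `NA` elsewhere. `NA` cells of the input (missing
#' observations) stay `NA` in both parts.
#'
#' @param y K x J matrix of non-negative abundances (relative abundances in
#'   `[0, 1]` for `transform = "log10"`); `NA` = missing cell.
#' @param transform `"log10"` (positive part is `log10 y`, the convention for
#'   real relative-abundance data) or `"neglog10"` (`-log10 y`, the
#'   simulation convention where transformed abundances are positive). Only
#'   the sign of the positive-part coefficients differs.
#' @return List of class `two_part_data`: `y0` (binary grid), `yp`
#'   (positive-part grid), `transform`.
#' @export
split_two_part <- function(y, transform = c("log10", "neglog10")) {
  transform <- match.arg(transform)
  y <- as.matrix(y)
  if (any(y < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  y0 <- ifelse(is.na(y), NA_real_, as.numeric(y > 0))
  yp <- ifelse(!is.na(y) & y > 0, log10(y), NA_real_)
  if (transform == "neglog10") yp <- -yp
  structure(list(y0 = y0, yp = yp, transform = transform),
            class = "two_part_data")
}

#' Fit the two-part Microbiome Taxonomic Longitudinal Correlation model
#'
#' Fits the prevalence part (binary outcomes, logit link) and the positive
#' relative-abundance part (log10-transformed positive outcomes, identity
#' link) as two GEEs sharing one symbolic working-correlation structure built
#' from the OTU taxonomy and the repeated-measure design; the correlation
#' coefficients are estimated separately per part. The default hypothesis —
#' every non-intercept coefficient zero in both parts — is tested per part by
#' a robust Wald test and jointly by the Cauchy combination test.
#'
#' @param y K x J abundance grid (clusters by OTU x repeat cells, OTU-major);
#'   `NA` = missing cell. Zeros are genuine zeros.
#' @param x covariates as in [fit_gee()] (matrix or named list of K x J
#'   matrices); the same design is used for both parts.
#' @param gamma taxonomic structure: a `structure_matrix`, or a
#'   `taxonomic_structure` / `numeric_representation` which is converted with
#'   [build_structure_matrix()].
#' @param omega repeat structure (`structure_matrix`) or `NULL` for a single
#'   observation per OTU.
#' @param transform see [split_two_part()].
#' @param pinned0,pinnedp classes pinned per part (see [fit_gee()]).
#' @param control see [gee_control()].
#' @return Object of class `mtlc_fit`: `fit0`, `fitp` (the two `gee_fit`s, or
#'   `NULL` for a degenerate part), `wald0`, `waldp`, `combined` (list with
#'   `statistic` and `p_value`), `degenerate` (character vector naming
#'   degenerate parts) and `structure`.
#' @examples
#' set.seed(1)
#' g <- structure_matrix(matrix(c("D", "I", "I", "D"), 2), kind = "taxonomic")
#' sc <- mtlc_scenario(K = 150, beta0 = 0, betap = 0)
#' d <- simulate_zero_inflated(sc)
#' fit <- fit_mtlc(d$y, d$x, gamma = g, omega = time_structure(2),
#'                 transform = "neglog10")
#' fit$combined$p_value
#' @export
fit_mtlc <- function(y, x, gamma, omega = NULL,
                     transform = c("log10", "neglog10"),
                     pinned0 = NULL, pinnedp = NULL,
                     control = gee_control()) {
  transform <- match.arg(transform)
  if (inherits(gamma, c("taxonomic_structure", "numeric_representation")))
    gamma <- build_structure_matrix(gamma)
  stopifnot(inherits(gamma, "structure_matrix"))
  structure_ <- build_integrative_structure(gamma, omega)
  parts <- split_two_part(y, transform)
  degenerate <- character()

  fit0 <- NULL
  v0 <- stats::var(as.numeric(parts$y0), na.rm = TRUE)
  if (!is.finite(v0) || v0 == 0) {
    degenerate <- c(degenerate, "prevalence")
  } else {
    fit0 <- fit_gee(parts$y0, x, structure_, family = "binomial",
                    pinned = pinned0, control = control)
  }
  fitp <- NULL
  np <- sum(!is.na(parts$yp))
  vp <- stats::var(as.numeric(parts$yp), na.rm = TRUE)
  if (np < 2L || !is.finite(vp) || vp == 0) {
    degenerate <- c(degenerate, "positive")
  } else {
    fitp <- fit_gee(parts$yp, x, structure_, family = "gaussian",
                    pinned = pinnedp, control = control)
  }
  if (is.null(fit0) && is.null(fitp))
    stop("both parts are degenerate; nothing to fit")
  res <- structure(list(fit0 = fit0, fitp = fitp,
                        wald0 = NULL, waldp = NULL, combined = NULL,
                        degenerate = degenerate, transform = transform,
                        structure = structure_),
                   class = "mtlc_fit")
  test_predictors(res)
}

#' Cauchy combination of the two part-wise p-values
#'
#' `W = 0.5 tan((0.5 - p0) pi) + 0.5 tan((0.5 - pplus) pi)`; under the joint
#' null `W` is standard Cauchy regardless of the dependence between the
#' parts, so the combined p-value is its upper-tail probability
#' `0.5 - atan(W) / pi`.
#'
#' @param p0 prevalence-part p-value in (0, 1).
#' @param pplus positive-part p-value in (0, 1).
#' @return List with `statistic` (W) and `p_value`.
#' @export
cauchy_combine <- function(p0, pplus) {
  clamp <- function(p, nm) {
    stopifnot(length(p) == 1L, is.finite(p), p >= 0, p <= 1)
    if (p <= 0 || p >= 1) {
      warning(nm, " clamped away from {0, 1}")
      p <- min(max(p, 1e-15), 1 - 1e-15)
    }
    p
  }
  p0 <- clamp(p0, "p0"); pplus <- clamp(pplus, "pplus")
  W <- 0.5 * tan((0.5 - p0) * pi) + 0.5 * tan((0.5 - pplus) * pi)
  list(statistic = W,
       p_value = stats::pcauchy(W, lower.tail = FALSE))
}

#' Joint test of predictor effects in a two-part fit
#'
#' Runs the Wald test of `H0: C beta^(0) = c` and `C beta^(+) = c` on each
#' part and combines the two p-values with [cauchy_combine()]. The default
#' contrast tests all non-intercept coefficients against zero. If one part is
#' degenerate the combined p-value falls back to the other part's, with a
#' warning.
#'
#' @param result an `mtlc_fit`.
#' @param C contrast matrix applied to both parts (default: select all
#'   non-intercept coefficients).
#' @param c right-hand side (default 0).
#' @return The `mtlc_fit` with `wald0`, `waldp` and `combined` filled in.
#' @export
test_predictors <- function(result, C = NULL, c = NULL) {
  stopifnot(inherits(result, "mtlc_fit"))
  some_fit <- if (!is.null(result$fit0)) result$fit0 else result$fitp
  p <- length(some_fit$beta)
  if (is.null(C)) {
    if (p < 2L) stop("no non-intercept coefficients to test; supply C")
    C <- cbind(matrix(0, p - 1L, 1L), diag(p - 1L))
  }
  result$wald0 <- if (!is.null(result$fit0)) wald_test(result$fit0, C, c)
  result$waldp <- if (!is.null(result$fitp)) wald_test(result$fitp, C, c)
  if (is.null(result$wald0)) {
    warning("prevalence part degenerate; combined test uses the positive ",
            "part alone")
    result$combined <- list(statistic = NA_real_,
                            p_value = result$waldp$p_value)
  } else if (is.null(result$waldp)) {
    warning("positive part degenerate; combined test uses the prevalence ",
            "part alone")
    result$combined <- list(statistic = NA_real_,
                            p_value = result$wald0$p_value)
  } else {
    result$combined <- cauchy_combine(result$wald0$p_value,
                                      result$waldp$p_value)
  }
  result
}

#' @export
print.mtlc_fit <- function(x, ...) {
  cat("Two-part MTLC model\n")
  if (!is.null(x$fit0)) {
    cat("\nPrevalence part (binomial, logit):\n")
    print(x$fit0)
  }
  if (!is.null(x$fitp)) {
    cat("\nPositive-abundance part (gaussian, identity, ",
        x$transform, "):\n", sep = "")
    print(x$fitp)
  }
  if (length(x$degenerate))
    cat("\nDegenerate part(s):", paste(x$degenerate, collapse = ", "), "\n")
  cat("\nTests (H0: contrast = 0):\n")
  if (!is.null(x$wald0))
    cat(sprintf("  prevalence: W = %.4f, df = %d, p = %.4g\n",
                x$wald0$statistic, x$wald0$df, x$wald0$p_value))
  if (!is.null(x$waldp))
    cat(sprintf("  positive:   W = %.4f, df = %d, p = %.4g\n",
                x$waldp$statistic, x$waldp$df, x$waldp$p_value))
  cat(sprintf("  combined (Cauchy): p = %.4g\n", x$combined$p_value))
  invisible(x)
}
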