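# construct an MR estimate on the log-odds-per-1-SD scale: 95% normal CI,
# two-sided normal P, odds ratio as the elementwise exp of the beta scale
mr_estimate <- function(method, beta, se, n_snps) {
  z <- stats::qnorm(0.975)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  pvalue <- 2 * stats::pnorm(-abs(beta) / se)
  pvalue <- max(pvalue, .Machine$double.xmin)
  structure(
    list(method = method, beta = beta, se = se,
         ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
         odds_ratio = exp(beta), or_ci_low = exp(ci_low),
         or_ci_high = exp(ci_high), n_snps = n_snps),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNP%s): beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], P = %.3g\n",
              x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
              x$beta, x$se, x$odds_ratio, x$or_ci_low, x$or_ci_high, x$pvalue))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high,
             odds_ratio = x$odds_ratio, or_ci_low = x$or_ci_low,
             or_ci_high = x$or_ci_high, pvalue = x$pvalue,
             stringsAsFactors = FALSE)
}

# pull the per-SNP vectors out of an mr_harmonized object
.hdata <- function(data, min_snps = 1L, what = "estimator") {
  if (!inherits(data, "mr_harmonized")) {
    stop("expected an mr_harmonized dataset", call. = FALSE)
  }
  d <- data$data
  if (nrow(d) < min_snps) {
    stop(sprintf("%s requires at least %d instrument(s), got %d",
                 what, min_snps, nrow(d)), call. = FALSE)
  }
  list(bx = d$beta_exposure, sx = d$se_exposure,
       by = d$beta_outcome, sy = d$se_outcome,
       ld = data$ld, k = nrow(d), ids = d$snp_id)
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate `by / bx` (variant-outcome over
#' variant-exposure association). The default standard error is the
#' first-order delta method `sy / |bx|`; `second_order = TRUE` adds the
#' exposure-side term: `sqrt(sy^2 / bx^2 + by^2 sx^2 / bx^4)`.
#'
#' @param bx,sx Variant-exposure beta and SE.
#' @param by,sy Variant-outcome beta and SE.
#' @param second_order Use the second-order delta-method SE.
#' @return An `mr_estimate` (method `"wald_ratio"`).
#' @export
wald_ratio <- function(bx, sx, by, sy, second_order = FALSE) {
  if (bx == 0) stop("Wald ratio undefined: variant-exposure beta is zero",
                    call. = FALSE)
  beta <- by / bx
  se <- if (second_order) {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else {
    sy / abs(bx)
  }
  mr_estimate("wald_ratio", beta, se, n_snps = 1L)
}

#' Fixed-effect IVW for correlated instruments
#'
#' Generalized weighted least squares of the outcome betas on the exposure
#' betas through the origin, with covariance
#' `Omega[i, j] = sy[i] * sy[j] * rho[i, j]` where `rho` is the signed LD
#' matrix: `beta = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by`, fixed-effect
#' `se = sqrt((bx' Omega^-1 bx)^-1)`. Equivalent to pooling the per-SNP
#' Wald ratios with their LD-induced correlation, but numerically stabler.
#' With identity LD this reduces exactly to classic fixed-effect IVW, and
#' with a single instrument to the Wald ratio (first-order SE).
#'
#' @param data An `mr_harmonized` dataset (K >= 1) whose `ld` block is
#'   positive semi-definite (repaired on construction if needed).
#' @return An `mr_estimate` (method `"ivw_correlated"`).
#' @export
mr_ivw_correlated <- function(data) {
  h <- .hdata(data, 1L, "correlated IVW")
  omega <- tcrossprod(h$sy) * h$ld
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) {
    stop(sprintf(
      "weighting matrix is singular (condition number %.3g); cannot pool",
      kappa(omega)), call. = FALSE)
  }
  # solve via the Cholesky factor: omega^-1 x = backsolve steps
  oinv_bx <- backsolve(ch, forwardsolve(t(ch), h$bx))
  oinv_by <- backsolve(ch, forwardsolve(t(ch), h$by))
  precision <- sum(h$bx * oinv_bx)
  beta <- sum(h$bx * oinv_by) / precision
  mr_estimate("ivw_correlated", beta, sqrt(1 / precision), n_snps = h$k)
}

#' Inverse-variance-weighted estimate for independent instruments
#'
#' Precision-weighted regression of outcome on exposure betas through the
#' origin with weights `1 / sy^2` (equivalently, the weighted mean of
#' per-SNP Wald ratios with weights `bx^2 / sy^2`). Under
#' `model = "multiplicative_random"` the fixed-effect SE is inflated by
#' `max(1, sqrt(Q / (K - 1)))`, Cochran's Q overdispersion.
#'
#' @param data An `mr_harmonized` dataset; any LD block is ignored.
#' @param model `"fixed"` or `"multiplicative_random"` (requires K >= 2).
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(data, model = c("fixed", "multiplicative_random")) {
  model <- match.arg(model)
  h <- .hdata(data, if (model == "fixed") 1L else 2L,
              paste0("IVW (", model, ")"))
  w <- 1 / h$sy^2
  precision <- sum(w * h$bx^2)
  beta <- sum(w * h$bx * h$by) / precision
  se <- sqrt(1 / precision)
  if (model == "multiplicative_random") {
    q <- sum(w * (h$by - beta * h$bx)^2)
    se <- se * max(1, sqrt(q / (h$k - 1)))
  }
  mr_estimate(paste0("ivw_", model), beta, se, n_snps = h$k)
}

#' MR-Egger regression and intercept test
#'
#' Weighted least squares of outcome betas on exposure betas *with* an
#' intercept (weights `1 / sy^2`), after orienting every instrument so its
#' exposure beta is positive (the result is invariant to flipping any
#' instrument's sign pair). The slope is a pleiotropy-robust causal
#' estimate under the InSIDE assumption; a nonzero intercept indicates
#' directional horizontal pleiotropy. The regression sigma enters the SEs
#' as estimated, and P-values for the slope and intercept are two-sided t
#' with K - 2 degrees of freedom (the usual small-K calibration for a
#' weighted regression with estimated scale).
#'
#' @param data An `mr_harmonized` dataset with K >= 3 instruments.
#' @return Object of class `mr_egger`: list with `slope` (an
#'   `mr_estimate`) and `intercept` (estimate, se, pvalue).
#' @export
mr_egger <- function(data) {
  h <- .hdata(data, 3L, "MR-Egger")
  flip <- sign(h$bx)
  flip[flip == 0] <- 1
  bx <- h$bx * flip
  by <- h$by * flip
  fit <- stats::lm(by ~ bx, weights = 1 / h$sy^2)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  df <- h$k - 2L
  slope <- mr_estimate("mr_egger", unname(est["bx"]), unname(se["bx"]),
                       n_snps = h$k)
  slope$pvalue <- max(2 * stats::pt(-abs(slope$beta) / slope$se, df),
                      .Machine$double.xmin)
  int <- unname(est["(Intercept)"])
  int_se <- unname(se["(Intercept)"])
  structure(
    list(slope = slope,
         intercept = list(estimate = int, se = int_se,
                          pvalue = max(2 * stats::pt(-abs(int) / int_se, df),
                                       .Machine$double.xmin))),
    class = "mr_egger"
  )
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  Egger intercept: %.4f (SE %.4f), P = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue))
  invisible(x)
}

#' Cochran's Q and I-squared heterogeneity
#'
#' `Q = sum_i (by_i - beta * bx_i)^2 / sy_i^2` around the pooled estimate,
#' with `K - 1` degrees of freedom, an upper-tail chi-square P-value, and
#' `I^2 = max(0, (Q - df) / Q)`.
#'
#' @param data An `mr_harmonized` dataset with K >= 2.
#' @param estimate Pooled `mr_estimate` to take residuals around; defaults
#'   to the matching IVW (correlated if the LD block is non-identity).
#' @return Object of class `mr_heterogeneity`: list with `Q`, `df`,
#'   `pvalue`, `i_squared`.
#' @export
mr_heterogeneity <- function(data, estimate = NULL) {
  h <- .hdata(data, 2L, "heterogeneity")
  if (is.null(estimate)) {
    estimate <- if (is_identity_ld(h$ld)) mr_ivw(data) else mr_ivw_correlated(data)
  }
  q <- sum((h$by - estimate$beta * h$bx)^2 / h$sy^2)
  df <- h$k - 1L
  structure(
    list(Q = q, df = df,
         pvalue = stats::pchisq(q, df, lower.tail = FALSE),
         i_squared = max(0, (q - df) / q)),
    class = "mr_heterogeneity"
  )
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f (df %d), P = %.3g, I^2 = %.1f%%\n",
              x$Q, x$df, x$pvalue, 100 * x$i_squared))
  invisible(x)
}

#' Leave-one-out analysis
#'
#' Re-estimates the pooled effect omitting each instrument in turn, using
#' the correlated-instrument IVW when the LD block is non-identity and the
#' classic fixed-effect IVW otherwise, to assess whether the pooled
#' estimate is driven by a single SNP.
#'
#' @param data An `mr_harmonized` dataset with K >= 2.
#' @return Data frame: omitted `snp_id`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `odds_ratio`, `pvalue` of the estimate without that SNP.
#' @export
mr_leave_one_out <- function(data) {
  h <- .hdata(data, 2L, "leave-one-out")
  correlated <- !is_identity_ld(h$ld)
  rows <- lapply(seq_len(h$k), function(i) {
    sub <- harmonized_subset(data, setdiff(seq_len(h$k), i))
    est <- if (correlated) mr_ivw_correlated(sub) else mr_ivw(sub)
    cbind(data.frame(snp_id = h$ids[i], stringsAsFactors = FALSE),
          as.data.frame(est)[c("beta", "se", "ci_low", "ci_high",
                               "odds_ratio", "pvalue")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Profile-likelihood MR estimate that accounts for sampling error in the
#' exposure associations. The estimate maximizes
#' `-1/2 * sum_i (by_i - beta * bx_i)^2 / (sy_i^2 + beta^2 * sx_i^2 + tau^2)`,
#' with `tau^2 = 0` when `overdispersion = FALSE`; with overdispersion the
#' full Gaussian log-likelihood (including its log-variance terms) is
#' maximized jointly over `(beta, tau^2 >= 0)`. The SE comes from the
#' observed information at the optimum. Instruments are treated as
#' independent (use the clumped set); the simple quadratic loss is used
#' rather than a Tukey/Huber robust loss.
#'
#' @param data An `mr_harmonized` dataset with K >= 3 (LD ignored).
#' @param overdispersion Profile out a systematic-pleiotropy variance
#'   `tau^2` in addition to `beta`.
#' @return An `mr_estimate` (method `"raps"` or `"raps_overdispersed"`).
#' @export
mr_raps <- function(data, overdispersion = FALSE) {
  h <- .hdata(data, 3L, "RAPS")
  bx <- h$bx; sx <- h$sx; by <- h$by; sy <- h$sy
  start <- mr_ivw(data)$beta
  span <- 10 + 10 * abs(start)
  if (!overdispersion) {
    nll <- function(beta) {
      v <- sy^2 + beta^2 * sx^2
      0.5 * sum((by - beta * bx)^2 / v)
    }
    opt <- stats::optim(start, nll, method = "Brent",
                        lower = start - span, upper = start + span)
    if (opt$convergence != 0 ||
        min(abs(opt$par - c(start - span, start + span))) < 1e-6) {
      stop("RAPS optimizer failed to converge to an interior optimum; ",
           "convergence code ", opt$convergence, call. = FALSE)
    }
    beta <- opt$par
    info <- stats::optimHess(beta, nll)[1, 1]
    if (!is.finite(info) || info <= 0) {
      stop("RAPS information matrix not positive at the optimum", call. = FALSE)
    }
    return(mr_estimate("raps", beta, sqrt(1 / info), n_snps = h$k))
  }
  nll2 <- function(par) {
    # clamp tau2 at 0 so numerical derivatives at the boundary stay finite
    beta <- par[1]; tau2 <- max(par[2], 0)
    v <- sy^2 + beta^2 * sx^2 + tau2
    0.5 * sum((by - beta * bx)^2 / v + log(v))
  }
  opt <- stats::optim(c(start, 0), nll2, method = "L-BFGS-B",
                      lower = c(start - span, 0),
                      upper = c(start + span, Inf), hessian = TRUE)
  if (opt$convergence != 0) {
    stop("RAPS optimizer failed to converge: ", opt$message, call. = FALSE)
  }
  hess <- opt$hessian
  se <- tryCatch(sqrt(solve(hess)[1, 1]),
                 error = function(e) sqrt(1 / hess[1, 1]))
  if (!is.finite(se)) se <- sqrt(1 / hess[1, 1])
  mr_estimate("raps_overdispersed", opt$par[1], se, n_snps = h$k)
}
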