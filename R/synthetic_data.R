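# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation rho,
# by 1-D reduction: integral of phi(x) * Phi((b - rho x)/sqrt(1 - rho^2))
bvn_cdf <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  if (rho > 1 - 1e-12) return(stats::pnorm(min(a, b)))
  if (rho < -1 + 1e-12) return(max(0, stats::pnorm(a) - stats::pnorm(-b)))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((b - rho * x) / s),
                   -Inf, a, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# correlation of two Bernoulli allele indicators obtained by thresholding a
# bivariate normal with latent correlation rho at frequencies p_i, p_j;
# dosages (sums of two independent haplotypes) inherit this correlation
allele_corr <- function(p_i, p_j, rho) {
  p11 <- bvn_cdf(stats::qnorm(p_i), stats::qnorm(p_j), rho)
  (p11 - p_i * p_j) / sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
}

# block-diagonal AR(1) latent correlation over n_snps in blocks of block_size
latent_block_corr <- function(n_snps, block_size, rho_block) {
  r <- diag(n_snps)
  n_blocks <- n_snps %/% block_size
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    r[idx, idx] <- rho_block^abs(outer(seq_len(block_size),
                                       seq_len(block_size), "-"))
  }
  r
}

#' Configuration of a synthetic two-sample GWAS study
#'
#' Fixes the generating model: two disjoint cohorts drawn from the same
#' LD structure, a continuous exposure driven additively by the SNPs, and a
#' binary outcome arising from a liability threshold. Haplotypes come from
#' a Gaussian copula with AR(1) correlation `rho_block` inside consecutive
#' blocks of `block_size` SNPs (independent across blocks), thresholded at
#' per-SNP minor-allele frequencies. The exposure is
#' `X = G gamma + c U + e`, standardized to unit variance by construction
#' (`U` a shared confounder, `c = confounder_strength`); the outcome
#' cohort's liability is
#' `L = causal_beta * X' + G alpha + c U + e'` (its own unobserved exposure
#' `X'`), also unit variance, with case status `L > qnorm(1 - prevalence)`.
#' Pleiotropic direct effects `alpha` are drawn
#' `N(pleiotropy_mean, pleiotropy_sd^2)` afresh for each simulated study
#' (`pleiotropy_mean = 0` is balanced pleiotropy); per-SNP MAFs and
#' instrument effects `gamma` are resolved once here, so a config describes
#' a fixed "study design" that can be replicated.
#'
#' The defaults mirror the motivating cortisol-periodontitis setting
#' qualitatively at desk scale: one block of 3 correlated instruments from
#' a single locus, cohorts of 5,000, expected per-instrument F well above
#' 30, outcome prevalence 0.38 (the case fraction of a 17,353 / 28,210
#' case-control GWAS), and a modest shared confounder.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_exposure,n_outcome Cohort sizes for the exposure and outcome
#'   GWAS (disjoint by construction).
#' @param n_snps Number of instrument SNPs.
#' @param block_size LD block size; must divide `n_snps`.
#' @param rho_block Latent AR(1) correlation within a block, in \[0, 1).
#' @param maf Either a length-2 range in (0, 0.5\] to draw per-SNP MAFs
#'   from, or a length-`n_snps` vector of fixed MAFs.
#' @param gamma Per-allele instrument effects on the (standardized)
#'   exposure; scalar recycled or length-`n_snps` vector.
#' @param causal_beta Effect of the exposure on the outcome liability per
#'   SD of exposure.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-SNP direct
#'   (horizontal-pleiotropy) effects on the liability; both 0 disables
#'   pleiotropy.
#' @param confounder_strength Loading `c` of the shared standard-normal
#'   confounder on both exposure and liability.
#' @param prevalence Outcome case fraction targeted by the liability
#'   threshold, in (0, 1).
#' @return Object of class `simulation_config` with resolved per-SNP
#'   `maf` and `gamma` vectors, SNP identifiers, and the true dosage LD
#'   matrix implied by the copula (`ld_true`).
#' @export
simulation_config <- function(seed = 1L, n_exposure = 5000L,
                              n_outcome = 5000L, n_snps = 3L,
                              block_size = n_snps, rho_block = 0.5,
                              maf = c(0.2, 0.5), gamma = 0.1,
                              causal_beta = 0, pleiotropy_mean = 0,
                              pleiotropy_sd = 0, confounder_strength = 0.3,
                              prevalence = 0.38) {
  stopifnot(n_exposure >= 2, n_outcome >= 2, n_snps >= 1,
            block_size >= 1, n_snps %% block_size == 0,
            rho_block >= 0, rho_block < 1,
            prevalence > 0, prevalence < 1,
            pleiotropy_sd >= 0, confounder_strength >= 0)
  if (any(maf <= 0) || any(maf > 0.5)) {
    stop("maf values must lie in (0, 0.5]", call. = FALSE)
  }
  set.seed(seed)
  maf <- if (length(maf) == 2L && n_snps != 2L) {
    stats::runif(n_snps, maf[1], maf[2])
  } else {
    rep_len(maf, n_snps)
  }
  gamma <- rep_len(gamma, n_snps)
  snp_id <- sprintf("rs%04d", seq_len(n_snps))
  latent <- latent_block_corr(n_snps, block_size, rho_block)
  ld_true <- diag(n_snps)
  for (i in seq_len(n_snps)) {
    for (j in seq_len(n_snps)) {
      if (i < j && latent[i, j] != 0) {
        ld_true[i, j] <- ld_true[j, i] <- allele_corr(maf[i], maf[j],
                                                      latent[i, j])
      }
    }
  }
  dimnames(ld_true) <- list(snp_id, snp_id)
  structure(
    list(seed = as.integer(seed), n_exposure = as.integer(n_exposure),
         n_outcome = as.integer(n_outcome), n_snps = as.integer(n_snps),
         block_size = as.integer(block_size), rho_block = rho_block,
         maf = maf, gamma = gamma, causal_beta = causal_beta,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         confounder_strength = confounder_strength, prevalence = prevalence,
         snp_id = snp_id, latent_corr = latent, ld_true = ld_true),
    class = "simulation_config"
  )
}

# dosage covariance implied by the copula: var_j = 2 p_j (1 - p_j)
dosage_cov <- function(config) {
  v <- 2 * config$maf * (1 - config$maf)
  config$ld_true * tcrossprod(sqrt(v))
}

# one cohort of dosages: two haplotypes from the thresholded copula
draw_cohort <- function(n, config) {
  k <- config$n_snps
  chol_u <- chol(config$latent_corr)
  thr <- stats::qnorm(config$maf)
  dos <- matrix(0L, n, k)
  for (h in 1:2) {
    z <- matrix(stats::rnorm(n * k), n, k) %*% chol_u
    dos <- dos + (sweep(z, 2, thr, "<") + 0L)
  }
  colnames(dos) <- config$snp_id
  dos
}

#' Simulate genotype dosages for both cohorts
#'
#' Draws the exposure and outcome cohorts independently from the same
#' Gaussian-copula LD structure: per haplotype, a latent normal vector with
#' block-AR(1) correlation is thresholded at each SNP's MAF quantile, and
#' the dosage is the sum of the two haplotype alleles (counts in 0..2).
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return List with integer dosage matrices `exposure`
#'   (`n_exposure x n_snps`) and `outcome` (`n_outcome x n_snps`).
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  list(exposure = draw_cohort(config$n_exposure, config),
       outcome = draw_cohort(config$n_outcome, config))
}

#' Simulate phenotypes on top of genotype dosages
#'
#' The exposure cohort gets the continuous exposure
#' `X = G gamma + c U + e` with residual variance chosen so `var(X) = 1`;
#' the outcome cohort gets case labels from the liability
#' `L = causal_beta * X' + G alpha + c U + e'` (its own latent exposure
#' `X'`, the same shared confounder `U`), with residual variance chosen so
#' `var(L) = 1`, thresholded at `qnorm(1 - prevalence)`. Pleiotropic
#' effects `alpha` are drawn here.
#'
#' @param config A [simulation_config()].
#' @param dosages Output of [simulate_genotypes()].
#' @return List: `exposure` (numeric, exposure cohort), `case_status`
#'   (0/1, outcome cohort), `alpha` (realized pleiotropic effects),
#'   `liability` (outcome-cohort liability).
#' @export
simulate_phenotypes <- function(config, dosages) {
  stopifnot(inherits(config, "simulation_config"))
  gamma <- config$gamma
  cc <- config$confounder_strength
  beta <- config$causal_beta
  sigma_g <- dosage_cov(config)
  var_gx <- drop(crossprod(gamma, sigma_g %*% gamma))
  var_ex <- 1 - var_gx - cc^2
  if (var_ex <= 0) {
    stop("instrument and confounder variance exceed 1; weaken gamma or the confounder",
         call. = FALSE)
  }
  center_x <- drop(crossprod(2 * config$maf, gamma)) # E[G gamma]

  make_exposure <- function(g) {
    n <- nrow(g)
    u <- stats::rnorm(n)
    x <- drop(g %*% gamma) - center_x + cc * u +
      stats::rnorm(n, 0, sqrt(var_ex))
    list(x = x, u = u)
  }

  exp_ph <- make_exposure(dosages$exposure)
  alpha <- stats::rnorm(config$n_snps, config$pleiotropy_mean,
                        config$pleiotropy_sd)
  out_ph <- make_exposure(dosages$outcome)
  var_l0 <- beta^2 + drop(crossprod(alpha, sigma_g %*% alpha)) + cc^2 +
    2 * beta * drop(crossprod(gamma, sigma_g %*% alpha)) + 2 * beta * cc^2
  var_el <- 1 - var_l0
  if (var_el <= 0) {
    stop("liability variance from causal, pleiotropic and confounder terms exceeds 1",
         call. = FALSE)
  }
  n_out <- nrow(dosages$outcome)
  liability <- beta * out_ph$x +
    drop(dosages$outcome %*% alpha) - drop(crossprod(2 * config$maf, alpha)) +
    cc * out_ph$u + stats::rnorm(n_out, 0, sqrt(var_el))
  cases <- as.integer(liability > stats::qnorm(1 - config$prevalence))
  list(exposure = exp_ph$x, case_status = cases, alpha = alpha,
       liability = liability)
}

#' Per-SNP GWAS of a phenotype on dosages
#'
#' For each SNP separately: simple linear regression (continuous
#' phenotype) or maximum-likelihood logistic regression (binary) of the
#' phenotype on the dosage, yielding beta, SE, Wald P, effect-allele
#' frequency and sample size in the package's summary-statistic format.
#' The counted (effect) allele is labelled `A`, the other `G`. SNPs that
#' are monomorphic in the sample, or whose logistic fit fails to converge
#' (separation), are dropped with a warning.
#'
#' @param dosages Dosage matrix (individuals x SNPs, named columns).
#' @param phenotype Numeric phenotype (0/1 when `binary = TRUE`).
#' @param binary Fit logistic rather than linear regressions.
#' @return A `gwas_sumstats` data frame, one row per retained SNP.
#' @export
gwas_fit <- function(dosages, phenotype, binary = FALSE) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  stopifnot(length(phenotype) == n)
  ids <- colnames(dosages)
  if (is.null(ids)) ids <- sprintf("snp%02d", seq_len(ncol(dosages)))
  eaf <- colMeans(dosages) / 2
  poly <- eaf > 0 & eaf < 1
  if (any(!poly)) {
    warning("dropping monomorphic SNP(s): ",
            paste(ids[!poly], collapse = ", "), call. = FALSE)
  }
  if (binary) {
    res <- lapply(which(poly), function(j) {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, dosages[, j]), phenotype,
                       family = stats::binomial())
      )
      b <- fit$coefficients[2]
      cov <- tryCatch(chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE]),
                      error = function(e) matrix(NA_real_, 2, 2))
      se <- sqrt(cov[2, 2])
      if (!fit$converged || !is.finite(b) || !is.finite(se) ||
          abs(b) > 15 || se > 100) {
        return(NULL) # separation / non-convergence
      }
      c(beta = unname(b), se = unname(se))
    })
    bad <- vapply(res, is.null, logical(1))
    if (any(bad)) {
      warning("dropping SNP(s) with non-converged logistic fits: ",
              paste(ids[which(poly)][bad], collapse = ", "), call. = FALSE)
    }
    keep <- which(poly)[!bad]
    beta <- vapply(res[!bad], `[[`, numeric(1), "beta")
    se <- vapply(res[!bad], `[[`, numeric(1), "se")
  } else {
    keep <- which(poly)
    x <- dosages[, keep, drop = FALSE]
    xm <- colMeans(x)
    sxx <- colSums(x^2) - n * xm^2
    ym <- mean(phenotype)
    syy <- sum(phenotype^2) - n * ym^2
    sxy <- drop(crossprod(x, phenotype)) - n * xm * ym
    beta <- sxy / sxx
    rss <- pmax(syy - beta * sxy, 0)
    se <- sqrt(rss / (n - 2) / sxx)
  }
  z <- ifelse(se > 0, abs(beta / se), 0)
  pvalue <- ifelse(se > 0, pmax(2 * stats::pnorm(-z), .Machine$double.xmin), 1)
  out <- data.frame(
    snp_id = ids[keep], chromosome = "1",
    effect_allele = "A", other_allele = "G",
    eaf = eaf[keep], beta = unname(beta), se = unname(se),
    pvalue = unname(pvalue), n = n, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- unique(c("gwas_sumstats", class(out)))
  out
}

#' Simulate a complete two-sample GWAS study
#'
#' Composes [simulate_genotypes()], [simulate_phenotypes()] and
#' [gwas_fit()] under a single seeded RNG stream: exposure-cohort linear
#' GWAS, outcome-cohort logistic GWAS, the true LD matrix, and the
#' generating truth. With `dir` set, writes `exposure.tsv`, `outcome.tsv`
#' and `ld.tsv` in the package's file dialects plus a flat key-value
#' `truth.tsv`; identical seeds give byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory (created if missing).
#' @param seed Seed for the study draw; defaults to `config$seed`. Vary it
#'   (keeping the config fixed) to draw replicate studies from the same
#'   design.
#' @return List: `exposure` and `outcome` (`gwas_sumstats`), `ld` (true
#'   dosage LD), `truth` (list: `gamma`, `alpha`, `causal_beta`, `ld_true`,
#'   `maf`, `case_fraction`, per-SNP marginal `variance_explained` and the
#'   expected per-SNP `f_expected`), and `paths` when `dir` was given.
#' @export
simulate_study <- function(config, dir = NULL, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  geno <- simulate_genotypes(config)
  pheno <- simulate_phenotypes(config, geno)
  exposure <- gwas_fit(geno$exposure, pheno$exposure)
  outcome <- gwas_fit(geno$outcome, pheno$case_status, binary = TRUE)
  sigma_g <- dosage_cov(config)
  v <- diag(sigma_g)
  marg_beta <- drop(sigma_g %*% config$gamma) / v # marginal per-SNP slopes
  r2 <- marg_beta^2 * v
  truth <- list(
    gamma = config$gamma, alpha = pheno$alpha,
    causal_beta = config$causal_beta, ld_true = config$ld_true,
    maf = config$maf, case_fraction = mean(pheno$case_status),
    variance_explained = r2,
    f_expected = 1 + config$n_exposure * r2 / (1 - r2)
  )
  out <- list(exposure = exposure, outcome = outcome, ld = config$ld_true,
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(exposure = file.path(dir, "exposure.tsv"),
                  outcome = file.path(dir, "outcome.tsv"),
                  ld = file.path(dir, "ld.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    write_summary_stats(exposure, paths$exposure)
    write_summary_stats(outcome, paths$outcome)
    write_ld_matrix(config$ld_true, paths$ld)
    fmt <- function(x) paste(sprintf("%.17g", x), collapse = ",")
    truth_lines <- c(
      sprintf("causal_beta\t%s", fmt(truth$causal_beta)),
      sprintf("gamma\t%s", fmt(truth$gamma)),
      sprintf("alpha\t%s", fmt(truth$alpha)),
      sprintf("maf\t%s", fmt(truth$maf)),
      sprintf("case_fraction\t%s", fmt(truth$case_fraction)),
      sprintf("variance_explained\t%s", fmt(truth$variance_explained)),
      sprintf("seed\t%d", seed)
    )
    writeLines(truth_lines, paths$truth)
    out$paths <- paths
  }
  out
}
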