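#' Plasma-cortisol instrument fixture
#'
#' The three SERPINA1/SERPINA6-locus variants (rs11621961, rs12589136,
#' rs2749527) used to instrument morning plasma cortisol, with their
#' published per-allele associations from the CORtisol NETwork (CORNET)
#' GWAS meta-analysis (n = 12,597; cortisol in SD units), shipped as a
#' ready-made exposure dataset.
#'
#' @return A `gwas_sumstats` data frame with three rows.
#' @export
#' @examples
#' instr <- cortisol_instruments()
#' f_statistic(instr$beta, instr$se)
cortisol_instruments <- function() {
  read_summary_stats(system.file("extdata", "cortisol_instruments.tsv",
                                 package = "mrsuite", mustWork = TRUE))
}

.as_sumstats_input <- function(x, what) {
  if (is.character(x) && length(x) == 1L) return(read_summary_stats(x))
  if (is.data.frame(x)) return(validate_sumstats(as.data.frame(x)))
  stop(what, " must be a file path or a summary-statistics data frame",
       call. = FALSE)
}

.as_ld_input <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) return(read_ld_matrix(x))
  as_ld_matrix(x)
}

#' Run the full two-sample MR pipeline
#'
#' Orchestrates the package end to end: instrument selection (P-value
#' filter with optional greedy LD clumping), allele harmonization,
#' instrument-strength reporting, the requested estimators, heterogeneity
#' and Egger-intercept diagnostics, leave-one-out analysis, and (when the
#' outcome case/control split is supplied) the a priori power calculation.
#' The IVW flavour follows the data: correlated-instrument GLS when a
#' non-identity LD matrix is supplied, classic independent-instrument IVW
#' otherwise. Estimators whose minimum instrument count is not met are
#' skipped with a message rather than aborting. The run is a pure function
#' of its inputs: identical inputs give identical outputs, and the written
#' tables carry no timestamps.
#'
#' @param exposure,outcome Summary statistics: file paths (the tab-delimited
#'   dialect of [read_summary_stats()]) or `gwas_sumstats` data frames.
#' @param ld Optional LD matrix (path or matrix) covering the instruments.
#' @param p_threshold Instrument inclusion P-value threshold (default
#'   5e-8; use 5e-5 with `r2_threshold = 0.2` for a liberal polygenic set).
#' @param r2_threshold Optional squared-LD clumping threshold.
#' @param methods Estimators to run, a subset of
#'   `c("ivw", "ivw_re", "egger", "raps")`; per-SNP Wald ratios are always
#'   reported.
#' @param palindromic_eaf_window Passed to [harmonize()].
#' @param n_cases,n_controls Optional outcome GWAS case/control counts for
#'   the power stage.
#' @param target_power Target power for the minimum detectable OR.
#' @param output_dir Optional directory; when given, tab-delimited
#'   `instruments.tsv`, `harmonized.tsv`, `estimates.tsv`,
#'   `leave_one_out.tsv` and a consolidated `report.tsv` are written.
#' @return Object of class `mr_report`: list with `selection`,
#'   `harmonized`, `instruments` (an `instrument_report`), `wald_ratios`,
#'   `estimates` (data frame, one row per method), `heterogeneity`,
#'   `egger_intercept`, `leave_one_out`, and `power` (or `NULL`).
#' @export
run_mr_pipeline <- function(exposure, outcome, ld = NULL,
                            p_threshold = 5e-8, r2_threshold = NULL,
                            methods = c("ivw", "ivw_re", "egger", "raps"),
                            palindromic_eaf_window = 0.08,
                            n_cases = NULL, n_controls = NULL,
                            target_power = 0.8, output_dir = NULL) {
  methods <- match.arg(methods, c("ivw", "ivw_re", "egger", "raps"),
                       several.ok = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  exposure <- stage("read exposure", .as_sumstats_input(exposure, "exposure"))
  outcome <- stage("read outcome", .as_sumstats_input(outcome, "outcome"))
  ld <- stage("read LD", .as_ld_input(ld))

  selected <- stage("instrument selection",
                    select_instruments(exposure, p_threshold, ld, r2_threshold))
  if (length(selected) == 0L) {
    stop("pipeline stage 'instrument selection' failed: no instrument passes P < ",
         format(p_threshold), call. = FALSE)
  }
  exposure_sel <- exposure[match(selected, exposure$snp_id), , drop = FALSE]
  h <- stage("harmonization",
             harmonize(exposure_sel, outcome, ld,
                       palindromic_eaf_window = palindromic_eaf_window))
  k <- nrow(h$data)
  correlated <- !is_identity_ld(h$ld)

  instruments <- stage("instrument report",
                       instrument_report(
                         structure(data.frame(
                           snp_id = h$data$snp_id,
                           effect_allele = h$data$effect_allele,
                           other_allele = h$data$other_allele,
                           eaf = h$data$eaf_exposure,
                           beta = h$data$beta_exposure,
                           se = h$data$se_exposure,
                           pvalue = exposure_sel$pvalue[match(h$data$snp_id,
                                                              exposure_sel$snp_id)],
                           stringsAsFactors = FALSE),
                           class = c("gwas_sumstats", "data.frame")),
                         ld = if (correlated) h$ld else NULL))

  wald <- lapply(seq_len(k), function(i) {
    d <- h$data[i, ]
    cbind(data.frame(snp_id = d$snp_id, stringsAsFactors = FALSE),
          as.data.frame(wald_ratio(d$beta_exposure, d$se_exposure,
                                   d$beta_outcome, d$se_outcome)))
  })
  wald <- do.call(rbind, wald)

  estimates <- list()
  skip_note <- function(m, need) {
    message(sprintf("skipping %s: requires >= %d instruments, have %d",
                    m, need, k))
  }
  if ("ivw" %in% methods) {
    estimates$ivw <- stage("IVW",
                           if (correlated) mr_ivw_correlated(h) else mr_ivw(h))
  }
  if ("ivw_re" %in% methods) {
    if (k >= 2) {
      estimates$ivw_re <- stage("IVW (random effects)",
                                mr_ivw(h, model = "multiplicative_random"))
    } else skip_note("ivw_re", 2)
  }
  egger <- NULL
  if ("egger" %in% methods) {
    if (k >= 3) {
      egger <- stage("MR-Egger", mr_egger(h))
      estimates$egger <- egger$slope
    } else skip_note("egger", 3)
  }
  if ("raps" %in% methods) {
    if (k >= 3) {
      estimates$raps <- stage("RAPS", mr_raps(h))
    } else skip_note("raps", 3)
  }
  est_table <- do.call(rbind, lapply(estimates, as.data.frame))
  rownames(est_table) <- NULL

  heterogeneity <- if (k >= 2) stage("heterogeneity", mr_heterogeneity(h)) else NULL
  loo <- if (k >= 2) stage("leave-one-out", mr_leave_one_out(h)) else NULL

  power <- NULL
  if (!is.null(n_cases) && !is.null(n_controls)) {
    r2 <- if (correlated) instruments$r2_ld_adjusted else instruments$r2_sum
    power <- stage("power", list(
      r2 = r2, n_cases = n_cases, n_controls = n_controls,
      target_power = target_power,
      min_detectable_or = min_detectable_or(n_cases, n_controls, r2,
                                            target_power = target_power)
    ))
  }

  report <- structure(
    list(selection = data.frame(snp_id = selected,
                                p_threshold = p_threshold,
                                r2_threshold = if (is.null(r2_threshold))
                                  NA_real_ else r2_threshold,
                                stringsAsFactors = FALSE),
         harmonized = h, instruments = instruments, wald_ratios = wald,
         estimates = est_table, heterogeneity = heterogeneity,
         egger_intercept = if (is.null(egger)) NULL else egger$intercept,
         leave_one_out = loo, power = power),
    class = "mr_report"
  )
  if (!is.null(output_dir)) write_mr_report(report, output_dir)
  report
}

# write the pipeline's tab-delimited result tables (no timestamps: outputs
# must be byte-identical across reruns on identical inputs)
write_mr_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, file) {
    utils::write.table(x, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  inst <- report$instruments
  wt(cbind(inst$per_snp,
           min_f = inst$min_f, r2_sum = inst$r2_sum,
           r2_ld_adjusted = inst$r2_ld_adjusted), "instruments.tsv")
  wt(report$harmonized$data, "harmonized.tsv")
  wt(report$estimates, "estimates.tsv")
  if (!is.null(report$leave_one_out)) wt(report$leave_one_out, "leave_one_out.tsv")
  consolidated <- report$estimates
  consolidated$Q <- if (is.null(report$heterogeneity)) NA_real_ else report$heterogeneity$Q
  consolidated$i_squared <- if (is.null(report$heterogeneity)) NA_real_ else report$heterogeneity$i_squared
  consolidated$egger_intercept <- if (is.null(report$egger_intercept)) NA_real_ else report$egger_intercept$estimate
  consolidated$egger_intercept_p <- if (is.null(report$egger_intercept)) NA_real_ else report$egger_intercept$pvalue
  consolidated$min_f <- inst$min_f
  wt(consolidated, "report.tsv")
  invisible(dir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR analysis: %d instrument(s), min F = %.1f, r2 (sum) = %.4f\n",
              x$instruments$n_snps, x$instruments$min_f, x$instruments$r2_sum))
  df <- x$estimates
  cat("\nEstimates (OR per 1-SD exposure):\n")
  print(data.frame(method = df$method, n_snps = df$n_snps,
                   OR = sprintf("%.3f", df$odds_ratio),
                   `95% CI` = sprintf("[%.3f, %.3f]", df$or_ci_low, df$or_ci_high),
                   P = sprintf("%.3g", df$pvalue), check.names = FALSE),
        row.names = FALSE)
  if (!is.null(x$heterogeneity)) {
    cat("\n"); print(x$heterogeneity)
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("Egger intercept: %.4f (SE %.4f), P = %.3g\n",
                x$egger_intercept$estimate, x$egger_intercept$se,
                x$egger_intercept$pvalue))
  }
  if (!is.null(x$power)) {
    cat(sprintf("Power: minimum detectable OR at %.0f%% power = %.3f (r2 = %.4f)\n",
                100 * x$power$target_power, x$power$min_detectable_or,
                x$power$r2))
  }
  invisible(x)
}
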