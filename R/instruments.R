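#' First-stage F statistic of a genetic instrument
#'
#' `F = (beta / se)^2`, the squared z score of the variant-exposure
#' association; values above 10 conventionally indicate a non-weak
#' instrument. Vectorized.
#'
#' @param beta Per-allele effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Numeric vector of F statistics.
#' @export
#' @examples
#' f_statistic(-0.077, 0.014) # 30.25
f_statistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) {
    stop("se must be strictly positive", call. = FALSE)
  }
  (beta / se)^2
}

#' Variance of a unit-variance trait explained by a variant
#'
#' Under Hardy-Weinberg equilibrium a biallelic variant with effect-allele
#' frequency `p` and per-allele effect `beta` on a unit-variance trait
#' explains `2 p (1 - p) beta^2` of the trait variance. Vectorized.
#'
#' @param eaf Effect-allele frequency in (0, 1).
#' @param beta Per-allele effect on the standardized trait.
#' @return Fraction of variance explained per variant.
#' @export
variance_explained <- function(eaf, beta) {
  if (any(!is.finite(eaf) | eaf <= 0 | eaf >= 1)) {
    stop("eaf must lie strictly in (0, 1)", call. = FALSE)
  }
  2 * eaf * (1 - eaf) * beta^2
}

#' Total variance explained by a set of (possibly correlated) instruments
#'
#' Returns both the plain sum of per-SNP terms and an LD-adjusted total,
#' the quadratic form `b' D R^- D b` with `D = diag(sqrt(2 p (1 - p)))` and
#' `R^-` the Moore-Penrose pseudo-inverse of the LD matrix. Plain summation
#' over correlated SNPs double-counts shared signal; with identity LD the
#' two coincide.
#'
#' @inheritParams variance_explained
#' @param ld Optional signed LD matrix over the variants (identity if
#'   `NULL`).
#' @return List with elements `sum` and `ld_adjusted`.
#' @export
total_variance_explained <- function(eaf, beta, ld = NULL) {
  per_snp <- variance_explained(eaf, beta)
  if (is.null(ld)) {
    return(list(sum = sum(per_snp), ld_adjusted = sum(per_snp)))
  }
  ld <- as_ld_matrix(ld)
  stopifnot(nrow(ld) == length(beta))
  d <- sqrt(2 * eaf * (1 - eaf)) * beta
  adj <- drop(crossprod(d, MASS::ginv(ld) %*% d))
  list(sum = sum(per_snp), ld_adjusted = adj)
}

#' Select instruments by P-value threshold and greedy LD clumping
#'
#' Candidates are the records with `pvalue < p_threshold`, sorted by
#' ascending P (ties broken by lexicographic rsID, so the result is
#' invariant to input row order). Greedy clumping then repeatedly keeps the
#' smallest-P remaining candidate and removes every remaining candidate
#' whose squared LD with it is at least `r2_threshold` — only the variant
#' with the smallest P-value in each correlated clump survives.
#'
#' @param records `gwas_sumstats` data frame of exposure associations.
#' @param p_threshold Inclusion threshold on the association P-value.
#' @param ld Signed LD matrix covering every record passing `p_threshold`;
#'   may be `NULL` only when `r2_threshold` is `NULL` (no clumping).
#' @param r2_threshold Squared-correlation threshold for clumping (e.g.
#'   0.2); `NULL` disables clumping and keeps all P-passing variants.
#' @return Character vector of kept `snp_id`s in keep (ascending-P) order;
#'   empty (with a warning) if nothing passes the P filter.
#' @export
select_instruments <- function(records, p_threshold, ld = NULL,
                               r2_threshold = NULL) {
  records <- validate_sumstats(as.data.frame(records))
  cand <- records[records$pvalue < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning(sprintf("no SNP passes P < %g", p_threshold), call. = FALSE)
    return(character(0))
  }
  cand <- cand[order(cand$pvalue, cand$snp_id), , drop = FALSE]
  if (is.null(r2_threshold)) return(cand$snp_id)
  if (is.null(ld)) stop("clumping requires an LD matrix", call. = FALSE)
  ld <- as_ld_matrix(ld)
  missing_ld <- setdiff(cand$snp_id, rownames(ld))
  if (length(missing_ld) > 0L) {
    stop("LD matrix does not cover candidate SNP(s): ",
         paste(missing_ld, collapse = ", "), call. = FALSE)
  }
  remaining <- cand$snp_id
  kept <- character(0)
  while (length(remaining) > 0L) {
    top <- remaining[1]
    kept <- c(kept, top)
    r2 <- ld[top, remaining]^2
    remaining <- remaining[r2 < r2_threshold & remaining != top]
  }
  kept
}

#' Instrument-strength report
#'
#' Per-SNP F statistics and variance explained, the minimum F, and the
#' total variance explained both as a plain sum and LD-adjusted (see
#' [total_variance_explained()]).
#'
#' @param records `gwas_sumstats` data frame of the selected instruments
#'   (exposure associations on a unit-variance trait).
#' @param ld Optional signed LD matrix over the instruments.
#' @return Object of class `instrument_report`: list with `per_snp` (data
#'   frame `snp_id`, `f_statistic`, `variance_explained`), `min_f`,
#'   `r2_sum`, `r2_ld_adjusted`, `n_snps`.
#' @export
instrument_report <- function(records, ld = NULL) {
  records <- validate_sumstats(as.data.frame(records))
  f <- f_statistic(records$beta, records$se)
  r2 <- variance_explained(records$eaf, records$beta)
  tot <- total_variance_explained(records$eaf, records$beta,
                                  if (is.null(ld)) NULL else as_ld_matrix(ld)[records$snp_id, records$snp_id])
  structure(
    list(per_snp = data.frame(snp_id = records$snp_id, f_statistic = f,
                              variance_explained = r2,
                              stringsAsFactors = FALSE),
         min_f = min(f), r2_sum = tot$sum, r2_ld_adjusted = tot$ld_adjusted,
         n_snps = nrow(records)),
    class = "instrument_report"
  )
}

#' @export
print.instrument_report <- function(x, ...) {
  cat(sprintf("Instrument report: %d SNP(s), min F = %.1f\n", x$n_snps, x$min_f))
  cat(sprintf("  variance explained: sum = %.4f, LD-adjusted = %.4f\n",
              x$r2_sum, x$r2_ld_adjusted))
  print(x$per_snp, ...)
  invisible(x)
}
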