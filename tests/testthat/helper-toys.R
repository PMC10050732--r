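# shared toy builders for the test suite

# random valid summary-statistics table
random_sumstats <- function(k, seed = NULL, ids = sprintf("rs%03d", seq_len(k))) {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(
    snp_id = ids,
    chromosome = "14",
    effect_allele = sample(c("A", "C", "G", "T"), k, replace = TRUE),
    other_allele = NA_character_,
    eaf = runif(k, 0.05, 0.95),
    beta = rnorm(k, 0, 0.1),
    se = runif(k, 0.005, 0.05),
    pvalue = runif(k, .Machine$double.xmin, 1),
    n = 12597,
    stringsAsFactors = FALSE
  )
  # other allele distinct from effect allele
  df$other_allele <- vapply(df$effect_allele, function(a) {
    sample(setdiff(c("A", "C", "G", "T"), a), 1)
  }, character(1))
  validate_sumstats(df)
  df
}

# random harmonized dataset with optional correlated LD
random_harmonized <- function(k, seed = NULL, causal_beta = 0.2,
                              correlated = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  bx <- runif(k, 0.05, 0.2) * sample(c(-1, 1), k, replace = TRUE)
  sx <- runif(k, 0.005, 0.02)
  sy <- runif(k, 0.01, 0.05)
  by <- causal_beta * bx + rnorm(k, 0, sy)
  ld <- if (correlated) {
    r <- 0.4^abs(outer(seq_len(k), seq_len(k), "-"))
    r
  } else NULL
  harmonized_dataset(bx, sx, by, sy, ld = ld)
}

# AR(1) correlation matrix helper
ar1_corr <- function(k, rho) rho^abs(outer(seq_len(k), seq_len(k), "-"))

# write a sumstats data frame to a temp file, returning the path
write_tmp_sumstats <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write_summary_stats(df, path)
  path
}
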