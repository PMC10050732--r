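#' Column mapping for GWAS summary-statistic files
#'
#' Builds a named character vector that maps the package's internal field
#' names to the column headers of a tab-delimited summary-statistics file.
#' The defaults (`SNP`/`CHR`/`EA`/`OA`/`EAF`/`BETA`/`SE`/`P`/`N`) match
#' common consortium exports; override individual entries to read other
#' dialects.
#'
#' @param snp_id,chromosome,effect_allele,other_allele,eaf,beta,se,pvalue,n
#'   Column headers used in the file for each field. `chromosome` and `n`
#'   are optional fields: if the named column is absent from the file the
#'   field is filled with `NA` rather than raising an error.
#' @return Named character vector (names are internal field names).
#' @export
#' @examples
#' gwas_columns(pvalue = "P_VALUE", n = "SAMPLE_SIZE")
gwas_columns <- function(snp_id = "SNP", chromosome = "CHR",
                         effect_allele = "EA", other_allele = "OA",
                         eaf = "EAF", beta = "BETA", se = "SE",
                         pvalue = "P", n = "N") {
  c(snp_id = snp_id, chromosome = chromosome,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n)
}

# fields that must be present in every file / record
.required_fields <- c("snp_id", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "pvalue")
.valid_alleles <- c("A", "C", "G", "T")

#' Validate GWAS summary-statistic records
#'
#' Checks the per-record invariants: alleles in A/C/G/T with effect allele
#' distinct from the other allele, effect-allele frequency strictly inside
#' (0, 1), positive standard error, P-value in (0, 1], finite beta.
#' Violations raise an error naming the offending SNP and field.
#'
#' @param x Data frame of summary statistics (internal column names).
#' @return `x` invisibly, with class `gwas_sumstats` prepended.
#' @export
validate_sumstats <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.required_fields, names(x))
  if (length(missing_cols) > 0L) {
    stop("summary statistics lack required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fail <- function(rows, field, why) {
    if (any(rows)) {
      stop(sprintf("invalid %s for SNP %s: %s", field,
                   paste(unique(x$snp_id[rows]), collapse = ", "), why),
           call. = FALSE)
    }
  }
  if (nrow(x) > 0L) {
    fail(!(x$effect_allele %in% .valid_alleles), "effect_allele",
         "must be one of A/C/G/T")
    fail(!(x$other_allele %in% .valid_alleles), "other_allele",
         "must be one of A/C/G/T")
    fail(x$effect_allele == x$other_allele, "alleles",
         "effect and other allele must differ")
    fail(!is.finite(x$eaf) | x$eaf <= 0 | x$eaf >= 1, "eaf",
         "must lie strictly in (0, 1)")
    fail(!is.finite(x$beta), "beta", "must be finite")
    fail(!is.finite(x$se) | x$se <= 0, "se", "must be positive")
    fail(!is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1, "pvalue",
         "must lie in (0, 1]")
    if (anyDuplicated(x$snp_id)) {
      stop("duplicated SNP identifier(s): ",
           paste(unique(x$snp_id[duplicated(x$snp_id)]), collapse = ", "),
           call. = FALSE)
    }
  }
  class(x) <- unique(c("gwas_sumstats", class(x)))
  invisible(x)
}

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file (header row required) into
#' a validated data frame with the package's internal column names
#' (`snp_id`, `chromosome`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `pvalue`, `n`). Row order is preserved. Allele letters are
#' upper-cased.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Mapping from internal fields to file headers, see
#'   [gwas_columns()].
#' @return A `gwas_sumstats` data frame, one row per variant.
#' @export
read_summary_stats <- function(path, column_map = gwas_columns()) {
  # colClasses = "character": an allele column of all T must not become
  # logical TRUE; numeric fields are converted explicitly below
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  for (field in .required_fields) {
    if (!column_map[[field]] %in% names(raw)) {
      stop(sprintf("column '%s' (field '%s') not found in %s",
                   column_map[[field]], field, path), call. = FALSE)
    }
  }
  grab <- function(field, default = NA) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  out <- data.frame(
    snp_id        = as.character(grab("snp_id")),
    chromosome    = as.character(grab("chromosome")),
    effect_allele = toupper(as.character(grab("effect_allele"))),
    other_allele  = toupper(as.character(grab("other_allele"))),
    eaf           = as.numeric(grab("eaf")),
    beta          = as.numeric(grab("beta")),
    se            = as.numeric(grab("se")),
    pvalue        = as.numeric(grab("pvalue")),
    n             = as.numeric(grab("n")),
    stringsAsFactors = FALSE
  )
  validate_sumstats(out)
  class(out) <- unique(c("gwas_sumstats", class(out)))
  out
}

#' Write GWAS summary statistics
#'
#' Writes the tab-delimited dialect read by [read_summary_stats()].
#' Numeric columns are serialized with 17 significant digits so that a
#' write/read round trip reproduces the records exactly.
#'
#' @param x A `gwas_sumstats` data frame (internal column names).
#' @param path Output file path.
#' @param column_map Header names to emit, see [gwas_columns()].
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path, column_map = gwas_columns()) {
  validate_sumstats(x)
  fields <- intersect(names(column_map), names(x))
  out <- x[, fields, drop = FALSE]
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.17g", out[[j]]))
    }
  }
  names(out) <- column_map[fields]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct and validate an LD correlation matrix
#'
#' Enforces the LD-matrix contract: square, symmetric (within 1e-10, then
#' symmetrized), unit diagonal, entries in \[-1, 1\], and positive
#' semi-definite. An indefinite matrix (smallest eigenvalue below -1e-8, as
#' can arise from small reference panels) is repaired by adding a ridge
#' `delta * I` with `delta = |lambda_min| + 1e-8`, rescaling back to unit
#' diagonal, and warning. Entries are *signed* allelic correlations; squaring
#' happens only inside clumping.
#'
#' @param r Square numeric matrix of pairwise correlations.
#' @param snp_ids Variant identifiers (defaults to `colnames(r)`).
#' @return Validated matrix with `snp_ids` as dimnames.
#' @export
as_ld_matrix <- function(r, snp_ids = colnames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(r)))
  if (length(snp_ids) != nrow(r)) {
    stop("snp_ids length must match LD matrix dimension", call. = FALSE)
  }
  if (max(abs(r - t(r))) > 1e-10) {
    stop("LD matrix is not symmetric (tolerance 1e-10)", call. = FALSE)
  }
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-8) {
    stop("LD matrix must have unit diagonal", call. = FALSE)
  }
  if (max(abs(r)) > 1 + 1e-8) {
    stop("LD entries must lie in [-1, 1]", call. = FALSE)
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  lambda_min <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_min < -1e-8) {
    delta <- abs(lambda_min) + 1e-8
    warning(sprintf(
      "LD matrix is not positive semi-definite (min eigenvalue %.3g); adding ridge %.3g",
      lambda_min, delta), call. = FALSE)
    r <- r + diag(delta, nrow(r))
    r <- stats::cov2cor(r)
  }
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

#' Read / write an LD matrix
#'
#' Tab-delimited square matrix with rsID header row and rsID row names.
#'
#' @param path File path.
#' @return For `read_ld_matrix`, a validated LD matrix.
#' @export
read_ld_matrix <- function(path) {
  m <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  as_ld_matrix(as.matrix(m))
}

#' @rdname read_ld_matrix
#' @param r LD matrix (as from [as_ld_matrix()]).
#' @export
write_ld_matrix <- function(r, path) {
  out <- matrix(sprintf("%.17g", r), nrow(r), dimnames = dimnames(r))
  utils::write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Estimate LD from a genotype-dosage matrix
#'
#' Pairwise Pearson correlation of dosage columns (counts in \[0, 2\]),
#' e.g. from a reference panel, validated as an LD matrix.
#'
#' @param dosages Numeric matrix, individuals in rows, SNPs in columns
#'   (column names are the SNP identifiers).
#' @return Validated signed LD correlation matrix.
#' @export
ld_from_dosages <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2L) stop("need at least 2 individuals", call. = FALSE)
  sds <- apply(dosages, 2, stats::sd)
  if (any(sds == 0)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(dosages)))
    stop("constant dosage column for SNP ",
         paste(ids[sds == 0], collapse = ", "), call. = FALSE)
  }
  as_ld_matrix(stats::cor(dosages))
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) .complement[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations to the exposure's effect alleles over the
#' intersection of SNPs. Where the outcome's allele pair is swapped (or
#' strand-complement swapped) relative to the exposure, the outcome beta is
#' sign-flipped and its effect-allele frequency replaced by `1 - eaf`.
#' Palindromic SNPs (A/T or C/G) whose frequency is within
#' `palindromic_eaf_window` of 0.5 in either study are dropped (strand
#' cannot be resolved); remaining palindromic SNPs are aligned by frequency.
#' Allele pairs that are neither identical, swapped, nor strand complements
#' are dropped with a warning. Every exposure-side SNP receives a provenance
#' flag: `kept-as-is`, `outcome-flipped`, `dropped-palindromic`,
#' `dropped-missing` or `dropped-mismatch`.
#'
#' @param exposure,outcome `gwas_sumstats` data frames keyed by `snp_id`.
#' @param ld Optional LD matrix covering the retained SNPs; it is subset and
#'   reordered to the retained SNPs. If `NULL`, instruments are treated as
#'   uncorrelated (identity LD).
#' @param palindromic_eaf_window Half-width of the ambiguity window around
#'   eaf 0.5 for palindromic SNPs (default 0.08).
#' @return An object of class `mr_harmonized`: list with `data` (retained
#'   SNPs: exposure/outcome betas, SEs, frequencies, alleles), `ld`, and
#'   `provenance` (flag for every exposure SNP).
#' @export
harmonize <- function(exposure, outcome, ld = NULL,
                      palindromic_eaf_window = 0.08) {
  exposure <- validate_sumstats(as.data.frame(exposure))
  outcome <- validate_sumstats(as.data.frame(outcome))
  actions <- character(nrow(exposure))
  names(actions) <- exposure$snp_id
  rows <- vector("list", nrow(exposure))

  out_idx <- match(exposure$snp_id, outcome$snp_id)
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    j <- out_idx[i]
    if (is.na(j)) {
      actions[i] <- "dropped-missing"
      next
    }
    ou <- outcome[j, ]
    ea <- ex$effect_allele; oa <- ex$other_allele
    b <- ou$beta; q <- ou$eaf
    if (.is_palindromic(ea, oa)) {
      # palindromic: letters are identical on both strands, use frequency
      if (abs(ex$eaf - 0.5) < palindromic_eaf_window ||
          abs(q - 0.5) < palindromic_eaf_window) {
        actions[i] <- "dropped-palindromic"
        next
      }
      if (ou$effect_allele == oa) { # reported for the opposite allele label
        b <- -b; q <- 1 - q
      } else if (ou$effect_allele != ea) {
        actions[i] <- "dropped-mismatch"
        next
      }
      if ((q < 0.5) != (ex$eaf < 0.5)) { # strand flip: re-align by frequency
        b <- -b; q <- 1 - q
      }
    } else {
      oea <- ou$effect_allele; ooa <- ou$other_allele
      if (oea == ea && ooa == oa) {
        # aligned
      } else if (oea == oa && ooa == ea) {
        b <- -b; q <- 1 - q
      } else if (oea == .complement[ea] && ooa == .complement[oa]) {
        # same orientation, other strand
      } else if (oea == .complement[oa] && ooa == .complement[ea]) {
        b <- -b; q <- 1 - q
      } else {
        actions[i] <- "dropped-mismatch"
        next
      }
    }
    actions[i] <- if (identical(b, ou$beta)) "kept-as-is" else "outcome-flipped"
    rows[[i]] <- data.frame(
      snp_id = ex$snp_id,
      effect_allele = ea, other_allele = oa,
      beta_exposure = ex$beta, se_exposure = ex$se, eaf_exposure = ex$eaf,
      beta_outcome = b, se_outcome = ou$se, eaf_outcome = q,
      stringsAsFactors = FALSE
    )
  }
  dropped_mismatch <- names(actions)[actions == "dropped-mismatch"]
  if (length(dropped_mismatch) > 0L) {
    warning("dropped SNP(s) with unresolvable allele pairs: ",
            paste(dropped_mismatch, collapse = ", "), call. = FALSE)
  }
  data <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(data) || nrow(data) == 0L) {
    stop("no SNPs shared between exposure and outcome after harmonization",
         call. = FALSE)
  }
  rownames(data) <- NULL
  if (is.null(ld)) {
    ld <- diag(nrow(data))
    dimnames(ld) <- list(data$snp_id, data$snp_id)
  } else {
    ld <- as_ld_matrix(ld)
    missing_ld <- setdiff(data$snp_id, rownames(ld))
    if (length(missing_ld) > 0L) {
      stop("LD matrix does not cover SNP(s): ",
           paste(missing_ld, collapse = ", "), call. = FALSE)
    }
    ld <- ld[data$snp_id, data$snp_id, drop = FALSE]
  }
  structure(
    list(data = data, ld = ld,
         provenance = data.frame(snp_id = exposure$snp_id,
                                 action = unname(actions),
                                 stringsAsFactors = FALSE),
         palindromic_eaf_window = palindromic_eaf_window),
    class = "mr_harmonized"
  )
}

#' Build a harmonized dataset directly from vectors
#'
#' Convenience constructor used for toy examples, simulations and tests,
#' when the allele bookkeeping of [harmonize()] is not needed.
#'
#' @param beta_exposure,se_exposure Per-SNP exposure association and SE.
#' @param beta_outcome,se_outcome Per-SNP outcome association and SE.
#' @param eaf Optional effect-allele frequencies.
#' @param ld Optional LD matrix (identity if `NULL`).
#' @param snp_id Variant identifiers.
#' @return An `mr_harmonized` object.
#' @export
harmonized_dataset <- function(beta_exposure, se_exposure,
                               beta_outcome, se_outcome,
                               eaf = NULL, ld = NULL,
                               snp_id = sprintf("snp%02d", seq_along(beta_exposure))) {
  k <- length(beta_exposure)
  stopifnot(length(se_exposure) == k, length(beta_outcome) == k,
            length(se_outcome) == k, all(se_exposure > 0), all(se_outcome > 0))
  data <- data.frame(
    snp_id = snp_id,
    effect_allele = "A", other_allele = "G",
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    eaf_exposure = if (is.null(eaf)) NA_real_ else eaf,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf_outcome = if (is.null(eaf)) NA_real_ else eaf,
    stringsAsFactors = FALSE
  )
  if (is.null(ld)) {
    ld <- diag(k)
    dimnames(ld) <- list(snp_id, snp_id)
  } else {
    ld <- as_ld_matrix(ld, snp_ids = snp_id)
  }
  structure(
    list(data = data, ld = ld,
         provenance = data.frame(snp_id = snp_id, action = "kept-as-is",
                                 stringsAsFactors = FALSE),
         palindromic_eaf_window = NA_real_),
    class = "mr_harmonized"
  )
}

# subset a harmonized dataset by row index, keeping the LD block consistent
harmonized_subset <- function(h, idx) {
  h$data <- h$data[idx, , drop = FALSE]
  h$ld <- h$ld[idx, idx, drop = FALSE]
  h
}

# TRUE when LD is (numerically) the identity: independent instruments
is_identity_ld <- function(ld, tol = 1e-12) {
  max(abs(ld - diag(nrow(ld)))) <= tol
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized MR dataset: %d SNP(s)%s\n", nrow(x$data),
              if (is_identity_ld(x$ld)) " (independent)" else " (correlated)"))
  tab <- table(x$provenance$action)
  cat("  provenance:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  print(x$data, ...)
  invisible(x)
}
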