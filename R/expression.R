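#' Read / write GCT expression matrices
#'
#' GCT is the three-line-header tab-delimited matrix format used by GTEx
#' expression releases: a `#1.2` version line, a dimensions line, then a table
#' whose first two columns are `Name` and `Description`.
#'
#' @param path GCT file.
#' @return Numeric matrix, genes x samples, with gene ids as rownames.
#' @export
read_gct <- function(path) {
  header <- readr::read_lines(path, n_max = 2)
  if (!startsWith(header[1], "#1.")) abort("not a GCT file: missing #1.x version line")
  tbl <- readr::read_tsv(path, skip = 2, show_col_types = FALSE)
  mat <- as.matrix(tbl[, -(1:2)])
  rownames(mat) <- tbl[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' @rdname read_gct
#' @param mat Genes x samples matrix with dimnames.
#' @param description Optional per-gene description column (defaults to the
#'   gene ids).
#' @export
write_gct <- function(mat, path, description = NULL) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("matrix must have gene rownames and sample colnames")
  }
  readr::write_lines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), path)
  tbl <- tibble(
    Name = rownames(mat),
    Description = description %||% rownames(mat)
  )
  tbl <- dplyr::bind_cols(tbl, as_tibble(mat))
  readr::write_tsv(tbl, path, col_names = TRUE, append = TRUE)
  invisible(path)
}

#' Expression-level gene filters
#'
#' A gene is retained only when it clears both hurdles: TPM at least
#' `tpm_min` in at least a `tpm_frac` fraction of samples, **and** at least
#' `count_min` unnormalized reads in at least a `count_frac` fraction of
#' samples. Defaults (0.1 TPM / 6 reads, each in >= 20% of samples) are the
#' GTEx eQTL discovery thresholds. Fractions compare with `>=`.
#'
#' @param tpm,counts Genes x samples matrices with identical dimnames.
#' @param tpm_min,tpm_frac,count_min,count_frac Filter parameters.
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(tpm, counts, tpm_min = 0.1, tpm_frac = 0.2,
                         count_min = 6, count_frac = 0.2) {
  if (!identical(dimnames(tpm), dimnames(counts))) {
    abort("`tpm` and `counts` must share identical gene and sample orderings")
  }
  ok_tpm <- rowMeans(tpm >= tpm_min) >= tpm_frac
  ok_cnt <- rowMeans(counts >= count_min) >= count_frac
  rownames(tpm)[ok_tpm & ok_cnt]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors for composition-aware library
#' normalization, computed with edgeR. The reference sample is the one whose
#' upper quartile is closest to the mean upper quartile; per-pair trimming of
#' 30% on log-ratios (M) and 5% on average abundance (A) — the standard TMM
#' trims. Factors are geometric-mean centred, so they multiply to 1.
#'
#' @param counts Genes x samples count matrix; no sample may be all zero.
#' @param trim_M,trim_A Trim fractions.
#' @return Named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  if (any(colSums(counts) == 0)) abort("sample with all-zero counts")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  setNames(as.numeric(f), colnames(counts))
}

#' Rank-based inverse normal transform
#'
#' Maps values through the standard normal quantile function at
#' `(rank - 0.5) / n`, with ties taking the average rank. The transform is
#' monotone in the input and antisymmetric under rank reversal.
#'
#' @param values Numeric vector, `n >= 2`, finite.
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2 || !all(is.finite(values))) {
    abort("`values` must be >= 2 finite numbers")
  }
  r <- rank(values, ties.method = "average")
  qnorm((r - 0.5) / length(values))
}

#' Prepare an expression matrix for association testing
#'
#' Applies the expression pipeline in order: gene filters ([filter_genes()]),
#' TMM-scaled counts-per-million ([tmm_factors()]), then a per-gene inverse
#' normal transform across samples ([inverse_normal_transform()]).
#'
#' @inheritParams filter_genes
#' @return List: `mat` (retained genes x samples, inverse-normal scale),
#'   `genes` (retained ids), `tmm` (scaling factors).
#' @export
prepare_expression <- function(tpm, counts, tpm_min = 0.1, tpm_frac = 0.2,
                               count_min = 6, count_frac = 0.2) {
  keep <- filter_genes(tpm, counts, tpm_min, tpm_frac, count_min, count_frac)
  if (length(keep) == 0) abort("no genes pass the expression filters")
  tmm <- tmm_factors(counts[keep, , drop = FALSE])
  eff_lib <- colSums(counts[keep, , drop = FALSE]) * tmm
  cpm <- t(t(counts[keep, , drop = FALSE]) / eff_lib) * 1e6
  mat <- t(apply(cpm, 1, inverse_normal_transform))
  dimnames(mat) <- dimnames(cpm)
  list(mat = mat, genes = keep, tmm = tmm)
}

#' Assemble an association covariate matrix
#'
#' Combines measured covariates (sex, platform, simulated confounders) with
#' the top genotype principal components and the top expression principal
#' components, the usual stand-ins for latent structure in eQTL designs.
#'
#' @param covariates Tibble of per-sample covariates; first column `sample`,
#'   remaining columns numeric.
#' @param dosages Variants x samples dosage matrix (missing entries are
#'   mean-imputed for the PCA only).
#' @param expression Genes x samples matrix on the transformed scale.
#' @param n_geno_pcs,n_expr_pcs Number of principal components of each kind
#'   (defaults 5 and 5).
#' @return Samples x covariates numeric matrix, sample names as rownames.
#' @export
build_covariates <- function(covariates, dosages = NULL, expression = NULL,
                             n_geno_pcs = 5, n_expr_pcs = 5) {
  assert_cols(covariates, "sample")
  base <- as.matrix(covariates[, setdiff(names(covariates), "sample"), drop = FALSE])
  rownames(base) <- covariates$sample
  parts <- list(base)
  pcs_of <- function(m, k, prefix) {
    m <- t(m)  # samples x features
    m[is.na(m)] <- mean(m, na.rm = TRUE)
    m <- m[, apply(m, 2, sd) > 0, drop = FALSE]
    k <- min(k, ncol(m), nrow(m) - 1)
    if (k < 1) return(NULL)
    p <- prcomp(m, center = TRUE, scale. = TRUE)$x[, seq_len(k), drop = FALSE]
    colnames(p) <- paste0(prefix, seq_len(k))
    p
  }
  if (!is.null(dosages) && n_geno_pcs > 0) {
    parts <- c(parts, list(pcs_of(dosages[, covariates$sample, drop = FALSE], n_geno_pcs, "geno_pc")))
  }
  if (!is.null(expression) && n_expr_pcs > 0) {
    parts <- c(parts, list(pcs_of(expression[, covariates$sample, drop = FALSE], n_expr_pcs, "expr_pc")))
  }
  do.call(cbind, Filter(Negate(is.null), parts))
}
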