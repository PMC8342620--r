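#' Covariate-adjusted association test for one SNP-gene pair
#'
#' Ordinary least squares of (inverse-normal) expression on alternate-allele
#' dosage plus covariates; the reported two-sided p value for the dosage
#' coefficient comes from the t distribution on the residual degrees of
#' freedom, `n - k - 2` with `k` covariates. Samples with a missing dosage
#' are dropped pairwise for that test only.
#'
#' @param dosage Numeric vector of dosages (0/1/2, `NA` allowed).
#' @param expression Numeric vector, same samples in the same order.
#' @param covariates Optional samples x k numeric matrix.
#' @param min_samples Minimum non-missing samples (default 10).
#'
#' @return One-row tibble: `beta`, `se`, `t`, `p`, `n`.
#' @export
test_association <- function(dosage, expression, covariates = NULL, min_samples = 10) {
  if (length(dosage) != length(expression)) {
    abort("`dosage` and `expression` must have equal length")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(dosage)) {
      abort("`covariates` must have one row per sample")
    }
  }
  keep <- !is.na(dosage) & !is.na(expression)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  n <- sum(keep)
  if (n < min_samples) {
    abort(sprintf("only %d non-missing samples (need >= %d)", n, min_samples))
  }
  x <- cbind(intercept = 1, dosage = dosage[keep], covariates[keep, , drop = FALSE])
  y <- expression[keep]
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) abort("rank-deficient design (collinear covariates?)")
  fit <- qr.coef(qr_x, y)
  res <- y - x %*% fit
  df <- n - ncol(x)
  if (df < 1) abort("no residual degrees of freedom")
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- unname(fit[2])
  tstat <- if (se > 0) beta / se else sign(beta) * Inf
  tibble(
    beta = beta, se = se, t = tstat,
    p = 2 * pt(-abs(tstat), df), n = n
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p values (`q = min over j >= i of p_(j) * m / j`,
#' capped at 1), returned in input order.
#'
#' @param p Numeric vector of p values.
#' @return Vector of q values.
#' @export
adjust_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Label a SNP-gene pair cis or trans
#'
#' Cis means same chromosome and within `window` bp of the gene start
#' (inclusive); everything else — including any cross-chromosome pair — is
#' trans. The conventional 1 Mb window is the default.
#'
#' @param snp_chrom,snp_pos SNP location (vectors allowed).
#' @param gene_chrom,gene_start Gene location (the annotated start, i.e. the
#'   left end regardless of strand).
#' @param window Window in bp (default 1e6).
#' @return Character vector, `"cis"` or `"trans"`.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, gene_start, window = 1e6) {
  ifelse(snp_chrom == gene_chrom & abs(snp_pos - gene_start) <= window, "cis", "trans")
}

#' eQTL mapping over a set of spatial SNP-gene pairs
#'
#' Tests each candidate pair with [test_association()], labels pairs cis or
#' trans, and applies a single Benjamini-Hochberg correction across every
#' tested pair in the tissue (cis and trans pooled).
#'
#' @param pairs Spatial pair table from [spatial_pairs()] (needs `snp`,
#'   `gene`, `tissue`).
#' @param dosages Variants x samples dosage matrix; rownames are SNP ids.
#' @param expression Genes x samples matrix on the transformed scale.
#' @param covariates Optional samples x k covariate matrix from
#'   [build_covariates()].
#' @param snp_positions Tibble `rsid`, `chrom`, `pos`.
#' @param gene_positions Tibble `gene_id`, `chrom`, `start`.
#' @param cis_window Cis window in bp (default 1e6).
#' @param min_samples Passed to [test_association()].
#'
#' @return Tibble `snp`, `gene`, `tissue`, `beta`, `se`, `t`, `p`, `q`,
#'   `cis_trans`, `n`; pairs whose SNP or gene is absent from the matrices
#'   are listed in `attr(, "untested")`.
#' @export
map_eqtls <- function(pairs, dosages, expression, covariates = NULL,
                      snp_positions, gene_positions, cis_window = 1e6,
                      min_samples = 10) {
  assert_cols(pairs, c("snp", "gene", "tissue"))
  assert_cols(snp_positions, c("rsid", "chrom", "pos"))
  assert_cols(gene_positions, c("gene_id", "chrom", "start"))
  testable <- pairs$snp %in% rownames(dosages) & pairs$gene %in% rownames(expression)
  untested <- pairs[!testable, , drop = FALSE]
  todo <- pairs[testable, , drop = FALSE]
  if (nrow(todo) == 0) {
    out <- tibble(
      snp = character(), gene = character(), tissue = character(),
      beta = numeric(), se = numeric(), t = numeric(), p = numeric(),
      q = numeric(), cis_trans = character(), n = integer()
    )
    attr(out, "untested") <- untested
    return(out)
  }
  samples <- intersect(colnames(dosages), colnames(expression))
  if (!is.null(covariates)) samples <- intersect(samples, rownames(covariates))
  stats <- purrr::map(seq_len(nrow(todo)), function(i) {
    test_association(
      dosages[todo$snp[i], samples],
      expression[todo$gene[i], samples],
      if (!is.null(covariates)) covariates[samples, , drop = FALSE],
      min_samples = min_samples
    )
  })
  out <- dplyr::bind_cols(todo[, c("snp", "gene", "tissue")], bind_rows(stats))
  sp <- snp_positions[match(out$snp, snp_positions$rsid), ]
  gp <- gene_positions[match(out$gene, gene_positions$gene_id), ]
  out$cis_trans <- classify_cis_trans(sp$chrom, sp$pos, gp$chrom, gp$start, cis_window)
  out$q <- adjust_fdr(out$p)
  out <- out[, c("snp", "gene", "tissue", "beta", "se", "t", "p", "q", "cis_trans", "n")]
  attr(out, "untested") <- untested
  out
}
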