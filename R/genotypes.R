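#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the p value
#' is the summed probability of every heterozygote count whose conditional
#' point probability does not exceed that of the observed count, enumerated
#' over heterozygote counts of matching parity. Preferred over the chi-square
#' approximation because the cohorts here are small.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major homozygote, heterozygote,
#'   minor homozygote; the labelling is symmetric).
#' @return The exact two-sided p value.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  counts <- c(n_aa, n_ab, n_bb)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) abort("at least one genotyped sample required")
  rare <- 2 * min(n_aa, n_bb) + n_ab   # rare allele count
  obs_het <- n_ab

  # heterozygote counts share the parity of the rare-allele count
  het_vals <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  if (length(het_vals) == 1) return(1)

  # log conditional probabilities, normalized in probability space
  hom_r <- (rare - het_vals) / 2
  hom_c <- n - het_vals - hom_r
  lp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(hom_c) -
    lfactorial(het_vals) + het_vals * log(2) +
    lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(obs_het, het_vals)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Standard variant-level filters: a variant is retained only when its exact
#' Hardy-Weinberg p value is at least `hwe_p_min`, its minor allele frequency
#' (over non-missing calls) is at least `maf_min`, and its missing-call
#' fraction is at most `max_missing`. Defaults follow common array-QC
#' practice: HWE p >= 1e-6, MAF >= 0.01, missingness <= 0.05.
#'
#' @param dosages Numeric matrix of allele dosages, variants x samples, values
#'   in `{0, 1, 2, NA}`.
#' @param hwe_p_min,maf_min,max_missing Filter thresholds.
#'
#' @return Tibble with one row per variant: `variant`, `maf`, `hwe_p`,
#'   `missing_rate`, `retained`, `drop_reason` (comma-joined; empty when
#'   retained). `attr(, "report")` holds per-filter drop counts.
#' @export
genotype_qc <- function(dosages, hwe_p_min = 1e-6, maf_min = 0.01, max_missing = 0.05) {
  if (!is.matrix(dosages)) abort("`dosages` must be a variants x samples matrix")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) abort("dosages must be 0, 1, 2 or NA")
  res <- purrr::map(seq_len(nrow(dosages)), function(i) {
    g <- dosages[i, ]
    miss <- mean(is.na(g))
    g <- g[!is.na(g)]
    if (length(g) == 0) {
      return(tibble(maf = NA_real_, hwe_p = NA_real_, missing_rate = miss,
                    drop_reason = "missingness"))
    }
    af <- mean(g) / 2
    maf <- min(af, 1 - af)
    hwe_p <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    reasons <- c(
      if (hwe_p < hwe_p_min) "hwe",
      if (maf < maf_min) "maf",
      if (miss > max_missing) "missingness"
    )
    tibble(maf = maf, hwe_p = hwe_p, missing_rate = miss,
           drop_reason = paste(reasons, collapse = ","))
  })
  out <- bind_rows(res)
  out <- mutate(out,
    variant = rownames(dosages) %||% as.character(seq_len(nrow(dosages))),
    retained = .data$drop_reason == "",
    .before = 1
  )
  attr(out, "report") <- list(
    n_variants = nrow(out),
    n_retained = sum(out$retained),
    n_dropped_hwe = sum(grepl("hwe", out$drop_reason)),
    n_dropped_maf = sum(grepl("maf", out$drop_reason)),
    n_dropped_missing = sum(grepl("missingness", out$drop_reason))
  )
  out
}

#' Read a VCF into a dosage matrix
#'
#' Converts diploid GT fields to alternate-allele dosages (0/1/2, `NA` for
#' missing). Variant ids keep the VCF ID column; a GTEx-style
#' `chrN_pos_ref_alt_b38` alias is added.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return List with `dosages` (variants x samples matrix), and `variants`
#'   (tibble `variant`, `variant_gtex`, `chrom`, `pos`, `ref`, `alt`).
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  allele_count <- function(x) {
    x <- sub("\\|", "/", x)
    ifelse(x %in% c("./.", ".", NA), NA_real_,
      vapply(strsplit(x, "/"), function(a) sum(as.numeric(a)), numeric(1))
    )
  }
  dos <- apply(gt, c(1, 2), allele_count)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  variants <- tibble(
    variant = fix$ID,
    variant_gtex = sprintf("%s_%s_%s_%s_b38", fix$CHROM, fix$POS, fix$REF, fix$ALT),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  rownames(dos) <- variants$variant
  list(dosages = dos, variants = variants)
}
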