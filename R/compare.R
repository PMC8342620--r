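#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the margins, the two-sided p value sums the hypergeometric
#' point probabilities of every table at least as extreme as (point
#' probability no larger than, within relative tolerance 1e-7) the observed
#' one — the convention of `fisher.test()`. Used to compare the proportion of
#' eQTL vs non-eQTL SNPs between tissues.
#'
#' @param a,b First row (e.g. fetal eQTLs, fetal non-eQTLs).
#' @param c,d Second row (e.g. adult eQTLs, adult non-eQTLs).
#' @return One-row tibble: `a`, `b`, `c`, `d`, `odds_ratio` (conditional MLE),
#'   `p`.
#' @export
#' @examples
#' fisher_exact_2x2(80, 264, 58, 286)
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero margin: the test is undefined")
  }
  ft <- fisher.test(m, alternative = "two.sided")
  tibble(a = a, b = b, c = c, d = d,
         odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Compare eQTL results between two tissues
#'
#' An eQTL is a SNP with at least one association at `q < fdr_threshold`; an
#' eGene is a gene so associated. The comparison reports shared and
#' tissue-specific eQTL and eGene sets, splits shared eQTLs by whether they
#' control the same eGene in both tissues, and classifies each eGene's effect
#' direction per tissue: `up` / `down` from the sign of its significant betas,
#' `opposing` when one gene carries significant associations of both signs
#' within a tissue.
#'
#' @param fetal,adult Association tables from [map_eqtls()] (any two tissues;
#'   the names reflect the motivating design).
#' @param fdr_threshold Significance threshold on `q` (default 0.05).
#' @return A `tissue_comparison` object: list of `eqtls` (named list of SNP
#'   sets: `shared`, `fetal_specific`, `adult_specific`, `fetal`, `adult`),
#'   `egenes` (same structure for genes), `shared_same_egene` /
#'   `shared_different_egene` SNP sets, and `directions` (tibble `gene`,
#'   `tissue`, `direction`).
#' @export
compare_tissues <- function(fetal, adult, fdr_threshold = 0.05) {
  for (tb in list(fetal, adult)) assert_cols(tb, c("snp", "gene", "beta", "q"))
  sig_f <- filter(fetal, .data$q < fdr_threshold)
  sig_a <- filter(adult, .data$q < fdr_threshold)
  eq_f <- unique(sig_f$snp); eq_a <- unique(sig_a$snp)
  eg_f <- unique(sig_f$gene); eg_a <- unique(sig_a$gene)
  shared_eq <- intersect(eq_f, eq_a)

  same_egene <- vapply(shared_eq, function(s) {
    length(intersect(sig_f$gene[sig_f$snp == s], sig_a$gene[sig_a$snp == s])) > 0
  }, logical(1))

  direction_of <- function(sig, tissue) {
    sig |>
      group_by(gene = .data$gene) |>
      summarise(
        direction = if (dplyr::n_distinct(sign(.data$beta)) > 1) "opposing"
          else if (all(.data$beta > 0)) "up" else "down",
        .groups = "drop"
      ) |>
      mutate(tissue = tissue)
  }

  structure(
    list(
      eqtls = list(
        fetal = eq_f, adult = eq_a, shared = shared_eq,
        fetal_specific = setdiff(eq_f, eq_a),
        adult_specific = setdiff(eq_a, eq_f)
      ),
      egenes = list(
        fetal = eg_f, adult = eg_a, shared = intersect(eg_f, eg_a),
        fetal_specific = setdiff(eg_f, eg_a),
        adult_specific = setdiff(eg_a, eg_f)
      ),
      shared_same_egene = shared_eq[same_egene],
      shared_different_egene = shared_eq[!same_egene],
      directions = bind_rows(direction_of(sig_f, "fetal"), direction_of(sig_a, "adult")),
      fdr_threshold = fdr_threshold
    ),
    class = "tissue_comparison"
  )
}

#' @export
print.tissue_comparison <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<tissue_comparison> (q < %g)\n",
      "  eQTLs : %d fetal / %d adult, %d shared (%d same eGene, %d different)\n",
      "  eGenes: %d fetal / %d adult, %d shared\n"
    ),
    x$fdr_threshold,
    length(x$eqtls$fetal), length(x$eqtls$adult), length(x$eqtls$shared),
    length(x$shared_same_egene), length(x$shared_different_egene),
    length(x$egenes$fetal), length(x$egenes$adult), length(x$egenes$shared)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tissue_comparison <- function(x, ...) {
  bind_rows(c(
    purrr::imap(x$eqtls[c("shared", "fetal_specific", "adult_specific")],
                ~ tibble(kind = "eqtl", set = .y, id = .x)),
    purrr::imap(x$egenes[c("shared", "fetal_specific", "adult_specific")],
                ~ tibble(kind = "egene", set = .y, id = .x))
  ))
}

#' @exportS3Method generics::glance
glance.tissue_comparison <- function(x, ...) {
  tibble(
    n_eqtl_fetal = length(x$eqtls$fetal),
    n_eqtl_adult = length(x$eqtls$adult),
    n_eqtl_shared = length(x$eqtls$shared),
    n_shared_same_egene = length(x$shared_same_egene),
    n_egene_fetal = length(x$egenes$fetal),
    n_egene_adult = length(x$egenes$adult),
    n_egene_shared = length(x$egenes$shared),
    fdr_threshold = x$fdr_threshold
  )
}
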