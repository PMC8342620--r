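#' Derive candidate SNP-gene pairs from fragment interactions
#'
#' The spatial-pairing core: for each SNP, find its restriction fragment,
#' collect every fragment that fragment contacts in the Hi-C interaction
#' index, and report each gene overlapping any of those fragments as a
#' candidate pair. A gene is emitted once per SNP no matter how many of its
#' fragments interact; its supporting contact count is the sum over all of
#' them. Because the interaction index excludes self-fragment pairs by
#' default, a gene sitting on the SNP's own fragment is only paired through
#' genuine contacts between two distinct fragments — an interpretive choice,
#' documented in the vignette.
#'
#' SNPs that cannot be located on the genome are skipped, not fatal; they are
#' listed in `attr(, "skipped")`.
#'
#' @param snps Tibble with `rsid`, `chrom`, `pos` (1-based). Extra columns
#'   (trait, p) pass through untouched to the skip report.
#' @param fragments Fragment table from [digest_genome()].
#' @param interactions Interaction index from [build_interaction_index()].
#' @param gene_fragments Tibble `feature_id`, `fragment_id` from
#'   [map_features_to_fragments()] run on the gene models.
#' @param tissue Tissue label stamped on every pair.
#' @param min_contacts Minimum summed contact support (default 1).
#'
#' @return Tibble `snp`, `gene`, `tissue`, `contacts`, `snp_fragment`,
#'   `gene_fragments` (list column of the gene's interacting fragment ids).
#' @export
spatial_pairs <- function(snps, fragments, interactions, gene_fragments,
                          tissue, min_contacts = 1) {
  assert_cols(snps, c("rsid", "chrom", "pos"))
  assert_cols(gene_fragments, c("feature_id", "fragment_id"))
  snp_frag <- locate_fragment(fragments, snps$chrom, snps$pos, strict = FALSE)
  skipped <- snps[is.na(snp_frag), , drop = FALSE]
  located <- tibble(snp = snps$rsid, snp_fragment = snp_frag)[!is.na(snp_frag), ]

  # symmetric view of the unordered-pair index
  sym <- bind_rows(
    tibble(from = interactions$frag_a, to = interactions$frag_b, count = interactions$count),
    tibble(from = interactions$frag_b, to = interactions$frag_a, count = interactions$count)
  )

  pairs <- located |>
    inner_join(sym, by = c(snp_fragment = "from"), relationship = "many-to-many") |>
    inner_join(
      rename(gene_fragments, gene = "feature_id"),
      by = c(to = "fragment_id"), relationship = "many-to-many"
    ) |>
    group_by(.data$snp, .data$snp_fragment, .data$gene) |>
    summarise(
      contacts = sum(.data$count),
      gene_fragments = list(sort(unique(.data$to))),
      .groups = "drop"
    ) |>
    filter(.data$contacts >= min_contacts) |>
    mutate(tissue = tissue) |>
    select("snp", "gene", "tissue", "contacts", "snp_fragment", "gene_fragments") |>
    arrange(.data$snp, .data$gene)
  attr(pairs, "skipped") <- skipped
  pairs
}

#' Read a GWAS-catalog-style SNP table
#'
#' Expects a TSV with columns `rsid`, `chrom`, `pos`, `trait`, `p`. Only
#' associations at genome-wide significance (default `p < 5e-8`) are kept.
#'
#' @param path TSV file.
#' @param trait Optional trait filter (exact match).
#' @param p_max Genome-wide significance threshold, exclusive (default 5e-8).
#' @return Tibble of retained SNP associations.
#' @export
read_gwas_snps <- function(path, trait = NULL, p_max = 5e-8) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(tbl, c("rsid", "chrom", "pos", "trait", "p"), "GWAS table")
  tbl <- filter(tbl, .data$p < p_max)
  if (!is.null(trait)) tbl <- tbl[tbl$trait == trait, , drop = FALSE]
  tbl
}
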