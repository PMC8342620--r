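#' Run the full spatial-eQTL pipeline on a directory of study files
#'
#' End-to-end orchestration: digest the genome, parse and index Hi-C
#' contacts, derive spatial SNP-gene pairs, QC genotypes, prepare expression,
#' map eQTLs per tissue, compare tissues (including the Fisher 2x2 test on
#' eQTL vs non-eQTL proportions), run chromatin-state counts and permutation
#' enrichment, trait-overlap bootstraps, pLI classification, tissue PPI
#' networks with Louvain modules and pathway over-representation. Every input
#' is read from file through the package's own parsers, so a freshly written
#' [write_study()] directory doubles as an integration test of the readers.
#'
#' @param paths Named list/vector of input paths, as produced by
#'   [write_study()]: `genome`, `genes`, `snps`, `gwas`, `states`,
#'   `pathways`, `pli`, `contacts`, `ppi`, and per tissue `<tissue>_vcf`,
#'   `<tissue>_covariates`, `<tissue>_tpm`, `<tissue>_counts`.
#' @param tissues Tissue labels (default `c("fetal", "adult")`).
#' @param out_dir Optional directory for TSV outputs and the JSON manifest.
#' @param seed Seed for the permutation and bootstrap stages.
#' @param min_mapq,min_contacts,fdr_threshold,cis_window,n_perm,n_boot
#'   Stage parameters, surfaced with their conventional defaults.
#' @param n_geno_pcs,n_expr_pcs Covariate PCs per kind.
#' @param bootstrap_trait Trait whose SNP set is tested for overlap with the
#'   discovered eQTLs (default `"schizophrenia"`).
#'
#' @return A `pipeline_result` list: `pairs`, `eqtls` (per tissue),
#'   `comparison`, `fisher`, `state_counts`, `state_enrichment`,
#'   `trait_overlap`, `pli`, `networks`, `modules`, `ora`, `manifest`.
#' @export
run_pipeline <- function(paths,
                         tissues = c("fetal", "adult"),
                         out_dir = NULL,
                         seed = 1L,
                         min_mapq = 30,
                         min_contacts = 1,
                         fdr_threshold = 0.05,
                         cis_window = 1e6,
                         n_perm = 1000,
                         n_boot = 10000,
                         n_geno_pcs = 5,
                         n_expr_pcs = 5,
                         bootstrap_trait = "schizophrenia") {
  paths <- as.list(paths)
  required <- c(
    "genome", "genes", "snps", "gwas", "states", "pathways", "pli",
    "contacts", "ppi",
    as.vector(outer(tissues, c("_vcf", "_covariates", "_tpm", "_counts"), paste0))
  )
  for (key in required) {
    if (is.null(paths[[key]])) abort(sprintf("config is missing input '%s'", key))
    if (!file.exists(paths[[key]])) {
      abort(sprintf("input '%s' not found: %s", key, paths[[key]]))
    }
  }

  # --- coordinate backbone ---
  genome <- read_genome_fasta(paths$genome)
  fragments <- digest_genome(genome)
  genes <- read_gtf_genes(paths$genes)
  gene_fragments <- map_features_to_fragments(
    fragments,
    dplyr::transmute(genes, feature_id = .data$gene_id, chrom = .data$chrom,
                     start = .data$start, end = .data$end)
  )

  # --- contacts ---
  records <- read_contacts(paths$contacts, min_mapq = min_mapq)
  interactions <- build_interaction_index(records, fragments)

  # --- SNPs and spatial pairs (one contact library shared by both tissues) ---
  snps <- readr::read_tsv(paths$snps, show_col_types = FALSE)
  assert_cols(snps, c("rsid", "chrom", "pos"), "study SNP table")

  eqtls <- list()
  pairs_all <- list()
  expr_summaries <- list()
  for (tissue in tissues) {
    pairs <- spatial_pairs(snps, fragments, interactions, gene_fragments,
                           tissue = tissue, min_contacts = min_contacts)
    pairs_all[[tissue]] <- pairs
    geno <- read_vcf_dosage(paths[[paste0(tissue, "_vcf")]])
    qc <- genotype_qc(geno$dosages)
    dos <- geno$dosages[qc$variant[qc$retained], , drop = FALSE]
    tpm <- read_gct(paths[[paste0(tissue, "_tpm")]])
    counts <- read_gct(paths[[paste0(tissue, "_counts")]])
    prep <- prepare_expression(tpm, counts)
    covs <- readr::read_tsv(paths[[paste0(tissue, "_covariates")]],
                            show_col_types = FALSE)
    cov_mat <- build_covariates(covs, dosages = dos, expression = prep$mat,
                                n_geno_pcs = n_geno_pcs, n_expr_pcs = n_expr_pcs)
    eqtls[[tissue]] <- map_eqtls(
      pairs, dos, prep$mat, cov_mat,
      snp_positions = snps[, c("rsid", "chrom", "pos")],
      gene_positions = dplyr::transmute(genes, gene_id = .data$gene_id,
                                        chrom = .data$chrom, start = .data$start),
      cis_window = cis_window
    )
    expr_summaries[[tissue]] <- tibble(
      gene_id = rownames(tpm),
      tpm = apply(tpm, 1, stats::median)
    )
  }

  # --- tissue comparison + Fisher on eQTL vs non-eQTL proportions ---
  comparison <- compare_tissues(eqtls[[1]], eqtls[[2]], fdr_threshold)
  n_snps <- nrow(snps)
  fisher <- fisher_exact_2x2(
    length(comparison$eqtls$fetal), n_snps - length(comparison$eqtls$fetal),
    length(comparison$eqtls$adult), n_snps - length(comparison$eqtls$adult)
  )

  # --- annotation of the discovered eQTLs ---
  states <- read_state_bed(paths$states)
  gwas <- read_gwas_snps(paths$gwas)
  eqtl_snp_ids <- union(comparison$eqtls$fetal, comparison$eqtls$adult)
  eqtl_snps <- snps[snps$rsid %in% eqtl_snp_ids, , drop = FALSE]
  universe <- distinct(gwas, .data$rsid, .keep_all = TRUE)
  state_counts <- state_overlap(eqtl_snps, states)$counts
  state_enrichment <- permutation_enrichment(
    eqtl_snps, states, universe[, c("rsid", "chrom", "pos")],
    n_perm = n_perm, seed = child_seed(seed, 11)
  )
  target <- unique(gwas$rsid[gwas$trait == bootstrap_trait])
  trait_overlap <- if (length(target) > 0) {
    mutate(
      bootstrap_overlap(eqtl_snp_ids, unique(gwas$rsid), target,
                        n_iter = n_boot, seed = child_seed(seed, 12)),
      trait = bootstrap_trait, .before = 1
    )
  } else {
    NULL
  }

  # --- eGene annotation: pLI ---
  egene_ids <- union(comparison$egenes$fetal, comparison$egenes$adult)
  pli_table <- readr::read_tsv(paths$pli, show_col_types = FALSE)
  pli <- classify_pli(egene_ids, pli_table)

  # --- PPI networks and pathways ---
  edges <- load_string_edges(paths$ppi)
  pw_tbl <- readr::read_tsv(paths$pathways, show_col_types = FALSE)
  pathways <- split(pw_tbl$gene_id, pw_tbl$pathway_id)
  networks <- list(); modules <- list(); ora <- list()
  asd_genes <- unique(unlist(purrr::map(pairs_all, "gene")))
  for (tissue in tissues) {
    net <- build_cs_ppi(edges, expr_summaries[[tissue]], tissue)
    networks[[tissue]] <- net
    sub <- extract_subnetwork(net, asd_genes)
    if (nrow(sub$nodes) > 0) {
      part <- louvain_cluster(sub, seed = child_seed(seed, 13))
      modules[[tissue]] <- part
      ora[[tissue]] <- ora_pathways(tidy(part), pathways, universe = genes$gene_id)
    }
  }

  manifest <- list(
    seed = seed,
    tissues = as.list(tissues),
    parameters = list(
      min_mapq = min_mapq, min_contacts = min_contacts,
      fdr_threshold = fdr_threshold, cis_window = cis_window,
      n_perm = n_perm, n_boot = n_boot,
      n_geno_pcs = n_geno_pcs, n_expr_pcs = n_expr_pcs
    ),
    counts = list(
      n_fragments = nrow(fragments),
      n_contact_records_kept = attr(records, "report")$n_kept,
      n_contact_records_dropped = attr(records, "report")$n_dropped_mapq,
      n_interacting_fragment_pairs = nrow(interactions),
      n_snps = n_snps,
      n_spatial_pairs = purrr::map_int(pairs_all, nrow),
      n_tested = purrr::map_int(eqtls, nrow),
      n_eqtls = purrr::map_int(
        setNames(tissues, tissues),
        ~ length(unique(eqtls[[.x]]$snp[eqtls[[.x]]$q < fdr_threshold]))
      ),
      n_egenes = purrr::map_int(
        setNames(tissues, tissues),
        ~ length(unique(eqtls[[.x]]$gene[eqtls[[.x]]$q < fdr_threshold]))
      )
    ),
    fisher_p = fisher$p
  )

  result <- structure(
    list(
      pairs = pairs_all, eqtls = eqtls, comparison = comparison,
      fisher = fisher, state_counts = state_counts,
      state_enrichment = state_enrichment, trait_overlap = trait_overlap,
      pli = pli, networks = networks, modules = modules, ora = ora,
      manifest = manifest
    ),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tissue in tissues) {
      readr::write_tsv(eqtls[[tissue]],
                       file.path(out_dir, paste0("eqtls_", tissue, ".tsv")))
    }
    readr::write_tsv(tidy(comparison), file.path(out_dir, "comparison_sets.tsv"))
    readr::write_tsv(state_counts, file.path(out_dir, "state_counts.tsv"))
    readr::write_tsv(state_enrichment, file.path(out_dir, "state_enrichment.tsv"))
    if (!is.null(trait_overlap)) {
      readr::write_tsv(trait_overlap, file.path(out_dir, "trait_overlap.tsv"))
    }
    readr::write_tsv(pli, file.path(out_dir, "egene_pli.tsv"))
    for (tissue in names(ora)) {
      readr::write_tsv(ora[[tissue]],
                       file.path(out_dir, paste0("ora_", tissue, ".tsv")))
    }
    jsonlite::write_json(
      c(manifest, list(generated_at = format(Sys.time(), usetz = TRUE))),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$comparison)
  cat(sprintf("  Fisher 2x2 (eQTL vs non-eQTL by tissue): p = %.5g\n", x$fisher$p))
  invisible(x)
}
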