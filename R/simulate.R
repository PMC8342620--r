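#' Simulation configuration with planted ground truth
#'
#' Builds the configuration object consumed by [simulate_study()] and the
#' individual `simulate_*()` generators. Identifiers are assigned
#' deterministically (`rs0001...`, `GENE0001...`), so planted effects can be
#' declared here, before anything is generated. Every generator is a pure
#' function of (config, seed): the same config yields byte-identical output
#' files.
#'
#' Defaults describe a compact two-tissue study: 2 chromosomes of 300 kb cut
#' at a HindIII-like density of 0.25 sites/kb (about 4 kb fragments, the
#' 4^6 expectation for a six-base cutter), 60 genes, 40 trait-associated
#' study SNPs inside a 240-SNP GWAS universe, and 120 samples per tissue with
#' MAF drawn from \[0.1, 0.5\]. Ten eQTLs of one expression-SD per allele are
#' planted — four fetal-specific, three adult-specific, three shared —
#' mirroring the fetal-heavy asymmetry such studies report, plus five
#' spatially connected but effect-free SNP-gene pairs so the false-discovery
#' machinery has genuine nulls to reject.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_chromosomes,chrom_length Genome shape (bp).
#' @param site_density Expected restriction sites per kb.
#' @param n_genes,n_snps,n_background_snps Feature counts; background SNPs
#'   fill out the GWAS universe used for permutation and bootstrap tests.
#' @param n_samples Samples per tissue.
#' @param maf_range Allele-frequency range, within (0, 0.5].
#' @param planted_eqtls Tibble `snp`, `gene`, `beta`, `tissue`; `beta` is the
#'   effect of one alternate allele in units of residual expression SD.
#' @param planted_contacts Tibble `snp`, `gene`, `count` of guaranteed
#'   high-quality Hi-C contacts joining the SNP's fragment to one of the
#'   gene's fragments.
#' @param background_contact_rate Expected background contacts per fragment
#'   pair.
#' @param decoy_fraction Fraction of all contact records written with
#'   sub-threshold mapq, to exercise the parser's filter.
#' @param missing_genotype_rate Fraction of genotype calls masked to missing.
#' @param n_confounders Simulated covariates beyond sex and platform.
#' @param library_size Fixed per-sample library size linking counts to TPM.
#' @param ppi_modules List with `sizes`, `p_within`, `p_between`: planted
#'   protein-interaction modules over the first `sum(sizes)` genes.
#' @param state_shares Named vector of 15 chromatin-state mnemonics and their
#'   genome shares (must sum to 1).
#' @param planted_state,planted_state_fold Chromatin state in which planted
#'   eQTL SNPs are placed at `fold` times its genome share.
#' @param trait_sets Named list; each element has `overlap_fraction` (of the
#'   planted eQTL SNPs shared with this trait) and `n_extra` background SNPs
#'   carrying the trait.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    seed = 1L,
    n_chromosomes = 2L,
    chrom_length = 300000L,
    site_density = 0.25,
    n_genes = 60L,
    n_snps = 40L,
    n_background_snps = 200L,
    n_samples = 120L,
    maf_range = c(0.1, 0.5),
    planted_eqtls = NULL,
    planted_contacts = NULL,
    background_contact_rate = 0.002,
    decoy_fraction = 0.1,
    missing_genotype_rate = 0.02,
    n_confounders = 3L,
    library_size = 5e6,
    ppi_modules = list(sizes = c(10L, 10L, 10L), p_within = 0.25, p_between = 0.02),
    state_shares = NULL,
    planted_state = "ReprPC",
    planted_state_fold = 5,
    trait_sets = list(
      schizophrenia = list(overlap_fraction = 0.9, n_extra = 40L),
      depression = list(overlap_fraction = 0.3, n_extra = 60L)
    )) {
  if (chrom_length < 1000) abort("`chrom_length` must be >= 1 kb")
  if (site_density < 0) abort("`site_density` must be >= 0")
  if (n_samples < 2) abort("`n_samples` must be >= 2")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be [low, high] within (0, 0.5]")
  }
  snp_ids <- sprintf("rs%04d", seq_len(n_snps))
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  if (is.null(planted_eqtls)) {
    planted_eqtls <- bind_rows(
      tibble(snp = snp_ids[1:3], gene = gene_ids[1:3],
             beta = c(1, -1, 1), tissue = "fetal"),
      tibble(snp = snp_ids[1:3], gene = gene_ids[1:3],
             beta = c(1, -1, 1), tissue = "adult"),
      tibble(snp = snp_ids[4:7], gene = gene_ids[4:7],
             beta = c(1, 1, -1, 1), tissue = "fetal"),
      tibble(snp = snp_ids[8:10], gene = gene_ids[8:10],
             beta = c(-1, 1, 1), tissue = "adult")
    )
  }
  assert_cols(planted_eqtls, c("snp", "gene", "beta", "tissue"), "planted_eqtls")
  if (!all(planted_eqtls$snp %in% snp_ids)) abort("planted eQTL references an unknown SNP")
  if (!all(planted_eqtls$gene %in% gene_ids)) abort("planted eQTL references an unknown gene")
  if (is.null(planted_contacts)) {
    eff <- distinct(planted_eqtls, .data$snp, .data$gene)
    nulls <- tibble(snp = snp_ids[11:15], gene = gene_ids[11:15])
    planted_contacts <- mutate(bind_rows(eff, nulls), count = 6L)
  }
  assert_cols(planted_contacts, c("snp", "gene", "count"), "planted_contacts")
  if (!all(planted_contacts$snp %in% snp_ids)) abort("planted contact references an unknown SNP")
  if (!all(planted_contacts$gene %in% gene_ids)) abort("planted contact references an unknown gene")
  # every planted eQTL needs the spatial support that makes it discoverable
  orphan <- anti_join(distinct(planted_eqtls, .data$snp, .data$gene),
                      planted_contacts, by = c("snp", "gene"))
  if (nrow(orphan) > 0) {
    abort("every planted eQTL pair must also appear in `planted_contacts`")
  }
  if (is.null(state_shares)) {
    state_shares <- c(
      TssA = 0.010, TssAFlnk = 0.010, TxFlnk = 0.005, Tx = 0.050, TxWk = 0.150,
      EnhG = 0.010, Enh = 0.030, "ZNF/Rpts" = 0.005, Het = 0.020,
      TssBiv = 0.005, BivFlnk = 0.005, EnhBiv = 0.005,
      ReprPC = 0.020, ReprPCWk = 0.050, Quies = 0.625
    )
  }
  if (abs(sum(state_shares) - 1) > 1e-8) abort("`state_shares` must sum to 1")
  if (!planted_state %in% names(state_shares)) abort("`planted_state` not in `state_shares`")
  structure(
    list(
      seed = as.integer(seed),
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.integer(chrom_length),
      site_density = site_density,
      n_genes = as.integer(n_genes),
      n_snps = as.integer(n_snps),
      n_background_snps = as.integer(n_background_snps),
      n_samples = as.integer(n_samples),
      maf_range = maf_range,
      planted_eqtls = planted_eqtls,
      planted_contacts = planted_contacts,
      background_contact_rate = background_contact_rate,
      decoy_fraction = decoy_fraction,
      missing_genotype_rate = missing_genotype_rate,
      n_confounders = as.integer(n_confounders),
      library_size = library_size,
      ppi_modules = ppi_modules,
      state_shares = state_shares,
      planted_state = planted_state,
      planted_state_fold = planted_state_fold,
      trait_sets = trait_sets,
      snp_ids = snp_ids,
      gene_ids = gene_ids
    ),
    class = "sim_config"
  )
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Remove every motif occurrence not in `wanted` (1-based starts), then plant
# the wanted ones; iterates because a repair can create a fresh occurrence.
plant_motifs <- function(seq, motif, wanted) {
  chars <- strsplit(seq, "")[[1]]
  w <- nchar(motif)
  for (s in wanted) chars[s:(s + w - 1)] <- strsplit(motif, "")[[1]]
  protected <- unlist(lapply(wanted, function(s) s:(s + w - 1)))
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  for (iter in 1:50) {
    txt <- paste(chars, collapse = "")
    hits <- gregexpr(motif, txt, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    rogue <- setdiff(hits, wanted)
    if (length(rogue) == 0 && setequal(hits, wanted)) return(txt)
    for (s in rogue) {
      block <- s:(s + w - 1)
      editable <- setdiff(block, protected)
      if (length(editable) == 0) next  # fully inside planted sites: impossible for w>1
      i <- editable[[1]]
      chars[i] <- swap[[chars[i]]]
    }
  }
  abort("failed to stabilise restriction sites after 50 repair passes")
}

#' Generate a genome with known restriction sites
#'
#' Random sequence with `AAGCTT` motifs embedded at Poisson-sampled
#' positions; any accidental motif arising from the random background is
#' repaired away, so the realized site set is exactly the planted one. The
#' companion fragment table is built directly from the planted cut positions,
#' independently of [digest_genome()], so the two can cross-check each other.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (named character vector) and `fragments` (tibble
#'   `chrom`, `start`, `end`, `fragment_id` with `chrom_lengths` attribute).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1))
  motif <- "AAGCTT"
  w <- nchar(motif)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  len <- config$chrom_length
  genome <- character(0)
  frag_list <- list()
  for (cn in chrom_names) {
    n_sites <- rpois(1, config$site_density * len / 1000)
    starts <- integer(0)
    if (n_sites > 0) {
      cand <- sort(sample(seq(10L, len - w - 10L), n_sites))
      # keep sites at least one motif-width apart so planted blocks don't overlap
      keep <- c(TRUE, diff(cand) >= w + 2)
      starts <- cand[keep]
    }
    seq <- plant_motifs(rand_dna(len), motif, starts)
    genome[cn] <- seq
    cuts <- starts - 1L + 1L  # 0-based cut coordinate, A^AGCTT offset 1
    bounds <- c(0L, cuts, len)
    frag_list[[cn]] <- tibble(chrom = cn, start = bounds[-length(bounds)], end = bounds[-1])
  }
  fragments <- bind_rows(frag_list)
  fragments$fragment_id <- seq_len(nrow(fragments))
  attr(fragments, "chrom_lengths") <- setNames(rep(len, length(chrom_names)), chrom_names)
  list(genome = genome, fragments = fragments)
}

#' Generate non-overlapping gene models
#'
#' Places `n_genes` genes (0.5-3 kb) uniformly without overlap, with random
#' strand; coordinates are 1-based inclusive (GTF convention).
#'
#' @param genome Named character vector from [simulate_genome()].
#' @param config A [sim_config()].
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_gene_models <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 2))
  chrom_names <- names(genome)
  lens <- nchar(genome)
  placed <- tibble(chrom = character(), start = integer(), end = integer())
  out <- list()
  for (i in seq_len(config$n_genes)) {
    ok <- FALSE
    for (try in 1:200) {
      cn <- sample(chrom_names, 1)
      glen <- sample(500:3000, 1)
      if (lens[[cn]] <= glen + 2) next
      s <- sample.int(lens[[cn]] - glen, 1)
      e <- s + glen - 1L
      clash <- any(placed$chrom == cn & placed$start <= e & placed$end >= s)
      if (!clash) {
        placed <- bind_rows(placed, tibble(chrom = cn, start = s, end = e))
        out[[i]] <- tibble(
          gene_id = config$gene_ids[i], chrom = cn,
          start = as.integer(s), end = as.integer(e),
          strand = sample(c("+", "-"), 1)
        )
        ok <- TRUE
        break
      }
    }
    if (!ok) abort(sprintf("could not place gene %d without overlap after 200 attempts", i))
  }
  bind_rows(out)
}

#' Write / read gene models as GTF
#'
#' Minimal single-feature GTF (one `gene` record per gene), 1-based inclusive.
#'
#' @param genes Tibble from [simulate_gene_models()].
#' @param path Output path.
#' @return `path` invisibly / tibble `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
write_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
    genes$chrom, genes$start, genes$end, genes$strand, genes$gene_id, genes$gene_id
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_gtf
#' @export
read_gtf_genes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t")
  bad <- which(lengths(fields) != 9)
  if (length(bad) > 0) abort(sprintf("malformed GTF line %d", bad[1]))
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", m[, 9])
  tibble(
    gene_id = gene_id, chrom = m[, 1],
    start = as.integer(m[, 4]), end = as.integer(m[, 5]), strand = m[, 7]
  )
}

#' Generate chromatin-state, SNP, trait, pathway and pLI annotations
#'
#' The chromatin-state track tiles every chromosome with 15-state mnemonics
#' at the configured genome shares (segment lengths around 2 kb). Study SNPs
#' are then placed: planted eQTL SNPs land inside `planted_state` with
#' probability `fold x share` (the planted enrichment) and never on a
#' fragment carrying their planted partner gene; all other SNPs are uniform.
#' Background SNPs fill the GWAS universe; trait sets are built with the
#' configured overlaps. All GWAS p values are below genome-wide significance
#' so ingest-time filtering keeps them.
#'
#' @param genome,fragments,genes Outputs of the upstream generators.
#' @param config A [sim_config()].
#' @return List: `states` (BED-convention tibble), `snps` (study SNP table:
#'   `rsid`, `chrom`, `pos`, `ref`, `alt`, `trait`, `p`), `gwas` (full
#'   GWAS-catalog-style table including other traits), `pathways` (named list
#'   of gene sets), `pli` (tibble `gene_id`, `pli`), `truth_state_snps`.
#' @export
simulate_annotations <- function(genome, fragments, genes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 3))
  chrom_names <- names(genome)
  len <- nchar(genome)

  # --- tiling state track ---
  shares <- config$state_shares
  states <- list()
  for (cn in chrom_names) {
    pos <- 0L
    segs <- list()
    while (pos < len[[cn]]) {
      st <- sample(names(shares), 1, prob = shares)
      sl <- max(200L, as.integer(round(stats::rexp(1, 1 / 2000))))
      e <- min(pos + sl, len[[cn]])
      segs[[length(segs) + 1]] <- tibble(chrom = cn, start = pos, end = e, state = st)
      pos <- e
    }
    states[[cn]] <- bind_rows(segs)
  }
  states <- bind_rows(states)

  # --- SNP placement ---
  gene_frag <- map_features_to_fragments(
    fragments,
    dplyr::transmute(genes, feature_id = .data$gene_id, chrom = .data$chrom,
                     start = .data$start, end = .data$end)
  )
  constrained <- bind_rows(
    distinct(config$planted_contacts, .data$snp, .data$gene)
  )
  planted_eqtl_snps <- unique(config$planted_eqtls$snp)
  p_in_state <- min(1, config$planted_state_fold * shares[[config$planted_state]])
  state_iv <- filter(states, .data$state == config$planted_state)
  all_frag <- fragments

  used_pos <- character(0)
  place_snp <- function(rsid) {
    partner_genes <- constrained$gene[constrained$snp == rsid]
    forbidden <- gene_frag$fragment_id[gene_frag$feature_id %in% partner_genes]
    biased <- rsid %in% planted_eqtl_snps && nrow(state_iv) > 0 &&
      runif(1) < p_in_state
    for (try in 1:500) {
      if (biased) {
        widths <- state_iv$end - state_iv$start
        i <- sample.int(nrow(state_iv), 1, prob = widths)
        cn <- state_iv$chrom[i]
        pos <- state_iv$start[i] + sample.int(widths[i], 1)  # 1-based
      } else {
        cn <- sample(chrom_names, 1)
        pos <- sample.int(len[[cn]], 1)
      }
      key <- paste(cn, pos)
      if (key %in% used_pos) next
      fid <- locate_fragment(all_frag, cn, pos)
      # a SNP must not sit on any fragment of its planted partner gene,
      # otherwise only a self-contact could join them
      if (fid %in% forbidden) next
      used_pos <<- c(used_pos, key)
      return(tibble(rsid = rsid, chrom = cn, pos = as.integer(pos)))
    }
    abort(sprintf("could not place SNP %s under its constraints", rsid))
  }
  snp_pos <- bind_rows(lapply(config$snp_ids, place_snp))
  ref <- vapply(seq_len(nrow(snp_pos)),
                function(i) substr(genome[[snp_pos$chrom[i]]], snp_pos$pos[i], snp_pos$pos[i]),
                character(1))
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  snps <- mutate(snp_pos, ref = ref, alt = alt,
                 trait = "autism spectrum disorder",
                 p = 10^-runif(dplyr::n(), 8.5, 20))

  # --- background GWAS SNPs and trait sets ---
  bg_ids <- sprintf("rsB%04d", seq_len(config$n_background_snps))
  bg <- tibble(
    rsid = bg_ids,
    chrom = sample(chrom_names, config$n_background_snps, replace = TRUE)
  )
  bg$pos <- vapply(bg$chrom, function(cn) sample.int(len[[cn]], 1), integer(1))
  bg$trait <- "unrelated trait"
  bg$p <- 10^-runif(nrow(bg), 8.5, 20)

  extra_rows <- list()
  bg_free <- bg_ids
  for (tn in names(config$trait_sets)) {
    ts <- config$trait_sets[[tn]]
    k <- round(ts$overlap_fraction * length(planted_eqtl_snps))
    shared <- head(planted_eqtl_snps, k)
    n_extra <- min(ts$n_extra, length(bg_free))
    extras <- head(bg_free, n_extra)
    bg_free <- setdiff(bg_free, extras)
    ids <- c(shared, extras)
    src <- bind_rows(
      snps[snps$rsid %in% shared, c("rsid", "chrom", "pos")],
      bg[bg$rsid %in% extras, c("rsid", "chrom", "pos")]
    )
    extra_rows[[tn]] <- mutate(src, trait = tn, p = 10^-runif(nrow(src), 8.5, 20))
  }
  gwas <- bind_rows(
    snps[, c("rsid", "chrom", "pos", "trait", "p")],
    bg[, c("rsid", "chrom", "pos", "trait", "p")],
    bind_rows(extra_rows)
  )

  # --- pathways: aligned with the planted PPI modules, plus random sets ---
  sizes <- config$ppi_modules$sizes
  mod_genes <- split(
    config$gene_ids[seq_len(sum(sizes))],
    rep(seq_along(sizes), sizes)
  )
  pathways <- list()
  for (i in seq_along(mod_genes)) {
    pathways[[sprintf("pathway_M%d", i)]] <-
      c(mod_genes[[i]], sample(config$gene_ids, 3))
  }
  for (i in 1:3) {
    pathways[[sprintf("pathway_R%d", i)]] <- sample(config$gene_ids, 15)
  }
  pathways <- lapply(pathways, unique)

  pli <- tibble(
    gene_id = config$gene_ids,
    pli = round(stats::rbeta(config$n_genes, 0.2, 0.2), 4)
  )

  list(
    states = states,
    snps = snps,
    gwas = gwas,
    pathways = pathways,
    pli = pli,
    truth_state_snps = tibble(
      rsid = planted_eqtl_snps, state = config$planted_state,
      fold = config$planted_state_fold
    )
  )
}

#' Generate genotype cohorts for both tissues
#'
#' One cohort per tissue with independent samples. Per-variant MAFs are drawn
#' once (shared across tissues) from `maf_range`; genotypes follow
#' Hardy-Weinberg proportions (`Binomial(2, maf)`); missing calls are masked
#' at the configured rate. Covariates are sex, platform and
#' `n_confounders` standard-normal confounders.
#'
#' @param snps Study SNP table from [simulate_annotations()].
#' @param config A [sim_config()].
#' @return Named list (`fetal`, `adult`); each element has `samples`,
#'   `dosages_full` (pre-masking, used to plant expression effects),
#'   `dosages` (with missing as `NA`), `covariates` (tibble), `maf`.
#' @export
simulate_cohort <- function(snps, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 4))
  n <- config$n_samples
  maf <- runif(nrow(snps), config$maf_range[1], config$maf_range[2])
  names(maf) <- snps$rsid
  cohorts <- list()
  for (tissue in c("fetal", "adult")) {
    prefix <- if (tissue == "fetal") "F" else "A"
    samples <- sprintf("%s%03d", prefix, seq_len(n))
    dos <- matrix(
      rbinom(nrow(snps) * n, 2, rep(maf, times = n)),
      nrow = nrow(snps), ncol = n,
      dimnames = list(snps$rsid, samples)
    )
    masked <- dos
    if (config$missing_genotype_rate > 0) {
      mask <- matrix(runif(length(dos)) < config$missing_genotype_rate, nrow = nrow(dos))
      masked[mask] <- NA
    }
    covariates <- tibble(sample = samples, sex = rbinom(n, 1, 0.5),
                         platform = rbinom(n, 1, 0.5))
    for (k in seq_len(config$n_confounders)) {
      covariates[[paste0("conf", k)]] <- rnorm(n)
    }
    cohorts[[tissue]] <- list(
      samples = samples, dosages_full = dos, dosages = masked,
      covariates = covariates, maf = maf
    )
  }
  cohorts
}

#' Write a dosage cohort as plain-text VCF
#'
#' @param snps Study SNP table (needs `rsid`, `chrom`, `pos`, `ref`, `alt`).
#' @param dosages Variants x samples matrix with `NA` for missing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, dosages, path) {
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, ]
  dosages <- dosages[snps$rsid, , drop = FALSE]
  gt <- matrix(c("0/0", "0/1", "1/1")[dosages + 1], nrow = nrow(dosages))
  gt[is.na(dosages)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dosages)), collapse = "\t")
  )
  body <- paste(
    snps$chrom, snps$pos, snps$rsid, snps$ref, snps$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Generate expression matrices with planted eQTL effects
#'
#' Per tissue, each gene's latent expression is
#' `y = beta * dosage + Gamma * C + eps` with `eps ~ N(0, 1)` — `beta` is the
#' planted allelic effect in residual-SD units, `C` the simulated covariates
#' with small random loadings. TPM is a gene-specific baseline scaled by
#' `2^(0.5 y)` (monotone in `y`, so rank-based transforms recover the planted
#' signal exactly), and counts are TPM times a fixed per-sample library size,
#' rounded — consistent with TPM ranks while exercising both count- and
#' TPM-based gene filters. About 10% of genes are near-silent so the filters
#' have something to remove.
#'
#' @param cohorts From [simulate_cohort()].
#' @param genes Gene models.
#' @param config A [sim_config()].
#' @return Named list per tissue: `tpm`, `counts` (genes x samples matrices).
#' @export
simulate_expression <- function(cohorts, genes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 5))
  ng <- nrow(genes)
  base_log2 <- runif(ng, 1, 7)
  silent <- runif(ng) < 0.1
  # planted eQTL genes are never silenced: their signal must survive filtering
  silent[genes$gene_id %in% config$planted_eqtls$gene] <- FALSE
  base_log2[silent] <- runif(sum(silent), -6, -3)
  out <- list()
  for (tissue in names(cohorts)) {
    co <- cohorts[[tissue]]
    n <- length(co$samples)
    cov_mat <- as.matrix(co$covariates[, -1])
    loadings <- matrix(rnorm(ng * ncol(cov_mat), 0, 0.3), nrow = ng)
    y <- loadings %*% t(cov_mat) + matrix(rnorm(ng * n), nrow = ng)
    rownames(y) <- genes$gene_id
    planted <- filter(config$planted_eqtls, .data$tissue == !!tissue)
    for (i in seq_len(nrow(planted))) {
      y[planted$gene[i], ] <- y[planted$gene[i], ] +
        planted$beta[i] * co$dosages_full[planted$snp[i], ]
    }
    tpm <- 2^(base_log2 + 0.5 * y)
    dimnames(tpm) <- list(genes$gene_id, co$samples)
    counts <- round(tpm * config$library_size / 1e6)
    out[[tissue]] <- list(tpm = tpm, counts = counts)
  }
  out
}

#' Generate Juicer-style Hi-C contact records
#'
#' Planted SNP-gene pairs are emitted exactly `count` times as high-quality
#' records joining the SNP's fragment to a fragment of the gene distinct from
#' the SNP's own; background contacts fall uniformly over fragment pairs at
#' `background_contact_rate`; a `decoy_fraction` of all records carries
#' sub-threshold mapq on at least one end. Read names are synthetic
#' UUID-like strings; strand and position fields are populated (positions lie
#' inside the stated fragment) though only chrom/pos/frag/mapq are consumed
#' downstream.
#'
#' @param fragments Fragment table.
#' @param snps Study SNP table.
#' @param gene_fragments Gene-to-fragment map.
#' @param config A [sim_config()].
#' @return List: `records` (tibble in merged_nodups column order) and
#'   `truth` (tibble `snp`, `gene`, `snp_fragment`, `gene_fragment`,
#'   `count`).
#' @export
simulate_contacts <- function(fragments, snps, gene_fragments, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 6))
  frag_of <- setNames(
    locate_fragment(fragments, snps$chrom, snps$pos),
    snps$rsid
  )
  frag_row <- function(fid) fragments[match(fid, fragments$fragment_id), ]
  rand_pos <- function(fid) {
    fr <- frag_row(fid)
    fr$start + sample.int(fr$end - fr$start, 1)  # 1-based within fragment
  }
  mk_name <- function(k) {
    sprintf("%08x-%04x", sample.int(.Machine$integer.max, k), sample.int(65535, k))
  }
  truth <- list()
  recs <- list()
  pc <- config$planted_contacts
  for (i in seq_len(nrow(pc))) {
    sf <- frag_of[[pc$snp[i]]]
    gf_all <- gene_fragments$fragment_id[gene_fragments$feature_id == pc$gene[i]]
    gf_ok <- setdiff(gf_all, sf)
    if (length(gf_ok) == 0) {
      abort(sprintf("planted contact %s-%s: gene has no fragment distinct from the SNP's",
                    pc$snp[i], pc$gene[i]))
    }
    gf <- gf_ok[1]
    k <- pc$count[i]
    recs[[length(recs) + 1]] <- tibble(
      read_name = mk_name(k),
      str1 = sample(c("0", "16"), k, replace = TRUE),
      chr1 = frag_row(sf)$chrom,
      pos1 = vapply(rep(sf, k), rand_pos, numeric(1)),
      frag1 = sf,
      mapq1 = sample(30:60, k, replace = TRUE),
      str2 = sample(c("0", "16"), k, replace = TRUE),
      chr2 = frag_row(gf)$chrom,
      pos2 = vapply(rep(gf, k), rand_pos, numeric(1)),
      frag2 = gf,
      mapq2 = sample(30:60, k, replace = TRUE)
    )
    truth[[length(truth) + 1]] <- tibble(
      snp = pc$snp[i], gene = pc$gene[i],
      snp_fragment = sf, gene_fragment = gf, count = k
    )
  }
  n_frag <- nrow(fragments)
  n_pairs <- n_frag * (n_frag - 1) / 2
  n_bg <- rpois(1, config$background_contact_rate * n_pairs)
  if (n_bg > 0) {
    fa <- sample.int(n_frag, n_bg, replace = TRUE)
    shift <- sample.int(n_frag - 1, n_bg, replace = TRUE)
    fb <- ((fa - 1 + shift) %% n_frag) + 1  # uniform over distinct partners
    recs[[length(recs) + 1]] <- tibble(
      read_name = mk_name(n_bg),
      str1 = sample(c("0", "16"), n_bg, replace = TRUE),
      chr1 = fragments$chrom[fa],
      pos1 = vapply(fragments$fragment_id[fa], rand_pos, numeric(1)),
      frag1 = fragments$fragment_id[fa],
      mapq1 = sample(30:60, n_bg, replace = TRUE),
      str2 = sample(c("0", "16"), n_bg, replace = TRUE),
      chr2 = fragments$chrom[fb],
      pos2 = vapply(fragments$fragment_id[fb], rand_pos, numeric(1)),
      frag2 = fragments$fragment_id[fb],
      mapq2 = sample(30:60, n_bg, replace = TRUE)
    )
  }
  good <- bind_rows(recs)
  n_decoy <- round(config$decoy_fraction / (1 - config$decoy_fraction) * nrow(good))
  if (n_decoy > 0) {
    fa <- sample.int(n_frag, n_decoy, replace = TRUE)
    shift <- sample.int(n_frag - 1, n_decoy, replace = TRUE)
    fb <- ((fa - 1 + shift) %% n_frag) + 1
    decoys <- tibble(
      read_name = mk_name(n_decoy),
      str1 = sample(c("0", "16"), n_decoy, replace = TRUE),
      chr1 = fragments$chrom[fa],
      pos1 = vapply(fragments$fragment_id[fa], rand_pos, numeric(1)),
      frag1 = fragments$fragment_id[fa],
      mapq1 = sample(0:29, n_decoy, replace = TRUE),
      str2 = sample(c("0", "16"), n_decoy, replace = TRUE),
      chr2 = fragments$chrom[fb],
      pos2 = vapply(fragments$fragment_id[fb], rand_pos, numeric(1)),
      frag2 = fragments$fragment_id[fb],
      mapq2 = sample(0:60, n_decoy, replace = TRUE)
    )
    good <- bind_rows(good, decoys)
  }
  records <- good[sample.int(nrow(good)), ]
  list(records = records, truth = bind_rows(truth))
}

#' Write contact records as merged_nodups-style text
#' @param records Tibble from [simulate_contacts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(records, path) {
  readr::write_lines(
    do.call(paste, c(as.list(records), sep = " ")),
    path
  )
  invisible(path)
}

#' Generate a STRING-style PPI edge list with planted modules
#'
#' The first `sum(sizes)` genes form the planted modules; each unordered pair
#' is connected with probability `p_within` inside a module and `p_between`
#' otherwise. Within-module edges carry higher combined scores (600-990) than
#' background edges (150-890), all within the STRING 150-999 range. Both
#' orientations of every edge are written, as in the STRING dialect.
#'
#' @param gene_ids Genes to use as proteins.
#' @param config A [sim_config()] (for `ppi_modules` and the seed), or a raw
#'   list with `sizes`, `p_within`, `p_between` plus a `seed` argument.
#' @param seed Optional seed override.
#' @return List: `edges` (tibble `a`, `b`, `score`, one row per unordered
#'   pair), `truth` (tibble `gene_id`, `module`; module 0 = background).
#' @export
simulate_ppi <- function(gene_ids, config, seed = NULL) {
  if (inherits(config, "sim_config")) {
    mods <- config$ppi_modules
    set.seed(seed %||% child_seed(config$seed, 7))
  } else {
    mods <- config
    set.seed(seed %||% 1L)
  }
  sizes <- mods$sizes
  if (sum(sizes) > length(gene_ids)) abort("not enough genes for the requested modules")
  module <- rep(0L, length(gene_ids))
  module[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
  names(module) <- gene_ids
  pairs <- utils::combn(gene_ids, 2)
  same <- module[pairs[1, ]] == module[pairs[2, ]] & module[pairs[1, ]] > 0
  p_edge <- ifelse(same, mods$p_within, mods$p_between)
  keep <- runif(ncol(pairs)) < p_edge
  a <- pairs[1, keep]; b <- pairs[2, keep]
  score <- integer(sum(keep))
  score[same[keep]] <- sample(600:990, sum(same[keep]), replace = TRUE)
  score[!same[keep]] <- sample(150:890, sum(!same[keep]), replace = TRUE)
  list(
    edges = tibble(a = pmin(a, b), b = pmax(a, b), score = score),
    truth = tibble(gene_id = gene_ids, module = unname(module))
  )
}

#' Write a PPI edge list in the two-orientation STRING dialect
#' @param edges Tibble `a`, `b`, `score` (one row per unordered pair).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(edges, path) {
  both <- bind_rows(
    edges,
    tibble(a = edges$b, b = edges$a, score = edges$score)
  )
  readr::write_lines(
    c("protein1 protein2 combined_score",
      paste(both$a, both$b, both$score)),
    path
  )
  invisible(path)
}

#' Simulate a complete two-tissue study with planted truth
#'
#' Runs every generator in dependency order under stage seeds derived from
#' the master seed, cross-checks the planted invariants (every planted eQTL's
#' SNP and gene exist; every planted contact joins the SNP's fragment to a
#' distinct fragment of its gene), and returns all pieces plus machine-
#' readable truth tables.
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list: `config`, `genome`, `fragments`, `genes`,
#'   `gene_fragments`, `annotations` (states/snps/gwas/pathways/pli),
#'   `cohorts`, `expression`, `contacts`, `ppi`, and `truth` (list of
#'   tibbles: `eqtls`, `contacts`, `modules`, `state_snps`).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  g <- simulate_genome(config)
  genes <- simulate_gene_models(g$genome, config)
  gene_fragments <- map_features_to_fragments(
    g$fragments,
    dplyr::transmute(genes, feature_id = .data$gene_id, chrom = .data$chrom,
                     start = .data$start, end = .data$end)
  )
  ann <- simulate_annotations(g$genome, g$fragments, genes, config)
  cohorts <- simulate_cohort(ann$snps, config)
  expression <- simulate_expression(cohorts, genes, config)
  contacts <- simulate_contacts(g$fragments, ann$snps, gene_fragments, config)
  ppi <- simulate_ppi(config$gene_ids, config)
  structure(
    list(
      config = config,
      genome = g$genome,
      fragments = g$fragments,
      genes = genes,
      gene_fragments = gene_fragments,
      annotations = ann,
      cohorts = cohorts,
      expression = expression,
      contacts = contacts,
      ppi = ppi,
      truth = list(
        eqtls = config$planted_eqtls,
        contacts = contacts$truth,
        modules = ppi$truth,
        state_snps = ann$truth_state_snps
      )
    ),
    class = "sim_study"
  )
}

#' Write every file of a simulated study
#'
#' Serializes the study to the plain-text formats the pipeline ingests:
#' FASTA genome, BED-like fragment table, GTF gene models, per-tissue VCF /
#' GCT (TPM and counts) / covariate TSV, merged_nodups-style contact text,
#' STRING-style edge list, ChromHMM-style BED, GWAS-catalog-style TSV,
#' pathway TSV, pLI TSV, and the truth tables.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- c()
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(study$genome), p("genome.fa"), width = 80
  )
  paths["genome"] <- p("genome.fa")
  write_fragments(study$fragments, p("fragments.tsv"))
  paths["fragments"] <- p("fragments.tsv")
  write_gtf(study$genes, p("genes.gtf"))
  paths["genes"] <- p("genes.gtf")
  readr::write_tsv(study$annotations$snps, p("study_snps.tsv"))
  paths["snps"] <- p("study_snps.tsv")
  readr::write_tsv(study$annotations$gwas, p("gwas_catalog.tsv"))
  paths["gwas"] <- p("gwas_catalog.tsv")
  readr::write_tsv(study$annotations$states, p("chromhmm_states.bed"),
                   col_names = FALSE)
  paths["states"] <- p("chromhmm_states.bed")
  pw <- bind_rows(purrr::imap(
    study$annotations$pathways,
    ~ tibble(pathway_id = .y, gene_id = .x)
  ))
  readr::write_tsv(pw, p("pathways.tsv"))
  paths["pathways"] <- p("pathways.tsv")
  readr::write_tsv(study$annotations$pli, p("pli.tsv"))
  paths["pli"] <- p("pli.tsv")
  for (tissue in names(study$cohorts)) {
    co <- study$cohorts[[tissue]]
    write_vcf(study$annotations$snps, co$dosages, p(tissue, "_genotypes.vcf"))
    paths[paste0(tissue, "_vcf")] <- p(tissue, "_genotypes.vcf")
    readr::write_tsv(co$covariates, p(tissue, "_covariates.tsv"))
    paths[paste0(tissue, "_covariates")] <- p(tissue, "_covariates.tsv")
    write_gct(study$expression[[tissue]]$tpm, p(tissue, "_tpm.gct"))
    paths[paste0(tissue, "_tpm")] <- p(tissue, "_tpm.gct")
    write_gct(study$expression[[tissue]]$counts, p(tissue, "_counts.gct"))
    paths[paste0(tissue, "_counts")] <- p(tissue, "_counts.gct")
  }
  write_contacts(study$contacts$records, p("contacts_merged_nodups.txt"))
  paths["contacts"] <- p("contacts_merged_nodups.txt")
  write_string_edges(study$ppi$edges, p("string_links.txt"))
  paths["ppi"] <- p("string_links.txt")
  readr::write_tsv(study$truth$eqtls, p("truth_eqtls.tsv"))
  readr::write_tsv(study$truth$contacts, p("truth_contacts.tsv"))
  readr::write_tsv(study$truth$modules, p("truth_modules.tsv"))
  readr::write_tsv(study$truth$state_snps, p("truth_state_snps.tsv"))
  paths["truth_eqtls"] <- p("truth_eqtls.tsv")
  invisible(paths)
}

#' Simulate a genotype/expression cohort for a single batch of SNP-gene pairs
#'
#' A lightweight generator for calibration studies: `n_pairs` independent
#' (dosage, expression) pairs over the same `n_samples` samples, with a
#' common planted `beta` (0 for a pure null), shared covariates, and
#' `eps ~ N(0,1)` noise.
#'
#' @param n_pairs,n_samples Problem size.
#' @param beta Planted allelic effect in residual-SD units (default 0).
#' @param maf Minor allele frequency, a single value or range.
#' @param n_confounders Covariates with random loadings.
#' @param seed RNG seed.
#' @return List: `dosages` and `expression` (`n_pairs` x `n_samples`
#'   matrices), `covariates` (samples x k matrix).
#' @export
simulate_pair_cohort <- function(n_pairs, n_samples, beta = 0, maf = c(0.1, 0.5),
                                 n_confounders = 3, seed = 1L) {
  set.seed(seed)
  mafs <- if (length(maf) == 2) runif(n_pairs, maf[1], maf[2]) else rep(maf, n_pairs)
  dos <- matrix(rbinom(n_pairs * n_samples, 2, rep(mafs, times = n_samples)),
                nrow = n_pairs)
  cov_mat <- matrix(rnorm(n_samples * n_confounders), nrow = n_samples)
  colnames(cov_mat) <- paste0("conf", seq_len(n_confounders))
  loadings <- matrix(rnorm(n_pairs * n_confounders, 0, 0.3), nrow = n_pairs)
  expr <- beta * dos + loadings %*% t(cov_mat) +
    matrix(rnorm(n_pairs * n_samples), nrow = n_pairs)
  rownames(dos) <- rownames(expr) <- sprintf("pair%04d", seq_len(n_pairs))
  list(dosages = dos, expression = expr, covariates = cov_mat)
}
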