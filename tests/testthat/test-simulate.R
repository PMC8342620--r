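small_config <- function(seed = 3, ...) {
  defaults <- list(
    seed = seed, chrom_length = 60000L, n_genes = 25L, n_snps = 20L,
    n_background_snps = 50L, n_samples = 40L,
    planted_eqtls = tibble::tibble(
      snp = sprintf("rs%04d", 1:4), gene = sprintf("GENE%04d", 1:4),
      beta = c(1, -1, 1, 1), tissue = c("fetal", "fetal", "adult", "adult")
    ),
    ppi_modules = list(sizes = c(8L, 8L), p_within = 0.6, p_between = 0.05)
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(sim_config, defaults)
}

test_that("generators are byte-deterministic in (config, seed)", {
  s1 <- simulate_study(small_config(seed = 5))
  s2 <- simulate_study(small_config(seed = 5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_study(s1, d1); p2 <- write_study(s2, d2)
  for (key in names(p1)) {
    expect_identical(readr::read_file(p1[[key]]), readr::read_file(p2[[key]]),
                     label = sprintf("file '%s'", key))
  }
})

test_that("a zero site density yields exactly one fragment per chromosome", {
  cfg <- small_config(site_density = 0)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$fragments), cfg$n_chromosomes)
  expect_equal(g$fragments$start, rep(0, cfg$n_chromosomes))
})

test_that("the companion fragment table equals an actual digest of the FASTA", {
  g <- simulate_genome(small_config(seed = 8))
  redig <- digest_genome(g$genome)
  expect_equal(g$fragments$chrom, redig$chrom)
  expect_equal(g$fragments$start, redig$start)
  expect_equal(g$fragments$end, redig$end)
  expect_equal(g$fragments$fragment_id, redig$fragment_id)
})

test_that("gene models respect counts, bounds and non-overlap", {
  cfg <- small_config(n_genes = 50L, chrom_length = 150000L,
                      ppi_modules = list(sizes = c(10L, 10L),
                                         p_within = 0.6, p_between = 0.05))
  g <- simulate_genome(cfg)
  genes <- simulate_gene_models(g$genome, cfg)
  expect_equal(nrow(genes), 50)
  expect_true(all(genes$start >= 1))
  expect_true(all(genes$end <= cfg$chrom_length))
  by_chrom <- split(genes, genes$chrom)
  for (gc in by_chrom) {
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1) expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))
  }
  # GTF round trip
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genes, path)
  expect_equal(read_gtf_genes(path), genes)
})

test_that("genotypes match the requested MAF and missingness", {
  sim <- simulate_pair_cohort(n_pairs = 200, n_samples = 1000, maf = 0.3, seed = 2)
  af <- rowMeans(sim$dosages) / 2
  expect_true(all(abs(af - 0.3) < 0.05))
  cfg <- small_config(missing_genotype_rate = 0)
  study_snps <- tibble::tibble(rsid = cfg$snp_ids,
                               chrom = "chr1", pos = seq_along(cfg$snp_ids))
  co <- simulate_cohort(study_snps, cfg)
  expect_false(anyNA(co$fetal$dosages))
  cfg2 <- small_config(missing_genotype_rate = 0.1, n_snps = 60L,
                       n_samples = 150L)
  study_snps2 <- tibble::tibble(rsid = cfg2$snp_ids,
                                chrom = "chr1", pos = seq_along(cfg2$snp_ids))
  co2 <- simulate_cohort(study_snps2, cfg2)
  expect_lt(abs(mean(is.na(co2$fetal$dosages)) - 0.1), 0.02)
})

test_that("simulated genotypes are Hardy-Weinberg calibrated", {
  set.seed(71)
  maf <- runif(300, 0.1, 0.5)
  dos <- matrix(rbinom(300 * 150, 2, rep(maf, times = 150)), nrow = 300)
  hwe <- apply(dos, 1, function(g) {
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  expect_gte(mean(hwe > 1e-6), 0.99)
})

test_that("planted contacts appear exactly count times at high mapq", {
  study <- simulate_study(small_config(seed = 9))
  truth <- study$truth$contacts
  rec <- study$contacts$records
  for (i in seq_len(nrow(truth))) {
    hits <- sum(
      (rec$frag1 == truth$snp_fragment[i] & rec$frag2 == truth$gene_fragment[i]) |
        (rec$frag1 == truth$gene_fragment[i] & rec$frag2 == truth$snp_fragment[i])
    )
    expect_gte(hits, truth$count[i])  # background can add, never subtract
    planted_only <- sum(
      rec$frag1 == truth$snp_fragment[i] & rec$frag2 == truth$gene_fragment[i] &
        rec$mapq1 >= 30 & rec$mapq2 >= 30
    )
    expect_gte(planted_only, truth$count[i])
  }
})

test_that("the decoy fraction is removed by mapq filtering on parse", {
  cfg <- small_config(seed = 12, decoy_fraction = 0.2,
                      background_contact_rate = 0.01)
  study <- simulate_study(cfg)
  path <- withr::local_tempfile(fileext = ".txt")
  write_contacts(study$contacts$records, path)
  rec <- read_contacts(path, min_mapq = 30)
  rep <- attr(rec, "report")
  frac_kept <- rep$n_kept / rep$n_total
  expect_lt(abs(frac_kept - 0.8), 0.05)
})

test_that("no background and no planted pairs gives an empty contact file", {
  cfg <- small_config(seed = 4, background_contact_rate = 0, decoy_fraction = 0,
                      planted_contacts = tibble::tibble(
                        snp = character(), gene = character(), count = integer()
                      ),
                      planted_eqtls = tibble::tibble(
                        snp = character(), gene = character(),
                        beta = numeric(), tissue = character()
                      ))
  study <- simulate_study(cfg)
  expect_equal(nrow(study$contacts$records), 0)
})

test_that("PPI edges stay in the STRING score range with both orientations on disk", {
  sim <- simulate_ppi(sprintf("g%02d", 1:20),
                      list(sizes = c(8L, 8L), p_within = 0.7, p_between = 0.05),
                      seed = 6)
  expect_true(all(sim$edges$score >= 150 & sim$edges$score <= 999))
  path <- withr::local_tempfile(fileext = ".txt")
  write_string_edges(sim$edges, path)
  raw <- readr::read_lines(path)[-1]
  parts <- strsplit(raw, " ")
  keys <- vapply(parts, function(p) paste(p[1], p[2]), character(1))
  rev_keys <- vapply(parts, function(p) paste(p[2], p[1]), character(1))
  expect_true(all(rev_keys %in% keys))
  expect_equal(length(raw), 2 * nrow(sim$edges))
})

test_that("state tracks tile chromosomes exactly; pLI stays within [0, 1]", {
  study <- simulate_study(small_config(seed = 13))
  st <- study$annotations$states
  for (cn in unique(st$chrom)) {
    sub <- st[st$chrom == cn, ]
    expect_equal(sub$start[1], 0)
    expect_equal(sub$end[nrow(sub)], nchar(study$genome[[cn]]))
    if (nrow(sub) > 1) expect_equal(sub$start[-1], sub$end[-nrow(sub)])
  }
  expect_true(all(study$annotations$pli$pli >= 0 &
                    study$annotations$pli$pli <= 1))
})

test_that("planted eQTL SNPs and genes exist and sit on distinct fragments", {
  study <- simulate_study(small_config(seed = 17))
  cfg <- study$config
  snps <- study$annotations$snps
  expect_true(all(cfg$planted_eqtls$snp %in% snps$rsid))
  expect_true(all(cfg$planted_eqtls$gene %in% study$genes$gene_id))
  truth <- study$truth$contacts
  expect_true(all(truth$snp_fragment != truth$gene_fragment))
  # and the gene fragment really overlaps the gene
  for (i in seq_len(nrow(truth))) {
    gf <- study$gene_fragments$fragment_id[
      study$gene_fragments$feature_id == truth$gene[i]
    ]
    expect_true(truth$gene_fragment[i] %in% gf)
  }
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(chrom_length = 100), ">= 1 kb")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(
    sim_config(planted_eqtls = tibble::tibble(
      snp = "rs9999", gene = "GENE0001", beta = 1, tissue = "fetal"
    )),
    "unknown SNP"
  )
  expect_error(
    sim_config(
      planted_eqtls = tibble::tibble(snp = "rs0001", gene = "GENE0001",
                                     beta = 1, tissue = "fetal"),
      planted_contacts = tibble::tibble(snp = "rs0002", gene = "GENE0002",
                                        count = 3L)
    ),
    "planted_contacts"
  )
})
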