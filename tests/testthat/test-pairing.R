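test_that("a SNP fragment contacting a gene fragment yields exactly one pair", {
  fr <- digest_genome(c(chr1 = "GGAAGCTTCCAAGCTTACGT"))  # [0,3) [3,11) [11,20)
  idx <- tibble::tibble(frag_a = 1L, frag_b = 3L, count = 1L)
  gene_frag <- tibble::tibble(feature_id = "G", fragment_id = 3L)
  snps <- tibble::tibble(rsid = "rs1", chrom = "chr1", pos = 2)
  pairs <- spatial_pairs(snps, fr, idx, gene_frag, tissue = "fetal")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$contacts, 1L)
  expect_equal(pairs$snp_fragment, 1L)
  expect_equal(pairs$tissue, "fetal")
})

test_that("SNPs without contacts produce no pairs; unlocatable SNPs are skipped", {
  fr <- digest_genome(c(chr1 = "GGAAGCTTCC"))
  idx <- tibble::tibble(frag_a = integer(), frag_b = integer(), count = integer())
  snps <- tibble::tibble(rsid = c("rs1", "rs_bad"), chrom = c("chr1", "chrZ"),
                         pos = c(2, 5))
  gene_frag <- tibble::tibble(feature_id = "G", fragment_id = 2L)
  pairs <- spatial_pairs(snps, fr, idx, gene_frag, tissue = "t")
  expect_equal(nrow(pairs), 0)
  expect_equal(attr(pairs, "skipped")$rsid, "rs_bad")
})

test_that("a multi-fragment gene is emitted once with summed contact support", {
  fr <- digest_genome(c(chr1 = "GGAAGCTTCCAAGCTTACGTAAGCTTGG"))
  idx <- tibble::tibble(frag_a = c(1L, 1L), frag_b = c(3L, 4L), count = c(2L, 3L))
  gene_frag <- tibble::tibble(feature_id = "G", fragment_id = c(3L, 4L))
  snps <- tibble::tibble(rsid = "rs1", chrom = "chr1", pos = 2)
  pairs <- spatial_pairs(snps, fr, idx, gene_frag, tissue = "t")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$contacts, 5L)
  expect_equal(pairs$gene_fragments[[1]], c(3L, 4L))
})

test_that("pairing equals the brute-force triple loop on random toy instances", {
  set.seed(404)
  for (rep in 1:5) {
    fr <- digest_genome(c(c1 = toy_chrom(600, 8), c2 = toy_chrom(400, 5)))
    nf <- nrow(fr)
    # random sparse interaction index
    npair <- min(30, nf * (nf - 1) / 2)
    ab <- t(replicate(npair, sort(sample(nf, 2))))
    idx <- dplyr::distinct(tibble::tibble(frag_a = ab[, 1], frag_b = ab[, 2]))
    idx$count <- sample(1:4, nrow(idx), replace = TRUE)
    # random genes and SNPs
    genes <- purrr::map(1:8, function(g) {
      cn <- sample(c("c1", "c2"), 1)
      len <- if (cn == "c1") 600 else 400
      s <- sample(len - 50, 1)
      tibble::tibble(feature_id = paste0("G", g), chrom = cn,
                     start = s, end = min(len, s + sample(80, 1)))
    }) |> dplyr::bind_rows()
    gene_frag <- map_features_to_fragments(fr, genes)
    snps <- tibble::tibble(
      rsid = paste0("rs", 1:20),
      chrom = sample(c("c1", "c2"), 20, replace = TRUE)
    )
    snps$pos <- ifelse(snps$chrom == "c1", sample(600, 20, TRUE), sample(400, 20, TRUE))
    got <- spatial_pairs(snps, fr, idx, gene_frag, tissue = "t")
    want <- brute_pairs(snps, fr, idx, gene_frag)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$snp, want$snp)
      expect_equal(got$gene, want$gene)
      expect_equal(as.numeric(got$contacts), as.numeric(want$contacts))
    }
  }
})

test_that("raising the contact threshold only removes pairs, never adds", {
  set.seed(77)
  fr <- digest_genome(c(c1 = toy_chrom(500, 6)))
  nf <- nrow(fr)
  expect_gte(nf, 3)
  idx <- tibble::tibble(frag_a = 1L, frag_b = 2:nf, count = sample(1:5, nf - 1, TRUE))
  gene_frag <- tibble::tibble(
    feature_id = paste0("G", 2:nf), fragment_id = 2:nf
  )
  snps <- tibble::tibble(rsid = "rs1", chrom = "c1", pos = 1)
  lo <- spatial_pairs(snps, fr, idx, gene_frag, "t", min_contacts = 1)
  hi <- spatial_pairs(snps, fr, idx, gene_frag, "t", min_contacts = 3)
  expect_true(all(hi$gene %in% lo$gene))
  expect_true(all(hi$contacts >= 3))
})

test_that("GWAS ingest keeps only genome-wide significant rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    rsid = c("a", "b", "c"), chrom = "chr1", pos = 1:3,
    trait = c("ASD", "ASD", "SCZ"), p = c(1e-9, 1e-6, 4e-8)
  ), path)
  got <- read_gwas_snps(path)
  expect_equal(got$rsid, c("a", "c"))
  expect_equal(read_gwas_snps(path, trait = "SCZ")$rsid, "c")
})
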