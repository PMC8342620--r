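tiling_track <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(0, 100, 250, 600),
    end = c(100, 250, 600, 1000),
    state = c("TssA", "ReprPC", "TxWk", "Quies")
  )
}

test_that("SNPs are assigned to the state interval containing their position", {
  snps <- tibble::tibble(rsid = paste0("rs", 1:4), chrom = "chr1",
                         pos = c(50, 101, 250, 999))
  ov <- state_overlap(snps, tiling_track())
  expect_equal(ov$assignments$state, c("TssA", "ReprPC", "ReprPC", "Quies"))
  expect_equal(sum(ov$counts$n), 4)
  # positions outside coverage fall in "uncovered"
  ov2 <- state_overlap(tibble::tibble(rsid = "x", chrom = "chr2", pos = 5),
                       tiling_track())
  expect_equal(ov2$assignments$state, "uncovered")
})

test_that("state counts equal a brute-force interval scan on random sets", {
  set.seed(15)
  track <- tiling_track()
  snps <- tibble::tibble(rsid = paste0("r", 1:200), chrom = "chr1",
                         pos = sample(1000, 200))
  got <- state_overlap(snps, track)$assignments
  brute <- vapply(snps$pos, function(p) {
    row <- which(track$start <= p - 1 & p - 1 < track$end)
    track$state[row]
  }, character(1))
  expect_equal(got$state, brute)
})

test_that("permutation enrichment detects a concentrated SNP set and honours the +1 floor", {
  set.seed(21)
  track <- tiling_track()
  universe <- tibble::tibble(rsid = paste0("u", 1:400), chrom = "chr1",
                             pos = sample(1000, 400))
  # concentrate the test set inside ReprPC [100, 250)
  snp_set <- tibble::tibble(rsid = paste0("s", 1:20), chrom = "chr1",
                            pos = sample(101:250, 20))
  enr <- permutation_enrichment(snp_set, track, universe, n_perm = 200, seed = 5)
  reprpc <- enr[enr$state == "ReprPC", ]
  expect_equal(reprpc$p, 1 / 201)  # the smallest attainable p
  expect_equal(reprpc$direction, "enriched")
  expect_true(all(enr$p >= 1 / 201))
  expect_error(
    permutation_enrichment(universe, track, snp_set, n_perm = 10),
    "universe smaller"
  )
})

test_that("identical seeds reproduce identical permutation p values", {
  set.seed(32)
  track <- tiling_track()
  universe <- tibble::tibble(rsid = paste0("u", 1:100), chrom = "chr1",
                             pos = sample(1000, 100))
  snp_set <- universe[1:10, ]
  a <- permutation_enrichment(snp_set, track, universe, n_perm = 100, seed = 9)
  b <- permutation_enrichment(snp_set, track, universe, n_perm = 100, seed = 9)
  expect_equal(a, b)
})

test_that("bootstrap overlap p is exactly count_ge / n with no +1 correction", {
  res <- bootstrap_overlap(c("a", "b"), letters[1:10], c("a", "b", "c"),
                           n_iter = 500, seed = 4)
  expect_equal(res$p, res$count_ge / res$n_iter)
  expect_equal(res$p_floor, 1 / 500)
  # a certain overlap: every resample of the full universe hits the target
  sure <- bootstrap_overlap("a", "a", "a", n_iter = 50, seed = 1)
  expect_equal(sure$p, 1)
  expect_error(bootstrap_overlap("a", character(0), "a"), "non-empty")
})

test_that("bootstrap p matches exhaustive enumeration on a 4-element universe", {
  universe <- c("w", "x", "y", "z")
  target <- c("w", "x")
  observed_set <- c("w", "x")  # observed overlap = 2
  # enumerate all 4^2 = 16 ordered resamples of size 2
  grid <- expand.grid(first = universe, second = universe,
                      stringsAsFactors = FALSE)
  overlaps <- apply(grid, 1, function(r) length(intersect(unique(r), target)))
  exact_p <- mean(overlaps >= 2)
  res <- bootstrap_overlap(observed_set, universe, target,
                           n_iter = 40000, seed = 8)
  expect_equal(res$observed, 2)
  # Monte-Carlo agreement within 4 binomial standard errors
  se <- sqrt(exact_p * (1 - exact_p) / 40000)
  expect_lt(abs(res$p - exact_p), 4 * se)
})

test_that("pLI classification is strict at the 0.9 boundary", {
  tbl <- tibble::tibble(gene_id = c("g1", "g2"), pli = c(0.95, 0.90))
  got <- classify_pli(c("g1", "g2", "g3"), tbl)
  expect_equal(got$class, c("intolerant", "tolerant", "unknown"))
  expect_error(classify_pli("g", tibble::tibble(gene_id = "g", pli = 1.2)),
               "\\[0, 1\\]")
})
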