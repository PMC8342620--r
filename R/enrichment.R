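#' Read a chromatin-state BED track
#'
#' ChromHMM mnemonics tracks are BED4: `chrom`, `start`, `end` (0-based
#' half-open) and the state mnemonic (e.g. `15_Quies`, `13_ReprPC`).
#'
#' @param path BED file.
#' @return Tibble `chrom`, `start`, `end`, `state`.
#' @export
read_state_bed <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "state"),
                         show_col_types = FALSE)
  if (any(tbl$start >= tbl$end)) abort("malformed BED: start >= end")
  tbl
}

#' Assign SNPs to chromatin states
#'
#' Each SNP's point position (1-based, converted internally to 0-based) is
#' looked up in the state track; when the track tiles the genome every SNP
#' lands in exactly one state. SNPs outside track coverage are tallied under
#' `"uncovered"`.
#'
#' @param snps Tibble `rsid`, `chrom`, `pos`.
#' @param states State track from [read_state_bed()].
#' @return List: `assignments` (tibble `rsid`, `state`) and `counts`
#'   (tibble `state`, `n`, descending).
#' @export
state_overlap <- function(snps, states) {
  assert_cols(snps, c("rsid", "chrom", "pos"))
  assert_cols(states, c("chrom", "start", "end", "state"))
  assigned <- purrr::map(unique(snps$chrom), function(cn) {
    sn <- snps[snps$chrom == cn, , drop = FALSE]
    st <- states[states$chrom == cn, , drop = FALSE]
    p0 <- sn$pos - 1L
    if (nrow(st) == 0) {
      return(tibble(rsid = sn$rsid, state = "uncovered"))
    }
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = p0 + 1L, width = 1L),
      IRanges::IRanges(start = st$start + 1L, end = st$end)
    )
    lab <- rep("uncovered", nrow(sn))
    lab[S4Vectors::queryHits(hits)] <- st$state[S4Vectors::subjectHits(hits)]
    tibble(rsid = sn$rsid, state = lab)
  })
  assignments <- bind_rows(assigned)
  counts <- assignments |>
    count(.data$state, name = "n") |>
    arrange(dplyr::desc(.data$n))
  list(assignments = assignments, counts = counts)
}

#' Permutation enrichment of a SNP set within chromatin states
#'
#' Compares the observed per-state counts of `snp_set` against sets of the
#' same size resampled (without replacement) from a SNP universe — by default
#' the full GWAS table the set was drawn from. Empirical p values use the
#' `(k + 1) / (n_perm + 1)` convention of permutation region tests, so the
#' smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param snp_set Tibble `rsid`, `chrom`, `pos` — the SNPs of interest.
#' @param states State track.
#' @param universe Tibble of the same shape containing all permissible SNPs;
#'   must contain at least `nrow(snp_set)` rows.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return Tibble per state: `state`, `observed`, `perm_mean`, `p`,
#'   `direction` (`"enriched"` / `"depleted"`).
#' @export
permutation_enrichment <- function(snp_set, states, universe, n_perm = 1000, seed = 1L) {
  if (nrow(universe) < nrow(snp_set)) abort("universe smaller than the SNP set")
  obs <- state_overlap(snp_set, states)$counts
  all_states <- union(unique(states$state), obs$state)
  observed <- setNames(rep(0L, length(all_states)), all_states)
  observed[obs$state] <- obs$n

  uni_states <- state_overlap(universe, states)$assignments$state
  k <- nrow(snp_set)
  withr_seed <- function(code) { set.seed(seed); code }
  perm_counts <- withr_seed(
    vapply(seq_len(n_perm), function(i) {
      draw <- uni_states[sample.int(length(uni_states), k)]
      tab <- table(factor(draw, levels = all_states))
      as.integer(tab)
    }, integer(length(all_states)))
  )
  rownames(perm_counts) <- all_states
  obs_vec <- as.integer(observed[all_states])
  perm_mean <- rowMeans(perm_counts)
  ge <- rowSums(perm_counts >= observed[all_states])
  tibble(
    state = all_states,
    observed = unname(obs_vec),
    perm_mean = unname(perm_mean),
    p = unname((ge + 1) / (n_perm + 1)),
    direction = unname(ifelse(obs_vec > perm_mean, "enriched", "depleted"))
  ) |>
    arrange(.data$p, dplyr::desc(.data$observed))
}

#' Bootstrap test of an observed overlap
#'
#' Tests whether the overlap between an observed item set and a target set is
#' larger than chance. Each iteration resamples, with replacement, a set of
#' the same size from the universe and counts its intersection with the
#' target (duplicates counted once). The p value is exactly
#' `count(bootstrapped >= observed) / n_iter` — no +1 correction — so a p of
#' 0 means "less than 1/n_iter", which is flagged in the output.
#'
#' @param observed_set Character vector of observed items (e.g. eQTL rsids).
#' @param universe Character vector to resample from (e.g. all GWAS SNPs).
#' @param target_set Character vector defining the overlap (e.g. SNPs of
#'   another trait).
#' @param n_iter Iterations (default 10000).
#' @param seed RNG seed.
#' @param replace Resample with replacement (default `TRUE`, the bootstrap).
#' @return One-row tibble: `observed` (overlap count), `n_iter`, `count_ge`,
#'   `p`, `p_floor` (`1 / n_iter`, the resolution of the estimate).
#' @export
bootstrap_overlap <- function(observed_set, universe, target_set,
                              n_iter = 10000, seed = 1L, replace = TRUE) {
  if (length(universe) == 0 || length(target_set) == 0) {
    abort("`universe` and `target_set` must be non-empty")
  }
  if (!replace && length(universe) < length(observed_set)) {
    abort("universe smaller than sample size with replace = FALSE")
  }
  observed <- length(intersect(unique(observed_set), unique(target_set)))
  k <- length(unique(observed_set))
  target <- unique(target_set)
  set.seed(seed)
  boot <- vapply(seq_len(n_iter), function(i) {
    s <- sample(universe, k, replace = replace)
    length(intersect(unique(s), target))
  }, integer(1))
  count_ge <- sum(boot >= observed)
  tibble(
    observed = observed, n_iter = as.integer(n_iter),
    count_ge = count_ge, p = count_ge / n_iter, p_floor = 1 / n_iter
  )
}

#' Classify genes by loss-of-function intolerance
#'
#' Genes with pLI strictly above the threshold (default 0.9) are classed
#' intolerant ("depleted for null variants"); genes at or below it tolerant;
#' genes absent from the pLI table unknown.
#'
#' @param genes Character vector of gene ids.
#' @param pli_table Tibble `gene_id`, `pli` with pLI in \[0, 1\].
#' @param threshold Strict lower bound for intolerance (default 0.9).
#' @return Tibble `gene_id`, `pli`, `class`.
#' @export
classify_pli <- function(genes, pli_table, threshold = 0.9) {
  assert_cols(pli_table, c("gene_id", "pli"))
  if (any(pli_table$pli < 0 | pli_table$pli > 1, na.rm = TRUE)) {
    abort("pLI values must lie in [0, 1]")
  }
  pli <- pli_table$pli[match(genes, pli_table$gene_id)]
  tibble(
    gene_id = genes,
    pli = pli,
    class = dplyr::case_when(
      is.na(pli) ~ "unknown",
      pli > threshold ~ "intolerant",
      TRUE ~ "tolerant"
    )
  )
}
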