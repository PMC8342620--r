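# Independent reference implementations used as oracles. Each is written
# from the defining formula of the quantity, not from the package's code
# path, so a bug in one side shows up as disagreement.

# naive scan-and-split digestion: substring comparison at every offset
naive_digest <- function(seq, motif = "AAGCTT", cut_offset = 1) {
  n <- nchar(seq)
  w <- nchar(motif)
  cuts <- integer(0)
  if (n >= w) {
    for (i in seq_len(n - w + 1)) {
      if (substr(seq, i, i + w - 1) == motif) {
        cut <- i - 1 + cut_offset  # 0-based
        if (cut > 0 && cut < n) cuts <- c(cuts, cut)
      }
    }
  }
  bounds <- c(0, sort(unique(cuts)), n)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

# per-bp overlap scan: which fragments share >= 1 base with [start, end] (1-based)
naive_feature_fragments <- function(frag_df, chrom, start, end) {
  fr <- frag_df[frag_df$chrom == chrom, ]
  hits <- integer(0)
  for (b in start:end) {
    p0 <- b - 1
    row <- which(fr$start <= p0 & p0 < fr$end)
    hits <- c(hits, fr$fragment_id[row])
  }
  sort(unique(hits))
}

# exact HWE enumeration from the counting formula:
# P(h) = multinomial(n; hom_r, h, hom_c) * 2^h / choose(2n, rare)
hwe_enum_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  rare <- 2 * min(n_aa, n_bb) + n_ab
  het_vals <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  lp <- vapply(het_vals, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lchoose(n, hom_r) + lchoose(n - hom_r, h) + h * log(2) - lchoose(2 * n, rare)
  }, numeric(1))
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, het_vals)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# TMM written from the published algorithm (weighted trimmed mean of M values)
naive_tmm <- function(x, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(x)
  f75 <- apply(x, 2, function(col) quantile(col, p = 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(obs, refv, nO, nR) {
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (is.na(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(x)), function(i) one(x[, i], x[, ref], lib[i], lib[ref]),
              numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(x))
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(k, labels, maxl) {
    if (k > n) {
      out[[length(out) + 1]] <<- labels
      return()
    }
    for (l in 1:(maxl + 1)) rec(k + 1, c(labels, l), max(maxl, l))
  }
  if (n == 1) return(list(1L))
  rec(2, 1L, 1L)
  out
}

# Newman modularity from its definition, for an undirected edge list
modularity_from_edges <- function(edges, nodes, membership) {
  m <- nrow(edges)
  if (m == 0) return(0)
  deg <- setNames(rep(0, length(nodes)), nodes)
  for (i in seq_len(m)) {
    deg[edges$a[i]] <- deg[edges$a[i]] + 1
    deg[edges$b[i]] <- deg[edges$b[i]] + 1
  }
  mem <- setNames(membership, nodes)
  q <- 0
  for (cm in unique(membership)) {
    inside <- sum(mem[edges$a] == cm & mem[edges$b] == cm)
    dc <- sum(deg[mem == cm])
    q <- q + inside / m - (dc / (2 * m))^2
  }
  q
}

max_modularity_exhaustive <- function(edges, nodes) {
  best <- -Inf
  for (p in all_partitions(length(nodes))) {
    q <- modularity_from_edges(edges, nodes, p)
    if (q > best) best <- q
  }
  best
}

# upper-tail hypergeometric by explicit combinatorial sum
hyper_upper_sum <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# two-sided Fisher by exhaustive enumeration over tables with fixed margins
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(r1 + r2, c1)
  sum(probs[probs <= probs[match(a, xs)] * (1 + 1e-7)])
}

# adjusted Rand index between two labelings
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxi <- (b + cc) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# random toy chromosome with roughly n_sites restriction sites planted in it
# (random six-mers are rare, so sites are embedded explicitly; accidental
# extras are fine because the implementation and the oracle both see them)
toy_chrom <- function(len, n_sites) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_sites > 0) {
    starts <- sort(sample(seq(8, len - 8), n_sites))
    starts <- starts[c(TRUE, diff(starts) >= 8)]
    for (s in starts) chars[s:(s + 5)] <- c("A", "A", "G", "C", "T", "T")
  }
  paste(chars, collapse = "")
}

# brute-force spatial pairing: triple loop over SNPs, contacts and gene overlaps
brute_pairs <- function(snps, fr, idx, gene_frag, min_contacts = 1) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    sf <- locate_fragment(fr, snps$chrom[i], snps$pos[i], strict = FALSE)
    if (is.na(sf)) next
    for (g in unique(gene_frag$feature_id)) {
      gfs <- gene_frag$fragment_id[gene_frag$feature_id == g]
      total <- 0
      for (r in seq_len(nrow(idx))) {
        a <- idx$frag_a[r]; b <- idx$frag_b[r]
        if (a == sf && b %in% gfs) total <- total + idx$count[r]
        if (b == sf && a %in% gfs) total <- total + idx$count[r]
      }
      if (total >= min_contacts) {
        out[[length(out) + 1]] <-
          data.frame(snp = snps$rsid[i], gene = g, contacts = total)
      }
    }
  }
  if (length(out) == 0) return(data.frame(snp = character(), gene = character(),
                                          contacts = numeric()))
  df <- do.call(rbind, out)
  df[order(df$snp, df$gene), ]
}

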