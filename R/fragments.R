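#' In-silico restriction digestion of a genome
#'
#' Cuts every chromosome at each occurrence of a restriction motif on the
#' forward strand and returns the resulting fragments. The default motif and
#' cut offset describe HindIII (`A^AGCTT`): the enzyme recognises `AAGCTT` and
#' cleaves after the first base. HindIII's site is palindromic, so scanning the
#' forward strand alone finds every site; for non-palindromic motifs the caller
#' must supply both strands' motifs separately.
#'
#' Ambiguous bases (`N` etc.) never match the motif. Fragment coordinates are
#' 0-based half-open (BED convention); `fragment_id` is a globally unique
#' integer assigned in genome order so it can serve as a join key across the
#' contact, pairing and annotation tables.
#'
#' @param sequences A named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param enzyme_motif Recognition motif (default `"AAGCTT"`, HindIII).
#' @param cut_offset Cut position within the motif, `0 <= cut_offset <=
#'   nchar(enzyme_motif)` (default 1, i.e. `A^AGCTT`).
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `fragment_id`,
#'   carrying the chromosome lengths in `attr(, "chrom_lengths")`. Fragments
#'   exactly partition each chromosome.
#' @export
#' @examples
#' digest_genome(c(chr1 = "GGAAGCTTCC"))
digest_genome <- function(sequences, enzyme_motif = "AAGCTT", cut_offset = 1L) {
  if (inherits(sequences, "DNAStringSet")) {
    seq_set <- sequences
  } else {
    if (!is.character(sequences) || length(sequences) == 0) {
      abort("`sequences` must be a non-empty named character vector or DNAStringSet")
    }
    seq_set <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (length(seq_set) == 0) abort("`sequences` is empty")
  if (is.null(names(seq_set)) || anyNA(names(seq_set)) || any(names(seq_set) == "")) {
    abort("every sequence must be named with its chromosome")
  }
  if (!is.character(enzyme_motif) || length(enzyme_motif) != 1 || nchar(enzyme_motif) == 0) {
    abort("`enzyme_motif` must be a non-empty string")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(enzyme_motif)) {
    abort("`cut_offset` must lie within the motif: 0 <= cut_offset <= nchar(motif)")
  }
  lens <- Biostrings::width(seq_set)
  if (any(lens <= 0)) abort("chromosome lengths must be positive")

  motif <- Biostrings::DNAString(enzyme_motif)
  frags <- purrr::map2(as.character(names(seq_set)), seq_along(seq_set), function(chrom, i) {
    # fixed = TRUE: IUPAC ambiguity codes in the subject never match
    hits <- Biostrings::matchPattern(motif, seq_set[[i]], fixed = TRUE)
    cuts <- IRanges::start(hits) - 1L + cut_offset  # 0-based cut coordinates
    cuts <- cuts[cuts > 0 & cuts < lens[i]]
    bounds <- c(0L, sort(unique(cuts)), lens[i])
    tibble(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1]
    )
  })
  out <- bind_rows(frags)
  out$fragment_id <- seq_len(nrow(out))
  attr(out, "chrom_lengths") <- setNames(as.integer(lens), names(seq_set))
  out
}

#' Locate the restriction fragment containing a position
#'
#' Maps 1-based positions (VCF/GWAS convention) onto the unique fragment with
#' `start <= pos - 1 < end`. A position falling exactly on a cut boundary is
#' assigned to the fragment ending there only when it is that fragment's last
#' base; the half-open convention makes the assignment unambiguous.
#'
#' @param fragments Fragment table from [digest_genome()].
#' @param chrom,pos Equal-length vectors of chromosome names and 1-based
#'   positions.
#' @param strict Error on unknown chromosome / out-of-range position (default);
#'   with `strict = FALSE` such queries yield `NA`.
#'
#' @return Integer vector of fragment ids, parallel to the query.
#' @export
locate_fragment <- function(fragments, chrom, pos, strict = TRUE) {
  assert_cols(fragments, c("chrom", "start", "end", "fragment_id"))
  if (length(chrom) != length(pos)) abort("`chrom` and `pos` must have equal length")
  pos <- as.numeric(pos)
  out <- rep(NA_integer_, length(pos))
  for (cn in unique(chrom)) {
    sel <- which(chrom == cn)
    fr <- fragments[fragments$chrom == cn, , drop = FALSE]
    if (nrow(fr) == 0) {
      if (strict) abort(sprintf("unknown chromosome '%s'", cn))
      next
    }
    p0 <- pos[sel] - 1  # to 0-based
    bad <- !is.finite(p0) | p0 < 0 | p0 >= max(fr$end)
    if (any(bad) && strict) {
      abort(sprintf(
        "position %s out of range for chromosome '%s' (length %d)",
        format(pos[sel][bad][1], scientific = FALSE), cn, max(fr$end)
      ))
    }
    idx <- findInterval(p0, fr$start)
    idx[bad] <- NA_integer_
    out[sel] <- fr$fragment_id[idx]
  }
  out
}

#' Map interval features (genes) to the restriction fragments they overlap
#'
#' Every fragment sharing at least one base with a feature is reported, so a
#' gene spanning a cut site maps to several fragments. Feature coordinates
#' follow the GTF convention (1-based, inclusive).
#'
#' @param fragments Fragment table from [digest_genome()].
#' @param features Tibble with `feature_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#'
#' @return A tibble `feature_id`, `fragment_id` with one row per overlap.
#' @export
map_features_to_fragments <- function(fragments, features) {
  assert_cols(fragments, c("chrom", "start", "end", "fragment_id"))
  assert_cols(features, c("feature_id", "chrom", "start", "end"))
  if (any(features$start > features$end)) abort("feature start > end")
  chrom_lengths <- attr(fragments, "chrom_lengths")
  if (!is.null(chrom_lengths)) {
    ln <- chrom_lengths[features$chrom]
    if (anyNA(ln) || any(features$start < 1 | features$end > ln)) {
      abort("feature interval outside chromosome bounds")
    }
  }
  out <- purrr::map(unique(features$chrom), function(cn) {
    fr <- fragments[fragments$chrom == cn, , drop = FALSE]
    fe <- features[features$chrom == cn, , drop = FALSE]
    if (nrow(fr) == 0 || nrow(fe) == 0) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = fe$start, end = fe$end),
      IRanges::IRanges(start = fr$start + 1L, end = fr$end)  # to 1-based inclusive
    )
    tibble(
      feature_id = fe$feature_id[S4Vectors::queryHits(hits)],
      fragment_id = fr$fragment_id[S4Vectors::subjectHits(hits)]
    )
  })
  arrange(bind_rows(out), .data$feature_id, .data$fragment_id)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; keep the first token as the name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  setNames(as.character(seqs), names(seqs))
}

#' Write a fragment table as BED-like TSV
#' @param fragments Fragment table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  readr::write_tsv(fragments[, c("chrom", "start", "end", "fragment_id")], path)
  invisible(path)
}
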