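#' Parse cleaned Hi-C contact records
#'
#' Reads Juicer "merged_nodups"-style whitespace-delimited text: one contact
#' per line with fields `read_name str1 chr1 pos1 frag1 mapq1 str2 chr2 pos2
#' frag2 mapq2`. A contact is retained only when **both** ends have
#' `mapq >= min_mapq`; the default of 30 is the usual cleaned-library rule.
#' Malformed lines (wrong field count, non-numeric mapq) are a hard error
#' naming the offending line.
#'
#' @param path Contact file.
#' @param min_mapq Minimum mapping quality required of both ends (default 30).
#'
#' @return Tibble of retained records with columns `read_name`, `str1`,
#'   `chr1`, `pos1`, `frag1`, `mapq1`, `str2`, `chr2`, `pos2`, `frag2`,
#'   `mapq2`. A parse report (`n_total`, `n_kept`, `n_dropped_mapq`) is
#'   attached as `attr(, "report")`.
#' @export
read_contacts <- function(path, min_mapq = 30) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- tibble(
      read_name = character(), str1 = character(), chr1 = character(),
      pos1 = integer(), frag1 = integer(), mapq1 = integer(),
      str2 = character(), chr2 = character(), pos2 = integer(),
      frag2 = integer(), mapq2 = integer()
    )
    attr(out, "report") <- list(n_total = 0L, n_kept = 0L, n_dropped_mapq = 0L)
    return(out)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 11)) {
    bad <- which(nf != 11)[1]
    abort(sprintf("malformed contact record at line %d: expected 11 fields, found %d", bad, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 11, byrow = TRUE)
  to_int <- function(col, what) {
    v <- suppressWarnings(as.integer(m[, col]))
    if (anyNA(v)) {
      abort(sprintf("malformed contact record at line %d: non-numeric %s", which(is.na(v))[1], what))
    }
    v
  }
  rec <- tibble(
    read_name = m[, 1],
    str1 = m[, 2], chr1 = m[, 3], pos1 = to_int(4, "pos1"),
    frag1 = to_int(5, "frag1"), mapq1 = to_int(6, "mapq1"),
    str2 = m[, 7], chr2 = m[, 8], pos2 = to_int(9, "pos2"),
    frag2 = to_int(10, "frag2"), mapq2 = to_int(11, "mapq2")
  )
  keep <- rec$mapq1 >= min_mapq & rec$mapq2 >= min_mapq
  out <- rec[keep, , drop = FALSE]
  attr(out, "report") <- list(
    n_total = nrow(rec),
    n_kept = sum(keep),
    n_dropped_mapq = sum(!keep)
  )
  out
}

#' Hi-C library quality control
#'
#' A library passes only when all three hold, with strict inequalities:
#' more than 90% alignable unique read pairs, more than 50% unique contacts,
#' and a duplication rate below 40%.
#'
#' @param pct_alignable_unique,pct_unique_contacts,duplication_rate
#'   Percentages in \[0, 100\].
#'
#' @return A one-row tibble with the metrics, `pass`, and a semicolon-joined
#'   `reasons` string for failures (empty when passing).
#' @export
library_qc <- function(pct_alignable_unique, pct_unique_contacts, duplication_rate) {
  for (v in list(pct_alignable_unique, pct_unique_contacts, duplication_rate)) {
    assert_scalar_number(v, "QC metric", 0, 100)
  }
  reasons <- c(
    if (!(pct_alignable_unique > 90)) "alignable unique read pairs <= 90%",
    if (!(pct_unique_contacts > 50)) "unique contacts <= 50%",
    if (!(duplication_rate < 40)) "duplication rate >= 40%"
  )
  tibble(
    pct_alignable_unique = pct_alignable_unique,
    pct_unique_contacts = pct_unique_contacts,
    duplication_rate = duplication_rate,
    pass = length(reasons) == 0,
    reasons = paste(reasons, collapse = "; ")
  )
}

#' Build a symmetric fragment-fragment interaction index
#'
#' Aggregates mapq-filtered contact records into counts per unordered
#' fragment pair. Fragment assignment is recomputed from each end's
#' chromosome/position against the fragment index, and any disagreement with
#' the file's own `frag` fields is an error — this keeps synthetic and real
#' contact files mutually checkable. Self-fragment pairs (both ends on one
#' fragment, typically self-ligation artifacts) are dropped by default.
#'
#' @param records Tibble from [read_contacts()] (already mapq-filtered).
#' @param fragments Fragment table from [digest_genome()].
#' @param exclude_self Drop contacts whose two ends share a fragment
#'   (default `TRUE`).
#'
#' @return Tibble `frag_a`, `frag_b`, `count` with `frag_a < frag_b`;
#'   symmetric by construction.
#' @export
build_interaction_index <- function(records, fragments, exclude_self = TRUE) {
  assert_cols(records, c("chr1", "pos1", "frag1", "chr2", "pos2", "frag2"))
  if (nrow(records) == 0) {
    return(tibble(frag_a = integer(), frag_b = integer(), count = integer()))
  }
  f1 <- locate_fragment(fragments, records$chr1, records$pos1)
  f2 <- locate_fragment(fragments, records$chr2, records$pos2)
  bad <- which(f1 != records$frag1 | f2 != records$frag2)
  if (length(bad) > 0) {
    abort(sprintf(
      "contact record %d: frag fields (%d, %d) disagree with fragment index (%d, %d)",
      bad[1], records$frag1[bad[1]], records$frag2[bad[1]], f1[bad[1]], f2[bad[1]]
    ))
  }
  idx <- tibble(frag_a = pmin(f1, f2), frag_b = pmax(f1, f2))
  if (exclude_self) idx <- filter(idx, .data$frag_a != .data$frag_b)
  idx |>
    count(.data$frag_a, .data$frag_b, name = "count") |>
    arrange(.data$frag_a, .data$frag_b)
}

#' Neighbours of a fragment in an interaction index
#'
#' @param index Tibble from [build_interaction_index()].
#' @param fragment_id Fragment to query.
#' @return Tibble `fragment_id`, `count` of interacting fragments.
#' @export
interacting_fragments <- function(index, fragment_id) {
  a <- index[index$frag_a == fragment_id, c("frag_b", "count")]
  b <- index[index$frag_b == fragment_id, c("frag_a", "count")]
  names(a) <- names(b) <- c("fragment_id", "count")
  arrange(bind_rows(a, b), .data$fragment_id)
}
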