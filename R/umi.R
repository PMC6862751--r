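# UMI extraction, exact-string clustering and per-cluster majority consensus.
# UMIs are extracted from the alignment frame (the references carry an N-padded
# UMI slot at their 5' end), clusters are exact-string groups (the simulator's
# UMI space, 4^12, makes collisions negligible), and the consensus is a simple
# per-column majority over the common reference frame.

#' Extract a UMI from an alignment
#'
#' Returns the query bases aligned to the UMI positions of the reference.
#' Reads with a gap in the UMI locus (deletion of a UMI position, or an
#' insertion inside it) are dropped: `NA` is returned and the caller counts
#' the exclusion.
#'
#' @param a an `alignment`.
#' @param umi_locus `c(start, end)` reference interval holding the UMI.
#' @param frame optional precomputed [alignment_ref_frame()].
#' @return UMI string, or `NA_character_` if the locus is not cleanly covered.
#' @export
extract_umi <- function(a, umi_locus = c(1L, 12L), frame = NULL) {
  if (is.null(frame)) frame <- alignment_ref_frame(a)
  idx <- seq.int(umi_locus[1], umi_locus[2])
  b <- frame$bases[idx]
  ins_inside <- any(frame$ins$pos >= umi_locus[1] & frame$ins$pos < umi_locus[2])
  if (any(b == "-") || ins_inside) return(NA_character_)
  paste(b, collapse = "")
}

#' Cluster reads by exact UMI
#'
#' @param umis character vector of UMIs (NAs are dropped).
#' @return list of clusters, each `list(umi, members)` where `members` indexes
#'   the input vector; cluster count equals the number of distinct UMIs.
#' @export
cluster_by_umi <- function(umis) {
  keep <- which(!is.na(umis))
  if (!length(keep)) return(list())
  groups <- split(keep, umis[keep])
  unname(Map(function(u, m) list(umi = u, members = m), names(groups), groups))
}

# per-column plurality under the tie rules: unique plurality base -> base;
# unique plurality gap -> NA (column dropped); any tie -> "N"
#' @noRd
column_consensus <- function(chars) {
  matrix_consensus(matrix(chars, nrow = 1L))
}

# vectorised column consensus: rows are reference-frame columns, columns are
# cluster members
#' @noRd
matrix_consensus <- function(mat) {
  symbols <- c("A", "C", "G", "T", "-")
  cnt <- vapply(symbols, function(s) rowSums(mat == s),
                numeric(nrow(mat)))
  if (nrow(mat) == 1L) cnt <- matrix(cnt, nrow = 1L,
                                     dimnames = list(NULL, symbols))
  mx <- do.call(pmax, as.data.frame(cnt))
  tied <- rowSums(cnt == mx) > 1L
  winner <- symbols[max.col(cnt, ties.method = "first")]
  out <- ifelse(tied, "N", winner)
  out[!tied & winner == "-"] <- NA_character_
  out
}

#' Majority consensus of a UMI cluster
#'
#' Members must be alignments against the same reference; the consensus is
#' taken per reference-frame column (reference positions, plus insertion
#' columns keyed by anchor position so that shared insertions survive). Per
#' column the plurality symbol among `{A, C, G, T, gap}` wins; a gap wins only
#' as unique plurality (the column is then dropped); any tie yields `N`, which
#' can never satisfy a perfect-match window. The consensus of a single read is
#' that read, and callers are expected to realign the consensus against the
#' references.
#'
#' @param alignments list of `alignment` objects over a common reference.
#' @param frames optional list of precomputed frames (parallel to
#'   `alignments`).
#' @return consensus DNA string (alphabet A/C/G/T/N).
#' @export
umi_consensus <- function(alignments, frames = NULL) {
  n <- length(alignments)
  if (n == 0L) stop("empty cluster")
  if (n == 1L) return(alignments[[1]]$query)
  if (is.null(frames)) frames <- lapply(alignments, alignment_ref_frame)
  rlen <- length(frames[[1]]$bases)

  base_mat <- vapply(frames, function(f) f$bases, character(rlen))
  if (rlen == 1L) base_mat <- matrix(base_mat, nrow = 1L)

  # insertion columns: anchor position -> max length across members
  ins_tabs <- lapply(frames, function(f) f$ins)
  all_pos <- sort(unique(unlist(lapply(ins_tabs, function(d) d$pos))))
  ins_cons <- list()
  for (p in all_pos) {
    seqs <- vapply(ins_tabs, function(d) {
      i <- match(p, d$pos)
      if (is.na(i)) "" else d$seq[i]
    }, character(1))
    width <- max(nchar(seqs))
    cols <- character(0)
    for (k in seq_len(width)) {
      chars <- ifelse(nchar(seqs) >= k, substr(seqs, k, k), "-")
      cc <- column_consensus(chars)
      if (!is.na(cc)) cols <- c(cols, cc)
    }
    if (length(cols)) ins_cons[[as.character(p)]] <- paste(cols, collapse = "")
  }

  col_cons <- matrix_consensus(base_mat)
  if (!length(ins_cons)) {
    return(paste(col_cons[!is.na(col_cons)], collapse = ""))
  }
  out <- character(0)
  pre <- ins_cons[["0"]]
  if (!is.null(pre)) out <- pre
  for (j in seq_len(rlen)) {
    if (!is.na(col_cons[j])) out <- c(out, col_cons[j])
    insj <- ins_cons[[as.character(j)]]
    if (!is.null(insj)) out <- c(out, insj)
  }
  paste(out, collapse = "")
}
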