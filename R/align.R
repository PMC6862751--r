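# Global pairwise alignment against forward and inverted references.
# The DP itself lives in src/align.cpp (banded affine-gap Gotoh); this file
# wraps it in an S3 `alignment` object and provides orientation selection,
# reference-frame projection, window extraction and indel-event extraction.

#' Alignment scoring scheme
#'
#' Affine-gap scoring. Defaults mirror the EMBOSS needle defaults
#' (EDNAFULL match +5 / mismatch -4, gap open 10, gap extend 0.5); a gap of
#' length L costs `gap_open + (L - 1) * gap_extend`. Any pairing involving
#' `N` scores 0 (neutral) but is classified as a mismatch operation, so an
#' `N` can never satisfy a perfect-match window; the neutral score lets the
#' N-padded UMI slot of the branch references capture UMIs without biasing
#' alignment placement.
#'
#' @param match,mismatch match score and mismatch penalty (penalty given as a
#'   negative score).
#' @param gap_open,gap_extend gap opening and extension penalties (positive;
#'   `gap_open >= gap_extend >= 0`).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap_open = 10,
                           gap_extend = 0.5) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Optimal global affine-gap alignment
#'
#' Needleman-Wunsch/Gotoh global alignment with deterministic tie-breaking
#' (substitution preferred over gap, deletion before insertion). With
#' `band > 0` the DP is restricted to a diagonal band that always contains the
#' net length difference; banded results are identical to the full DP whenever
#' the optimal path stays within the band (junction indels in this pipeline
#' are capped well below the default band).
#'
#' @param query,ref DNA strings over A/C/G/T/N.
#' @param scoring a [scoring_scheme()].
#' @param band band half-width (0 = full DP).
#' @param query_id,ref_id identifiers carried into the result.
#' @return an object of class `alignment`: query/ref ids and sequences, score,
#'   and run-length encoded operations (`M` match, `X` mismatch, `I` insertion
#'   relative to the reference, `D` deletion).
#' @export
global_align <- function(query, ref, scoring = scoring_scheme(), band = 0,
                         query_id = "query", ref_id = "ref") {
  assert_dna(query); assert_dna(ref)
  res <- align_affine_cpp(query, ref, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend, as.integer(band))
  structure(list(query_id = query_id, ref_id = ref_id,
                 query = query, ref = ref,
                 orientation = "as-is", ref_class = "forward",
                 ambiguous = FALSE,
                 score = res$score,
                 ops = data.frame(op = unlist(res$op), len = unlist(res$len),
                                  stringsAsFactors = FALSE)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment>", x$query_id, "vs", x$ref_id,
      sprintf("(%s, score %.1f)\n", x$orientation, x$score))
  cat("  CIGAR:", cigar(x), "\n")
  invisible(x)
}

#' CIGAR string of an alignment (M/X/I/D)
#'
#' @param a an `alignment`.
#' @return a CIGAR-like string.
#' @export
cigar <- function(a) paste0(a$ops$len, a$ops$op, collapse = "")

#' Project an alignment onto the reference frame
#'
#' @param a an `alignment`.
#' @return a list with `bases` (query base per reference position, `"-"` at
#'   deletions), `op` (per-position operation, one of M/X/D), and `ins`
#'   (insertions: data.frame of anchor reference position — 0 for an insertion
#'   before the first base — and inserted query string).
#' @export
alignment_ref_frame <- function(a) {
  qc <- strsplit(a$query, "", fixed = TRUE)[[1]]
  rlen <- nchar(a$ref)
  bases <- character(rlen); opv <- character(rlen)
  ins_pos <- integer(0); ins_seq <- character(0)
  qi <- 0L; ri <- 0L
  for (k in seq_len(nrow(a$ops))) {
    op <- a$ops$op[k]; len <- a$ops$len[k]
    if (op == "M" || op == "X") {
      idx <- ri + seq_len(len)
      bases[idx] <- qc[qi + seq_len(len)]
      opv[idx] <- op
      qi <- qi + len; ri <- ri + len
    } else if (op == "D") {
      idx <- ri + seq_len(len)
      bases[idx] <- "-"; opv[idx] <- "D"
      ri <- ri + len
    } else { # I
      ins_pos <- c(ins_pos, ri)
      ins_seq <- c(ins_seq, paste(qc[qi + seq_len(len)], collapse = ""))
      qi <- qi + len
    }
  }
  list(bases = bases, op = opv,
       ins = data.frame(pos = ins_pos, seq = ins_seq, stringsAsFactors = FALSE))
}

#' Indel events of an alignment
#'
#' Signed sizes: deletions negative, insertions positive. An insertion is
#' anchored at the reference position it follows (`ref_start == ref_end`);
#' a deletion spans `ref_start..ref_end`.
#'
#' @param a an `alignment`.
#' @return data.frame with `size`, `ref_start`, `ref_end` (empty if none).
#' @export
indel_events <- function(a) {
  out <- list(); ri <- 0L
  for (k in seq_len(nrow(a$ops))) {
    op <- a$ops$op[k]; len <- a$ops$len[k]
    if (op == "D") {
      out[[length(out) + 1L]] <- data.frame(size = -len, ref_start = ri + 1L,
                                            ref_end = ri + len)
      ri <- ri + len
    } else if (op == "I") {
      out[[length(out) + 1L]] <- data.frame(size = len, ref_start = ri,
                                            ref_end = ri)
    } else ri <- ri + len
  }
  if (!length(out))
    return(data.frame(size = integer(0), ref_start = integer(0),
                      ref_end = integer(0)))
  do.call(rbind, out)
}

#' Build a reference set for orientation selection
#'
#' @param ids,seqs,classes parallel vectors: reference id, sequence, and
#'   orientation class (`"forward"` or `"inverted"`).
#' @return a `reference_set` (list of refs).
#' @export
reference_set <- function(ids, seqs, classes) {
  stopifnot(length(ids) == length(seqs), length(ids) == length(classes),
            all(classes %in% c("forward", "inverted")))
  structure(Map(function(i, s, cl) list(id = i, seq = s, class = cl),
                ids, seqs, classes),
            class = "reference_set", names = ids)
}

#' Orientation-resolved alignment against a reference set
#'
#' Aligns the query and its reverse complement against every reference and
#' returns the single highest-scoring combination. If the best score is
#' reached by references in both orientation classes, the result is flagged
#' `ambiguous` rather than silently broken.
#'
#' @param query DNA string.
#' @param refs a [reference_set()].
#' @param scoring a [scoring_scheme()].
#' @param band band half-width passed to [global_align()].
#' @param query_id identifier.
#' @param cache optional environment used to memoise the chosen alignment by
#'   query string (one cache per reference set); useful when many identical
#'   reads are aligned, e.g. error-free simulations.
#' @return an `alignment` with `ref_class` (`"forward"`/`"inverted"`),
#'   `orientation` (`"as-is"`/`"revcomp"`, the query orientation used) and
#'   `ambiguous` set.
#' @export
choose_orientation <- function(query, refs, scoring = scoring_scheme(),
                               band = 0, query_id = "query", cache = NULL) {
  stopifnot(inherits(refs, "reference_set"))
  if (!is.null(cache) && !is.null(cache[[query]])) {
    best <- cache[[query]]
    best$query_id <- query_id
    return(best)
  }
  qrc <- revcomp(query)
  alns <- list(); orients <- character(0); classes <- character(0)
  for (r in refs) {
    for (orient in c("as-is", "revcomp")) {
      q <- if (orient == "as-is") query else qrc
      alns[[length(alns) + 1L]] <- global_align(q, r$seq, scoring, band,
                                                query_id, r$id)
      orients <- c(orients, orient)
      classes <- c(classes, r$class)
    }
  }
  scores <- vapply(alns, function(a) a$score, numeric(1))
  win <- which.max(scores)  # first maximum: refs order, as-is before revcomp
  best <- alns[[win]]
  best$orientation <- orients[win]
  best$ref_class <- classes[win]
  best$ambiguous <- length(unique(classes[scores == scores[win]])) > 1L
  if (!is.null(cache)) cache[[query]] <- best
  best
}

#' Write alignments as a SAM-like TSV
#'
#' One row per alignment: read id, reference id, orientation, score and the
#' M/X/I/D CIGAR string.
#'
#' @param alignments list of `alignment` objects.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_alignments_tsv <- function(alignments, path) {
  df <- do.call(rbind, lapply(alignments, function(a)
    data.frame(read_id = a$query_id, ref_id = a$ref_id,
               orientation = a$orientation, score = a$score,
               cigar = cigar(a), stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the query bases aligned to a reference window
#'
#' @param a an `alignment`.
#' @param window `c(start, end)` reference interval (1-based inclusive).
#' @param frame optional precomputed [alignment_ref_frame()] of `a`.
#' @return list with `seq` (query bases aligned to the window, gaps removed),
#'   `exact_match` (TRUE iff every window position is an exact match and no
#'   insertion falls strictly inside the window; boundary-abutting indels do
#'   not violate it), and `indel_overlap`.
#' @export
extract_window <- function(a, window, frame = NULL) {
  rlen <- nchar(a$ref)
  if (window[1] < 1 || window[2] > rlen || window[1] > window[2])
    stop("window outside reference")
  if (is.null(frame)) frame <- alignment_ref_frame(a)
  idx <- seq.int(window[1], window[2])
  ops <- frame$op[idx]
  ins_inside <- any(frame$ins$pos >= window[1] & frame$ins$pos < window[2])
  has_del <- any(ops == "D")
  list(seq = paste(frame$bases[idx][frame$bases[idx] != "-"], collapse = ""),
       exact_match = all(ops == "M") && !ins_inside,
       indel_overlap = has_del || ins_inside)
}
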