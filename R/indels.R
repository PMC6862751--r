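# Junction indel profiling: per-position indel occupancy along the reference,
# junction indel size spectra with max-1 scaling, and per-group indel rates
# for contingency comparisons.

#' Per-position indel occupancy profile
#'
#' For each reference position, the fraction of included reads whose alignment
#' has an indel covering that position. A deletion covers its reference span;
#' an insertion (which has no reference span) covers only the reference
#' position flanking it on the left (position 1 for an insertion before the
#' first base).
#'
#' @param alignments list of `alignment` objects on a common reference frame.
#' @param positions reference positions to profile (default: whole reference).
#' @return an `indel_profile` data.frame (`pos`, `fraction`) with attribute
#'   `n` (included reads).
#' @export
positional_profile <- function(alignments, positions = NULL) {
  n <- length(alignments)
  if (n == 0L) stop("empty inclusion set")
  rlen <- nchar(alignments[[1]]$ref)
  if (is.null(positions)) positions <- seq_len(rlen)
  cov <- numeric(rlen)
  for (a in alignments) {
    events <- indel_events(a)
    hit <- logical(rlen)
    for (k in seq_len(nrow(events))) {
      if (events$size[k] < 0) {
        hit[events$ref_start[k]:events$ref_end[k]] <- TRUE
      } else {
        hit[max(1L, events$ref_start[k])] <- TRUE
      }
    }
    cov <- cov + hit
  }
  out <- data.frame(pos = positions, fraction = cov[positions] / n)
  attr(out, "n") <- n
  class(out) <- c("indel_profile", "data.frame")
  out
}

#' Junction indel size distribution
#'
#' Counts indel events whose position falls within `window` bases of either
#' cut site, signed (deletions negative, insertions positive); each event is
#' counted. Reads with no junction event contribute to the size-0 bin. The
#' scaled variant divides every bin by the maximum bin count, so the largest
#' bin is 1.
#'
#' @param alignments list of `alignment` objects on a common reference frame.
#' @param cuts inter-base cut positions in reference coordinates
#'   (`c(left, right)`).
#' @param window bases on either side of a cut within which an event counts.
#' @return a `size_distribution` data.frame (`size`, `count`, `scaled`).
#' @export
junction_sizes <- function(alignments, cuts, window = 5L) {
  sizes <- integer(0)
  for (a in alignments) {
    events <- indel_events(a)
    ev <- integer(0)
    for (cut in cuts) {
      if (nrow(events)) {
        del <- events$size < 0
        hit <- (del & events$ref_start <= cut + window &
                  events$ref_end >= cut - window + 1L) |
          (!del & events$ref_start >= cut - window &
             events$ref_start <= cut + window)
        ev <- c(ev, events$size[hit])
      }
    }
    sizes <- c(sizes, if (length(ev)) ev else 0L)
  }
  tab <- table(sizes)
  out <- data.frame(size = as.integer(names(tab)), count = as.integer(tab))
  out <- out[order(out$size), , drop = FALSE]
  rownames(out) <- NULL
  out$scaled <- if (nrow(out)) out$count / max(out$count) else numeric(0)
  class(out) <- c("size_distribution", "data.frame")
  out
}

#' Rescale a size distribution to maximum 1
#'
#' Idempotent: scaling an already-scaled distribution is the identity.
#'
#' @param dist a `size_distribution`.
#' @return the distribution with `scaled` recomputed from `count`.
#' @export
scale_distribution <- function(dist) {
  dist$scaled <- if (nrow(dist)) dist$count / max(dist$count) else numeric(0)
  dist
}

#' Junction indel rate of a read group
#'
#' Proportion of reads with at least one junction indel (a read counts once
#' however many events it has), plus the numerator/denominator pair for
#' contingency tests.
#'
#' @param calls data.frame with `left_indel`/`right_indel` columns (signed
#'   sizes, 0 = none) for the group's reads.
#' @return list with `rate`, `k` (reads with an indel) and `n`.
#' @export
indel_rate <- function(calls) {
  n <- nrow(calls)
  if (n == 0L) stop("zero denominator: empty group")
  has <- (!is.na(calls$left_indel) & calls$left_indel != 0L) |
    (!is.na(calls$right_indel) & calls$right_indel != 0L)
  k <- sum(has)
  list(rate = k / n, k = k, n = n)
}
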