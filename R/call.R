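# Allele x orientation calling under perfect-match rules, and frequency
# tabulation under the two denominator conventions.
#
# Branch reference sets carry an N-padded UMI slot at the 5' end (an N can
# only ever score as mismatch, identically for every read, so the pad fixes
# coordinates without biasing scores) and coordinate maps from insert-relative
# offsets to reference positions for both orientations.

#' Build the long-read (PacBio) branch reference set
#'
#' Forward and inverted wild-type locus references with a UMI pad. Orientation
#' and alignment coordinates are decided against these two references; allele
#' identity (which differs from wild type only by point substitutions that
#' cannot move the alignment) is decided afterwards by the perfect-match
#' window and SNV/PAM pattern, so results equal an all-references sweep.
#'
#' @param model an `amplicon_model`.
#' @param umi_len UMI length (pad width).
#' @return list with `refs` (a [reference_set()]), `umi_locus`, cut positions
#'   (`cut_left`/`cut_right`, 0-based inter-base in reference coordinates),
#'   the insert span, and an offset map closure.
#' @export
pacbio_refs <- function(model, umi_len = 12L) {
  pad <- strrep("N", umi_len)
  refs <- reference_set(
    ids = c("locus_wt_fwd", "locus_wt_inv"),
    seqs = c(paste0(pad, allele_locus(model, "wildtype", "forward")),
             paste0(pad, allele_locus(model, "wildtype", "inverted"))),
    classes = c("forward", "inverted"))
  base <- umi_len + model$flank_up
  allele_seqs <- list()
  for (al in c("allele1", "allele2"))
    for (ori in c("forward", "inverted"))
      allele_seqs[[paste(al, ori, sep = "_")]] <-
        paste0(pad, allele_locus(model, al, ori, pam_mutated = TRUE))
  list(refs = refs,
       allele_seqs = allele_seqs,
       umi_locus = c(1L, umi_len),
       umi_len = umi_len,
       cut_left = base,
       cut_right = base + model$insert_len,
       insert_span = c(base + 1L, base + model$insert_len),
       map_offset = function(offset, orientation) {
         if (orientation == "inverted") base + (model$insert_len + 1L - offset)
         else base + offset
       })
}

#' Build the short-read (Illumina) branch reference set
#'
#' The nested short-read amplicon (insert offsets
#' `model$illumina_amplicon[1]..model$illumina_amplicon[2]`) with a UMI pad;
#' forward orientation only, mirroring the nested PCR design that cannot
#' amplify inversions or deletions.
#'
#' @param model an `amplicon_model`.
#' @param umi_len UMI length.
#' @return list like [pacbio_refs()] (no cut positions: the amplicon does not
#'   reach the cut sites).
#' @export
illumina_refs <- function(model, umi_len = 12L) {
  pad <- strrep("N", umi_len)
  amp <- substr(model$insert_seq, model$illumina_amplicon[1],
                model$illumina_amplicon[2])
  refs <- reference_set(ids = "amplicon_wt_fwd",
                        seqs = paste0(pad, amp),
                        classes = "forward")
  shift <- umi_len - model$illumina_amplicon[1] + 1L
  list(refs = refs, umi_locus = c(1L, umi_len), umi_len = umi_len,
       map_offset = function(offset, orientation = "forward") offset + shift)
}

# expected insert-relative base at given offsets for an allele
#' @noRd
expected_allele_chars <- function(model, allele_id, offsets, pam_mutated) {
  strsplit(derive_allele(model, allele_id, pam_mutated), "", fixed = TRUE)[[1]][offsets]
}

#' @noRd
complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

#' @noRd
unassigned_call <- function(id, branch, reason, orientation = NA_character_) {
  data.frame(id = id, branch = branch, group = "unassigned",
             orientation = orientation, left_indel = NA_integer_,
             right_indel = NA_integer_, reason = reason,
             stringsAsFactors = FALSE)
}

# junction indel of largest magnitude whose event lies within +/- `window`
# of the inter-base cut position `cut` (reference coordinates); 0 if none
#' @noRd
junction_indel_at <- function(events, cut, window = 5L) {
  if (!nrow(events)) return(0L)
  del <- events$size < 0
  hit <- (del & events$ref_start <= cut + window & events$ref_end >= cut - window + 1L) |
    (!del & events$ref_start >= cut - window & events$ref_start <= cut + window)
  if (!any(hit)) return(0L)
  ev <- events[hit, , drop = FALSE]
  ev$size[which.max(abs(ev$size))]
}

#' Call allele and orientation for a long-read consensus
#'
#' Implements the perfect-match rules of the long-read branch: wholesale
#' deletion is called when the alignment removes (almost) the whole insert;
#' otherwise assignment to wild type / allele 1 / allele 2 requires an exact
#' match over the 250-bp promoter/exon/splice-donor window and the expected
#' bases at the four SNV and two PAM positions on the winning orientation's
#' frame. Junction indels within +/-5 bp of either cut are recorded; a
#' junction deletion reaching 6+ bp into the insert necessarily removes a PAM
#' base and yields `unassigned (pam_mismatch)`.
#'
#' @param aln orientation-resolved `alignment` (from [choose_orientation()]
#'   against [pacbio_refs()]).
#' @param model an `amplicon_model`.
#' @param refs the [pacbio_refs()] used for alignment.
#' @param deletion_tolerance a deletion of at least
#'   `insert_len - deletion_tolerance` spanning the insert counts as wholesale
#'   deletion.
#' @param scoring,band used for the per-allele realignment.
#' @return one-row data.frame: `id`, `branch`, `group`, `orientation`,
#'   `left_indel`, `right_indel`, `reason`.
#' @export
call_pacbio <- function(aln, model, refs, deletion_tolerance = 50L,
                        scoring = scoring_scheme(), band = 64L) {
  cl <- call_pacbio_frame(aln, model, refs, deletion_tolerance)
  if (cl$group != "unassigned" ||
      !isTRUE(cl$reason %in% c("pam_mismatch", "window_mismatch", "snv_mixed")))
    return(cl)
  # The wild-type frame left the consensus unassigned. Alleles differ from
  # the wild type at the SNV/PAM point substitutions, and near a junction
  # deletion those mismatches can create equal-scoring gap placements on the
  # wild-type reference that a per-allele reference resolves. Realign against
  # the allele references in the winning orientation class and call on the
  # highest-scoring frame, exactly as an alignment against the full reference
  # set would.
  orientation <- if (aln$ref_class == "inverted") "inverted" else "forward"
  best_aln <- aln; best_cl <- cl
  for (al in c("allele1", "allele2")) {
    rseq <- refs$allele_seqs[[paste(al, orientation, sep = "_")]]
    if (is.null(rseq)) next
    a2 <- global_align(aln$query, rseq, scoring, band, aln$query_id,
                       paste("locus", al, orientation, sep = "_"))
    a2$ref_class <- aln$ref_class
    a2$orientation <- aln$orientation
    if (a2$score > best_aln$score) {
      best_aln <- a2
      best_cl <- call_pacbio_frame(a2, model, refs, deletion_tolerance)
    }
  }
  best_cl
}

#' @noRd
call_pacbio_frame <- function(aln, model, refs, deletion_tolerance = 50L) {
  id <- aln$query_id
  events <- indel_events(aln)
  big <- events$size <= -(model$insert_len - deletion_tolerance) &
    events$ref_start <= refs$insert_span[2] &
    events$ref_end >= refs$insert_span[1]
  if (any(big)) {
    jd <- events[!big, , drop = FALSE]
    return(data.frame(id = id, branch = "pacbio", group = "deletion",
                      orientation = NA_character_,
                      left_indel = junction_indel_at(jd, refs$cut_left),
                      right_indel = junction_indel_at(jd, refs$cut_right),
                      reason = NA_character_, stringsAsFactors = FALSE))
  }

  # a wholesale deletion carries no orientation information, so the
  # (expected) score tie between the forward and inverted references is
  # checked only after the deletion test
  if (isTRUE(aln$ambiguous))
    return(unassigned_call(id, "pacbio", "ambiguous_orientation"))

  orientation <- if (aln$ref_class == "inverted") "inverted" else "forward"
  frame <- alignment_ref_frame(aln)
  offsets <- seq.int(model$pacbio_window[1], model$pacbio_window[2])
  rpos <- refs$map_offset(offsets, orientation)
  obs <- frame$bases[rpos]
  rng <- range(rpos)
  ins_inside <- any(frame$ins$pos >= rng[1] & frame$ins$pos < rng[2])
  left_indel <- junction_indel_at(events, refs$cut_left)
  right_indel <- junction_indel_at(events, refs$cut_right)

  if (any(obs == "-") || ins_inside)
    return(unassigned_call(id, "pacbio", "window_mismatch", orientation))
  if (orientation == "inverted") obs <- complement_chars(obs)

  groups <- c("wildtype", "allele1", "allele2")
  pam_flag <- c(FALSE, TRUE, TRUE)
  match_mat <- vapply(seq_along(groups), function(i) {
    obs == expected_allele_chars(model, groups[i], offsets, pam_flag[i])
  }, logical(length(offsets)))
  candidates <- which(colSums(!match_mat) == 0L)

  if (length(candidates) != 1L) {
    snv_cols <- offsets %in% model$snvs$offset
    # mismatches confined to SNV columns means a mixed SNV pattern (chimera)
    reason <- if (all(apply(!match_mat, 2, function(mm) all(which(mm) %in% which(snv_cols)))))
      "snv_mixed" else "window_mismatch"
    return(unassigned_call(id, "pacbio", reason, orientation))
  }

  grp <- groups[candidates]
  pam_pos <- refs$map_offset(model$pams$offset, orientation)
  pam_obs <- frame$bases[pam_pos]
  if (orientation == "inverted") pam_obs <- complement_chars(pam_obs)
  pam_exp <- if (grp == "wildtype") model$pams$ref else model$pams$alt
  if (any(pam_obs == "-") || !all(pam_obs == pam_exp))
    return(unassigned_call(id, "pacbio", "pam_mismatch", orientation))

  data.frame(id = id, branch = "pacbio", group = grp, orientation = orientation,
             left_indel = left_indel, right_indel = right_indel,
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Call allele for a short-read consensus
#'
#' Assignment requires an exact match over the 44-bp exon 1 window including
#' the four SNV positions; the SNV pattern must equal exactly one of wild
#' type, allele 1 or allele 2. Orientation is always forward: the nested
#' design cannot amplify inversions or deletions, so this branch is blind to
#' junction indels by construction.
#'
#' @param aln orientation-resolved `alignment` against [illumina_refs()].
#' @param model an `amplicon_model`.
#' @param refs the [illumina_refs()] used.
#' @return one-row data.frame as in [call_pacbio()] (indels are `NA`).
#' @export
call_illumina <- function(aln, model, refs) {
  id <- aln$query_id
  frame <- alignment_ref_frame(aln)
  offsets <- seq.int(model$illumina_window[1], model$illumina_window[2])
  rpos <- refs$map_offset(offsets)
  obs <- frame$bases[rpos]
  rng <- range(rpos)
  ins_inside <- any(frame$ins$pos >= rng[1] & frame$ins$pos < rng[2])
  if (any(obs == "-") || ins_inside) {
    out <- unassigned_call(id, "illumina", "window_mismatch", "forward")
    return(out)
  }
  groups <- c("wildtype", "allele1", "allele2")
  match_mat <- vapply(groups, function(g) {
    obs == expected_allele_chars(model, g, offsets, pam_mutated = FALSE)
  }, logical(length(offsets)))
  candidates <- which(colSums(!match_mat) == 0L)
  if (length(candidates) != 1L) {
    snv_cols <- which(offsets %in% model$snvs$offset)
    reason <- if (all(apply(!match_mat, 2, function(mm) all(which(mm) %in% snv_cols))))
      "snv_mixed" else "window_mismatch"
    return(unassigned_call(id, "illumina", reason, "forward"))
  }
  data.frame(id = id, branch = "illumina", group = groups[candidates],
             orientation = "forward", left_indel = NA_integer_,
             right_indel = NA_integer_, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Tabulate allele calls into a frequency table
#'
#' Three denominator conventions:
#' * `strict_matched`: percentages of assigned, forward-oriented groups
#'   (wild type / allele 1 / allele 2) over their own total — the headline
#'   per-allele convention (wild type included in the denominator).
#' * `orientation`: forward vs inverted among assigned, non-deletion calls —
#'   the orientation-summary convention (deletions not counted).
#' * `all_aligned_minus_deletions`: per (group x orientation) percentages over
#'   all aligned non-deletion consensi including unassigned — the
#'   insertion-rate convention.
#'
#' @param calls data.frame of calls (rows from [call_pacbio()] /
#'   [call_illumina()]).
#' @param policy denominator policy.
#' @return a `frequency_table` data.frame (`group`, `orientation`, `count`,
#'   `pct`) with attributes `policy`, `denominator` and `zero_denominator`.
#' @export
tabulate_calls <- function(calls,
                           policy = c("strict_matched", "orientation",
                                      "all_aligned_minus_deletions")) {
  policy <- match.arg(policy)
  assigned <- calls[calls$group %in% c("wildtype", "allele1", "allele2"), ,
                    drop = FALSE]
  if (policy == "strict_matched") {
    sub <- assigned[assigned$orientation == "forward", , drop = FALSE]
    denom <- nrow(sub)
    grp <- factor(sub$group, levels = c("wildtype", "allele1", "allele2"))
    counts <- as.integer(table(grp))
    out <- data.frame(group = levels(grp), orientation = "forward",
                      count = counts,
                      pct = if (denom > 0) 100 * counts / denom else rep(NA_real_, 3),
                      stringsAsFactors = FALSE)
  } else if (policy == "orientation") {
    denom <- nrow(assigned)
    ori <- factor(assigned$orientation, levels = c("forward", "inverted"))
    counts <- as.integer(table(ori))
    out <- data.frame(group = "all", orientation = levels(ori), count = counts,
                      pct = if (denom > 0) 100 * counts / denom else rep(NA_real_, 2),
                      stringsAsFactors = FALSE)
  } else {
    nondel <- calls[!(calls$group %in% "deletion"), , drop = FALSE]
    denom <- nrow(nondel)
    grp <- interaction(nondel$group,
                       ifelse(is.na(nondel$orientation), "na", nondel$orientation),
                       drop = TRUE, sep = "_")
    counts <- as.integer(table(grp))
    nm <- levels(grp)
    out <- data.frame(group = sub("_[^_]+$", "", nm),
                      orientation = sub("^.*_", "", nm),
                      count = counts,
                      pct = if (denom > 0) 100 * counts / denom else NA_real_,
                      stringsAsFactors = FALSE)
  }
  attr(out, "policy") <- policy
  attr(out, "denominator") <- denom
  attr(out, "zero_denominator") <- denom == 0L
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> policy:", attr(x, "policy"),
      " denominator:", attr(x, "denominator"), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
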