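# Bisulfite branch: conversion-aware reference construction, allele
# assignment, and per-read methylated-CpG counting.
#
# Everything is modelled on the bisulfite top strand. After conversion a C>T
# SNV cannot be told apart from conversion of an unmethylated C, so those SNV
# positions accept {C, T}; alleles stay mutually distinguishable because every
# pair differs at at least one conversion-immune SNV (the C>G at offset 535
# and the T>A at offset 541). The locus generator guarantees no SNV sits in a
# CpG, so genotype and methylation state never mix.

#' Bisulfite-convert a DNA string (top strand)
#'
#' @param seq DNA string.
#' @param retain_pos 1-based positions whose C is retained (methylated CpG Cs
#'   for the all-methylated variant; empty for full conversion).
#' @return converted string (unmethylated C becomes T).
#' @export
bisulfite_convert <- function(seq, retain_pos = integer(0)) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(ch == "C")
  idx <- setdiff(idx, retain_pos)
  ch[idx] <- "T"
  paste(ch, collapse = "")
}

#' Build the bisulfite reference set
#'
#' For each allele (wild type, allele 1, allele 2), three UMI-padded variants
#' of the bisulfite amplicon (the insert's bisulfite window): the fully
#' converted sequence, the converted sequence assuming all CpGs methylated
#' (CpG Cs retained), and the unconverted sequence. All nine references are
#' forward-class (the nested bisulfite amplicon cannot amplify inversions or
#' deletions).
#'
#' @param model an `amplicon_model`.
#' @param umi_len UMI length.
#' @return list with `refs` (a [reference_set()]), `umi_locus`, the CpG and
#'   SNV reference positions, the window span in reference coordinates, and
#'   the per-allele allowed-base patterns used for assignment.
#' @export
build_bisulfite_refs <- function(model, umi_len = 12L) {
  win <- model$bisulfite_window
  shift <- umi_len - win[1] + 1L       # insert offset -> reference position
  pad <- strrep("N", umi_len)
  groups <- c("wildtype", "allele1", "allele2")
  ids <- character(0); seqs <- character(0)
  patterns <- list()
  cpg_local <- model$cpg_offsets - win[1] + 1L  # within-amplicon positions
  for (g in groups) {
    amp <- substr(derive_allele(model, g, pam_mutated = g != "wildtype"),
                  win[1], win[2])
    conv_un <- bisulfite_convert(amp)
    conv_meth <- bisulfite_convert(amp, retain_pos = cpg_local)
    ids <- c(ids, paste0(g, c("_converted", "_converted_methylated",
                              "_unconverted")))
    seqs <- c(seqs, paste0(pad, conv_un), paste0(pad, conv_meth),
              paste0(pad, amp))
    # allowed bases per amplicon position: the two converted variants differ
    # only at C positions ({T} vs {C,T} sets collapse to accepting either)
    a <- strsplit(conv_un, "", fixed = TRUE)[[1]]
    b <- strsplit(conv_meth, "", fixed = TRUE)[[1]]
    c0 <- strsplit(amp, "", fixed = TRUE)[[1]]
    pat <- vector("list", nchar(amp))
    for (j in seq_along(pat)) pat[[j]] <- unique(c(a[j], b[j],
                                                   if (c0[j] == "C") c("C", "T")))
    patterns[[g]] <- pat
  }
  list(refs = reference_set(ids, seqs, rep("forward", length(ids))),
       umi_locus = c(1L, umi_len), umi_len = umi_len,
       window_span = c(umi_len + 1L, umi_len + (win[2] - win[1] + 1L)),
       cpg_pos = cpg_local + umi_len,
       snv_pos = model$snvs$offset + shift,
       patterns = patterns)
}

#' Call allele and methylation state for a bisulfite consensus
#'
#' The consensus is orientation-resolved against the nine-variant reference
#' set (best variant gives the coordinate frame). Assignment requires the
#' aligned window to be gap-free and to match exactly one allele's
#' conversion-aware pattern: conversion-invariant positions must match
#' exactly, non-CpG C positions accept C or T (incomplete conversion), CpG
#' positions accept C or T (methylation state), and SNV positions must match
#' the allele's post-conversion base set. Methylation is then read per CpG
#' site: C = methylated, T = unmethylated, anything else uncallable.
#'
#' @param aln orientation-resolved `alignment` against
#'   [build_bisulfite_refs()]`$refs`.
#' @param refs the [build_bisulfite_refs()] result.
#' @return one-row data.frame: `id`, `group`, `count` (methylated sites),
#'   `n_callable`, and `meth_vector` (35-character M/U/N string).
#' @export
call_methylation <- function(aln, refs) {
  id <- aln$query_id
  frame <- alignment_ref_frame(aln)
  span <- refs$window_span
  idx <- seq.int(span[1], span[2])
  obs <- frame$bases[idx]
  ins_inside <- any(frame$ins$pos >= span[1] & frame$ins$pos < span[2])
  n_sites <- length(refs$cpg_pos)
  blank <- paste(rep("N", n_sites), collapse = "")
  if (any(obs == "-") || ins_inside)
    return(data.frame(id = id, group = "unassigned", count = NA_integer_,
                      n_callable = 0L, meth_vector = blank,
                      stringsAsFactors = FALSE))

  ok <- vapply(names(refs$patterns), function(g) {
    pat <- refs$patterns[[g]]
    all(vapply(seq_along(obs), function(j) obs[j] %in% pat[[j]], logical(1)))
  }, logical(1))
  if (sum(ok) != 1L)
    return(data.frame(id = id, group = "unassigned", count = NA_integer_,
                      n_callable = 0L, meth_vector = blank,
                      stringsAsFactors = FALSE))

  site_base <- frame$bases[refs$cpg_pos]
  state <- ifelse(site_base == "C", "M", ifelse(site_base == "T", "U", "N"))
  data.frame(id = id, group = names(ok)[ok],
             count = sum(state == "M"),
             n_callable = sum(state != "N"),
             meth_vector = paste(state, collapse = ""),
             stringsAsFactors = FALSE)
}

#' Histogram of methylated-site counts
#'
#' @param calls data.frame of [call_methylation()] rows, optionally with
#'   grouping columns already bound (e.g. `arm`).
#' @param by character vector of grouping columns (default `"group"`).
#' @return data.frame with the grouping columns, `count` (0..35) and `n`
#'   (number of consensi); empty groups yield no rows.
#' @export
methylation_histogram <- function(calls, by = "group") {
  calls <- calls[!is.na(calls$count), , drop = FALSE]
  if (!nrow(calls))
    return(data.frame(group = character(0), count = integer(0), n = integer(0)))
  key <- interaction(calls[by], drop = TRUE, sep = "|")
  out <- do.call(rbind, lapply(split(calls, key), function(d) {
    tab <- table(d$count)
    cbind(d[rep(1L, length(tab)), by, drop = FALSE],
          data.frame(count = as.integer(names(tab)), n = as.integer(tab)))
  }))
  rownames(out) <- NULL
  out
}
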