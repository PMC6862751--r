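# Truth-labelled read simulation under the editing-outcome model: each
# (haploid) cell draws one outcome — wholesale deletion, re-insertion of the
# wild type, or insertion of the methylated/unmethylated exogenous allele,
# each in forward or inverted orientation — plus junction indels, per-CpG
# methylation states, a UMI, and per-branch sequencing errors. 6-TG selection
# resamples cells by survival weight (cells survive iff the locus no longer
# expresses: deletion, any inversion, methylated forward insert, or a
# functional-window-disrupting junction deletion).

OUTCOME_CLASSES <- c("deletion", "wt_fwd", "wt_inv", "meth_fwd", "meth_inv",
                     "unmeth_fwd", "unmeth_inv")
FORWARD_EXPRESSING <- c("wt_fwd", "unmeth_fwd")
FORWARD_CLASSES <- c("wt_fwd", "meth_fwd", "unmeth_fwd")

#' Simulation configuration
#'
#' Defaults are the package's standing description of the study conditions:
#' insertion of the exogenous allele is rare (methylated rarer than
#' unmethylated), wholesale deletion and wild-type re-ligation (forward more
#' often than inverted) dominate, about half of junctions carry a small
#' NHEJ indel, long-read consensus accuracy is 99.4%, and in vitro
#' methylation is maintained at most CpGs.
#'
#' @param class_proportions named simplex over
#'   `deletion, wt_fwd, wt_inv, meth_fwd, meth_inv, unmeth_fwd, unmeth_inv`.
#' @param methylated_allele which allele carries the in vitro methylation in
#'   this arm (`"allele1"` or `"allele2"`; the other allele is the
#'   unmethylated insert — the reciprocal arm swaps them).
#' @param n_cells cells per sample.
#' @param reads_per_cell reads per cell; `reads_dist = "fixed"` emits exactly
#'   this many, `"poisson"` draws Poisson counts (cells may yield 0 reads).
#' @param umi_length UMI length (bases).
#' @param error_rates named per-base substitution error rates per branch.
#' @param indel_prob probability of an indel at each junction.
#' @param indel_p_insertion probability a junction event is an insertion.
#' @param indel_mean_size mean event size (geometric, size >= 1).
#' @param indel_max_size size cap.
#' @param epsilon survival weight of expressing cells under 6-TG
#'   (selection is nearly complete).
#' @param functional_window insert-relative interval whose disruption by a
#'   junction deletion silences the gene (default: the promoter/exon 1/splice
#'   donor match window; set via [build_model()] coordinates).
#' @param maintenance per-CpG probability that in vitro methylation is
#'   maintained in the cell.
#' @param conversion_failure per-C probability that an unmethylated C escapes
#'   bisulfite conversion in a read.
#' @return a `sim_config` list.
#' @export
sim_config <- function(class_proportions = c(deletion = 0.30, wt_fwd = 0.42,
                                             wt_inv = 0.25, meth_fwd = 0.0035,
                                             meth_inv = 0.0035,
                                             unmeth_fwd = 0.0115,
                                             unmeth_inv = 0.0115),
                       methylated_allele = c("allele1", "allele2"),
                       n_cells = 2000L,
                       reads_per_cell = 3L,
                       reads_dist = c("fixed", "poisson"),
                       umi_length = 12L,
                       error_rates = c(illumina = 0.001, pacbio = 0.006,
                                       bisulfite = 0.001),
                       indel_prob = 0.5,
                       indel_p_insertion = 0.2,
                       indel_mean_size = 3,
                       indel_max_size = 50L,
                       epsilon = 0.001,
                       functional_window = NULL,
                       maintenance = 0.95,
                       conversion_failure = 0.005) {
  methylated_allele <- match.arg(methylated_allele)
  reads_dist <- match.arg(reads_dist)
  stopifnot(setequal(names(class_proportions), OUTCOME_CLASSES),
            abs(sum(class_proportions) - 1) < 1e-8,
            all(class_proportions >= 0),
            all(error_rates >= 0 & error_rates <= 1),
            indel_prob >= 0, indel_prob <= 1,
            indel_p_insertion >= 0, indel_p_insertion <= 1,
            indel_mean_size >= 1, indel_max_size >= 1,
            epsilon >= 0, epsilon <= 1,
            maintenance >= 0, maintenance <= 1,
            conversion_failure >= 0, conversion_failure <= 1)
  structure(list(class_proportions = class_proportions[OUTCOME_CLASSES],
                 methylated_allele = methylated_allele,
                 n_cells = as.integer(n_cells),
                 reads_per_cell = reads_per_cell, reads_dist = reads_dist,
                 umi_length = as.integer(umi_length),
                 error_rates = error_rates,
                 indel_prob = indel_prob,
                 indel_p_insertion = indel_p_insertion,
                 indel_mean_size = indel_mean_size,
                 indel_max_size = as.integer(indel_max_size),
                 epsilon = epsilon,
                 functional_window = functional_window,
                 maintenance = maintenance,
                 conversion_failure = conversion_failure),
            class = "sim_config")
}

#' @noRd
class_allele <- function(class, methylated_allele) {
  other <- if (methylated_allele == "allele1") "allele2" else "allele1"
  switch(class,
         deletion = NA_character_,
         wt_fwd = , wt_inv = "wildtype",
         meth_fwd = , meth_inv = methylated_allele,
         unmeth_fwd = , unmeth_inv = other)
}

#' @noRd
draw_indel_size <- function(cfg) {
  min(1L + rgeom(1L, 1 / cfg$indel_mean_size), cfg$indel_max_size)
}

# apply a junction event between `left` and `right`; deletions chew
# ceil(s/2) from the left piece and floor(s/2) from the right piece when
# chew_left_into = "left" is the flank side (the split is swapped at the
# right junction so that floor(s/2) always goes into the insert)
#' @noRd
join_with_indel <- function(left, right, size, split_right) {
  if (size == 0L) return(paste0(left, right))
  if (size > 0L)
    return(paste0(left, rand_dna(size, gc = 0.5), right))
  s <- -size
  dl <- if (split_right) floor(s / 2) else ceiling(s / 2)
  dr <- s - dl
  paste0(substr(left, 1L, nchar(left) - dl),
         substr(right, dr + 1L, nchar(right)))
}

#' Simulate edited cells
#'
#' Draws an outcome class per cell, applies junction indels at the cut
#' positions (deletions chew symmetrically into insert and flank; insertions
#' add random bases), draws the per-CpG methylation truth vector, and assigns
#' a UMI per cell.
#'
#' @param model an `amplicon_model`.
#' @param cfg a [sim_config()].
#' @param seed integer seed (deterministic output).
#' @param n_cells override `cfg$n_cells`.
#' @return a `truth` data.frame: `cell_id`, `class`, `allele`, `orientation`,
#'   `left_indel`, `right_indel` (signed, 0 = none), `meth_vector`
#'   (M/U string over the CpG sites), `umi`, `seq` (the cell's locus).
#' @export
simulate_cells <- function(model, cfg, seed = 1L, n_cells = cfg$n_cells) {
  n_sites <- length(model$cpg_offsets)
  with_seed(seed, {
    classes <- sample(OUTCOME_CLASSES, n_cells, replace = TRUE,
                      prob = cfg$class_proportions)
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      cl <- classes[i]
      allele <- class_allele(cl, cfg$methylated_allele)
      orientation <- if (cl == "deletion") NA_character_
        else if (grepl("_inv$", cl)) "inverted" else "forward"
      exogenous <- cl %in% c("meth_fwd", "meth_inv", "unmeth_fwd", "unmeth_inv")

      draw_junction <- function() {
        if (runif(1) >= cfg$indel_prob) return(0L)
        s <- draw_indel_size(cfg)
        if (runif(1) < cfg$indel_p_insertion) s else -s
      }

      if (cl == "deletion") {
        li <- draw_junction()
        seq <- join_with_indel(model$flank_up_seq, model$flank_down_seq,
                               li, split_right = FALSE)
        ri <- 0L
      } else {
        ins <- derive_allele(model, allele, pam_mutated = exogenous)
        if (orientation == "inverted") ins <- revcomp(ins)
        li <- draw_junction(); ri <- draw_junction()
        left_part <- join_with_indel(model$flank_up_seq, ins, li,
                                     split_right = TRUE)
        seq <- join_with_indel(left_part, model$flank_down_seq, ri,
                               split_right = FALSE)
      }

      meth <- if (cl %in% c("meth_fwd", "meth_inv"))
        paste(ifelse(runif(n_sites) < cfg$maintenance, "M", "U"), collapse = "")
      else paste(rep("U", n_sites), collapse = "")

      rows[[i]] <- data.frame(
        cell_id = sprintf("cell%05d", i), class = cl, allele = allele,
        orientation = orientation, left_indel = li, right_indel = ri,
        meth_vector = meth,
        umi = paste(sample(DNA_BASES, cfg$umi_length, replace = TRUE),
                    collapse = ""),
        seq = seq, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("truth", "data.frame")
    out
  })
}

#' Apply a selection arm to simulated cells
#'
#' `pre` returns the input; `mock` resamples cells uniformly with replacement
#' (composition unchanged in expectation); `6tg` resamples with survival
#' weights: deletion, every inverted class and the methylated forward insert
#' survive (weight 1); expressing forward classes (`wt_fwd`, `unmeth_fwd`)
#' get weight `epsilon`, unless a junction deletion chews into the functional
#' window (promoter/exon 1/splice donor), which silences the gene and
#' restores weight 1. Resampled cells receive fresh UMIs (each surviving cell
#' is a distinct molecule at library preparation).
#'
#' @param truth a `truth` data.frame from [simulate_cells()].
#' @param cfg a [sim_config()].
#' @param arm `"pre"`, `"mock"` or `"6tg"`.
#' @param model the `amplicon_model` (for the functional window default).
#' @param seed integer seed.
#' @param n_cells post-selection cell count (default: input size).
#' @return a `truth` data.frame.
#' @export
apply_selection <- function(truth, cfg, arm = c("pre", "mock", "6tg"),
                            model = NULL, seed = 1L, n_cells = nrow(truth)) {
  arm <- match.arg(arm)
  if (arm == "pre") return(truth)
  fw <- cfg$functional_window %||%
    if (!is.null(model)) model$pacbio_window else c(306L, 555L)
  insert_len <- if (!is.null(model)) model$insert_len else 1120L
  with_seed(seed, {
    if (arm == "mock") {
      idx <- sample.int(nrow(truth), n_cells, replace = TRUE)
    } else {
      w <- vapply(seq_len(nrow(truth)), function(i) {
        cl <- truth$class[i]
        if (!cl %in% FORWARD_EXPRESSING) return(1)
        # depth of junction deletions into the insert (insert side gets the
        # ceiling share of the symmetric chew; see join_with_indel)
        dl <- if (truth$left_indel[i] < 0) ceiling(-truth$left_indel[i] / 2) else 0
        dr <- if (truth$right_indel[i] < 0) ceiling(-truth$right_indel[i] / 2) else 0
        disrupted <- (dl >= fw[1]) || (dr >= insert_len - fw[2] + 1L)
        if (disrupted) 1 else cfg$epsilon
      }, numeric(1))
      if (sum(w) == 0) stop("empty surviving pool under 6-TG selection")
      idx <- sample.int(nrow(truth), n_cells, replace = TRUE, prob = w)
    }
    out <- truth[idx, , drop = FALSE]
    out$cell_id <- sprintf("cell%05d", seq_len(nrow(out)))
    out$umi <- vapply(seq_len(nrow(out)), function(i)
      paste(sample(DNA_BASES, cfg$umi_length, replace = TRUE), collapse = ""),
      character(1))
    rownames(out) <- NULL
    out
  })
}

#' @noRd
add_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Emit reads for a sequencing branch
#'
#' * `illumina`: the nested short amplicon over the exon 1 window plus
#'   margins, emitted only from forward-oriented, non-deletion templates (the
#'   nested design cannot amplify inversions, deletions or off-target
#'   integrations). Junction indels never reach the amplified interior.
#' * `pacbio`: the full locus for every class; wholesale-deletion templates
#'   are excluded by default, mirroring the gel extraction of the full-length
#'   band (`keep_deletions = TRUE` retains them for insertion-rate
#'   denominators).
#' * `bisulfite`: the bisulfite window amplicon from forward, non-deletion
#'   templates, converted on the top strand according to the cell's truth
#'   methylation vector, with conversion failures at the configured rate.
#'
#' Each read is the UMI followed by the template (emitted on either strand
#' with probability 1/2), with per-base substitution errors at the branch
#' rate. Reads are emitted already merged/consensus-called; quality is
#' constant.
#'
#' @param model an `amplicon_model`.
#' @param truth a `truth` data.frame.
#' @param branch `"illumina"`, `"pacbio"` or `"bisulfite"`.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param keep_deletions retain wholesale-deletion templates in the pacbio
#'   branch.
#' @return data.frame: `read_id`, `cell_id`, `class`, `left_indel`,
#'   `right_indel`, `umi`, `meth_vector`, `seq`.
#' @export
emit_reads <- function(model, truth, branch = c("illumina", "pacbio",
                                                "bisulfite"),
                       cfg, seed = 1L, keep_deletions = FALSE) {
  branch <- match.arg(branch)
  keep <- switch(branch,
                 illumina = truth$class %in% FORWARD_CLASSES,
                 pacbio = if (keep_deletions) rep(TRUE, nrow(truth))
                          else truth$class != "deletion",
                 bisulfite = truth$class %in% FORWARD_CLASSES)
  tmpl <- truth[keep, , drop = FALSE]
  rate <- cfg$error_rates[[branch]]
  bw <- model$bisulfite_window
  cpg_local <- model$cpg_offsets - bw[1] + 1L

  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(tmpl))) {
      cell <- tmpl[i, ]
      base <- switch(branch,
        pacbio = cell$seq,
        illumina = {
          ins <- derive_allele(model, cell$allele,
                               pam_mutated = !cell$class %in% c("wt_fwd", "wt_inv"))
          substr(ins, model$illumina_amplicon[1], model$illumina_amplicon[2])
        },
        bisulfite = {
          ins <- derive_allele(model, cell$allele,
                               pam_mutated = !cell$class %in% c("wt_fwd", "wt_inv"))
          amp <- substr(ins, bw[1], bw[2])
          st <- strsplit(cell$meth_vector, "", fixed = TRUE)[[1]]
          retained <- cpg_local[st == "M"]
          ch <- strsplit(amp, "", fixed = TRUE)[[1]]
          cs <- which(ch == "C")
          conv <- setdiff(cs, retained)
          fail <- conv[runif(length(conv)) < cfg$conversion_failure]
          ch[setdiff(conv, fail)] <- "T"
          paste(ch, collapse = "")
        })
      k <- if (cfg$reads_dist == "fixed") as.integer(cfg$reads_per_cell)
           else rpois(1L, cfg$reads_per_cell)
      if (k <= 0L) next
      for (j in seq_len(k)) {
        read <- paste0(cell$umi, base)
        read <- add_substitutions(read, rate)
        if (runif(1) < 0.5) read <- revcomp(read)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = paste0(branch, "_", cell$cell_id, "_r", j),
          cell_id = cell$cell_id, class = cell$class,
          left_indel = cell$left_indel, right_indel = cell$right_indel,
          umi = cell$umi, meth_vector = cell$meth_vector,
          seq = read, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows))
      return(data.frame(read_id = character(0), cell_id = character(0),
                        class = character(0), left_indel = integer(0),
                        right_indel = integer(0), umi = character(0),
                        meth_vector = character(0), seq = character(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write reads as FASTQ (Phred+33, constant quality) plus a truth TSV
#'
#' @param reads data.frame from [emit_reads()].
#' @param fastq,truth_tsv output paths.
#' @return invisibly, the fastq path.
#' @export
write_reads_fastq <- function(reads, fastq, truth_tsv = NULL) {
  seqs <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  quals <- Biostrings::BStringSet(vapply(nchar(reads$seq),
                                         function(n) strrep("I", n),
                                         character(1)))
  Biostrings::writeXStringSet(seqs, fastq, format = "fastq", qualities = quals)
  if (!is.null(truth_tsv))
    write.table(reads[, setdiff(names(reads), "seq")], truth_tsv,
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastq)
}
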