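# small shared helpers for constructing reads and noisy sequences in tests

add_noise <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# a truth data.frame row as produced by simulate_cells(), for hand-built cells
truth_row <- function(model, cell_id, class, allele, orientation,
                      left_indel = 0L, right_indel = 0L,
                      meth_vector = strrep("U", length(model$cpg_offsets)),
                      umi = random_dna(12),
                      seq = NA_character_) {
  data.frame(cell_id = cell_id, class = class, allele = allele,
             orientation = orientation, left_indel = left_indel,
             right_indel = right_indel, meth_vector = meth_vector,
             umi = umi, seq = seq, stringsAsFactors = FALSE)
}

# build a long-read query: UMI + locus for an allele/orientation, optionally
# with a junction deletion reaching `left_into`/`right_into` bases into the
# insert (flank untouched), as produced by exonuclease chew-back on one side
pacbio_query <- function(model, allele = "wildtype",
                         orientation = "forward",
                         pam_mutated = allele != "wildtype",
                         left_into = 0L, right_into = 0L,
                         umi = random_dna(12)) {
  ins <- derive_allele(model, allele, pam_mutated)
  if (orientation == "inverted") ins <- revcomp(ins)
  ins <- substr(ins, left_into + 1L, nchar(ins) - right_into)
  paste0(umi, model$flank_up_seq, ins, model$flank_down_seq)
}
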