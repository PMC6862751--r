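# Locus model: a surrogate CpG-island locus carrying the experiment's printed
# coordinate structure. The real locus (GRCh37 chrX:133593819-133594938 plus
# flanks) is not bundled; a seeded random sequence with CpG-island-like GC
# content is generated under the same structural constraints, so that every
# coordinate relationship used by the callers is preserved.

# Fixed genomic structure (1-based inclusive, insert-relative offsets).
GENOMIC_CHROM <- "chrX"
GENOMIC_INSERT_START <- 133593819
GENOMIC_INSERT_END <- 133594938
INSERT_LEN <- 1120L

# Allele-defining synonymous SNVs in the exon 1 coding sequence.
SNV_TABLE <- data.frame(
  offset = c(532L, 535L, 538L, 541L),
  ref = c("C", "C", "C", "T"),
  alt = c("T", "G", "T", "A"),
  allele = c("allele1", "allele2", "allele2", "allele1"),
  stringsAsFactors = FALSE
)

# PAM-destroying mutations, sixth base from each insert end.
PAM_TABLE <- data.frame(
  offset = c(6L, 1115L),
  ref = c("G", "C"),
  alt = c("C", "G"),
  side = c("left", "right"),
  stringsAsFactors = FALSE
)

# Analysis windows, insert-relative (derived from printed genomic spans).
WINDOW_ILLUMINA <- c(502L, 545L)     # 44-bp exon 1 perfect-match window
WINDOW_PACBIO <- c(306L, 555L)       # 250-bp promoter/exon1/splice-donor window
WINDOW_BISULFITE <- c(478L, 760L)    # bisulfite analysis window, 35 CpGs
AMPLICON_ILLUMINA <- c(480L, 704L)   # short-read amplicon span

N_CPG <- 35L

#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @noRd
rand_dna <- function(n, gc = 0.6) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# count CG dinucleotide starts within [from, to-1] of a character vector
#' @noRd
cg_starts <- function(chars, from, to) {
  idx <- seq.int(from, to - 1L)
  idx[chars[idx] == "C" & chars[idx + 1L] == "G"]
}

#' Build the surrogate amplicon locus model
#'
#' Generates a seeded surrogate sequence for the dual-cut locus: an 1120-bp
#' insert (the cut-out CpG island segment) with upstream/downstream flanks,
#' carrying the experiment's structural constraints: allele-defining SNVs at
#' insert offsets 532/535/538/541 (C>T, C>G, C>T, T>A), PAM mutations at the
#' sixth base from each insert end (offsets 6 and 1115), perfect-match windows
#' for each sequencing branch, and exactly 35 CpG dinucleotides in the
#' bisulfite analysis window. No CpG overlaps an SNV offset, so bisulfite
#' allele assignment stays well defined.
#'
#' Cut sites are modelled as blunt, at the insert boundaries (3 bp 5' of each
#' PAM). Internally coordinates are handled 0-based half-open; all user-facing
#' offsets are 1-based inclusive, insert-relative.
#'
#' @param seed integer seed; the model is deterministic given the seed.
#' @param flank_up,flank_down flank lengths (defaults 700 and 165, matching
#'   the amplicon primer placement ~700 bp upstream / ~165 bp downstream of
#'   the cuts). Must be >= 100.
#' @param max_attempts bound on constraint-repair iterations.
#' @return an object of class `amplicon_model`.
#' @export
build_model <- function(seed = 1L, flank_up = 700L, flank_down = 165L,
                        max_attempts = 2000L) {
  stopifnot(flank_up >= 100L, flank_down >= 100L)
  flank_up <- as.integer(flank_up); flank_down <- as.integer(flank_down)

  built <- with_seed(seed, {
    ins <- strsplit(rand_dna(INSERT_LEN, gc = 0.6), "", fixed = TRUE)[[1]]
    # forced reference bases at SNV and PAM offsets
    ins[SNV_TABLE$offset] <- SNV_TABLE$ref
    ins[PAM_TABLE$offset] <- PAM_TABLE$ref
    # keep SNV offsets out of CpG context (also for alt alleles):
    # a C at an SNV offset must not be followed by G; the C>G alt at 535 must
    # not be preceded by C.
    for (o in c(532L, 535L, 538L)) if (ins[o + 1L] == "G") ins[o + 1L] <- "A"
    if (ins[534L] == "C") ins[534L] <- "A"
    # block equal-scoring junction-deletion shifts onto/off the PAM bases
    ins[1L] <- "A"; ins[INSERT_LEN] <- "T"
    protected <- 530:543

    # repair the bisulfite window to exactly N_CPG CpGs
    attempt <- 0L
    repeat {
      starts <- cg_starts(ins, WINDOW_BISULFITE[1], WINDOW_BISULFITE[2])
      k <- length(starts)
      if (k == N_CPG) break
      attempt <- attempt + 1L
      if (attempt > max_attempts)
        stop("could not satisfy CpG-count constraint in ", max_attempts,
             " attempts")
      if (k > N_CPG) {
        cand <- setdiff(starts, protected)
        cand <- cand[!(cand + 1L) %in% protected]
        if (!length(cand)) stop("no repairable CpG outside protected region")
        p <- sample(cand, 1L)
        ins[p + 1L] <- "A"
      } else {
        pos <- seq.int(WINDOW_BISULFITE[1], WINDOW_BISULFITE[2] - 1L)
        cand <- pos[!pos %in% protected & !(pos + 1L) %in% protected &
                      !(pos %in% starts)]
        p <- sample(cand, 1L)
        ins[p] <- "C"; ins[p + 1L] <- "G"
      }
    }

    fu <- strsplit(rand_dna(flank_up, gc = 0.45), "", fixed = TRUE)[[1]]
    fd <- strsplit(rand_dna(flank_down, gc = 0.45), "", fixed = TRUE)[[1]]
    # junction homology guard: the five flank bases abutting each cut are
    # A/T only, so no equal-scoring placement of a junction deletion can
    # slide the gap onto or off a PAM base (both PAM alleles are C/G)
    fu[(flank_up - 4L):flank_up] <- sample(c("A", "T"), 5L, replace = TRUE)
    fd[1:5] <- sample(c("A", "T"), 5L, replace = TRUE)
    fu[flank_up] <- "T"
    fd[1L] <- "A"
    list(ins = ins, fu = fu, fd = fd)
  })

  insert_seq <- paste(built$ins, collapse = "")
  flank_up_seq <- paste(built$fu, collapse = "")
  flank_down_seq <- paste(built$fd, collapse = "")

  model <- structure(list(
    seed = seed,
    flank_up = flank_up,
    flank_down = flank_down,
    flank_up_seq = flank_up_seq,
    flank_down_seq = flank_down_seq,
    insert_seq = insert_seq,
    insert_len = INSERT_LEN,
    locus_seq = paste0(flank_up_seq, insert_seq, flank_down_seq),
    cut_left = flank_up,                 # 0-based inter-base, locus coords
    cut_right = flank_up + INSERT_LEN,
    snvs = SNV_TABLE,
    pams = PAM_TABLE,
    illumina_window = WINDOW_ILLUMINA,
    pacbio_window = WINDOW_PACBIO,
    bisulfite_window = WINDOW_BISULFITE,
    illumina_amplicon = AMPLICON_ILLUMINA,
    cpg_offsets = cg_starts(built$ins, WINDOW_BISULFITE[1], WINDOW_BISULFITE[2]),
    genomic_anchor = list(chrom = GENOMIC_CHROM,
                          insert_start = GENOMIC_INSERT_START,
                          insert_end = GENOMIC_INSERT_END)
  ), class = "amplicon_model")
  validate_model(model)
  model
}

#' Validate an amplicon model's invariants
#'
#' Checks insert length, window widths, CpG count, SNV/PAM reference bases and
#' SNV placement inside both match windows. Called by [build_model()]; exposed
#' for tests.
#'
#' @param model an `amplicon_model`.
#' @return the model, invisibly; errors if an invariant fails.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "amplicon_model"))
  ins <- strsplit(model$insert_seq, "", fixed = TRUE)[[1]]
  if (length(ins) != INSERT_LEN) stop("insert length != 1120")
  if (diff(model$illumina_window) + 1L != 44L) stop("illumina window != 44 bp")
  if (diff(model$pacbio_window) + 1L != 250L) stop("pacbio window != 250 bp")
  if (!all(ins[model$snvs$offset] == model$snvs$ref))
    stop("wild-type base at an SNV offset != ref base")
  if (!all(ins[model$pams$offset] == model$pams$ref))
    stop("wild-type base at a PAM offset != ref base")
  if (!all(model$snvs$offset >= model$illumina_window[1] &
             model$snvs$offset <= model$illumina_window[2]))
    stop("SNV offset outside illumina window")
  if (!all(model$snvs$offset >= model$pacbio_window[1] &
             model$snvs$offset <= model$pacbio_window[2]))
    stop("SNV offset outside pacbio window")
  ncpg <- length(cg_starts(ins, model$bisulfite_window[1],
                           model$bisulfite_window[2]))
  if (ncpg != N_CPG) stop("bisulfite window has ", ncpg, " CpGs, expected 35")
  near <- unlist(lapply(model$cpg_offsets, function(p) c(p, p + 1L)))
  if (any(model$snvs$offset %in% near)) stop("SNV offset inside a CpG")
  if (nchar(model$locus_seq) != model$flank_up + INSERT_LEN + model$flank_down)
    stop("locus length inconsistent")
  invisible(model)
}

#' @export
print.amplicon_model <- function(x, ...) {
  cat("<amplicon_model> seed", x$seed, "\n")
  cat("  locus:", nchar(x$locus_seq), "bp (", x$flank_up, "+",
      x$insert_len, "+", x$flank_down, ")\n")
  cat("  anchor:", x$genomic_anchor$chrom,
      paste0(x$genomic_anchor$insert_start, "-", x$genomic_anchor$insert_end),
      "\n")
  cat("  SNVs at", paste(x$snvs$offset, collapse = "/"),
      "; PAM mutations at", paste(x$pams$offset, collapse = "/"), "\n")
  cat("  CpGs in bisulfite window:", length(x$cpg_offsets), "\n")
  invisible(x)
}

#' Derive an allele's insert sequence
#'
#' Applies the allele-defining SNVs (and, optionally, both PAM mutations) to
#' the wild-type insert.
#'
#' @param model an `amplicon_model`.
#' @param allele_id one of `"wildtype"`, `"allele1"`, `"allele2"`.
#' @param pam_mutated apply the two PAM mutations (exogenous insert templates
#'   carry them; the wild type does not).
#' @return insert-length DNA string.
#' @export
derive_allele <- function(model, allele_id = c("wildtype", "allele1", "allele2"),
                          pam_mutated = FALSE) {
  allele_id <- match.arg(allele_id)
  ins <- strsplit(model$insert_seq, "", fixed = TRUE)[[1]]
  if (allele_id != "wildtype") {
    s <- model$snvs[model$snvs$allele == allele_id, ]
    ins[s$offset] <- s$alt
  }
  if (pam_mutated) ins[model$pams$offset] <- model$pams$alt
  paste(ins, collapse = "")
}

#' Invert the segment between the cut sites
#'
#' Returns the full locus with the given insert sequence reverse-complemented
#' between the cuts, flanks unaltered (the inverted-reference construction).
#'
#' @param model an `amplicon_model`.
#' @param insert_seq insert-length DNA string (default: the wild-type insert).
#' @return full-locus DNA string.
#' @export
invert_between_cuts <- function(model, insert_seq = model$insert_seq) {
  if (nchar(insert_seq) != model$insert_len)
    stop("insert_seq must have length ", model$insert_len)
  paste0(model$flank_up_seq, revcomp(insert_seq), model$flank_down_seq)
}

#' Assemble a full locus for an allele and orientation
#'
#' @param model an `amplicon_model`.
#' @param allele_id allele of the insert.
#' @param orientation `"forward"` or `"inverted"`.
#' @param pam_mutated whether the insert carries the PAM mutations.
#' @return full-locus DNA string.
#' @export
allele_locus <- function(model, allele_id = "wildtype",
                         orientation = c("forward", "inverted"),
                         pam_mutated = allele_id != "wildtype") {
  orientation <- match.arg(orientation)
  ins <- derive_allele(model, allele_id, pam_mutated)
  if (orientation == "inverted") invert_between_cuts(model, ins)
  else paste0(model$flank_up_seq, ins, model$flank_down_seq)
}

#' Convert insert-relative offsets to genomic coordinates and back
#'
#' Offsets are 1-based inclusive and insert-relative (offset 1 is the first
#' base of the cut-out segment); positions in the flanks are allowed
#' (offset 0 is the flank base left of the cut). Round-trips exactly.
#'
#' @param model an `amplicon_model`.
#' @param offset insert-relative offset(s).
#' @param coord genomic coordinate(s) on the anchored chromosome.
#' @return `to_genomic()`: a data.frame with `chrom` and `pos`;
#'   `from_genomic()`: integer offset(s).
#' @export
to_genomic <- function(model, offset) {
  offset <- as.integer(offset)
  lo <- 1L - model$flank_up
  hi <- model$insert_len + model$flank_down
  if (any(offset < lo | offset > hi)) stop("offset outside modeled span")
  data.frame(chrom = model$genomic_anchor$chrom,
             pos = model$genomic_anchor$insert_start + offset - 1L,
             stringsAsFactors = FALSE)
}

#' @rdname to_genomic
#' @export
from_genomic <- function(model, coord) {
  off <- as.integer(coord - model$genomic_anchor$insert_start + 1)
  lo <- 1L - model$flank_up
  hi <- model$insert_len + model$flank_down
  if (any(off < lo | off > hi)) stop("coordinate outside modeled span")
  off
}

#' Write reference FASTA and coordinate sidecar
#'
#' Writes the six locus references (`locus_{wt,allele1,allele2}_{fwd,inv}`)
#' and a JSON sidecar with all windows and offsets (1-based inclusive).
#'
#' @param model an `amplicon_model`.
#' @param dir output directory (created if missing).
#' @return invisibly, the FASTA path.
#' @export
write_model_fasta <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- c(wt = "wildtype", allele1 = "allele1", allele2 = "allele2")
  seqs <- character(0)
  for (nm in names(ids)) {
    seqs[paste0("locus_", nm, "_fwd")] <-
      allele_locus(model, ids[[nm]], "forward")
    seqs[paste0("locus_", nm, "_inv")] <-
      allele_locus(model, ids[[nm]], "inverted")
  }
  fa <- file.path(dir, "references.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  sidecar <- list(
    seed = model$seed,
    flank_up = model$flank_up, flank_down = model$flank_down,
    genomic_anchor = model$genomic_anchor,
    snvs = model$snvs, pams = model$pams,
    illumina_window = model$illumina_window,
    pacbio_window = model$pacbio_window,
    bisulfite_window = model$bisulfite_window,
    cpg_offsets = model$cpg_offsets
  )
  jsonlite::write_json(sidecar, file.path(dir, "references.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fa)
}
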