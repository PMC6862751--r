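one_class <- function(class) {
  p <- setNames(rep(0, 7), c("deletion", "wt_fwd", "wt_inv", "meth_fwd",
                             "meth_inv", "unmeth_fwd", "unmeth_inv"))
  p[class] <- 1
  p
}

test_that("pure outcome classes produce the expected locus sequences", {
  m <- build_model(seed = 1)
  cfg <- sim_config(class_proportions = one_class("wt_fwd"), indel_prob = 0)
  tr <- simulate_cells(m, cfg, seed = 1, n_cells = 5)
  expect_true(all(tr$seq == m$locus_seq))

  cfg_d <- sim_config(class_proportions = one_class("deletion"),
                      indel_prob = 0)
  trd <- simulate_cells(m, cfg_d, seed = 1, n_cells = 5)
  expect_true(all(nchar(trd$seq) == m$flank_up + m$flank_down))
  expect_true(all(trd$seq == paste0(m$flank_up_seq, m$flank_down_seq)))

  cfg_i <- sim_config(class_proportions = one_class("meth_inv"),
                      indel_prob = 0)
  tri <- simulate_cells(m, cfg_i, seed = 1, n_cells = 3)
  expect_true(all(tri$seq ==
                    invert_between_cuts(m, derive_allele(m, "allele1", TRUE))))
})

test_that("class draws follow the configured proportions", {
  m <- build_model(seed = 1)
  cfg <- sim_config(class_proportions = c(deletion = 0, wt_fwd = 0, wt_inv = 0.7,
                                          meth_fwd = 0.3, meth_inv = 0,
                                          unmeth_fwd = 0, unmeth_inv = 0),
                    indel_prob = 0)
  tr <- simulate_cells(m, cfg, seed = 3, n_cells = 10000)
  k <- sum(tr$class == "meth_fwd")
  expect_lt(abs(k - 3000), 3 * sqrt(10000 * 0.3 * 0.7))
  expect_identical(sort(unique(tr$class)), c("meth_fwd", "wt_inv"))
})

test_that("zero-error emission reproduces templates exactly, deterministically", {
  m <- build_model(seed = 1)
  cfg <- sim_config(error_rates = c(illumina = 0, pacbio = 0, bisulfite = 0),
                    reads_per_cell = 2, indel_prob = 0.5)
  tr <- simulate_cells(m, cfg, seed = 9, n_cells = 30)
  rd <- emit_reads(m, tr, "pacbio", cfg, seed = 10)
  # conservation: class labels carried per read, counts per cell as drawn
  expect_true(all(table(rd$cell_id) == 2))
  expect_identical(rd$class, tr$class[match(rd$cell_id, tr$cell_id)])
  # exact template (possibly reverse-complemented), UMI prepended
  tmpl <- paste0(tr$umi, tr$seq)[match(rd$cell_id, tr$cell_id)]
  expect_true(all(rd$seq == tmpl | rd$seq == revcomp(tmpl)))
  # deletion-class templates are excluded unless kept
  expect_false(any(rd$class == "deletion"))
  rd_keep <- emit_reads(m, tr, "pacbio", cfg, seed = 10, keep_deletions = TRUE)
  expect_identical(sum(rd_keep$class == "deletion"),
                   2L * sum(tr$class == "deletion"))
  # determinism: identical seeds give identical output
  expect_identical(rd, emit_reads(m, tr, "pacbio", cfg, seed = 10))
  # nested short-read branch never emits inversions or deletions
  rdi <- emit_reads(m, tr, "illumina", cfg, seed = 11)
  expect_true(all(rdi$class %in% c("wt_fwd", "meth_fwd", "unmeth_fwd")))
})

test_that("substitution errors occur at the configured per-base rate", {
  m <- build_model(seed = 1)
  cfg <- sim_config(class_proportions = one_class("wt_fwd"), indel_prob = 0,
                    reads_per_cell = 1,
                    error_rates = c(illumina = 0, pacbio = 0.006, bisulfite = 0))
  tr <- simulate_cells(m, cfg, seed = 13, n_cells = 300)
  rd <- emit_reads(m, tr, "pacbio", cfg, seed = 14)
  tmpl <- paste0(tr$umi, tr$seq)[match(rd$cell_id, tr$cell_id)]
  # compare on whichever strand the read was emitted
  nsub <- vapply(seq_len(nrow(rd)), function(i) {
    b <- strsplit(tmpl[i], "")[[1]]
    a1 <- strsplit(rd$seq[i], "")[[1]]
    a2 <- strsplit(revcomp(rd$seq[i]), "")[[1]]
    min(sum(a1 != b), sum(a2 != b))
  }, numeric(1))
  len <- nchar(tmpl[1])
  mu <- len * 0.006
  expect_lt(abs(mean(nsub) - mu), 4 * sqrt(mu / nrow(rd)))
})

test_that("6-TG selection removes expressing cells and mock preserves mixtures", {
  m <- build_model(seed = 1)
  cfg <- sim_config(epsilon = 0, indel_prob = 0,
                    class_proportions = c(deletion = 0, wt_fwd = 0.5,
                                          wt_inv = 0.5, meth_fwd = 0,
                                          meth_inv = 0, unmeth_fwd = 0,
                                          unmeth_inv = 0))
  tr <- simulate_cells(m, cfg, seed = 15, n_cells = 400)
  sel <- apply_selection(tr, cfg, "6tg", m, seed = 16)
  expect_identical(nrow(sel), 400L)
  expect_true(all(sel$class == "wt_inv"))
  # pre is the identity; mock preserves composition in expectation
  expect_identical(apply_selection(tr, cfg, "pre", m), tr)
  mock <- apply_selection(tr, cfg, "mock", m, seed = 17)
  expect_lt(abs(mean(mock$class == "wt_inv") - mean(tr$class == "wt_inv")),
            0.1)

  # all cells expressing and epsilon = 0: empty surviving pool
  cfg_w <- sim_config(epsilon = 0, indel_prob = 0,
                      class_proportions = one_class("wt_fwd"))
  trw <- simulate_cells(m, cfg_w, seed = 18, n_cells = 50)
  expect_error(apply_selection(trw, cfg_w, "6tg", m, seed = 19), "empty")

  # all cells silenced: selection is a no-op on class composition
  cfg_m <- sim_config(epsilon = 0, class_proportions = one_class("meth_fwd"))
  trm <- simulate_cells(m, cfg_m, seed = 20, n_cells = 50)
  selm <- apply_selection(trm, cfg_m, "6tg", m, seed = 21)
  expect_true(all(selm$class == "meth_fwd"))
})

test_that("FASTQ export writes valid 4-line records with truth sidecar", {
  m <- build_model(seed = 1)
  cfg <- sim_config(reads_per_cell = 1)
  tr <- simulate_cells(m, cfg, seed = 22, n_cells = 10)
  rd <- emit_reads(m, tr, "pacbio", cfg, seed = 23)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "reads.fastq")
  write_reads_fastq(rd, fq, file.path(dir, "truth.tsv"))
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_identical(length(back), nrow(rd))
  expect_identical(as.character(back[[1]]), rd$seq[1])
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_identical(nrow(truth), nrow(rd))
  expect_true(all(c("read_id", "class", "left_indel", "umi") %in%
                    names(truth)))
})
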