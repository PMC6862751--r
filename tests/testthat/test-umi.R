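test_that("UMIs are recovered from the alignment frame and gaps drop reads", {
  m <- build_model(seed = 1)
  refs <- pacbio_refs(m)
  umi <- "ACGTACGTACGT"
  q <- paste0(umi, allele_locus(m, "wildtype", "forward"))
  a <- choose_orientation(q, refs$refs, band = 32)
  expect_identical(extract_umi(a, refs$umi_locus), umi)

  # same read on the other strand
  b <- choose_orientation(revcomp(q), refs$refs, band = 32)
  expect_identical(extract_umi(b, refs$umi_locus), umi)

  # a deletion spanning part of the UMI excludes the read
  q2 <- paste0(substr(umi, 1, 6), allele_locus(m, "wildtype", "forward"))
  a2 <- choose_orientation(q2, refs$refs, band = 32)
  expect_true(is.na(extract_umi(a2, refs$umi_locus)))
})

test_that("UMI recovery under long-read noise matches the binomial rate", {
  # a 12-base UMI read at per-base error 0.006 is recovered exactly with
  # probability 0.994^12 ~ 0.93
  m <- build_model(seed = 1)
  cfg <- sim_config(n_cells = 150, reads_per_cell = 1,
                    class_proportions = c(deletion = 0, wt_fwd = 1, wt_inv = 0,
                                          meth_fwd = 0, meth_inv = 0,
                                          unmeth_fwd = 0, unmeth_inv = 0),
                    indel_prob = 0)
  tr <- simulate_cells(m, cfg, seed = 21)
  rd <- emit_reads(m, tr, "pacbio", cfg, seed = 22)
  refs <- pacbio_refs(m)
  got <- vapply(seq_len(nrow(rd)), function(i) {
    a <- choose_orientation(rd$seq[i], refs$refs, band = 48)
    u <- extract_umi(a, refs$umi_locus)
    !is.na(u) && u == rd$umi[i]
  }, logical(1))
  p <- 0.994^12
  sigma <- sqrt(p * (1 - p) / nrow(rd))
  expect_gte(mean(got), p - 4 * sigma)
})

test_that("exact-string UMI clustering groups reads as specified", {
  cl <- cluster_by_umi(c("AA", "AA", "AB"))
  expect_identical(length(cl), 2L)
  expect_setequal(vapply(cl, function(x) length(x$members), integer(1)),
                  c(2L, 1L))
  expect_identical(cluster_by_umi(character(0)), list())
  # NAs (dropped reads) are excluded, conservation holds on the rest
  umis <- c("AAA", NA, "AAA", "CCC", NA)
  cl2 <- cluster_by_umi(umis)
  expect_identical(sum(vapply(cl2, function(x) length(x$members), integer(1))),
                   3L)
})

test_that("majority consensus follows the plurality and tie rules", {
  ref <- "ACGTACGTAC"
  mk <- function(q) global_align(q, ref)
  # identical members reproduce the member
  cons <- umi_consensus(list(mk(ref), mk(ref), mk(ref)))
  expect_identical(cons, ref)
  # A,A,C column -> A
  q2 <- "ACGTCCGTAC"
  expect_identical(umi_consensus(list(mk(ref), mk(ref), mk(q2))), ref)
  # two-way base tie -> N
  cons3 <- umi_consensus(list(mk(ref), mk(q2)))
  expect_identical(substr(cons3, 5, 5), "N")
  # single-member cluster is that read
  expect_identical(umi_consensus(list(mk(q2))), q2)
  # gap wins only as unique plurality: 2 deletions vs 1 base drops the column
  qdel <- "ACGTCGTAC"
  cons4 <- umi_consensus(list(mk(qdel), mk(qdel), mk(ref)))
  expect_identical(cons4, qdel)
  # gap vs base tie -> N, never silently dropped
  cons5 <- umi_consensus(list(mk(qdel), mk(ref)))
  expect_identical(nchar(cons5), 10L)
  expect_identical(substr(cons5, 5, 5), "N")
  expect_error(umi_consensus(list()), "empty")
})

test_that("vectorised column consensus equals a brute-force counter", {
  set.seed(13)
  brute <- function(chars) {
    tab <- table(factor(chars, levels = c("A", "C", "G", "T", "-")))
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1) "N" else if (winners == "-") NA_character_
    else winners
  }
  for (k in 1:200) {
    chars <- sample(c("A", "C", "G", "T", "-"), sample(1:6, 1), replace = TRUE)
    expect_identical(islandswap:::column_consensus(chars), brute(chars),
                     info = paste(chars, collapse = ""))
  }
})

test_that("shared insertions survive the consensus, private ones do not", {
  ref <- "AAACCCGGGTTT"
  qins <- "AAACCCTTAGGGTTT"  # TTA inserted after position 6
  a <- global_align(qins, ref)
  expect_identical(sum(indel_events(a)$size > 0), 1L)
  cons_maj <- umi_consensus(list(global_align(qins, ref),
                                 global_align(qins, ref),
                                 global_align(ref, ref)))
  expect_identical(cons_maj, qins)
  cons_min <- umi_consensus(list(global_align(ref, ref),
                                 global_align(ref, ref),
                                 global_align(qins, ref)))
  expect_identical(cons_min, ref)
})

test_that("consensus suppresses independent read errors", {
  m <- build_model(seed = 4)
  refs <- pacbio_refs(m)
  truth_seq <- paste0("ACGTACGTACGT", allele_locus(m, "wildtype", "forward"))
  set.seed(31)
  err_read <- 0; err_cons <- 0; n_rep <- 8
  for (k in seq_len(n_rep)) {
    alns <- lapply(1:5, function(j)
      choose_orientation(add_noise(truth_seq, 0.006), refs$refs, band = 48))
    cons <- umi_consensus(alns)
    a <- global_align(cons, truth_seq, band = 48)
    err_cons <- err_cons + sum(a$ops$len[a$ops$op != "M"])
    b <- global_align(alns[[1]]$query, truth_seq, band = 48)
    err_read <- err_read + sum(b$ops$len[b$ops$op != "M"])
  }
  expect_lt(err_cons, err_read)
})
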