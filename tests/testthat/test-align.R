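test_that("global alignment matches hand-checked examples", {
  a <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(a$score, 40)  # 8 matches at +5
  expect_identical(nrow(indel_events(a)), 0L)
  expect_identical(cigar(a), "8M")

  b <- global_align("ACGT", "ACGGT")
  expect_equal(b$score, oracle_align_score("ACGT", "ACGGT"))
  ev <- indel_events(b)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$size, -1L)

  # substitutions are preferred over gap pairs on equal-length mismatches
  d <- global_align("AC", "AG")
  expect_identical(cigar(d), "1M1X")

  expect_error(global_align("", "ACGT"))
  expect_error(global_align("ACGU", "ACGT"), "DNA")
})

test_that("the recursive oracle agrees with exhaustive path enumeration", {
  set.seed(42)
  for (k in 1:25) {
    q <- random_dna(sample(1:4, 1))
    r <- random_dna(sample(1:4, 1))
    expect_equal(oracle_align_score(q, r), enum_align_score(q, r),
                 info = paste(q, r))
  }
})

test_that("alignment scores equal the independent oracle on random pairs", {
  set.seed(7)
  for (k in 1:60) {
    q <- random_dna(sample(1:8, 1), alphabet = c("A", "C", "G", "T", "N"))
    r <- random_dna(sample(1:8, 1))
    expect_equal(global_align(q, r)$score, oracle_align_score(q, r),
                 info = paste(q, r))
  }
})

test_that("banded alignment equals the full DP when indels fit the band", {
  set.seed(11)
  for (k in 1:10) {
    r <- random_dna(400)
    # query: reference with a small indel and a few substitutions
    pos <- sample(100:300, 1)
    del <- sample(1:20, 1)
    q <- paste0(substr(r, 1, pos), substr(r, pos + del + 1, 400))
    full <- global_align(q, r, band = 0)
    banded <- global_align(q, r, band = 48)
    expect_equal(banded$score, full$score)
    expect_identical(cigar(banded), cigar(full))
  }
})

test_that("one extra substitution never increases the score", {
  set.seed(5)
  for (k in 1:20) {
    r <- random_dna(60)
    q <- r
    p <- sample(60, 1)
    base <- substr(q, p, p)
    substr(q, p, p) <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    expect_lte(global_align(q, r)$score, global_align(r, r)$score)
  }
})

test_that("orientation selection picks the generating reference and strand", {
  m <- build_model(seed = 2)
  refs <- reference_set(
    ids = c("fwd", "inv"),
    seqs = c(allele_locus(m, "wildtype", "forward"),
             allele_locus(m, "wildtype", "inverted")),
    classes = c("forward", "inverted"))

  a <- choose_orientation(allele_locus(m, "wildtype", "inverted"), refs,
                          band = 32)
  expect_identical(a$ref_id, "inv")
  expect_identical(a$ref_class, "inverted")
  expect_equal(a$score, 5 * nchar(m$locus_seq))  # identity score
  expect_false(a$ambiguous)

  b <- choose_orientation(revcomp(allele_locus(m, "wildtype", "forward")),
                          refs, band = 32)
  expect_identical(b$ref_id, "fwd")
  expect_identical(b$orientation, "revcomp")

  # strand symmetry: the reverse complement selects the same reference class
  # with the orientation flag flipped
  set.seed(3)
  for (k in 1:5) {
    q <- add_noise(allele_locus(m, "wildtype", "inverted"), 0.006)
    f <- choose_orientation(q, refs, band = 32)
    g <- choose_orientation(revcomp(q), refs, band = 32)
    expect_identical(f$ref_class, g$ref_class)
    expect_false(f$orientation == g$orientation)
  }

  # a tie across orientation classes is flagged, not silently broken
  trefs <- reference_set(c("f", "i"), c("ACGTACGT", "ACGTACGT"),
                         c("forward", "inverted"))
  tie <- choose_orientation("ACGTACGT", trefs)
  expect_true(tie$ambiguous)
})

test_that("inverted-class reads are assigned to the inverted reference", {
  m <- build_model(seed = 2)
  refs <- pacbio_refs(m)
  inv_locus <- paste0(strrep("A", 12), allele_locus(m, "wildtype", "inverted"))
  set.seed(9)
  hits <- 0L
  for (k in 1:40) {
    q <- add_noise(inv_locus, 0.006)
    a <- choose_orientation(q, refs$refs, band = 48)
    if (a$ref_class == "inverted") hits <- hits + 1L
  }
  expect_gte(hits, 40L * 0.99)
})

test_that("window extraction distinguishes exact matches from indel overlap", {
  r <- "ACGTACGTACGTACGTACGT"
  a <- global_align(r, r)
  w <- extract_window(a, c(5, 12))
  expect_true(w$exact_match)
  expect_false(w$indel_overlap)
  expect_identical(w$seq, substr(r, 5, 12))

  # deletion inside the window
  q <- paste0(substr(r, 1, 7), substr(r, 9, 20))
  b <- global_align(q, r)
  wb <- extract_window(b, c(5, 12))
  expect_false(wb$exact_match)
  expect_true(wb$indel_overlap)

  # a deletion abutting but not overlapping the window leaves it exact;
  # use distinct flanking content so the gap placement is unambiguous
  r2 <- "AAACCCGGGTTTACGTACGA"
  q2 <- paste0(substr(r2, 1, 9), substr(r2, 13, 20))  # drop TTT at 10..12
  b2 <- global_align(q2, r2)
  ev <- indel_events(b2)
  expect_identical(ev$ref_start, 10L)
  expect_identical(ev$ref_end, 12L)
  w2 <- extract_window(b2, c(13, 20))
  expect_true(w2$exact_match)
  w3 <- extract_window(b2, c(1, 9))
  expect_true(w3$exact_match)

  expect_error(extract_window(a, c(15, 25)), "window")
})
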