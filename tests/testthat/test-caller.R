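call_query <- function(model, refs, q, branch = "pacbio", band = 64) {
  a <- choose_orientation(q, refs$refs, band = band, query_id = "q")
  if (branch == "pacbio") call_pacbio(a, model, refs)
  else call_illumina(a, model, refs)
}

test_that("error-free long reads are called by allele and orientation", {
  m <- build_model(seed = 1)
  refs <- pacbio_refs(m)
  cases <- expand.grid(allele = c("wildtype", "allele1", "allele2"),
                       orientation = c("forward", "inverted"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    q <- pacbio_query(m, cases$allele[i], cases$orientation[i])
    cl <- call_query(m, refs, q)
    expect_identical(cl$group, cases$allele[i])
    expect_identical(cl$orientation, cases$orientation[i])
    expect_identical(c(cl$left_indel, cl$right_indel), c(0L, 0L))
  }
  # reverse-complement reads give the same calls
  q <- revcomp(pacbio_query(m, "allele1", "inverted"))
  cl <- call_query(m, refs, q)
  expect_identical(cl$group, "allele1")
  expect_identical(cl$orientation, "inverted")
})

test_that("wholesale deletion reads are called deletion", {
  m <- build_model(seed = 1)
  refs <- pacbio_refs(m)
  q <- paste0(random_dna(12), m$flank_up_seq, m$flank_down_seq)
  cl <- call_query(m, refs, q)
  expect_identical(cl$group, "deletion")
})

test_that("junction deletions into the insert obey the PAM-window rule", {
  # deletions of up to 5 bases into the insert leave the PAM (sixth base)
  # observable and stay assignable; 6..10 remove it and must be unassigned
  m <- build_model(seed = 1)
  refs <- pacbio_refs(m)
  for (s in 0:10) {
    cl_l <- call_query(m, refs, pacbio_query(m, "allele1", left_into = s))
    cl_r <- call_query(m, refs, pacbio_query(m, "allele1", right_into = s))
    if (s <= 5) {
      expect_identical(cl_l$group, "allele1", info = paste("left", s))
      expect_identical(cl_r$group, "allele1", info = paste("right", s))
      expect_identical(cl_l$left_indel, -s, info = paste("left", s))
      expect_identical(cl_r$right_indel, -s, info = paste("right", s))
    } else {
      expect_identical(cl_l$group, "unassigned", info = paste("left", s))
      expect_identical(cl_l$reason, "pam_mismatch", info = paste("left", s))
      expect_identical(cl_r$group, "unassigned", info = paste("right", s))
      expect_identical(cl_r$reason, "pam_mismatch", info = paste("right", s))
    }
  }
})

test_that("every combination of SNV states maps to 3 calls + 13 unassigned", {
  m <- build_model(seed = 1)
  refs <- illumina_refs(m)
  amp <- substr(m$insert_seq, m$illumina_amplicon[1], m$illumina_amplicon[2])
  shift <- m$illumina_amplicon[1] - 1L
  n_assigned <- 0L; n_unassigned <- 0L
  for (mask in 0:15) {
    ch <- strsplit(amp, "", fixed = TRUE)[[1]]
    on <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    ch[m$snvs$offset[on] - shift] <- m$snvs$alt[on]
    q <- paste0(strrep("T", 12), paste(ch, collapse = ""))
    cl <- call_query(m, refs, q, branch = "illumina")
    expected <- if (mask == 0L) "wildtype"
      else if (identical(sort(m$snvs$allele[on]), rep("allele1", 2))) "allele1"
      else if (identical(sort(m$snvs$allele[on]), rep("allele2", 2))) "allele2"
      else "unassigned"
    expect_identical(cl$group, expected, info = mask)
    if (expected == "unassigned") {
      n_unassigned <- n_unassigned + 1L
      expect_identical(cl$reason, "snv_mixed", info = mask)
    } else n_assigned <- n_assigned + 1L
  }
  expect_identical(c(n_assigned, n_unassigned), c(3L, 13L))
})

test_that("short-read window violations are unassigned with a reason", {
  m <- build_model(seed = 1)
  refs <- illumina_refs(m)
  amp <- substr(m$insert_seq, m$illumina_amplicon[1], m$illumina_amplicon[2])
  # one substitution inside the 44-bp window (not at an SNV)
  winpos <- setdiff(seq(m$illumina_window[1], m$illumina_window[2]),
                    m$snvs$offset)[1]
  local <- winpos - m$illumina_amplicon[1] + 1L
  ch <- strsplit(amp, "", fixed = TRUE)[[1]]
  ch[local] <- setdiff(c("A", "C", "G", "T"), ch[local])[1]
  cl <- call_query(m, refs, paste0(strrep("A", 12), paste(ch, collapse = "")),
                   branch = "illumina")
  expect_identical(cl$group, "unassigned")
  expect_identical(cl$reason, "window_mismatch")
  # a mutation outside the window does not block assignment
  ch2 <- strsplit(amp, "", fixed = TRUE)[[1]]
  ch2[1] <- setdiff(c("A", "C", "G", "T"), ch2[1])[1]
  cl2 <- call_query(m, refs, paste0(strrep("A", 12),
                                    paste(ch2, collapse = "")),
                    branch = "illumina")
  expect_identical(cl2$group, "wildtype")
})

test_that("frequency tables follow the three denominator policies", {
  calls <- data.frame(
    id = sprintf("c%02d", 1:20),
    branch = "pacbio",
    group = c(rep("wildtype", 8), rep("allele1", 4), rep("allele2", 2),
              rep("deletion", 3), rep("unassigned", 3)),
    orientation = c(rep("forward", 6), rep("inverted", 2),  # wildtype
                    rep("forward", 3), "inverted",          # allele1
                    rep("inverted", 2),                     # allele2
                    rep(NA, 3), rep("forward", 3)),
    stringsAsFactors = FALSE)

  ts <- tabulate_calls(calls, "strict_matched")
  expect_equal(attr(ts, "denominator"), 9)  # forward-assigned only
  expect_equal(ts$pct[ts$group == "wildtype"], 100 * 6 / 9)
  expect_equal(sum(ts$pct), 100)

  to <- tabulate_calls(calls, "orientation")
  expect_equal(attr(to, "denominator"), 14)  # assigned, both orientations
  expect_equal(to$pct[to$orientation == "forward"], 100 * 9 / 14)
  expect_equal(sum(to$pct), 100)

  ta <- tabulate_calls(calls, "all_aligned_minus_deletions")
  expect_equal(attr(ta, "denominator"), 17)  # everything except deletions
  expect_equal(sum(ta$count), 17)

  # degenerate input
  t0 <- tabulate_calls(calls[0, ], "strict_matched")
  expect_true(attr(t0, "zero_denominator"))
})

test_that("single-class tabulations give 100% to that class", {
  calls <- data.frame(id = as.character(1:10), branch = "pacbio",
                      group = "wildtype", orientation = "forward",
                      stringsAsFactors = FALSE)
  ts <- tabulate_calls(calls, "strict_matched")
  expect_equal(ts$pct[ts$group == "wildtype"], 100)
  mix <- data.frame(id = as.character(1:10), branch = "pacbio",
                    group = c(rep("allele1", 5), rep("wildtype", 5)),
                    orientation = c(rep("forward", 5), rep("inverted", 5)),
                    stringsAsFactors = FALSE)
  to <- tabulate_calls(mix, "orientation")
  expect_equal(to$pct, c(50, 50))
})
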