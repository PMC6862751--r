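# Independent alignment oracles, written top-down (recursive scoring over
# end-states) rather than as a banded matrix fill, so they share no structure
# with the implementation they check. Same scoring convention: affine gap of
# length L costs open + (L-1)*ext; pairings involving N score 0.

oracle_sub_score <- function(a, b, match, mismatch) {
  if (a == b && a != "N") match
  else if (a == "N" || b == "N") 0
  else mismatch
}

# optimal global affine score by memoised recursion over (i, j, end-state)
oracle_align_score <- function(q, r, scoring = scoring_scheme()) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  rc <- strsplit(r, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(rc)
  memo <- new.env(parent = emptyenv())
  f <- function(i, j, state) {
    if (state == "S") return(if (i == 0 && j == 0) 0 else -Inf)
    key <- paste(i, j, state)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- -Inf
    if (state == "M" && i >= 1 && j >= 1) {
      prev <- max(f(i - 1, j - 1, "S"), f(i - 1, j - 1, "M"),
                  f(i - 1, j - 1, "D"), f(i - 1, j - 1, "I"))
      v <- prev + oracle_sub_score(qc[i], rc[j], scoring$match, scoring$mismatch)
    } else if (state == "D" && j >= 1) {
      v <- max(f(i, j - 1, "S") - scoring$gap_open,
               f(i, j - 1, "M") - scoring$gap_open,
               f(i, j - 1, "D") - scoring$gap_extend,
               f(i, j - 1, "I") - scoring$gap_open)
    } else if (state == "I" && i >= 1) {
      v <- max(f(i - 1, j, "S") - scoring$gap_open,
               f(i - 1, j, "M") - scoring$gap_open,
               f(i - 1, j, "I") - scoring$gap_extend,
               f(i - 1, j, "D") - scoring$gap_open)
    }
    memo[[key]] <- v
    v
  }
  if (n == 0 && m == 0) return(0)
  max(f(n, m, "M"), f(n, m, "D"), f(n, m, "I"))
}

# exhaustive enumeration of every global alignment path (tiny inputs only),
# scoring each path as a flat operation sequence
enum_align_score <- function(q, r, scoring = scoring_scheme()) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  rc <- strsplit(r, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(rc)
  score_path <- function(ops) {
    s <- 0; i <- 0; j <- 0; prev <- ""
    for (op in ops) {
      if (op == "M") {
        i <- i + 1; j <- j + 1
        s <- s + oracle_sub_score(qc[i], rc[j], scoring$match, scoring$mismatch)
      } else if (op == "D") {
        j <- j + 1
        s <- s - if (prev == "D") scoring$gap_extend else scoring$gap_open
      } else {
        i <- i + 1
        s <- s - if (prev == "I") scoring$gap_extend else scoring$gap_open
      }
      prev <- op
    }
    s
  }
  best <- -Inf
  rec <- function(i, j, ops) {
    if (i == n && j == m) {
      best <<- max(best, score_path(ops))
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, c(ops, "M"))
    if (j < m) rec(i, j + 1, c(ops, "D"))
    if (i < n) rec(i + 1, j, c(ops, "I"))
  }
  rec(0, 0, character(0))
  best
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
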