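# End-to-end orchestration: simulate -> align -> UMI consensus -> call ->
# tabulate -> profile -> stats, over the full experimental design (two
# reciprocal arms x replicates x selection arms x sequencing branches).
# One global seed expands into per-stage streams so any stage can be
# reproduced in isolation; identical configs give identical outputs.

#' Pipeline run configuration
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @param n_cells cells per sample.
#' @param reads_per_cell reads per cell.
#' @param replicates replicates per reciprocal arm.
#' @param arms selection arms to run.
#' @param branches sequencing branches to run.
#' @param band alignment band half-width (covers junction indels up to the
#'   simulator's size cap with slack).
#' @param model_seed seed for [build_model()].
#' @param ... further arguments passed to [sim_config()] (e.g.
#'   `class_proportions`, `epsilon`, `indel_prob`).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_cells = 150L, reads_per_cell = 3L,
                       replicates = 3L,
                       arms = c("pre", "mock", "6tg"),
                       branches = c("illumina", "pacbio", "bisulfite"),
                       band = 64L, model_seed = seed, ...) {
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 reads_per_cell = reads_per_cell,
                 replicates = as.integer(replicates),
                 arms = arms, branches = branches, band = as.integer(band),
                 model_seed = model_seed, sim_args = list(...)),
            class = "run_config")
}

#' @noRd
branch_refs <- function(model, branch, umi_len = 12L) {
  switch(branch,
         pacbio = pacbio_refs(model, umi_len),
         illumina = illumina_refs(model, umi_len),
         bisulfite = build_bisulfite_refs(model, umi_len))
}

#' Process one sample of one branch: align, consensus, call
#'
#' Aligns every read (orientation-resolved), extracts UMIs by alignment
#' coordinates (reads with a gap in the UMI locus are dropped and counted),
#' clusters by exact UMI, builds the majority consensus per cluster on the
#' modal winning reference's frame, realigns each consensus, and calls it.
#'
#' @param reads data.frame from [emit_reads()].
#' @param model an `amplicon_model`.
#' @param branch `"illumina"`, `"pacbio"` or `"bisulfite"`.
#' @param refs branch reference bundle (built from `model` if NULL).
#' @param scoring a [scoring_scheme()].
#' @param band alignment band half-width.
#' @param cache optional memoisation environment (per branch).
#' @return list with `calls` (one row per consensus, with `umi` and cluster
#'   `size` bound), `consensus_alignments`, `read_alignments`,
#'   `n_reads`, `n_umi_dropped`.
#' @export
process_sample <- function(reads, model, branch, refs = NULL,
                           scoring = scoring_scheme(), band = 64L,
                           cache = NULL) {
  refs <- refs %||% branch_refs(model, branch)
  empty <- list(calls = NULL, consensus_alignments = list(),
                read_alignments = list(), n_reads = nrow(reads),
                n_umi_dropped = 0L)
  if (nrow(reads) == 0L) return(empty)

  n <- nrow(reads)
  alns <- vector("list", n); frames <- vector("list", n)
  umis <- character(n)
  for (i in seq_len(n)) {
    a <- choose_orientation(reads$seq[i], refs$refs, scoring, band,
                            reads$read_id[i], cache)
    f <- alignment_ref_frame(a)
    alns[[i]] <- a; frames[[i]] <- f
    umis[i] <- extract_umi(a, refs$umi_locus, f)
  }
  clusters <- cluster_by_umi(umis)
  n_dropped <- sum(is.na(umis))

  calls <- vector("list", length(clusters))
  cons_alns <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    m <- cl$members
    ref_ids <- vapply(m, function(i) alns[[i]]$ref_id, character(1))
    modal <- names(sort(table(ref_ids), decreasing = TRUE))[1]
    mem_alns <- list(); mem_frames <- list()
    modal_ref <- refs$refs[[modal]]
    for (i in m) {
      if (alns[[i]]$ref_id == modal) {
        mem_alns[[length(mem_alns) + 1L]] <- alns[[i]]
        mem_frames[[length(mem_frames) + 1L]] <- frames[[i]]
      } else {
        a1 <- global_align(alns[[i]]$query, modal_ref$seq, scoring, band,
                           alns[[i]]$query_id, modal)
        mem_alns[[length(mem_alns) + 1L]] <- a1
        mem_frames[[length(mem_frames) + 1L]] <- alignment_ref_frame(a1)
      }
    }
    cons_seq <- umi_consensus(mem_alns, mem_frames)
    cons_id <- paste0("cons_", branch, "_", cl$umi)
    ca <- choose_orientation(cons_seq, refs$refs, scoring, band, cons_id, cache)
    cons_alns[[k]] <- ca
    call <- switch(branch,
                   pacbio = call_pacbio(ca, model, refs),
                   illumina = call_illumina(ca, model, refs),
                   bisulfite = call_methylation(ca, refs))
    call$umi <- cl$umi
    call$size <- length(m)
    calls[[k]] <- call
  }
  list(calls = if (length(calls)) do.call(rbind, calls) else NULL,
       consensus_alignments = cons_alns,
       read_alignments = alns,
       n_reads = n, n_umi_dropped = n_dropped)
}

#' Run the full pipeline
#'
#' Simulates both reciprocal arms (allele 1 methylated / allele 2 methylated)
#' across replicates and selection arms, processes every requested branch,
#' tabulates frequency tables under all denominator policies, profiles
#' junction indels, and computes the comparison statistics: log-transformed
#' paired t on the short-read fold changes (6-TG over mock, methylated vs
#' unmethylated allele), arcsine-square-root paired t on long-read 6-TG
#' percentages, orientation summaries, and Fisher tests on junction indel
#' rates (excluding 6-TG samples).
#'
#' @param config a [run_config()].
#' @return an `islandswap_run` list: `model`, `samples` (per
#'   sample x branch: calls, tables, counts), `stats`.
#' @export
run_end_to_end <- function(config = run_config()) {
  model <- build_model(config$model_seed)
  scoring <- scoring_scheme()
  refs <- lapply(setNames(nm = config$branches), branch_refs, model = model)
  caches <- lapply(setNames(nm = config$branches), function(b) new.env())

  samples <- list()
  ctr <- 0L
  for (recip in c("allele1", "allele2")) {
    for (rep_i in seq_len(config$replicates)) {
      cfg <- do.call(sim_config, c(list(
        methylated_allele = recip, n_cells = config$n_cells,
        reads_per_cell = config$reads_per_cell), config$sim_args))
      ctr <- ctr + 1L
      base_truth <- simulate_cells(model, cfg,
                                   seed = stage_seed(config$seed, ctr))
      for (arm in config$arms) {
        ctr <- ctr + 1L
        truth <- apply_selection(base_truth, cfg, arm, model,
                                 seed = stage_seed(config$seed, ctr))
        for (branch in config$branches) {
          ctr <- ctr + 1L
          reads <- emit_reads(model, truth, branch, cfg,
                              seed = stage_seed(config$seed, ctr))
          proc <- process_sample(reads, model, branch, refs[[branch]],
                                 scoring, config$band, caches[[branch]])
          sid <- paste("meth", recip, "rep", rep_i, arm, branch, sep = "_")
          rec <- list(sample_id = sid, methylated_allele = recip,
                      replicate = rep_i, arm = arm, branch = branch,
                      truth = truth, calls = proc$calls,
                      n_reads = proc$n_reads,
                      n_umi_dropped = proc$n_umi_dropped)
          if (branch %in% c("pacbio", "illumina") && !is.null(proc$calls)) {
            rec$table_strict <- tabulate_calls(proc$calls, "strict_matched")
            if (branch == "pacbio") {
              rec$table_orientation <- tabulate_calls(proc$calls, "orientation")
              rec$table_all <- tabulate_calls(proc$calls,
                                              "all_aligned_minus_deletions")
              rec$junction_sizes <- junction_sizes(
                proc$consensus_alignments,
                cuts = c(refs$pacbio$cut_left, refs$pacbio$cut_right))
            }
          }
          samples[[sid]] <- rec
        }
      }
    }
  }

  stats <- compute_run_stats(samples, config)
  structure(list(config = config, model = model, samples = samples,
                 stats = stats),
            class = "islandswap_run")
}

#' @noRd
strict_pct <- function(rec, group) {
  if (is.null(rec$table_strict)) return(NA_real_)
  t <- rec$table_strict
  t$pct[t$group == group]
}

#' @noRd
find_sample <- function(samples, recip, rep_i, arm, branch) {
  sid <- paste("meth", recip, "rep", rep_i, arm, branch, sep = "_")
  samples[[sid]]
}

#' @noRd
compute_run_stats <- function(samples, config) {
  stats <- list()
  recips <- c("allele1", "allele2")
  other <- c(allele1 = "allele2", allele2 = "allele1")

  # short-read fold changes (6-TG over mock), methylated vs unmethylated
  if (all(c("mock", "6tg") %in% config$arms) &&
      "illumina" %in% config$branches) {
    fc_meth <- c(); fc_unmeth <- c()
    for (recip in recips) for (r in seq_len(config$replicates)) {
      s6 <- find_sample(samples, recip, r, "6tg", "illumina")
      sm <- find_sample(samples, recip, r, "mock", "illumina")
      if (is.null(s6) || is.null(sm)) next
      # undefined fold changes (zero mock frequency) drop out of the paired
      # test below; no pseudo-count is applied
      fc_meth <- c(fc_meth,
                   suppressWarnings(fold_change(strict_pct(s6, recip),
                                                strict_pct(sm, recip))))
      fc_unmeth <- c(fc_unmeth,
                     suppressWarnings(fold_change(strict_pct(s6, other[recip]),
                                                  strict_pct(sm, other[recip]))))
    }
    ok <- is.finite(fc_meth) & is.finite(fc_unmeth) &
      fc_meth > 0 & fc_unmeth > 0
    stats$illumina_fold_change <- list(
      fc_methylated = fc_meth, fc_unmethylated = fc_unmeth,
      mean_methylated = mean(fc_meth[ok]),
      mean_unmethylated = mean(fc_unmeth[ok]),
      n_pairs = sum(ok),
      test = if (sum(ok) >= 2)
        paired_t(fc_meth[ok], fc_unmeth[ok], "log") else NULL)
  }

  # long-read 6-TG percentages, methylated vs unmethylated
  if ("6tg" %in% config$arms && "pacbio" %in% config$branches) {
    p_meth <- c(); p_unmeth <- c()
    for (recip in recips) for (r in seq_len(config$replicates)) {
      s6 <- find_sample(samples, recip, r, "6tg", "pacbio")
      if (is.null(s6)) next
      p_meth <- c(p_meth, strict_pct(s6, recip))
      p_unmeth <- c(p_unmeth, strict_pct(s6, other[recip]))
    }
    ok <- is.finite(p_meth) & is.finite(p_unmeth)
    stats$pacbio_6tg <- list(
      pct_methylated = p_meth, pct_unmethylated = p_unmeth,
      mean_methylated = mean(p_meth[ok]),
      mean_unmethylated = mean(p_unmeth[ok]),
      test = if (sum(ok) >= 2)
        paired_t(p_meth[ok] / 100, p_unmeth[ok] / 100, "arcsine_sqrt")
      else NULL)
  }

  # orientation summary per arm (long-read)
  if ("pacbio" %in% config$branches) {
    ori <- list()
    for (arm in config$arms) {
      pct_inv <- c()
      for (recip in recips) for (r in seq_len(config$replicates)) {
        s <- find_sample(samples, recip, r, arm, "pacbio")
        if (is.null(s) || is.null(s$table_orientation)) next
        t <- s$table_orientation
        pct_inv <- c(pct_inv, t$pct[t$orientation == "inverted"])
      }
      ori[[arm]] <- list(pct_inverted = pct_inv,
                         mean_inverted = mean(pct_inv, na.rm = TRUE))
    }
    stats$orientation <- ori
  }

  # junction indel rate contrasts on non-selected long-read calls
  if ("pacbio" %in% config$branches &&
      length(setdiff(config$arms, "6tg")) > 0) {
    calls <- list()
    for (recip in recips) for (r in seq_len(config$replicates))
      for (arm in setdiff(config$arms, "6tg")) {
        s <- find_sample(samples, recip, r, arm, "pacbio")
        if (is.null(s) || is.null(s$calls)) next
        cc <- s$calls
        cc$meth_status <- ifelse(cc$group == recip, "methylated",
                                 ifelse(cc$group == other[recip],
                                        "unmethylated", cc$group))
        calls[[length(calls) + 1L]] <- cc
      }
    if (length(calls)) {
      calls <- do.call(rbind, calls)
      assigned <- calls[calls$group %in% c("wildtype", "allele1", "allele2"), ]
      rate_test <- function(sel_a, sel_b, label_a, label_b) {
        ga <- assigned[sel_a, ]; gb <- assigned[sel_b, ]
        if (!nrow(ga) || !nrow(gb)) return(NULL)
        ra <- indel_rate(ga); rb <- indel_rate(gb)
        tab <- matrix(c(ra$k, ra$n - ra$k, rb$k, rb$n - rb$k), 2,
                      dimnames = list(c("indel", "no_indel"),
                                      c(label_a, label_b)))
        list(rate_a = ra$rate, rate_b = rb$rate, table = tab,
             p = fisher_exact(tab))
      }
      stats$indel_meth_vs_unmeth <- rate_test(
        assigned$meth_status == "methylated",
        assigned$meth_status == "unmethylated",
        "methylated", "unmethylated")
      stats$indel_exo_vs_endo <- rate_test(
        assigned$group %in% c("allele1", "allele2"),
        assigned$group == "wildtype", "exogenous", "endogenous")
      stats$indel_wtfwd_vs_wtinv <- rate_test(
        assigned$group == "wildtype" & assigned$orientation == "forward",
        assigned$group == "wildtype" & assigned$orientation == "inverted",
        "wt_forward", "wt_inverted")
    }
  }

  # methylation histograms summed across arms
  if ("bisulfite" %in% config$branches) {
    mc <- list()
    for (sid in names(samples)) {
      s <- samples[[sid]]
      if (s$branch != "bisulfite" || is.null(s$calls)) next
      cc <- s$calls
      cc$arm <- s$arm
      cc$methylated_allele <- s$methylated_allele
      mc[[length(mc) + 1L]] <- cc
    }
    if (length(mc)) {
      mc <- do.call(rbind, mc)
      mc$meth_status <- ifelse(mc$group == mc$methylated_allele, "methylated",
                               ifelse(mc$group == "wildtype", "wildtype",
                                      ifelse(mc$group == "unassigned",
                                             "unassigned", "unmethylated")))
      stats$methylation <- list(
        calls = mc[, c("id", "group", "meth_status", "arm", "count")],
        histogram = methylation_histogram(mc, by = "meth_status"),
        mean_count = tapply(mc$count, mc$meth_status,
                            function(x) mean(x, na.rm = TRUE)))
    }
  }
  stats
}

#' @export
print.islandswap_run <- function(x, ...) {
  cat("<islandswap_run>", length(x$samples), "sample x branch units\n")
  if (!is.null(x$stats$pacbio_6tg)) {
    s <- x$stats$pacbio_6tg
    cat(sprintf("  long-read 6-TG: methylated %.1f%% vs unmethylated %.1f%%",
                s$mean_methylated, s$mean_unmethylated))
    if (!is.null(s$test)) cat(sprintf(" (arcsine-sqrt paired t, p = %.3g)",
                                      s$test$p.value))
    cat("\n")
  }
  if (!is.null(x$stats$illumina_fold_change)) {
    s <- x$stats$illumina_fold_change
    cat(sprintf("  short-read fold change (6-TG/mock): %.1f vs %.1f",
                s$mean_methylated, s$mean_unmethylated))
    if (!is.null(s$test)) cat(sprintf(" (log paired t, p = %.3g)",
                                      s$test$p.value))
    cat("\n")
  }
  if (!is.null(x$stats$orientation)) {
    for (arm in names(x$stats$orientation))
      cat(sprintf("  %% inverted (%s): %.1f\n", arm,
                  x$stats$orientation[[arm]]$mean_inverted))
  }
  if (!is.null(x$stats$methylation)) {
    mm <- x$stats$methylation$mean_count
    cat("  mean methylated CpGs (of 35):",
        paste(sprintf("%s %.1f", names(mm), mm), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write pipeline outputs as TSV/JSON
#'
#' Writes the combined frequency tables, calls, and the stats report. Output
#' is deterministic for a given configuration; the config (including seed) is
#' written alongside.
#'
#' @param run an `islandswap_run`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  freq <- list(); calls <- list()
  for (sid in names(run$samples)) {
    s <- run$samples[[sid]]
    for (tb in c("table_strict", "table_orientation", "table_all")) {
      if (is.null(s[[tb]])) next
      t <- as.data.frame(s[[tb]])
      t$sample <- sid; t$policy <- attr(s[[tb]], "policy")
      freq[[length(freq) + 1L]] <- t
    }
    if (!is.null(s$calls)) {
      cc <- s$calls; cc$sample <- sid
      calls[[length(calls) + 1L]] <- cc
    }
  }
  if (length(freq))
    write.table(do.call(rbind, freq), file.path(dir, "frequency_tables.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(calls)) {
    cc <- do.call(rbind, lapply(calls, function(d) {
      base <- data.frame(id = d$id, sample = d$sample,
                         group = d$group, stringsAsFactors = FALSE)
      for (col in c("orientation", "left_indel", "right_indel", "reason",
                    "count", "umi", "size"))
        base[[col]] <- if (col %in% names(d)) d[[col]] else NA
      base
    }))
    write.table(cc, file.path(dir, "calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  st <- run$stats
  if (!is.null(st$methylation)) st$methylation$calls <- NULL
  jsonlite::write_json(
    list(config = run$config[c("seed", "n_cells", "reads_per_cell",
                               "replicates", "arms", "branches", "band")],
         stats = st),
    file.path(dir, "stats.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}
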