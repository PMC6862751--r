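---
title: "Models and methods behind islandswap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind islandswap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandswap)
```

## The experiment being modelled

`islandswap` simulates and analyses amplicon sequencing of a dual-cut
CRISPR/Cas9 *sequence replacement* experiment in haploid cells. Two guides
excise an 1120-bp CpG island (the promoter-associated region of a selectable
gene); co-transfected PCR copies of the same island — one allele methylated
in vitro, one not — can be captured by non-homologous end joining (NHEJ) at
the double cut. Each cell ends up in one of seven outcome classes: wholesale
deletion of the island, re-ligation of the endogenous (wild-type) island in
forward or inverted orientation, or capture of the methylated or unmethylated
exogenous allele in either orientation. Exogenous alleles are distinguishable
from the wild type by four synonymous SNVs in the exon 1 coding sequence
(insert offsets 532, 535, 538, 541: C→T and T→A for allele 1, C→G and C→T for
allele 2) and by two PAM-destroying mutations at the sixth base from each end
of the insert (offsets 6 and 1115), which prevent re-cutting of inserted
copies. Cells that silence the gene — by methylation of the inserted island,
by deletion, by inversion, or by a regulatory-region-disrupting junction
indel — survive 6-thioguanine (6-TG) selection; expressing cells die.

Three sequencing branches read the outcome out:

* a nested short-read amplicon over a 44-bp exon 1 window containing the
  SNVs (blind to the cut sites; cannot amplify inversions or deletions),
* a long-read amplicon spanning the whole locus with ~700/165-bp flanks,
  UMI-tagged, which resolves orientation, junction indels and deletions,
* a bisulfite amplicon over a 283-bp window containing the SNVs and 35 CpG
  dinucleotides, which reads per-molecule methylation.

## The surrogate locus

The real genomic sequence is not bundled. `build_model()` generates a seeded
surrogate with the same coordinate skeleton: a 1120-bp insert at 60% GC
(CpG-island-like), flanks at 45% GC, the SNV/PAM reference bases forced at
their printed offsets, and the bisulfite window repaired until it contains
exactly 35 CpGs. Every quantity the callers test — window widths, SNV/PAM
offsets, CpG count, cut positions — is therefore identical to the real
design, while the package needs no external data. Three generator
constraints deserve a note:

* **No CpG overlaps an SNV.** Otherwise a methylation state could mimic or
  mask a genotype after bisulfite conversion.
* **Junction-abutting flank bases are A/T.** Both PAM bases are C/G, so no
  equal-scoring placement of a junction deletion can slide the gap onto or
  off a PAM base. On the real locus this kind of coincidental homology is
  absent; the constraint keeps the surrogate equally unambiguous.
* **Cut sites are blunt** at the insert boundaries (3 bp 5′ of each PAM).
  Whether the guides are treated as blunt or staggered is not derivable from
  the design; blunt is assumed throughout and only affects how junction
  indel sizes are bookkept, not who survives selection.

Coordinates are 0-based half-open internally and 1-based inclusive at every
user-facing surface; `to_genomic()`/`from_genomic()` convert between
insert-relative offsets and genomic coordinates of the anchored region.

## The simulator

`simulate_cells()` draws one outcome class per cell from a configurable
simplex. The defaults are the package's standing description of the study
conditions: deletion 30%, wild-type forward 42%, wild-type inverted 25%,
methylated insert 0.7% and unmethylated insert 2.3% (each split evenly
between orientations). These reproduce the qualitative regime reported for
this design — insertion is rare, the methylated allele inserts less often
than the unmethylated one, and roughly 60% of oriented outcomes are forward
before selection.

Junction indels occur independently at each junction with probability 0.5
(matching the observed ~50% junction indel rates), are deletions 80% of the
time, and have geometric sizes with mean 3 capped at 50. The size law is a
modelling choice, not a claim: it populates both the ≤5-bp regime that stays
assignable and the >5-bp regime that destroys a PAM match. Deletions chew
symmetrically across the junction (ceiling half into the insert, floor half
into the flank); insertions add random bases.

Methylation maintenance (default 0.95 per CpG) is applied when the *cell's*
truth vector is drawn, so a methylated cell's 35-site state is
Binomial(35, maintenance); bisulfite conversion failure (default 0.005 per
C) is read-level noise. Sequencing is modelled as already merged/consensus
reads with per-base substitution errors only — 0.006 for the long-read
branch (99.4% consensus accuracy) and 0.001 for the short-read branches.
UMIs are 12 random bases per cell; substitution errors hit the UMI like any
other base, so exact UMI recovery runs at 0.994^12 ≈ 93% for long reads and
error-bearing UMIs found singleton clusters.

6-TG selection resamples cells with survival weights: deletion, all inverted
classes and the methylated forward insert survive (weight 1); expressing
forward classes get ε = 0.001 (selection is nearly complete), unless a
junction deletion reaches the functional window (the promoter/exon 1/splice
donor region, offsets 306–555), which restores weight 1. Under the default
size cap junction deletions never reach that window, so the rescue path is
dormant by default; it exists because analytically excluded large indels are
the accepted explanation for unmethylated inserts surviving selection, and
it activates when the cap or window is reconfigured. The simulator does not
model PCR chimeras, family-size distributions beyond reads-per-cell, gel
size bias beyond excluding deletion templates from the long-read branch, or
multi-insert concatemers — so passing tests demonstrate correctness of the
analysis under these idealised conditions, not robustness to artefacts real
libraries may contain.

## Alignment

All classification is alignment-based. The aligner (`global_align()`) is a
global affine-gap Needleman–Wunsch/Gotoh DP written in C++ with EMBOSS-like
defaults (match +5, mismatch −4, gap open 10, gap extend 0.5; a gap of
length L costs open + (L−1)·ext) and deterministic tie-breaking:
substitution preferred over gap, deletion before insertion. Any pairing
involving N scores 0 — neutral — and is classified as a mismatch operation,
so an N can never satisfy a perfect-match window; the neutral score lets the
N-padded UMI slot at the 5′ end of every reference absorb the UMI without
distorting placement. A diagonal band (default half-width 64, always
containing the net length difference) makes full-locus alignments cheap; the
band exceeds the worst-case path deviation under the simulator's indel cap,
and tests verify banded results equal the full DP.

`choose_orientation()` aligns the read and its reverse complement against
every reference and keeps the single best combination; a score tie across
orientation classes is flagged ambiguous rather than silently broken. The
pipeline orients long reads against the wild-type forward and inverted
references only: the allele-defining substitutions cannot move coordinates
or flip the winner. When the wild-type frame leaves a consensus unassigned,
`call_pacbio()` realigns it against the per-allele references in the winning
orientation and calls on the highest-scoring frame — equivalent to having
aligned against the full reference set, at a fraction of the cost.

## UMI consensus

Reads are clustered by exact UMI string (no edit-distance merging: with a
4^12 UMI space collisions are negligible, and exact grouping is the minimal
reproducible reading of "clustered by UMI"; the cost is that an error-bearing
UMI spawns a singleton cluster). The consensus is a per-column simple
majority over the winning reference's frame, with insertion columns keyed by
anchor position so insertions shared by the cluster survive. A gap wins a
column only as unique plurality; any tie yields N, which conservatively
fails every perfect-match window downstream. The consensus is then realigned
before calling. No minimum family size is imposed.

## Calling rules

* **Long reads** (`call_pacbio()`): wholesale deletion is called when the
  alignment deletes at least insert−50 bases overlapping the insert
  (replacing the gel-band criterion with an alignment criterion); otherwise
  the 250-bp promoter/exon/splice-donor window must match exactly, the four
  SNVs must equal exactly one allele pattern, and both PAM bases must match
  that allele. Junction indels within ±5 bp of either cut are recorded
  signed (deletion negative). A junction deletion reaching ≥6 bp into the
  insert removes a PAM base and is unassigned (`pam_mismatch`) — this is the
  analytic size cutoff, verified exhaustively for depths 0–10. Mixed SNV
  patterns (chimera-like) are unassigned, never partially called. Orientation
  ties are counted separately as `ambiguous_orientation`.
* **Short reads** (`call_illumina()`): exact match over the 44-bp window and
  an exact single-allele SNV pattern; always forward (the nested design is
  structurally blind to inversions, deletions, and junction indels).
* **Bisulfite** (`call_methylation()`): reads are aligned against nine
  references (three alleles × converted / converted-all-methylated /
  unconverted); the best variant fixes the frame and assignment uses
  conversion-aware allowed-base patterns: conversion-invariant positions
  must match exactly, non-CpG C positions accept C or T (incomplete
  conversion), CpG positions accept C (methylated) or T (unmethylated).
  After top-strand conversion a C→T SNV is indistinguishable from a
  converted C, so offsets 532 and 538 do not discriminate; every allele pair
  still differs at a conversion-immune SNV (535 C→G, 541 T→A), so
  assignment stays unambiguous — this is the package's resolution of a
  genuine ambiguity in the assay design, and it is why the generator keeps
  SNVs out of CpGs. Methylation is read per site (C = methylated,
  T = unmethylated, gap = uncallable, excluded from the count).

## Tabulation and statistics

`tabulate_calls()` implements the three denominator conventions: the strict
per-allele convention (assigned forward-oriented groups, wild type included
in the denominator), the orientation summary (forward vs inverted among
assigned calls, deletions excluded), and the insertion-rate convention (all
aligned non-deletion consensi, including unassigned, as denominator).

The comparison statistics are the field's standard tests behind a thin
surface: fold changes are plain ratios (no automatic pseudo-count; zero
denominators are reported undefined, with an opt-in pseudo-count), the
paired t-test is applied to natural-log fold changes or arcsine-square-root
proportions, Fisher's exact test compares junction indel rates, and
Clopper–Pearson intervals back the recovery tests. Pairing is within
replicate × reciprocal-arm (up to n = 6 pairs) — the experiment's paired
structure; tests verify Fisher against a from-scratch hypergeometric
enumeration and the t-test's type-I calibration at n = 6.

## Numerical and design choices

* Gap-cost convention `open + (L−1)·ext` (the named aligner's parameters are
  not published; the scheme is explicit in `scoring_scheme()`).
* Leftmost-style deterministic trace-back; CIGARs use M/X/I/D.
* An insertion "covers" only its left-flanking reference position in the
  positional indel profile (it has no reference span).
* Size distributions count events; indel *rates* count reads (once each,
  however many events). Whether per-event or per-read counting was intended
  for the spectra is ambiguous in the source design; per-event is used and
  flagged here.
* Indels abutting but not overlapping a perfect-match window do not violate
  it.
* The mock arm resamples uniformly with replacement (composition unchanged
  in expectation); 6-TG resampling uses the survival weights above. Every
  stage derives its own RNG stream from the global seed, so identical
  configurations give byte-identical outputs.

## Problem sizes used in the test-suite

The simulation scales in the shipped tests are the package's own choices:
2000 cells per sample (6 samples) for the zero-error completeness check, 250
cells × 3 reads across 6 replicates for mixture recovery, 200–500 cells for
selection and bisulfite checks, and 1000 replicates for t-test calibration.
They are large enough that every binomial acceptance band is meaningful, and
small enough that the whole suite runs on a laptop in minutes.

## Known limitations

* The error model is substitution-only; indel sequencing errors (the
  dominant raw long-read mode, largely removed by circular consensus) are
  not simulated, so consensus behaviour under indel noise is untested.
* Bisulfite modelling is top-strand only; no non-CpG methylation, no
  per-strand reconciliation.
* Exact UMI clustering does not merge near-identical UMIs; with high error
  rates this inflates singleton clusters rather than miscalling them.
* The deletion-class exclusion reproduces the gel extraction qualitatively;
  no quantitative size-bias model is attempted, so absolute insertion rates
  under the permissive denominator inherit that caveat.
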