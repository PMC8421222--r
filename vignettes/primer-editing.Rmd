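---
title: "Measuring primer editing with synthetic sequencing standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring primer editing with synthetic sequencing standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primeredit)
```

## The measurement problem

Proofreading DNA polymerases carry a 3′→5′ exonuclease that can excise a
primer's mismatched 3′ end during PCR and resynthesize it against the
template.  The amplicon then carries the *template* base at the mismatch
position — "primer editing".  For amplicon microbiome profiling this is
double-edged: it rescues taxa whose rRNA genes mismatch the universal
primers, but it also means the primer-derived bases of a read can report
template variation.  Measuring the activity per primer position requires
templates with *known* single mismatches at known positions and a way to
measure their pool proportions without amplification bias.  That is what a
synthetic standards pool provides: every single-base substitution in the
3′-terminal window of the forward primer binding site, one construct each,
each carrying a unique quantification barcode read out PCR-free.

`primeredit` implements the full in-silico counterpart: standards design,
a generative simulator of the experiments, barcode quantification, and the
per-position edit and penalty analyses.

## Standards design

`enumerate_variants(site, window)` lists the wild type plus the three
alternative bases at each of the last `window` positions, `3·window + 1`
entries in total — 31 for the 19-base V4_515F locus portion
(`GTGCCAGCAGCCGCGGTAA`) with `window = 10`.  Positions are counted
**1-based from the 3′ end** throughout the package (position 1 = terminal
base); this is the natural axis because both editing and the amplification
penalty decay with distance from the 3′ terminus.

Degenerate bases are rejected inside the mutagenized window (a degenerate
position has no single reference base to mutate) but tolerated elsewhere;
standards should be built on non-degenerate, organism-specific primers.

Each construct is the template region with the substitution applied,
flanked by 20 bases of shared random flank, plus a 20-base barcode drawn by
`generate_barcodes()` under a pairwise Hamming distance floor of 5.  The
floor is chosen to make barcode assignment provably unambiguous at the
2-mismatch read tolerance: two reads at distance ≤ 2 from different
barcodes would force the barcodes within distance 4.  The barcode is
modeled as a bare 20-base sequence (the mapped read prefix); the promoter/
terminator architecture of a physical quantification cassette, restriction
sites and vector backbone have no computational role here and are omitted.
`synthetic_template()` provides a 332-base V4-like template — primer sites
joined by a seeded random core, GC 0.54 — and is labelled synthetic: it is
a stand-in with the right length and composition, not a 16S sequence.

## The generative model

No kinetic model of exonucleolytic excision is attempted; the simulator
uses the simplest aggregate process that reproduces both observed limits
(complete editing ⇒ observed/expected ≈ 1; zero editing ⇒ fold-of-expected
= penalty).  For a class (template construct, or primer variant in the
reciprocal run) mismatched at 3′-distance $p$:

$$y_p = e_p + (1 - e_p)\,a_p, \qquad y = 1 \text{ for matched classes,}$$

with $e_p \in [0,1]$ the editing efficiency and $a_p \in [0,1]$ the
relative amplification efficiency of the unedited mismatch.  Reads are
drawn with probability $\propto \text{abundance} \times y_p$, and
conditional on the class a read shows the edited outcome with probability
$e_p / y_p$.  In the standards run "edited" means the read carries the
template (variant) base; in the variant-primer run it means the primer was
excised back to the wild-type template base.  Editing is all-or-none at the
single mismatch position per read — the standards carry single mismatches
only, so stepwise partial excision is unobservable and not modeled.

The marginal edited-base frequency at position $p$ is therefore

$$f_p = \frac{\sum_{c:\,\text{var at } p} \text{ab}_c\, e_p}
             {\sum_c \text{ab}_c\, y_c},$$

the closed form the test suite uses as an independent oracle against the
simulated streams.

Other modelling choices:

* **Phosphorothioate protection** is the `block_after` field of
  `editing_profile()`: only the `block_after` 3′-terminal positions remain
  editable, all others get effective $e = 0$.  A bond between the 4th- and
  3rd-to-last bases maps to `block_after = 3`.  Which exact backbone bond
  stops the exonuclease is a biochemical question the aggregate model
  sidesteps: the block is modeled as a hard positional cutoff, which is
  what the protected-primer profiles show.
* **Annealing temperature** is accepted in `sim_config()` and deliberately
  ignored — editing and mismatch permissiveness are insensitive to it over
  the usual 50–60 °C range — so configs can record it as provenance
  without it touching the stream.
* **Sequencing error** is a uniform per-base substitution at a single
  configured rate with one constant quality symbol; no indel or
  position-dependent error model.  The ≤ 3-mismatch analyzer filter exists
  to absorb indel noise in real data; under the default simulator it is
  exercised by substitution pile-ups only.
* **Read geometry**: pairs fully overlap the amplicon end-to-end by
  default (`read_length = NULL`), so the merger is always exercised; a
  longer `read_length` runs past the amplicon into the reverse-complement
  of the opposite adapter tail, exercising the trimmer.
* Identical seed + configuration gives byte-identical FASTQ; ground truth
  (source class, edited flag, injected error positions) is emitted per
  read.

## Analysis choices

**Barcode assignment** maps each read's first 20 bases against the
reference by Hamming distance (no indels — the prefix is fixed-length), at
most 2 mismatches, N counting as a mismatch.  Two references tying at the
minimal admissible distance yield `ambiguous`, which is excluded from the
abundance denominator along with `unassigned`; with the distance-5 design
the ambiguous class is empty by construction, so the policy only matters
for user-supplied references (the package warns when their minimum
distance is < 5).  Proportions are over assigned reads only.

**Trimming and merging** re-implement the standard 3′-adapter and
overlap-consensus steps: adapter suffix match with ≥ 3-base overlap and
≤ 10 % mismatches (longest admissible trim wins); merge candidates need
≥ 20 bases of ungapped overlap with ≤ 10 % mismatches, the minimal
mismatch fraction wins with ties to the longest overlap, and conflicting
overlap bases take the higher-quality call.  Unmerged pairs are tallied
and excluded downstream.

**Edit profiling** compares the first `L` bases of each merged read
(L = 19 for the printed forward primer, 20 for the reverse) to the
reference, drops reads with more than 3 mismatches (tallied as filtered)
or shorter than `L` (tallied as short), and counts each base at each
position over the passing reads.  IUPAC-degenerate reference positions
match any compatible base, are never counted as mismatches, and report
`NA` non-reference proportion — a degenerate position defines no single
reference base.  The observed/expected table reports positions where the
pool expects zero variants as `NA` ("undefined"), never 0: an undefined
ratio and an absence of editing are different statements.  A
sequencing-error floor (mean non-reference proportion outside the window,
`error_floor()`) is reported alongside and never subtracted from the
metric.

**Penalty analysis** classifies each read's primer region as wild type
(0 mismatches), one of the `3·window` pool variants (exactly 1 mismatch,
inside the window), or `other`.  The default normalization anchors on the
wild-type class, `(n_v / n_{WT}) / (p_v / p_{WT})`: under the generative
model this recovers $a_p$ exactly, independent of the pool-mean yield,
whereas the whole-pool normalization `obs/exp` compresses folds toward 1
when many classes are penalized.  Both are provided
(`anchor = "whole_pool"`), since either is a defensible reading of
"fold of expected"; wild-type anchoring is the default for its
parameter-recovery property.

## Problem sizes and tolerances

Stochastic checks run at the sizes a bench experiment of this design would
produce and are asserted within 3 binomial standard errors: 50,000 reads
for edit-profile recovery (per-position expectation 3/31 ⇒ SE ≈ 0.13
percentage points), 100,000 for the penalty recovery (terminal fold 0.189
⇒ 3 SE ≈ 0.015), 31,000 barcode reads for pool quantification (≈ 1,000
per construct).  The pipeline demo and unit fixtures use smaller streams
(1,500–30,000 reads) where only qualitative behavior is asserted.

## What passing tests do and do not show

The simulator emulates: pool composition effects, per-position editing and
penalty, exonuclease blocks, uniform sequencing error, adapter
read-through, and fully-overlapping paired reads.  It does not emulate:
PCR cycle dynamics and stochastic early-cycle jackpots, chimeras, primer
dimers, polymerase-specific substitution spectra, indels, quality-score
decay along reads, or multi-mismatch templates.  Green tests therefore
show the *analyzers* are correct for the stated model and that the model's
closed forms are self-consistent — they do not certify polymerase-specific
editing profiles of real enzymes, which must come from sequencing the
physical standards pool.

## Known limitations

* Editing is all-or-none per read at a single known position;
  multi-mismatch interactions are out of scope.
* The Hamming-only primer comparison mis-scores true indels near the
  primer 3′ end as multiple substitutions; such reads are filtered, not
  realigned.
* The penalty analyzer requires a non-empty wild-type class under the
  default anchoring and degrades to `NA` folds with a warning otherwise.
* Barcode quantification assumes fixed-length, position-locked barcodes at
  the read start; it is not a general demultiplexer.
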