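---
title: "Authenticating ancient DNA reads: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating ancient DNA reads: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomapr)
```

## The problem

Shotgun sequencing of ancient specimens yields a mixture of short,
damaged endogenous fragments and abundant exogenous DNA (environmental
microbes, modern human contamination). Authenticating the endogenous
fraction runs into three platform- and chemistry-specific obstacles:

* **Post-mortem damage.** Cytosine deamination at single-stranded 5'
  overhangs is read as C→T substitutions at the 5' ends of
  library-prepared (Illumina) reads, mirrored by G→A at 3' ends; on
  template-strand single-molecule chemistry (Helicos tSMS) the same
  lesions surface as G→A at 5' ends. These mismatches cluster in the
  first few sequenced positions and can push genuine reads past an
  aligner's edit-distance cap — precisely the reads that prove
  authenticity.
* **Platform error profiles.** tSMS errors are indel-dominated (no base
  qualities are produced); Illumina errors are substitution-dominated
  with per-base qualities.
* **Contamination.** Reads of (e.g.) human origin can align to a
  mammalian target genome, and conversely genuine target reads map to
  the human genome in conserved regions, so contaminant filtering
  trades false positives against lost endogenous sequence.

`paleomapr` implements the computational side of a mapping-based
authentication workflow: an explicit model of the aligner's
read-length-dependent edit-distance tolerance, high-quality-hit
classification, two contamination-filtering criteria, terminal
misincorporation profiling, damage-aware 5' trimming bookkeeping, a
damage-robust divergence estimator, and a read simulator with truth
alignments that makes the whole chain testable without an external
aligner.

## The edit-distance model

Seed-and-extend aligners in `aln` mode cap the edit distance of a
reported alignment as a function of read length: modelling the number
of errors in a read of length $L$ as Poisson with mean $L\varepsilon$
(per-base error $\varepsilon = 0.02$), the cap is the smallest
$k \ge 1$ with

$$P(X > k) < n,$$

where $n$ is the tolerated fraction of missed alignments (the `-n`
option, default 0.04). `max_edit_distance()` implements exactly this
construction (via `ppois()`), and `threshold_table()` reports the read
lengths at which the cap steps up:

```{r}
threshold_table(0.02, 0.04, 17, 105)
```

For the read-length ranges relevant to ancient samples the steps fall
at 38/64 nt (`-n 0.04`), 34/58 nt (`-n 0.03`) and 29/51 nt
(`-n 0.02`). Aligner logs phrase these same breakpoints as "k
mismatches for reads shorter than …", attaching the count to the other
side of the boundary; the breakpoints themselves are identical, and we
implement the verifiable tail construction rather than the prose.

`recommend_parameters()` returns the platform-specific parameter
vectors this package recommends for `bwa aln`: Illumina — defaults with
the seed disabled (`-l 1024`), because two seed mismatches silently
discard 5'-damaged reads; Helicos — additionally `-i 0` (indels
tolerated at read termini), `-o 2` (two gap opens, matching
indel-dominated errors at 1–2 expected indels per read) and `-n 0.03`.
Mismatch/gap-open/gap-extension penalties stay at 3/11/4; lowering the
gap-open penalty is counter-productive and the extension penalty is
nearly inert.

## High-quality hits and contamination filtering

A hit is *high-quality endogenous* when it is uniquely placed (XT-style
tag), has no suboptimal alternative hits (X1 = 0), mapping quality
≥ 25, and (for merged Illumina data) is not a flagged PCR duplicate.
Two contaminant criteria are provided:

* `strict_filter()` discards any candidate whose read also hits the
  contaminant genome — in the conservative `any_hit` mode even repeat
  placements with paralogs count.
* `besthit_filter()` keeps a candidate only when its edit distance to
  the target genome is *strictly* smaller than to the contaminant; ties
  are filtered. This recovers conserved-region endogenous reads that
  the strict criterion throws away, at a small contamination risk.

Duplicate flags are honoured on the target side only; contaminant-side
duplicate marking is not assumed trustworthy. Whether the
contaminant-side "hit" should itself be held to the high-quality bar is
genuinely ambiguous for quality-free platforms, so both modes are
exposed (`contaminant_mode`). `spurious_rate()` monitors chance
alignments via a distant outgroup genome, with a read-length histogram,
since spurious hits concentrate at the shortest lengths.

## Misincorporation profiling

`reconstruct_columns()` rebuilds read-versus-reference columns from
CIGAR + MD alone (no reference FASTA needed). Conventions, chosen once
and used everywhere:

* All per-position statistics are computed in **read orientation**
  (position 1 = sequenced 5' base); reverse-strand alignments are
  complemented and re-indexed.
* **Soft clips** are excluded from substitution denominators and
  tracked as their own rate class.
* Columns with **N** in read or reconstructed reference are excluded
  from numerators and denominators alike.
* **Insertions** are assigned the read position of their first inserted
  base; **deletions** are anchored to the read position following the
  deleted reference bases. The damage statistics themselves do not
  depend on this choice, but deterministic tests do, so it is fixed.
* **NM** is counted as mismatches + inserted + deleted bases (clipped
  bases excluded). Aligners differ here; this is the convention the
  whole package, including the simulator, uses consistently.

`accumulate_profile()` tabulates the 12 ordered substitution classes
per position from each end (default window 15 nt), dividing mismatch
counts by the per-position reference-base counts, and indel/clip counts
by read depth. The 3' block is indexed 1..window counting inward from
the 3' terminus, as in the familiar dual-panel damage plots
(`autoplot()` draws them). `cumulative_terminal_damage()` reports the
fraction of all mismatches that are GC→AT within the five terminal
positions; whether to pool both termini or only the 5' end is an
option (`ends`), defaulting to both. `damage_length_correlation()`
captures a subtle selection effect: short damaged reads fail to map
more often than short undamaged ones, so among mapped reads the
terminal damage rate rises with read length.

## Damage-aware trimming

Reads that failed high-quality classification are trimmed of one or two
5' bases (`trim_candidates()`; never more — positions 1–2 hold most
deaminations) provided they are at least 30 nt *before* trimming, since
shortening reads inflates spurious alignments. After realignment,
`classify_trimmed()` reconstructs the mismatch each trimmed base would
have caused by extending the new alignment upstream: on the forward
strand to the reference positions immediately before the hit, on the
reverse strand to the positions immediately past the reference end,
complemented and reversed so trimmed-base order matches sequencing
order. The would-have-been mismatch is evaluated against the genome of
the accepted hit only. `gain_report()` bins newly recovered reads by
that class; for two-base trims the default requires both bases to share
the class ("two consecutive mismatches"), with an `any` mode as the
alternative. `conservative_posttrim_filter()` drops a candidate if
either its trimmed or untrimmed version maps to the contaminant.

## Divergence estimation

Raw mismatch rates against a modern reference conflate true divergence
with sequencing error and deamination. The estimator counts, over
aligned sites passing a base-quality threshold,

$$\hat d = \frac{\text{transversions} + \text{indel bases} +
  2\,(\mathrm{AT{\to}GC})}{\text{sites}},$$

doubling the AT→GC transitions because true-divergence transitions are
symmetric between the two transition classes while GC→AT is
damage-inflated. Numerical choices: indels are counted per base rather
than per event so they share the per-site denominator (switchable);
deletion columns carry no base quality and are exempt from the
threshold while insertion bases must pass it; the site denominator
counts aligned (M) columns passing the threshold, mismatches included;
`divergence_curve()` thresholds cumulatively (BQ ≥ t) by default, with
a per-bin mode available. End masking (0/5/10 nt) excludes terminal
columns, which makes the estimate robust to 5' damage — the property
the tests verify directly. Quality-free (Helicos) input is rejected
rather than silently estimated. `mapping_count_test()` is the Pearson
chi-square (1 df, no continuity correction) used to compare read
recovery across references or parameter sets.

## The simulator

`simulate_reads()` emits reads from a reference whose forward and
reverse-complement strands are concatenated per chromosome; reads
crossing the junction or containing N are discarded and resampled, and
sampled coordinates are mapped back to forward-strand positions plus a
strand flag. Start sites are drawn uniformly or biased by an 11-position
PWM over the −5..+5 context, scored as a frequency product (log-odds is
not the default because a background model is an extra assumption;
rejection sampling against the maximum attainable score bounds memory
instead of materialising a genome-wide score table).

Per emitted base the event model is: insertion with probability
$p_{ins}$ (default 0.015); otherwise the next reference base is taken
after discarding each successive reference base with probability
$p_{del}$ (default 0.03, geometric), and the taken base is substituted
with probability $p_{sub}$ (defaults explored over 0–0.015; 0.005 is
the package default as a mid-range single value). The geometric
deletion draw is deliberate: it makes the realized ratio of deleted to
traversed reference bases equal $p_{del}$ exactly, so configured and
realized rates agree to binomial noise — a single deletion draw per
emitted base would bias the realized rate to $p_{del}/(1+p_{del})$.

The ancient-damage overlay is an extension beyond the error-only
simulator (off by default): a template cytosine at 5' position $i$ is
read as thymine with probability $p_0\,\lambda^{i-1}$ up to a maximum
overhang. A damaged base later hit by a substitution error that
restores the genomic base is recorded as no event, keeping the truth
event list equal to the net read-versus-reference differences.
Illumina-profile reads receive a two-level base-quality model (high/low
quality with an extra substitution rate at low-quality bases) —
deliberately simple, as quality simulation is not the point of the
toolkit. `polyT_trim = TRUE` emulates the instrument-side removal of
leading thymine runs on tSMS reads; such reads are flagged in the truth
table because their coordinates are no longer truth-exact.

`truth_hits()`/`write_truth_sam()` turn the truth tables into SAM
records with CIGAR, MD and NM computed exactly from the event list.
Re-referencing against a coordinate-homologous diverged genome
(`make_diverged_reference()`) produces contaminant-genome alignments,
and `simulate_mappability()` converts exhaustive truth alignments into
realistic aligner output by unmapping reads whose edit distance exceeds
the model cap. Every stochastic step draws from one seeded stream, so
results are fully reproducible.

## Fixture calibration for statistical checks

Two of the validation checks compare stochastic estimates against
binomial confidence intervals, and their fixtures are constructed so
the interval is actually calibrated:

* The divergence-recovery fixture carries its 1% divergence entirely by
  balanced transversions: under the estimator's AT→GC doubling, mixed
  transition/transversion divergence gives every AT→GC site weight 2,
  inflating the estimator's true sampling variance 1.5-fold over
  binomial (the check would then reject ~11% of seeds while testing
  nothing). Diverged sites are also spaced farther apart than the
  longest read, so no read covers two sites and per-site coverages are
  independent — removing the cluster-sampling design effect of reads.
  The mixed-class pathway is still exercised by the module tests.
* Rate-recovery checks compare realized event fractions against their
  exact per-trial probabilities (3 SD), which the geometric deletion
  scheme makes well-defined.

## Problem sizes and defaults

The validation suite runs at desk scale, chosen as the smallest sizes
at which the statistical checks are well-powered: 100 kb synthetic
genomes; 100,000 reads for indel-rate calibration; 20,000 reads for
truth-SAM oracle closure and damage-curve recovery; 5,000 reads for
divergence recovery; 1,500–2,000 reads for filter-semantics fixtures.
Read lengths default to 25–57 nt (the single-molecule ancient-read
range); deamination fixtures use $p_0 = 0.3$, $\lambda = 0.5$,
overhang 5 — terminal damage rates of the magnitude real Pleistocene
samples show. QC defaults (minimum length 25, start quality 10,
end-trim quality 2, empty adapter list) follow the preprocessing the
workflow assumes upstream; the original pipeline's exact PHRED cut-offs
are not published, so they are exposed as configuration rather than
hard-coded.

## What passing tests do and do not show

The simulator emulates controlled divergence, platform error profiles,
terminal deamination, start-site context bias and truth alignments. It
does not emulate: real genomic repeat structure and mappability (all
synthetic genomes are i.i.d. sequence), library-preparation base
composition bias, PCR duplicate structure, quality-score
miscalibration, or indel *clustering*. Consequently, green tests
demonstrate that the statistics and filters compute what they claim on
data satisfying their assumptions — not that any particular real
sample will show a given recovery gain; those magnitudes are
data-dependent. The toolkit deliberately stops short of likelihood
modelling of damage (no rescaling of base qualities) and of running an
aligner itself: it emits the recommended command lines and consumes the
resulting SAM.
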