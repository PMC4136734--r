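---
title: "Methods: dual-phase bisulfite mapping and methylation calling for degraded reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-phase bisulfite mapping and methylation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bisulfite treatment converts unmethylated cytosine to uracil (read as T after
PCR) while 5-methylcytosine is protected. Sequencing bisulfite-converted DNA
therefore encodes methylation state in C/T (and, on the opposite strand, G/A)
differences — but the same differences defeat ordinary read mapping, because
an unmethylated read no longer matches its reference locus. DNA recovered
from formalin-fixed, paraffin-embedded (FFPE) archival tissue compounds the
problem: it is fragmented (reads from tens of bp up to several hundred bp),
chemically damaged, and available only in small amounts, and whole-genome
amplification after conversion puts all four bisulfite strand states into the
library.

`bisulfitr` implements the complete computational tail of such an experiment
at desk scale: dual conversion-phase mapping, repeat- and overlap-based read
filtering, iterative remapping of unmapped reads, and strand- and
context-resolved methylation quantification — together with a simulator that
generates FFPE-like bisulfite reads with known truth so that every stage has
a parameter-recovery test.

## Mapping model

Mapping happens in "three-letter" space. For each read, two in-silico
versions are made: tag **a** (every C replaced by T) and tag **b** (every G
replaced by A). The reference is likewise converted — Watson and Crick strand
each in both phases, four sequences per contig. Tag-a versions are aligned to
the C→T-converted Watson and Crick strands, tag-b versions to the
G→A-converted strands. In this space the methylation-dependent base
difference vanishes, so alignment is unbiased with respect to methylation
state. All coordinates are reported on the Watson axis (0-based, half-open
internally; 1-based inclusive in human-facing reports, where read ids carry a
`/a` or `/b` suffix).

The alignment core is an exact affine-gap Smith–Waterman (match 1, mismatch
−3, gap of length L costs 5 + 2L, minimum reported score 30 — the defaults of
the long-read external aligner the pipeline can optionally delegate to).
`local_align()` exposes the exact DP directly. Against genome-scale
references, running the full DP for every read–strand–phase combination is
quadratically infeasible, so `map_reads()` finds candidate windows by exact
k-mer seeding (k = 16, diagonals clustered within 32 bp, seed k-mers
occurring more than 32 times in the target skipped as low-complexity) and
runs the *same exact DP* inside each padded window. Clusters supported by at
least 2 seeds are preferred; queries too short to expect 2 seeds may fall
back to singleton clusters. For contigs under 5 kb the full DP is used
directly. Tie-breaks are fixed (diagonal over gap, first-best cell in
row-major order; across placements: contig, Watson start, Watson before
Crick, tag a before b) so the whole pipeline is byte-deterministic.

An adapter around the external BWA-SW binary (`map_with_bwa()`, forwarding
the band heuristic `z = 50`) is available but never used implicitly; a
missing binary is an explicit error.

## Filtering

Candidate placements pass through three rule sets:

1. **Repeat rules.** Aligned ('M') positions overlapping annotated repeat
   intervals of the recognized classes (Alu, simple repeats, ERVL-MaLR,
   low-complexity, L1HS, L1M, L1P, LTR ERV, Segmental Dups, CNVs) are marked.
   A placement is removed if it touches two different recognized classes, or
   if fewer than 20 bp of its aligned length remain unmarked. All annotation
   tracks are supplied as one BED4 file with a class label.
2. **Multi-mapping.** Among the surviving placements of one (read, tag), only
   the one with the shortest total repeat overlap is kept (ties broken by the
   deterministic order above).
3. **a/b overlap.** The two phase versions of a read usually map the same
   locus; the duplicate must be removed. If one version's aligned segments
   are totally contained in the other's, the contained one is removed; with
   identical coverage the lower-scoring version is removed — the score
   difference is exactly the misfit of the wrong conversion phase, so this
   keeps the version whose conversion model matches the molecule's actual
   strand state. A partially overlapping version whose non-overlapped aligned
   length is at most 20 bp is also removed. Versions at disjoint loci both
   survive and are flagged `cross-locus-pair` in the filter audit (their
   joint interpretation is ambiguous; both contribute calls, and the read
   counts as multi-mapped).

Reads left without any surviving placement, and longer than 35 bp, are split
at their midpoint; fragments of at least 35 bp re-enter steps 1–3, for at
most two split rounds. Because the aligner is an exact local DP, a fragment
can never out-score the whole read, so splitting rescues reads whose whole-
read placements were *filtered* (e.g. spanning two repeat classes), not reads
that merely failed to align — a chimeric read, in particular, simply maps via
its better half in round 1.

A read is **uniquely mapped** if exactly one placement survives and its score
strictly exceeds every alternative-locus candidate (margin configurable,
default 0). Every input read ends in exactly one of four fates — unique,
multi, filtered (with reason), unmapped — and the four counts always sum to
the input count.

## Methylation readout

Calls use only the read's *original* bases at aligned positions over genomic
cytosines. The strand a call informs follows from (tag, aligned strand):
(a, Watson) → Watson cytosines via C/T; (a, Crick) → Crick cytosines via C/T
in Crick orientation; (b, Watson) → Crick cytosines via G/A at Watson G
positions; (b, Crick) → Watson cytosines via G/A. Any other base (N, error)
is uninformative. Context is determined on the site's own strand: CpG if the
next base on that strand is G, CpA if A, otherwise "other". `N` never
participates.

Reported statistics:

* **Conversion rate** — the converted fraction of informative cytosine
  observations outside CpG *and* CpA context. Two deliberate choices live
  here. First, the quantity reported is the converted fraction (the
  complement, the unconverted fraction, is also reported as "Unconverted
  rate"); the two always sum to exactly 100%. Second, CpA cytosines are
  excluded by default — CpA methylation is itself quantified by this
  pipeline, so leaving CpA in (as a literal "outside CpG context" definition
  would) deflates the conversion estimate by the CpA methylation level;
  `contexts_excluded = "CpG"` restores the literal behaviour.
* **Context methylation rates** — call-level pooling: methylated calls over
  informative calls across all sites of a context and strand. At the 2–4×
  depths this design produces, per-site percentages are unstable, so pooling
  is the primary estimate. Raw pooled rates estimate
  $p + (1-p)(1-c)$, not $p$: an unmethylated cytosine escapes conversion
  with probability $1-c$ and then reads as methylated. The summary therefore
  also reports conversion-corrected rates
  $\hat p = (\hat m - (1-\hat c))/\hat c$, clamped to [0, 1]; these are the
  estimates whose target is the generating methylation probability, and they
  are what the parameter-recovery tests assert. The Table-style report
  prints the raw rates.
* **Single-methylation polymorphism (SMP)** — among sites with ≥ 2
  informative calls on one strand, the percentage showing both states. Two
  calls is the minimum at which within-strand disagreement is observable.
* **Symmetric / asymmetric CpG** — over CpG dyads with ≥ 1 informative call
  on each strand, a strand counts as methylated on strict majority (ties
  count unmethylated, a conservative deterministic choice); symmetric =
  both strands methylated, asymmetric = exactly one.
* **Coverage** — covered fraction (distinct Watson positions under unique
  placements over genome length), mean depth (aligned bases of unique
  placements per covered position), and consistency rate (percentage of
  aligned bases matching the phase-converted reference — this quantity has
  no published definition, so the package states its own).

## The simulator

`sim_config()` defaults describe the study conditions the package targets: a
100 kb single-contig reference at GC 0.41, 5,000 reads with truncated-normal
lengths (mean 312.60, sd 136.83, range 40–745 bp), bisulfite conversion
efficiency 0.967, methylation probabilities CpG Watson/Crick 0.651/0.427 and
CpA 0.164/0.217, per-base substitution error 0.01 (pyrosequencing-like), and
a uniform mixture over the four bisulfite strand states (whole-genome
amplification after conversion produces all four). Conversion failure is
i.i.d. per cytosine per read — the simplest model consistent with a single
global conversion rate. FFPE age is modelled only through the length
distribution and error rate; there is no explicit damage-chemistry model, no
homopolymer indel model (indels would conflate aligner stress with
methylation readout), and no amplification bias. Chimeras (two joined loci)
and labelled repeat intervals (disjoint, 150–500 bp) are available as
fractions, default 0.

These choices mean passing tests demonstrate correct *computation* — exact
alignment, rule-faithful filtering, unbiased readout, estimator calibration —
on data matching the stated generative model. They do not demonstrate
robustness to indel-rich chemistry, reference divergence, or real repeat
structure, which a synthetic i.i.d. genome underrepresents.

The recovery experiments used by the test suite run at the study's stated
scale (100 kb, 5,000 reads) over a parameter grid spanning both conversion
efficiencies (0.886, 0.967), three CpG levels (0.32, 0.45, 0.65) and two CpA
levels (0.16, 0.58), with error rate 0 so that mapping accuracy is assessed
on error-free reads; every corrected estimate must fall within 3 binomial
standard errors of its generating value, with the standard error computed on
the effective number of independent sites $(\sum d)^2 / \sum d^2$ (site
truth is fixed, so calls at depth > 1 are not independent) and divided by
$c$ for the corrected estimator. Unit tests exercise error rates above zero,
repeats and chimeras separately.

## Numerical and degenerate-input choices

* Percentages in reports are printed to 1 decimal; means and standard
  deviations to 2. The read-length standard deviation uses the population
  form (divide by N) by default, configurable to the sample form; the median
  of an even count is the mean of the central pair.
* Undefined statistics (no informative calls, empty read set, zero coverage)
  render as `NA`, never as 0. "Raw wells" and "Key pass wells" are
  instrument-level counts that cannot be derived from read files; they render
  `NA` unless supplied.
* Reads shorter than 40 bp are dropped before mapping (the instrument's own
  short-read filtration); the length-bin profile bins from 40 bp in 40 bp
  steps by default.
* Seeds: the simulator is byte-deterministic given (config, seed); the
  pipeline proper has no randomness, so staged and monolithic execution, and
  repeated runs, are byte-identical.

## Known limitations

Desk scale is a design point: the seeded-window aligner handles ~10⁵–10⁶ bp
references comfortably but is not engineered for mammalian genomes (no
FM-index, single-threaded). SAM/BAM is not emitted (TSV is the native report;
the mapping table carries CIGAR strings, so a writer would be
straightforward). Differential methylation between samples, smoothing, and
browser-track export are out of scope. The multi-mapping rule keeps at most
one placement per (read, tag), so a genuine chimera contributes only its
better half to calls.
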