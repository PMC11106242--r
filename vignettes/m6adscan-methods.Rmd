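---
title: "Predicting variants that alter distal m6A site accessibility"
author: "m6adscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting variants that alter distal m6A site accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6adscan)
```

## The problem

N6-methyladenosine (m6A) is the most abundant internal mRNA modification.
It is written by the METTL3 complex at DRACH consensus motifs (D = A/G/U,
R = A/G, then the methylated A, then C, H = A/C/U; DNA-alphabet regex
`[AGT][AG]AC[ACT]`), read by YTH-domain proteins, and influences nuclear
export, translation and stability.  Most mRNA m6A residues cluster in a
CDS-terminal hotspot: the last coding exons and the start of the 3'UTR.

Methyltransferase access to a DRACH site depends on local RNA secondary
structure: motifs sequestered inside base-paired stems are poor substrates.
A single-nucleotide variant far from any DRACH motif can therefore change
m6A deposition *at a distance*, by tipping the minimum-free-energy (MFE)
fold of the surrounding region so that distal motifs become buried or
exposed.  Such m6A-distal variants (m6Ad-SNVs) are a structural,
riboSNitch-like mechanism, distinct from m6A-SNPs that rewrite the motif
itself.  `m6adscan` screens variant catalogues for them.

## The procedure

For every variant joined to a validated m6A site on a shared transcript:

1. **Analysis window.** Build the spliced CDS-terminal window: the tail of
   the coding sequence restricted to the *last two CDS exons*, ending at
   and including the stop codon, followed by the first
   `min(100, available)` nt of the spliced 3'UTR.  The total window is
   capped at 250 nt, so the CDS tail receives `min(250 - utrLen, last two
   exon CDS length)` nt.  The window cap keeps single-sequence MFE
   prediction in the regime where it is most reliable; the composition
   targets the m6A hotspot.  When the 3'UTR is shorter than 100 nt, the
   CDS portion may exceed 150 nt up to the 250-nt cap (the UTR is taken
   first; the CDS fills the remainder).  The stop codon counts as part of
   the CDS portion, since the UTR nucleotides follow the stop codon.
   5'UTR sequence never participates.
2. **Variant placement and filters.** The variant is mapped into the
   window (alleles reverse-complemented for minus-strand transcripts), its
   coding consequence classified with the reading frame anchored at the
   stop codon, and the record rejected when it creates a premature
   termination codon (nonsense), shifts the frame (frameshift), converts
   the stop codon to sense (stop-loss), or overlaps a DRACH motif of the
   *reference* window (those are direct motif variants, a different
   mechanism).  Junction-spanning alleles and transcripts without a
   terminal stop codon are also rejected, each with a logged reason, and
   an accounting identity (`pairs = kept + rejected`) is asserted on every
   run.
3. **Folding.** Reference and alternate windows are folded to a single
   MFE structure under one constraint: isolated base pairs (helices of
   length one) are not formed.
4. **Accessibility scoring.** Every DRACH site is profiled against the
   dot-bracket: a site is *free* when 3 or more of its 5 nucleotides are
   unpaired, *paired* when 3 or more are paired.  Sites are matched
   between reference and alternate structures by coordinate
   (offset-adjusted past indels) and transitions
   (`free->paired` / `paired->free`) reported, together with
   `deltaMFE = |MFE_ref| - |MFE_alt|` (positive = variant destabilizes)
   and the non-overlapping segment counters described below.

### Non-overlapping segment counters

Beside the 3-of-5 site label, each site contributes to twelve counters:
free and paired counts of the motif sub-segments DRA, RAC, ACH, DRAC,
RACH and DRACH.  Segments are evaluated in priority order -- longer
segments first, 5' before 3' at equal length (DRACH; DRAC, RACH; DRA,
RAC, ACH).  A segment scores *free* when every one of its positions is
unpaired (*paired* when every position is paired), and a scored segment
consumes its positions, so e.g. a free DRAC is not additionally counted
as free DRA or free RAC.  The DRAC-before-RACH order at the 4-mer tie is
a documented convention; the two quantities (homogeneous segments vs the
3-of-5 label) are deliberately distinct and both reported.

## Folding engines

Two engines satisfy one contract (`fold()`), and every result records
which engine produced it; cross-engine numbers are never mixed in a table.

* **vienna** -- an adapter around the `RNAfold` executable, run with
  `--noLP`.  This is the production engine, with the full nearest-neighbor
  energy model at its default 37 degC temperature.
* **builtin** -- an exact dynamic program compiled with the package.  Its
  energy model is deliberately simple and fully documented: pair
  stabilities GC -3.0, AU -2.0, GU -1.0 kcal/mol, plus a helix initiation
  penalty of +4.0 kcal/mol per maximal stack.  The helix penalty is a
  coarse stand-in for loop entropy; without it, a purely additive model
  happily fragments sequences into scattered 2-bp helices that no
  physical model would form.  Hairpin loops require at least 3 unpaired
  nt, N never pairs, and windows with more than 10% N are rejected.  The
  DP is exact under this model and is verified in the test suite against
  exhaustive enumeration of all legal structures for short sequences;
  tie-breaks in the traceback are fixed (leave the 3' base unpaired
  first, then the 5'-most branch; keep stacking inside a helix), so
  output is deterministic.

DNA input is folded as RNA (T as U) and rendered as RNA in results; all
other processing uses one internal DNA alphabet with U converted to T on
read.

## Coordinates

All internal coordinates are 1-based inclusive -- the native convention of
the IRanges/GenomicRanges containers that back every interval operation
here.  BED12 half-open fields and VCF positions are converted on read, so
a single convention holds throughout and off-by-one drift has one
boundary to cross, at parse time.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maxWindow` | 250 nt | total analysis-window cap |
| `utrCap` | 100 nt | 3'UTR nucleotides taken after the stop codon |
| `cdsSoftCap` | 150 nt | nominal CDS tail when the full UTR is present (informative; the binding constraint is `maxWindow - utrLen`) |
| `engine` | builtin | `"vienna"` or `"builtin"` |
| `noLonelyPairs` | TRUE | forbid helices of length 1 |
| `explodeSites` | FALSE | one row per (variant, transcript, site) instead of a site-list column |
| `sortKey` | transitions | candidate order: altered-site count desc, then absolute deltaMFE desc |

Because a published "hit" count can be read either as (variant,
transcript) pairs or as (variant, transcript, site) triples, the default
output keeps one row per (variant, transcript) with the m6A sites as a
list column, and `explodeSites` produces the triple form; both counts are
thereby available.

A motif *gained* in the alternate sequence at the variant site does not
reject the record (the rejection filter is defined on the reference motif
set) but is flagged in the `gained_motif_at_variant` column.

## The synthetic data generator

`makeFixtures()` writes a deterministic, fully self-contained bundle:
genome FASTA, BED12 transcripts, VCF variants, m6A-site TSV and a truth
manifest.  Its loci are engineered so the expected outcomes are analytic
rather than measured:

* **Structure-switch cassettes.** Each cassette realises a two-state
  fold: a hairpin family H (an anchor helix plus a 5-bp stem of four
  sequential G-C pairs and one A-U pair, the stem's central C being the
  variant) competes with a long-range helix R:X that pairs the DRACH
  region R against an antisense arm X placed in the 3'UTR.  Every pair of
  H crosses every pair of R:X, so the two families are topologically
  mutually exclusive, and the energy balance is set so that one
  substitution in the stem decides the winner in *both* engines' models.
  The EPRS1-like locus folds H in the reference (DRACH sites free) and
  flips to R:X when the variant breaks the stem (two sites
  `free->paired`); the VHL-like and TSC2-like loci carry the broken stem
  as their reference allele, so the variant *restores* H (two sites freed
  plus one anchor-arm site buried, and three sites freed, respectively;
  the TSC2-like locus is on the minus strand).  Spacer sequence inside
  the structured windows is poly-A, which cannot pair with itself, so no
  competing helix exists that the design did not put there.
* **Census locus.** A transcript whose terminal two exons carry exactly
  13 DRACH motifs -- three dense three-motif clusters (one in the
  penultimate exon, one in the last coding exon, one in the 3'UTR,
  mirroring a polymethylated-region layout) plus four isolated single
  motifs.  It exists for motif-census checks and is never folded.
* **Filter-matrix transcript.** A random sense-codon backbone (the only
  windowed locus with random content) with planted codons providing all
  eight variant classes: synonymous-distal, missense-distal, nonsense,
  frameshift, stop-loss, DRACH-overlapping, 3'UTR, and a
  junction-spanning deletion.  Generation re-rolls the backbone until no
  accidental DRACH motif touches a planted variant span, so the planted
  verdicts stay analytic for every seed.
* A transcript whose CDS lacks a terminal stop codon exercises the
  annotation-error path (rejected with a logged reason, not an error).

Randomness is confined to intergenic DNA, introns and the filter-matrix
backbone; identical seeds reproduce the bundle byte-for-byte.

The named loci are *synthetic stand-ins*: they reproduce the documented
geometry and transition patterns of their real counterparts (motif
census, a variant 55 nt downstream of the last exon-exon junction inside
the G-C stem, the freed/buried site counts) but are not human sequence.
Passing on them demonstrates that the machinery -- window construction on
both strands, filtering, folding, scoring, diffing -- recovers planted
truths exactly.  It does not demonstrate that MFE prediction of real
250-nt windows predicts in-cell methylation; that link rests on the
underlying biology, not on this code, and real applications should treat
candidates as hypotheses for experimental follow-up.

## Numerical and degenerate-input choices

* DeltaMFE sign: `|MFE_ref| - |MFE_alt|`; positive means the variant
  destabilizes the reference fold.
* The first (possibly partial) codon of a window is completed from up to
  2 nt of upstream CDS context stored with the window, so every CDS
  variant is classifiable even though the window need not start on a
  codon boundary.
* Indels: in-frame indels are processed with an offset map for site
  matching; sites overlapping the variant span itself are not matched
  across structures.  Junction-spanning alleles are rejected.
* Windows shorter than 9 nt, CDS tails shorter than 9 nt and transcripts
  without a terminal stop are rejected with logged reasons.
* REF/genome disagreements are hard errors naming chrom and position --
  never silent skips.

## Problem sizes

The package's own test and demonstration sizes: analysis windows are at
most 250 nt (engine-enforced); the exhaustive-enumeration check of the
builtin folder uses 200 random sequences of 9-16 nt; the fixture bundle
holds six transcripts on six toy chromosomes, 12 variants and 15 m6A
sites.  These sizes make every expected value either enumerable or
analytic while exercising all code paths, including the 250-nt cap
arithmetic.

## Known limitations

* Single MFE structures only: no partition function, base-pair
  probabilities, suboptimal ensembles or pseudoknots.  A site that is
  paired in the MFE structure may still be transiently accessible.
* The builtin energy model is intentionally coarse; for production scans
  use the vienna engine and read builtin results as a deterministic,
  dependency-free approximation.
* Phased multi-variant haplotypes and multi-nucleotide substitution
  normalization are out of scope; records are evaluated one variant at a
  time.
* Non-DRACH m6A consensus variants are not scanned.
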