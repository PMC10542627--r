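---
title: "Models and methods: an alternatively spliced GFP reporter and its siRNA-mediated silencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: an alternatively spliced GFP reporter and its siRNA-mediated silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceReporter)
```

# The system being modelled

spliceReporter emulates a class of plant reporter transgenes in which a GFP
coding sequence sits downstream of a viral enhancer and a minimal promoter,
and in which transcription unexpectedly initiates at a cryptic start inside
the enhancer's tandem repeats rather than at the annotated TATA promoter.
The resulting pre-mRNA can be processed three ways:

* left **unspliced**;
* spliced at a **canonical GU-AG** donor-acceptor pair nested inside the
  upstream region;
* spliced at a larger, **noncanonical AU-AC** pair.

Only the AU-AC product is translatable: in the unspliced and GU-AG
transcripts, in-frame stop codons between the effective start codon and the
GFP coding sequence terminate translation early. In the AU-AC transcript,
translation initiates at an upstream in-frame ATG that adds 27 codons to the
standard GFP open reading frame. Because the untranslatable transcripts are
substrates for RNA-dependent RNA polymerase (RDR6) and DICER-LIKE (DCL)
processing, they seed populations of 21/22/24-nt small interfering RNAs that
silence the reporter posttranscriptionally; mutations in the silencing
machinery (rdr6, dcl4) or in splicing factors reshape those populations in
characteristic ways.

The package provides a synthetic, fully seeded stand-in for this locus and
its sequencing readouts, plus the bespoke analyses the system calls for:
tiered small-RNA mapping, size-class/strand and coverage profiling,
chi-square detection of differential alternative splicing, and splice
variant/translatability quantification.

# The synthetic locus

`build_reporter_locus()` places, on a 2088-bp expression region (enhancer
1277 bp, minimal promoter 91 bp, GFP CDS 720 bp):

* the transcription start at position 100, inside three 22-nt tandem
  repeats at the enhancer 5' end;
* an AU-AC pair spanning positions 160 to 1341 and a GU-AG pair nested
  inside it (400 to 1100), so that the upstream exon 160-400 is present in
  the GU-AG and unspliced transcripts but absent from the AU-AC product,
  and the GU-AG intron interior is unique to the unspliced form;
* an upstream ATG at position 106, 81 nt (27 codons) upstream of and in
  frame with the standard GFP start in AU-AC mature coordinates;
* planted stop codons that terminate the reading frames available to the
  unspliced and GU-AG transcripts, while the AU-AC frame is kept stop-free
  from the upstream ATG through the CDS terminator.

Everything outside these fixed motifs is pseudo-random sequence drawn from
the configuration seed; the architecture is therefore exact while the
sequence differs per seed, which is what the logic-level tests need. The
frame bookkeeping is constructive, not search-based: open-reading-frame
regions are assembled from non-stop codons, decoy ATGs are planted with
context chosen so they cannot create stops in the AU-AC frame, and the
killing stops for the other frames are placed inside regions the AU-AC
product splices out. `validate_locus()` re-checks the invariants
(dinucleotides, interval sanity, frame relations) after construction, and
`enumerate_splice_variants()` verifies with `orf_scan()` that exactly one
variant is translatable. Region lengths are configurable for stress tests;
the constraints are `enhancer >= 600`, `promoter >= 30`, CDS length
divisible by 3, and enhancer+promoter divisible by 3 (so the upstream ATG
can be in frame).

# The simulators

`simulate_rnaseq()` draws paired-end fragments (default 2000 pairs, 75-nt
mates, Gaussian fragment length 180 +/- 20) from the three mature
transcripts according to `variant_mix`, projects them to locus coordinates
(split blocks across junctions), and injects substitutions at `error_rate`.
The default wild-type mix (0.25 unspliced, 0.45 GU-AG, 0.30 AU-AC) is a
package choice: the mix must leave the GU-AG product as the dominant
untranslatable species (it is the main siRNA source in this system) while
keeping enough AU-AC product for an intermediate-fluorescence phenotype; no
quantitative mix is published for the system, so these values are fixed once
here and used everywhere.

`simulate_sirna()` draws small RNAs only from the two untranslatable
transcripts — the translatable AU-AC variant is excluded from the biogenesis
pathway, which the tests verify as an exclusion property. Free parameters
and their defaults:

* `size_mix` over 21/22/24 nt, default (0.75, 0.15, 0.10): a 21-nt-dominant
  wild-type population;
* `antisense_fraction` 0.5: both arms of the dsRNA precursor are diced;
* `source_weights` (0.9 CDS, 0.1 upstream exon): reproduces the CDS-biased
  coverage with sparse upstream signal;
* `source_variant_weights` (0.85 GU-AG, 0.15 unspliced): the GU-AG
  transcript is the primary source; reads from the unspliced-only central
  region stay rare;
* `gradient_strength` 2: per-start weight `exp(-g * dist_from_3p / length)`,
  the simplest monotone model of an RNA-dependent polymerase losing
  processivity as it travels 3' to 5'; at `g = 2` the 5' end is sampled at
  ~14% of the 3' rate.

Genotype presets override these fields: `rdr6` (and any preset containing
it) zeroes the library; `dcl4` presets make 22 nt modal and raise abundance
(DCL2 compensation); `cwc16a` leaves ~20 reads (negligible); `coi1_zch1`
triples abundance with a sharpened 21-nt mode. These are qualitative
phenotypes turned into fixed numbers once; they are the study conditions,
not tuning knobs.

What the generator does **not** emulate: DNA methylation and transcriptional
silencing, developmental timing (the delayed-silencing phenomenon), ligation
and PCR biases of real small-RNA libraries, quality scores, and
multi-mapping against a whole genome. Passing tests therefore demonstrate
the correctness of the analysis logic under a faithful locus geometry, not
performance on real libraries.

# Tiered small-RNA mapping

`map_library()` implements a four-step prioritized cascade; a read is
assigned at the first tier with any hit, and all equally good positions at
that tier are reported:

1. perfect match (either orientation) to the **canonical transcript** — the
   contiguous transcript anticipated from the construct design, running from
   the cryptic start to the locus end;
2. perfect match to **junction-spanning fragments** (29-nt flanks
   concatenated around each donor-acceptor gap), built only for junctions
   with split-read support in the RNA-seq alignments, and only accepted when
   the read straddles the junction point;
3. tiers 1-2 repeated allowing **one substitution** (transcript first, then
   fragments — mirroring the order of steps 1-2);
4. a **fine-grained fallback scan** of the whole vector: full-length
   placement with at most one substitution, then any ungapped partial
   placement with at least 14 matching bases (the completeness of an
   exhaustive scan subsumes what a 9-mer seed-and-extend search could find;
   a randomized comparison against such an oracle is part of the test
   suite).

Design choices: mismatches are substitutions only (dicer products carry no
indels relative to their source); `N` never matches; multi-hit reads weight
each position `1/n_hits` downstream so coverage stays unbiased without
arbitrary tie-breaking; the read-length filter defaults to 18-30 nt. The
tier-1 reference is deliberately the contiguous pre-mRNA, not the spliced
AU-AC product: junction-spanning reads are then captured exactly once, at
tier 2, by fragments for *observed* junctions, and an error-free library
resolves entirely at tiers 1-2. Exact matching is done with a base-R
scanner that reports overlapping occurrences (relevant in the tandem-repeat
region); the one-mismatch tiers use a vectorised mismatch-count scan.

# Profiles and coverage

`size_strand_table()` tabulates reads per (length, strand) and normalises to
reads per million. The denominator defaults to all reads passing the length
filter (not only vector-mapped reads) so that profiles are comparable across
samples whose mapping rates differ; a mapped-only denominator is available
by passing that number instead. `coverage_track()` spreads
`(1/n_hits) * 1e6 / library_size` over every aligned base (block-resolved,
so split reads do not cover their gap). Conservation (track mass equals
total weighted aligned bases) and scale equivariance are asserted in the
tests. `compare_profiles()` reports per-class ratios with explicit
`infinite`/`undefined` flags instead of substituting numbers for zero
denominators.

# Differential alternative splicing

For each candidate event the package accumulates a signal/background count
pair per group (control, treatment), sums it over biological replicates
("merge then test", which is identical to testing summed counts and raises
power for sparse events), and applies the Pearson chi-square on the 2x2
table

```
        signal   background
ctrl      s_c        b_c
trt       s_t        b_t
```

with one degree of freedom, no continuity correction and no multiplicity
correction: the goal is a uniform comparison standard across events, not a
controlled discovery list, so raw p-values are reported and thresholded at
alpha = 0.05. Events whose pooled total is below `min_total` (default 10)
are reported untested rather than tested on noise. A zero marginal total
carries no information about differential preference and returns chi2 = 0,
p = 1.

Counting rules per event class:

* **Intron retention**: the signal measures intron expression, the
  background that of the flanking exon windows (100 nt each side by
  default). The default mode assigns each non-split read once, to whichever
  region holds the majority of its aligned bases. This keeps all four cells
  genuine read counts — i.e. the multinomial sampling model the chi-square
  assumes — and the test's type-I error sits at the nominal level (verified
  by Monte Carlo in the acceptance suite). A `mean_depth` mode (rounded
  mean per-base depth over each region; split reads count toward exon depth
  only) is also provided: it is the natural "depth" summary for display,
  but as a chi-square input it shrinks every cell by roughly
  read_length/region_length and makes the test conservative in proportion,
  which is why it is not the default.
* **Exon skipping**: signal = split reads whose gap fully contains the
  exon; background = split reads using either flanking inclusion junction.
  Gaps that only partially overlap the exon count in neither cell. An exon
  without two flanking junction candidates is reported unsupported — on the
  default locus the candidate skippable exons have only one inclusion
  junction each, so ES rows appear as untested there; the counting logic is
  exercised on constructed three-exon cases in the tests.
* **Alternative donor/acceptor**: signal = split reads exactly matching the
  pair; background = split reads sharing the donor or acceptor but pairing
  it differently (the shared-site rule). Because this reporter's two
  junctions share no site, the shared-site background is structurally zero
  here and those tests return p = 1; an `all_split` background is exposed
  for the cross-junction comparison instead.

One further statistical point: mates of one fragment are strongly correlated
in which cell they fall, which would overdisperse the counts roughly
twofold. The analysis scripts and the acceptance suite therefore count one
mate per fragment. `detect_events()` itself counts whatever alignments it
is handed, so a single-end user is unaffected.

# Variant quantification and translatability

`classify_reads()` labels an alignment `au_ac` or `gu_ag` when its gap
matches that donor-acceptor pair exactly, `unspliced` when a contiguous read
overlaps the GU-AG intron interior (sequence found only in the unspliced
form), and `ambiguous` otherwise. `variant_proportions()` reports
proportions over informative reads only; ambiguous reads are counted but
never redistributed (an expectation-maximisation reallocation would be
uncheckable against anything this system reports). Note that these
proportions weight each variant by how much diagnostic sequence it exposes —
a GU-AG read is diagnostic only if it spans the junction, an unspliced read
whenever it touches the intron interior — so they are a comparison statistic
across samples, not estimates of transcript abundance; the tests check them
against the truth-conditional expectation, and mixture recovery is asserted
on the generator's per-fragment sampling, where the multinomial error model
actually applies.

`orf_scan()` models initiation by choosing the 5'-most ATG upstream of and
in frame with the standard start (bounded to the mature transcript), then
scans codons to the CDS end; a transcript is translatable if no stop
intervenes before the terminator codon. On the default locus this yields
translatable = (FALSE, FALSE, TRUE) for (unspliced, GU-AG, AU-AC) and a
27-codon N-terminal extension for the AU-AC product.

# Numerical and reproducibility choices

* All internal coordinates are 0-based half-open; conversion happens only at
  the SAM (1-based) and bedGraph boundaries.
* One global seed determines everything; the simulators draw from
  `withr::with_seed` on derived seeds (locus: seed; RNA-seq: seed+1;
  small RNAs: seed+2; pipeline replicate groups: seed+1000/2000+r), so
  stages can be rerun in isolation and the global RNG state is never
  touched.
* Coverage accumulation uses a delta/cumsum encoding; values within 1e-8 of
  zero are snapped to zero to keep bedGraph output clean of floating dust.
* Ties in tier-4 scoring (matches minus mismatches) are kept, not broken:
  all top-scoring placements are reported and weighted fractionally.
* Monte Carlo problem sizes in the tests: the type-I study uses 1000 null
  comparisons of merged triplicates at 300 fragments per replicate; the
  power study uses 100 comparisons at 2000 fragments per replicate; mapping
  soundness is brute-force-verified on 200-read libraries. These sizes give
  stable checks (3 SE bands) at desk scale.

# Known limitations

* The fallback scan is exhaustive over a ~2-kb vector; it is complete but
  would need indexing for genome-scale references, which are out of scope.
* The SAM dialect is minimal (single reference, M/N CIGARs, one gap); BAM
  and multi-reference headers are not supported.
* The IR flanking-exon window is a fixed-width proxy for "neighboring
  exons"; with a richer annotation the true exon intervals should be
  passed to `count_ir()` directly.
* The chi-square is asymptotic; `min_total` guards the small-count regime
  in place of a continuity correction, and p-values are intentionally not
  adjusted for multiple testing.
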