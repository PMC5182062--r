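---
title: "Models and methods for germline-soma rearrangement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for germline-soma rearrangement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`micmac` analyses the two programmed rearrangements that turn a ciliate
germline (MIC) genome into its somatic (MAC) counterpart: chromosome
breakage at a conserved 15-bp element with de novo telomere addition, and
excision of internal eliminated sequences (IESs). This vignette records
the models behind each component, the parameters that matter, the
numerical conventions, and the design choices made where the problem was
genuinely open. Everything quantitative stated here is computed by the
test suite or by `scripts/acceptance.R`; nothing is asserted from memory.

## The simulator defines the study conditions

`sim_config()` fixes the conditions every downstream module is exercised
under. Defaults are the empirical parameters of the *T. thermophila*
system, scaled to a desk-sized genome:

* **Background composition.** Bases are drawn i.i.d. with A+T = 77.9%
  (`gc_fraction = 0.221`), the germline assembly's composition. The
  generated composition is within 2% of the target by construction.
* **Cbs variant spectrum.** Planted breakage elements are drawn from the
  published family table bundled with the package (109 canonical copies
  of 225; single and double substitutions only at positions 1, 11, 13,
  14, 15). Strand is uniform. A distributional test checks planted
  frequencies against binomial 99% intervals at n ≥ 500.
* **IES lengths.** The literature reports a wide size range summarised by
  mean 3.78 kb and median 2.78 kb on a log-scaled axis, but no explicit
  distribution family. We model removed lengths as lognormal — the only
  two-parameter family on the positive axis matching a (mean, median)
  summary with right skew — parameterised as `meanlog = log(median)`,
  `sdlog = sqrt(2 (log mean − log median))`, truncated by rejection to
  [136 bp, 20 kb] at miniature scale (the shortest published element is
  136 bp). This choice is flagged as an assumption; under it, about 85%
  of lengths fall in 1–10 kb, which matches the published fraction.
* **Terminal direct repeats.** Each IES is planted as
  `TDR + interior + TDR`, so one copy survives excision. TDR lengths 0–4
  are drawn from a class-weight vector (no-TDR the largest class); bases
  inside TDRs of lengths 2–4 are 97% A/T (92% for length 1), and with
  probability `tdr_tt_bias = 0.4` a length-k TDR is the first k letters
  of the TTAA consensus.
* **Tandem Cbs duplications.** A tandem locus is `copies` repeats of
  (Cbs + 200 bp shared flank + unique filler), with consecutive Cbs
  starts `tandem_spacer_length` apart. The spacer segments between
  consecutive Cbs are the future non-maintained chromosomes (one fewer
  than the number of repeat units); the shared flank is what makes the
  flanking Cbs segments cluster as a clade, while the unique fillers
  keep the NMC body absent from the soma.
* **Telomere addition.** Each broken segment end is trimmed by an offset
  drawn uniformly from 5–25 bp beyond the Cbs, and 20 copies of `CCCCAA`
  are appended as a marker (telomere assembly is out of scope; natural
  chromosome ends receive no telomere, as germline telomeres are not
  part of the assembly model).
* **Excision endpoint jitter.** Observed junction variability peaks at
  the parental endpoint and decays with distance. A plain discretized
  Gaussian puts its mode off zero once left and right offsets combine,
  so the generative model is zero-inflated: each endpoint reproduces the
  parental position with probability `excision_stay_prob = 0.25`, else
  adds `round(N(0, excision_endpoint_sd))`, truncated so realized
  removals stay inside their segment and endpoints never cross. With
  sd = 3 this yields a modal progeny-parent distance of 0 and
  essentially all validated endpoints within 20 bp, the qualitative
  pattern reported for real progeny pools.

Two hygiene steps make ground truth exact rather than approximate.
First, the two background bases bracketing each planted IES are adjusted
so that the planted removal interval is already left-normalized and the
planted TDR is maximal — otherwise roughly a third of junctions would
acquire accidental one-base extensions and "exact junction recovery"
would be ill-defined. Second, the finished chromosome is rescanned for
Cbs-family matches and any background (non-planted) match is disrupted by
a single substitution at a constrained family position, so scanning
recall and precision against truth are exactly 1 by construction.

All randomness flows from the single `seed` field; derived stages
(somatic derivation, read simulation, progeny pools) use fixed offsets of
that seed so each stage is independently reproducible. Identical
configurations produce byte-identical FASTA output.

## Coordinates and junction normalization

All coordinates are 1-based inclusive in R structures (the IRanges
convention); BED output converts to 0-based half-open, TSV output stays
1-based. A deletion that turns germline into soma is ambiguous up to
shifts wherever the boundary bases repeat — precisely the TDR ambiguity —
so every junction is reported **left-normalized**: the removal interval
is shifted left while the base before the removal equals its last base.
The TDR is then the longest common prefix of the removed sequence and the
sequence following it (capped at 10 bp; lengths 0–4 dominate). The
alternative (rightmost) placement is the same physical event; symmetry
under reverse-complementing the locus maps a TDR to its reverse
complement, which the tests check.

## Cbs statistics

Scanning uses the family pattern `WAAACCAACCYCNHW` as a regular
expression with overlapping matches on both strands; minus-strand hits
are reported with C-rich-strand sequence and forward coordinates, and an
`N` in the sequence never matches, even at the fully degenerate position.
Variant labels concatenate position+base of each mismatch to the
consensus ("11C", "1A,15A"); more than two substitutions marks a
non-functional sequence. Conservation is the standard information
content `2 + Σ f log2 f` per column with `N` excluded; strand asymmetry
counts substituted bases that are C or G on the C-rich strand (each
mismatch of a double counts) and applies a df = 1 chi-square against a
50/50 split without continuity correction — at the published counts
(27, 1) this is 338/14 ≈ 24.14, far beyond the 0.01 level. The bundled
table sums to 116 non-consensus copies; the accompanying text says 117,
and the package reports computed counts without reconciling the
discrepancy.

**Centromere mapping.** Viable germline arm deletions never remove the
centromere. The deletion-mapping evidence brackets each centromere by the
most centromere-proximal Cbs *removed* by a viable deletion on each arm
(on chromosome 5, viable deletions remove every arm Cbs, so the bracketing
pair is 5L-1/5R-1). If no deletion touches a Cbs on an arm, the innermost
Cbs on that side of the chromosome midpoint is used. On the bundled
interval table this reproduces the chromosome-1 span of 9.26 Mb with
midpoint 18.61 Mb and a total centromere fraction of 24.76% of the
152.54 Mb assembly (printed as 24.7% at one decimal).

**NMC detection.** A non-maintained chromosome is an internal inter-Cbs
segment absent from the somatic assembly: its covered fraction under
filtered cross-assembly blocks (length > 1 kb, identity > 95%) falls
below 5%. The absence definition gives no numeric cutoff; 5% is the
package default and configurable. Terminal segments are never classified
— the definition requires two bounding Cbs.

**Parsimony.** Cross-species variant evolution is summarised by Fitch
small parsimony on a rooted binary species tree, with missing tips
(unsequenced sites) unconstrained. The implementation is checked
exhaustively against enumeration of all internal labelings for every tree
up to 6 tips.

## Duplication clades

Each Cbs contributes a nominal 415-bp segment (motif ± 200 bp); Cbs
closer than 400 bp merge into one segment with outer flanks. Pairs are
aligned locally with BLASTN-like scoring (+1/−2, gap open 5, extend 2)
via `Biostrings::pairwiseAlignment`, in both orientations. Expectations
follow the Karlin–Altschul form `E = m n 2^(−bits)` with λ solved from
the scoring scheme and K fixed at 0.1: these E-values are internally
consistent but **not** comparable to NCBI BLAST's, so clustering is
calibrated against the randomized-flank null — flanks shuffled
independently with exact composition preservation, motif kept intact —
rather than against literal published cutoffs. On synthetic data the
separation is enormous (planted duplications reach E ≈ 1e−120 while the
best null pair sits near 1e−7), so the nominal 1e−18 default threshold is
conservative on both sides. Edges count only if both motifs lie inside
the aligned region. Two clustering routes are provided: connected
components over passing edges, and a Markov-cluster-style iteration
(expansion by matrix squaring, inflation 2.0 — the standard setting, as
none is published — with column renormalization to convergence); on
well-separated duplications they agree exactly.

## IES detection

Three evidence methods feed one merged set:

1. **Split somatic reads on the germline.** The built-in aligner places
   each read exactly (31-mer prefix seed, vectorized full-length
   verification); unplaced reads are extended maximally without gaps
   from prefix and suffix seeds, and a colinear piece pair yields a
   left-normalized removal interval. A candidate needs ≥ 3 spanning
   reads agreeing on the exact junction pair, mean internal somatic
   coverage < 1× (the published contamination guard), and junctions
   outside `N` runs. Support and coverage thresholds are monotone:
   raising them never adds candidates.
2. **Broken germline reads on the soma.** Reads whose alignment stops
   mid-read cluster by breakpoint (single linkage, 10 bp); a residual
   site validates with ≥ 6 broken reads including ≥ 1 from each
   direction. The modal rightward and leftward breakpoints usually
   overlap by the TDR length. Validated sites are translated to germline
   junctions through the cross-assembly block pair that brackets them.
3. **Cross-assembly gaps.** Adjacent colinear blocks whose germline-side
   gap exceeds the somatic-side gap by > 100 bp mark an eliminated
   interval; a non-positive somatic gap (block overlap = retained TDR)
   gives exact junctions, a positive one flags the candidate imprecise.

Merging demands exact junction agreement (`merge_tol = 0`) for the
high-confidence set; junction-gap or `N`-run records are demoted to
provisional and provisional/high tallies are reported separately. On
error-free simulated data at the study conditions (5 Mb germline, 10×
long somatic reads, zero jitter) method 1 alone achieves recall ≈ 0.99
and precision 1.0 at exact junctions, and the merged high-confidence set
equals the truth set exactly; an exhaustive substring-matching oracle
reproduces the split-read calls on toy genomes. Real data enters through
SAM/PAF readers; the bespoke logic is downstream of alignment either way.

Genomic context labels follow containment: any coding-exon overlap is
exonic; otherwise containment in a gene is intronic; boundary-straddling
intervals follow a majority rule. The coding-region screen tests exonic
records for the piggyBac-like feature set: TTAA TDR, a CACTTT-consensus
terminal inverted repeat internal to the TTAA (≤ 2 mismatches per end,
configurable), and exceptional shortness (below the 1st length percentile
by default).

## Super-assembly tiling and density tracks

Two germline scaffolds are proposed adjacent when their terminal regions
(blocks passing identity > 95%, length > 1 kb, ending within 100 bp of a
scaffold end) align to consecutive intervals of one somatic contig,
separated by ≤ 2 kb and overlapping by ≤ 50 bp, in consistent
orientation; the symmetric rule proposes somatic joins bridged by a
germline scaffold. Where the original analysis resolved ambiguous cases
by human judgment, the package instead flags any scaffold end with more
than one distinct proposal and accepts none of its edges — with planted
repeats, affected joins are flagged, never silently wrong. Accepted
edges must form simple paths; cycles are an error listing their edges.
Layouts are emitted AGP-style with fixed 100-N spacers (no spacer length
is published). On unique-sequence fragmentations whose cut points sit
more than 1.2 kb from any eliminated region, order and orientation
recovery is 100%.

Density tracks report covered base pairs (interval union, not sum) per
500 kb window sliding by 100 kb (both configurable); the final partial
window is included and flagged. Tracks are invariant to feature order
and to splitting features into abutting pieces, and non-overlapping
windows sum to the total feature span.

## Problem sizes and what passing tests show

The test suite runs on miniature genomes (150 kb chromosomes for module
tests; one 5 Mb genome for the detection-scale property), chosen so the
full suite completes in a few minutes on one CPU. The simulator plants
features at higher density than the real genome (one Cbs per ~25 kb
versus ~700 kb) to keep miniature chromosomes informative; densities,
not absolute counts, are the emulated quantity. Synthetic data are
error-free and repeat-poor outside the planted duplications: passing
tests demonstrate correctness of the junction arithmetic, thresholds,
clustering and tiling logic under the stated models, not robustness to
sequencing error, polymorphism, or the repeat content of real germline
assemblies. Genome-scale published counts (total Cbs and IES numbers,
clade counts) depend on the deposited assemblies and read sets and are
not reproduced at desk scale; the deterministic motif census is instead
verified against planted truth on the bundled miniature assembly.

## Known limitations

* The aligner is exact-match seed-and-extend: built for the error-free
  simulator and small fixtures. Real reads should be aligned externally
  and imported via SAM/PAF.
* E-values are calibrated only relative to the package's own null;
  clade counts on real data would require threshold re-calibration.
* Scrambled (non-colinear) germline-soma maps are out of scope; the
  organism modelled is nearly always colinear.
* The jitter model is independent per endpoint; correlated left/right
  variation (e.g. overhang-repair signatures beyond the +4 spike) is not
  modelled.
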