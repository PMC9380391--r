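---
title: "Methods: simulation-based optimization of SV-calling filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-based optimization of SV-calling filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Breakend-based SV callers report candidate novel adjacencies (junctions)
with rich per-breakend annotations — supporting fragment counts, variant
allele frequencies computed under a small-event and a large-event model,
QUAL, exact (microhomology) and inexact homology lengths around the
junction, strand bias, read-pair and split-read support flags, inserted
sequence, and FILTER tags. Which thresholds on these annotations produce a
good call set depends strongly on the genome, the ploidy/zygosity of the
variants, and the sequencing depth. svtune treats threshold selection as an
optimization problem: simulate SVs on the genome of interest, run the
calling machinery on the simulation, and pick the filter-parameter
combination maximizing the F-value

$$F = \frac{2 \cdot \mathrm{precision} \cdot \mathrm{recall}}
           {\mathrm{precision} + \mathrm{recall}},$$

with precision $= TP/(TP+FP)$ and recall $= TP/(TP+FN)$, per SV type and
integrated over all types. True positives are called SVs matching at least
one known SV; a known SV may satisfy several calls (there is no bipartite
assignment). When a denominator is zero we define precision, recall and F
as 0 — a pessimistic convention that keeps the optimizer's objective
monotone and never rewards empty output.

The filtered breakpoints are then summarized into SVs. Junction
orientations define type hints (deletion-geometry, tandem-duplication
geometry, inversion geometry, interchromosomal); DEL-like and TAN-like
junctions are only *confirmed* as deletions or tandem duplications when the
relative read depth of the spanned interval falls strictly below
`max_rel_coverage_to_consider_del` or rises strictly above
`min_rel_coverage_to_consider_dup`. This separates the thresholding of the
two classes — a junction with deletion geometry over a normally covered
interval stays unclassified rather than becoming a false deletion.

## Filter parameters

All defaults of the rule model (see `?filter_params` for the full
semantics):

| parameter | default | unit / domain |
|---|---|---|
| min_Nfragments | 5 | fragments |
| min_af | 0.25 | VAF fraction |
| min_af_EitherSmallOrLargeEvent | 0.25 | VAF fraction |
| min_QUAL | 0 | QUAL (inert at default) |
| max_to_be_considered_small_event | 1000 | bp (applicability modifier) |
| min_length_inversions | 40 | bp |
| maximum_lenght_inexactHomology | 50 | bp, non-small events only |
| maximum_microhomology | 50 | bp |
| maximum_strand_bias | 0.99 | fraction, small events only |
| filter_noReadPairs / filter_noSplitReads | off | non-small / small only |
| filter_overlappingRepeats | off | needs a repeat annotation |
| filter_polyGC | on | G/C runs > 15 bp in inserted sequence |
| wrong_FILTERtags | NO_ASSEMBLY | FILTER tags |
| range_filt_DEL_breakpoints | [0, 1] | bp range, DEL-like with inexact homology > 5 bp |
| dif_between_insert_and_del | 5 | bp margin, small DEL-like only |
| max_rel_coverage_to_consider_del | 0.1 | relative coverage |
| min_rel_coverage_to_consider_dup | 1.8 | relative coverage |

Boundary semantics are wording-literal and applied uniformly: "minimum"/
"maximum" thresholds are inclusive at the stated value ("minimum 5" accepts
5), "below"/"above" comparisons are strict, overlap fractions ("by 75%",
"by at least 80%") are inclusive, and breakend distances ("< 50 bp") are
strict. A *small* event is an intrachromosomal junction shorter than
`max_to_be_considered_small_event`; interchromosomal junctions are never
small (their event length is undefined), and they read `vaf_large` for the
`min_af` rule. The small/large VAF switch flips when the event length
exceeds the insert-size median plus its (unscaled) median absolute
deviation. The two coverage thresholds default to values appropriate for
haploid genomes or homozygous variants; for heterozygous simulations the
grid contains more permissive values (e.g. 0.6) and the optimizer selects
them. A breakpoint is discarded when *either* of its breakends fails any
enabled rule.

The exact VAF formulas of a real caller are treated as input annotations
(the emulator draws them; a VCF supplies them); svtune stores both
`vaf_small` and `vaf_large` per breakend and only decides which one a rule
reads.

## The caller emulator and what it does not emulate

`emulate_caller()` stands in for an external breakend caller so the whole
optimization loop runs in-process and deterministically. It detects each
truth junction with probability `detection_prob` (default 0.9), jitters
positions with a normal error (sd 3 bp), adds false junctions at
`fp_rate_per_mb` (default 20/Mb, 70% intrachromosomal), and draws
annotations from separate distributions for true and false breakends: true
breakends get high lognormal QUAL, Poisson fragment counts scaled by
coverage times the expected VAF, short homologies and balanced strand bias,
with a NO_ASSEMBLY tag probability of 0.1; false breakends get low QUAL,
Poisson(2) fragments, Beta-distributed low VAFs, long homologies, extreme
strand bias and NO_ASSEMBLY with probability 0.6, plus occasional long G/C
inserts. This creates a separable but imperfect filtering problem.
`noiseless_noise_model()` is the exactly invertible limit used by the
round-trip checks.

What the emulator deliberately does not model: alignment and assembly
artifacts correlated with local sequence (false junctions are placed
uniformly, not preferentially in repeats), coverage estimation noise from
real alignments (the synthetic coverage track is the expected copy-number
profile with optional log-normal noise), library-preparation biases, and
the specific annotation distributions of any particular caller. Passing
tests therefore demonstrate that the optimizer recovers planted structure
and that every rule behaves exactly as specified — not that the default
noise model matches any real dataset. With a real caller, its breakend VCF
is parsed by `parse_breakend_vcf()` and enters the identical path.
Similarly, the synthetic coverage assigns a cut-and-paste insertion's
moved copy to its destination locus (origin depth $1-f_v$, with $f_v$ the
variant-fragment fraction), the idealization under which origin depth
separates copy from cut insertions.

## The grid search

Candidate values per parameter are ordered most-permissive-first; every
list contains the unconservative extreme and the default. Pruning keeps a
value only if toggling it alone — all other parameters at their
unconservative extremes — changes which breakpoints pass on the catalog at
hand; values with identical single-toggle outcomes collapse onto the most
permissive of them. Because the overall pass set is the intersection of
per-rule pass sets and each rule depends only on its own parameter (given
the small-event bound), this pruning is outcome-sound whenever the
small-event bound is single-valued; when a grid explores several
small-event bounds, signatures are computed under each retained bound.
Coverage thresholds collapse when they order identically against every
relative coverage any classification or copy/cut decision inspects.

Enumeration is exhaustive over the pruned Cartesian product (budgeted;
exceeding the budget is an error recommending a smaller preset), in two
stages: breakend-filter combinations are collapsed onto distinct passing
sets, and each distinct set is scored once per coverage-threshold pair by
running the full classification pipeline against the truth set. Ties in F
keep the earliest combination in enumeration order — earlier parameters
vary fastest and candidate lists are permissive-first, so ties resolve
toward permissive values, deterministically across platforms.

The final parameter set is chosen from the union of all per-(simulation,
ploidy, type) winners plus the default, re-scored on every (simulation,
type) instance: the winner maximizes the minimum F, tie-broken by mean F,
then by fewest active filters. Only (simulation, type) cells with at least
one known record inform the selection — a type absent from a simulation
carries no signal (its F is 0 by the zero-denominator convention, which
would otherwise dominate the minimum). Two template genomes are the
default so the selection sees between-simulation variability.

## Junction grouping

Graph-based breakpoint summarizing is replaced by a deterministic
surrogate. Surviving junctions not confirmed as deletions, tandem
duplications or inversions are paired: a pair whose endpoints agree within
40 bp on both sides with complementary orientations is a balanced
translocation (inverted when within-junction orientations are equal); a
pair sharing one endpoint (within 1 kb) whose other endpoints span an
origin interval with left/right orientations is an insertion, decided
copy-and-paste when the origin's relative coverage reaches
`min_rel_coverage_to_consider_dup` and cut-and-paste when it falls to
`max_rel_coverage_to_consider_del` (when degenerate thresholds satisfy
both, coverage at or above 1 means copy; a junction pair satisfying
neither stays unclassified). The 40 bp translocation tolerance sits below
the minimum simulated SV size (50 bp) and above plausible positional
jitter, which is what disambiguates a short insertion's two near-identical
junctions from a balanced translocation pair. A lone surviving
interchromosomal junction is still typed as a translocation — its balanced
mate may simply have gone undetected — while lone intrachromosomal
junctions, complex inverted signatures and undecided pairs go to the
unclassified table. Inversion junctions are clustered when both boundary
coordinates agree within 50 bp; either junction of an inversion suffices
to call it.

## Simulation defaults

The generator's defaults are the package's study conditions: up to 50 SVs
of each of five types per template genome; variant sizes drawn uniformly
from $[10^{-4}, 1.5\times10^{-3}]$ of the total genome length with a 50 bp
floor (proportionality keeps kilobase-scale SVs on megabase-scale
genomes); placement by rejection sampling with 1,000 attempts per record
and a no-overlap constraint between all edited intervals (records that do
not fit are dropped with a warning); at most one translocation per
chromosome, with breakpoints uniform in the central 80% of each chromosome
(a stand-in for arm-level breakpoints when no centromere annotation
exists). Reads: fragment lengths normal with the configured median and
MAD, per-base substitution rate 0.1%, no indels — sequencing errors are
not the object of study. Ploidy strings set the reference:variant fragment
ratio (`diploid_hetero` = 1:1, `ref:3_var:1` = 3:1). The insert-size
statistics the filters consume are the median and unscaled MAD of the
fragment lengths.

## Region inference

`find_homologous_regions()` tiles the genome into non-overlapping 500 bp
windows and aligns each window against both strands of the whole genome
with an internal seed-and-extend aligner: exact 11-mer seeds, ungapped
extension along each seed diagonal scored +1/−2 with the best segment
found by maximum subarray, and a Karlin–Altschul e-value
$E = K m n e^{-\lambda S}$ with $K = 0.41$, $\lambda = 1.28$ (declared
approximations for this scoring scheme; $n$ counts both strands). Hits
need $E < 10^{-5}$ (strict) and must cover more than half the window
(strict); a window's exact self-hit is excluded, and only the exact self
is excluded — near-diagonal hits remain reportable. Gapped extension is
omitted: at the scales this operation serves (finding duplicated or
repeated regions to constrain simulations), ungapped segments plus the
coverage rule decide membership, and an outfmt-6-style adapter
(`homologous_regions_from_alignments()`) accepts external alignments when
gapped sensitivity is required. `find_known_sv_regions()` emits the
±100 bp interval pair around every junction of previously called SVs,
clipped at chromosome ends.

## Read-depth CNV path

Relative coverage (fraction of the genome-wide median) is corrected by
sequential lowess regression on GC content, then mappability, then
distance to the nearest chromosome end (the telomere stand-in when no
annotation is available), dividing by the fitted trend at each step —
multiplicative correction, since depth biases act as rate multipliers —
and renormalizing to median 1. The lowess span is 0.3 (config-exposed);
with fewer than 30 windows no trend is fittable and correction is skipped
with a warning. Mappability comes from a supplied track or a built-in
exact k-mer-uniqueness fallback. Consensus across CNV callers' tracks
keeps, per bin, the copy number closest to 1 (ties: 1 if any program says
1, else the smaller value) — deliberately conservative and invariant to
track order. Coverage CNVs reciprocally overlapping an SV-derived CNV by
at least 80% are removed as redundant. The unified VCF decomposes each SV
into the rows relevant for functional annotation (DEL, DUP, TDUP, BND,
insertionBND), grouped by a shared `variantID`.

## Problem sizes

The test suite and the acceptance script run at desk scale by choice:
genomes of 2–5 chromosomes totalling 70–200 kb, 3–8 SVs per type, 100 bp
coverage windows, the `small` grid preset (~10^4 combinations before
pruning), 20 replicates for the planted-recovery experiment and 200 for
the binomial-detection property. These sizes keep every stochastic check
well-powered while the whole suite completes in minutes; nothing in the
implementation is specific to them, and the `medium`/`large` presets plus
larger `nvars` scale the same machinery up.

## Known limitations

De novo insertions of non-reference sequence are not simulated or called;
complex inverted SVs are routed to the unclassified table only. The
emulator's false junctions are uniform in the genome, so
`filter_overlappingRepeats` is exercised mechanically (via annotation
flags) rather than through sequence-driven artifacts. The internal
homology search is ungapped. Translocations are limited to one per
chromosome per truth set, and insertion/translocation grouping assumes at
most pairwise junction interactions — nested or overlapping complex events
are out of scope.
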