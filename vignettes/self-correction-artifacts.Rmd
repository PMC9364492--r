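---
title: "Why self-correcting noisy long reads corrupts allopolyploid assemblies: the model behind ucrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why self-correcting noisy long reads corrupts allopolyploid assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucrsim)
```

## The phenomenon

An allotetraploid genome carries two subgenomes whose homoeologous regions
alternate between stretches that are essentially identical (conserved
blocks) and stretches that differ by substitutions at a local rate of about
5%. Noisy long reads carry far more errors than that — the ONT-class
profile modeled here is 17.5% mismatches and 7.5% gaps — so a
self-correction step that pools overlapping reads and votes per column
cannot tell a fixed subgenome difference from a sequencing error. Reads
from *both* subgenomes join one cluster whenever they share a long enough
span that includes a conserved anchor; at each divergent site within the
shared span the vote then installs whichever allele is the plurality of the
chimeric cluster. The corrected reads are locally *wrong in the same way*,
the consensus assembly inherits those errors in dense patches, and accurate
short reads — which only map below a 2% mismatch rate — drop out of exactly
those patches. The result is the assembly's central quality defect studied
here: uncovered regions (UCR), enriched in complete discordances (pileup
sites where every read contradicts the assembly base) and in artificial
heterozygous calls.

`ucrsim` makes this chain executable and auditable end to end. Everything
is coordinate-preserving and truth-tracked: the genome generator records
every site class, the read simulator records every injected error, and every
downstream statistic can therefore be joined back to what is actually true.

## The model, step by step

**Genome.** `make_subgenomes(length, divergence, block_model)` draws
subgenome A uniformly over A/C/G/T and derives subgenome B by substituting
each base inside divergent blocks independently with probability
`divergence` (substitutions are drawn uniformly over the three alternative
bases). Blocks alternate deterministically, conserved first. Divergence is
substitution-only: the subgenomes stay colinear base-for-base, which makes
cross-subgenome projection the identity and keeps every coordinate joinable
to the truth table. Modeling indel divergence, repeats, or more than two
subgenomes is out of scope — repeats in particular would confound the
mechanism with an unrelated source of multi-mapping.
`add_heterozygosity(genome, h)` then gives each subgenome a diploid allele
pair at rate `h` at positions disjoint from divergent sites.

**Reads.** `simulate_long_reads()` draws origins uniformly (reads may
overhang either genome end and are clipped, so marginal coverage has no edge
ramp) until the requested fold-coverage is reached, with lengths from a
truncated geometric distribution (default mean 10 kb, minimum 1 kb). Per
template base: deletion with probability `deletion`, otherwise mismatch with
probability `mismatch`; an independent length-1 insertion follows each base
with probability `insertion`. Expected ledger fractions therefore equal the
profile rates, and the 7.5% gap total is split evenly between insertions
and deletions (the aggregate is what is empirically anchored; the split is a
modeling choice). Indels are length-1 events because only aggregate gap
length enters the statistics. Reads at heterozygous sites draw one allele
with probability 1/2. Strand is simulated for FASTQ realism, but sequences
are stored in genome orientation and placement is strand-resolved through
the truth, so no strand ambiguity reaches any statistic. Accurate presets
(CCS-like: 10–15 kb; NGS-like: 150 bp; both 0.2% error) inject mismatches
only — the short-read mapper stand-in is gapless, and sub-percent indel
rates would not change any conclusion drawn here. Quality scores are not
modeled; FASTQ output uses a constant placeholder.

**Correction.** `find_overlaps()` connects two reads when their origin
intervals share at least `min_overlap` bases (default 2 kb), and — for
cross-subgenome pairs — only when the shared span includes at least
`anchor_min` (default 500) conserved bases, the stand-in for the shared
k-mers that make a real all-vs-all aligner cluster homoeologous reads.
`correct_reads()` then votes per target column over all cluster members
(the target read included): columns with at least `min_support` (default 3)
votes adopt the plurality allele over {A, C, G, T, deletion}; ties and
under-supported columns keep the target's original allele, so correction
never invents an allele nobody carries and a unanimous column is never
changed. An insertion survives at a junction only when a strict majority of
covering members carries one. `min_support = 3` mirrors real correctors
skipping low-coverage spans; the `tie -> keep original` rule makes the
procedure deterministic. The corrected read's ledger is recomputed against
its haplotype truth, so `correction_accounting()` can classify every
position exactly as removed, retained, or introduced, with
`removed + retained = raw errors` holding as an identity, not an
approximation.

A deliberately idealized counterfactual is exposed as
`find_overlaps(..., cross_subgenome = FALSE)`: with truth-mode overlaps,
subgenome identity *is* the phase, so refusing cross-subgenome edges is
exactly what a perfectly phasing-aware corrector (one that splits clusters
at divergent sites) would achieve. Under it, introduced errors collapse to
the voting-noise floor.

**Assembly and polishing.** `consensus_assembly()` is a
coordinate-preserving consensus: per subgenome and position, the plurality
base over covering reads (ties to the first base in A<C<G<T order; deletion
votes carry no emittable base; zero coverage emits N). There is no contig
graph on purpose — the phenomenon lives in base-level error density, and a
string-graph assembler would only obscure the coordinate joins to truth.
Corrected reads are placed at their *original* origins even when correction
moved their content toward the other subgenome; that is precisely the
channel by which chimeric-cluster errors reach the assembly. `polish()`
re-votes every position covered by the polishing read set and is idempotent
under its own input.

**Short-read mapping.** `seed_extend_map()` indexes every k-mer (k = 21) of
the targets, extends each exact seed hit to a gapless end-to-end placement,
scores it by mismatches, and accepts a read only if its best placement has
at most 2% mismatches — the empirical boundary below which mapped short
reads fall. For any accepted read the pigeonhole bound guarantees a shared
21-mer, so on small instances the mapper's decisions are provably identical
to exhaustive all-offset comparison, and the test suite asserts that
equivalence. Two tie rules are provided: the deterministic default (lowest
target coordinate) and `ties = "random"`, which places multireads uniformly
among equal-best placements through the seeded R RNG. The pipeline uses the
random rule: deterministic-lowest placement would leave one subgenome's
conserved blocks with zero coverage on even a perfect assembly — an
artifact of determinism, not of the biology — whereas random placement
reproduces how production mappers spread multireads, which is the behavior
the coverage and UCR statistics presuppose.

**Evaluation statistics.** All coordinates are 0-based half-open; coverage
denominators exclude N positions throughout.

* `depth_profile()` counts spanning primary records per position, capped at
  200 (the conventional cap of genome-coverage counting).
* `ucr_intervals()` returns maximal zero-depth non-N runs; together with
  the covered positions they tile the non-N assembly exactly.
* `bin_discordance()` splits the assembly into 100 bp bins and attributes a
  read base to the bin containing its target position, deletion length to
  the bins of the deleted reference positions, and insertion length to the
  bin of the anchoring position — this makes the mismatch-rate and gap-rate
  ratios well-defined at bin edges. Bins with no aligned bases have their
  rates flagged `NA`; the final partial bin is kept and flagged. Bases over
  assembly Ns count as aligned but never as mismatched (there is no
  reference to disagree with).
* `classify_high_ucr()` applies the strict rule: a bin is high-UCR when
  *more than* 90% of its bases are uncovered (a bin at exactly 0.9 is
  non-UCR).
* `call_sites()` implements the pileup classifier: depth below 5 is
  low-depth; a site where no read supports the reference is a complete
  discordance; otherwise the allele frequency of the leading non-reference
  allele (deletion pseudo-allele included) calls heterozygous inside
  [0.25, 0.75], homozygous-alt above. The leading-allele AF keeps the
  heterozygous call biallelic; a summed-AF variant and a stricter
  same-allele complete-discordance rule are available behind flags for
  sensitivity analysis, because "every read disagrees with the reference"
  does not by itself say whether the reads must also agree with each other.
  Insertions never create calls (they have no reference position).
* `heterozygosity()` divides heterozygous calls by depth-eligible
  positions. Whether the denominator should instead be all assembly
  positions is genuinely ambiguous; eligible-positions is the default and
  both are reportable.
* `divergence_ucr_correlation()` selects non-N blocks of at least
  `block_min`, cuts them into `bin`-sized windows, and correlates
  per-window divergence from truth with per-window UCR ratio
  (`stats::cor.test`, Pearson, t-based p-value; single test, no
  multiple-testing machinery). Windows with constant input are flagged
  degenerate rather than silently returning `NA`, and fewer than three
  usable windows is an error.

## Study conditions and problem sizes

The pipeline defaults (`pipeline_config()`) are the package's synthetic
study conditions: 150 kb subgenomes with alternating 5 kb conserved / 5 kb
divergent blocks, 5% local divergence, 0.22% heterozygosity, ONT-like reads
at 30× (17.5% / 3.75% / 3.75%), CCS-like and NGS-like reads at 20×. With
10 kb mean read length and 5 kb blocks nearly every read spans a conserved
anchor, so the chimeric-cluster channel is active genome-wide — the regime
the mechanism needs. The correlation windows are scaled to the genome (5 kb
windows over blocks of at least 20 kb; the function defaults keep the
field-standard 100 kb windows over 200 kb blocks for full-size data). The
heterozygosity-recovery experiment uses a 1 Mb diploid genome at 30×
error-free coverage. These sizes were fixed once when the study conditions
were chosen; they are large enough that every directional claim below holds
with wide margins on seeded runs.

The diploid mechanism control runs with `h = 0` as well as zero divergence.
Heterozygous genotype loss — the majority vote collapsing a true C/T site
to its plurality allele, shown by the diploid panel of `run_fig7()` — is a
real but separate channel that introduces errors at a depth-independent
floor (about 6 per 10 kb at h = 0.22%). Setting `h = 0` in the control
isolates subgenome divergence as the only systematic difference channel,
and is also the condition under which the clean limit "introduced errors
vanish as coverage grows" actually holds.

## What the generator does and does not emulate

Emulated: block-structured homoeologous divergence with conserved anchors;
within-subgenome heterozygosity; ONT-scale error rates with separate
mismatch/insertion/deletion channels and full error provenance; coverage
sampling including multiread ambiguity in duplicated sequence.

Not emulated: repeat families and transposable elements, structural
variants, homopolymer-context error models, quality scores, chimeric reads,
read pairing, real assembler/corrector parameterizations (the corrector
here is the mechanism in its simplest deterministic form, not a
reimplementation of any production tool), and indel divergence between
subgenomes. Passing tests therefore demonstrate the *mechanism* — that
majority-vote self-correction above the divergence rate manufactures
errors at divergent sites and that those errors produce UCR, complete
discordances, and artificial heterozygosity — not that any particular real
pipeline will show a particular UCR percentage. Real genomes add repeat
content and sequencing biases that generate UCR through additional routes
this model deliberately excludes.

## Numerical choices and degenerate inputs

* All randomness flows through explicit integer seeds; stage seeds are
  derived from the single config seed, and a rerun with the same config
  reproduces the report bundle byte-exactly.
* Ties: correction keeps the target's allele; consensus takes the first
  base in reference order; mapping is lowest-coordinate by default and
  seeded-random in the pipeline (see above).
* Degenerate inputs are flagged, not silently absorbed: rates over zero
  aligned bases are `NA`; the complete-discordance density over an empty
  interval set warns and returns `NA`; constant correlation input is marked
  degenerate; an empty read set refuses to assemble.
* `error_profile()` rejects rates above 0.3 or totals of 0.5 and beyond —
  past that the length model loses meaning. `make_subgenomes()` rejects
  divergence above 0.25 (the substitution-only model breaks down) and
  genomes shorter than two block cycles.
* Long-read FASTQ is written record-by-record with a plain text writer
  because common FASTQ serializers assume bounded line lengths that 20 kb+
  reads exceed; reading still uses the standard parsers.

## Known limitations

* Truth-mode overlap detection and oracle placement sidestep alignment
  error; the anchor-k-mer overlap mode and the seed-and-extend mapper are
  provided to show the mechanism does not depend on the oracle, but a full
  noisy all-vs-all aligner is intentionally out of scope.
* The corrected-read error rates here are better than any real corrector's
  (voting over exact columns with exact membership), so absolute
  removed/retained percentages are optimistic; the *introduced*-error
  mechanism is the transferable part.
* SAM/BAM ingestion treats CIGAR M by direct base comparison against the
  supplied reference (exact here, since the reference is always provided);
  it is designed for fixture-scale and analysis-mode data, not for
  hundred-gigabase BAMs.
* `n_subgenomes` is limited to 2 (plus the diploid control); autopolyploid
  allele graphs are a different problem.
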