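---
title: "Quantifying repeat landscapes, microsatellite seeding, and LINE life history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeat landscapes, microsatellite seeding, and LINE life history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscape)
```

# The problem

Squamate reptile genomes differ enormously in how much of them is repetitive:
microsatellite (SSR) densities vary more than tenfold between species, and
snake genomes in particular carry large expansions of a few motifs (AATAG
above all). Two mechanistic questions sit behind those observations:

1. **Seeding** — are new microsatellite loci created by retrotransposition of
   LINEs (CR1-L3, Rex) that carry an SSR-like tail at their 3' end? If so,
   copies of those families should sit next to the motif far more often than
   random genomic background does.
2. **Life history** — does genome-wide repeat accumulation reflect
   element-level dynamics (how truncated and how old the LINE copies are) or
   species-level demography (effective population size, for which adult body
   mass serves as an inverse proxy)? LINE retrotransposition aborts from the
   5' end, so the ratio of read depth over the 3' half of a family consensus
   to depth over the 5' half measures how prevalent truncated copies are;
   per-read divergence from the consensus (pairwise &pi;) proxies copy age.

`repeatscape` implements the full analysis chain as a tested R package:
microsatellite scanning and density statistics, TE-adjacency enrichment
against resampled backgrounds, reference-free LINE consensus building from
shotgun reads, truncation/divergence profiling, and the
phylogenetic-comparative tests — plus a synthetic-genome generator with truth
tables so that every stage can be validated end to end without any download.

# Microsatellite scanning

A locus is a **maximal whole-unit perfect tandem array** of a primitive
(non-self-repetitive) 2–6 bp unit. Thresholds follow the source analysis:
arrays of 2–4 bp units must span at least 12 bp; arrays of 5–6 bp units must
exceed 15 bp. With whole-unit counting the effective minima are
12/12/12/20/18 bp for 2/3/4/5/6-mers. Whole-unit counting is the strictest
reading of "perfect tandem repeat"; whether a 17 bp (3 units + 2 bases)
pentamer array should count is genuinely open, and we document rather than
assert our choice. Any mismatch or `N` terminates an array. Scanning is
forward-strand only; `canonicalize_motif()` (lexicographic minimum over all
rotations of the unit and of its reverse complement) makes counts
strand-symmetric, so TAGAA, CTATT and AATAG pool into one class.

When arrays of different unit lengths overlap, the longer array wins, ties go
to the smaller unit, remaining ties to the leftmost array — deterministic and
favouring the maximal description. Homopolymer runs are detected separately
and never enter landscape totals. Densities are reported as loci/Mbp and
bp/Mbp; `fold_variation()` is simply max/min over species.

The scanner is validated against an independent brute-force enumerator on the
full exhaustive set of binary-alphabet strings to length 14 plus thousands of
random strings. The literal exhaustive sweep to length 24 (~33M strings) is
out of reach at R speeds; random strings of length 15–24 cover the 5/6-mer
thresholds instead.

```{r scan-example}
g <- as_genome_assembly(c(chr = "ACACACACACACGGTTAATAGAATAGAATAGAATAGCC"))
scan_ssrs(g)
```

# Seeding analysis

For a target motif, `extract_flanks()` takes the 400 bp upstream and
downstream of each locus (clipped at contig ends; the array itself is never
part of a flank). `sample_background()` draws, per replicate (default 5),
regions matching the flank set's length multiset, uniformly over contigs
weighted by placeable length, rejecting placements that overlap assembly gaps
(runs of ≥10 `N`). Background regions may overlap each other, mirroring how
random-interval tools behave.

`enrichment_test()` compares per-family flank content with mean background
content (the ratio shown on a log scale in reports) and computes a one-tailed
exact test on the 2×2 table of **region-level presence/absence** — flank
regions vs pooled background regions, alternative = enrichment in flanks, at
α = 0.01. Bases within a region are not independent trials, so
presence/absence is the conservative table design; whether the original
analysis used region or base counts is unstated, and this choice is flagged
here. Simple-repeat and low-complexity annotations are excluded from content
so a family's signal never includes the target motif's own bases.

`co_occurrence()` reports the conditional probability (fraction of loci with
a family annotation within 400 bp) against the joint probability (fraction of
genome tiles containing both the motif and the family). The tile width
defaults to `2 × flank_width + median array length` — the footprint of a
flanked locus — because the genome-wide sampling unit is otherwise undefined
and this makes the two probabilities commensurable: they agree under
independence and the conditional exceeds the joint-derived expectation under
genuine adjacency. When TE strand is known, side-resolved counts are obtained
by filtering the flank set's `side` column ("TE at the SSR's 5' side" means
the SSR lies downstream of the element's 3' end on the element's strand).

# LINE consensus from reads

`build_consensus_iterative()` reproduces the reference-free procedure: map
reads to the consensus of the most closely related species, call a simple
majority-rule consensus, use it as the new reference, and repeat until no
additional reads are recovered (iteration cap 10; "no additional reads" is
read as no increase in the mapped-read count, with a distinct-read-ID rule
available via `count_rule = "distinct"`). Coverage masks follow the
<10x-after-second-iteration and <20x-final rule.

Two deliberate choices:

* **The internal mapper is ungapped** (exact k-mer seeds, default k = 17,
  both strands; ungapped extension; mismatch rate ≤ 0.2 over the overlap;
  best placement per read, ties to fewer mismatches then leftmost then
  forward). Synthetic data is substitution-only, so ungapped mapping is exact
  there; externally produced alignments can be supplied to
  `majority_consensus()`, `coverage_profile()` and `pairwise_pi()` for
  gapped real data.
* **Re-mapping uses the unmasked majority calls.** The coverage masks are a
  reporting-level filter on the consensus; remapping against an N-masked
  sequence sheds edge reads and makes the mapped-read count non-monotone,
  contradicting the stopping rule's premise. Masks are therefore applied to
  the reported model (and the final consensus) but not to the working
  mapping reference.

Majority ties prefer the previous iteration's base (avoiding oscillation),
then alphabetical order.

# Truncation and age profiles

`coverage_profile()` computes per-position depth from the alignments,
summarized over 10 bp windows, halves, and thirds, all normalized by the
total number of aligned reads so profiles are comparable across sequencing
depths. "Sliding" windows are tiled (step = width): no step is specified in
the source, and the halves/thirds actually used downstream are
step-independent. The 3':5' ratio uses mean depth per half (mean vs summed
depth differ only by a constant). If a fraction *q* of copies lack exactly
the 5' half, the expected ratio is 1/(1−q) — the generator's default
truncation extent is therefore 0.5, making that prediction exact.

`subfamily_site_filter()` implements the binned-mode rule for separating age
from subfamily structure: per consensus column, take the frequency of the
most frequent base; histogram those frequencies in bins of 0.01; discard
columns more than 3 bins from the mode bin as subfamily-diagnostic.
Columns covered by fewer than 30 reads are not assessed (at lower depth the
frequency estimate itself spans several bins of sampling noise; configurable
via `min_depth`). A quantitative caveat the criterion forces into the open:
with `n` copies at per-copy divergence `d`, a clean column's modal frequency
has sd ≈ sqrt(d(1−d)/n). The fixed 3-bin cutoff therefore needs
n ≳ 800 at d = 0.10 to keep false exclusions below 1% — which real LINE
families (10^3–10^5 copies) comfortably satisfy, and which the synthetic
fixtures emulate with 1200 copies. At desk-scale copy numbers (tens) the
filter over-excludes high-divergence columns and biases &pi; downward.

`pairwise_pi()` computes per-read divergence over covered, unmasked,
non-excluded sites; reads with fewer than 30 comparable sites are dropped
(below that, per-read &pi; is dominated by sampling noise); the median over
reads is the family's age proxy, unitless as in the source analysis.
Sequencing error adds ~e to &pi; additively; the recovery fixtures simulate
reads at the planted divergence (error 0) so that "planted d" is exactly what
the reads carry.

# Comparative statistics

`pic_contrasts()` is our own Felsenstein pruning implementation (contrast =
trait difference standardized by branch-length variance; parent branches
extended by v₁v₂/(v₁+v₂)); it is cross-checked against `ape::pic` and, via
`pic_regression()`, against the generalized-least-squares slope under the BM
covariance — the two are equal to 1e-8 on all fixture trees. Contrast
regressions are forced through the origin; two-sided t tests are reported
(the source does not state sidedness). Polytomies are resolved to zero-length
binary branches and flagged.

`censored_rate_test()` partitions tips into regimes, computes contrasts
within each regime's induced subtree (so each contrast belongs wholly to one
regime), estimates σ² per regime as the mean squared contrast (REML), and
calibrates the likelihood ratio against a single shared rate by parametric
simulation of single-rate BM on the full tree (default 1000 simulations; p =
fraction of simulations with LR ≥ observed). Because contrasts are linear in
tip values, per-regime contrast operators are precomputed once and applied to
a tips × n_sims matrix — exact and fast. Both σ² and σ are printed, since the
source's "rate parameter (σ)" is ambiguous between the two. The
posterior-tree replication is exposed as a loop over user-supplied trees, not
re-implemented tree sampling.

`asr_bm()` returns GLS/ML Brownian ancestral states; the root equals the
PIC-weighted mean. `kruskal_wallis()` and `dunn_bh()` implement the
tie-corrected rank statistics with Benjamini–Hochberg step-up adjustment
(validated against base R and hand arithmetic; the {1..9} three-group fixture
gives H = 7.2 exactly). `gate_and_transform()` reproduces the gating used for
truncation values: Shapiro–Wilk (and Bartlett across groups) on raw and
log-transformed values; linear analyses use the first passing scale, rank
tests otherwise; non-positive values make the log scale unavailable — we
refuse silent offsets and recommend the rank path explicitly.

`median_ne()` summarizes a PSMC-style Ne series by the median after one of
four filters: drop first and last points (the primary scheme), drop 10% or
25% of points — read as that share of points removed evenly from the two
extremes, since the motivation is distrust of the most recent and most
ancient estimates — or keep only points between 20 kyBP and 10 myBP. The
default generation time is 3 years (the cross-species average used for
squamates) and the default mutation rate 2.4e-9/site/year.

# The synthetic world

`simulate_genome()` builds an i.i.d. background at the configured GC (default
0.44, squamate-like), plants TE copies derived from a random family consensus
with i.i.d. per-copy substitutions at rate d over non-diagnostic sites, fixed
diagnostic differences shared within subfamilies, 5' truncation of a fraction
q of copies (default extent: exactly the 5' half), an optional perfect SSR
tail at each copy's 3' end, and standalone SSR loci — all placed uniformly
without overlap by rejection sampling (100× budget), reverse-complemented on
the minus strand, with every feature recorded in a truth table. One detail
matters for exactness: if a flanking background base happens to continue a
planted array's period, the scanner would correctly report a longer array
than planted, so the generator breaks the period just outside each planted
array (only where the flank is unoccupied background).

`simulate_reads()` draws uniform start positions (contigs weighted by
length), equiprobable strands, and i.i.d. substitution errors (default 1%,
read length 150, depth 30× — desk-scale stand-ins for low-coverage shotgun
data). The mutation model is substitution-only, so ungapped mapping and &pi;
are exact; indels, nested insertions, TE phylogenies and quality models are
out of scope.

**What a green test does and does not establish.** The generator reproduces
the *statistical structure* each stage assumes — adjacency of tails,
truncation geometry, subfamily column-frequency structure, BM trait
covariance — at desk scale. It does not emulate real assembly artifacts,
indels, nested or fragmented insertions, GC heterogeneity, or library biases;
passing tests validate the implementation of the method, not the method's
robustness to those violations. Headline real-data numbers (repeat content of
66 genomes, the 87.7-fold AATAG expansion, real-genome Fisher p-values)
require the original datasets and are expressly out of desk-scale reach; the
two worked-example targets (10.9- and 16.6-fold variation) are recomputed
from printed per-species extremes by `scripts/acceptance.R`.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion happens
  only at format boundaries (RepeatMasker `.out` is 1-based inclusive with
  `C` for the complement strand; BED needs no conversion).
* Zero background *and* zero flank content for a family defines the
  enrichment ratio as 1 (logged); zero background with positive flank content
  gives an infinite ratio, and the exact test remains well defined either way.
* `fold_variation()` rejects non-positive values; `gc_content()` errors on
  all-N input; an Ne series needs ≥ 3 points so endpoint trimming leaves a
  median.
* Mapping ties: fewer mismatches, then leftmost reference start, then the
  forward orientation. Majority ties: previous consensus base, then
  alphabetical.
* The exact test uses `phyper` (the hypergeometric distribution function);
  the test suite keeps an independent enumeration oracle over all 2×2 tables
  with margins ≤ 40.
* Random draws are all funnelled through R's RNG under caller-supplied seeds;
  identical seeds reproduce identical genomes, reads, backgrounds and
  simulation p-values.

# Known limitations

Ungapped mapping loses reads spanning insertion junctions in diverged or
truncated copies, which slightly depresses the 3':5' ratio (junction reads
fail the mismatch-rate filter); the effect is well inside the ±15% recovery
band at 30×. Mapping also mildly selects against the most diverged reads, so
median &pi; at d = 0.10 sits ~0.009 low — inside the ±0.01 recovery band, but
a real gapped aligner would do better. The subfamily filter's copy-number
requirement is derived above. `map_reads()` requires equal-length reads;
split mixed-length inputs by length, or supply external alignments.
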