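---
title: "Recovering a genome from single cells plus a metagenome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering a genome from single cells plus a metagenome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screcon)
```

## The problem

Multiple displacement amplification (MDA) makes it possible to sequence
the genome of a single microbial cell, but at a price: amplification gain
varies by orders of magnitude along the genome, so any one cell yields a
patchy assembly — typically on the order of 60% of the genome at 10–30×
sequencing depth. A bulk metagenome of an enrichment culture has much
flatter coverage of the dominant organism, but carries reads from every
other community member. `screcon` implements the hybrid strategy that
plays the two against each other:

1. the G+C content distribution of the (contamination-free) single-cell
   reads defines a stringent composition filter that strips most
   contaminant reads out of the bulk dataset before assembly;
2. filtered-out high-GC reads that map to related reference genomes at
   90% identity over 40 bases are rescued, so conserved high-GC loci
   (rRNA operons) are not lost;
3. MDA chimeras are detected by split alignment against an independent
   assembly and excluded;
4. single-cell contigs are shredded into 550-mers with 50-base overlaps
   and co-assembled with the filtered bulk reads into a consensus;
5. the consensus is screened against known reagent contaminants and its
   elements are oriented and ordered against a related reference genome.

Downstream statistics (rarefaction genome-size estimation, reciprocal
best hits, floored whole-genome identity, per-position novelty,
nucleotide and oligomer skews, codon usage against a scrambled control,
expected-error budgets) quantify the result.

Everything is exercised against a ground-truthed synthetic community, so
each stage has a measurable right answer.

## The synthetic community and the MDA bias model

The default desk-scale community is a 200 kb target genome at 32.4% G+C
(with a strand-composition switch at its midpoint, so skew statistics
have something to find) plus two 100 kb contaminants at 58% and 65% G+C;
the target makes up 84% of cells. Genomes are i.i.d. in composition —
real genomes have codon structure, repeats and operons that these
genomes lack, which is exactly why the assembly stages are *easier* here
than in real data and why passing tests demonstrate the statistical
logic of the workflow rather than performance on real repeat-laden
genomes.

MDA bias is modelled segmentally: segment lengths are exponential with
mean 10 kb, per-segment log-gains are normal with standard deviation
2.5, and segments in the lowest 10% of the gain distribution drop out
entirely (gain 0). Read start positions are drawn proportionally to
gain. The *recoverable fraction* of a profile at depth $d$ is the
fraction of bases whose expected depth $d \cdot g_i / \bar g$ reaches
`min_cov`; `min_cov = 1` was chosen once, by Monte Carlo comparison
against the fraction of the genome the built-in assembler actually
reconstructs from one cell's reads at 20× — the two agree closely — and
gives a long-run mean recoverable fraction of ~0.62 per cell. A bulk
profile uses log-gain spread 0.8 and no dropout, leaving >97%
recoverable, mirroring the single-cell versus bulk contrast the workflow
exploits. Because the profiles are independent across cells, the union
of $k$ cells recovers $1-(1-c)^k$ of the genome in expectation — with
$c \approx 0.6$ and $k = 5$, about 99% — which is why pooling a handful
of cells works so much better than sequencing one cell deeper.

Reads are 454-like: shotgun lengths 400 ± 50 (truncated to [50, 800]),
paired-end outer spans 3000 ± 300, per-base Phred qualities around Q30,
substitution errors at the quality-implied rate plus an MDA polymerase
rate of $10^{-5}$ per base. One percent of shotgun reads are chimeric:
two loci at least 2 kb apart joined at a junction uniform within the
read, the second segment inverted with probability 0.5. Homopolymer
indels, the signature 454 error mode, are deliberately not modelled:
every downstream stage is alignment-based and none depends on the indel
error type.

## Alignment

All nucleotide alignment goes through one local aligner with
megablast-like scoring (+2/−3, gap open 5, extend 2). Small problems
(≤ 250,000 DP cells) are solved exactly by affine-gap Smith–Waterman
with traceback; larger ones by exact 11-mer seeding with ungapped X-drop
extension, reporting every locally maximal hit above a score floor of
50. The seeded path produces gapless hits — the right regime for
substitution-dominated synthetic data and the high-identity (90%/40 bp)
acceptance rule — and the test suite holds the exact path equal to an
independent Smith–Waterman implementation on seeded random pairs.
Identity is always matches over alignment columns. Best-hit ties break
lexicographically (subject id, then subject start) so runs reproduce.

Chimera flagging operationalises "tagged by the assembler as chimeric"
as: no single hit covers ≥ 80% of the read, while two near-disjoint
query segments (each meeting the 90%/40 criteria, up to 20 bp of overlap
to absorb seed-extension overshoot) map > 2 kb apart or on inconsistent
strands. A consequence worth knowing: with junctions uniform within the
read, only junctions in the central 20–80% of the read are callable
under the 80%-cover rule, so recall against all simulated chimeras has a
geometric ceiling near 0.6 even though precision is high; the thresholds
are arguments if a different operating point is wanted.

## Assembly, shredding and rarefaction

The built-in assembler is a deterministic greedy
overlap-layout-consensus: reads are processed longest-first, contigs
grow by repeatedly merging the best-scoring suffix–prefix overlap
(≥ 40 bases at ≥ 97% identity, both strands), reads wholly contained in
a finished contig are absorbed, and a per-column vote pileup gives a
majority consensus. It exists so that every downstream stage is testable
hermetically; `rarefy_and_fit()` accepts any function with the
signature `reads -> assembly`, so an external assembler can be plugged
in. Chimeric reads *will* occasionally mislead greedy extension — which
is precisely why the workflow excludes detected chimeras before
assembly, and why rarefaction is run on the cleaned read pool.

Rarefaction subsamples the reads without replacement (seeded per
fraction × replicate), assembles each subsample, and fits
$S(d) = G\,(1 - e^{-d/\kappa})$ to total assembly bases versus read
count by Levenberg–Marquardt least squares; $G$ estimates the genome
size, and an assembly's completeness is its bases divided by $G$. The
exponential form is the coverage-saturation limit of random sequencing;
a Michaelis–Menten alternative is available (`model = "michaelis"`), and
both report residuals. Constant (already-saturated) curves short-circuit
to the plateau. The suite verifies noiseless model recovery to 0.1%, a
synthetic 200 kb genome to within 5% (10,000 reads, fractions 0.1–1.0),
and the qualitative contrast that biased single-cell pools approach
roughly the same asymptote more slowly than bulk data (larger fitted
$\kappa$).

Scaffolding links contigs supported by ≥ 3 read pairs with consistent
relative orientation and implied gaps coherent with the 3 kb ± 300 bp
library (within 3 standard deviations); links are accepted in support
order, so conflicting or cycle-forming links lose to better-supported
ones.

## Reference-guided layout

Orientation of each element maximises the summed alignment score over
its hits to the reference, computed separately for the forward and
reverse readings; exact ties and hit-less elements default to `+` with a
warning. Ordering uses only hits co-oriented with the chosen
orientation: the order key is the hit-length-weighted mean of hit
subject midpoints. The midpoint was chosen as the "subject position" of
a hit because it is symmetric and invariant to splitting a hit into
abutting pieces — an invariance the tests assert directly. Contigs
mostly (≥ 50% of their length) covered by hits to a known contaminant
genome are excluded; the 50% threshold is an argument, since only the
outcome, not the rule, is fixed by the workflow this reproduces.

## Genome statistics

GC, GC-skew and oligomer-skew tracks use 5 kb windows at 1 kb steps by
default (cumulative variants use non-overlapping windows so counts
telescope to the genome-wide difference). "GGG+T skew" is implemented as
the tetramer GGGT against its reverse complement ACCC, the
oligomer-skew convention of the archaeal replication-origin literature;
the motif is an argument. Transition points of a cumulative track are
found on the *detrended* curve (value minus the chord joining the track
ends): a change in skew regime is an extremum of the detrended curve at
the changepoint, whereas raw-curve extrema wander with the random-walk
noise of the flat regime — the planted-switch tests demand the
changepoint to ±2 windows and the detrended detector meets that.

Codon usage is counted in frame over all CDS with frequencies per
thousand codons; the scrambled control shuffles each CDS at the
nucleotide level (exact base multiset preserved), and table comparisons
default to Euclidean distance on the per-mille vectors (cosine
available). N-containing codons are skipped; N bases are excluded from
numerator and denominator of every composition statistic.

The annotation summary reports ORF density to two decimals (count per
kb) and coding fraction as the interval-union of CDS plus pseudogene
footprints over the assembly length — nested and overlapping genes are
counted once.

## Comparative statistics

Reciprocal best hits use local BLOSUM62 protein alignment (gap open 11,
extend 1); a pair is high-confidence when the forward hit covers ≥ 60%
of the query gene. Whole-genome identity applies the floored formula
$(i_c \cdot b_c + f \cdot (L_r - b_c)) / L_r$ with corresponding bases
$b_c$ measured on the reference genome's coordinate space and floor
$f = 0.25$; that coordinate convention is the one that reproduces the
published worked example this formula comes with (33.3% for
corresponding regions of 398,085 bp at 67.4% over a 2,045,086 bp
reference). The companion row of that table (68.1%) is *not*
reproducible from the same formula under any denominator we tried; the
package implements the stated formula and leaves that discrepancy
documented rather than fitted.

The novelty index at a position is $R - \sum_r \mathrm{id}_r$ over $R$
references, where $\mathrm{id}_r$ is the best-hit identity covering the
position (0 if uncovered) — bounded in $[0, R]$, 2 with the classic two
references. Per-position best-hit identity (rather than a sum over
overlapping hits) keeps the index bounded and split-invariant.

The expected-error budget uses the Phred closed form
$\sum_b 10^{-Q_b/10}$: a two-tier estimate from counts at assumed Q10
and Q40, an exact estimate when full quality strings are available, and
a separately reported MDA contribution (rate × assembly length; $10^{-5}
\times 1{,}769{,}573 \approx 17.7 < 20$). Note that 5,904 bases at Q10
contribute 590.4 expected errors and ~1.76 Mb at Q40 another ~176 — the
two-tier formula as stated does not yield a materially smaller number,
and the package reports both tiers rather than a single opaque total.

## Problem sizes, determinism and limitations

The shipped tests and the acceptance script use the desk-scale
community (200 kb target, two 100 kb contaminants, five cells at 20×
plus a 20× bulk sample, ~10,000 reads per dataset); full-scale (multi-Mb)
genomes are supported by the same code paths. These sizes were chosen so
the whole statistical argument — filter operating points, coverage
union, consensus recovery — is measurable in minutes on a laptop.

Every stochastic step derives its stream from one user seed (stage
labels are hashed into per-stage seeds), so identical seeds give
byte-identical reads, assemblies and reports. Known limitations: the
greedy assembler does not resolve repeats (the synthetic genomes have
none beyond chance k-mer collisions) and its consensus is majority-vote
only; seeded alignment is gapless, so indel-rich data would need the
exact path or an external aligner; and the GC filter's guarantees
degrade as the target and contaminant GC distributions approach each
other — the operating point analysis in `derive_gc_threshold()`
(mode + 5.8 binomial standard deviations, reproducing the 0.46 cutoff
from a 32.4% mode at 400 bp reads) makes that trade-off explicit.

## A short tour

```{r tour, eval = FALSE}
cfg <- pipeline_config(seed = 1)
run <- run_consensus(cfg)
run$stats
report(run)

# genome-size estimate from the cleaned bulk reads
fit <- rarefy_and_fit(run$enrichment_clean, replicates = 1, seed = 1)
glance(fit)
autoplot(fit)

# composition tracks over the ordered assembly
ordered <- apply_layout(run$consensus$contigs, run$layout)
genome <- seq_tbl("assembly", paste(ordered$bases, collapse = ""))
plot_track(gc_skew(genome, cumulative = TRUE))
```
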