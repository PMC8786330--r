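---
title: "Models and methods behind maglow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind maglow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`maglow` characterizes metagenome-assembled genomes (MAGs) from deeply
sequenced communities, with the design emphasis on species below 1%
relative abundance. This vignette documents the models the package
implements, the parameters that matter, the synthetic data the test
suite rests on, and the numerical decisions taken where the design was
genuinely open. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## The problem

At common sequencing depths (5–10 Gbp per stool sample) a species at
0.1% relative abundance contributes about `total × abundance` = 5 Mbp of
reads — roughly 1× coverage of a typical bacterial genome — so its
genome cannot be assembled or characterized. Ultra-deep sequencing
pushes that detection limit down an order of magnitude, and everything
in this package exists to turn the extra depth into characterized
genomes: bins with quality scores, abundances and tiers, growth rates,
within-species variation, mobile elements and pathway complements.

## Scaffold features

Scaffolds shorter than 2 kb are removed before binning; the boundary is
inclusive (exactly 2000 bp survives). Composition is summarized as the
canonical tetranucleotide frequency (TNF) vector: all 256 4-mers pooled
with their reverse complements into 136 classes (the lexicographic
minimum of each pair names the class; 16 4-mers are their own reverse
complement), ordered lexicographically via `tnf_keys()`. Pooling makes
TNF strand-invariant, which the suite asserts as a property. 4-mers
containing `N` are skipped; GC content likewise excludes ambiguous bases
from numerator and denominator.

N50 is the length at which the descending cumulative sum of scaffold
lengths first reaches half the assembly; the implementation is checked
against an exhaustive oracle on random length sets. Windowed depth
averages the trailing partial window over its actual span rather than
padding.

### Cumulative GC skew and the replication origin

Per-window skew is `(G − C)/(G + C)` (0 for windows with neither G nor
C); its running sum changes direction at the replication origin and
terminus. Convention: **ori at the global minimum** of the cumulative
series, ter at the maximum — equivalent to saying the ori→ter replichore
on the forward strand is G-rich. The opposite orientation is a flag
(`ori_at = "max"`), since deposited genomes can face either way. Because
genomes are circular, a profile that starts exactly at the origin puts
its minimum at either the first or the last window; all comparisons
against a known origin therefore use circular window distance. The
default window of 1 kb is a choice, not an estimate: larger windows
smooth noise but coarsen localization.

## Marker-guided binning

Each scaffold is described by TNF, length-weighted mean depth and an
optional taxonomy label. The composite score of a scaffold against a
cluster centroid is

    S = w1 · cor(TNF, TNF_c) + w2 · exp(−|log2 d − log2 d_c|) + w3 · [tax = tax_c]

with default weights (0.4, 0.4, 0.2) and joining threshold 0.5.
Scaffolds seed clusters from the longest down; assignment and
length-weighted centroids are iterated to a fixed point (≤ 50 rounds);
exact score ties resolve to the cluster with more total bp, and the only
stochastic step (the 2-means fallback below) is governed by the run
seed. These weights and the threshold are this package's own defaults —
they are configurable and should not be read as anyone else's tuned
values.

The 123-marker single-copy gene (SCG) set acts as a hard constraint in
three places: a scaffold may not join a cluster if the union would push
the duplicated-marker fraction above 5%; after convergence, any cluster
above that budget is split — by taxonomy label when labels disagree,
else by 2-means on TNF + depth — until compliant; and cluster pairs
merge greedily only while the union stays compliant and their centroid
score clears the joining threshold. Marker detection on synthetic
communities is exact tag search on both strands (the generator plants
markers as reserved 60-bp tags, see below); hit tables from a real
profile-HMM search drop into the same interface.

Incompatible-sequence removal prunes a bin member when its depth
deviates more than 3-fold from the bin's length-weighted median, its
taxonomy conflicts with the bin majority, or its TNF correlation
distance to the centroid exceeds the 0.99 quantile of member distances.
Two guards keep the rule sane: the quantile fence is floored at 3× the
median distance (otherwise the farthest member of a perfectly
homogeneous bin would always be "an outlier"), and the longest scaffold
is never removed, so a bin cannot be emptied.

Bin merging follows the dereplication convention: merge at ANI ≥ 0.95
with aligned coverage ≥ 0.30, transitively closed, representative = the
largest bin. Re-running the merge on its own output is a no-op.

## Genome quality

- completeness = distinct markers present / 123
- contamination = marker copies beyond one each / 123
- score = 100·completeness − 5·(100·contamination)
- draft: completeness > 0.80, contamination < 0.05, score > 60 (all strict)
- MIMAG high-quality: completeness > 0.90, contamination < 0.05, 5S +
  16S + 23S rRNA present, ≥ 18 tRNAs
- estimated genome size = assembly size / (completeness + contamination)

The size formula takes completeness and contamination as **fractions**:
with percent units the denominator would sit near 100 and shrink every
genome about 100-fold, and the draft threshold "score > 60" only makes
sense on the percent scale — both readings are flagged here because the
units are easy to get wrong. The marker census is an SCG analogue of
lineage-workflow completeness estimators, not a reimplementation of one.

ANI is fragment-based: the query is cut into 1 kb fragments, each seeded
onto the reference by exact 16-mer matches (stride 50), the best-voted
diagonals scored by ungapped identity, both strands tried, and a
fragment maps at identity ≥ 0.8. ANI is the mean identity of mapped
fragments and coverage the mapped fraction; the ≥ 95% ANI / ≥ 40%
coverage rule then separates known species from novel ones, and a known
genome is "quality-improved" when its score strictly exceeds the
reference genome's.

### Growth rate

The peak-to-trough ratio (PTR) proxies in-situ replication: actively
dividing populations show excess coverage near the replication origin.
The estimator averages depth over the 5% of windows circularly nearest
the skew-inferred ori and ter, and reports the ratio ≥ 1 (inverting and
flagging when the anchors are swapped). The 5%-window local mean is a
deliberate simplification of heavier robust-regression machinery used
by dedicated tools; it is scale-invariant and, on the simulator's
log-linear gradients, recovers planted ratios of 1.5 and 2.0 within 10%
(the local averaging flattens the extremes slightly, a known ~3% bias
toward 1 at PTR = 2). The window fraction is configurable.

## Abundance

MAG depth is the length-weighted mean of member-scaffold depths.
Relative abundance = depth × size / total mapped bases, i.e. the
fraction of the sample's sequencing attributable to the MAG. The
normalization is by **bases**, not read count: depth × length is in
base units, making the abundance an exact mapped-base fraction (read
normalization would differ only by a mean-read-length factor). Tiers:
high > 1%; low 0.1–1% inclusive at both ends; extra-low < 0.1%. The
detectability model counts a genome at data amount `D` when
`D · abundance / size ≥ min coverage`, giving the nondecreasing
rarefaction-style curves; re-assembly at subsampled depth is explicitly
not modelled.

## SNPs and selection

The pileup chain applies, in order: quality filtering (mapping quality
≥ 20 and base quality ≥ 30 kept), depth capping (sites above 40 reads
subsampled to exactly 40 without replacement), SNP calling (major allele
frequency < 0.95 and top minor allele supported by ≥ 2 reads). Applied
in the reverse order the cap would preferentially discard post-filter
reads and bias depth, which is why the order is fixed. MAG-level
eligibility requires 200,000 sites at ≥ 20× — on the scaled-down test
genomes that constant is exercised directly by unit tests rather than by
the simulated MAGs.

Two decisions the filtering rules leave open:

- **Per-site calling floor.** Eligibility is MAG-level; nothing fixes a
  per-site minimum. Here only sites with ≥ 20 post-filter reads are
  callable *and* only those count in the density denominator, keeping
  numerator and denominator consistent (SNPs per kb of callable sites).
- **Minor support.** "At least two matching reads" is read as the top
  minor allele having ≥ 2 supporting reads; only that allele is
  evaluated at multi-allelic sites.

The subsampler draws a multivariate hypergeometric sample over the
site's (base, quality) categories, vectorized across sites; the pileup
is put in canonical (scaffold, position) order first so one seed
reproduces the draw regardless of input row order (a single ordered
stream replaces per-site hash seeding — simpler, and equally
deterministic for a serial run).

pN/pS follows the observed/expected construction: for every codon, all
9 single-nucleotide changes are enumerated and classified under the
standard genetic code (changes creating a stop codon count as
nonsynonymous; an ORF's terminal stop codon is excluded from the sums;
internal stops are an error), pooled over all covered ORFs of a MAG;
pN/pS = (obsN/expN)/(obsS/expS), undefined and flagged when obsS = 0.
The enumeration is verified against an exhaustive oracle for all 61
sense codons (N + S = 9 each).

Feature correlations are Spearman with mid-ranked ties and two-sided
p-values from the large-sample t approximation; constant columns are
flagged undefined rather than silently dropped.

## Mobilome and function

Chromosomal MGE classification is a case-insensitive keyword search of
product descriptions in fixed priority transposon → plasmid → phage →
other. The shipped lists (`mge_keywords()`) are a **reconstruction** of
the published keyword scheme, which is not reprinted anywhere — they
live in one editable function precisely so users can substitute the real
inventory. Counts are normalized per Mbp so incomplete genomes do not
look MGE-poor, and tier comparisons use the Wilcoxon rank-sum test
(exact for small untied samples); the test behind the original
per-tier significance stars is unnamed, so rank-sum is this package's
choice.

Extrachromosomal calls: a scaffold ≥ 5 kb is a putative phage when it
has a confident detector category (1, 2 or 4) **or** a k-mer-model score
≥ 0.9 with p < 0.01 — the two evidence channels are combined as a union
(recall-maximizing; an intersection switch exists because the source
rule can be read either way). Putative plasmids are a reconstruction:
unbinned, > 10 kb, and circular by terminal exact overlap (≥ 55 bp) —
the original procedure is under-specified, so this is labelled as this
package's criterion. Viral taxonomy needs a strict majority (> 50%) of
*all* predicted proteins agreeing on one family after discarding hits
with bitscore ≤ 50.

Pathway presence requires strictly more than 66% of a pathway's key
reactions; KEGG hits pass at identity ≥ 0.30 and coverage ≥ 0.70, CARD
(resistance) hits at ≥ 0.95 and ≥ 0.90. Enrichment is a one-sided
Fisher exact test (direction "greater") with Hochberg step-up
adjustment; the test suite pins the p-values to explicit hypergeometric
tail sums on all small tables and the adjustment to the step-up algebra.

## The synthetic community

The generator is first-class, tested code: every planted quantity is
recovered by the corresponding estimator, which is what the test suite
demonstrates. Defaults describe a deeply sequenced stool-like community:

| parameter | default | why |
|---|---|---|
| genomes | 30 | enough to span all three abundance tiers |
| genome length | 100–180 kb | scaled-down "mini-genomes"; every statistic is per-base or per-window, so small genomes exercise identical code paths cheaply |
| abundance | log-normal, sdlog 1.8, renormalized | spans >1%, 0.1–1% and <0.1% tiers in one 30-genome draw |
| GC | 0.30–0.62 | gut-typical range |
| yield | 45 Gbp | ultra-deep per-sample scale; keeps even the rarest default genome above ~5× |
| markers | 123 unique 60-bp tags | exact search stands in for profile-HMM search |
| PTR | 1.2–2.5 | realistic in-situ replication ratios |
| SNP density | 0.5–5 /kb | typical within-species polymorphism |
| dN/dS | 0.3 | mild purifying selection |
| skew amplitude | 0.12 | G/C excess per replichore; strong enough for window-level ori localization |

Construction per genome: a layout of repeating
[intergenic, marker tag, spacer, ORF] units; ori fixed at position 0 and
ter at L/2 with a symmetric two-segment skew (G-rich then C-rich);
forward-strand ORFs sanitized to an ATG start, TAA stop and no internal
stops. Two compensations keep the target GC within 1%: the tag content
(fixed at GC ≈ 0.5 community-wide) is subtracted analytically, and the
background GC is solved (via the expected composition of codons
conditioned on not being stops) so that stop-codon sanitization does not
enrich GC. Coordinates are 0-based, half-open throughout; fragments
concatenate back to the exact genome.

Depth simulation gives each genome `total_bases × abundance / length`
mean depth, modulated log-linearly from √PTR at ori to 1/√PTR at ter
(renormalized so the genome mean is exact), with Poisson noise at base
resolution. Pileups plant SNPs at the genome's density with minor-allele
frequencies uniform on [0.15, 0.5]; within ORFs the
nonsynonymous:synonymous mix realizes the planted dN/dS against the
genome's enumerated opportunities, with class counts planted at their
expectation so the realized ratio carries no extra sampling noise. A
configurable fraction of reads (default 10%) draws qualities below the
filtering cutoffs to exercise the filters.

What the simulator does **not** emulate — and therefore what passing
tests do not show about real data: shared or horizontally transferred
sequence between genomes (synthetic TNF separability is optimistic;
conversely, i.i.d. same-GC genomes are *harder* to separate by
composition than real genomes with distinct codon usage, which is why
the binning acceptance run provides taxonomy labels, standing in for the
homology assignments a real run would have); assembly artefacts,
chimeras and repeat collapse; read-level errors and mapping bias
(pileups are generated above the mapping layer); strain mixtures beyond
a single planted allele frequency per site; rRNA/tRNA sequence content
(annotation rows only, with nominal coordinates).

## Problem sizes

The suite and the acceptance script size their simulations for a
single-CPU desk run: the full 30-genome community (~4 Mbp of sequence,
~860 scaffolds) for binning and abundance recovery; single 120–150 kb
genomes at 60× for SNP/pN-pS recovery (≥ 2000 SNPs for the neutral and
purifying checks); 50 seeded replicates per planted PTR; 20 genomes for
origin detection. These are the package's chosen study conditions, and
the same seeds always reproduce them.

## Known limitations

- The binning score weights and threshold are sensible defaults, not
  fitted values; communities with strong within-genome composition
  heterogeneity will need the taxonomy term or lower thresholds.
- ANI is ungapped; indel-rich divergence deflates identity relative to
  aligner-based ANI.
- The PTR estimator assumes a single circular replicon with one
  ori/ter pair; plasmid-heavy bins or linear replicons violate it.
- pN/pS pools ORFs per MAG; per-gene selection signals are averaged out
  by design (one value per MAG).
- `eligible_mag`'s 200,000-site constant presumes real genome sizes; on
  mini-genome simulations it is exercised only by unit tests.
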