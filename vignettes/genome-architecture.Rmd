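---
title: "Genome architecture landscapes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome architecture landscapes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

genarch re-implements, as a tested and reusable pipeline, the windowed
genome-architecture analyses used to characterize chromosome-level plant
assemblies: tandem-repeat monomer canonicalization with telomere and
centromere calling, detection of nuclear insertions of organelle DNA
(NUPTs/NUMTs) and their integration anomalies, allele-balance SNP
classification with density-anomaly mapping, and the mapping-population
computations (1:1 segregation filtering and Mendelian-exclusion paternity
assignment). A seeded synthetic-genome generator with machine-readable
ground truth closes the loop: every analysis is validated by recovering
what the generator planted.

All internal coordinates are 0-based half-open; conversion to and from
1-based conventions (BLAST tabular, VCF, GFF3, TRF) happens only in the
readers and writers. This single-convention rule removes the usual
off-by-one failure class, and round-trip tests pin it down.

## Tandem-repeat canonicalization and telomere/centromere calling

Tandem-repeat finders report the same monomer phase-shifted (an arbitrary
cyclic rotation) and on either strand, so one repeat family appears as
many records and its frequency is split among them. `canonical_monomer()`
maps each monomer to the lexicographic minimum over the `2n` cyclic
rotations of the monomer and of its reverse complement. This is a
deterministic replacement for alignment-based monomer merging: two
monomers are the same family exactly when their canonical forms are
equal, and `merge_monomer_frequencies()` then sums copy numbers per
canonical form (an optional approximate mode additionally merges
equal-length forms with normalized edit distance at most 0.1, for
slightly diverged variants). The plant telomere motif TTTAGGG has
canonical form AAACCCT.

Telomeres are called per chromosome end: records of the telomere family
overlapping the terminal `end_zone` (default 100 kb) are merged, and the
end is positive when the merged span reaches `min_array_bp` (default
1 kb). Neither value is forced by the underlying biology; they are wide
enough to catch the 3-12 kb terminal arrays typical of well-assembled
plant chromosomes while rejecting isolated interstitial heptamer runs,
and both are parameters.

Centromeres are called from records whose canonical monomer length is in
`monomer_lengths` (default 79 and 80 bp, the two satellite families of
interest here; families can be pooled or split with `per_family`). The
call maximizes contained copy number over a sliding `cluster_window`
(default 1 Mb) anchored at record midpoints — an exhaustive scan at the
resolution the data supports — with ties broken leftmost; copies outside
the chosen window are reported as scattered, reflecting the observation
that centromeric monomers also occur dispersed along the chromosomes.

`find_exact_tandem_arrays()` is a deliberately simple exact-periodicity
scanner (smallest period, arrays split at N) used to detect perfect
synthetic arrays without an external repeat finder; it is not a
substitute for a general repeat finder on real, mutated arrays.

## Organelle insertions

Alignment hits of the organelle genomes against the nuclear assembly are
filtered at identity ≥ 95%, length ≥ 100 bp and e-value ≤ 1e-10
(defaults; all parameters). Hits whose nuclear intervals overlap or abut
within `max_gap` (default 0) merge into insertion *events*: the unit of
interest is the integrated fragment, and abutting local alignments of
one integration event should not be double-counted. Identity thresholds
are applied per hit; an event records the maximum identity over its
members. Length tiers (≥ 100 bp, ≥ 1 kb, ≥ 5 kb, ≥ 10 kb) are assigned
from the merged event length.

Per-window counting is by overlap: an event spanning a window boundary
counts in every window it touches (midpoint assignment is an alternative
convention; overlap counting is used because it preserves tier
monotonicity per window and is verified against a per-base oracle in the
tests). Four anomaly detectors follow:

* **end-proximal** — a chromosome end where at least one chloroplast and
  one mitochondrial event lie within 500 kb of the terminus;
* **co-localized** — interior windows (farther than 500 kb from both
  termini) holding at least one event of each organelle;
* **hotspot** — maximal runs of windows whose event-covered base
  fraction is at least 0.5, spanning at least 1 Mb, with per-organelle
  covered bp as evidence;
* **tandem-like** — at least three nearby events of one organelle whose
  organelle source spans mutually overlap by at least half of the
  shorter span (the signature of one segment integrated repeatedly).
  Within a positional cluster the largest mutually compatible group is
  taken greedily in positional order; clique search would be exact but
  is unnecessary at realistic event densities.

A dense hotspot fed from a short circular organelle genome necessarily
contains events with heavily overlapping source spans, so the
tandem-like detector also fires inside hotspots. That is consistent with
the "almost repeat-like" character of such regions and is treated as
expected behaviour in the tests.

## SNP classification and density anomalies

A pileup site is classified from pooled base counts: all non-reference
bases form the alternate count, and the alternate fraction
alt/(ref + alt) decides the state — heterozygous in [0.25, 0.75),
homozygous-alternate at ≥ 0.75, reference below 0.25 — gated by depth
≥ 10 and by a 3 bp exclusion flank around assembly gaps. The thresholds
are half-open exactly as printed, and the boundary cases are asserted in
tests. Threshold rules of this kind are sometimes phrased as a ratio of
alternate to reference alleles; read literally as alt/ref odds, a 50/50
site would be called homozygous, which contradicts the rule's purpose,
so the alternate *fraction* is the default and the literal odds reading
is available via `ratio = "alt_ref"`. Inter-individual (homozygous) SNPs
are emitted where the first individual is homozygous and the second
individual's consensus base differs; a depth gate on the second
individual is inherited from its consensus caller.

Window profiles count heterozygous and homozygous SNPs per 100 kb
window, split genic/intergenic (genic = anywhere in the gene span,
introns included; exon-only counting via `genic = "cds"`). Anomaly
detectors:

* **low-het regions** — windows at or below the genome-wide 0.1
  heterozygosity quantile are "low"; maximal runs of low windows
  spanning ≥ 1 Mb are reported, marked `extended` at ≥ 5 Mb, and typed
  `low_both` when the run's homozygous counts are also at or below their
  quantile threshold. "Very few heterozygous SNPs" has no printed
  number, so a quantile parameter defines it; the default synthetic
  conditions plant het-free stretches, making recovery exact.
* **decoupled windows** — gene-bearing windows (gene-covered fraction at
  or above the genome median) where the overall and genic signals
  disagree: overall heterozygous counts strictly above the top quartile
  with genic heterozygous counts at or below the bottom quartile
  (conserved genes), or overall homozygous counts strictly below the
  bottom quartile with genic homozygous counts at or above the top
  quartile (diversifying genes). The strict inequality on the overall
  count makes a flat profile yield nothing; the inclusive genic bound
  lets zero-genic windows qualify when the quartile itself is zero.
  Quartile rules have a non-zero baseline hit rate on noisy data — they
  flag candidates, not certainties.
* **repeat-rich regions** — window runs of span ≥ 5 Mb in which at least
  90% of windows exceed 70% repeat coverage (high runs are bridged
  across short low gaps before the proportion check);
* **duplicated-gene clusters** — a 1 Mb window slid one grid-window at a
  time, genes assigned by midpoint, flagged where the duplicated-gene
  fraction strictly exceeds 0.2, with overlapping placements merged.

## Segregation filtering and paternity

`four_step_filter()` implements the four-step genotype filter for a
half-sib mapping population whose informative loci are heterozygous in
the mother and monomorphic in the fathers (expected 1:1 het:hom): (1)
heterozygous genotypes with depth < 20 are recoded as monomorphic,
i.e. homozygous (a `low_depth_to = "missing"` switch covers the
alternative reading); (2) loci need a heterozygote fraction ≥ 0.5, by default among
non-missing individuals (an absolute-population denominator is a flag);
(3) loci need Pearson chi-square < 6.635 against 1:1 (no continuity
correction; 6.635 is the upper 1% point of chi-square with 1 d.f.,
though it is sometimes mislabelled as a 90% confidence threshold — the
numeric value is what the filter uses); (4) one locus per contig survives, the one with
fewest missing genotypes, ties broken by smallest position (the
tie-break is not specified anywhere; smallest position is deterministic
and reproducible).

`assign_paternity()` is exclusion-based: per locus, the paternal-allele
set consists of the offspring alleles whose partner allele the mother
carries (both when she carries both); a candidate mismatches when it
carries no allele of that set. An offspring is assigned when exactly one
candidate attains the minimum mismatch count and that minimum is at most
`max_mismatch` (default 0); equal minima give `ambiguous`, never an
assignment. Selfing is handled by listing the mother among the
candidates. Likelihood-based machinery (simulated confidence levels,
typing-error models) is out of scope; exclusion at 0-1 mismatches covers
the operating points of interest.

## The synthetic-data generator

`sim_config()` fixes the study conditions. The default genome is three
chromosomes of 12, 10 and 8 Mb — large enough to hold every planted
structure at the 100 kb window size, small enough that the full
generator-plus-analysis loop runs in well under a minute. Background
sequence is i.i.d. uniform ACGT, which maximizes detectability contrast;
real genomes have compositional structure the generator does not
emulate, so passing recovery tests demonstrates correctness of the
bookkeeping and thresholds, not robustness to low-complexity background.

Planted structures mirror the magnitudes reported for a chromosome-level
beech assembly: TTTAGGG telomere arrays of 3-12 kb at five of six
chromosome ends (one left-only chromosome); 79/80 bp centromere
satellites as one 500-copy main cluster per chromosome plus 20 scattered
copies; organelle insertions spanning the length tiers from 150 bp to
50 kb at 95-100% identity, including a 2 Mb chloroplast+mitochondrion
hotspot at 60% window coverage, a three-event tandem-like chloroplast
cluster, an end-proximal cp+mt pair, and a co-localized interior window;
a 6 Mb het-free stretch with elevated homozygous density, a 1.2 Mb
low-het run, and a low-both region inside a 6 Mb repeat-rich annotation
(97% of windows at 75% coverage) plus a 1.5 Mb duplicated-gene cluster
at 40% flagged genes. SNP windows draw Poisson(50) heterozygous,
Poisson(30) homozygous and Poisson(10) reference sites; depths are
Poisson(30) and heterozygous alternate counts Binomial(depth, 0.5), so
the expected heterozygote recall equals the Binomial tail
P(0.25 ≤ X/d < 0.75) — about 99.5% at depth 30 — and the tests compare
measured recall to that analytic value within Monte-Carlo error.

Alignment hits are synthesized from the planted truth (coordinates plus
the substitutions applied to reach the target identity, with sub-
threshold noise hits that the filter must remove) rather than by running
an aligner, so the test loop needs no external binary.
`mutate_to_identity()` applies exactly `round((1 - identity/100) * len)`
substitutions, so planted identities are exact by construction. The
mapping matrix plants exact-count 1:1 loci (heterozygote count
`ceiling(n/2)` among non-missing individuals, so step 2 and step 3 pass
deterministically at zero error) against distorted loci at 30% and 80%
heterozygote fractions; depths are Poisson(40) truncated at 20 so step 1
is inert under the default error-free conditions (unit tests exercise it
directly). The paternity panel uses 36 multi-allelic markers (four
equifrequent alleles): with biallelic SNPs, zero-mismatch exclusion
alone cannot reliably separate 19 candidates — that is what likelihood
methods are for — whereas four-allele markers give a per-locus exclusion
probability high enough that 50 offspring are uniquely assignable, which
is the property the module is specified to have. Windows fully covered
by planted features simply receive fewer callable SNP sites, as in real
data.

Every draw happens inside `withr::with_seed(seed, ...)`; identical seeds
give byte-identical output files, which the tests assert.

## Numerical and degenerate-input choices

Quantiles use R's default type-7 definition. Chi-square with zero
observations is an error (the statistic is undefined). Chromosomes with
no candidate centromere records yield a call with `NA` cluster
coordinates rather than being dropped. Empty region sets write valid
header-only files. The last, shorter window of each chromosome is
retained and all per-window fractions are computed against actual window
width. Low-het detection refuses to run on fewer than 10 windows, since
a genome-wide quantile over a handful of windows is meaningless.

## Problem sizes

The default synthetic dataset (30 Mb genome, ~24,000 SNP sites, 55
insertions, 525 mapping loci over 300 contigs, 50 offspring against 20
candidates) generates in roughly 20 s and every analysis completes in a
few seconds; the scaled-down unit-test configuration (0.7 Mb, 10 kb
windows) exercises the same planted structures in about 2 s. These sizes
were chosen as the smallest at which every planted feature is
unambiguous at its detector's default thresholds.

## Known limitations

The generator does not simulate reads, alignment noise, structural
variation, or low-complexity background; recovery results therefore
validate the analysis logic, not upstream variant calling or alignment.
The tandem-like detector's greedy grouping is order-dependent in
principle (exact on the planted configurations). Real TRF output
contains indel-containing, imperfect arrays whose monomers differ by
more than rotation; the approximate merge mode covers small divergence
only. Paternity exclusion without a likelihood model cannot rank
candidates tied at the same mismatch count, by design.
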